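#' Project entity spans onto token labels
#'
#' Gives every token the label of the entity covering it (any character
#' overlap counts, so an entity partially covering a token still labels
#' it); uncovered tokens get `"O"`.  When two entities overlap on a
#' token, the one with the smaller start offset wins and a warning
#' reports the conflict.
#'
#' @param doc an [fh_document()].
#' @return A list of character vectors, one per sentence, aligned with
#'   the sentence's tokens.
#' @export
project_entities_to_tokens <- function(doc) {
  stopifnot(inherits(doc, "fh_document"))
  tok <- doc$tokens
  ents <- doc$entities[order(doc$entities$start, doc$entities$end), , drop = FALSE]
  labels <- rep("O", nrow(tok))
  conflicts <- 0L
  if (nrow(ents) > 0 && nrow(tok) > 0) {
    for (i in seq_len(nrow(ents))) {
      hit <- which(tok$start < ents$end[i] & ents$start[i] < tok$end)
      fresh <- labels[hit] == "O"
      conflicts <- conflicts + sum(!fresh)
      labels[hit[fresh]] <- ents$label[i]  # earlier-starting entity keeps its claim
    }
  }
  if (conflicts > 0)
    warning(doc$doc_id, ": ", conflicts,
            " token(s) covered by overlapping entities; earliest span kept")
  split(labels, tok$sentence)[as.character(unique(tok$sentence))]
}

#' Recover entity spans from a token label sequence
#'
#' Maximal runs of identical non-`"O"` labels become one entity spanning
#' the first to the last token of the run.  This is the inverse of
#' [project_entities_to_tokens()] for documents whose same-label entities
#' are not token-adjacent.
#'
#' @param labels character vector of token labels.
#' @param tokens token data frame of the same sentence (same length).
#' @param id_prefix prefix for generated entity ids.
#' @param text the document text (for the entity surface strings); may be
#'   `NULL` to fill surfaces from token forms.
#' @return An entity data frame (see [fh_document()]).
#' @export
tokens_to_entities <- function(labels, tokens, id_prefix = "T", text = NULL) {
  if (length(labels) != nrow(tokens))
    stop("label sequence length (", length(labels),
         ") does not match token count (", nrow(tokens), ")")
  if (length(labels) == 0) return(empty_entities())
  runs <- rle(labels)
  stops <- cumsum(runs$lengths)
  starts <- stops - runs$lengths + 1L
  keep <- runs$values != "O"
  if (!any(keep)) return(empty_entities())
  out <- data.frame(
    id = paste0(id_prefix, seq_len(sum(keep))),
    label = runs$values[keep],
    start = tokens$start[starts[keep]],
    end = tokens$end[stops[keep]])
  out$text <- if (is.null(text))
    vapply(which(keep), function(k) paste(tokens$surface[starts[k]:stops[k]], collapse = " "),
           character(1))
  else substr(rep(text, nrow(out)), out$start + 1L, out$end)
  out
}

#' Derive a document's predicted-entity layer from label sequences
#'
#' @param doc an [fh_document()].
#' @param label_seqs list of per-sentence label vectors (as produced by a
#'   tagger), aligned with the document's sentences.
#' @return A copy of `doc` whose entities are the recovered spans and
#'   whose relations are emptied.
#' @export
with_predicted_entities <- function(doc, label_seqs) {
  sents <- unique(doc$tokens$sentence)
  stopifnot(length(label_seqs) == length(sents))
  ents <- list()
  for (k in seq_along(sents)) {
    tok <- doc$tokens[doc$tokens$sentence == sents[k], , drop = FALSE]
    e <- tokens_to_entities(label_seqs[[k]], tok, id_prefix = paste0("T", k, "_"),
                            text = doc$text)
    if (nrow(e) > 0) ents[[length(ents) + 1L]] <- e
  }
  doc$entities <- if (length(ents)) do.call(rbind, ents) else empty_entities()
  doc$entities$id <- paste0("T", seq_len(nrow(doc$entities)))
  doc$relations <- empty_relations()
  doc
}

#' Filter sentences mentioning first-degree family members
#'
#' Retains sentences containing at least one token whose lemma (or, when
#' no lemma layer is attached, lowercased surface form) matches an entry
#' of `lemma_list` as a whole word.  This mirrors the regular-expression
#' pre-filter used to pull family-history statements out of running
#' clinical notes.
#'
#' @param docs an [fh_document()] or list of them.
#' @param lemma_list character vector of family-member lemmas.  The
#'   default list of Norwegian first-degree kin terms is a package
#'   default, configurable per corpus.
#' @return Data frame with columns `doc_id`, `sentence`, `text`.
#' @export
filter_family_sentences <- function(docs, lemma_list = default_family_lemmas()) {
  if (length(lemma_list) == 0) stop("lemma_list must be non-empty")
  if (inherits(docs, "fh_document")) docs <- list(docs)
  lemma_list <- tolower(lemma_list)
  rows <- list()
  for (doc in docs) {
    tok <- doc$tokens
    for (s in unique(tok$sentence)) {
      st <- tok[tok$sentence == s, , drop = FALSE]
      keys <- ifelse(st$lemma == "UNK", tolower(st$surface), tolower(st$lemma))
      if (any(keys %in% lemma_list)) {
        rows[[length(rows) + 1L]] <- data.frame(
          doc_id = doc$doc_id, sentence = s,
          text = substr(doc$text, min(st$start) + 1L, max(st$end)))
      }
    }
  }
  if (length(rows) == 0)
    return(data.frame(doc_id = character(), sentence = integer(), text = character()))
  do.call(rbind, rows)
}

#' @rdname filter_family_sentences
#' @export
default_family_lemmas <- function() {
  c("mor", "far", "bror", "søster", "sønn", "datter",
    "søsken", "foreldre", "barn", "tvilling")
}

#' Corpus distribution statistics
#'
#' Counts entities per label (with the number of multi-word "span"
#' entities), relations per label, sentences and tokens, in the style of
#' a corpus distribution table.
#'
#' @param corpus an [fh_document()] or list of them.
#' @return An object of class `fh_corpus_stats` with components
#'   `entities` (data frame label/n/spans), `relations` (label/n),
#'   `n_sentences`, `n_tokens`.
#' @export
corpus_stats <- function(corpus) {
  if (inherits(corpus, "fh_document")) corpus <- list(corpus)
  elab <- character(); espan <- logical(); rlab <- character()
  n_sent <- 0L; n_tok <- 0L
  for (doc in corpus) {
    n_sent <- n_sent + n_sentences(doc)
    n_tok <- n_tok + nrow(doc$tokens)
    ents <- doc$entities
    if (nrow(ents) > 0) {
      elab <- c(elab, ents$label)
      multi <- vapply(seq_len(nrow(ents)), function(i) {
        ntok <- sum(doc$tokens$start < ents$end[i] & ents$start[i] < doc$tokens$end)
        if (ntok > 0) ntok > 1 else grepl("\\s", ents$text[i])
      }, logical(1))
      espan <- c(espan, multi)
    }
    rlab <- c(rlab, doc$relations$label)
  }
  ent_tab <- if (length(elab)) {
    agg <- data.frame(label = elab, span = espan)
    out <- aggregate(cbind(n = rep(1L, nrow(agg)), spans = as.integer(agg$span)) ~ label,
                     data = agg, FUN = sum)
    out[order(-out$n, out$label), ]
  } else data.frame(label = character(), n = integer(), spans = integer())
  rel_tab <- if (length(rlab)) {
    out <- as.data.frame(table(label = rlab), stringsAsFactors = FALSE)
    names(out)[2] <- "n"
    out[order(-out$n, out$label), ]
  } else data.frame(label = character(), n = integer())
  rownames(ent_tab) <- NULL; rownames(rel_tab) <- NULL
  structure(list(entities = ent_tab, relations = rel_tab,
                 n_sentences = n_sent, n_tokens = n_tok),
            class = "fh_corpus_stats")
}

#' @export
print.fh_corpus_stats <- function(x, ...) {
  cat(sprintf("Corpus: %d sentences, %d tokens\n", x$n_sentences, x$n_tokens))
  cat("Entities (n, multi-word spans):\n")
  if (nrow(x$entities) > 0)
    for (i in seq_len(nrow(x$entities)))
      cat(sprintf("  %-10s %5d %5d\n", x$entities$label[i], x$entities$n[i],
                  x$entities$spans[i]))
  cat("Relations:\n")
  if (nrow(x$relations) > 0)
    for (i in seq_len(nrow(x$relations)))
      cat(sprintf("  %-11s %5d\n", x$relations$label[i], x$relations$n[i]))
  invisible(x)
}

#' Two-column token/label export (CoNLL-style)
#'
#' @param doc an [fh_document()].
#' @param labels optional list of per-sentence label vectors; default
#'   projects the document's own entities.
#' @return A single string: one `token<TAB>label` line per token, blank
#'   line between sentences.
#' @export
format_token_labels <- function(doc, labels = NULL) {
  if (is.null(labels)) labels <- project_entities_to_tokens(doc)
  sents <- unique(doc$tokens$sentence)
  out <- character()
  for (k in seq_along(sents)) {
    st <- doc$tokens[doc$tokens$sentence == sents[k], , drop = FALSE]
    out <- c(out, paste(st$surface, labels[[k]], sep = "\t"), "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
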