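#' Annotated document container
#'
#' An `fh_document` bundles one document's raw text with three aligned
#' layers: a token layer (grouped into sentences, optionally carrying
#' universal POS tags, dependency labels and lemmas from a CoNLL-U run),
#' an entity layer of contiguous character spans, and a relation layer of
#' directed binary links between entities.  All character offsets are
#' 0-based and end-exclusive, the brat standoff convention.
#'
#' @param doc_id document identifier.
#' @param text raw document text; one sentence per line unless a token
#'   layer says otherwise.
#' @param tokens data frame with columns `sentence`, `surface`, `start`,
#'   `end`, `upos`, `deprel`, `lemma` (missing annotation uses the
#'   unknown-marker `"UNK"`).  `NULL` applies the fallback tokenizer.
#' @param entities data frame with columns `id`, `label`, `start`, `end`,
#'   `text`.
#' @param relations data frame with columns `id`, `label`, `arg1`, `arg2`
#'   (entity ids).
#' @return An object of class `fh_document`.
#' @export
fh_document <- function(doc_id, text, tokens = NULL,
                        entities = empty_entities(), relations = empty_relations()) {
  if (is.null(tokens)) tokens <- tokenize_text(text)
  rownames(tokens) <- NULL; rownames(entities) <- NULL; rownames(relations) <- NULL
  doc <- structure(
    list(doc_id = doc_id, text = text, tokens = tokens,
         entities = entities, relations = relations),
    class = "fh_document")
  bad <- entities$start < 0 | entities$end > nchar(text)
  if (any(bad))
    stop("entity span outside text bounds in document ", doc_id, ": ",
         paste(entities$id[bad], collapse = ", "))
  dangling <- setdiff(c(relations$arg1, relations$arg2), entities$id)
  if (length(dangling) > 0)
    stop("relation argument(s) not among entities in document ", doc_id, ": ",
         paste(dangling, collapse = ", "))
  doc
}

empty_entities <- function() {
  data.frame(id = character(), label = character(), start = integer(),
             end = integer(), text = character())
}

empty_relations <- function() {
  data.frame(id = character(), label = character(),
             arg1 = character(), arg2 = character())
}

empty_tokens <- function() {
  data.frame(sentence = integer(), surface = character(), start = integer(),
             end = integer(), upos = character(), deprel = character(),
             lemma = character())
}

#' @export
print.fh_document <- function(x, ...) {
  cat(sprintf("<fh_document> %s: %d sentence(s), %d token(s), %d entit%s, %d relation(s)\n",
              x$doc_id, n_sentences(x), nrow(x$tokens), nrow(x$entities),
              if (nrow(x$entities) == 1) "y" else "ies", nrow(x$relations)))
  invisible(x)
}

#' @rdname fh_document
#' @param doc an `fh_document`.
#' @export
n_sentences <- function(doc) {
  if (nrow(doc$tokens) == 0) 0L else length(unique(doc$tokens$sentence))
}

#' Fallback whitespace-and-punctuation tokenizer
#'
#' Used when no CoNLL-U layer is available: each line of the text is one
#' sentence; tokens are maximal non-space runs with leading/trailing
#' punctuation split off as separate tokens.  POS, dependency and lemma
#' fields are set to the unknown-marker `"UNK"`.
#'
#' @param text character scalar.
#' @return A token data frame (see [fh_document()]).
#' @export
tokenize_text <- function(text) {
  if (!nzchar(text)) return(empty_tokens())
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- c(0L, cumsum(nchar(lines) + 1L))  # line start offsets, 0-based
  out <- list()
  sent <- 0L
  for (li in seq_along(lines)) {
    line <- lines[li]
    if (!nzchar(trimws(line))) next
    sent <- sent + 1L
    m <- gregexpr("\\S+", line)[[1]]
    if (m[1] == -1) next
    for (k in seq_along(m)) {
      s <- starts[li] + m[k] - 1L                  # 0-based chunk start
      chunk <- substr(line, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      for (piece in split_punct(chunk)) {
        out[[length(out) + 1L]] <- data.frame(
          sentence = sent, surface = piece$tok, start = s + piece$off,
          end = s + piece$off + nchar(piece$tok), upos = "UNK",
          deprel = "UNK", lemma = "UNK")
      }
    }
  }
  if (length(out) == 0) return(empty_tokens())
  do.call(rbind, out)
}

# split leading/trailing punctuation off a whitespace-delimited chunk,
# keeping inner punctuation (hyphens, digits with separators) intact
split_punct <- function(chunk) {
  punct <- "[.,;:!?()\"«»]"
  pieces <- list()
  off <- 0L
  while (nchar(chunk) > 1 && grepl(paste0("^", punct), chunk)) {
    pieces[[length(pieces) + 1L]] <- list(tok = substr(chunk, 1, 1), off = off)
    chunk <- substr(chunk, 2, nchar(chunk)); off <- off + 1L
  }
  trail <- list()
  while (nchar(chunk) > 1 && grepl(paste0(punct, "$"), chunk)) {
    n <- nchar(chunk)
    trail <- c(list(list(tok = substr(chunk, n, n), off = off + n - 1L)), trail)
    chunk <- substr(chunk, 1, n - 1L)
  }
  c(pieces, list(list(tok = chunk, off = off)), trail)
}

#' Explode a corpus into single-sentence documents
#'
#' Cross-validation and the classifiers operate at the sentence level;
#' this helper re-bases every sentence of every document as its own
#' `fh_document` (offsets shifted to the sentence, cross-sentence
#' relations dropped with a message reporting how many).
#'
#' @param corpus list of `fh_document`.
#' @return List of single-sentence `fh_document`s.
#' @export
split_sentences <- function(corpus) {
  if (inherits(corpus, "fh_document")) corpus <- list(corpus)
  out <- list()
  dropped <- 0L
  for (doc in corpus) {
    if (nrow(doc$tokens) == 0) next
    sent_of <- entity_sentences(doc)
    if (nrow(doc$relations) > 0) {
      s1 <- sent_of[doc$relations$arg1]; s2 <- sent_of[doc$relations$arg2]
      dropped <- dropped + sum(is.na(s1) | is.na(s2) | s1 != s2)
    }
    for (s in unique(doc$tokens$sentence)) {
      tok <- doc$tokens[doc$tokens$sentence == s, , drop = FALSE]
      lo <- min(tok$start); hi <- max(tok$end)
      ents <- doc$entities[doc$entities$start >= lo & doc$entities$end <= hi, , drop = FALSE]
      rels <- doc$relations[doc$relations$arg1 %in% ents$id &
                            doc$relations$arg2 %in% ents$id, , drop = FALSE]
      text <- substr(doc$text, lo + 1L, hi)
      tok$start <- tok$start - lo; tok$end <- tok$end - lo; tok$sentence <- 1L
      if (nrow(ents) > 0) { ents$start <- ents$start - lo; ents$end <- ents$end - lo }
      rownames(tok) <- NULL; rownames(ents) <- NULL; rownames(rels) <- NULL
      out[[length(out) + 1L]] <- fh_document(
        paste0(doc$doc_id, "-s", s), text, tokens = tok,
        entities = ents, relations = rels)
    }
  }
  if (dropped > 0)
    message(dropped, " cross-sentence relation(s) dropped during sentence split")
  out
}

# sentence index of each entity (by first overlapping token), named by entity id
entity_sentences <- function(doc) {
  ents <- doc$entities
  tok <- doc$tokens
  res <- vapply(seq_len(nrow(ents)), function(i) {
    hit <- which(tok$start < ents$end[i] & ents$start[i] < tok$end)
    if (length(hit) == 0) NA_integer_ else tok$sentence[hit[1]]
  }, integer(1))
  stats::setNames(res, ents$id)
}
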