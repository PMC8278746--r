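#' Parse CoNLL-U content into a token table
#'
#' Reads the 10-column CoNLL-U format (ID, FORM, LEMMA, UPOS, XPOS,
#' FEATS, HEAD, DEPREL, DEPS, MISC).  Comment lines, multi-word-token
#' ranges (`1-2`) and empty nodes (`1.1`) are skipped.  Character offsets
#' are not part of CoNLL-U; they are reconstructed later during alignment.
#'
#' @param content CoNLL-U text (single string or vector of lines).
#' @return Data frame with columns `sentence`, `surface`, `lemma`, `upos`,
#'   `deprel`.
#' @export
parse_conllu <- function(content) {
  lines <- if (length(content) == 1)
    strsplit(content, "\n", fixed = TRUE)[[1]] else content
  sent <- 1L
  in_sent <- FALSE
  out <- list()
  for (line in lines) {
    if (!nzchar(trimws(line))) {
      if (in_sent) { sent <- sent + 1L; in_sent <- FALSE }
      next
    }
    if (startsWith(line, "#")) next
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 8) stop("malformed CoNLL-U line (needs >= 8 tab fields): ", line)
    if (grepl("[-.]", f[1])) next  # MWT range or empty node
    in_sent <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      sentence = sent, surface = f[2], lemma = f[3], upos = f[4], deprel = f[8])
  }
  if (length(out) == 0)
    return(data.frame(sentence = integer(), surface = character(),
                      lemma = character(), upos = character(), deprel = character()))
  do.call(rbind, out)
}

#' Attach a CoNLL-U layer to a document
#'
#' Aligns CoNLL-U tokens to the document text by reconstructing character
#' offsets (scanning the text left to right, skipping whitespace), then
#' transfers UPOS, dependency label and lemma to the document tokens with
#' the maximal character overlap.  CoNLL-U tokens that cannot be located
#' in the text, and document tokens that receive no annotation, keep the
#' unknown-marker and are reported in a warning.
#'
#' @param doc an [fh_document()].
#' @param conllu_content CoNLL-U text for the same document.
#' @param min_aligned minimum fraction of document tokens that must be
#'   annotated; below it alignment is considered failed and an error is
#'   raised.
#' @return The document with annotated tokens.
#' @export
attach_conllu <- function(doc, conllu_content, min_aligned = 0.5) {
  stopifnot(inherits(doc, "fh_document"))
  cu <- parse_conllu(conllu_content)
  if (nrow(cu) == 0) stop("empty CoNLL-U content for ", doc$doc_id)
  text <- doc$text
  cursor <- 0L  # 0-based; next unread character index
  cu$start <- NA_integer_; cu$end <- NA_integer_
  unaligned <- 0L
  for (i in seq_len(nrow(cu))) {
    form <- cu$surface[i]
    hit <- find_ahead(text, form, cursor)
    if (is.na(hit)) { unaligned <- unaligned + 1L; next }
    cu$start[i] <- hit
    cu$end[i] <- hit + nchar(form)
    cursor <- cu$end[i]
  }
  tok <- doc$tokens
  if (nrow(tok) == 0) stop("document has no token layer to annotate: ", doc$doc_id)
  annotated <- 0L
  aligned <- cu[!is.na(cu$start), , drop = FALSE]
  for (j in seq_len(nrow(tok))) {
    ov <- pmin(aligned$end, tok$end[j]) - pmax(aligned$start, tok$start[j])
    if (length(ov) == 0 || max(ov) <= 0) next
    k <- which.max(ov)
    tok$upos[j] <- aligned$upos[k]
    tok$deprel[j] <- aligned$deprel[k]
    tok$lemma[j] <- aligned$lemma[k]
    annotated <- annotated + 1L
  }
  if (annotated / nrow(tok) < min_aligned)
    stop(sprintf("CoNLL-U alignment failed for %s: only %d/%d tokens annotated",
                 doc$doc_id, annotated, nrow(tok)))
  if (unaligned > 0 || annotated < nrow(tok))
    warning(sprintf("%s: %d CoNLL-U token(s) not located in text; %d document token(s) left unannotated",
                    doc$doc_id, unaligned, nrow(tok) - annotated))
  doc$tokens <- tok
  doc
}

# locate `form` in `text` at/after 0-based `cursor`, allowing only
# whitespace (or a short slack window) in between; NA when not found
find_ahead <- function(text, form, cursor, slack = 24L) {
  n <- nchar(text)
  pos <- cursor
  while (pos < n && substr(text, pos + 1L, pos + 1L) %in% c(" ", "\n", "\t"))
    pos <- pos + 1L
  window_end <- min(n, pos + slack + nchar(form))
  window <- substr(text, pos + 1L, window_end)
  m <- regexpr(form, window, fixed = TRUE)
  if (m == -1L) return(NA_integer_)
  if (m > 1L && grepl("[^ \n\t]", substr(window, 1L, m - 1L))) {
    # something other than whitespace precedes the match: accept only if
    # the match is within the slack window (handles mid-chunk punctuation)
    if (m - 1L > slack) return(NA_integer_)
  }
  pos + m - 1L
}

#' Format a document's token layer as CoNLL-U
#'
#' Inverse-direction writer used when generating synthetic corpora: emits
#' one CoNLL-U sentence per sentence of the document, with UPOS, lemma and
#' dependency label taken from the token table (head indices are not
#' modelled and are written as `0`/`_` placeholders except the deprel).
#'
#' @param doc an [fh_document()].
#' @return A single CoNLL-U string.
#' @export
format_conllu <- function(doc) {
  tok <- doc$tokens
  out <- character()
  for (s in unique(tok$sentence)) {
    st <- tok[tok$sentence == s, , drop = FALSE]
    sent_text <- substr(doc$text, min(st$start) + 1L, max(st$end))
    out <- c(out, paste0("# sent_id = ", doc$doc_id, "-", s),
             paste0("# text = ", gsub("\n", " ", sent_text)))
    for (i in seq_len(nrow(st))) {
      out <- c(out, paste(i, st$surface[i], st$lemma[i], st$upos[i], "_", "_",
                          "0", st$deprel[i], "_", "_", sep = "\t"))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
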