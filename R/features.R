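#' Feature configuration
#'
#' Controls the indicator feature templates.  For token-level entity
#' classification the templates are: word identity in a symmetric context
#' window, UPOS in the same window, and the two previously assigned
#' entity tags (gold at training time, predicted at decoding time).
#' Optional extras — lowercased word, 3-character prefix/suffix, and the
#' previous-tag bigram — are off by default; in development they did not
#' have to be enabled to reach the reference scores.  For relation
#' classification `relation_level` selects the cumulative feature set:
#' entity words only, plus UPOS, plus dependency labels, plus the entity
#' labels of the two arguments.
#'
#' @param window context window radius for word/POS templates (the POS
#'   window is read as the same +/-2 radius as the lexical window).
#' @param affixes add 3-character prefix/suffix features.
#' @param lowercase add a lowercased-word feature.
#' @param prevtag_bigram also add the bigram of the two previous tags.
#' @param relation_level one of `"words"`, `"pos"`, `"dep"`, `"labels"`
#'   (each level includes the previous ones).
#' @return A list of class `fh_feature_config`.
#' @export
fh_feature_config <- function(window = 2L, affixes = FALSE, lowercase = FALSE,
                              prevtag_bigram = FALSE,
                              relation_level = c("labels", "words", "pos", "dep")) {
  relation_level <- match.arg(relation_level)
  structure(list(window = as.integer(window), affixes = affixes,
                 lowercase = lowercase, prevtag_bigram = prevtag_bigram,
                 relation_level = relation_level),
            class = "fh_feature_config")
}

BOS <- "<BOS>"
EOS <- "<EOS>"

#' Token-level entity features
#'
#' Builds the indicator feature bag for classifying the entity label of
#' one token: word and UPOS identity at relative positions within the
#' window (positions beyond the sentence contribute boundary markers),
#' and the two previous entity tags.  Keys are namespaced by template and
#' relative position so identical strings in different roles never
#' collide.
#'
#' @param tokens token data frame of one sentence.
#' @param position 1-based token index within the sentence.
#' @param prev_tags character vector `c(tag at -2, tag at -1)`; pad with
#'   the BOS symbol at sentence start.
#' @param config an [fh_feature_config()].
#' @return Character vector of feature keys (a feature bag).
#' @export
entity_features <- function(tokens, position, prev_tags = c(BOS, BOS),
                            config = fh_feature_config()) {
  n <- nrow(tokens)
  stopifnot(position >= 1, position <= n, length(prev_tags) == 2)
  w <- config$window
  rel <- (-w):w
  idx <- position + rel
  words <- ifelse(idx < 1, BOS, ifelse(idx > n, EOS, tokens$surface[pmax(pmin(idx, n), 1)]))
  pos <- ifelse(idx < 1, BOS, ifelse(idx > n, EOS, tokens$upos[pmax(pmin(idx, n), 1)]))
  bag <- c(sprintf("w[%+d]=%s", rel, words),
           sprintf("p[%+d]=%s", rel, pos),
           paste0("t[-2]=", prev_tags[1]),
           paste0("t[-1]=", prev_tags[2]))
  if (config$prevtag_bigram)
    bag <- c(bag, paste0("t[-2,-1]=", prev_tags[1], "|", prev_tags[2]))
  if (config$lowercase)
    bag <- c(bag, paste0("lw[0]=", tolower(tokens$surface[position])))
  if (config$affixes) {
    word <- tokens$surface[position]
    bag <- c(bag, paste0("pre3=", substr(word, 1, 3)),
             paste0("suf3=", substr(word, max(1, nchar(word) - 2), nchar(word))))
  }
  bag
}

# tokens (row indices) covered by an entity span, in surface order
entity_token_rows <- function(tokens, start, end) {
  which(tokens$start < end & start < tokens$end)
}

#' Entity-pair relation features
#'
#' Builds the feature bag for classifying the relation between two
#' entities of the same sentence.  Per argument slot the bag contains the
#' entity's word feature, its UPOS feature and the dependency label of
#' each entity word's incoming arc; a multi-word entity contributes a
#' single concatenated key per template, not one key per word.  When
#' `labels_source` is not `"none"`, the two entity labels are added
#' (gold labels from the annotation, or predicted labels supplied by the
#' caller).  Keys are namespaced by argument slot, so swapping the
#' arguments changes the bag.
#'
#' @param tokens token data frame of one sentence.
#' @param ent1,ent2 one-row entity data frames (same sentence).
#' @param labels_source `"none"`, `"gold"` or `"predicted"`; with
#'   `"predicted"`, pass the labels via `ent1$label`/`ent2$label` of the
#'   predicted-entity layer.
#' @param config an [fh_feature_config()]; `relation_level` selects the
#'   cumulative template set.
#' @return Character vector of feature keys.
#' @export
relation_features <- function(tokens, ent1, ent2, labels_source = "gold",
                              config = fh_feature_config()) {
  lvl <- match(config$relation_level, c("words", "pos", "dep", "labels"))
  slot <- function(prefix, ent) {
    rows <- entity_token_rows(tokens, ent$start, ent$end)
    if (length(rows) == 0)
      stop("entity [", ent$start, ",", ent$end, ") covers no token of the sentence")
    bag <- paste0(prefix, ".w=", paste(tokens$surface[rows], collapse = "_"))
    if (lvl >= 2)
      bag <- c(bag, paste0(prefix, ".p=", paste(tokens$upos[rows], collapse = "_")))
    if (lvl >= 3)
      bag <- c(bag, paste0(prefix, ".d=", paste(tokens$deprel[rows], collapse = "_")))
    bag
  }
  bag <- c(slot("a1", ent1), slot("a2", ent2))
  if (lvl >= 4 && labels_source != "none")
    bag <- c(bag, paste0("a1.l=", ent1$label), paste0("a2.l=", ent2$label))
  bag
}

#' Fit a feature vocabulary and vectorize feature bags
#'
#' The vocabulary maps feature keys to column indices and is frozen after
#' fitting on the training bags; keys unseen at prediction time map to no
#' column.  Vectors are binary indicators (duplicate keys in a bag count
#' once).
#'
#' @param bags list of feature bags (character vectors).
#' @return `fit_vocabulary` returns an `fh_vocabulary`; `vectorize`
#'   returns a sparse `dgCMatrix` with one row per bag.
#' @export
fit_vocabulary <- function(bags) {
  keys <- sort(unique(unlist(bags, use.names = FALSE)))
  structure(list(keys = keys, index = stats::setNames(seq_along(keys), keys)),
            class = "fh_vocabulary")
}

#' @rdname fit_vocabulary
#' @param vocab an `fh_vocabulary`.
#' @export
vectorize <- function(bags, vocab) {
  if (!inherits(vocab, "fh_vocabulary"))
    stop("vectorize called without a fitted vocabulary")
  if (inherits(bags, "character")) bags <- list(bags)
  n <- length(bags)
  lens <- lengths(bags)
  i <- rep(seq_len(n), lens)
  j <- unname(vocab$index[unlist(bags, use.names = FALSE)])
  keep <- !is.na(j)
  ij <- unique(cbind(i[keep], j[keep]))
  Matrix::sparseMatrix(i = ij[, 1], j = ij[, 2], x = 1,
                       dims = c(n, length(vocab$keys)))
}

#' @export
print.fh_vocabulary <- function(x, ...) {
  cat("<fh_vocabulary>", length(x$keys), "features\n")
  invisible(x)
}
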