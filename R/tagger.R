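#' Dictionary baseline for entity tagging
#'
#' Collects every word of the training data with its projected token
#' label and stores, per exact surface form, the most frequent label
#' (including `"O"` occurrences by default).  Ties are broken by fixed
#' lexicographic label order; the number of tie-broken words is reported.
#'
#' @param training_docs list of [fh_document()]s.
#' @param count_o include `"O"` occurrences when computing the modal
#'   label (default `TRUE`).
#' @return An `fh_dictionary`: a named character vector word -> label,
#'   with the full count table kept for inspection in
#'   `attr(, "counts")`.
#' @export
build_dictionary <- function(training_docs, count_o = TRUE) {
  if (inherits(training_docs, "fh_document")) training_docs <- list(training_docs)
  if (length(training_docs) == 0) stop("empty training set")
  words <- character(); labs <- character()
  for (doc in training_docs) {
    lab <- unlist(project_entities_to_tokens(doc), use.names = FALSE)
    words <- c(words, doc$tokens$surface)
    labs <- c(labs, lab)
  }
  if (length(words) == 0) stop("empty training set")
  if (!count_o) { keepw <- labs != "O"; words <- words[keepw]; labs <- labs[keepw] }
  counts <- table(word = words, label = labs)
  lab_order <- sort(colnames(counts))
  ties <- 0L
  modal <- apply(counts[, lab_order, drop = FALSE], 1, function(r) {
    m <- which(r == max(r))
    if (length(m) > 1) ties <<- ties + 1L
    lab_order[m[1]]  # lexicographically first label wins on ties
  })
  if (ties > 0)
    message("dictionary: ", ties, " word(s) with tied label counts; ",
            "lexicographically first label kept")
  structure(modal, counts = counts, class = "fh_dictionary")
}

#' @rdname build_dictionary
#' @param tokens token data frame of one sentence (or a whole document's
#'   token table).
#' @param model an `fh_dictionary`.
#' @return `dictionary_tag` returns a character vector of labels;
#'   out-of-dictionary words are tagged `"O"`.
#' @export
dictionary_tag <- function(tokens, model) {
  if (nrow(tokens) == 0) return(character())
  hit <- unname(unclass(model)[tokens$surface])
  ifelse(is.na(hit), "O", hit)
}

#' @export
print.fh_dictionary <- function(x, ...) {
  cat("<fh_dictionary>", length(unclass(x)), "words\n")
  invisible(x)
}

#' Train the linear entity tagger
#'
#' Token-level multi-class classification over the 11 labels (the 10
#' entity types plus `"O"`).  Features follow [entity_features()];
#' previous-tag features use the *gold* tags at training time (teacher
#' forcing) and the model's own predictions at decoding time.  The
#' classifier is a one-vs-rest L2-regularized linear model fitted on the
#' sparse indicator matrix.
#'
#' @param training_docs list of [fh_document()]s with token layers.
#' @param config an [fh_feature_config()].
#' @param lambda ridge penalty of the linear model.
#' @param seed integer seed (the fit is deterministic; the seed fixes any
#'   auxiliary randomness so that identical calls yield identical models).
#' @return An `fh_tagger` with the fitted model, the frozen vocabulary,
#'   the feature config and the label inventory.
#' @export
train_tagger <- function(training_docs, config = fh_feature_config(),
                         lambda = 1e-4, seed = 1L) {
  if (inherits(training_docs, "fh_document")) training_docs <- list(training_docs)
  set.seed(seed)
  bags <- list(); y <- character()
  for (doc in training_docs) {
    labs <- project_entities_to_tokens(doc)
    sents <- unique(doc$tokens$sentence)
    for (k in seq_along(sents)) {
      tok <- doc$tokens[doc$tokens$sentence == sents[k], , drop = FALSE]
      lab <- labs[[k]]
      padded <- c(BOS, BOS, lab)
      for (i in seq_len(nrow(tok))) {
        bags[[length(bags) + 1L]] <-
          entity_features(tok, i, prev_tags = padded[c(i, i + 1L)], config = config)
      }
      y <- c(y, lab)
    }
  }
  if (length(y) == 0) stop("no training tokens")
  missing_cls <- setdiff(token_labels(), unique(y))
  if (length(missing_cls) > 0)
    warning("label(s) absent from training data: ",
            paste(missing_cls, collapse = ", "),
            "; the model will never predict them")
  vocab <- fit_vocabulary(bags)
  x <- vectorize(bags, vocab)
  fit <- fit_linear(x, y, lambda)
  structure(list(fit = fit, vocab = vocab, config = config, lambda = lambda,
                 labels = token_labels(), classes = fit$classes),
            class = "fh_tagger")
}

# one-vs-rest regularized linear classifier over a sparse indicator
# matrix; fitted as multinomial logistic regression with ungrouped
# (per-class) L2 penalties, decoded by maximum response
fit_linear <- function(x, y, lambda) {
  counts <- table(y)
  rare <- names(counts)[counts < 2]
  if (length(rare) > 0) {
    # the solver needs >= 2 observations per class; duplicate singleton
    # instances so the class stays predictable
    idx <- which(y %in% rare)
    x <- rbind(x, x[idx, , drop = FALSE])
    y <- c(y, y[idx])
  }
  classes <- sort(unique(y))
  if (length(classes) < 2) stop("need at least 2 distinct labels to fit a classifier")
  path <- sort(unique(c(0.1, 0.03, 0.01, 0.003, lambda)), decreasing = TRUE)
  path <- path[path >= lambda]
  fit <- glmnet::glmnet(x, factor(y, levels = classes), family = "multinomial",
                        alpha = 0, lambda = path, standardize = FALSE,
                        type.multinomial = "ungrouped")
  # freeze the decision function: per-class weight vectors and intercepts
  # at the target penalty, so prediction is one matrix product
  cf <- stats::coef(fit, s = lambda)
  beta <- do.call(cbind, lapply(cf, function(b) b[-1, 1, drop = TRUE]))
  a0 <- vapply(cf, function(b) b[1, 1], numeric(1))
  colnames(beta) <- classes
  list(beta = beta, a0 = a0, classes = classes, lambda = lambda)
}

predict_linear <- function(model, x) {
  if (nrow(x) == 0) return(character())
  scores <- as.matrix(x %*% model$beta)
  scores <- sweep(scores, 2, model$a0, "+")
  model$classes[max.col(scores, ties.method = "first")]
}

#' Greedy left-to-right decoding
#'
#' Predicts one label per token in a single left-to-right pass; the
#' features of token *i* use the model's own predictions at *i-1* and
#' *i-2* (BOS padding at the sentence start).  There is no lookahead and
#' no interaction between sentences.
#'
#' @param model an `fh_tagger`.
#' @param tokens token data frame of one sentence.
#' @return Character vector of predicted labels, one per token.
#' @export
greedy_decode <- function(model, tokens) {
  greedy_decode_batch(model, list(tokens))[[1]]
}

# decode many sentences at once, batching the classifier calls by token
# position (sentence s's prediction at position p never depends on any
# other sentence)
greedy_decode_batch <- function(model, sentences) {
  ns <- length(sentences)
  lens <- vapply(sentences, nrow, integer(1))
  preds <- lapply(lens, function(l) character(l))
  if (ns == 0 || max(lens) == 0) return(preds)
  for (p in seq_len(max(lens))) {
    active <- which(lens >= p)
    bags <- lapply(active, function(s) {
      prev <- c(BOS, BOS, preds[[s]])[c(p, p + 1L)]
      entity_features(sentences[[s]], p, prev_tags = prev, config = model$config)
    })
    lab <- predict_linear(model$fit, vectorize(bags, model$vocab))
    for (k in seq_along(active)) preds[[active[k]]][p] <- lab[k]
  }
  preds
}

#' Tag a document with a trained model
#'
#' @param model an `fh_tagger` or `fh_dictionary`.
#' @param doc an [fh_document()].
#' @return List of per-sentence predicted label vectors.
#' @export
tag_document <- function(model, doc) {
  sents <- unique(doc$tokens$sentence)
  toks <- lapply(sents, function(s) doc$tokens[doc$tokens$sentence == s, , drop = FALSE])
  if (inherits(model, "fh_dictionary"))
    lapply(toks, dictionary_tag, model = model)
  else
    greedy_decode_batch(model, toks)
}

#' Merge the CONDITION and EVENT labels
#'
#' The demarcation between prolonged conditions and point-like clinical
#' events is the scheme's least sharp boundary; this transform collapses
#' both labels to `CONDITION_EVENT` so that gold and predicted sequences
#' can be evaluated under the merged inventory.  Idempotent; all other
#' labels are unchanged.
#'
#' @param labels character vector, or list of vectors.
#' @return Same shape as the input.
#' @export
merge_condition_event <- function(labels) {
  if (is.list(labels)) return(lapply(labels, merge_condition_event))
  ifelse(labels %in% c("CONDITION", "EVENT", "CONDITION_EVENT"),
         "CONDITION_EVENT", labels)
}
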