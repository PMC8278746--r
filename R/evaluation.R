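#' Per-class and support-weighted precision/recall/F1
#'
#' Computes per-class precision, recall and F1 over all labels appearing
#' in gold or prediction, and their support-weighted averages.  Supports
#' are counted on the gold sequence.  Labels in `exclude` keep their
#' per-class rows but contribute no weight to the averages (their gold
#' instances are removed from the weighting; predictions into or out of
#' them still affect the other classes' precision and recall).  Undefined
#' precision or recall (zero denominator) is reported as 0, the standard
#' convention that keeps weighted averages well defined.
#'
#' @param gold,pred label vectors, or lists of aligned vectors.
#' @param exclude labels excluded from the weighted average (e.g. `"O"`
#'   for entity evaluation, as in the "excluding O" reporting variant).
#' @return An `fh_metrics` object: `per_class` data frame (label,
#'   precision, recall, f1, support), `weighted` named numeric vector,
#'   `excluded`, `n` evaluated units.
#' @export
weighted_prf <- function(gold, pred, exclude = character()) {
  gold <- unlist(gold, use.names = FALSE)
  pred <- unlist(pred, use.names = FALSE)
  if (length(gold) != length(pred))
    stop("gold and prediction have different lengths (",
         length(gold), " vs ", length(pred), ")")
  classes <- sort(unique(c(gold, pred)))
  per <- data.frame(label = classes, precision = 0, recall = 0, f1 = 0,
                    support = 0L)
  for (k in seq_along(classes)) {
    cl <- classes[k]
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    per$precision[k] <- p
    per$recall[k] <- r
    per$f1[k] <- if (p + r > 0) 2 * p * r / (p + r) else 0
    per$support[k] <- tp + fn
  }
  inc <- !(per$label %in% exclude)
  wsum <- sum(per$support[inc])
  weighted <- if (wsum > 0) c(
    precision = sum(per$precision[inc] * per$support[inc]) / wsum,
    recall = sum(per$recall[inc] * per$support[inc]) / wsum,
    f1 = sum(per$f1[inc] * per$support[inc]) / wsum)
  else c(precision = 0, recall = 0, f1 = 0)
  structure(list(per_class = per, weighted = weighted, excluded = exclude,
                 n = length(gold)),
            class = "fh_metrics")
}

#' @export
print.fh_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("%-12s %9s %9s %9s %8s\n", "label", "precision", "recall", "F1", "support"))
  for (i in seq_len(nrow(x$per_class)))
    cat(sprintf("%-12s %9.*f %9.*f %9.*f %8d\n", x$per_class$label[i],
                digits, x$per_class$precision[i], digits, x$per_class$recall[i],
                digits, x$per_class$f1[i], x$per_class$support[i]))
  cat(sprintf("%-12s %9.*f %9.*f %9.*f %8d%s\n", "weighted", digits,
              x$weighted["precision"], digits, x$weighted["recall"], digits,
              x$weighted["f1"], x$n,
              if (length(x$excluded)) paste0("  (excl. ", paste(x$excluded, collapse = ","), ")") else ""))
  invisible(x)
}

#' Confusion matrix
#'
#' @param gold,pred label vectors or lists of aligned vectors.
#' @param label_order fixed row/column order; defaults to the sorted
#'   union of observed labels.
#' @return Integer matrix, rows = gold, columns = predicted.
#' @export
confusion <- function(gold, pred, label_order = NULL) {
  gold <- unlist(gold, use.names = FALSE)
  pred <- unlist(pred, use.names = FALSE)
  stopifnot(length(gold) == length(pred))
  if (is.null(label_order)) label_order <- sort(unique(c(gold, pred)))
  tab <- table(factor(gold, levels = label_order),
               factor(pred, levels = label_order))
  m <- matrix(as.integer(tab), nrow = length(label_order),
              dimnames = list(gold = label_order, predicted = label_order))
  m
}

#' Paired two-sided t-test across cross-validation folds
#'
#' Classical paired t-test on two equal-length score vectors (one score
#' per fold).  With zero variance of the differences the statistic is
#' undefined; the degenerate case is reported explicitly: p = 1 when the
#' two systems are identical, p = 0 when one is constantly better.
#'
#' @param scores_a,scores_b numeric vectors of equal length >= 2.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(scores_a, scores_b) {
  if (length(scores_a) != length(scores_b))
    stop("score vectors must have equal length")
  if (length(scores_a) < 2)
    stop("need at least 2 paired scores")
  d <- scores_a - scores_b
  if (isTRUE(all.equal(stats::var(d), 0)) || stats::var(d) == 0) {
    md <- mean(d)
    return(list(t = if (md == 0) 0 else sign(md) * Inf,
                p = if (md == 0) 1 else 0,
                df = length(d) - 1L, mean_diff = md, degenerate = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), mean_diff = unname(tt$estimate),
       degenerate = FALSE)
}

#' Exact-match span-level precision/recall/F1
#'
#' Micro-averaged scoring of predicted entity spans against gold spans:
#' a predicted entity counts as correct iff a gold entity has exactly the
#' same character span and the same label.
#'
#' @param gold_entities,pred_entities entity data frames.
#' @return Named numeric vector `precision`, `recall`, `f1`, plus the
#'   match counts as attributes.
#' @export
span_prf <- function(gold_entities, pred_entities) {
  key <- function(e) paste(e$start, e$end, e$label)
  matches <- sum(key(pred_entities) %in% key(gold_entities))
  p <- if (nrow(pred_entities) > 0) matches / nrow(pred_entities) else 0
  r <- if (nrow(gold_entities) > 0) matches / nrow(gold_entities) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  structure(c(precision = p, recall = r, f1 = f),
            matches = matches, n_gold = nrow(gold_entities),
            n_pred = nrow(pred_entities))
}

#' Inter-annotator agreement on entity spans and labels
#'
#' Micro-averaged precision, recall and F1 of one annotator's (span,
#' label) entity pairs against another's, exact match; `annotation_a` is
#' treated as the gold standard.
#'
#' @param annotation_a,annotation_b lists of [fh_document()]s over the
#'   same texts, in the same order.
#' @return Named numeric vector `precision`, `recall`, `f1`.
#' @export
iaa <- function(annotation_a, annotation_b) {
  if (inherits(annotation_a, "fh_document")) annotation_a <- list(annotation_a)
  if (inherits(annotation_b, "fh_document")) annotation_b <- list(annotation_b)
  if (length(annotation_a) != length(annotation_b))
    stop("annotation sets have different numbers of documents")
  matches <- 0L; n_a <- 0L; n_b <- 0L
  for (i in seq_along(annotation_a)) {
    a <- annotation_a[[i]]; b <- annotation_b[[i]]
    if (!identical(a$text, b$text))
      stop("document ", i, ": the two annotations cover different texts")
    key <- function(e) paste(e$start, e$end, e$label)
    matches <- matches + sum(key(b$entities) %in% key(a$entities))
    n_a <- n_a + nrow(a$entities); n_b <- n_b + nrow(b$entities)
  }
  p <- if (n_b > 0) matches / n_b else 0
  r <- if (n_a > 0) matches / n_a else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f)
}

#' Sentence-level k-fold cross-validation
#'
#' Splits a corpus into k sentence-level folds (seeded random partition)
#' and, per fold, trains the requested pipeline strictly on the training
#' split — dictionary, feature vocabulary and classifier are all
#' re-fitted per fold — then evaluates on the held-out split.  Reported
#' averages are unweighted means of the fold-level weighted metrics.
#'
#' @param corpus list of [fh_document()]s (multi-sentence documents are
#'   exploded into sentences first).
#' @param task `"entity"` or `"relation"`.
#' @param k number of folds (>= 2).
#' @param seed integer seed for the fold partition.
#' @param config an [fh_feature_config()].
#' @param lambda ridge penalty passed to the classifier.
#' @param labels_source for the relation task: `"gold"`, `"predicted"`
#'   or `"none"` entity-label features.
#' @param merge_condition_event evaluate the entity task under the
#'   merged CONDITION/EVENT inventory.
#' @return An `fh_cv` object: `folds` (per-fold list with `metrics`, a
#'   named list of `fh_metrics`, plus train/test sizes) and `mean`, a
#'   data frame of averaged weighted precision/recall/F1 per variant.
#' @export
cross_validate <- function(corpus, task = c("entity", "relation"), k = 5,
                           seed = 1L, config = fh_feature_config(),
                           lambda = 1e-4, labels_source = "gold",
                           merge_condition_event = FALSE) {
  task <- match.arg(task)
  if (k < 2) stop("k must be at least 2")
  sents <- split_sentences(corpus)
  n <- length(sents)
  if (k > n) stop("k (", k, ") exceeds the number of sentences (", n, ")")
  set.seed(seed)
  assignment <- sample(rep(seq_len(k), length.out = n))
  folds <- vector("list", k)
  for (f in seq_len(k)) {
    train <- sents[assignment != f]
    test <- sents[assignment == f]
    metrics <- if (task == "entity")
      eval_entity_fold(train, test, config, lambda, seed, merge_condition_event)
    else
      eval_relation_fold(train, test, config, lambda, seed, labels_source)
    folds[[f]] <- c(list(fold = f, n_train = length(train), n_test = length(test)),
                    metrics)
  }
  variant_names <- names(folds[[1]]$metrics)
  mean_tab <- do.call(rbind, lapply(variant_names, function(v) {
    w <- vapply(folds, function(fd) fd$metrics[[v]]$weighted, numeric(3))
    data.frame(variant = v, precision = mean(w["precision", ]),
               recall = mean(w["recall", ]), f1 = mean(w["f1", ]))
  }))
  structure(list(task = task, k = k, seed = seed, folds = folds, mean = mean_tab),
            class = "fh_cv")
}

#' @export
print.fh_cv <- function(x, digits = 3, ...) {
  cat(sprintf("<fh_cv> %s task, %d folds (seed %d); mean of fold-level weighted metrics:\n",
              x$task, x$k, x$seed))
  m <- x$mean
  for (i in seq_len(nrow(m)))
    cat(sprintf("  %-28s P %.*f  R %.*f  F1 %.*f\n", m$variant[i],
                digits, m$precision[i], digits, m$recall[i], digits, m$f1[i]))
  invisible(x)
}

eval_entity_fold <- function(train, test, config, lambda, seed, merge) {
  dict <- build_dictionary(train)
  tagger <- train_tagger(train, config = config, lambda = lambda, seed = seed)
  gold <- lapply(test, function(d) unlist(project_entities_to_tokens(d), use.names = FALSE))
  toks <- lapply(test, function(d) d$tokens)
  pred_svm <- greedy_decode_batch(tagger, toks)
  pred_dict <- lapply(toks, dictionary_tag, model = dict)
  if (merge) {
    gold <- merge_condition_event(gold)
    pred_svm <- merge_condition_event(pred_svm)
    pred_dict <- merge_condition_event(pred_dict)
  }
  list(metrics = list(
    svm_incl_o = weighted_prf(gold, pred_svm),
    svm_excl_o = weighted_prf(gold, pred_svm, exclude = "O"),
    dictionary_incl_o = weighted_prf(gold, pred_dict),
    dictionary_excl_o = weighted_prf(gold, pred_dict, exclude = "O")))
}

eval_relation_fold <- function(train, test, config, lambda, seed, labels_source) {
  tagger <- if (labels_source == "predicted")
    train_tagger(train, config = fh_feature_config(), lambda = lambda, seed = seed)
  model <- train_relation_model(train, config = config, labels_source = labels_source,
                                tagger = tagger, lambda = lambda, seed = seed)
  gold <- character(); pred <- character()
  for (doc in test) {
    cands <- classify_candidates(model, doc, tagger)
    gold <- c(gold, cands$gold_label)
    pred <- c(pred, cands$pred_label)
  }
  list(metrics = list(relation = weighted_prf(gold, pred)))
}
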