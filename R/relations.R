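#' Generate within-sentence relation candidates
#'
#' Every unordered pair of distinct entities in the same sentence becomes
#' one candidate instance, ordered canonically by surface position.  If a
#' gold relation links the pair (in either direction) the instance keeps
#' that relation's label, otherwise it is labelled `No_Relation`.
#' Cross-sentence gold relations are excluded and their count reported.
#'
#' @param doc an [fh_document()].
#' @param directed generate both ordered pairs per entity pair instead of
#'   one canonical instance (default `FALSE`; the exhaustive unordered
#'   scheme matches the instance accounting of the reference corpus).
#' @return Data frame with columns `sentence`, `arg1`, `arg2` (entity
#'   ids, surface order), `gold_label`, `gold_dir` (`+1` when the gold
#'   relation ran arg1->arg2, `-1` when reversed, `0` for No_Relation).
#' @export
generate_candidates <- function(doc, directed = FALSE) {
  stopifnot(inherits(doc, "fh_document"))
  ents <- doc$entities
  out <- data.frame(sentence = integer(), arg1 = character(), arg2 = character(),
                    gold_label = character(), gold_dir = integer())
  if (nrow(ents) < 2) return(out)
  sent_of <- entity_sentences(doc)
  rels <- doc$relations
  if (nrow(rels) > 0) {
    cross <- sum(sent_of[rels$arg1] != sent_of[rels$arg2], na.rm = TRUE)
    if (cross > 0)
      message(doc$doc_id, ": ", cross, " cross-sentence gold relation(s) excluded from candidates")
  }
  rows <- list()
  for (s in unique(sent_of[!is.na(sent_of)])) {
    ids <- ents$id[which(sent_of == s)]
    if (length(ids) < 2) next
    # canonical surface order within the sentence
    ord <- order(ents$start[match(ids, ents$id)], ents$end[match(ids, ents$id)])
    ids <- ids[ord]
    for (a in seq_len(length(ids) - 1)) for (b in seq(a + 1, length(ids))) {
      i <- ids[a]; j <- ids[b]
      fwd <- which(rels$arg1 == i & rels$arg2 == j)
      rev <- which(rels$arg1 == j & rels$arg2 == i)
      lab <- "No_Relation"; dir <- 0L
      if (length(fwd) > 0) { lab <- rels$label[fwd[1]]; dir <- 1L }
      else if (length(rev) > 0) { lab <- rels$label[rev[1]]; dir <- -1L }
      rows[[length(rows) + 1L]] <- data.frame(
        sentence = s, arg1 = i, arg2 = j, gold_label = lab, gold_dir = dir)
      if (directed)
        rows[[length(rows) + 1L]] <- data.frame(
          sentence = s, arg1 = j, arg2 = i,
          gold_label = if (length(rev) > 0) rels$label[rev[1]] else "No_Relation",
          gold_dir = if (length(rev) > 0) 1L else 0L)
    }
  }
  if (length(rows) == 0) return(out)
  do.call(rbind, rows)
}

# feature bags for a candidate table; label_map optionally overrides the
# entity labels used for the label-feature templates (eg tagger output)
candidate_bags <- function(doc, cands, labels_source = "gold",
                           config = fh_feature_config(), label_map = NULL) {
  bags <- vector("list", nrow(cands))
  if (nrow(cands) == 0) return(bags)
  ents <- doc$entities
  if (!is.null(label_map)) ents$label <- unname(label_map[ents$id])
  for (i in seq_len(nrow(cands))) {
    tok <- doc$tokens[doc$tokens$sentence == cands$sentence[i], , drop = FALSE]
    e1 <- ents[ents$id == cands$arg1[i], , drop = FALSE]
    e2 <- ents[ents$id == cands$arg2[i], , drop = FALSE]
    bags[[i]] <- relation_features(tok, e1, e2, labels_source = labels_source,
                                   config = config)
  }
  bags
}

#' Predicted labels for gold entity spans
#'
#' Runs a trained tagger over the document and assigns each gold entity
#' span the modal predicted token label over its covered tokens (the
#' first covered token's label on ties).  Used to feed *predicted* entity
#' labels into the relation classifier while keeping the gold spans, so
#' that the candidate set is identical across the gold/predicted label
#' conditions.
#'
#' @param doc an [fh_document()].
#' @param tagger an `fh_tagger` (or `fh_dictionary`).
#' @return Named character vector entity id -> predicted label.
#' @export
predicted_span_labels <- function(doc, tagger) {
  seqs <- tag_document(tagger, doc)
  flat <- unlist(seqs, use.names = FALSE)
  tok <- doc$tokens
  ents <- doc$entities
  res <- vapply(seq_len(nrow(ents)), function(i) {
    hit <- which(tok$start < ents$end[i] & ents$start[i] < tok$end)
    if (length(hit) == 0) return("O")
    tab <- table(flat[hit])
    best <- names(tab)[tab == max(tab)]
    if (length(best) > 1) flat[hit[1]] else best
  }, character(1))
  stats::setNames(res, ents$id)
}

#' Train the 6-way relation classifier
#'
#' Fits a one-vs-rest regularized linear model over the five relation
#' labels plus `No_Relation`, on candidate instances from a training
#' corpus.  The feature set is controlled by the config's
#' `relation_level` (entity words; plus UPOS; plus dependency labels;
#' plus entity labels) and `labels_source` selects whether the
#' label-feature templates see gold or tagger-predicted entity labels.
#'
#' @param corpus list of [fh_document()]s (gold annotation).
#' @param config an [fh_feature_config()].
#' @param labels_source `"gold"`, `"predicted"` or `"none"`.
#' @param tagger required when `labels_source = "predicted"`.
#' @param lambda ridge penalty.
#' @param seed integer seed.
#' @return An `fh_relation_model`.
#' @export
train_relation_model <- function(corpus, config = fh_feature_config(),
                                 labels_source = "gold", tagger = NULL,
                                 lambda = 1e-4, seed = 1L) {
  if (inherits(corpus, "fh_document")) corpus <- list(corpus)
  set.seed(seed)
  if (labels_source == "predicted" && is.null(tagger))
    stop("labels_source = 'predicted' requires a tagger")
  bags <- list(); y <- character()
  for (doc in corpus) {
    cands <- generate_candidates(doc)
    if (nrow(cands) == 0) next
    lm <- if (labels_source == "predicted") predicted_span_labels(doc, tagger) else NULL
    bags <- c(bags, candidate_bags(doc, cands, labels_source, config, lm))
    y <- c(y, cands$gold_label)
  }
  if (length(unique(y)) < 2)
    stop("fewer than 2 distinct relation labels in training data")
  vocab <- fit_vocabulary(bags)
  fit <- fit_linear(vectorize(bags, vocab), y, lambda)
  structure(list(fit = fit, vocab = vocab, config = config,
                 labels_source = labels_source, lambda = lambda,
                 labels = relation_labels()),
            class = "fh_relation_model")
}

#' Classify a document's candidate pairs
#'
#' @param model an `fh_relation_model`.
#' @param doc an [fh_document()] (candidates come from its entity layer).
#' @param tagger tagger for predicted label features, when the model was
#'   trained with `labels_source = "predicted"`.
#' @return The candidate table with a `pred_label` column.
#' @export
classify_candidates <- function(model, doc, tagger = NULL) {
  cands <- generate_candidates(doc)
  if (nrow(cands) == 0) { cands$pred_label <- character(); return(cands) }
  lm <- if (model$labels_source == "predicted") {
    if (is.null(tagger)) stop("model uses predicted entity labels; supply a tagger")
    predicted_span_labels(doc, tagger)
  }
  bags <- candidate_bags(doc, cands, model$labels_source, model$config, lm)
  cands$pred_label <- predict_linear(model$fit, vectorize(bags, model$vocab))
  cands
}

#' Predict relations for a document
#'
#' Generates candidates, classifies them, and materializes every
#' non-`No_Relation` prediction as a relation.  Emitted relations are
#' re-oriented to satisfy the schema when the orientation is unambiguous
#' (e.g. a Holder's first argument must be the CONDITION/EVENT);
#' ambiguous cases keep surface order.  With `schema_filter = TRUE`,
#' predictions that violate [allowed_relation()] in both orientations are
#' dropped and counted in a message.
#'
#' @inheritParams classify_candidates
#' @param entities `"gold"` uses the document's entity layer;
#'   `"predicted"` replaces it first with spans recovered from the
#'   tagger's output ([with_predicted_entities()]).
#' @param schema_filter drop schema-violating predictions.
#' @param schema an [fh_schema()].
#' @return The input document with its `relations` slot replaced by the
#'   predictions (ids `R1..Rn`).
#' @export
predict_relations <- function(model, doc, entities = c("gold", "predicted"),
                              tagger = NULL, schema_filter = FALSE,
                              schema = fh_schema()) {
  entities <- match.arg(entities)
  if (entities == "predicted") {
    if (is.null(tagger)) stop("entities = 'predicted' requires a tagger")
    doc <- with_predicted_entities(doc, tag_document(tagger, doc))
  }
  cands <- classify_candidates(model, doc, tagger)
  keep <- cands[cands$pred_label != "No_Relation", , drop = FALSE]
  ents <- doc$entities
  lab_of <- stats::setNames(ents$label, ents$id)
  rels <- list(); dropped <- 0L
  for (i in seq_len(nrow(keep))) {
    r <- keep$pred_label[i]; a1 <- keep$arg1[i]; a2 <- keep$arg2[i]
    ok_fwd <- allowed_relation(r, lab_of[a1], lab_of[a2], schema)
    ok_rev <- allowed_relation(r, lab_of[a2], lab_of[a1], schema)
    if (!ok_fwd && ok_rev) { tmp <- a1; a1 <- a2; a2 <- tmp }
    else if (!ok_fwd && !ok_rev && schema_filter) { dropped <- dropped + 1L; next }
    rels[[length(rels) + 1L]] <- data.frame(
      id = paste0("R", length(rels) + 1L), label = r, arg1 = a1, arg2 = a2)
  }
  if (dropped > 0)
    message(doc$doc_id, ": ", dropped, " schema-violating predicted relation(s) dropped")
  doc$relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  doc
}
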