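three_entity_doc <- function() {
  fh_document(
    "t3", "onkel har hatt hjertestans i fjor.",
    entities = data.frame(
      id = c("T1", "T2", "T3"), label = c("FAMILY", "EVENT", "TEMPORAL"),
      start = c(0L, 15L, 27L), end = c(5L, 26L, 33L),
      text = c("onkel", "hjertestans", "i fjor")),
    relations = data.frame(id = "R1", label = "Holder", arg1 = "T2", arg2 = "T1"))
}

test_that("candidates are all unordered within-sentence pairs with gold labels", {
  cands <- generate_candidates(three_entity_doc())
  expect_identical(nrow(cands), 3L)  # C(3,2)
  expect_identical(sort(cands$gold_label), c("Holder", "No_Relation", "No_Relation"))
  # canonical order is surface order; the Holder gold ran T2 -> T1
  h <- cands[cands$gold_label == "Holder", ]
  expect_identical(h$arg1, "T1")
  expect_identical(h$arg2, "T2")
  expect_identical(h$gold_dir, -1L)

  one <- fh_document("one", "mor.", entities = data.frame(
    id = "T1", label = "FAMILY", start = 0L, end = 3L, text = "mor"))
  expect_identical(nrow(generate_candidates(one)), 0L)
})

test_that("candidate counts equal the brute-force pair enumeration", {
  for (doc in small_corpus(80, seed = 111))
    expect_identical(nrow(generate_candidates(doc)),
                     as.integer(oracle_candidate_count(doc)), info = doc$doc_id)
})

test_that("every within-sentence gold relation appears exactly once with its label", {
  for (doc in small_corpus(60, seed = 121)) {
    cands <- generate_candidates(doc)
    gold <- doc$relations
    for (i in seq_len(nrow(gold))) {
      hit <- which((cands$arg1 == gold$arg1[i] & cands$arg2 == gold$arg2[i]) |
                   (cands$arg1 == gold$arg2[i] & cands$arg2 == gold$arg1[i]))
      expect_length(hit, 1L)
      expect_identical(cands$gold_label[hit], gold$label[i])
    }
  }
})

test_that("relation training is deterministic and needs two classes", {
  corpus <- small_corpus(60, seed = 131)
  m1 <- train_relation_model(corpus, seed = 3)
  m2 <- train_relation_model(corpus, seed = 3)
  test <- small_corpus(10, seed = 132)
  for (d in test)
    expect_identical(classify_candidates(m1, d)$pred_label,
                     classify_candidates(m2, d)$pred_label)
  expect_error(train_relation_model(list(tiny_doc())), "2 distinct")
})

test_that("predicted relations conserve candidate counts and respect the schema filter", {
  corpus <- small_corpus(80, seed = 141)
  model <- train_relation_model(corpus, seed = 1)
  for (doc in small_corpus(15, seed = 142)) {
    cands <- classify_candidates(model, doc)
    pred <- predict_relations(model, doc)
    expect_identical(nrow(pred$relations),
                     sum(cands$pred_label != "No_Relation"))
    filtered <- predict_relations(model, doc, schema_filter = TRUE)
    if (nrow(filtered$relations) > 0) {
      labs <- stats::setNames(filtered$entities$label, filtered$entities$id)
      ok <- vapply(seq_len(nrow(filtered$relations)), function(i)
        allowed_relation(filtered$relations$label[i],
                         labs[filtered$relations$arg1[i]],
                         labs[filtered$relations$arg2[i]]), logical(1))
      expect_true(all(ok))
    }
  }
  empty <- fh_document("e", "ingen ting her.")
  expect_identical(nrow(predict_relations(model, empty)$relations), 0L)
})

test_that("gold entity labels outperform predicted labels on held-out synthetic data", {
  train <- small_corpus(150, seed = 151)
  test <- small_corpus(40, seed = 152)
  tagger <- suppressWarnings(train_tagger(train, seed = 1))
  f1_of <- function(labels_source) {
    m <- train_relation_model(train, labels_source = labels_source,
                              tagger = tagger, seed = 1)
    g <- character(); p <- character()
    for (d in test) {
      cc <- classify_candidates(m, d, tagger)
      g <- c(g, cc$gold_label); p <- c(p, cc$pred_label)
    }
    weighted_prf(g, p)$weighted["f1"]
  }
  expect_gte(f1_of("gold") + 0.02, f1_of("predicted"))
})
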