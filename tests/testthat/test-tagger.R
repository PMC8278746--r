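doc_with_labels <- function(text, labels) {
  doc <- fh_document("d", text)
  doc$entities <- tokens_to_entities(labels, doc$tokens, text = text)
  doc
}

test_that("the dictionary stores the modal label per word", {
  docs <- list(
    doc_with_labels("mor mor mor ukjent", c("FAMILY", "FAMILY", "FAMILY", "O")),
    doc_with_labels("mor ukjent", c("O", "O")))
  dict <- build_dictionary(docs)
  expect_identical(unname(unclass(dict)["mor"]), "FAMILY")    # 3 FAMILY vs 1 O
  expect_identical(unname(unclass(dict)["ukjent"]), "O")
})

test_that("dictionary ties break by lexicographic label order", {
  docs <- list(doc_with_labels("slag slag slag slag",
                               c("CONDITION", "EVENT", "EVENT", "CONDITION")))
  expect_message(dict <- build_dictionary(docs), "tie")
  expect_identical(unname(unclass(dict)["slag"]), "CONDITION")
})

test_that("out-of-dictionary words are tagged O and empty input handled", {
  dict <- build_dictionary(list(tiny_doc()))
  unseen <- tokenize_text("helt nye ord her")
  expect_identical(dictionary_tag(unseen, dict), rep("O", 4))
  expect_identical(dictionary_tag(tokenize_text(""), dict), character())
  expect_error(build_dictionary(list()), "empty")
})

test_that("a dictionary reproduces gold labels on label-unambiguous training text", {
  corpus <- small_corpus(40, seed = 61, ambiguity = 0)
  dict <- build_dictionary(corpus)
  for (doc in corpus[1:10]) {
    gold <- unlist(project_entities_to_tokens(doc), use.names = FALSE)
    expect_identical(dictionary_tag(doc$tokens, dict), gold, info = doc$doc_id)
  }
})

test_that("tagger training is deterministic and beats the dictionary on its training set", {
  corpus <- small_corpus(50, seed = 71)
  tg1 <- suppressWarnings(train_tagger(corpus, seed = 5))
  tg2 <- suppressWarnings(train_tagger(corpus, seed = 5))
  held <- small_corpus(10, seed = 72)
  p1 <- lapply(held, function(d) tag_document(tg1, d))
  p2 <- lapply(held, function(d) tag_document(tg2, d))
  expect_identical(p1, p2)

  dict <- build_dictionary(corpus)
  gold <- unlist(lapply(corpus, function(d)
    unlist(project_entities_to_tokens(d), use.names = FALSE)))
  pred_svm <- unlist(lapply(corpus, function(d) tag_document(tg1, d)))
  pred_dict <- unlist(lapply(corpus, function(d) dictionary_tag(d$tokens, dict)))
  expect_gte(mean(pred_svm == gold), mean(pred_dict == gold))
})

test_that("a class absent from training triggers a warning but prediction still works", {
  corpus <- list(tiny_doc(), doc_with_labels("far har synkope.",
                                             c("FAMILY", "O", "EVENT", "O")))
  expect_warning(tg <- train_tagger(corpus), "absent")
  expect_length(greedy_decode(tg, tiny_doc()$tokens), 4L)
})

test_that("greedy decoding is left-to-right with no cross-sentence leakage", {
  corpus <- small_corpus(30, seed = 81)
  tg <- suppressWarnings(train_tagger(corpus[1:25], seed = 1))
  target <- corpus[[26]]
  alone <- tag_document(tg, target)
  # decode the same sentence inside two different batch orderings
  batchA <- greedy_decode_batch(tg, list(target$tokens, corpus[[27]]$tokens))
  batchB <- greedy_decode_batch(tg, list(corpus[[28]]$tokens, target$tokens))
  expect_identical(batchA[[1]], alone[[1]])
  expect_identical(batchB[[2]], alone[[1]])
  # output length always equals input length
  for (d in corpus[26:30])
    expect_length(greedy_decode(tg, d$tokens), nrow(d$tokens))
})

test_that("fully unseen sentences fall back to the model's prior-preferred class", {
  corpus <- small_corpus(30, seed = 91)
  tg <- suppressWarnings(train_tagger(corpus, seed = 1))
  unseen <- tokenize_text("xxqq zzpp yyrr")
  out <- greedy_decode(tg, unseen)
  expect_length(out, 3L)
  expect_true(all(out %in% token_labels()))
})

test_that("condition/event confusion tracks the lexicon ambiguity rate", {
  ce_confusions <- function(ambiguity) {
    train <- generate_corpus(fh_generator_config(n_sentences = 200,
                                                 ambiguity = ambiguity),
                             seed = 501)$corpus
    test <- generate_corpus(fh_generator_config(n_sentences = 80,
                                                ambiguity = ambiguity),
                            seed = 502)$corpus
    tg <- suppressWarnings(train_tagger(train, seed = 1))
    gold <- unlist(lapply(test, function(d)
      unlist(project_entities_to_tokens(d), use.names = FALSE)))
    pred <- unlist(lapply(test, function(d) unlist(tag_document(tg, d))))
    cm <- confusion(gold, pred, token_labels())
    ce <- cm["CONDITION", "EVENT"] + cm["EVENT", "CONDITION"]
    c(ce = ce, other = sum(cm) - sum(diag(cm)) - ce)
  }
  disjoint <- ce_confusions(0)
  expect_identical(unname(disjoint["ce"]), 0L)
  overlapping <- ce_confusions(1)
  expect_gt(overlapping["ce"], 0L)
  expect_gte(overlapping["ce"], overlapping["other"])
})

test_that("condition/event merging is idempotent and leaves other labels alone", {
  expect_identical(merge_condition_event(c("CONDITION", "EVENT", "O")),
                   c("CONDITION_EVENT", "CONDITION_EVENT", "O"))
  x <- c("FAMILY", "EVENT", "SIDE")
  expect_identical(merge_condition_event(merge_condition_event(x)),
                   merge_condition_event(x))
  expect_identical(merge_condition_event(list(c("SELF", "CONDITION"))),
                   list(c("SELF", "CONDITION_EVENT")))
})

test_that("merging does not change FAMILY and SELF scores", {
  corpus <- small_corpus(80, seed = 101)
  cv <- suppressWarnings(cross_validate(corpus, "entity", k = 3, seed = 2))
  cvm <- suppressWarnings(cross_validate(corpus, "entity", k = 3, seed = 2,
                                         merge_condition_event = TRUE))
  for (f in 1:3) {
    a <- cv$folds[[f]]$metrics$svm_incl_o$per_class
    b <- cvm$folds[[f]]$metrics$svm_incl_o$per_class
    for (lab in c("FAMILY", "SELF")) {
      if (lab %in% a$label && lab %in% b$label)
        expect_equal(a$f1[a$label == lab], b$f1[b$label == lab], tolerance = 1e-12)
    }
  }
})
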