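test_that("entity feature bags have the template-determined size and content", {
  tok <- tokenize_text("hjertestans")
  bag <- entity_features(tok, 1)
  # 5 word-window + 5 POS-window + 2 previous-tag features
  expect_length(bag, 12L)
  expect_true("w[+0]=hjertestans" %in% bag)
  expect_identical(sum(grepl("=<BOS>", bag[grep("^w", bag)])), 2L)
  expect_identical(sum(grepl("=<EOS>", bag[grep("^w", bag)])), 2L)
  expect_true(all(c("t[-2]=<BOS>", "t[-1]=<BOS>") %in% bag))

  with_bigram <- entity_features(tok, 1, prev_tags = c("O", "FAMILY"),
                                 config = fh_feature_config(prevtag_bigram = TRUE))
  expect_length(with_bigram, 13L)
  expect_true("t[-2,-1]=O|FAMILY" %in% with_bigram)
})

test_that("affix features are 3-character prefixes and suffixes", {
  tok <- tokenize_text("hjertestans")
  bag <- entity_features(tok, 1, config = fh_feature_config(affixes = TRUE))
  expect_true("pre3=hje" %in% bag)
  expect_true("suf3=ans" %in% bag)
})

test_that("identical inputs produce identical bags", {
  doc <- small_corpus(3, seed = 2)[[1]]
  tok <- doc$tokens
  expect_identical(entity_features(tok, 2, c("FAMILY", "O")),
                   entity_features(tok, 2, c("FAMILY", "O")))
})

relation_fixture <- function() {
  doc <- fh_document("r", "onkel har hatt hjertestans.", entities = data.frame(
    id = c("T1", "T2"), label = c("FAMILY", "EVENT"),
    start = c(0L, 15L), end = c(5L, 26L), text = c("onkel", "hjertestans")))
  doc$tokens$upos <- c("NOUN", "AUX", "VERB", "NOUN", "PUNCT")
  doc$tokens$deprel <- c("nsubj", "aux", "root", "obj", "punct")
  doc
}

test_that("relation bags carry slot-namespaced word, POS, dep and label features", {
  doc <- relation_fixture()
  e1 <- doc$entities[1, ]; e2 <- doc$entities[2, ]
  bag <- relation_features(doc$tokens, e1, e2, "gold",
                           fh_feature_config(relation_level = "labels"))
  expect_true(all(c("a1.w=onkel", "a2.w=hjertestans",
                    "a1.p=NOUN", "a2.p=NOUN", "a1.d=nsubj", "a2.d=obj",
                    "a1.l=FAMILY", "a2.l=EVENT") %in% bag))
  words_only <- relation_features(doc$tokens, e1, e2, "gold",
                                  fh_feature_config(relation_level = "words"))
  expect_identical(sort(words_only), c("a1.w=onkel", "a2.w=hjertestans"))
  no_labels <- relation_features(doc$tokens, e1, e2, "none",
                                 fh_feature_config(relation_level = "labels"))
  expect_false(any(grepl("\\.l=", no_labels)))
})

test_that("multi-word entities contribute one concatenated feature per template", {
  doc <- fh_document("m", "den ene har mutasjonen.", entities = data.frame(
    id = c("T1", "T2"), label = c("FAMILY", "CONDITION"),
    start = c(0L, 12L), end = c(7L, 22L), text = c("den ene", "mutasjonen")))
  bag <- relation_features(doc$tokens, doc$entities[1, ], doc$entities[2, ],
                           "gold", fh_feature_config(relation_level = "words"))
  expect_true("a1.w=den_ene" %in% bag)
  expect_false(any(grepl("a1.w=den$", bag)))
})

test_that("swapping the argument slots changes the bag", {
  doc <- relation_fixture()
  fwd <- relation_features(doc$tokens, doc$entities[1, ], doc$entities[2, ])
  rev <- relation_features(doc$tokens, doc$entities[2, ], doc$entities[1, ])
  expect_false(setequal(fwd, rev))
})

test_that("the vocabulary freezes at fit time and unknown keys vanish", {
  vocab <- fit_vocabulary(list(c("a", "b"), "c"))
  expect_length(vocab$keys, 3L)
  x <- vectorize(list(c("a", "c", "zz")), vocab)
  expect_identical(Matrix::rowSums(x)[[1]], 2)
  expect_identical(ncol(x), 3L)
  # duplicates count once; empty bag gives a zero row
  y <- vectorize(list(c("a", "a"), character()), vocab)
  expect_identical(unname(Matrix::rowSums(y)), c(1, 0))
  expect_error(vectorize(list("a"), list()), "vocabulary")
})

test_that("test-fold keys never extend a fitted vocabulary", {
  corpus <- small_corpus(30, seed = 51)
  bags_train <- unlist(lapply(corpus[1:20], function(d) {
    lapply(seq_len(nrow(d$tokens)), function(i) entity_features(d$tokens, i))
  }), recursive = FALSE)
  vocab <- fit_vocabulary(bags_train)
  size_before <- length(vocab$keys)
  for (d in corpus[21:30]) {
    x <- vectorize(lapply(seq_len(nrow(d$tokens)),
                          function(i) entity_features(d$tokens, i)), vocab)
    expect_identical(ncol(x), size_before)
  }
})
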