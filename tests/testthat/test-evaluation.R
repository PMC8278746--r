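test_that("weighted metrics match hand-computed values on a worked example", {
  m <- weighted_prf(c("A", "A", "B", "O"), c("A", "B", "B", "O"))
  a <- m$per_class[m$per_class$label == "A", ]
  expect_equal(a$precision, 1)
  expect_equal(a$recall, 0.5)
  expect_equal(a$f1, 2 / 3)
  expect_equal(unname(m$weighted["f1"]), 0.75)  # (2*2/3 + 1*2/3 + 1*1)/4

  ident <- weighted_prf(c("A", "B"), c("A", "B"))
  expect_equal(unname(ident$weighted), c(1, 1, 1))
})

test_that("weighted metrics and confusion agree with a brute-force oracle", {
  set.seed(42)
  labels <- c("FAMILY", "CONDITION", "EVENT", "O")
  for (rep in 1:200) {
    n <- sample(3:30, 1)
    gold <- sample(labels, n, replace = TRUE)
    pred <- sample(labels, n, replace = TRUE)
    excl <- if (rep %% 2 == 0) "O" else character()
    expect_equal(unname(weighted_prf(gold, pred, exclude = excl)$weighted),
                 unname(oracle_prf(gold, pred, exclude = excl)),
                 tolerance = 1e-12)
    cm <- confusion(gold, pred, labels)
    for (g in labels) for (p in labels)
      expect_identical(cm[g, p], sum(gold == g & pred == p))
  }
})

test_that("excluding a label changes only the weighted average", {
  gold <- c("A", "A", "B", "O", "O", "O")
  pred <- c("A", "B", "B", "O", "O", "O")
  incl <- weighted_prf(gold, pred)
  excl <- weighted_prf(gold, pred, exclude = "O")
  expect_identical(incl$per_class, excl$per_class)
  expect_false(isTRUE(all.equal(incl$weighted, excl$weighted)))
})

test_that("a predicted-only class has zero recall by convention", {
  m <- weighted_prf(c("A", "A"), c("A", "B"))
  b <- m$per_class[m$per_class$label == "B", ]
  expect_identical(b$support, 0L)
  expect_equal(b$recall, 0)
  expect_error(weighted_prf(c("A"), c("A", "B")), "length")
})

test_that("confusion rows sum to gold supports", {
  set.seed(7)
  gold <- sample(LETTERS[1:4], 50, replace = TRUE)
  pred <- sample(LETTERS[1:4], 50, replace = TRUE)
  cm <- confusion(gold, pred)
  expect_equal(unname(rowSums(cm)),
               as.vector(table(factor(gold, levels = LETTERS[1:4]))),
               ignore_attr = TRUE)
  expect_identical(sum(cm), 50L)
  diag_cm <- confusion(gold, gold)
  expect_identical(sum(diag_cm) - sum(diag(diag_cm)), 0L)
})

test_that("the paired t-test matches the textbook formula and handles degeneracy", {
  a <- c(0.80, 0.82, 0.79, 0.85, 0.81)
  b <- c(0.78, 0.80, 0.76, 0.80, 0.80)
  res <- paired_t_test(a, b)
  d <- a - b
  t_manual <- mean(d) / (sd(d) / sqrt(length(d)))
  p_manual <- 2 * pt(-abs(t_manual), length(d) - 1)
  expect_equal(res$t, t_manual, tolerance = 1e-12)
  expect_equal(res$p, p_manual, tolerance = 1e-12)
  expect_false(res$degenerate)

  same <- paired_t_test(c(1, 2, 3), c(1, 2, 3))
  expect_true(same$degenerate)
  expect_identical(same$p, 1)
  shifted <- paired_t_test(c(2, 3, 4), c(1, 2, 3))
  expect_true(shifted$degenerate)
  expect_identical(shifted$p, 0)
  expect_error(paired_t_test(1, 1), "at least 2")
  expect_error(paired_t_test(1:3, 1:4), "equal length")
})

test_that("inter-annotator agreement scores exact span+label matches", {
  a <- tiny_doc()
  expect_equal(unname(iaa(a, a)), c(1, 1, 1))

  b <- a
  b$entities$label[2] <- "CONDITION"  # same spans, one label differs
  expect_equal(unname(iaa(a, b)), c(0.5, 0.5, 0.5))

  c_ <- a
  c_$entities$start <- c(4L, 4L); c_$entities$end <- c(7L, 7L)
  c_$entities <- c_$entities[1, ]
  c_$relations <- c_$relations[0, ]
  expect_equal(unname(iaa(a, c_)), c(0, 0, 0))

  other <- fh_document("x", "Helt annen tekst.")
  expect_error(iaa(a, other), "different texts")
})

test_that("cross-validation partitions sentences and is seed-deterministic", {
  corpus <- small_corpus(40, seed = 161)
  cv1 <- suppressWarnings(cross_validate(corpus, "entity", k = 4, seed = 9))
  cv2 <- suppressWarnings(cross_validate(corpus, "entity", k = 4, seed = 9))
  expect_equal(cv1$mean, cv2$mean, tolerance = 1e-12)
  sizes <- vapply(cv1$folds, function(f) f$n_test, integer(1))
  expect_identical(sum(sizes), 40L)
  expect_true(all(sizes == 10L))
  expect_error(cross_validate(corpus, "entity", k = 1), "at least 2")
  expect_error(cross_validate(corpus, "entity", k = 100), "exceeds")
})

test_that("relation cross-validation reports six-class weighted metrics", {
  corpus <- small_corpus(60, seed = 171)
  cv <- suppressWarnings(cross_validate(corpus, "relation", k = 3, seed = 4))
  expect_identical(nrow(cv$mean), 1L)
  expect_true(cv$mean$f1 > 0 && cv$mean$f1 <= 1)
  labs <- cv$folds[[1]]$metrics$relation$per_class$label
  expect_true(all(labs %in% relation_labels()))
})
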