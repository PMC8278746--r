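test_that("pedigree simulation is seed-deterministic and respects penetrance", {
  cfg <- fh_generator_config(n_sentences = 5)
  p1 <- simulate_pedigree(cfg, seed = 13)
  p2 <- simulate_pedigree(cfg, seed = 13)
  expect_identical(p1$members, p2$members)
  expect_identical(sum(p1$members$carrier[p1$members$generation == 1]), 1L)

  none <- simulate_pedigree(fh_generator_config(n_sentences = 5, penetrance = 0),
                            seed = 17)
  expect_false(any(none$members$affected))
  expect_true(all(is.na(none$members$condition)))
})

test_that("carriers manifest disease at the configured penetrance rate", {
  cfg <- fh_generator_config(n_sentences = 1, penetrance = 0.8)
  carriers <- 0L; affected <- 0L
  for (s in 1:500) {
    ped <- simulate_pedigree(cfg, seed = 1000 + s)
    carriers <- carriers + sum(ped$members$carrier)
    affected <- affected + sum(ped$members$affected)
  }
  expect_lt(abs(affected / carriers - 0.8), 0.05)
})

test_that("carrier status follows parent-child transmission only", {
  cfg <- fh_generator_config(n_sentences = 1)
  for (s in 1:50) {
    ped <- simulate_pedigree(cfg, seed = 2000 + s)
    m <- ped$members
    carrier <- stats::setNames(m$carrier, m$id)
    for (id in m$id[m$generation > 1]) {
      pa <- ped$parents$parent[ped$parents$child == id]
      if (!any(carrier[pa])) expect_false(carrier[[id]])
    }
  }
})

test_that("every generated document is schema-valid with exact offsets", {
  corpus <- small_corpus(120, seed = 181)
  for (doc in corpus) {
    expect_identical(nrow(validate_document(doc)), 0L, info = doc$doc_id)
    # surfaces match their character spans exactly
    expect_identical(doc$entities$text,
                     substr(rep(doc$text, nrow(doc$entities)),
                            doc$entities$start + 1, doc$entities$end))
  }
})

test_that("generation is byte-identical under a fixed seed and config", {
  g1 <- generate_corpus(fh_generator_config(n_sentences = 25), seed = 23)
  g2 <- generate_corpus(fh_generator_config(n_sentences = 25), seed = 23)
  expect_identical(g1$corpus, g2$corpus)
  expect_identical(g1$manifest, g2$manifest)
  g3 <- generate_corpus(fh_generator_config(n_sentences = 25), seed = 24)
  expect_false(identical(g1$corpus, g3$corpus))
})

test_that("the empirical entity mix tracks the target proportions", {
  target <- default_entity_mix()
  for (seed in c(31, 32, 33)) {
    st <- corpus_stats(generate_corpus(fh_generator_config(n_sentences = 200),
                                       seed = seed)$corpus)
    mix <- stats::setNames(st$entities$n / sum(st$entities$n), st$entities$label)
    for (lab in names(target)) {
      got <- if (lab %in% names(mix)) mix[[lab]] else 0
      expect_lt(abs(got - target[[lab]]), 0.05)
    }
    expect_identical(st$entities$label[1], "FAMILY")
  }
})

test_that("all five relation types and all ten entity labels are generated", {
  st <- corpus_stats(small_corpus(300, seed = 191))
  expect_setequal(st$relations$label,
                  setdiff(relation_labels(), "No_Relation"))
  expect_setequal(st$entities$label, entity_labels())
})

test_that("subset and negation constructions carry their relations", {
  templates <- default_templates()
  cfg <- fh_generator_config(n_sentences = 1)
  sub <- realize_template(templates$subset_cond, cfg$lexicons, NULL, "sub")
  expect_true("Subset" %in% sub$relations$label)
  expect_true("AMOUNT" %in% sub$entities$label)
  grp <- sub$entities$id[sub$entities$label == "FAMILY"]
  s <- sub$relations[sub$relations$label == "Subset", ]
  expect_true(s$arg1 %in% grp && s$arg2 %in% grp)

  neg <- realize_template(templates$self_neg_cond, cfg$lexicons, NULL, "neg")
  expect_true("NEG" %in% neg$entities$label)
  m <- neg$relations[neg$relations$label == "Modifier", ]
  expect_identical(neg$entities$label[neg$entities$id == m$arg1], "NEG")
  expect_identical(neg$entities$label[neg$entities$id == m$arg2], "CONDITION")

  par <- realize_template(templates$partner, cfg$lexicons, NULL, "par")
  expect_true("Partner" %in% par$relations$label)
})

test_that("an empty lexicon is rejected at generation time", {
  cfg <- fh_generator_config(n_sentences = 5)
  cfg$lexicons$SIDE <- character()
  expect_error(generate_corpus(cfg, seed = 1), "empty lexicon")
})

test_that("written corpora regenerate from their manifest", {
  dir <- withr::local_tempdir()
  gen <- generate_corpus(fh_generator_config(n_sentences = 8), seed = 37)
  write_corpus(gen, dir)
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  regen <- generate_corpus(
    fh_generator_config(n_sentences = man$n_sentences,
                        ambiguity = man$ambiguity,
                        penetrance = man$penetrance),
    seed = man$seed)
  expect_identical(vapply(regen$corpus, function(d) d$text, character(1)),
                   vapply(gen$corpus, function(d) d$text, character(1)))
})
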