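# Shared fixtures and independent oracles for the test suite.

# Hand-built one-sentence document: "Mor har hjertestans ." with a FAMILY
# and an EVENT entity linked by a Holder relation.
tiny_doc <- function() {
  text <- "Mor har hjertestans."
  fh_document(
    "tiny", text,
    entities = data.frame(
      id = c("T1", "T2"), label = c("FAMILY", "EVENT"),
      start = c(0L, 8L), end = c(3L, 19L),
      text = c("Mor", "hjertestans")),
    relations = data.frame(id = "R1", label = "Holder", arg1 = "T2", arg2 = "T1"))
}

small_corpus <- function(n = 40, seed = 11, ambiguity = 0.2) {
  generate_corpus(fh_generator_config(n_sentences = n, ambiguity = ambiguity),
                  seed = seed)$corpus
}

# independent brute-force precision/recall/F1 oracle: plain counting
# loops, no shared code with weighted_prf
oracle_prf <- function(gold, pred, exclude = character()) {
  classes <- sort(unique(c(gold, pred)))
  rows <- lapply(classes, function(cl) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(gold)) {
      if (pred[i] == cl && gold[i] == cl) tp <- tp + 1
      if (pred[i] == cl && gold[i] != cl) fp <- fp + 1
      if (pred[i] != cl && gold[i] == cl) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f, s = tp + fn)
  })
  tab <- do.call(rbind, rows)
  keep <- !(classes %in% exclude)
  w <- tab[keep, "s", drop = TRUE]
  if (sum(w) == 0) return(c(precision = 0, recall = 0, f1 = 0))
  c(precision = sum(tab[keep, "p"] * w) / sum(w),
    recall = sum(tab[keep, "r"] * w) / sum(w),
    f1 = sum(tab[keep, "f"] * w) / sum(w))
}

# brute-force within-sentence unordered pair enumeration
oracle_candidate_count <- function(doc) {
  tok <- doc$tokens
  total <- 0L
  for (s in unique(tok$sentence)) {
    lo <- min(tok$start[tok$sentence == s]); hi <- max(tok$end[tok$sentence == s])
    ne <- sum(doc$entities$start >= lo & doc$entities$end <= hi)
    total <- total + choose(ne, 2)
  }
  total
}

# candidate local paths where a NorSynthClinical checkout may live; the
# loader itself never downloads anything
norsynth_path <- function() {
  cands <- c(system.file("extdata", "norsynthclinical", package = "famhx"),
             file.path("..", "..", "NorSynthClinical"),
             file.path("..", "..", "..", "NorSynthClinical"))
  for (p in cands) if (nzchar(p) && dir.exists(p)) return(p)
  NA_character_
}
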