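#' Default lexicons for the synthetic family-history generator
#'
#' Norwegian-like surface forms for each entity label.  Lexicons are
#' data, not code: any list with the same shape can be passed to the
#' generator.  `ambiguity` controls cross-label lexical ambiguity between
#' CONDITION and EVENT — the fraction of a shared pool of terms that is
#' added to *both* lexicons — because condition/event confusion is the
#' dominant error class this generator must be able to reproduce.
#'
#' @param ambiguity fraction in \[0,1\] of the shared condition/event
#'   pool injected into both lexicons (default 0.2).
#' @return Named list of character vectors, one per entity label, plus
#'   the auxiliary pools `FAMILY_PLURAL`, `FAMILY_SUBSET` and
#'   `PARTNER_TERM` used by specific sentence templates.
#' @export
default_lexicons <- function(ambiguity = 0.2) {
  lex <- list(
    FAMILY = c("mor", "far", "bror", "onkel", "tante", "bestefar", "bestemor",
               "mormor", "farfar", "fetter", "kusine", "datter", "søster", "sønn"),
    FAMILY_PLURAL = c("brødre", "søstre", "søsken"),
    FAMILY_SUBSET = c("den ene", "den yngste"),
    PARTNER_TERM = c("ektemann", "kone", "samboer"),
    SELF = c("pasienten", "hun", "han"),
    INDEX = c("indekspasienten"),
    CONDITION = c("koronarsykdom", "hjertesykdom", "kardiomyopati", "atrieflimmer",
                  "diabetes", "hjertesvikt", "mutasjonen", "hypertrofi",
                  "genetisk hjertesykdom", "nedsatt pumpefunksjon"),
    EVENT = c("hjertestans", "synkope", "hjerteinfarkt", "slag", "besvimelse",
              "plutselig død", "nærdrukning"),
    SIDE = c("farssiden", "morssiden", "mors side"),
    AGE = c("40 år gammel", "50 år gammel", "60 år gammel", "55 år"),
    NEG = c("ikke", "aldri", "ingen", "ikke lenger"),
    AMOUNT = c("to", "tre", "fire", "mange", "flere", "fire-fem"),
    TEMPORAL = c("i fjor", "i sommer", "for en tid tilbake",
                 "de siste månedene", "i barndommen", "nylig"))
  stopifnot(ambiguity >= 0, ambiguity <= 1)
  shared_pool <- c("arytmi", "hjerteflimmer", "kollaps", "blodpropp", "anfall")
  n_shared <- round(ambiguity * length(shared_pool))
  if (n_shared > 0) {
    shared <- shared_pool[seq_len(n_shared)]
    lex$CONDITION <- c(lex$CONDITION, shared)
    lex$EVENT <- c(lex$EVENT, shared)
  }
  lex
}

#' Generator configuration
#'
#' @param n_sentences number of sentences to generate.
#' @param lexicons lexicon list (see [default_lexicons()]).
#' @param ambiguity condition/event lexical ambiguity rate, used when
#'   `lexicons` is `NULL`.
#' @param penetrance probability that a mutation carrier in a simulated
#'   pedigree manifests disease.
#' @param target_mix named numeric vector of target entity-label
#'   proportions; the default follows the label distribution of the
#'   reference synthetic corpus (FAMILY most frequent, then CONDITION,
#'   EVENT, SELF, ...).
#' @param sentences_per_pedigree how many sentences are drawn from one
#'   simulated family before a fresh pedigree is simulated.
#' @return A list of class `fh_generator_config`.
#' @export
fh_generator_config <- function(n_sentences = 477, lexicons = NULL,
                                ambiguity = 0.2, penetrance = 0.8,
                                target_mix = default_entity_mix(),
                                sentences_per_pedigree = 25L) {
  if (is.null(lexicons)) lexicons <- default_lexicons(ambiguity)
  for (need in c("FAMILY", "SELF", "CONDITION", "EVENT"))
    if (length(lexicons[[need]]) == 0) stop("lexicon for ", need, " must be non-empty")
  structure(list(n_sentences = as.integer(n_sentences), lexicons = lexicons,
                 ambiguity = ambiguity, penetrance = penetrance,
                 target_mix = target_mix / sum(target_mix),
                 sentences_per_pedigree = as.integer(sentences_per_pedigree)),
            class = "fh_generator_config")
}

#' @rdname fh_generator_config
#' @export
default_entity_mix <- function() {
  # proportions of the reference corpus distribution table
  c(FAMILY = 1704, CONDITION = 681, EVENT = 542, SELF = 509, AMOUNT = 273,
    TEMPORAL = 214, NEG = 131, AGE = 57, SIDE = 36, INDEX = 7) / 4154
}

#' Simulate a small family pedigree with autosomal-dominant disease
#'
#' Builds a fixed three-generation kinship graph (four grandparents, the
#' parents plus an uncle and an aunt, the patient with two siblings and
#' two cousins), picks one founder grandparent as the mutation carrier,
#' and propagates carrier status down parent-child links with probability
#' 0.5 per child, the autosomal-dominant transmission rule.  Carriers
#' manifest disease with probability `penetrance`, in which case they are
#' assigned a condition and/or event term from the lexicons.
#'
#' @param config an [fh_generator_config()].
#' @param seed integer seed; the pedigree is deterministic given the
#'   seed.
#' @return An `fh_pedigree`: `members` data frame (id, kin, generation,
#'   sex, side, carrier, affected, condition, event), `partners`,
#'   `parents` (parent/child edges), `self_id`, `index_id`.
#' @export
simulate_pedigree <- function(config = fh_generator_config(), seed = 1L) {
  set.seed(seed)
  m <- data.frame(
    id = c("mormor", "morfar", "farmor", "farfar",
           "mor", "far", "onkel", "tante",
           "self", "bror", "soster", "fetter", "kusine"),
    kin = c("mormor", "bestefar", "bestemor", "farfar",
            "mor", "far", "onkel", "tante",
            "pasienten", "bror", "søster", "fetter", "kusine"),
    generation = c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 3L, 3L, 3L),
    sex = c("F", "M", "F", "M", "F", "M", "M", "F", sample(c("F", "M"), 1),
            "M", "F", "M", "F"),
    side = c("mor", "mor", "far", "far", "mor", "far", "far", "mor",
             NA, NA, NA, "far", "mor"))
  partners <- data.frame(a = c("mormor", "farmor", "mor"),
                         b = c("morfar", "farfar", "far"))
  parents <- data.frame(
    parent = c("mormor", "morfar", "farmor", "farfar", "farmor", "farfar",
               "mormor", "morfar", "mor", "far", "mor", "far", "mor", "far",
               "onkel", "tante"),
    child = c("mor", "mor", "far", "far", "onkel", "onkel", "tante", "tante",
              "self", "self", "bror", "bror", "soster", "soster",
              "fetter", "kusine"))
  founder <- sample(c("mormor", "morfar", "farmor", "farfar"), 1)
  carrier <- stats::setNames(rep(FALSE, nrow(m)), m$id)
  carrier[founder] <- TRUE
  for (gen in 2:3) {
    for (id in m$id[m$generation == gen]) {
      pa <- parents$parent[parents$child == id]
      if (any(carrier[pa])) carrier[id] <- stats::runif(1) < 0.5
    }
  }
  m$carrier <- unname(carrier[m$id])
  m$affected <- m$carrier & stats::runif(nrow(m)) < config$penetrance
  m$condition <- ifelse(m$affected,
                        sample(config$lexicons$CONDITION, nrow(m), replace = TRUE),
                        NA_character_)
  m$event <- ifelse(m$affected & stats::runif(nrow(m)) < 0.6,
                    sample(config$lexicons$EVENT, nrow(m), replace = TRUE),
                    NA_character_)
  structure(list(members = m, partners = partners, parents = parents,
                 self_id = "self",
                 index_id = m$id[which(m$affected & m$id != "self")[1]]),
            class = "fh_pedigree")
}

#' @export
print.fh_pedigree <- function(x, ...) {
  cat(sprintf("<fh_pedigree> %d members, %d carrier(s), %d affected; index: %s\n",
              nrow(x$members), sum(x$members$carrier), sum(x$members$affected),
              if (is.na(x$index_id)) "none" else x$index_id))
  invisible(x)
}

# --- sentence templates -----------------------------------------------------

lex_slot <- function(label, role = NULL, pool = NULL, upos = NULL, deprel = NULL) {
  defaults <- list(
    FAMILY = c("NOUN", "nsubj"), SELF = c("PRON", "nsubj"),
    INDEX = c("NOUN", "nsubj"), CONDITION = c("NOUN", "obj"),
    EVENT = c("NOUN", "obj"), SIDE = c("NOUN", "nmod"),
    AGE = c("NUM", "nmod"), NEG = c("ADV", "advmod"),
    AMOUNT = c("NUM", "nummod"), TEMPORAL = c("ADV", "advmod"))
  d <- defaults[[label]]
  list(type = "lex", label = label, role = role %||% label,
       pool = pool %||% label,
       upos = upos %||% d[1], deprel = deprel %||% d[2])
}

lit_slot <- function(text, upos = "VERB", deprel = "root") {
  list(type = "lit", text = text, upos = upos, deprel = deprel)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Default sentence templates
#'
#' Each template is a list of slots (lexicon-filled entity slots and
#' literal function words) plus the relations holding between the entity
#' slots.  Together the templates cover all ten entity labels and all
#' five relation types, including the subset construction ("two
#' brothers, one of them ..."), partner couples, negation, temporal,
#' amount, age and side modifiers.
#'
#' @return List of template objects.
#' @export
default_templates <- function() {
  P <- function() lit_slot(".", "PUNCT", "punct")
  CM <- function() lit_slot(",", "PUNCT", "punct")
  t <- list()
  t$fam_cond <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("har", "VERB", "root"),
                 lex_slot("CONDITION"), P()),
    rels = list(c("Holder", "CONDITION", "FAMILY")))
  t$fam_cond_side <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("på", "ADP", "case"),
                 lex_slot("SIDE"), lit_slot("har", "VERB", "root"),
                 lex_slot("CONDITION"), P()),
    rels = list(c("Holder", "CONDITION", "FAMILY"),
                c("Modifier", "SIDE", "FAMILY")))
  t$fam_event <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("har", "AUX", "aux"),
                 lit_slot("hatt", "VERB", "root"), lex_slot("EVENT"), P()),
    rels = list(c("Holder", "EVENT", "FAMILY")))
  t$fam_event_temporal <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("fikk", "VERB", "root"),
                 lex_slot("EVENT"), lex_slot("TEMPORAL"), P()),
    rels = list(c("Holder", "EVENT", "FAMILY"),
                c("Modifier", "TEMPORAL", "EVENT")))
  t$fam_event_age <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("fikk", "VERB", "root"),
                 lex_slot("EVENT"), lex_slot("AGE"), P()),
    rels = list(c("Holder", "EVENT", "FAMILY"),
                c("Modifier", "AGE", "FAMILY")))
  # a condition in the perfect-tense context shared with events: with an
  # ambiguous lexicon this context no longer disambiguates, reproducing
  # the condition/event confusion structure of real annotation
  t$fam_cond_hatt <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("har", "AUX", "aux"),
                 lit_slot("hatt", "VERB", "root"), lex_slot("CONDITION"), P()),
    rels = list(c("Holder", "CONDITION", "FAMILY")))
  t$self_cond <- list(
    slots = list(lex_slot("SELF"), lit_slot("har", "VERB", "root"),
                 lex_slot("CONDITION"), P()),
    rels = list(c("Holder", "CONDITION", "SELF")))
  t$self_neg_cond <- list(
    slots = list(lex_slot("SELF"), lit_slot("har", "VERB", "root"),
                 lex_slot("NEG"), lit_slot("påvist", "VERB", "xcomp"),
                 lex_slot("CONDITION"), P()),
    rels = list(c("Holder", "CONDITION", "SELF"),
                c("Modifier", "NEG", "CONDITION")))
  t$fam_neg_event <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("har", "AUX", "aux"),
                 lex_slot("NEG"), lit_slot("hatt", "VERB", "root"),
                 lex_slot("EVENT"), P()),
    rels = list(c("Holder", "EVENT", "FAMILY"),
                c("Modifier", "NEG", "EVENT")))
  t$self_event_temporal <- list(
    slots = list(lex_slot("SELF"), lit_slot("har", "AUX", "aux"),
                 lit_slot("kjent", "VERB", "root"), lex_slot("EVENT"),
                 lex_slot("TEMPORAL"), P()),
    rels = list(c("Holder", "EVENT", "SELF"),
                c("Modifier", "TEMPORAL", "EVENT")))
  t$fam_related_event <- list(
    slots = list(lex_slot("FAMILY", role = "F1"), lit_slot("sin", "ADP", "case"),
                 lex_slot("FAMILY", role = "F2"), lit_slot("har", "AUX", "aux"),
                 lit_slot("hatt", "VERB", "root"), lex_slot("EVENT"), P()),
    rels = list(c("Related_to", "F2", "F1"),
                c("Holder", "EVENT", "F2")))
  t$fam_related_cond <- list(
    slots = list(lex_slot("FAMILY", role = "F1"), lit_slot("til", "ADP", "case"),
                 lex_slot("FAMILY", role = "F2"), lit_slot("har", "VERB", "root"),
                 lex_slot("CONDITION"), P()),
    rels = list(c("Related_to", "F1", "F2"),
                c("Holder", "CONDITION", "F1")))
  t$subset_cond <- list(
    slots = list(lex_slot("SELF"), lit_slot("har", "VERB", "root"),
                 lex_slot("AMOUNT"), lex_slot("FAMILY", role = "Fgrp", pool = "FAMILY_PLURAL"),
                 CM(), lex_slot("FAMILY", role = "Fsub", pool = "FAMILY_SUBSET",
                                upos = "PRON", deprel = "nsubj"),
                 lit_slot("har", "VERB", "conj"), lex_slot("CONDITION"), P()),
    rels = list(c("Modifier", "AMOUNT", "Fgrp"),
                c("Subset", "Fsub", "Fgrp"),
                c("Holder", "CONDITION", "Fsub")))
  t$subset_event <- list(
    slots = list(lex_slot("SELF"), lit_slot("har", "VERB", "root"),
                 lex_slot("AMOUNT"), lex_slot("FAMILY", role = "Fgrp", pool = "FAMILY_PLURAL"),
                 CM(), lex_slot("FAMILY", role = "Fsub", pool = "FAMILY_SUBSET",
                                upos = "PRON", deprel = "nsubj"),
                 lit_slot("fikk", "VERB", "conj"), lex_slot("EVENT"), P()),
    rels = list(c("Modifier", "AMOUNT", "Fgrp"),
                c("Subset", "Fsub", "Fgrp"),
                c("Holder", "EVENT", "Fsub")))
  t$partner <- list(
    slots = list(lex_slot("FAMILY", role = "F1"), lit_slot("og", "CCONJ", "cc"),
                 lit_slot("hennes", "PRON", "nmod"),
                 lex_slot("FAMILY", role = "F2", pool = "PARTNER_TERM"),
                 lit_slot("har", "VERB", "root"), lex_slot("AMOUNT"),
                 lex_slot("FAMILY", role = "F3", pool = "FAMILY_PLURAL",
                          deprel = "obj"), P()),
    rels = list(c("Partner", "F1", "F2"),
                c("Modifier", "AMOUNT", "F3")))
  t$index_event <- list(
    slots = list(lex_slot("INDEX"), lit_slot("er", "AUX", "cop"),
                 lit_slot("hans", "PRON", "nmod"), lex_slot("FAMILY"),
                 lit_slot("på", "ADP", "case"), lex_slot("SIDE"), CM(),
                 lit_slot("som", "PRON", "nsubj"), lit_slot("hadde", "VERB", "acl"),
                 lex_slot("EVENT"), P()),
    rels = list(c("Holder", "EVENT", "FAMILY"),
                c("Modifier", "SIDE", "FAMILY")))
  t$two_fam_cond <- list(
    slots = list(lit_slot("Både", "CCONJ", "cc"), lex_slot("FAMILY", role = "F1"),
                 lit_slot("og", "CCONJ", "cc"), lex_slot("FAMILY", role = "F2"),
                 lit_slot("har", "VERB", "root"), lex_slot("CONDITION"), P()),
    rels = list(c("Holder", "CONDITION", "F1"),
                c("Holder", "CONDITION", "F2")))
  t$amount_fam_cond <- list(
    slots = list(lex_slot("AMOUNT"), lit_slot("av", "ADP", "case"),
                 lit_slot("hans", "PRON", "nmod"),
                 lex_slot("FAMILY", pool = "FAMILY_PLURAL"),
                 lit_slot("har", "VERB", "root"), lex_slot("CONDITION"), P()),
    rels = list(c("Modifier", "AMOUNT", "FAMILY"),
                c("Holder", "CONDITION", "FAMILY")))
  t$fam_cond_age <- list(
    slots = list(lex_slot("FAMILY"), lit_slot("fikk", "AUX", "aux"),
                 lit_slot("påvist", "VERB", "root"), lex_slot("CONDITION"),
                 lex_slot("AGE"), P()),
    rels = list(c("Holder", "CONDITION", "FAMILY"),
                c("Modifier", "AGE", "FAMILY")))
  for (nm in names(t)) t[[nm]]$name <- nm
  t
}

# entity-label counts contributed by one template
template_signature <- function(template) {
  labs <- vapply(Filter(function(s) s$type == "lex", template$slots),
                 function(s) s$label, character(1))
  table(factor(labs, levels = entity_labels()))
}

# --- realization ------------------------------------------------------------

# draw a surface form for a lexicon slot, preferring pedigree-assigned
# terms for FAMILY / CONDITION / EVENT slots
draw_form <- function(slot, lexicons, pedigree) {
  pool <- lexicons[[slot$pool]]
  if (is.null(pool) || length(pool) == 0)
    stop("template references an empty lexicon: ", slot$pool)
  if (!is.null(pedigree)) {
    mem <- pedigree$members
    if (slot$pool == "FAMILY") {
      aff <- mem$kin[mem$affected & mem$id != pedigree$self_id]
      if (length(aff) > 0 && stats::runif(1) < 0.6) return(sample(aff, 1))
    } else if (slot$label == "CONDITION") {
      conds <- stats::na.omit(mem$condition)
      if (length(conds) > 0 && stats::runif(1) < 0.6) return(sample(conds, 1))
    } else if (slot$label == "EVENT") {
      evs <- stats::na.omit(mem$event)
      if (length(evs) > 0 && stats::runif(1) < 0.6) return(sample(evs, 1))
    }
  }
  sample(pool, 1)
}

# instantiate one template as a single-sentence annotated document
realize_template <- function(template, lexicons, pedigree, doc_id) {
  toks <- list(); ents <- list(); role_id <- character()
  pos <- 0L; text <- ""
  for (slot in template$slots) {
    form <- if (slot$type == "lit") slot$text else draw_form(slot, lexicons, pedigree)
    words <- strsplit(form, " ", fixed = TRUE)[[1]]
    first_start <- NA_integer_
    for (w in words) {
      sep <- if (nzchar(text) && !w %in% c(".", ",", ";", ":")) " " else ""
      start <- nchar(text) + nchar(sep)
      text <- paste0(text, sep, w)
      toks[[length(toks) + 1L]] <- data.frame(
        sentence = 1L, surface = w, start = start, end = start + nchar(w),
        upos = slot$upos, deprel = slot$deprel, lemma = tolower(w))
      if (is.na(first_start)) first_start <- start
    }
    if (slot$type == "lex") {
      ents[[length(ents) + 1L]] <- data.frame(
        id = paste0("T", length(ents) + 1L), label = slot$label,
        start = first_start, end = nchar(text),
        text = substr(text, first_start + 1L, nchar(text)))
      role_id[slot$role] <- paste0("T", length(ents))
    }
  }
  entities <- do.call(rbind, ents)
  rels <- lapply(seq_along(template$rels), function(k) {
    r <- template$rels[[k]]
    data.frame(id = paste0("R", k), label = r[1],
               arg1 = role_id[r[2]], arg2 = role_id[r[3]])
  })
  relations <- if (length(rels)) do.call(rbind, rels) else empty_relations()
  fh_document(doc_id, text, tokens = do.call(rbind, toks),
              entities = entities, relations = relations)
}

#' Realize annotated sentences from a pedigree
#'
#' Instantiates sentence templates against a simulated pedigree: family,
#' condition and event slots preferentially verbalize affected pedigree
#' members and their assigned terms, other slots draw from the lexicons.
#' Template choice is steered so that the running entity-label mix tracks
#' the configured target proportions: at each step the controller scores
#' every template by how close the mix would be after adding its entity
#' signature, and samples among the closest three.
#'
#' @param pedigree an `fh_pedigree` (or `NULL` for lexicon-only draws).
#' @param templates list of templates (see [default_templates()]).
#' @param config an [fh_generator_config()].
#' @param seed integer seed.
#' @param n number of sentences; defaults to `config$n_sentences`.
#' @param id_prefix document id prefix.
#' @return List of single-sentence [fh_document()]s.
#' @export
realize_sentences <- function(pedigree, templates = default_templates(),
                              config = fh_generator_config(), seed = 1L,
                              n = NULL, id_prefix = "synth",
                              ensure_coverage = FALSE) {
  set.seed(seed)
  n <- n %||% config$n_sentences
  sigs <- lapply(templates, template_signature)
  target <- config$target_mix[entity_labels()]
  counts <- stats::setNames(rep(0, length(entity_labels())), entity_labels())
  docs <- vector("list", n)
  for (i in seq_len(n)) {
    if (ensure_coverage && i <= length(templates)) {
      # opening cycle through every template guarantees that all entity
      # labels and relation types occur even in small corpora
      pick <- i
    } else {
      score <- vapply(sigs, function(sg) {
        new <- counts + as.numeric(sg)
        sum(abs(new / sum(new) - target))
      }, numeric(1))
      pick <- sample(order(score)[seq_len(min(3, length(score)))], 1)
    }
    tmpl <- templates[[pick]]
    docs[[i]] <- realize_template(tmpl, config$lexicons, pedigree,
                                  sprintf("%s-%04d", id_prefix, i))
    counts <- counts + as.numeric(sigs[[pick]])
  }
  docs
}

#' Generate a synthetic annotated corpus
#'
#' Simulates a sequence of pedigrees and realizes annotated sentences
#' from them until `n_sentences` are produced.  The empirical
#' entity-label mix is steered to the configured target proportions
#' (within a few percentage points for corpora of a few hundred
#' sentences).  Every document carries exact character-offset entities,
#' schema-valid relations and a template-derived token/UPOS/dependency
#' layer, so no external parser is needed.
#'
#' @param config an [fh_generator_config()].
#' @param seed integer seed; the corpus is byte-identical given the same
#'   seed and config.
#' @return List with `corpus` (list of [fh_document()]s) and `manifest`
#'   (seed plus config echo, sufficient for exact regeneration).
#' @export
generate_corpus <- function(config = fh_generator_config(), seed = 1L) {
  templates <- default_templates()
  # reachability: every template's lexicon pools must be non-empty
  for (tm in templates)
    for (s in Filter(function(x) x$type == "lex", tm$slots))
      if (length(config$lexicons[[s$pool]]) == 0)
        stop("target mix unreachable: template ", tm$name,
             " references empty lexicon ", s$pool)
  n <- config$n_sentences
  per <- config$sentences_per_pedigree
  docs <- list()
  block <- 0L
  while (length(docs) < n) {
    block <- block + 1L
    ped <- simulate_pedigree(config, seed = seed + 7919L * block)
    m <- min(per, n - length(docs))
    docs <- c(docs, realize_sentences(
      ped, templates, config, seed = seed + 104729L * block, n = m,
      id_prefix = sprintf("synth%03d", block),
      ensure_coverage = block == 1L && n >= 2L * length(templates)))
  }
  docs <- docs[seq_len(n)]
  for (i in seq_along(docs)) docs[[i]]$doc_id <- sprintf("synth-%04d", i)
  manifest <- list(seed = seed, n_sentences = n, ambiguity = config$ambiguity,
                   penetrance = config$penetrance,
                   target_mix = as.list(config$target_mix),
                   sentences_per_pedigree = per)
  list(corpus = docs, manifest = manifest)
}

#' Write a generated corpus to disk as a brat project
#'
#' Writes `.txt`/`.ann`/`.conllu` files for every document plus a
#' `manifest.json` recording the seed and config echo needed for exact
#' regeneration.
#'
#' @param generated the list returned by [generate_corpus()].
#' @param dir output directory.
#' @return The directory path, invisibly.
#' @export
write_corpus <- function(generated, dir) {
  write_brat_project(generated$corpus, dir)
  jsonlite::write_json(generated$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
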