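---
title: "Extracting family history from clinical text: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting family history from clinical text: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famhx)
```

## The task

A patient's family history — which relatives had which cardiac conditions and
events, on which side of the family, at what age — is central to risk
assessment in genetic heart disease such as hypertrophic cardiomyopathy, where
sudden cardiac death in first-degree relatives is itself a risk factor.  In
the health record this information lives in free text.  `famhx` implements a
feature-based pipeline for recovering it:

1. **Entity recognition.** Each token of a sentence is assigned one of 11
   classes: five clinical entity types (`FAMILY`, `SELF`, `INDEX`,
   `CONDITION`, `EVENT`), five modifier types (`SIDE`, `AGE`, `NEG`,
   `AMOUNT`, `TEMPORAL`), or the out-label `O`.
2. **Relation extraction.** Every pair of entities within a sentence is a
   candidate for one of six classes: `Holder` (a condition/event and the
   person bearing it), `Modifier` (a modifier and a clinical entity),
   `Related_to`, `Subset` and `Partner` (links among family members), or
   `No_Relation`.

The annotation scheme constrains which entity types each relation may
connect; `fh_schema()` encodes these constraints and
`validate_document()` audits any annotated document against them.

## Models

### Entity tagger

The tagger is a one-vs-rest regularized linear classifier over sparse binary
indicator features, decoded greedily left to right:

* word identity at relative positions $-2 \dots +2$ (boundary markers
  beyond the sentence);
* universal POS tag at the same positions (the POS window is read as the
  same $\pm 2$ radius as the lexical window, a choice recorded in the
  feature config);
* the two previous entity tags — *gold* tags during training (teacher
  forcing), the model's *own predictions* during decoding.

Optional templates (lowercased word, 3-character prefix/suffix, the
previous-tag bigram) are off by default; they are cheap to enable through
`fh_feature_config()` but were not needed to reach the reference behaviour.
The baseline is a training-set dictionary mapping each word to its most
frequent label (`build_dictionary()`), with out-of-dictionary words tagged
`O` and ties broken in fixed lexicographic label order so results are
reproducible and auditable.

The classifier behind both taggers is multinomial logistic regression with
per-class (ungrouped) L2 penalties on a sparse design matrix, fitted with
glmnet — a one-vs-rest linear model, decoded by maximum response.  The
default penalty `lambda = 1e-4` corresponds to the weak regularization of a
unit-cost margin classifier at the corpus sizes this package targets (a few
thousand training tokens); it is exposed as a parameter everywhere.
Singleton training classes are duplicated once so the solver accepts them
rather than silently dropping a rare label such as `INDEX`.

### Relation classifier

Candidates are **all unordered within-sentence entity pairs**, ordered
canonically by surface position; a pair linked by a gold relation in either
direction carries that relation's label, all others `No_Relation`.  The
feature sets are cumulative, mirroring the ablation axes of the
experimental protocol: entity words → + UPOS → + dependency label of each
entity word's incoming arc → + the two entity labels.  A multi-word entity
contributes a single concatenated key per template (underscore join, surface
order), not one key per word.  The entity-label features can be taken from
the gold annotation or from the tagger's predictions over the *same gold
spans* (`predicted_span_labels()`), so the candidate set — and hence the
instance counts — is identical across the two conditions and scores are
directly comparable.  For end-to-end use, `predict_relations()` can instead
build candidates from fully predicted entity spans recovered from the
tagger output.

### Evaluation

`weighted_prf()` reports per-class precision/recall/F1 and their
support-weighted averages, the standard summary under heavy class imbalance
(most tokens are `O`, most candidate pairs `No_Relation`).  Excluding a
label (`exclude = "O"`) removes its weight from the averages without
touching the other classes' per-class scores.  Zero denominators score 0, a
stated convention that keeps weighted averages defined.
`cross_validate()` partitions *sentences* at random (seeded) into k folds
and refits everything — dictionary, vocabulary, classifier — per training
fold; reported numbers are unweighted means of fold-level weighted metrics,
not pooled counts.  `paired_t_test()` compares two systems across folds and
reports the zero-variance case explicitly instead of erroring.  `iaa()`
scores one annotator's entity (span, label) pairs against another's by
exact match, micro-averaged, with the first annotation as gold.

## The synthetic corpus generator

Clinical text cannot be redistributed, so the package's test bed is a
generator that emulates annotated family-history statements.

**Pedigree simulation.** `simulate_pedigree()` builds a fixed
three-generation family (4 grandparents, parents plus an uncle and aunt,
the patient with two siblings and two cousins), marks one founder
grandparent as mutation carrier and propagates carrier status down
parent–child links with probability 0.5 — the autosomal-dominant
transmission rule.  Carriers manifest disease with probability
`penetrance` (default 0.8, a realistic figure for adult-onset dominant
cardiomyopathy) and then receive condition/event terms.  A Monte-Carlo test
confirms the affected-carrier fraction matches the configured penetrance.

**Realization.** Sentences are instantiated from templates covering every
entity label and all five relation types, including the subset construction
("har to brødre, den ene har …"), partner couples, negation cues, temporal,
amount, age and side modifiers, and an index-patient construction.  Family,
condition and event slots preferentially verbalize affected pedigree
members.  Every sentence carries exact character-offset entities,
schema-valid relations, and a token layer with fixed plausible UPOS/deprel
tags per template slot, so no external parser is required anywhere in the
test suite.  Texts are Norwegian-like because the lexicons ship with
Norwegian defaults, but lexicons and templates are data, not code.

**Mix control.** The target entity-label mix defaults to the distribution
of the published synthetic reference corpus (FAMILY ≈ 41% of entities, then
CONDITION, EVENT, SELF, …).  Rather than hand-tuned template weights, the
generator uses a steering controller: at each step it scores every template
by the total absolute deviation of the post-hoc label mix from the target
and samples among the three best.  An opening cycle through all templates
guarantees that even small corpora contain every label and relation type.
Empirically the mix lands within ±5 percentage points of the target for
corpora of 200+ sentences.

**Ambiguity as a dial.** The dominant error class in real family-history
annotation is CONDITION/EVENT confusion.  The generator makes this
reproducible: `ambiguity` controls how much of a shared term pool is
injected into *both* the condition and event lexicons (default 0.2), and
one template places conditions in the perfect-tense context otherwise
characteristic of events, so that at high ambiguity neither the word nor
its context is decisive.  At `ambiguity = 0` the default lexicons are fully
collision-free — no surface form carries two different labels anywhere in
the template inventory — which is what makes the dictionary-reproduces-gold
and near-zero-confusion properties exact.

**What the generator does not emulate:** real clinical narrative
(abbreviations, typos, ellipsis), genuine parser noise in POS/dependency
layers, discontinuous or overlapping spans, cross-sentence relations, and
pragmatic ambiguity beyond the lexical dial.  Scores on generated data are
therefore ceilings, useful for verifying the machinery (parameter
recovery), not estimates of clinical performance.

## Numerical and design choices

* Character offsets are 0-based, end-exclusive (brat convention).
  Discontinuous spans are rejected; the scheme defines entities as
  continuous spans.  Overlapping entities are reported by the validator but
  tolerated at parse time; token projection resolves them in favour of the
  earlier-starting span, with a warning.
* `Modifier` relations may target any clinical entity in the default
  permissive schema; strict mode pins `SIDE` to `FAMILY`.  Whether a
  modifier may target another modifier is left forbidden in strict mode and
  allowed in permissive mode.  `Related_to`/`Subset`/`Partner` endpoints
  are FAMILY-only by default, with an opt-in to admit SELF/INDEX for
  corpora that use them.
* The dictionary counts `O` occurrences when computing the modal label
  (configurable), and breaks ties lexicographically with a logged count.
* Fold averaging is mean-of-fold-metrics, never pooled-then-scored.
* Relation candidates are unordered pairs by default; a directed mode
  exists.  Emitted relations are re-oriented to satisfy the schema when
  unambiguous; an optional schema filter drops unrepairable predictions.
* Cross-sentence gold relations are kept on reading but excluded from
  candidate generation with a reported count.
* CoNLL-U alignment reconstructs character offsets by left-to-right
  scanning; tokens that cannot be located keep `UNK` markers, and alignment
  below 50% is an error rather than a silent degradation.

## Problem sizes used by the test suite

The bundled checks train on generated corpora of 200–477 sentences with
5-fold cross-validation, and the parameter-recovery check uses 400 training
/ 100 test sentences over five seeds — the same order of magnitude as the
reference synthetic corpus (477 sentences, 6030 tokens), which keeps every
result reproducible on a single CPU in minutes.

## Known limitations

* No BIO/BIOES span encoding: labels are raw per-token classes, so two
  *adjacent* same-label entities merge during token-level round trips (the
  generator never produces them, and the recovery property is stated for
  non-adjacent entities).
* No CRF or neural sequence models; the greedy linear decoder is the point
  of comparison, and a CRF hook would be an external package run at its
  defaults.
* Dependency features use each entity word's incoming arc label only —
  no paths, no heads.
* The IAA scorer is exact-match micro-F1; no partial credit, no kappa.
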