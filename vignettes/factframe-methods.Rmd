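---
title: "Frame-semantics fact extraction from mammography reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frame-semantics fact extraction from mammography reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(factframe)
```

## The information model

`factframe` extracts structured clinical statements from the free-text
findings section of mammography reports. The unit of extraction is a
**fact**: a continuous text span carrying one clinically relevant statement,
typed by a **fact schema**. Inside its span a fact holds **entities**:
exactly one **anchor** — the keyword or phrase that identifies the fact type
("Läsion", "BI-RADS", "Mamillenabstand") — and any number of optional
**modifiers** carrying attributes such as size, laterality, o'clock
position, ACR density class or negation. This is a frame-semantic view of
the report: the anchor evokes the frame and the modifiers fill its roles.
The schema is a JSON document (`read_fact_schema()`); every other module is
driven by it.

Two structural invariants are enforced by `validate_schema()`: every name a
fact type references resolves to a declared entity type, and every fact type
has exactly one anchor-role entity. Rare classes are removed before
modeling by `apply_frequency_filter()`: fact types or modifiers annotated
fewer than `min_class_frequency` times (default 20) are dropped, anchors
following their facts unless another retained fact shares them. Counts for
modifiers shared across fact types are aggregated globally, which is what
makes the retained modifier inventory a property of the schema rather than
of any one fact.

## The two-step extraction pipeline

Extraction runs once per fact type of the schema. Step one is extractive
question answering: the fact-type name is the question, the findings
section the context, and a span extractor returns scored candidate answer
spans. Step two is sequence labeling: a token labeler assigns each token of
each candidate span a probability distribution over the IOB label inventory
(`O` plus `B-`/`I-` per entity type). Decoded entity chunks are poured into
the fact type's slot template (`assemble_fact()`): entities outside the
template are dropped with a warning, a missing anchor flags the instance as
anchorless but keeps it. Finally each entity string is looked up in a
terminology dictionary (`normalize_entity()`), a case- and
whitespace-insensitive exact-match TSV stub standing in for a terminology
server; candidates preserve dictionary order, and an optional subtype
column can restrict candidates per entity type.

How a single extractive-QA pass should yield *several* instances of one
fact type in one report is genuinely open; we enumerate all token pairs
`(s, e)` with `e − s < max_answer_tokens`, score them as
`start_scores[s] + end_scores[e]`, and keep up to `top_k_per_fact`
non-overlapping candidates above a score threshold (greedy, in score
order). This n-best mechanism is an approximation and is confined to
`enumerate_spans()`, so a different strategy can be swapped in. Backends
may also return candidate span lists directly, which is what the
deterministic rule backend does.

Illegal IOB sequences (an `I-x` that continues nothing) are repaired at
decode time: `conservative` drops the tokens, `begin-coercion` reinterprets
the first as `B-x`. The default is conservative, which is also what the
entity-level evaluation uses, so evaluation never invents chunks the
labeler did not commit to.

### Backends

The package ships two backends. The **rule backend**
(`rule_backends()`) compiles each clause template of a clause bank into a
regular expression with one capture group per entity slot; span extraction
is regex search, token labeling reads the capture groups back as one-hot
distributions. It is deterministic and, on text generated from the same
clause bank, reproduces the gold annotation exactly — the oracle-closure
property the test suite relies on. The **trainable backend**
(`train_token_labeler()`) is a single-hidden-layer softmax network (via
`nnet`) over hashed token, neighbour and shape features, parameterized by
the `ner` block of `training_config()`. It exists to exercise the training
contracts (early stopping, label inventories, probability rows summing
to 1) at desk scale; it is not a contextual encoder, and no claim about
clinical performance follows from it. The reference hyperparameters carried
by `training_config()` — QA at learning rate 3e-5, 5 epochs, maximum
sequence length 384, document stride 128; sequence labeling at 5e-5, up to
100 epochs, weight decay 1e-2, batch size 16, early-stopping patience 5;
masked-LM at 2e-5, weight decay 0.01, masking probability 0.15, 3 epochs —
document the intended large-model recipe and configure the small one.

Early stopping halts training once the monitored metric has stayed
strictly below its running best for `patience` consecutive epochs, and
reports the best epoch for checkpoint reloading. Perplexity is
`exp(mean validation loss)` (`perplexity_from_loss()`).

## Corpus curation

`clean_corpus()` repairs mojibake with an explicit garble→character map
(default: UTF-8 umlauts misread as Latin-1), drops records failing the
modality filter, and collapses exact duplicates. "Duplicate" means byte
equality of the whitespace-normalized full text, the weakest definition
that is still deterministic; near-duplicate detection is out of scope.
Repairs run before duplicate detection, so a garbled copy of a clean
report still deduplicates. The cleaning statistics reconcile exactly:
`n_output = n_input − n_duplicates_removed − n_nonmodality_removed`.

Tokenization and sentence splitting are implemented in the package: words
and single punctuation marks with exact 0-based half-open character
offsets, sentence breaks at `.`/`!`/`?` before whitespace, suppressed
inside any abbreviation of a user-supplied lexicon ("Vd. a.", "z.B.").
Character offsets are 0-based and half-open everywhere in the package;
token *indices* (in IOB decoding and span enumeration) are 1-based, as is
natural in R. The 512-token cap used during sampling counts these word
tokens, not model subwords — a deliberate model-independence choice whose
divergence from any specific subword vocabulary is accepted.

"Maximum variance" stratified sampling is implemented as greedy
farthest-point selection within each BI-RADS category under a pluggable
pairwise distance, by default cosine distance on hashed character-3-gram
counts. Greedy farthest-point is deterministic, embedder-agnostic and
approximates maximum dispersion; ties (and the degenerate constant-zero
distance) resolve by document id, so the procedure is reproducible without
randomness. Pretraining splits (`pretrain_split()`) are seeded
permutations with `floor(ratio · N)` training items.

## Training-data conversion

`to_qa_dataset()` splits at the **document** level (seeded permutation,
70/15/15 by default) before expanding examples, so a fact instance can
never appear in two splits. Train and test splits emit one single-answer
example per fact instance; the validation split groups all instances of a
fact type in a document into one example with multiple gold answers, which
is what max-over-golds span evaluation expects. No unanswerable examples
are emitted by default; a flag synthesizes them (absent fact types →
empty-answer examples) for experiments that need them.

`to_iob_dataset()` emits one example per fact instance, covering only the
fact span by default (`pad_tokens` adds `O`-labeled context). An entity
boundary that splits a token resolves to the whole token with a warning —
annotation granularity is token-level, and silently truncating tokens
would break the offset invariants.

## Evaluation suite

*Unitizing agreement.* Annotators who segment and categorize a continuum
are compared with `unitizing_alpha()`, an agreement coefficient of the
Krippendorff family: `alpha = 1 − Do/De`. For every ordered annotator pair
and every unit, the observed disagreement adds the squared start- and
end-boundary gaps to each overlapping same-category unit of the other
annotator, or the squared unit length when nothing overlaps; the expected
disagreement replaces each term with its exact expectation under
independent uniform placement of the involved units over all integer
positions of the continuum. Published unitizing coefficients come in
several variants and the exact one behind any given tool is often unclear,
so we fixed a precise definition and verify it against an independent
brute-force enumerator in the tests rather than against any published
table. Identical unitizations give 1; `De = 0` with `Do > 0` is an
explicit error state, and the fully degenerate `Do = De = 0` case is
defined as perfect agreement.

*Span metrics.* `qa_em_f1()` is the usual span EM / token-overlap-F1 pair
with max over multiple golds, averaged and reported as percentages. The
normalization lowercases, strips punctuation and collapses whitespace but
deliberately does **not** strip English articles — the corpus is German.

*Entity metrics.* `entity_prf()` scores exact chunk matches (type and
token range) with no partial credit; per-class precision/recall/F1 are
macro-averaged unweighted over classes, and accuracy is token-level. The
implementation is cross-checked against an independent quadratic chunk
matcher on a thousand random IOB cases.

*Uncertainty.* `bootstrap_ci()` draws seeded resamples with replacement
(default 599 at confidence 0.95) and reports the percentile interval and
the resample standard deviation. `kfold_plan()` produces k folds (default
9) sharing one seeded validation split of 10%, each fold testing on a
near-equal block of the remainder and training on the rest — 80/10/10
with the defaults. Percentages round half-up to one decimal by default
(two where a quantity is conventionally printed with two).

*Corpus similarity.* `dataset_similarity()` averages cosine similarity
over all cross pairs under a pluggable embedder (default: hashed
character-3-gram counts). The default embedder is a lexical, not a
semantic, measure; plugging in a sentence-embedding model is the intended
use when one is available.

## The synthetic generator

`generate_report()` builds a findings section from German-styled clause
templates conditioned on the BI-RADS category: negative statements for
category 1, lesions with size/quadrant/o'clock/nipple-distance for
suspicious categories, suspicious lymph nodes and malignancy statements
for 4-6, foreign material for 6, and one or two BI-RADS statements per
report. Each template is a sequence of literals and entity slots with
finite filler options, so rendering yields the fact span and every entity
span with exact character offsets; `generate_dataset()` is seeded and
balanced (default 3 reports per category over 0-6, i.e. 21 reports,
mirroring a typical qualitative-evaluation set). Clause inclusion
probabilities are configurable (`fact_weights`); the defaults were chosen
once to make every fact type reasonably frequent at small corpus sizes.

What the generator emulates is the *structure* of reports — sections,
clause-level facts, entity slot fillers, category conditioning — not their
linguistic variability: real reports paraphrase, abbreviate
inconsistently, interleave findings, and violate reporting standards.
Passing tests on synthetic data therefore demonstrate the correctness of
offsets, conversions, metrics and pipeline plumbing, and the closure
property of the rule backend; they say nothing about extraction quality on
clinical text, which requires annotated hospital data and trained
encoders, both outside this package.

Two corruption utilities close the remaining loops:
`perturb_annotations()` simulates a second annotator (boundary jitter,
unit deletion, label swaps) in the format `unitizing_alpha()` consumes,
with zero noise giving agreement 1; `corrupt_corpus()` injects exact
duplicates, reversible encoding garbles and foreign-modality records into
a clean corpus and returns the statistics `clean_corpus()` must recover.
Garbles are applied only to non-duplicated originals so each corruption
count maps one-to-one to a cleaning action.

## Numerical and scale choices

All randomness is seeded through a single helper that restores the
caller's RNG state, so library use never perturbs a session's random
stream. The expected-disagreement enumeration in `unitizing_alpha()` is
exact (no Monte Carlo) and cached per unit-length pair; it is quadratic in
the continuum length, comfortable for report sections of a few hundred
characters. The test suite and the reproduction script run the corpus
machinery at the full reported sizes (a 219,029-item split; a 3,274-record
cleaning stage) and the annotation machinery on generated corpora of 21
and 210 documents — sizes chosen to exercise every counting identity in
seconds on one CPU. Model-quality figures (span F1 around 0.9, entity F1
around 0.8, perplexities near 1.1–1.2 for further-pretrained encoders) are
properties of trained transformer weights on clinical corpora; the package
covers their *computation* (the metrics, the split plans, the bootstrap)
but does not claim to reproduce their values, and its tests assert
properties (oracle equivalence, closure, determinism) rather than those
numbers.

## Known limitations

- Fact spans are continuous by construction; discontinuous or coreferent
  findings cannot be represented.
- Terminology normalization is exact-match lookup; no fuzzy matching,
  morphology or subtype reasoning beyond the optional filter column.
- The trainable labeler is feature-hashed and context-window-local; it is
  a contract-exerciser, not a clinical model.
- The sentence splitter is rule-based; abbreviation coverage is exactly
  the supplied lexicon.
- Schema editing is file-based; there is no collaborative tooling.
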