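---
title: "Generating and labeling nursing-record dialogue data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating and labeling nursing-record dialogue data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

Natural language understanding (NLU) for a voice-driven nursing record
system must classify the *intent* of an utterance ("add-vital",
"clean-oral", ...) and extract its *entities* ("@vital-value = 103
systolic bp"). Collecting and hand-labeling such utterances in a care
facility is slow, privacy-constrained and requires domain experts.
`dialogforge` implements a desk-scale pipeline that removes that
bottleneck: it *generates* a gold-labeled corpus from a declarative
ontology, optionally *extends* it with a character-level language model,
and *labels* new utterances by embedding them and clustering
semantically similar items. This vignette is the package's account of
the methods, the choices behind them, and what they do and do not
demonstrate.

## The data model

Utterances are short action-driven commands. Each intent is an action
verb plus an activity class that completes it; the remaining information
is carried by *record* entities reached through prepositional phrases:
time expressions, targets (patients, rooms), and per-activity values.
An ontology declares:

* `entity_slot`: a named slot of kind `activity` or `record` with its
  surface values and optional per-value synonyms;
* `phrase_template`: a preposition, optional modifiers, and a record
  slot (pattern 1 = preposition + placeholder, pattern 2 = preposition +
  modifier + placeholder);
* `intent_spec`: verbs, the activity slot, and record phrase templates.

The packaged fixture (`builtin_fixture()`) declares six nursing-care
intents (vital signs, oral care, toilet assistance, meal preparation,
bathing, diaper change) with their activity and record slots, plus the
shared record slots `start-time`, `stop-time` and `target`. The diaper
intent has no published activity values, so the fixture derives a
`diaper-type` slot from the sample command forms ("dirty diaper",
"nappies"); for meal preparation the food is the verb's direct object,
so `food-type` is the activity slot and `meal-type` a record slot with
preposition "for". The schema is a single YAML document (see
`extdata/nursing_ontology.yaml`); `write_ontology()` and
`load_ontology()` round-trip it.

## Utterance augmentation

`generate_corpus()` composes three steps per intent:

1. **Phrase shuffling.** `enumerate_orderings()` produces every
   permutation of the record phrases behind the verb + activity head
   (subject–verb–object order is preserved), crossed with the intent's
   verbs — `|verbs| * m!` distinct templates for `m` phrases.
2. **Slot filling.** `fill_slots()` substitutes declared values and
   their synonyms into the placeholders. When the Cartesian product of
   choices fits the budget it is enumerated exhaustively; otherwise a
   seeded uniform sample without replacement is drawn. Every filled slot
   yields an entity span; spans are 0-based half-open character offsets,
   and a pattern-2 span covers modifier + value ("103 systolic bp"), as
   the value alone is not a useful record.
3. **Paraphrasing.** Four rule families create syntactic variants with
   recomputed spans: question forms (modal and Wh-, chosen by seeded
   draw), politeness prefixes ("please, ", "i "), a template-based
   active-to-passive transformation over the closed verb inventory, and
   keyword synonym substitution from a packaged lexicon (a trained
   `vector_table` can serve as the synonym source instead, via
   `expand_synonyms()` with its defaults of top 10 neighbors at cosine
   0.5).

Texts are rendered in lower case: it keeps the character-level
vocabulary small and makes span arithmetic across transformations
exact. Duplicates are removed corpus-wide, per-intent budgets default to
the study-scale profile (876, 606, 408, 756, 560, 340; 3546 in total),
and the whole generation is a pure function of (ontology, config,
seed). A budget that exceeds the attainable unique variants yields the
attainable maximum plus a shortfall report rather than an error.

The generator emulates the *shape* of nursing commands: short templated
verb-object utterances over a closed vocabulary. It does not emulate
speech-recognition noise, spelling variation, open vocabulary, ellipsis
or multi-intent turns. Tests passing on generated corpora therefore
demonstrate correctness of the pipeline, not performance on real ward
transcripts.

## Word embeddings

No pre-trained vectors are downloaded; both backends train on the
generated corpus.

* `train_skipgram()`: skip-gram with negative sampling. Defaults are 32
  dimensions, minimum count 3, context window 6 (with the customary
  per-position reduced window), downsampling threshold `1e-3`, 50
  epochs. The negative-sampling count (5) and initial learning rate
  (0.025, linear decay) are the conventional values and are
  configurable.
* `train_subword()`: the same objective with each word represented as a
  bag of boundary-marked character n-grams (`<fe`, `fev`, ...; default
  range 3–6, configurable). A word vector is defined as the *sum* of its
  n-gram vectors — an identity that holds exactly on the returned table
  and lets out-of-vocabulary words be composed from shared n-grams.

Training is single-threaded by design so that equal seeds give
bit-identical tables; at this corpus scale the run takes seconds, so
parallelism buys nothing that determinism costs. Vector tables read and
write the word2vec text format (`read_vectors()` / `write_vectors()`),
so externally trained vectors can be plugged in where available.

## Features and entity candidates

Word-level preprocessing follows a fixed order: contraction expansion,
lower-casing, tokenization, stopword removal, lemmatization, and
removal of non-ASCII/punctuation tokens. The stopword list, contraction
table and lemma exceptions are packaged, versioned text resources; the
lemmatizer is lexicon-backed with regular plural/`-ing`/`-ed` rules and
passes unknown words through. The word-level feature of an utterance is
the arithmetic mean of its token vectors, `F_w = (1/N) sum_n v_wn`;
tokens a non-subword table cannot represent are skipped rather than
zero-imputed, because zero-imputation drags the mean toward the origin.

Sentence-level preprocessing removes only non-ASCII characters —
lemmatization would collapse forms ("close"/"closer"/"closest") whose
semantics differ. Sentence encoders are an interface (`name`,
`dimension`, `encode`); the packaged default mean-pools the trained
word vectors over the sentence-preprocessed text, and adapters over
external contextual encoders can be substituted without touching the
pipeline.

Entity candidates are noun phrases. The package ships a deterministic
rule-based chunker matched to the corpus's sentence shapes — the
verb-object phrase (tag `dobj`), prepositional objects (`pobj`),
leading number phrases (`nummod`), with determiners stripped — behind a
parser interface that accepts any user-supplied
`function(text) -> data.frame(phrase, start, end, tag)`; if a supplied
parser fails, the chunker takes over with a notice.

## Clustering-based labeling

`kmeans_fit()` minimizes the within-cluster sum of squared Euclidean
distances `J = sum_j sum_i ||x_i - c_j||^2` with Lloyd iterations from
k-means++ seeds. Numerical policies, all deterministic per seed:

* 10 restarts by default, best objective kept;
* the recorded objective trace is non-increasing;
* an empty cluster is re-seeded at the point farthest from its current
  centroid;
* equidistant points join the lowest-index centroid; tied majority
  labels resolve to the lexicographically smallest label;
* features are used raw; an optional L2-normalization flag exists but
  is off by default.

`k` is the gold number of classes: the intent count for intent
clustering, and the number of distinct gold slot names among matched
candidates for entity clustering (which always uses word-level
features, since an entity phrase is a fragment, not a sentence).
`majority_labels()` names each cluster by its most frequent gold label
and reports labeling accuracy; `evaluate_clustering()` adds
pair-counting precision/recall/F1 and the silhouette.

## The character-level language model

`train_charlm()` implements an embedding → single LSTM layer → dense
softmax architecture trained with Adam on categorical cross-entropy for
next-character prediction. Defaults: 256-dimensional character lookup,
1024 memory units, dropout 0.2 on the recurrent output, batch 64, 30
epochs, window length 100. `charlm_desk_profile()` is the same model at
256 units; it is the profile used by the tests and the acceptance
script, sized so a full training run completes in minutes on one CPU.
Only the LSTM cell is provided: a second recurrent cell would double
the hand-written backpropagation surface for a comparison that is not
part of this package's scope.

Data preparation: every utterance is newline-terminated
(`corpus_text()`), the character vocabulary maps newline to id 0 and
the remaining characters by descending frequency then codepoint (any
fixed bijection works; this one is reproducible across platforms), and
the text is split into non-overlapping stride-`L` windows whose targets
are the inputs shifted by one character. Training accuracy is the
fraction of next-character predictions that match, averaged over the
epoch's batches; the pre-training loss over the dataset sits at
`ln(vocab size)` under the near-uniform initial softmax, a useful
integrity check. The trainer runs in single precision with fused-gate
BLAS kernels — at these sizes the rounding difference is far below the
stochastic variation between seeds, and the speedup is what makes the
desk profile practical. `sample_charlm()` feeds characters back
autoregressively from the temperature-scaled softmax; temperature 0 is
greedy argmax decoding, and generation stops at a newline.

Generated lines can be labeled by the clustering pipeline rather than
adjudicated by hand; lines whose cluster label disagrees with their
nearest references can be flagged for review.

## Evaluation utilities

* `pair_confusion()` / `pair_prf()`: all `n(n-1)/2` unordered item
  pairs counted by same-cluster vs same-class agreement;
  `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F1 = 2PR/(P+R)`, with zero
  conventions for empty denominators.
* `silhouette_score()`: `S(i) = (b(i) - a(i)) / max(a(i), b(i))` with
  Euclidean distances (matching the clustering metric); singleton
  clusters score 0 by convention.
* `bleu()`: geometric mean of modified n-gram precisions (orders 1–4)
  times a brevity penalty. The order and smoothing are configurable;
  the default applies add-one smoothing to orders ≥ 2 because
  single-digit-length utterances otherwise hit zero higher-order counts
  almost surely. `bleu_corpus()` scores each generated utterance
  against all references, keeps the maximum, and averages — the
  reference pairing for generated text is a design choice, made
  explicit here.
* `corpus_stats()`: per-class utterance and whitespace word counts with
  the average length reported at full precision and *truncated* (not
  rounded) to 3 decimals, the truncation being the reporting
  convention of the reference statistics this mirrors.
* `aggregate_ratings()`: unweighted mean of group means, 2 decimals.

## Problem sizes and reproducibility

The packaged study-scale profile generates 3546 utterances (~170k
characters, vocabulary of ~36 characters, ~1700 windows of length 100).
The test suite exercises the full pipeline at this scale once (the
desk-profile training run) and otherwise uses miniature fixtures:
hand-built ontologies with 0–5 record phrases, toy vector tables with
hand-set vectors, a two-interchangeable-token corpus for the
distributional property, and ten short utterances for the memorization
check. Every stochastic component takes an explicit seed, and equal
seeds give identical corpora, tables, clusterings and samples.

## Known limitations

* The generator's linguistic coverage is bounded by its templates: no
  free word order beyond phrase permutations, no anaphora, no
  multi-intent utterances.
* The passive and politeness transformations rely on a closed verb
  inventory; verbs outside it are skipped with a warning.
* The rule-based chunker is tuned to generated sentence shapes and is
  not a general dependency parser (the parser interface exists for
  that).
* The lemmatizer is intentionally small; distributional quality of the
  embeddings, not linguistic perfection of lemmas, drives the
  clustering.
* Clustering quality metrics on generated data are optimistic relative
  to real transcripts, for the reasons given above.
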