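---
title: "notesieve: methods, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{notesieve: methods, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(notesieve)
```

This vignette is the package's own account of its science: what the
weak-supervision model assumes, which tunable parameters matter and why
their defaults are what they are, what the synthetic generator does and
does not emulate, and where the design was genuinely open. It states no
empirical result that the test suite does not itself compute.

## 1. The labeling model

The unit of weak supervision is the *note*, but the signal lives on the
*encounter*: diagnosis codes are attached to dated encounters, and every
note belongs to exactly one encounter. Given a target code set (the default
is the closed 11 + 11 ICD-9-CM/ICD-10-CM administrative COPD definition),
`build_pools()` partitions all notes:

| pool | rule | silver label |
|---|---|---|
| `COPD_ENCOUNTER` | encounter carries ≥ 1 target code | positive |
| `NON_COPD` | patient carries no target code anywhere | negative |
| `PRE_COPD` | note date ≤ first coded diagnosis − 24 calendar months | negative |
| `EXCLUDED` | uncoded note in the pre-diagnosis grey zone, or uncoded post-diagnosis | none |

Assumptions worth making explicit:

* **Exact code matching.** Membership is exact set membership after
  normalization (uppercase, dots stripped). No prefix/child expansion:
  the default definition is a closed enumeration and silent widening would
  change the cohort. Custom code sets can opt into broader lists.
* **Patient-level negatives.** `NON_COPD` requires the *patient* to be
  code-free, not just the encounter. An uncoded visit of a coded patient is
  not evidence of irrelevance — it may simply be under-coded — so such notes
  are never negatives; they are `PRE_COPD` if old enough, otherwise
  `EXCLUDED`. `negatives_scope = "encounter"` exposes the alternative
  reading.
* **Boundary-inclusive calendar arithmetic.** "24 months or more prior"
  is implemented as `date <= add_months(first_dx, -24)` with day-of-month
  clamping (Mar 31 − 1 month = Feb 28/29). The grey zone is deliberately
  excluded from negatives because it is exactly where prodromal disease
  would contaminate them.
* **The gold set never comes from heuristics.** Annotation provenance is a
  field, not a convention: gold labels enter only through an annotation
  file (or the simulator's truth), and are spent on threshold calibration
  (validation split) and final testing only.

Training subsets are balanced (`n_pos = n_neg`) with three designs
(`MIXED`, `NON_ONLY`, `PRE_ONLY`). The source framework's "diversity in
demographics, timing, and note types" has no published procedure, so the
package states one: at most `ceil(n/20)` notes per patient per draw, and
proportional allocation across calendar-year × note-type strata with
largest-remainder rounding, relaxed only on infeasibility. The gold
validation/test split is stratified by pool of origin, mirroring the
reference 107/100/100 draw shape.

## 2. Text representations

All five backends consume one token stream: lowercased maximal runs of
ASCII letters/digits. No stemming or stop-word removal — simplicity is the
point of a lightweight filter, and every representation seeing identical
tokens keeps comparisons fair.

* **BoW / TF-IDF.** Raw counts; TF-IDF uses the smoothed inverse document
  frequency `ln((1+N)/(1+df)) + 1` with L2 row normalization — the common
  modern default, chosen because the source framework does not pin a
  variant. Both the idf and the normalization are stored so unseen gold
  documents are projected into the *training* space (`transform_counts()`).
* **Paragraph vectors.** One distributed-memory and one distributed-BoW
  sub-model, hierarchical softmax over a Huffman tree of corpus
  frequencies, concatenated at inference (the original paragraph-vector
  recommendation). Defaults: 25 dimensions per sub-model (50 total),
  window 5, 20 training epochs, `min_count` 2, learning rate 0.025 → 1e-4.
  These are configuration, not claims about the original study, which
  states none of them. Training is single-threaded with one seeded RNG:
  the package chooses bit-reproducibility over multi-core speed, because
  every acceptance property downstream depends on determinism. Inference
  freezes all shared weights and fits only the document vector (50 epochs,
  per-document seeds, so results are independent of batch composition).
* **Compression features.** `compressed_length(x)` is the RFC 1952 gzip
  byte length at level 6 with zeroed header metadata (verified
  byte-identical to other gzip implementations at the same settings;
  the empty string compresses to exactly 20 bytes, frozen as a regression
  fixture). The default feature matrix is that single column; a flag adds
  raw byte length and compression ratio.
* **NCD.** `(C(xy) − min(C(x), C(y))) / max(C(x), C(y))`, concatenation
  with no separator, both-empty defined as 0. NCD with a real-world
  compressor is only approximately a metric: symmetry holds to ~0.1 and
  self-distance is bounded away from 0 by gzip's ~28 bytes of fixed
  framing. On vocabulary-drawn text ≥ 500 bytes self-distance stays below
  0.15; on degenerate single-token repetition (`C(x)` ≈ 33 bytes) the
  overhead ratio pushes self-distance to ~0.33 — a property of gzip, not a
  bug, and the reason the self-distance test uses structured text.
* **Concept vectors.** A generic lexicon engine stands in for a full
  terminology service: TSV of surface terms → CUI-style identifiers,
  greedy longest n-gram match (n ≤ 5), case-insensitive. Assertion is a
  NegEx-style simplification: a trigger within the 6 tokens preceding the
  mention, sentence-bounded on `.!?` and newline, flips the value to −1.
  Document cells are +1 / −1 / 0; when one document both affirms and
  negates a concept, *affirmation dominates* (a single affirmed mention is
  clinically informative), with `negation_dominates = TRUE` as the flip.
  The bundled 40-term respiratory lexicon is synthetic except for anchor
  identifiers such as C0018787 ("heart").

## 3. Classifiers and tuning

Random forest (bootstrap + per-node feature subsampling, Gini, leaf =
weighted positive fraction), Newton-boosted trees (logistic loss, XGBoost
parameterization: gain `½[G_L²/(H_L+λ) + G_R²/(H_R+λ) − G²/(H+λ)]`, leaf
`−G/(H+λ)`, row/column subsampling), k-NN (brute force; `leaf_size` is
accepted for interface parity and has no effect at these scales), and
NCD-kNN (uniform-weight vote among the k smallest distances, ties broken
by reference order). The compiled ensembles live in `src/` because that is
where every serious R implementation of trees puts them; all randomness
flows from one seeded `std::mt19937` per fit.

Grid search uses stratified 5-fold CV with a fixed shuffling seed
(stratification is the safe default with balanced classes), records F1,
precision, recall and specificity per fold, and selects by mean F1 with
ties broken by higher mean recall, then grid order. The default grids
discretize the standard ranges exactly (720 forest candidates). The `fast`
preset deviates from a literal "2 points per axis" shrink — that would
still be 64 forest candidates × 5 folds, far beyond a CI budget — and
instead keeps 2 points on the two most influential axes (trees/depth;
learning rate/rounds; k/weighting) with the rest pinned at defaults.

## 4. Calibration and evaluation

Thresholds sweep 0.0–1.0 in 0.1 steps with the decision rule `p ≥ t`, which
makes the 0.0 row the all-positive anchor (recall 1). Selection is argmax
F1, ties to higher recall then lower threshold; the source framework's
"maximize recall while maintaining precision" is ambiguous, so a
`min_recall` constraint mode is provided alongside. Metrics with zero
denominators return 0 with an explicit undefined flag instead of erroring,
so sweeps never abort. Confidence intervals are percentile bootstrap
(document-level resampling, 1000 iterations, 2.5th/97.5th percentiles) — no
bias correction, and no class stratification, neither being stated in the
source.

One printed-number discrepancy is documented rather than tuned away: the
reference best-model confusion matrix (tp 128, fp 47, fn 21, tn 27) implies
F1 0.79 at two decimals while the prose reports 0.80; the package
reproduces precision/recall/specificity exactly and asserts nothing about
the rounded F1.

## 5. What the synthetic generator does and does not establish

`generate_cohort()` emulates the *noise structure* of the problem, not
clinical text. Patients get uniform encounter timelines in a 2012–2020
window; condition patients get a first-diagnosis date placed ≥ 30 months
into the window (guaranteeing a non-empty pre-diagnosis pool) with
post-diagnosis encounters coded at rate 0.7. Relevance couples to coding
through three knobs: notes at coded encounters are irrelevant with
probability `miscoding_rate` (0.3), notes at uncoded encounters outside the
grey zone are relevant with probability `uncoded_relevant_rate` (0.6), and
grey-zone notes are relevant with probability `pre_window_contamination`
(0.5). The first two defaults are chosen so the code-heuristic baseline on
a 107/100/100 gold draw lands at precision ≈ 107·0.7/107 = 0.70 and recall
≈ 74.9/(74.9 + 200·0.6) ≈ 0.38 — the reference regime — as arithmetic, not
calibration-after-measurement. Text is a two-topic unigram mixture (Zipf
tilt 0.5): relevant notes draw 70% of tokens from a respiratory topic
seeded by the bundled lexicon, irrelevant notes 5%, ~80 tokens per note,
with occasional negated respiratory mentions in irrelevant notes to
exercise assertion handling.

Consequences for interpreting green tests: the generator makes relevance
*linearly recoverable from unigram statistics*, so it establishes that the
pipeline is correctly wired (silver pools match construction, noise rates
are honored, a learnable signal flows end to end, thresholds calibrate,
bootstrap machinery is sound). It does not establish clinical performance:
real notes have discourse structure, templated boilerplate, section
headers, negation far subtler than a 6-token window, and label noise that
is correlated with care patterns rather than independent coin flips. The
end-to-end criterion (silver-trained, gold-calibrated forest beats the code
heuristics in ≥ 4/5 seeds) is a qualitative reproduction of the framework's
central ordering, at ~1/100 of the reference scale.

## 6. Numerical conventions and degenerate inputs

* All stochastic operations take explicit seeds; library code saves and
  restores R's RNG state, and per-stage child seeds are derived by hashing
  (seed, stage-name), so stages are independent and reorder-stable.
* Dates are `Date`s end to end; month arithmetic clamps the day.
* Empty corpus files read as empty corpora; empty documents produce zero
  count-rows, finite embedding vectors (their seeded initialization), and
  `C("") = 20`; both-empty NCD is 0 by definition.
* Probability ties at the threshold go to "relevant" (`≥`); k-NN distance
  ties break by training-set order; CV score ties break by recall then grid
  order. Every tie-break is deterministic and documented next to its code.
* Single-class training labels, feature-dimension mismatches, unknown or
  duplicate annotation ids, and infeasible generator parameters raise
  typed errors (`notesieve_error`) naming the offending object.

## 7. Known limitations

* The negation model is a deliberate simplification (no hypothetical,
  family-history, or historical assertion classes; no scope termination on
  conjunctions).
* No probability calibration (Platt/isotonic) — thresholding on raw votes
  is the framework's mechanism, and forest vote fractions are not
  calibrated probabilities.
* k-NN is brute force; fine to ~10⁴ documents, not beyond.
* The embedding trainer is single-threaded by design (reproducibility
  mode); a faster nondeterministic mode would need a threading model and
  is out of scope.
* Compression features use one global gzip level; per-document adaptive
  compressors (zstd dictionaries etc.) are out of scope.
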