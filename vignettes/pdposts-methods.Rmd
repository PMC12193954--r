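---
title: "Mining longitudinal Facebook archives for PD-related posting: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining longitudinal Facebook archives for PD-related posting: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdposts)
```

## The problem

A clinically characterized movement-disorder cohort — people with
Parkinson's disease (PD), essential tremor (ET), atypical parkinsonism (AP),
and caregivers (CG) — donates complete Facebook data exports. Each export is
a directory of JSON files covering the account's full history, typically
reaching years before the clinical diagnosis. The analytic questions are:
what fraction of a person's posting is PD-related, how does that fraction
change across the diagnosis boundary, and do people with PD differ from
caregivers before diagnosis?

`pdposts` implements that pipeline: text harvesting and cleaning,
dictionary-based candidate flagging, supervised classification of
candidates, rule-based explicit-mention flags, per-participant longitudinal
percentages, and a nonparametric statistical battery. Because real archives
are identifiable and cannot be shared, a synthetic-cohort generator with
known ground truth is part of the package, and every downstream stage is
tested against it.

## Ingest: from export files to a clean post stream

Export files are **not mutually exclusive**: the same post can appear in
`posts.json` and `comments.json`. The harvester walks every JSON value and
collects `(timestamp, text)` pairs from the text-bearing keys `post`,
`comment`, `description` and `title`; records without a timestamp are
excluded because every downstream analysis is time-indexed.

Three cleaning steps follow.

* **Encoding repair.** Real exports frequently contain UTF-8 text that was
  at some point decoded as Windows-1252 ("café" → "cafÃ©"). The repair maps
  each character back to a byte (identity below 0x100, the CP1252 specials
  above it) and re-reads the byte string as UTF-8, but only when the input
  contains marker characters (Â, Ã, â, €) and the reinterpretation is valid
  UTF-8. That guard makes the operation idempotent and safe on clean text;
  doubly encoded text unwinds over repeated passes. Output is NFC-normalized.
* **Memory timestamps.** Reshared "memory" posts carry in-text relative
  dates. The pattern removed is *quantity* (digits or a number word) +
  *unit* (day/month/year, singular or plural) + "ago", with punctuation
  attached to the phrase; "I met her years ago" has no quantity and is left
  alone. Whitespace is re-collapsed afterwards, so the recovered text equals
  the original post body byte for byte — which is what makes ground-truth
  joins by content hash possible.
* **Deduplication.** Two stages, per participant, on
  whitespace-collapsed case-sensitive text: (1) identical (timestamp, text)
  pairs collapse; (2) within each text group in time order, the earliest
  instance is retained and a later one is kept only if at least 180 s have
  elapsed since the most recently **retained** instance of that text.
  Anchoring the window to retained instances (rather than the immediately
  preceding occurrence) makes the rule deterministic on chains: occurrences
  at 0 s, 100 s and 200 s keep 0 s and 200 s. The implementation is checked
  against an independent brute-force O(n²) implementation on a thousand
  random inputs.

## Lexicon: candidate flagging and explicit mentions

The dictionary is a flat file of lowercase terms with optional tags
(`symptom`, `medication`, `advocacy`, `exercise`, `other`). Matching is
deliberately over-inclusive — "I fell down" and "I fell in love" both hit —
because the classifier, not the dictionary, is responsible for precision.
Text and terms are preprocessed identically: lowercase, punctuation
removal (apostrophes deleted, so "Parkinson's" → "parkinsons"), stopword
removal against a fixed list bundled with the package, and Porter stemming.
A post is flagged if any term matches its stemmed or unstemmed token
sequence; multi-word terms must appear as consecutive tokens after stopword
removal. The Porter stemmer is implemented in the package (no stemming
package is required at runtime) and verified against the algorithm's classic
example pairs.

The bundled dictionary is a **synthetic reconstruction** assembled from
standard PD vocabulary (motor and non-motor symptoms, medications, advocacy
events, exercise programs); any dictionary file in the documented format can
be supplied instead.

Two rule-based flags operate on the raw text: a case-insensitive substring
match for "parkinson", and the case-sensitive word-boundary regex `\bPD\b`
for the standalone abbreviation. Case sensitivity is the point: a
case-insensitive match would fire on "pd" inside casual text, and the word
boundary prevents false matches such as "updated".

## Features

Dictionary-flagged posts enter the model in four blocks, every
transformation fitted on the training split only:

* **Lemma TF-IDF.** Tokens are cleaned (URLs, @-tags, #-hashtags,
  punctuation and stopwords removed) and lemmatized with a noun-default
  rule-based lemmatizer: regular and irregular noun plurals reduce to the
  singular, while verb inflections pass through untouched ("trembling"
  stays "trembling" — a deliberate property of noun-default lemmatization,
  distinct from the stemmer used for dictionary matching). Terms are all
  1-, 2- and 3-grams with document frequency ≥ 2 in training. The TF-IDF
  variant is raw count × smoothed idf, `idf = ln((1+N)/(1+df)) + 1`, with
  each block's rows L2-normalized; the variant is part of the package
  contract and the unit tests pin it to a hand-computed toy corpus.
* **Cluster TF-IDF.** Tokens map through a two-column token → cluster-id
  table (out-of-vocabulary tokens map to a reserved `OOV` id); cluster
  unigrams are TF-IDF-weighted under the same df ≥ 2 rule. The package
  bundles a small synthetic table; any larger clustering resource in the
  same format is exchangeable input.
* **Age at posting**, derived as age at interview minus the interview/post
  date gap (birth dates are not collected), floored at 0 and min–max scaled
  to [0, 1] by the training bounds. Min–max rather than z-scaling keeps the
  whole matrix nonnegative, which is what makes a multinomial naive Bayes
  model applicable.
* **One-hot demographics**: gender and diagnosis group (PD/ET/AP/CG —
  the finest available reading of "diagnosis status"), levels fixed by the
  training split; unseen levels yield all-zero blocks.

## Classifier

The labeled corpus is split 80/20, stratified by label (each class
contributes `round(n_class × 0.2)` posts to the test set). Stratification
guarantees both classes in the test set; the folds used for
cross-validation are likewise stratified, with per-class fold sizes within
one example of each other.

Seven families are tuned by grid search under 5-fold cross-validation
scoring **macro-averaged recall** — the average of per-class recalls, which
protects the minority PD class. Default grids are small and documented
(`default_grids()`): naive Bayes smoothing α ∈ {0.1, 0.5, 1}; tree depth ∈
{4, 8, 30}; k ∈ {3, 5, 11}; SVM cost ∈ {0.1, 1, 10}; forest min-node ∈
{1, 10} at 100 trees; AdaBoost rounds ∈ {25, 50}; boosted-tree depth ∈
{3, 6} at 60 rounds. Every grid is overridable. Engines: multinomial naive
Bayes, sparse k-NN probabilities and boosted presence-stumps are
implemented in-package (the naive Bayes variant is multinomial because the
features are nonnegative TF-IDF counts); the linear SVM (e1071, with a
logistic calibration of decision values so it can join the soft-voting
ensemble), CART (rpart), random forest (ranger) and gradient-boosted trees
(xgboost) come from their standard packages. The soft-voting ensemble is
the unweighted mean of member probabilities.

Classification uses the fixed threshold 0.5, with the boundary classified
positive. Test-set metrics carry 95% percentile-bootstrap confidence
intervals from 1000 resamples of the test set (models are not refit);
discrimination is summarized by the ROC curve and the rank-based AUC, which
equals the trapezoidal area and the concordant-pair fraction, and is tested
against a brute-force pair count. Model selection takes the family with the
highest macro recall; ties break by macro F1, then by the documented family
order (simplest first, naive Bayes leading). Degenerate-case conventions:
per-class precision with no predicted members counts as 0, and bootstrap
resamples are redrawn until both classes are present.

## Flagging and the longitudinal analysis

The final per-post verdict is the union
`(dictionary hit AND classifier positive) OR "parkinson" OR \bPD\b`:
the rules exist to catch dictionary and classifier misses, so they dominate
the classifier by construction. The classifier is only consulted for posts
with at least one dictionary hit. A post is `exercise_only` when its
PD-relatedness rests solely on exercise-tagged dictionary matches and it has
no explicit mention; the exercise-excluded analysis removes exactly those
posts. Explicit mentions are never excluded.

Per participant and timeframe, the quantity of interest is
`percentage = 100 × n_PD-related / n_posts`, normalizing by post volume
rather than account age (an old but quiet account should not dilute its
owner's PD share). Phase assignment is by calendar day in UTC: strictly
before the diagnosis date is `pre`, the diagnosis day itself and later is
`post` (the boundary must land somewhere, and day-level resolution is all
the metadata offers). Participants without a diagnosis date contribute to
the overall timeframe only. Year-only diagnosis dates coerce to July 1 with
a message. A timeframe with zero posts has an **undefined** percentage
(`NA`, never 0) and drops out of that cell's N in the group table and out
of the paired tests — zero would fabricate a signal.

Keyword-frequency tables (the tabular form of a word cloud) count
model-cleaned tokens of PD-related posts per group and phase, ties broken
lexicographically.

## Statistical battery

All p-values are two-sided; no multiple-testing correction is applied.

* **Welch's t** from group summaries, with Welch–Satterthwaite df and
  pooled-SD Cohen's d (n−1 weights).
* **Fisher's exact test** by direct hypergeometric enumeration: the
  two-sided p sums all table probabilities not exceeding the observed one.
* **Wilcoxon signed-rank** for pre/post percentages: pairs with missing or
  zero difference are dropped first ("valid, non-identical pairs"),
  absolute differences get midranks, and W is the **smaller** of the
  positive/negative rank sums. p comes from exhaustive sign-flip
  enumeration when n ≤ 12 and otherwise from the tie-corrected normal
  approximation **without** continuity correction.
* **Mann–Whitney U** for between-group comparisons: U is the smaller of
  the two U statistics; exact enumeration of group assignments when
  `n_x · n_y ≤ 100`, otherwise the tie-corrected normal approximation
  **with** continuity correction.
* **Shapiro–Wilk** via the standard algorithm, with explicit errors on
  degenerate input; **Cohen's kappa** with marginal-product expected
  agreement (κ defined as 1 when both raters are constant and identical).

The signed-rank and U conventions (min-sum, min-U, the asymmetric
continuity-correction choices) are fixed so that the package's statistics
correspond to the convention family used by the common Python scientific
stack, which published analyses of this design typically report; the
small-sample paths are verified against exhaustive enumeration, and over
the whole statistic support at n = 10–12 the normal approximation stays
within 0.05 of the exact signed-rank p.

## The synthetic generator: what it emulates, and what it does not

`synth_config()` defaults are the study conditions: 30 PD + 3 ET + 1 AP +
12 CG donating accounts; account spans of 14 ± 3 years; post counts with
mean 4018 and SD 5570 (drawn lognormal to reproduce the heavy upper tail of
very active accounts, floored at 20); diagnosis about 5 years after account
creation with 90% of accounts created pre-diagnosis; caregiver diagnosis
dates present for 60% of caregivers; phase-specific PD-content rates per
group (PD 1.7% pre / 4.0% post; ET 1.0/0.7; AP 9.3/4.9; CG 1.1/1.0); 40% of
PD-related posts exercise-themed; 6.5% of non-PD posts using ambiguous
dictionary vocabulary; duplicate-injection rates of 5% exact, 3% near
(< 180 s) and 2% reshare (≥ 180 s); 5% memory posts and 2% encoding
corruption. Caregivers without a diagnosis date post PD content at the
caregiver pre-diagnosis rate.

Texts come from sentence templates in three strata: PD-related templates
(symptom, medication, advocacy, exercise) that always embed dictionary
vocabulary; ambiguous negatives that embed dictionary words in non-PD
contexts ("I fell in love", "work life balance"); and plain negatives with
no dictionary vocabulary. A **shared ambiguous pool** ("took a hard fall
today", "rough night, could not sleep") is drawn by both classes — 12% of
non-exercise positives and 30% of ambiguous negatives — which puts the Bayes
error above zero and keeps the classifier stage honest: without it every
family would reach recall 1.0 and the harness would be vacuous. Texts are
unique within a participant (colliding instantiations get filler-word
variation), which is what makes the expected post-deduplication count exact.

The generator emulates structure, not language: template variation is no
substitute for real lexical diversity, topic drift, dialect, or the long
tail of personal vocabulary. A classifier that clears the harness here has
demonstrated that the pipeline's machinery — splitting, feature fitting
without leakage, tuning, selection, thresholding — is correct, **not** that
comparable metrics would be reached on real annotated Facebook posts.
Likewise the recovery study shows the longitudinal arithmetic is unbiased
under known rates, not that real cohorts have those rates; real
between-participant variance is far larger than the binomial variation the
generator produces at fixed per-group rates.

## Numerical and design choices worth knowing

* Post identity is a 64-bit hash of participant id, timestamp and
  whitespace-collapsed text, computed after encoding repair and memory
  stripping; the generator computes the same hash on its clean texts, so
  ground-truth labels join losslessly across the file round-trip.
* `split_data` rounds per class (`round(n_class × fraction)`) and clamps so
  both splits retain at least one member of each class.
* Grid ties take the first grid row; selection ties take the earlier family
  in the documented order.
* The linear SVM's probabilities come from a logistic fit to its training
  decision values — a deliberate, documented simplification of
  cross-validated Platt scaling, adequate for soft voting.
* AdaBoost weak learners are feature-presence stumps evaluated for all
  features at once with two sparse matrix–vector products per round; on
  TF-IDF data presence carries almost all of a stump's usable signal.
* The empty-archive participant case (zero harvested posts) flows through
  the whole pipeline: undefined percentages, exclusion from cohort shares
  and from paired tests.

## Problem sizes used in the checks

The classifier harness runs at the annotation-corpus scale (6750 labeled
posts, 35.6% positive, 80/20 split). The longitudinal recovery study uses
27 PD participants with ~1900 posts each over a 10-year span with diagnosis
at 5 years — at least 500 posts in each phase for every participant — over
100 simulated cohorts in the test suite (50 in the acceptance script).
Type-I calibration uses 1000 null simulations per test: two binomials of
n = 500, p = 0.5 for Fisher (large enough that the exact test's
discreteness does not push the attainable level below the nominal band),
30 normal pairs for the signed-rank test, and 25-vs-25 normals for
Mann–Whitney. These sizes are the package's chosen study conditions for its
own verification and are stated here so they can be varied deliberately
rather than rediscovered.

## Known limitations

* The bundled dictionary is a compact reconstruction; a production study
  should supply its own (larger) dictionary file and cluster table.
* The lemmatizer is rule-based and noun-only; it does not consult a lexical
  database, so rare irregular plurals outside its exception list pass
  through unchanged.
* Welch df computed from rounded summary statistics can differ in the
  second decimal from the value computed on raw data; the package reports
  the exact Welch–Satterthwaite value for its inputs.
* The explicit-mention rules are English-specific, as is the stopword list.
* `\bPD\b` deliberately misses lowercase "pd"; that is the documented
  trade-off against false matches.
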