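---
title: "Methods: linguistic-cognitive screening for the FX premutation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linguistic-cognitive screening for the FX premutation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxscreen)
```

## The screening problem

The Fragile X (FX) premutation — 55–200 CGG repeats in *FMR1* — affects
roughly 1 in 151 females, yet most carriers are unaware of their status
because population-scale genotyping is impractical. Carriers show subtle
cognitive and linguistic phenotypes: elevated speech dysfluency (filled
pauses such as *um*/*uh*, and repetitions of words or phrases), shorter and
simpler utterances, and self-reported executive-function difficulties,
especially in organizing materials and self-monitoring. `fxscreen`
implements an automated screening framework built on exactly these signals:
it turns a five-minute monologue transcript plus a BRIEF-A-style
executive-function questionnaire into a 103-feature phenotype and evaluates
how well machine-learning classifiers separate carriers from a matched
comparison group.

The package works entirely at the phenotype level. It contains no genetic
data and no participant data; everything it can be demonstrated on is
produced by its own synthetic cohort generator.

## Transcript model and feature extraction

Transcripts use a one-utterance-per-line dialect with terminators `.`,
`?`, `!` (a line without one is read as a statement — statements dominate
monologue). Parenthesized spans are SALT-style *mazes*: dysfluent material
(false starts, repeated words, fillers) excluded from propositional
content. Tokenization is a whitespace split with punctuation stripped at
token edges, keeping word-internal apostrophes; everything is matched on
lower-cased forms, so profiles are case-invariant.

Three measurement conventions matter and are worth stating explicitly:

* **Filled pauses** are lexicon hits. The default lexicon
  `{um, uh, ah, oh, er, hmm, mm}` covers the canonical clinical examples
  plus common transcription variants, and is configurable. Fillers are
  counted wherever they occur, including inside mazes.
* **Repetitions** are exact duplications of a token unit of any length
  (default cap: 6 tokens), with only filler tokens allowed between copies.
  Fillers can never *be* the repeated unit. Longest units take precedence,
  scanning left to right, and tokens consumed by an accepted event cannot
  seed another one — this makes word-level and phrase-level counts
  disjoint, so "(he is) he is John" is one phrase repetition, not a phrase
  repetition plus two word repetitions. A maximal run of `c` copies counts
  as `c − 1` repetitions. The detector is verified against a brute-force
  enumeration oracle over small token alphabets.
* **Morphemes** follow a deterministic approximation of Brown/SALT
  counting: one per word, plus one for each regular inflection
  (`-s`, `-ed`, `-ing`, possessive) and each contraction part, with a
  minimum-stem-length guard and small exception lists (so *yes*, *his*,
  *during* stay monomorphemic). Clinical morpheme conventions are not
  fully mechanizable; the rule table is a documented, configurable
  approximation, and the same table is applied to both groups, which is
  what matters for discrimination.

The default schema emits 28 global features (utterance/terminator counts,
words, morphemes, MLU, one-word utterances, length-bin counts and
proportions, filled pauses and rate, repetition counts by unit length,
repeated words and percentage, dysfluent-utterance counts per length bin,
dysfluencies per 100 words) plus 12 features for each of five segments —
88 in total. Two choices here were genuinely open:

* **Length bins.** The clinical definitions ("less than 5", "6 to 10"
  morphemes) leave exactly-5 unassigned; we use short ≤ 5, medium 6–10,
  long ≥ 11 so the bins partition the utterances (an invariant the tests
  enforce).
* **Segmentation.** The five segments are token quintiles (near-equal
  token counts, remainder to the earliest segments; an utterance belongs
  to the segment holding its first token). Segmenting by *time* is not
  possible — transcripts carry no timestamps — so "equal length" is read
  as equal text length.

Maze tokens are excluded from word counts, MLU and length bins (they are
dysfluent, not propositional, material) but duplicated words inside them
still count toward repeated words: this mirrors the clinical coding the
framework was validated against, where the maze annotation *is* the
dysfluency record.

Rates with a zero denominator are defined as 0, so an empty transcript
yields an all-zero 88-feature profile rather than NaNs.

## Cognitive block

The BRIEF-A instrument is proprietary at item level, so the package
ingests scale-level scores only: nine clinical scales, from which the BRI
(four scales), MI (five scales) and GEC (BRI + MI) composites are
recomputed by the sum convention and checked against any provided
composite columns (default tolerance 0.5, i.e. printed rounding).
With a single validity composite, maternal age and ordinal education
(1–4) the block has 15 features, giving the 103-feature comprehensive
profile. The identity of the 15th feature is a documented reconstruction
(the scale-level instrument also yields validity indexes); a missing
validity column defaults to the T-score midpoint 50.

## Information gain with MDL discretization

Feature value is measured by information gain,
`IG(class, feature) = H(class) − H(class | feature)` in bits, with
`H(X) = −Σ p(x) log2 p(x)`. Continuous features are discretized by
entropy-based recursive binary splitting with the
minimum-description-length stopping criterion: a split is accepted only
when its gain exceeds `(log2(n−1) + log2(3^k − 2) − (k·H(S) − k1·H(S1) −
k2·H(S2)))/n`. A feature whose first cut is rejected scores 0 — this is
what makes "non-zero information gain" a meaningful selection rule rather
than a ranking of noise. Because the discretization depends only on the
ordering of values, IG is invariant under strictly monotone transforms
(property-tested), and normalization cannot change it.

Ranking is by descending gain with ties broken by fixed schema order, so
results are deterministic. The *optimized profile* is the positive-gain
subset; during cross-validation the selection is recomputed inside every
training fold, never on the full data, to avoid selection leakage. When a
training fold yields no positive-gain feature (e.g. null data) the
harness falls back to the full feature set rather than fitting on
nothing.

## Classifiers and evaluation

Five standard learners are supported behind one interface: logistic
regression (`stats::glm`), Gaussian naive Bayes (`e1071`), a decision
tree (`rpart`, Gini impurity), a random forest (`randomForest`, 500
trees, `sqrt(p)` features per split, vote fraction as score) and discrete
AdaBoost over 50 depth-1 `rpart` stumps (implemented in the package; the
stump ensemble's margin is mapped to a probability by the logistic of
twice the additive score). Features are z-scored with training-fold
statistics inside each fit — IG is unaffected, scale-sensitive learners
benefit — and zero-variance features are dropped.

Cross-validation is stratified 10-fold (sizes differ by ≤ 1; per-fold
class ratio within one sample of the global ratio), seeded and exactly
reproducible. The published design is a balanced 100 vs 100 cohort, where
stratification is the faithful, lower-variance reading of "randomly
split". Out-of-fold scores are pooled into a single ROC curve, and the
summary metrics come from the pooled confusion counts at a 0.5 score
threshold.

All evaluation statistics are implemented natively: sensitivity,
specificity, accuracy, MCC (defined as 0 when its denominator vanishes,
the continuous-limit convention) and `F1 = 2TP/(2TP+FN+FP)` from the
confusion matrix; the ROC from all distinct thresholds with trapezoid
AUC, which equals the pairwise rank statistic with ties worth ½
(property-tested against exhaustive pair enumeration and against pROC);
the pooled/Welch two-sample t from raw vectors or printed summary
statistics; and the screening PPV
`sens·prev / (sens·prev + (1−spec)(1−prev))` with its enrichment factor
`PPV/prevalence`, which translates an operating point into the factor by
which follow-on genetic testing is concentrated.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without
participant data; its defaults are the study conditions the package
emulates, chosen once:

* **Scale.** ~60 utterances and ~600 words per transcript (negative
  binomial utterance count, mean 60, size 20; words per utterance
  NB(mean 9, size 8) + 1) — the size of a five-minute monologue.
  Over-dispersed counts match natural speech better than Poisson.
* **Group contrast** (at `effect_scale = 1`): carrier filled-pause hazard
  0.04/token vs 0.02, repetition hazard 0.16/utterance vs 0.08 (unit
  length 1 with probability 0.6, else 2), utterances one word shorter on
  average, dysfluency hazards raised ~30% in the first and last
  utterance-order quintiles (the beginning and end of a sample are the
  more demanding parts), and +5 T-score shifts (worse) on Organization of
  Materials, Self-Monitor and Task Monitor. Ages differ slightly
  (48.9 vs 47.4 years); education is identically distributed, matching a
  deliberately education-matched design. `effect_scale = 0` gives an
  exact null — both groups identically distributed — and larger values
  scale every contrast up together.
* **Ground truth.** Injected repetitions are written as maze annotations,
  and the sidecar records the five injected mechanisms
  (`n_filled_pauses`, `n_repetitions`, and the three shifted scales).

What the generator does *not* emulate: real lexical content and syntax
(tokens come from a fixed Zipf-sampled synthetic vocabulary and matter
only through the morpheme rules), discourse structure, speech-rate and
timing phenomena, and any correlation between CGG repeat length and
phenotype severity. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers the statistical structure it is
told to inject — detector correctness, selection behaviour, calibration
under the null, monotone response to effect size — not that real
carriers are classifiable at any particular accuracy.

One consequence is worth stating plainly: because all 88 linguistic
features derive from two injected linguistic mechanisms, strongly
correlated derivatives (rates, per-segment counts, MLU) legitimately
out-rank the raw mechanism counts and the cognitive scales in the IG
ordering on synthetic cohorts. Recovery of the *mechanisms* is checked at
the matrix level (five independent informative columns among noise all
land in the top 10); on transcript-level cohorts the faithful statement
is that the injected mechanisms' derived family dominates the ranking.

## Numerical and design choices

* Missing terminator → statement; empty file → empty transcript (not an
  error); unbalanced parentheses → an error naming the line.
* Education outside 1–4, missing scale columns, and composite
  disagreements are hard errors, not warnings — silent coercion of
  clinical scores is worse than failure.
* IG of a categorical feature uses its observed values as bins (no MDL);
  numeric features always go through MDL. Constant labels are an error:
  with `H(class) = 0` a ranking is meaningless.
* Positive class defaults to `"carrier"` when present, else the last
  factor level; every stochastic step (fold assignment, learner fits,
  generator draws) is governed by an explicit integer seed, and per-fold
  fits derive their seeds from it, so whole runs are byte-reproducible.
* Problem sizes used by the test suite were chosen to keep the full suite
  in a few minutes: calibration and effect-recovery checks run 10-fold CV
  with 100-tree forests on cohorts of 50 per group across 20 (null) and
  3×10 (effect grid) seeds; the acceptance script evaluates the
  study-scale 100-per-group cohort with the default 500-tree forest.

## Known limitations

Morpheme counting is heuristic; the transcription dialect is a
reconstruction (the original conventions are unpublished beyond worked
examples); BRIEF-A T-score norm conversion is out of scope; probability
calibration, hyperparameter tuning and confidence intervals on AUC are
deliberately absent. Results on real cohorts are not bit-reproducible
against the original study because its fold seeds and exact feature list
are unpublished.
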