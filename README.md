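# fxscreen

Linguistic and cognitive computational phenotyping for Fragile X (FX)
premutation screening.

## The problem

The FX premutation (55–200 CGG repeats in *FMR1*) affects about 1 in 151
females. Carriers are at risk for FXTAS and for having children with
Fragile X syndrome, yet most are undiagnosed: genotyping at population
scale is impractical. Carriers show measurable *phenotypic* signals,
though — elevated speech dysfluency (filled pauses, word/phrase
repetitions), shorter and simpler utterances, and executive-function
difficulties on BRIEF-A-type self-report scales. `fxscreen` is for
researchers in computational phenotyping and clinical language analysis
who want to evaluate pre-screening classifiers built on exactly these
cheap, non-genetic measurements.

## What it implements

* **Transcript model** — a one-utterance-per-line dialect with `.?!`
  terminators and SALT-style parenthesized maze annotations;
  deterministic tokenization and round-trip I/O.
* **Linguistic profiler** — 88 features per five-minute-scale language
  sample: dysfluency (lexicon-based filled pauses; repetition events as
  exact duplications of a token unit with only fillers allowed between
  copies, longest-unit precedence), complexity and density (morpheme
  counts, MLU, length bins), and a five-segment (token-quintile)
  decomposition.
* **Cognitive block** — 15 features: nine BRIEF-A-style scale scores,
  recomputed BRI/MI/GEC composites, validity, age, education; combined
  into the 103-feature comprehensive profile.
* **Feature selection** — information gain
  `IG(C, F) = H(C) − H(C | F)` with entropy-based recursive binary
  discretization under the MDL stopping criterion; the "optimized
  profile" is the positive-gain subset, recomputed inside each training
  fold.
* **Classifiers** — logistic regression, naive Bayes, AdaBoost (depth-1
  stump ensemble), decision tree, random forest behind one fitting
  function `fxs_fit()`, with a stratified seeded `cross_validate()`
  harness (pooled out-of-fold ROC) and `evaluate_independent()` for a
  held-out set.
* **Metrics, implemented natively** — sensitivity, specificity,
  accuracy, MCC, `F1 = 2TP/(2TP+FN+FP)`, trapezoid ROC/AUC (equals the
  rank statistic with ties worth ½), pooled/Welch two-sample t, and the
  screening PPV `sens·π / (sens·π + (1−spec)(1−π))` at population
  prevalence π.
* **Synthetic cohorts** — `generate_cohort()` produces seeded two-group
  corpora (transcripts + cognitive tables + labels + ground truth) with
  controllable effect sizes, so the whole pipeline is testable without
  participant data.

A thin CLI (`inst/cli/fxscreen.R`) exposes the stages as
`profile / simulate / select / run / screen` subcommands.

## Worked example

Profile a tiny transcript:

```r
library(fxscreen)
tr <- parse_transcript("She is uh a very uh lovely girl.\n(He is) He is John.\nYes.\n")
p <- profile_transcript(tr)
p[c("n_utterances", "n_filled_pauses", "n_repetitions",
    "n_repeated_words", "mlu", "n_one_word")]
#>     n_utterances  n_filled_pauses    n_repetitions n_repeated_words
#>         3.000000         2.000000         1.000000         2.000000
#>              mlu       n_one_word
#>         3.333333         1.000000
```

Two filled pauses (*uh*, *uh*), one phrase repetition ("(he is) he is",
two repeated words), MLU 10/3 morphemes per utterance, one one-word
utterance ("Yes."). Now a full synthetic screening experiment:

```r
spec <- cohort_spec(n_per_group = 30, seed = 7)   # carrier vs comparison
cohort <- generate_cohort(spec)
prof <- t(vapply(cohort$transcripts, profile_transcript, numeric(88)))
ling <- cbind(data.frame(participant_id = rownames(prof)), as.data.frame(prof))
assembled <- assemble_profiles(ling, load_cognitive_table(cohort$cognitive),
                               cohort$labels)
cv <- cross_validate(profile_subset(assembled, "optimized"), assembled$label,
                     model_spec("random_forest"), k = 10, select = TRUE,
                     seed = 7)
cv
#> <fxs_cv> random_forest, 10-fold (seed 7, selection on), n = 60
#>   F1 = 0.862  AUC = 0.969  MCC = 0.735  acc = 0.867  sens = 0.833  spec = 0.900

screening_ppv(cv$metrics[["sensitivity"]], cv$metrics[["specificity"]], 1/151)
#> <fx_screening> PPV = 5.263% at prevalence 0.662% (sens 0.83, spec 0.90): 7.9-fold enrichment
```

The cross-validated F1/AUC/MCC summarize pooled out-of-fold performance
of the fold-wise information-gain-selected random forest; the screening
estimate translates that operating point to population prevalence: a
positive screen would concentrate carriers ~8-fold before confirmatory
genetic testing.

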