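# rrsa — regression-based representational similarity analysis for EEG

`rrsa` implements time-resolved and cross-temporal representational
similarity analysis (RSA) of multichannel EEG epochs, decomposed by
regression into word-specific, semantic, and orthographic-form components.
It is aimed at language/EEG researchers studying lexical prediction: given
sentences whose final word is highly predictable, the spatial pattern of
pre-word neural activity should be more similar for two sentences that
predict the *same* word, a *semantically related* word, or an
*orthographically similar* word — and the latencies at which those three
relations emerge index when each level of representation is pre-activated.

## The model

For every unordered pair of sentences, three pair-level regressors are
built from the expected words:

* **Word-Specific** — 1 if the expected words are identical, else 0;
* **Semantic** — Lin similarity from a taxonomy with corpus counts,
  `sim(a,b) = 2·IC(lcs(a,b)) / (IC(a)+IC(b))`, `IC(c) = −log p(c)`;
* **Form** — normalized Levenshtein similarity,
  `1 − 2d/(|a|+|b|+d)` for edit distance `d`.

The neural similarity of a pair at time *t* is the Pearson correlation of
the two spatial patterns (channel vectors) at *t*. Each participant's
pairs × time similarity matrix is then modelled per time sample by OLS:

```
RSA(t) ≈ β0(t) + β_WS(t)·WordSpecific + β_Sem(t)·Semantic + β_Form(t)·Form + ε
```

and four predicted condition signals are read off the fit:
Unrelated = β0; Semantic = β0+β_Sem; Form = β0+β_Form;
Word-Specific = β0+β_WS+β_Sem+β_Form (identical words carry the maximum
value on all three predictors). The same decomposition applies cell-wise
to cross-temporal similarity (temporal-generalization) matrices.

Inference follows the standard nonparametric EEG toolbox: a chance level
(median of the across-condition average), Benjamini–Yekutieli-corrected
against-chance tests to delimit analysis windows, cluster-mass permutation
tests (threshold t = 2.04, per-participant condition swaps), jack-knife
latency comparisons of the maximum-t within the largest cluster, and
Bonferroni-corrected 2-D cluster tests for the cross-temporal matrices.

A synthetic-data module plants word/semantic-family/form-family spatial
patterns in configurable latency windows, so the entire pipeline can be
validated against ground truth without any data download.

## Worked example

Simulate a 24-participant study (12 target words × 2 sentences, 34
channels, planted semantic → form → word-specific ordering), fit the
decomposition, and test the semantic effect against the Unrelated baseline:

```r
library(rrsa)

study <- simulate_study(n_participants = 24, seed = 7)
round(variance_inflation_factors(study$predictors), 2)
#> word_specific      semantic          form
#>          2.06          1.76          1.37

sigs <- lapply(study$epochs, function(ep) {
  ep <- crop_window(ep, -730, -550)
  condition_signals(rrsa(pairwise_rsa_series(ep), study$predictors))
})
tm   <- attr(sigs[[1]], "times")
cm   <- function(cd) t(sapply(sigs, function(s) unclass(s)[, cd]))
base <- cm("unrelated")

cluster_permutation_test(cm("semantic"), base, tm, n_perm = 1000, seed = 1)
#> <cluster_test> threshold t=2.04, 1000 permutations, seed 1
#>   start_ms end_ms   mass max_t max_t_ms        p significant
#> 1     -667   -663 23.075 5.947     -663 0.000999        TRUE
#> 2     -661   -661  2.353 2.353     -661 0.919081       FALSE

jackknife_latency_comparison(cm("semantic"), cm("form"), base, tm,
                             n_perm = 1000, seed = 2)
#> <jackknife_latency> A: -663.2 ms, B: -647.0 ms, delta -16.2 ms
#>   permutation p = 0.000999 (1000 permutations)
#>   jack-knife-corrected t = -9.045 (p = 4.9e-09); naive t = -208.042 (p = 3.6e-39)
```

The semantic effect forms one significant cluster peaking at −663 ms —
the centre of the planted semantic window — and its jack-knife latency
precedes the form effect by ~16 ms, matching the planted ordering. The
permutation p of 0.000999 is the smallest value 1,000 permutations can
resolve (the estimator never returns 0).

For file-based runs, `write_synthetic_dataset()` writes an epochs
container + lexicon/taxonomy TSVs, and `run_pipeline(read_run_config("cfg.yaml"))`
executes predictors → RSA → decomposition → statistics (optionally the
cross-temporal stage) with full provenance in `report.json`.

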