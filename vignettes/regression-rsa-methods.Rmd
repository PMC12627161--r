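---
title: "Methods: regression-based RSA of EEG epochs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regression-based RSA of EEG epochs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, algorithms and numerical conventions
behind `rrsa`, the reasoning for its tunable defaults, and what the
synthetic-data validation does and does not establish.

## 1. The similarity model

The unit of analysis is the unordered sentence pair. At every time sample
the package correlates (Pearson, across channels) the spatial EEG patterns
of the two sentences' epochs; the resulting pairs × time matrix is the
representational similarity signal. Per participant and per time sample,
that signal is decomposed by ordinary least squares into

$$ r \approx \beta_0 + \beta_{WS}\,\text{WordSpecific}
   + \beta_{Sem}\,\text{Semantic} + \beta_{Form}\,\text{Form} + \varepsilon $$

with three pair-level regressors:

* **WordSpecific** ∈ {0, 1}: expected final words identical. Identity is
  exact string equality after lower-casing and Unicode NFC normalization.
  Accents are normalized but never stripped — in Spanish-type orthography
  an accent distinguishes words, so `árbol` and `arbol` are different.
* **Semantic** ∈ [0, 1]: Lin similarity over a rooted taxonomy with
  corpus counts. Information content uses the natural logarithm (Lin's
  ratio is base-invariant). The semantic source is pluggable: a taxonomy
  (computed internally) or any symmetric word × word matrix, so no corpus
  download is ever required; how surface words map onto taxonomy nodes is
  deliberately an explicit user input.
* **Form** ∈ [0, 1]: normalized edit similarity
  $1 - 2d/(|a|+|b|+d)$ with unit edit costs (the length-normalized
  variant of Levenshtein distance). Two empty strings are defined as
  similarity 1: the identity clause dominates the formula's 0/0.

Fitting is per participant, then statistics across participants; no mixed
model is used. The four reported condition signals are affine reads of the
betas — Unrelated $=\beta_0$, Semantic $=\beta_0+\beta_{Sem}$, Form
$=\beta_0+\beta_{Form}$, WordSpecific
$=\beta_0+\beta_{WS}+\beta_{Sem}+\beta_{Form}$. The Word-Specific
configuration sets Semantic = Form = 1, not their empirical means:
identical words are maximally similar on all three predictors, and the
algebraic identity (WordSpecific − Unrelated) − (Semantic − Unrelated) −
(Form − Unrelated) $=\beta_{WS}$ holds at machine precision.

Raw correlations are regressed by default; a Fisher-z option exists
(`fisher_z = TRUE`) but is off, since the similarity values involved are
small enough that the transform is near-identity and the raw scale is the
conventional one for this analysis.

## 2. Missing data, degeneracies, tie-breaks

* A spatial pattern with zero variance across channels has no direction to
  correlate: its pairs get the missing marker `NA`, never a silent 0.
* Pairs missing from a participant's series (artifact-rejected epochs) are
  simply absent; the per-sample fit uses surviving pairs. Samples with
  fewer than 5 finite pairs (coefficients + 1), or whose surviving design
  is rank-deficient, are flagged missing and excluded listwise from group
  statistics at that sample. How rejected epochs entered the original
  analyses of this kind is generally unstated; drop-and-flag is this
  package's policy.
* One-sample t-series: a sample where every participant sits exactly at
  the null value reports t = 0, p = 1 (no evidence); zero variance away
  from the null is a missing marker.
* Latency ties (equal maximum t at two samples) break toward the earlier
  sample, and the largest-cluster tie (equal mass) toward the earlier
  cluster.
* Permutation p-values use the +1 correction, (1 + #{null ≥ observed}) /
  (1 + n_perm), and therefore never return 0. Null-vs-observed
  comparisons use a 1e-9 tie tolerance: under sign-flipping, exact ties
  with the observed statistic are genuine (e.g. the identity sign
  pattern), and the tolerance stops floating-point rounding from flipping
  a tie count between otherwise identical runs.
* Numerical reproducibility: permutation draws are bit-identical given a
  seed (every stochastic routine requires one). Matrix reductions go
  through the BLAS, whose threaded summation order may differ between
  runs; results are therefore reproducible to floating-point rounding
  (~1e-14 relative), with the tie tolerance above keeping discrete
  outputs (cluster counts, p-values) stable.

## 3. Time axis and cross-temporal analysis

Epochs are stored on a half-open grid: −800..0 ms at 1,000 Hz is the 800
samples −800…−1 ms. Window cropping, in contrast, is inclusive of both
endpoints on the stored grid (`crop_window(ep, -150, -1)` keeps 150
samples). The half-open storage makes resampling arithmetic exact:
800 samples at 1,000 Hz → exactly 240 at 300 Hz, matching 240 × 240
cross-temporal matrices.

Downsampling (unavoidable before the quadratic-cost cross-temporal step)
is polyphase: zero-stuff by p, apply a zero-phase FIR low-pass at the
target Nyquist (`signal::fir1` of order 10·max(p,q), run forward-backward
with `signal::filtfilt` so no group delay is introduced), then keep every
q-th sample. A `subsample` mode (nearest-sample decimation, no filter) is
provided for exactness tests on signals known to be smooth. Validation:
a 10 Hz sinusoid resampled 1,000 → 300 Hz correlates > 0.999 with its
analytic sampling away from the filter's edge transients.

The cross-temporal matrix of a pair puts time-in-sentence-i on rows and
time-in-sentence-j on columns; swapping the trials transposes it, so only
unordered pairs are stored, oriented by sentence-id order, and no
symmetrization is applied. Regression is per cell with the same three
regressors; the fit streams over pairs accumulating normal equations
(4 × S² running sums), so the full pairs × S × S stack is never resident.
Cells touched by any undefined correlation are flagged missing rather than
fitted on a shifting pair set. Two properties tie the stages together:
the diagonal of each predicted condition matrix equals the time-resolved
condition signal computed on the same downsampled epochs (checked to
1e-8), and effects planted only in disjoint windows produce no
off-diagonal generalization (checked exactly in the noise-free case).

## 4. Inferential layer

* **Chance level**: median over time of the across-condition average of
  the grand-average signals; an explicit override is available when a
  study-specific value is preferred.
* **Window detection**: per-sample one-sample t against chance,
  Benjamini–Yekutieli adjustment (valid under arbitrary dependence —
  neighbouring samples are strongly dependent), maximal runs of adjusted
  p < α, and the envelope from earliest onset to latest offset.
* **Cluster-mass permutation test**: paired t-series of condition A − B;
  clusters are contiguous runs with t above the cluster-forming threshold
  (default 2.04 ≈ the two-tailed 5% critical t at 30 df); the null is the
  maximum cluster mass under per-participant condition-label swaps, which
  for paired signals is sign-flipping of the differences. Whether such
  shuffling should instead pool across participants is ambiguous in the
  literature this implements; the per-participant swap is this package's
  choice and is stated, not claimed, to be the original one. The test is
  one-sided positive by default (hypotheses are "more similar than
  Unrelated"); a two-sided mode forms negative clusters as well.
* **Jack-knife latency**: for each leave-one-out subsample the t-series is
  recomputed, the largest suprathreshold cluster acts as a mask, and the
  latency of its maximum t is extracted. Latency sets of two conditions
  are compared by sign-flip permutation of the paired leave-one-out
  differences. Two t statistics accompany the permutation p: a naive
  paired t on the leave-one-out values, and the jack-knife-corrected
  statistic whose standard error carries the (n−1) inflation required for
  leave-one-out estimates (Miller-style). Leave-one-out values are nearly
  identical by construction, so the naive t is wildly anticonservative —
  it is reported only for comparability with analyses that use it; the
  corrected statistic is the default for interpretation. Comparisons are
  gated on both effects being significant in the full-sample cluster test;
  subsamples where an effect vanishes are flagged unstable and dropped
  pairwise.
* **Cross-temporal clusters**: one-sample test per cell against 0,
  clusters under 4-connectivity (diagonal touches do not connect),
  max-cluster sign-flip null, and Bonferroni multiplication by the number
  of condition tests (default 4), capped at 1.

## 5. The synthetic generator

`make_lexicon()` builds pseudo-words grouped two ways: form families
(shared 5-letter stems → high edit similarity) and taxonomy branches
(shared parent → high Lin similarity), with the two groupings decoupled by
a seeded permutation so the regressors stay distinguishable. Word nodes
carry count 2 under their branch, giving within-branch Lin similarity
log(n/size)/log(n) and 0 across branches.

`simulate_epochs()` mixes, at each time sample, a sentence-unique spatial
pattern with shared patterns scheduled by `effect_schedule()`: the
semantic-branch pattern inside the semantic window, the form-family
pattern inside the form window, and the word pattern (shared only by
sentences expecting the same word) inside the word-specific window, plus
white Gaussian sensor noise. Amplitudes are pattern-share fractions of a
convex mixture, so expected pair correlations are analytically computable
(≈ a²/((1−a)²+a²) at a window peak for a sharing pair, noise-free).
Activation follows a raised-cosine profile inside each window — zero at
the edges, maximal at the centre — so planted peak latencies are well
defined on the sample grid. Every participant receives a random
orthogonal rotation of all patterns within the zero-mean channel
subspace: patterns differ across participants, the planted correlation
structure does not, and group-level statistics stay honest.

Defaults (chosen once, as study conditions, not tuning knobs): 12 words ×
2 sentences, 34 channels, 1,000 Hz over −800..0 ms, 24 participants,
signal scale 2, noise sd 1, windows semantic −672..−657 ms, form
−650..−644 ms, word-specific −650..−614 ms, pattern shares 0.6 / 0.55 /
0.7. The windows plant the semantic → form → word-specific ordering that
the latency machinery must recover, with realistic gaps (~16 and ~14 ms).
The shares were calibrated so the planted cluster masses are of the order
reported in EEG studies of this design (tens of summed t-units; the
narrow 7-ms form window otherwise leaves a single suprathreshold sample
and a form cluster no latency analysis could use). With these values the
recovered per-sample t peaks sit at the planted window centres
(−663 / −647 / −633 ms at 24 participants).

Two deliberate idealizations, and what they imply:

* Noise is white per channel and sample. Real EEG noise is temporally
  autocorrelated (1/f) and spatially correlated, which is why real data
  show a nonzero chance level (≈ 0.02 in the motivating literature) while
  the simulation's sits near 0. A pink-noise option exists
  (`noise_model = "pink"`) but is off by default to keep the oracle
  arithmetic analytic. Passing tests therefore validate the *pipeline's
  arithmetic and inference*, not robustness to structured noise.
* Shared components are family-structured (binary sharing), while the
  semantic predictor is graded Lin similarity; within a family the
  planted correlation is flat. The regression slope remains positive and
  the timing is exact, but the generator does not test the fine-grained
  linearity of similarity in Lin values.

With `orthonormal = TRUE` (and a lexicon small enough that all patterns
fit below the channel count), patterns are mutually orthogonal and
orthogonal to the constant vector, making pairwise correlations *exactly*
zero outside planted windows — the basis of the package's exactness tests.

## 6. Problem sizes in the test suite

The validation suite runs at sizes chosen to make each property sharp
rather than large: oracle equivalences on 1,000 random string pairs;
noise-free beta recovery on the full 94-sentence / 4,371-pair design;
type-I calibration of the cluster test on 200 null replicates of 20
participants × 60 samples at 1,000 permutations (observed rate must fall
in [0.02, 0.09]); and latency-ordering recovery on 50 replicates of the
default 24-participant recipe at 1,000 permutations, cropped to
−730..−550 ms where all planted windows live. The 1,000-permutation
setting is a scaled-down stand-in for the 100,000 permutations a
publication-grade run would use (and which `run_pipeline()` defaults to);
it bounds the resolvable p at ~0.001, which is ample for calibration and
recovery checks.

## 7. Known limitations

* Inputs are cleaned epochs; no preprocessing (filtering, re-referencing,
  artifact correction) is provided or planned.
* The cross-temporal analysis is the correlation/RSA variant of temporal
  generalization; no classifier-based decoding.
* No regularized or robust regression variants; no TFCE or Bayesian
  cluster inference.
* The jack-knife permutation test treats leave-one-out latencies as
  paired observations; its permutation p shares the anticonservatism of
  the naive t when effects are deterministic across subsamples, which is
  why the corrected t is reported alongside and preferred.
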