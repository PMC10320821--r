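---
title: "Models and methods behind lexcon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind lexcon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lexcon)
```

This vignette documents the statistical machinery of `lexcon`: the models it
fits, the estimators it defines, the synthetic data it generates, and the
numerical and design choices a maintainer or reviewer would want stated
explicitly. It states no empirical result beyond what the package's own test
suite computes.

## The scientific setting

Three word properties systematically shape fixation durations during
reading: word **length** (characters, punctuation excluded), **frequency**
(negative log2 unigram probability: rarer words carry more bits), and
**surprisal** (negative log2 probability in sentence context). Reading
times per word are summarised by three nested measures — First Fixation
(FF), Gaze Duration (GD: the first pass, from entering the word until first
leaving it) and Total Fixation (TF: all fixations on the word) — capturing
successively later stages of processing.

The package's focus is the comparison of these effects between native (L1)
and non-native (L2) readers: their functional form (is the response to
log-scale predictors superlinear?), their magnitude (per-participant
average slowdown in ms), and their dependence on L2 proficiency measured by
a 0–50 placement-test score.

## Annotation and exclusions

Frequency comes from a `(word, count)` table (case-folded by default, as in
standard subtitle-based norms); surprisal from any language model
implementing the two-generic contract `lm_tokenize()` /
`lm_conditional_prob()`. When a model splits a word into sub-tokens, the
word's surprisal is the sum of sub-token surprisals — by the chain rule
this equals the negative log probability of the whole word regardless of
the split. The bundled model is a word-level add-lambda bigram; large
neural LMs can be wrapped behind the same contract.

Analyses use only tokens that survive the standard exclusions, applied in a
fixed order with one recorded reason per removed row: sentence-initial and
-final words, words containing any punctuation character (Unicode `P*`;
configurable), words containing any digit, out-of-vocabulary or
zero-probability words, and words the participant skipped (no fixation of
any kind — first-pass-only skipping definitions exist in the literature,
but nothing downstream depends on the distinction, so the simplest
definition is the default). The reasons partition the removed rows, so
`retained + sum(removed) = input` is asserted in tests.

## The additive models

Two model families are fitted with `mgcv` (the de-facto standard penalized
GAM implementation), using cubic regression splines with basis dimension
`k = 20` for current- and previous-word property smooths and penalized
identity (random-effect) blocks for participants:

* the **surprisal model**: smooths of current and previous surprisal,
  tensor-product smooths `te(freq, len)` for the current and previous word
  (frequency and length are correlated and jointly nonlinear), and
  participant random effects (intercept, surprisal slope, and a random
  coefficient for the frequency × length interaction, spelled
  `s(subj, freq, len, bs = "re")` in mgcv);
* the **frequency/length model**: separate univariate smooths of surprisal,
  frequency and length for both words, with per-property participant random
  slopes.

Previous-word (`prev_`) terms absorb spillover: the well-established
carry-over of a word's processing cost onto the next fixation.

Numerical choices:

* **Smoothing criterion**: fast REML (`bam(..., method = "fREML",
  discrete = TRUE)`) by default, plain REML with `gam()` for small
  per-participant fits, GCV available as a switch; the criterion actually
  used is recorded in every `FitResult`.
* **Knots** are placed at equally spaced covariate quantiles (mgcv's
  default for `bs = "cr"`), which is robust to the right-skewed surprisal
  and frequency distributions.
* **Basis dimension** is reduced automatically (with a warning) for
  covariates with fewer distinct values than `k` — word length typically
  has ~10 distinct values.
* **Centering**: every univariate spline's partial effect is reported under
  the sum-to-zero convention (mean zero over the fitting data). `bam`'s
  discretized path absorbs identifiability by dropping coefficients rather
  than centering, so the package computes and stores the centering offset
  at fit time; tests assert the convention to 1e-6 ms.
* **Out-of-range evaluation** extends the boundary segment linearly (a
  natural cubic spline is linear beyond its boundary knots; the package
  enforces this by explicit tangent extension, independent of backend).
  The number of extrapolated corpus words is recorded on every evaluation.

Oracle properties asserted in the tests: with smoothing parameters forced
to zero the fit equals unpenalized basis least squares; forced to
infinity, each second-derivative-penalized smooth collapses to a straight
line; fitted values decompose exactly into intercept + term contributions;
noiseless linear data is recovered with slope error below 1%.

## Slowdown effects and the lexicon–context tradeoff

Per-participant effect sizes come from the same models with all
random-effect terms dropped, fitted on that participant's rows only
(participants under 200 retained rows are skipped — below that, individual
smooths are not reliably estimable). For property `p` with partial effect
`s_ip`, the **average slowdown** is

    Slowdown_ip = (1/|C|) * sum_{w in C} s_ip(p(w))

evaluated at every word of the reference corpus `C`, so all participants
are averaged over identical material even though each read different
sentences. The partial effect enters **anchored at zero property value**
(`s_ip(0) = 0`): a hypothetical zero-bit, zero-length word incurs no
slowdown, so a linear effect of `b` ms/bit contributes `b * x` at `x` bits
and the corpus average reduces to `b * mean(p)` exactly — the closed form
the tests verify to 1e-10 relative tolerance. Anchoring is what makes
slowdowns comparable across participants; centered effects would average
to ~0 over the fitting corpus by construction.

The **tradeoff statistic** is the within-participant difference
`Diff_i = Slowdown_i,freq − Slowdown_i,surp`; positive values indicate
reliance on context-invariant lexical information over contextual
prediction. Group contrasts use Welch's unequal-variance t-test (group
sizes and variances differ substantially between L1 and L2 samples);
within-group frequency-vs-surprisal contrasts use the paired t-test.

## Superlinearity testing

To test whether a property's effect is convex in its log-scale predictor,
the current-word smooth is replaced by a linear term, a quadratic term,
and a per-participant random slope on the quadratic (penalized as its own
block), all other terms unchanged; the fixed quadratic coefficient is
Wald-tested against the penalized-fit summary's reference distribution.
The test suite calibrates this test by Monte Carlo: under a linear
generative model its rejection rate at alpha = 0.05 stays within the
binomial band [0.03, 0.08] over 500 simulated datasets of about 5,000
retained rows (20 participants), and under a quadratic curvature of
1 ms/bit² at ~20,000 rows its power exceeds 0.9 with the estimated
curvature signed correctly in over 95% of rejecting runs.

## Bootstrap bands

Confidence bands for partial effects resample **participants** with
replacement (cluster bootstrap) — the resampling unit matches the random
effect structure, and duplicated participants are relabelled so they
remain distinct clusters in the refit. Bands are pointwise percentile
intervals over `B` refits; replicate failures are recorded and tolerated
up to 20%. Bands are deterministic given the top-level seed (each
replicate draws from its own named substream). For per-participant effect
sizes (one number per participant) the proficiency-curve band uses the
ordinary iid bootstrap over records, there being no within-cluster
structure left to respect.

## Proficiency analysis

Five pre-specified regressions relate per-participant responses (slowdown
or tradeoff values) to the proficiency score, with native readers assigned
the maximum score of 50 while keeping a separate 0/1 nativeness indicator
(an L2 reader scoring 50 remains `english = 0`: the indicator encodes
nativeness, not attainment):

* `m1: response ~ s(MPT)` — approximate significance of the smooth term;
* `m2: response ~ MPT + MPT²` — the quadratic term;
* `m3: response ~ English + MPT`, above-median-score participants only —
  the nativeness term;
* `m4: response ~ English + MPT + MPT²`, all participants — the
  nativeness term;
* `m5: response ~ MPT`, above-median-score participants — the linear term.

The median is computed over all participants (natives included at 50), and
ties at the median are excluded from "above"; a switch restricts the
m3/m5 subset to L2 readers only. All five tests are deterministic given
the records. The comprehension-accuracy proportion can substitute for the
score (rescaled to 0–50) in every analysis.

The score → CEFR mapping is the fixed interval lookup 0–16 A1, 17–21 A2,
22–31 B1, 32–36 B2, 37–50 C1 — a total monotone step function on the
score range.

## The synthetic-data generator

The generator produces data with exactly the structure the analyses
assume, so pipeline recovery is checkable against known truth.

**Corpus.** The bigram joint is `p(w, w') = u(w) u(w') t(w, w')` with
Zipfian unigram `u(r) ∝ r^(-s)` and a topic-mixture tilt: the vocabulary
is split round-robin by rank into 6 topics (so topic is independent of
frequency) and `t = (1 − ρ) + ρ·[same topic]/mass(topic)` with
`ρ = 0.5`. Both marginals equal `u` exactly, every sentence position is
marginally `u`-distributed, and surprisal varies around negative
log-frequency by roughly ±1–2 bits given frequency, keeping the two
predictors correlated (as in real text) but separately estimable. Word
length is assigned per type as `round(0.55 · freq_bits)` clipped to
[1, 15], inducing the familiar negative length–frequency correlation; word
strings are random letter sequences, so the length/punctuation/digit
machinery operates on real tokens.

**Participants.** L2 proficiency scores are drawn from a rounded
Normal(30, 10) truncated to [0, 50] (a unimodal mid-range distribution
typical of placement-test samples); natives carry 50. Comprehension
accuracy is `0.55 + 0.40·score/50` plus Normal(0, 0.04) noise, clipped to
[0, 1] — above chance for essentially everyone and increasing with
proficiency. Subject random effects are a Normal intercept (SD 20 ms) and
per-property amplitude multipliers `1 + e_p`, `e_p ~ Normal(0, 0.15)`.

**Reading times.** TF is the base intercept (200 ms) plus per-property
polynomial effects of the current word (defaults: 3 ms/bit frequency,
5 ms/bit surprisal, 2 ms/char length — effect sizes in the range reported
across the reading literature), linear spillover from the previous word
(1, 1.5, 0.5 ms/unit), the subject intercept, and Gaussian ms-scale noise
(SD 30) truncated at 1 ms. GD and FF are fixed fractions of TF (0.6, 0.4)
plus independent noise (SD 10, 8), clamped so `0 < FF ≤ GD ≤ TF` always
holds — the analyses depend only on this inclusion ordering, not on a
mechanistic eye-movement model. A configurable proportion of words (10%)
is marked skipped. Effect amplitudes can be modulated by proficiency; the
bundled `prof_mod_inverted_u()` multiplies amplitudes by
`1 + a·4t(1−t)`, `t = score/50`, producing the U-shaped
proficiency-effect relation the m-tests must detect, with unmodulated
amplitudes at both the bottom and the (native-equivalent) top.

What the generator does **not** emulate: saccade targeting and landing
positions, regressive reading paths, binocular artefacts, word
predictability from long-range or extra-sentential context, and the
heavy-tailed duration distributions of real fixations. Passing tests
therefore demonstrate that the estimators recover the quantities they
define under the assumed additive structure — not that real reading data
satisfies that structure.

**Determinism.** All randomness flows from one top-level seed through
named substreams (`substream_seed(seed, stage)`), so changing, say, the
bootstrap replicate count cannot perturb the simulated data, and repeated
runs are byte-identical.

## The sample-size simulation

A reader whose probability estimates come from a small sample will
systematically overestimate surprisal on average: negative log is convex,
so for mean-unbiased subjective probabilities `E[−log x] ≥ −log E[x]`
(Jensen), strictly when the estimates vary. The simulation asks whether
this mechanism alone could manufacture the superlinear shapes and
magnified effect sizes attributed to L2 readers:

1. learn a *subjective* bigram model from `n` sampled tokens (unsmoothed
   counts by default — tokens involving zero-count events in the
   reference, learning, or analysis models are excluded rather than
   smoothed);
2. generate reading times *exactly linear* in the subjective property
   (the generative truth must be linear for any apparent curvature to be
   an artefact);
3. regress those reading times on the property estimated from a large
   corpus — mimicking the real analysis pipeline, which never observes
   subjective values — and record the apparent slope, the apparent
   quadratic curvature with its CI, and the mean slowdown per condition,
   aggregated over replicates with Monte-Carlo SEs.

Setting the analysis corpus size to `Inf` regresses on the reference
model's exact probabilities (the clean null: curvature consistent with
zero, slope equal to the generative slope); `subjective_from =
"reference"` makes the reader's expectations exact as well. Condition
grids (corpus sizes, replicate counts) are fully configurable; the
bundled defaults (learning sizes spanning 300–50,000 tokens against a
60–300-type vocabulary, tens of replicates) are desk-scale choices sized
for the test suite, not empirical claims.

## Serialization

Result tables are CSVs stamped with the producing seed and an 8-hex
configuration hash in a leading comment line; the round trip is lossless.
Fitted models serialize their univariate smooths to JSON as (knots,
value-at-knots) pairs — a cubic regression spline is a natural cubic
spline and is fully determined by its knot values — and the restored
evaluator interpolates with a natural spline and extends linearly beyond
the knot range. Tensor and random-effect blocks are not round-tripped;
downstream effect computation only requires the univariate smooths.

## Problem sizes in the test suite

The simulations in the test suite are sized for a single CPU: calibration
studies use 500 Monte-Carlo replicates (the smallest count at which the
[0.03, 0.08] binomial band is meaningful) on ~5,000-row datasets, power
studies 100 replicates at up to ~35,000 rows, pipeline recovery 50
participants × ~1,000 words, and bootstrap examples use B between 12 and
199. Larger reproductions only require raising the corresponding
arguments.

## Known limitations

* The bundled language model is a word-level bigram; sub-word tokenization
  is supported by the contract but not shipped.
* Interest-area report dialects vary; the `column_map` mechanism covers
  renamed columns but not multi-file or wide-format reports.
* `freq_surp_diff()` compares partial effects taken from two different
  model fits per participant (surprisal from the surprisal model,
  frequency from the frequency/length model), mirroring how each curve is
  defined; a single-model variant would confound the tensor interaction.
* The Wald test for the quadratic term is mildly conservative in small
  participant samples (random-effect variances estimated at the boundary);
  its calibration is asserted only for the tested study sizes.
* Speed-normalized reading-time variants are not implemented (no accepted
  definition of the normalization); responses are raw ms.
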