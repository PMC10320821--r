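# lexcon

Eye movements during reading are shaped by three "benchmark" word
properties: **word length**, **word frequency** (operationalised as negative
log unigram probability, in bits) and **surprisal** (negative log
probability in context, in bits). `lexcon` is a tidy R pipeline for
quantifying these influences on fixation durations in native (L1) and
non-native (L2) readers, and for asking how they trade off against each
other as a function of second-language proficiency.

It is aimed at psycholinguists working with word-level fixation reports
(e.g. interest-area reports from sentence-reading experiments) who want to
go beyond linear models of log-frequency and surprisal effects.

## What it computes

For each fixation measure — First Fixation (FF), Gaze Duration (GD), Total
Fixation (TF), with FF ≤ GD ≤ TF — reading times are modelled with
penalized cubic-regression-spline additive models (fitted via mgcv):

    RT ~ s(surp, k=20) + s(surp_pr, k=20) + te(freq, len) + te(freq_pr, len_pr)
         + s(subj) + s(subj, surp) + s(subj, freq, len)          [surprisal model]

    RT ~ s(surp, k=20) + s(surp_pr, k=20) + s(freq, k=20) + s(freq_pr, k=20)
         + s(len) + s(len_pr) + s(subj) + s(subj, surp)
         + s(subj, freq) + s(subj, len)                          [frequency/length model]

where `_pr` terms carry the previous word's properties (spillover) and
`s(subj, ...)` terms are participant random effects. On top of the fits,
the package provides:

- **Average slowdown effects.** For participant *i* and property *p*, the
  scalar effect size `Slowdown_ip = (1/|C|) * sum_{w in C} s_ip(p(w))`:
  the participant's partial effect (anchored at zero property value),
  evaluated at every word of the corpus *C* and averaged. A linear
  surprisal effect of 5 ms/bit contributes exactly 30 ms for a 6-bit word.
- **The lexicon–context tradeoff.** The per-participant difference
  `Diff_i` between frequency and surprisal slowdowns; positive values mean
  context-invariant lexical knowledge dominates contextual prediction.
- **Superlinearity tests.** Each property's smooth can be replaced by
  linear + quadratic terms (plus a per-participant random quadratic slope)
  and the quadratic coefficient Wald-tested.
- **Proficiency analysis.** Five regression tests (m1–m5) of how effect
  sizes relate to a 0–50 placement-test score (natives scored 50), a
  penalized-spline proficiency curve with bootstrap band, and the score →
  CEFR band lookup.
- **Cluster bootstrap bands.** Participants are resampled with replacement
  to form 95% pointwise bands for any partial effect.
- **Sample-size simulation.** A computational check of whether small
  learning samples alone can fake superlinear, magnified effects:
  subjective n-gram models learned from `n` tokens drive exactly-linear
  reading times, which are then analysed against large-corpus estimates
  (with convexity/Jensen magnification checks).
- **Synthetic data.** A seeded generator for Zipfian bigram corpora (with
  exactly preserved unigram marginals), participant profiles, and reading
  times with spillover, subject random effects and proficiency-modulated
  amplitudes — every analysis is testable end-to-end without any external
  dataset.

## Worked example

Simulate a small study in which effect amplitudes follow an inverted-U in
proficiency (peaking mid-range, L1-like at the top), then recover the
pattern with the full pipeline:

```r
library(lexcon)
library(dplyr)

study <- simulate_study(
  corpus  = corpus_spec(vocab_size = 300, n_sentences = 150, seed = 3),
  n_l1 = 6, n_l2 = 18,
  effects = effect_spec(prof_mod = prof_mod_inverted_u(1)),
  seed = 42
)
d  <- apply_exclusions(study$annotations, study$fixations)$retained
sl <- compute_slowdowns(d, measures = "tf")

sl |>
  inner_join(select(study$profiles, participant_id, group), by = "participant_id") |>
  group_by(group, property) |>
  summarise(mean_slowdown = round(mean(slowdown), 1), .groups = "drop") |>
  tidyr::pivot_wider(names_from = property, values_from = mean_slowdown)
#>   group freq freq_minus_surp length surp
#> 1    L1 18.3           -11.6    5.8 29.9
#> 2    L2 38.4           -16.2   10.9 54.6
```

Mean slowdowns are in ms per word: e.g. frequency costs the average L2
reader 38.4 ms per word against 18.3 ms for L1 readers (the generative
modulation doubles mid-proficiency amplitudes), while surprisal remains
the larger influence within both groups on Total Fixation. A Welch test
confirms the group difference for frequency:

```r
l1 <- study$profiles$participant_id[study$profiles$group == "L1"]
group_compare(sl$slowdown[sl$property == "freq" & sl$participant_id %in% l1],
              sl$slowdown[sl$property == "freq" & !sl$participant_id %in% l1])
#>   mean_l1 mean_l2     t  df p_value stars
#> 1   18.26   38.37 -3.19 6.7    0.02     *
```

and the five proficiency tests detect the U-shape (m1, m2), its falling
upper branch (m5), and no residual L1/L2 gap once proficiency is in the
model (m3, m4):

```r
rec <- proficiency_records(filter(sl, property == "freq"), study$profiles)
run_proficiency_tests(rec)
#>   test    term estimate p_value stars
#> 1   m1  s(mpt)       NA  0.0126     *
#> 2   m2   mpt^2  -0.0402  0.0253     *
#> 3   m3 english  -9.7600  0.4500   (.)
#> 4   m4 english -11.0000  0.3590   (.)
#> 5   m5     mpt  -1.5200  0.0116     *
```

`autoplot()` on a fit, `plot_effect_band()` on a `bootstrap_ci()` result,
and `plot_proficiency_curve()` give the standard curve + ribbon figures.
Each pipeline stage can also be driven from a shell via `inst/exec/lexcon`
(subcommands `simulate`, `annotate`, `measures`, `fit`, `effects`,
`proficiency`, `appendix-sim`).

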