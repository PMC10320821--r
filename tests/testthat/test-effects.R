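test_that("a linear 5 ms/bit effect contributes 30 ms at 6 bits", {
  stub <- linear_effect_stub(c(surp = 5))
  expect_identical(as.numeric(partial_effect(stub, "surp", 6)), 30)
  sl <- participant_slowdown(stub, tibble::tibble(surp = 6), "surp")
  expect_identical(sl$slowdown, 30)
})

test_that("linear slowdowns equal slope x corpus mean in closed form", {
  corp <- shared_study()$annotations
  stub <- linear_effect_stub(c(surp = 5, freq = 3, length = 2))
  for (p in c("surp", "freq", "length")) {
    got <- participant_slowdown(stub, corp, p)$slowdown
    x <- corp[[p]][!is.na(corp[[p]])]
    slope <- c(surp = 5, freq = 3, length = 2)[[p]]
    # closed form vs the brute-force average, to 1e-10 relative tolerance
    expect_equal(got, slope * mean(x), tolerance = 1e-10)
    expect_equal(got, mean(slope * x), tolerance = 1e-10)
  }
  zero <- linear_effect_stub(c(surp = 0))
  expect_identical(participant_slowdown(zero, corp, "surp")$slowdown, 0)
})

test_that("the frequency-surprisal difference is an exact antisymmetric contrast", {
  corp <- shared_study()$annotations
  stub <- linear_effect_stub(c(freq = 3, surp = 5))
  d <- freq_surp_diff(stub, corpus = corp)
  expect_equal(d$diff, d$slowdown_freq - d$slowdown_surp, tolerance = 1e-12)
  x <- corp[!is.na(corp$freq) & !is.na(corp$surp), ]
  expect_equal(d$slowdown_freq, 3 * mean(x$freq), tolerance = 1e-10)
  expect_equal(d$slowdown_surp, 5 * mean(x$surp), tolerance = 1e-10)

  # identical partial effects on identical values cancel exactly
  same <- tibble::tibble(freq = x$freq, surp = x$freq)
  stub_same <- linear_effect_stub(c(freq = 4, surp = 4))
  expect_equal(freq_surp_diff(stub_same, same)$diff, 0, tolerance = 1e-12)

  # swapping the two partial effects flips the sign
  swapped <- linear_effect_stub(c(freq = 5, surp = 3))
  d2 <- freq_surp_diff(swapped, corpus = same)
  d1 <- freq_surp_diff(linear_effect_stub(c(freq = 3, surp = 5)), corpus = same)
  expect_equal(d2$diff, -d1$diff, tolerance = 1e-10)
})

test_that("per-participant fits separate participants with different slopes", {
  corp <- generate_corpus(corpus_spec(vocab_size = 150, n_sentences = 260, seed = 23))
  ann <- annotate_corpus(corp$sentences, corp$frequency_table, corp$lm)
  prof <- generate_participants(0, 2,
    random_effect_sds = c(intercept = 0, freq = 0, surp = 0, len = 0), seed = 1
  )
  # amplitudes 3 vs 8 ms/bit, injected via per-participant modulation
  prof$re_surp <- c(3 / 5 - 1, 8 / 5 - 1)
  fx <- generate_reading_times(
    ann, prof, effect_spec(tf = list(surp = 5), spill = c(), noise_sd = 8, p_skip = 0),
    seed = 2
  )
  d <- apply_exclusions(ann, fx)$retained
  corpus <- dplyr::distinct(d, trial_id, word_index, .keep_all = TRUE)
  sl <- vapply(c("p001", "p002"), function(pid) {
    f <- suppressWarnings(fit_per_participant(
      d[d$participant_id == pid, ],
      reading_model_spec("tf", "freq_len")
    ))
    participant_slowdown(f, corpus, "surp")$slowdown
  }, numeric(1))
  truth <- c(3, 8) * mean(corpus$surp)
  expect_lt(abs(sl[1] - truth[1]) / truth[1], 0.10)
  expect_lt(abs(sl[2] - truth[2]) / truth[2], 0.10)
})

test_that("participants under the row minimum are skipped with a message", {
  d <- shared_retained()
  one <- d[d$participant_id == "p001", ]
  expect_message(
    res <- fit_per_participant(one[1:50, ], reading_model_spec("tf", "freq_len")),
    "skipped"
  )
  expect_null(res)
})

test_that("group comparison is a calibrated Welch test with star codes", {
  expect_error(group_compare(1:5, 3), class = "lexcon_config_error")
  same <- c(10, 12, 14, 16)
  res <- group_compare(same, same)
  expect_equal(res$t, 0)
  expect_identical(res$stars, "(.)")

  # type-I calibration and power by direct Monte Carlo on the test itself
  set.seed(99)
  null_p <- replicate(500, group_compare(rnorm(30, 20, 5), rnorm(60, 20, 5))$p_value)
  expect_gte(mean(null_p < 0.05), 0.03)
  expect_lte(mean(null_p < 0.05), 0.08)
  alt_p <- replicate(200, group_compare(rnorm(40, 20, 5), rnorm(40, 40, 10))$p_value)
  expect_gte(mean(alt_p < 0.01), 0.9)
})

test_that("paired comparison is antisymmetric and null at equality", {
  x <- c(3, 6, 2, 9, 4)
  expect_equal(paired_compare(x, x)$t, 0)
  y <- x + c(1, -2, 3, 0.5, -1)
  expect_equal(paired_compare(x, y)$t, -paired_compare(y, x)$t, tolerance = 1e-12)
})

test_that("compute_slowdowns returns one row per participant, property and measure", {
  d <- shared_retained()
  sub <- d[d$participant_id %in% c("p001", "p002"), ]
  sl <- suppressWarnings(compute_slowdowns(sub, measures = "tf", min_rows = 100))
  expect_setequal(
    unique(sl$property), c("freq", "surp", "length", "freq_minus_surp")
  )
  expect_identical(nrow(sl), 8L)
  wide <- tidyr::pivot_wider(
    sl[sl$property != "length", ],
    id_cols = "participant_id", names_from = "property", values_from = "slowdown"
  )
  expect_equal(wide$freq_minus_surp, wide$freq - wide$surp, tolerance = 1e-12)
})
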