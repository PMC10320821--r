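test_that("design dimensions follow basis algebra", {
  set.seed(1)
  d <- data.frame(x = runif(100), subj = factor(rep(1:10, 10)))
  # k = 4 cubic regression spline: 3 columns after the centering constraint
  sm <- mgcv::smoothCon(mgcv::s(x, bs = "cr", k = 4),
    data = d, absorb.cons = TRUE
  )[[1]]
  expect_identical(ncol(sm$X), 3L)
  # random intercept block: one indicator column per participant
  re <- mgcv::smoothCon(mgcv::s(subj, bs = "re"), data = d)[[1]]
  expect_identical(ncol(re$X), 10L)
  expect_equal(re$S[[1]], diag(10))
  # tensor product with 5 x 5 marginals: 25 columns before constraint
  d$y <- runif(100)
  te <- mgcv::smoothCon(mgcv::te(x, y, k = c(5, 5)), data = d, absorb.cons = FALSE)[[1]]
  expect_identical(ncol(te$X), 25L)
})

test_that("forced smoothing parameters recover the two analytic limits", {
  set.seed(7)
  n <- 400
  d <- tibble::tibble(
    participant_id = rep(sprintf("p%d", 1:4), each = n / 4),
    surp = runif(n, 1, 9), prev_surp = runif(n, 1, 9),
    freq = runif(n, 2, 10), prev_freq = runif(n, 2, 10),
    length = sample(1:9, n, replace = TRUE),
    prev_length = sample(1:9, n, replace = TRUE)
  )
  d$tf <- 150 + 4 * d$surp + sin(d$freq) * 8 + rnorm(n, 0, 5)
  spec <- reading_model_spec("tf", "freq_len", k = 6, random_effects = FALSE)

  # lambda -> 0: equals unpenalized least squares on the same basis
  f0 <- suppressWarnings(fit_reading_gam(d, spec, engine = "gam", sp = rep(0, 6)))
  X <- stats::model.matrix(f0$fit)
  beta_ls <- qr.coef(qr(X), d$tf)
  expect_lt(max(abs(coef(f0$fit) - beta_ls)), 1e-8)

  # lambda -> infinity: a 2nd-derivative-penalized spline collapses to a line
  finf <- suppressWarnings(fit_reading_gam(d, spec, engine = "gam", sp = rep(1e9, 6)))
  g <- seq(2, 8, length.out = 21)
  pe <- as.numeric(partial_effect(finf, "surp", g))
  curv <- diff(pe, differences = 2)
  expect_lt(max(abs(curv)), 1e-4)
})

test_that("noiseless linear data is recovered with the generator as oracle", {
  set.seed(3)
  n <- 3000
  d <- tibble::tibble(
    participant_id = rep(sprintf("p%d", 1:6), each = n / 6),
    surp = runif(n, 1, 9), prev_surp = runif(n, 1, 9),
    freq = runif(n, 2, 10), prev_freq = runif(n, 2, 10),
    length = sample(1:9, n, replace = TRUE),
    prev_length = sample(1:9, n, replace = TRUE)
  )
  d$tf <- 100 + 5 * d$surp
  f <- suppressWarnings(fit_reading_gam(
    d, reading_model_spec("tf", "freq_len", random_effects = FALSE),
    engine = "gam"
  ))
  g <- seq(1.5, 8.5, length.out = 20)
  pe <- as.numeric(partial_effect(f, "surp", g))
  slope <- coef(lm(pe ~ g))[2]
  expect_lt(abs(slope - 5), 0.05)
})

test_that("partial effects are centered and the fit decomposes additively", {
  d <- shared_retained()
  f <- suppressWarnings(fit_reading_gam(d, reading_model_spec("tf", "freq_len")))
  used <- d[stats::complete.cases(d[, c(
    "tf", "surp", "prev_surp", "freq",
    "prev_freq", "length", "prev_length"
  )]), ]
  for (v in c("surp", "freq", "length")) {
    expect_lt(abs(sum(partial_effect(f, v, used[[v]]))), 1e-6)
  }
  # fitted = intercept + sum of term contributions, row by row
  tm <- predict(f$fit, type = "terms")
  const <- attr(tm, "constant")
  if (is.null(const)) const <- unname(coef(f$fit)["(Intercept)"])
  resid_decomp <- rowSums(tm) + const - fitted(f$fit)
  expect_identical(length(resid_decomp), nrow(used))
  expect_lt(max(abs(resid_decomp)), 1e-6)
  expect_identical(f$criterion, "fREML")
})

test_that("out-of-range evaluation extends the boundary segment linearly", {
  d <- shared_retained()
  f <- suppressWarnings(fit_reading_gam(d, reading_model_spec("tf", "freq_len")))
  rng <- f$ranges$surp
  hi <- rng[2] + c(1, 2)
  pe <- partial_effect(f, "surp", c(rng[2], hi))
  expect_identical(attr(pe, "n_extrapolated"), 2L)
  # equal spacing beyond the boundary: constant increments
  expect_equal(pe[3] - pe[2], pe[2] - pe[1], tolerance = 1e-6)
})

test_that("serialized fits evaluate identically to the live fit", {
  d <- shared_retained()
  f <- suppressWarnings(fit_reading_gam(d, reading_model_spec("tf", "freq_len")))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(f, path)
  back <- read_fit_json(path)
  g <- seq(f$ranges$surp[1], f$ranges$surp[2], length.out = 31)
  expect_equal(
    as.numeric(partial_effect(back, "surp", g)),
    as.numeric(partial_effect(f, "surp", g)),
    tolerance = 1e-6
  )
})

test_that("bootstrap bands are seeded-deterministic and collapse on noiseless data", {
  corp <- generate_corpus(corpus_spec(vocab_size = 80, n_sentences = 60, seed = 31))
  ann <- annotate_corpus(corp$sentences, corp$frequency_table, corp$lm)
  prof <- generate_participants(0, 6,
    random_effect_sds = c(intercept = 0, freq = 0, surp = 0, len = 0), seed = 1
  )
  fx <- generate_reading_times(
    ann, prof,
    effect_spec(
      tf = list(surp = 5, freq = 3, len = 2), noise_sd = 0,
      gd_noise_sd = 0, ff_noise_sd = 0, p_skip = 0
    ),
    seed = 2
  )
  d <- apply_exclusions(ann, fx)$retained
  spec <- reading_model_spec("tf", "freq_len", k = 8, random_effects = FALSE)
  grid <- seq(3, 8, length.out = 11)
  b1 <- suppressWarnings(bootstrap_ci(d, spec, "surp", grid, B = 12, seed = 5, engine = "gam"))
  b2 <- suppressWarnings(bootstrap_ci(d, spec, "surp", grid, B = 12, seed = 5, engine = "gam"))
  expect_identical(b1, b2)
  # identical participants, no noise: every replicate refits the same curve
  expect_lt(max(b1$upper - b1$lower), 1e-6)
})

test_that("superlinearity test reports Wald quadratics with correct sign", {
  corp <- generate_corpus(corpus_spec(vocab_size = 150, n_sentences = 120, seed = 17))
  ann <- annotate_corpus(corp$sentences, corp$frequency_table, corp$lm)
  prof <- generate_participants(2, 8, seed = 3)
  fx <- generate_reading_times(
    ann, prof, effect_spec(tf = list(freq = 3, surp = c(5, 1.5), len = 2)),
    seed = 4
  )
  d <- apply_exclusions(ann, fx)$retained
  st <- suppressWarnings(superlinearity_test(d, "surp"))
  expect_gt(st$estimate, 0)
  expect_lt(st$p_value, 0.05)
  expect_s3_class(tidy(st), "tbl_df")
})
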