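test_that("score-to-CEFR lookup reproduces the printed boundaries and partitions", {
  expect_identical(
    mpt_to_cefr(c(0, 16, 17, 21, 22, 31, 32, 36, 37, 50)),
    c("A1", "A1", "A2", "A2", "B1", "B1", "B2", "B2", "C1", "C1")
  )
  # total monotone step function over the whole range
  all_levels <- mpt_to_cefr(0:50)
  expect_false(anyNA(all_levels))
  ord <- match(all_levels, c("A1", "A2", "B1", "B2", "C1"))
  expect_true(all(diff(ord) >= 0))
  expect_identical(
    as.integer(table(all_levels)[c("A1", "A2", "B1", "B2", "C1")]),
    c(17L, 5L, 10L, 5L, 14L)
  )
  expect_error(mpt_to_cefr(51), class = "lexcon_config_error")
  expect_error(mpt_to_cefr(-1), class = "lexcon_config_error")
})

test_that("proficiency records score natives at the maximum but keep nativeness separate", {
  sl <- tibble::tibble(
    participant_id = c("a", "b", "c"), measure = "tf", property = "freq",
    slowdown = c(10, 20, 30)
  )
  prof <- tibble::tibble(
    participant_id = c("a", "b", "c"), group = c("L1", "L2", "L2"),
    mpt = c(NA_integer_, 50L, 31L)
  )
  rec <- proficiency_records(sl, prof)
  expect_identical(rec$mpt, c(50L, 50L, 31L))
  # an L2 participant scoring 50 is still english = 0
  expect_identical(rec$english, c(1L, 0L, 0L))
  expect_identical(rec$response, c(10, 20, 30))
})

sim_records <- function(n_l2 = 300, n_l1 = 40, shape = c("u", "linear", "null"),
                        noise = 5, seed = 1) {
  shape <- match.arg(shape)
  set.seed(seed)
  mpt <- sample(0:50, n_l2, replace = TRUE)
  mu <- switch(shape,
    u = 20 + 15 * 4 * (mpt / 50) * (1 - mpt / 50),
    linear = 35 - 0.3 * mpt,
    null = rep(20, n_l2)
  )
  mu_l1 <- switch(shape,
    u = 20,
    linear = 35 - 0.3 * 50,
    null = 20
  )
  dplyr::bind_rows(
    tibble::tibble(
      participant_id = sprintf("l2_%03d", 1:n_l2), mpt = mpt,
      english = 0L, response = mu + rnorm(n_l2, 0, noise)
    ),
    tibble::tibble(
      participant_id = sprintf("l1_%03d", 1:n_l1), mpt = 50L,
      english = 1L, response = mu_l1 + rnorm(n_l1, 0, noise)
    )
  )
}

test_that("the proficiency curve localizes a generative U-shape vertex", {
  rec <- sim_records(shape = "u", seed = 11)
  cv <- fit_proficiency_curve(rec, B = 60, seed = 2)
  peak <- cv$curve$mpt[which.max(cv$curve$estimate)]
  expect_lt(abs(peak - 25), 5)
  # determinism given the seed
  cv2 <- fit_proficiency_curve(rec, B = 60, seed = 2)
  expect_identical(cv$curve, cv2$curve)
  # flat generative relation: fitted range smaller than the band width
  rec0 <- sim_records(shape = "null", seed = 12)
  cv0 <- fit_proficiency_curve(rec0, B = 60, seed = 3)
  expect_lt(
    max(cv0$curve$estimate) - min(cv0$curve$estimate),
    max(cv0$curve$upper - cv0$curve$lower)
  )
})

test_that("m1-m5 are deterministic and detect the shapes they target", {
  rec <- sim_records(shape = "u", seed = 21)
  t1 <- run_proficiency_tests(rec)
  t2 <- run_proficiency_tests(rec)
  expect_identical(t1, t2)
  expect_identical(t1$test, c("m1", "m2", "m3", "m4", "m5"))
  # strong U-shape: nonlinearity flagged by both m1 and m2, negative quadratic
  expect_lt(t1$p_value[t1$test == "m1"], 0.001)
  expect_lt(t1$p_value[t1$test == "m2"], 0.001)
  expect_lt(t1$estimate[t1$test == "m2"], 0)
  # L1 indistinguishable from top L2 here: m3 non-significant
  expect_gt(t1$p_value[t1$test == "m3"], 0.05)
  # descending top half of the U: m5 slope negative
  expect_lt(t1$estimate[t1$test == "m5"], 0)
})

test_that("m5 recovers a negative above-median slope under a linear relation", {
  hits <- vapply(1:40, function(s) {
    tt <- run_proficiency_tests(sim_records(shape = "linear", seed = 100 + s))
    tt$estimate[tt$test == "m5"] < 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("comprehension accuracy summarises outcomes and substitutes for the score", {
  qa <- tibble::tibble(
    participant_id = "p1",
    correct = c(rep(TRUE, 117), rep(FALSE, 39))
  )
  out <- comprehension_proficiency(qa)
  expect_equal(out$accuracy, 0.75)
  expect_identical(out$n_questions, 156L)
  expect_equal(
    comprehension_proficiency(tibble::tibble(participant_id = "q", correct = TRUE))$accuracy, 1
  )
  expect_equal(comprehension_proficiency(qa, rescale_to = 50)$accuracy, 37.5)

  # when the generator ties accuracy to proficiency, curves on either
  # variable agree (rank correlation of fitted values > 0.8)
  prof <- generate_participants(0, 300, seed = 9)
  resp <- 20 + 15 * 4 * (prof$mpt / 50) * (1 - prof$mpt / 50) + rnorm(300, 0, 4)
  rec_mpt <- tibble::tibble(
    participant_id = prof$participant_id, mpt = prof$mpt,
    english = 0L, response = resp
  )
  rec_acc <- rec_mpt
  rec_acc$mpt <- round(50 * prof$comprehension_accuracy)
  cv_m <- fit_proficiency_curve(rec_mpt, B = 20, seed = 1)
  cv_a <- fit_proficiency_curve(rec_acc, B = 20, seed = 1)
  # accuracy is (noisily) linear in the score, so position along either grid
  # corresponds; the two fitted curves must share their shape
  expect_gt(
    cor(cv_m$curve$estimate, cv_a$curve$estimate, method = "spearman"), 0.8
  )
})
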