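#' Map a proficiency test score to a CEFR band
#'
#' Interval lookup on the 0-50 placement-test scale:
#' 0-16 A1, 17-21 A2, 22-31 B1, 32-36 B2, 37-50 C1.
#'
#' @param score Integer vector in `[0, 50]`.
#' @return Character vector of CEFR levels.
#' @export
#' @examples
#' mpt_to_cefr(c(0, 16, 17, 37, 50))
mpt_to_cefr <- function(score) {
  if (any(is.na(score)) || any(score < 0 | score > 50)) {
    abort_lexcon("scores must lie in [0, 50]", "lexcon_config_error")
  }
  as.character(cut(score,
    breaks = c(-1, 16, 21, 31, 36, 50),
    labels = c("A1", "A2", "B1", "B2", "C1")
  ))
}

#' Build per-participant proficiency records
#'
#' Joins per-participant responses (slowdown or difference effects) with
#' profiles, assigning native readers the maximum proficiency score (50) and
#' an `english` 0/1 nativeness indicator. L2 participants who score 50 keep
#' `english = 0`: the indicator encodes nativeness, not the score.
#'
#' @param slowdowns Tibble from [compute_slowdowns()] (or any tibble with
#'   `participant_id` and a response column).
#' @param profiles Participant tibble with `participant_id`, `group`, `mpt`.
#' @param response Name of the response column (default `"slowdown"`).
#' @return Tibble with `participant_id`, `mpt`, `english`, `response` plus
#'   any grouping columns (`measure`, `property`) present.
#' @export
proficiency_records <- function(slowdowns, profiles, response = "slowdown") {
  d <- dplyr::inner_join(
    slowdowns, profiles[, c("participant_id", "group", "mpt")],
    by = "participant_id"
  )
  d$mpt <- ifelse(d$group == "L1", 50L, d$mpt)
  d$english <- as.integer(d$group == "L1")
  d$response <- d[[response]]
  keep <- intersect(
    c("participant_id", "measure", "property", "mpt", "english", "response"),
    names(d)
  )
  d[, keep]
}

#' Smooth proficiency curve through L2 effect sizes
#'
#' Fits a penalized spline `response ~ s(mpt)` through the L2 records only,
#' with a bootstrap (records resampled with replacement; effect sizes are
#' one-per-participant, so there is no within-cluster structure to respect)
#' percentile band, and returns the L1 reference mean with a
#' normal-approximation CI.
#'
#' @param records Tibble from [proficiency_records()] for one (property,
#'   measure).
#' @param B Bootstrap replicates (default 199).
#' @param seed Integer seed; bands are reproducible given the seed.
#' @param grid_n Evaluation grid size over the observed L2 score range.
#' @param k Spline basis dimension (default 10, reduced for few distinct
#'   scores).
#' @return List with `curve` (tibble `mpt`, `estimate`, `lower`, `upper`) and
#'   `l1` (one-row tibble `mean`, `lower`, `upper`, `n`).
#' @export
fit_proficiency_curve <- function(records, B = 199, seed = 1, grid_n = 101, k = 10) {
  l2 <- records[records$english == 0, ]
  if (nrow(l2) < 20) abort_lexcon("need >= 20 L2 records", "lexcon_config_error")
  if (dplyr::n_distinct(l2$mpt) < 2) {
    abort_lexcon("all proficiency scores identical", "lexcon_config_error")
  }
  k <- min(k, dplyr::n_distinct(l2$mpt))
  fml <- stats::as.formula(sprintf('response ~ s(mpt, bs = "cr", k = %d)', k))
  grid <- tibble::tibble(mpt = seq(min(l2$mpt), max(l2$mpt), length.out = grid_n))
  fit <- mgcv::gam(fml, data = l2, method = "REML")
  est <- as.numeric(stats::predict(fit, grid))
  curves <- matrix(NA_real_, B, grid_n)
  for (b in seq_len(B)) {
    idx <- with_seed(
      substream_seed(seed, paste0("prof-boot-", b)),
      sample.int(nrow(l2), nrow(l2), replace = TRUE)
    )
    res <- tryCatch(
      {
        fb <- mgcv::gam(fml, data = l2[idx, ], method = "REML")
        as.numeric(stats::predict(fb, grid))
      },
      error = function(e) NULL
    )
    if (!is.null(res)) curves[b, ] <- res
  }
  l1 <- records$response[records$english == 1]
  l1_row <- if (length(l1) >= 2) {
    half <- stats::qnorm(0.975) * stats::sd(l1) / sqrt(length(l1))
    tibble::tibble(mean = mean(l1), lower = mean(l1) - half, upper = mean(l1) + half, n = length(l1))
  } else {
    tibble::tibble(mean = NA_real_, lower = NA_real_, upper = NA_real_, n = length(l1))
  }
  list(
    curve = tibble::tibble(
      mpt = grid$mpt, estimate = est,
      lower = apply(curves, 2, stats::quantile, probs = 0.025, na.rm = TRUE),
      upper = apply(curves, 2, stats::quantile, probs = 0.975, na.rm = TRUE)
    ),
    l1 = l1_row
  )
}

#' The five proficiency-shape hypothesis tests
#'
#' Runs, on per-participant effect sizes with native readers scored 50:
#' \describe{
#'   \item{m1}{`response ~ s(MPT)` - approximate significance of the smooth
#'     term (is the proficiency relation non-flat/non-linear?).}
#'   \item{m2}{`response ~ MPT + MPT^2` - the quadratic term (is it curved?).}
#'   \item{m3}{`response ~ English + MPT` on above-median-score participants
#'     only - the nativeness indicator (are top L2 readers distinguishable
#'     from natives?).}
#'   \item{m4}{`response ~ English + MPT + MPT^2` on all participants - the
#'     nativeness indicator.}
#'   \item{m5}{`response ~ MPT` on above-median-score participants - the
#'     linear term (do effects still shrink with proficiency at the top?).}
#' }
#' The median is computed over all records (natives included at 50); ties at
#' the median are excluded from "above". All five tests are deterministic
#' given the records.
#'
#' @param records Tibble from [proficiency_records()] for one (property,
#'   measure).
#' @param above_median `"all"` (default: subset keeps both groups) or
#'   `"l2_only"`.
#' @return Tibble with one row per test: `test`, `term`, `estimate` (`NA`
#'   for the smooth term), `p_value`, `stars`.
#' @export
run_proficiency_tests <- function(records, above_median = c("all", "l2_only")) {
  above_median <- match.arg(above_median)
  if (!any(records$english == 1) || !any(records$english == 0)) {
    abort_lexcon("records must include both native and non-native readers", "lexcon_config_error")
  }
  d <- records
  d$mpt2 <- d$mpt^2
  med <- stats::median(d$mpt)
  top <- d[d$mpt > med, ]
  if (above_median == "l2_only") top <- top[top$english == 0, ]
  if (nrow(top) == 0) abort_lexcon("above-median subset is empty", "lexcon_config_error")

  k1 <- min(10, dplyr::n_distinct(d$mpt))
  m1 <- mgcv::gam(response ~ s(mpt, bs = "cr", k = k1), data = d, method = "REML")
  s1 <- summary(m1)$s.table
  p1 <- unname(s1[1, "p-value"])

  wald <- function(fit, term) {
    ct <- summary(fit)$coefficients
    c(est = ct[term, 1], p = ct[term, 4])
  }
  m2 <- stats::lm(response ~ mpt + mpt2, data = d)
  w2 <- wald(m2, "mpt2")
  m3 <- stats::lm(response ~ english + mpt, data = top)
  w3 <- if ("english" %in% rownames(summary(m3)$coefficients) &&
    !is.na(stats::coef(m3)["english"])) {
    wald(m3, "english")
  } else {
    c(est = NA_real_, p = NA_real_)
  }
  m4 <- stats::lm(response ~ english + mpt + mpt2, data = d)
  w4 <- wald(m4, "english")
  m5 <- stats::lm(response ~ mpt, data = top)
  w5 <- wald(m5, "mpt")

  tibble::tibble(
    test = c("m1", "m2", "m3", "m4", "m5"),
    term = c("s(mpt)", "mpt^2", "english", "english", "mpt"),
    estimate = c(NA_real_, w2["est"], w3["est"], w4["est"], w5["est"]),
    p_value = c(p1, w2["p"], w3["p"], w4["p"], w5["p"]),
    stars = p_stars(c(p1, w2["p"], w3["p"], w4["p"], w5["p"]))
  )
}

#' Comprehension accuracy as an alternative proficiency measure
#'
#' Proportion of correctly answered comprehension questions per participant,
#' optionally rescaled to the placement-test range so it can substitute for
#' the test score in every proficiency analysis.
#'
#' @param outcomes Tibble with `participant_id` and logical/0-1 `correct`
#'   (one row per question).
#' @param rescale_to `NULL` (keep proportions in `[0, 1]`) or a numeric
#'   maximum (e.g. `50`) to put accuracy on the score scale.
#' @return Tibble `(participant_id, n_questions, accuracy)`.
#' @export
#' @examples
#' qa <- tibble::tibble(participant_id = "p1", correct = c(rep(TRUE, 117), rep(FALSE, 39)))
#' comprehension_proficiency(qa)$accuracy # 0.75
comprehension_proficiency <- function(outcomes, rescale_to = NULL) {
  stopifnot(all(c("participant_id", "correct") %in% names(outcomes)))
  out <- outcomes |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_questions = dplyr::n(),
      accuracy = mean(as.numeric(.data$correct)),
      .groups = "drop"
    )
  if (any(out$n_questions == 0)) {
    abort_lexcon("participants need >= 1 question outcome", "lexcon_config_error")
  }
  if (!is.null(rescale_to)) out$accuracy <- out$accuracy * rescale_to
  out
}
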