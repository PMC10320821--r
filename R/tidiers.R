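#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the terms of a fitted reading-time model
#'
#' One row per smooth term with effective degrees of freedom and the
#' approximate significance test from the penalized-fit summary.
#'
#' @param x A `reading_gam_fit`.
#' @param ... Unused.
#' @return Tibble `(term, edf, ref_df, statistic, p_value)`.
#' @export
tidy.reading_gam_fit <- function(x, ...) {
  st <- summary(x$fit)$s.table
  tibble::tibble(
    term = rownames(st),
    edf = unname(st[, "edf"]),
    ref_df = unname(st[, "Ref.df"]),
    statistic = unname(st[, 3]),
    p_value = unname(st[, 4])
  )
}

#' One-row summary of a fitted reading-time model
#'
#' @param x A `reading_gam_fit`.
#' @param ... Unused.
#' @return Tibble with the measure, model family, sample size, smoothing
#'   criterion and its value, residual SD and deviance explained.
#' @export
glance.reading_gam_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble::tibble(
    measure = x$spec$measure, model = x$spec$model, n = x$n,
    criterion = x$criterion, criterion_value = x$criterion_value,
    sigma = sqrt(s$scale), deviance_explained = s$dev.expl
  )
}

#' @export
tidy.superlinearity_test <- function(x, ...) {
  tibble::tibble(
    property = x$property, measure = x$measure,
    estimate = x$estimate, se = x$se,
    p_value = x$p_value, stars = x$stars, n = x$n
  )
}
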