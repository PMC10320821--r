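#' Specify a reading-time additive model
#'
#' Two model families are used throughout. The surprisal model predicts a
#' fixation measure from penalized cubic regression splines of current- and
#' previous-word surprisal (basis dimension `k`), tensor-product smooths of
#' (frequency, length) for the current and previous word, and participant
#' random effects (intercept, surprisal slope, and a random coefficient for
#' the frequency-length interaction). The frequency/length model replaces the
#' tensor terms with separate splines of frequency and length (current and
#' previous) plus per-property participant random slopes. Per-participant
#' fits drop all random-effect terms ([strip_random_effects()]).
#'
#' @param measure Response column: `"ff"`, `"gd"` or `"tf"`.
#' @param model `"surprisal"` or `"freq_len"`.
#' @param k Spline basis dimension for current/previous word property smooths
#'   (default 20; reduced automatically, with a warning, for covariates with
#'   fewer distinct values).
#' @param random_effects Include participant random-effect terms?
#' @return An object of class `reading_model_spec`.
#' @export
reading_model_spec <- function(measure = c("tf", "gd", "ff"),
                               model = c("surprisal", "freq_len"),
                               k = 20, random_effects = TRUE) {
  measure <- match.arg(measure)
  model <- match.arg(model)
  if (k < 3) abort_lexcon("spline basis dimension k must be >= 3", "lexcon_config_error")
  structure(
    list(measure = measure, model = model, k = k, random_effects = random_effects),
    class = "reading_model_spec"
  )
}

#' @rdname reading_model_spec
#' @param spec A `reading_model_spec`.
#' @export
strip_random_effects <- function(spec) {
  spec$random_effects <- FALSE
  spec
}

# resolve basis dimensions against the data and assemble the mgcv formula
build_formula <- function(spec, data) {
  kk <- function(var, k) {
    nu <- dplyr::n_distinct(data[[var]][is.finite(data[[var]])])
    if (nu < k) {
      warning(sprintf(
        "reducing k from %d to %d for '%s' (%d distinct values)", k, max(nu, 3), var, nu
      ), call. = FALSE)
      k <- max(nu, 3)
    }
    k
  }
  sm <- function(var, k) sprintf('s(%s, bs = "cr", k = %d)', var, kk(var, k))
  terms <- if (spec$model == "surprisal") {
    c(
      sm("surp", spec$k), sm("prev_surp", spec$k),
      'te(freq, length, bs = "cr")', 'te(prev_freq, prev_length, bs = "cr")',
      if (spec$random_effects) {
        c(
          's(subj, bs = "re")', 's(subj, surp, bs = "re")',
          's(subj, freq, length, bs = "re")'
        )
      }
    )
  } else {
    c(
      sm("surp", spec$k), sm("prev_surp", spec$k),
      sm("freq", spec$k), sm("prev_freq", spec$k),
      sm("length", 10), sm("prev_length", 10),
      if (spec$random_effects) {
        c(
          's(subj, bs = "re")', 's(subj, surp, bs = "re")',
          's(subj, freq, bs = "re")', 's(subj, length, bs = "re")'
        )
      }
    )
  }
  stats::as.formula(
    paste(spec$measure, "~", paste(terms, collapse = " + ")),
    env = globalenv()
  )
}

model_vars <- function(spec) {
  c(
    "surp", "prev_surp", "freq", "prev_freq", "length", "prev_length",
    if (spec$random_effects) "subj"
  )
}

#' Fit a penalized-spline reading-time model
#'
#' Fits the model described by a [reading_model_spec()] with mgcv, selecting
#' smoothing parameters by fast restricted maximum likelihood (the default)
#' or generalized cross-validation. The criterion actually used is recorded
#' in the result. Each spline term carries the standard sum-to-zero
#' identifiability constraint, so its partial effect is centered over the
#' observed covariate values.
#'
#' @param data Tibble holding the response column and `surp`, `freq`,
#'   `length`, their `prev_` copies, and `participant_id` (rows with missing
#'   values in any used variable are dropped).
#' @param spec A [reading_model_spec()].
#' @param criterion `"REML"` (fast REML via [mgcv::bam()] / REML via
#'   [mgcv::gam()]) or `"GCV"`.
#' @param engine `"bam"` (fast, default for random-effect models) or
#'   `"gam"`.
#' @param sp Optional vector of forced smoothing parameters (mgcv order);
#'   `0` gives the unpenalized basis least-squares fit, very large values
#'   collapse a second-derivative-penalized spline to a straight line.
#' @param ... Passed on to the mgcv fitting function.
#' @return Object of class `reading_gam_fit`: the mgcv fit plus the spec,
#'   the criterion name/value and observed covariate ranges.
#' @export
fit_reading_gam <- function(data, spec, criterion = c("REML", "GCV"),
                            engine = c("bam", "gam"), sp = NULL, ...) {
  stopifnot(inherits(spec, "reading_model_spec"))
  criterion <- match.arg(criterion)
  engine <- match.arg(engine)
  need <- c(spec$measure, setdiff(model_vars(spec), "subj"), "participant_id")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort_lexcon(paste("data lacks columns:", paste(miss, collapse = ", ")), "lexcon_config_error")
  }
  d <- data[stats::complete.cases(data[, need]), need]
  d$subj <- factor(d$participant_id)
  for (v in setdiff(names(d), c("subj", "participant_id"))) {
    if (!all(is.finite(d[[v]]))) abort_lexcon(sprintf("non-finite values in '%s'", v), "lexcon_config_error")
    if (v != spec$measure && stats::var(d[[v]]) == 0) {
      abort_lexcon(sprintf("zero-variance covariate '%s'", v), "lexcon_config_error")
    }
  }
  fml <- build_formula(spec, d)
  method <- if (engine == "bam") {
    if (criterion == "REML") "fREML" else "GCV.Cp"
  } else {
    if (criterion == "REML") "REML" else "GCV.Cp"
  }
  fit <- if (engine == "bam") {
    mgcv::bam(fml, data = d, method = method, sp = sp, discrete = criterion == "REML", ...)
  } else {
    mgcv::gam(fml, data = d, method = method, sp = sp, ...)
  }
  ranges <- lapply(
    stats::setNames(nm = setdiff(need, c(spec$measure, "participant_id"))),
    function(v) range(d[[v]])
  )
  # enforce the sum-to-zero identifiability convention for every univariate
  # spline regardless of how the backend absorbed it (bam's discrete path
  # uses coefficient-drop constraints, which leave terms uncentered)
  offsets <- list()
  for (sm in fit$smooth) {
    if (length(sm$term) == 1L && !inherits(sm, "random.effect") &&
      sm$term %in% names(d)) {
      X <- mgcv::PredictMat(sm, d[, sm$term, drop = FALSE])
      beta <- stats::coef(fit)[sm$first.para:sm$last.para]
      offsets[[sm$term]] <- mean(X %*% beta)
    }
  }
  structure(
    list(
      fit = fit, spec = spec, formula = fml,
      criterion = method, criterion_value = as.numeric(fit$gcv.ubre),
      n = nrow(d), ranges = ranges, offsets = offsets
    ),
    class = "reading_gam_fit"
  )
}

#' @export
print.reading_gam_fit <- function(x, ...) {
  cat(sprintf(
    "<reading_gam_fit> %s model for %s, n = %d, %s = %.4g\n",
    x$spec$model, toupper(x$spec$measure), x$n, x$criterion, x$criterion_value
  ))
  invisible(x)
}

find_univariate_smooth <- function(fit, var) {
  for (sm in fit$fit$smooth) {
    if (length(sm$term) == 1L && sm$term == var &&
      !inherits(sm, "random.effect")) {
      return(sm)
    }
  }
  abort_lexcon(sprintf("no univariate smooth of '%s' in this fit", var), "lexcon_config_error")
}

#' Evaluate the centered partial effect of one smooth term
#'
#' Returns the contribution, in ms, of the penalized spline of `var` at the
#' given covariate values. The partial effect is centered: it sums to zero
#' over the covariate values seen when fitting. Outside the observed
#' covariate range the curve is continued by linear extension of the boundary
#' segment; the number of extrapolated points is attached as attribute
#' `n_extrapolated`.
#'
#' This is the per-word integrand of the average-slowdown statistic (see
#' [participant_slowdown()]): e.g. for a participant whose surprisal partial
#' effect is linear at 5 ms/bit, a word with 6 bits of surprisal contributes
#' 30 ms.
#'
#' @param fit A `reading_gam_fit` (or [linear_effect_stub()]).
#' @param var Covariate name: `"surp"`, `"freq"` or `"length"`.
#' @param x Numeric values at which to evaluate.
#' @return Numeric vector of ms values, attribute `n_extrapolated`.
#' @export
partial_effect <- function(fit, var, x) UseMethod("partial_effect")

#' @export
partial_effect.reading_gam_fit <- function(fit, var, x) {
  sm <- find_univariate_smooth(fit, var)
  rng <- fit$ranges[[var]]
  xc <- pmin(pmax(x, rng[1]), rng[2])
  beta <- stats::coef(fit$fit)[sm$first.para:sm$last.para]
  ctr <- fit$offsets[[var]] %||% 0
  eval_sm <- function(v) {
    X <- mgcv::PredictMat(sm, stats::setNames(data.frame(v), var))
    drop(X %*% beta) - ctr
  }
  y <- eval_sm(xc)
  out_lo <- x < rng[1]
  out_hi <- x > rng[2]
  if (any(out_lo) || any(out_hi)) {
    h <- diff(rng) * 1e-4
    if (any(out_lo)) {
      slope <- (eval_sm(rng[1] + h) - eval_sm(rng[1])) / h
      y[out_lo] <- y[out_lo] + slope[1] * (x[out_lo] - rng[1])
    }
    if (any(out_hi)) {
      slope <- (eval_sm(rng[2]) - eval_sm(rng[2] - h)) / h
      y[out_hi] <- y[out_hi] + slope[1] * (x[out_hi] - rng[2])
    }
  }
  attr(y, "n_extrapolated") <- sum(out_lo) + sum(out_hi)
  y
}

#' A fitted-model stub with a known linear partial effect
#'
#' Useful for worked examples and closed-form checks: behaves like a fitted
#' reading-time model whose partial effect for each named property is exactly
#' `slope * x` (already centered by construction at 0).
#'
#' @param slopes Named numeric, ms per unit, e.g. `c(surp = 5)`.
#' @return Object of class `linear_effect_stub` supporting [partial_effect()].
#' @export
#' @examples
#' stub <- linear_effect_stub(c(surp = 5))
#' partial_effect(stub, "surp", 6) # 30 ms
linear_effect_stub <- function(slopes) {
  stopifnot(is.numeric(slopes), !is.null(names(slopes)))
  structure(list(slopes = slopes), class = "linear_effect_stub")
}

#' @export
partial_effect.linear_effect_stub <- function(fit, var, x) {
  if (!var %in% names(fit$slopes)) {
    abort_lexcon(sprintf("stub has no slope for '%s'", var), "lexcon_config_error")
  }
  y <- unname(fit$slopes[[var]]) * x
  attr(y, "n_extrapolated") <- 0L
  y
}

#' Test a word-property effect for superlinearity
#'
#' Refits the relevant reading-time model with the current-word smooth of the
#' property replaced by a linear term, a quadratic term, and a
#' per-participant random slope for the quadratic term, all other terms
#' unchanged, and returns the Wald p-value for the fixed quadratic
#' coefficient.
#'
#' @param data As for [fit_reading_gam()].
#' @param property `"surp"`, `"freq"` or `"length"`.
#' @param spec Model specification; defaults to the surprisal model for
#'   surprisal and the frequency/length model otherwise, on measure
#'   `measure`.
#' @param measure Response used when `spec` is `NULL`.
#' @param engine,criterion As for [fit_reading_gam()].
#' @return Object of class `superlinearity_test`: property, measure,
#'   quadratic estimate, SE, p-value, star code.
#' @export
superlinearity_test <- function(data, property = c("surp", "freq", "length"),
                                spec = NULL, measure = "tf",
                                engine = c("bam", "gam"),
                                criterion = c("REML", "GCV")) {
  property <- match.arg(property)
  engine <- match.arg(engine)
  criterion <- match.arg(criterion)
  if (is.null(spec)) {
    spec <- reading_model_spec(
      measure = measure,
      model = if (property == "surp") "surprisal" else "freq_len"
    )
  }
  need <- c(spec$measure, setdiff(model_vars(spec), "subj"), "participant_id")
  d <- data[stats::complete.cases(data[, intersect(need, names(data))]), ]
  d$subj <- factor(d$participant_id)
  d$.q <- d[[property]]^2
  fml <- build_formula(spec, d)
  rhs <- attr(stats::terms(fml), "term.labels")
  target <- sprintf("s(%s, bs = \"cr\"", property)
  keep <- !startsWith(gsub(" ", "", rhs), gsub(" ", "", target))
  rhs <- c(
    property, ".q",
    if (spec$random_effects) 's(subj, .q, bs = "re")',
    rhs[keep]
  )
  fml2 <- stats::as.formula(
    paste(spec$measure, "~", paste(rhs, collapse = " + ")),
    env = globalenv()
  )
  method <- if (engine == "bam") {
    if (criterion == "REML") "fREML" else "GCV.Cp"
  } else if (criterion == "REML") "REML" else "GCV.Cp"
  fit <- if (engine == "bam") {
    mgcv::bam(fml2, data = d, method = method, discrete = criterion == "REML")
  } else {
    mgcv::gam(fml2, data = d, method = method)
  }
  pt <- summary(fit)$p.table
  row <- pt[".q", , drop = TRUE]
  structure(
    list(
      property = property, measure = spec$measure,
      estimate = unname(row[1]), se = unname(row[2]),
      p_value = unname(row[4]), stars = p_stars(unname(row[4])),
      n = nrow(d)
    ),
    class = "superlinearity_test"
  )
}

#' @export
print.superlinearity_test <- function(x, ...) {
  cat(sprintf(
    "Superlinearity of %s on %s: quadratic = %.4g (SE %.3g), p = %.3g %s\n",
    x$property, toupper(x$measure), x$estimate, x$se, x$p_value, x$stars
  ))
  invisible(x)
}

#' Cluster-bootstrap confidence band for a partial effect
#'
#' Resamples participants with replacement `B` times (the cluster bootstrap,
#' matching the participant random-effect structure), refits the model on
#' each resample, evaluates the partial effect of `var` on `grid`, and
#' returns pointwise percentile bands at level `level`. Replicates whose
#' refit fails are recorded and skipped; more than 20% failures is an error.
#'
#' @param data,spec,engine,criterion As for [fit_reading_gam()].
#' @param var Covariate whose partial effect is banded.
#' @param grid Numeric evaluation grid.
#' @param B Number of bootstrap replicates (>= 1; >= 50 recommended for
#'   reporting).
#' @param seed Integer seed; bands are reproducible given the seed.
#' @param level Coverage level (default 0.95).
#' @return Tibble `(x, estimate, lower, upper)` with attributes `B_failed`
#'   and `B`.
#' @export
bootstrap_ci <- function(data, spec, var, grid, B = 199, seed = 1, level = 0.95,
                         engine = c("bam", "gam"), criterion = c("REML", "GCV")) {
  engine <- match.arg(engine)
  criterion <- match.arg(criterion)
  if (B < 1) abort_lexcon("B must be >= 1", "lexcon_config_error")
  base_fit <- fit_reading_gam(data, spec, engine = engine, criterion = criterion)
  est <- partial_effect(base_fit, var, grid)
  ids <- unique(data$participant_id)
  curves <- matrix(NA_real_, B, length(grid))
  failed <- 0L
  for (b in seq_len(B)) {
    take <- with_seed(
      substream_seed(seed, paste0("bootstrap-", b)),
      sample(ids, length(ids), replace = TRUE)
    )
    boot <- purrr::map_dfr(seq_along(take), function(j) {
      d <- data[data$participant_id == take[j], , drop = FALSE]
      d$participant_id <- sprintf("boot%03d", j) # duplicated clusters stay distinct
      d
    })
    res <- tryCatch(
      partial_effect(
        fit_reading_gam(boot, spec, engine = engine, criterion = criterion),
        var, grid
      ),
      error = function(e) NULL
    )
    if (is.null(res)) failed <- failed + 1L else curves[b, ] <- res
  }
  if (failed > 0.2 * B) {
    abort_lexcon(sprintf("%d of %d bootstrap refits failed", failed, B), "lexcon_bootstrap_error")
  }
  a <- (1 - level) / 2
  out <- tibble::tibble(
    x = grid,
    estimate = as.numeric(est),
    lower = apply(curves, 2, stats::quantile, probs = a, na.rm = TRUE),
    upper = apply(curves, 2, stats::quantile, probs = 1 - a, na.rm = TRUE)
  )
  attr(out, "B") <- B
  attr(out, "B_failed") <- failed
  out
}

#' Serialize the univariate partial effects of a fit to JSON
#'
#' A cubic regression spline is a natural cubic spline, fully determined by
#' its values at the knots; each univariate smooth is therefore stored as
#' (knots, value-at-knots) pairs. [read_fit_json()] restores an evaluator
#' (class `partial_effect_table`) that interpolates with a natural cubic
#' spline and extends linearly beyond the knot range, so downstream effect
#' computations can run from saved fits. Tensor and random-effect blocks are
#' not serialized.
#'
#' @param fit A `reading_gam_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "reading_gam_fit"))
  sms <- list()
  for (sm in fit$fit$smooth) {
    if (length(sm$term) == 1L && !inherits(sm, "random.effect") && !is.null(sm$xp)) {
      v <- sm$term
      sms[[v]] <- list(knots = as.numeric(sm$xp), values = as.numeric(partial_effect(fit, v, as.numeric(sm$xp))))
    }
  }
  jsonlite::write_json(
    list(
      measure = fit$spec$measure, model = fit$spec$model,
      criterion = fit$criterion, criterion_value = fit$criterion_value,
      n = fit$n, smooths = sms,
      coefficients = as.list(stats::coef(fit$fit)),
      smoothing_parameters = as.list(fit$fit$sp)
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(smooths = x$smooths, measure = x$measure, model = x$model),
    class = "partial_effect_table"
  )
}

#' @export
partial_effect.partial_effect_table <- function(fit, var, x) {
  sm <- fit$smooths[[var]]
  if (is.null(sm)) abort_lexcon(sprintf("no serialized smooth for '%s'", var), "lexcon_config_error")
  kx <- sm$knots
  ky <- sm$values
  f <- stats::splinefun(kx, ky, method = "natural")
  y <- f(pmin(pmax(x, min(kx)), max(kx)))
  lo <- x < min(kx)
  hi <- x > max(kx)
  if (any(lo)) y[lo] <- y[lo] + f(min(kx), deriv = 1) * (x[lo] - min(kx))
  if (any(hi)) y[hi] <- y[hi] + f(max(kx), deriv = 1) * (x[hi] - max(kx))
  attr(y, "n_extrapolated") <- sum(lo) + sum(hi)
  y
}
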