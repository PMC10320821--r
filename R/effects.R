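#' Fit a reading-time model for a single participant
#'
#' The per-participant version of the additive model: identical term
#' structure with all random-effect terms dropped, fitted on that
#' participant's retained rows only. Participants with fewer than `min_rows`
#' rows are skipped (returns `NULL` with a message), since their smooths are
#' not reliably estimable.
#'
#' @param data Retained rows for one participant (see [apply_exclusions()]).
#' @param spec A [reading_model_spec()]; its random-effect terms are removed.
#' @param min_rows Minimum retained rows (default 200).
#' @param engine mgcv engine, `"gam"` by default (small single-subject fits).
#' @return A `reading_gam_fit`, or `NULL` when skipped.
#' @export
fit_per_participant <- function(data, spec, min_rows = 200, engine = c("gam", "bam")) {
  engine <- match.arg(engine)
  if (nrow(data) < min_rows) {
    message(sprintf(
      "participant %s skipped: %d rows < minimum %d",
      data$participant_id[1] %||% "?", nrow(data), min_rows
    ))
    return(NULL)
  }
  fit_reading_gam(data, strip_random_effects(spec), engine = engine)
}

#' Average slowdown effect of a word property (per participant)
#'
#' The participant's scalar effect size for property `p`: the partial effect
#' `s_ip` of the property in their individual model, evaluated at the
#' property's value for every word of the corpus and averaged,
#' `(1/|C|) * sum_w s_ip(p(w))`. The partial effect enters anchored at zero
#' property value (`s_ip(0) = 0` ms: a hypothetical zero-bit,
#' zero-length word incurs no slowdown), so that a linear effect of slope
#' `b` ms/bit contributes `b * x` ms at `x` bits and the average equals
#' `b * mean_C(p)` exactly. Fitted splines are centered; anchoring subtracts
#' their value at 0, reached by linear extension of the boundary segment.
#' Corpus words outside the participant's fitted covariate range are
#' evaluated the same way; their number is attached as `n_extrapolated`.
#'
#' @param fit A `reading_gam_fit`, [linear_effect_stub()], or restored
#'   [read_fit_json()] evaluator.
#' @param corpus The annotated corpus rows over which to average (the
#'   retained word tokens); must carry the property column.
#' @param property `"surp"`, `"freq"` or `"length"`.
#' @return A one-row tibble `(property, slowdown, n_words, n_extrapolated)`.
#' @export
#' @examples
#' stub <- linear_effect_stub(c(surp = 5))
#' participant_slowdown(stub, tibble::tibble(surp = 6), "surp")$slowdown # 30
participant_slowdown <- function(fit, corpus, property = c("surp", "freq", "length")) {
  property <- match.arg(property)
  x <- corpus[[property]]
  if (is.null(x)) abort_lexcon(sprintf("corpus lacks column '%s'", property), "lexcon_config_error")
  x <- x[!is.na(x)]
  y <- partial_effect(fit, property, x)
  anchor <- as.numeric(partial_effect(fit, property, 0))
  tibble::tibble(
    property = property,
    slowdown = mean(y) - anchor,
    n_words = length(x),
    n_extrapolated = attr(y, "n_extrapolated") %||% 0L
  )
}

#' Frequency-surprisal slowdown difference (lexicon-context tradeoff)
#'
#' The per-participant difference between the frequency and surprisal
#' slowdown effects,
#' `(1/|C|) * sum_w [s_freq(freq(w)) - s_surp(surp(w))]`. Positive values
#' indicate that context-invariant lexical information (frequency) dominates
#' contextual predictability (surprisal) for this participant.
#'
#' @inheritParams participant_slowdown
#' @return One-row tibble `(diff, slowdown_freq, slowdown_surp)`.
#' @export
freq_surp_diff <- function(fit, corpus) {
  sf <- participant_slowdown(fit, corpus, "freq")
  ss <- participant_slowdown(fit, corpus, "surp")
  tibble::tibble(
    diff = sf$slowdown - ss$slowdown,
    slowdown_freq = sf$slowdown,
    slowdown_surp = ss$slowdown
  )
}

#' Per-participant slowdown effects for a whole study
#'
#' Chains [fit_per_participant()] and [participant_slowdown()] /
#' [freq_surp_diff()] over all participants, properties and measures:
#' Eq.-style effect sizes for downstream group comparison and proficiency
#' analysis. For each measure, surprisal slowdowns come from the surprisal
#' model and frequency/length slowdowns from the frequency/length model.
#'
#' @param data Retained analysis rows (annotations joined with measures; see
#'   [apply_exclusions()]), all participants.
#' @param corpus Annotated corpus rows to average over (defaults to the
#'   distinct (trial, word) rows of `data`).
#' @param measures Character subset of `c("ff", "gd", "tf")`.
#' @param properties Character subset of `c("freq", "surp", "length")`.
#' @param k Basis dimension passed to [reading_model_spec()].
#' @param min_rows Passed to [fit_per_participant()].
#' @param diff Also compute the frequency-surprisal difference per
#'   participant and measure?
#' @return Tibble `(participant_id, measure, property, slowdown,
#'   n_extrapolated)`, plus rows with `property = "freq_minus_surp"` when
#'   `diff = TRUE`.
#' @export
compute_slowdowns <- function(data, corpus = NULL, measures = c("ff", "gd", "tf"),
                              properties = c("freq", "surp", "length"),
                              k = 20, min_rows = 200, diff = TRUE) {
  if (is.null(corpus)) {
    corpus <- dplyr::distinct(data, .data$trial_id, .data$word_index, .keep_all = TRUE)
  }
  model_for <- function(p) if (p == "surp") "surprisal" else "freq_len"
  purrr::map_dfr(split(data, data$participant_id), function(d) {
    pid <- d$participant_id[1]
    purrr::map_dfr(measures, function(m) {
      fits <- list()
      rows <- purrr::map_dfr(properties, function(p) {
        mod <- model_for(p)
        if (is.null(fits[[mod]])) {
          fits[[mod]] <<- fit_per_participant(
            d, reading_model_spec(measure = m, model = mod, k = k),
            min_rows = min_rows
          )
        }
        f <- fits[[mod]]
        if (is.null(f)) {
          return(tibble::tibble())
        }
        sl <- participant_slowdown(f, corpus, p)
        tibble::tibble(
          participant_id = pid, measure = m, property = p,
          slowdown = sl$slowdown, n_extrapolated = sl$n_extrapolated
        )
      })
      if (diff && nrow(rows) && all(c("freq", "surp") %in% rows$property)) {
        rows <- dplyr::bind_rows(rows, tibble::tibble(
          participant_id = pid, measure = m, property = "freq_minus_surp",
          slowdown = rows$slowdown[rows$property == "freq"] -
            rows$slowdown[rows$property == "surp"],
          n_extrapolated = NA_integer_
        ))
      }
      rows
    })
  })
}

#' Welch comparison of slowdown effects between L1 and L2
#'
#' Welch two-sample t-test on per-participant slowdown effects, with group
#' means, normal-approximation 95% confidence intervals and the conventional
#' star code.
#'
#' @param l1,l2 Numeric vectors of per-participant slowdowns (>= 2 each).
#' @return One-row tibble: group means, CI bounds, `t`, `df`, `p_value`,
#'   `stars`.
#' @export
group_compare <- function(l1, l2) {
  l1 <- l1[!is.na(l1)]
  l2 <- l2[!is.na(l2)]
  if (length(l1) < 2 || length(l2) < 2) {
    abort_lexcon("each group needs >= 2 participants", "lexcon_config_error")
  }
  tt <- stats::t.test(l1, l2) # Welch by default
  ci <- function(x) stats::qnorm(0.975) * stats::sd(x) / sqrt(length(x))
  tibble::tibble(
    mean_l1 = mean(l1), lower_l1 = mean(l1) - ci(l1), upper_l1 = mean(l1) + ci(l1),
    mean_l2 = mean(l2), lower_l2 = mean(l2) - ci(l2), upper_l2 = mean(l2) + ci(l2),
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value, stars = p_stars(tt$p.value)
  )
}

#' Paired comparison of surprisal vs frequency slowdowns within a group
#'
#' Paired t-test on per-participant `surp - freq` slowdown differences
#' (positive mean: surprisal effects dominate frequency effects).
#'
#' @param freq,surp Paired numeric vectors (same participants, same order).
#' @return One-row tibble `(mean_diff, t, df, p_value, stars)`.
#' @export
paired_compare <- function(freq, surp) {
  ok <- !is.na(freq) & !is.na(surp)
  freq <- freq[ok]
  surp <- surp[ok]
  if (length(freq) < 2) abort_lexcon("need >= 2 pairs", "lexcon_config_error")
  if (all(surp - freq == 0)) {
    # identical columns: zero difference with zero variance
    return(tibble::tibble(
      mean_diff = 0, t = 0, df = length(freq) - 1, p_value = 1, stars = "(.)"
    ))
  }
  tt <- stats::t.test(surp, freq, paired = TRUE)
  tibble::tibble(
    mean_diff = unname(tt$estimate), t = unname(tt$statistic),
    df = unname(tt$parameter), p_value = tt$p.value, stars = p_stars(tt$p.value)
  )
}
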