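#' Learn a subjective language model from a small sample
#'
#' Emulates a reader whose probability estimates come from limited exposure:
#' samples an `n`-token corpus from the true generative bigram model and
#' returns add-lambda count estimates. With `smoothing = 0` (the default
#' policy), events unseen in the learning sample have probability zero and
#' are flagged; downstream analysis excludes tokens involving such
#' zero-count events rather than smoothing them.
#'
#' @param true_lm The generative `bigram_lm` (see [generate_corpus()]).
#' @param n Target number of learning tokens (>= 1).
#' @param smoothing Add-lambda constant (default 0).
#' @param seed Integer seed.
#' @param sentence_length Integer `(min, max)` sentence-length range used
#'   when sampling the learning corpus.
#' @return A `bigram_lm` with `meta$n_tokens`, `meta$smoothing` and
#'   `meta$zero_unigram` (words never seen).
#' @export
learn_subjective_lm <- function(true_lm, n, smoothing = 0, seed = 1,
                                sentence_length = c(5, 12)) {
  stopifnot(inherits(true_lm, "bigram_lm"))
  if (n < 1) abort_lexcon("learning-sample size must be >= 1", "lexcon_config_error")
  sen <- sample_sentences(true_lm, n, seed, sentence_length)
  train_bigram_lm(sen, vocab = true_lm$vocab, smoothing = smoothing)
}

# sample sentences from a bigram_lm until >= n tokens are emitted
sample_sentences <- function(lm, n_tokens, seed, sentence_length = c(5, 12)) {
  v <- length(lm$vocab)
  with_seed(substream_seed(seed, "sample-sentences"), {
    out_tok <- integer(0)
    out_trial <- character(0)
    out_idx <- integer(0)
    i <- 0L
    while (length(out_tok) < n_tokens) {
      i <- i + 1L
      L <- sample(seq(sentence_length[1], sentence_length[2]), 1L)
      s <- integer(L)
      s[1] <- sample.int(v, 1L, prob = lm$unigram)
      if (L > 1) for (k in 2:L) s[k] <- sample.int(v, 1L, prob = lm$cond[s[k - 1L], ])
      out_tok <- c(out_tok, s)
      out_trial <- c(out_trial, rep(sprintf("r%05d", i), L))
      out_idx <- c(out_idx, 0:(L - 1L))
    }
    tibble::tibble(trial_id = out_trial, word_index = out_idx, word = lm$vocab[out_tok])
  })
}

#' Simulate reading times driven by subjective word probabilities
#'
#' The reader's response is linear in their subjective property value:
#' `RT(w) = intercept + slope * x_subjective(w) + noise`, where the property
#' is surprisal (bigram conditional) or negative log-frequency (unigram)
#' under the subjective model. Tokens whose subjective value involves a
#' zero-count event get `NA` and `excluded = TRUE`.
#'
#' @param sentences Reading corpus tibble `(trial_id, word_index, word)`.
#' @param subjective_lm A `bigram_lm` (e.g. from [learn_subjective_lm()]).
#' @param slope ms per bit.
#' @param intercept Base reading time in ms.
#' @param noise_sd Gaussian noise SD in ms (>= 0).
#' @param property `"surprisal"` or `"frequency"`.
#' @param seed Integer seed (noise).
#' @return Tibble `(trial_id, word_index, word, x_subjective, rt, excluded)`.
#' @export
simulate_reader_rts <- function(sentences, subjective_lm, slope = 5, intercept = 200,
                                noise_sd = 0, property = c("surprisal", "frequency"),
                                seed = 1) {
  property <- match.arg(property)
  if (nrow(sentences) == 0) abort_lexcon("empty reading corpus", "lexcon_config_error")
  x <- lm_property_values(sentences, subjective_lm, property)
  with_seed(substream_seed(seed, "reader-noise"), {
    rt <- intercept + slope * x + stats::rnorm(length(x), 0, noise_sd)
    tibble::tibble(
      trial_id = sentences$trial_id, word_index = sentences$word_index,
      word = sentences$word, x_subjective = x, rt = rt, excluded = is.na(x)
    )
  })
}

# per-token surprisal / negative log-frequency under a bigram_lm, NA on
# zero-count events
lm_property_values <- function(sentences, lm, property) {
  if (property == "frequency") {
    p <- unname(lm$unigram[match(sentences$word, lm$vocab)])
    return(ifelse(is.na(p) | p <= 0, NA_real_, -log2(p)))
  }
  sen <- dplyr::arrange(sentences, .data$trial_id, .data$word_index)
  stopifnot(identical(sen$word, sentences$word)) # callers pass ordered corpora
  x <- numeric(nrow(sentences))
  idx <- match(sentences$word, lm$vocab)
  prev_same <- c(FALSE, sentences$trial_id[-1] == sentences$trial_id[-nrow(sentences)])
  for (k in seq_len(nrow(sentences))) {
    p <- if (!prev_same[k]) {
      lm$unigram[[idx[k]]]
    } else {
      lm$cond[idx[k - 1L], idx[k]]
    }
    x[k] <- if (is.na(p) || p <= 0) NA_real_ else -log2(p)
  }
  x
}

#' Apparent effect shapes and sizes as a function of learning-sample size
#'
#' The appendix-style computational experiment: for each learning-sample
#' size, repeatedly (a) learn a subjective model from that many tokens, (b)
#' generate reading times that are exactly linear in the subjective property,
#' (c) regress those RTs on the property estimated from a large corpus
#' (mimicking the analysis pipeline, which never sees subjective values), and
#' (d) record the apparent slope, the apparent quadratic curvature with its
#' 95% CI, and the mean-slowdown effect size. Tokens involving zero-count
#' events in the reference (true), small, or large models are excluded
#' before analysis. Replicates are aggregated with Monte-Carlo standard
#' errors.
#'
#' @param true_lm Generative `bigram_lm` (the reference model; its
#'   probabilities are exact, so it contributes no zero counts).
#' @param reading_sentences Reading corpus (e.g. from [generate_corpus()]).
#' @param small_sizes Integer vector of learning-sample sizes (>= 2 values).
#' @param large_size Tokens for the large analysis corpus; `Inf` uses the
#'   reference model's exact probabilities as the analysis predictor.
#' @param slope,intercept,noise_sd Reader response model (see
#'   [simulate_reader_rts()]).
#' @param property `"surprisal"` or `"frequency"`.
#' @param replicates Monte-Carlo replicates per condition (>= 1).
#' @param subjective_from `"sample"` (default: the reader's model is learned
#'   from `small_sizes` tokens) or `"reference"` (the reader's expectations
#'   are the true model itself - the null diagnostic, in which any apparent
#'   curvature reflects estimation noise in the analysis corpus alone).
#' @param seed Integer seed.
#' @return List with `replicates` (long tibble: one row per condition x
#'   replicate with `slope`, `curvature`, `curvature_lo`, `curvature_hi`,
#'   `slowdown`, `n_excluded`, `n_used`) and `summary` (per-condition means
#'   with Monte-Carlo SEs).
#' @export
apparent_effect_analysis <- function(true_lm, reading_sentences, small_sizes,
                                     large_size = 50000, slope = 5, intercept = 200,
                                     noise_sd = 0, property = c("surprisal", "frequency"),
                                     replicates = 20,
                                     subjective_from = c("sample", "reference"),
                                     seed = 1) {
  property <- match.arg(property)
  subjective_from <- match.arg(subjective_from)
  if (length(small_sizes) < 2) {
    abort_lexcon("need >= 2 learning-sample sizes", "lexcon_config_error")
  }
  if (replicates < 1) abort_lexcon("replicates must be >= 1", "lexcon_config_error")
  x_ref <- lm_property_values(reading_sentences, true_lm, property)
  rows <- purrr::map_dfr(small_sizes, function(n_small) {
    purrr::map_dfr(seq_len(replicates), function(r) {
      s1 <- substream_seed(seed, sprintf("appendix-%d-%d-small", n_small, r))
      s2 <- substream_seed(seed, sprintf("appendix-%d-%d-large", n_small, r))
      res <- tryCatch(
        {
          small_lm <- if (subjective_from == "reference") {
            true_lm
          } else {
            learn_subjective_lm(true_lm, n_small, smoothing = 0, seed = s1)
          }
          large_lm <- if (is.infinite(large_size)) {
            true_lm
          } else {
            learn_subjective_lm(true_lm, large_size, smoothing = 0, seed = s2)
          }
          rts <- simulate_reader_rts(
            reading_sentences, small_lm,
            slope = slope, intercept = intercept, noise_sd = noise_sd,
            property = property,
            seed = substream_seed(seed, sprintf("appendix-%d-%d-noise", n_small, r))
          )
          x_large <- lm_property_values(reading_sentences, large_lm, property)
          keep <- !is.na(x_ref) & !is.na(x_large) & !rts$excluded
          if (sum(keep) < 10) stop("too few tokens after zero-count exclusion")
          d <- data.frame(rt = rts$rt[keep], x = x_large[keep])
          fit <- stats::lm(rt ~ x + I(x^2), data = d)
          ci <- stats::confint(fit)["I(x^2)", ]
          b <- stats::coef(fit)
          tibble::tibble(
            learning_size = n_small, replicate = r,
            slope = unname(b["x"]), curvature = unname(b["I(x^2)"]),
            curvature_lo = ci[1], curvature_hi = ci[2],
            slowdown = unname(b["x"]) * mean(d$x) + unname(b["I(x^2)"]) * mean(d$x^2),
            n_excluded = sum(!keep), n_used = sum(keep)
          )
        },
        error = function(e) {
          tibble::tibble(
            learning_size = n_small, replicate = r,
            slope = NA_real_, curvature = NA_real_,
            curvature_lo = NA_real_, curvature_hi = NA_real_,
            slowdown = NA_real_, n_excluded = NA_integer_, n_used = NA_integer_
          )
        }
      )
      res
    })
  })
  summ <- rows |>
    dplyr::group_by(.data$learning_size) |>
    dplyr::summarise(
      dplyr::across(
        c("slope", "curvature", "slowdown"),
        list(
          mean = ~ mean(.x, na.rm = TRUE),
          se = ~ stats::sd(.x, na.rm = TRUE) / sqrt(sum(!is.na(.x)))
        )
      ),
      n_failed = sum(is.na(.data$slope)),
      .groups = "drop"
    )
  list(replicates = rows, summary = summ)
}

#' Monte-Carlo check of the surprisal-magnification inequality
#'
#' Negative log is convex, so for mean-unbiased subjective probabilities
#' (`E[x] = p`) the expected subjective surprisal can only exceed the
#' reference surprisal: `E[-log x] >= -log E[x]`, strictly when `Var(x) > 0`.
#' Subjective probability vectors are drawn from a Dirichlet centered on the
#' true distribution (`x ~ Dirichlet(c * p)`, so each component is unbiased);
#' `concentration = Inf` gives the degenerate draw `x = p` (gap 0 to machine
#' tolerance).
#'
#' @param p Numeric probability vector (sums to 1).
#' @param concentration Dirichlet precision `c > 0`, or `Inf`.
#' @param n_draws Monte-Carlo draws.
#' @param seed Integer seed.
#' @return Tibble per word: `p`, `reference_surprisal`,
#'   `mean_subjective_surprisal`, `gap` (bits).
#' @export
jensen_gap <- function(p, concentration = 50, n_draws = 4000, seed = 1) {
  stopifnot(abs(sum(p) - 1) < 1e-8, all(p > 0))
  v <- length(p)
  ref <- -log2(p)
  mean_subj <- if (is.infinite(concentration)) {
    ref
  } else {
    with_seed(substream_seed(seed, "jensen"), {
      acc <- numeric(v)
      for (d in seq_len(n_draws)) {
        g <- pmax(stats::rgamma(v, shape = concentration * p, rate = 1), 1e-300)
        x <- g / sum(g)
        acc <- acc - log2(x)
      }
      acc / n_draws
    })
  }
  tibble::tibble(
    p = p, reference_surprisal = ref,
    mean_subjective_surprisal = mean_subj,
    gap = mean_subj - ref
  )
}
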