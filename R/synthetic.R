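#' Specify a synthetic reading corpus
#'
#' The generator emulates a newswire-style single-sentence reading corpus:
#' Zipfian unigram frequencies, bigram (topic-mixture) conditional structure
#' so that surprisal varies around negative log-frequency, and word lengths
#' correlated with frequency.
#'
#' The bigram joint is `p(w, w') = u(w) u(w') t(w, w')` with tilt
#' `t = (1 - rho) + rho * [same topic] / mass(topic)`: both marginals are
#' exactly the Zipfian unigram `u`, every sentence position is marginally
#' `u`-distributed, and `rho` (`context_strength`) controls how much contextual
#' predictability deviates from frequency. Topics are assigned round-robin by
#' frequency rank so topic membership is independent of frequency.
#'
#' @param vocab_size Number of word types (>= 2).
#' @param zipf_exponent Zipf rank-frequency exponent `s >= 0`
#'   (`u(r) %prop% r^-s`); 0 gives a uniform unigram distribution.
#' @param n_sentences Number of sentences to emit.
#' @param sentence_length Integer `(min, max)` range; lengths are uniform on
#'   the range. `min >= 3` so interior words survive sentence-edge exclusion.
#' @param context_strength Mixture weight `rho` in `[0, 1)` of the topic
#'   component (default 0.5).
#' @param n_topics Number of topics (default 6).
#' @param length_a,length_b Word length is assigned per type as
#'   `round(length_a + length_b * (-log2 u(w)))` clipped to `[1, 15]`,
#'   inducing the natural length-frequency correlation.
#' @param seed Integer seed.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(vocab_size = 1000, zipf_exponent = 1, n_sentences = 1500,
                        sentence_length = c(5, 12), context_strength = 0.5,
                        n_topics = 6, length_a = 0, length_b = 0.55, seed = 1) {
  if (vocab_size < 2) abort_lexcon("vocab_size must be >= 2", "lexcon_config_error")
  if (zipf_exponent < 0) abort_lexcon("zipf_exponent must be >= 0", "lexcon_config_error")
  if (sentence_length[1] < 3) {
    abort_lexcon("minimum sentence length must be >= 3", "lexcon_config_error")
  }
  if (context_strength < 0 || context_strength >= 1) {
    abort_lexcon("context_strength must be in [0, 1)", "lexcon_config_error")
  }
  structure(
    list(
      vocab_size = as.integer(vocab_size), zipf_exponent = zipf_exponent,
      n_sentences = as.integer(n_sentences),
      sentence_length = as.integer(sentence_length),
      context_strength = context_strength, n_topics = as.integer(n_topics),
      length_a = length_a, length_b = length_b, seed = as.integer(seed)
    ),
    class = "corpus_spec"
  )
}

# letters-only unique word strings with target lengths (lengths may be bumped
# when a short length class is exhausted: 26 one-letter strings exist)
make_word_strings <- function(target_len) {
  used <- new.env(hash = TRUE)
  vapply(target_len, function(L) {
    repeat {
      for (try in 1:60) {
        w <- paste(sample(letters, L, replace = TRUE), collapse = "")
        if (is.null(used[[w]])) {
          used[[w]] <- TRUE
          return(w)
        }
      }
      L <- L + 1L
    }
  }, character(1))
}

#' Generate a synthetic corpus, its true bigram model, and frequency table
#'
#' @param spec A [corpus_spec()].
#' @return A list with components
#'   \describe{
#'     \item{sentences}{Tibble `(trial_id, word_index, word)`, `word_index`
#'       0-based within sentence.}
#'     \item{lm}{The true generative `bigram_lm`.}
#'     \item{frequency_table}{Tibble `(word, count)` of exact token counts of
#'       the emitted corpus (types with zero emitted tokens are absent); the
#'       emitted token total is in `attr(, "total")`.}
#'     \item{vocab}{Tibble `(word, rank, p, topic, length)` of the generative
#'       vocabulary.}
#'   }
#' @export
#' @examples
#' corp <- generate_corpus(corpus_spec(vocab_size = 50, n_sentences = 20, seed = 7))
#' head(corp$sentences)
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "corpus_spec"))
  with_seed(substream_seed(spec$seed, "corpus"), {
    v <- spec$vocab_size
    u <- (1:v)^(-spec$zipf_exponent)
    u <- u / sum(u)
    topic <- rep_len(seq_len(spec$n_topics), v) # round-robin by rank
    mass <- vapply(seq_len(spec$n_topics), function(z) sum(u[topic == z]), numeric(1))
    rho <- spec$context_strength
    same <- outer(topic, topic, "==")
    tilt <- (1 - rho) + rho * same / mass[topic][col(same)]
    cond <- sweep(tilt, 2, u, "*") # p(w'|w) = u(w') * t(w, w')
    len <- pmin(pmax(round(spec$length_a + spec$length_b * (-log2(u))), 1L), 15L)
    words <- make_word_strings(len)
    lm <- new_bigram_lm(words, u, cond, meta = list(generative = TRUE, rho = rho))

    n_sen <- spec$n_sentences
    lens <- sample(seq(spec$sentence_length[1], spec$sentence_length[2]),
      n_sen,
      replace = TRUE
    )
    tok <- integer(sum(lens))
    pos <- 1L
    for (i in seq_len(n_sen)) {
      L <- lens[i]
      s <- integer(L)
      s[1] <- sample.int(v, 1L, prob = u)
      for (k in 2:L) s[k] <- sample.int(v, 1L, prob = cond[s[k - 1L], ])
      tok[pos:(pos + L - 1L)] <- s
      pos <- pos + L
    }
    sentences <- tibble::tibble(
      trial_id = sprintf("s%05d", rep(seq_len(n_sen), lens)),
      word_index = unlist(lapply(lens, function(L) 0:(L - 1L))),
      word = words[tok]
    )
    counts <- tabulate(tok, nbins = v)
    freq_table <- tibble::tibble(word = words[counts > 0], count = counts[counts > 0])
    attr(freq_table, "total") <- sum(counts)
    list(
      sentences = sentences, lm = lm, frequency_table = freq_table,
      vocab = tibble::tibble(
        word = words, rank = seq_len(v), p = u, topic = topic,
        length = nchar(words)
      )
    )
  })
}

#' Generate synthetic participant profiles
#'
#' L1 participants are native readers and carry the maximum proficiency score
#' (50) by assignment; L2 scores are drawn from `mpt_distribution` truncated
#' to `[0, 50]`. Realized subject random effects (an intercept in ms and one
#' multiplicative amplitude deviation per word property) are drawn with the
#' given SDs. Comprehension accuracy increases with proficiency and is
#' above-chance for essentially all participants.
#'
#' @param n_l1,n_l2 Group sizes (>= 0).
#' @param mpt_distribution Function `n -> numeric` drawing raw proficiency
#'   scores for L2 participants; defaults to a rounded Normal(30, 10).
#' @param random_effect_sds Named numeric: `intercept` (ms) and one amplitude
#'   SD per property (`freq`, `surp`, `len`; unitless multipliers).
#' @param seed Integer seed.
#' @return Tibble with one row per participant: `participant_id`, `group`,
#'   `native_language`, `mpt`, `comprehension_accuracy`, `re_intercept`,
#'   `re_freq`, `re_surp`, `re_len`.
#' @export
generate_participants <- function(n_l1, n_l2,
                                  mpt_distribution = function(n) round(stats::rnorm(n, 30, 10)),
                                  random_effect_sds = c(
                                    intercept = 20, freq = 0.15,
                                    surp = 0.15, len = 0.15
                                  ),
                                  seed = 1) {
  if (n_l1 < 0 || n_l2 < 0) abort_lexcon("group sizes must be >= 0", "lexcon_config_error")
  if (any(random_effect_sds < 0)) {
    abort_lexcon("random-effect SDs must be >= 0", "lexcon_config_error")
  }
  sds <- random_effect_sds
  for (nm in c("intercept", "freq", "surp", "len")) {
    if (is.na(sds[nm])) sds[nm] <- 0
  }
  with_seed(substream_seed(seed, "participants"), {
    n <- n_l1 + n_l2
    group <- rep(c("L1", "L2"), c(n_l1, n_l2))
    l2_langs <- c("Arabic", "Chinese", "Japanese", "Portuguese", "Spanish")
    mpt <- c(
      rep(50L, n_l1),
      as.integer(pmin(pmax(mpt_distribution(n_l2), 0), 50))
    )
    tibble::tibble(
      participant_id = sprintf("p%03d", seq_len(n)),
      group = group,
      native_language = c(
        rep("English", n_l1),
        if (n_l2 > 0) sample(l2_langs, n_l2, replace = TRUE) else character(0)
      ),
      mpt = mpt,
      comprehension_accuracy = pmin(pmax(
        0.55 + 0.40 * mpt / 50 + stats::rnorm(n, 0, 0.04), 0
      ), 1),
      re_intercept = stats::rnorm(n, 0, sds[["intercept"]]),
      re_freq = stats::rnorm(n, 0, sds[["freq"]]),
      re_surp = stats::rnorm(n, 0, sds[["surp"]]),
      re_len = stats::rnorm(n, 0, sds[["len"]])
    )
  })
}

#' Specify the generative reading-time model
#'
#' Total fixation for participant i on word w is
#' `TF = base + re_intercept_i + sum_p m_i(p) f_p(x_p(w)) +
#'  sum_p spill_p x_p(w_prev) + noise`, where `f_p` is an intercept-free
#' polynomial (coefficients in ms per unit, unit^2, ...),
#' `m_i(p) = (1 + re_p_i) * prof_mod(mpt_i)` modulates amplitude by subject
#' and proficiency, and noise is Gaussian on the ms scale truncated at 1 ms.
#' Gaze duration and first fixation are generated top-down as fixed fractions
#' of TF plus independent noise, then clamped so `0 < FF <= GD <= TF`.
#'
#' @param tf Named list of polynomial coefficient vectors for the current
#'   word, per property (`freq`, `surp` in ms/bit; `len` in ms/character).
#' @param spill Named numeric of linear spillover slopes for the previous
#'   word's properties.
#' @param base Base intercept in ms.
#' @param noise_sd Residual TF noise SD in ms (>= 0).
#' @param gd_frac,ff_frac Mean fractions of TF giving GD and FF.
#' @param gd_noise_sd,ff_noise_sd Independent noise SDs (ms) for GD and FF.
#' @param p_skip Proportion of (participant, word) cells marked skipped.
#' @param prof_mod `NULL` (no proficiency modulation) or a function
#'   `mpt -> multiplier` applied to every property amplitude. See
#'   [prof_mod_inverted_u()].
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(tf = list(freq = 3, surp = 5, len = 2),
                        spill = c(freq = 1, surp = 1.5, len = 0.5),
                        base = 200, noise_sd = 30,
                        gd_frac = 0.6, ff_frac = 0.4,
                        gd_noise_sd = 10, ff_noise_sd = 8,
                        p_skip = 0.1, prof_mod = NULL) {
  if (noise_sd < 0 || gd_noise_sd < 0 || ff_noise_sd < 0) {
    abort_lexcon("noise SDs must be >= 0", "lexcon_config_error")
  }
  if (p_skip < 0 || p_skip >= 1) abort_lexcon("p_skip must be in [0, 1)", "lexcon_config_error")
  structure(
    list(
      tf = tf, spill = spill, base = base, noise_sd = noise_sd,
      gd_frac = gd_frac, ff_frac = ff_frac,
      gd_noise_sd = gd_noise_sd, ff_noise_sd = ff_noise_sd,
      p_skip = p_skip, prof_mod = prof_mod
    ),
    class = "effect_spec"
  )
}

#' Inverted-U proficiency modulation of effect amplitudes
#'
#' Returns `function(mpt)` giving `1 + amp * 4 t (1 - t)` with `t = mpt / 50`:
#' amplitude peaks mid-proficiency and equals 1 at both `mpt = 0` and
#' `mpt = 50` (so L1 readers, at 50, are unmodulated). Used to generate the
#' U-shaped proficiency-effect relation the proficiency tests must detect.
#'
#' @param amp Peak extra amplitude (default 1 doubles the effect at mpt 25).
#' @export
prof_mod_inverted_u <- function(amp = 1) {
  function(mpt) {
    t <- mpt / 50
    1 + amp * 4 * t * (1 - t)
  }
}

eval_poly <- function(coefs, x) {
  y <- 0
  for (k in seq_along(coefs)) y <- y + coefs[[k]] * x^k
  y
}

#' Generate per-participant reading times for an annotated corpus
#'
#' Every participant reads every sentence of the corpus. The generative model
#' is described in [effect_spec()].
#'
#' @param annotations Word-property annotations as returned by
#'   [annotate_corpus()] (one row per (trial, word) with `freq`, `surp`,
#'   `length` and previous-word copies).
#' @param profiles Participant tibble from [generate_participants()].
#' @param spec An [effect_spec()].
#' @param seed Integer seed.
#' @return Tibble `(participant_id, trial_id, word_index, word, skipped,
#'   ff, gd, tf)`; measures are `NA` for skipped words and satisfy
#'   `0 < ff <= gd <= tf` otherwise.
#' @export
generate_reading_times <- function(annotations, profiles, spec = effect_spec(), seed = 1) {
  stopifnot(inherits(spec, "effect_spec"))
  need <- c("trial_id", "word_index", "word", "freq", "surp", "length")
  if (!all(need %in% names(annotations))) {
    abort_lexcon(
      paste("annotations must contain:", paste(need, collapse = ", ")),
      "lexcon_config_error"
    )
  }
  if (anyNA(annotations$freq) || anyNA(annotations$surp)) {
    abort_lexcon("annotations contain unknown (unannotated) words", "lexcon_oov_error")
  }
  props <- c("freq", "surp", "len")
  x <- list(
    freq = annotations$freq, surp = annotations$surp,
    len = as.numeric(annotations$length)
  )
  xp <- list(
    freq = annotations$prev_freq %||% dplyr::lag(annotations$freq),
    surp = annotations$prev_surp %||% dplyr::lag(annotations$surp),
    len = as.numeric(annotations$prev_length %||% dplyr::lag(annotations$length))
  )
  nw <- nrow(annotations)
  with_seed(substream_seed(seed, "reading-times"), {
    out <- purrr::map_dfr(seq_len(nrow(profiles)), function(i) {
      pr <- profiles[i, ]
      mod <- if (is.null(spec$prof_mod)) 1 else spec$prof_mod(pr$mpt)
      tf <- rep(spec$base + pr$re_intercept, nw)
      for (p in props) {
        amp <- (1 + pr[[paste0("re_", p)]]) * mod
        if (!is.null(spec$tf[[p]])) tf <- tf + amp * eval_poly(spec$tf[[p]], x[[p]])
        sp <- spec$spill[[p]] %||% 0
        if (sp != 0) {
          prev <- ifelse(is.na(xp[[p]]), 0, xp[[p]])
          tf <- tf + sp * prev
        }
      }
      tf <- pmax(tf + stats::rnorm(nw, 0, spec$noise_sd), 1)
      gd <- pmax(pmin(spec$gd_frac * tf + stats::rnorm(nw, 0, spec$gd_noise_sd), tf), 1)
      ff <- pmax(pmin(spec$ff_frac * tf + stats::rnorm(nw, 0, spec$ff_noise_sd), gd), 1)
      skipped <- stats::runif(nw) < spec$p_skip
      tibble::tibble(
        participant_id = pr$participant_id,
        trial_id = annotations$trial_id,
        word_index = annotations$word_index,
        word = annotations$word,
        skipped = skipped,
        ff = ifelse(skipped, NA_real_, ff),
        gd = ifelse(skipped, NA_real_, gd),
        tf = ifelse(skipped, NA_real_, tf)
      )
    })
    out
  })
}

#' One-call synthetic study: corpus, participants, annotations, reading times
#'
#' Convenience wrapper chaining [generate_corpus()], [annotate_corpus()],
#' [generate_participants()] and [generate_reading_times()] with substreams of
#' one seed.
#'
#' @param corpus A [corpus_spec()].
#' @param n_l1,n_l2 Group sizes.
#' @param effects An [effect_spec()].
#' @param seed Top-level integer seed.
#' @param ... Passed to [generate_participants()].
#' @return List with `corpus`, `annotations`, `profiles`, `fixations`
#'   (the reading-time table).
#' @export
simulate_study <- function(corpus = corpus_spec(), n_l1 = 10, n_l2 = 40,
                           effects = effect_spec(), seed = 1, ...) {
  corpus$seed <- substream_seed(seed, "study-corpus")
  corp <- generate_corpus(corpus)
  ann <- annotate_corpus(corp$sentences, corp$frequency_table, corp$lm)
  prof <- generate_participants(n_l1, n_l2, seed = substream_seed(seed, "study-participants"), ...)
  fix <- generate_reading_times(ann, prof, effects,
    seed = substream_seed(seed, "study-rts")
  )
  list(corpus = corp, annotations = ann, profiles = prof, fixations = fix)
}
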