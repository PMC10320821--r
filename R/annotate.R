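#' Negative log2 unigram frequency (bits)
#'
#' `-log2(count / total)` looked up in a frequency table. Out-of-vocabulary
#' words yield `NA` with an OOV marker rather than a fabricated value; the
#' exclusion stage removes them.
#'
#' @param word Character vector of words.
#' @param table Frequency tibble `(word, count)`; token total is taken from
#'   `attr(table, "total")` or computed as `sum(count)`.
#' @param case_fold Lower-case words before lookup (default `TRUE`, matching
#'   case-collapsed frequency norms).
#' @return Numeric vector of bits (`>= 0`), `NA` where out of vocabulary.
#' @export
#' @examples
#' tab <- tibble::tibble(word = c("the", "cat"), count = c(512, 512))
#' neg_log_frequency("the", tab) # 1 bit
neg_log_frequency <- function(word, table, case_fold = TRUE) {
  total <- attr(table, "total") %||% sum(table$count)
  key <- if (case_fold) tolower(table$word) else table$word
  qry <- if (case_fold) tolower(word) else word
  cnt <- table$count[match(qry, key)]
  -log2(cnt / total)
}

#' Word length excluding punctuation
#'
#' Characters in the Unicode punctuation categories (`\\p{P}`) are removed
#' before counting. A word that is empty after stripping has length 0 (the
#' exclusion stage flags it).
#'
#' @param word Character vector.
#' @param punct_pattern Regex (PCRE) matching characters to strip.
#' @return Integer vector of lengths.
#' @export
#' @examples
#' word_length(c("cat", "don't", "..."))
word_length <- function(word, punct_pattern = "\\p{P}") {
  nchar(gsub(punct_pattern, "", word, perl = TRUE))
}

#' Surprisal of a word in context (bits)
#'
#' Tokenizes `word` with the language model and sums `-log2 P(token | prefix)`
#' over its sub-tokens (the chain rule: the total equals `-log2` of the joint
#' probability of the sub-token sequence, whatever the split).
#'
#' @param word A single word.
#' @param sentence_prefix Character vector of the words preceding `word` in
#'   the sentence (already-tokenized context is built by re-tokenizing each).
#' @param lm A language model implementing [lm_tokenize()] and
#'   [lm_conditional_prob()].
#' @return Surprisal in bits (`>= 0`).
#' @export
surprisal <- function(word, sentence_prefix, lm) {
  ctx <- if (length(sentence_prefix)) {
    unlist(lapply(sentence_prefix, function(w) lm_tokenize(lm, w)))
  } else {
    character(0)
  }
  toks <- lm_tokenize(lm, word)
  total <- 0
  for (tk in toks) {
    p <- lm_conditional_prob(lm, tk, ctx)
    if (is.na(p) || p <= 0) {
      abort_lexcon(
        sprintf("zero-probability token '%s' in context", tk),
        "lexcon_zero_prob_error"
      )
    }
    total <- total - log2(p)
    ctx <- c(ctx, tk)
  }
  total
}

#' Annotate a sentence table with the three benchmark word properties
#'
#' For every token: length (punctuation excluded), negative log2 frequency,
#' surprisal given the sentence prefix, and previous-word copies of each
#' (spillover predictors; `NA` for sentence-initial words). Zero-probability
#' LM events and out-of-vocabulary words are annotated `NA` and flagged, not
#' errors: the exclusion stage consumes the flags.
#'
#' @param sentences Tibble `(trial_id, word_index, word)`; `word_index`
#'   0-based within sentence.
#' @param frequency_table Tibble `(word, count)` (see
#'   [read_frequency_table()]).
#' @param lm Language model for surprisal.
#' @param case_fold Passed to [neg_log_frequency()].
#' @param punct_pattern Passed to [word_length()].
#' @return Tibble with columns `trial_id`, `word_index`, `word`, `length`,
#'   `freq`, `surp`, `prev_length`, `prev_freq`, `prev_surp`, `oov`,
#'   `zero_prob`.
#' @export
annotate_corpus <- function(sentences, frequency_table, lm,
                            case_fold = TRUE, punct_pattern = "\\p{P}") {
  stopifnot(all(c("trial_id", "word_index", "word") %in% names(sentences)))
  sen <- dplyr::arrange(sentences, .data$trial_id, .data$word_index)
  sen$length <- word_length(sen$word, punct_pattern)
  sen$freq <- neg_log_frequency(sen$word, frequency_table, case_fold)
  surp <- numeric(nrow(sen))
  zero_prob <- logical(nrow(sen))
  for (g in split(seq_len(nrow(sen)), sen$trial_id)) {
    words <- sen$word[g]
    for (k in seq_along(g)) {
      s <- tryCatch(
        surprisal(words[k], words[seq_len(k - 1L)], lm),
        lexcon_zero_prob_error = function(e) NA_real_,
        lexcon_oov_error = function(e) NA_real_
      )
      surp[g[k]] <- s
      zero_prob[g[k]] <- is.na(s)
    }
  }
  sen$surp <- surp
  sen |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::mutate(
      prev_length = dplyr::lag(.data$length),
      prev_freq = dplyr::lag(.data$freq),
      prev_surp = dplyr::lag(.data$surp)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(oov = is.na(.data$freq), zero_prob = zero_prob)
}

#' Apply the standard word-level exclusion filters
#'
#' Removes, in order and with one reason recorded per removed row:
#' sentence-initial/final words (`sentence_edge`), words containing any
#' punctuation character (`punctuation`), words containing any digit
#' (`numeric`), out-of-vocabulary or zero-probability words (`oov`), and
#' words the participant skipped (`skipped`, zero fixations of any kind).
#' The reasons partition the removed rows; retained + removed = input rows.
#'
#' Annotations are per (trial, word); fixations are per (participant, trial,
#' word), so the filter operates on their join and `skipped` is
#' participant-specific.
#'
#' @param annotations Output of [annotate_corpus()].
#' @param fixations Measures table with `participant_id`, `trial_id`,
#'   `word_index` and a `skipped` logical (see [compute_measures()] or
#'   [generate_reading_times()]).
#' @param punct_pattern,digit_pattern Regexes (PCRE) defining "contains
#'   punctuation" / "contains a number".
#' @return List with `retained` (the joined rows that survive all filters)
#'   and `counts` (tibble `reason`, `n`, including `retained`).
#' @export
apply_exclusions <- function(annotations, fixations,
                             punct_pattern = "\\p{P}", digit_pattern = "\\p{N}") {
  key <- c("trial_id", "word_index")
  if (!all(key %in% names(fixations)) || !"participant_id" %in% names(fixations)) {
    abort_lexcon("fixations must carry participant_id, trial_id, word_index", "lexcon_config_error")
  }
  ann <- annotations |>
    dplyr::group_by(.data$trial_id) |>
    dplyr::mutate(
      .edge = .data$word_index == min(.data$word_index) |
        .data$word_index == max(.data$word_index)
    ) |>
    dplyr::ungroup()
  joined <- dplyr::inner_join(fixations, ann, by = intersect(names(fixations), names(ann)))
  if (nrow(joined) != nrow(fixations)) {
    abort_lexcon("annotation and fixation tables are misaligned", "lexcon_align_error")
  }
  reason <- dplyr::case_when(
    joined$.edge ~ "sentence_edge",
    grepl(punct_pattern, joined$word, perl = TRUE) ~ "punctuation",
    grepl(digit_pattern, joined$word, perl = TRUE) ~ "numeric",
    joined$oov | joined$zero_prob ~ "oov",
    joined$skipped ~ "skipped",
    TRUE ~ "retained"
  )
  lv <- c("sentence_edge", "punctuation", "numeric", "oov", "skipped", "retained")
  n_by_reason <- as.integer(table(factor(reason, levels = lv)))
  counts <- tibble::tibble(reason = lv, n = n_by_reason)
  retained <- joined[reason == "retained", , drop = FALSE]
  retained$.edge <- NULL
  list(retained = retained, counts = counts)
}
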