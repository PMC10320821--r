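#' Language-model contract
#'
#' Surprisal annotation is pluggable: any object that implements
#' [lm_tokenize()] and [lm_conditional_prob()] can supply conditional word
#' probabilities. The package bundles a word-level bigram model
#' ([train_bigram_lm()], and the true generative model returned by
#' [generate_corpus()]); large neural models can be wrapped behind the same
#' two generics.
#'
#' @param lm A language-model object.
#' @param word A single word string.
#' @return For `lm_tokenize()`, the ordered character vector of sub-tokens the
#'   model scores for `word` (word-level models return the word itself).
#' @name language-model
NULL

#' @rdname language-model
#' @export
lm_tokenize <- function(lm, word) UseMethod("lm_tokenize")

#' @rdname language-model
#' @param token A single sub-token produced by `lm_tokenize()`.
#' @param prefix Character vector of the sub-tokens preceding `token` in the
#'   sentence (empty for the sentence-initial token).
#' @return For `lm_conditional_prob()`, `P(token | prefix)` in `[0, 1]`.
#' @export
lm_conditional_prob <- function(lm, token, prefix) UseMethod("lm_conditional_prob")

new_bigram_lm <- function(vocab, unigram, cond, meta = list()) {
  stopifnot(
    length(vocab) == length(unigram),
    is.matrix(cond),
    nrow(cond) == length(vocab), ncol(cond) == length(vocab)
  )
  names(unigram) <- vocab
  dimnames(cond) <- list(vocab, vocab)
  structure(
    list(vocab = vocab, unigram = unigram, cond = cond, meta = meta),
    class = "bigram_lm"
  )
}

#' @export
lm_tokenize.bigram_lm <- function(lm, word) word

#' @export
lm_conditional_prob.bigram_lm <- function(lm, token, prefix) {
  i <- match(token, lm$vocab)
  if (is.na(i)) {
    abort_lexcon(
      sprintf("token '%s' is not in the model vocabulary", token),
      "lexcon_oov_error"
    )
  }
  if (length(prefix) == 0L) {
    return(unname(lm$unigram[[i]]))
  }
  j <- match(prefix[length(prefix)], lm$vocab)
  if (is.na(j)) {
    abort_lexcon(
      sprintf("context token '%s' is not in the model vocabulary", prefix[length(prefix)]),
      "lexcon_oov_error"
    )
  }
  unname(lm$cond[j, i])
}

#' @export
print.bigram_lm <- function(x, ...) {
  cat(
    "<bigram_lm> vocabulary:", length(x$vocab), "words",
    if (!is.null(x$meta$smoothing)) sprintf("(add-%g smoothing)", x$meta$smoothing),
    if (!is.null(x$meta$n_tokens)) sprintf("trained on %d tokens", x$meta$n_tokens),
    "\n"
  )
  invisible(x)
}

#' Train an add-lambda bigram language model on a sentence table
#'
#' Word-level maximum-likelihood bigram estimates with optional additive
#' (add-lambda) smoothing. With `smoothing = 0`, events unseen in training
#' have probability zero; [surprisal()] raises an error for such events, and
#' the sample-size simulation excludes them (its zero-count policy).
#'
#' @param sentences Tibble with columns `trial_id`, `word_index` (0-based) and
#'   `word`, one row per token.
#' @param vocab Optional character vector fixing the vocabulary (defaults to
#'   the words observed in `sentences`).
#' @param smoothing Non-negative add-lambda constant (default 0).
#' @return A `bigram_lm` whose conditional probabilities sum to one at every
#'   context whenever `smoothing > 0` or the context was observed.
#' @export
train_bigram_lm <- function(sentences, vocab = NULL, smoothing = 0) {
  stopifnot(all(c("trial_id", "word_index", "word") %in% names(sentences)))
  if (smoothing < 0) abort_lexcon("smoothing must be >= 0", "lexcon_config_error")
  vocab <- vocab %||% sort(unique(sentences$word))
  v <- length(vocab)
  sen <- dplyr::arrange(sentences, .data$trial_id, .data$word_index)
  idx <- match(sen$word, vocab)
  if (anyNA(idx)) {
    abort_lexcon("sentences contain words outside the supplied vocabulary", "lexcon_oov_error")
  }
  uni <- tabulate(idx, nbins = v)
  big <- matrix(0, v, v)
  # bigram counts within sentences only
  split_idx <- split(idx, sen$trial_id)
  for (s in split_idx) {
    if (length(s) >= 2L) {
      for (k in seq_len(length(s) - 1L)) big[s[k], s[k + 1L]] <- big[s[k], s[k + 1L]] + 1
    }
  }
  n_tok <- sum(uni)
  p_uni <- (uni + smoothing) / (n_tok + smoothing * v)
  ctx_tot <- rowSums(big)
  denom <- ctx_tot + smoothing * v
  cond <- (big + smoothing) / ifelse(denom > 0, denom, 1)
  # unseen context with no smoothing: fall back to the unigram distribution
  if (any(denom == 0)) cond[denom == 0, ] <- matrix(p_uni, sum(denom == 0), v, byrow = TRUE)
  new_bigram_lm(
    vocab, p_uni, cond,
    meta = list(
      smoothing = smoothing, n_tokens = n_tok,
      unigram_counts = stats::setNames(uni, vocab),
      zero_unigram = vocab[uni == 0]
    )
  )
}

#' Serialize / restore a bigram language model as JSON
#'
#' @param lm A `bigram_lm`.
#' @param path File path.
#' @return `read_bigram_lm()` returns the restored `bigram_lm`.
#' @export
write_bigram_lm <- function(lm, path) {
  stopifnot(inherits(lm, "bigram_lm"))
  jsonlite::write_json(
    list(
      vocab = lm$vocab, unigram = unname(lm$unigram),
      cond = apply(lm$cond, 1, identity, simplify = FALSE),
      meta = lm$meta[setdiff(names(lm$meta), "unigram_counts")]
    ),
    path,
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_bigram_lm
#' @export
read_bigram_lm <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cond <- if (is.list(x$cond)) do.call(rbind, x$cond) else x$cond
  new_bigram_lm(x$vocab, x$unigram, cond, meta = as.list(x$meta))
}
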