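# Shared fixtures, built once per test run.

# A small complete study: 300-type Zipf corpus, 12 participants, default
# generative effects (3 ms/bit frequency, 5 ms/bit surprisal, 2 ms/char
# length, with spillover and subject random effects).
shared_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_study(
        corpus = corpus_spec(vocab_size = 300, n_sentences = 200, seed = 3),
        n_l1 = 4, n_l2 = 8, seed = 11
      )
    }
    cache
  }
})

shared_retained <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      s <- shared_study()
      cache <<- apply_exclusions(s$annotations, s$fixations)$retained
    }
    cache
  }
})

# 12-sentence toy corpus over a 6-word vocabulary, for hand-checked bigram
# surprisal values.
toy_sentences <- function() {
  sen <- list(
    c("the", "cat", "sat"), c("the", "dog", "sat"), c("the", "cat", "ran"),
    c("a", "dog", "ran"), c("a", "cat", "sat"), c("the", "dog", "ran"),
    c("the", "cat", "sat"), c("a", "cat", "ran"), c("the", "dog", "sat"),
    c("a", "dog", "sat"), c("the", "cat", "ran"), c("a", "cat", "sat")
  )
  tibble::tibble(
    trial_id = sprintf("t%02d", rep(seq_along(sen), lengths(sen))),
    word_index = unlist(lapply(lengths(sen), function(L) 0:(L - 1))),
    word = unlist(sen)
  )
}

# a deterministic two-token toy LM used to check the chain rule:
# "ab" tokenizes into "a" (P = 1/2 in any context) and "b" (P = 1/4)
two_token_lm <- function() {
  structure(list(), class = "two_token_lm")
}
lm_tokenize.two_token_lm <- function(lm, word) {
  if (word == "ab") c("a", "b") else word
}
lm_conditional_prob.two_token_lm <- function(lm, token, prefix) {
  switch(token,
    a = 0.5,
    b = 0.25,
    sure = 1,
    0.125
  )
}
registerS3method("lm_tokenize", "two_token_lm", lm_tokenize.two_token_lm,
  envir = asNamespace("lexcon")
)
registerS3method("lm_conditional_prob", "two_token_lm", lm_conditional_prob.two_token_lm,
  envir = asNamespace("lexcon")
)
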