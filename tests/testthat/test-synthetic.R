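test_that("corpus generation is deterministic and marginally Zipfian", {
  spec <- corpus_spec(vocab_size = 200, n_sentences = 150, seed = 21)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$sentences, c2$sentences)
  expect_identical(c1$frequency_table, c2$frequency_table)
  expect_identical(c1$lm$cond, c2$lm$cond)

  # frequency table records exact token counts of the emitted corpus
  emp <- table(c1$sentences$word)
  expect_identical(
    sort(as.integer(emp)), sort(c1$frequency_table$count)
  )
  expect_identical(attr(c1$frequency_table, "total"), nrow(c1$sentences))

  # rank-frequency slope of a zipf_exponent = 1 corpus is about -1
  big <- generate_corpus(corpus_spec(
    vocab_size = 1000, zipf_exponent = 1,
    n_sentences = 12000, seed = 8
  ))
  cnt <- sort(table(big$sentences$word), decreasing = TRUE)
  top <- as.numeric(cnt[1:200]) # ranks with stable counts
  slope <- coef(lm(log(top) ~ log(seq_along(top))))[2]
  expect_lt(abs(slope - (-1)), 0.1)
})

test_that("zipf_exponent 0 yields uniform unigram frequencies", {
  corp <- generate_corpus(corpus_spec(
    vocab_size = 100, zipf_exponent = 0,
    n_sentences = 12000, seed = 2
  ))
  cnt <- table(factor(corp$sentences$word, levels = corp$vocab$word))
  x2 <- sum((cnt - mean(cnt))^2 / mean(cnt))
  expect_gt(pchisq(x2, length(cnt) - 1, lower.tail = FALSE), 0.01)
})

test_that("the generative model is a proper conditional distribution", {
  corp <- generate_corpus(corpus_spec(vocab_size = 60, n_sentences = 10, seed = 4))
  expect_equal(sum(corp$lm$unigram), 1, tolerance = 1e-12)
  expect_equal(unname(rowSums(corp$lm$cond)), rep(1, 60), tolerance = 1e-12)
  # exact stationarity: the unigram marginal is preserved by one transition
  expect_equal(
    as.numeric(corp$lm$unigram %*% corp$lm$cond),
    unname(corp$lm$unigram),
    tolerance = 1e-12
  )
  # word length correlates negatively with frequency by construction
  expect_lt(cor(corp$vocab$p, corp$vocab$length), 0)
  expect_error(corpus_spec(vocab_size = 1), class = "lexcon_config_error")
})

test_that("participant generation honours group structure and degenerate SDs", {
  p0 <- generate_participants(5, 0, seed = 1)
  expect_true(all(p0$group == "L1"))
  expect_true(all(p0$mpt == 50L))

  pz <- generate_participants(3, 3, random_effect_sds = c(
    intercept = 0, freq = 0, surp = 0, len = 0
  ), seed = 1)
  expect_true(all(pz$re_intercept == 0 & pz$re_freq == 0 & pz$re_surp == 0 & pz$re_len == 0))

  expect_error(
    generate_participants(1, 1, random_effect_sds = c(intercept = -1)),
    class = "lexcon_config_error"
  )

  # CLT check on a uniform proficiency distribution
  pu <- generate_participants(0, 10000,
    mpt_distribution = function(n) sample(0:50, n, replace = TRUE), seed = 6
  )
  se <- sd(0:50) / sqrt(10000)
  expect_lt(abs(mean(pu$mpt) - 25), 3 * se)
})

test_that("reading times reduce to the base intercept in the zero-effect case", {
  corp <- generate_corpus(corpus_spec(vocab_size = 50, n_sentences = 20, seed = 9))
  ann <- annotate_corpus(corp$sentences, corp$frequency_table, corp$lm)
  prof <- generate_participants(2, 2,
    random_effect_sds = c(intercept = 0, freq = 0, surp = 0, len = 0), seed = 2
  )
  fx <- generate_reading_times(
    ann, prof,
    effect_spec(
      tf = list(), spill = c(), noise_sd = 0,
      gd_noise_sd = 0, ff_noise_sd = 0, p_skip = 0, base = 200
    ),
    seed = 3
  )
  expect_true(all(fx$tf == 200))
  expect_true(all(fx$gd == 0.6 * 200))
  expect_true(all(fx$ff == 0.4 * 200))
})

test_that("generated measures always satisfy FF <= GD <= TF", {
  fx <- shared_study()$fixations
  ok <- !fx$skipped
  expect_true(all(fx$ff[ok] > 0))
  expect_true(all(fx$ff[ok] <= fx$gd[ok]))
  expect_true(all(fx$gd[ok] <= fx$tf[ok]))
  expect_true(all(is.na(fx$tf[!ok])))
})

test_that("reading-time generation is deterministic and recovers a pure linear effect", {
  corp <- generate_corpus(corpus_spec(vocab_size = 200, n_sentences = 300, seed = 13))
  ann <- annotate_corpus(corp$sentences, corp$frequency_table, corp$lm)
  prof <- generate_participants(0, 20,
    random_effect_sds = c(intercept = 0, freq = 0, surp = 0, len = 0), seed = 5
  )
  spec <- effect_spec(
    tf = list(surp = 5), spill = c(), noise_sd = 10, p_skip = 0
  )
  fx1 <- generate_reading_times(ann, prof, spec, seed = 7)
  fx2 <- generate_reading_times(ann, prof, spec, seed = 7)
  expect_identical(fx1, fx2)

  # OLS oracle at ~50k rows: slope recovered within 0.2 ms/bit
  d <- dplyr::inner_join(fx1, ann, by = c("trial_id", "word_index", "word"))
  expect_gte(nrow(d), 50000)
  slope <- coef(lm(tf ~ surp, data = d))["surp"]
  expect_lt(abs(slope - 5), 0.2)
})
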