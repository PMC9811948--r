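test_that("Stroop scoring counts ink-colour matches per second", {
  # all 18 correct in 20 s total -> 0.9 correct/s
  res <- score_stroop(make_stroop_trials(18L, times = 20 / 18))
  expect_equal(res$n_correct, 18L)
  expect_equal(res$total_time, 20)
  expect_equal(subtest_raw_score(res), 0.9)
  expect_true(res$completed)

  # scoring the same trial set twice is identical
  tr <- make_stroop_trials(11L, times = c(1.2, 0.8))
  expect_identical(score_stroop(tr), score_stroop(tr))

  # invalid designs are rejected
  expect_error(score_stroop(make_stroop_trials()[1:17, ]), "invalid design")
  bad <- make_stroop_trials()
  bad$ink_colour <- bad$word_text           # 18 congruent trials
  expect_error(score_stroop(bad), "congruent")
  neg <- make_stroop_trials(times = -1)
  expect_error(score_stroop(neg), "positive")
})

test_that("a skipped response makes a subtest incomplete with no raw score", {
  res <- score_stroop(make_stroop_trials(18L, skip_idx = 4L))
  expect_false(res$completed)
  expect_true(is.na(res$total_time))
  expect_true(is.na(subtest_raw_score(res)))

  res <- score_symbols(make_symbol_trials(9L, skip_idx = 2L))
  expect_false(res$completed)
  expect_true(is.na(subtest_raw_score(res)))

  res <- score_memory(make_memory_items(skip_idx = 7L))
  expect_false(res$completed)
  expect_true(is.na(subtest_raw_score(res)))
})

test_that("symbol scoring matches a per-item hand tally", {
  expect_equal(subtest_raw_score(score_symbols(
    make_symbol_trials(9L, times = 30 / 9))), 0.3)
  expect_equal(subtest_raw_score(score_symbols(
    make_symbol_trials(0L, times = 2))), 0)

  # 6 correct in 24 s -> 0.25, cross-checked by independent summation
  tr <- make_symbol_trials(6L, times = c(2, 3, 2, 3, 2, 3, 2, 3, 4))
  ora_correct <- sum(tr$entered_digit == tr$correct_digit)
  ora_time <- sum(tr$response_time_s)
  expect_equal(ora_correct, 6L)
  expect_equal(ora_time, 24)
  expect_equal(subtest_raw_score(score_symbols(tr)),
               ora_correct / ora_time)

  bad <- make_symbol_trials()
  bad$entered_digit[3] <- 12L
  expect_error(score_symbols(bad), "invalid response")
})

test_that("memory scoring counts the configured recall trial out of eight", {
  expect_equal(score_memory(make_memory_items(8L))$n_correct, 8L)
  expect_true(is.na(score_memory(make_memory_items())$total_time))

  it <- make_memory_items(n_correct_second = 3L, n_correct_first = 6L)
  expect_equal(score_memory(it, trial = "second")$n_correct, 3L)
  expect_equal(score_memory(it, trial = "first")$n_correct, 6L)
  expect_equal(score_memory(it, trial = "both")$n_correct, 3L)

  expect_error(score_memory(make_memory_items()[1:5, ]), "invalid design")
})

test_that("uniform guessing over 8 delayed options scores 1/8 per item", {
  # Monte-Carlo mean of Binomial(8, 1/8) = 1
  set.seed(42)
  words <- make_memory_items()$target_word
  n_sim <- 4000L
  scores <- vapply(seq_len(n_sim), function(i) {
    it <- make_memory_items()
    it$second_choice <- vapply(it$target_word, function(w)
      sample(c(w, paste0("d", 1:7)), 1L), character(1))
    score_memory(it)$n_correct
  }, integer(1))
  se <- sd(scores) / sqrt(n_sim)
  expect_lt(abs(mean(scores) - 1), 3 * se)
})

test_that("timed raw scores are monotone in accuracy and time", {
  raw <- function(nc, tt) subtest_raw_score(
    score_stroop(make_stroop_trials(nc, times = tt / 18)))
  expect_true(all(diff(vapply(1:18, raw, numeric(1), tt = 20)) > 0))
  expect_true(all(diff(vapply(c(10, 20, 40), function(tt)
    raw(12L, tt), numeric(1))) < 0))
})

test_that("reference fitting uses complete participants and the n-1 sd", {
  sc <- data.frame(raw_stroop = c(1, 3), raw_symbols = c(2, 6),
                   raw_memory = c(5, 7))
  ref <- fit_reference(sc)
  expect_equal(unname(ref$mean), c(2, 4, 6))
  expect_equal(unname(ref$sd), c(sd(c(1, 3)), sd(c(2, 6)), sd(c(5, 7))))
  expect_identical(fit_reference(sc), fit_reference(sc))

  # incomplete rows are excluded from the norms
  sc2 <- rbind(sc, data.frame(raw_stroop = 100, raw_symbols = NA,
                              raw_memory = 100))
  expect_equal(fit_reference(sc2)$mean, ref$mean)
  expect_equal(fit_reference(sc2)$n, 2L)

  expect_error(fit_reference(data.frame(raw_stroop = c(1, 1),
                                        raw_symbols = c(2, 6),
                                        raw_memory = c(5, 7))),
               "degenerate")
})

test_that("composite is the mean z-score, only for complete triplets", {
  set.seed(1)
  sc <- data.frame(raw_stroop = rnorm(30, 0.8, 0.2),
                   raw_symbols = rnorm(30, 0.3, 0.05),
                   raw_memory = sample(0:8, 30, replace = TRUE))
  ref <- fit_reference(sc)

  # a participant exactly at the reference means has composite 0:
  # construct results whose raw scores equal the reference means exactly
  stroop <- structure(list(n_correct = 18L, n_items = 18L,
                           total_time = 18 / ref$mean[["stroop"]],
                           completed = TRUE), class = "subtest_result")
  symbols <- structure(list(n_correct = 9L, n_items = 9L,
                            total_time = 9 / ref$mean[["symbols"]],
                            completed = TRUE), class = "subtest_result")
  ref$mean[["memory"]] <- 6     # integer-valued raw for the memory test
  memory <- structure(list(n_correct = 6L, n_items = 8L,
                           total_time = NA_real_, completed = TRUE),
                      class = "subtest_result")
  comp <- composite_mcog(stroop, symbols, memory, ref)
  expect_equal(comp$m_cogscore, 0, tolerance = 1e-12)
  expect_equal(comp$status, "complete")
  expect_equal(comp$m_cogscore, mean(comp$z))

  # incomplete propagation: no partial mean
  incomplete <- score_memory(make_memory_items(skip_idx = 1L))
  comp2 <- composite_mcog(stroop, symbols, incomplete, ref)
  expect_equal(comp2$status, "incomplete")
  expect_true(is.na(comp2$m_cogscore))
  expect_true(all(is.na(comp2$z)))
})

test_that("self-referenced cohort composites average zero with sd <= 1", {
  set.seed(7)
  for (n in c(10, 72, 300)) {
    sc <- data.frame(raw_stroop = rnorm(n, 0.8, 0.2),
                     raw_symbols = rnorm(n, 0.3, 0.05),
                     raw_memory = rnorm(n, 6, 1.5))
    out <- add_composites(sc)
    expect_lt(abs(mean(out$m_cogscore)), 1e-9)
    expect_lte(sd(out$m_cogscore), 1 + 1e-12)
    # invariant to the order of the three subtests in the mean
    expect_equal(out$m_cogscore,
                 (out$z_memory + out$z_stroop + out$z_symbols) / 3)
  }
})
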