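# Fixture builders and independent oracles shared across the suite.

# Stroop trial set with a valid 6/12 congruency design; the first
# `n_correct` trials are answered with the ink colour, the rest with a
# wrong colour.  `times` recycles over the 18 trials.
make_stroop_trials <- function(n_correct = 18L, times = 1,
                               skip_idx = integer()) {
  word <- rep(c("red", "green", "blue"), each = 6L)
  ink <- word
  incong <- 7:18                     # first 6 congruent, last 12 not
  ink[incong] <- vapply(incong, function(i)
    setdiff(c("red", "green", "blue"), word[i])[1L + i %% 2L], character(1))
  wrong <- vapply(ink, function(cl)
    setdiff(c("red", "green", "blue"), cl)[1L], character(1))
  chosen <- ifelse(seq_len(18L) <= n_correct, ink, wrong)
  tr <- data.frame(word_text = word, ink_colour = ink,
                   chosen_option = chosen,
                   response_time_s = rep_len(times, 18L),
                   stringsAsFactors = FALSE)
  tr$chosen_option[skip_idx] <- NA
  tr$response_time_s[skip_idx] <- NA
  tr
}

make_symbol_trials <- function(n_correct = 9L, times = 1,
                               skip_idx = integer()) {
  key <- c(3L, 1L, 4L, 5L, 9L, 2L, 6L, 8L, 7L)
  entered <- ifelse(seq_len(9L) <= n_correct, key, (key %% 9L) + 1L)
  tr <- data.frame(target_symbol_id = 1:9, correct_digit = key,
                   entered_digit = entered,
                   response_time_s = rep_len(times, 9L))
  tr$entered_digit[skip_idx] <- NA
  tr$response_time_s[skip_idx] <- NA
  tr
}

make_memory_items <- function(n_correct_second = 8L, n_correct_first = 8L,
                              skip_idx = integer()) {
  words <- c("apple", "table", "river", "candle",
             "garden", "mirror", "basket", "bridge")
  it <- data.frame(
    target_word = words,
    first_choice = ifelse(seq_len(8L) <= n_correct_first, words, "window"),
    second_choice = ifelse(seq_len(8L) <= n_correct_second, words, "window"),
    stringsAsFactors = FALSE)
  it$second_choice[skip_idx] <- NA
  it
}

# brute-force AUC oracle: concordant/tied pair counting
auc_pairs_oracle <- function(score, label, direction = "lower") {
  risk <- if (direction == "lower") -score else score
  x <- risk[label == 1]; y <- risk[label == 0]
  (sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))) /
    (length(x) * length(y))
}

# minimal roster/items cohort wrapper for pipeline tests
as_cohort <- function(roster, items) {
  structure(list(roster = roster, items = items, config = NULL,
                 seed = NA_integer_), class = "mcog_cohort")
}
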