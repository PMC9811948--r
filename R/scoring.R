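#' @title Subtest scoring for the digital cognitive screening battery
#' @description
#' The battery has three smartphone-administered subtests:
#' \itemize{
#'   \item \strong{Stroop}: 18 colour-word trials (6 congruent, 12
#'     incongruent) over the words/inks red, green, blue; the participant
#'     picks the ink colour from three options.  Scored as correct answers
#'     per second.
#'   \item \strong{Symbols}: 9 symbol-to-digit substitution trials (a fixed
#'     bijective key over nine symbols, presented as three blocks of three).
#'     Scored as correct answers per second.
#'   \item \strong{Memory}: 8 words recalled twice by cued multiple choice —
#'     an immediate trial with 4 options (3 distractors) and a delayed trial
#'     with 8 options (7 distractors).  Scored as the number of delayed-trial
#'     items correct out of 8; time is deliberately excluded so the memory
#'     score is not coupled to the two time-normalised scores.
#' }
#' The composite (M-CogScore) is the mean of the three subtest z-scores
#' against a reference sample, and is only defined when all three subtests
#' are complete: a skipped item yields no score, never a zero.
#' @name scoring
NULL

STROOP_COLOURS <- c("red", "green", "blue")
N_STROOP_TRIALS <- 18L
N_STROOP_CONGRUENT <- 6L
N_SYMBOL_TRIALS <- 9L
N_MEMORY_ITEMS <- 8L

new_subtest_result <- function(n_correct, n_items, total_time, completed) {
  structure(
    list(n_correct = as.integer(n_correct), n_items = as.integer(n_items),
         total_time = total_time, completed = isTRUE(completed)),
    class = "subtest_result")
}

#' @export
print.subtest_result <- function(x, ...) {
  cat(sprintf("Subtest result: %d/%d correct%s [%s]\n", x$n_correct,
              x$n_items,
              if (is.na(x$total_time)) "" else
                sprintf(" in %.2f s", x$total_time),
              if (x$completed) "complete" else "incomplete"))
  invisible(x)
}

#' Raw score of a scored subtest
#'
#' Correct answers per second for the timed subtests (Stroop, Symbols);
#' the plain correct count for the untimed memory subtest.  `NA` for an
#' incomplete subtest.
#'
#' @param result A `subtest_result`.
#' @return A single numeric raw score, or `NA` if incomplete.
#' @export
subtest_raw_score <- function(result) {
  stopifnot(inherits(result, "subtest_result"))
  if (!result$completed) return(NA_real_)
  if (is.na(result$total_time)) as.numeric(result$n_correct)
  else result$n_correct / result$total_time
}

#' Score the Stroop subtest
#'
#' Eighteen colour-word trials; a trial is correct when the chosen option
#' equals the ink colour.  The raw score downstream is
#' `n_correct / total_time` (correct per second).  Any trial without a
#' response (or without a response time) marks the subtest incomplete,
#' in which case `total_time` is `NA`.
#'
#' @param trials Data frame with one row per trial and columns `word_text`,
#'   `ink_colour` (both in red/green/blue), `chosen_option` (colour or `NA`
#'   for a skipped trial) and `response_time_s` (seconds, `NA` if skipped).
#' @return A `subtest_result` with `n_items = 18`.
#' @examples
#' trials <- data.frame(
#'   word_text  = rep(c("red", "green", "blue"), each = 6),
#'   ink_colour = c(rep(c("red", "green", "blue"), 2),
#'                  rep(c("green", "blue", "red"), 4)),
#'   stringsAsFactors = FALSE)
#' trials$chosen_option <- trials$ink_colour
#' trials$response_time_s <- rep(2, 18)
#' score_stroop(trials)  # 18/18 in 36 s -> raw 0.5/s
#' @export
score_stroop <- function(trials) {
  trials <- as.data.frame(trials)
  need <- c("word_text", "ink_colour", "chosen_option", "response_time_s")
  if (!all(need %in% names(trials)))
    stop("stroop trials need columns: ", paste(need, collapse = ", "))
  if (nrow(trials) != N_STROOP_TRIALS)
    stop("invalid design: expected ", N_STROOP_TRIALS, " Stroop trials, got ",
         nrow(trials))
  if (!all(trials$word_text %in% STROOP_COLOURS) ||
      !all(trials$ink_colour %in% STROOP_COLOURS))
    stop("invalid design: Stroop stimuli must be red/green/blue")
  n_congruent <- sum(trials$word_text == trials$ink_colour)
  if (n_congruent != N_STROOP_CONGRUENT)
    stop("invalid design: expected ", N_STROOP_CONGRUENT,
         " congruent trials, got ", n_congruent)
  answered <- !is.na(trials$chosen_option) & !is.na(trials$response_time_s)
  if (any(trials$response_time_s[answered] <= 0))
    stop("invalid design: response times must be positive")
  completed <- all(answered)
  n_correct <- sum(answered &
                     trials$chosen_option == trials$ink_colour, na.rm = TRUE)
  total_time <- if (completed) sum(trials$response_time_s) else NA_real_
  new_subtest_result(n_correct, N_STROOP_TRIALS, total_time, completed)
}

#' Score the symbol-digit substitution subtest
#'
#' Nine trials matching symbols to digits through a bijective 9-symbol key.
#' Handwritten answers are assumed already digitised upstream; this function
#' sees entered digits.  Raw score downstream is correct per second.
#'
#' @param trials Data frame with columns `target_symbol_id` (1..9),
#'   `correct_digit` (1..9), `entered_digit` (1..9 or `NA` for a skip) and
#'   `response_time_s`.
#' @return A `subtest_result` with `n_items = 9`.
#' @export
score_symbols <- function(trials) {
  trials <- as.data.frame(trials)
  need <- c("target_symbol_id", "correct_digit", "entered_digit",
            "response_time_s")
  if (!all(need %in% names(trials)))
    stop("symbol trials need columns: ", paste(need, collapse = ", "))
  if (nrow(trials) != N_SYMBOL_TRIALS)
    stop("invalid design: expected ", N_SYMBOL_TRIALS, " symbol trials, got ",
         nrow(trials))
  if (!all(trials$correct_digit %in% 1:9))
    stop("invalid design: correct digits must be in 1..9")
  entered <- trials$entered_digit[!is.na(trials$entered_digit)]
  if (!all(entered %in% 1:9))
    stop("invalid response: entered digits must be in 1..9")
  answered <- !is.na(trials$entered_digit) & !is.na(trials$response_time_s)
  if (any(trials$response_time_s[answered] <= 0))
    stop("invalid design: response times must be positive")
  completed <- all(answered)
  n_correct <- sum(answered &
                     trials$entered_digit == trials$correct_digit,
                   na.rm = TRUE)
  total_time <- if (completed) sum(trials$response_time_s) else NA_real_
  new_subtest_result(n_correct, N_SYMBOL_TRIALS, total_time, completed)
}

#' Score the cued-recall memory subtest
#'
#' Eight words, each recalled in an immediate cued trial (4 options) and a
#' delayed cued trial (8 options).  The score is the number correct out of
#' eight on the delayed trial by default — the delayed trial is the standard
#' diagnostic trial in word-list batteries; `trial = "first"` or `"both"`
#' (an item counts only if both trials are correct) are available for
#' sensitivity analyses.  Time is never part of this score.
#'
#' @param items Data frame with columns `target_word`, `first_choice` and
#'   `second_choice` (the chosen word tokens, `NA` for a skipped item).
#' @param trial Which recall trial feeds the count: `"second"` (delayed,
#'   default), `"first"`, or `"both"`.
#' @return A `subtest_result` with `n_items = 8` and `total_time = NA`.
#' @export
score_memory <- function(items, trial = c("second", "first", "both")) {
  trial <- match.arg(trial)
  items <- as.data.frame(items)
  need <- c("target_word", "first_choice", "second_choice")
  if (!all(need %in% names(items)))
    stop("memory items need columns: ", paste(need, collapse = ", "))
  if (nrow(items) != N_MEMORY_ITEMS)
    stop("invalid design: expected ", N_MEMORY_ITEMS, " memory items, got ",
         nrow(items))
  first_ok <- items$first_choice == items$target_word
  second_ok <- items$second_choice == items$target_word
  correct <- switch(trial,
                    second = second_ok,
                    first = first_ok,
                    both = first_ok & second_ok)
  answered <- switch(trial,
                     second = !is.na(items$second_choice),
                     first = !is.na(items$first_choice),
                     both = !is.na(items$first_choice) &
                       !is.na(items$second_choice))
  completed <- all(answered)
  n_correct <- sum(correct[answered], na.rm = TRUE)
  new_subtest_result(n_correct, N_MEMORY_ITEMS, NA_real_, completed)
}

#' Fit a z-score reference from cohort raw scores
#'
#' Per-subtest mean and sample (n-1) standard deviation computed over
#' participants with all three subtests complete.  By default the analysis
#' cohort is its own reference, which makes self-referenced composites
#' average exactly zero over the cohort; an externally normed reference can
#' be supplied to [composite_mcog()] instead.
#'
#' @param scores Data frame with columns `raw_stroop`, `raw_symbols`,
#'   `raw_memory` (one row per participant; `NA` marks an incomplete
#'   subtest).
#' @return A `z_reference` with fields `mean`, `sd` (named length-3
#'   vectors) and `n` (number of complete participants used).
#' @export
fit_reference <- function(scores) {
  scores <- as.data.frame(scores)
  cols <- c("raw_stroop", "raw_symbols", "raw_memory")
  if (!all(cols %in% names(scores)))
    stop("scores need columns: ", paste(cols, collapse = ", "))
  complete <- stats::complete.cases(scores[cols])
  if (sum(complete) < 2L)
    stop("need at least 2 participants with all three subtests complete")
  sub <- scores[complete, cols]
  mu <- vapply(sub, mean, numeric(1))
  sdv <- vapply(sub, stats::sd, numeric(1))
  if (any(sdv <= 0))
    stop("degenerate reference: zero variance in ",
         paste(cols[sdv <= 0], collapse = ", "))
  names(mu) <- names(sdv) <- c("stroop", "symbols", "memory")
  structure(list(mean = mu, sd = sdv, n = sum(complete)),
            class = "z_reference")
}

#' @export
print.z_reference <- function(x, ...) {
  cat(sprintf("z-reference over %d complete participants\n", x$n))
  print(rbind(mean = x$mean, sd = x$sd))
  invisible(x)
}

#' Compute the z-score composite for one participant
#'
#' Each raw subtest score is standardised against the reference
#' (`z = (raw - mean) / sd`) and the composite is the unweighted mean of
#' the three z-scores.  If any subtest is incomplete the status is
#' `"incomplete"` and no composite (and no partial mean) is produced.
#'
#' @param stroop,symbols,memory `subtest_result` objects for one
#'   participant.
#' @param reference A `z_reference` from [fit_reference()].
#' @return A `composite_score` with raw scores, z-scores, `m_cogscore`
#'   and `status` (`"complete"` or `"incomplete"`).
#' @export
composite_mcog <- function(stroop, symbols, memory, reference) {
  stopifnot(inherits(reference, "z_reference"))
  raw <- c(stroop = subtest_raw_score(stroop),
           symbols = subtest_raw_score(symbols),
           memory = subtest_raw_score(memory))
  complete <- stroop$completed && symbols$completed && memory$completed
  if (complete) {
    z <- (raw - reference$mean) / reference$sd
    m <- mean(z)
    status <- "complete"
  } else {
    z <- c(stroop = NA_real_, symbols = NA_real_, memory = NA_real_)
    m <- NA_real_
    status <- "incomplete"
  }
  structure(list(raw = raw, z = z, m_cogscore = m, status = status),
            class = "composite_score")
}

#' @export
print.composite_score <- function(x, ...) {
  if (x$status == "complete")
    cat(sprintf("M-CogScore %.3f (z: stroop %.2f, symbols %.2f, memory %.2f)\n",
                x$m_cogscore, x$z["stroop"], x$z["symbols"], x$z["memory"]))
  else cat("M-CogScore: incomplete (no composite)\n")
  invisible(x)
}

#' Add z-scores and composites to a cohort score table
#'
#' Vectorised counterpart of [composite_mcog()]: standardises the raw score
#' columns against `reference` (fitted on the table itself when omitted) and
#' appends `z_stroop`, `z_symbols`, `z_memory`, `m_cogscore` and `status`.
#'
#' @param scores Data frame with `raw_stroop`, `raw_symbols`, `raw_memory`.
#' @param reference Optional `z_reference`; default self-reference.
#' @return The input data frame with composite columns appended.
#' @export
add_composites <- function(scores, reference = NULL) {
  scores <- as.data.frame(scores)
  if (is.null(reference)) reference <- fit_reference(scores)
  z <- function(raw, k) (raw - reference$mean[[k]]) / reference$sd[[k]]
  scores$z_stroop <- z(scores$raw_stroop, "stroop")
  scores$z_symbols <- z(scores$raw_symbols, "symbols")
  scores$z_memory <- z(scores$raw_memory, "memory")
  complete <- stats::complete.cases(
    scores[c("raw_stroop", "raw_symbols", "raw_memory")])
  scores$m_cogscore <- ifelse(
    complete,
    (scores$z_stroop + scores$z_symbols + scores$z_memory) / 3,
    NA_real_)
  scores$status <- ifelse(complete, "complete", "incomplete")
  scores
}
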