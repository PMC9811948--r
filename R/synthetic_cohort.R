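# Synthetic case-control cohort generator.
#
# A single latent severity factor per participant drives subtest accuracy,
# response times, the MMSE-2 total, and the propensity to skip sections, so
# the generated data reproduce the couplings the analysis relies on: group
# separation on every score, a healthy-group MMSE ceiling, cross-subtest
# correlation, and missingness concentrated in the impaired group.
#
# Participant i in group g (healthy shift 0, impaired shift delta) draws a
# shared standard-normal factor Z0 and per-instrument noise Zk; instrument k
# sees severity S_k = shift_g + sd_g * (loading * Z0 +
# sqrt(1 - loading^2) * Zk), so S_k ~ N(shift_g, sd_g^2) marginally and
# `loading` controls how strongly the instruments co-vary within a group.
# The impaired group gets a larger latent sd: the CDR 0.5-1 label spans a
# range of severities, and the published group summaries show the impaired
# spread roughly double the healthy spread on both instruments.

MEMORY_TARGET_WORDS <- c("apple", "table", "river", "candle",
                         "garden", "mirror", "basket", "bridge")
MEMORY_DISTRACTOR_WORDS <- c("window", "bottle", "forest", "pillow",
                             "street", "hammer", "island", "ladder",
                             "carpet", "branch", "pocket", "silver",
                             "meadow", "turtle", "anchor", "helmet")
EDUCATION_LEVELS <- c("none", "GCSE", "A-levels", "University")

#' Generative configuration for a synthetic screening cohort
#'
#' Defaults are calibrated so that the included groups reproduce the
#' published cohort's moments: MMSE-2 means 28.6 (healthy) and 26.1
#' (impaired) with the healthy ceiling at 30, and self-referenced composite
#' group means near +0.47 / -0.52.  See [default_config()] for the
#' participant-flow emulation that also reproduces the study's exclusion
#' counts.
#'
#' @param n_healthy,n_impaired Recruited participants per group.
#' @param age_mean,age_sd Length-2 vectors (healthy, impaired), years.
#' @param sex_p_male Length-2 vector of male probabilities.
#' @param education_p 2 x 4 matrix of education-level probabilities
#'   (rows healthy/impaired; columns none, GCSE, A-levels, University).
#' @param severity_shift Latent severity mean of the impaired group
#'   (healthy is 0).
#' @param severity_sd Length-2 vector of within-group latent severity
#'   sds (healthy, impaired).  The impaired default exceeds 1 because the
#'   CDR 0.5-1 range mixes degrees of impairment: published group
#'   summaries show roughly twice the healthy spread on both MMSE-2 and
#'   the composite, which a common within-group sd cannot reproduce.
#' @param loading Shared-factor loading in `[0, 1]` for the three
#'   subtests; 0 makes subtests conditionally independent within group.
#' @param mmse_loading Shared-factor loading for the MMSE-2; tunes the
#'   within-group MMSE-composite correlation.
#' @param stroop,symbols Per-subtest models: `acc_base`/`acc_slope` are
#'   the correctness log-odds intercept and per-severity-unit decrement;
#'   `rt_meanlog`/`rt_slope`/`rt_sdlog` give per-item response times
#'   `lognormal(rt_meanlog + rt_slope * S, rt_sdlog)` in seconds.
#' @param memory `acc_base`/`acc_slope` for recall success on top of the
#'   guessing floors (1/4 immediate trial, 1/8 delayed trial).
#' @param mmse `intercept`, `slope`, `noise_sd`: MMSE-2 total is
#'   `round(intercept - slope * S + N(0, noise_sd))` clamped to `[0, 30]`;
#'   the clamp at 30 is what produces the healthy-group ceiling.
#' @param skip_base Per-subtest log-odds of skipping a section at severity
#'   0 (named: stroop, symbols, memory).
#' @param skip_slope Added log-odds of skipping per severity unit.
#' @param upload_p Probability a participant's app data fails to upload.
#' @param p_cdr1 Probability an impaired participant is CDR 1 (vs 0.5).
#' @param flow Either `NULL` (fully stochastic missingness) or a list of
#'   fixed participant-flow counts, see [default_config()].
#' @return A validated `sim_config`.
#' @export
sim_config <- function(n_healthy = 50L, n_impaired = 55L,
                       age_mean = c(69.1, 69.5), age_sd = c(5.5, 6.6),
                       sex_p_male = c(17 / 38, 15 / 34),
                       education_p = rbind(c(2, 9, 6, 21) / 38,
                                           c(4, 4, 12, 14) / 34),
                       severity_shift = 2.0,
                       severity_sd = c(1.0, 1.6),
                       loading = 0.6, mmse_loading = 0.75,
                       stroop = list(acc_base = 3.2, acc_slope = 0.27,
                                     rt_meanlog = 0.10, rt_slope = 0.132,
                                     rt_sdlog = 0.30),
                       symbols = list(acc_base = 3.0, acc_slope = 0.27,
                                      rt_meanlog = 1.16, rt_slope = 0.132,
                                      rt_sdlog = 0.30),
                       memory = list(acc_base = 2.6, acc_slope = 0.54),
                       mmse = list(intercept = 29.0, slope = 1.45,
                                   noise_sd = 1.2),
                       skip_base = c(stroop = stats::qlogis(0.045),
                                     symbols = stats::qlogis(0.025),
                                     memory = stats::qlogis(0.060)),
                       skip_slope = 0.5,
                       upload_p = 7 / 105,
                       p_cdr1 = 7 / 55,
                       flow = NULL) {
  cfg <- list(n_healthy = as.integer(n_healthy),
              n_impaired = as.integer(n_impaired),
              age_mean = age_mean, age_sd = age_sd,
              sex_p_male = sex_p_male, education_p = education_p,
              severity_shift = severity_shift,
              severity_sd = severity_sd,
              loading = loading, mmse_loading = mmse_loading,
              stroop = stroop, symbols = symbols, memory = memory,
              mmse = mmse, skip_base = skip_base, skip_slope = skip_slope,
              upload_p = upload_p, p_cdr1 = p_cdr1, flow = flow)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_healthy >= 0L, cfg$n_impaired >= 0L,
            length(cfg$severity_sd) == 2L, all(cfg$severity_sd > 0),
            all(cfg$age_sd > 0),
            all(cfg$sex_p_male >= 0 & cfg$sex_p_male <= 1),
            all(cfg$education_p >= 0),
            nrow(cfg$education_p) == 2L, ncol(cfg$education_p) == 4L,
            cfg$loading >= 0, cfg$loading <= 1,
            cfg$mmse_loading >= 0, cfg$mmse_loading <= 1,
            cfg$stroop$rt_sdlog > 0, cfg$symbols$rt_sdlog > 0,
            cfg$mmse$noise_sd > 0,
            cfg$upload_p >= 0, cfg$upload_p <= 1,
            cfg$p_cdr1 >= 0, cfg$p_cdr1 <= 1)
  if (abs(sum(cfg$education_p[1, ]) - 1) > 1e-8 ||
      abs(sum(cfg$education_p[2, ]) - 1) > 1e-8)
    stop("education probabilities must sum to 1 per group")
  if (!is.null(cfg$flow)) {
    fl <- cfg$flow
    need <- c("n_revoked", "n_cdr_gt1", "upload_failed", "incomplete",
              "skip_split", "cdr1_included", "cdr1_incomplete")
    if (!all(need %in% names(fl)))
      stop("flow needs fields: ", paste(need, collapse = ", "))
    if (any(unlist(fl[c("n_revoked", "n_cdr_gt1")]) < 0))
      stop("flow counts must be non-negative")
    if (fl$upload_failed[1] + fl$incomplete[1] > cfg$n_healthy ||
        fl$upload_failed[2] + fl$incomplete[2] > cfg$n_impaired)
      stop("flow exclusion counts exceed group sizes")
  }
  invisible(cfg)
}

#' Default configuration emulating the published participant flow
#'
#' Recruits 50 healthy and 55 impaired participants plus 1 who revokes
#' consent and 2 screening failures (CDR > 1), for a roster of 108.  Fixed
#' flow counts remove 7 participants through upload failure (5 healthy, 2
#' impaired) and 26 through a skipped section (7 healthy, 19 impaired;
#' section drawn with probabilities 9:5:12 for Stroop:Symbols:Memory), so
#' exactly 38 healthy and 34 impaired participants remain included.
#' Within the impaired group, 1 included and 6 incomplete participants are
#' CDR 1; all other impaired participants are CDR 0.5.
#'
#' @param ... Overrides passed on to [sim_config()].
#' @return A `sim_config` with flow emulation enabled.
#' @export
default_config <- function(...) {
  sim_config(flow = list(n_revoked = 1L, n_cdr_gt1 = 2L,
                         upload_failed = c(healthy = 5L, impaired = 2L),
                         incomplete = c(healthy = 7L, impaired = 19L),
                         skip_split = c(stroop = 9, symbols = 5,
                                        memory = 12),
                         cdr1_included = 1L, cdr1_incomplete = 6L),
             ...)
}

# stroop trial design: 6 congruent + 12 incongruent over red/green/blue
stroop_design <- function() {
  word <- rep(STROOP_COLOURS, each = 6L)
  ink <- character(18L)
  congruent <- c(1L, 4L, 7L, 10L, 13L, 16L)   # two per colour
  ink[congruent] <- word[congruent]
  other <- lapply(word, function(w) setdiff(STROOP_COLOURS, w))
  incong <- setdiff(seq_len(18L), congruent)
  ink[incong] <- vapply(seq_along(incong), function(j) {
    other[[incong[j]]][1L + (j %% 2L)]
  }, character(1))
  data.frame(item_index = seq_len(18L), word_text = word, ink_colour = ink,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic screening cohort
#'
#' Draws a participant roster and the full item-level response table for
#' the three subtests under `config`.  With flow emulation on (see
#' [default_config()]) the exclusion categories have fixed counts and the
#' section-skippers are chosen with probability increasing in latent
#' severity, so that participants with missing data are more impaired and
#' score lower on the MMSE-2, as observed; without it, skipping and upload
#' failure are drawn per participant from the configured probabilities.
#'
#' Revoked-consent and CDR > 1 participants carry no MMSE-2 or item data
#' (testing stops at screening); upload-failed participants carry no item
#' data (the app data never arrived).
#'
#' @param config A `sim_config`.
#' @param seed Integer seed; the same seed reproduces the cohort exactly.
#' @return A `mcog_cohort`: list with `roster` (one row per participant:
#'   participant_id, cdr_global, age, sex, education, mmse2_total,
#'   uploaded, revoked_consent) and `items` (one row per trial/item),
#'   plus the `config` and `seed` used.
#' @export
simulate_cohort <- function(config = default_config(), seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  fl <- config$flow
  n_h <- config$n_healthy; n_i <- config$n_impaired
  n_extra <- if (is.null(fl)) 0L else fl$n_revoked + fl$n_cdr_gt1
  n <- n_h + n_i + n_extra

  group <- c(rep("healthy", n_h), rep("impaired", n_i),
             rep(c("revoked", "cdr_gt1"),
                 if (is.null(fl)) c(0L, 0L) else
                   c(fl$n_revoked, fl$n_cdr_gt1)))
  gi <- ifelse(group == "healthy", 1L, 2L)   # demographics row index
  gi[group == "revoked" | group == "cdr_gt1"] <- 2L

  age <- round(stats::rnorm(n, config$age_mean[gi], config$age_sd[gi]))
  age <- pmax(age, 45)                        # inclusion: age >= 45
  sex <- ifelse(stats::runif(n) < config$sex_p_male[gi], "M", "F")
  education <- vapply(gi, function(g)
    sample(EDUCATION_LEVELS, 1L, prob = config$education_p[g, ]),
    character(1))

  shift <- ifelse(group == "impaired", config$severity_shift,
                  ifelse(group == "healthy", 0,
                         config$severity_shift + 1.5))  # beyond-inclusion
  sev_sd <- ifelse(group == "healthy", config$severity_sd[1],
                   config$severity_sd[2])
  z0 <- stats::rnorm(n)
  lam <- config$loading
  sev <- function(lambda, zk)
    shift + sev_sd * (lambda * z0 + sqrt(1 - lambda^2) * zk)
  s_stroop <- sev(lam, stats::rnorm(n))
  s_symbols <- sev(lam, stats::rnorm(n))
  s_memory <- sev(lam, stats::rnorm(n))
  s_mmse <- sev(config$mmse_loading, stats::rnorm(n))
  s_shared <- shift + sev_sd * z0             # drives skip propensity

  mmse <- pmin(pmax(round(config$mmse$intercept -
                            config$mmse$slope * s_mmse +
                            stats::rnorm(n, 0, config$mmse$noise_sd)),
                    0), 30)

  cdr <- numeric(n)
  cdr[group == "healthy"] <- 0
  cdr[group == "impaired"] <- 0.5             # refined below
  cdr[group == "cdr_gt1"] <- 2
  cdr[group == "revoked"] <- NA_real_

  revoked <- group == "revoked"
  screened_out <- group == "cdr_gt1"
  tested <- !revoked & !screened_out          # reached the digital test
  mmse[!tested] <- NA_real_

  # disposition: upload failures and skipped sections
  skip_section <- rep(NA_character_, n)
  uploaded <- tested
  if (is.null(fl)) {
    uploaded[tested] <- stats::runif(sum(tested)) >= config$upload_p
    # a participant may skip several sections; each skipped section is
    # blanked in the items table
    skip_flags <- matrix(vapply(c("stroop", "symbols", "memory"),
                                function(k) {
      p_skip <- stats::plogis(config$skip_base[[k]] +
                                config$skip_slope * s_shared)
      tested & (stats::runif(n) < p_skip)
    }, logical(n)), nrow = n,
      dimnames = list(NULL, c("stroop", "symbols", "memory")))
    imp <- which(group == "impaired")
    cdr[imp] <- ifelse(stats::runif(length(imp)) < config$p_cdr1, 1, 0.5)
  } else {
    # fixed-count flow: upload failures at random; section-skippers chosen
    # with probability increasing in latent severity within each group
    skip_flags <- matrix(FALSE, n, 3L,
                         dimnames = list(NULL,
                                         c("stroop", "symbols", "memory")))
    pick <- function(x, size, prob = NULL)
      x[sample.int(length(x), size, prob = prob)]
    for (g in 1:2) {
      members <- which(gi == g & tested)
      grp <- c("healthy", "impaired")[g]
      up_fail <- pick(members, fl$upload_failed[g])
      uploaded[up_fail] <- FALSE
      rest <- setdiff(members, up_fail)
      w <- stats::plogis(config$skip_slope * s_shared[rest])
      skippers <- pick(rest, fl$incomplete[g], prob = w)
      section <- sample(c("stroop", "symbols", "memory"),
                        length(skippers), replace = TRUE,
                        prob = fl$skip_split)
      skip_section[skippers] <- section
      skip_flags[cbind(skippers, match(section, colnames(skip_flags)))] <- TRUE
      if (grp == "impaired") {
        inc <- setdiff(rest, skippers)
        cdr[pick(inc, min(fl$cdr1_included, length(inc)))] <- 1
        cdr[pick(skippers,
                 min(fl$cdr1_incomplete, length(skippers)))] <- 1
      }
    }
  }

  roster <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    cdr_global = cdr, age = age, sex = sex, education = education,
    mmse2_total = mmse, uploaded = uploaded, revoked_consent = revoked,
    stringsAsFactors = FALSE)

  with_items <- which(tested & uploaded)
  items <- do.call(rbind, lapply(with_items, function(i) {
    simulate_items(roster$participant_id[i], config,
                   c(stroop = s_stroop[i], symbols = s_symbols[i],
                     memory = s_memory[i]),
                   skip_flags[i, ])
  }))
  if (is.null(items)) items <- empty_items()
  rownames(items) <- NULL

  structure(list(roster = roster, items = items, config = config,
                 seed = seed),
            class = "mcog_cohort")
}

empty_items <- function() {
  data.frame(participant_id = character(), subtest = character(),
             item_index = integer(), stimulus = character(),
             stimulus2 = character(), correct_response = character(),
             response = character(), response2 = character(),
             response_time_s = numeric(), stringsAsFactors = FALSE)
}

# item-level responses for one tested, uploaded participant
simulate_items <- function(pid, config, sev, skipped) {
  draw_rt <- function(m, mod, s)
    stats::rlnorm(m, mod$rt_meanlog + mod$rt_slope * s, mod$rt_sdlog)

  des <- stroop_design()
  p <- stats::plogis(config$stroop$acc_base -
                       config$stroop$acc_slope * sev[["stroop"]])
  correct <- stats::runif(18L) < p
  chosen <- ifelse(correct, des$ink_colour,
                   vapply(des$ink_colour, function(cl)
                     sample(setdiff(STROOP_COLOURS, cl), 1L), character(1)))
  stroop <- data.frame(
    participant_id = pid, subtest = "stroop", item_index = des$item_index,
    stimulus = des$word_text, stimulus2 = des$ink_colour,
    correct_response = des$ink_colour, response = chosen,
    response2 = NA_character_,
    response_time_s = draw_rt(18L, config$stroop, sev[["stroop"]]),
    stringsAsFactors = FALSE)
  if (skipped[["stroop"]])
    stroop$response <- stroop$response_time_s <- NA

  key <- sample(1:9)                           # symbol -> digit bijection
  p <- stats::plogis(config$symbols$acc_base -
                       config$symbols$acc_slope * sev[["symbols"]])
  correct <- stats::runif(9L) < p
  entered <- ifelse(correct, key,
                    vapply(key, function(d) sample(setdiff(1:9, d), 1L),
                           integer(1)))
  symbols <- data.frame(
    participant_id = pid, subtest = "symbols", item_index = 1:9,
    stimulus = as.character(1:9), stimulus2 = NA_character_,
    correct_response = as.character(key), response = as.character(entered),
    response2 = NA_character_,
    response_time_s = draw_rt(9L, config$symbols, sev[["symbols"]]),
    stringsAsFactors = FALSE)
  if (skipped[["symbols"]])
    symbols$response <- symbols$response_time_s <- NA

  p_know <- stats::plogis(config$memory$acc_base -
                            config$memory$acc_slope * sev[["memory"]])
  p1 <- 1 / 4 + (3 / 4) * p_know               # guessing floors per trial
  p2 <- 1 / 8 + (7 / 8) * p_know
  first <- ifelse(stats::runif(8L) < p1, MEMORY_TARGET_WORDS,
                  sample(MEMORY_DISTRACTOR_WORDS, 8L, replace = TRUE))
  second <- ifelse(stats::runif(8L) < p2, MEMORY_TARGET_WORDS,
                   sample(MEMORY_DISTRACTOR_WORDS, 8L, replace = TRUE))
  memory <- data.frame(
    participant_id = pid, subtest = "memory", item_index = 1:8,
    stimulus = MEMORY_TARGET_WORDS, stimulus2 = NA_character_,
    correct_response = MEMORY_TARGET_WORDS, response = first,
    response2 = second, response_time_s = NA_real_,
    stringsAsFactors = FALSE)
  if (skipped[["memory"]])
    memory$response <- memory$response2 <- NA_character_

  rbind(stroop, symbols, memory)
}

#' Per-subtest section-skip counts by group
#'
#' Counts, for each subtest and CDR-defined group, the participants whose
#' uploaded data contain at least one absent response in that section.
#' Participants without item data (not tested, or upload failed) are not
#' section-skippers and are excluded from the denominator.
#'
#' @param cohort A `mcog_cohort` (or a list with `roster` and `items`).
#' @return Data frame with columns `subtest`, `group`, `n_skipped`,
#'   `n_with_items`.
#' @export
missingness_report <- function(cohort) {
  roster <- cohort$roster; items <- cohort$items
  grp <- ifelse(is.na(roster$cdr_global), NA_character_,
                ifelse(roster$cdr_global == 0, "healthy",
                       ifelse(roster$cdr_global <= 1, "impaired", "cdr_gt1")))
  names(grp) <- roster$participant_id
  out <- expand.grid(subtest = c("stroop", "symbols", "memory"),
                     group = c("healthy", "impaired"),
                     stringsAsFactors = FALSE)
  out$n_skipped <- 0L; out$n_with_items <- 0L
  for (r in seq_len(nrow(out))) {
    sub <- items[items$subtest == out$subtest[r], ]
    pid <- unique(sub$participant_id)
    pid <- pid[!is.na(grp[pid]) & grp[pid] == out$group[r]]
    sub <- sub[sub$participant_id %in% pid, ]
    absent <- is.na(sub$response) |
      (sub$subtest == "memory" & is.na(sub$response2))
    skipped <- tapply(absent, sub$participant_id, any)
    out$n_skipped[r] <- sum(skipped)
    out$n_with_items[r] <- length(pid)
  }
  out
}
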