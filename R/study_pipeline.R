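# End-to-end study pipeline: ingestion with validation, participant-flow
# exclusions, cohort scoring, the Table-1 style summary, the validation
# statistics battery, the missing-data analysis, and a machine-readable
# report.

CDR_INCLUDED <- c(0, 0.5, 1)

cdr_group <- function(cdr) {
  ifelse(is.na(cdr), NA_character_,
         ifelse(cdr == 0, "healthy",
                ifelse(cdr <= 1, "impaired", "cdr_gt1")))
}

#' Write a cohort to CSV files
#'
#' Writes `roster.csv`, `items.csv` and (for simulated cohorts)
#' `config.json` recording the generative configuration and seed.
#'
#' @param cohort A `mcog_cohort` or a list with `roster` and `items`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort_csv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$roster, file.path(dir, "roster.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(cohort$items, file.path(dir, "items.csv"),
                   row.names = FALSE, na = "")
  if (!is.null(cohort$config))
    jsonlite::write_json(
      list(seed = cohort$seed,
           config = unclass(cohort$config)),
      file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA,
      null = "null", pretty = TRUE)
  invisible(dir)
}

#' Load a cohort from roster and item CSV files
#'
#' Validates the schema and row contents; all violations are collected and
#' reported together with their line numbers.  Empty response cells are
#' parsed as skipped (`NA`), never as zero or an empty answer.
#'
#' @param roster_csv,items_csv File paths.
#' @return A `mcog_cohort` (without a generative config).
#' @export
load_cohort <- function(roster_csv, items_csv) {
  roster <- utils::read.csv(roster_csv, stringsAsFactors = FALSE,
                            na.strings = c("", "NA"))
  items <- utils::read.csv(items_csv, stringsAsFactors = FALSE,
                           na.strings = c("", "NA"),
                           colClasses = c(participant_id = "character"))
  need_r <- c("participant_id", "cdr_global", "age", "sex", "education",
              "mmse2_total", "uploaded", "revoked_consent")
  need_i <- c("participant_id", "subtest", "item_index", "stimulus",
              "correct_response", "response", "response_time_s")
  missing_r <- setdiff(need_r, names(roster))
  missing_i <- setdiff(need_i, names(items))
  if (length(missing_r) || length(missing_i))
    stop("schema error: missing columns ",
         paste(c(missing_r, missing_i), collapse = ", "))
  if (!"response2" %in% names(items)) items$response2 <- NA_character_
  roster$participant_id <- as.character(roster$participant_id)

  problems <- character()
  line <- function(i) i + 1L   # header occupies line 1
  dup <- which(duplicated(roster$participant_id))
  for (i in dup)
    problems <- c(problems, sprintf(
      "roster line %d: duplicate participant_id '%s'", line(i),
      roster$participant_id[i]))
  bad_mmse <- which(!is.na(roster$mmse2_total) &
                      (roster$mmse2_total < 0 | roster$mmse2_total > 30))
  for (i in bad_mmse)
    problems <- c(problems, sprintf(
      "roster line %d: mmse2_total %s out of range 0-30", line(i),
      roster$mmse2_total[i]))
  bad_cdr <- which(!is.na(roster$cdr_global) &
                     !roster$cdr_global %in% c(0, 0.5, 1, 2, 3))
  for (i in bad_cdr)
    problems <- c(problems, sprintf(
      "roster line %d: cdr_global %s not a CDR global score", line(i),
      roster$cdr_global[i]))
  bad_sub <- which(!items$subtest %in% c("stroop", "symbols", "memory"))
  for (i in bad_sub)
    problems <- c(problems, sprintf(
      "items line %d: unknown subtest '%s'", line(i), items$subtest[i]))
  orphan <- which(!items$participant_id %in% roster$participant_id)
  for (i in utils::head(orphan, 5L))
    problems <- c(problems, sprintf(
      "items line %d: participant '%s' not in roster", line(i),
      items$participant_id[i]))
  if (length(problems))
    stop("integrity error(s):\n", paste(problems, collapse = "\n"))

  if (anyDuplicated(dup <- paste(items$participant_id, items$subtest,
                                 items$item_index)))
    stop("integrity error: duplicated item rows")
  structure(list(roster = roster, items = items, config = NULL,
                 seed = NA_integer_),
            class = "mcog_cohort")
}

#' Score every participant's subtests
#'
#' Vectorised cohort-level counterpart of [score_stroop()],
#' [score_symbols()] and [score_memory()]: reduces the item table to one
#' row per roster participant with raw subtest scores and completeness
#' flags.  A participant with no uploaded items, or any absent response in
#' a section, is incomplete on that section and gets no raw score for it.
#'
#' @param cohort A `mcog_cohort`.
#' @param memory_trial Which recall trial feeds the memory count
#'   (see [score_memory()]).
#' @return Data frame: `participant_id`, `raw_stroop`, `raw_symbols`,
#'   `raw_memory`, `stroop_complete`, `symbols_complete`,
#'   `memory_complete`.
#' @export
score_cohort <- function(cohort, memory_trial = "second") {
  roster <- cohort$roster; items <- cohort$items
  out <- data.frame(participant_id = roster$participant_id,
                    stringsAsFactors = FALSE)
  expected <- c(stroop = 18L, symbols = 9L, memory = 8L)
  for (k in names(expected)) {
    sub <- items[items$subtest == k, ]
    if (k == "memory") {
      answered <- switch(memory_trial,
                         second = !is.na(sub$response2),
                         first = !is.na(sub$response),
                         both = !is.na(sub$response) & !is.na(sub$response2))
      correct <- switch(memory_trial,
                        second = sub$response2 == sub$correct_response,
                        first = sub$response == sub$correct_response,
                        both = sub$response == sub$correct_response &
                          sub$response2 == sub$correct_response)
    } else {
      answered <- !is.na(sub$response) & !is.na(sub$response_time_s)
      correct <- sub$response == sub$correct_response
    }
    correct[is.na(correct)] <- FALSE
    pid <- factor(sub$participant_id, levels = roster$participant_id)
    # tapply over the full level set keeps roster order and fills absent
    # participants with 0 rows
    agg <- function(x) {
      v <- tapply(x, pid, sum, default = 0)
      as.numeric(v)
    }
    n_answered <- agg(as.integer(answered))
    n_correct <- agg(as.integer(correct & answered))
    total_time <- agg(ifelse(is.na(sub$response_time_s), 0,
                             sub$response_time_s))
    n_rows <- agg(rep(1L, nrow(sub)))
    complete <- n_rows == expected[[k]] & n_answered == expected[[k]]
    raw <- rep(NA_real_, nrow(roster))
    if (k == "memory") raw[complete] <- n_correct[complete]
    else raw[complete] <- n_correct[complete] / total_time[complete]
    out[[paste0("raw_", k)]] <- raw
    out[[paste0(k, "_complete")]] <- complete
  }
  out
}

#' Apply the participant-flow exclusions
#'
#' Assigns each participant exactly one disposition, in fixed priority
#' order: `revoked_consent`, then `cdr_gt_1` (screening failure), then
#' `upload_failed`, then `incomplete_mcog` (any subtest section without a
#' complete response set), and otherwise `included`.
#'
#' @param cohort A `mcog_cohort`.
#' @param scores Optional precomputed [score_cohort()] table.
#' @return List with `included` (roster subset), `ledger` (data frame
#'   `participant_id`, `disposition`) and `counts` (named disposition
#'   counts, including `included`).
#' @export
apply_exclusions <- function(cohort, scores = score_cohort(cohort)) {
  roster <- cohort$roster
  stopifnot(identical(scores$participant_id, roster$participant_id))
  complete <- scores$stroop_complete & scores$symbols_complete &
    scores$memory_complete
  disposition <- ifelse(
    roster$revoked_consent, "revoked_consent",
    ifelse(!is.na(roster$cdr_global) & roster$cdr_global > 1, "cdr_gt_1",
           ifelse(!roster$uploaded, "upload_failed",
                  ifelse(!complete, "incomplete_mcog", "included"))))
  ledger <- data.frame(participant_id = roster$participant_id,
                       disposition = disposition,
                       stringsAsFactors = FALSE)
  lv <- c("revoked_consent", "cdr_gt_1", "upload_failed",
          "incomplete_mcog", "included")
  counts <- vapply(lv, function(d) sum(disposition == d), integer(1))
  list(included = roster[disposition == "included", ],
       ledger = ledger, counts = counts)
}

summary_block <- function(x) {
  x <- x[!is.na(x)]
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(x), mean = mean(x), sd = stats::sd(x),
       median = q[2], q1 = q[1], q3 = q[3], min = min(x), max = max(x))
}

#' Table-1 style per-group summary of the included cohort
#'
#' Per CDR-defined group: n, sex counts, age, MMSE-2 and composite
#' summaries (mean, sd, median, quartiles by the linear-interpolation
#' convention, min, max) and education counts.
#'
#' @param roster Included roster (post-exclusion).
#' @param scores Score table with an `m_cogscore` column (see
#'   [add_composites()]).
#' @return Nested list with `healthy` and `impaired` blocks.
#' @export
table1_summary <- function(roster, scores) {
  scores <- scores[match(roster$participant_id, scores$participant_id), ]
  grp <- cdr_group(roster$cdr_global)
  out <- lapply(c(healthy = "healthy", impaired = "impaired"), function(g) {
    sel <- !is.na(grp) & grp == g
    list(n = sum(sel),
         sex = as.list(table(factor(roster$sex[sel], c("M", "F")))),
         age = summary_block(roster$age[sel]),
         education = as.list(table(factor(roster$education[sel],
                                          EDUCATION_LEVELS))),
         mmse2 = summary_block(roster$mmse2_total[sel]),
         m_cogscore = summary_block(scores$m_cogscore[sel]))
  })
  out
}

#' Run the validation statistics battery on the included cohort
#'
#' In order: Shapiro-Wilk normality gates on both scores (advisory; the
#' reported comparisons are always the non-parametric ones, so outputs
#' stay comparable across cohorts), Spearman correlation of the composite
#' with MMSE-2, Mann-Whitney U of each score against the dichotomised CDR
#' label, proportional median differences, both empirical ROCs with
#' Youden cut-offs and stratified proportion-bootstrap CIs, and the
#' paired DeLong comparison of the two AUCs.
#'
#' @param roster Included roster.
#' @param scores Score table with `m_cogscore` (complete participants).
#' @param n_boot,boot_proportion,alpha Bootstrap settings (defaults:
#'   10000 replicates, 0.75 proportion, 95% intervals).
#' @param seed Seed for the bootstrap resampling.
#' @return Nested list: `normality`, `spearman`, `mwu`,
#'   `proportional_median_difference`, `roc` (per score: auc, ci,
#'   cutoff), `delong`.
#' @export
run_validation <- function(roster, scores, n_boot = 10000L,
                           boot_proportion = 0.75, alpha = 0.05,
                           seed = 1L) {
  scores <- scores[match(roster$participant_id, scores$participant_id), ]
  grp <- cdr_group(roster$cdr_global)
  stopifnot(all(grp %in% c("healthy", "impaired")))
  impaired <- as.integer(grp == "impaired")
  mmse <- roster$mmse2_total
  mcog <- scores$m_cogscore
  stopifnot(!anyNA(mcog), !anyNA(mmse))

  tidy <- function(tr)
    tr[intersect(c("statistic_name", "statistic", "p_value", "u1", "u2",
                   "method"), names(tr))]
  med_prop <- function(x) {
    m <- tapply(x, grp, stats::median)
    list(median_healthy = unname(m["healthy"]),
         median_impaired = unname(m["impaired"]),
         observed_min = min(x), observed_max = max(x),
         fraction = proportional_median_difference(
           m["healthy"], m["impaired"], max(x), min(x)))
  }
  roc_block <- function(x, boot_seed) {
    ls <- labelled_scores(x, impaired, direction = "lower")
    roc <- empirical_roc(ls)
    cut <- youden_cutoff(roc)
    ci <- bootstrap_auc_ci(ls, n_boot = n_boot,
                           proportion = boot_proportion, alpha = alpha,
                           seed = boot_seed)
    list(auc = roc$auc,
         ci = list(lower = ci$lower, upper = ci$upper,
                   n_boot = ci$n_boot, proportion = ci$proportion,
                   alpha = ci$alpha),
         cutoff = list(threshold = cut$threshold,
                       sensitivity = cut$sensitivity,
                       specificity = cut$specificity,
                       youden_j = cut$youden_j,
                       rule = "score < threshold predicts impaired"))
  }

  dl <- delong_paired(mcog, mmse, impaired)
  list(
    normality = list(mmse2 = tidy(shapiro_wilk(mmse)),
                     m_cogscore = tidy(shapiro_wilk(mcog))),
    spearman = tidy(spearman_rho(mcog, mmse)),
    mwu = list(mmse2 = tidy(mann_whitney_u(mmse[impaired == 1],
                                           mmse[impaired == 0])),
               m_cogscore = tidy(mann_whitney_u(mcog[impaired == 1],
                                                mcog[impaired == 0]))),
    proportional_median_difference = list(mmse2 = med_prop(mmse),
                                          m_cogscore = med_prop(mcog)),
    roc = list(m_cogscore = roc_block(mcog, seed),
               mmse2 = roc_block(mmse, seed + 1L)),
    delong = list(auc_m_cogscore = dl$auc_a, auc_mmse2 = dl$auc_b,
                  z = dl$z, p_value = dl$p_value))
}

#' Missing-data analysis of the excluded participants
#'
#' Quantifies which sections were skipped (per subtest and group),
#' and compares participants with missing data (upload failures plus
#' incomplete composites) against the included cohort: age by t-test
#' within each group, MMSE-2 by Mann-Whitney U within each group, and the
#' proportion with impaired cognition by Yates-corrected chi-squared —
#' once for all participants with missing data and once for the
#' incomplete-composite subgroup only.
#'
#' @param cohort The full `mcog_cohort` (pre-exclusion).
#' @param exclusions Result of [apply_exclusions()].
#' @return Nested list; `applicable = FALSE` when nothing was excluded
#'   for missingness.
#' @export
missing_data_analysis <- function(cohort,
                                  exclusions = apply_exclusions(cohort)) {
  roster <- cohort$roster
  disp <- exclusions$ledger$disposition
  missing_sel <- disp %in% c("upload_failed", "incomplete_mcog")
  if (!any(missing_sel))
    return(list(applicable = FALSE,
                skip_counts = missingness_report(cohort)))
  grp <- cdr_group(roster$cdr_global)
  incl <- disp == "included"

  group_compare <- function(sel) {
    res <- list()
    for (g in c("healthy", "impaired")) {
      ex <- sel & !is.na(grp) & grp == g
      inc <- incl & !is.na(grp) & grp == g
      res[[g]] <- list(
        n = sum(ex),
        age_mean = mean(roster$age[ex]),
        mmse2_mean = mean(roster$mmse2_total[ex], na.rm = TRUE),
        age_t = if (sum(ex) >= 2 && sum(inc) >= 2)
          two_sample_t(roster$age[ex], roster$age[inc])$p_value
        else NA_real_,
        mmse2_mwu = if (sum(!is.na(roster$mmse2_total[ex])) >= 1)
          mann_whitney_u(roster$mmse2_total[ex],
                         roster$mmse2_total[inc])$p_value
        else NA_real_)
    }
    res
  }
  impaired_table <- function(sel) {
    # rows: this subset, included; cols: impaired, healthy
    rbind(c(sum(sel & grp == "impaired", na.rm = TRUE),
            sum(sel & grp == "healthy", na.rm = TRUE)),
          c(sum(incl & grp == "impaired", na.rm = TRUE),
            sum(incl & grp == "healthy", na.rm = TRUE)))
  }
  incomplete_sel <- disp == "incomplete_mcog"
  tab_all <- impaired_table(missing_sel)
  tab_inc <- impaired_table(incomplete_sel)
  chi <- function(tab)
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0)) {
      r <- chi2_2x2(tab, yates = TRUE)
      list(table = tab, chi_squared = r$statistic, p_value = r$p_value)
    } else list(table = tab, chi_squared = NA_real_, p_value = NA_real_)

  list(applicable = TRUE,
       skip_counts = missingness_report(cohort),
       n_missing = sum(missing_sel),
       n_incomplete = sum(incomplete_sel),
       missing_vs_included = group_compare(missing_sel),
       impaired_proportion_missing = chi(tab_all),
       impaired_proportion_incomplete = chi(tab_inc))
}

#' Run the whole study pipeline and assemble the report
#'
#' Scores the cohort, applies the participant-flow exclusions, fits the
#' z-reference on the included participants only, computes composites,
#' the Table-1 summary, the validation battery and the missing-data
#' analysis, and returns everything as one report list with provenance.
#' Numbers are carried at full precision; round at presentation time.
#'
#' @param cohort A `mcog_cohort`.
#' @param n_boot,boot_proportion Bootstrap settings for the AUC CIs.
#' @param seed Seed for the bootstrap resampling.
#' @param memory_trial Which recall trial feeds the memory score.
#' @return A `study_report` list with blocks `provenance`, `exclusions`,
#'   `table1`, `validation`, `missingness`.
#' @export
run_study <- function(cohort, n_boot = 10000L, boot_proportion = 0.75,
                      seed = 1L, memory_trial = "second") {
  scores <- score_cohort(cohort, memory_trial = memory_trial)
  excl <- apply_exclusions(cohort, scores)
  inc_scores <- scores[scores$participant_id %in%
                         excl$included$participant_id, ]
  inc_scores <- add_composites(inc_scores)   # self-referenced z-scores
  report <- list(
    provenance = list(package_version =
                        as.character(utils::packageVersion("mcogscore")),
                      schema_version = "1.0",
                      sim_seed = cohort$seed,
                      analysis_seed = seed,
                      config_hash = config_hash(cohort$config),
                      n_boot = n_boot, boot_proportion = boot_proportion,
                      memory_trial = memory_trial),
    exclusions = as.list(excl$counts),
    table1 = table1_summary(excl$included, inc_scores),
    validation = run_validation(excl$included, inc_scores,
                                n_boot = n_boot,
                                boot_proportion = boot_proportion,
                                seed = seed),
    missingness = missing_data_analysis(cohort, excl))
  class(report) <- c("study_report", class(report))
  report
}

config_hash <- function(config) {
  if (is.null(config)) return(NA_character_)
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(unclass(config), f, auto_unbox = TRUE, digits = NA,
                       null = "null")
  unname(tools::md5sum(f))
}

#' Write a study report to JSON
#'
#' @param report A `study_report` from [run_study()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE,
                       force = TRUE)
  invisible(path)
}
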