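#!/usr/bin/env Rscript
# Run the full validation analysis and write the machine-readable study
# report: Table-1 style group summaries, Spearman convergent validity,
# Mann-Whitney group comparisons, proportional median differences, both
# ROC curves with Youden cut-offs and 0.75-proportion bootstrap CIs, the
# paired DeLong AUC comparison, and the missing-data analysis.
#
# Usage: Rscript analysis/03_validate.R [cohortdir] [outdir] [n_boot] [seed]

suppressPackageStartupMessages(library(mcogscore))

args <- commandArgs(trailingOnly = TRUE)
cohortdir <- if (length(args) >= 1) args[1] else "results/cohort"
outdir <- if (length(args) >= 2) args[2] else "results"
n_boot <- if (length(args) >= 3) as.integer(args[3]) else 10000L
seed <- if (length(args) >= 4) as.integer(args[4]) else 1L

cohort <- load_cohort(file.path(cohortdir, "roster.csv"),
                      file.path(cohortdir, "items.csv"))
report <- run_study(cohort, n_boot = n_boot, seed = seed)
write_report(report, file.path(outdir, "report.json"))

# ROC point coordinates for plotting / inspection
all_scores <- score_cohort(cohort)
excl <- apply_exclusions(cohort, all_scores)
inc <- excl$included
inc_scores <- add_composites(all_scores[all_scores$participant_id %in%
                                          inc$participant_id, ])
impaired <- as.integer(inc$cdr_global > 0)
pts <- do.call(rbind, lapply(
  c("m_cogscore", "mmse2"), function(nm) {
    x <- if (nm == "m_cogscore") inc_scores$m_cogscore else
      inc$mmse2_total
    roc <- empirical_roc(labelled_scores(x, impaired))
    data.frame(score = nm, threshold = roc$thresholds,
               sensitivity = roc$sensitivity,
               specificity = roc$specificity)
  }))
utils::write.csv(pts, file.path(outdir, "roc_points.csv"),
                 row.names = FALSE)

v <- report$validation
cat(sprintf("Spearman rho (composite ~ MMSE-2) = %.2f, p = %.2g\n",
            v$spearman$statistic, v$spearman$p_value))
cat(sprintf("AUC composite %.2f [%.2f, %.2f]; AUC MMSE-2 %.2f [%.2f, %.2f]\n",
            v$roc$m_cogscore$auc, v$roc$m_cogscore$ci$lower,
            v$roc$m_cogscore$ci$upper, v$roc$mmse2$auc,
            v$roc$mmse2$ci$lower, v$roc$mmse2$ci$upper))
cat(sprintf("DeLong p = %.2f\n", v$delong$p_value))
cat("wrote", file.path(outdir, c("report.json", "roc_points.csv")), "\n")
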