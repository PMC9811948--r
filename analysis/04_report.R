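#!/usr/bin/env Rscript
# Render a human-readable summary of the study report, rounded the way
# screening-validation papers print their numbers (2 d.p. for rho, AUC
# and p; 1 d.p. for chi-squared).
#
# Usage: Rscript analysis/04_report.R [report.json]

suppressPackageStartupMessages(library(mcogscore))

args <- commandArgs(trailingOnly = TRUE)
path <- if (length(args) >= 1) args[1] else "results/report.json"
rep <- jsonlite::read_json(path)

cat("== Participant flow ==\n")
for (k in names(rep$exclusions))
  cat(sprintf("  %-16s %d\n", k, rep$exclusions[[k]]))

cat("\n== Group summaries (included) ==\n")
for (g in c("healthy", "impaired")) {
  t1 <- rep$table1[[g]]
  cat(sprintf("  %s (n = %d): age %.1f +/- %.1f; MMSE-2 %.1f +/- %.1f; composite %.2f +/- %.2f\n",
              g, t1$n, t1$age$mean, t1$age$sd, t1$mmse2$mean, t1$mmse2$sd,
              t1$m_cogscore$mean, t1$m_cogscore$sd))
}

v <- rep$validation
cat("\n== Validation ==\n")
cat(sprintf("  Spearman rho (composite ~ MMSE-2) = %.2f (p = %.2g)\n",
            v$spearman$statistic, v$spearman$p_value))
cat(sprintf("  Mann-Whitney U: MMSE-2 %d, composite %d\n",
            round(v$mwu$mmse2$statistic), round(v$mwu$m_cogscore$statistic)))
pmd <- v$proportional_median_difference
cat(sprintf("  median gap / observed range: MMSE-2 %.0f%%, composite %.0f%%\n",
            100 * pmd$mmse2$fraction, 100 * pmd$m_cogscore$fraction))
for (s in c("m_cogscore", "mmse2")) {
  r <- v$roc[[s]]
  cat(sprintf("  %-10s AUC %.2f [%.2f, %.2f]; cut-off < %.2f (sens %.2f, spec %.2f)\n",
              s, r$auc, r$ci$lower, r$ci$upper, r$cutoff$threshold,
              r$cutoff$sensitivity, r$cutoff$specificity))
}
cat(sprintf("  DeLong comparison: p = %.2f\n", v$delong$p_value))

m <- rep$missingness
if (isTRUE(m$applicable)) {
  cat("\n== Missing data ==\n")
  cat(sprintf("  %d participants without a full test triplet (%d incomplete composite)\n",
              m$n_missing, m$n_incomplete))
  sk <- m$skip_counts
  for (i in seq_along(sk$subtest))
    if (sk$n_skipped[[i]] > 0)
      cat(sprintf("    skipped %s: %d (%s)\n", sk$subtest[[i]],
                  sk$n_skipped[[i]], sk$group[[i]]))
  cat(sprintf("  impaired proportion, missing vs included: chi-squared = %.1f, p = %.2f\n",
              m$impaired_proportion_missing$chi_squared,
              m$impaired_proportion_missing$p_value))
  cat(sprintf("  impaired proportion, incomplete vs included: chi-squared = %.1f, p = %.2f\n",
              m$impaired_proportion_incomplete$chi_squared,
              m$impaired_proportion_incomplete$p_value))
}
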