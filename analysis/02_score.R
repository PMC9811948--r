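#!/usr/bin/env Rscript
# Score the cohort: apply the participant-flow exclusions, compute raw
# subtest scores, fit the z-reference on the included participants, and
# derive the composite M-CogScore for each of them.
#
# Usage: Rscript analysis/02_score.R [cohortdir] [outdir]

suppressPackageStartupMessages(library(mcogscore))

args <- commandArgs(trailingOnly = TRUE)
cohortdir <- if (length(args) >= 1) args[1] else "results/cohort"
outdir <- if (length(args) >= 2) args[2] else "results"

cohort <- load_cohort(file.path(cohortdir, "roster.csv"),
                      file.path(cohortdir, "items.csv"))
scores <- score_cohort(cohort)
excl <- apply_exclusions(cohort, scores)

cat("participant flow:\n")
print(excl$counts)

included <- scores[scores$participant_id %in%
                     excl$included$participant_id, ]
included <- add_composites(included)   # z-reference = included cohort

dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
utils::write.csv(included, file.path(outdir, "scores.csv"),
                 row.names = FALSE, na = "")
utils::write.csv(excl$ledger, file.path(outdir, "exclusions.csv"),
                 row.names = FALSE)

grp <- ifelse(excl$included$cdr_global == 0, "healthy", "impaired")
m <- tapply(included$m_cogscore, grp, mean)
cat(sprintf("composite means: healthy %.2f, impaired %.2f (n = %d)\n",
            m[["healthy"]], m[["impaired"]], nrow(included)))
cat("wrote", file.path(outdir, c("scores.csv", "exclusions.csv")), "\n")
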