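no_missing <- function(...) {
  # stochastic-mode config with skipping and upload failure switched off
  sim_config(skip_base = c(stroop = -50, symbols = -50, memory = -50),
             upload_p = 0, ...)
}

test_that("the same seed reproduces the cohort exactly", {
  a <- simulate_cohort(default_config(), seed = 123)
  b <- simulate_cohort(default_config(), seed = 123)
  expect_identical(a$roster, b$roster)
  expect_identical(a$items, b$items)
  c <- simulate_cohort(default_config(), seed = 124)
  expect_false(identical(a$roster, c$roster))
})

test_that("flow emulation reproduces the published participant flow", {
  co <- simulate_cohort(default_config(), seed = 42)
  expect_equal(nrow(co$roster), 108)

  ex <- apply_exclusions(co)
  expect_equal(unname(ex$counts["revoked_consent"]), 1L)
  expect_equal(unname(ex$counts["cdr_gt_1"]), 2L)
  expect_equal(unname(ex$counts["upload_failed"]), 7L)
  expect_equal(unname(ex$counts["incomplete_mcog"]), 26L)
  expect_equal(unname(ex$counts["included"]), 72L)

  # group split of the included and of the 33 with missing data
  grp <- ifelse(ex$included$cdr_global == 0, "healthy", "impaired")
  expect_equal(as.integer(table(grp)[c("healthy", "impaired")]),
               c(38L, 34L))
  disp <- ex$ledger$disposition
  miss <- co$roster[disp %in% c("upload_failed", "incomplete_mcog"), ]
  expect_equal(nrow(miss), 33L)
  expect_equal(sum(miss$cdr_global == 0), 12L)
  expect_equal(sum(miss$cdr_global > 0), 21L)
  # CDR composition: 1 included and 6 excluded participants at CDR 1
  expect_equal(sum(ex$included$cdr_global == 1), 1L)
  expect_equal(sum(miss$cdr_global == 1), 6L)
})

test_that("zero skip probability yields zero skip counts", {
  co <- simulate_cohort(no_missing(n_healthy = 30, n_impaired = 30),
                        seed = 2)
  rep_ <- missingness_report(co)
  expect_true(all(rep_$n_skipped == 0))
  expect_equal(sum(rep_$n_with_items), 60 * 3)
})

test_that("severity-linked skipping hits the impaired group harder", {
  # Monte-Carlo over seeds in stochastic mode
  tot <- c(healthy = 0, impaired = 0)
  den <- c(healthy = 0, impaired = 0)
  for (s in 1:100) {
    co <- simulate_cohort(
      sim_config(n_healthy = 25, n_impaired = 25, upload_p = 0,
                 skip_base = c(stroop = stats::qlogis(0.08),
                               symbols = stats::qlogis(0.08),
                               memory = stats::qlogis(0.08)),
                 skip_slope = 0.8),
      seed = 1000 + s)
    r <- missingness_report(co)
    for (g in c("healthy", "impaired")) {
      tot[g] <- tot[g] + sum(r$n_skipped[r$group == g])
      den[g] <- den[g] + sum(r$n_with_items[r$group == g])
    }
  }
  p <- tot / den
  expect_gt(p[["impaired"]], p[["healthy"]])
})

test_that("flow-mode skip sections split 9:5:12 in expectation", {
  counts <- c(stroop = 0, symbols = 0, memory = 0)
  n_seeds <- 40
  for (s in 1:n_seeds) {
    r <- missingness_report(simulate_cohort(default_config(),
                                            seed = 3000 + s))
    for (k in names(counts))
      counts[k] <- counts[k] + sum(r$n_skipped[r$subtest == k])
  }
  m <- counts / n_seeds
  # multinomial(26, (9,5,12)/26) per cohort; 3 SEs of the mean over seeds
  se <- sqrt(26 * (c(9, 5, 12) / 26) * (1 - c(9, 5, 12) / 26) / n_seeds)
  expect_true(all(abs(m - c(9, 5, 12)) < 3 * se))
  expect_equal(sum(counts) / n_seeds, 26)
})

test_that("null severity slopes make the groups indistinguishable", {
  cfg <- no_missing(
    n_healthy = 600, n_impaired = 600,
    stroop = list(acc_base = 3.2, acc_slope = 0, rt_meanlog = 0.10,
                  rt_slope = 0, rt_sdlog = 0.30),
    symbols = list(acc_base = 3.0, acc_slope = 0, rt_meanlog = 1.16,
                   rt_slope = 0, rt_sdlog = 0.30),
    memory = list(acc_base = 2.6, acc_slope = 0))
  co <- simulate_cohort(cfg, seed = 5)
  sc <- add_composites(score_cohort(co))
  impaired <- as.integer(co$roster$cdr_global > 0)
  auc <- empirical_roc(labelled_scores(sc$m_cogscore, impaired))$auc
  # null AUC ~ 0.5 with MC sd ~ sqrt(1/(12)*(1/n1+1/n0)) ~ 0.017
  expect_lt(abs(auc - 0.5), 3 * 0.017)
})

test_that("positive slopes fix the group ordering on every score", {
  co <- simulate_cohort(no_missing(n_healthy = 1500, n_impaired = 1500),
                        seed = 6)
  sc <- score_cohort(co)
  grp <- ifelse(co$roster$cdr_global == 0, "healthy", "impaired")
  for (v in list(co$roster$mmse2_total, sc$raw_stroop, sc$raw_symbols,
                 sc$raw_memory)) {
    expect_gt(mean(v[grp == "healthy"]), mean(v[grp == "impaired"]))
  }
})

test_that("zero latent loading removes cross-subtest correlation", {
  co <- simulate_cohort(no_missing(n_healthy = 2000, n_impaired = 0,
                                   loading = 0),
                        seed = 7)
  sc <- score_cohort(co)
  raw <- sc[c("raw_stroop", "raw_symbols", "raw_memory")]
  cors <- cor(raw)[upper.tri(diag(3))]
  expect_true(all(abs(cors) < 3 / sqrt(2000)))

  co2 <- simulate_cohort(no_missing(n_healthy = 2000, n_impaired = 0,
                                    loading = 0.8),
                         seed = 7)
  sc2 <- score_cohort(co2)
  cors2 <- cor(sc2[c("raw_stroop", "raw_symbols", "raw_memory")])[
    upper.tri(diag(3))]
  expect_true(all(cors2 > 3 / sqrt(2000)))
})

test_that("education marginals follow the configured group frequencies", {
  co <- simulate_cohort(no_missing(n_healthy = 3800, n_impaired = 3400),
                        seed = 8)
  grp <- ifelse(co$roster$cdr_global == 0, 1, 2)
  p_target <- rbind(c(2, 9, 6, 21) / 38, c(4, 4, 12, 14) / 34)
  for (g in 1:2) {
    n_g <- sum(grp == g)
    obs <- table(factor(co$roster$education[grp == g],
                        c("none", "GCSE", "A-levels", "University")))
    se <- sqrt(p_target[g, ] * (1 - p_target[g, ]) / n_g)
    expect_true(all(abs(as.numeric(obs) / n_g - p_target[g, ]) < 3.5 * se))
  }
})
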