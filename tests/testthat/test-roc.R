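test_that("empirical AUC handles separation, ties and direction", {
  # perfectly separated classes (impaired score lower)
  ls <- labelled_scores(c(1, 2, 3, 10, 11, 12), c(1, 1, 1, 0, 0, 0))
  expect_equal(empirical_roc(ls)$auc, 1)

  # all scores identical -> pure ties -> 0.5
  ls <- labelled_scores(rep(4, 8), c(1, 1, 1, 1, 0, 0, 0, 0))
  expect_equal(empirical_roc(ls)$auc, 0.5)

  expect_error(labelled_scores(1:5, rep(1, 5)), "both classes")

  # n = 8 fixture with between-class ties vs pair-counting oracle
  score <- c(25, 26, 26, 28, 26, 29, 29, 30)
  label <- c(1, 1, 1, 1, 0, 0, 0, 0)
  ls <- labelled_scores(score, label)
  expect_equal(empirical_roc(ls)$auc, auc_pairs_oracle(score, label),
               tolerance = 1e-12)
})

test_that("trapezoid, rank and pair-counting AUCs agree to 1e-12", {
  set.seed(21)
  for (i in 1:30) {
    n1 <- sample(3:25, 1); n0 <- sample(3:25, 1)
    score <- c(sample(20:30, n1, replace = TRUE) + rnorm(n1, 0, 2),
               sample(24:32, n0, replace = TRUE) + rnorm(n0, 0, 2))
    if (i %% 3 == 0) score <- round(score)      # force heavy ties
    label <- rep(c(1, 0), c(n1, n0))
    ls <- labelled_scores(score, label)
    roc <- empirical_roc(ls)
    a_trap <- mcogscore:::auc_trapezoid(roc)
    a_pairs <- auc_pairs_oracle(score, label)
    expect_equal(roc$auc, a_pairs, tolerance = 1e-12)
    expect_equal(a_trap, a_pairs, tolerance = 1e-12)
    # sensitivity is monotone along the threshold sweep
    expect_true(all(diff(roc$sensitivity) >= 0) ||
                  all(diff(roc$sensitivity) <= 0))
  }
})

test_that("AUC is invariant under monotone transforms and sign flips", {
  set.seed(8)
  score <- rnorm(40); label <- rbinom(40, 1, 0.4)
  if (sum(label) %in% c(0, 40)) label[1:2] <- c(0, 1)
  a <- empirical_roc(labelled_scores(score, label))$auc
  expect_equal(empirical_roc(labelled_scores(exp(score), label))$auc, a)
  expect_equal(empirical_roc(labelled_scores(-score, label,
                                             direction = "higher"))$auc, a)
})

test_that("Youden cut-off maximises J with the screening tie-break", {
  # perfect separation at score 10: J = 1 at the boundary
  ls <- labelled_scores(c(5, 6, 7, 12, 13, 14), c(1, 1, 1, 0, 0, 0))
  cut <- youden_cutoff(empirical_roc(ls))
  expect_equal(cut$youden_j, 1)
  expect_equal(cut$sensitivity, 1)
  expect_equal(cut$specificity, 1)

  # integer score fixture with impaired mass below 27: threshold is 27
  # under the "score < c => impaired" rule
  score <- c(20, 22, 24, 24, 25, 26, 26, 28,            # impaired
             26, 27, 28, 28, 29, 29, 30, 30, 30, 27)    # healthy
  label <- rep(c(1, 0), c(8, 10))
  roc <- empirical_roc(labelled_scores(score, label))
  cut <- youden_cutoff(roc)
  # oracle: enumerate J over every candidate cut point from the raw data
  cand <- c(sort(unique(score)), Inf)
  j_all <- vapply(cand, function(c0)
    mean(score[label == 1] < c0) + mean(score[label == 0] >= c0) - 1,
    numeric(1))
  expect_equal(cut$threshold, 27)
  expect_equal(cut$youden_j, max(j_all), tolerance = 1e-12)
  # reported pair is consistent with the raw data at that threshold
  expect_equal(cut$sensitivity, mean(score[label == 1] < cut$threshold))
  expect_equal(cut$specificity, mean(score[label == 0] >= cut$threshold))
})

test_that("Youden threshold maps through strictly monotone transforms", {
  set.seed(13)
  score <- round(rnorm(60, 27, 3))
  label <- as.integer(score + rnorm(60, 0, 3) < 26)
  if (sum(label) %in% c(0, 60)) label[1:2] <- c(0, 1)
  cut <- youden_cutoff(empirical_roc(labelled_scores(score, label)))
  f <- function(s) s^3 + 2 * s            # strictly increasing
  cut_f <- youden_cutoff(empirical_roc(labelled_scores(f(score), label)))
  expect_equal(cut_f$threshold, f(cut$threshold))
  expect_equal(cut_f$youden_j, cut$youden_j, tolerance = 1e-12)
})

test_that("bootstrap CI is reproducible, degenerate-safe, and shrinks with n", {
  ls <- labelled_scores(c(1, 2, 3, 10, 11, 12, 13), rep(c(1, 0), c(3, 4)))
  ci <- bootstrap_auc_ci(ls, n_boot = 200, proportion = 1, seed = 4)
  expect_equal(ci$lower, 1)
  expect_equal(ci$upper, 1)

  ci_a <- bootstrap_auc_ci(ls, n_boot = 300, seed = 99)
  ci_b <- bootstrap_auc_ci(ls, n_boot = 300, seed = 99)
  expect_identical(ci_a[c("lower", "upper")], ci_b[c("lower", "upper")])

  # width shrinks with n under a fixed binormal generative model
  widths <- vapply(c(50, 200, 1000), function(n) {
    set.seed(17)
    sc <- c(rnorm(n, -0.5, 1), rnorm(n, 0.5, 1))
    lb <- rep(c(1, 0), each = n)
    ci <- bootstrap_auc_ci(labelled_scores(sc, lb), n_boot = 400,
                           seed = 17)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  # subsampling variant is exposed
  ci_s <- bootstrap_auc_ci(ls, n_boot = 200, proportion = 0.75,
                           seed = 1, resample = "subsample")
  expect_true(ci_s$lower <= ci_s$upper)
})

test_that("DeLong test is null on equal curves and antisymmetric", {
  set.seed(31)
  s <- rnorm(40); lb <- rep(c(1, 0), each = 20)
  r <- delong_paired(s, s, lb)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)

  # monotone transform of the same score: identical ROC, p = 1
  r2 <- delong_paired(s, exp(s), lb)
  expect_equal(r2$auc_a, r2$auc_b)
  expect_equal(r2$p_value, 1)

  a <- rnorm(40); b <- a * 0.5 + rnorm(40, 0, 0.8)
  r_ab <- delong_paired(a, b, lb)
  r_ba <- delong_paired(b, a, lb)
  expect_equal(r_ab$z, -r_ba$z, tolerance = 1e-12)
  expect_equal(r_ab$p_value, r_ba$p_value, tolerance = 1e-12)
})

test_that("DeLong AUCs, z and p agree with the pROC reference", {
  set.seed(55)
  lb <- rep(c(1, 0), c(30, 34))
  u <- rnorm(64, ifelse(lb == 1, -0.8, 0), 1)
  a <- u + rnorm(64, 0, 0.6)
  b <- 0.6 * u + rnorm(64, 0, 0.8)
  ours <- delong_paired(a, b, lb)

  ra <- pROC::roc(lb, a, direction = ">", quiet = TRUE)
  rb <- pROC::roc(lb, b, direction = ">", quiet = TRUE)
  ref <- pROC::roc.test(ra, rb, method = "delong", paired = TRUE)
  expect_equal(ours$auc_a, as.numeric(pROC::auc(ra)), tolerance = 1e-12)
  expect_equal(ours$auc_b, as.numeric(pROC::auc(rb)), tolerance = 1e-12)
  expect_equal(abs(ours$z), abs(as.numeric(ref$statistic)),
               tolerance = 1e-10)
  expect_equal(ours$p_value, as.numeric(ref$p.value), tolerance = 1e-10)
})
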