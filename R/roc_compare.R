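# Empirical ROC machinery: rank-based AUC, Youden cut-offs, stratified
# proportion-bootstrap confidence intervals, and the paired DeLong test.
# The decision rule is "score < c => impaired" (strict) when lower scores
# predict impairment, which is the direction both screening scores here use.

#' Bundle scores with their class labels
#'
#' @param score Numeric vector of screening scores.
#' @param label Binary vector, 1 = impaired (case), 0 = healthy (control).
#' @param direction `"lower"` when lower scores predict impairment
#'   (cognitive scores), `"higher"` otherwise.
#' @return A `labelled_scores` object.
#' @export
labelled_scores <- function(score, label, direction = c("lower", "higher")) {
  direction <- match.arg(direction)
  ok <- stats::complete.cases(score, label)
  score <- score[ok]; label <- as.integer(label[ok])
  if (!all(label %in% c(0L, 1L))) stop("labels must be 0/1")
  if (!any(label == 1L) || !any(label == 0L))
    stop("undefined ROC: both classes must be present")
  structure(list(score = score, label = label, direction = direction),
            class = "labelled_scores")
}

# risk orientation: larger risk = more case-like, rule "risk > t"
.risk <- function(ls) if (ls$direction == "lower") -ls$score else ls$score

# AUC by the rank (Mann-Whitney) formulation; ties contribute 0.5
auc_rank <- function(risk, label) {
  r <- rank(risk)
  n1 <- sum(label == 1L); n0 <- length(label) - n1
  (sum(r[label == 1L]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Empirical ROC curve
#'
#' Thresholds are the unique observed scores plus a sentinel that
#' classifies everyone as impaired, under the strict rule
#' "score < c => impaired" (for `direction = "lower"`).  The AUC is the
#' rank-based (Mann-Whitney) value, identical to the trapezoidal area
#' under the empirical curve; between-class ties contribute 0.5.
#'
#' @param data A `labelled_scores` object.
#' @return A `roc_curve` with `thresholds`, `sensitivity`, `specificity`
#'   (aligned vectors, from the all-negative to the all-positive corner)
#'   and `auc`.
#' @export
empirical_roc <- function(data) {
  stopifnot(inherits(data, "labelled_scores"))
  risk <- .risk(data)
  lab <- data$label
  # cut points on the risk scale: rule is "risk > t"
  t_risk <- c(sort(unique(risk), decreasing = TRUE), -Inf)
  sens <- vapply(t_risk, function(t) mean(risk[lab == 1L] > t), numeric(1))
  spec <- vapply(t_risk, function(t) mean(risk[lab == 0L] <= t), numeric(1))
  # (1,1) corner needs t below min(risk); prepend the all-negative corner
  sens <- c(0, sens); spec <- c(1, spec)
  thr_risk <- c(Inf, t_risk)
  thresholds <- if (data$direction == "lower") -thr_risk else thr_risk
  structure(list(thresholds = thresholds, sensitivity = sens,
                 specificity = spec, direction = data$direction,
                 auc = auc_rank(risk, lab),
                 n_impaired = sum(lab == 1L), n_healthy = sum(lab == 0L)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: AUC = %.3f (%d impaired vs %d healthy, %s score predicts impairment)\n",
              x$auc, x$n_impaired, x$n_healthy, x$direction))
  invisible(x)
}

# trapezoidal area under (FPR, TPR); used as an internal cross-check
auc_trapezoid <- function(roc) {
  fpr <- 1 - roc$specificity
  o <- order(fpr, roc$sensitivity)
  sum(diff(fpr[o]) * (roc$sensitivity[o][-1] +
                        roc$sensitivity[o][-length(o)]) / 2)
}

#' Youden-optimal cut-off
#'
#' The threshold maximising J = sensitivity + specificity - 1.  Ties are
#' broken toward higher sensitivity (the screening priority), then toward
#' the less extreme threshold (smaller on the risk scale).
#'
#' @param roc A `roc_curve`.
#' @return A `cutoff_result` with `threshold`, `sensitivity`,
#'   `specificity` and `youden_j`.
#' @export
youden_cutoff <- function(roc) {
  stopifnot(inherits(roc, "roc_curve"))
  j <- roc$sensitivity + roc$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-roc$sensitivity[best], roc$thresholds[best])]
  i <- best[1L]
  structure(list(threshold = roc$thresholds[i],
                 sensitivity = roc$sensitivity[i],
                 specificity = roc$specificity[i],
                 youden_j = j[i], direction = roc$direction),
            class = "cutoff_result")
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Youden cut-off: score %s %.4g (sens %.2f, spec %.2f, J = %.2f)\n",
              if (x$direction == "lower") "<" else ">", x$threshold,
              x$sensitivity, x$specificity, x$youden_j))
  invisible(x)
}

#' Bootstrap confidence interval for the AUC
#'
#' Per replicate, `ceiling(proportion * n_g)` observations are resampled
#' with replacement within each class (stratified), and the percentile
#' interval of the replicate AUCs is returned.  `proportion = 0.75`
#' reproduces the 0.75-proportion bootstrap this validation design uses;
#' `resample = "subsample"` switches to drawing without replacement.
#'
#' @param data A `labelled_scores` object.
#' @param n_boot Number of bootstrap replicates (>= 100; 10000 in the
#'   full design).
#' @param proportion Fraction of each class resampled per replicate.
#' @param alpha Interval level is `1 - alpha` (default 95%).
#' @param seed Optional integer seed for reproducibility.
#' @param resample `"bootstrap"` (with replacement, default) or
#'   `"subsample"` (without).
#' @return A `bootstrap_ci` with `lower`, `upper`, `auc` (point estimate
#'   on the full data), `n_boot`, `proportion`, `alpha`, `seed`.
#' @export
bootstrap_auc_ci <- function(data, n_boot = 10000L, proportion = 0.75,
                             alpha = 0.05, seed = NULL,
                             resample = c("bootstrap", "subsample")) {
  stopifnot(inherits(data, "labelled_scores"))
  resample <- match.arg(resample)
  if (n_boot < 100L) stop("n_boot must be at least 100")
  if (proportion <= 0 || proportion > 1)
    stop("proportion must be in (0, 1]")
  if (!is.null(seed)) set.seed(seed)
  risk <- .risk(data)
  i1 <- which(data$label == 1L); i0 <- which(data$label == 0L)
  m1 <- ceiling(proportion * length(i1))
  m0 <- ceiling(proportion * length(i0))
  if (m1 < 1L || m0 < 1L)
    stop("proportion too small: a replicate would lose a class")
  with_replacement <- resample == "bootstrap"
  lab_boot <- rep(c(1L, 0L), c(m1, m0))
  # stratified draws keep both classes in every replicate, so the
  # single-class redraw rule never fires; guarded above instead
  aucs <- vapply(seq_len(n_boot), function(b) {
    r <- c(risk[sample(i1, m1, replace = with_replacement)],
           risk[sample(i0, m0, replace = with_replacement)])
    auc_rank(r, lab_boot)
  }, numeric(1))
  qs <- unname(stats::quantile(aucs, c(alpha / 2, 1 - alpha / 2)))
  structure(list(lower = qs[1L], upper = qs[2L],
                 auc = auc_rank(risk, data$label),
                 n_boot = n_boot, proportion = proportion, alpha = alpha,
                 seed = seed, resample = resample),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("AUC %.3f, %d%% CI [%.3f, %.3f] (%d reps, proportion %.2f)\n",
              x$auc, round(100 * (1 - x$alpha)), x$lower, x$upper,
              x$n_boot, x$proportion))
  invisible(x)
}

# placement values: V10[i] = P-hat(case i outranks a random control), etc.
delong_placements <- function(risk, label) {
  x <- risk[label == 1L]; y <- risk[label == 0L]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' Paired DeLong test for two correlated AUCs
#'
#' Non-parametric comparison of the AUCs of two scores measured on the
#' same participants, via the structural-components (placement-value)
#' estimator of the variance of the AUC difference, which accounts for the
#' pairing.  z = (AUC_a - AUC_b) / se, with a two-sided normal p-value.
#'
#' @param scores_a,scores_b Numeric score vectors over the same
#'   participants.
#' @param label Binary labels (1 = impaired).
#' @param direction_a,direction_b Score orientations, as in
#'   [labelled_scores()].
#' @return A `delong_result` with `auc_a`, `auc_b`, `var_diff`, `z`,
#'   `p_value`.
#' @export
delong_paired <- function(scores_a, scores_b, label,
                          direction_a = "lower", direction_b = "lower") {
  stopifnot(length(scores_a) == length(scores_b),
            length(scores_a) == length(label))
  la <- labelled_scores(scores_a, label, direction_a)
  lb <- labelled_scores(scores_b, label, direction_b)
  pa <- delong_placements(.risk(la), la$label)
  pb <- delong_placements(.risk(lb), lb$label)
  m <- length(pa$v10); n <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d_auc <- pa$auc - pb$auc
  if (var_diff <= 0) {
    if (abs(d_auc) < 1e-12) { z <- 0; p <- 1 }
    else {
      warning("degenerate DeLong variance with nonzero AUC difference")
      z <- sign(d_auc) * Inf; p <- 0
    }
  } else {
    z <- d_auc / sqrt(var_diff)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(auc_a = pa$auc, auc_b = pb$auc, var_diff = var_diff,
                 z = z, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("DeLong: AUC %.3f vs %.3f, z = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$z, x$p_value))
  invisible(x)
}
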