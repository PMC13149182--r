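# ROC machinery: empirical AUC via the Mann-Whitney identity (ties counted
# one half), Youden-optimal cutoff reporting, DeLong placement-value
# variance for single-AUC confidence intervals and for the paired two-AUC
# test, and the closed-form binormal-mixture AUC that bridges printed group
# summaries to an expected AUC under a Gaussian working model.

# orient scores so that larger = more disease-like
orient_scores <- function(scores, orientation) {
  if (orientation == "lower") -scores else scores
}

#' Empirical AUC by the Mann-Whitney identity
#'
#' `AUC = P(score_d > score_n) + 0.5 P(score_d = score_n)` over all
#' diseased/non-diseased pairs, after orienting scores so the diseased
#' direction is high.
#'
#' @param scores numeric marker values.
#' @param labels logical or 0/1, TRUE/1 = diseased.
#' @param orientation `"lower"` if lower scores indicate disease (the
#'   default here: cortical parameters fall with osteoporosis), `"higher"`
#'   otherwise.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(scores, labels, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), any(labels), any(!labels),
            all(is.finite(scores)))
  x <- orient_scores(scores[labels], orientation)
  y <- orient_scores(scores[!labels], orientation)
  r <- rank(c(x, y), ties.method = "average")
  n1 <- length(x); n0 <- length(y)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# DeLong placement values: for each diseased i, V10_i = mean_j psi(x_i, y_j)
# and for each non-diseased j, V01_j = mean_i psi(x_i, y_j), with psi the
# Mann-Whitney kernel. Computed from midranks, O(n log n).
delong_placements <- function(scores, labels, orientation) {
  labels <- as.logical(labels)
  x <- orient_scores(scores[labels], orientation)
  y <- orient_scores(scores[!labels], orientation)
  n1 <- length(x); n0 <- length(y)
  r_all <- rank(c(x, y), ties.method = "average")
  r_x <- rank(x, ties.method = "average")
  r_y <- rank(y, ties.method = "average")
  v10 <- (r_all[seq_len(n1)] - r_x) / n0
  v01 <- 1 - (r_all[n1 + seq_len(n0)] - r_y) / n1
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' Empirical ROC analysis with Youden-optimal cutoff
#'
#' Builds the empirical ROC over all observed thresholds, computes the AUC
#' by the Mann-Whitney identity, picks the cutoff maximizing the Youden
#' index (sensitivity + specificity - 1), and attaches a 95% confidence
#' interval from the DeLong variance with a normal approximation, truncated
#' to `[0, 1]`. The decision rule is `score <= cutoff` flags disease under
#' `"lower"` orientation, `score >= cutoff` under `"higher"`. Youden ties
#' are broken toward higher sensitivity, then toward the cutoff admitting
#' more subjects (lower cutoff for `"lower"`); ties are flagged.
#'
#' @inheritParams auc_mw
#' @param conf_level confidence level for the AUC interval (default 0.95).
#' @return An object of class `roc_result`: `auc`, `ci_low`, `ci_high`,
#'   `cutoff`, `sensitivity` and `specificity` (percent), `youden`,
#'   `orientation`, `n_diseased`, `n_nondiseased`, `flags`, and the full
#'   `curve` (data frame of cutoff/sens/spec).
#' @examples
#' set.seed(1)
#' s <- c(rnorm(40, 1.2, 0.6), rnorm(60, 1.8, 0.6))
#' roc_youden(s, rep(c(TRUE, FALSE), c(40, 60)), "lower")
#' @export
roc_youden <- function(scores, labels, orientation = c("lower", "higher"),
                       conf_level = 0.95) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  if (!any(labels) || !any(!labels)) stop("both classes must be non-empty")
  stopifnot(length(scores) == length(labels), all(is.finite(scores)))

  auc <- auc_mw(scores, labels, orientation)
  pl <- delong_placements(scores, labels, orientation)
  v <- stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * zq * sqrt(max(v, 0))))

  cuts <- sort(unique(scores))
  d <- scores[labels]; nd <- scores[!labels]
  if (orientation == "lower") {
    sens <- vapply(cuts, function(c0) mean(d <= c0), 0)
    spec <- vapply(cuts, function(c0) mean(nd > c0), 0)
  } else {
    cuts <- rev(cuts)
    sens <- vapply(cuts, function(c0) mean(d >= c0), 0)
    spec <- vapply(cuts, function(c0) mean(nd < c0), 0)
  }
  youden <- sens + spec - 1
  best <- which(youden == max(youden))
  flags <- character(0)
  if (length(best) > 1L) {
    flags <- "youden_tie"
    best <- best[sens[best] == max(sens[best])]
    best <- best[which.min(cuts[best])]  # then the lower threshold value
  }
  structure(list(
    auc = auc, ci_low = ci[1], ci_high = ci[2],
    cutoff = cuts[best],
    sensitivity = 100 * sens[best], specificity = 100 * spec[best],
    youden = youden[best], orientation = orientation,
    n_diseased = sum(labels), n_nondiseased = sum(!labels),
    flags = flags,
    curve = data.frame(cutoff = cuts, sensitivity = sens, specificity = spec)
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(paste0("<roc_result> AUC %.3f (%.3f-%.3f), cutoff %.4g ",
                     "(%s), sens %.2f%%, spec %.2f%%\n"),
              x$auc, x$ci_low, x$ci_high, x$cutoff,
              if (x$orientation == "lower") "<= flags disease" else ">= flags disease",
              x$sensitivity, x$specificity))
  invisible(x)
}

#' Paired DeLong test for two correlated AUCs
#'
#' Both markers are measured on the same subjects. AUC covariance is
#' estimated from the placement values (structural components);
#' `Z = (AUC_a - AUC_b) / sqrt(var(diff))` with a two-sided standard-normal
#' p. Degenerate variance (e.g. identical markers) yields Z = 0, p = 1 by
#' convention.
#'
#' @param scores_a,scores_b paired marker values on the same subjects.
#' @param labels logical or 0/1 disease status.
#' @param orientation as in [auc_mw()], applied to both markers.
#' @return list of class `delong_result`: `z_stat`, `p_value`, `auc_a`,
#'   `auc_b`, `var_diff`.
#' @export
delong_test <- function(scores_a, scores_b, labels,
                        orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  labels <- as.logical(labels)
  stopifnot(length(scores_a) == length(labels),
            length(scores_b) == length(labels),
            any(labels), any(!labels))
  pa <- delong_placements(scores_a, labels, orientation)
  pb <- delong_placements(scores_b, labels, orientation)
  n1 <- length(pa$v10); n0 <- length(pa$v01)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / n1 +
              (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n0
  if (!is.finite(var_diff) || var_diff <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- (pa$auc - pb$auc) / sqrt(var_diff)
    p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  }
  structure(list(z_stat = z, p_value = p, auc_a = pa$auc, auc_b = pb$auc,
                 var_diff = var_diff),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> AUC %.3f vs %.3f, Z = %.3f, p = %.3f\n",
              x$auc_a, x$auc_b, x$z_stat, x$p_value))
  invisible(x)
}

#' DeLong variance of a single empirical AUC
#'
#' Exposed for calibration checks (e.g. against bootstrap variance).
#'
#' @inheritParams auc_mw
#' @return variance estimate of the AUC.
#' @export
auc_variance <- function(scores, labels, orientation = c("lower", "higher")) {
  orientation <- match.arg(orientation)
  pl <- delong_placements(scores, as.logical(labels), orientation)
  stats::var(pl$v10) / length(pl$v10) + stats::var(pl$v01) / length(pl$v01)
}

#' Closed-form AUC under a binormal (Gaussian-mixture) working model
#'
#' For a Gaussian diseased group against a Gaussian-mixture non-diseased
#' group with lower-is-disease orientation,
#' `AUC = sum_j w_j Phi((mu_j - mu_d) / sqrt(sigma_j^2 + sigma_d^2))`,
#' with mixture weights `w_j` proportional to component sizes. Components
#' with zero variance on both sides degenerate to a step function handled
#' analytically (ties count one half).
#'
#' @param mean_d,sd_d diseased-group mean and SD.
#' @param mean_nd,sd_nd vectors of non-diseased component means and SDs.
#' @param n_nd component sizes (weights); default equal weights.
#' @return AUC in `[0, 1]`.
#' @examples
#' # one component, mean gap equal to the RMS spread: Phi(1)
#' binormal_auc(0, 1, sqrt(2) * 1, 1)
#' @export
binormal_auc <- function(mean_d, sd_d, mean_nd, sd_nd, n_nd = NULL) {
  stopifnot(length(mean_nd) == length(sd_nd), sd_d >= 0, all(sd_nd >= 0))
  w <- n_nd %||% rep(1, length(mean_nd))
  stopifnot(length(w) == length(mean_nd), all(w > 0))
  w <- w / sum(w)
  comp <- mapply(function(m, s) {
    pooled <- sqrt(s^2 + sd_d^2)
    if (pooled == 0) {
      (m > mean_d) + 0.5 * (m == mean_d)
    } else {
      stats::pnorm((m - mean_d) / pooled)
    }
  }, mean_nd, sd_nd)
  sum(w * comp)
}
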