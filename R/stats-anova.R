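# Group-comparison statistics: classic Levene's test, one-way ANOVA with
# LSD post hoc on raw data, and the algebraically identical summary-
# statistic form that recomputes F directly from printed (n, mean, SD)
# triplets — the route by which published group tables are replayed.

check_groups <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  lapply(groups, function(g) stopifnot(is.numeric(g), length(g) >= 2L,
                                       all(is.finite(g))))
  invisible(groups)
}

#' Levene's test for homogeneity of variances
#'
#' Classic form: one-way ANOVA on absolute deviations from the group means
#' (not medians), with an F reference on (k-1, N-k) degrees of freedom.
#'
#' @param groups list of numeric vectors, one per group; each n >= 2.
#' @return list with `statistic`, `df` (length 2) and `p_value`. Constant
#'   data in every group yields statistic 0 and p = 1.
#' @export
levene_test <- function(groups) {
  check_groups(groups)
  dev <- lapply(groups, function(g) abs(g - mean(g)))
  if (all(unlist(dev) == 0))
    return(list(statistic = 0, df = c(length(groups) - 1L,
                                      sum(lengths(groups)) - length(groups)),
                p_value = 1))
  a <- anova_oneway(dev, lsd = FALSE)
  list(statistic = a$f_stat, df = c(a$df_between, a$df_within),
       p_value = a$p_value)
}

anova_result <- function(f_stat, df_between, df_within, p_value,
                         lsd = NULL, flags = character(0)) {
  structure(list(f_stat = f_stat, df_between = df_between,
                 df_within = df_within, p_value = p_value,
                 lsd = lsd, flags = flags),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  if (!is.null(x$lsd)) {
    cat("  LSD pairwise:\n")
    print(x$lsd, row.names = FALSE)
  }
  invisible(x)
}

# shared core: everything below is a function of (n_i, mean_i, sd_i)
anova_core <- function(n, m, s, labels, lsd, lsd_gate) {
  k <- length(n)
  N <- sum(n)
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * s^2)
  df_b <- k - 1L
  df_w <- N - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w
  flags <- character(0)
  if (ms_w == 0) {
    if (ss_between == 0)
      return(anova_result(0, df_b, df_w, 1, flags = "no_variance"))
    return(anova_result(Inf, df_b, df_w, 0, flags = "infinite_f"))
  }
  f <- ms_b / ms_w
  p <- stats::pf(f, df_b, df_w, lower.tail = FALSE)
  lsd_df <- NULL
  if (lsd && p < lsd_gate) {
    pairs <- utils::combn(k, 2)
    lsd_df <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c2) {
      i <- pairs[1, c2]; j <- pairs[2, c2]
      diff <- m[i] - m[j]
      se <- sqrt(ms_w * (1 / n[i] + 1 / n[j]))
      tt <- diff / se
      data.frame(pair = paste(labels[i], labels[j], sep = " vs "),
                 mean_diff = diff, t = tt,
                 p = 2 * stats::pt(abs(tt), df_w, lower.tail = FALSE),
                 stringsAsFactors = FALSE)
    }))
  }
  anova_result(f, df_b, df_w, p, lsd_df, flags)
}

#' One-way ANOVA with LSD post hoc
#'
#' Classic between/within decomposition. When the omnibus test is
#' significant at `lsd_gate`, least-significant-difference pairwise t tests
#' are run with the pooled within-group variance on N-k degrees of freedom
#' (unadjusted, the conventional LSD).
#'
#' @param groups list of numeric vectors, one per group; each n >= 2.
#' @param lsd run LSD pairwise comparisons (default TRUE).
#' @param lsd_gate omnibus significance level gating LSD (default 0.05).
#' @return An `anova_result`: `f_stat`, `df_between`, `df_within`,
#'   `p_value`, `lsd` (data frame or NULL), `flags`. Zero pooled
#'   within-group variance with differing means is flagged `infinite_f`.
#' @export
anova_oneway <- function(groups, lsd = TRUE, lsd_gate = 0.05) {
  check_groups(groups)
  labels <- names(groups) %||% paste0("g", seq_along(groups))
  n <- lengths(groups)
  m <- vapply(groups, mean, 0)
  s <- vapply(groups, stats::sd, 0)
  anova_core(n, m, s, labels, lsd, lsd_gate)
}

#' One-way ANOVA from summary statistics
#'
#' Recomputes the omnibus F from per-group (n, mean, SD) alone:
#' `F = [sum n_i (m_i - m)^2 / (k-1)] / [sum (n_i - 1) s_i^2 / (N-k)]`
#' with `m` the size-weighted grand mean. Algebraically identical to
#' [anova_oneway()] on the raw data the summaries came from.
#'
#' @param summaries data frame with columns `n`, `mean`, `sd` and optionally
#'   `group` (labels); one row per group, each n >= 2.
#' @param lsd,lsd_gate as in [anova_oneway()].
#' @return An `anova_result`.
#' @examples
#' # replay a printed three-group row
#' anova_from_summary(data.frame(n = c(59, 58, 52),
#'                               mean = c(416.75, 365.61, 202.91),
#'                               sd = c(217.28, 221.03, 159.19)))
#' @export
anova_from_summary <- function(summaries, lsd = TRUE, lsd_gate = 0.05) {
  stopifnot(is.data.frame(summaries),
            all(c("n", "mean", "sd") %in% names(summaries)),
            nrow(summaries) >= 2L, all(summaries$n >= 2),
            all(summaries$sd >= 0))
  labels <- summaries$group %||% paste0("g", seq_len(nrow(summaries)))
  anova_core(summaries$n, summaries$mean, summaries$sd, labels, lsd, lsd_gate)
}
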