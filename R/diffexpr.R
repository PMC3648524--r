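#' Wilcoxon rank-sum test with recorded method
#'
#' Exact two-sided p-value (full null enumeration of rank assignments) when
#' the pooled sample size is at most 20 and there are no ties; otherwise
#' the normal approximation with tie and continuity correction.
#'
#' @param x,y Numeric vectors, each with >= 2 observations.
#' @return List with \code{statistic} (Mann-Whitney W of x vs y),
#'   \code{p_value}, \code{method} ("exact" or "normal_approx").
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each group needs >= 2 values")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && (length(x) + length(y)) <= 20L
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approx")
}

#' Log2 expression ratio with a rank-test-derived confidence interval
#'
#' Point estimate: the log2 ratio of the two group means on the linear
#' scale, \code{log2(mean(2^x) / mean(2^y))}; inputs are log2 expression.
#' The interval is the Hodges-Lehmann interval obtained by inverting the
#' Wilcoxon rank-sum test for a location shift on the log2 scale, so it is
#' reported in log2 units. A \code{"log_mean_diff"} mode estimating
#' \code{mean(x) - mean(y)} is available.
#'
#' @param x,y Log2 expression vectors (nonempty).
#' @param conf Confidence level in (0,1); default 0.99.
#' @param estimate \code{"ratio_of_means"} (default) or
#'   \code{"log_mean_diff"}.
#' @return List with \code{log2_ratio}, \code{ci_low}, \code{ci_high},
#'   \code{conf}.
#' @export
log_ratio_with_ci <- function(x, y, conf = 0.99,
                              estimate = c("ratio_of_means", "log_mean_diff")) {
  estimate <- match.arg(estimate)
  if (!length(x) || !length(y)) stop("empty group")
  if (conf <= 0 || conf >= 1) stop("conf must lie in (0,1)")
  est <- if (estimate == "ratio_of_means") {
    log2(mean(2^x) / mean(2^y))
  } else {
    mean(x) - mean(y)
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  ci <- tryCatch({
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, conf.int = TRUE, conf.level = conf,
                         exact = !ties && (length(x) + length(y)) <= 20L)
    )
    unname(wt$conf.int)
  }, error = function(e) {
    # degenerate shift (e.g. constant groups): all pairwise differences
    # carry the same information, the interval collapses to their range
    d <- range(outer(x, y, `-`))
    warning("rank-sum interval degenerate; using pairwise-difference range")
    d
  })
  list(log2_ratio = est, ci_low = ci[1L], ci_high = ci[2L], conf = conf)
}

#' Two-group differential expression over an expression matrix
#'
#' Per gene: Wilcoxon rank-sum p-value, log2 ratio of group means with a
#' Hodges-Lehmann confidence interval, and an up/down/ns direction call at
#' the significance threshold (0.001, the heatmap-star convention; 0.01 is
#' the common alternative).
#'
#' @param expr genes x samples matrix.
#' @param group_a,group_b Sample id (or column index) vectors for the two
#'   groups.
#' @param conf Confidence level for the interval.
#' @param alpha Significance threshold for the direction call.
#' @param adjust Add a Benjamini-Hochberg adjusted p column (off by
#'   default; the analysis convention applies no correction).
#' @return data.frame, one row per gene: \code{gene}, \code{log2_ratio},
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{direction}, and
#'   \code{p_adjusted} if requested.
#' @export
diff_expression <- function(expr, group_a, group_b, conf = 0.99,
                            alpha = 0.001, adjust = FALSE) {
  a <- expr[, group_a, drop = FALSE]
  b <- expr[, group_b, drop = FALSE]
  res <- lapply(rownames(expr), function(g) {
    x <- a[g, ]
    y <- b[g, ]
    p <- rank_sum_test(x, y)$p_value
    lr <- log_ratio_with_ci(x, y, conf = conf)
    data.frame(gene = g, log2_ratio = lr$log2_ratio, ci_low = lr$ci_low,
               ci_high = lr$ci_high, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$direction <- ifelse(out$p_value >= alpha, "ns",
                          ifelse(out$log2_ratio > 0, "up", "down"))
  if (adjust) out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Mean absolute log2 difference over a set of genes
#'
#' Summary used to compare overall effect magnitude between gene groups
#' (e.g. ligands vs receptors).
#'
#' @param log2_ratios Numeric vector of per-gene log2 ratios (nonempty).
#' @return Mean of absolute values.
#' @export
mean_abs_difference <- function(log2_ratios) {
  if (!length(log2_ratios)) stop("empty subset")
  mean(abs(log2_ratios))
}
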