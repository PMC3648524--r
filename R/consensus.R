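#' Best-of-restarts K-means
#'
#' Lloyd-style K-means restarted from random initial centers; the solution
#' with the lowest total within-cluster sum of squares is kept.
#' Deterministic for a fixed seed.
#'
#' @param X samples x features matrix.
#' @param k Number of clusters (<= nrow(X)).
#' @param restarts Random restarts (default 50).
#' @param seed Optional integer seed.
#' @param init \code{"random"} (uniform random points as initial centers,
#'   the \code{kmeans} default) or \code{"plusplus"} for k-means++ seeding.
#' @return List with \code{labels} (integer vector) and \code{wss} (total
#'   within-cluster sum of squares).
#' @export
kmeans_best_of <- function(X, k, restarts = 50L, seed = NULL,
                           init = c("random", "plusplus")) {
  init <- match.arg(init)
  X <- as.matrix(X)
  if (k > nrow(X)) stop("k exceeds the number of samples")
  if (any(!is.finite(X))) stop("non-finite values in X")
  if (!is.null(seed)) set.seed(seed)
  if (k == 1L) {
    ctr <- colMeans(X)
    return(list(labels = rep(1L, nrow(X)),
                wss = sum(sweep(X, 2L, ctr)^2)))
  }
  if (init == "random") {
    km <- stats::kmeans(X, centers = k, nstart = restarts, iter.max = 100L)
  } else {
    best <- NULL
    for (r in seq_len(restarts)) {
      ctr <- .kmeanspp_centers(X, k)
      fit <- suppressWarnings(stats::kmeans(X, centers = ctr,
                                            iter.max = 100L))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    km <- best
  }
  list(labels = unname(km$cluster), wss = km$tot.withinss)
}

.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1L)
  for (j in seq_len(k - 1L)) {
    d2 <- apply(X, 1L, function(x) {
      min(colSums((t(X[idx, , drop = FALSE]) - x)^2))
    })
    d2[idx] <- 0
    idx <- c(idx, sample.int(n, 1L, prob = d2 / sum(d2)))
  }
  X[idx, , drop = FALSE]
}

#' Subsampled consensus K-means clustering
#'
#' Runs [kmeans_best_of()] on repeated random subsamples (without
#' replacement) and records, for every sample pair, the fraction of
#' co-sampled iterations in which the pair co-clustered (Monti-style
#' normalization; \code{denominator = "iterations"} divides by the total
#' iteration count instead). The area under the empirical CDF of the
#' consensus values summarizes cluster stability at this K.
#'
#' @param X samples x features matrix.
#' @param k Number of clusters.
#' @param iterations Number of subsampled clustering runs (default 100).
#' @param subsample_fraction Fraction sampled per iteration (default 0.8);
#'   \code{floor(fraction * n)} must be >= k.
#' @param restarts K-means restarts per iteration.
#' @param seed Integer seed.
#' @param denominator \code{"cosampled"} (default) or \code{"iterations"}.
#' @return List of class \code{"consensus_result"}: \code{k},
#'   \code{consensus} (samples x samples in [0,1]), \code{co_cluster} and
#'   \code{co_sample} count matrices, \code{cdf_area}, \code{labels}
#'   (full-data K-means at k), \code{never_cosampled} pair count, and
#'   \code{assignments} (per-iteration sampled indices and labels, kept so
#'   the matrix can be recounted independently).
#' @export
consensus_cluster <- function(X, k, iterations = 100L,
                              subsample_fraction = 0.8, restarts = 50L,
                              seed = NULL,
                              denominator = c("cosampled", "iterations")) {
  denominator <- match.arg(denominator)
  X <- as.matrix(X)
  n <- nrow(X)
  m <- floor(subsample_fraction * n)
  if (subsample_fraction <= 0 || subsample_fraction > 1) {
    stop("subsample_fraction must lie in (0,1]")
  }
  if (iterations < 1L) stop("iterations must be >= 1")
  if (m < k) stop("floor(subsample_fraction * n) must be >= k")
  if (!is.null(seed)) set.seed(seed)
  S <- matrix(0, n, n)  # co-cluster counts
  N <- matrix(0, n, n)  # co-sample counts
  assignments <- vector("list", iterations)
  for (it in seq_len(iterations)) {
    idx <- sort(sample.int(n, m))
    fit <- kmeans_best_of(X[idx, , drop = FALSE], k, restarts = restarts)
    Z <- outer(fit$labels, fit$labels, `==`) * 1
    S[idx, idx] <- S[idx, idx] + Z
    N[idx, idx] <- N[idx, idx] + 1
    assignments[[it]] <- list(idx = idx, labels = fit$labels)
  }
  consensus <- if (denominator == "cosampled") {
    ifelse(N > 0, S / ifelse(N > 0, N, 1), 0)
  } else {
    S / iterations
  }
  never <- sum(N[upper.tri(N)] == 0)
  if (never > 0) {
    warning(never, " sample pairs were never co-sampled; their consensus is 0")
  }
  full <- kmeans_best_of(X, k, restarts = restarts)
  rn <- rownames(X) %||% as.character(seq_len(n))
  dimnames(consensus) <- list(rn, rn)
  structure(list(k = k, consensus = consensus, co_cluster = S, co_sample = N,
                 cdf_area = consensus_cdf_area(consensus),
                 labels = stats::setNames(full$labels, rn), wss = full$wss,
                 never_cosampled = never, assignments = assignments),
            class = "consensus_result")
}

#' Area under the consensus-value CDF
#'
#' Empirical CDF of the upper-triangle (off-diagonal) consensus entries
#' evaluated on a 100-bin grid over [0,1]; the area is the bin-width sum of
#' the CDF at the upper bin edges. Clean cluster structure pushes consensus
#' values toward {0,1} and the area toward its maximum.
#'
#' @param consensus Symmetric consensus matrix.
#' @return Scalar area in [0,1].
#' @export
consensus_cdf_area <- function(consensus) {
  v <- consensus[upper.tri(consensus)]
  edges <- seq(0, 1, length.out = 101L)[-1L]
  cdf <- stats::ecdf(v)
  sum(cdf(edges)) * 0.01
}

#' Choose the cluster number from consensus CDF areas
#'
#' Across an ascending contiguous K range, the chosen K is the smallest
#' whose relative area increase to K+1 drops below
#' \code{min_relative_change} — the point where adding clusters stops
#' improving consensus. If no K qualifies the maximum K is returned with a
#' warning. The full area/change table is reported so the consensus
#' matrices themselves can still be inspected.
#'
#' @param results List of \code{consensus_result} objects at consecutive K.
#' @param min_relative_change Threshold on (A(k+1)-A(k))/A(k); default
#'   0.05.
#' @return List with \code{k_range}, \code{cdf_areas},
#'   \code{relative_area_changes} (change from k to k+1; NA for the last
#'   k), \code{chosen_k}.
#' @export
select_k <- function(results, min_relative_change = 0.05) {
  ks <- vapply(results, `[[`, numeric(1), "k")
  if (length(ks) < 3L || any(diff(ks) != 1)) {
    stop("need a contiguous ascending k range of >= 3 values")
  }
  areas <- vapply(results, `[[`, numeric(1), "cdf_area")
  rel <- c((areas[-1L] - areas[-length(areas)]) / areas[-length(areas)], NA)
  ok <- which(!is.na(rel) & rel < min_relative_change)
  if (length(ok)) {
    chosen <- ks[ok[1L]]
  } else {
    warning("no k reached the relative-change criterion; returning max k")
    chosen <- ks[length(ks)]
  }
  list(k_range = ks, cdf_areas = areas, relative_area_changes = rel,
       chosen_k = chosen)
}

#' Complete-linkage leaf order for heatmap rows
#'
#' Rows (genes) are optionally z-scaled (zero mean, unit variance;
#' zero-variance rows are flagged and left unscaled), then ordered by the
#' dendrogram of complete-linkage agglomeration on Euclidean distances.
#'
#' @param expr genes x samples matrix with >= 2 rows.
#' @param z_scale Scale rows before clustering (default TRUE).
#' @return Character vector of row names in dendrogram leaf order, with
#'   the \code{hclust} object as attribute \code{"hclust"} and any
#'   unscalable rows in attribute \code{"unscaled_rows"}.
#' @export
complete_linkage_order <- function(expr, z_scale = TRUE) {
  stopifnot(is.matrix(expr), nrow(expr) >= 2L)
  x <- expr
  unscaled <- character(0)
  if (z_scale) {
    sds <- apply(x, 1L, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      unscaled <- rownames(x)[zero]
      warning("zero-variance rows left unscaled: ",
              paste(unscaled, collapse = ", "))
    }
    x[!zero, ] <- (x[!zero, , drop = FALSE] - rowMeans(x[!zero, , drop = FALSE])) /
      sds[!zero]
    x[zero, ] <- x[zero, , drop = FALSE] - rowMeans(x[zero, , drop = FALSE])
  }
  hc <- stats::hclust(stats::dist(x, method = "euclidean"),
                      method = "complete")
  ord <- rownames(expr)[hc$order]
  attr(ord, "hclust") <- hc
  attr(ord, "unscaled_rows") <- unscaled
  ord
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie adjusted Rand index from the contingency table of the two
#' label vectors; 1 for identical partitions, ~0 for independent ones.
#'
#' @param a,b Equal-length label vectors.
#' @return Scalar index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
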