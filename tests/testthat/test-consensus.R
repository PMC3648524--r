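test_that("k-means best-of handles k = 1 and separable clouds", {
  set.seed(71)
  X <- rbind(matrix(rnorm(40, 0, 0.3), 20), matrix(rnorm(40, 10, 0.3), 20))
  one <- kmeans_best_of(X, 1)
  expect_equal(one$wss, sum(scale(X, scale = FALSE)^2), tolerance = 1e-10)
  two <- kmeans_best_of(X, 2, seed = 71)
  expect_equal(length(unique(two$labels[1:20])), 1L)
  expect_equal(length(unique(two$labels[21:40])), 1L)
  expect_false(two$labels[1] == two$labels[21])
  expect_error(kmeans_best_of(X, 50), "exceeds")
})

test_that("best-of WSS attains the exhaustive two-partition minimum", {
  set.seed(72)
  for (rep in 1:5) {
    X <- matrix(rnorm(16), 8, 2)
    got <- kmeans_best_of(X, 2, restarts = 50, seed = 72 + rep)$wss
    # enumerate all 2^7 - 1 bipartitions
    best <- Inf
    for (code in 1:(2^7 - 1)) {
      grp <- c(0L, as.integer(intToBits(code)[1:7]))
      w <- 0
      for (g in 0:1) {
        sub <- X[grp == g, , drop = FALSE]
        if (nrow(sub)) w <- w + sum(scale(sub, scale = FALSE)^2)
      }
      best <- min(best, w)
    }
    expect_equal(got, best, tolerance = 1e-8)
  }
})

test_that("consensus matrix is symmetric, bounded and matches a recount", {
  set.seed(73)
  X <- matrix(rnorm(30 * 5), 30)
  res <- consensus_cluster(X, 3, iterations = 40, seed = 73)
  C <- res$consensus
  expect_equal(C, t(C), tolerance = 1e-12)
  expect_true(all(C >= 0 & C <= 1))
  expect_true(all(diag(C)[diag(res$co_sample) > 0] == 1))
  # independent recount from the logged per-iteration assignments
  S <- matrix(0, 30, 30)
  N <- matrix(0, 30, 30)
  for (a in res$assignments) {
    for (i in seq_along(a$idx)) {
      for (j in seq_along(a$idx)) {
        N[a$idx[i], a$idx[j]] <- N[a$idx[i], a$idx[j]] + 1
        if (a$labels[i] == a$labels[j]) {
          S[a$idx[i], a$idx[j]] <- S[a$idx[i], a$idx[j]] + 1
        }
      }
    }
  }
  ref <- ifelse(N > 0, S / ifelse(N > 0, N, 1), 0)
  expect_equal(unname(C), ref, tolerance = 1e-12)
})

test_that("single-iteration consensus is 0/1 on co-sampled pairs", {
  set.seed(74)
  X <- matrix(rnorm(20 * 3), 20)
  res <- suppressWarnings(consensus_cluster(X, 2, iterations = 1, seed = 74))
  on <- res$co_sample > 0
  expect_true(all(res$consensus[on] %in% c(0, 1)))
  expect_gt(res$never_cosampled, 0)
})

test_that("separated clouds give block-perfect consensus at k = 2", {
  set.seed(75)
  X <- rbind(matrix(rnorm(50 * 4, 0, 0.3), 50),
             matrix(rnorm(50 * 4, 8, 0.3), 50))
  res <- consensus_cluster(X, 2, iterations = 50, seed = 75)
  expect_equal(min(res$consensus[1:50, 1:50][res$co_sample[1:50, 1:50] > 0]), 1)
  expect_equal(max(res$consensus[1:50, 51:100]), 0)
})

test_that("within-cluster consensus rises monotonically with separation", {
  seps <- c(0.5, 1.5, 3)
  mean_within <- vapply(seps, function(s) {
    cfg <- three_cluster_config(seed = 76L, n_tumor = 90L, shift = s)
    ch <- generate_cohort(cfg)
    X <- t(subset_panel(ch$expression))
    res <- consensus_cluster(X, 3, iterations = 40, seed = 76)
    same <- outer(ch$truth$cluster, ch$truth$cluster, "==")
    mean(res$consensus[same & upper.tri(same)])
  }, numeric(1))
  expect_true(all(diff(mean_within) > 0))
})

test_that("select_k reports areas and applies the relative-change rule", {
  mk <- function(k, area) structure(list(k = k, cdf_area = area),
                                    class = "consensus_result")
  # forced case: equal areas -> first k chosen, change 0
  sel <- select_k(list(mk(2, 0.5), mk(3, 0.5), mk(4, 0.5)))
  expect_identical(sel$chosen_k, 2)
  expect_equal(sel$relative_area_changes[1], 0)
  # rising then flat: chosen at the flattening point
  sel <- select_k(list(mk(2, 0.4), mk(3, 0.7), mk(4, 0.71), mk(5, 0.715)))
  expect_identical(sel$chosen_k, 3)
  # never flattens: max k with a warning
  expect_warning(
    sel <- select_k(list(mk(2, 0.4), mk(3, 0.6), mk(4, 0.9))),
    "max k")
  expect_identical(sel$chosen_k, 4)
  expect_error(select_k(list(mk(2, 1), mk(4, 1), mk(5, 1))), "contiguous")
})

test_that("final labels recover well-separated planted clusters", {
  cfg <- three_cluster_config(seed = 77L, n_tumor = 300L)
  ch <- generate_cohort(cfg)
  X <- t(subset_panel(ch$expression))
  res <- consensus_cluster(X, 3, iterations = 50, seed = 77)
  expect_gt(adjusted_rand_index(res$labels, ch$truth$cluster), 0.9)
})

test_that("complete-linkage ordering matches merge structure and an oracle", {
  # forced merge order: a,b merge first; c ends up at an end
  m <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
  colnames(m) <- c("s1", "s2")
  ord <- complete_linkage_order(m, z_scale = FALSE)
  expect_true(ord[1] == "c" || ord[3] == "c")
  hc <- attr(ord, "hclust")
  expect_setequal(abs(hc$merge[1, ]), c(1, 2))  # a and b first
  # 2 rows: order is the input pair
  two <- complete_linkage_order(m[1:2, ], z_scale = FALSE)
  expect_setequal(as.character(two), c("a", "b"))
  # n = 6 random case: merge heights equal a naive O(n^3) recomputation
  set.seed(78)
  x <- toy_matrix(6, 5, seed = 78)
  ord <- complete_linkage_order(x, z_scale = FALSE)
  hc <- attr(ord, "hclust")
  naive_heights <- local({
    d <- as.matrix(stats::dist(x))
    active <- as.list(seq_len(6))
    heights <- numeric(0)
    while (length(active) > 1) {
      best <- c(Inf, NA, NA)
      for (i in seq_along(active)) {
        for (j in seq_len(i - 1)) {
          h <- max(d[active[[i]], active[[j]]])
          if (h < best[1]) best <- c(h, j, i)
        }
      }
      heights <- c(heights, best[1])
      active[[best[2]]] <- c(active[[best[2]]], active[[best[3]]])
      active[[best[3]]] <- NULL
    }
    heights
  })
  expect_equal(hc$height, naive_heights, tolerance = 1e-10)
  # zero-variance row with scaling: flagged, not fatal
  y <- rbind(flat = rep(2, 5), x[1:2, ])
  expect_warning(ozy <- complete_linkage_order(y, z_scale = TRUE), "flat")
  expect_setequal(as.character(ozy), rownames(y))
})

test_that("adjusted Rand index behaves at its reference points", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, rep(c("x", "y", "z"), each = 10)), 1)
  set.seed(79)
  b <- sample(1:3, 30, replace = TRUE)
  expect_lt(abs(adjusted_rand_index(a, b)), 0.35)
  if (requireNamespace("mclust", quietly = TRUE)) {
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
})
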