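test_that("loadings and variances match an eigendecomposition oracle", {
  set.seed(61)
  m <- toy_matrix(6, 30, seed = 61)
  fit <- fit_pca(m)
  S <- stats::cov(t(m))
  eig <- eigen(S, symmetric = TRUE)
  expect_equal(fit$explained_variance, eig$values, tolerance = 1e-8)
  for (j in seq_along(eig$values)) {
    v <- eig$vectors[, j]
    i <- which.max(abs(v))
    if (v[i] < 0) v <- -v  # same sign convention
    expect_equal(unname(fit$loadings[, j]), v, tolerance = 1e-8)
  }
  # orthonormal loadings; scores centered with diagonal covariance
  expect_equal(crossprod(fit$loadings), diag(6), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(unname(colMeans(fit$scores)), rep(0, 6), tolerance = 1e-10)
  sc_cov <- stats::cov(fit$scores)
  expect_equal(unname(sc_cov), diag(fit$explained_variance),
               tolerance = 1e-8)
  # reconstruction with all components retained
  centered <- m - rowMeans(m)
  expect_equal(unname(t(fit$scores %*% t(fit$loadings))), unname(centered),
               tolerance = 1e-8)
})

test_that("collinear two-gene data yields the diagonal first component", {
  m <- rbind(g1 = c(1, 2, 3), g2 = c(1, 2, 3))
  colnames(m) <- paste0("S", 1:3)
  fit <- fit_pca(m)
  expect_equal(unname(fit$loadings[, 1]), c(1, 1) / sqrt(2),
               tolerance = 1e-10)
  expect_equal(fit$explained_variance[2], 0, tolerance = 1e-12)
  # zero-variance gene with scaling on is an error
  m2 <- rbind(g1 = c(1, 2, 3), g2 = c(5, 5, 5))
  colnames(m2) <- paste0("S", 1:3)
  expect_error(fit_pca(m2, scale = TRUE), "zero-variance")
})

test_that("a dominant planted contrast is recovered by PC1", {
  # one strong two-cluster contrast, noise scaled so it dominates
  cs <- default_cluster_spec(shift = 3)[c("A", "F")]
  cs$A$proportion <- cs$F$proportion <- 0.5
  cfg <- cohort_config(n_tumor = 400L, n_normal = 0L,
                       n_background_genes = 0L, cluster_spec = cs,
                       noise_sd = 1, seed = 63L)
  ch <- generate_cohort(cfg)
  fit <- fit_pca(subset_panel(ch$expression))
  expect_gte(fit$prop_variance[1], 0.30)
  planted <- planted_signature_directions(cfg)[, "A-F"]
  cosine <- abs(sum(fit$loadings[, 1] * planted))
  expect_gt(cosine, 0.95)
})

test_that("top loading genes are the brute-force norm filter", {
  set.seed(64)
  fit <- fit_pca(toy_matrix(8, 25, seed = 64))
  nrm <- sqrt(fit$loadings[, 1]^2 + fit$loadings[, 2]^2)
  got <- top_loading_genes(fit, 1, 2, radius = stats::median(nrm))
  expect_setequal(got$gene, names(nrm)[nrm > stats::median(nrm)])
  expect_false(is.unsorted(rev(got$norm)))
  expect_identical(nrow(top_loading_genes(fit, 1, 2, radius = 2)), 0L)
  expect_identical(nrow(top_loading_genes(fit, 1, 2, radius = 0)), 8L)
  expect_error(top_loading_genes(fit, 1, 2, radius = -1), "radius")
})

test_that("loading comparison detects identical and sign-flipped signatures", {
  set.seed(65)
  fit <- fit_pca(toy_matrix(6, 40, seed = 65))
  expect_equal(compare_loadings(fit, 1, fit, 1)$r, 1, tolerance = 1e-12)
  flipped <- fit
  flipped$loadings[, 1] <- -flipped$loadings[, 1]
  cmp <- compare_loadings(fit, 1, flipped, 1)
  expect_equal(cmp$r, -1, tolerance = 1e-12)
  expect_true(cmp$sign_flipped)
  # split halves of one cohort with a strong planted direction agree
  cs <- default_cluster_spec(shift = 3)[c("A", "F")]
  cs$A$proportion <- cs$F$proportion <- 0.5
  cfg <- cohort_config(n_tumor = 400L, n_normal = 0L,
                       n_background_genes = 0L, cluster_spec = cs,
                       seed = 66L)
  ch <- generate_cohort(cfg)
  expr <- subset_panel(ch$expression)
  f1 <- fit_pca(expr[, 1:200])
  f2 <- fit_pca(expr[, 201:400])
  expect_gt(abs(compare_loadings(f1, 1, f2, 1)$r), 0.9)
})

test_that("logistic association recovers construction and flags separation", {
  set.seed(67)
  n <- 300
  scores <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("PC", 1:8)))
  # outcome driven by PC1 with a margin: large positive coefficient
  y <- as.numeric(scores[, 1] > 0.3 | (scores[, 1] > -0.3 & runif(n) < 0.1))
  res <- logistic_association(scores, y)
  expect_gt(res$coef[res$component == "PC1"], 2)
  expect_lt(res$p[res$component == "PC1"], 1e-6)
  # null outcome: coefficients small, p roughly uniform
  y0 <- rbinom(2000, 1, 0.5)
  s0 <- matrix(rnorm(2000 * 8), 2000,
               dimnames = list(NULL, paste0("PC", 1:8)))
  r0 <- logistic_association(s0, y0)
  expect_true(all(abs(r0$coef) < 0.2))
  expect_gt(suppressWarnings(stats::ks.test(r0$p, "punif")$p.value), 0.001)
  expect_error(logistic_association(s0, rep(1, 2000)), "single class")
  # marginal mode returns one row per component
  rm <- logistic_association(scores, y, mode = "marginal")
  expect_identical(nrow(rm), 8L)
})

test_that("logistic MLE matches an independent Newton oracle", {
  set.seed(68)
  n <- 40
  X <- cbind(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, stats::plogis(0.5 + 0.8 * X[, 1] - 0.4 * X[, 2]))
  res <- logistic_association(X, y, components = 1:2)
  # Newton-Raphson on the log-likelihood, written from the formulas
  Xd <- cbind(1, X)
  beta <- rep(0, 3)
  for (it in 1:50) {
    eta <- drop(Xd %*% beta)
    mu <- 1 / (1 + exp(-eta))
    grad <- drop(crossprod(Xd, y - mu))
    H <- crossprod(Xd * (mu * (1 - mu)), Xd)
    beta <- beta + solve(H, grad)
  }
  expect_equal(unname(res$coef), unname(beta[2:3]), tolerance = 1e-6)
  se_oracle <- sqrt(diag(solve(H)))[2:3]
  expect_equal(unname(res$se), unname(se_oracle), tolerance = 1e-6)
})

test_that("Wilks' lambda matches a determinant oracle and null behavior", {
  set.seed(69)
  s1 <- matrix(rnorm(20, 0), 10, 2)
  s2 <- matrix(rnorm(16, 1), 8, 2)
  scores <- rbind(s1, s2)
  grp <- rep(c("a", "b"), c(10, 8))
  got <- manova_wilks(scores, grp)
  W <- crossprod(scale(s1, scale = FALSE)) +
    crossprod(scale(s2, scale = FALSE))
  Tt <- crossprod(scale(scores, scale = FALSE))
  expect_equal(got$lambda, det(W) / det(Tt), tolerance = 1e-10)
  expect_equal(got$df, 2)
  # identical group point sets: W = T, lambda = 1, chi2 = 0
  same <- rbind(s1, s1)
  g2 <- rep(c("a", "b"), each = 10)
  eq <- manova_wilks(same, g2)
  expect_equal(eq$lambda, 1, tolerance = 1e-12)
  expect_equal(eq$chi2, 0, tolerance = 1e-10)
  expect_error(manova_wilks(scores, rep("a", 18)), ">= 2 groups")
})
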