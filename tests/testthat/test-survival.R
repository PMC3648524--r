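test_that("Kaplan-Meier matches hand product-limit values", {
  # four events, no censoring
  km <- km_estimate(1:4, rep(1, 4))
  expect_equal(km$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(km$n_risk, c(4, 3, 2, 1))
  # censored case: S(1) = 2/3, S(3) = 0
  km <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km$time, c(1, 3))
  expect_equal(km$survival, c(2 / 3, 0))
  # all censored: survival stays at 1 (no event rows)
  expect_identical(nrow(km_estimate(c(2, 5, 7), c(0, 0, 0))), 0L)
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "negative")
  # no censoring: KM equals the empirical survival function
  set.seed(81)
  t <- round(rexp(40, 0.1), 3)
  km <- km_estimate(t, rep(1, 40))
  for (i in seq_len(nrow(km))) {
    expect_equal(km$survival[i], mean(t > km$time[i]), tolerance = 1e-12)
  }
})

test_that("log-rank matches a hand O/E/V tabulation and its square identity", {
  # identical event patterns in both groups: statistic 0
  lr <- logrank_test(c(1, 2, 3, 1, 2, 3), c(1, 1, 1, 1, 1, 1),
                     rep(c("a", "b"), each = 3))
  expect_equal(lr$chi2, 0, tolerance = 1e-12)
  # 6-subject toy case tabulated by hand: times/events/groups
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 1, 1, 0, 1)
  grp <- c("a", "b", "a", "b", "a", "b")
  lr <- logrank_test(time, event, grp)
  # hand tabulation of observed minus expected with hypergeometric variance
  oe <- 0
  v <- 0
  at_risk <- data.frame(time, event, grp)
  for (t in time[event == 1]) {
    risk <- at_risk[at_risk$time >= t, ]
    n <- nrow(risk)
    n_a <- sum(risk$grp == "a")
    d <- sum(at_risk$time == t & at_risk$event == 1)
    d_a <- sum(at_risk$time == t & at_risk$event == 1 & at_risk$grp == "a")
    oe <- oe + d_a - d * n_a / n
    if (n > 1) v <- v + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  expect_equal(lr$chi2, oe^2 / v, tolerance = 1e-10)
  expect_equal(lr$df, 1L)
  expect_error(logrank_test(time, event, rep("a", 6)), ">= 2 groups")
})

test_that("log-rank has power against a threefold hazard ratio", {
  set.seed(82)
  rej <- replicate(200, {
    t1 <- rexp(200, 0.01)
    t2 <- rexp(200, 0.03)
    cens <- runif(400, 0, 150)
    tt <- pmin(c(t1, t2), cens)
    ev <- as.numeric(c(t1, t2) <= cens)
    logrank_test(tt, ev, rep(c("a", "b"), each = 200))$p < 0.05
  })
  expect_gt(mean(rej), 0.95)
})

test_that("Cox coefficient matches a partial-likelihood grid oracle", {
  # 8 untied subjects, one covariate
  time <- c(2, 5, 7, 9, 12, 16, 20, 25)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1.2, -0.4, 0.6, 1.8, -1.1, 0.3, -0.7, -1.6)
  fit <- cox_fit(time, event, matrix(x, ncol = 1))
  # no ties, so the partial likelihood is a plain product over event times
  pl <- function(b) {
    ll <- 0
    for (i in which(event == 1)) {
      risk <- which(time >= time[i])
      ll <- ll + b * x[i] - log(sum(exp(b * x[risk])))
    }
    ll
  }
  grid <- seq(-3, 3, by = 1e-4)
  beta_grid <- grid[which.max(vapply(grid, pl, numeric(1)))]
  expect_equal(unname(fit$coefficients), beta_grid, tolerance = 1e-4)
  expect_equal(unname(fit$hazard_ratios), exp(unname(fit$coefficients)))
  expect_error(cox_fit(time, event, matrix(1, 8)), "constant")
})

test_that("Cox estimates are invariant to affine time rescaling", {
  set.seed(83)
  n <- 120
  x <- rnorm(n)
  t <- rexp(n, 0.02 * exp(0.6 * x))
  ev <- rbinom(n, 1, 0.7)
  f1 <- cox_fit(t, ev, matrix(x))
  f2 <- cox_fit(t * 12.5, ev, matrix(x))
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-8)
})

test_that("Cox recovers a planted log hazard ratio and holds its size", {
  set.seed(84)
  coefs <- replicate(200, {
    x <- rbinom(400, 1, 0.5)
    t <- rexp(400, 0.01 * exp(log(2) * x))
    cens <- runif(400, 0, 200)
    tt <- pmin(t, cens)
    ev <- as.numeric(t <= cens)
    unname(cox_fit(tt, ev, matrix(x))$coefficients)
  })
  expect_lt(abs(mean(coefs) - log(2)), 0.05)
  # null covariate: Wald test holds its nominal level
  set.seed(85)
  rej <- replicate(500, {
    x <- rnorm(500)
    t <- rexp(500, 0.02)
    ev <- rbinom(500, 1, 0.6)
    unname(cox_fit(t, ev, matrix(x))$wald_p) < 0.05
  })
  expect_lt(abs(mean(rej) - 0.05), 0.02)
})

test_that("median dichotomization splits at the median with logged counts", {
  d <- median_dichotomize(c(1, 2, 3))
  expect_identical(as.integer(d), c(0L, 0L, 1L))
  expect_equal(attr(d, "median"), 2)
  expect_warning(d0 <- median_dichotomize(rep(4, 5)), "all scores equal")
  expect_true(all(d0 == 0L))
  set.seed(86)
  v <- rnorm(101)
  d <- median_dichotomize(v)
  expect_identical(as.integer(sum(d == 1)), 50L)
})

test_that("dichotomized prognostic scores reach log-rank significance", {
  # hazard depends on the planted signature score in the generator
  hits <- vapply(1:8, function(s) {
    cfg <- cohort_config(n_tumor = 600L, n_normal = 0L,
                         n_background_genes = 0L, seed = 900L + s)
    ch <- generate_cohort(cfg)
    ann <- ch$annotation
    grp <- median_dichotomize(ch$truth$signature_score)
    logrank_test(ann$time, ann$event, grp)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 7 / 8)
})

test_that("the prognostic table reports univariate and multivariate columns", {
  set.seed(87)
  n <- 300
  x1 <- rbinom(n, 1, 0.4)
  x2 <- rnorm(n)
  t <- rexp(n, 0.02 * exp(0.8 * x1))
  ev <- rbinom(n, 1, 0.7)
  tab <- prognostic_table(t, ev, data.frame(risk = x1, noise = x2))
  expect_identical(tab$factor, c("risk", "noise"))
  expect_gt(tab$hr_uni[1], 1)
  expect_lt(tab$p_uni[1], 0.01)
  expect_gt(tab$p_uni[2], 0.01)
})
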