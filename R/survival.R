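#' Kaplan-Meier product-limit estimate
#'
#' @param time Nonnegative follow-up times (months).
#' @param event Event indicator, 1 = death, 0 = censored.
#' @return data.frame over distinct event times: \code{time},
#'   \code{n_risk}, \code{n_event}, \code{survival} (nonincreasing,
#'   starting from 1 before the first event).
#' @export
km_estimate <- function(time, event) {
  if (any(time < 0)) stop("negative follow-up time")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  keep <- fit$n.event > 0
  data.frame(time = fit$time[keep], n_risk = fit$n.risk[keep],
             n_event = fit$n.event[keep], survival = fit$surv[keep])
}

#' Log-rank test across survival groups
#'
#' Observed-minus-expected statistic with hypergeometric variance across
#' distinct event times; df = number of groups - 1.
#'
#' @param time,event As in [km_estimate()].
#' @param group Group label per subject, >= 2 levels.
#' @return List with \code{chi2}, \code{df}, \code{p}, and the per-group
#'   \code{observed} / \code{expected} event counts.
#' @export
logrank_test <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(group) < 2L) stop("need >= 2 groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1L
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
       observed = sd$obs, expected = sd$exp)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization by Newton-Raphson with Efron tie
#' handling by default; standard errors from the observed information,
#' Wald p-values. Constant covariates and nonconvergence are errors or
#' flagged, never silent.
#'
#' @param time,event As in [km_estimate()].
#' @param covariates samples x p numeric matrix or data.frame.
#' @param ties \code{"efron"} (default) or \code{"breslow"}.
#' @return List of class \code{"cox_fit"}: \code{coefficients},
#'   \code{hazard_ratios}, \code{se}, \code{wald_p}, \code{loglik},
#'   \code{ties}, \code{converged}, \code{n}, \code{n_event}.
#' @export
cox_fit <- function(time, event, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (sum(event) < 1L) stop("need at least one event")
  if (any(!is.finite(X))) stop("non-finite covariate values")
  const <- apply(X, 2L, function(x) length(unique(x)) == 1L)
  if (any(const)) {
    stop("constant covariates: ", paste(colnames(X)[const], collapse = ", "))
  }
  fit <- survival::coxph(survival::Surv(time, event) ~ X, ties = ties)
  converged <- is.null(fit$info) && all(is.finite(stats::coef(fit)))
  if (!converged || any(!is.finite(sqrt(diag(fit$var))))) {
    stop("Cox model failed to converge")
  }
  co <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  names(co) <- names(se) <- colnames(X)
  structure(list(coefficients = co, hazard_ratios = exp(co), se = se,
                 wald_p = 2 * stats::pnorm(-abs(co / se)),
                 loglik = fit$loglik[2L], ties = ties, converged = TRUE,
                 n = fit$n, n_event = fit$nevent),
            class = "cox_fit")
}

#' Median dichotomization of a score
#'
#' @param scores Numeric vector (nonempty).
#' @return Integer vector: 1 above the median, 0 at or below; the median
#'   and group sizes in attributes \code{"median"} and \code{"counts"}.
#'   All-equal input yields all 0 with a warning.
#' @export
median_dichotomize <- function(scores) {
  if (!length(scores)) stop("empty score vector")
  med <- stats::median(scores)
  out <- as.integer(scores > med)
  if (all(out == 0L) && length(unique(scores)) == 1L) {
    warning("all scores equal; every sample in the lower group")
  }
  attr(out, "median") <- med
  attr(out, "counts") <- table(factor(out, levels = c(0L, 1L)))
  out
}

#' Univariate and multivariate prognostic factor table
#'
#' For each factor: a single-covariate Cox fit (univariate hazard ratio and
#' p); then one Cox fit of all factors jointly (multivariate column).
#' Mirrors the usual clinical survival-analysis table layout.
#'
#' @param time,event As in [km_estimate()].
#' @param factors samples x p data.frame of numeric (possibly dichotomized)
#'   factors.
#' @param ties Passed to [cox_fit()].
#' @return data.frame per factor: \code{factor}, \code{hr_uni},
#'   \code{p_uni}, \code{hr_multi}, \code{p_multi}.
#' @export
prognostic_table <- function(time, event, factors, ties = "efron") {
  factors <- as.data.frame(factors)
  keep <- stats::complete.cases(factors) & !is.na(time) & !is.na(event)
  time <- time[keep]
  event <- event[keep]
  factors <- factors[keep, , drop = FALSE]
  uni <- lapply(colnames(factors), function(f) {
    fit <- cox_fit(time, event, factors[, f, drop = FALSE], ties = ties)
    c(hr = unname(fit$hazard_ratios[1L]), p = unname(fit$wald_p[1L]))
  })
  multi <- cox_fit(time, event, factors, ties = ties)
  data.frame(factor = colnames(factors),
             hr_uni = vapply(uni, `[[`, numeric(1), "hr"),
             p_uni = vapply(uni, `[[`, numeric(1), "p"),
             hr_multi = unname(multi$hazard_ratios),
             p_multi = unname(multi$wald_p),
             row.names = NULL, stringsAsFactors = FALSE)
}
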