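#' Fit class-conditional Gaussian densities for triple-negative calling
#'
#' One multivariate Gaussian is fit to ESR1/PGR/ERBB2 log2 expression of
#' IHC triple-negative samples and another to IHC receptor-positive
#' samples; unlabeled samples are later assigned by posterior probability
#' under the two densities. Maximum-likelihood estimates (covariance with
#' 1/n denominator); near-singular covariances are regularized by adding
#' eps*I with eps = 1e-6 times the mean diagonal.
#'
#' @param expr3 3 x n matrix of receptor-gene expression (rows ESR1, PGR,
#'   ERBB2), labeled samples only.
#' @param tn_labels Logical vector over columns: TRUE for IHC TN.
#' @param covariance \code{"full"} (default, trivariate with covariances) or
#'   \code{"diagonal"} (independent per-gene densities).
#' @return A \code{gaussian_status_model}: class means, covariances, and
#'   \code{prior_tn} = labeled TN fraction.
#' @export
fit_status_model <- function(expr3, tn_labels, covariance = c("full", "diagonal")) {
  covariance <- match.arg(covariance)
  stopifnot(is.matrix(expr3), nrow(expr3) == 3L,
            length(tn_labels) == ncol(expr3))
  if (any(!is.finite(expr3))) stop("non-finite receptor expression")
  tn_labels <- as.logical(tn_labels)
  fit_class <- function(x) {
    if (ncol(x) < 4L) stop("need >= 4 labeled samples per class")
    m <- rowMeans(x)
    xc <- x - m
    S <- tcrossprod(xc) / ncol(x)  # MLE, 1/n
    if (covariance == "diagonal") S <- diag(diag(S), nrow = 3L)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < 1e-10 * max(mean(diag(S)), .Machine$double.eps)) {
      eps <- 1e-6 * mean(diag(S))
      if (eps == 0) eps <- 1e-6  # fully degenerate class: identity scale
      S <- S + diag(eps, 3L)
    }
    list(mean = m, cov = S)
  }
  tn <- fit_class(expr3[, tn_labels, drop = FALSE])
  rp <- fit_class(expr3[, !tn_labels, drop = FALSE])
  structure(list(mean_tn = tn$mean, cov_tn = tn$cov,
                 mean_rp = rp$mean, cov_rp = rp$cov,
                 prior_tn = mean(tn_labels), covariance = covariance),
            class = "gaussian_status_model")
}

# log density of a multivariate normal, evaluated via Cholesky
.dmvnorm_log <- function(x, mean, sigma) {
  R <- chol(sigma)
  z <- backsolve(R, x - mean, transpose = TRUE)
  -0.5 * colSums(z^2) - sum(log(diag(R))) - 0.5 * nrow(sigma) * log(2 * pi)
}

#' Assign triple-negative status from receptor expression
#'
#' Posterior probability of TN under the two fitted class densities,
#' evaluated in log space: \eqn{p(TN|x) = \pi \phi_{TN}(x) /
#' (\pi \phi_{TN}(x) + (1-\pi) \phi_{RP}(x))}. A sample is called TN iff
#' its posterior exceeds 0.5; a posterior of exactly 0.5 is called RP
#' (conservative toward the treatable class).
#'
#' @param model A [fit_status_model()] fit.
#' @param expr3 3 x m matrix of receptor expression for samples to call.
#' @return data.frame with \code{sample_id}, \code{posterior_tn},
#'   \code{call} ("TN"/"RP").
#' @export
assign_tn_status <- function(model, expr3) {
  stopifnot(inherits(model, "gaussian_status_model"),
            is.matrix(expr3), nrow(expr3) == 3L)
  if (any(!is.finite(expr3))) stop("non-finite receptor expression")
  lt <- .dmvnorm_log(expr3, model$mean_tn, model$cov_tn) + log(model$prior_tn)
  lr <- .dmvnorm_log(expr3, model$mean_rp, model$cov_rp) +
    log(1 - model$prior_tn)
  m <- pmax(lt, lr)
  post <- exp(lt - m) / (exp(lt - m) + exp(lr - m))
  data.frame(
    sample_id = colnames(expr3) %||% as.character(seq_len(ncol(expr3))),
    posterior_tn = post,
    call = ifelse(post > 0.5, "TN", "RP"),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Cohort-level TN status calling combining IHC with the Gaussian model
#'
#' IHC dominates where informative: any IHC-positive receptor forces RP;
#' all three receptors IHC-negative gives TN. Samples with no decisive IHC
#' are called by [assign_tn_status()]. The model is trained on the
#' IHC-decided samples.
#'
#' @param expr genes x samples matrix containing ESR1, PGR, ERBB2 rows.
#' @param annotation Annotation table with ihc_er/ihc_pr/ihc_her2 columns.
#' @param covariance Passed to [fit_status_model()].
#' @return data.frame per sample: \code{tn_call}, \code{posterior_tn}
#'   (NA where IHC decided), \code{source} ("ihc" or "model"), plus the
#'   fitted model as attribute \code{"model"}.
#' @export
call_tn_status <- function(expr, annotation, covariance = "full") {
  rg <- receptor_genes()
  stopifnot(all(rg %in% rownames(expr)),
            all(annotation$sample_id %in% colnames(expr)))
  expr3 <- expr[rg, annotation$sample_id, drop = FALSE]
  ihc <- rbind(er = annotation$ihc_er, pr = annotation$ihc_pr,
               her2 = annotation$ihc_her2)
  any_pos <- apply(ihc, 2L, function(x) any(x == "pos", na.rm = TRUE))
  all_neg <- apply(ihc, 2L, function(x) all(x == "neg"))
  decided <- any_pos | all_neg
  model <- fit_status_model(expr3[, decided, drop = FALSE],
                            all_neg[decided], covariance = covariance)
  out <- data.frame(sample_id = annotation$sample_id,
                    tn_call = ifelse(all_neg, "TN", ifelse(any_pos, "RP", NA)),
                    posterior_tn = NA_real_,
                    source = ifelse(decided, "ihc", "model"),
                    stringsAsFactors = FALSE)
  if (any(!decided)) {
    mc <- assign_tn_status(model, expr3[, !decided, drop = FALSE])
    out$tn_call[!decided] <- mc$call
    out$posterior_tn[!decided] <- mc$posterior_tn
  }
  attr(out, "model") <- model
  out
}

#' Misclassification fraction of status calls against truth
#'
#' @param calls,truth Equal-length vectors (any comparable labels).
#' @return List with \code{error_rate}, \code{n}, \code{n_wrong} and the
#'   confusion \code{table}.
#' @export
status_error_rate <- function(calls, truth) {
  if (length(calls) != length(truth)) stop("length mismatch")
  wrong <- calls != truth
  list(error_rate = mean(wrong), n = length(calls),
       n_wrong = sum(wrong), table = table(call = calls, truth = truth))
}
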