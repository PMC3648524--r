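#' Principal component analysis of a gene panel
#'
#' PCA of samples over panel genes (genes centered; unit-variance scaling
#' optional and off by default). Loading signs follow a deterministic
#' convention — each component's largest-magnitude loading is positive — so
#' signatures are comparable across fits.
#'
#' @param expr_panel genes x samples matrix (>= 2 genes, >= 2 samples).
#' @param scale Scale genes to unit variance before PCA (default FALSE).
#' @param label_suffix Suffix appended to component labels, e.g. "a" for an
#'   all-tumor fit giving "PC1a".
#' @return List of class \code{"panel_pca"} with \code{gene_symbols},
#'   \code{center}, \code{scale}, \code{loadings} (genes x components,
#'   orthonormal), \code{explained_variance} (component variances,
#'   nonincreasing), \code{prop_variance}, \code{component_labels}, and
#'   \code{scores} (samples x components).
#' @export
fit_pca <- function(expr_panel, scale = FALSE, label_suffix = "") {
  validate_expression_matrix(expr_panel)
  if (nrow(expr_panel) < 2L || ncol(expr_panel) < 2L) {
    stop("need >= 2 genes and >= 2 samples")
  }
  if (scale) {
    v <- apply(expr_panel, 1L, stats::var)
    if (any(v == 0)) {
      stop("zero-variance gene with scaling on: ",
           paste(rownames(expr_panel)[v == 0], collapse = ", "))
    }
  }
  pc <- stats::prcomp(t(expr_panel), center = TRUE, scale. = scale)
  load <- pc$rotation
  scores <- pc$x
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  labels <- paste0("PC", seq_len(ncol(load)), label_suffix)
  colnames(load) <- labels
  colnames(scores) <- labels
  structure(list(
    gene_symbols = rownames(expr_panel),
    center = pc$center,
    scale = if (scale) pc$scale else NULL,
    loadings = load,
    explained_variance = unname(pc$sdev^2),
    prop_variance = unname(pc$sdev^2 / sum(pc$sdev^2)),
    component_labels = labels,
    scores = scores
  ), class = "panel_pca")
}

#' Project new samples onto a fitted PCA
#'
#' @param model A [fit_pca()] model.
#' @param expr_panel genes x samples matrix covering the model genes.
#' @return samples x components score matrix.
#' @export
pca_scores <- function(model, expr_panel) {
  stopifnot(inherits(model, "panel_pca"))
  x <- expr_panel[model$gene_symbols, , drop = FALSE]
  xc <- x - model$center
  if (!is.null(model$scale)) xc <- xc / model$scale
  t(xc) %*% model$loadings
}

#' Genes with large loadings on a 2-D component plane
#'
#' @param model A [fit_pca()] model.
#' @param comp_i,comp_j Component indices or labels.
#' @param radius Minimum 2-D loading norm (default 0.2).
#' @return data.frame of genes with \code{loading_i}, \code{loading_j},
#'   \code{norm}, sorted by norm descending.
#' @export
top_loading_genes <- function(model, comp_i = 1L, comp_j = 2L, radius = 0.2) {
  stopifnot(inherits(model, "panel_pca"))
  if (radius < 0) stop("radius must be >= 0")
  li <- model$loadings[, comp_i]
  lj <- model$loadings[, comp_j]
  nrm <- sqrt(li^2 + lj^2)
  keep <- which(nrm > radius)
  out <- data.frame(gene = model$gene_symbols[keep],
                    loading_i = unname(li[keep]),
                    loading_j = unname(lj[keep]),
                    norm = unname(nrm[keep]), stringsAsFactors = FALSE)
  out[order(-out$norm), , drop = FALSE]
}

#' Compare loading vectors between two PCA fits
#'
#' Pearson correlation of the two loading vectors over shared genes; a
#' negative correlation flags a sign-reversed version of the same
#' signature.
#'
#' @param model_a,model_b [fit_pca()] models.
#' @param comp_a,comp_b Component index or label in each model.
#' @return List with \code{r}, \code{sign_flipped}, \code{n_shared}.
#' @export
compare_loadings <- function(model_a, comp_a, model_b, comp_b) {
  shared <- intersect(model_a$gene_symbols, model_b$gene_symbols)
  if (length(shared) < 3L) stop("fewer than 3 shared genes")
  a <- model_a$loadings[match(shared, model_a$gene_symbols), comp_a]
  b <- model_b$loadings[match(shared, model_b$gene_symbols), comp_b]
  r <- stats::cor(a, b)
  list(r = r, sign_flipped = r < 0, n_shared = length(shared))
}

#' Logistic regression of a binary outcome on PCA scores
#'
#' Maximum-likelihood logistic fit (IRLS via \code{glm}) of the outcome on
#' the first \code{k} component scores jointly (or one at a time with
#' \code{mode = "marginal"}). Perfect or near-perfect separation is
#' reported, never silently returned.
#'
#' @param scores samples x components score matrix.
#' @param outcome Binary vector (0/1 or logical), both classes present.
#' @param components Which score columns to use (default first 8).
#' @param mode \code{"joint"} (one model, all components) or
#'   \code{"marginal"} (one single-covariate model per component).
#' @return data.frame per component: \code{component}, \code{coef},
#'   \code{se}, \code{z}, \code{p}; attributes \code{"converged"} and
#'   \code{"separation"}.
#' @export
logistic_association <- function(scores, outcome,
                                 components = seq_len(min(8L, ncol(scores))),
                                 mode = c("joint", "marginal")) {
  mode <- match.arg(mode)
  outcome <- as.numeric(outcome)
  stopifnot(nrow(scores) == length(outcome))
  if (length(unique(outcome[!is.na(outcome)])) < 2L) {
    stop("outcome has a single class")
  }
  X <- scores[, components, drop = FALSE]
  if (mode == "joint" && nrow(X) <= ncol(X) + 1L) {
    stop("need n > number of components + 1")
  }
  fit_one <- function(Xp) {
    df <- data.frame(y = outcome, Xp)
    wflag <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., data = df, family = stats::binomial(),
                 control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
      warning = function(w) {
        wflag <<- TRUE
        invokeRestart("muffleWarning")
      })
    mu <- stats::fitted(fit)
    sep <- wflag || any(mu < 1e-8 | mu > 1 - 1e-8)
    co <- summary(fit)$coefficients
    list(coef = co[-1L, , drop = FALSE], converged = fit$converged,
         separation = sep)
  }
  if (mode == "joint") {
    f <- fit_one(as.data.frame(X))
    co <- f$coef
    out <- data.frame(component = colnames(X), coef = co[, 1L],
                      se = co[, 2L], z = co[, 3L], p = co[, 4L],
                      row.names = NULL, stringsAsFactors = FALSE)
    attr(out, "converged") <- f$converged
    attr(out, "separation") <- f$separation
  } else {
    rows <- lapply(seq_len(ncol(X)), function(j) {
      f <- fit_one(X[, j, drop = FALSE])
      data.frame(component = colnames(X)[j], coef = f$coef[1L, 1L],
                 se = f$coef[1L, 2L], z = f$coef[1L, 3L],
                 p = f$coef[1L, 4L], converged = f$converged,
                 separation = f$separation, stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
  }
  out
}

#' Wilks' lambda MANOVA of 2-D scores across groups
#'
#' \eqn{\Lambda = det(W)/det(T)} with W and T the within-group and total
#' cross-product matrices; significance from Bartlett's chi-squared
#' approximation \eqn{-(n - 1 - (p+g)/2) \log\Lambda} on \eqn{p(g-1)}
#' degrees of freedom.
#'
#' @param scores samples x p score matrix (typically p = 2, a score plot).
#' @param groups Group label per sample; >= 2 groups with >= 3 samples
#'   each.
#' @return List with \code{lambda}, \code{chi2}, \code{df}, \code{p}.
#' @export
manova_wilks <- function(scores, groups) {
  scores <- as.matrix(scores)
  groups <- as.character(groups)
  stopifnot(nrow(scores) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L || any(sizes < 3L)) {
    stop("need >= 2 groups with >= 3 samples each")
  }
  n <- nrow(scores)
  p <- ncol(scores)
  g <- length(sizes)
  Tc <- scale(scores, center = TRUE, scale = FALSE)
  Tot <- crossprod(Tc)
  W <- matrix(0, p, p)
  for (cl in names(sizes)) {
    xc <- scale(scores[groups == cl, , drop = FALSE], center = TRUE,
                scale = FALSE)
    W <- W + crossprod(xc)
  }
  dT <- det(Tot)
  if (dT <= 0) stop("singular total cross-product matrix")
  lambda <- det(W) / dT
  chi2 <- -(n - 1 - (p + g) / 2) * log(lambda)
  df <- p * (g - 1)
  list(lambda = lambda, chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}
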