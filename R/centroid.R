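#' Fit a nearest-centroid subtype classifier
#'
#' Each class centroid is the per-gene mean (optionally median) of its
#' members' expression. Classes are stored in sorted order so the fit is
#' deterministic under relabeling.
#'
#' @param expr genes x samples matrix.
#' @param labels Class label per sample (column).
#' @param statistic \code{"mean"} (default) or \code{"median"}.
#' @param correlation_threshold Minimum Spearman correlation for a call;
#'   below it a sample is unclassified. The conventional cutoff is 0.1.
#' @return A \code{centroid_model}: genes, class names, genes x classes
#'   centroid matrix, threshold.
#' @export
fit_centroids <- function(expr, labels, statistic = c("mean", "median"),
                          correlation_threshold = 0.1) {
  statistic <- match.arg(statistic)
  stopifnot(is.matrix(expr), ncol(expr) == length(labels),
            correlation_threshold >= -1, correlation_threshold <= 1)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  sizes <- table(labels)
  if (any(sizes < 2L)) {
    stop("classes with < 2 samples: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  fun <- if (statistic == "mean") rowMeans else
    function(x) apply(x, 1L, stats::median)
  cent <- vapply(classes, function(cl) fun(expr[, labels == cl, drop = FALSE]),
                 numeric(nrow(expr)))
  structure(list(gene_symbols = rownames(expr), class_names = classes,
                 centroids = cent, statistic = statistic,
                 correlation_threshold = correlation_threshold),
            class = "centroid_model")
}

#' Classify samples by Spearman correlation to class centroids
#'
#' Each sample's expression over the model genes is rank-correlated
#' (average ranks on ties) with every class centroid; the highest
#' correlation wins unless all correlations fall below the model threshold,
#' in which case the sample is unclassified (NA label). Model genes missing
#' from \code{expr} are dropped pairwise with a warning; at least 3
#' overlapping genes are required. Exact correlation ties go to the first
#' class in sorted class order.
#'
#' @param model A [fit_centroids()] model.
#' @param expr genes x samples matrix.
#' @return data.frame with \code{sample_id}, \code{label} (NA =
#'   unclassified), \code{max_correlation}; all per-class correlations in
#'   attribute \code{"correlations"} (samples x classes).
#' @export
classify_centroid <- function(model, expr) {
  stopifnot(inherits(model, "centroid_model"), is.matrix(expr))
  shared <- intersect(model$gene_symbols, rownames(expr))
  if (length(shared) < 3L) {
    stop("fewer than 3 model genes present in expression matrix")
  }
  if (length(shared) < length(model$gene_symbols)) {
    warning(sprintf("%d model genes absent; classifying on %d shared genes",
                    length(model$gene_symbols) - length(shared),
                    length(shared)))
  }
  cent <- model$centroids[match(shared, model$gene_symbols), , drop = FALSE]
  x <- expr[shared, , drop = FALSE]
  cors <- stats::cor(x, cent, method = "spearman")  # samples x classes
  best <- apply(cors, 1L, which.max)                # first index on ties
  maxc <- cors[cbind(seq_len(nrow(cors)), best)]
  label <- model$class_names[best]
  label[maxc < model$correlation_threshold] <- NA_character_
  out <- data.frame(sample_id = colnames(expr) %||%
                      as.character(seq_len(ncol(expr))),
                    label = label, max_correlation = maxc,
                    stringsAsFactors = FALSE)
  attr(out, "correlations") <- cors
  out
}

#' Leave-one-out cross-validation of the centroid classifier
#'
#' Each sample is classified by a model fit to all other samples
#' (\code{refit = TRUE}, statistically correct) or by the full-data model
#' (\code{refit = FALSE}, resubstitution-style). Unclassified samples count
#' as incorrect.
#'
#' @param expr genes x samples matrix.
#' @param labels True class per sample; every class needs >= 3 samples.
#' @param refit Refit centroids per fold (default TRUE).
#' @param ... Passed to [fit_centroids()].
#' @return List with \code{accuracy}, \code{n_correct}, \code{n},
#'   \code{predicted} labels and the \code{confusion} table.
#' @export
loocv_centroid <- function(expr, labels, refit = TRUE, ...) {
  labels <- as.character(labels)
  stopifnot(ncol(expr) == length(labels))
  if (any(table(labels) < 3L)) stop("LOOCV needs >= 3 samples per class")
  n <- ncol(expr)
  pred <- character(n)
  full <- if (!refit) fit_centroids(expr, labels, ...) else NULL
  for (i in seq_len(n)) {
    model <- if (refit) {
      fit_centroids(expr[, -i, drop = FALSE], labels[-i], ...)
    } else full
    pred[i] <- classify_centroid(model, expr[, i, drop = FALSE])$label
  }
  correct <- !is.na(pred) & pred == labels
  list(accuracy = mean(correct), n_correct = sum(correct), n = n,
       predicted = pred,
       confusion = table(truth = labels,
                         predicted = factor(pred, exclude = NULL)))
}
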