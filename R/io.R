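#' Validate a genes x samples expression matrix
#'
#' The pipeline's universal container is a plain numeric matrix of log2
#' expression values with unique gene symbols as rownames and unique sample
#' ids as colnames. This checks those invariants.
#'
#' @param expr Numeric matrix.
#' @return The matrix, invisibly, if valid; otherwise an error.
#' @export
validate_expression_matrix <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) {
    stop("expression must be a numeric matrix")
  }
  if (is.null(rownames(expr)) || is.null(colnames(expr))) {
    stop("expression matrix must have gene rownames and sample colnames")
  }
  dup <- unique(rownames(expr)[duplicated(rownames(expr))])
  if (length(dup)) {
    stop("duplicated gene ids: ", paste(dup, collapse = ", "))
  }
  dup <- unique(colnames(expr)[duplicated(colnames(expr))])
  if (length(dup)) {
    stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  }
  if (any(!is.finite(expr))) {
    bad <- which(!is.finite(expr), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite expression value at gene '%s', sample '%s'",
                 rownames(expr)[bad[1L]], colnames(expr)[bad[2L]]))
  }
  invisible(expr)
}

#' Read a tab-separated expression matrix
#'
#' Expects a TSV with the identifier in the first column and one header row
#' of sample ids. Values must be numeric, finite and free of duplicate ids.
#'
#' @param path File path.
#' @param genes_in_rows If FALSE, the file is samples x genes and is
#'   transposed on read.
#' @return genes x samples numeric matrix.
#' @export
read_expression <- function(path, genes_in_rows = TRUE) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs an id column plus data")
  ids <- as.character(tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated row ids in ", path, ": ", paste(dup, collapse = ", "))
  }
  vals <- tab[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      if (any(is.na(vn) & !is.na(v))) {
        i <- which(is.na(vn) & !is.na(v))[1L]
        stop(sprintf("non-numeric cell at row '%s', column '%s': %s",
                     ids[i], colnames(vals)[j], v[i]))
      }
      vals[[j]] <- vn
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (!genes_in_rows) m <- t(m)
  validate_expression_matrix(m)
  message(sprintf("read expression matrix: %d genes x %d samples from %s",
                  nrow(m), ncol(m), path))
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr genes x samples matrix.
#' @param path Output path.
#' @param id_column Header for the identifier column.
#' @return The path, invisibly.
#' @export
write_expression <- function(expr, path, id_column = "gene") {
  validate_expression_matrix(expr)
  df <- data.frame(rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- id_column
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample annotation table
#'
#' Annotation tables are TSVs keyed by \code{sample_id}, carrying IHC
#' receptor status (\code{pos}/\code{neg}/\code{unknown}), triple-negative
#' status, clinical covariates and survival columns (\code{time} in months,
#' \code{event} 0/1).
#'
#' @param path File path.
#' @return data.frame with unique \code{sample_id}.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% colnames(ann)) {
    stop("annotation table must have a sample_id column")
  }
  dup <- unique(ann$sample_id[duplicated(ann$sample_id)])
  if (length(dup)) {
    stop("duplicated sample ids: ", paste(dup, collapse = ", "))
  }
  if ("event" %in% colnames(ann)) {
    ev <- ann$event[!is.na(ann$event)]
    if (length(ev) && !all(ev %in% c(0, 1))) stop("event must be 0/1")
  }
  ann
}

#' @rdname read_annotation
#' @param ann Annotation data.frame.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to one row per gene by maximal variance
#'
#' When several probe sets measure one gene, the probe with the highest
#' sample variance (n-1 denominator, across all samples jointly) represents
#' the gene; exact ties keep the first probe in input order. The chosen
#' probe per gene is recorded in the \code{"probe_provenance"} attribute.
#'
#' @param expr probes x samples matrix with probe ids as rownames.
#' @param probe_map data.frame with columns \code{probe_id},
#'   \code{gene_symbol}; every probe in \code{expr} must be mapped.
#' @return genes x samples matrix; each row is bit-identical to one input
#'   probe row.
#' @export
collapse_probes <- function(expr, probe_map) {
  validate_expression_matrix(expr)
  stopifnot(all(c("probe_id", "gene_symbol") %in% colnames(probe_map)))
  if (anyDuplicated(probe_map$probe_id)) {
    stop("probe map assigns some probe more than one gene")
  }
  unmapped <- setdiff(rownames(expr), probe_map$probe_id)
  if (length(unmapped)) {
    stop("unmapped probes: ", paste(unmapped, collapse = ", "))
  }
  gene_of <- probe_map$gene_symbol[match(rownames(expr), probe_map$probe_id)]
  v <- apply(expr, 1L, stats::var)
  keep <- integer(0)
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    keep <- c(keep, idx[which.max(v[idx])])  # which.max: first index on ties
  }
  out <- expr[keep, , drop = FALSE]
  rownames(out) <- gene_of[keep]
  attr(out, "probe_provenance") <- data.frame(
    gene_symbol = gene_of[keep],
    probe_id = rownames(expr)[keep],
    variance = unname(v[keep]),
    stringsAsFactors = FALSE
  )
  validate_expression_matrix(out)
  out
}
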