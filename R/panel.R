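#' The 31-gene VEGF/semaphorin panel
#'
#' Registry of the angiogenesis-related gene panel the pipeline analyses:
#' the five VEGF ligands, their three receptor tyrosine kinases, the two
#' neuropilin co-receptors, the secreted class-3 semaphorins, the
#' membrane-bound class 4-7 semaphorins, and the plexin receptors.
#'
#' @param name Panel name; currently only \code{"vegf_sema"}.
#' @return A data.frame with columns \code{gene} (HGNC symbol), \code{family}
#'   (\code{vegf}, \code{vegfr}, \code{nrp}, \code{sema3}, \code{sema4_7},
#'   \code{plexin}), \code{role} (\code{ligand} or \code{receptor}) and
#'   \code{alias} (legacy array symbol where one exists).
#' @export
gene_panel <- function(name = "vegf_sema") {
  if (!identical(name, "vegf_sema")) {
    stop("unknown panel: ", name)
  }
  p <- rbind(
    data.frame(gene = c("VEGFA", "VEGFB", "VEGFC", "VEGFD", "PGF"),
               family = "vegf", role = "ligand"),
    data.frame(gene = c("FLT1", "KDR", "FLT4"),
               family = "vegfr", role = "receptor"),
    data.frame(gene = c("NRP1", "NRP2"),
               family = "nrp", role = "receptor"),
    data.frame(gene = c("SEMA3A", "SEMA3B", "SEMA3C", "SEMA3E", "SEMA3F",
                        "SEMA3G"),
               family = "sema3", role = "ligand"),
    data.frame(gene = c("SEMA4D", "SEMA4F", "SEMA4G", "SEMA5A", "SEMA5B",
                        "SEMA6A", "SEMA6B", "SEMA7A"),
               family = "sema4_7", role = "ligand"),
    data.frame(gene = c("PLXNA1", "PLXNA3", "PLXNB1", "PLXNB2", "PLXNB3",
                        "PLXNC1", "PLXND1"),
               family = "plexin", role = "receptor")
  )
  p$alias <- ifelse(p$gene == "VEGFD", "FIGF", NA_character_)
  stopifnot(nrow(p) == 31L, !anyDuplicated(p$gene))
  p
}

#' Receptor genes used for triple-negative status calling
#'
#' @return Character vector \code{c("ESR1", "PGR", "ERBB2")} (estrogen
#'   receptor, progesterone receptor, HER2).
#' @export
receptor_genes <- function() c("ESR1", "PGR", "ERBB2")

#' Restrict an expression matrix to a gene panel
#'
#' Rows are returned in panel order. Panel genes absent from the matrix are
#' dropped with a warning listing them.
#'
#' @param expr genes x samples numeric matrix (see [read_expression()]).
#' @param panel Character vector of gene symbols, or a panel data.frame with
#'   a \code{gene} column as returned by [gene_panel()].
#' @return The row-subset expression matrix, in panel order.
#' @export
subset_panel <- function(expr, panel = gene_panel()) {
  if (is.data.frame(panel)) panel <- panel$gene
  stopifnot(is.character(panel), length(panel) > 0L, !anyDuplicated(panel))
  present <- panel %in% rownames(expr)
  if (!any(present)) {
    stop("none of the panel genes are present in the expression matrix")
  }
  if (any(!present)) {
    warning("panel genes absent from expression matrix: ",
            paste(panel[!present], collapse = ", "))
  }
  expr[panel[present], , drop = FALSE]
}
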