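#' Pipeline configuration
#'
#' One validated object drives the whole analysis: either a simulation
#' config or paths to expression/annotation TSVs, plus per-stage
#' parameters and a single seed from which every stage's seed is derived
#' deterministically (stage seed = (seed * 31 + stage index) mod 2^31-1),
#' so stages can be rerun in isolation.
#'
#' @param simulate Simulate the cohort (default TRUE).
#' @param sim_config A [cohort_config()]; its seed is overridden by the
#'   derived stage seed.
#' @param expression_path,annotation_path Input TSVs when
#'   \code{simulate = FALSE}.
#' @param stages Character vector of stages to run, in dependency order.
#' @param de_conf Confidence level for differential-expression intervals.
#' @param de_alpha Significance threshold for direction calls.
#' @param k_min,k_max Consensus-clustering K range.
#' @param consensus_iterations,subsample_fraction,restarts Consensus /
#'   K-means parameters.
#' @param correlation_threshold Centroid-classifier unclassified cutoff.
#' @param seed Global integer seed.
#' @return Validated list of class \code{"pipeline_config"}.
#' @export
pipeline_config <- function(simulate = TRUE,
                            sim_config = cohort_config(),
                            expression_path = NULL,
                            annotation_path = NULL,
                            stages = c("simulate", "status", "subtype",
                                       "diffexp", "pca", "cluster",
                                       "survival"),
                            de_conf = 0.99,
                            de_alpha = 0.001,
                            k_min = 2L,
                            k_max = 9L,
                            consensus_iterations = 100L,
                            subsample_fraction = 0.8,
                            restarts = 50L,
                            correlation_threshold = 0.1,
                            seed = 1L) {
  cfg <- list(simulate = simulate, sim_config = sim_config,
              expression_path = expression_path,
              annotation_path = annotation_path, stages = stages,
              de_conf = de_conf, de_alpha = de_alpha,
              k_min = as.integer(k_min), k_max = as.integer(k_max),
              consensus_iterations = as.integer(consensus_iterations),
              subsample_fraction = subsample_fraction,
              restarts = as.integer(restarts),
              correlation_threshold = correlation_threshold,
              seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  validate_pipeline_config(cfg)
  cfg
}

validate_pipeline_config <- function(cfg) {
  if (cfg$k_max < cfg$k_min) stop("k_max < k_min")
  if (cfg$k_max - cfg$k_min < 2L) stop("k range must span >= 3 values")
  if (cfg$de_conf <= 0 || cfg$de_conf >= 1) stop("de_conf outside (0,1)")
  if (cfg$subsample_fraction <= 0 || cfg$subsample_fraction > 1) {
    stop("subsample_fraction outside (0,1]")
  }
  if (cfg$consensus_iterations < 1L || cfg$restarts < 1L) {
    stop("iterations and restarts must be >= 1")
  }
  if (!cfg$simulate &&
      (is.null(cfg$expression_path) || is.null(cfg$annotation_path))) {
    stop("need expression_path and annotation_path when simulate = FALSE")
  }
  if (cfg$simulate) validate_cohort_config(cfg$sim_config)
  invisible(cfg)
}

stage_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 31 + stage_index) %% (2^31 - 1))
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(cfg[order(names(unclass(cfg)))]), collapse = ""), f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Sequences the analysis end-to-end: cohort (simulated or read from TSV)
#' -> TN status calling -> centroid subtype LOOCV -> tumor-vs-normal
#' differential expression -> panel PCA with clinical association ->
#' consensus K-means with CDF-area K selection -> survival analysis
#' (log-rank by TN status; multivariate Cox on clinical factors and
#' median-dichotomized PC scores). Every output table is written under
#' \code{output_dir} and recorded in a JSON manifest with the config hash
#' and seed; identical configs reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param output_dir Output directory (created if missing).
#' @return Invisible list with the in-memory stage results and the
#'   \code{manifest}.
#' @export
run_pipeline <- function(config, output_dir = tempfile("vegfsema_")) {
  validate_pipeline_config(config)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = list())
  outputs <- list()
  log_stage <- function(stage, files, params = list()) {
    manifest$stages[[stage]] <<- list(
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      files = files, params = params)
    message(sprintf("[%s] wrote %s", stage, paste(files, collapse = ", ")))
  }
  path <- function(f) file.path(output_dir, f)
  run <- function(stage, fun) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      jsonlite::write_json(manifest, path("manifest.json"),
                           auto_unbox = TRUE, pretty = TRUE)
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
  }

  ## cohort
  run("simulate", function() {
    if (config$simulate) {
      sim_cfg <- config$sim_config
      sim_cfg$seed <- stage_seed(config$seed, 1L)
      cohort <- generate_cohort(sim_cfg)
      write_expression(cohort$expression, path("expression.tsv"))
      write_annotation(cohort$annotation, path("annotation.tsv"))
      jsonlite::write_json(
        list(cluster = as.list(cohort$truth$cluster),
             tn_true = as.list(cohort$truth$tn_true),
             coefficients = cohort$truth$coefficients,
             seed = cohort$truth$seed),
        path("truth.json"), auto_unbox = TRUE)
      outputs$cohort <<- cohort
      log_stage("simulate",
                c("expression.tsv", "annotation.tsv", "truth.json"),
                list(seed = sim_cfg$seed, n_tumor = sim_cfg$n_tumor))
    } else {
      outputs$cohort <<- list(
        expression = read_expression(config$expression_path),
        annotation = read_annotation(config$annotation_path),
        truth = NULL)
      log_stage("simulate", character(0),
                list(expression = config$expression_path))
    }
  })
  cohort <- outputs$cohort
  ann <- cohort$annotation
  tumors <- ann$sample_id[ann$group == "tumor"]
  normals <- ann$sample_id[ann$group == "normal"]
  panel_expr <- subset_panel(cohort$expression, gene_panel())

  ## TN status
  run("status", function() {
    calls <- call_tn_status(cohort$expression, ann[ann$group == "tumor", ])
    utils::write.table(calls, path("tn_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs$status <<- calls
    log_stage("status", "tn_calls.tsv")
  })

  ## centroid subtype LOOCV on planted clusters
  run("subtype", function() {
    if (is.null(cohort$truth)) {
      message("[subtype] no truth labels available; skipping LOOCV")
      outputs$subtype <<- NULL
      return(invisible(NULL))
    }
    labels <- cohort$truth$cluster[tumors]
    cv <- loocv_centroid(panel_expr[, tumors, drop = FALSE], labels,
                         correlation_threshold = config$correlation_threshold)
    df <- data.frame(sample_id = tumors, truth = labels,
                     predicted = cv$predicted, stringsAsFactors = FALSE)
    utils::write.table(df, path("subtype_loocv.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs$subtype <<- cv
    log_stage("subtype", "subtype_loocv.tsv",
              list(accuracy = cv$accuracy))
  })

  ## tumor vs normal differential expression
  run("diffexp", function() {
    if (!length(normals)) {
      message("[diffexp] no normal samples; skipping")
      return(invisible(NULL))
    }
    de <- diff_expression(panel_expr, tumors, normals,
                          conf = config$de_conf, alpha = config$de_alpha)
    de <- merge(de, gene_panel()[, c("gene", "role")], by = "gene",
                sort = FALSE)
    utils::write.table(de, path("diffexp.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    outputs$diffexp <<- de
    log_stage("diffexp", "diffexp.tsv",
              list(conf = config$de_conf, alpha = config$de_alpha))
  })

  ## PCA + clinical association
  run("pca", function() {
    pca <- fit_pca(panel_expr[, tumors, drop = FALSE], label_suffix = "a")
    tn_call <- if (!is.null(outputs$status)) {
      outputs$status$tn_call == "TN"
    } else {
      ann$tn_status[match(tumors, ann$sample_id)] == "TN"
    }
    assoc <- logistic_association(pca$scores, as.numeric(tn_call))
    wilks <- manova_wilks(pca$scores[, c(1L, 2L)],
                          ifelse(tn_call, "TN", "RP"))
    utils::write.table(
      data.frame(gene = rownames(pca$loadings), pca$loadings,
                 check.names = FALSE),
      path("pca_loadings.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = rownames(pca$scores), pca$scores,
                 check.names = FALSE),
      path("pca_scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(assoc, path("pca_tn_association.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs$pca <<- list(model = pca, association = assoc, wilks = wilks)
    log_stage("pca", c("pca_loadings.tsv", "pca_scores.tsv",
                       "pca_tn_association.tsv"),
              list(wilks_p = wilks$p))
  })

  ## consensus clustering
  run("cluster", function() {
    X <- t(panel_expr[, tumors, drop = FALSE])
    ks <- seq(config$k_min, config$k_max)
    results <- lapply(ks, function(k) {
      consensus_cluster(X, k, iterations = config$consensus_iterations,
                        subsample_fraction = config$subsample_fraction,
                        restarts = config$restarts,
                        seed = stage_seed(config$seed, 100L + k))
    })
    sel <- select_k(results)
    chosen <- results[[match(sel$chosen_k, ks)]]
    utils::write.table(
      data.frame(k = sel$k_range, cdf_area = sel$cdf_areas,
                 relative_change = sel$relative_area_changes),
      path("consensus_k_selection.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = names(chosen$labels),
                 cluster = unname(chosen$labels)),
      path("consensus_labels.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    write_expression(chosen$consensus, path("consensus_matrix.tsv"),
                     id_column = "sample_id")
    outputs$cluster <<- list(results = results, selection = sel,
                             chosen = chosen)
    log_stage("cluster", c("consensus_k_selection.tsv",
                           "consensus_labels.tsv", "consensus_matrix.tsv"),
              list(chosen_k = sel$chosen_k))
  })

  ## survival
  run("survival", function() {
    tann <- ann[ann$group == "tumor" & !is.na(ann$time), ]
    if (!nrow(tann)) {
      message("[survival] no survival data; skipping")
      return(invisible(NULL))
    }
    tn <- if (!is.null(outputs$status)) {
      outputs$status$tn_call[match(tann$sample_id, outputs$status$sample_id)]
    } else tann$tn_status
    lr <- logrank_test(tann$time, tann$event, tn)
    factors <- data.frame(
      tn = as.numeric(tn == "TN"),
      grade3 = as.numeric(tann$grade == 3),
      stage3 = as.numeric(tann$stage == 3),
      age_gt50 = as.numeric(tann$age > 50),
      node = tann$node)
    if (!is.null(outputs$pca)) {
      sc <- outputs$pca$model$scores
      sc <- sc[match(tann$sample_id, rownames(sc)), , drop = FALSE]
      for (j in seq_len(min(6L, ncol(sc)))) {
        factors[[paste0("pc", j, "a_gt_median")]] <-
          median_dichotomize(sc[, j])
      }
    }
    tab <- prognostic_table(tann$time, tann$event, factors)
    utils::write.table(tab, path("survival_table.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    km <- km_estimate(tann$time, tann$event)
    utils::write.table(km, path("km_overall.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    outputs$survival <<- list(logrank_tn = lr, table = tab, km = km)
    log_stage("survival", c("survival_table.tsv", "km_overall.tsv"),
              list(logrank_tn_p = lr$p))
  })

  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(c(outputs, list(manifest = manifest, output_dir = output_dir)))
}

#' Cross-tabulate two label vectors with conditional percentages
#'
#' @param labels_a,labels_b Equal-length label vectors over the same
#'   samples.
#' @return List with \code{counts} (table), \code{row_pct} (percent of each
#'   row's total) and \code{col_pct}.
#' @export
crosstab <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b)) stop("mismatched sample sets")
  counts <- table(a = labels_a, b = labels_b)
  list(counts = counts,
       row_pct = 100 * prop.table(counts, margin = 1L),
       col_pct = 100 * prop.table(counts, margin = 2L))
}
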