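#' Default cluster templates for the synthetic cohort
#'
#' Seven tumor clusters (A-G) with log2 mean-shift patterns over the 31-gene
#' panel that qualitatively mirror the expression contrasts the consensus
#' clusters of breast-tumor cohorts show: A/B high VEGFA with low secreted
#' class-3 semaphorins (A additionally high FLT1/FLT4/SEMA3A, B high
#' VEGFC/KDR/NRP1), C high FLT1/FLT4/SEMA3A with low VEGFA, D high
#' VEGFC/KDR/NRP1/SEMA5A, E a mild plexin-B pattern, F/G high class-3
#' semaphorins with low VEGFA. Each cluster also carries the fraction of its
#' members that are truly triple-negative.
#'
#' @param shift Magnitude of each nonzero mean shift, log2 units.
#' @return Named list of clusters, each with \code{proportion},
#'   \code{tn_prop} and a named \code{shift} vector over the panel genes.
#' @export
default_cluster_spec <- function(shift = 2) {
  genes <- gene_panel()$gene
  zero <- stats::setNames(numeric(length(genes)), genes)
  mk <- function(up = character(0), down = character(0)) {
    s <- zero
    s[up] <- shift
    s[down] <- -shift
    s
  }
  list(
    A = list(proportion = 0.130, tn_prop = 0.78, shift = mk(
      up = c("VEGFA", "SEMA4D", "NRP2", "PLXNA1", "FLT1", "FLT4", "SEMA3A"),
      down = c("SEMA3B", "SEMA3C", "SEMA3F", "SEMA3G", "VEGFC", "KDR", "NRP1"))),
    B = list(proportion = 0.160, tn_prop = 0.66, shift = mk(
      up = c("VEGFA", "SEMA4D", "NRP2", "PLXNA1", "VEGFC", "KDR", "NRP1"),
      down = c("SEMA3B", "SEMA3C", "SEMA3F", "SEMA3G"))),
    C = list(proportion = 0.100, tn_prop = 0.43, shift = mk(
      up = c("FLT1", "FLT4", "SEMA3A", "SEMA6B", "SEMA7A"),
      down = c("VEGFA", "VEGFC", "KDR", "NRP1", "SEMA3C", "PLXNA1", "PLXND1"))),
    D = list(proportion = 0.185, tn_prop = 0.16, shift = mk(
      up = c("VEGFC", "KDR", "NRP1", "SEMA5A", "PLXNC1"),
      down = c("VEGFA"))),
    E = list(proportion = 0.125, tn_prop = 0.25, shift = mk(
      up = c("PLXNB1", "PLXNB2"),
      down = c("SEMA4D"))),
    F = list(proportion = 0.160, tn_prop = 0.08, shift = mk(
      up = c("SEMA3B", "SEMA3E", "SEMA3F", "SEMA3G"),
      down = c("VEGFA", "SEMA4D"))),
    G = list(proportion = 0.140, tn_prop = 0.05, shift = mk(
      up = c("SEMA3B", "SEMA3C", "SEMA3E", "SEMA3F"),
      down = c("VEGFA", "PLXNA1")))
  )
}

#' Default tumor-vs-normal mean shift over the panel
#'
#' Log2 mean difference applied to every tumor (on top of its cluster
#' shift) relative to normal tissue. Signs follow the qualitative
#' tumor-vs-normal pattern of breast cohorts: VEGF ligands up except PGF,
#' secreted class-3 semaphorins down, most receptors modestly up with
#' FLT4 and PLXNA1 down and KDR unchanged. Magnitudes (0.7 for ligands,
#' 0.38 for receptors) put the panel-wide mean absolute differences near
#' 0.58 and 0.32 respectively, the effect sizes reported for pooled
#' breast-tumor compilations.
#'
#' @return Named numeric vector over the 31 panel genes.
#' @export
default_tumor_shift <- function() {
  p <- gene_panel()
  s <- stats::setNames(numeric(nrow(p)), p$gene)
  up_lig <- c("VEGFA", "VEGFB", "VEGFC", "VEGFD",
              "SEMA4D", "SEMA4F", "SEMA5B", "SEMA6B", "SEMA7A")
  down_lig <- c("PGF", "SEMA3A", "SEMA3B", "SEMA3C", "SEMA3E", "SEMA3F",
                "SEMA3G")
  up_rec <- c("FLT1", "NRP1", "NRP2", "PLXNA3", "PLXNB1", "PLXNB2",
              "PLXNC1", "PLXND1")
  down_rec <- c("FLT4", "PLXNA1")
  s[up_lig] <- 0.7
  s[down_lig] <- -0.7
  s[up_rec] <- 0.38
  s[down_rec] <- -0.38
  s  # KDR, SEMA4G, SEMA5A, SEMA6A, PLXNB3 unchanged
}

#' Build a simulation configuration
#'
#' Defaults describe the cohort structure the pipeline assumes: seven
#' planted expression clusters over the 31-gene panel, bimodal
#' ESR1/PGR/ERBB2 receptor expression (two-component Gaussian mixtures 4 sd
#' apart), iid Gaussian log2 noise, imperfect and partially missing IHC
#' labels, and exponential proportional-hazards survival whose log hazard
#' depends on a planted pro-angiogenic signature score, triple-negative
#' status, stage and nodal status.
#'
#' @param n_tumor,n_normal Sample counts.
#' @param n_background_genes Number of iid noise genes appended so probe
#'   collapsing / gene ordering operate at realistic sizes.
#' @param cluster_spec As from [default_cluster_spec()]; proportions must
#'   sum to 1.
#' @param receptor_spec Named list over ESR1/PGR/ERBB2, each with
#'   \code{mu_neg}, \code{mu_pos}, \code{sigma_neg}, \code{sigma_pos},
#'   \code{p_pos} (marginal probability of the positive component among
#'   receptor-positive tumors).
#' @param tumor_shift Named log2 mean shift over the panel applied to all
#'   tumors relative to normals (see [default_tumor_shift()]).
#' @param baseline_mean Baseline log2 expression of panel and background
#'   genes.
#' @param noise_sd Residual log2 sd around each gene's mean.
#' @param ihc_missing_rate,ihc_error_rate Per-receptor probabilities that an
#'   IHC label is missing, or flipped relative to the true component.
#' @param survival_spec List with \code{baseline_rate} (events/month),
#'   \code{beta_score} (per SD of the planted signature score),
#'   \code{beta_tn}, \code{beta_stage} (per stage step), \code{beta_node},
#'   and \code{censoring_rate} (fraction administratively censored).
#' @param seed Integer seed; fixed seed implies fully reproducible output.
#' @return A validated list of class \code{"cohort_config"}.
#' @export
cohort_config <- function(n_tumor = 800L,
                          n_normal = 40L,
                          n_background_genes = 500L,
                          cluster_spec = default_cluster_spec(),
                          tumor_shift = default_tumor_shift(),
                          receptor_spec = list(
                            ESR1  = list(mu_neg = 7.5, mu_pos = 10.5,
                                         sigma_neg = 0.75, sigma_pos = 0.75,
                                         p_pos = 0.85),
                            PGR   = list(mu_neg = 6.5, mu_pos = 9.5,
                                         sigma_neg = 0.75, sigma_pos = 0.75,
                                         p_pos = 0.75),
                            ERBB2 = list(mu_neg = 9.0, mu_pos = 12.0,
                                         sigma_neg = 0.75, sigma_pos = 0.75,
                                         p_pos = 0.25)),
                          baseline_mean = 8,
                          noise_sd = 1,
                          ihc_missing_rate = 0.3,
                          ihc_error_rate = 0.02,
                          survival_spec = list(baseline_rate = 0.003,
                                               beta_score = -0.7,
                                               beta_tn = 0.54,
                                               beta_stage = 0.46,
                                               beta_node = 0.77,
                                               censoring_rate = 0.6),
                          seed = 20130508L) {
  cfg <- list(n_tumor = as.integer(n_tumor), n_normal = as.integer(n_normal),
              n_background_genes = as.integer(n_background_genes),
              cluster_spec = cluster_spec, tumor_shift = tumor_shift,
              receptor_spec = receptor_spec,
              baseline_mean = baseline_mean, noise_sd = noise_sd,
              ihc_missing_rate = ihc_missing_rate,
              ihc_error_rate = ihc_error_rate,
              survival_spec = survival_spec, seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_tumor >= 1L, cfg$n_normal >= 0L,
            cfg$n_background_genes >= 0L)
  props <- vapply(cfg$cluster_spec, `[[`, numeric(1), "proportion")
  if (any(props < 0) || abs(sum(props) - 1) > 1e-8) {
    stop("cluster proportions must be nonnegative and sum to 1")
  }
  tps <- vapply(cfg$cluster_spec, `[[`, numeric(1), "tn_prop")
  if (any(tps < 0 | tps > 1)) stop("tn_prop must lie in [0,1]")
  genes <- gene_panel()$gene
  for (cl in cfg$cluster_spec) {
    if (!identical(names(cl$shift), genes)) {
      stop("each cluster shift must be named over the full panel, panel order")
    }
  }
  if (!identical(names(cfg$tumor_shift), genes)) {
    stop("tumor_shift must be named over the full panel, panel order")
  }
  for (g in receptor_genes()) {
    rs <- cfg$receptor_spec[[g]]
    if (is.null(rs)) stop("receptor_spec missing gene ", g)
    if (rs$sigma_neg <= 0 || rs$sigma_pos <= 0) stop("receptor sigmas must be > 0")
    if (rs$p_pos < 0 || rs$p_pos > 1) stop("receptor p_pos must lie in [0,1]")
  }
  for (p in c(cfg$ihc_missing_rate, cfg$ihc_error_rate,
              cfg$survival_spec$censoring_rate)) {
    if (p < 0 || p > 1) stop("rates must lie in [0,1]")
  }
  if (cfg$noise_sd < 0) stop("noise_sd must be >= 0")
  if (cfg$survival_spec$baseline_rate <= 0) stop("baseline_rate must be > 0")
  invisible(cfg)
}

#' Normalized between-cluster contrast directions
#'
#' Returns the planted co-expression directions as unit vectors over the
#' panel genes: for every pair of clusters, the normalized difference of
#' their mean-shift vectors. These are the directions PCA is expected to
#' recover on generated cohorts.
#'
#' @param config A [cohort_config()].
#' @return genes x contrasts matrix of unit columns named "A-B" etc.
#' @export
planted_signature_directions <- function(config) {
  cls <- config$cluster_spec
  if (length(cls) < 2L) stop("need at least two clusters for a contrast")
  nm <- names(cls)
  shifts <- vapply(cls, `[[`, cls[[1L]]$shift, "shift")
  pairs <- utils::combn(seq_along(cls), 2L)
  out <- apply(pairs, 2L, function(ij) {
    d <- shifts[, ij[1L]] - shifts[, ij[2L]]
    nrm <- sqrt(sum(d^2))
    if (nrm == 0) stop("clusters ", nm[ij[1L]], " and ", nm[ij[2L]],
                       " have identical mean vectors")
    d / nrm
  })
  colnames(out) <- apply(pairs, 2L, function(ij) paste(nm[ij], collapse = "-"))
  rownames(out) <- names(cls[[1L]]$shift)
  out
}

# Prognostic axis used by the survival generator: the normalized contrast
# between the class-3-semaphorin-high clusters (F,G) and the VEGFA-high
# clusters (A,B); high score = anti-angiogenic expression = protective.
planted_prognostic_direction <- function(config) {
  cls <- config$cluster_spec
  nm <- names(cls)
  hi <- intersect(c("F", "G"), nm)
  lo <- intersect(c("A", "B"), nm)
  if (!length(hi) || !length(lo)) {  # fall back to first-vs-last contrast
    hi <- nm[length(nm)]
    lo <- nm[1L]
  }
  shifts <- vapply(cls, `[[`, cls[[1L]]$shift, "shift")
  d <- rowMeans(shifts[, hi, drop = FALSE]) -
    rowMeans(shifts[, lo, drop = FALSE])
  nrm <- sqrt(sum(d^2))
  if (nrm == 0) {
    # degenerate cluster structure: no prognostic expression axis
    return(stats::setNames(numeric(length(d)), names(d)))
  }
  d / nrm
}

#' Generate a synthetic breast-tumor cohort
#'
#' Draws cluster memberships, panel expression (cluster mean shift + iid
#' Gaussian log2 noise), bimodal receptor-gene expression, background noise
#' genes, IHC labels with configurable error and missingness, clinical
#' covariates, and exponential proportional-hazards survival times with
#' administrative censoring calibrated to the configured rate.
#'
#' @param config A [cohort_config()].
#' @return List with \code{expression} (genes x samples: 31 panel genes,
#'   ESR1/PGR/ERBB2, background genes), \code{annotation} (per-sample
#'   clinical table) and \code{truth} (planted cluster, receptor components,
#'   TN status, signature scores, generative coefficients).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  set.seed(config$seed)
  genes <- gene_panel()$gene
  n_t <- config$n_tumor
  n_n <- config$n_normal
  n <- n_t + n_n
  sample_id <- c(sprintf("T%04d", seq_len(n_t)),
                 if (n_n) sprintf("N%04d", seq_len(n_n)))
  group <- c(rep("tumor", n_t), rep("normal", n_n))

  ## planted clusters (tumors only)
  cls <- config$cluster_spec
  props <- vapply(cls, `[[`, numeric(1), "proportion")
  cluster <- sample(names(cls), n_t, replace = TRUE, prob = props)

  ## panel expression: baseline + tumor shift + cluster contrast + noise;
  ## normals at baseline. Cluster shifts are centered under the configured
  ## proportions so they are pure between-cluster contrasts and the
  ## tumor-vs-normal mean difference is exactly tumor_shift.
  shifts <- vapply(cls, `[[`, cls[[1L]]$shift, "shift")  # genes x clusters
  shifts <- shifts - drop(shifts %*% props)
  mu <- matrix(config$baseline_mean, nrow = length(genes), ncol = n,
               dimnames = list(genes, sample_id))
  mu[, seq_len(n_t)] <- mu[, seq_len(n_t)] + config$tumor_shift +
    shifts[, cluster]
  panel_expr <- mu + matrix(stats::rnorm(length(genes) * n, 0, config$noise_sd),
                            nrow = length(genes))

  ## receptor components: tumors are TN (all-negative) with the cluster's
  ## propensity; receptor-positive tumors draw each gene's component from
  ## its mixture, conditioned on at least one receptor being positive.
  ## Normal breast tissue is treated as receptor-positive-like (ESR1/PGR
  ## expressed at their positive-component level, ERBB2 unamplified).
  rg <- receptor_genes()
  tn_true <- rep(NA, n)
  comp <- matrix(NA_integer_, nrow = 3L, ncol = n,
                 dimnames = list(rg, sample_id))  # 1 = positive component
  tn_prop <- vapply(cls, `[[`, numeric(1), "tn_prop")
  tn_true[seq_len(n_t)] <- stats::runif(n_t) < tn_prop[cluster]
  p_pos <- vapply(rg, function(g) config$receptor_spec[[g]]$p_pos, numeric(1))
  for (i in seq_len(n_t)) {
    if (tn_true[i]) {
      comp[, i] <- 0L
    } else {
      repeat {
        draw <- as.integer(stats::runif(3L) < p_pos)
        if (any(draw == 1L)) break
      }
      comp[, i] <- draw
    }
  }
  if (n_n) {
    tn_true[n_t + seq_len(n_n)] <- FALSE
    comp["ESR1", n_t + seq_len(n_n)] <- 1L
    comp["PGR", n_t + seq_len(n_n)] <- 1L
    comp["ERBB2", n_t + seq_len(n_n)] <- 0L
  }
  receptor_expr <- matrix(NA_real_, nrow = 3L, ncol = n,
                          dimnames = list(rg, sample_id))
  for (g in rg) {
    rs <- config$receptor_spec[[g]]
    mu_g <- ifelse(comp[g, ] == 1L, rs$mu_pos, rs$mu_neg)
    sd_g <- ifelse(comp[g, ] == 1L, rs$sigma_pos, rs$sigma_neg)
    receptor_expr[g, ] <- stats::rnorm(n, mu_g, sd_g)
  }

  ## background noise genes
  if (config$n_background_genes > 0L) {
    bg <- matrix(stats::rnorm(config$n_background_genes * n,
                              config$baseline_mean, config$noise_sd),
                 nrow = config$n_background_genes,
                 dimnames = list(sprintf("BG%04d",
                                         seq_len(config$n_background_genes)),
                                 sample_id))
  } else {
    bg <- matrix(numeric(0), nrow = 0L, ncol = n,
                 dimnames = list(character(0), sample_id))
  }
  expr <- rbind(panel_expr, receptor_expr, bg)
  validate_expression_matrix(expr)

  ## IHC labels: true component, flipped with error rate, masked with
  ## missing rate
  ihc <- matrix(NA_character_, nrow = 3L, ncol = n, dimnames = list(rg, NULL))
  for (g in rg) {
    lab <- ifelse(comp[g, ] == 1L, "pos", "neg")
    flip <- stats::runif(n) < config$ihc_error_rate
    lab[flip] <- ifelse(lab[flip] == "pos", "neg", "pos")
    lab[stats::runif(n) < config$ihc_missing_rate] <- "unknown"
    ihc[g, ] <- lab
  }
  ihc[, group == "normal"] <- "unknown"
  tn_ihc <- apply(ihc, 2L, function(x) {
    if (any(x == "pos")) "RP"
    else if (all(x == "neg")) "TN"
    else "unknown"
  })
  tn_ihc[group == "normal"] <- "unknown"

  ## clinical covariates (tumors only)
  stage <- ifelse(group == "tumor",
                  sample(1:3, n, replace = TRUE, prob = c(0.35, 0.45, 0.20)),
                  NA_integer_)
  grade <- ifelse(group == "tumor",
                  sample(1:3, n, replace = TRUE, prob = c(0.2, 0.4, 0.4)),
                  NA_integer_)
  node <- ifelse(group == "tumor",
                 stats::rbinom(n, 1L, 0.4), NA_integer_)
  age <- ifelse(group == "tumor", round(stats::rnorm(n, 58, 11)), NA_real_)

  ## survival: exponential PH on planted signature score + clinical truth
  dir <- planted_prognostic_direction(config)
  raw_score <- drop(crossprod(panel_expr - rowMeans(panel_expr), dir))
  score_sd <- stats::sd(raw_score[group == "tumor"])
  if (!is.finite(score_sd) || score_sd == 0) score_sd <- 1  # degenerate cohort
  score <- (raw_score - mean(raw_score[group == "tumor"])) / score_sd
  ss <- config$survival_spec
  loghaz <- log(ss$baseline_rate) + ss$beta_score * score +
    ss$beta_tn * as.numeric(tn_true) +
    ss$beta_stage * (stage - 2) + ss$beta_node * node
  time <- rep(NA_real_, n)
  event <- rep(NA_integer_, n)
  tumor_idx <- which(group == "tumor")
  t_event <- stats::rexp(length(tumor_idx), rate = exp(loghaz[tumor_idx]))
  event[tumor_idx] <- 1L
  n_cens <- floor(ss$censoring_rate * length(tumor_idx))
  cens_idx <- tumor_idx[sample.int(length(tumor_idx), n_cens)]
  t_obs <- t_event
  censored <- tumor_idx %in% cens_idx
  t_obs[censored] <- stats::runif(sum(censored)) * t_event[censored]
  event[cens_idx] <- 0L
  time[tumor_idx] <- round(t_obs, 2)

  annotation <- data.frame(
    sample_id = sample_id, group = group,
    ihc_er = ihc["ESR1", ], ihc_pr = ihc["PGR", ], ihc_her2 = ihc["ERBB2", ],
    tn_status = tn_ihc, stage = stage, grade = grade, node = node, age = age,
    time = time, event = event, stringsAsFactors = FALSE
  )
  truth <- list(
    cluster = stats::setNames(c(cluster, rep(NA_character_, n_n)), sample_id),
    tn_true = stats::setNames(tn_true, sample_id),
    receptor_component = comp,
    signature_score = stats::setNames(score, sample_id),
    prognostic_direction = dir,
    coefficients = ss,
    seed = config$seed
  )
  list(expression = expr, annotation = annotation, truth = truth)
}
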