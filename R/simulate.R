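# Generators for every input the pipeline consumes: negative-binomial count
# matrices with batch structure, covariates and a sentinel gene whose
# control-group signal sits in a few outlier samples; pathology burdens;
# binding titrations; and noisy sedimentation-velocity scans.
# Every generator is a pure function of its configuration and seed.

#' Configuration for the synthetic count generator
#'
#' Defaults describe the desk-scale fixture: 2,000 genes, 60 cases and 60
#' controls in two batches, 17% differentially expressed genes with
#' predominantly modest fold changes (mirroring the DEG fraction and
#' fold-change spectrum of the emulated cohort), and a
#' sentinel gene with a modest case elevation (log2FC 0.5338) whose
#' control-group expression is concentrated in 4 outlier samples carrying
#' 55% of the total control signal.
#'
#' @param n_genes,n_case,n_control Dimensions.
#' @param baseline_logmean Mean and SD of per-gene natural-log baseline
#'   means.
#' @param dispersion_gamma Shape and scale of the gamma distribution of
#'   per-gene NB dispersions.
#' @param de_fraction Proportion of genes differentially expressed.
#' @param de_log2fc Mean and SD of the (signed normal) true log2
#'   fold changes of DE genes.
#' @param n_batches Number of batches (samples assigned at random).
#' @param batch_log2fc_sd SD of per-gene log2 shifts of non-reference
#'   batches.
#' @param depth_log_sd SD of natural-log per-sample depth factors.
#' @param sentinel List with `case_log2fc`, `n_outlier_controls`, `share`
#'   (fraction of total control signal carried by the outliers),
#'   `base_mean` (NB mean of non-outlier control expression),
#'   `control_dispersion` (NB dispersion of control expression: high, so
#'   that the majority of controls are near zero while a few are not) and
#'   `case_dispersion` (NB dispersion in cases: low, so the case elevation
#'   is consistent); `NULL` disables the sentinel.
#' @param seed RNG seed.
#' @return A list of class `sim_count_config`.
#' @export
sim_count_config <- function(n_genes = 2000, n_case = 60, n_control = 60,
                             baseline_logmean = c(mean = 4, sd = 2),
                             dispersion_gamma = c(shape = 2, scale = 0.05),
                             de_fraction = 0.17,
                             de_log2fc = c(mean = 0, sd = 0.8),
                             n_batches = 2, batch_log2fc_sd = 0.15,
                             depth_log_sd = 0.2,
                             sentinel = list(case_log2fc = 0.5338,
                                             n_outlier_controls = 4,
                                             share = 0.55, base_mean = 2,
                                             control_dispersion = 3.5,
                                             case_dispersion = 0.5),
                             seed = 1) {
  stopifnot(n_genes >= 1, n_case >= 2, n_control >= 2,
            de_fraction >= 0, de_fraction <= 1, n_batches >= 1)
  if (!is.null(sentinel)) {
    stopifnot(sentinel$share > 0, sentinel$share < 1,
              sentinel$n_outlier_controls >= 1,
              sentinel$n_outlier_controls < n_control)
  }
  structure(as.list(environment()), class = "sim_count_config")
}

#' Simulate a count matrix with metadata and ground truth
#'
#' Counts are negative binomial with mean
#' `baseline x group-effect x batch-effect x depth` and per-gene gamma
#' dispersions; covariates (age, sex, RIN, study) are drawn with mild group
#' imbalance. The sentinel gene is constructed so that cases show a
#' consistent moderate elevation while control expression is near zero
#' except for the designated outlier controls, which are deterministically
#' scaled up until they carry at least the configured share of total
#' control signal.
#'
#' @param cfg A [sim_count_config()].
#' @return A list with `counts` (integer matrix, genes x samples), `meta`
#'   (data.frame: sample_id, group, batch, age, sex, rin, study) and
#'   `truth` (is_de, true_log2fc, sentinel_gene_id, dispersion, depth).
#' @export
simulate_counts <- function(cfg = sim_count_config()) {
  set.seed(cfg$seed)
  G <- cfg$n_genes; n <- cfg$n_case + cfg$n_control
  gene_ids <- sprintf("gene%04d", seq_len(G))
  sample_ids <- sprintf("s%03d", seq_len(n))
  group <- factor(rep(c("case", "control"), c(cfg$n_case, cfg$n_control)),
                  levels = c("control", "case"))
  is_case <- group == "case"

  batch <- factor(sample(seq_len(cfg$n_batches), n, replace = TRUE))
  # guarantee every batch has >= 2 samples per the metadata invariant
  for (b in seq_len(cfg$n_batches)) {
    while (sum(batch == b) < 2) {
      donor <- which(batch == names(which.max(table(batch))))[1]
      batch[donor] <- b
    }
  }
  age <- stats::rnorm(n, 85, 6) + 1.5 * is_case
  sex <- factor(ifelse(stats::runif(n) < 0.55 + 0.05 * is_case, "F", "M"))
  rin <- stats::rnorm(n, 7, 0.5) - 0.15 * is_case
  study <- factor(sample(c("ROS", "MAP"), n, replace = TRUE))
  depth <- exp(stats::rnorm(n, 0, cfg$depth_log_sd))

  baseline <- exp(stats::rnorm(G, cfg$baseline_logmean[["mean"]],
                               cfg$baseline_logmean[["sd"]]))
  disp <- stats::rgamma(G, shape = cfg$dispersion_gamma[["shape"]],
                        scale = cfg$dispersion_gamma[["scale"]])
  disp <- pmax(disp, 1e-4)
  is_de <- stats::runif(G) < cfg$de_fraction
  lfc <- ifelse(is_de,
                stats::rnorm(G, cfg$de_log2fc[["mean"]],
                             cfg$de_log2fc[["sd"]]), 0)
  batch_eff <- matrix(0, G, cfg$n_batches)
  if (cfg$n_batches > 1)
    batch_eff[, -1] <- stats::rnorm(G * (cfg$n_batches - 1), 0,
                                    cfg$batch_log2fc_sd)

  mu <- baseline * 2^(outer(lfc, as.numeric(is_case))) *
    2^batch_eff[, as.integer(batch)] *
    matrix(depth, G, n, byrow = TRUE)
  counts <- matrix(stats::rnbinom(G * n, mu = mu,
                                  size = rep(1 / disp, n)), G, n)

  sentinel_id <- NA_character_
  if (!is.null(cfg$sentinel)) {
    sg <- sample.int(G, 1)
    sentinel_id <- gene_ids[sg]
    ctrl <- which(!is_case)
    cs <- which(is_case)
    disp_ctrl <- cfg$sentinel$control_dispersion %||% disp[sg]
    disp_case <- cfg$sentinel$case_dispersion %||% disp[sg]
    disp[sg] <- disp_ctrl
    ctrl_counts <- stats::rnbinom(length(ctrl),
                                  mu = cfg$sentinel$base_mean * depth[ctrl],
                                  size = 1 / disp_ctrl)
    out_idx <- sample(seq_along(ctrl), cfg$sentinel$n_outlier_controls)
    if (sum(ctrl_counts[out_idx]) == 0)
      ctrl_counts[out_idx] <- 1L
    s_out <- sum(ctrl_counts[out_idx])
    s_rest <- sum(ctrl_counts[-out_idx])
    if (s_rest > 0) {
      share <- cfg$sentinel$share
      fac <- share / (1 - share) * s_rest / s_out
      if (fac > 1)
        ctrl_counts[out_idx] <- as.integer(ceiling(ctrl_counts[out_idx] * fac))
    }
    ctrl_mean <- mean(ctrl_counts / depth[ctrl])
    case_counts <- stats::rnbinom(length(cs),
                                  mu = ctrl_mean *
                                    2^cfg$sentinel$case_log2fc * depth[cs],
                                  size = 1 / disp_case)
    counts[sg, ctrl] <- ctrl_counts
    counts[sg, cs] <- case_counts
    is_de[sg] <- TRUE
    lfc[sg] <- cfg$sentinel$case_log2fc
  }

  dimnames(counts) <- list(gene_ids, sample_ids)
  meta <- data.frame(sample_id = sample_ids, group = group, batch = batch,
                     age = age, sex = sex, rin = rin, study = study,
                     stringsAsFactors = FALSE)
  truth <- list(is_de = stats::setNames(is_de, gene_ids),
                true_log2fc = stats::setNames(lfc, gene_ids),
                sentinel_gene_id = sentinel_id,
                dispersion = stats::setNames(disp, gene_ids),
                depth = stats::setNames(depth, sample_ids))
  list(counts = counts, meta = meta, truth = truth)
}

#' Fraction of a group's signal carried by its top-k samples
#'
#' @param x Per-sample expression values of one gene.
#' @param k Number of top samples.
#' @return The share in [0, 1] (`NA` if the total is zero).
#' @export
top_k_share <- function(x, k = 4) {
  tot <- sum(x)
  if (tot == 0) return(NA_real_)
  sum(sort(x, decreasing = TRUE)[seq_len(min(k, length(x)))]) / tot
}

#' Simulate a continuous pathology burden
#'
#' `burden = softplus(effect * z(sentinel) + group_offset * case + noise)`,
#' guaranteeing non-negative values that track the sentinel gene's
#' expression when `effect > 0`.
#'
#' @param meta Sample metadata from [simulate_counts()] (uses `group`).
#' @param sentinel_expr Per-sample expression of the sentinel gene
#'   (log-scale values recommended).
#' @param effect Slope on the standardized sentinel expression.
#' @param noise_sd Gaussian noise SD.
#' @param group_offset Additive case offset before the softplus.
#' @param seed RNG seed.
#' @return Numeric burden per sample.
#' @export
simulate_pathology <- function(meta, sentinel_expr, effect = 1,
                               noise_sd = 0.5, group_offset = 0.5, seed = 1) {
  if (!is.finite(effect)) stop("effect must be finite")
  set.seed(seed)
  z <- as.numeric(scale(sentinel_expr))
  if (all(is.na(z))) z <- rep(0, length(sentinel_expr))
  z[is.na(z)] <- 0
  lin <- effect * z + group_offset * (meta$group == "case") +
    stats::rnorm(nrow(meta), 0, noise_sd)
  log1p(exp(lin))
}

#' Titration design for the synthetic binding experiments
#'
#' Defaults follow the sedimentation titration design: acceptor fixed at
#' 2.5 uM with ligand titrated from 0 to 5 uM, 1% multiplicative noise.
#'
#' @param a_tot Total acceptor concentration in molar.
#' @param l_tot_grid Ascending ligand totals in molar.
#' @param noise_cv Coefficient of variation of the multiplicative noise.
#' @param n_replicates Replicates per grid point.
#' @param seed RNG seed.
#' @return A list of class `sim_titration_design`.
#' @export
sim_titration_design <- function(a_tot = 2.5e-6,
                                 l_tot_grid = seq(0, 5e-6, length.out = 9),
                                 noise_cv = 0.01, n_replicates = 1,
                                 seed = 1) {
  if (is.unsorted(l_tot_grid) || any(l_tot_grid < 0))
    stop("l_tot_grid must be ascending and non-negative")
  if (noise_cv < 0) stop("noise_cv must be >= 0")
  structure(list(a_tot = a_tot, l_tot_grid = l_tot_grid,
                 noise_cv = noise_cv, n_replicates = n_replicates,
                 seed = seed),
            class = "sim_titration_design")
}

.simulate_titration <- function(model_vals, design, cls) {
  set.seed(design$seed)
  l <- rep(design$l_tot_grid, design$n_replicates)
  m <- rep(model_vals, design$n_replicates)
  eps <- stats::rnorm(length(m), 0, design$noise_cv)
  sigma <- pmax(design$noise_cv * m, 1e-12)
  .titration(rep(design$a_tot, length(l)), l, m * (1 + eps), sigma, cls)
}

#' Simulate a weight-average sedimentation titration
#'
#' Observations are `sw_model(...) * (1 + eps)` with
#' `eps ~ N(0, noise_cv)`; the `sigma` column is `noise_cv` times the model
#' value.
#'
#' @param params A [two_site_params()] object (ground truth).
#' @param design A [sim_titration_design()].
#' @return An `sw_titration` data.frame.
#' @export
simulate_sw_titration <- function(params = two_site_params(),
                                  design = sim_titration_design()) {
  m <- sw_model(params, design$a_tot, design$l_tot_grid)
  .simulate_titration(m, design, "sw_titration")
}

#' Simulate a tryptophan-fluorescence titration
#'
#' @param params A [fluor_params()] object (ground truth).
#' @param design A [sim_titration_design()].
#' @return A `fluor_titration` data.frame.
#' @export
simulate_fluor_titration <- function(params = fluor_params(),
                                     design = sim_titration_design()) {
  m <- fluor_model(params, design$a_tot, design$l_tot_grid)
  .simulate_titration(m, design, "fluor_titration")
}

#' Simulate noisy sedimentation-velocity scans
#'
#' [lamm_simulate()] output plus i.i.d. Gaussian noise.
#'
#' @param species List of [hydro_species()] (or a single one).
#' @param geom A [cell_geometry()].
#' @param cond A [solution_conditions()].
#' @param times Scan times in seconds.
#' @param noise_sd Per-point noise SD in AU.
#' @param seed RNG seed.
#' @param n_radial Radial cells.
#' @return A `radial_scans` data.frame.
#' @export
simulate_auc_scans <- function(species, geom = cell_geometry(),
                               cond = solution_conditions(),
                               times = seq(420, 6300, by = 420),
                               noise_sd = 0.005, seed = 1, n_radial = 400) {
  sc <- lamm_simulate(species, geom, times, cond, n_radial)
  set.seed(seed)
  sc$signal_au <- sc$signal_au + stats::rnorm(nrow(sc), 0, noise_sd)
  sc
}
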