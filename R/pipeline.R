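# End-to-end orchestration of the two analysis arms. The exported functions
# (plus the package vignette) are the user interface; both emit a machine-
# readable report list and optionally write TSV/JSON artefacts.

.validate_config <- function(cfg, known) {
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg
}

.write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the transcriptomic arm end to end
#'
#' simulate -> filter -> TMM -> log-CPM -> ComBat -> (a) NB differential
#' expression on the counts, (b) Boruta on the batch-corrected matrix,
#' (c) rank comparison with a divergence summary for the sentinel gene.
#'
#' @param cfg A list of configuration overrides; recognised keys:
#'   `sim` (a [sim_count_config()]), `boruta_max_runs`, `boruta_alpha`,
#'   `n_trees`, `top_k`, `seed`. Unknown keys are rejected.
#' @param out_dir Optional directory for TSV/JSON artefacts.
#' @return A list with the stage outputs (`counts`, `meta`, `truth`,
#'   `factors`, `logcpm`, `corrected`, `dea`, `boruta`, `comparison`) and a
#'   `summary` holding the sentinel ranks and the seed.
#' @export
run_transcriptomic_arm <- function(cfg = list(), out_dir = NULL) {
  cfg <- .validate_config(cfg, c("sim", "boruta_max_runs", "boruta_alpha",
                                 "n_trees", "top_k", "seed"))
  seed <- cfg$seed %||% 1
  sim_cfg <- cfg$sim %||% sim_count_config(seed = seed)
  sim <- simulate_counts(sim_cfg)
  counts <- filter_expressed(sim$counts)
  factors <- tmm_factors(counts)
  lc <- log_cpm(counts, factors)
  corrected <- combat_adjust(
    lc, sim$meta$batch,
    preserve = stats::model.matrix(~ group, sim$meta)[, -1, drop = FALSE])
  dea <- nb_dea(counts, sim$meta, factors)
  bor <- boruta_select(corrected, sim$meta$group, task = "classify",
                       max_runs = cfg$boruta_max_runs %||% 100,
                       alpha = cfg$boruta_alpha %||% 0.01,
                       n_trees = cfg$n_trees %||% 300, seed = seed)
  cmp <- compare_rankings(bor, dea, top_k = cfg$top_k %||% 10,
                          x = corrected, group = sim$meta$group)
  sent <- sim$truth$sentinel_gene_id
  summary <- list(seed = seed, sentinel_gene = sent)
  if (!is.na(sent) && sent %in% cmp$table$feature) {
    row <- cmp$table[cmp$table$feature == sent, ]
    summary$sentinel_boruta_rank <- row$boruta_rank
    summary$sentinel_dea_rank <- row$dea_rank
    summary$sentinel_divergence <- row$divergence
  }
  res <- list(counts = counts, meta = sim$meta, truth = sim$truth,
              factors = factors, logcpm = lc, corrected = corrected,
              dea = dea, boruta = bor, comparison = cmp, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_counts(counts, file.path(out_dir, "counts.tsv"))
    utils::write.csv(sim$meta, file.path(out_dir, "metadata.csv"),
                     row.names = FALSE)
    write_dea(dea, file.path(out_dir, "dea.tsv"))
    utils::write.table(as.data.frame(bor),
                       file.path(out_dir, "boruta_decisions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(cmp$table, file.path(out_dir, "rank_comparison.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .write_json(summary, file.path(out_dir, "summary.json"))
  }
  res
}

#' Run the biophysics arm end to end
#'
#' Simulates a weight-average sedimentation titration (optionally via full
#' scan simulation, c(s) deconvolution and s_w integration per titration
#' point), fits one-site and two-site binding models, compares them, and
#' reports hydrodynamic masses with the implied stoichiometry.
#'
#' @param cfg A list of configuration overrides; recognised keys: `params`
#'   (a [two_site_params()] truth), `fluor_params` (a [fluor_params()]
#'   truth), `design` (a [sim_titration_design()]), `mode` (`"direct-sw"`
#'   fits the analytic s_w observations; `"scans"` reconstructs each s_w
#'   from simulated noisy scans via [fit_cs()]/[integrate_sw()]), `n_starts`,
#'   `seed`, and for scan mode `s_grid`, `ff0`, `noise_sd`, `n_radial`,
#'   `times`. Unknown keys are rejected.
#' @param out_dir Optional directory for artefacts.
#' @return A list with `titration`, the four `fit_*` results (sw/fluor x
#'   one/two-site), `comparison_sw`, `comparison_fluor`, `masses` (printed
#'   species masses from [mass_from_hydro()]) and `stoichiometry`.
#' @export
run_biophysics_arm <- function(cfg = list(), out_dir = NULL) {
  cfg <- .validate_config(cfg, c("params", "fluor_params", "design",
                                 "fluor_design", "mode", "n_starts", "seed",
                                 "s_grid", "ff0", "noise_sd", "n_radial",
                                 "times"))
  seed <- cfg$seed %||% 1
  params <- cfg$params %||% two_site_params()
  fpar <- cfg$fluor_params %||% fluor_params()
  design <- cfg$design %||% sim_titration_design(seed = seed)
  mode <- cfg$mode %||% "direct-sw"
  n_starts <- cfg$n_starts %||% 16

  if (mode == "direct-sw") {
    tit <- simulate_sw_titration(params, design)
  } else if (mode == "scans") {
    geom <- cell_geometry(); cond <- solution_conditions()
    times <- cfg$times %||% seq(420, 6300, by = 420)
    n_radial <- cfg$n_radial %||% 250
    s_grid <- cfg$s_grid %||% default_s_grid()
    ff0 <- cfg$ff0 %||% 1.38
    noise_sd <- cfg$noise_sd %||% 0.005
    sw_obs <- vapply(seq_along(design$l_tot_grid), function(i) {
      lt <- design$l_tot_grid[i]
      st <- solve_equilibrium(design$a_tot, lt, params$kd1, params$kd2)
      cc <- c(st$conc_A, st$conc_L, st$conc_AL, st$conc_AL2)
      sig <- params$w * cc * 1e6  # AU per uM-scale loading
      species <- mapply(function(s, load, lab)
        hydro_species(lab, s, ff0, loading_signal = load, cond = cond),
        params$s, sig, names(params$s), SIMPLIFY = FALSE)
      species <- species[sig > 1e-6]
      sc <- simulate_auc_scans(species, geom, cond, times, noise_sd,
                               seed = seed + i, n_radial = n_radial)
      cs <- fit_cs(sc, geom, cond, s_grid, ff0, noise_sd = noise_sd,
                   n_radial = n_radial)
      integrate_sw(cs)
    }, numeric(1))
    tit <- sw_titration(rep(design$a_tot, length(sw_obs)),
                        design$l_tot_grid, sw_obs,
                        pmax(design$noise_cv * sw_obs, 1e-12))
  } else stop("unknown mode: ", mode)

  fit_sw_two <- fit_binding(tit, "two-site", n_starts = n_starts, seed = seed)
  fit_sw_one <- fit_binding(tit, "one-site", n_starts = n_starts, seed = seed)
  cmp_sw <- compare_models(fit_sw_one, fit_sw_two)

  fdesign <- cfg$fluor_design %||% sim_titration_design(
    l_tot_grid = seq(0, 2e-5, length.out = 16), noise_cv = 0.001,
    n_replicates = 3, seed = seed)
  ftit <- simulate_fluor_titration(fpar, fdesign)
  fit_fl_two <- fit_binding(ftit, "two-site", n_starts = n_starts,
                            seed = seed, tie_amplitudes = TRUE)
  fit_fl_one <- fit_binding(ftit, "one-site", n_starts = n_starts, seed = seed)
  cmp_fl <- compare_models(fit_fl_one, fit_fl_two)

  peaks <- data.frame(
    species = c("APP", "Lf", "1:1 complex", "1:2 complex"),
    s = c(3.9, 5.1, 6.9, 9.8), ff0 = c(1.40, 1.38, 1.39, 1.36))
  peaks$mass_kda <- mass_from_hydro(peaks$s, peaks$ff0) / 1000
  stoich <- stoichiometry_select(peaks$mass_kda[1], peaks$mass_kda[2],
                                 peaks$mass_kda[4], 4)

  res <- list(titration = tit, fit_sw_two = fit_sw_two,
              fit_sw_one = fit_sw_one, comparison_sw = cmp_sw,
              fluor_titration = ftit, fit_fluor_two = fit_fl_two,
              fit_fluor_one = fit_fl_one, comparison_fluor = cmp_fl,
              masses = peaks, stoichiometry = stoich,
              summary = list(seed = seed, mode = mode,
                             kd1_nM = fit_sw_two$estimates$kd1 * 1e9,
                             kd2_uM = fit_sw_two$estimates$kd2 * 1e6,
                             r2_two = fit_sw_two$r_squared,
                             r2_one = fit_sw_one$r_squared))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(as.data.frame(tit),
                     file.path(out_dir, "sw_titration.csv"), row.names = FALSE)
    write_fit_report(fit_sw_two, file.path(out_dir, "fit_sw_two_site.json"))
    write_fit_report(fit_sw_one, file.path(out_dir, "fit_sw_one_site.json"))
    .write_json(res$summary, file.path(out_dir, "summary.json"))
  }
  res
}
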