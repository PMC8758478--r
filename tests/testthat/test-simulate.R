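test_that("count simulation is a pure function of its seed", {
  a <- simulate_counts(sim_count_config(n_genes = 200, n_case = 10,
                                        n_control = 10, seed = 7))
  b <- simulate_counts(sim_count_config(n_genes = 200, n_case = 10,
                                        n_control = 10, seed = 7))
  expect_identical(a$counts, b$counts)
  expect_identical(a$meta, b$meta)
  expect_identical(a$truth, b$truth)
  c_ <- simulate_counts(sim_count_config(n_genes = 200, n_case = 10,
                                         n_control = 10, seed = 8))
  expect_false(identical(a$counts, c_$counts))
})

test_that("the sentinel's outlier controls carry at least the stated share", {
  for (s in 1:5) {
    sim <- simulate_counts(sim_count_config(n_genes = 300, seed = 30 + s))
    sent <- sim$truth$sentinel_gene_id
    ctrl_expr <- sim$counts[sent, sim$meta$group == "control"]
    expect_gte(top_k_share(ctrl_expr, 4), 0.55)
    expect_true(sim$truth$is_de[sent])
    expect_equal(unname(sim$truth$true_log2fc[sent]), 0.5338)
  }
})

test_that("generated counts match their negative-binomial moments", {
  cfg <- sim_count_config(n_genes = 60, n_case = 400, n_control = 400,
                          de_fraction = 0, n_batches = 1, depth_log_sd = 0,
                          sentinel = NULL, seed = 12)
  sim <- simulate_counts(cfg)
  # per-gene sample variance should track mu + phi mu^2
  mus <- rowMeans(sim$counts)
  vars <- apply(sim$counts, 1, stats::var)
  phi <- sim$truth$dispersion
  expected <- mus + phi * mus^2
  keep <- mus > 5
  ratio <- vars[keep] / expected[keep]
  expect_gt(mean(ratio), 0.8); expect_lt(mean(ratio), 1.25)
})

test_that("null simulation yields approximately uniform DEA p-values", {
  cfg <- sim_count_config(n_genes = 1000, n_case = 20, n_control = 20,
                          de_fraction = 0, n_batches = 2, sentinel = NULL,
                          seed = 2)
  sim <- simulate_counts(cfg)
  dea <- nb_dea(filter_expressed(sim$counts), sim$meta)
  ks <- stats::ks.test(dea$pvalue, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("pathology burden tracks the sentinel when the effect is on", {
  sim <- simulate_counts(sim_count_config(n_genes = 100, seed = 3))
  sent_expr <- log1p(sim$counts[sim$truth$sentinel_gene_id, ])
  b1 <- simulate_pathology(sim$meta, sent_expr, effect = 1.5,
                           noise_sd = 0.3, seed = 4)
  expect_true(all(b1 >= 0))
  expect_gt(stats::cor(b1, sent_expr), 0.5)
  # effect = 0: correlation is indistinguishable from zero
  b0 <- simulate_pathology(sim$meta, sent_expr, effect = 0, noise_sd = 0.3,
                           group_offset = 0, seed = 4)
  ct <- stats::cor.test(b0, sent_expr)
  expect_gt(ct$p.value, 0.001)
  # determinism
  expect_identical(b1, simulate_pathology(sim$meta, sent_expr, effect = 1.5,
                                          noise_sd = 0.3, seed = 4))
})

test_that("titration generators honour their noise and seed contracts", {
  p <- two_site_params()
  d0 <- simulate_sw_titration(p, sim_titration_design(noise_cv = 1e-15,
                                                      seed = 1))
  expect_equal(d0$observable,
               sw_model(p, 2.5e-6, d0$l_tot_molar), tolerance = 1e-10)
  d1 <- simulate_sw_titration(p, sim_titration_design(seed = 5))
  d2 <- simulate_sw_titration(p, sim_titration_design(seed = 5))
  expect_identical(d1, d2)
  fp <- fluor_params()
  f0 <- simulate_fluor_titration(fp, sim_titration_design(noise_cv = 1e-15,
                                                          seed = 1))
  expect_equal(f0$observable[f0$l_tot_molar == 0][1], fp$f0,
               tolerance = 1e-10)
})

test_that("noiseless scan simulation reproduces lamm_simulate bit-exactly", {
  sp <- hydro_species("x", 5.1, 1.38, loading_signal = 0.4)
  times <- c(600, 1800)
  clean <- lamm_simulate(sp, cell_geometry(), times, n_radial = 150)
  noisy0 <- simulate_auc_scans(sp, times = times, noise_sd = 0, seed = 9,
                               n_radial = 150)
  expect_identical(clean$signal_au, noisy0$signal_au)
  n1 <- simulate_auc_scans(sp, times = times, noise_sd = 0.005, seed = 9,
                           n_radial = 150)
  n2 <- simulate_auc_scans(sp, times = times, noise_sd = 0.005, seed = 9,
                           n_radial = 150)
  expect_identical(n1, n2)
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_count_config(n_case = 1))
  expect_error(sim_count_config(sentinel = list(case_log2fc = 0.5,
                                                n_outlier_controls = 70,
                                                share = 0.5, base_mean = 2)))
  expect_error(sim_titration_design(l_tot_grid = c(2e-6, 1e-6)), "ascending")
})
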