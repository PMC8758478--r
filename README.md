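# LfAPP

Tools for the two computational arms of an APP–lactoferrin interaction
study: the biophysical characterisation of soluble amyloid precursor
protein (sAPPα) binding holo-lactoferrin (Lf), and the transcriptomic
contrast between parametric differential expression and outlier-robust
all-relevant feature selection that flagged *LTF* in Alzheimer's disease
cortex.

## Who this is for

* Analytical-ultracentrifugation users who want a transparent, scriptable
  route from sedimentation-velocity scans to c(s) distributions,
  weight-average sedimentation coefficients, hydrodynamic masses and
  two-site binding constants.
* Transcriptomics practitioners who want to reproduce — and stress-test on
  synthetic data — the phenomenon where a gene with a few extreme control
  outliers ranks highly under random-forest feature selection (Boruta) but
  lowly under negative-binomial differential expression.

## The models at the core

**Hydrodynamics.** The Svedberg relation combined with Stokes friction of
the equivalent sphere gives the closed form

    M = [ s·N_A·(f/f0)·6πη·(3v̄/4πN_A)^(1/3) / (1 − v̄ρ) ]^(3/2)

(`mass_from_hydro`). Sedimentation-velocity scans are simulated by a
conservative finite-volume Lamm-equation solver (`lamm_simulate`),
deconvolved into c(s) distributions by non-negative Tikhonov-regularized
least squares against Lamm kernels (`fit_cs`), and integrated to the
weight-average s_w (`integrate_sw`).

**Binding.** s_w titrations follow the sequential two-site scheme
A + L ⇌ AL (Kd1), AL + L ⇌ AL2 (Kd2) solved exactly per titration point
(`solve_equilibrium`, `sw_model`); fluorescence titrations follow the
two-independent-site model F = f0 + ΔF1·θ1 + ΔF2·θ2 with exact ligand
depletion (`fluor_model`). `fit_binding` does weighted multi-start
Levenberg–Marquardt fits; `compare_models` reports ΔR², AICc and an exact
runs test on residual signs.

**Transcriptomics.** TMM normalization, log-CPM, empirical-Bayes batch
correction (`combat_adjust`), negative-binomial GLMs with covariates via
edgeR (`nb_dea`), a from-scratch Boruta with a constant-strength shadow
contest (`boruta_select`), and the Boruta-vs-DEA rank comparison
(`compare_rankings`). `simulate_counts` generates the full synthetic
cohort, including the sentinel gene whose four outlier controls carry 55%
of total control signal.

## Worked example

```r
library(LfAPP)

# Hydrodynamic masses of the observed species peaks
peaks <- data.frame(s = c(3.9, 5.1, 6.9, 9.8),
                    ff0 = c(1.40, 1.38, 1.39, 1.36))
round(mass_from_hydro(peaks$s, peaks$ff0) / 1000, 1)
#> [1]  58.9  86.2 137.2 224.7

# 58.9 + 2 x 86.2 kDa is closest to the 224.7 kDa heavy complex:
stoichiometry_select(58.9, 86.2, 224.7, 4)
#> $n_a: 1   $n_l: 2   $rel_error: 0.0294  (one APP binding two Lf)

# Simulate the s_w titration (APP 2.5 uM, Lf 0-5 uM, 1% noise) from the
# published constants and re-fit both binding models
tit <- simulate_sw_titration(two_site_params(kd1 = 620e-9, kd2 = 8.2e-6),
                             sim_titration_design(seed = 1))
two <- fit_binding(tit, "two-site", n_starts = 16, seed = 1)
one <- fit_binding(tit, "one-site", n_starts = 16, seed = 1)
c(kd1_nM = two$estimates$kd1 * 1e9, kd2_uM = two$estimates$kd2 * 1e6)
#>     kd1_nM     kd2_uM
#> 620.48746  7.651026
c(r2_two = two$r_squared, r2_one = one$r_squared)
#>    r2_two    r2_one
#> 0.9977048 0.9085071
compare_models(one, two)$preferred
#> [1] "two-site"
```

The recovered constants sit within the titration's statistical resolution
of the generating values (620 nM, 8.2 µM), and the one-site fit is
decisively worse — the same model discrimination reported for the real
titrations.

```r
# Transcriptomic arm, desk scale: sentinel gene diverges between rankings
res <- run_transcriptomic_arm(list(seed = 101, boruta_max_runs = 40))
res$summary
#> $sentinel_gene         "gene1087"
#> $sentinel_boruta_rank  116   (top decile of 2,000 genes)
#> $sentinel_dea_rank     399   (outside the top decile)
#> $sentinel_divergence   283   (feature selection ranks it 283 places better)
```

The sentinel — a gene with a modest, consistent case elevation whose
control-group signal is dominated by four outlier samples — is exactly the
expression pattern that parametric differential expression down-ranks
(its dispersion estimate is inflated by the outliers) while the
rank-based random forest does not.

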