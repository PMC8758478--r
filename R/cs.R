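# Regularized non-negative c(s) deconvolution of sedimentation-velocity
# scans, and weight-average s integration of the resulting distribution.

.scan_matrix <- function(scans) {
  times <- sort(unique(scans$time_s))
  sp <- split(scans$signal_au, scans$time_s)
  radius <- scans$radius_cm[scans$time_s == times[1]]
  list(times = times, radius = radius,
       y = unlist(sp[as.character(times)], use.names = FALSE))
}

# simulate the unit-loading kernel for one grid species, flattened over
# (scan, radius) in the same order as .scan_matrix
.cs_kernel <- function(s_grid, ff0, geom, cond, times, n_radial) {
  K <- matrix(NA_real_, length(times) * n_radial, length(s_grid))
  for (j in seq_along(s_grid)) {
    sp <- hydro_species("grid", s_grid[j], ff0, loading_signal = 1,
                        cond = cond)
    sol <- .lamm_one_species(sp$s, sp$diffusion_coeff, 1, geom, times,
                             n_radial)
    K[, j] <- as.vector(t(sol$conc))
  }
  K
}

#' Default log-spaced sedimentation-coefficient grid
#'
#' @param n Number of grid points.
#' @param s_min,s_max Grid limits in Svedberg.
#' @return Strictly increasing numeric vector of s values.
#' @export
default_s_grid <- function(n = 30, s_min = 1, s_max = 15) {
  exp(seq(log(s_min), log(s_max), length.out = n))
}

#' Fit a c(s) sedimentation-coefficient distribution
#'
#' Deconvolves boundary scans against Lamm-equation kernels: finds the
#' non-negative `c` minimizing `||K c - y||^2 + lambda ||P c||^2` where
#' column j of `K` is the simulated unit-loading signal of a species with
#' sedimentation coefficient `s_grid[j]` (diffusion derived from the shared
#' frictional ratio) and `P` is a second-difference roughness penalty
#' (non-negative Tikhonov regularization). With `lam = "auto"` the penalty
#' weight is chosen by the discrepancy principle at the stated noise SD.
#'
#' @param scans A `radial_scans` data.frame; all scans must share one radial
#'   grid. At least 3 scans are required.
#' @param geom A [cell_geometry()] object.
#' @param cond A [solution_conditions()] object.
#' @param s_grid Sedimentation-coefficient grid in Svedberg.
#' @param ff0 Frictional ratio shared by all grid species.
#' @param lam Penalty weight (>= 0), or `"auto"` for the discrepancy
#'   principle.
#' @param noise_sd Assumed per-point noise SD in AU (used by `lam = "auto"`).
#' @param n_radial Radial cells used for the kernel simulation; defaults to
#'   the number of radii per scan.
#' @return An object of class `cs_distribution`: a data.frame with columns
#'   `s_svedberg`, `c_au_per_s`, plus attributes `ff0`, `lam`, `rss`,
#'   `loading` (fitted total signal, the integral of c over s).
#' @export
fit_cs <- function(scans, geom = cell_geometry(), cond = solution_conditions(),
                   s_grid = default_s_grid(), ff0 = 1.38, lam = "auto",
                   noise_sd = 0.005, n_radial = NULL) {
  sm <- .scan_matrix(scans)
  if (length(sm$times) < 3) stop("need at least 3 scans")
  if (is.unsorted(s_grid, strictly = TRUE)) stop("s_grid must be increasing")
  if (is.null(n_radial)) n_radial <- length(sm$radius)
  K <- .cs_kernel(s_grid, ff0, geom, cond, sm$times, n_radial)
  y <- sm$y
  if (all(y == 0)) {
    warning("all-zero scan data; returning zero distribution")
    out <- data.frame(s_svedberg = s_grid, c_au_per_s = 0)
    class(out) <- c("cs_distribution", "data.frame")
    attr(out, "ff0") <- ff0; attr(out, "lam") <- 0
    attr(out, "rss") <- 0; attr(out, "loading") <- 0
    return(out)
  }
  ns <- length(s_grid)
  # second-difference penalty on the density scale
  P <- matrix(0, ns - 2, ns)
  for (k in seq_len(ns - 2)) P[k, k + 0:2] <- c(1, -2, 1)

  solve_lam <- function(l) {
    A <- rbind(K, sqrt(l) * P)
    b <- c(y, rep(0, nrow(P)))
    fit <- pracma::lsqnonneg(A, b)
    rss <- sum((K %*% fit$x - y)^2)
    list(x = fit$x, rss = rss)
  }

  if (identical(lam, "auto")) {
    target <- noise_sd^2 * length(y)
    lams <- 10^seq(-4, 4, length.out = 9) * max(colSums(K^2))
    best <- NULL; best_lam <- 0
    for (l in lams) {
      sol <- solve_lam(l)
      if (sol$rss <= target) { best <- sol; best_lam <- l } else break
    }
    if (is.null(best)) { best_lam <- lams[1]; best <- solve_lam(best_lam) }
    lam <- best_lam; sol <- best
  } else {
    if (lam < 0) stop("lam must be >= 0")
    sol <- solve_lam(lam)
  }

  # convert amplitudes (AU of loading per grid species) to density per S
  ds <- diff(s_grid)
  wgrid <- c(ds[1] / 2, (ds[-length(ds)] + ds[-1]) / 2,
             ds[length(ds)] / 2)  # trapezoid weights
  dens <- sol$x / wgrid
  out <- data.frame(s_svedberg = s_grid, c_au_per_s = dens)
  class(out) <- c("cs_distribution", "data.frame")
  attr(out, "ff0") <- ff0
  attr(out, "lam") <- lam
  attr(out, "rss") <- sol$rss
  attr(out, "loading") <- sum(sol$x)
  out
}

#' Weight-average sedimentation coefficient from a c(s) distribution
#'
#' Trapezoid evaluation of `s_w = integral(s c(s) ds) / integral(c(s) ds)`
#' over a stated range.
#'
#' @param cs A `cs_distribution` (or any data.frame with `s_svedberg` and
#'   `c_au_per_s` columns).
#' @param s_range Numeric length-2 integration range in Svedberg; defaults to
#'   the full grid.
#' @return The weight-average s in Svedberg.
#' @export
integrate_sw <- function(cs, s_range = range(cs$s_svedberg)) {
  keep <- cs$s_svedberg >= s_range[1] & cs$s_svedberg <= s_range[2]
  s <- cs$s_svedberg[keep]; c_ <- cs$c_au_per_s[keep]
  if (length(s) < 2) stop("s_range must contain at least two grid points")
  trap <- function(f) sum(diff(s) * (f[-1] + f[-length(f)]) / 2)
  denom <- trap(c_)
  if (denom <= 0) stop("zero total signal in s_range")
  trap(s * c_) / denom
}

#' Read/write c(s) distributions as CSV
#'
#' CSV with mandatory headers `s_svedberg, c_au_per_s`.
#' @param path File path.
#' @export
read_cs <- function(path) {
  d <- utils::read.csv(path)
  need <- c("s_svedberg", "c_au_per_s")
  if (!all(need %in% names(d)))
    stop("c(s) CSV must have columns: ", paste(need, collapse = ", "))
  out <- d[, need]
  class(out) <- c("cs_distribution", "data.frame")
  out
}

#' @rdname read_cs
#' @param cs A `cs_distribution` data.frame.
#' @export
write_cs <- function(cs, path) {
  utils::write.csv(as.data.frame(cs)[, c("s_svedberg", "c_au_per_s")], path,
                   row.names = FALSE)
  invisible(path)
}
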