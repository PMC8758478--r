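#' Centrifuge cell geometry
#'
#' @param meniscus Meniscus radius in cm.
#' @param base Cell base radius in cm.
#' @param rotor_speed Rotor speed in rpm.
#' @return An object of class `cell_geometry`.
#' @examples
#' cell_geometry()  # 6 to 7.25 cm at 50,000 rpm
#' @export
cell_geometry <- function(meniscus = 6.0, base = 7.25, rotor_speed = 50000) {
  if (!(base > meniscus && meniscus > 0)) stop("need base > meniscus > 0")
  if (rotor_speed <= 0) stop("rotor speed must be positive")
  structure(list(meniscus = meniscus, base = base, rotor_speed = rotor_speed),
            class = "cell_geometry")
}

.omega <- function(geom) geom$rotor_speed * 2 * pi / 60  # rad/s

# One-species Lamm propagation on a finite-volume sector grid.
# Conservative scheme: upwinded sedimentation flux (explicit) and
# Crank-Nicolson diffusion; face fluxes carry the sector area factor r, so
# the discrete mass sum(c_i * r_i * dr) is conserved exactly with zero-flux
# boundaries. Time steps are sub-divided to respect the advective CFL limit.
.lamm_one_species <- function(s_svedberg, D, loading, geom, times, n_radial,
                              cfl = 0.5) {
  m <- geom$meniscus; b <- geom$base
  n <- n_radial
  dr <- (b - m) / n
  r_face <- m + dr * (0:n)
  r_cell <- (r_face[-1] + r_face[-(n + 1)]) / 2
  vol <- r_cell * dr
  w2 <- .omega(geom)^2
  s_sec <- s_svedberg * 1e-13

  # interior faces 2..n (faces 1 and n+1 are zero-flux walls)
  rf <- r_face[2:n]
  adv_coef <- s_sec * w2 * rf^2     # flux = adv_coef * c_upwind (signal*cm/s * r)
  dif_coef <- D * rf / dr           # flux = -dif_coef * (c_right - c_left)

  # advection matrix A: dc/dt = A c (upwind: sedimentation moves outward)
  # face k (between cells k and k+1) takes from cell k, gives to cell k+1
  A_low <- adv_coef / vol[2:n]            # into cell k+1 from cell k
  A_dia <- c(-adv_coef / vol[1:(n - 1)], 0)
  # diffusion matrix Dm (tridiagonal, symmetric flux form)
  Dm <- matrix(0, n, n)
  for (k in 1:(n - 1)) {
    g <- dif_coef[k]
    Dm[k, k] <- Dm[k, k] - g / vol[k]
    Dm[k, k + 1] <- Dm[k, k + 1] + g / vol[k]
    Dm[k + 1, k + 1] <- Dm[k + 1, k + 1] - g / vol[k + 1]
    Dm[k + 1, k] <- Dm[k + 1, k] + g / vol[k + 1]
  }

  vmax <- s_sec * w2 * b
  dt_cfl <- if (vmax > 0) cfl * dr / vmax else Inf
  # accuracy cap on the Crank-Nicolson step: keep the diffusion number
  # D dt / dr^2 modest so sharp fronts are resolved in time as well
  if (D > 0) dt_cfl <- min(dt_cfl, 2.5 * dr^2 / D)

  c_now <- if (length(loading) == n) loading else rep(loading, n)
  out <- matrix(NA_real_, length(times), n)
  t_now <- 0
  prop_cache <- list()
  step_mat <- function(dt) {
    key <- sprintf("%.12e", dt)
    if (is.null(prop_cache[[key]])) {
      I <- diag(n)
      CN <- solve(I - dt / 2 * Dm, I + dt / 2 * Dm)
      Adv <- I
      if (vmax > 0) {
        Adv <- I + dt * (diag(A_dia) +
          rbind(0, cbind(diag(A_low, n - 1, n - 1), 0)))
      }
      prop_cache[[key]] <<- CN %*% Adv
    }
    prop_cache[[key]]
  }

  for (i in seq_along(times)) {
    gap <- times[i] - t_now
    if (gap < 0) stop("times must be sorted ascending and non-negative")
    if (gap > 0) {
      nsub <- max(1L, ceiling(gap / dt_cfl))
      dt <- gap / nsub
      P <- step_mat(dt)
      for (k in seq_len(nsub)) c_now <- as.vector(P %*% c_now)
    }
    t_now <- times[i]
    out[i, ] <- c_now
  }
  list(radius = r_cell, conc = out, vol = vol)
}

#' Simulate sedimentation-velocity absorbance scans (Lamm equation)
#'
#' Solves the Lamm equation `dc/dt = (1/r) d/dr [ r D dc/dr - s w^2 r^2 c ]`
#' per species on a sector-shaped cell with zero-flux boundaries and uniform
#' initial loading, then sums species signals. A conservative finite-volume
#' scheme with upwinded sedimentation flux and Crank-Nicolson diffusion is
#' used; time steps are automatically sub-divided to satisfy the advective
#' CFL limit, so the scheme never goes unstable silently.
#'
#' @param species A list of [hydro_species()] objects (or a single one).
#' @param geom A [cell_geometry()] object.
#' @param times Scan times in seconds since speed was attained, ascending.
#' @param cond A [solution_conditions()] object.
#' @param n_radial Number of radial cells (>= 100).
#' @return A data.frame of class `radial_scans` with columns
#'   `time_s, radius_cm, signal_au` (one row per scan point); the radial grid
#'   is identical across scans.
#' @export
lamm_simulate <- function(species, geom = cell_geometry(), times,
                          cond = solution_conditions(), n_radial = 400) {
  if (inherits(species, "hydro_species")) species <- list(species)
  if (n_radial < 100) stop("n_radial must be >= 100")
  if (is.unsorted(times) || any(times < 0))
    stop("times must be ascending and non-negative")
  total <- NULL
  for (sp in species) {
    sol <- .lamm_one_species(sp$s, sp$diffusion_coeff, sp$loading_signal,
                             geom, times, n_radial)
    total <- if (is.null(total)) sol$conc else total + sol$conc
    radius <- sol$radius
  }
  out <- data.frame(
    time_s = rep(times, each = length(radius)),
    radius_cm = rep(radius, times = length(times)),
    signal_au = as.vector(t(total)))
  class(out) <- c("radial_scans", "data.frame")
  out
}

#' Sector mass of a set of radial scans
#'
#' Computes the sector-weighted mass integral `sum(c * r * dr)` per scan;
#' used to verify conservation of the Lamm solver.
#'
#' @param scans A `radial_scans` data.frame from [lamm_simulate()].
#' @return A data.frame with columns `time_s` and `mass`.
#' @export
sector_mass <- function(scans) {
  sp <- split(scans, scans$time_s)
  res <- lapply(sp, function(d) {
    dr <- diff(d$radius_cm)
    dr <- c(dr, dr[length(dr)])
    data.frame(time_s = d$time_s[1], mass = sum(d$signal_au * d$radius_cm * dr))
  })
  out <- do.call(rbind, res)
  out[order(out$time_s), , drop = FALSE]
}

#' Read/write radial scans as CSV
#'
#' CSV with mandatory headers `time_s, radius_cm, signal_au`, one row per
#' (scan, radius) pair.
#'
#' @param path File path.
#' @return `read_scans` returns a `radial_scans` data.frame.
#' @export
read_scans <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "radius_cm", "signal_au")
  if (!all(need %in% names(d)))
    stop("scan CSV must have columns: ", paste(need, collapse = ", "))
  d <- d[order(d$time_s, d$radius_cm), need]
  class(d) <- c("radial_scans", "data.frame")
  d
}

#' @rdname read_scans
#' @param scans A `radial_scans` data.frame.
#' @export
write_scans <- function(scans, path) {
  utils::write.csv(as.data.frame(scans)[, c("time_s", "radius_cm", "signal_au")],
                   path, row.names = FALSE)
  invisible(path)
}
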