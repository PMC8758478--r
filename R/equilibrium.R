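# Two-site APP-lactoferrin equilibrium: sequential scheme
#   A + L <=> AL   (Kd1 = A*L/AL)
#   AL + L <=> AL2 (Kd2 = AL*L/AL2)
# solved by monotone bracketing on free ligand.

#' Parameters of the two-site sedimentation observable model
#'
#' Sequential dissociation constants plus per-species sedimentation
#' coefficients and signal weights. Default s values are the observed peak
#' positions (3.9, 5.1, 6.9, 9.8 S for APP, Lf, 1:1 and 1:2 complexes);
#' default signal weights are proportional to species molar mass (absorbance
#' at 280 nm scales roughly with mass at fixed loading).
#'
#' @param kd1,kd2 Dissociation constants in molar for the first and second
#'   lactoferrin binding events.
#' @param s_A,s_L,s_AL,s_AL2 Species sedimentation coefficients in Svedberg.
#' @param w_A,w_L,w_AL,w_AL2 Signal weights in AU per molar.
#' @return An object of class `two_site_params`.
#' @export
two_site_params <- function(kd1 = 620e-9, kd2 = 8.2e-6,
                            s_A = 3.9, s_L = 5.1, s_AL = 6.9, s_AL2 = 9.8,
                            w_A = 61, w_L = 79, w_AL = 140, w_AL2 = 219) {
  if (kd1 <= 0 || kd2 <= 0) stop("dissociation constants must be positive")
  if (!(s_AL2 > s_AL && s_AL > s_A))
    stop("complex s values must increase with size: s_AL2 > s_AL > s_A")
  if (any(c(w_A, w_L, w_AL, w_AL2) < 0)) stop("signal weights must be >= 0")
  structure(list(kd1 = kd1, kd2 = kd2,
                 s = c(A = s_A, L = s_L, AL = s_AL, AL2 = s_AL2),
                 w = c(A = w_A, L = w_L, AL = w_AL, AL2 = w_AL2)),
            class = "two_site_params")
}

#' Solve the sequential two-site binding equilibrium
#'
#' Finds the unique non-negative species concentrations satisfying mass
#' action and both conservation balances for the scheme A + L = AL (Kd1),
#' AL + L = AL2 (Kd2). The free-ligand balance is strictly increasing in
#' free L, so the root is bracketed on [0, l_tot] and found by
#' [stats::uniroot()].
#'
#' @param a_tot,l_tot Total acceptor and ligand concentrations in molar.
#' @param kd1,kd2 Sequential dissociation constants in molar.
#' @param tol Relative root tolerance on free ligand.
#' @return A list of class `species_state` with elements `conc_A`, `conc_L`,
#'   `conc_AL`, `conc_AL2` (molar).
#' @export
solve_equilibrium <- function(a_tot, l_tot, kd1, kd2, tol = 1e-12) {
  if (a_tot < 0 || l_tot < 0) stop("total concentrations must be >= 0")
  if (kd1 <= 0 || kd2 <= 0) stop("dissociation constants must be positive")
  state <- function(L) {
    A <- a_tot / (1 + L / kd1 + L^2 / (kd1 * kd2))
    AL <- A * L / kd1
    AL2 <- AL * L / kd2
    list(conc_A = A, conc_L = L, conc_AL = AL, conc_AL2 = AL2)
  }
  if (l_tot == 0 || a_tot == 0) {
    out <- state(l_tot)
  } else {
    g <- function(L) {
      st <- state(L)
      L + st$conc_AL + 2 * st$conc_AL2 - l_tot
    }
    L <- stats::uniroot(g, c(0, l_tot), tol = tol * max(l_tot, 1e-30))$root
    # Newton polish to machine precision (g is smooth and increasing)
    for (i in 1:3) {
      h <- max(L, l_tot * 1e-9) * 1e-7
      dg <- (g(L + h) - g(L - h)) / (2 * h)
      if (is.finite(dg) && dg > 0) L <- min(max(L - g(L) / dg, 0), l_tot)
    }
    out <- state(L)
  }
  class(out) <- "species_state"
  out
}

#' Weight-average sedimentation coefficient of the equilibrium mixture
#'
#' Forward model for s_w titrations: the signal-weighted species average
#' `s_w = sum(w_i c_i s_i) / sum(w_i c_i)` over A, L, AL and AL2 at the
#' equilibrium set by [solve_equilibrium()]. By default free ligand signal
#' is included, matching integration of whole-mixture c(s) distributions;
#' `complex_only = TRUE` restricts the average to acceptor-containing
#' species.
#'
#' @param params A [two_site_params()] object.
#' @param a_tot,l_tot Total concentrations in molar (l_tot may be a vector).
#' @param complex_only Exclude free ligand (and free acceptor remains
#'   included) from the signal average.
#' @return Weight-average s in Svedberg (vectorized over `l_tot`).
#' @export
sw_model <- function(params, a_tot, l_tot, complex_only = FALSE) {
  w <- params$w
  if (complex_only) w["L"] <- 0
  if (all(w == 0)) stop("all signal weights are zero")
  vapply(l_tot, function(lt) {
    st <- solve_equilibrium(a_tot, lt, params$kd1, params$kd2)
    cc <- c(A = st$conc_A, L = st$conc_L, AL = st$conc_AL, AL2 = st$conc_AL2)
    sig <- w * cc
    if (sum(sig) == 0) return(unname(params$s["A"]))
    sum(sig * params$s) / sum(sig)
  }, numeric(1))
}

#' Parameters of the two-independent-site fluorescence model
#'
#' @param f0 Unliganded baseline fluorescence at 340 nm (arbitrary units).
#' @param df1,df2 Fluorescence-change amplitudes at full occupancy of the
#'   first and second site. The defaults are equal (total 1.15-fold change
#'   at saturation of both sites), reflecting the assumption that the
#'   intensity change is proportional to the fraction of complex formed.
#' @param kd1,kd2 Site dissociation constants in molar.
#' @return An object of class `fluor_params`.
#' @export
fluor_params <- function(f0 = 1, df1 = 0.075, df2 = 0.075,
                         kd1 = 690e-9, kd2 = 9.4e-6) {
  if (kd1 <= 0 || kd2 <= 0) stop("dissociation constants must be positive")
  structure(list(f0 = f0, df1 = df1, df2 = df2, kd1 = kd1, kd2 = kd2),
            class = "fluor_params")
}

# free ligand for the independent-two-site scheme with depletion:
# l_tot = L + a_tot*(theta1 + theta2), theta_i = L/(kd_i + L); strictly
# increasing in L so the root is bracketed on [0, l_tot]
.free_ligand_two_site <- function(a_tot, l_tot, kd1, kd2, tol = 1e-14) {
  if (l_tot == 0) return(0)
  g <- function(L) L + a_tot * (L / (kd1 + L) + L / (kd2 + L)) - l_tot
  stats::uniroot(g, c(0, l_tot), tol = tol * l_tot)$root
}

#' Fluorescence of a ligand binding two independent sites
#'
#' `F = f0 + df1 theta1 + df2 theta2` with `theta_i = L/(kd_i + L)` at the
#' free-ligand concentration solving the exact depletion balance
#' `l_tot = L + a_tot (theta1 + theta2)`.
#'
#' @param params A [fluor_params()] object.
#' @param a_tot Total acceptor concentration in molar.
#' @param l_tot Total ligand concentration in molar (may be a vector).
#' @return Fluorescence in the units of `f0` (vectorized over `l_tot`).
#' @export
fluor_model <- function(params, a_tot, l_tot) {
  vapply(l_tot, function(lt) {
    L <- .free_ligand_two_site(a_tot, lt, params$kd1, params$kd2)
    th1 <- L / (params$kd1 + L)
    th2 <- L / (params$kd2 + L)
    params$f0 + params$df1 * th1 + params$df2 * th2
  }, numeric(1))
}

#' Integer stoichiometry most consistent with a complex mass
#'
#' Enumerates `n_a, n_l` in `[1, max_n]` and returns the pair minimizing the
#' relative mass error `|n_a M_a + n_l M_l - M_complex| / M_complex`.
#'
#' @param mass_free_a,mass_free_l,mass_complex Masses in any common unit.
#' @param max_n Largest copy number considered per component.
#' @return A list with `n_a`, `n_l` and `rel_error`.
#' @examples
#' stoichiometry_select(61, 79, 223, 4)  # 1 APP : 2 Lf
#' @export
stoichiometry_select <- function(mass_free_a, mass_free_l, mass_complex,
                                 max_n = 4) {
  if (any(c(mass_free_a, mass_free_l, mass_complex) <= 0))
    stop("masses must be positive")
  if (max_n < 1) stop("max_n must be >= 1")
  grid <- expand.grid(n_a = 1:max_n, n_l = 1:max_n)
  err <- abs(grid$n_a * mass_free_a + grid$n_l * mass_free_l - mass_complex) /
    mass_complex
  i <- which.min(err)
  list(n_a = grid$n_a[i], n_l = grid$n_l[i], rel_error = err[i])
}
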