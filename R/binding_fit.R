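# Nonlinear weighted least-squares fitting of binding titrations, one-site
# versus two-site model comparison, and the exact Wald-Wolfowitz runs test.

#' Titration containers
#'
#' `sw_titration` holds weight-average sedimentation observations
#' (`a_tot_molar, l_tot_molar, observable, sigma` with the observable in
#' Svedberg); `fluor_titration` holds fluorescence observations in arbitrary
#' units. `sigma` is the per-point observation SD used for 1/sigma^2
#' weighting.
#'
#' @param a_tot,l_tot Total concentrations in molar.
#' @param observable Observed s_w (Svedberg) or fluorescence (units of f0).
#' @param sigma Per-point SD, same units as the observable.
#' @return A data.frame of class `sw_titration` or `fluor_titration`.
#' @export
sw_titration <- function(a_tot, l_tot, observable, sigma) {
  .titration(a_tot, l_tot, observable, sigma, "sw_titration")
}

#' @rdname sw_titration
#' @export
fluor_titration <- function(a_tot, l_tot, observable, sigma) {
  .titration(a_tot, l_tot, observable, sigma, "fluor_titration")
}

.titration <- function(a_tot, l_tot, observable, sigma, cls) {
  if (any(a_tot < 0) || any(l_tot < 0)) stop("totals must be >= 0")
  if (any(sigma <= 0)) stop("sigma must be positive")
  d <- data.frame(a_tot_molar = a_tot, l_tot_molar = l_tot,
                  observable = observable, sigma = sigma)
  class(d) <- c(cls, "data.frame")
  d
}

#' Read a titration CSV
#'
#' Columns `a_tot_molar, l_tot_molar, observable, sigma` are mandatory.
#'
#' @param path File path.
#' @param type `"sw"` or `"fluorescence"`.
#' @export
read_titration <- function(path, type = c("sw", "fluorescence")) {
  type <- match.arg(type)
  d <- utils::read.csv(path)
  need <- c("a_tot_molar", "l_tot_molar", "observable", "sigma")
  if (!all(need %in% names(d)))
    stop("titration CSV must have columns: ", paste(need, collapse = ", "))
  if (type == "sw")
    sw_titration(d$a_tot_molar, d$l_tot_molar, d$observable, d$sigma)
  else
    fluor_titration(d$a_tot_molar, d$l_tot_molar, d$observable, d$sigma)
}

# model evaluators ----------------------------------------------------------

# sw: one-site realised as the sequential scheme with the second site
# switched off (kd2 effectively infinite, no AL2 signal)
.sw_eval <- function(kds, data, fixed) {
  defaults <- two_site_params()
  sv <- fixed$s %||% defaults$s
  wv <- fixed$w %||% defaults$w
  if (length(kds) == 1) {
    p <- two_site_params(kd1 = kds[1], kd2 = 1e9,
                         s_A = sv["A"], s_L = sv["L"], s_AL = sv["AL"],
                         s_AL2 = sv["AL2"],
                         w_A = wv["A"], w_L = wv["L"], w_AL = wv["AL"],
                         w_AL2 = 0)
  } else {
    p <- two_site_params(kd1 = kds[1], kd2 = kds[2],
                         s_A = sv["A"], s_L = sv["L"], s_AL = sv["AL"],
                         s_AL2 = sv["AL2"],
                         w_A = wv["A"], w_L = wv["L"], w_AL = wv["AL"],
                         w_AL2 = wv["AL2"])
  }
  mapply(function(a, l) sw_model(p, a, l), data$a_tot_molar, data$l_tot_molar)
}

# fluorescence: occupancies for given kds; baseline/amplitudes are linear
# and profiled out by weighted least squares (variable projection). With
# tied amplitudes the change is proportional to total fractional occupancy
# (equal signal per site), collapsing the two amplitudes into one.
.fluor_design <- function(kds, data, tied = FALSE) {
  th <- t(mapply(function(a, l) {
    if (length(kds) == 1) {
      L <- .free_ligand_two_site(a, l, kds[1], 1e9)
      c(1, L / (kds[1] + L))
    } else {
      L <- .free_ligand_two_site(a, l, kds[1], kds[2])
      th1 <- L / (kds[1] + L); th2 <- L / (kds[2] + L)
      if (tied) c(1, th1 + th2) else c(1, th1, th2)
    }
  }, data$a_tot_molar, data$l_tot_molar))
  th
}

.fluor_eval <- function(kds, data, return_linear = FALSE, tied = FALSE) {
  X <- .fluor_design(kds, data, tied = tied)
  wts <- 1 / data$sigma^2
  fit <- stats::lm.wfit(X, data$observable, wts)
  beta <- fit$coefficients
  beta[is.na(beta)] <- 0
  pred <- drop(X %*% beta)
  if (return_linear) list(pred = pred, beta = beta) else pred
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a binding model to a titration
#'
#' Weighted (1/sigma^2) least squares via the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]) over log10-transformed dissociation constants,
#' started from `n_starts` log-uniform random points in [1 nM, 1 mM]; the
#' best converged start is returned. For sedimentation data the observable
#' is the signal-weighted species average ([sw_model()]) with species s
#' values and signal weights fixed (overridable via `fixed$s` / `fixed$w`,
#' named vectors over A, L, AL, AL2); the one-site model is the same scheme
#' with the second binding event switched off. For fluorescence data the
#' baseline and amplitudes are linear and profiled out exactly at each Kd
#' evaluation.
#'
#' @param data An `sw_titration` or `fluor_titration`.
#' @param model_tag `"one-site"` or `"two-site"`.
#' @param fixed Optional list of fixed quantities (`s`, `w` for sw data).
#' @param n_starts Number of random multi-starts (>= 1).
#' @param seed RNG seed controlling the starts; identical seeds give
#'   bit-identical results.
#' @param kd_bounds Length-2 search bounds for the dissociation constants in
#'   molar (starts are drawn log-uniformly within them).
#' @param tie_amplitudes Fluorescence two-site fits only: assume the
#'   fluorescence change is proportional to total fractional occupancy
#'   (equal amplitude per site), estimating a single `df_per_site` instead
#'   of `df1`, `df2`. This reflects the common assumption that the signal
#'   change reports the fraction of complex formed, and greatly improves
#'   the identifiability of the weak site.
#' @return A list of class `fit_result`: `model_tag`, `estimates` (named,
#'   Kds in molar; fluorescence fits also include `f0`, `df1`, `df2`),
#'   `stderr` (delta-method approximate, present when converged),
#'   `r_squared` (1 - SS_res/SS_tot on the raw observable), `residuals`
#'   (observed - fitted), `fitted`, `converged`, `n_starts_used`, `data`.
#' @export
fit_binding <- function(data, model_tag = c("two-site", "one-site"),
                        fixed = list(), n_starts = 32, seed = 20210816,
                        kd_bounds = c(1e-9, 1e-3), tie_amplitudes = FALSE) {
  model_tag <- match.arg(model_tag)
  if (n_starts < 1) stop("n_starts must be >= 1")
  obs <- data$observable
  if (stats::var(obs) == 0) stop("degenerate data: observable has zero variance")
  is_fluor <- inherits(data, "fluor_titration")
  n_kd <- if (model_tag == "two-site") 2L else 1L
  n_par <- n_kd + if (is_fluor) n_kd + 1L else 0L
  if (nrow(data) < n_par + 1) stop("need at least free parameters + 1 points")

  wts <- 1 / data$sigma
  resid_fn <- function(logkd) {
    kds <- 10^logkd
    pred <- if (is_fluor) .fluor_eval(kds, data, tied = tie_amplitudes)
      else .sw_eval(kds, data, fixed)
    (obs - pred) * wts
  }

  set.seed(seed)
  lb <- log10(kd_bounds[1]); ub <- log10(kd_bounds[2])
  starts <- matrix(stats::runif(n_starts * n_kd, lb, ub), ncol = n_kd)
  best <- NULL
  for (i in seq_len(n_starts)) {
    fit <- try(minpack.lm::nls.lm(
      par = starts[i, ], fn = resid_fn,
      lower = rep(lb, n_kd), upper = rep(ub, n_kd),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(model_tag = model_tag, estimates = NULL,
                          stderr = NULL, r_squared = NA_real_,
                          residuals = NULL, fitted = NULL, converged = FALSE,
                          n_starts_used = n_starts, data = data),
                     class = "fit_result"))
  }
  converged <- best$info %in% 1:3
  kds <- 10^best$par
  names(kds) <- c("kd1", "kd2")[seq_len(n_kd)]
  if (is_fluor) {
    # the two independent sites are exchangeable: canonicalize kd1 <= kd2
    if (n_kd == 2 && kds[1] > kds[2]) {
      kds <- kds[c(2, 1)]; names(kds) <- c("kd1", "kd2")
      best$par <- rev(best$par)
      best$hessian <- best$hessian[c(2, 1), c(2, 1)]
    }
    fl <- .fluor_eval(kds, data, return_linear = TRUE,
                      tied = tie_amplitudes)
    pred <- fl$pred
    lin <- fl$beta
    names(lin) <- if (tie_amplitudes && n_kd == 2) c("f0", "df_per_site")
      else c("f0", "df1", "df2")[seq_along(lin)]
    estimates <- c(as.list(kds), as.list(lin))
  } else {
    pred <- .sw_eval(kds, data, fixed)
    estimates <- as.list(kds)
  }
  res <- obs - pred
  r2 <- 1 - sum(res^2) / sum((obs - mean(obs))^2)

  stderr <- NULL
  if (converged) {
    dof <- nrow(data) - n_par
    cov_try <- try({
      s2 <- best$deviance / max(dof, 1)
      covm <- s2 * solve(best$hessian)
      se_log <- sqrt(pmax(diag(covm), 0))
      se_kd <- kds * log(10) * se_log
      names(se_kd) <- names(kds)
      as.list(se_kd)
    }, silent = TRUE)
    if (!inherits(cov_try, "try-error")) stderr <- cov_try
  }

  structure(list(model_tag = model_tag, estimates = estimates,
                 stderr = stderr, r_squared = r2, residuals = res,
                 fitted = pred, converged = converged,
                 n_starts_used = n_starts, data = data),
            class = "fit_result")
}

#' Exact Wald-Wolfowitz runs test on residual signs
#'
#' Tests whether a sign sequence has fewer runs than expected under random
#' arrangement (systematic, non-random residuals give few runs). The
#' p-value is the exact lower tail P(R <= r_obs) from the combinatorial
#' runs distribution conditional on the sign counts.
#'
#' @param x Numeric residuals (zeros dropped) or a +/-1 sign vector.
#' @return A list with `runs`, `n_pos`, `n_neg`, `p_value`.
#' @export
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0); n2 <- sum(s < 0); n <- n1 + n2
  if (n1 == 0 || n2 == 0)
    return(list(runs = 1L, n_pos = n1, n_neg = n2, p_value = 1))
  r_obs <- 1L + sum(diff(s) != 0)
  p_r <- function(r) {
    if (r %% 2 == 0) {
      k <- r / 2
      2 * choose(n1 - 1, k - 1) * choose(n2 - 1, k - 1) / choose(n, n1)
    } else {
      k <- (r - 1) / 2
      (choose(n1 - 1, k - 1) * choose(n2 - 1, k) +
         choose(n1 - 1, k) * choose(n2 - 1, k - 1)) / choose(n, n1)
    }
  }
  p <- sum(vapply(2:r_obs, p_r, numeric(1)))
  list(runs = r_obs, n_pos = n1, n_neg = n2, p_value = min(p, 1))
}

#' Compare one-site and two-site fits of the same titration
#'
#' Reports the R-squared difference, exact runs-test p-values on each fit's
#' residual signs, and the small-sample-corrected information criterion
#' (AICc, computed from the weighted residual sum of squares) difference;
#' the preferred model has the lower AICc.
#'
#' @param fit_one,fit_two `fit_result` objects for the one-site and two-site
#'   models fitted to identical data.
#' @return A list of class `model_comparison` with `delta_r2`
#'   (two-site minus one-site), `runs_p_one`, `runs_p_two`, `aicc_one`,
#'   `aicc_two`, `delta_aicc` and `preferred`.
#' @export
compare_models <- function(fit_one, fit_two) {
  if (!isTRUE(all.equal(as.data.frame(fit_one$data),
                        as.data.frame(fit_two$data))))
    stop("fits were not performed on identical data")
  n <- nrow(fit_one$data)
  aicc <- function(fit) {
    k <- length(fit$estimates) + 1  # + residual variance
    wrss <- sum((fit$residuals / fit$data$sigma)^2)
    n * log(wrss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  }
  a1 <- aicc(fit_one); a2 <- aicc(fit_two)
  dr2 <- fit_two$r_squared - fit_one$r_squared
  preferred <- if (abs(a2 - a1) < 1e-12 && abs(dr2) < 1e-12) "none"
    else if (a2 < a1) fit_two$model_tag else fit_one$model_tag
  structure(list(delta_r2 = dr2,
                 runs_p_one = runs_test(fit_one$residuals)$p_value,
                 runs_p_two = runs_test(fit_two$residuals)$p_value,
                 aicc_one = a1, aicc_two = a2, delta_aicc = a2 - a1,
                 preferred = preferred),
            class = "model_comparison")
}

#' Write a fit report as JSON
#'
#' @param fit A `fit_result`.
#' @param path Output path.
#' @export
write_fit_report <- function(fit, path) {
  rep <- list(model_tag = fit$model_tag, estimates = fit$estimates,
              stderr = fit$stderr, r_squared = fit$r_squared,
              residuals = fit$residuals, converged = fit$converged,
              n_starts_used = fit$n_starts_used)
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
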