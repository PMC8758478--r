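# All-relevant feature selection: shadow-feature (Boruta) wrapper around
# random-forest permutation importances, with exact binomial hit testing,
# plus the feature-selection-versus-DEA rank comparison.

#' Random-forest permutation importance
#'
#' Out-of-bag permutation importance (mean decrease in accuracy for
#' classification, mean increase in squared error for regression) from a
#' random-forest ensemble (ranger). Deterministic given the seed.
#'
#' @param x Feature matrix, features x samples (expression convention), or
#'   samples x features with `features_in_rows = FALSE`.
#' @param y Labels: a factor/two-level vector (classification) or numeric
#'   vector (regression).
#' @param task `"classify"` or `"regress"`.
#' @param n_trees Trees per forest.
#' @param seed RNG seed.
#' @param features_in_rows Whether `x` has features as rows.
#' @return Named numeric importance per feature.
#' @export
ensemble_importance <- function(x, y, task = c("classify", "regress"),
                                n_trees = 300, seed = 1,
                                features_in_rows = TRUE) {
  task <- match.arg(task)
  xm <- if (features_in_rows) t(x) else as.matrix(x)
  if (nrow(xm) < 10) stop("need at least 10 samples")
  if (length(unique(y)) < 2) stop("labels are constant")
  y <- if (task == "classify") factor(y) else as.numeric(y)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  fit <- ranger::ranger(x = xm, y = y, num.trees = n_trees,
                        importance = "permutation", num.threads = 1,
                        seed = seed)
  fit$variable.importance
}

#' Minimum hit count for a Boruta decision
#'
#' Smallest number of hits in `n_runs` shadow comparisons for which the
#' upper binomial tail `P(X >= k | n_runs, 1/2)` falls at or below the
#' Bonferroni-corrected level `alpha / m`.
#'
#' @param n_runs Number of completed runs.
#' @param alpha Nominal level.
#' @param m Number of features over which the correction is applied.
#' @return Integer hit count (may exceed `n_runs` when no decision is
#'   possible yet).
#' @export
boruta_min_hits <- function(n_runs, alpha = 0.05, m = 1) {
  thr <- alpha / m
  k <- match(TRUE, stats::pbinom(0:n_runs - 1, n_runs, 0.5,
                                 lower.tail = FALSE) <= thr)
  if (is.na(k)) n_runs + 1L else k - 1L
}

#' Boruta shadow-feature selection
#'
#' Each run appends independently permuted shadow copies of the surviving
#' real features, fits a random forest, and scores a hit for each undecided
#' feature whose permutation importance exceeds the maximum shadow
#' importance. After each run, two-sided binomial tests against
#' Binomial(n_runs, 1/2) with Bonferroni correction over the starting
#' feature count confirm (upper tail) or reject (lower tail) features;
#' rejected features leave the pool. Iteration stops when every feature is
#' decided or `max_runs` is reached.
#'
#' By default (`shadow_scheme = "full"`) the number of shadows is held at
#' the starting feature count throughout, drawing extra permuted copies of
#' surviving features as the pool shrinks. This keeps the null contest --
#' the maximum over shadow importances that a feature must beat -- at
#' constant strength: if shadows shrink with the pool (the original scheme,
#' available as `shadow_scheme = "pool"`, minimum 5 shadows), features that
#' are correlated with the labels purely by chance face an ever-weaker
#' maximum once the bulk of features has been rejected, and accumulate hits
#' toward spurious confirmation on small samples.
#'
#' Two Z-scores are reported per feature: `z_history`, the mean of the
#' feature's own importance history divided by its SD, and `z_population`,
#' the feature's mean importance standardized against the across-feature
#' distribution of mean importances.
#'
#' @param x Feature matrix, features x samples (see
#'   [ensemble_importance()]).
#' @param y Labels (factor for classification, numeric for regression).
#' @param task `"classify"` or `"regress"`.
#' @param max_runs Maximum number of runs (>= 10).
#' @param alpha Nominal level of the binomial decision tests.
#' @param n_trees Trees per forest.
#' @param seed Base seed; run r uses seed + r.
#' @param features_in_rows Whether `x` has features as rows.
#' @param shadow_scheme `"full"` keeps the shadow ensemble at the starting
#'   feature count every run (default); `"pool"` uses one shadow per
#'   surviving feature (minimum 5).
#' @return A data.frame of class `boruta_decision` with columns `feature`,
#'   `status` (confirmed/tentative/rejected), `hits`, `n_runs`,
#'   `z_history`, `z_population`, `rank` (descending `z_history`);
#'   the per-run importance history is attached as attribute
#'   `importance_history` (runs x features, NA once a feature left the
#'   pool).
#' @export
boruta_select <- function(x, y, task = c("classify", "regress"),
                          max_runs = 100, alpha = 0.01, n_trees = 300,
                          seed = 1, features_in_rows = TRUE,
                          shadow_scheme = c("full", "pool")) {
  task <- match.arg(task)
  shadow_scheme <- match.arg(shadow_scheme)
  if (max_runs < 10) stop("max_runs must be >= 10")
  xm <- if (features_in_rows) t(x) else as.matrix(x)
  if (is.null(colnames(xm))) colnames(xm) <- paste0("f", seq_len(ncol(xm)))
  feats <- colnames(xm)
  m0 <- length(feats)
  ns <- nrow(xm)
  status <- stats::setNames(rep("tentative", m0), feats)
  hits <- stats::setNames(rep(0L, m0), feats)
  nrun <- stats::setNames(rep(0L, m0), feats)
  history <- matrix(NA_real_, max_runs, m0, dimnames = list(NULL, feats))

  run <- 0L
  while (run < max_runs && any(status == "tentative")) {
    run <- run + 1L
    set.seed(seed + run)
    pool <- feats[status != "rejected"]
    n_shadow <- if (shadow_scheme == "full") m0 else max(5, length(pool))
    shadow_src <- pool
    if (length(shadow_src) < n_shadow)
      shadow_src <- c(shadow_src,
                      sample(pool, n_shadow - length(shadow_src),
                             replace = TRUE))
    shadows <- vapply(shadow_src, function(f) xm[sample.int(ns), f],
                      numeric(ns))
    colnames(shadows) <- paste0(".shadow", seq_along(shadow_src))
    imp <- ensemble_importance(cbind(xm[, pool, drop = FALSE], shadows), y,
                               task, n_trees = n_trees, seed = seed + run,
                               features_in_rows = FALSE)
    shadow_max <- max(imp[grep("^\\.shadow", names(imp))])
    real_imp <- imp[pool]
    history[run, pool] <- real_imp

    und <- pool[status[pool] == "tentative"]
    hits[und] <- hits[und] + (real_imp[und] > shadow_max)
    nrun[und] <- nrun[und] + 1L
    up <- stats::pbinom(hits[und] - 1, nrun[und], 0.5, lower.tail = FALSE)
    lo <- stats::pbinom(hits[und], nrun[und], 0.5)
    status[und][up <= alpha / m0] <- "confirmed"
    status[und][lo <= alpha / m0] <- "rejected"
  }
  if (all(status == "tentative") && run >= max_runs)
    warning("max_runs too small for any decision at this alpha and ",
            "feature count; all features tentative")

  history <- history[seq_len(run), , drop = FALSE]
  mean_imp <- colMeans(history, na.rm = TRUE)
  sd_imp <- apply(history, 2, stats::sd, na.rm = TRUE)
  z_hist <- mean_imp / sd_imp
  z_hist[!is.finite(z_hist)] <- 0
  z_pop <- (mean_imp - mean(mean_imp, na.rm = TRUE)) /
    stats::sd(mean_imp, na.rm = TRUE)
  rank_ <- integer(m0)
  rank_[order(-z_hist, -mean_imp)] <- seq_len(m0)
  out <- data.frame(feature = feats, status = unname(status),
                    hits = unname(hits), n_runs = unname(nrun),
                    z_history = unname(z_hist), z_population = unname(z_pop),
                    rank = rank_, stringsAsFactors = FALSE)
  class(out) <- c("boruta_decision", "data.frame")
  attr(out, "importance_history") <- history
  attr(out, "alpha") <- alpha
  attr(out, "total_runs") <- run
  out
}

#' Boruta regression on a continuous pathology burden
#'
#' [boruta_select()] with `task = "regress"`; provided as the named entry
#' point for predicting a quantitative pathology measure (e.g. areal
#' fraction of immunopositive amyloid) from expression.
#'
#' @inheritParams boruta_select
#' @param burden Continuous outcome per sample.
#' @return A `boruta_decision` data.frame.
#' @export
boruta_regress_pathology <- function(x, burden, max_runs = 100, alpha = 0.01,
                                     n_trees = 300, seed = 1,
                                     features_in_rows = TRUE,
                                     shadow_scheme = c("full", "pool")) {
  boruta_select(x, burden, task = "regress", max_runs = max_runs,
                alpha = alpha, n_trees = n_trees, seed = seed,
                features_in_rows = features_in_rows,
                shadow_scheme = shadow_scheme)
}

#' Compare Boruta and DEA rankings of the same gene universe
#'
#' Ranks features by Boruta `z_history` (descending) and genes by DEA FDR
#' (ascending, ties by p-value), reports the overlap of the confirmed set
#' with the FDR < `fdr_cutoff` DEG set and with the top `top_k` of each
#' ranking, and a per-gene divergence score `dea_rank - boruta_rank`
#' (positive = feature selection ranks the gene better than DEA). When the
#' expression matrix and group labels are supplied, an outlier-sensitivity
#' table reports, for each confirmed feature, the fraction of its
#' opposite-group (control) signal carried by the top 4 samples.
#'
#' @param boruta A `boruta_decision` from [boruta_select()].
#' @param dea A `dea_result` from [nb_dea()].
#' @param top_k Cutoff for top-k overlap counting.
#' @param fdr_cutoff DEG threshold.
#' @param x Optional expression matrix (features x samples) for the
#'   outlier-sensitivity table.
#' @param group Optional group labels aligned to the columns of `x`.
#' @return A list of class `rank_comparison`: `table` (per-gene ranks and
#'   divergence), `n_confirmed`, `n_deg`, `overlap_confirmed_deg`,
#'   `overlap_top_k`, and optionally `outlier_sensitivity`.
#' @export
compare_rankings <- function(boruta, dea, top_k = 10, fdr_cutoff = 0.05,
                             x = NULL, group = NULL) {
  common <- intersect(boruta$feature, dea$gene_id)
  if (length(common) == 0) stop("disjoint gene universes")
  b <- boruta[match(common, boruta$feature), ]
  d <- dea[match(common, dea$gene_id), ]
  brank <- integer(length(common))
  brank[order(-b$z_history)] <- seq_along(common)
  drank <- integer(length(common))
  drank[order(d$fdr, d$pvalue)] <- seq_along(common)
  tab <- data.frame(feature = common, status = b$status,
                    boruta_rank = brank, dea_rank = drank,
                    z_history = b$z_history, fdr = d$fdr,
                    divergence = drank - brank, stringsAsFactors = FALSE)
  tab <- tab[order(tab$boruta_rank), ]
  conf <- tab$feature[tab$status == "confirmed"]
  deg <- tab$feature[tab$fdr < fdr_cutoff]
  out <- list(table = tab, n_confirmed = length(conf), n_deg = length(deg),
              overlap_confirmed_deg = length(intersect(conf, deg)),
              overlap_top_k = length(intersect(
                tab$feature[tab$boruta_rank <= top_k],
                tab$feature[tab$dea_rank <= top_k])))
  if (!is.null(x) && !is.null(group)) {
    grp <- as.character(group)
    ctrl <- grp == "control"
    out$outlier_sensitivity <- data.frame(
      feature = conf,
      control_top4_share = vapply(conf, function(f)
        top_k_share(x[f, ctrl], 4), numeric(1)),
      stringsAsFactors = FALSE)
  }
  class(out) <- "rank_comparison"
  out
}
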