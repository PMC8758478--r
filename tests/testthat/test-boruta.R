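.noise_fixture <- function(m = 100, n = 60, seed = 1) {
  set.seed(seed)
  x <- matrix(rnorm(m * n), m, n,
              dimnames = list(paste0("g", seq_len(m)),
                              paste0("s", seq_len(n))))
  y <- factor(rep(c("a", "b"), length.out = n))
  list(x = x, y = y)
}

.planted_fixture <- function(m = 100, n = 60, effect = 1.5, seed = 1) {
  f <- .noise_fixture(m, n, seed)
  f$x["g1", f$y == "b"] <- f$x["g1", f$y == "b"] + effect
  f
}

test_that("a label-copy feature dominates the importances, deterministically", {
  f <- .noise_fixture(20, 40, seed = 2)
  f$x["g5", ] <- as.numeric(f$y == "b")
  imp1 <- ensemble_importance(f$x, f$y, "classify", n_trees = 100, seed = 9)
  imp2 <- ensemble_importance(f$x, f$y, "classify", n_trees = 100, seed = 9)
  expect_identical(imp1, imp2)
  expect_equal(names(which.max(imp1)), "g5")
})

test_that("importances of label-independent features centre on zero", {
  f <- .noise_fixture(50, 60, seed = 3)
  imp <- ensemble_importance(f$x, f$y, "classify", n_trees = 200, seed = 1)
  # sign-flip null: importances should straddle 0
  expect_lt(abs(mean(imp)) / stats::sd(imp), 1)
  expect_error(ensemble_importance(f$x, rep("a", 60), "classify"),
               "constant")
})

test_that("the binomial decision threshold matches exact enumeration", {
  # smallest k with P(X >= k | 20 runs, 1/2) <= 0.05/500
  expect_identical(boruta_min_hits(20, 0.05, 500), 19L)
  expect_equal(stats::pbinom(18, 20, 0.5, lower.tail = FALSE), 21 / 2^20)
  expect_gt(stats::pbinom(17, 20, 0.5, lower.tail = FALSE), 0.05 / 500)
  # and no decision is possible with too few runs
  expect_gt(boruta_min_hits(10, 0.05, 500), 10)
})

test_that("pure-noise features are rejected, not confirmed", {
  confirmed <- integer(0)
  for (s in 1:5) {
    f <- .noise_fixture(100, 60, seed = 10 + s)
    dec <- boruta_select(f$x, f$y, "classify", max_runs = 40,
                         n_trees = 100, seed = 10 + s)
    confirmed <- c(confirmed, sum(dec$status == "confirmed"))
    expect_true(all(dec$hits <= dec$n_runs))
  }
  expect_true(all(confirmed == 0))
})

test_that("a strongly informative feature is confirmed with the top z-score", {
  ok <- 0
  for (s in 1:5) {
    f <- .planted_fixture(100, 60, effect = 1.5, seed = 20 + s)
    dec <- boruta_select(f$x, f$y, "classify", max_runs = 40,
                         n_trees = 100, seed = 20 + s)
    row <- dec[dec$feature == "g1", ]
    if (row$status == "confirmed" && row$rank == 1) ok <- ok + 1
  }
  expect_gte(ok, 4)
})

test_that("confirmation frequency is monotone in effect size", {
  freq <- sapply(c(0.4, 1.6), function(eff) {
    mean(sapply(1:5, function(s) {
      f <- .planted_fixture(60, 60, effect = eff, seed = 40 + s)
      dec <- boruta_select(f$x, f$y, "classify", max_runs = 30,
                           n_trees = 100, seed = 40 + s)
      dec$status[dec$feature == "g1"] == "confirmed"
    }))
  })
  expect_lte(freq[1], freq[2])
  expect_equal(freq[2], 1)
})

test_that("regression mode confirms a linear driver and not its permutation", {
  set.seed(55)
  f <- .noise_fixture(60, 60, seed = 55)
  burden <- 2 * f$x["g1", ] + rnorm(60, 0, 2)  # R^2 = 0.5
  dec <- boruta_regress_pathology(f$x, burden, max_runs = 30, n_trees = 150,
                                  seed = 55)
  expect_equal(dec$status[dec$feature == "g1"], "confirmed")
  expect_equal(dec$rank[dec$feature == "g1"], 1L)
  # permuting the outcome destroys the confirmation
  dec0 <- boruta_regress_pathology(f$x, sample(burden), max_runs = 30,
                                   n_trees = 150, seed = 56)
  expect_true(dec0$status[dec0$feature == "g1"] != "confirmed")
})

test_that("single-run shadow hit rate matches the max-order-statistic null", {
  # with k shadows, a noise feature beats the max of k exchangeable shadows
  # with probability 1/(k+1); check empirically over independent runs
  set.seed(77)
  k <- 20; reps <- 4000
  hit <- replicate(reps, {
    vals <- rnorm(k + 1)
    vals[1] > max(vals[-1])
  })
  expect_equal(mean(hit), 1 / (k + 1), tolerance = 0.2)
})

test_that("rank comparison counts overlaps and flags the toy divergence", {
  bor <- data.frame(feature = paste0("g", 1:10),
                    status = c(rep("confirmed", 3), rep("rejected", 7)),
                    hits = 0L, n_runs = 10L,
                    z_history = 10:1, z_population = 10:1,
                    rank = 1:10, stringsAsFactors = FALSE)
  class(bor) <- c("boruta_decision", "data.frame")
  dea <- data.frame(gene_id = paste0("g", 1:10),
                    log2fc = 0, mean = 5, dispersion = 0.1,
                    pvalue = c(0.5, 0.01, 0.02, 0.03, 0.04,
                               0.2, 0.3, 0.4, 0.6, 0.7),
                    stringsAsFactors = FALSE)
  dea$fdr <- bh_adjust(dea$pvalue)
  dea$rank <- order(order(dea$fdr, dea$pvalue))
  class(dea) <- c("dea_result", "data.frame")
  cmp <- compare_rankings(bor, dea, top_k = 3)
  tab <- cmp$table
  expect_equal(tab$divergence[tab$feature == "g1"],
               tab$dea_rank[tab$feature == "g1"] - 1L)
  # g1: top of boruta, near-bottom of dea -> strongly positive divergence
  expect_gt(tab$divergence[tab$feature == "g1"], 5)
  expect_equal(cmp$n_confirmed, 3)
  expect_equal(cmp$overlap_top_k, length(intersect(
    tab$feature[tab$boruta_rank <= 3], tab$feature[tab$dea_rank <= 3])))
  # identical rankings give zero divergence everywhere
  dea2 <- dea; dea2$pvalue <- seq(0.01, 0.1, length.out = 10)
  dea2$fdr <- bh_adjust(dea2$pvalue)
  dea2$rank <- order(order(dea2$fdr, dea2$pvalue))
  cmp2 <- compare_rankings(bor, dea2)
  expect_true(all(cmp2$table$divergence == 0))
  expect_error(compare_rankings(bor, transform(dea, gene_id = paste0("x", 1:10))),
               "disjoint")
})
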