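.toy_meta <- function(n_case, n_control, batches = 1) {
  n <- n_case + n_control
  data.frame(sample_id = sprintf("s%02d", 1:n),
             group = rep(c("case", "control"), c(n_case, n_control)),
             batch = factor(rep_len(seq_len(batches), n)),
             age = seq(70, 90, length.out = n),
             sex = rep_len(c("F", "M"), n),
             rin = 6 + (seq_len(n) * 7) %% 5 / 2,  # not affine in age
             study = rep_len(c("ROS", "MAP", "MAP"), n))
}

test_that("pure depth differences leave TMM factors equal", {
  set.seed(1)
  a <- rpois(500, 60)
  counts <- cbind(A = a, B = 2L * a, C = a)
  f <- tmm_factors(counts)
  expect_equal(as.numeric(f), rep(1, 3), tolerance = 1e-10)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
})

test_that("identical samples give unit factors", {
  counts <- matrix(rep(rpois(200, 40), 4), ncol = 4,
                   dimnames = list(NULL, paste0("s", 1:4)))
  expect_equal(as.numeric(tmm_factors(counts)), rep(1, 4))
})

test_that("a composition outlier shifts the factor as the trimmed mean says", {
  # 20-gene toy: sample B has one gene (5%) 8-fold up, all else identical
  set.seed(42)
  a <- rpois(20, 100) + 10L
  b <- a; b[1] <- a[1] * 8L
  counts <- cbind(A = a, B = b)
  f <- tmm_factors(counts)

  # independent hand computation of the trimmed weighted mean of M-values
  libA <- sum(a); libB <- sum(b)
  M <- log2((b / libB) / (a / libA))
  A_ <- 0.5 * log2((b / libB) * (a / libA))
  w <- (libA - a) / (libA * a) + (libB - b) / (libB * b)
  keepM <- rank(M) > 0.3 * 20 & rank(M) <= 0.7 * 20
  keepA <- rank(A_) > 0.05 * 20 & rank(A_) <= 0.95 * 20
  keep <- keepM & keepA
  fB_raw <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  centred <- fB_raw / sqrt(fB_raw)  # geometric-mean centering of c(1, fB)
  expect_equal(unname(f["B"]), centred, tolerance = 1e-6)
  # the sample with the high-count outlier gets a factor below 1: its
  # effective library is enlarged by the composition bias
  expect_lt(f["B"], 1)
  expect_gt(f["A"], 1)
})

test_that("TMM errors on zero libraries", {
  counts <- cbind(A = c(5L, 0L), B = c(0L, 0L))
  expect_error(tmm_factors(counts), "zero library")
})

test_that("log_cpm arithmetic matches hand computation", {
  counts <- matrix(c(0, 10, 100, 5, 50, 500, 1, 2, 3), 3, 3,
                   dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  lc <- log_cpm(counts, factors = rep(1, 3), prior = 0.5)
  libs <- colSums(counts)
  byhand <- log2(sweep(counts + 0.5, 2, libs, "/") * 1e6)
  expect_equal(lc, byhand)
  # the stated single-point example: count 0, library 1e6, prior 0.5
  one <- matrix(c(0, 999999), 2, 1)
  expect_equal(log_cpm(one, prior = 0.5)[1, 1], log2(0.5), tolerance = 1e-4)
  # depth invariance for counts >= 100
  lc2 <- log_cpm(2L * counts, factors = rep(1, 3), prior = 0.5)
  expect_lt(max(abs((lc2 - lc)[counts >= 100])), 0.01)
})

test_that("BH adjustment matches the exhaustive step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")

  step_up <- function(p) {  # oracle straight from the definition
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    out <- numeric(m); out[o] <- pmin(q, 1); out
  }
  set.seed(8)
  base_p <- c(0.001, 0.02, 0.2, 0.5, 0.9)
  perms <- rbind(base_p, base_p[5:1], base_p[c(3, 1, 5, 2, 4)],
                 matrix(base_p[t(replicate(5, sample(5)))], 5, 5))
  for (i in seq_len(nrow(perms))) {
    p <- perms[i, ]
    expect_equal(bh_adjust(p), step_up(p))
    expect_true(all(bh_adjust(p) >= p))
  }
})

test_that("percent increase arithmetic", {
  expect_equal(round(percent_increase(0.5338), 1), 44.8)
  expect_equal(percent_increase(0), 0)
  expect_equal(percent_increase(1), 100)
})

test_that("identical groups give zero log fold changes", {
  set.seed(3)
  half <- matrix(rnbinom(200 * 5, mu = 50, size = 5), 200, 5)
  counts <- cbind(half, half)
  rownames(counts) <- paste0("g", 1:200)
  colnames(counts) <- paste0("s", 1:10)
  meta <- .toy_meta(5, 5)
  # mirror covariates so the design is balanced between identical halves
  meta$age <- rep(meta$age[1:5], 2); meta$rin <- rep(meta$rin[1:5], 2)
  meta$sex <- rep(meta$sex[1:5], 2); meta$study <- rep(meta$study[1:5], 2)
  meta$rin <- c(6.1, 7.3, 6.8, 7.9, 6.4)[rep(1:5, 2)]  # break collinearity
  dea <- nb_dea(counts, meta)
  expect_lt(max(abs(dea$log2fc)), 1e-6)
  expect_true(all(dea$fdr >= dea$pvalue - 1e-12))
})

test_that("DEA ranks are FDR-ordered and the design check catches aliasing", {
  sim <- simulate_counts(sim_count_config(n_genes = 300, n_case = 15,
                                          n_control = 15, seed = 4))
  dea <- nb_dea(sim$counts, sim$meta)
  expect_setequal(dea$rank, seq_len(nrow(dea)))
  expect_true(all(diff(dea$fdr[order(dea$rank)]) >= -1e-12))
  meta_bad <- sim$meta
  meta_bad$rin <- as.numeric(meta_bad$age)  # aliased covariate
  expect_error(nb_dea(sim$counts, meta_bad), "full rank")
})

test_that("a planted log2FC = 1 gene is recovered across replicates", {
  hits <- 0; reps <- 60
  for (r in seq_len(reps)) {
    set.seed(4000 + r)
    n <- 100
    counts <- matrix(rnbinom(120 * n, mu = 150, size = 1 / 0.08), 120, n)
    grp <- rep(c("control", "case"), each = 50)
    counts[1, grp == "case"] <- rnbinom(50, mu = 400, size = 1 / 0.05)
    counts[1, grp == "control"] <- rnbinom(50, mu = 200, size = 1 / 0.05)
    rownames(counts) <- paste0("g", 1:120)
    colnames(counts) <- paste0("s", 1:n)
    meta <- data.frame(sample_id = colnames(counts), group = grp,
                       batch = factor(1), age = rnorm(n, 80, 5),
                       sex = rep_len(c("F", "M"), n), rin = rnorm(n, 7, 0.5),
                       study = rep_len(c("ROS", "MAP", "MAP"), n))
    dea <- nb_dea(counts, meta)
    est <- dea$log2fc[dea$gene_id == "g001"]
    if (length(est) == 0) est <- dea$log2fc[dea$gene_id == "g1"]
    if (est >= 0.8 && est <= 1.2) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.9)
})
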