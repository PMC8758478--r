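# Parametric arm: TMM normalization, log-CPM, negative-binomial differential
# expression with covariates (via edgeR), BH adjustment and fold-change
# arithmetic.

.check_counts <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (any(counts < 0)) stop("count matrix has negative entries")
  if (any(colSums(counts) == 0))
    stop("samples with zero library size: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  counts
}

#' Drop genes with zero counts across all samples
#'
#' @param counts Genes x samples count matrix.
#' @return The filtered matrix.
#' @export
filter_expressed <- function(counts) {
  counts <- .check_counts(counts)
  counts[rowSums(counts) > 0, , drop = FALSE]
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: per-sample scaling factors computed from
#' gene-wise log-ratios against a reference sample after trimming the most
#' extreme 30% of M-values and 5% of A-values, weighting by inverse binomial
#' asymptotic variances, and centering the factors to geometric mean 1. The
#' reference is the sample whose upper-quartile count fraction is closest
#' to the mean (or a named sample). Computation is delegated to
#' edgeR's TMM implementation.
#'
#' @param counts Genes x samples count matrix.
#' @param ref_sample `"auto"` or the name/index of the reference sample.
#' @return Named numeric vector of factors (geometric mean 1), class
#'   `norm_factors`.
#' @export
tmm_factors <- function(counts, ref_sample = "auto") {
  counts <- .check_counts(counts)
  if (ncol(counts) < 2) stop("need at least 2 samples")
  ref <- NULL
  if (!identical(ref_sample, "auto")) {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1 || ref > ncol(counts))
      stop("unknown reference sample: ", ref_sample)
  }
  expressed <- counts[rowSums(counts) > 0, , drop = FALSE]
  shared <- colSums(expressed > 0)
  if (any(shared == 0))
    stop("sample(s) share no expressed genes with the reference: ",
         paste(colnames(counts)[shared == 0], collapse = ", "))
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  class(f) <- "norm_factors"
  f
}

#' Log2 counts per million with TMM-effective library sizes
#'
#' `log2((count + prior) / (library size x factor) x 1e6)`.
#'
#' @param counts Genes x samples count matrix.
#' @param factors Normalization factors from [tmm_factors()] (default: all
#'   ones).
#' @param prior Pseudo-count added to every count.
#' @return Real matrix, genes x samples.
#' @export
log_cpm <- function(counts, factors = NULL, prior = 0.5) {
  counts <- .check_counts(counts)
  if (is.null(factors)) factors <- rep(1, ncol(counts))
  eff <- colSums(counts) * as.numeric(factors)
  log2(sweep(counts + prior, 2, eff, "/") * 1e6)
}

.dea_design <- function(meta) {
  need <- c("group", "batch", "age", "sex", "rin", "study")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop("metadata lacks columns: ", paste(miss, collapse = ", "))
  covars <- c("batch", "age", "sex", "rin", "study")
  # drop single-level categorical covariates (e.g. one batch or one study)
  keep <- vapply(covars, function(v) length(unique(meta[[v]])) > 1, logical(1))
  form <- stats::as.formula(paste("~", paste(c(covars[keep], "group"),
                                             collapse = " + ")))
  design <- stats::model.matrix(form, data = meta)
  qr_ <- qr(design)
  if (qr_$rank < ncol(design)) {
    aliased <- colnames(design)[qr_$pivot[(qr_$rank + 1):ncol(design)]]
    stop("design is not full rank; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  design
}

#' Negative-binomial differential expression with covariates
#'
#' Per-gene NB log-linear model with offset `log(library size x factor)` and
#' design `~ batch + age + sex + rin + study + group` (single-level
#' covariates dropped automatically). Gene-wise dispersions are
#' adjusted-profile-likelihood estimates shrunk toward the common
#' dispersion with a configurable prior weight (default 20 prior degrees of
#' freedom, no trend), and the group coefficient is tested by
#' likelihood-ratio test; fitting is delegated to edgeR (estimateDisp,
#' glmFit, glmLRT).
#'
#' @param counts Genes x samples count matrix (all-zero genes are dropped).
#' @param meta Sample metadata with columns `group` (levels control, case),
#'   `batch`, `age`, `sex`, `rin`, `study`.
#' @param factors Optional [tmm_factors()] output; computed when `NULL`.
#' @param prior_df Prior degrees of freedom for dispersion shrinkage.
#' @return A data.frame of class `dea_result`: `gene_id`, `log2fc`
#'   (case vs control), `mean` (average log2 CPM), `dispersion` (tagwise),
#'   `pvalue`, `fdr`, `rank` (ascending FDR, ties by p-value).
#' @export
nb_dea <- function(counts, meta, factors = NULL, prior_df = 20) {
  counts <- filter_expressed(counts)
  if (nrow(meta) != ncol(counts)) stop("metadata/sample mismatch")
  meta$group <- factor(meta$group, levels = c("control", "case"))
  if (min(table(meta$group)) < 2) stop("need >= 2 samples per group")
  design <- .dea_design(meta)
  if (is.null(factors)) factors <- tmm_factors(counts)
  y <- edgeR::DGEList(counts = counts, norm.factors = as.numeric(factors))
  y <- edgeR::estimateGLMCommonDisp(y, design)
  y <- edgeR::estimateGLMTagwiseDisp(y, design, prior.df = prior_df,
                                     trend = FALSE)
  fit <- edgeR::glmFit(y, design)
  lrt <- edgeR::glmLRT(fit, coef = "groupcase")
  tab <- lrt$table
  fdr <- bh_adjust(tab$PValue)
  ord <- order(fdr, tab$PValue)
  rank_ <- integer(nrow(tab)); rank_[ord] <- seq_len(nrow(tab))
  out <- data.frame(gene_id = rownames(tab), log2fc = tab$logFC,
                    mean = tab$logCPM, dispersion = y$tagwise.dispersion,
                    pvalue = tab$PValue, fdr = fdr, rank = rank_,
                    stringsAsFactors = FALSE)
  class(out) <- c("dea_result", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rates
#'
#' Step-up adjustment via [stats::p.adjust()]; validates the input range.
#'
#' @param p_values Numeric p-values in [0, 1].
#' @return FDR values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Percent increase implied by a log2 fold change
#'
#' `100 (2^log2fc - 1)`; e.g. a 0.5338 log2 fold change is a 44.8% increase.
#'
#' @param log2fc Log2 fold change(s).
#' @return Percent change.
#' @export
percent_increase <- function(log2fc) 100 * (2^log2fc - 1)

#' Read/write count matrices and DEA tables
#'
#' Counts are TSV with genes as rows and a header of sample ids; DEA output
#' is TSV with columns `gene_id, log2fc, mean, dispersion, pvalue, fdr,
#' rank`.
#'
#' @param path File path.
#' @export
read_counts <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  .check_counts(as.matrix(d))
}

#' @rdname read_counts
#' @param counts Genes x samples matrix.
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' @rdname read_counts
#' @param dea A `dea_result` data.frame.
#' @export
write_dea <- function(dea, path) {
  utils::write.table(as.data.frame(dea), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
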