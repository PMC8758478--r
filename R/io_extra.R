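# Additional interchange formats: MatrixMarket counts and YAML simulation
# presets.

#' Read/write counts as MatrixMarket with gene/sample sidecars
#'
#' Writes `<stem>.mtx` plus `<stem>.genes.txt` and `<stem>.samples.txt`
#' (one identifier per line), the sparse interchange convention used by
#' count-matrix tooling.
#'
#' @param counts Genes x samples integer matrix.
#' @param stem Path stem (without extension).
#' @export
write_counts_mtx <- function(counts, stem) {
  m <- Matrix::Matrix(counts, sparse = TRUE)
  Matrix::writeMM(m, paste0(stem, ".mtx"))
  writeLines(rownames(counts), paste0(stem, ".genes.txt"))
  writeLines(colnames(counts), paste0(stem, ".samples.txt"))
  invisible(stem)
}

#' @rdname write_counts_mtx
#' @export
read_counts_mtx <- function(stem) {
  m <- as.matrix(Matrix::readMM(paste0(stem, ".mtx")))
  rownames(m) <- readLines(paste0(stem, ".genes.txt"))
  colnames(m) <- readLines(paste0(stem, ".samples.txt"))
  storage.mode(m) <- "integer"
  .check_counts(m)
}

#' Load a simulation preset from YAML
#'
#' Reads a configuration file (see `inst/extdata/desk.yaml` and
#' `inst/extdata/rosmap_like.yaml` for the shipped presets) into a
#' [sim_count_config()], validating the keys.
#'
#' @param path YAML file path.
#' @param seed Optional seed override.
#' @return A `sim_count_config` object.
#' @export
sim_config_from_yaml <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  known <- names(formals(sim_count_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  pair <- function(v) if (is.list(v)) unlist(v) else v
  args <- lapply(y, pair)
  if (!is.null(args$sentinel)) args$sentinel <- as.list(args$sentinel)
  if (!is.null(seed)) args$seed <- seed
  do.call(sim_count_config, args)
}
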