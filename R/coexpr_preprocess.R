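#' Aggregate single-cell counts to pseudobulk profiles
#'
#' Sums raw counts over all cells belonging to each biological sample, so
#' every sample becomes one replicate column. Total counts are conserved
#' exactly.
#'
#' @param cell_counts gene x cell count matrix (dense or `Matrix` sparse)
#'   with column names = cell ids.
#' @param cell_sample named character vector, cell id -> sample id, covering
#'   every cell in `cell_counts`.
#' @return Dense gene x sample matrix of summed counts.
#' @export
pseudobulk_aggregate <- function(cell_counts, cell_sample) {
  cells <- colnames(cell_counts)
  if (is.null(cells)) stop("cell_counts must have cell ids as column names")
  unmapped <- setdiff(cells, names(cell_sample))
  if (length(unmapped)) {
    stop("unmapped cell(s): ", paste(utils::head(unmapped, 5), collapse = ", "))
  }
  samp <- factor(cell_sample[cells])
  ind <- Matrix::sparseMatrix(i = seq_along(cells),
                              j = as.integer(samp),
                              x = 1,
                              dims = c(length(cells), nlevels(samp)))
  out <- as.matrix(cell_counts %*% ind)
  colnames(out) <- levels(samp)
  out
}

#' Normalize counts to log2 counts per million
#'
#' `log2(count / library_size * 1e6 + 1)`; the pseudocount of 1 maps zero
#' counts to zero. Values are monotone in counts within a sample and
#' invariant to scaling all counts of a sample by a constant.
#'
#' @param counts gene x sample matrix of non-negative counts.
#' @return Gene x sample log2CPM matrix.
#' @export
normalize_log2cpm <- function(counts) {
  libsize <- colSums(counts)
  if (any(libsize <= 0)) {
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[libsize <= 0], collapse = ", "))
  }
  log2(sweep(counts, 2, libsize, "/") * 1e6 + 1)
}

#' Sequential gene filtering for co-expression analysis
#'
#' Applies three filters in order: (1) remove housekeeping genes matching the
#' supplied patterns (ribosomal, mitochondrial, histone-related by default);
#' (2) remove genes below the `mad_percentile`-th percentile of median
#' absolute deviation; (3) keep the `top_n` most variable genes among the
#' remainder (variance of the log-scale values). If fewer than `top_n` genes
#' survive the upstream filters, all are kept with a warning.
#'
#' @param m gene x sample numeric matrix (log2CPM).
#' @param housekeeping_patterns regular expressions for gene names to drop.
#' @param mad_percentile percentile (0-100) of the MAD distribution below
#'   which genes are dropped.
#' @param top_n number of most-variable genes to retain.
#' @return List with `matrix` (filtered) and `report` (data frame of genes
#'   removed at each step).
#' @export
filter_genes <- function(m,
                         housekeeping_patterns = c("^Rpl", "^Rps", "^mt-",
                                                   "^Hist"),
                         mad_percentile = 10, top_n = 5000) {
  n0 <- nrow(m)
  hk <- grepl(paste(housekeeping_patterns, collapse = "|"), rownames(m))
  m1 <- m[!hk, , drop = FALSE]
  mads <- apply(m1, 1, stats::mad)
  thr <- stats::quantile(mads, mad_percentile / 100, names = FALSE)
  m2 <- m1[mads >= thr, , drop = FALSE]
  if (nrow(m2) > top_n) {
    v <- apply(m2, 1, stats::var)
    keep <- rank(-v, ties.method = "first") <= top_n
    m3 <- m2[keep, , drop = FALSE]
  } else {
    if (nrow(m2) < top_n) {
      warning(sprintf("only %d genes survive upstream filters (top_n = %d); keeping all",
                      nrow(m2), top_n))
    }
    m3 <- m2
  }
  report <- data.frame(
    step = c("input", "housekeeping", "mad", "top_variable"),
    removed = c(0L, sum(hk), nrow(m1) - nrow(m2), nrow(m2) - nrow(m3)),
    remaining = c(n0, nrow(m1), nrow(m2), nrow(m3)))
  list(matrix = m3, report = report)
}
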