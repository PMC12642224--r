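#' Motif usage matrix (animals x motifs)
#'
#' Fraction of frames each animal spends in each motif; rows sum to 1.
#'
#' @param sequences list of [motif_sequence()] objects.
#' @param motifs optional common motif vocabulary (column order); defaults to
#'   the sorted union of observed motifs.
#' @return Numeric matrix, one row per animal (rownames = animal ids), one
#'   column per motif, with attribute `genotype` (per-row genotype labels).
#' @export
motif_usage <- function(sequences, motifs = NULL) {
  if (length(sequences) == 0) stop("no sequences")
  for (s in sequences) if (length(s$labels) == 0) stop("empty sequence")
  if (is.null(motifs)) {
    motifs <- sort(unique(unlist(lapply(sequences, `[[`, "labels"))))
  }
  usage <- t(vapply(sequences, function(s) {
    tab <- table(factor(s$labels, levels = motifs))
    as.numeric(tab) / length(s$labels)
  }, numeric(length(motifs))))
  dimnames(usage) <- list(vapply(sequences, `[[`, character(1), "animal_id"),
                          motifs)
  attr(usage, "genotype") <- vapply(sequences, `[[`, character(1),
                                    "genotype_label")
  usage
}

#' Correlation-based dissimilarity of motif-usage profiles
#'
#' Pairwise dissimilarity is one minus the Pearson correlation between usage
#' profiles (range `[0, 2]`, self-dissimilarity 0); the per-animal reference
#' dissimilarity is 1 - r against the WT group-mean profile. Zero-variance
#' profiles are flagged and excluded from the pairwise matrix.
#'
#' @param usage animals x motifs usage matrix ([motif_usage()]).
#' @param wt_mean_profile reference profile (e.g. WT group mean usage).
#' @return List with `dissimilarity` (square matrix over non-flagged
#'   animals), `wt_dissimilarity` (named vector, all animals; `NA` when
#'   flagged), and `flagged` (animal ids with zero-variance profiles).
#' @export
usage_dissimilarity <- function(usage, wt_mean_profile) {
  stopifnot(ncol(usage) == length(wt_mean_profile))
  v <- apply(usage, 1, stats::var)
  flagged <- rownames(usage)[v == 0]
  keep <- v > 0
  if (stats::var(wt_mean_profile) == 0) {
    stop("reference profile has zero variance")
  }
  d <- 1 - stats::cor(t(usage[keep, , drop = FALSE]))
  wt_d <- rep(NA_real_, nrow(usage))
  names(wt_d) <- rownames(usage)
  wt_d[keep] <- 1 - as.numeric(stats::cor(t(usage[keep, , drop = FALSE]),
                                          wt_mean_profile))
  list(dissimilarity = d, wt_dissimilarity = wt_d, flagged = flagged)
}

#' Hierarchical clustering of a dissimilarity matrix
#'
#' Thin wrapper around average-linkage (default) agglomerative clustering,
#' returning the leaf ordering used to reorder usage heatmaps.
#'
#' @param dissimilarity symmetric, zero-diagonal dissimilarity matrix with no
#'   missing values.
#' @param linkage linkage rule passed to [stats::hclust()] (default
#'   `"average"`).
#' @return List with `order` (leaf ordering, a permutation of labels),
#'   `labels`, and `tree` (the `hclust` object; `n - 1` merges).
#' @export
hierarchical_cluster <- function(dissimilarity, linkage = "average") {
  if (any(is.na(dissimilarity))) stop("NaN/NA entries in dissimilarity")
  if (!isSymmetric(unname(dissimilarity), tol = 1e-8)) {
    stop("dissimilarity must be symmetric")
  }
  if (any(abs(diag(dissimilarity)) > 1e-8)) {
    stop("dissimilarity must have zero diagonal")
  }
  h <- stats::hclust(stats::as.dist(dissimilarity), method = linkage)
  list(order = h$order, labels = h$labels, tree = h)
}

#' Per-motif usage shift of each genotype relative to WT
#'
#' For each motif, the genotype group-mean usage minus the WT group-mean
#' usage (an interpretation of a per-genotype "delta index" of motif usage;
#' no closed formula is standard).
#'
#' @param usage animals x motifs usage matrix with a `genotype` attribute
#'   (see [motif_usage()]), or supply `genotype` explicitly.
#' @param genotype per-row genotype labels.
#' @param reference reference group label (default `"WT"`).
#' @return genotypes x motifs matrix of usage differences (reference row 0).
#' @export
usage_delta_index <- function(usage, genotype = attr(usage, "genotype"),
                              reference = "WT") {
  stopifnot(!is.null(genotype), reference %in% genotype)
  groups <- unique(genotype)
  means <- t(vapply(groups, function(g) {
    colMeans(usage[genotype == g, , drop = FALSE])
  }, numeric(ncol(usage))))
  sweep(means, 2, means[reference, ])
}
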