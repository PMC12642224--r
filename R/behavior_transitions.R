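#' Transition-matrix container
#'
#' Square matrix of transition probabilities between motifs or communities.
#' Self-transitions are excluded (diagonal is `NA`, undefined by
#' construction); rows with at least one off-diagonal transition sum to 1;
#' rows with no off-diagonal transitions at all are degenerate and carried as
#' `NA` (missing), never as zero probability mass.
#'
#' @param values square numeric matrix with dimnames; diagonal `NA`.
#' @param level `"motif"` or `"community"`.
#' @param flagged_rows labels of degenerate (all-`NA`) rows.
#' @return An object of class `transition_matrix`.
#' @export
transition_matrix <- function(values, level = c("motif", "community"),
                              flagged_rows = character(0)) {
  level <- match.arg(level)
  stopifnot(is.matrix(values), nrow(values) == ncol(values),
            !is.null(rownames(values)),
            identical(rownames(values), colnames(values)))
  structure(list(values = values, labels = rownames(values), level = level,
                 flagged_rows = flagged_rows),
            class = "transition_matrix")
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf("<transition_matrix> level=%s, %d labels", x$level,
              length(x$labels)))
  if (length(x$flagged_rows)) {
    cat(", degenerate rows:", paste(x$flagged_rows, collapse = ", "))
  }
  cat("\n")
  print(round(x$values, 3))
  invisible(x)
}

#' Motif-level transition matrix of one sequence
#'
#' Counts frame-to-frame transitions between distinct motifs (self-transitions
#' are excluded at the count stage, before normalization, since remaining in
#' the same motif is trivial) and row-normalizes the off-diagonal counts.
#'
#' @param sequence a [motif_sequence()] (or any list with `labels`).
#' @param motifs optional motif vocabulary fixing the matrix dimensions.
#' @return A [transition_matrix()] at motif level; rows that never transition
#'   to a different motif are `NA` and listed in `flagged_rows`.
#' @export
motif_transition_matrix <- function(sequence, motifs = NULL) {
  labels <- sequence$labels
  if (length(labels) < 2) stop("need >= 2 frames")
  if (is.null(motifs)) motifs <- sort(unique(labels))
  from <- factor(labels[-length(labels)], levels = motifs)
  to <- factor(labels[-1], levels = motifs)
  keep <- as.integer(from) != as.integer(to)   # drop self-transitions
  counts <- table(from[keep], to[keep])
  counts <- matrix(as.numeric(counts), nrow = length(motifs),
                   dimnames = list(motifs, motifs))
  rs <- rowSums(counts)
  p <- counts / ifelse(rs > 0, rs, NA_real_)
  p[rs == 0, ] <- NA_real_
  diag(p) <- NA_real_
  transition_matrix(p, "motif", flagged_rows = motifs[rs == 0])
}

#' Community-level transition matrix from a motif-level matrix
#'
#' Each community-pair entry (P, Q), P != Q, is the unweighted mean of the
#' motif-level transition values over all motif pairs (i in P, j in Q);
#' motif pairs with zero observed transitions contribute 0, while degenerate
#' (missing) motif rows are excluded from the mean. Community
#' self-transitions are excluded (diagonal `NA`).
#'
#' @param motif_matrix a motif-level [transition_matrix()].
#' @param map named character vector, motif id -> community label; must cover
#'   every motif in the matrix.
#' @return A [transition_matrix()] at community level.
#' @export
community_transition_matrix <- function(motif_matrix, map) {
  stopifnot(inherits(motif_matrix, "transition_matrix"),
            motif_matrix$level == "motif")
  motifs <- motif_matrix$labels
  missing_ids <- setdiff(motifs, names(map))
  if (length(missing_ids)) {
    stop("unmapped motif(s): ", paste(missing_ids, collapse = ", "))
  }
  comm <- sort(unique(unname(map[motifs])))
  k <- length(comm)
  out <- matrix(NA_real_, k, k, dimnames = list(comm, comm))
  v <- motif_matrix$values
  grp <- unname(map[motifs])
  for (p in comm) {
    for (q in comm) {
      if (p == q) next
      block <- v[grp == p, grp == q, drop = FALSE]
      out[p, q] <- if (all(is.na(block))) NA_real_ else
        mean(block, na.rm = TRUE)
    }
  }
  flagged <- comm[apply(out, 1, function(r) all(is.na(r)))]
  transition_matrix(out, "community", flagged_rows = flagged)
}

#' Average session-level transition matrices within animal
#'
#' The animal is the unit of replication: session matrices are averaged
#' element-wise (missing cells excluded per element) before any group-level
#' comparison.
#'
#' @param session_matrices list of [transition_matrix()] objects for one
#'   animal, all at the same level with matching labels.
#' @return A single [transition_matrix()].
#' @export
animal_average <- function(session_matrices) {
  stopifnot(length(session_matrices) >= 1)
  lv <- unique(vapply(session_matrices, `[[`, character(1), "level"))
  if (length(lv) != 1) stop("mixed transition-matrix levels")
  labs <- session_matrices[[1]]$labels
  for (m in session_matrices) {
    if (!identical(m$labels, labs)) stop("label mismatch across sessions")
  }
  arr <- simplify2array(lapply(session_matrices, `[[`, "values"))
  avg <- apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
  flagged <- labs[apply(avg, 1, function(r) all(is.na(r)))]
  transition_matrix(avg, lv, flagged_rows = flagged)
}

group_mean_matrix <- function(matrices) {
  arr <- simplify2array(lapply(matrices, `[[`, "values"))
  apply(arr, c(1, 2), function(x) {
    if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  })
}

#' Genotype-minus-WT difference of transition matrices
#'
#' Element-wise difference of group mean matrices (per-animal matrices are
#' averaged within group first); positive values mean the transition is more
#' likely in the genotype group than in WT.
#'
#' @param genotype_matrices list of per-animal [transition_matrix()] objects
#'   for the genotype group.
#' @param wt_matrices list of per-animal matrices for the WT group.
#' @return A list of class `delta_transition`: `values` (signed difference
#'   matrix), `labels`, `reference = "WT"`.
#' @export
delta_transition <- function(genotype_matrices, wt_matrices) {
  stopifnot(length(genotype_matrices) >= 1, length(wt_matrices) >= 1)
  labs <- genotype_matrices[[1]]$labels
  for (m in c(genotype_matrices, wt_matrices)) {
    if (!identical(m$labels, labs)) stop("label mismatch between groups")
  }
  d <- group_mean_matrix(genotype_matrices) - group_mean_matrix(wt_matrices)
  structure(list(values = d, labels = labs, reference = "WT"),
            class = "delta_transition")
}

#' Animal-block permutation test for transition-matrix differences
#'
#' Builds the null distribution of the genotype-minus-WT difference by
#' shuffling group labels at the animal level (the animal is the permutation
#' block), preserving group sizes. Two-sided per-cell p-values use add-one
#' smoothing: `p = (1 + #(|delta_perm| >= |delta_obs|)) / (n_perm + 1)`, so
#' the minimum attainable p is `1 / (n_perm + 1)`.
#'
#' @param genotype_matrices,wt_matrices per-animal [transition_matrix()]
#'   lists (>= 3 animals in total; groups must admit more than one distinct
#'   label assignment).
#' @param n_perm number of label permutations (>= 100; default 10000).
#' @param seed integer RNG seed.
#' @return A list of class `permutation_result`: `observed_delta`,
#'   `p_two_sided` (matrix), `null_samples = n_perm`, `seed`.
#' @export
permutation_test <- function(genotype_matrices, wt_matrices,
                             n_perm = 10000, seed = 1) {
  stopifnot(n_perm >= 100)
  n_g <- length(genotype_matrices)
  n_w <- length(wt_matrices)
  n <- n_g + n_w
  if (n < 3) stop("need >= 3 animals in total")
  if (choose(n, n_g) < 2) stop("groups too small for any distinct permutation")
  obs <- delta_transition(genotype_matrices, wt_matrices)$values
  arr <- simplify2array(lapply(c(genotype_matrices, wt_matrices),
                               `[[`, "values"))
  dims <- dim(arr)[1:2]
  flat <- matrix(arr, nrow = prod(dims), ncol = n)   # cells x animals
  set.seed(as.integer(seed))
  exceed <- matrix(0, dims[1], dims[2])
  aobs <- abs(obs)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, n_g)
    d_perm <- rowMeans(flat[, idx, drop = FALSE], na.rm = TRUE) -
      rowMeans(flat[, -idx, drop = FALSE], na.rm = TRUE)
    cmp <- abs(matrix(d_perm, dims[1], dims[2])) >= aobs - 1e-12
    cmp[is.na(cmp)] <- TRUE   # undefined permutation delta counts as exceeding
    exceed <- exceed + cmp
  }
  p <- (1 + exceed) / (n_perm + 1)
  p[is.na(obs)] <- NA_real_
  dimnames(p) <- dimnames(obs)
  structure(list(observed_delta = obs, p_two_sided = p,
                 null_samples = n_perm, seed = seed),
            class = "permutation_result")
}
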