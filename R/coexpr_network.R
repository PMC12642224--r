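#' Choose a soft-thresholding power approximating scale-free topology
#'
#' For each candidate power, computes the unsigned adjacency, the
#' connectivity distribution, and the scale-free model fit R^2 (regression of
#' log10 frequency on log10 connectivity over connectivity bins, signed
#' negative slopes only). Returns the smallest power reaching `r2_target`,
#' or the grid maximum if none does. Known per-dataset powers (e.g. per cell
#' type) can simply be passed downstream instead.
#'
#' @param m gene x sample matrix.
#' @param powers candidate powers.
#' @param r2_target minimal acceptable fit (default 0.8).
#' @param n_bins connectivity histogram bins.
#' @return List: `power` (selected), `fit` (data frame power x R^2).
#' @export
pick_soft_threshold <- function(m, powers = c(1:10, 12, 14, 16, 18, 20, 24),
                                r2_target = 0.8, n_bins = 10) {
  if (ncol(m) < 8) stop("need >= 8 samples")
  cors <- abs(stats::cor(t(m)))
  diag(cors) <- 0
  r2 <- vapply(powers, function(b) {
    k <- rowSums(cors^b)
    scale_free_r2(k, n_bins)
  }, numeric(1))
  ok <- which(r2 >= r2_target)
  list(power = if (length(ok)) powers[min(ok)] else max(powers),
       fit = data.frame(power = powers, r2 = r2))
}

scale_free_r2 <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) return(0)
  cuts <- cut(k, breaks = n_bins)
  dk <- tapply(k, cuts, mean)
  pk <- tabulate(cuts, nbins = n_bins) / length(k)
  keep <- !is.na(dk) & pk > 0
  if (sum(keep) < 3) return(0)
  x <- log10(dk[keep]); y <- log10(pk[keep])
  fit <- stats::lm(y ~ x)
  r2 <- summary(fit)$r.squared
  # scale-free topology requires a decreasing p(k); penalize positive slopes
  if (stats::coef(fit)[[2]] > 0) -r2 else r2
}

#' Build an unsigned co-expression network and its topological overlap
#'
#' Adjacency `a_ij = |cor(g_i, g_j)|^beta` (unsigned), and topological
#' overlap `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)`
#' with unit diagonal, where `k_i` is the connectivity of gene i.
#'
#' @param m gene x sample matrix (filtered; no zero-variance genes).
#' @param beta soft-thresholding power.
#' @return List with `adjacency` and `tom` (symmetric gene x gene matrices,
#'   entries in `[0, 1]`).
#' @export
build_network <- function(m, beta) {
  v <- apply(m, 1, stats::var)
  if (any(v == 0)) {
    stop("zero-variance gene(s): ",
         paste(utils::head(rownames(m)[v == 0], 5), collapse = ", "))
  }
  a <- abs(stats::cor(t(m)))^beta
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a) <- list(rownames(m), rownames(m))
  list(adjacency = a, tom = tom)
}

#' Detect co-expression modules from a topological overlap matrix
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut at a height
#' fraction of the tree determined by `deep_split` (0 -> 0.97 of the maximum
#' merge height, 1 -> 0.95, down to 4 -> 0.89; larger values cut lower and
#' split more finely -- the topological-overlap transform compresses
#' between-module dissimilarities toward 1, so useful cuts sit just below
#' the top of the tree), with
#' clusters smaller than `min_module_size` sent to `"grey"`. Modules whose
#' eigengenes are closer than `merge_cut_height` (1 - correlation) are then
#' merged iteratively. Modules are labelled `"M1", "M2", ...` by decreasing
#' size.
#'
#' @param tom square topological overlap matrix.
#' @param expr gene x sample matrix (needed for eigengene-based merging).
#' @param merge_cut_height eigengene dissimilarity below which modules merge.
#' @param deep_split integer 0-4 controlling cut granularity.
#' @param min_module_size smallest allowed module.
#' @return Named character vector gene -> module label (`"grey"` =
#'   unassigned), with attribute `tree` (the `hclust` object).
#' @export
detect_modules <- function(tom, expr, merge_cut_height = 0.30, deep_split = 1,
                           min_module_size = 10) {
  stopifnot(nrow(tom) == ncol(tom), nrow(tom) == nrow(expr))
  cut_frac <- c(`0` = 0.97, `1` = 0.95, `2` = 0.93, `3` = 0.91, `4` = 0.89)
  frac <- cut_frac[as.character(deep_split)]
  if (is.na(frac)) stop("deep_split must be an integer in 0:4")
  h <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(h, h = frac * max(h$height))
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < min_module_size])] <- 0L
  if (all(cl == 0L)) {
    warning("all genes unassigned (grey)")
    out <- stats::setNames(rep("grey", nrow(tom)), rownames(tom))
    attr(out, "tree") <- h
    return(out)
  }
  # iterative eigengene merging
  repeat {
    mods <- setdiff(unique(cl), 0L)
    if (length(mods) < 2 || merge_cut_height <= 0) break
    me <- vapply(mods, function(mm) {
      sub <- expr[cl == mm, , drop = FALSE]
      pc <- module_pc1(sub)
      # orient toward the module's mean profile (PC sign is arbitrary)
      r <- stats::cor(pc, colMeans(sub))
      if (!is.na(r) && r < 0) pc <- -pc
      pc
    }, numeric(ncol(expr)))
    # signed eigengene correlation: anti-correlated modules are distinct
    # programs and must not merge, matching the field convention
    dis <- 1 - stats::cor(me)
    diag(dis) <- Inf
    if (min(dis) >= merge_cut_height) break
    ij <- which(dis == min(dis), arr.ind = TRUE)[1, ]
    cl[cl == mods[ij[2]]] <- mods[ij[1]]
  }
  mods <- setdiff(unique(cl), 0L)
  mods <- mods[order(-tabulate(factor(cl, levels = mods)))]
  lab <- stats::setNames(paste0("M", seq_along(mods)), mods)
  out <- ifelse(cl == 0L, "grey", lab[as.character(cl)])
  names(out) <- rownames(tom)
  attr(out, "tree") <- h
  out
}

# First principal component of a module (scores over samples, unit norm),
# from the gene-standardized submatrix.
module_pc1 <- function(sub) {
  x <- t(scale(t(sub)))
  x[!is.finite(x)] <- 0
  sv <- svd(t(x), nu = 1, nv = 0)
  sv$u[, 1]
}
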