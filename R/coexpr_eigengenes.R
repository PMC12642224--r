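#' Module eigengenes
#'
#' The eigengene (ME) of a module is the first principal component of its
#' gene-standardized expression submatrix: the unit-norm scores over samples
#' that explain the most variance of the module. Modules must have at least
#' 2 genes; the grey (unassigned) module gets no eigengene.
#'
#' @param expr gene x sample matrix.
#' @param assignment named character vector gene -> module label
#'   ([detect_modules()] or planted ground truth).
#' @return Module x sample numeric matrix of eigengenes.
#' @export
module_eigengene <- function(expr, assignment) {
  mods <- setdiff(sort(unique(assignment)), "grey")
  if (length(mods) == 0) stop("no non-grey modules")
  me <- t(vapply(mods, function(mm) {
    genes <- names(assignment)[assignment == mm]
    if (length(genes) < 2) stop("module ", mm, " has fewer than 2 genes")
    module_pc1(expr[genes, , drop = FALSE])
  }, numeric(ncol(expr))))
  dimnames(me) <- list(mods, colnames(expr))
  me
}

#' Gene-module membership (kME)
#'
#' Pearson correlation between each gene's expression profile and each
#' module eigengene; the absolute kME against a gene's own module defines
#' hub ranking.
#'
#' @param expr gene x sample matrix.
#' @param me module x sample eigengene matrix ([module_eigengene()]).
#' @return Gene x module matrix of correlations in `[-1, 1]`.
#' @export
kme_table <- function(expr, me) {
  stats::cor(t(expr), t(me))
}

#' Align eigengene signs to their hub genes
#'
#' A principal component's sign is arbitrary; to standardize polarity, each
#' ME is flipped (together with its kME column) whenever its correlation with
#' the mean expression of the module's top `n_hub` hub genes (ranked by
#' |kME|) is negative, so that the post-condition correlation is positive for
#' every module. Applying the alignment twice equals applying it once.
#'
#' @param me module x sample eigengene matrix.
#' @param kme gene x module kME matrix.
#' @param expr gene x sample matrix.
#' @param assignment gene -> module assignment.
#' @param n_hub number of hub genes defining the reference polarity.
#' @return List with `me` and `kme` (sign-aligned) and `flipped` (module
#'   labels that were inverted).
#' @export
align_sign <- function(me, kme, expr, assignment, n_hub = 50) {
  flipped <- character(0)
  for (mm in rownames(me)) {
    genes <- names(assignment)[assignment == mm]
    ord <- order(-abs(kme[genes, mm]))
    hubs <- genes[ord][seq_len(min(n_hub, length(genes)))]
    hub_mean <- colMeans(expr[hubs, , drop = FALSE])
    r <- stats::cor(me[mm, ], hub_mean)
    if (is.na(r) || r == 0) {
      warning("module ", mm, ": zero hub correlation; sign left unchanged")
      next
    }
    if (r < 0) {
      me[mm, ] <- -me[mm, ]
      kme[, mm] <- -kme[, mm]
      flipped <- c(flipped, mm)
    }
  }
  list(me = me, kme = kme, flipped = flipped)
}

#' Center eigengenes on the WT group
#'
#' Subtracts the WT group mean from each module eigengene and divides by
#' either the WT standard deviation (`mode = "wt_sd"`, used for the
#' contribution decomposition) or the pooled within-genotype standard
#' deviation (`mode = "pooled_sd"`, used for effect-size heatmaps). After
#' centering the WT group mean is 0 in both modes. A zero-variance divisor is
#' floored at a machine-safe epsilon and the module flagged.
#'
#' @param me module x sample eigengene matrix (sign-aligned).
#' @param design [genotype_design()] rows matching the ME columns.
#' @param mode `"wt_sd"` or `"pooled_sd"`.
#' @return Centered module x sample matrix with attribute `flagged`
#'   (modules whose divisor was floored).
#' @export
wt_center <- function(me, design, mode = c("wt_sd", "pooled_sd")) {
  mode <- match.arg(mode)
  stopifnot(identical(colnames(me), design$sample_id))
  wt <- design$genotype == "WT"
  if (sum(wt) < 2) stop("need >= 2 WT samples")
  flagged <- character(0)
  out <- me
  for (mm in rownames(me)) {
    mu <- mean(me[mm, wt])
    s <- if (mode == "wt_sd") {
      stats::sd(me[mm, wt])
    } else {
      gs <- split(me[mm, ], design$genotype, drop = TRUE)
      df <- vapply(gs, length, integer(1)) - 1L
      sqrt(sum(vapply(gs, stats::var, numeric(1)) * df) / sum(df))
    }
    if (!is.finite(s) || s < .Machine$double.eps) {
      flagged <- c(flagged, mm)
      s <- .Machine$double.eps
    }
    out[mm, ] <- (me[mm, ] - mu) / s
  }
  attr(out, "flagged") <- flagged
  attr(out, "centering") <- mode
  out
}

#' Top hub genes per module
#'
#' Genes ranked by decreasing |kME| within their own module; ties broken
#' lexicographically by gene id for reproducibility. Modules smaller than
#' `n` return all their genes.
#'
#' @param kme gene x module kME matrix.
#' @param assignment gene -> module assignment.
#' @param n hubs per module (default 25).
#' @return Named list, module -> character vector of hub gene ids.
#' @export
hub_genes <- function(kme, assignment, n = 25) {
  mods <- setdiff(sort(unique(assignment)), "grey")
  out <- lapply(mods, function(mm) {
    genes <- names(assignment)[assignment == mm]
    genes <- genes[order(-abs(kme[genes, mm]), genes)]
    genes[seq_len(min(n, length(genes)))]
  })
  stats::setNames(out, mods)
}
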