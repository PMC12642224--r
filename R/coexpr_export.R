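#' Export within-module correlation networks as edge and node tables
#'
#' For each (non-grey) module, pairwise Pearson correlations among member
#' genes are computed and edges with `|r| >= threshold` retained (inclusive).
#' Edges are undirected with canonical ordering (`gene_a < gene_b`), no
#' self-edges. The node table carries each gene's own-module kME (node size
#' attribute = |kME|, node color attribute = signed kME) and a hub flag for
#' the top `n_hub` genes. The two tables are the standard input of network
#' viewers such as Cytoscape.
#'
#' @param expr gene x sample matrix.
#' @param assignment gene -> module assignment.
#' @param kme gene x module kME matrix.
#' @param threshold minimum |r| for an edge (default 0.3).
#' @param n_hub hub genes per module for the node flag (default 25).
#' @return List with `edges` (gene_a, gene_b, r, module) and `nodes` (gene,
#'   module, kme, abs_kme, hub).
#' @export
export_edges <- function(expr, assignment, kme, threshold = 0.3, n_hub = 25) {
  mods <- setdiff(sort(unique(assignment)), "grey")
  if (length(mods) == 0) stop("no non-grey modules")
  hubs <- hub_genes(kme, assignment, n = n_hub)
  edges <- list()
  nodes <- list()
  for (mm in mods) {
    genes <- sort(names(assignment)[assignment == mm])
    r <- stats::cor(t(expr[genes, , drop = FALSE]))
    ut <- which(upper.tri(r) & abs(r) >= threshold, arr.ind = TRUE)
    if (nrow(ut)) {
      edges[[mm]] <- data.frame(
        gene_a = genes[ut[, 1]], gene_b = genes[ut[, 2]],
        r = r[ut], module = mm)
    }
    nodes[[mm]] <- data.frame(
      gene = genes, module = mm, kme = kme[genes, mm],
      abs_kme = abs(kme[genes, mm]), hub = genes %in% hubs[[mm]],
      row.names = NULL)
  }
  list(edges = if (length(edges)) do.call(rbind, c(edges, make.row.names = FALSE))
       else data.frame(gene_a = character(0), gene_b = character(0),
                       r = numeric(0), module = character(0)),
       nodes = do.call(rbind, c(nodes, make.row.names = FALSE)))
}

#' Gene x genotype heatmap values for one module
#'
#' Genes of the module are ranked by |kME| (variance as a fallback when kME
#' is unavailable) and up to `top_n` retained. Gene-wise WT-centered values
#' are computed by subtracting the gene's WT mean and dividing by its pooled
#' within-genotype SD, with zero variance guarded to one; genotype means of
#' both the raw and centered values are returned, along with a row-scaled
#' (unit-variance) version of the centered means.
#'
#' @param expr gene x sample matrix.
#' @param assignment gene -> module assignment.
#' @param module module label to extract.
#' @param design [genotype_design()] matching the columns.
#' @param kme optional gene x module kME matrix (ranking falls back to
#'   variance when NULL).
#' @param top_n maximum genes retained (default 100).
#' @return List with `raw_means`, `centered_means`, `row_scaled` (gene x
#'   genotype matrices, genes in rank order).
#' @export
module_gene_heatmap_values <- function(expr, assignment, module, design,
                                       kme = NULL, top_n = 100) {
  genes <- names(assignment)[assignment == module]
  if (length(genes) == 0) stop("module has no genes")
  rank_stat <- if (!is.null(kme) && module %in% colnames(kme)) {
    abs(kme[genes, module])
  } else {
    apply(expr[genes, , drop = FALSE], 1, stats::var)
  }
  genes <- genes[order(-rank_stat, genes)]
  genes <- genes[seq_len(min(top_n, length(genes)))]
  sub <- expr[genes, , drop = FALSE]
  wt <- design$genotype == "WT"
  g <- factor(design$genotype, levels = genotype_levels())
  centered <- sub
  for (i in seq_len(nrow(sub))) {
    gs <- split(sub[i, ], g, drop = TRUE)
    df <- vapply(gs, length, integer(1)) - 1L
    s <- sqrt(sum(vapply(gs, stats::var, numeric(1)) * df) / sum(df))
    if (!is.finite(s) || s == 0) s <- 1        # zero variance guarded to one
    centered[i, ] <- (sub[i, ] - mean(sub[i, wt])) / s
  }
  gmeans <- function(m) {
    out <- vapply(levels(g), function(gt) {
      rowMeans(m[, g == gt, drop = FALSE])
    }, numeric(nrow(m)))
    if (nrow(m) == 1) out <- matrix(out, nrow = 1,
                                    dimnames = list(rownames(m), levels(g)))
    out
  }
  cm <- gmeans(centered)
  rs <- t(apply(cm, 1, function(x) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) x * 0 else (x - mean(x)) / s
  }))
  dimnames(rs) <- dimnames(cm)
  list(raw_means = gmeans(sub), centered_means = cm, row_scaled = rs)
}
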