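#' Run the pseudobulk co-expression pipeline end to end
#'
#' Convenience driver: builds the unsigned network and TOM, detects modules,
#' computes eigengenes and kME, aligns eigengene signs to hub genes, centers
#' on the WT group, and applies the contribution decomposition. Input is
#' expected to be an already filtered log2CPM matrix (see [filter_genes()]).
#'
#' @param expr gene x sample log-scale matrix.
#' @param design [genotype_design()] matching the columns.
#' @param beta soft-thresholding power (pass a known per-cell-type value or
#'   the result of [pick_soft_threshold()]).
#' @param merge_cut_height,deep_split,min_module_size module detection
#'   parameters, see [detect_modules()].
#' @param assignment optional precomputed gene -> module assignment
#'   (skips network construction and module detection).
#' @param n_hub hub genes used for sign alignment.
#' @return List: `assignment`, `me` (sign-aligned), `kme`, `centered`
#'   (WT-SD centered MEs), `contribution` (see [contribution()]).
#' @export
run_coexpression <- function(expr, design, beta = 6, merge_cut_height = 0.30,
                             deep_split = 1, min_module_size = 10,
                             assignment = NULL, n_hub = 50) {
  if (is.null(assignment)) {
    net <- build_network(expr, beta)
    assignment <- detect_modules(net$tom, expr,
                                 merge_cut_height = merge_cut_height,
                                 deep_split = deep_split,
                                 min_module_size = min_module_size)
  }
  me <- module_eigengene(expr, assignment)
  km <- kme_table(expr, me)
  al <- align_sign(me, km, expr, assignment, n_hub = n_hub)
  centered <- wt_center(al$me, design, mode = "wt_sd")
  list(assignment = assignment, me = al$me, kme = al$kme,
       centered = centered, contribution = contribution(centered, design))
}
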