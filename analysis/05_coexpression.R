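#!/usr/bin/env Rscript
# Pseudobulk co-expression analysis per cell type: module detection,
# eigengene statistics, the genotype contribution decomposition,
# neuron-vs-glia comparison, factorial ANOVA aggregation, ME contrasts,
# and network export.

library(phenomod)
data_dir <- "scratch/data/pseudobulk"
out <- "results/coexpression"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

des <- read.table("scratch/data/design.tsv", header = TRUE, sep = "\t")
des <- genotype_design(des$sample_id, des$genotype)
cells <- c(interneuron = "neuron", pyramidal = "neuron",
           microglia = "glia", astrocyte = "glia")

shares <- list()
props <- list()
for (ct in names(cells)) {
  expr <- as.matrix(read.table(
    file.path(data_dir, paste0(ct, "_log2cpm.tsv")),
    header = TRUE, sep = "\t", check.names = FALSE))
  r <- run_coexpression(expr, des, beta = 6)
  ctr <- r$contribution

  write.table(round(r$centered, 4),
              file.path(out, paste0(ct, "_me_centered.tsv")),
              sep = "\t", quote = FALSE)
  write.table(cbind(ctr$per_module[1],
                    round(ctr$per_module[-1], 4)),
              file.path(out, paste0(ct, "_contribution.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # factorial ANOVA aggregated to module level
  ga <- gene_two_way_anova(expr, des)
  af <- aggregate_fisher(ga, r$assignment)
  write.table(cbind(af[c("module", "term", "n_genes", "df")],
                    round(af[c("fisher_X2", "p_combined", "q_fdr",
                               "frac_nominal", "mean_eta2")], 5)),
              file.path(out, paste0(ct, "_module_anova.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # ME contrasts vs WT (pooled-SD centering for effect-size scale)
  mc <- me_contrasts(wt_center(r$me, des, "pooled_sd"), des)
  write.table(cbind(mc[c("module", "contrast")],
                    round(mc[c("estimate", "t", "p", "p_adj")], 5),
                    significant = mc$significant),
              file.path(out, paste0(ct, "_me_contrasts.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # network export for viewers
  ex <- export_edges(expr, r$assignment, r$kme)
  write.table(cbind(ex$edges[c("gene_a", "gene_b", "module")],
                    r = round(ex$edges$r, 3)),
              file.path(out, paste0(ct, "_edges.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cbind(ex$nodes[c("gene", "module", "hub")],
                    round(ex$nodes[c("kme", "abs_kme")], 3)),
              file.path(out, paste0(ct, "_nodes.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)

  shares[[ct]] <- ctr$per_module
  props[[ct]] <- ctr$proportions
  cat(sprintf("%s (%s): %d modules; contributions E4 %.0f%%, NLF %.0f%%, E4xNLF %.0f%%\n",
              ct, cells[[ct]], nrow(ctr$per_module),
              100 * ctr$proportions["c_E4"], 100 * ctr$proportions["c_NLF"],
              100 * ctr$proportions["c_E4NLF"]))
}

prop_tab <- data.frame(cell_type = names(props), class = unname(cells),
                       round(100 * do.call(rbind, props), 1))
write.table(prop_tab, file.path(out, "contribution_by_celltype.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

neuron <- do.call(rbind, shares[names(cells)[cells == "neuron"]])
glia <- do.call(rbind, shares[names(cells)[cells == "glia"]])
cmp <- compare_contributions(neuron, glia)
write.table(cbind(cmp[c("component", "n_a", "n_b", "statistic")],
                  round(cmp[c("p", "p_bonferroni")], 5)),
            file.path(out, "neuron_vs_glia.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("\nneuron vs glia per-module share comparison (Wilcoxon, Bonferroni):\n")
print(cmp, row.names = FALSE)
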