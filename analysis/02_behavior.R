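#!/usr/bin/env Rscript
# Behavioral motif analytics on the simulated cohort: usage matrices,
# WT-dissimilarity clustering, community transition matrices, genotype
# delta matrices, and the animal-block permutation test.

library(phenomod)
data_dir <- "scratch/data"
out <- "results/behavior"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

files <- list.files(file.path(data_dir, "motifs"), full.names = TRUE)
seqs <- lapply(files, read_motif_sequence)
map <- read_community_map(file.path(data_dir, "community_map.tsv"))
genos <- vapply(seqs, `[[`, character(1), "genotype_label")

## usage, dissimilarity to the WT mean profile, clustering
usage <- motif_usage(seqs)
wt_profile <- colMeans(usage[genos == "WT", , drop = FALSE])
dis <- usage_dissimilarity(usage, wt_profile)
cl <- hierarchical_cluster(dis$dissimilarity)
write.table(round(usage[cl$order, ], 4), file.path(out, "usage.tsv"),
            sep = "\t", quote = FALSE)
write.table(data.frame(animal = names(dis$wt_dissimilarity),
                       genotype = genos,
                       wt_dissimilarity = round(dis$wt_dissimilarity, 4)),
            file.path(out, "wt_dissimilarity.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
di <- usage_delta_index(usage, genos)
write.table(round(di, 4), file.path(out, "usage_delta_index.tsv"),
            sep = "\t", quote = FALSE)
cat("mean WT-dissimilarity by genotype:\n")
print(round(tapply(dis$wt_dissimilarity, genos, mean), 4))

## per-animal community transition matrices
per_animal <- lapply(seqs, function(s) {
  community_transition_matrix(motif_transition_matrix(s), map)
})
names(per_animal) <- vapply(seqs, `[[`, character(1), "animal_id")

wt_m <- per_animal[genos == "WT"]
for (g in c("E4", "NLF", "E4NLF")) {
  gm <- per_animal[genos == g]
  d <- delta_transition(gm, wt_m)
  pr <- permutation_test(gm, wt_m, n_perm = 2000, seed = 7)
  write.table(round(d$values, 4),
              file.path(out, paste0("delta_", g, ".tsv")),
              sep = "\t", quote = FALSE)
  write.table(round(pr$p_two_sided, 4),
              file.path(out, paste0("pvals_", g, ".tsv")),
              sep = "\t", quote = FALSE)
  sig <- which(pr$p_two_sided < 0.05, arr.ind = TRUE)
  cat(sprintf("%s vs WT: %d significant community transitions\n",
              g, nrow(sig)))
  if (nrow(sig)) {
    labs <- d$labels
    for (k in seq_len(nrow(sig))) {
      cat(sprintf("  %s -> %s: delta %+0.3f, p = %.4f\n",
                  labs[sig[k, 1]], labs[sig[k, 2]],
                  d$values[sig[k, 1], sig[k, 2]],
                  pr$p_two_sided[sig[k, 1], sig[k, 2]]))
    }
  }
}
cat("tables written to", out, "\n")
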