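#!/usr/bin/env Rscript
# Generate one synthetic study cohort across all four modalities and write
# the raw inputs for the downstream analysis scripts.
#
# Cohort: 4 genotypes (WT, E4, NLF, E4NLF); behavioral motif sequences with a
# genotype-specific transition perturbation, an EEG/EMG recording per
# genotype, fEPSP sweeps, and pseudobulk expression matrices for two
# "neuronal" and two "glial" cell types.

library(phenomod)
seed <- 20260924L
out <- "scratch/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

## ---- behavior: 5 motifs, E4NLF has a suppressed E->D (explore) transition ----
P <- local({
  set.seed(seed)
  M <- matrix(runif(25), 5, 5); diag(M) <- diag(M) + 2
  M <- M / rowSums(M)
  dimnames(M) <- list(LETTERS[1:5], LETTERS[1:5]); M
})
P_e4nlf <- P
P_e4nlf["E", "D"] <- P_e4nlf["E", "D"] * 0.3   # planted transition deficit
P_e4nlf <- P_e4nlf / rowSums(P_e4nlf)
gens <- list(WT = P, E4 = P, NLF = P, E4NLF = P_e4nlf)
seqs <- simulate_motif_sequences(gens, n_animals = 8, n_frames = 2e4,
                                 frame_rate = 30, seed = seed)
dir.create(file.path(out, "motifs"), showWarnings = FALSE)
for (s in seqs) {
  write_motif_sequence(s, file.path(out, "motifs", paste0(s$animal_id, ".tsv")))
}
write_community_map(setNames(c("explore", "explore", "groom", "inspect",
                               "rear"), LETTERS[1:5]),
                    file.path(out, "community_map.tsv"))
cat("behavior:", length(seqs), "animals x 2e4 frames\n")

## ---- sleep EEG: one recording per genotype with genotype-shaped events ----
dir.create(file.path(out, "eeg"), showWarnings = FALSE)
eeg_params <- list(
  WT    = list(spindle_rate = 4, spike_rate = 4),
  E4    = list(spindle_rate = 4, spike_rate = 8),    # REM handled via states
  NLF   = list(spindle_rate = 7, spike_rate = 8),    # NLF: more spindles
  E4NLF = list(spindle_rate = 7, spike_rate = 60))   # synergistic spikes
for (g in names(eeg_params)) {
  spec <- planted_eeg_spec(spindle_rate = eeg_params[[g]]$spindle_rate,
                           spike_rate = eeg_params[[g]]$spike_rate,
                           n_cycles = 9)
  rec <- simulate_eeg(spec, seed = seed + match(g, names(eeg_params)))
  write_recording(rec, file.path(out, "eeg", paste0(g, ".tsv")))
  write_hypnogram(rec$hypnogram, file.path(out, "eeg", paste0(g, "_truth.tsv")))
}
cat("eeg: 4 recordings x 30 min\n")

## ---- ephys: I/O curves and LTP series per genotype ----
dir.create(file.path(out, "fepsp"), showWarnings = FALSE)
ltp_strength <- c(WT = 1.6, E4 = 1.55, NLF = 1.25, E4NLF = 1.2)  # NLF deficit
for (g in names(ltp_strength)) {
  i <- match(g, names(ltp_strength))
  base <- simulate_fepsp(-0.5, 0.8, noise_sd = 0.02, n_sweeps = 30,
                         seed = seed + 10 + i)
  post_slopes <- -0.5 * (1 + (ltp_strength[[g]] - 1) *
                           exp(-(0:119) / 80))      # decaying potentiation
  post <- unlist(lapply(seq_along(post_slopes), function(j) {
    simulate_fepsp(post_slopes[j], 0.8 * ltp_strength[[g]], noise_sd = 0.02,
                   n_sweeps = 1, seed = seed + 1000 + 200 * i + j)
  }), recursive = FALSE)
  dir.create(file.path(out, "fepsp", g), showWarnings = FALSE)
  for (j in seq_along(base)) {
    write_sweep(base[[j]], file.path(out, "fepsp", g,
                                     sprintf("base_%03d.tsv", j)))
  }
  for (j in seq_along(post)) {
    write_sweep(post[[j]], file.path(out, "fepsp", g,
                                     sprintf("post_%03d.tsv", j)))
  }
}
cat("fepsp: 4 genotypes x (30 baseline + 120 post) sweeps\n")

## ---- pseudobulk: neuronal vs glial module structure, n = 7/genotype ----
des <- balanced_design(7)
write.table(des, file.path(out, "design.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
cells <- c(interneuron = "neuron", pyramidal = "neuron",
           microglia = "glia", astrocyte = "glia")
dir.create(file.path(out, "pseudobulk"), showWarnings = FALSE)
# cohort cell types carry the canonical class conditions plus extra additive
# programs so each matrix yields several detectable modules
neuron_rich <- c(neuron_module_specs(),
  list(planted_module_spec("n4", 25, effect_e4 = 1.2, noise_sd = 0.3),
       planted_module_spec("n5", 20, effect_nlf = 1.2, noise_sd = 0.3)))
glia_rich <- c(glia_module_specs(),
  list(planted_module_spec("g4", 25, effect_e4 = 0.69, effect_nlf = 0.98,
                           noise_sd = 0.3),
       planted_module_spec("g5", 20, effect_e4 = 0.42, effect_nlf = 0.91,
                           noise_sd = 0.3)))
for (ct in names(cells)) {
  specs <- if (cells[[ct]] == "neuron") neuron_rich else glia_rich
  sim <- simulate_pseudobulk(des, specs, n_background_genes = 200,
                             seed = seed + 100 + match(ct, names(cells)))
  write.table(round(sim$expr, 5),
              file.path(out, "pseudobulk", paste0(ct, "_log2cpm.tsv")),
              sep = "\t", quote = FALSE)
  write.table(data.frame(gene = names(sim$gene_module),
                         module = sim$gene_module),
              file.path(out, "pseudobulk", paste0(ct, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
cat("pseudobulk: 4 cell types x", nrow(des), "samples\n")
cat("done: inputs under", out, "\n")
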