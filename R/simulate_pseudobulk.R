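#' Specify a planted co-expression module
#'
#' Describes one module of a synthetic pseudobulk expression matrix. Genes in
#' the module follow a shared per-sample latent factor scaled by a per-gene
#' loading, plus independent Gaussian noise. The latent mean per sample is
#' `effect_e4 * e4 + effect_nlf * nlf + effect_interaction * e4 * nlf`, so the
#' module carries an additive E4 shift, an additive NLF shift, and/or a
#' non-additive shift present only in E4NLF samples. One `noise_sd` controls
#' both the per-sample latent scatter and the per-gene measurement noise;
#' with `noise_sd = 0` the matrix is fully determined by the genotype means,
#' giving exact closed-form ground truth, and effects are expressed in
#' noise-SD units otherwise.
#'
#' @param module_id module label.
#' @param n_genes number of genes in the module (>= 3).
#' @param effect_e4,effect_nlf,effect_interaction latent mean shifts.
#' @param noise_sd Gaussian noise SD (>= 0) for latent and gene-level noise.
#' @param loading_range interval on `[0, 1]` for the per-gene loadings.
#' @return An object of class `planted_module_spec`.
#' @export
planted_module_spec <- function(module_id, n_genes,
                                effect_e4 = 0, effect_nlf = 0,
                                effect_interaction = 0,
                                noise_sd = 0.3,
                                loading_range = c(0.7, 1)) {
  stopifnot(n_genes >= 3, noise_sd >= 0,
            length(loading_range) == 2,
            loading_range[1] >= 0, loading_range[2] <= 1,
            loading_range[1] <= loading_range[2])
  structure(
    list(module_id = as.character(module_id), n_genes = as.integer(n_genes),
         effect_e4 = effect_e4, effect_nlf = effect_nlf,
         effect_interaction = effect_interaction,
         noise_sd = noise_sd, loading_range = loading_range),
    class = "planted_module_spec"
  )
}

#' Canonical planted-module conditions for neuronal and glial cell types
#'
#' The study conditions emulated by the generator: neuronal cell types carry
#' modules dominated by the non-additive E4 x NLF interaction (dysregulation
#' emerging only in the double mutant), while glial cell types carry purely
#' additive modules (`effect_interaction = 0`) in which the two factors act
#' independently -- partly in opposite directions, so the double mutant's
#' deviation does not simply accumulate both single-factor shifts. Effects
#' are in noise-SD units at the default `noise_sd = 0.3`.
#'
#' @param noise_sd noise level for all modules.
#' @return List of [planted_module_spec()] objects.
#' @export
neuron_module_specs <- function(noise_sd = 0.3) {
  list(
    planted_module_spec("n1", 30, effect_interaction = 2, noise_sd = noise_sd),
    planted_module_spec("n2", 25, effect_interaction = -1.5,
                        noise_sd = noise_sd),
    planted_module_spec("n3", 20, effect_e4 = 0.5, effect_interaction = 1.5,
                        noise_sd = noise_sd))
}

#' @rdname neuron_module_specs
#' @export
glia_module_specs <- function(noise_sd = 0.3) {
  list(
    planted_module_spec("g1", 30, effect_e4 = 2, effect_nlf = -1.5,
                        noise_sd = noise_sd),
    planted_module_spec("g2", 25, effect_e4 = -1, effect_nlf = 1.2,
                        noise_sd = noise_sd),
    planted_module_spec("g3", 20, effect_e4 = 1.5, noise_sd = noise_sd))
}

#' Simulate a pseudobulk log-expression matrix with planted modules
#'
#' Generates a gene x sample matrix on a log2CPM-like scale: planted module
#' genes follow their latent genotype structure (see [planted_module_spec()]),
#' background genes are pure i.i.d. Gaussian noise around the baseline.
#'
#' @param design a [genotype_design()] data frame; at least 2 samples per
#'   genotype present in the design.
#' @param modules list of [planted_module_spec()] objects (non-empty).
#' @param n_background_genes number of unstructured background genes.
#' @param baseline additive baseline expression level.
#' @param background_sd SD of background-gene noise.
#' @param seed integer RNG seed; identical inputs give identical output.
#' @return A list with elements
#'   \describe{
#'     \item{expr}{numeric gene x sample matrix,}
#'     \item{gene_module}{named character vector, gene -> planted module id
#'       (`"background"` for noise genes),}
#'     \item{effects}{data frame of planted per-module effects,}
#'     \item{design}{the input design.}
#'   }
#' @export
simulate_pseudobulk <- function(design, modules, n_background_genes = 200,
                                baseline = 5, background_sd = 1, seed = 1) {
  if (anyDuplicated(design$sample_id)) stop("duplicate sample_id in design")
  if (length(modules) == 0) stop("empty module list")
  if (!all(vapply(modules, inherits, logical(1), "planted_module_spec"))) {
    stop("modules must be a list of planted_module_spec objects")
  }
  tab <- table(design$genotype)
  if (any(tab[genotype_levels() %in% names(tab)[tab > 0]] < 2)) {
    stop("need >= 2 samples per genotype present in the design")
  }
  ids <- vapply(modules, `[[`, character(1), "module_id")
  if (anyDuplicated(ids)) stop("duplicate module_id")

  set.seed(as.integer(seed))
  n_s <- nrow(design)
  rows <- list()
  gene_module <- character(0)
  for (m in modules) {
    mu <- m$effect_e4 * design$e4 + m$effect_nlf * design$nlf +
      m$effect_interaction * design$e4 * design$nlf
    latent <- mu + stats::rnorm(n_s, sd = m$noise_sd)
    loading <- stats::runif(m$n_genes, m$loading_range[1], m$loading_range[2])
    block <- baseline + outer(loading, latent) +
      matrix(stats::rnorm(m$n_genes * n_s, sd = m$noise_sd), m$n_genes, n_s)
    rownames(block) <- sprintf("%s_g%03d", m$module_id, seq_len(m$n_genes))
    rows[[m$module_id]] <- block
    gm <- rep(m$module_id, m$n_genes)
    names(gm) <- rownames(block)
    gene_module <- c(gene_module, gm)
  }
  if (n_background_genes > 0) {
    bg <- baseline + matrix(stats::rnorm(n_background_genes * n_s,
                                         sd = background_sd),
                            n_background_genes, n_s)
    rownames(bg) <- sprintf("bg_g%04d", seq_len(n_background_genes))
    rows[["..background"]] <- bg
    gm <- rep("background", n_background_genes)
    names(gm) <- rownames(bg)
    gene_module <- c(gene_module, gm)
  }
  expr <- do.call(rbind, rows)
  colnames(expr) <- design$sample_id
  effects <- data.frame(
    module_id = ids,
    effect_e4 = vapply(modules, `[[`, numeric(1), "effect_e4"),
    effect_nlf = vapply(modules, `[[`, numeric(1), "effect_nlf"),
    effect_interaction = vapply(modules, `[[`, numeric(1),
                                "effect_interaction"),
    noise_sd = vapply(modules, `[[`, numeric(1), "noise_sd"),
    n_genes = vapply(modules, `[[`, integer(1), "n_genes"),
    stringsAsFactors = FALSE
  )
  list(expr = expr, gene_module = gene_module, effects = effects,
       design = design)
}
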