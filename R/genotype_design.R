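#' Construct a two-factor genotype design table
#'
#' The four genotypes of the factorial cross are encoded by two binary
#' indicators: `e4` (humanized APOE4 allele, present in E4 and E4NLF) and
#' `nlf` (humanized-Abeta App knock-in allele, present in NLF and E4NLF).
#' The genotype label is uniquely determined by the pair:
#' WT = (0,0), E4 = (1,0), NLF = (0,1), E4NLF = (1,1).
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param genotype character vector of genotype labels, one of
#'   `"WT"`, `"E4"`, `"NLF"`, `"E4NLF"`.
#' @return A data frame with columns `sample_id`, `genotype` (factor with
#'   levels WT, E4, NLF, E4NLF), and numeric indicators `e4` and `nlf`.
#' @examples
#' genotype_design(c("s1", "s2"), c("WT", "E4NLF"))
#' @export
genotype_design <- function(sample_id, genotype) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  }
  if (length(genotype) != length(sample_id)) {
    stop("sample_id and genotype must have equal length")
  }
  genotype <- as.character(genotype)
  bad <- setdiff(unique(genotype), genotype_levels())
  if (length(bad)) {
    stop("unknown genotype label(s): ", paste(bad, collapse = ", "))
  }
  data.frame(
    sample_id = sample_id,
    genotype = factor(genotype, levels = genotype_levels()),
    e4 = as.numeric(genotype %in% c("E4", "E4NLF")),
    nlf = as.numeric(genotype %in% c("NLF", "E4NLF")),
    stringsAsFactors = FALSE
  )
}

#' Genotype labels of the factorial design
#' @return Character vector `c("WT", "E4", "NLF", "E4NLF")`.
#' @export
genotype_levels <- function() c("WT", "E4", "NLF", "E4NLF")

#' Balanced genotype design with n samples per genotype
#'
#' @param n_per_genotype number of samples per genotype.
#' @return A [genotype_design()] data frame with `4 * n_per_genotype` rows.
#' @export
balanced_design <- function(n_per_genotype) {
  stopifnot(n_per_genotype >= 1)
  g <- rep(genotype_levels(), each = n_per_genotype)
  genotype_design(paste0(g, "_", rep(seq_len(n_per_genotype), times = 4)), g)
}
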