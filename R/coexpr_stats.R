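#' Gene-level two-way factorial ANOVA
#'
#' Fits `y ~ e4 * nlf` for every gene and returns per-term p-values (E4,
#' NLF, interaction) and effect sizes (eta-squared, the term sum of squares
#' as a fraction of the total). Sequential sums of squares are used; with a
#' balanced design the factors are orthogonal and the decomposition is
#' unique. Genes with zero residual degrees of freedom are skipped and
#' counted.
#'
#' @param expr gene x sample matrix.
#' @param design [genotype_design()] matching the columns; at least 2
#'   samples per genotype cell.
#' @return Data frame: gene, p_E4, p_NLF, p_int, eta2_E4, eta2_NLF, eta2_int;
#'   attribute `skipped` counts genes without residual df.
#' @export
gene_two_way_anova <- function(expr, design) {
  stopifnot(identical(colnames(expr), design$sample_id))
  cell <- interaction(design$e4, design$nlf)
  if (any(table(cell) < 2)) stop("need >= 2 samples per genotype cell")
  e4 <- design$e4; nlf <- design$nlf
  q0 <- qr(matrix(1, length(e4), 1))               # intercept only
  q1 <- qr(cbind(1, e4))
  q2 <- qr(cbind(1, e4, nlf))
  q3 <- qr(cbind(1, e4, nlf, e4 * nlf))
  Y <- t(expr)                                     # samples x genes
  rss <- function(q) colSums(qr.resid(q, Y)^2)
  r0 <- rss(q0); r1 <- rss(q1); r2 <- rss(q2); r3 <- rss(q3)
  df_res <- nrow(Y) - q3$rank
  if (df_res < 1) stop("zero residual degrees of freedom")
  ms_res <- r3 / df_res
  skipped <- ms_res <= 0
  p_of <- function(ss) stats::pf(ss / ms_res, 1, df_res, lower.tail = FALSE)
  ss1 <- pmax(r0 - r1, 0); ss2 <- pmax(r1 - r2, 0); ss3 <- pmax(r2 - r3, 0)
  out <- data.frame(
    gene = rownames(expr),
    p_E4 = p_of(ss1), p_NLF = p_of(ss2), p_int = p_of(ss3),
    eta2_E4 = ss1 / r0, eta2_NLF = ss2 / r0, eta2_int = ss3 / r0,
    row.names = NULL)
  out[skipped, c("p_E4", "p_NLF", "p_int")] <- NA_real_
  attr(out, "skipped") <- sum(skipped)
  out
}

#' Combine gene-level p-values to module level by Fisher's method
#'
#' For each module and term, the Fisher statistic `X2 = -2 * sum(log p)` is
#' referred to a chi-square distribution with `2k` degrees of freedom (k =
#' genes tested), and Benjamini-Hochberg FDR is controlled across modules
#' within each term. Summaries include the fraction of genes nominally
#' significant (p < 0.05) and the mean eta-squared. The grey module is
#' excluded.
#'
#' @param gene_stats data frame from [gene_two_way_anova()].
#' @param assignment gene -> module assignment covering the genes.
#' @return Data frame: module, term, n_genes, fisher_X2, df, p_combined,
#'   q_fdr, frac_nominal, mean_eta2.
#' @export
aggregate_fisher <- function(gene_stats, assignment) {
  terms <- c(E4 = "p_E4", NLF = "p_NLF", `E4xNLF` = "p_int")
  etas <- c(E4 = "eta2_E4", NLF = "eta2_NLF", `E4xNLF` = "eta2_int")
  mod <- assignment[gene_stats$gene]
  keep <- !is.na(mod) & mod != "grey"
  gs <- gene_stats[keep, , drop = FALSE]
  mod <- mod[keep]
  mods <- sort(unique(mod))
  rows <- list()
  for (tm in names(terms)) {
    p <- gs[[terms[tm]]]
    eta <- gs[[etas[tm]]]
    for (mm in mods) {
      sel <- mod == mm & !is.na(p)
      k <- sum(sel)
      x2 <- -2 * sum(log(pmax(p[sel], .Machine$double.xmin)))
      rows[[length(rows) + 1L]] <- data.frame(
        module = mm, term = tm, n_genes = k,
        fisher_X2 = x2, df = 2L * k,
        p_combined = stats::pchisq(x2, df = 2 * k, lower.tail = FALSE),
        frac_nominal = mean(p[sel] < 0.05),
        mean_eta2 = mean(eta[sel]))
    }
  }
  out <- do.call(rbind, rows)
  out$q_fdr <- NA_real_
  for (tm in unique(out$term)) {
    sel <- out$term == tm
    out$q_fdr[sel] <- stats::p.adjust(out$p_combined[sel], method = "BH")
  }
  out
}

#' Per-module genotype-vs-WT eigengene contrasts
#'
#' Fits `ME ~ genotype` (WT reference) per module by ordinary least squares
#' and reports the three genotype-vs-WT contrast estimates with t-test
#' p-values, Benjamini-Hochberg adjusted across all module x contrast tests.
#'
#' @param me module x sample ME matrix (typically pooled-SD WT-centered).
#' @param design [genotype_design()] matching the columns; all genotypes
#'   present.
#' @param fdr significance threshold for the `significant` flag.
#' @return Data frame: module, contrast, estimate, t, p, p_adj, significant.
#' @export
me_contrasts <- function(me, design, fdr = 0.05) {
  stopifnot(identical(colnames(me), design$sample_id))
  if (!all(genotype_levels() %in% design$genotype)) stop("singular design: all genotypes required")
  g <- factor(design$genotype, levels = genotype_levels())
  rows <- list()
  for (mm in rownames(me)) {
    fit <- summary(stats::lm(me[mm, ] ~ g))$coefficients
    for (gt in c("E4", "NLF", "E4NLF")) {
      cf <- fit[paste0("g", gt), ]
      rows[[length(rows) + 1L]] <- data.frame(
        module = mm, contrast = paste0(gt, "_vs_WT"),
        estimate = cf[["Estimate"]], t = cf[["t value"]],
        p = cf[["Pr(>|t|)"]])
    }
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < fdr
  out
}
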