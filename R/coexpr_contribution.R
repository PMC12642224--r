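#' Contribution decomposition of module-eigengene change
#'
#' For each (non-grey) module, the magnitude of activity change in each
#' mutant genotype group is the absolute deviation of its ME group mean from
#' the WT mean: `d_g = |mean_g(ME) - mean_WT(ME)|` for g in E4, NLF, E4NLF.
#' Per-module shares `d_g / sum_g d_g` apportion that module's change among
#' the three groups. Summing `d_g` across modules gives the totals `T_g`, and
#' proportions `c_g = T_g / sum_g T_g` apportion the overall co-expression
#' disruption of the cell type among E4 alone, NLF alone, and their
#' combination. Shares and proportions each sum to 1.
#'
#' @param centered_me WT-centered (mode `"wt_sd"`), sign-aligned module x
#'   sample ME matrix ([wt_center()]).
#' @param design [genotype_design()] matching the ME columns; all four
#'   genotypes must be present.
#' @return List of class `contribution_result`:
#'   \describe{
#'     \item{per_module}{data frame: module, d_E4, d_NLF, d_E4NLF,
#'       share_E4, share_NLF, share_E4NLF (shares `NA` for modules with zero
#'       total shift; such modules still count toward totals),}
#'     \item{totals}{named vector T_E4, T_NLF, T_E4NLF,}
#'     \item{proportions}{named vector c_E4, c_NLF, c_E4NLF summing to 1.}
#'   }
#' @export
contribution <- function(centered_me, design) {
  stopifnot(identical(colnames(centered_me), design$sample_id))
  if (!all(genotype_levels() %in% design$genotype)) {
    stop("all four genotypes must be present")
  }
  mods <- setdiff(rownames(centered_me), "grey")
  groups <- c("E4", "NLF", "E4NLF")
  d <- t(vapply(mods, function(mm) {
    wt_mean <- mean(centered_me[mm, design$genotype == "WT"])
    vapply(groups, function(g) {
      abs(mean(centered_me[mm, design$genotype == g]) - wt_mean)
    }, numeric(1))
  }, numeric(3)))
  tot_by_mod <- rowSums(d)
  shares <- d / tot_by_mod
  shares[tot_by_mod == 0, ] <- NA_real_
  per_module <- data.frame(
    module = mods,
    d_E4 = d[, "E4"], d_NLF = d[, "NLF"], d_E4NLF = d[, "E4NLF"],
    share_E4 = shares[, "E4"], share_NLF = shares[, "NLF"],
    share_E4NLF = shares[, "E4NLF"],
    row.names = NULL)
  totals <- colSums(d)
  names(totals) <- paste0("T_", groups)
  if (sum(totals) == 0) stop("zero total shift across all modules")
  proportions <- colSums(d) / sum(d)
  names(proportions) <- paste0("c_", groups)
  structure(list(per_module = per_module, totals = totals,
                 proportions = proportions),
            class = "contribution_result")
}

#' @export
print.contribution_result <- function(x, ...) {
  cat("<contribution_result>\n  proportions:",
      paste(sprintf("%s = %.3f", names(x$proportions), x$proportions),
            collapse = ", "), "\n")
  cat(sprintf("  %d modules\n", nrow(x$per_module)))
  invisible(x)
}

#' Compare contribution components between module classes
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney U) tests of each per-module
#' contribution component between two classes of modules (e.g. neuronal vs
#' glial), Bonferroni-corrected over the three components.
#'
#' @param class_a,class_b data frames with per-module share columns
#'   `share_E4`, `share_NLF`, `share_E4NLF` (e.g. `per_module` tables from
#'   [contribution()], possibly row-bound over cell types); >= 3 modules per
#'   class.
#' @return Data frame: component, n_a, n_b, statistic (U), p, p_bonferroni.
#' @export
compare_contributions <- function(class_a, class_b) {
  comps <- c("share_E4", "share_NLF", "share_E4NLF")
  stopifnot(all(comps %in% names(class_a)), all(comps %in% names(class_b)))
  a_ok <- stats::complete.cases(class_a[comps])
  b_ok <- stats::complete.cases(class_b[comps])
  if (sum(a_ok) < 3 || sum(b_ok) < 3) stop("need >= 3 modules per class")
  res <- lapply(comps, function(cc) {
    x <- class_a[[cc]][a_ok]; y <- class_b[[cc]][b_ok]
    if (length(unique(c(x, y))) == 1) {
      return(data.frame(component = cc, n_a = length(x), n_b = length(y),
                        statistic = length(x) * length(y) / 2, p = 1))
    }
    w <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL))
    data.frame(component = cc, n_a = length(x), n_b = length(y),
               statistic = unname(w$statistic), p = w$p.value)
  })
  res <- do.call(rbind, res)
  res$p_bonferroni <- pmin(1, 3 * res$p)
  res
}
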