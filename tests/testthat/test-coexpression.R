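# Co-expression module: preprocessing, network, eigengenes, contribution,
# factorial statistics, export.

test_that("pseudobulk aggregation sums per sample and conserves totals", {
  cc <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2,
               dimnames = list(c("g1", "g2"), c("c1", "c2", "c3")))
  map <- c(c1 = "s1", c2 = "s1", c3 = "s2")
  pb <- pseudobulk_aggregate(cc, map)
  expect_equal(pb[, "s1"], c(g1 = 1 + 3, g2 = 2 + 4))
  expect_equal(sum(pb), sum(cc))                       # conservation
  # one cell per sample: identity
  pb1 <- pseudobulk_aggregate(cc, c(c1 = "a", c2 = "b", c3 = "c"))
  expect_equal(unname(pb1[, c("a", "b", "c")]), unname(cc))
  expect_error(pseudobulk_aggregate(cc, c(c1 = "s1")), "unmapped")
  # sparse input works identically
  pbs <- pseudobulk_aggregate(Matrix::Matrix(cc, sparse = TRUE), map)
  expect_equal(pbs, pb)
})

test_that("log2CPM normalization has its closed forms and invariances", {
  m <- matrix(c(0, 10, 90, 50, 0, 50), nrow = 3,
              dimnames = list(c("g1", "g2", "g3"), c("s1", "s2")))
  lc <- normalize_log2cpm(m)
  expect_equal(lc["g1", "s1"], 0)                      # log2(1)
  one <- matrix(7, 1, 1, dimnames = list("g", "s"))
  expect_equal(normalize_log2cpm(one)[1, 1], log2(1e6 + 1))
  expect_equal(normalize_log2cpm(m * 2), lc)           # CPM invariance
  # monotone within sample
  expect_true(all(diff(lc[order(m[, 1]), 1]) >= 0))
  bad <- m; bad[, 2] <- 0
  expect_error(normalize_log2cpm(bad), "zero library")
})

test_that("gene filtering applies the three steps in order with a hard cap", {
  set.seed(5)
  n <- 8300
  m <- matrix(rnorm(n * 10, sd = rep(seq(0.2, 2, length.out = n), 10)),
              nrow = n)
  rownames(m) <- sprintf("gene%05d", seq_len(n))
  rownames(m)[1:100] <- sprintf("Rpl%03d", 1:100)
  rownames(m)[101:150] <- sprintf("mt-X%03d", 1:50)
  m[151:200, ] <- 3                                    # constant genes, MAD 0
  f <- filter_genes(m)
  expect_equal(nrow(f$matrix), 5000)                   # exact cap
  expect_false(any(grepl("^Rpl|^mt-", rownames(f$matrix))))
  expect_false("gene00151" %in% rownames(f$matrix))    # constant removed
  expect_equal(f$report$removed[f$report$step == "housekeeping"], 150)
  # fewer genes than the cap: keep all, warn
  expect_warning(fs <- filter_genes(m[1:500, ]), "keeping all")
  expect_lte(nrow(fs$matrix), 500)
})

test_that("soft threshold: override, structured data, and noise behaviour", {
  des <- balanced_design(7)
  # known per-cell-type powers are passed straight through the pipeline
  sim <- simulate_pseudobulk(des, glia_module_specs(), seed = 1)
  net <- build_network(sim$expr, beta = 14)
  expect_equal(dim(net$tom), dim(net$adjacency))

  # graded-loading structured data: a small power suffices
  simg <- simulate_pseudobulk(
    des, list(planted_module_spec("hub", 300, effect_e4 = 1, noise_sd = 0.3,
                                  loading_range = c(0, 1))),
    n_background_genes = 50, seed = 1)
  st <- pick_soft_threshold(simg$expr)
  expect_lte(st$power, 6)
  expect_gte(max(st$fit$r2[st$fit$power <= 6]), 0.8)

  # uncorrelated noise: poor fit at power 1, larger power selected
  set.seed(3)
  noise <- matrix(rnorm(200 * nrow(des)), 200,
                  dimnames = list(paste0("g", 1:200), des$sample_id))
  stn <- pick_soft_threshold(noise)
  expect_lt(stn$fit$r2[stn$fit$power == 1], 0.8)
  expect_gt(stn$power, 1)
  expect_error(pick_soft_threshold(noise[, 1:5]), ">= 8 samples")
})

test_that("network construction: perfect correlation, independence, TOM bounds", {
  s <- seq_len(12)
  two <- rbind(g1 = s, g2 = 2 * s + 3)
  colnames(two) <- paste0("s", 1:12)
  net <- build_network(two, 6)
  expect_equal(net$adjacency["g1", "g2"], 1)
  expect_equal(net$tom["g1", "g2"], 1)

  set.seed(4)
  ind <- matrix(rnorm(20 * 300), 20, dimnames = list(paste0("g", 1:20), NULL))
  neti <- build_network(ind, 6)
  expect_lt(max(neti$adjacency[upper.tri(neti$adjacency)]), 0.05)
  expect_lt(max(neti$tom[upper.tri(neti$tom)]), 0.05)
  expect_true(isSymmetric(neti$tom))
  expect_true(all(neti$tom >= 0 & neti$tom <= 1 + 1e-12))

  degen <- rbind(g1 = rep(1, 12), g2 = s)
  expect_error(build_network(degen, 6), "zero-variance")
})

test_that("module detection recovers planted blocks exactly when noiseless", {
  des <- balanced_design(6)
  sim <- simulate_pseudobulk(
    des,
    list(planted_module_spec("mA", 15, effect_e4 = 1, noise_sd = 0,
                             loading_range = c(0.5, 1)),
         planted_module_spec("mB", 12, effect_nlf = 1, noise_sd = 0,
                             loading_range = c(0.5, 1))),
    n_background_genes = 0, seed = 3)
  net <- build_network(sim$expr, 6)
  asg <- detect_modules(net$tom, sim$expr, min_module_size = 5)
  expect_equal(length(setdiff(unique(asg), "grey")), 2)
  expect_equal(mclust::adjustedRandIndex(asg, sim$gene_module), 1)

  # noisy planted modules with distinct latent programs recovered at
  # ARI >= 0.8 (SNR >= 3), at the study sample size of 7 per genotype;
  # three mutually orthogonal genotype programs: E4 contrast, NLF contrast,
  # and the pure interaction contrast (-1,-1,+2 parameterization)
  simn <- simulate_pseudobulk(
    balanced_design(7),
    list(planted_module_spec("d1", 30, effect_e4 = 2, noise_sd = 0.3),
         planted_module_spec("d2", 25, effect_nlf = 2, noise_sd = 0.3),
         planted_module_spec("d3", 20, effect_e4 = -2, effect_nlf = -2,
                             effect_interaction = 4, noise_sd = 0.3)),
    n_background_genes = 100, seed = 5)
  netn <- build_network(simn$expr, 6)
  asgn <- detect_modules(netn$tom, simn$expr, min_module_size = 10)
  expect_gte(mclust::adjustedRandIndex(asgn, simn$gene_module), 0.8)

  # pure noise: most genes grey
  set.seed(6)
  noise <- matrix(rnorm(120 * 24), 120,
                  dimnames = list(paste0("g", 1:120), des$sample_id))
  netx <- build_network(noise, 6)
  asgx <- suppressWarnings(detect_modules(netx$tom, noise,
                                          min_module_size = 10))
  expect_gt(mean(asgx == "grey"), 0.5)
})

test_that("eigengenes, kME and sign alignment satisfy their contracts", {
  des <- balanced_design(5)
  sim <- simulate_pseudobulk(des, neuron_module_specs(noise_sd = 0.2),
                             n_background_genes = 0, seed = 8)
  me <- module_eigengene(sim$expr, sim$gene_module)
  expect_equal(unname(sqrt(rowSums(me^2))), rep(1, nrow(me)))  # unit norm

  # kME matches an independent per-gene correlation recomputation
  km <- kme_table(sim$expr, me)
  for (g in sample(rownames(sim$expr), 10)) {
    for (mm in rownames(me)) {
      expect_equal(km[g, mm], cor(sim$expr[g, ], me[mm, ]),
                   tolerance = 1e-12)
    }
  }

  # PCA optimality: the ME direction explains at least as much variance as
  # any other sample-space direction (checked against random directions)
  mm <- "n1"
  sub <- t(scale(t(sim$expr[sim$gene_module == mm, ])))  # genes x samples
  X <- t(sub)                                            # samples x genes
  me_var <- sum((crossprod(X, me[mm, ]))^2)
  set.seed(99)
  for (i in 1:20) {
    w <- rnorm(ncol(sim$expr)); w <- w / sqrt(sum(w^2))
    expect_lte(sum((crossprod(X, w))^2), me_var + 1e-8)
  }

  # sign alignment: positive hub correlation afterwards, involution, flip
  al <- align_sign(me, km, sim$expr, sim$gene_module)
  hubs <- hub_genes(al$kme, sim$gene_module, n = 50)
  for (mm in rownames(al$me)) {
    expect_gt(cor(al$me[mm, ], colMeans(sim$expr[hubs[[mm]], ])), 0)
  }
  al2 <- align_sign(al$me, al$kme, sim$expr, sim$gene_module)
  expect_equal(al2$me, al$me)                          # involution
  neg <- al; neg$me["n1", ] <- -al$me["n1", ]; neg$kme[, "n1"] <- -al$kme[, "n1"]
  re <- align_sign(neg$me, neg$kme, sim$expr, sim$gene_module)
  expect_equal(re$me, al$me)
})

test_that("module of identical genes has ME proportional to the profile, kME 1", {
  prof <- sin(seq_len(16))
  expr <- rbind(g1 = prof, g2 = prof, g3 = prof)
  colnames(expr) <- paste0("s", 1:16)
  asg <- c(g1 = "M1", g2 = "M1", g3 = "M1")
  me <- module_eigengene(expr, asg)
  expect_equal(abs(cor(me["M1", ], prof)), 1)
  km <- kme_table(expr, me)
  expect_equal(abs(unname(km[, "M1"])), rep(1, 3))
})

test_that("WT centering: zero WT mean, unit WT SD, zero-variance guard", {
  des <- balanced_design(4)
  set.seed(10)
  me <- matrix(rnorm(2 * 16), 2, dimnames = list(c("M1", "M2"),
                                                 des$sample_id))
  cw <- wt_center(me, des, "wt_sd")
  wt <- des$genotype == "WT"
  expect_equal(unname(rowMeans(cw[, wt])), c(0, 0))
  expect_equal(unname(apply(cw[, wt], 1, sd)), c(1, 1))
  cp <- wt_center(me, des, "pooled_sd")
  expect_equal(unname(rowMeans(cp[, wt])), c(0, 0))

  cst <- matrix(5, 1, 16, dimnames = list("M1", des$sample_id))
  cc <- wt_center(cst, des, "wt_sd")
  expect_equal(attr(cc, "flagged"), "M1")
  expect_equal(unname(cc[1, ]), rep(0, 16))
  expect_error(wt_center(me[, 4:16], des[4:16, ], "wt_sd"), "WT samples")
})

test_that("contribution decomposition: closed forms and normalization", {
  des <- balanced_design(6)
  # noiseless E4-only additive effect -> proportions (1/2, 0, 1/2)
  sim <- simulate_pseudobulk(
    des, list(planted_module_spec("m", 20, effect_e4 = 1, noise_sd = 0)),
    n_background_genes = 0, seed = 7)
  r <- run_coexpression(sim$expr, des, assignment = sim$gene_module)
  expect_equal(unname(r$contribution$proportions), c(0.5, 0, 0.5),
               tolerance = 1e-12)

  # pure interaction -> (0, 0, 1)
  sim2 <- simulate_pseudobulk(
    des, list(planted_module_spec("m", 20, effect_interaction = 2,
                                  noise_sd = 0)),
    n_background_genes = 0, seed = 7)
  r2 <- run_coexpression(sim2$expr, des, assignment = sim2$gene_module)
  expect_equal(unname(r2$contribution$proportions), c(0, 0, 1),
               tolerance = 1e-12)

  # shares and proportions each sum to 1 on noisy data
  sim3 <- simulate_pseudobulk(des, glia_module_specs(), seed = 9)
  r3 <- run_coexpression(sim3$expr, des, assignment = sim3$gene_module)
  pm <- r3$contribution$per_module
  expect_true(all(abs(rowSums(pm[, c("share_E4", "share_NLF",
                                     "share_E4NLF")]) - 1) < 1e-12))
  expect_lt(abs(sum(r3$contribution$proportions) - 1), 1e-12)
})

test_that("zero-shift modules are excluded from shares but kept in totals", {
  des <- balanced_design(3)
  me <- rbind(M1 = rep(c(0, 1, 0, 1), each = 3),   # E4/E4NLF shift
              M2 = rep(0, 12))
  colnames(me) <- des$sample_id
  ct <- contribution(me, des)
  expect_true(all(is.na(ct$per_module[ct$per_module$module == "M2",
                                      c("share_E4", "share_NLF",
                                        "share_E4NLF")])))
  expect_equal(unname(ct$proportions), c(0.5, 0, 0.5))
})

test_that("contribution comparison: Bonferroni, ties, separation oracle", {
  a <- data.frame(share_E4 = c(.1, .2, .3, .15), share_NLF = c(.2, .3, .1, .2),
                  share_E4NLF = c(.7, .5, .6, .65))
  b <- data.frame(share_E4 = c(.5, .6, .7, .55),
                  share_NLF = c(.3, .2, .25, .28),
                  share_E4NLF = c(.2, .18, .05, .15))
  res <- compare_contributions(a, b)
  expect_equal(res$p_bonferroni, pmin(1, 3 * res$p))
  # completely separated: minimal exact two-sided p = 2 / choose(8, 4)
  expect_equal(res$p[res$component == "share_E4NLF"], 2 / choose(8, 4))

  ties <- data.frame(share_E4 = rep(.3, 3), share_NLF = rep(.3, 3),
                     share_E4NLF = rep(.4, 3))
  rt <- compare_contributions(ties, ties)
  expect_true(all(rt$p == 1))
  expect_error(compare_contributions(a[1:2, ], b), ">= 3")
})

test_that("two-way ANOVA matches aov and Fisher aggregation matches its oracle", {
  des <- balanced_design(4)
  set.seed(12)
  expr <- matrix(rnorm(6 * 16), 6,
                 dimnames = list(paste0("g", 1:6), des$sample_id))
  expr[1, ] <- expr[1, ] + 1.5 * des$e4
  ga <- gene_two_way_anova(expr, des)
  for (i in 1:6) {
    ref <- summary(stats::aov(expr[i, ] ~ factor(e4) * factor(nlf),
                              data = des))[[1]]
    expect_equal(c(ga$p_E4[i], ga$p_NLF[i], ga$p_int[i]),
                 ref[["Pr(>F)"]][1:3], tolerance = 1e-10)
  }

  # Fisher combination vs closed-form Erlang survival oracle, to 1e-10
  asg <- setNames(rep(c("M1", "M2"), each = 3), paste0("g", 1:6))
  af <- aggregate_fisher(ga, asg)
  for (mm in c("M1", "M2")) {
    genes <- names(asg)[asg == mm]
    x2 <- -2 * sum(log(ga$p_E4[match(genes, ga$gene)]))
    expect_equal(af$p_combined[af$module == mm & af$term == "E4"],
                 chisq_sf_even(x2, length(genes)), tolerance = 1e-10)
  }
  # k = 1 identity and all-ones degenerate case
  g1 <- data.frame(gene = "g", p_E4 = 0.05, p_NLF = 1, p_int = 1,
                   eta2_E4 = 0.1, eta2_NLF = 0, eta2_int = 0)
  a1 <- aggregate_fisher(g1, c(g = "M1"))
  expect_equal(a1$p_combined[a1$term == "E4"], 0.05)
  expect_equal(a1$p_combined[a1$term == "NLF"], 1)
})

test_that("ME contrasts: null exactness, planted power, BH monotonicity", {
  des <- balanced_design(6)
  # identical group patterns -> zero estimates, p = 1
  patt <- rep(c(-1, 0, 1, -2, 2, 0), times = 4)
  me0 <- matrix(patt, 1, dimnames = list("M1", des$sample_id))
  mc0 <- me_contrasts(me0, des)
  expect_equal(mc0$estimate, rep(0, 3))
  expect_equal(mc0$p, rep(1, 3))

  # planted 3 SD shift in E4 only at n = 6/group: E4 significant, NLF not
  set.seed(14)
  me1 <- matrix(rnorm(24), 1, dimnames = list("M1", des$sample_id))
  me1[1, des$genotype %in% c("E4", "E4NLF")] <-
    me1[1, des$genotype %in% c("E4", "E4NLF")] + 3
  mc1 <- me_contrasts(me1, des)
  expect_true(mc1$significant[mc1$contrast == "E4_vs_WT"])
  expect_false(mc1$significant[mc1$contrast == "NLF_vs_WT"])

  # BH adjusted p non-decreasing in raw-p rank
  set.seed(15)
  meN <- matrix(rnorm(5 * 24), 5,
                dimnames = list(paste0("M", 1:5), des$sample_id))
  mcN <- me_contrasts(meN, des)
  o <- order(mcN$p)
  expect_true(all(diff(mcN$p_adj[o]) >= -1e-12))
})

test_that("edge export respects the inclusive threshold and module structure", {
  # two genes with exact correlations around the boundary
  s <- seq_len(10)
  set.seed(16)
  base <- rnorm(10)
  make_pair <- function(r) {
    y <- r * scale(base)[, 1] + sqrt(1 - r^2) * scale(rnorm(10))[, 1]
    rbind(a = scale(base)[, 1], b = y)
  }
  des <- balanced_design(5)
  sim <- simulate_pseudobulk(des, neuron_module_specs(noise_sd = 0),
                             n_background_genes = 0, seed = 17)
  r <- run_coexpression(sim$expr, des, assignment = sim$gene_module)
  ex <- export_edges(sim$expr, r$assignment, r$kme, threshold = 0.3)
  # noiseless planted block: complete within-module graphs
  n_by_mod <- table(sim$gene_module)
  expect_equal(nrow(ex$edges),
               sum(choose(n_by_mod, 2)))
  expect_true(all(ex$edges$gene_a < ex$edges$gene_b))   # canonical order
  expect_true(all(abs(ex$edges$r) >= 0.3))

  # boundary: r just below threshold excluded, exactly at threshold kept
  expr2 <- matrix(rnorm(40), 4, dimnames = list(paste0("g", 1:4), NULL))
  km2 <- matrix(0.5, 4, 1, dimnames = list(rownames(expr2), "M1"))
  asg2 <- setNames(rep("M1", 4), rownames(expr2))
  ex2 <- export_edges(expr2, asg2, km2, threshold = 1.01)
  expect_equal(nrow(ex2$edges), 0)
})

test_that("hub genes: ranking, caps and tie handling", {
  des <- balanced_design(5)
  sim <- simulate_pseudobulk(des, list(
    planted_module_spec("m", 10, effect_e4 = 1, noise_sd = 0.3)),
    n_background_genes = 0, seed = 18)
  r <- run_coexpression(sim$expr, des, assignment = sim$gene_module)
  h <- hub_genes(r$kme, r$assignment, n = 25)
  expect_length(h$m, 10)                     # smaller module: all, no padding
  # ranking equals a brute-force sort of recomputed correlations
  brute <- names(sort(-abs(vapply(rownames(sim$expr), function(g) {
    cor(sim$expr[g, ], r$me["m", ])
  }, numeric(1)))))
  expect_equal(h$m, brute)
})

test_that("module gene heatmap values: guard, WT column, cap", {
  des <- balanced_design(4)
  sim <- simulate_pseudobulk(des, list(
    planted_module_spec("m", 150, effect_e4 = 1, noise_sd = 0.3)),
    n_background_genes = 0, seed = 19)
  r <- run_coexpression(sim$expr, des, assignment = sim$gene_module)
  hv <- module_gene_heatmap_values(sim$expr, r$assignment, "m", des,
                                   kme = r$kme)
  expect_equal(nrow(hv$centered_means), 100)          # top-100 cap
  expect_equal(unname(hv$centered_means[, "WT"]),
               rep(0, 100))                           # WT column centered to 0

  cst <- rbind(flat = rep(2, nrow(des)))
  colnames(cst) <- des$sample_id
  hv2 <- module_gene_heatmap_values(cst, c(flat = "m"), "m", des)
  expect_equal(unname(hv2$centered_means["flat", ]), rep(0, 4))  # guard
})

test_that("neuron and glia conditions separate by interaction dominance", {
  des <- balanced_design(7)
  simn <- simulate_pseudobulk(des, neuron_module_specs(), seed = 21)
  simg <- simulate_pseudobulk(des, glia_module_specs(), seed = 22)
  pn <- run_coexpression(simn$expr, des, beta = 6)$contribution$proportions
  pg <- run_coexpression(simg$expr, des, beta = 6)$contribution$proportions
  expect_equal(names(which.max(pn)), "c_E4NLF")
  expect_false(names(which.max(pg)) == "c_E4NLF")
})
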