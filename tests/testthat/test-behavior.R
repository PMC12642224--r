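# Behavior module: bouts, usage, clustering, transitions, permutation test.

test_that("movement binarization uses a strict threshold and rejects bad input", {
  expect_equal(binarize_movement(c(0, 0, 0), 1)$states, c(0L, 0L, 0L))
  expect_equal(binarize_movement(c(2, 2), 2)$states, c(0L, 0L))  # boundary
  expect_equal(binarize_movement(c(3, 1, 3, 1), 2)$states, c(1L, 0L, 1L, 0L))
  expect_error(binarize_movement(c(-1, 2), 1), "negative")
})

test_that("bout metrics match hand enumeration", {
  s <- list(states = c(1L, 1L, 0L, 0L, 1L), bin_width = 0.5,
            displacements = c(2, 2, 0, 0, 2))
  m <- bout_metrics(s)
  expect_equal(m$n_moving_bouts, 2)
  expect_equal(m$n_still_bouts, 1)
  expect_equal(m$n_transitions, 2)
  expect_equal(m$mean_moving_duration, 0.75)
  expect_equal(m$mean_still_duration, 1)

  all1 <- bout_metrics(list(states = rep(1L, 8), bin_width = 0.5,
                            displacements = rep(1.5, 8)))
  expect_equal(all1$n_moving_bouts, 1)
  expect_equal(all1$n_transitions, 0)
  expect_true(is.na(all1$mean_still_duration))  # never-visited state undefined
  # straight-line constant velocity: speed equals that velocity
  expect_equal(all1$moving_speed, 1.5 / 0.5)
})

test_that("motif usage rows are simplex vectors", {
  s1 <- motif_sequence("a1", "WT", rep("A", 10))
  s2 <- motif_sequence("a2", "E4", c("A", "A", "B", "B"))
  u <- motif_usage(list(s1, s2))
  expect_equal(unname(u["a1", ]), c(1, 0))
  expect_equal(unname(u["a2", ]), c(0.5, 0.5))
  P <- fixture_transition_matrix(4)
  seqs <- simulate_motif_sequences(list(WT = P, E4 = P), 3, 500, seed = 2)
  u2 <- motif_usage(seqs)
  expect_true(all(abs(rowSums(u2) - 1) < 1e-12))
  expect_error(motif_usage(list()), "no sequences")
})

test_that("usage dissimilarity is 1 - Pearson r with zero-variance flagging", {
  a <- c(0.5, 0.3, 0.2)
  u <- rbind(a = a, b = 2 / 3 - a,     # deviations exactly negated: r = -1
             c = c(0.5, 0.25, 0.25))
  ref <- c(0.55, 0.3, 0.15)
  d <- usage_dissimilarity(u, ref)
  expect_equal(diag(d$dissimilarity), c(a = 0, b = 0, c = 0))
  # perfectly anti-correlated profiles reach 2
  expect_equal(d$dissimilarity["a", "b"], 2)
  # matches an independent correlation recomputation
  for (i in rownames(u)) {
    expect_equal(d$wt_dissimilarity[[i]], 1 - cor(u[i, ], ref))
  }
  uz <- rbind(u, z = c(1, 1, 1) / 3)
  dz <- usage_dissimilarity(uz, ref)
  expect_equal(dz$flagged, "z")
  expect_true(is.na(dz$wt_dissimilarity["z"]))
})

test_that("hierarchical clustering keeps planted blocks contiguous and is label-equivariant", {
  set.seed(7)
  d_small <- matrix(0.1, 8, 8)             # two blocks 1:4 and 5:8
  d_small[1:4, 5:8] <- d_small[5:8, 1:4] <- 0.9
  diag(d_small) <- 0
  dimnames(d_small) <- list(letters[1:8], letters[1:8])
  cl <- hierarchical_cluster(d_small)
  blk <- (cl$order > 4)[order(seq_along(cl$order))]
  expect_equal(length(rle(cl$order > 4)$values), 2)  # blocks contiguous
  expect_equal(sort(cl$order), 1:8)                  # a permutation

  two <- matrix(c(0, 0.4, 0.4, 0), 2, dimnames = list(c("x", "y"), c("x", "y")))
  cl2 <- hierarchical_cluster(two)
  expect_equal(cl2$tree$height, 0.4)                 # single merge there

  # permuting input order changes labels, not topology (same merge heights)
  perm <- sample(8)
  clp <- hierarchical_cluster(d_small[perm, perm])
  expect_equal(sort(clp$tree$height), sort(cl$tree$height))

  bad <- d_small; bad[1, 2] <- NA
  expect_error(hierarchical_cluster(bad), "NaN|NA")
})

test_that("motif transition matrices match hand enumeration and flag degenerate rows", {
  tm <- motif_transition_matrix(list(labels = c("A", "A", "B", "A", "C")))
  expect_equal(tm$values["A", "B"], 0.5)
  expect_equal(tm$values["A", "C"], 0.5)
  expect_equal(tm$values["B", "A"], 1)
  expect_equal(tm$flagged_rows, "C")
  expect_true(all(is.na(tm$values["C", ])))

  t2 <- motif_transition_matrix(list(labels = c("A", "A", "A")))
  expect_equal(t2$flagged_rows, "A")
  expect_error(motif_transition_matrix(list(labels = "A")), ">= 2 frames")
})

test_that("small-instance oracle: transition matrices equal exhaustive enumeration", {
  set.seed(13)
  motifs <- c("A", "B", "C", "D")
  for (rep in 1:25) {
    labs <- sample(motifs, sample(2:10, 1), replace = TRUE)
    got <- motif_transition_matrix(list(labels = labs), motifs = motifs)$values
    expect_equal(got, brute_transition(labs, motifs))
  }
})

test_that("community averaging is the unweighted motif-pair mean within bounds", {
  v <- matrix(NA_real_, 3, 3,
              dimnames = list(c("m1", "m2", "m3"), c("m1", "m2", "m3")))
  v["m1", "m3"] <- 0.2; v["m2", "m3"] <- 0.4
  v["m1", "m2"] <- 0.1; v["m2", "m1"] <- 0.3
  v["m3", "m1"] <- 1; v["m3", "m2"] <- 0             # observed zero, not NA
  tm <- transition_matrix(v, "motif")
  map <- c(m1 = "P", m2 = "P", m3 = "Q")
  cm <- community_transition_matrix(tm, map)
  expect_equal(cm$values["P", "Q"], 0.3)             # hand average
  expect_equal(cm$values["Q", "P"], (1 + 0) / 2)     # unweighted pair mean
  expect_true(all(cm$values >= 0 & cm$values <= 1, na.rm = TRUE))

  # one motif per community: community matrix equals motif off-diagonals
  idmap <- c(m1 = "X", m2 = "Y", m3 = "Z")
  cid <- community_transition_matrix(tm, idmap)
  expect_equal(unname(cid$values["X", "Z"]), unname(v["m1", "m3"]))
  expect_error(community_transition_matrix(tm, c(m1 = "P")), "unmapped")
})

test_that("animal averaging and delta matrices behave element-wise", {
  mk <- function(x) {
    v <- matrix(c(NA, x, 1 - x, NA), 2, byrow = TRUE,
                dimnames = list(c("P", "Q"), c("P", "Q")))
    transition_matrix(v, "community")
  }
  avg <- animal_average(list(mk(0.2), mk(0.6)))
  expect_equal(avg$values["P", "Q"], 0.4)
  expect_equal(animal_average(list(mk(0.3)))$values, mk(0.3)$values)
  expect_error(animal_average(list(mk(0.3), transition_matrix(
    mk(0.3)$values, "motif"))), "mixed")

  d0 <- delta_transition(list(mk(0.4), mk(0.6)), list(mk(0.4), mk(0.6)))
  expect_equal(d0$values["P", "Q"], 0)
  d1 <- delta_transition(list(mk(0.5), mk(0.5)), list(mk(0.4), mk(0.4)))
  expect_equal(d1$values["P", "Q"], 0.1)             # inflated -> positive
  expect_equal(d1$values["Q", "P"], -0.1)
})

test_that("permutation test: add-one p-values, exact behaviour at the extremes", {
  mk <- function(x) {
    v <- matrix(c(NA, x, 1 - x, NA), 2, byrow = TRUE,
                dimnames = list(c("P", "Q"), c("P", "Q")))
    transition_matrix(v, "community")
  }
  # identical groups -> delta 0 -> p = 1 everywhere
  g <- list(mk(0.5), mk(0.5)); w <- list(mk(0.5), mk(0.5))
  pr <- permutation_test(g, w, n_perm = 199, seed = 1)
  expect_true(all(pr$p_two_sided == 1, na.rm = TRUE))

  # fully separated groups -> p at (or near) the attainable minimum
  g2 <- lapply(c(0.9, 0.91, 0.92, 0.93), mk)
  w2 <- lapply(c(0.1, 0.11, 0.12, 0.13), mk)
  pr2 <- permutation_test(g2, w2, n_perm = 999, seed = 2)
  expect_gte(min(pr2$p_two_sided, na.rm = TRUE), 1 / 1000)
  expect_lt(min(pr2$p_two_sided, na.rm = TRUE), 0.05)

  expect_error(permutation_test(list(mk(0.5)), list(), n_perm = 100),
               ">= 1|>= 3")
  expect_error(permutation_test(g, w, n_perm = 10), "n_perm")
})

test_that("usage delta index is the genotype-minus-WT mean per motif", {
  u <- rbind(c(0.6, 0.4), c(0.5, 0.5), c(0.2, 0.8), c(0.3, 0.7))
  colnames(u) <- c("A", "B")
  gt <- c("WT", "WT", "E4", "E4")
  d <- usage_delta_index(u, gt)
  expect_equal(unname(d["WT", ]), c(0, 0))
  expect_equal(unname(d["E4", "A"]), 0.25 - 0.55)
})
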