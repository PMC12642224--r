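#' Construct a motif sequence object
#'
#' A per-animal sequence of frame-wise behavioral motif labels, as produced by
#' unsupervised pose-sequence segmentation, together with the animal's
#' genotype and the video frame rate.
#'
#' @param animal_id animal identifier.
#' @param genotype_label genotype group label.
#' @param labels character vector of motif labels, one per frame (non-empty).
#' @param frame_rate frames per second.
#' @return An object of class `motif_sequence`.
#' @export
motif_sequence <- function(animal_id, genotype_label, labels, frame_rate = 30) {
  labels <- as.character(labels)
  if (length(labels) == 0) stop("labels must be non-empty")
  stopifnot(frame_rate > 0)
  structure(
    list(animal_id = as.character(animal_id),
         genotype_label = as.character(genotype_label),
         labels = labels, frame_rate = frame_rate),
    class = "motif_sequence"
  )
}

#' @export
print.motif_sequence <- function(x, ...) {
  cat(sprintf("<motif_sequence> animal %s (%s): %d frames @ %g fps, %d motifs\n",
              x$animal_id, x$genotype_label, length(x$labels), x$frame_rate,
              length(unique(x$labels))))
  invisible(x)
}

check_stochastic <- function(P, what = "transition matrix") {
  if (!is.matrix(P) || nrow(P) != ncol(P)) stop(what, " must be square")
  if (is.null(rownames(P))) {
    rownames(P) <- colnames(P) <- paste0("m", seq_len(nrow(P)))
  }
  if (any(P < 0)) stop(what, " has negative entries")
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-8)) {
    stop(what, " rows must sum to 1 (row-stochastic)")
  }
  P
}

#' Simulate first-order Markov motif sequences per genotype
#'
#' Each animal's label sequence is drawn as a first-order Markov chain from
#' its genotype's transition matrix; empirical transition frequencies converge
#' to the generator as the number of frames grows.
#'
#' @param transition_matrices named list, genotype label -> row-stochastic
#'   motif transition matrix (all matrices share motif labels).
#' @param n_animals animals per genotype (scalar or named vector).
#' @param n_frames frames per animal (>= 2).
#' @param usage_init initial state distribution; default uniform.
#' @param frame_rate frames per second.
#' @param seed integer RNG seed.
#' @return A list of [motif_sequence()] objects.
#' @export
simulate_motif_sequences <- function(transition_matrices, n_animals, n_frames,
                                     usage_init = NULL, frame_rate = 30,
                                     seed = 1) {
  stopifnot(n_frames >= 2, length(transition_matrices) >= 1)
  if (is.null(names(transition_matrices))) {
    stop("transition_matrices must be a named list (genotype -> matrix)")
  }
  transition_matrices <- lapply(transition_matrices, check_stochastic)
  k <- nrow(transition_matrices[[1]])
  motifs <- rownames(transition_matrices[[1]])
  for (P in transition_matrices) {
    if (!identical(rownames(P), motifs)) stop("matrices must share motif labels")
  }
  if (is.null(usage_init)) usage_init <- rep(1 / k, k)
  stopifnot(length(usage_init) == k, all(usage_init >= 0),
            abs(sum(usage_init) - 1) < 1e-8)
  genos <- names(transition_matrices)
  if (length(n_animals) == 1) {
    n_animals <- stats::setNames(rep(n_animals, length(genos)), genos)
  }
  set.seed(as.integer(seed))
  out <- list()
  for (g in genos) {
    cum <- t(apply(transition_matrices[[g]], 1, cumsum))
    for (a in seq_len(n_animals[[g]])) {
      x <- integer(n_frames)
      x[1] <- findInterval(stats::runif(1), cumsum(usage_init),
                           left.open = TRUE) + 1L
      u <- stats::runif(n_frames - 1)
      for (t in 2:n_frames) {
        x[t] <- findInterval(u[t - 1L], cum[x[t - 1L], ], left.open = TRUE) + 1L
      }
      out[[length(out) + 1L]] <- motif_sequence(
        sprintf("%s_a%02d", g, a), g, motifs[x], frame_rate)
    }
  }
  out
}
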