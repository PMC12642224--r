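#' Binarize per-bin displacement into a moving/still state series
#'
#' A bin is "moving" (state 1) iff its displacement strictly exceeds the
#' movement threshold; a displacement exactly at the threshold is "not
#' moving" (strict inequality).
#'
#' @param displacements non-negative per-bin displacement (distance units).
#' @param threshold movement threshold (> 0), same units.
#' @param bin_width bin width in seconds (default 0.5).
#' @param animal_id optional identifier carried through.
#' @return An object of class `bout_series`: list with `states` (0/1 integer
#'   vector), `displacements`, `bin_width`, `animal_id`.
#' @export
binarize_movement <- function(displacements, threshold, bin_width = 0.5,
                              animal_id = NA_character_) {
  stopifnot(threshold > 0, bin_width > 0)
  if (any(displacements < 0)) stop("negative displacement")
  structure(
    list(states = as.integer(displacements > threshold),
         displacements = as.numeric(displacements),
         bin_width = bin_width, animal_id = animal_id),
    class = "bout_series"
  )
}

#' Bout structure metrics of a binary movement series
#'
#' Consecutive bins with identical states are grouped into bouts. Mean bout
#' duration is total time in the state divided by the number of bouts; a state
#' never visited has `NA` (undefined) mean duration, not zero. Moving speed is
#' total distance over moving bins divided by total moving time.
#'
#' @param series a [binarize_movement()] result (or compatible list).
#' @return A one-row data frame: `n_moving_bouts`, `n_still_bouts`,
#'   `n_transitions`, `mean_moving_duration`, `mean_still_duration` (s),
#'   `moving_speed` (distance/s; `NA` if never moving).
#' @export
bout_metrics <- function(series) {
  s <- series$states
  if (length(s) == 0) stop("empty series")
  bw <- series$bin_width
  r <- rle(s)
  n_mov <- sum(r$values == 1L)
  n_still <- sum(r$values == 0L)
  t_mov <- sum(s == 1L) * bw
  t_still <- sum(s == 0L) * bw
  speed <- if (t_mov > 0 && !is.null(series$displacements)) {
    sum(series$displacements[s == 1L]) / t_mov
  } else NA_real_
  data.frame(
    n_moving_bouts = n_mov,
    n_still_bouts = n_still,
    n_transitions = length(r$values) - 1L,
    mean_moving_duration = if (n_mov > 0) t_mov / n_mov else NA_real_,
    mean_still_duration = if (n_still > 0) t_still / n_still else NA_real_,
    moving_speed = speed
  )
}
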