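#' Read and write the pipeline's delimited text formats
#'
#' Plain-text interchange for the four modalities: motif sequences as
#' (frame, motif_id) tables, community maps as two-column tables, recordings
#' as per-sample trace tables with the sampling rate in a header comment,
#' fEPSP sweeps as (t_ms, mV) tables, and count matrices as MatrixMarket
#' (MTX) plus feature/sample TSVs.
#'
#' @param x object to write (see the individual functions).
#' @param path file path.
#' @name phenomod-io
NULL

#' @rdname phenomod-io
#' @param seq_obj a [motif_sequence()].
#' @export
write_motif_sequence <- function(seq_obj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# animal_id=%s genotype=%s frame_rate=%g",
                     seq_obj$animal_id, seq_obj$genotype_label,
                     seq_obj$frame_rate), con)
  utils::write.table(
    data.frame(frame = seq_along(seq_obj$labels), motif_id = seq_obj$labels),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname phenomod-io
#' @export
read_motif_sequence <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  motif_sequence(kv[["animal_id"]], kv[["genotype"]],
                 as.character(tab$motif_id),
                 as.numeric(kv[["frame_rate"]]))
}

#' @rdname phenomod-io
#' @param map named character vector motif -> community.
#' @export
write_community_map <- function(map, path) {
  utils::write.table(
    data.frame(motif_id = names(map), community = unname(map)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname phenomod-io
#' @export
read_community_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           colClasses = "character")
  stats::setNames(tab$community, tab$motif_id)
}

#' @rdname phenomod-io
#' @param rec an `eeg_recording` (or compatible list).
#' @export
write_recording <- function(rec, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sampling_rate=%g", rec$sampling_rate), con)
  utils::write.table(
    data.frame(eeg = rec$eeg, emg = rec$emg, movement = rec$movement),
    con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname phenomod-io
#' @export
read_recording <- function(path) {
  hdr <- readLines(path, n = 1)
  fs <- as.numeric(sub(".*sampling_rate=([0-9.]+).*", "\\1", hdr))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(eeg = tab$eeg, emg = tab$emg, movement = tab$movement,
       sampling_rate = fs)
}

#' @rdname phenomod-io
#' @param h a [hypnogram()].
#' @export
write_hypnogram <- function(h, path) {
  utils::write.table(
    data.frame(epoch = seq_along(h$states), state = h$states,
               epoch_len = h$epoch_len),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname phenomod-io
#' @param sweep a single fEPSP sweep.
#' @export
write_sweep <- function(sweep, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stimulus_time=%g intensity=%g", sweep$stimulus_time,
                     sweep$intensity), con)
  utils::write.table(data.frame(t_ms = sweep$time, mV = sweep$voltage),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname phenomod-io
#' @export
read_sweep <- function(path) {
  hdr <- readLines(path, n = 1)
  kv <- regmatches(hdr, gregexpr("[a-z_]+=[^ ]+", hdr))[[1]]
  kv <- stats::setNames(sub(".*=", "", kv), sub("=.*", "", kv))
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  list(time = tab$t_ms, voltage = tab$mV,
       stimulus_time = as.numeric(kv[["stimulus_time"]]),
       intensity = suppressWarnings(as.numeric(kv[["intensity"]])))
}

#' @rdname phenomod-io
#' @param counts gene x sample (or gene x cell) count matrix.
#' @param dir output directory; writes `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv`.
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
}

#' @rdname phenomod-io
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  rownames(m) <- readLines(file.path(dir, "features.tsv"))
  colnames(m) <- readLines(file.path(dir, "barcodes.tsv"))
  m
}
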