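#' Continuous multichannel EEG recording
#'
#' @param data numeric matrix, time x channel, in microvolts.
#' @param fs_hz sampling rate in Hz.
#' @param montage an [channel_montage()] whose size matches `ncol(data)`.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs_hz, montage) {
  data <- as.matrix(data)
  if (!is.numeric(data) || any(!is.finite(data)))
    stop("recording data must be a finite numeric matrix")
  if (!inherits(montage, "eeg_montage")) stop("montage must be an eeg_montage")
  if (ncol(data) != length(montage$names))
    stop("channel count (", ncol(data), ") does not match montage (",
         length(montage$names), ")")
  if (!is.numeric(fs_hz) || length(fs_hz) != 1 || fs_hz <= 0)
    stop("fs_hz must be a positive scalar")
  colnames(data) <- montage$names
  structure(list(data = data, fs_hz = fs_hz, montage = montage),
            class = "eeg_recording")
}

# fast path for internally produced data already known to be valid
new_recording <- function(data, fs_hz, montage) {
  structure(list(data = data, fs_hz = fs_hz, montage = montage),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat("<eeg_recording> ", ncol(x$data), " channels x ",
      nrow(x$data), " samples @ ", x$fs_hz, " Hz (",
      round(nrow(x$data) / x$fs_hz, 2), " s)\n", sep = "")
  invisible(x)
}

#' Set of fixed-length EEG epochs
#'
#' @param epochs 3-D numeric array, epoch x time x channel (microvolts).
#' @param fs_hz sampling rate in Hz.
#' @param montage the channel montage.
#' @param epoch_length_s nominal epoch length in seconds.
#' @param rejected_count number of epochs removed by artifact rejection.
#' @return An object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(epochs, fs_hz, montage, epoch_length_s,
                       rejected_count = 0L) {
  if (length(dim(epochs)) != 3) stop("epochs must be a 3-D array")
  n_samp <- round(epoch_length_s * fs_hz)
  if (dim(epochs)[2] != n_samp)
    stop("epoch length mismatch: expected ", n_samp, " samples per epoch")
  if (dim(epochs)[3] != length(montage$names))
    stop("channel count does not match montage")
  structure(list(epochs = epochs, fs_hz = fs_hz, montage = montage,
                 epoch_length_s = epoch_length_s,
                 rejected_count = as.integer(rejected_count)),
            class = "eeg_epochs")
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$epochs)
  cat("<eeg_epochs> ", d[1], " epochs x ", d[2], " samples x ", d[3],
      " channels @ ", x$fs_hz, " Hz; ", x$rejected_count, " rejected\n",
      sep = "")
  invisible(x)
}

n_epochs <- function(ep) dim(ep$epochs)[1]

#' Write / read a recording as a flat matrix plus JSON sidecar
#'
#' The signal is stored as a plain whitespace-delimited text matrix
#' (time x channel, microvolts) next to a `.json` sidecar carrying the
#' channel names, sampling rate, units and regional electrode sets.
#'
#' @param rec an `eeg_recording`.
#' @param path base file path; `path` gets the matrix, `path.json` the
#'   sidecar.
#' @return `write_recording` returns `path` invisibly; `read_recording`
#'   returns an `eeg_recording`.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(rec$data, path, row.names = FALSE, col.names = FALSE)
  sidecar <- list(
    channels = rec$montage$names,
    fs_hz = rec$fs_hz,
    units = "uV",
    anterior_set = rec$montage$anterior_set,
    posterior_set = rec$montage$posterior_set,
    positions = unname(apply(rec$montage$positions, 1, as.numeric,
                             simplify = FALSE)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  data <- as.matrix(utils::read.table(path))
  pos <- sidecar$positions
  pos <- if (is.matrix(pos)) pos else do.call(rbind, lapply(pos, as.numeric))
  montage <- channel_montage(sidecar$channels, pos,
                             anterior_set = sidecar$anterior_set %||% character(),
                             posterior_set = sidecar$posterior_set %||% character())
  eeg_recording(data, sidecar$fs_hz, montage)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
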