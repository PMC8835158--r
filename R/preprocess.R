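# -- zero-phase FIR filtering ------------------------------------------------
#
# Filters are windowed-sinc (Hamming) FIR designs from signal::fir1, applied
# zero-phase by multiplying the spectrum with |H(f)|^2 — the magnitude
# response of a forward-backward pass — after odd reflection padding at both
# ends to suppress edge transients. FFT application keeps long kernels cheap.

fir_order <- function(fs_hz, trans_hz, n_samples) {
  ord <- ceiling(3.3 * fs_hz / trans_hz)
  ord <- ord + ord %% 2            # even order, type-I linear phase
  max(4L, min(ord, 2L * (n_samples %/% 3L)))
}

# FIR designs are deterministic in (order, edges, type); cache them
.fir_cache <- new.env(parent = emptyenv())
fir_design <- function(ord, w, type) {
  key <- paste(ord, paste(signif(w, 12), collapse = ","), type, sep = "|")
  b <- .fir_cache[[key]]
  if (is.null(b)) {
    b <- signal::fir1(ord, w, type = type)
    .fir_cache[[key]] <- b
  }
  b
}

apply_fir_zerophase <- function(x, b) {
  x <- as.matrix(x)
  n <- nrow(x)
  nb <- length(b)
  p <- min(nb, n - 1L)
  # odd reflection about the end points (as in filtfilt)
  top <- 2 * matrix(x[1, ], p, ncol(x), byrow = TRUE) - x[(p + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], p, ncol(x), byrow = TRUE) - x[(n - 1):(n - p), , drop = FALSE]
  xp <- rbind(top, x, bot)
  l <- nrow(xp)
  nfft <- stats::nextn(l + nb, c(2, 3, 5))
  h2 <- Mod(stats::fft(c(b, numeric(nfft - nb))))^2
  xpad <- rbind(xp, matrix(0, nfft - l, ncol(xp)))
  y <- Re(stats::mvfft(stats::mvfft(xpad) * h2, inverse = TRUE)) / nfft
  y[(p + 1):(p + n), , drop = FALSE]
}

# one forward FFT, several zero-phase responses: returns the broadband
# (bandpass [+ notch]) signal and the same signal further restricted to
# the microstate analysis band, as two recordings
filter_broadband_and_msband <- function(rec, low_hz, high_hz, notch_hz,
                                        ms_band = c(2, 20)) {
  x <- rec$data
  n <- nrow(x)
  fs <- rec$fs_hz
  nyq <- fs / 2
  b_bp <- fir_design(fir_order(fs, min(1, low_hz), n),
                     c(low_hz, high_hz) / nyq, "pass")
  b_ms <- fir_design(fir_order(fs, 1, n), ms_band / nyq, "pass")
  b_nt <- if (!is.null(notch_hz) && notch_hz < nyq - 2)
    fir_design(fir_order(fs, 2, n), c(notch_hz - 2, notch_hz + 2) / nyq,
               "stop") else NULL
  nbmax <- max(length(b_bp), length(b_ms), length(b_nt))
  p <- min(nbmax, n - 1L)
  top <- 2 * matrix(x[1, ], p, ncol(x), byrow = TRUE) - x[(p + 1):2, , drop = FALSE]
  bot <- 2 * matrix(x[n, ], p, ncol(x), byrow = TRUE) - x[(n - 1):(n - p), , drop = FALSE]
  xp <- rbind(top, x, bot)
  l <- nrow(xp)
  nfft <- stats::nextn(l + nbmax, c(2, 3, 5))
  X <- stats::mvfft(rbind(xp, matrix(0, nfft - l, ncol(xp))))
  h2 <- function(b) Mod(stats::fft(c(b, numeric(nfft - length(b)))))^2
  h_bb <- h2(b_bp)
  if (!is.null(b_nt)) h_bb <- h_bb * h2(b_nt)
  inv <- function(h) Re(stats::mvfft(X * h, inverse = TRUE))[
    (p + 1):(p + n), , drop = FALSE] / nfft
  list(broadband = new_recording(inv(h_bb), fs, rec$montage),
       msband = new_recording(inv(h_bb * h2(b_ms)), fs, rec$montage))
}

#' Zero-phase FIR bandpass filter
#'
#' Windowed (Hamming) finite-impulse-response bandpass applied zero-phase
#' (forward-backward magnitude response). The filter order is chosen so the
#' transition band at the lower edge is at most `min(1, low_hz)` Hz wide,
#' which keeps passband sinusoids within 1 dB and attenuates components one
#' octave outside the edges by more than 20 dB.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz band edges in Hz; `0 < low < high < fs/2`.
#' @return The filtered `eeg_recording`.
#' @export
bandpass_filter <- function(rec, low_hz, high_hz) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs_hz / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq))
    stop("band edges must satisfy 0 < low < high < fs/2")
  ord <- fir_order(rec$fs_hz, min(1, low_hz), nrow(rec$data))
  b <- fir_design(ord, c(low_hz, high_hz) / nyq, "pass")
  new_recording(apply_fir_zerophase(rec$data, b), rec$fs_hz, rec$montage)
}

#' Zero-phase FIR notch (band-stop) filter
#'
#' @param rec an [eeg_recording()].
#' @param freq_hz centre frequency to suppress (default 50 Hz mains).
#' @param width_hz full stop-band width in Hz.
#' @return The filtered `eeg_recording`.
#' @export
notch_filter <- function(rec, freq_hz = 50, width_hz = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs_hz / 2
  edges <- c(freq_hz - width_hz / 2, freq_hz + width_hz / 2)
  if (edges[1] <= 0 || edges[2] >= nyq)
    stop("notch band must lie strictly inside (0, fs/2)")
  ord <- fir_order(rec$fs_hz, width_hz / 2, nrow(rec$data))
  b <- fir_design(ord, edges / nyq, "stop")
  new_recording(apply_fir_zerophase(rec$data, b), rec$fs_hz, rec$montage)
}

# -- epoching and referencing ------------------------------------------------

#' Cut a recording into consecutive non-overlapping epochs
#'
#' Trailing samples that do not fill a whole epoch are discarded.
#'
#' @param rec an [eeg_recording()].
#' @param length_s epoch length in seconds (default 2 s).
#' @return An [eeg_epochs()] object.
#' @export
epoch_recording <- function(rec, length_s = 2) {
  stopifnot(inherits(rec, "eeg_recording"), length_s > 0)
  n_samp <- round(length_s * rec$fs_hz)
  n_ep <- nrow(rec$data) %/% n_samp
  if (n_ep < 1)
    stop("recording shorter (", nrow(rec$data) / rec$fs_hz,
         " s) than one epoch (", length_s, " s)")
  arr <- aperm(array(rec$data[seq_len(n_ep * n_samp), , drop = FALSE],
                     dim = c(n_samp, n_ep, ncol(rec$data))), c(2, 1, 3))
  eeg_epochs(arr, rec$fs_hz, rec$montage, length_s)
}

#' Re-reference epochs to the average reference
#'
#' Subtracts, at every sample, the instantaneous mean over all channels.
#' Idempotent.
#'
#' @param ep an [eeg_epochs()] object with at least two channels.
#' @return The re-referenced `eeg_epochs`.
#' @export
rereference_average <- function(ep) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  if (d[3] < 2) stop("average reference needs at least two channels")
  means <- rowMeans(matrix(ep$epochs, d[1] * d[2], d[3]))
  ep$epochs <- ep$epochs - array(means, dim = d)
  ep
}

#' Amplitude-threshold artifact rejection
#'
#' Drops every epoch whose absolute amplitude exceeds `peak_uV` on any
#' channel; a deterministic stand-in for interactive artifact screening.
#'
#' @param ep an [eeg_epochs()] object.
#' @param peak_uV rejection threshold in microvolts (default 100).
#' @return `eeg_epochs` containing only the surviving epochs, with
#'   `rejected_count` incremented.
#' @export
reject_artifacts <- function(ep, peak_uV = 100) {
  stopifnot(inherits(ep, "eeg_epochs"), peak_uV > 0)
  peaks <- apply(abs(ep$epochs), 1, max)
  keep <- peaks <= peak_uV
  if (!any(keep)) stop("artifact rejection removed every epoch")
  ep$rejected_count <- ep$rejected_count + sum(!keep)
  ep$epochs <- ep$epochs[keep, , , drop = FALSE]
  ep
}

#' Standard preprocessing chain
#'
#' Bandpass (default 0.5-45 Hz) and notch (default 50 Hz) filtering,
#' epoching into 2-s segments, average re-referencing, and
#' amplitude-threshold artifact rejection.
#'
#' @param rec an [eeg_recording()].
#' @param low_hz,high_hz bandpass edges in Hz.
#' @param notch_hz notch centre frequency, or `NULL` to skip.
#' @param epoch_s epoch length in seconds.
#' @param reject_uV artifact rejection threshold, or `NULL` to skip.
#' @return An average-referenced [eeg_epochs()] object.
#' @export
preprocess <- function(rec, low_hz = 0.5, high_hz = 45, notch_hz = 50,
                       epoch_s = 2, reject_uV = 100) {
  rec <- bandpass_filter(rec, low_hz, high_hz)
  if (!is.null(notch_hz) && notch_hz < rec$fs_hz / 2)
    rec <- notch_filter(rec, notch_hz)
  ep <- rereference_average(epoch_recording(rec, epoch_s))
  if (!is.null(reject_uV)) ep <- reject_artifacts(ep, reject_uV)
  ep
}
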