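# shared fixture builders (everything is generated in code)

# small montage for cheap tests: 8 channels on a circle, front half
# anterior-ish; regional sets only where a test needs them
tiny_montage <- function(n = 8) {
  th <- pi / 2 - 2 * pi * (seq_len(n) - 1) / n
  channel_montage(paste0("c", seq_len(n)), cbind(cos(th), sin(th)))
}

# single-epoch eeg_epochs from a time x channel matrix
as_epochs <- function(mat, fs_hz, montage = NULL) {
  if (is.null(montage)) montage <- tiny_montage(ncol(mat))
  eeg_epochs(array(mat, dim = c(1, nrow(mat), ncol(mat))), fs_hz, montage,
             nrow(mat) / fs_hz)
}

# sinusoid recording on n channels
sine_recording <- function(freq_hz, fs_hz = 250, dur_s = 10, n_chan = 4,
                           amp = 1, dc = 0) {
  t <- seq(0, dur_s - 1 / fs_hz, by = 1 / fs_hz)
  mat <- matrix(rep(amp * sin(2 * pi * freq_hz * t) + dc, n_chan),
                ncol = n_chan)
  eeg_recording(mat, fs_hz, tiny_montage(n_chan))
}

# middle-section RMS amplitude (avoids filter edge transients)
mid_amplitude <- function(x) {
  n <- length(x)
  sqrt(2) * sqrt(mean(x[round(n * 0.3):round(n * 0.7)]^2))
}

# random Hermitian PSD matrix (complex if asked)
random_psd <- function(k, complex = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(k * k), k)
  if (complex) A <- A + 1i * matrix(rnorm(k * k), k)
  A %*% Conj(t(A))
}
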