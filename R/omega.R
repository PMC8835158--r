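# Spatial-dynamics stage: band-wise cross-spectral matrices and omega
# complexity — the exponential of the Shannon entropy of the
# trace-normalised eigenvalue spectrum. Omega ranges from 1 (a single
# spatial mode, maximal synchronization) to K, the number of channels
# (uniform eigenvalues, maximal spatial complexity).

#' Default analysis frequency bands
#'
#' delta 1-3.5, theta 4-7.5, alpha-1 8-10, alpha-2 11-13, beta-1 13-20,
#' beta-2 20-30, gamma 30-45 Hz. Band membership of a frequency bin is
#' half-open, `low <= f < high`, so an edge shared by two bands (13 Hz)
#' belongs to the upper band.
#'
#' @return A tibble with columns `name`, `low_hz`, `high_hz`.
#' @export
default_bands <- function() {
  tibble::tibble(
    name = c("delta", "theta", "alpha-1", "alpha-2", "beta-1", "beta-2",
             "gamma"),
    low_hz = c(1, 4, 8, 11, 13, 20, 30),
    high_hz = c(3.5, 7.5, 10, 13, 20, 30, 45))
}

#' Epoch-averaged cross-spectral matrices
#'
#' Each epoch is Hann-tapered and Fourier-transformed per channel; at each
#' frequency bin the K x K cross-spectral matrix is the average over
#' epochs of the outer product of the channel coefficient vector with its
#' conjugate. A 2-s epoch gives 0.5 Hz bin resolution.
#'
#' @param ep an [eeg_epochs()] object with at least 2 epochs.
#' @param scope `"global"`, `"anterior"`, or `"posterior"` — selects the
#'   channel set from the montage.
#' @param max_freq_hz highest bin to retain (default: Nyquist).
#' @return Object of class `cross_spectra`: list with `freq_hz`,
#'   `matrices` (list of Hermitian K x K complex matrices), `scope`, `K`.
#' @export
cross_spectra <- function(ep, scope = "global", max_freq_hz = NULL) {
  stopifnot(inherits(ep, "eeg_epochs"))
  d <- dim(ep$epochs)
  if (d[1] < 2) stop("cross-spectral estimation needs at least 2 epochs")
  chans <- scope_channels(ep$montage, scope)
  K <- length(chans)
  n <- d[2]
  taper <- 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))  # Hann
  freqs <- (seq_len(n %/% 2 - 1)) * ep$fs_hz / n
  if (is.null(max_freq_hz)) max_freq_hz <- ep$fs_hz / 2
  keep <- which(freqs <= max_freq_hz)
  freqs <- freqs[keep]
  coefs <- array(0 + 0i, dim = c(d[1], length(freqs), K))
  for (e in seq_len(d[1])) {
    X <- matrix(ep$epochs[e, , chans], n, K) * taper
    coefs[e, , ] <- stats::mvfft(X)[keep + 1L, , drop = FALSE]  # skip DC
  }
  acc <- lapply(seq_along(freqs), function(b) {
    V <- matrix(coefs[, b, ], d[1], K)
    crossprod(V, Conj(V)) / d[1]     # sum_e v_e v_e^H, epoch-averaged
  })
  structure(list(freq_hz = freqs, matrices = acc, scope = scope, K = K),
            class = "cross_spectra")
}

#' Omega complexity of one cross-spectral matrix
#'
#' Eigenvalues of the Hermitian matrix are normalised by their sum,
#' `lambda'_i = lambda_i / sum(lambda)`, and
#' `Omega = exp(-sum lambda'_i log lambda'_i)` (natural log, with
#' `0 log 0 := 0`). A rank-one matrix gives exactly 1; a matrix
#' proportional to the identity gives K.
#'
#' @param C a Hermitian positive semidefinite matrix (complex or real).
#' @return Omega in `[1, K]`.
#' @export
omega_from_matrix <- function(C) {
  C <- as.matrix(C)
  if (max(Mod(C - Conj(t(C)))) > 1e-8 * max(1, max(Mod(C))))
    stop("cross-spectral matrix must be Hermitian")
  lam <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(lam) < -1e-8 * max(abs(lam)))
    stop("matrix is not positive semidefinite")
  lam <- pmax(lam, 0)
  tr <- sum(lam)
  if (tr <= 0) stop("omega undefined for a zero-trace matrix")
  lp <- lam / tr
  nz <- lp > 0
  exp(-sum(lp[nz] * log(lp[nz])))
}

#' Band-average omega complexity
#'
#' Arithmetic mean of per-bin omega values over the bins with
#' `low_hz <= f < high_hz`.
#'
#' @param spectra a `cross_spectra` object.
#' @param band one row of [default_bands()] (or any list with `low_hz`,
#'   `high_hz`).
#' @return Mean omega for the band.
#' @export
band_omega <- function(spectra, band) {
  stopifnot(inherits(spectra, "cross_spectra"))
  sel <- which(spectra$freq_hz >= band$low_hz & spectra$freq_hz < band$high_hz)
  if (length(sel) == 0)
    stop("band ", band$low_hz, "-", band$high_hz,
         " Hz contains no frequency bins")
  mean(vapply(spectra$matrices[sel], omega_from_matrix, 0))
}

#' Omega complexity table for one recording
#'
#' Runs [cross_spectra()] at each scope and averages per-bin omega within
#' each band: 7 default bands x 3 scopes = 21 values per recording, each
#' in `[1, K(scope)]`. Per-bin omega, trace, and frequency are retained in
#' the `audit` attribute.
#'
#' @param ep preprocessed (0.5-45 Hz) [eeg_epochs()].
#' @param bands band table as from [default_bands()].
#' @param scopes character vector of scopes.
#' @return A tibble (`scope`, `band`, `omega`) of class `omega_table`.
#' @export
omega_pipeline <- function(ep, bands = default_bands(),
                           scopes = c("global", "anterior", "posterior")) {
  audit <- list()
  rows <- list()
  # the regional cross-spectra are principal submatrices of the global one,
  # so the Fourier pass is done once on the full montage
  glob <- cross_spectra(ep, "global", max_freq_hz = max(bands$high_hz) + 1)
  for (sc in scopes) {
    sp <- if (sc == "global") glob else {
      idx <- match(scope_channels(ep$montage, sc),
                   scope_channels(ep$montage, "global"))
      structure(list(freq_hz = glob$freq_hz,
                     matrices = lapply(glob$matrices, function(m)
                       m[idx, idx, drop = FALSE]),
                     scope = sc, K = length(idx)),
                class = "cross_spectra")
    }
    per_bin <- vapply(sp$matrices, omega_from_matrix, 0)
    traces <- vapply(sp$matrices, function(m) Re(sum(diag(m))), 0)
    audit[[sc]] <- tibble::tibble(freq_hz = sp$freq_hz, omega = per_bin,
                                  trace = traces)
    for (b in seq_len(nrow(bands))) {
      sel <- sp$freq_hz >= bands$low_hz[b] & sp$freq_hz < bands$high_hz[b]
      if (!any(sel))
        stop("band ", bands$name[b], " contains no frequency bins")
      rows[[length(rows) + 1]] <- tibble::tibble(
        scope = sc, band = bands$name[b], omega = mean(per_bin[sel]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "audit") <- audit
  class(out) <- c("omega_table", class(out))
  out
}
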