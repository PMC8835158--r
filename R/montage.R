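#' Electrode montage for scalp EEG
#'
#' A montage holds ordered channel labels with schematic 2-D scalp
#' coordinates (top view, nose up, unit head radius), plus the anterior
#' (prefrontal) and posterior electrode subsets used for regional
#' spatial-complexity analysis.
#'
#' @param names character vector of unique channel labels (10/10 system).
#' @param positions numeric matrix, one row per channel, columns `x`, `y`.
#' @param anterior_set,posterior_set character vectors naming the regional
#'   electrode subsets; must be disjoint subsets of `names`.
#' @return An object of class `eeg_montage`.
#' @export
channel_montage <- function(names, positions,
                            anterior_set = character(),
                            posterior_set = character()) {
  names <- as.character(names)
  if (anyDuplicated(names)) stop("montage channel names must be unique")
  positions <- as.matrix(positions)
  if (nrow(positions) != length(names) || ncol(positions) != 2)
    stop("positions must be an n x 2 matrix matching 'names'")
  if (any(!is.finite(positions))) stop("montage positions must be finite")
  if (!all(anterior_set %in% names) || !all(posterior_set %in% names))
    stop("regional sets must be subsets of channel names")
  if (length(intersect(anterior_set, posterior_set)) > 0)
    stop("anterior and posterior sets must be disjoint")
  dimnames(positions) <- list(names, c("x", "y"))
  structure(list(names = names, positions = positions,
                 anterior_set = anterior_set, posterior_set = posterior_set),
            class = "eeg_montage")
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat("<eeg_montage> ", length(x$names), " channels\n", sep = "")
  cat("  anterior:  ", paste(x$anterior_set, collapse = " "), "\n", sep = "")
  cat("  posterior: ", paste(x$posterior_set, collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
length.eeg_montage <- function(x) length(x$names)

# Schematic 10/10 coordinates for the default 30-channel analysis montage.
# 14 channels are the regional anterior/posterior electrodes; the other 16
# are a standard 10/10 complement (CPz serves as reference and AFz as
# ground in the acquisition setup, so neither appears as a data channel).
.default_montage_table <- function() {
  m <- matrix(c(
    -0.31,  0.95,   # Fp1
     0.31,  0.95,   # Fp2
    -0.81,  0.59,   # F7
    -0.43,  0.55,   # F3
     0.00,  0.52,   # Fz
     0.43,  0.55,   # F4
     0.81,  0.59,   # F8
    -0.95,  0.31,   # FT7
    -0.47,  0.28,   # FC3
     0.00,  0.26,   # FCz
     0.47,  0.28,   # FC4
     0.95,  0.31,   # FT8
    -1.00,  0.00,   # T3
    -0.50,  0.00,   # C3
     0.00,  0.00,   # Cz
     0.50,  0.00,   # C4
     1.00,  0.00,   # T4
    -0.95, -0.31,   # TP7
    -0.47, -0.28,   # CP3
     0.47, -0.28,   # CP4
     0.95, -0.31,   # TP8
    -0.81, -0.59,   # T5
    -0.43, -0.55,   # P3
     0.00, -0.52,   # Pz
     0.43, -0.55,   # P4
     0.81, -0.59,   # T6
     0.00, -0.74,   # POz
    -0.31, -0.95,   # O1
     0.00, -0.98,   # Oz
     0.31, -0.95),  # O2
    ncol = 2, byrow = TRUE)
  rownames(m) <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
                   "FT7", "FC3", "FCz", "FC4", "FT8",
                   "T3", "C3", "Cz", "C4", "T4",
                   "TP7", "CP3", "CP4", "TP8",
                   "T5", "P3", "Pz", "P4", "T6",
                   "POz", "O1", "Oz", "O2")
  m
}

#' Default 30-channel 10/10 analysis montage
#'
#' Thirty scalp channels with schematic 2-D positions. The anterior set is
#' the prefrontal group Fp1, Fp2, F7, F3, Fz, F4, F8 and the posterior set
#' is T5, T6, P3, P4, Pz, O1, O2; each regional set has seven electrodes
#' and drives the 7 x 7 regional cross-spectral matrices, while all 30
#' channels drive the 30 x 30 global matrix.
#'
#' @return An `eeg_montage` with 30 channels.
#' @export
default_montage <- function() {
  pos <- .default_montage_table()
  channel_montage(rownames(pos), pos,
                  anterior_set = c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8"),
                  posterior_set = c("T5", "T6", "P3", "P4", "Pz", "O1", "O2"))
}

# channel indices for a scope ("global", "anterior", "posterior")
scope_channels <- function(montage, scope) {
  scope <- match.arg(scope, c("global", "anterior", "posterior"))
  chans <- switch(scope,
                  global = montage$names,
                  anterior = montage$anterior_set,
                  posterior = montage$posterior_set)
  if (length(chans) == 0) stop("scope '", scope, "' not defined in montage")
  match(chans, montage$names)
}

# pairwise electrode distances on the schematic layout
montage_distances <- function(montage) {
  as.matrix(stats::dist(montage$positions))
}
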