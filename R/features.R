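# Band-power feature extraction on 2 s windows.
#
# Per channel and window: 15 mean powers over overlapping bands spanning
# delta/theta (1 Hz wide, 0.5 Hz steps) plus 8-14 and 14-20 Hz, and the peak
# frequency — 16 features per channel, concatenated channel-major into one
# vector per window (width 16 x channels: 352 for the 22-channel scalp
# montage, 64 for the 4-channel ear montage). The per-window spectrum is a
# single Hann-tapered periodogram (2 s at 250 Hz -> 0.5 Hz bins), since Welch
# sub-averaging inside 2 s would leave under 3 bins per 1 Hz band.

#' The fixed 15-band feature set
#'
#' @return 15 x 2 matrix of band edges (Hz), in feature order.
#' @export
feature_bands <- function() {
  lo <- c(seq(1, 7, by = 0.5), 8, 14)
  hi <- c(seq(2, 8, by = 0.5), 14, 20)
  cbind(lo = lo, hi = hi)
}

#' Feature-extraction configuration
#'
#' @param window_s analysis window length (2 s clinical convention).
#' @param step_s window step (defaults to `window_s`: non-overlapping).
#' @param peak_range_hz search range for the peak-frequency feature.
#' @return a `feature_config` list; the band list itself is fixed (see
#'   [feature_bands()]).
#' @export
feature_config <- function(window_s = 2, step_s = window_s,
                           peak_range_hz = c(1, 20)) {
  if (window_s <= 0 || step_s <= 0) stop("window and step must be positive")
  structure(list(window_s = window_s, step_s = step_s,
                 peak_range_hz = peak_range_hz, bands = feature_bands()),
            class = "feature_config")
}

# single Hann-tapered periodogram, one-sided density scaling
periodogram_psd <- function(x, fs) {
  n <- length(x)
  w <- hann(n)
  nf <- n %/% 2 + 1
  X <- stats::fft(w * x)[1:nf]
  one_sided <- c(1, rep(2, nf - 2), if (n %% 2 == 0) 1 else 2)
  list(freq = (0:(nf - 1)) * fs / n,
       psd = Re(X * Conj(X)) / (fs * sum(w^2)) * one_sided)
}

#' Enumerate analysis windows over an epoch
#'
#' Half-open windows `[start, start + window_s)` at `step_s` spacing. A window
#' is labelled `seizure` when its midpoint lies inside any epoch-relative
#' annotation.
#'
#' @param epoch an `eeg_epoch` (or [eeg_signal()], then all `non_seizure`).
#' @param cfg a [feature_config()].
#' @return tibble with `window`, `start_s`, `mid_s`, `label`.
#' @export
window_signal <- function(epoch, cfg = feature_config()) {
  sig <- if (inherits(epoch, "eeg_epoch")) epoch$signal else epoch
  ann <- if (inherits(epoch, "eeg_epoch")) epoch$annotations else NULL
  dur <- duration_s(sig)
  starts <- seq(0, dur - cfg$window_s, by = cfg$step_s)
  starts <- starts[starts + cfg$window_s <= dur + 1e-9]
  mid <- starts + cfg$window_s / 2
  lab <- rep("non_seizure", length(starts))
  if (!is.null(ann) && nrow(ann)) {
    for (j in seq_len(nrow(ann))) {
      lab[mid >= ann$onset_s[j] & mid < ann$end_s[j]] <- "seizure"
    }
  }
  tibble::tibble(window = seq_along(starts), start_s = starts, mid_s = mid,
                 label = lab)
}

#' Band powers of one window
#'
#' Mean of the periodogram bins whose centre frequency lies in each band
#' (closed intervals), in the fixed feature order. Scaling the signal by `a`
#' scales every band power by `a^2`.
#'
#' @param x single-channel window samples.
#' @param fs sampling rate (Hz).
#' @param cfg a [feature_config()].
#' @return numeric vector of 15 mean powers.
#' @export
band_powers <- function(x, fs, cfg = feature_config()) {
  pg <- periodogram_psd(x, fs)
  b <- cfg$bands
  vapply(seq_len(nrow(b)), function(i) {
    mean(pg$psd[pg$freq >= b[i, 1] & pg$freq <= b[i, 2]])
  }, 0)
}

#' Peak frequency of one window
#'
#' Frequency of the maximum periodogram bin within the search range. An
#' all-zero (degenerate) window reports 0 with attribute `degenerate = TRUE`.
#'
#' @inheritParams band_powers
#' @return peak frequency in Hz.
#' @export
peak_frequency <- function(x, fs, cfg = feature_config()) {
  if (all(x == 0)) return(structure(0, degenerate = TRUE))
  pg <- periodogram_psd(x, fs)
  sel <- pg$freq >= cfg$peak_range_hz[1] & pg$freq <= cfg$peak_range_hz[2]
  f <- pg$freq[sel]
  f[which.max(pg$psd[sel])]
}

# band-membership averaging matrix for a given bin grid: 16 x nf, last row
# left zero (peak frequency handled separately)
band_matrix <- function(freq, cfg) {
  b <- cfg$bands
  M <- matrix(0, nrow(b), length(freq))
  for (i in seq_len(nrow(b))) {
    sel <- freq >= b[i, 1] & freq <= b[i, 2]
    M[i, sel] <- 1 / sum(sel)
  }
  M
}

#' Build the per-window feature matrix of an epoch
#'
#' Concatenates the 16 per-channel features channel-major (15 band powers in
#' band order, then peak frequency), giving vectors of width 16 x channels.
#' Columns are named `<channel>.bp_<lo>-<hi>` and `<channel>.peakf`.
#'
#' @param epoch an `eeg_epoch` or [eeg_signal()].
#' @param cfg a [feature_config()].
#' @return a `feature_matrix` tibble: `window`, `start_s`, `mid_s`, `label`,
#'   then feature columns; attribute `channel_block_names` records the block
#'   order.
#' @export
build_feature_matrix <- function(epoch, cfg = feature_config()) {
  sig <- if (inherits(epoch, "eeg_epoch")) epoch$signal else epoch
  wins <- window_signal(epoch, cfg)
  fs <- sig$fs_hz
  nper <- round(cfg$window_s * fs)
  nf <- nper %/% 2 + 1
  freq <- (0:(nf - 1)) * fs / nper
  w <- hann(nper)
  one_sided <- c(1, rep(2, nf - 2), if (nper %% 2 == 0) 1 else 2)
  scale <- one_sided / (fs * sum(w^2))
  B <- band_matrix(freq, cfg)
  peak_sel <- freq >= cfg$peak_range_hz[1] & freq <= cfg$peak_range_hz[2]
  peak_freqs <- freq[peak_sel]

  i0 <- time_to_sample(wins$start_s, fs)
  nchan <- nrow(sig$data)
  blocks <- vector("list", nchan)
  for (ci in seq_len(nchan)) {
    # all windows of this channel as one matrix -> single mvfft call
    seg <- matrix(0, nper, nrow(wins))
    for (j in seq_len(nrow(wins))) {
      seg[, j] <- sig$data[ci, i0[j]:(i0[j] + nper - 1L)]
    }
    X <- stats::mvfft(seg * w)[1:nf, , drop = FALSE]
    P <- (Re(X)^2 + Im(X)^2) * scale
    bp <- t(B %*% P) # windows x 15
    degen <- colSums(seg != 0) == 0
    pk <- peak_freqs[max.col(t(P[peak_sel, , drop = FALSE]),
                             ties.method = "first")]
    pk[degen] <- 0
    blocks[[ci]] <- cbind(bp, pk)
  }
  feats <- do.call(cbind, blocks)
  b <- cfg$bands
  fnames <- as.vector(vapply(sig$channel_names, function(ch) {
    c(sprintf("%s.bp_%g-%g", ch, b[, 1], b[, 2]), sprintf("%s.peakf", ch))
  }, character(16)))
  colnames(feats) <- fnames
  out <- dplyr::bind_cols(wins, tibble::as_tibble(feats))
  attr(out, "channel_block_names") <- sig$channel_names
  class(out) <- c("feature_matrix", class(out))
  out
}

#' Feature columns of a feature matrix, as a plain matrix
#' @param fm a `feature_matrix`.
#' @return numeric matrix, windows x features.
#' @export
feature_values <- function(fm) {
  as.matrix(fm[, setdiff(names(fm), c("window", "start_s", "mid_s", "label"))])
}
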