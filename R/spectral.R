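# Welch spectral estimation and magnitude-squared coherence.
#
# Averaged modified periodograms with a Hann taper and 50% overlap, one-sided
# density scaling (integral of the PSD over frequency equals the variance).
# Defaults (2 s segments -> 0.5 Hz resolution) cover the 2-20 Hz comparison
# band used for the ear-vs-scalp channel matchup.

hann <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))

welch_segments <- function(n, nper, overlap) {
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, n - nper + 1L, by = step)
  starts
}

# Averaged cross-periodogram matrix for the segment list. Returns one-sided
# frequency grid and averaged auto/cross spectra.
welch_cross <- function(x, y, fs, seg_s, overlap) {
  n <- length(x)
  nper <- round(seg_s * fs)
  if (n < nper) stop("segment shorter than one Welch window")
  starts <- welch_segments(n, nper, overlap)
  w <- hann(nper)
  u <- sum(w^2) # window power normalization
  nf <- nper %/% 2 + 1
  gxx <- gyy <- numeric(nf)
  gxy <- complex(nf)
  for (s0 in starts) {
    idx <- s0:(s0 + nper - 1L)
    X <- stats::fft(w * x[idx])[1:nf]
    Y <- stats::fft(w * y[idx])[1:nf]
    gxx <- gxx + Re(X * Conj(X))
    gyy <- gyy + Re(Y * Conj(Y))
    gxy <- gxy + X * Conj(Y)
  }
  k <- length(starts)
  scale <- 1 / (k * fs * u)
  one_sided <- c(1, rep(2, nf - 2), if (nper %% 2 == 0) 1 else 2)
  list(
    freqs_hz = (0:(nf - 1)) * fs / nper,
    gxx = gxx * scale * one_sided,
    gyy = gyy * scale * one_sided,
    gxy = gxy * scale * one_sided,
    n_segments = k
  )
}

#' Welch power spectral density estimate
#'
#' @param x single-channel numeric vector (microvolts).
#' @param fs sampling rate (Hz).
#' @param seg_s Welch segment length in seconds.
#' @param overlap fractional overlap between segments.
#' @return a `psd_estimate`: tibble with `freq_hz` and `psd` (uV^2/Hz) plus
#'   estimation parameters as attributes. The PSD integrates to the signal
#'   variance (Parseval, within estimation error).
#' @export
estimate_psd <- function(x, fs, seg_s = 2, overlap = 0.5) {
  if (length(x) < 2 * round(seg_s * fs)) {
    stop("segment must be at least twice the Welch window")
  }
  cw <- welch_cross(x, x, fs, seg_s, overlap)
  out <- tibble::tibble(freq_hz = cw$freqs_hz, psd = cw$gxx)
  attr(out, "params") <- list(seg_s = seg_s, overlap = overlap,
                              taper = "hann", n_segments = cw$n_segments)
  class(out) <- c("psd_estimate", class(out))
  out
}

#' Magnitude-squared coherence between two channels
#'
#' `Cxy(f) = |Gxy(f)|^2 / (Gxx(f) Gyy(f))` on the Welch grid, where `Gxy` is
#' the averaged cross-spectral density. Coherence of a single segment is
#' identically 1, so at least `min_segments` averaging segments are required.
#' The summary `band_mean` averages `Cxy` over `band` (closed, default 2-20 Hz).
#'
#' @param x,y equal-length single-channel vectors.
#' @param fs sampling rate (Hz).
#' @param seg_s,overlap Welch parameters.
#' @param band frequency band for `band_mean`, Hz.
#' @param pair optional `c(ear_channel, scalp_channel)` labels.
#' @param min_segments minimum averaging segments (estimation is degenerate
#'   below this; 1 segment gives coherence identically 1).
#' @return a `coherence_result` list: `freqs_hz`, `cxy` in `[0,1]`,
#'   `band_mean`, `pair`, `n_segments`.
#' @export
coherence <- function(x, y, fs, seg_s = 2, overlap = 0.5, band = c(2, 20),
                      pair = c(NA_character_, NA_character_),
                      min_segments = 8) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  nper <- round(seg_s * fs)
  k <- length(welch_segments(length(x), nper, overlap))
  if (k < min_segments) {
    stop(sprintf(
      "coherence needs >= %d averaging segments, got %d (single-segment coherence is identically 1)",
      min_segments, k
    ))
  }
  cw <- welch_cross(x, y, fs, seg_s, overlap)
  cxy <- Mod(cw$gxy)^2 / (cw$gxx * cw$gyy)
  cxy[!is.finite(cxy)] <- 0
  in_band <- cw$freqs_hz >= band[1] & cw$freqs_hz <= band[2]
  structure(list(
    freqs_hz = cw$freqs_hz, cxy = cxy,
    band_mean = mean(cxy[in_band]),
    band = band, pair = pair, n_segments = cw$n_segments
  ), class = "coherence_result")
}

#' @export
print.coherence_result <- function(x, ...) {
  cat(sprintf("<coherence> %s ~ %s: band mean [%g, %g] Hz = %.3f (%d segments)\n",
              x$pair[1], x$pair[2], x$band[1], x$band[2], x$band_mean,
              x$n_segments))
  invisible(x)
}

#' @method tidy coherence_result
#' @export
tidy.coherence_result <- function(x, ...) {
  tibble::tibble(freq_hz = x$freqs_hz, coherence = x$cxy)
}

#' @method glance coherence_result
#' @export
glance.coherence_result <- function(x, ...) {
  tibble::tibble(band_lo_hz = x$band[1], band_hi_hz = x$band[2],
                 band_mean = x$band_mean, n_segments = x$n_segments)
}

#' @method autoplot coherence_result
#' @export
autoplot.coherence_result <- function(object, ...) {
  ggplot2::ggplot(tidy.coherence_result(object),
                  ggplot2::aes(x = .data$freq_hz, y = .data$coherence)) +
    ggplot2::geom_line() +
    ggplot2::annotate("rect", xmin = object$band[1], xmax = object$band[2],
                      ymin = 0, ymax = 1, alpha = 0.08) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "frequency (Hz)", y = "magnitude-squared coherence") +
    ggplot2::theme_minimal()
}

#' Best-matchup scalp channel for one ear channel
#'
#' For each scalp channel, band-mean coherence with the ear channel is
#' computed over every ictal window and averaged across windows; the scalp
#' channel with the highest average wins (ties broken by montage order).
#'
#' @param ear_x single-channel vector (one behind-the-ear derivation).
#' @param scalp an [eeg_signal()] of candidate scalp channels, sample-aligned
#'   with `ear_x`.
#' @param ictal_windows list of `c(start_s, end_s)` ictal intervals (one per
#'   seizure), in the signal's time base.
#' @param ... passed to [coherence()].
#' @return one-row tibble: `scalp_channel`, `mean_coherence`.
#' @export
best_matchup <- function(ear_x, scalp, ictal_windows, ...) {
  if (!length(ictal_windows)) stop("at least one ictal window is required")
  fs <- scalp$fs_hz
  per_chan <- purrr::map_dbl(seq_along(scalp$channel_names), function(ci) {
    mean(purrr::map_dbl(ictal_windows, function(w) {
      i0 <- time_to_sample(w[1], fs)
      i1 <- min(time_to_sample(w[2], fs) - 1L, ncol(scalp$data))
      coherence(ear_x[i0:i1], scalp$data[ci, i0:i1], fs, ...)$band_mean
    }))
  })
  best <- which.max(per_chan) # which.max takes the first maximum: montage order
  tibble::tibble(scalp_channel = scalp$channel_names[best],
                 mean_coherence = per_chan[best])
}

#' Round half away from zero
#'
#' Report-table rounding convention (0.815 -> 0.82), unlike base `round()`
#' which rounds half to even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Aggregate per-patient matchup rows into a summary table
#'
#' @param rows tibble with columns `pid`, `ear_channel`, `scalp_channel`,
#'   `coherence` (one row per patient x ear channel).
#' @return a `matchup_table`: list with `rows` and `column_summary` (per ear
#'   channel: `mean`, `sd` — sample SD, n-1 — and their 2-decimal half-up
#'   rounded report values; single-patient columns get `sd = 0` and
#'   `sd_defined = FALSE`).
#' @export
aggregate_matchup_table <- function(rows) {
  summ <- rows |>
    dplyr::group_by(.data$ear_channel) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean = mean(.data$coherence),
      sd = if (dplyr::n() > 1) stats::sd(.data$coherence) else 0,
      sd_defined = dplyr::n() > 1,
      .groups = "drop"
    ) |>
    dplyr::mutate(
      mean_report = round_half_up(.data$mean, 2),
      sd_report = round_half_up(.data$sd, 2)
    )
  # preserve ear-channel order of first appearance
  summ <- summ[match(unique(rows$ear_channel), summ$ear_channel), ]
  structure(list(rows = rows, column_summary = summ), class = "matchup_table")
}

#' @export
print.matchup_table <- function(x, ...) {
  cat("<matchup_table>\n")
  print(x$column_summary)
  invisible(x)
}

#' @method tidy matchup_table
#' @export
tidy.matchup_table <- function(x, ...) x$column_summary
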