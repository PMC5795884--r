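# Blink EOG quantification: ICA decomposition, automated EOG-component
# selection, amplitude-gated peak detection, peri-blink averaging, and the
# paired signed-rank comparison of per-patient amplitudes across channels.

#' FastICA decomposition of a multichannel signal
#'
#' Symmetric FastICA with the logcosh contrast: the signal is whitened by PCA
#' (optionally reduced to `n_components`), an orthogonal unmixing matrix is
#' iterated to a fixed point, and components are returned with unit-variance
#' timecourses plus their mixing pattern (component -> channel weights).
#' Deterministic under `seed`.
#'
#' @param sig an [eeg_signal()] with >= 2 channels.
#' @param n_components number of components (default: number of channels).
#' @param seed RNG seed for the initial rotation.
#' @param max_iter,tol fixed-point iteration controls.
#' @return list of `eog_component` objects, each with `timecourse`
#'   (unit variance), `spatial_pattern` (named channel weights),
#'   `selection_method = "auto"`, `score = NA`, and the sampling rate.
#' @export
decompose_components <- function(sig, n_components = NULL, seed = 1,
                                 max_iter = 200, tol = 1e-4) {
  X <- sig$data
  p <- nrow(X)
  if (p < 2) stop("ICA needs at least 2 channels")
  if (is.null(n_components)) n_components <- p
  if (n_components > p) {
    stop("`n_components` cannot exceed the number of channels")
  }
  k <- n_components
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- tcrossprod(Xc) / ncol(Xc)
  eg <- eigen(C, symmetric = TRUE)
  if (eg$values[k] <= eg$values[1] * 1e-12) {
    stop("ICA convergence failure: requested components exceed signal rank (",
         "leading eigenvalues: ", paste(signif(eg$values[1:k], 3), collapse = ", "), ")")
  }
  K <- diag(1 / sqrt(eg$values[1:k])) %*% t(eg$vectors[, 1:k, drop = FALSE])
  Z <- K %*% Xc # whitened, k x n

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(stats::rnorm(k * k), k)
  W <- svd(W)$u %*% t(svd(W)$v)
  sym_decorrelate <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decorrelate(W)
  n <- ncol(Z)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    WZ <- W %*% Z
    G <- tanh(WZ)
    Gp <- 1 - G^2
    W1 <- (G %*% t(Z)) / n - diag(rowMeans(Gp)) %*% W
    W1 <- sym_decorrelate(W1)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  if (anyNA(W)) {
    stop(sprintf("ICA diverged (NaN in unmixing) after %d iterations", it))
  }
  if (!converged) {
    # near-Gaussian trailing components have no fixed point and rotate
    # freely; the strongly non-Gaussian (artifact) components stabilise long
    # before maxit, so return the estimate rather than fail
    warning(sprintf("ICA not fully converged: delta %.2e after %d iterations",
                    delta, max_iter))
  }
  S <- W %*% Z
  sdev <- apply(S, 1, stats::sd)
  S <- S / sdev
  # mixing: X ~ A S with A = pinv(W K) scaled by component sd
  A <- t(eg$vectors[, 1:k, drop = FALSE] %*% diag(sqrt(eg$values[1:k])) %*%
           t(W)) # k x p, rows are patterns
  A <- A * sdev
  purrr::map(seq_len(k), function(i) {
    structure(list(
      timecourse = S[i, ],
      spatial_pattern = stats::setNames(A[i, ], sig$channel_names),
      selection_method = "auto",
      score = NA_real_,
      fs_hz = sig$fs_hz,
      low_confidence = FALSE
    ), class = "eog_component")
  })
}

#' Select the EOG (blink) component
#'
#' Automated surrogate for visual component inspection: the component whose
#' timecourse correlates most strongly (in absolute value) with the
#' frontopolar channel is selected and sign-flipped so blink deflections are
#' positive. A score below 0.2 flags the selection as low-confidence.
#'
#' @param components list from [decompose_components()].
#' @param frontal_channel_signal the frontopolar bipolar channel (numeric
#'   vector, e.g. Fp2-F8), sample-aligned with the decomposition.
#' @param manual_index optional integer override (sets
#'   `selection_method = "manual"`).
#' @return the chosen `eog_component` with `score` filled in and timecourse
#'   sign-aligned to the frontal channel.
#' @export
identify_eog_component <- function(components, frontal_channel_signal,
                                   manual_index = NULL) {
  cors <- purrr::map_dbl(components, function(cp) {
    stats::cor(cp$timecourse, frontal_channel_signal)
  })
  if (!is.null(manual_index)) {
    cp <- components[[manual_index]]
    cp$selection_method <- "manual"
    cp$score <- abs(cors[manual_index])
    if (cors[manual_index] < 0) cp <- flip_component(cp)
    return(cp)
  }
  best <- which.max(abs(cors))
  cp <- components[[best]]
  cp$score <- abs(cors[best])
  if (cors[best] < 0) cp <- flip_component(cp)
  if (cp$score < 0.2) {
    cp$low_confidence <- TRUE
    warning(sprintf(
      "no component correlates with the frontal channel above 0.2 (best %.2f)",
      cp$score
    ))
  }
  cp
}

flip_component <- function(cp) {
  cp$timecourse <- -cp$timecourse
  cp$spatial_pattern <- -cp$spatial_pattern
  cp
}

#' Microvolt-scaled component timecourse
#'
#' The ICA timecourse is unit-variance; multiplying by the component's mixing
#' weight onto the frontopolar channel expresses it in microvolts as seen
#' frontally, making the 30-80 uV blink amplitude window meaningful.
#'
#' @param component an `eog_component`.
#' @param frontal_channel name of the frontopolar channel in the pattern.
#' @return numeric vector in microvolts.
#' @export
component_uv <- function(component, frontal_channel = "Fp2-F8") {
  w <- component$spatial_pattern[[frontal_channel]]
  component$timecourse * w
}

#' Detect blink peaks within an amplitude window
#'
#' Local maxima of the microvolt-scaled component timecourse with amplitude in
#' `[min_amp, max_amp]`, separated by at least `refractory_s` (physiological
#' blink separation).
#'
#' @param x microvolt-scaled timecourse (see [component_uv()]), or an
#'   `eog_component` (scaled via its frontopolar weight).
#' @param fs sampling rate (Hz); taken from the component if one is given.
#' @param min_amp,max_amp amplitude gate in microvolts.
#' @param refractory_s minimum peak separation in seconds.
#' @param frontal_channel channel used for microvolt scaling of a component.
#' @return numeric vector of peak times in seconds.
#' @export
detect_blink_peaks <- function(x, fs = NULL, min_amp = 30, max_amp = 80,
                               refractory_s = 0.25,
                               frontal_channel = "Fp2-F8") {
  if (inherits(x, "eog_component")) {
    fs <- x$fs_hz
    x <- component_uv(x, frontal_channel)
  }
  if (is.null(fs)) stop("`fs` required for a plain numeric timecourse")
  n <- length(x)
  if (n < 3) return(numeric(0))
  is_peak <- c(FALSE, x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n],
               FALSE)
  cand <- which(is_peak & x >= min_amp & x <= max_amp)
  if (!length(cand)) return(numeric(0))
  cand <- cand[order(-x[cand])] # keep the taller peak within a refractory gap
  keep <- logical(0)
  kept <- integer(0)
  min_gap <- round(refractory_s * fs)
  for (i in cand) {
    if (!length(kept) || all(abs(kept - i) >= min_gap)) kept <- c(kept, i)
  }
  sort((kept - 1) / fs)
}

#' Average peri-blink epochs on one channel
#'
#' Extracts `[-pre_s, +post_s]` epochs time-locked to each peak and averages
#' them pointwise. Peaks whose epoch would run past either signal edge are
#' skipped with a warning.
#'
#' @param x single-channel numeric vector.
#' @param fs sampling rate (Hz).
#' @param peak_times_s blink peak times (seconds).
#' @param pre_s,post_s epoch extent around the peak.
#' @return numeric waveform of length `round((pre_s + post_s) * fs) + 1`,
#'   with attribute `n_epochs`.
#' @export
average_blink_epochs <- function(x, fs, peak_times_s, pre_s = 0.2,
                                 post_s = 0.2) {
  npre <- round(pre_s * fs)
  npost <- round(post_s * fs)
  centers <- round(peak_times_s * fs) + 1L
  ok <- centers - npre >= 1 & centers + npost <= length(x)
  if (any(!ok)) {
    warning(sum(!ok), " blink epoch(s) at the signal edge skipped")
  }
  centers <- centers[ok]
  if (!length(centers)) stop("no blink epoch with full support inside the signal")
  acc <- numeric(npre + npost + 1)
  for (c0 in centers) acc <- acc + x[(c0 - npre):(c0 + npost)]
  out <- acc / length(centers)
  attr(out, "n_epochs") <- length(centers)
  out
}

#' Mean EOG amplitude of an averaged waveform
#'
#' Arithmetic mean of the averaged blink waveform over `[-half_window_s,
#' +half_window_s]` around the time-locked peak sample. Linear in the
#' waveform.
#'
#' @param avg_waveform averaged waveform from [average_blink_epochs()] (peak
#'   at the centre sample).
#' @param fs sampling rate (Hz).
#' @param half_window_s half-width of the averaging window (seconds).
#' @return amplitude in microvolts.
#' @export
eog_amplitude <- function(avg_waveform, fs, half_window_s = 0.1) {
  nh <- round(half_window_s * fs)
  center <- (length(avg_waveform) - 1) %/% 2 + 1
  idx <- (center - nh):(center + nh)
  if (idx[1] < 1 || idx[length(idx)] > length(avg_waveform)) {
    stop("half window exceeds the waveform extent")
  }
  mean(avg_waveform[idx])
}

#' Paired signed-rank comparison of per-patient EOG amplitudes
#'
#' @param per_patient_a,per_patient_b equal-length numeric vectors paired by
#'   patient (n >= 5 recommended for a meaningful test).
#' @return tibble with `statistic`, `p_value`, `n_used`, `method`.
#' @seealso [signed_rank_test()]
#' @export
compare_amplitudes_wilcoxon <- function(per_patient_a, per_patient_b) {
  res <- signed_rank_test(per_patient_a, per_patient_b)
  tibble::tibble(statistic = res$statistic, p_value = res$p_value,
                 n_used = res$n_used, method = res$method)
}

#' Blink EOG report for one recording
#'
#' Runs the full blink pipeline on a referential recording: scalp montage ->
#' band-pass -> ICA -> automatic EOG component selection -> 30-80 uV peak
#' detection -> peri-blink averaging on the frontopolar channel and every
#' behind-the-ear channel -> per-channel mean amplitude.
#'
#' @param rec an [eeg_recording()] containing scalp and ear electrodes.
#' @param channels channels to quantify (default frontopolar + the four
#'   behind-the-ear derivations).
#' @param n_components ICA components (default 12; frontal blink variance is
#'   captured in the leading subspace).
#' @param seed ICA seed.
#' @return an `eog_report`: list with `amplitudes` (tibble channel /
#'   amplitude_uv / n_blinks), `waveforms` (tibble channel / time_s /
#'   mean_uv), `peak_times_s`, `component`.
#' @export
eog_report <- function(rec, channels = c("Fp2-F8", "LC-RC", "LT-RT", "LT-LC",
                                         "RT-RC"),
                       n_components = 12, seed = 1) {
  # blink morphology is quantified on the unfiltered derivations: the 0.5 Hz
  # high-pass of the detection path undershoots around the ~300 ms transient
  # and biases the +/-0.1 s mean low by ~20%
  scalp <- apply_montage(rec, define_scalp_montage())
  ear <- apply_montage(rec, define_ear_montage())
  comps <- decompose_components(scalp, n_components = n_components,
                                seed = seed)
  frontal <- scalp$data["Fp2-F8", ]
  cp <- identify_eog_component(comps, frontal)
  peaks <- detect_blink_peaks(cp)
  all_sig <- rbind(scalp$data, ear$data)
  fs <- rec$fs_hz
  wf <- purrr::map_dfr(channels, function(ch) {
    avg <- average_blink_epochs(all_sig[ch, ], fs, peaks)
    tibble::tibble(
      channel = ch,
      time_s = seq(-0.2, 0.2, by = 1 / fs),
      mean_uv = as.numeric(avg)
    )
  })
  amp <- wf |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(
      amplitude_uv = eog_amplitude(.data$mean_uv, fs),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_blinks = length(peaks))
  amp <- amp[match(channels, amp$channel), ]
  structure(list(amplitudes = amp, waveforms = wf, peak_times_s = peaks,
                 component = cp),
            class = "eog_report")
}

#' @export
print.eog_report <- function(x, ...) {
  cat(sprintf("<eog_report> %d blinks (component score %.2f)\n",
              length(x$peak_times_s), x$component$score))
  print(x$amplitudes)
  invisible(x)
}

#' @method tidy eog_report
#' @export
tidy.eog_report <- function(x, ...) x$amplitudes

#' @method autoplot eog_report
#' @export
autoplot.eog_report <- function(object, ...) {
  ggplot2::ggplot(object$waveforms,
                  ggplot2::aes(x = .data$time_s, y = .data$mean_uv,
                               colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time from blink peak (s)", y = "grand-average EOG (uV)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
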