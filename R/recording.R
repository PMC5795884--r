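#' Construct a referential EEG recording
#'
#' A recording holds referential electrode signals in microvolts, all measured
#' against a single common reference electrode (clinically, Fpz here), at a
#' fixed sampling rate. Rows of `data` are electrodes, columns are samples.
#'
#' @param data numeric matrix, electrodes x samples, in microvolts.
#' @param fs_hz sampling rate in Hz (clinical default 250).
#' @param electrode_labels character vector naming the rows of `data`; must be
#'   unique.
#' @param reference_label label of the common reference electrode.
#' @param start_time recording start offset in seconds (0-based).
#' @return an object of class `eeg_recording`.
#' @examples
#' rec <- eeg_recording(matrix(rnorm(500), 2), 250, c("Fp1", "Fp2"))
#' n_samples(rec)
#' @export
eeg_recording <- function(data, fs_hz, electrode_labels,
                          reference_label = "Fpz", start_time = 0) {
  data <- as.matrix(data)
  stopifnot(is.numeric(data), is.numeric(fs_hz), length(fs_hz) == 1L)
  if (fs_hz <= 0) stop("`fs_hz` must be positive")
  if (length(electrode_labels) != nrow(data)) {
    stop("`electrode_labels` must have one entry per row of `data`")
  }
  if (anyDuplicated(electrode_labels)) stop("electrode labels must be unique")
  rownames(data) <- electrode_labels
  structure(
    list(
      fs_hz = fs_hz,
      electrode_labels = as.character(electrode_labels),
      data = data,
      reference_label = reference_label,
      start_time = start_time
    ),
    class = "eeg_recording"
  )
}

#' Construct a derived multichannel signal
#'
#' Container for bipolar-derived (or otherwise transformed) channels. The time
#' axis is the half-open interval `[start_time, start_time + n/fs)`.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs_hz sampling rate in Hz.
#' @param channel_names character vector naming the channels.
#' @param start_time start offset in seconds.
#' @return an object of class `eeg_signal`.
#' @export
eeg_signal <- function(data, fs_hz, channel_names, start_time = 0) {
  data <- as.matrix(data)
  if (fs_hz <= 0) stop("`fs_hz` must be positive")
  if (length(channel_names) != nrow(data)) {
    stop("`channel_names` must have one entry per row of `data`")
  }
  rownames(data) <- channel_names
  structure(
    list(
      fs_hz = fs_hz,
      channel_names = as.character(channel_names),
      data = data,
      start_time = start_time
    ),
    class = "eeg_signal"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d electrodes x %d samples @ %g Hz (%.1f s), ref %s\n",
    nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz,
    x$reference_label
  ))
  invisible(x)
}

#' @export
print.eeg_signal <- function(x, ...) {
  cat(sprintf(
    "<eeg_signal> %d channels x %d samples @ %g Hz (%.1f s)\n",
    nrow(x$data), ncol(x$data), x$fs_hz, ncol(x$data) / x$fs_hz
  ))
  invisible(x)
}

#' Number of samples in a recording or signal
#' @param x an `eeg_recording` or `eeg_signal`.
#' @return integer sample count.
#' @export
n_samples <- function(x) ncol(x$data)

#' Duration in seconds
#' @param x an `eeg_recording` or `eeg_signal`.
#' @return duration in seconds.
#' @export
duration_s <- function(x) ncol(x$data) / x$fs_hz

#' Sample index of a time point
#'
#' Maps a time in seconds (relative to `start_time`) to a 1-based sample index
#' using the half-open convention `floor(t * fs) + 1`.
#'
#' @param t time in seconds.
#' @param fs_hz sampling rate.
#' @return 1-based sample index.
#' @keywords internal
time_to_sample <- function(t, fs_hz) as.integer(floor(t * fs_hz + 1e-9)) + 1L

#' Convert a multichannel signal to a long tibble
#'
#' @param x an `eeg_signal`.
#' @param ... unused.
#' @return tibble with columns `time_s`, `channel`, `value_uv`.
#' @method as_tibble eeg_signal
#' @export
as_tibble.eeg_signal <- function(x, ...) {
  t <- x$start_time + (seq_len(ncol(x$data)) - 1) / x$fs_hz
  tibble::tibble(
    time_s = rep(t, each = nrow(x$data)),
    channel = rep(x$channel_names, times = ncol(x$data)),
    value_uv = as.vector(x$data)
  )
}

#' Stacked-trace plot of a multichannel signal
#'
#' Standard clinical-style stacked display: channels offset vertically,
#' time on the x axis.
#'
#' @param object an `eeg_signal`.
#' @param spacing_uv vertical offset between traces.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot eeg_signal
#' @export
autoplot.eeg_signal <- function(object, spacing_uv = NULL, ...) {
  df <- as_tibble.eeg_signal(object)
  if (is.null(spacing_uv)) {
    spacing_uv <- 4 * stats::median(apply(object$data, 1, stats::sd))
    if (!is.finite(spacing_uv) || spacing_uv == 0) spacing_uv <- 1
  }
  offs <- stats::setNames(
    (length(object$channel_names) - seq_along(object$channel_names)) * spacing_uv,
    object$channel_names
  )
  df$y <- df$value_uv + offs[df$channel]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$y,
                                   group = .data$channel)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::scale_y_continuous(
      breaks = unname(offs), labels = names(offs)
    ) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
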