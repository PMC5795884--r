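# Seeded synthetic EEG generator.
#
# Emulates the statistical structure the downstream analysis assumes: spatially
# correlated 1/f background with an occipital alpha rhythm, frontally dominant
# left-right-symmetric blink EOG, lateralized rhythmic ictal discharges with a
# spatial gain profile decaying from the focus, high-frequency EMG bursts, and
# single-electrode contact faults (which phase-reverse across bipolar channels
# sharing the electrode). All injectors are additive and take private sub-seeds
# derived from the master seed, so they are reproducible and commute.

#' Approximate 2-D head layout
#'
#' Flattened electrode coordinates on a unit head: `x` runs posterior (-1) to
#' anterior (+1), `y` left (-) to right (+). Mirror-image electrodes share `x`
#' and have opposite `y`, so any source on the midline projects with exactly
#' equal gain to homologous left/right electrodes. Behind-the-ear electrodes
#' (LT/LC left top/center, RT/RC right) sit posterior-lateral, below T3/T4.
#'
#' @return tibble with columns `label`, `x`, `y`.
#' @export
head_layout <- function() {
  tibble::tribble(
    ~label, ~x, ~y,
    "Fpz", 1.00, 0.00,
    "Fp1", 0.95, -0.31, "Fp2", 0.95, 0.31,
    "F7", 0.59, -0.81, "F8", 0.59, 0.81,
    "F3", 0.55, -0.48, "F4", 0.55, 0.48,
    "Fz", 0.58, 0.00,
    "T3", 0.00, -1.00, "T4", 0.00, 1.00,
    "C3", 0.00, -0.50, "C4", 0.00, 0.50,
    "Cz", 0.00, 0.00,
    "T5", -0.59, -0.81, "T6", -0.59, 0.81,
    "P3", -0.55, -0.48, "P4", -0.55, 0.48,
    "Pz", -0.58, 0.00,
    "O1", -0.95, -0.31, "O2", -0.95, 0.31,
    "Sph1", 0.10, -1.10, "Sph2", 0.10, 1.10,
    "LT", -0.35, -1.15, "RT", -0.35, 1.15,
    "LC", -0.45, -1.20, "RC", -0.45, 1.20
  )
}

sub_seed <- function(seed, k) {
  (as.numeric(seed) * 7919 + 104729 * k) %% 2147483629
}

gauss_gain <- function(layout, cx, cy, lambda) {
  exp(-((layout$x - cx)^2 + (layout$y - cy)^2) / lambda^2)
}

# 1/f^beta noise, unit RMS, deterministic given the RNG state
colored_noise <- function(n, beta, fs) {
  x <- stats::rnorm(n)
  if (beta != 0) {
    X <- stats::fft(x)
    k <- 0:(n - 1)
    k <- pmin(k, n - k) # two-sided frequency index
    f <- k * fs / n
    a <- c(0, f[-1]^(-beta / 2))
    x <- Re(stats::fft(X * a, inverse = TRUE)) / n
  }
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

# white noise band-limited to [lo, hi] Hz via an FFT mask, unit RMS
bandlimited_noise <- function(n, lo, hi, fs) {
  X <- stats::fft(stats::rnorm(n))
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n
  X[f < lo | f > hi] <- 0
  x <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s > 0) x / s else x
}

#' Synthetic EEG configuration
#'
#' Collects every tunable of the generator with defaults emulating the
#' reference clinical cohort at desk scale: 250 Hz referential recordings,
#' ~15 uV RMS 1/f background with occipital alpha, blinks at 15/min with
#' 50-70 uV frontopolar peaks, 60 s rhythmic 3-5 Hz ictal discharges at
#' 150 uV focus amplitude (a clearly supra-background, high-SNR seizure),
#' occasional 20-35 Hz EMG bursts over temporal/auricular electrodes, and an
#' optional single-electrode fault.
#'
#' @param seed master integer seed; each injector derives a private sub-seed.
#' @param duration_s recording length in seconds.
#' @param fs_hz sampling rate (Hz).
#' @param background list: `exponent` (1/f^beta), `rms_uv`, `alpha_hz` band,
#'   `alpha_gain_uv` (RMS at the occipital pole), `n_sources` shared spatial
#'   sources, `lambda` spatial gain width.
#' @param blink list: `rate_per_min`, `template_s`, `peak_uv` (length-2 range,
#'   within the 30-80 uV detectable window), `asymmetry` in `[0,1]` (0 =
#'   perfectly left-right symmetric), `lambda` spatial falloff.
#' @param ictal list: `onset_s` (vector; `NULL` disables), `duration_s`,
#'   `freq_hz` (3-5), `amplitude_uv` at the focus, `focus_side`, `focus_lobe`,
#'   `lambda` spatial falloff.
#' @param emg list: `rate_per_hour`, `burst_s`, `band_hz`, `amplitude_uv`,
#'   `electrodes`.
#' @param fault list: `electrode` (`NA` disables), `start_s`, `duration_s`,
#'   `amplitude_uv`, `kind` (`"rhythmic"` or `"step"`).
#' @param patient_id optional patient id stamped on annotations.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       duration_s = 600,
                       fs_hz = 250,
                       background = list(),
                       blink = list(),
                       ictal = list(),
                       emg = list(),
                       fault = list(),
                       patient_id = 1L) {
  if (duration_s <= 0) stop("`duration_s` must be positive")
  bg <- utils::modifyList(list(
    exponent = 1, rms_uv = 15, alpha_hz = c(8, 12), alpha_gain_uv = 8,
    n_sources = 4, lambda = 1.0
  ), background)
  bl <- utils::modifyList(list(
    rate_per_min = 15, template_s = 0.3, peak_uv = c(50, 70),
    asymmetry = 0, lambda = 0.6
  ), blink)
  ic <- utils::modifyList(list(
    onset_s = NULL, duration_s = 60, freq_hz = 4, amplitude_uv = 150,
    focus_side = "right", focus_lobe = "temporal", lambda = 0.8
  ), ictal)
  em <- utils::modifyList(list(
    rate_per_hour = 6, burst_s = 2, band_hz = c(20, 35), amplitude_uv = 20,
    electrodes = c("T3", "T4", "Sph1", "Sph2", "LT", "LC", "RT", "RC")
  ), emg)
  fl <- utils::modifyList(list(
    electrode = NA_character_, start_s = 0, duration_s = 0,
    amplitude_uv = 0, kind = "rhythmic"
  ), fault)
  if (bl$rate_per_min < 0 || em$rate_per_hour < 0) stop("rates must be >= 0")
  if (bl$asymmetry < 0 || bl$asymmetry > 1) stop("blink asymmetry must be in [0,1]")
  if (length(ic$onset_s)) {
    if (any(ic$onset_s < 0) || any(ic$onset_s + ic$duration_s > duration_s)) {
      stop("ictal interval(s) must lie inside the recording")
    }
  }
  structure(list(
    seed = seed, duration_s = duration_s, fs_hz = fs_hz,
    background = bg, blink = bl, ictal = ic, emg = em, fault = fl,
    patient_id = patient_id
  ), class = "sim_config")
}

#' Generate spatially correlated 1/f background EEG
#'
#' Each electrode receives a mixture of a few shared 1/f^beta sources (smooth
#' Gaussian gain maps over the head layout, giving realistic inter-electrode
#' correlation), an alpha-band source weighted toward O1/O2, and independent
#' per-electrode 1/f noise. Rows are scaled so each electrode has the
#' configured RMS in expectation.
#'
#' @param cfg a [sim_config()].
#' @return an [eeg_recording()] over all layout electrodes.
#' @export
generate_background <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  lay <- head_layout()
  n <- round(cfg$duration_s * cfg$fs_hz)
  ne <- nrow(lay)
  bg <- cfg$background
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, 1))

  ns <- bg$n_sources
  G <- matrix(0, ne, ns)
  for (k in seq_len(ns)) {
    ang <- stats::runif(1, 0, 2 * pi)
    r <- sqrt(stats::runif(1))
    G[, k] <- gauss_gain(lay, r * cos(ang), r * sin(ang), bg$lambda)
  }
  S <- matrix(0, ns, n)
  for (k in seq_len(ns)) S[k, ] <- colored_noise(n, bg$exponent, cfg$fs_hz)

  alpha_g <- gauss_gain(lay, -0.95, 0, 0.5)
  alpha <- bandlimited_noise(n, bg$alpha_hz[1], bg$alpha_hz[2], cfg$fs_hz)

  ind_frac <- 0.45 # independent noise share of per-electrode RMS
  shared_var <- rowSums(G^2)
  shared_scale <- sqrt(1 - ind_frac^2) / sqrt(pmax(shared_var, 1e-12))
  data <- (G * shared_scale) %*% S
  for (e in seq_len(ne)) {
    data[e, ] <- data[e, ] +
      ind_frac * colored_noise(n, bg$exponent, cfg$fs_hz)
  }
  data <- data * bg$rms_uv
  if (bg$alpha_gain_uv > 0) {
    data <- data + (bg$alpha_gain_uv * alpha_g) %*% t(alpha)
  }
  eeg_recording(data, cfg$fs_hz, lay$label, reference_label = "Fpz")
}

# raised-cosine bump of unit peak
blink_template <- function(template_s, fs) {
  m <- round(template_s * fs / 2)
  t <- (-m):m
  0.5 * (1 + cos(pi * t / m))
}

# blink spatial gains: single midline anterior source, normalized to 1 at Fp2
blink_gains <- function(lambda = 0.6, asymmetry = 0) {
  lay <- head_layout()
  g <- gauss_gain(lay, 1.15, 0, lambda)
  g <- g / g[lay$label == "Fp2"]
  g <- g * ifelse(lay$y < 0, 1 + asymmetry / 2,
                  ifelse(lay$y > 0, 1 - asymmetry / 2, 1))
  stats::setNames(g, lay$label)
}

#' Inject blink EOG artifacts
#'
#' Adds a smooth positive raised-cosine deflection (~300 ms) at pseudo-random
#' times. The spatial gain is maximal at Fp1/Fp2 and decays posteriorly; at
#' `asymmetry = 0` homologous left/right electrodes receive exactly equal gain,
#' so cross-head derivations (LC-RC, LT-RT) cancel the blink identically.
#'
#' @param rec an [eeg_recording()] covering the layout electrodes.
#' @param cfg a [sim_config()].
#' @return list with `recording` and `blink_times_s` (peak times).
#' @export
inject_blinks <- function(rec, cfg) {
  bl <- cfg$blink
  if (bl$rate_per_min <= 0) {
    return(list(recording = rec, blink_times_s = numeric(0)))
  }
  if (bl$template_s >= duration_s(rec)) {
    stop("blink template longer than the recording")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, 2))

  tmpl <- blink_template(bl$template_s, rec$fs_hz)
  half <- (length(tmpl) - 1) / 2
  # renewal process: exponential gaps with a physiological 0.5 s refractory
  times <- c()
  t <- 0
  repeat {
    t <- t + 0.5 + stats::rexp(1, rate = bl$rate_per_min / 60)
    if (t > duration_s(rec) - bl$template_s) break
    times <- c(times, t)
  }
  g <- blink_gains(bl$lambda, bl$asymmetry)[rec$electrode_labels]
  data <- rec$data
  amps <- stats::runif(length(times), bl$peak_uv[1], bl$peak_uv[2])
  for (i in seq_along(times)) {
    c0 <- time_to_sample(times[i], rec$fs_hz)
    idx <- (c0 - half):(c0 + half)
    if (idx[1] < 1 || idx[length(idx)] > ncol(data)) next
    data[, idx] <- data[, idx] + (amps[i] * g) %*% t(tmpl)
  }
  rec$data <- data
  list(recording = rec, blink_times_s = times)
}

focus_electrode <- function(side, lobe) {
  stopifnot(side %in% c("left", "right"))
  base <- switch(lobe,
    temporal = c(left = "T3", right = "T4"),
    parietal = c(left = "P3", right = "P4"),
    occipital = c(left = "O1", right = "O2"),
    stop("unknown focus lobe: ", lobe)
  )
  unname(base[side])
}

#' Inject lateralized rhythmic ictal discharges
#'
#' Adds an amplitude-modulated rhythm at the configured base frequency plus a
#' weak second harmonic over each configured onset, with a spatial gain profile
#' decaying with layout distance from the focus electrode (ipsilateral gains
#' strictly exceed their contralateral mirror images).
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [sim_config()]; `cfg$ictal$onset_s` may be a vector.
#' @return list with `recording` and `annotations` (a seizure annotation
#'   tibble, one row per onset; empty if ictal is disabled).
#' @export
inject_seizure <- function(rec, cfg) {
  ic <- cfg$ictal
  empty <- seizure_annotations(integer(0), numeric(0), numeric(0), character(0))
  if (!length(ic$onset_s)) {
    return(list(recording = rec, annotations = empty))
  }
  if (any(ic$onset_s < 0) || any(ic$onset_s + ic$duration_s > duration_s(rec))) {
    stop("ictal interval(s) must lie inside the recording")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, 3))

  lay <- head_layout()
  foc <- focus_electrode(ic$focus_side, ic$focus_lobe)
  fx <- lay$x[lay$label == foc]
  fy <- lay$y[lay$label == foc]
  g <- stats::setNames(gauss_gain(lay, fx, fy, ic$lambda), lay$label)
  g <- g[rec$electrode_labels]

  fs <- rec$fs_hz
  data <- rec$data
  for (on in ic$onset_s) {
    nsamp <- round(ic$duration_s * fs)
    tt <- (0:(nsamp - 1)) / fs
    phi <- stats::runif(2, 0, 2 * pi)
    ramp_s <- min(3, ic$duration_s / 4)
    env <- pmin(1, pmin(tt, ic$duration_s - tt) / ramp_s)
    env <- env * (1 + 0.25 * sin(2 * pi * 0.15 * tt + phi[2]))
    wave <- env * (sin(2 * pi * ic$freq_hz * tt + phi[1]) +
                     0.25 * sin(4 * pi * ic$freq_hz * tt + 2 * phi[1]))
    i0 <- time_to_sample(on, fs)
    idx <- i0:(i0 + nsamp - 1)
    data[, idx] <- data[, idx] + (ic$amplitude_uv * g) %*% t(wave)
  }
  rec$data <- data
  ann <- seizure_annotations(cfg$patient_id, ic$onset_s,
                             ic$onset_s + ic$duration_s)
  list(recording = rec, annotations = ann)
}

#' Inject EMG bursts
#'
#' Adds Hann-windowed bursts of band-limited (>= 20 Hz) noise, independent per
#' affected electrode, at pseudo-random times.
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [sim_config()].
#' @return list with `recording` and `intervals` tibble (`start_s`, `end_s`).
#' @export
inject_emg <- function(rec, cfg) {
  em <- cfg$emg
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  if (em$rate_per_hour <= 0 || em$amplitude_uv <= 0) {
    return(list(recording = rec, intervals = empty))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(sub_seed(cfg$seed, 4))

  fs <- rec$fs_hz
  n_burst <- stats::rpois(1, em$rate_per_hour * duration_s(rec) / 3600)
  if (n_burst == 0) return(list(recording = rec, intervals = empty))
  starts <- sort(stats::runif(n_burst, 0, duration_s(rec) - em$burst_s))
  el <- intersect(em$electrodes, rec$electrode_labels)
  nsamp <- round(em$burst_s * fs)
  win <- 0.5 * (1 - cos(2 * pi * seq(0, 1, length.out = nsamp)))
  data <- rec$data
  for (s in starts) {
    i0 <- time_to_sample(s, fs)
    idx <- i0:(i0 + nsamp - 1)
    for (e in el) {
      noise <- bandlimited_noise(nsamp, em$band_hz[1], em$band_hz[2], fs)
      data[e, idx] <- data[e, idx] + em$amplitude_uv * win * noise
    }
  }
  rec$data <- data
  list(recording = rec,
       intervals = tibble::tibble(start_s = starts, end_s = starts + em$burst_s))
}

#' Inject a single-electrode contact fault
#'
#' Adds a high-amplitude rhythmic or step artifact to exactly one electrode.
#' Because the artifact lives on one referential electrode, any two derived
#' bipolar channels sharing it on opposite poles show the artifact with
#' opposite sign (the classic phase-reversal signature of a bad contact).
#'
#' @param rec an [eeg_recording()].
#' @param cfg a [sim_config()].
#' @return list with `recording` and `intervals` tibble.
#' @export
inject_electrode_fault <- function(rec, cfg) {
  fl <- cfg$fault
  empty <- tibble::tibble(start_s = numeric(0), end_s = numeric(0))
  if (is.na(fl$electrode) || fl$amplitude_uv <= 0 || fl$duration_s <= 0) {
    return(list(recording = rec, intervals = empty))
  }
  if (!fl$electrode %in% rec$electrode_labels) {
    stop("fault electrode not present in recording: ", fl$electrode)
  }
  fs <- rec$fs_hz
  nsamp <- round(fl$duration_s * fs)
  tt <- (0:(nsamp - 1)) / fs
  ramp <- pmin(1, pmin(tt, fl$duration_s - tt) / 0.5)
  wave <- switch(fl$kind,
    rhythmic = ramp * sin(2 * pi * 1.5 * tt),
    step = ramp,
    stop("fault kind must be 'rhythmic' or 'step'")
  )
  i0 <- time_to_sample(fl$start_s, fs)
  idx <- i0:(i0 + nsamp - 1)
  if (idx[length(idx)] > ncol(rec$data)) stop("fault extends past the recording")
  rec$data[fl$electrode, idx] <- rec$data[fl$electrode, idx] +
    fl$amplitude_uv * wave
  list(recording = rec,
       intervals = tibble::tibble(start_s = fl$start_s,
                                  end_s = fl$start_s + fl$duration_s))
}

#' Simulate one annotated recording
#'
#' Composes background, blinks, seizures, EMG, and fault injection, and
#' returns the recording together with the full ground truth needed to score
#' every downstream stage without re-inspecting the signal.
#'
#' @param cfg a [sim_config()].
#' @return list with `recording` and `truth` (blink times, seizure
#'   annotations, EMG and fault intervals).
#' @export
simulate_recording <- function(cfg) {
  rec <- generate_background(cfg)
  b <- inject_blinks(rec, cfg)
  s <- inject_seizure(b$recording, cfg)
  e <- inject_emg(s$recording, cfg)
  f <- inject_electrode_fault(e$recording, cfg)
  list(
    recording = f$recording,
    truth = list(
      blink_times_s = b$blink_times_s,
      seizure_annotations = s$annotations,
      emg_intervals = e$intervals,
      fault_intervals = f$intervals
    )
  )
}

#' Configurations for a pseudo-cohort mirroring the reference metadata
#'
#' Builds one [sim_config()] per patient in the packaged metadata table:
#' seizure counts, focus side and lobe are taken from the table, seizures are
#' placed at the centre of consecutive `epoch_len_s` blocks, and a seizure-free
#' tail long enough for `n_nonseizure` guarded epochs is appended. Recordings
#' are desk-scale (10-minute epochs by default) stand-ins for the cohort's 1 h
#' clinical epochs; pass `epoch_len_s = 3600` for full scale.
#'
#' @param seed master seed; patient p uses sub-seed `seed + p`.
#' @param epoch_len_s epoch length the cohort is built around.
#' @param n_nonseizure seizure-free epochs the tail must accommodate.
#' @param guard_s guard distance between seizures and the seizure-free tail.
#' @param meta metadata tibble (defaults to the packaged reference cohort).
#' @param ... overrides passed to every patient's [sim_config()] (e.g.
#'   `blink = list(asymmetry = 0)`).
#' @return list of `sim_config` objects.
#' @export
cohort_configs <- function(seed = 1L, epoch_len_s = 600, n_nonseizure = 2,
                           guard_s = 600, meta = load_patient_metadata(),
                           ...) {
  extra <- list(...)
  purrr::pmap(meta, function(pid, n_seizures, focus_side, focus_lobe, ...) {
    onsets <- epoch_len_s * (seq_len(n_seizures) - 1) + epoch_len_s / 2
    # tail slack of one full epoch guarantees the admissible-start range for
    # the seizure-free sampler can always host n_nonseizure disjoint epochs
    dur <- epoch_len_s * n_seizures + guard_s +
      (n_nonseizure + 1) * epoch_len_s
    args <- utils::modifyList(list(
      seed = sub_seed(seed, 100 + pid),
      duration_s = dur,
      ictal = list(onset_s = onsets, focus_side = focus_side,
                   focus_lobe = focus_lobe),
      patient_id = pid
    ), extra)
    args$ictal <- utils::modifyList(
      list(onset_s = onsets, focus_side = focus_side, focus_lobe = focus_lobe),
      if (is.null(extra$ictal)) list() else extra$ictal
    )
    do.call(sim_config, args)
  })
}

#' Generate a pseudo-patient dataset
#'
#' @param cfg_list list of [sim_config()]s (see [cohort_configs()]).
#' @return list of `list(recording, truth)`, one per patient.
#' @export
generate_patient_dataset <- function(cfg_list) {
  purrr::map(cfg_list, simulate_recording)
}

# save/restore global RNG state so injectors do not disturb the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
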