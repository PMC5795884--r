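# Shared builders for small synthetic fixtures. Everything is generated in
# code; seeds are fixed so every run sees identical data.

tiny_recording <- function(n_electrodes = 4, n_samples = 1000, fs = 250,
                           sd = 20, seed = 99) {
  withr::with_seed(seed, {
    eeg_recording(matrix(rnorm(n_electrodes * n_samples, sd = sd),
                         n_electrodes),
                  fs, paste0("E", seq_len(n_electrodes)))
  })
}

# a multichannel signal carrying named sinusoids
sine_signal <- function(freqs, n_s = 20, fs = 250, phases = NULL) {
  tt <- (1:(n_s * fs)) / fs
  if (is.null(phases)) phases <- seq_along(freqs) * 0.7
  data <- t(mapply(function(f, ph) sin(2 * pi * f * tt + ph), freqs, phases))
  eeg_signal(data, fs, paste0("s", freqs))
}

# direct-DFT brute-force Welch cross-spectra: the independent oracle used
# against the pipeline implementation (no shared code path)
brute_cross <- function(x, y, fs, seg_s = 2, overlap = 0.5) {
  nper <- round(seg_s * fs)
  step <- round(nper * (1 - overlap))
  starts <- seq(1, length(x) - nper + 1, by = step)
  w <- 0.5 * (1 - cos(2 * pi * (0:(nper - 1)) / nper))
  nf <- nper %/% 2 + 1
  gxx <- gyy <- numeric(nf)
  gxy <- complex(real = numeric(nf), imaginary = numeric(nf))
  for (s0 in starts) {
    xs <- x[s0:(s0 + nper - 1)] * w
    ys <- y[s0:(s0 + nper - 1)] * w
    X <- vapply(0:(nf - 1), function(k) {
      sum(xs * exp(-2i * pi * k * (0:(nper - 1)) / nper))
    }, complex(1))
    Y <- vapply(0:(nf - 1), function(k) {
      sum(ys * exp(-2i * pi * k * (0:(nper - 1)) / nper))
    }, complex(1))
    gxx <- gxx + Re(X * Conj(X))
    gyy <- gyy + Re(Y * Conj(Y))
    gxy <- gxy + X * Conj(Y)
  }
  os <- c(1, rep(2, nf - 2), if (nper %% 2 == 0) 1 else 2)
  sc <- os / (length(starts) * fs * sum(w^2))
  list(freq = (0:(nf - 1)) * fs / nper,
       gxx = gxx * sc, gyy = gyy * sc, gxy = gxy * sc)
}

# tiny ear-montage patient for detection tests: rhythmic 4 Hz seizures on a
# noisy background, epochs scaled to `epoch_s`
tiny_patient_epochs <- function(n_seizures = 3, epoch_s = 60, fs = 250,
                                amp = 8, seed = 31) {
  withr::with_seed(seed, {
    chans <- define_ear_montage()$channel
    mk_sig <- function(with_seiz) {
      n <- epoch_s * fs
      data <- matrix(rnorm(4 * n, sd = 3), 4)
      if (with_seiz) {
        on <- epoch_s / 2
        len <- round(epoch_s / 3 * fs)
        idx <- (on * fs + 1):(on * fs + len)
        tt <- (1:len) / fs
        gains <- c(1, 0.8, 0.6, 0.9)
        for (ci in 1:4) {
          data[ci, idx] <- data[ci, idx] + amp * gains[ci] * sin(2 * pi * 4 * tt)
        }
      }
      eeg_signal(data, fs, chans)
    }
    seiz <- lapply(seq_len(n_seizures), function(i) {
      sig <- mk_sig(TRUE)
      ann <- seizure_annotations(1L, epoch_s / 2, epoch_s / 2 + epoch_s / 3)
      earseiz:::new_epoch(sig, ann, "seizure", 1L, 0)
    })
    nons <- lapply(1:2, function(i) {
      earseiz:::new_epoch(mk_sig(FALSE),
                          seizure_annotations(integer(0), numeric(0),
                                              numeric(0), character(0)),
                          "non_seizure", 1L, 0)
    })
    list(seizure = seiz, nonseizure = nons)
  })
}
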