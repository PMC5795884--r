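test_that("ICA recovers independent sources up to sign and permutation", {
  withr::local_seed(3)
  n <- 5000
  S <- rbind(runif(n) - 0.5,
             sin(2 * pi * 7 * (1:n) / 250) * (runif(n) > 0.3))
  A <- matrix(rnorm(8), 4)
  sig <- eeg_signal(A %*% S, 250, paste0("c", 1:4))
  comps <- decompose_components(sig, n_components = 2, seed = 5)
  cors <- vapply(comps, function(cp) {
    max(abs(stats::cor(cp$timecourse, S[1, ])),
        abs(stats::cor(cp$timecourse, S[2, ])))
  }, 0)
  expect_true(all(cors > 0.95))
  expect_equal(stats::sd(comps[[1]]$timecourse), 1, tolerance = 1e-6)

  comps2 <- decompose_components(sig, n_components = 2, seed = 5)
  expect_identical(comps[[1]]$timecourse, comps2[[1]]$timecourse)

  expect_error(decompose_components(sig, n_components = 9), "exceed")
})

test_that("the blink component is identified by frontal correlation", {
  withr::local_seed(4)
  n <- 4000
  blink <- numeric(n)
  tmpl <- earseiz:::blink_template(0.3, 250)
  for (t0 in seq(200, 3800, by = 400)) {
    idx <- t0:(t0 + length(tmpl) - 1)
    blink[idx] <- blink[idx] + tmpl
  }
  other <- sin(2 * pi * 9 * (1:n) / 250)
  A <- rbind(c(0.2, 1.5), c(1.0, 0.3), c(0.5, 0.2), c(0.1, 1.0))
  sig <- eeg_signal(A %*% rbind(other, blink) + 0.05 * matrix(rnorm(4 * n), 4),
                    250, c("Fp2-F8", "x1", "x2", "x3"))
  comps <- decompose_components(sig, seed = 6)
  frontal <- sig$data["Fp2-F8", ]
  picked <- identify_eog_component(comps, frontal)
  # the picked component must carry the blink train, sign-aligned positive
  expect_gt(stats::cor(picked$timecourse, blink), 0.9)
  expect_gt(picked$score, 0.5)
  expect_equal(picked$selection_method, "auto")

  manual <- identify_eog_component(comps, frontal, manual_index = 2)
  expect_equal(manual$selection_method, "manual")

  noise_comps <- decompose_components(
    eeg_signal(matrix(rnorm(4 * n), 4), 250, paste0("c", 1:4)), seed = 7
  )
  expect_warning(low <- identify_eog_component(noise_comps, frontal),
                 "0.2")
  expect_true(low$low_confidence)
})

test_that("blink peak detection gates on amplitude and refractory spacing", {
  fs <- 250
  x <- numeric(60 * fs)
  tmpl <- earseiz:::blink_template(0.3, fs)
  truth <- seq(2, 58, length.out = 20)
  for (t0 in truth) {
    i <- round(t0 * fs)
    idx <- i:(i + length(tmpl) - 1)
    x[idx] <- x[idx] + 50 * tmpl
  }
  pk <- detect_blink_peaks(x, fs)
  expect_length(pk, 20)
  expect_true(all(vapply(truth, function(t0) {
    min(abs(pk - (t0 + 0.15))) < 0.02
  }, TRUE)))

  expect_length(detect_blink_peaks(2 * x, fs), 0) # 100 uV: above the gate
  expect_length(detect_blink_peaks(numeric(1000), fs), 0)
})

test_that("peri-blink averaging is exact for templates and unbiased under noise", {
  fs <- 250
  tmpl <- earseiz:::blink_template(0.3, fs)
  pad <- numeric(fs)
  x <- c(pad, tmpl, pad, tmpl, pad)
  pk_i <- (length(tmpl) + 1) / 2
  pk <- c((length(pad) + pk_i - 1) / fs,
          (2 * length(pad) + length(tmpl) + pk_i - 1) / fs)
  avg <- average_blink_epochs(x, fs, pk)
  expect_equal(attr(avg, "n_epochs"), 2)
  expect_equal(max(avg), 1, tolerance = 1e-9)
  expect_length(avg, 101)

  # template + zero-mean noise, 100 peaks: pointwise CLT bound
  withr::local_seed(8)
  sigma <- 0.5
  n <- 120 * fs
  x2 <- rnorm(n, sd = sigma)
  truth <- seq(1, 119, length.out = 100)
  for (t0 in truth) {
    i <- round(t0 * fs)
    idx <- i:(i + length(tmpl) - 1)
    x2[idx] <- x2[idx] + tmpl
  }
  pk_idx <- (length(tmpl) + 1) / 2 # template peak sample
  avg2 <- average_blink_epochs(x2, fs, truth + (pk_idx - 1) / fs)
  # avg is centred on the peak (index 51) <-> template peak
  off <- -25:25
  expect_lt(max(abs(avg2[51 + off] - tmpl[pk_idx + off])),
            3 * sigma / sqrt(100) + 0.02)

  # epochs at the signal edge are skipped with a warning
  expect_warning(avg3 <- average_blink_epochs(x, fs, c(0.01, pk)),
                 "edge")
  expect_equal(attr(avg3, "n_epochs"), 2)
  expect_error(average_blink_epochs(x, fs, 0.01), "no blink epoch")
})

test_that("EOG amplitude is the +/-0.1 s mean and is linear", {
  fs <- 250
  expect_equal(eog_amplitude(numeric(101), fs), 0)
  expect_equal(eog_amplitude(rep(5, 101), fs), 5)
  withr::local_seed(9)
  w1 <- rnorm(101)
  w2 <- rnorm(101)
  expect_equal(eog_amplitude(2 * w1 + 3 * w2, fs),
               2 * eog_amplitude(w1, fs) + 3 * eog_amplitude(w2, fs))
})

test_that("symmetric blinks vanish on cross-head but persist frontally", {
  cfg <- sim_config(seed = 22, duration_s = 240,
                    blink = list(rate_per_min = 20, peak_uv = c(55, 65)))
  zero <- generate_background(cfg)
  zero$data[] <- 0
  bl <- inject_blinks(zero, cfg)
  scalp <- apply_montage(bl$recording, define_scalp_montage())
  ear <- apply_montage(bl$recording, define_ear_montage())
  amp <- function(x) {
    eog_amplitude(average_blink_epochs(x, 250, bl$blink_times_s), 250)
  }
  a_front <- amp(scalp$data["Fp2-F8", ])
  a_cross1 <- amp(ear$data["LC-RC", ])
  a_cross2 <- amp(ear$data["LT-RT", ])
  a_uni <- amp(ear$data["LT-LC", ])
  # the clinically observed ordering: cross-head < unilateral < frontopolar
  expect_equal(a_cross1, 0)
  expect_equal(a_cross2, 0)
  expect_lt(abs(a_cross1), abs(a_uni))
  expect_lt(abs(a_uni), abs(a_front))
  # frontal amplitude tracks the injected template's +/-0.1 s mean
  tmpl <- earseiz:::blink_template(0.3, 250)
  pk_i <- (length(tmpl) + 1) / 2
  oracle <- 60 * mean(tmpl[(pk_i - 25):(pk_i + 25)])
  expect_equal(a_front, oracle, tolerance = 0.2)
})

test_that("the detector-free blink pipeline has high recall at high SNR", {
  cfg <- sim_config(seed = 23, duration_s = 300,
                    blink = list(rate_per_min = 15))
  sim <- inject_blinks(generate_background(cfg), cfg)
  rep <- suppressWarnings(eog_report(sim$recording, seed = 2))
  truth <- sim$blink_times_s
  matched <- sum(vapply(truth, function(t0) {
    any(abs(rep$peak_times_s - t0) < 0.05)
  }, TRUE))
  expect_gte(matched / length(truth), 0.95)
  expect_equal(nrow(rep$amplitudes), 5)
  # single short subject: residual-noise bound scales as rms/sqrt(n_blinks)
  expect_lt(max(abs(rep$amplitudes$amplitude_uv[
    rep$amplitudes$channel %in% c("LC-RC", "LT-RT")])), 3)
})

test_that("paired amplitude comparison matches exact signed-rank results", {
  withr::local_seed(10)
  b <- rnorm(12)
  res <- compare_amplitudes_wilcoxon(b + 10, b)
  expect_equal(res$p_value, 2 * (1 / 2)^12)
  expect_equal(res$method, "exact")

  same <- compare_amplitudes_wilcoxon(b, b)
  expect_equal(same$p_value, 1)

  expect_error(compare_amplitudes_wilcoxon(b, b[1:5]), "equal length")
})
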