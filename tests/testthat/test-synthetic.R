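cfg_small <- sim_config(seed = 11, duration_s = 120)

test_that("background generation is deterministic and spectrally shaped", {
  r1 <- generate_background(cfg_small)
  r2 <- generate_background(cfg_small)
  expect_identical(r1$data, r2$data)
  expect_equal(nrow(r1$data), nrow(head_layout()))
  expect_equal(ncol(r1$data), 120 * 250)

  # flat-spectrum condition: beta = 0, no alpha -> log-log Welch slope ~ 0
  cfg0 <- sim_config(seed = 12, duration_s = 120,
                     background = list(exponent = 0, alpha_gain_uv = 0))
  p0 <- estimate_psd(generate_background(cfg0)$data["Cz", ], 250, seg_s = 2)
  sel <- p0$freq_hz > 1 & p0$freq_hz < 100
  slope <- stats::coef(stats::lm(log(psd) ~ log(freq_hz), data = p0[sel, ]))[2]
  expect_lt(abs(slope), 0.1)

  # occipital alpha: 8-12 Hz band power at O1 exceeds neighbouring bands
  p <- estimate_psd(generate_background(cfg_small)$data["O1", ], 250,
                    seg_s = 4)
  alpha <- mean(p$psd[p$freq_hz >= 8 & p$freq_hz <= 12])
  neigh <- mean(p$psd[(p$freq_hz >= 4 & p$freq_hz < 7) |
                        (p$freq_hz > 13 & p$freq_hz <= 16)])
  expect_gt(alpha, neigh)

  expect_error(sim_config(duration_s = 0), "positive")
})

test_that("blink injection is symmetric, amplitude-calibrated and optional", {
  cfg <- sim_config(seed = 21, duration_s = 240,
                    blink = list(rate_per_min = 20))
  rec <- generate_background(cfg)
  zero <- rec
  zero$data[] <- 0
  bl <- inject_blinks(zero, cfg)
  expect_gt(length(bl$blink_times_s), 50)

  ear <- apply_montage(bl$recording, define_ear_montage())
  scalp <- apply_montage(bl$recording, define_scalp_montage())
  # asymmetry 0: cross-head derivations cancel the blink exactly
  expect_equal(max(abs(ear$data["LC-RC", ])), 0)
  expect_equal(max(abs(ear$data["LT-RT", ])), 0)

  # Fp2-F8 mean blink peak within 20% of the configured 50-70 uV range mean
  avg <- average_blink_epochs(scalp$data["Fp2-F8", ], 250, bl$blink_times_s)
  expect_equal(max(avg), 60, tolerance = 0.2)

  # rate 0 leaves the recording untouched
  cfg0 <- sim_config(seed = 21, duration_s = 240,
                     blink = list(rate_per_min = 0))
  expect_identical(inject_blinks(rec, cfg0)$recording$data, rec$data)

  cfg_bad <- sim_config(seed = 1, duration_s = 0.2,
                        blink = list(template_s = 0.3))
  expect_error(inject_blinks(generate_background(sim_config(seed = 1, duration_s = 0.2)),
                             cfg_bad), "longer than")
})

test_that("ictal injection is rhythmic, lateralized and annotated", {
  cfg <- sim_config(seed = 31, duration_s = 180,
                    ictal = list(onset_s = 60, duration_s = 60,
                                 focus_side = "right", focus_lobe = "temporal"))
  rec <- generate_background(cfg)
  out <- inject_seizure(rec, cfg)
  expect_equal(out$annotations$onset_s, 60)
  expect_equal(out$annotations$end_s, 120)

  ict <- out$recording$data["T4", (60 * 250 + 1):(120 * 250)]
  p <- estimate_psd(ict, 250, seg_s = 4)
  expect_equal(p$freq_hz[which.max(p$psd)], 4, tolerance = 0.26)

  # ipsilateral temporal channel carries more ictal band power
  band_p <- function(el) {
    x <- out$recording$data[el, (60 * 250 + 1):(120 * 250)]
    p <- estimate_psd(x, 250, seg_s = 4)
    mean(p$psd[p$freq_hz >= 3 & p$freq_hz <= 5])
  }
  expect_gt(band_p("T4"), band_p("T3"))

  # zero amplitude leaves the samples unchanged
  cfg0 <- sim_config(seed = 31, duration_s = 180,
                     ictal = list(onset_s = 60, amplitude_uv = 0))
  expect_equal(inject_seizure(rec, cfg0)$recording$data, rec$data)

  expect_error(sim_config(duration_s = 100, ictal = list(onset_s = 80,
                                                         duration_s = 60)),
               "inside")
})

test_that("EMG bursts are band-limited, local in time and channel", {
  cfg <- sim_config(seed = 41, duration_s = 120,
                    emg = list(rate_per_hour = 120, amplitude_uv = 30,
                               electrodes = c("T4", "RT")))
  rec <- generate_background(cfg)
  out <- inject_emg(rec, cfg)
  expect_gt(nrow(out$intervals), 0)

  hb_power <- function(data, el, t0, t1) {
    x <- data[el, (round(t0 * 250) + 1):round(t1 * 250)]
    p <- estimate_psd(x, 250, seg_s = 0.5)
    mean(p$psd[p$freq_hz >= 20 & p$freq_hz <= 35])
  }
  iv <- out$intervals[1, ]
  before <- max(0, iv$start_s - 4)
  ratio <- hb_power(out$recording$data, "T4", iv$start_s, iv$end_s) /
    hb_power(rec$data, "T4", iv$start_s, iv$end_s)
  expect_gt(ratio, 5)

  # unaffected electrodes byte-identical, and deterministic under the seed
  expect_identical(out$recording$data["Cz", ], rec$data["Cz", ])
  out2 <- inject_emg(rec, cfg)
  expect_identical(out$recording$data, out2$recording$data)
})

test_that("an electrode fault phase-reverses across its two derivations", {
  cfg <- sim_config(seed = 51, duration_s = 60,
                    fault = list(electrode = "RT", start_s = 20,
                                 duration_s = 20, amplitude_uv = 150))
  rec <- generate_background(cfg)
  out <- inject_electrode_fault(rec, cfg)
  ear_in <- apply_montage(rec, define_ear_montage())
  ear_out <- apply_montage(out$recording, define_ear_montage())
  idx <- (20 * 250 + 1):(40 * 250)
  art_ltrt <- ear_out$data["LT-RT", idx] - ear_in$data["LT-RT", idx]
  art_rtrc <- ear_out$data["RT-RC", idx] - ear_in$data["RT-RC", idx]
  expect_lt(stats::cor(art_ltrt, art_rtrc), -0.99)

  # fault confined to its interval; disabled fault is a no-op
  pre <- 1:(20 * 250)
  expect_identical(out$recording$data[, pre], rec$data[, pre])
  cfg0 <- sim_config(seed = 51, duration_s = 60,
                     fault = list(electrode = "RT", start_s = 20,
                                  duration_s = 20, amplitude_uv = 0))
  expect_identical(inject_electrode_fault(rec, cfg0)$recording$data, rec$data)
})

test_that("injectors are additive and commute", {
  cfg <- sim_config(seed = 61, duration_s = 60,
                    blink = list(rate_per_min = 12),
                    emg = list(rate_per_hour = 120))
  rec <- generate_background(cfg)
  ab <- inject_emg(inject_blinks(rec, cfg)$recording, cfg)$recording
  ba <- inject_blinks(inject_emg(rec, cfg)$recording, cfg)$recording
  expect_equal(ab$data, ba$data)
})

test_that("the default cohort carries 47 seizures and valid annotations", {
  cfgs <- cohort_configs(seed = 3)
  expect_length(cfgs, 12)
  counts <- vapply(cfgs, function(cf) length(cf$ictal$onset_s), 0L)
  expect_equal(counts, c(1, 9, 8, 1, 2, 2, 5, 6, 2, 1, 3, 7))
  expect_equal(sum(counts), 47)

  # realize two small patients and check the ground truth contract
  meta <- load_patient_metadata()[c(1, 5), ]
  ds <- generate_patient_dataset(
    cohort_configs(seed = 3, epoch_len_s = 60, guard_s = 60,
                   n_nonseizure = 1, meta = meta)
  )
  for (sim in ds) {
    ann <- sim$truth$seizure_annotations
    expect_true(all(ann$onset_s >= 0))
    expect_true(all(ann$end_s <= duration_s(sim$recording)))
    expect_true(all(sim$truth$blink_times_s <= duration_s(sim$recording)))
  }
  # byte-identical EDF export under a fixed master seed
  f1 <- withr::local_tempfile(fileext = ".edf")
  f2 <- withr::local_tempfile(fileext = ".edf")
  write_recording(ds[[1]]$recording, f1)
  ds2 <- generate_patient_dataset(
    cohort_configs(seed = 3, epoch_len_s = 60, guard_s = 60,
                   n_nonseizure = 1, meta = meta[1, ])
  )
  write_recording(ds2[[1]]$recording, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})
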