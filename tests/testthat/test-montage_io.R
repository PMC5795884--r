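test_that("scalp and ear montage definitions match the clinical channel sets", {
  scalp <- define_scalp_montage()
  expect_equal(nrow(scalp), 22)
  expect_equal(scalp$channel[1], "Fp2-F8")
  expect_true(all(c("T4-Sph2", "T3-Sph1") %in% scalp$channel))
  expect_false(anyDuplicated(scalp$channel) > 0)

  ear <- define_ear_montage()
  expect_equal(ear$channel, c("LC-RC", "LT-RT", "LT-LC", "RT-RC"))
  expect_equal(unlist(ear[3, ], use.names = FALSE), c("LT-LC", "LT", "LC"))
  expect_true(all(ear$anode != ear$cathode))
  expect_true(all(scalp$anode != scalp$cathode))
})

test_that("apply_montage takes sample-aligned potential differences", {
  rec <- eeg_recording(rbind(c(3, 3), c(1, 2)), 250, c("A", "B"))
  m <- tibble::tibble(channel = "A-B", anode = "A", cathode = "B")
  out <- apply_montage(rec, m)
  expect_equal(unname(out$data[1, ]), c(2, 1))
  expect_equal(out$fs_hz, 250)

  # anode == cathode signal -> identically zero channel
  rec2 <- eeg_recording(rbind(c(5, 7), c(5, 7)), 250, c("A", "B"))
  expect_equal(unname(apply_montage(rec2, m)$data[1, ]), c(0, 0))

  # linearity: montage of a*x equals a * montage of x
  rec3 <- tiny_recording(3)
  m3 <- tibble::tibble(channel = c("c1", "c2"), anode = c("E1", "E2"),
                       cathode = c("E3", "E3"))
  scaled <- rec3
  scaled$data <- 2.5 * scaled$data
  expect_equal(apply_montage(scaled, m3)$data,
               2.5 * apply_montage(rec3, m3)$data)

  expect_error(apply_montage(rec, tibble::tibble(channel = "A-Z",
                                                 anode = "A", cathode = "Z")),
               "missing.*A-Z")
})

test_that("a source projected with equal gain cancels in the derivation", {
  # blink-like bump with equal gain on LC and RC; LC-RC must be zero while a
  # frontal channel with unequal gains keeps the bump
  n <- 500
  bump <- c(numeric(200), earseiz:::blink_template(0.3, 250), numeric(n))[1:n]
  gains <- c(Fp2 = 1, F8 = 0.1, LC = 0.25, RC = 0.25)
  rec <- eeg_recording(outer(gains, bump), 250, names(gains))
  m <- tibble::tibble(channel = c("Fp2-F8", "LC-RC"),
                      anode = c("Fp2", "LC"), cathode = c("F8", "RC"))
  out <- apply_montage(rec, m)
  expect_equal(max(abs(out$data["LC-RC", ])), 0)
  expect_equal(max(abs(out$data["Fp2-F8", ])), 0.9, tolerance = 1e-8)
})

test_that("EDF round trip preserves labels, rate and samples to quantization", {
  rec <- tiny_recording(25, 2500, sd = 40, seed = 12)
  tf <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, tf)
  back <- read_recording(tf)
  expect_identical(back$electrode_labels, rec$electrode_labels)
  expect_equal(back$fs_hz, rec$fs_hz)
  expect_equal(dim(back$data), dim(rec$data))
  # 16-bit quantization bound: (physical range) / 65535 per electrode
  qstep <- 2 * ceiling(apply(abs(rec$data), 1, max) * 1.0001 * 100) / 100 / 65535
  err <- apply(abs(back$data - rec$data), 1, max)
  expect_true(all(err <= qstep + 1e-9))
  expect_equal(back$reference_label, "Fpz")
})

test_that("unreadable EDF inputs give labelled errors", {
  expect_error(read_recording(""), "non-empty")
  expect_error(read_recording(file.path(tempdir(), "nope.edf")), "not found")
  bad <- withr::local_tempfile(fileext = ".edf")
  writeBin(as.raw(sample(255, 600, replace = TRUE)), bad)
  expect_error(read_recording(bad), "EDF")
})

test_that("annotation CSV round trips and validates interval order", {
  ann <- seizure_annotations(c(1L, 1L, 2L), c(120, 500, 30),
                             c(180, 560, 95))
  expect_equal(ann$onset_s[1], 120)
  tf <- withr::local_tempfile(fileext = ".csv")
  write_annotations(ann, tf)
  back <- read_annotations(tf)
  expect_equal(as.data.frame(back), as.data.frame(ann))

  # 47-row round trip
  big <- seizure_annotations(rep(1:12, length.out = 47),
                             seq(10, by = 100, length.out = 47),
                             seq(70, by = 100, length.out = 47))
  write_annotations(big, tf)
  expect_equal(as.data.frame(read_annotations(tf)), as.data.frame(big))

  expect_error(seizure_annotations(1, 100, 90), "greater than")
  expect_error(seizure_annotations(1, 100, 100), "greater than")
  expect_error(seizure_annotations(1, -5, 10), ">= 0")
})

test_that("cohort metadata fixture matches the clinical reference table", {
  meta <- load_patient_metadata()
  expect_equal(nrow(meta), 12)
  expect_setequal(meta$pid, 1:12)
  expect_equal(meta$n_seizures[meta$pid == 2], 9)
  expect_equal(meta$recording_h[meta$pid == 2], 91)
  expect_equal(meta$recording_h[meta$pid == 4], 3)
  expect_true(all(meta$n_seizures >= 1))
  expect_true(all(meta$focus_side %in% c("left", "right")))
  expect_true(all(meta$focus_lobe %in% c("temporal", "parietal", "occipital")))

  s <- summarize_metadata(meta)
  expect_equal(s$total_seizures, 47)
  expect_equal(s$total_hours, 431)
  expect_equal(s$mean_age, 36)
})
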