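pat <- tiny_patient_epochs(n_seizures = 3)

test_that("training sets pair onset positives with seizure-free negatives", {
  pat8 <- tiny_patient_epochs(n_seizures = 8, epoch_s = 30, seed = 32)
  ts <- build_training_set(pat8$seizure, pat8$nonseizure, 3)
  expect_equal(sum(ts$train$label == "seizure"), 7 * 3)
  expect_equal(sum(ts$train$label == "non_seizure"), 2 * 30 / 2)
  expect_identical(ts$test_epoch, pat8$seizure[[3]])
  expect_error(build_training_set(pat8$seizure, pat8$nonseizure, 9),
               "out of range")

  # single-seizure patients train on their only seizure's onset windows
  ts1 <- build_training_set(pat8$seizure[1], pat8$nonseizure, 1)
  expect_equal(sum(ts1$train$label == "seizure"), 3)
})

test_that("grid search separates separable classes and is deterministic", {
  withr::local_seed(11)
  n <- 60
  X <- rbind(matrix(rnorm(n * 4), n), matrix(rnorm(n * 4, mean = 10), n))
  fm <- tibble::tibble(window = 1:(2 * n), start_s = 1:(2 * n), mid_s = 0,
                       label = rep(c("non_seizure", "seizure"), each = n))
  fm <- dplyr::bind_cols(fm, tibble::as_tibble(
    stats::setNames(as.data.frame(X), paste0("ch.f", 1:4))
  ))
  class(fm) <- c("feature_matrix", class(tibble::tibble()))
  det <- grid_search_train(fm, svm_config())
  expect_s3_class(det, "seizure_detector")
  expect_equal(min(det$inner_errors$error, na.rm = TRUE), 0)
  expect_equal(classify_windows(det, fm),
               ifelse(fm$label == "seizure", 1L, -1L))

  det2 <- grid_search_train(fm, svm_config())
  expect_equal(det$c, det2$c)
  expect_equal(det$sigma, det2$sigma)
  expect_equal(classify_windows(det2, fm), classify_windows(det, fm))

  # duplicated grid values are deduplicated
  cfg_dup <- svm_config(c_grid = c(1, 1, 10), sigma_grid = c(1, 1))
  expect_equal(cfg_dup$c_grid, c(1, 10))
  expect_equal(cfg_dup$sigma_grid, 1)

  fm_one <- fm
  fm_one$label <- "non_seizure"
  expect_error(grid_search_train(fm_one, svm_config()), "single class")

  # permuting windows permutes predictions identically; all-zero rows classify
  perm <- sample(nrow(fm))
  expect_equal(classify_windows(det, fm[perm, ]),
               classify_windows(det, fm)[perm])
  fm_zero <- fm
  fm_zero[, 5:8] <- 0
  expect_length(classify_windows(det, fm_zero), nrow(fm))
})

test_that("event declaration follows the run-length and merge rules", {
  starts <- seq(0, by = 2, length.out = 40)
  lab <- rep(-1L, 40)
  lab[c(2, 3)] <- 1L
  ev <- declare_events(lab, starts)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_s, 2)
  expect_equal(ev$end_s, 6)

  expect_equal(nrow(declare_events(c(1L, -1L, 1L), c(0, 2, 4))), 0)

  # two runs 10 s apart merge under a 30 s gap
  lab2 <- rep(-1L, 40)
  lab2[c(2, 3, 9, 10)] <- 1L
  ev2 <- declare_events(lab2, starts)
  expect_equal(nrow(ev2), 1)
  expect_equal(ev2$end_s, 20)
  ev2b <- declare_events(lab2, starts, merge_gap_s = 5)
  expect_equal(nrow(ev2b), 2)

  # monotonicity: higher min_consecutive never yields more events
  withr::local_seed(12)
  for (i in 1:20) {
    lab_r <- sample(c(-1L, 1L), 60, replace = TRUE)
    st <- seq(0, by = 2, length.out = 60)
    n_ev <- vapply(1:4, function(mc) {
      nrow(declare_events(lab_r, st, min_consecutive = mc, merge_gap_s = 0))
    }, 0L)
    expect_true(all(diff(n_ev) <= 0))
  }
})

test_that("epoch scoring counts overlaps and false events correctly", {
  ann <- seizure_annotations(1L, 100, 160)
  inside <- tibble::tibble(start_s = 110, end_s = 130)
  outside <- tibble::tibble(start_s = 400, end_s = 420)
  expect_equal(score_epoch(inside, ann), list(detected = TRUE, n_false = 0L))
  both <- dplyr::bind_rows(inside, outside)
  expect_equal(score_epoch(both, ann), list(detected = TRUE, n_false = 1L))
  expect_equal(score_epoch(inside[0, ], ann),
               list(detected = FALSE, n_false = 0L))

  # brute-force recount on randomized small cases
  withr::local_seed(13)
  for (i in 1:25) {
    ev <- tibble::tibble(start_s = sort(runif(3, 0, 500)))
    ev$end_s <- ev$start_s + runif(3, 1, 30)
    ann_r <- seizure_annotations(1L, runif(1, 0, 400), runif(1, 401, 500))
    got <- score_epoch(ev, ann_r)
    hit <- mapply(function(s, e) s <= ann_r$end_s && e >= ann_r$onset_s,
                  ev$start_s, ev$end_s)
    expect_equal(got$detected, any(hit))
    expect_equal(got$n_false, sum(!hit))
  }
})

test_that("leave-one-seizure-out detects high-SNR rhythmic seizures", {
  pf <- prepare_patient_features(pat$seizure, pat$nonseizure)
  cfg <- svm_config(merge_gap_s = 10)
  rep <- loo_evaluate(pf, cfg, label = "ear")
  expect_equal(rep$n_seizures, 3)
  expect_equal(rep$sensitivity, 100)
  expect_equal(rep$fdr_per_h, 0)
  expect_equal(nrow(rep$events[[1]]), rep$n_detected + rep$n_false)

  # determinism end to end
  rep2 <- loo_evaluate(pf, cfg, label = "ear")
  expect_equal(dplyr::select(rep, -events, -chosen),
               dplyr::select(rep2, -events, -chosen))

  # single-channel evaluation uses that channel's feature block only
  rep_lc <- loo_evaluate(pf, cfg, channels = "LC-RC", label = "LC-RC")
  expect_equal(rep_lc$montage, "LC-RC")
  expect_equal(rep_lc$n_seizures, 3)
})

test_that("report comparison and channel subset labelling are consistent", {
  a <- tibble::tibble(patient_id = 1:6, montage = "x",
                      sensitivity = c(100, 90, 80, 100, 70, 60),
                      fdr_per_h = c(0, 1, 2, 0, 1, 3))
  expect_equal(compare_reports_wilcoxon(a, a)$p_sensitivity, 1)
  b <- a
  b$patient_id <- 7:12
  expect_error(compare_reports_wilcoxon(a, b), "different patient sets")

  pf <- prepare_patient_features(pat$seizure, pat$nonseizure)
  meta <- tibble::tibble(pid = 1L, focus_side = "right")
  cmp <- channel_subset_comparison(list(pf), meta,
                                   svm_config(merge_gap_s = 10))
  expect_setequal(cmp$per_channel$montage,
                  c("LC-RC", "LT-RT", "ipsilateral", "contralateral"))
  # focus right: RT-RC is the ipsilateral unilateral channel
  expect_equal(nrow(cmp$pairwise_tests), 6)

  meta_bad <- tibble::tibble(pid = 1L, focus_side = NA_character_)
  expect_error(channel_subset_comparison(list(pf), meta_bad, svm_config()),
               "focus_side")
})
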