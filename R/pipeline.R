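# Cohort orchestration and report rendering.

#' Montaged, preprocessed epochs for one simulated patient
#'
#' Applies the scalp and ear montages jointly, band-passes 0.5-35 Hz,
#' optionally removes muscle artifacts by BSSCCA (jointly over all derived
#' channels), and extracts one epoch per annotated seizure plus guarded
#' seizure-free epochs.
#'
#' @param sim a `list(recording, truth)` as from [simulate_recording()].
#' @param epoch_len_s,guard_s,n_nonseizure epoching parameters.
#' @param denoise apply [bsscca_denoise()] to each epoch.
#' @param bcfg a [bsscca_config()].
#' @param seed seed for the seizure-free epoch sampler.
#' @return list with `scalp` and `ear` elements, each
#'   `list(seizure_epochs, nonseizure_epochs)`, plus `patient_id`.
#' @export
preprocess_patient <- function(sim, epoch_len_s = 600, guard_s = 600,
                               n_nonseizure = 2, denoise = TRUE,
                               bcfg = bsscca_config(), seed = 1) {
  ann <- sim$truth$seizure_annotations
  pid <- if (nrow(ann)) ann$patient_id[1] else 1L
  scalp_m <- define_scalp_montage()
  ear_m <- define_ear_montage()
  joint <- dplyr::bind_rows(scalp_m, ear_m)
  sig <- bandpass(apply_montage(sim$recording, joint))

  split_epochs <- function(sig) {
    se <- extract_seizure_epochs(sig, ann, epoch_len_s)
    ne <- sample_nonseizure_epochs(sig, ann, n = n_nonseizure,
                                   epoch_len_s = epoch_len_s,
                                   guard_s = guard_s, seed = seed,
                                   patient_id = pid)
    if (denoise) {
      se <- purrr::map(se, function(ep) {
        ep$signal <- bsscca_denoise(ep$signal, bcfg); ep
      })
      ne <- purrr::map(ne, function(ep) {
        ep$signal <- bsscca_denoise(ep$signal, bcfg); ep
      })
    }
    list(seizure_epochs = se, nonseizure_epochs = ne)
  }
  both <- split_epochs(sig)
  take <- function(eps, chans) purrr::map(eps, function(ep) {
    ep$signal <- eeg_signal(ep$signal$data[chans, , drop = FALSE],
                            ep$signal$fs_hz, chans, ep$signal$start_time)
    ep
  })
  list(
    patient_id = pid,
    scalp = list(seizure_epochs = take(both$seizure_epochs, scalp_m$channel),
                 nonseizure_epochs = take(both$nonseizure_epochs, scalp_m$channel)),
    ear = list(seizure_epochs = take(both$seizure_epochs, ear_m$channel),
               nonseizure_epochs = take(both$nonseizure_epochs, ear_m$channel))
  )
}

#' Leave-one-seizure-out evaluation of a simulated cohort
#'
#' @param dataset list of `list(recording, truth)` (see
#'   [generate_patient_dataset()]).
#' @param montage `"scalp"` or `"ear"`.
#' @param fcfg,scfg feature / detector configurations.
#' @param ... passed to [preprocess_patient()].
#' @return a `performance_report` tibble, one row per patient.
#' @export
evaluate_cohort <- function(dataset, montage = c("scalp", "ear"),
                            fcfg = feature_config(), scfg = svm_config(),
                            ...) {
  montage <- match.arg(montage)
  purrr::map_dfr(dataset, function(sim) {
    prep <- preprocess_patient(sim, ...)[[montage]]
    pf <- prepare_patient_features(prep$seizure_epochs,
                                   prep$nonseizure_epochs, fcfg,
                                   positive_s = scfg$positive_s)
    loo_evaluate(pf, scfg, label = montage)
  })
}

#' Aggregate a performance report into the clinical summary table
#'
#' Median (min, max) and mean +/- SD of sensitivity and false-detection rate
#' per montage label, half-up rounded to 2 decimals.
#'
#' @param report a `performance_report` tibble (any number of montage labels).
#' @return tibble with one row per montage and statistic.
#' @export
render_tables <- function(report) {
  if (!nrow(report)) stop("empty report")
  report |>
    dplyr::group_by(.data$montage) |>
    dplyr::summarise(
      n_patients = dplyr::n(),
      sens_median = round_half_up(stats::median(.data$sensitivity)),
      sens_min = round_half_up(min(.data$sensitivity)),
      sens_max = round_half_up(max(.data$sensitivity)),
      sens_mean = round_half_up(mean(.data$sensitivity)),
      sens_sd = round_half_up(stats::sd(.data$sensitivity)),
      fdr_median = round_half_up(stats::median(.data$fdr_per_h)),
      fdr_min = round_half_up(min(.data$fdr_per_h)),
      fdr_max = round_half_up(max(.data$fdr_per_h)),
      fdr_mean = round_half_up(mean(.data$fdr_per_h)),
      fdr_sd = round_half_up(stats::sd(.data$fdr_per_h)),
      .groups = "drop"
    )
}

#' @method glance performance_report
#' @export
glance.performance_report <- function(x, ...) render_tables(x)

#' Per-patient sensitivity / FDR plot
#'
#' @param object a `performance_report` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot performance_report
#' @export
autoplot.performance_report <- function(object, ...) {
  long <- object |>
    dplyr::select("patient_id", "montage", "sensitivity", "fdr_per_h") |>
    tidyr::pivot_longer(c("sensitivity", "fdr_per_h"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$patient_id),
                                     y = .data$value,
                                     fill = .data$montage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~metric, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "patient", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Run the full synthetic-cohort pipeline
#'
#' Simulate (or reuse) a cohort, run the blink-EOG quantification, the
#' coherence matchup aggregation, and leave-one-seizure-out detection on both
#' montages, and write figure-ready CSV reports into `out_dir`. Idempotent
#' for a fixed configuration: identical configs produce identical reports.
#'
#' @param out_dir output directory (created if missing).
#' @param seed master seed; expands into per-stage sub-seeds.
#' @param n_patients number of cohort patients to include (prefix of the
#'   reference metadata table).
#' @param epoch_len_s,n_nonseizure,guard_s cohort scale parameters.
#' @param denoise run BSSCCA muscle-artifact removal.
#' @param fcfg,scfg feature / detector configurations.
#' @return (invisibly) a list with `detection_report`, `summary_table`,
#'   `eog_amplitudes`, `matchup_summary`, and the output paths.
#' @export
run_pipeline <- function(out_dir, seed = 1, n_patients = 12,
                         epoch_len_s = 600, n_nonseizure = 2, guard_s = 600,
                         denoise = TRUE, fcfg = feature_config(),
                         scfg = svm_config()) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  meta <- load_patient_metadata()[seq_len(n_patients), ]
  cfgs <- cohort_configs(seed, epoch_len_s = epoch_len_s,
                         n_nonseizure = n_nonseizure, guard_s = guard_s,
                         meta = meta)

  reports <- list()
  eog_rows <- list()
  for (i in seq_along(cfgs)) {
    sim <- simulate_recording(cfgs[[i]])
    rep_eog <- eog_report(sim$recording, seed = sub_seed(seed, 200 + i))
    eog_rows[[i]] <- dplyr::mutate(rep_eog$amplitudes,
                                   patient_id = meta$pid[i], .before = 1)
    prep <- preprocess_patient(sim, epoch_len_s = epoch_len_s,
                               guard_s = guard_s,
                               n_nonseizure = n_nonseizure,
                               denoise = denoise,
                               seed = sub_seed(seed, 300 + i))
    for (m in c("scalp", "ear")) {
      pf <- prepare_patient_features(prep[[m]]$seizure_epochs,
                                     prep[[m]]$nonseizure_epochs, fcfg,
                                     positive_s = scfg$positive_s)
      reports[[paste(i, m)]] <- loo_evaluate(pf, scfg, label = m)
    }
    rm(sim, prep); gc(FALSE)
  }
  detection_report <- dplyr::bind_rows(reports)
  class(detection_report) <- c("performance_report",
                               class(tibble::tibble()))
  summary_table <- render_tables(detection_report)
  eog_amplitudes <- dplyr::bind_rows(eog_rows)
  matchup <- aggregate_matchup_table(load_matchup_reference())

  paths <- list(
    detection = file.path(out_dir, "detection_per_patient.csv"),
    summary = file.path(out_dir, "detection_summary.csv"),
    eog = file.path(out_dir, "eog_amplitudes.csv"),
    matchup = file.path(out_dir, "matchup_summary.csv")
  )
  readr::write_csv(dplyr::select(detection_report, -"events", -"chosen"),
                   paths$detection)
  readr::write_csv(summary_table, paths$summary)
  readr::write_csv(eog_amplitudes, paths$eog)
  readr::write_csv(matchup$column_summary, paths$matchup)
  invisible(list(detection_report = detection_report,
                 summary_table = summary_table,
                 eog_amplitudes = eog_amplitudes,
                 matchup_summary = matchup$column_summary,
                 paths = paths))
}
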