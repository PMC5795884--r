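#' Clinical cohort metadata
#'
#' Loads the packaged reference table describing the 12-patient focal-epilepsy
#' monitoring cohort the synthetic generator emulates: per-patient seizure
#' counts, demographics, seizure-focus side and lobe, and hours of monitoring.
#'
#' @return a tibble with columns `pid`, `n_seizures`, `sex`, `age`,
#'   `focus_side`, `focus_lobe`, `recording_h`.
#' @examples
#' load_patient_metadata()
#' summarize_metadata(load_patient_metadata())
#' @export
load_patient_metadata <- function() {
  path <- system.file("extdata", "patients.csv", package = "earseiz",
                      mustWork = TRUE)
  meta <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = "iiciccd")
  stopifnot(all(meta$n_seizures >= 1), !anyDuplicated(meta$pid))
  meta
}

#' @rdname load_patient_metadata
#' @param meta a metadata tibble as returned by `load_patient_metadata()`.
#' @return `summarize_metadata()` returns a one-row tibble with
#'   `total_seizures`, `total_hours`, `mean_age`.
#' @export
summarize_metadata <- function(meta) {
  tibble::tibble(
    total_seizures = sum(meta$n_seizures),
    total_hours = sum(meta$recording_h),
    mean_age = mean(meta$age)
  )
}

#' Reference best-matchup coherence table
#'
#' Per-patient magnitude-squared coherence between each behind-the-ear channel
#' and its best-matching scalp channel during seizures, for the reference
#' clinical cohort. Used to exercise the matchup aggregation ops.
#'
#' @return tibble with columns `pid`, `ear_channel`, `scalp_channel`,
#'   `coherence` (48 rows: 12 patients x 4 ear channels).
#' @export
load_matchup_reference <- function() {
  path <- system.file("extdata", "matchup_coherence.csv", package = "earseiz",
                      mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, col_types = "iccd")
}
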