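#' Seizure annotation table
#'
#' Annotations mark expert-labelled seizure onset and end, in seconds from
#' recording start (half-open intervals `[onset_s, end_s)`).
#'
#' @param patient_id integer patient identifiers.
#' @param onset_s seizure onsets, seconds from recording start.
#' @param end_s seizure ends; must exceed the paired onset.
#' @param label free-text label, default `"seizure"`.
#' @return a tibble with columns `patient_id`, `onset_s`, `end_s`, `label`.
#' @examples
#' seizure_annotations(1, 120, 180)
#' @export
seizure_annotations <- function(patient_id, onset_s, end_s,
                                label = "seizure") {
  out <- tibble::tibble(
    patient_id = as.integer(patient_id),
    onset_s = as.numeric(onset_s),
    end_s = as.numeric(end_s),
    label = as.character(label)
  )
  validate_annotations(out)
}

validate_annotations <- function(ann) {
  stopifnot(all(c("patient_id", "onset_s", "end_s", "label") %in% names(ann)))
  if (any(ann$onset_s < 0)) stop("annotation onset_s must be >= 0")
  if (any(ann$end_s <= ann$onset_s)) {
    stop("annotation end_s must be greater than onset_s")
  }
  ann
}

#' Read / write seizure annotations as CSV
#'
#' The CSV dialect is a header row `patient_id,onset_s,end_s,label`,
#' comma-separated, UTF-8, seconds as decimals. Reading validates that every
#' end exceeds its onset.
#'
#' @param path CSV file path.
#' @return `read_annotations()` returns the validated annotation tibble;
#'   `write_annotations()` returns `path` invisibly.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ann <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_integer(),
                           onset_s = readr::col_double(),
                           end_s = readr::col_double(),
                           label = readr::col_character()
                         ))
  validate_annotations(ann)
}

#' @rdname read_annotations
#' @param ann annotation tibble as produced by [seizure_annotations()].
#' @export
write_annotations <- function(ann, path) {
  validate_annotations(ann)
  readr::write_csv(ann, path)
  invisible(path)
}
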