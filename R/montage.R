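#' Bipolar montage definitions
#'
#' A bipolar montage is an ordered set of channels, each the potential
#' difference between an anode and a cathode electrode. `define_scalp_montage()`
#' returns the 22-channel clinical longitudinal montage (10-20 electrodes plus
#' sphenoidal Sph1/Sph2); `define_ear_montage()` returns the four behind-the-ear
#' channels: two cross-head derivations (LC-RC, LT-RT) linking the left and
#' right mastoid region, and two unilateral derivations (LT-LC, RT-RC) within
#' one side.
#'
#' @return a tibble of class `eeg_montage` with columns `channel`, `anode`,
#'   `cathode`.
#' @examples
#' define_scalp_montage()
#' define_ear_montage()
#' @export
define_scalp_montage <- function() {
  pairs <- c(
    "Fp2-F8", "F8-T4", "T4-T6", "T6-O2", "T4-Sph2",
    "Fp2-F4", "F4-C4", "C4-P4", "P4-O2",
    "Fz-Cz", "Cz-Pz", "Pz-O2", "Pz-O1",
    "Fp1-F7", "F7-T3", "T3-T5", "T5-O1", "T3-Sph1",
    "Fp1-F3", "F3-C3", "C3-P3", "P3-O1"
  )
  new_montage(pairs)
}

#' @rdname define_scalp_montage
#' @export
define_ear_montage <- function() {
  new_montage(c("LC-RC", "LT-RT", "LT-LC", "RT-RC"))
}

new_montage <- function(pairs) {
  parts <- strsplit(pairs, "-", fixed = TRUE)
  out <- tibble::tibble(
    channel = pairs,
    anode = vapply(parts, `[`, "", 1L),
    cathode = vapply(parts, `[`, "", 2L)
  )
  if (anyDuplicated(out$channel)) stop("montage channel names must be unique")
  class(out) <- c("eeg_montage", class(out))
  out
}

#' Apply a bipolar montage to a referential recording
#'
#' Each derived channel is the sample-aligned difference anode minus cathode.
#' Derivation is linear, so any source projected with equal gain to both
#' members of a pair cancels exactly.
#'
#' @param rec an [eeg_recording()].
#' @param montage an `eeg_montage` tibble (columns `channel`, `anode`,
#'   `cathode`); all referenced electrodes must exist in `rec`.
#' @return an [eeg_signal()] with one row per montage channel.
#' @examples
#' rec <- eeg_recording(rbind(c(3, 3), c(1, 2)), 250, c("A", "B"))
#' m <- tibble::tibble(channel = "A-B", anode = "A", cathode = "B")
#' apply_montage(rec, m)$data
#' @export
apply_montage <- function(rec, montage) {
  stopifnot(inherits(rec, "eeg_recording"))
  need <- unique(c(montage$anode, montage$cathode))
  missing <- setdiff(need, rec$electrode_labels)
  if (length(missing)) {
    bad <- montage$channel[montage$anode %in% missing |
                             montage$cathode %in% missing]
    stop(sprintf(
      "electrode(s) %s missing from recording (needed by channel(s) %s)",
      paste(missing, collapse = ", "), paste(bad, collapse = ", ")
    ))
  }
  data <- rec$data[montage$anode, , drop = FALSE] -
    rec$data[montage$cathode, , drop = FALSE]
  eeg_signal(data, rec$fs_hz, montage$channel, rec$start_time)
}
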