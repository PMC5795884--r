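# Minimal European Data Format (EDF) reader/writer.
#
# EDF stores an ASCII header (256 bytes + 256 per signal) followed by data
# records of little-endian int16 samples, linearly calibrated per signal via
# the physical/digital min/max fields. Amplitude resolution is therefore
# bounded by (phys_max - phys_min) / (dig_max - dig_min) per signal.

edf_pad <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(signif(x, 8), format = "fg", width = -1)
  if (nchar(s) > width) s <- substr(formatC(x, format = "f", digits = width), 1, width)
  edf_pad(s, width)
}

# calibration extremes are 2-decimal by construction; write them exactly
edf_cal <- function(x, width = 8) {
  s <- formatC(x, format = "f", digits = 2)
  if (nchar(s) > width) s <- formatC(signif(x, width - 2), format = "g")
  edf_pad(s, width)
}

#' Write a recording to an EDF file
#'
#' Signals are calibrated per electrode to a symmetric physical range covering
#' the data, quantized to 16 bits. The common-reference label is stored in the
#' recording-identification header field and recovered by [read_recording()].
#'
#' @param rec an [eeg_recording()]; `fs_hz` must be a whole number.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (abs(rec$fs_hz - round(rec$fs_hz)) > 1e-9) {
    stop("EDF export requires an integer sampling rate")
  }
  fs <- as.integer(round(rec$fs_hz))
  n <- ncol(rec$data)
  ns <- nrow(rec$data)
  if (n %% fs == 0) {
    rec_dur <- 1
    spr <- fs
    n_rec <- n %/% fs
  } else {
    rec_dur <- n / fs
    spr <- n
    n_rec <- 1L
  }

  pmax <- apply(abs(rec$data), 1, max)
  pmax[pmax < 1e-6] <- 1e-6
  # round the physical range up to 2 decimals: exactly representable in the
  # 8-char ASCII header field, and guaranteed to cover the data extremes
  pmax <- ceiling(pmax * 1.0001 * 100) / 100
  dig_min <- -32768L
  dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad("X X X X", 80),
    edf_pad(paste("Startdate X Ref", rec$reference_label), 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256L * (1L + ns), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_num(rec_dur, 8),
    edf_pad(ns, 4)
  )
  writeChar(hdr, con, eos = NULL)
  writeChar(paste0(vapply(rec$electrode_labels, edf_pad, "", 16), collapse = ""),
            con, eos = NULL)
  writeChar(strrep(edf_pad("", 80), ns), con, eos = NULL)
  writeChar(strrep(edf_pad("uV", 8), ns), con, eos = NULL)
  writeChar(paste0(vapply(-pmax, edf_cal, "", 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(pmax, edf_cal, "", 8), collapse = ""), con, eos = NULL)
  writeChar(strrep(edf_pad(dig_min, 8), ns), con, eos = NULL)
  writeChar(strrep(edf_pad(dig_max, 8), ns), con, eos = NULL)
  writeChar(strrep(edf_pad("", 80), ns), con, eos = NULL)
  writeChar(strrep(edf_pad(spr, 8), ns), con, eos = NULL)
  writeChar(strrep(edf_pad("", 32), ns), con, eos = NULL)

  # re-read the rounded calibration so quantization matches what a reader sees
  pmin_r <- as.numeric(vapply(-pmax, edf_cal, "", 8))
  pmax_r <- as.numeric(vapply(pmax, edf_cal, "", 8))
  scale <- (pmax_r - pmin_r) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    block <- matrix(0L, spr, ns)
    for (s in seq_len(ns)) {
      d <- round((rec$data[s, idx] - pmin_r[s]) / scale[s]) + dig_min
      block[, s] <- as.integer(pmin(pmax(d, dig_min), dig_max))
    }
    writeBin(as.integer(block), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Read an EDF recording
#'
#' @param path path to an EDF file with microvolt-calibrated signals.
#' @return an [eeg_recording()].
#' @export
read_recording <- function(path) {
  if (!is.character(path) || length(path) != 1L || !nzchar(path)) {
    stop("`path` must be a single non-empty file path")
  }
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  fixed <- readChar(con, 256, useBytes = TRUE)
  # EDF headers are ASCII; map arbitrary bytes safely before string ops
  fixed <- iconv(fixed, "latin1", "ASCII", sub = " ")
  if (is.na(fixed) || nchar(fixed, type = "bytes") < 256 ||
      trimws(substr(fixed, 1, 8)) != "0") {
    stop("not an EDF file (bad version field): ", path)
  }
  rid <- trimws(substr(fixed, 89, 168))
  hdr_bytes <- as.integer(substr(fixed, 185, 192))
  n_rec <- as.integer(substr(fixed, 237, 244))
  rec_dur <- as.numeric(substr(fixed, 245, 252))
  ns <- as.integer(substr(fixed, 253, 256))
  if (is.na(ns) || ns < 1L || is.na(hdr_bytes) ||
      hdr_bytes != 256L * (1L + ns)) {
    stop("corrupt EDF header: ", path)
  }
  sig_hdr <- iconv(readChar(con, 256L * ns, useBytes = TRUE),
                   "latin1", "ASCII", sub = " ")
  fld <- function(off, width) {
    vapply(seq_len(ns), function(i) {
      trimws(substr(sig_hdr, off + (i - 1L) * width + 1L, off + i * width))
    }, "")
  }
  labels <- fld(0L, 16L)
  pmin <- as.numeric(fld(ns * (16L + 80L + 8L), 8L))
  pmax <- as.numeric(fld(ns * (16L + 80L + 8L + 8L), 8L))
  dmin <- as.numeric(fld(ns * (16L + 80L + 8L * 3L), 8L))
  dmax <- as.numeric(fld(ns * (16L + 80L + 8L * 4L), 8L))
  spr <- as.integer(fld(ns * (16L + 80L + 8L * 5L + 80L), 8L))
  if (anyNA(c(pmin, pmax, dmin, dmax, spr))) stop("missing EDF calibration: ", path)
  scale <- (pmax - pmin) / (dmax - dmin)

  data <- matrix(0, ns, sum(rep(spr[1], n_rec)))
  raw <- readBin(con, "integer", n = n_rec * sum(spr), size = 2,
                 endian = "little", signed = TRUE)
  if (length(raw) < n_rec * sum(spr)) stop("truncated EDF data: ", path)
  pos <- 0L
  col0 <- integer(ns)
  data <- matrix(0, ns, 0)
  chunks <- vector("list", n_rec)
  for (r in seq_len(n_rec)) {
    block <- matrix(NA_real_, ns, max(spr))
    for (s in seq_len(ns)) {
      v <- raw[(pos + 1L):(pos + spr[s])]
      pos <- pos + spr[s]
      block[s, seq_len(spr[s])] <- (v - dmin[s]) * scale[s] + pmin[s]
    }
    chunks[[r]] <- block
  }
  data <- do.call(cbind, chunks)
  fs <- spr[1] / rec_dur
  ref <- "Fpz"
  m <- regmatches(rid, regexec("Ref (\\S+)", rid))[[1]]
  if (length(m) == 2) ref <- m[2]
  eeg_recording(data, fs, labels, reference_label = ref)
}
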