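# Minimal European Data Format (EDF) support: fixed-layout ASCII header,
# per-signal header block, then data records of little-endian int16 samples
# scaled between physical and digital ranges. Only continuous recordings
# with a common sampling rate across channels are handled — enough to
# ingest exported iEEG segments. Resampling is deliberately not performed.

edf_field <- function(raw, offset, width) {
  trimws(rawToChar(raw[(offset + 1L):(offset + width)]))
}

#' Read an EDF file
#'
#' Parses the EDF/EDF+ fixed header and loads all signals into a
#' channels-by-samples matrix in physical units. All channels must share
#' one sampling rate. Annotation channels ("EDF Annotations") are dropped.
#'
#' @param path EDF file path.
#' @param expect_fs optional sampling rate in Hz; if given and the file's
#'   rate differs, a parameter error is raised (the pipeline never
#'   resamples).
#' @return list with `signals` (channels x samples matrix), `fs`,
#'   `channel_labels`, `n_records`, `record_duration`.
#' @export
read_edf <- function(path, expect_fs = NULL) {
  if (!file.exists(path)) stop_format("EDF file '%s' does not exist", path)
  fsize <- file.info(path)$size
  if (fsize < 256) stop_format("EDF file truncated: no fixed header")
  con <- file(path, "rb")
  on.exit(close(con))
  head_raw <- readBin(con, "raw", 256L)
  ns <- suppressWarnings(as.integer(edf_field(head_raw, 252, 4)))
  header_bytes <- suppressWarnings(as.integer(edf_field(head_raw, 184, 8)))
  n_records <- suppressWarnings(as.integer(edf_field(head_raw, 236, 8)))
  record_duration <- suppressWarnings(as.numeric(edf_field(head_raw, 244, 8)))
  if (is.na(ns) || ns < 1L || is.na(header_bytes) || is.na(n_records) ||
      is.na(record_duration) || record_duration <= 0) {
    stop_format("malformed EDF header")
  }
  if (header_bytes != 256L + 256L * ns || fsize < header_bytes) {
    stop_format("EDF header size inconsistent with signal count")
  }
  sig_raw <- readBin(con, "raw", 256L * ns)
  # per-signal blocks are stored field-major: all labels, all transducers, ...
  widths <- c(label = 16, transducer = 80, phys_dim = 8, phys_min = 8,
              phys_max = 8, dig_min = 8, dig_max = 8, prefilter = 80,
              samples_per_record = 8, reserved = 32)
  offsets <- cumsum(c(0, head(unname(widths), -1)))
  get_fields <- function(name) {
    i <- match(name, names(widths))
    vapply(seq_len(ns) - 1L, function(s) {
      edf_field(sig_raw, offsets[i] * ns + s * widths[i], widths[i])
    }, "")
  }
  labels <- get_fields("label")
  phys_min <- as.numeric(get_fields("phys_min"))
  phys_max <- as.numeric(get_fields("phys_max"))
  dig_min <- as.numeric(get_fields("dig_min"))
  dig_max <- as.numeric(get_fields("dig_max"))
  spr <- as.integer(get_fields("samples_per_record"))
  if (anyNA(c(phys_min, phys_max, dig_min, dig_max, spr)) ||
      any(dig_max <= dig_min)) {
    stop_format("malformed EDF signal headers")
  }
  keep <- labels != "EDF Annotations"
  if (!any(keep)) stop_format("EDF file contains no signal channels")
  fs_all <- spr / record_duration
  if (length(unique(fs_all[keep])) != 1L) {
    stop_param("EDF channels have mixed sampling rates; not supported")
  }
  fs <- fs_all[keep][1L]
  if (!is.null(expect_fs) && abs(fs - expect_fs) > 1e-9) {
    stop_param("EDF sampling rate %g Hz differs from expected %g Hz (no resampling is performed)",
               fs, expect_fs)
  }
  rec_samples <- sum(spr)
  expected <- header_bytes + 2 * rec_samples * n_records
  if (fsize < expected) {
    stop_format("EDF file truncated: expected %d bytes, found %d",
                expected, fsize)
  }
  data <- readBin(con, "integer", n = rec_samples * n_records, size = 2L,
                  signed = TRUE, endian = "little")
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  offset_phys <- phys_min - gain * dig_min
  out <- matrix(NA_real_, sum(keep), spr[keep][1L] * n_records)
  starts <- cumsum(c(0L, spr))
  row <- 0L
  for (s in seq_len(ns)) {
    if (!keep[s]) next
    row <- row + 1L
    for (r in seq_len(n_records)) {
      seg <- data[((r - 1L) * rec_samples + starts[s] + 1L):
                    ((r - 1L) * rec_samples + starts[s] + spr[s])]
      out[row, ((r - 1L) * spr[s] + 1L):(r * spr[s])] <-
        gain[s] * seg + offset_phys[s]
    }
  }
  list(signals = out, fs = fs, channel_labels = labels[keep],
       n_records = n_records, record_duration = record_duration)
}

pad_field <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1L, width)
  formatC(x, width = -width)
}

# widest numeric representation that fits an 8-char EDF header field
edf_num <- function(v) {
  for (d in 7:1) {
    s <- sprintf("%.*g", d, v)
    if (nchar(s) <= 8L) return(s)
  }
  substr(sprintf("%g", v), 1L, 8L)
}

#' Write a channels-by-samples matrix as an EDF file
#'
#' Writes a minimal valid EDF: one-second data records, int16 samples
#' scaled to each channel's physical range. Quantization to the 16-bit
#' digital range limits round-trip precision; this writer exists to build
#' test fixtures and to export synthetic data to EDF consumers.
#'
#' @param signals channels-by-samples numeric matrix.
#' @param fs sampling rate in Hz (samples per 1-s record; must be an
#'   integer and divide the number of samples).
#' @param path output path.
#' @param channel_labels optional channel labels (<= 16 ASCII chars).
#' @param patient,recording free-text header fields.
#' @return `path`, invisibly.
#' @export
write_edf <- function(signals, fs, path, channel_labels = NULL,
                      patient = "X", recording = "synthetic") {
  if (!is.matrix(signals)) signals <- matrix(signals, nrow = 1L)
  if (any(!is.finite(signals))) stop_data("signals contain non-finite samples")
  if (!is_count(fs)) stop_param("fs must be a positive integer (1-s records)")
  ns <- nrow(signals)
  n <- ncol(signals)
  if (n %% fs != 0) stop_param("sample count must be a whole number of 1-s records")
  n_records <- n %/% fs
  channel_labels <- channel_labels %||% sprintf("ch%02d", seq_len(ns))
  phys_min <- apply(signals, 1L, min)
  phys_max <- apply(signals, 1L, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  # scale with the rounded header values so reader and writer agree exactly
  phys_min_str <- vapply(phys_min, edf_num, "")
  phys_max_str <- vapply(phys_max, edf_num, "")
  phys_min <- as.numeric(phys_min_str)
  phys_max <- as.numeric(phys_max_str)
  dig_min <- -32768; dig_max <- 32767

  con <- file(path, "wb")
  on.exit(close(con))
  wr <- function(x, width) writeBin(charToRaw(pad_field(x, width)), con)
  wr("0", 8); wr(patient, 80); wr(recording, 80)
  wr("01.01.26", 8); wr("00.00.00", 8)
  wr(256L + 256L * ns, 8); wr("", 44)
  wr(n_records, 8); wr("1", 8); wr(ns, 4)
  for (lab in channel_labels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr("uV", 8)
  for (v in phys_min_str) wr(v, 8)
  for (v in phys_max_str) wr(v, 8)
  for (i in seq_len(ns)) wr(dig_min, 8)
  for (i in seq_len(ns)) wr(dig_max, 8)
  for (i in seq_len(ns)) wr("", 80)
  for (i in seq_len(ns)) wr(fs, 8)
  for (i in seq_len(ns)) wr("", 32)

  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_records)) {
    for (s in seq_len(ns)) {
      seg <- signals[s, ((r - 1L) * fs + 1L):(r * fs)]
      dig <- round((seg - phys_min[s]) / gain[s] + dig_min)
      writeBin(as.integer(pmin(pmax(dig, dig_min), dig_max)), con,
               size = 2L, endian = "little")
    }
  }
  invisible(path)
}
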