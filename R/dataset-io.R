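DATASET_SCHEMA_VERSION <- 1L

#' Write seizure records to a dataset directory
#'
#' Stores each segment as a raw little-endian float32 array (column-major,
#' i.e. the channel index varies fastest, matching the in-memory
#' channels-by-samples matrix layout) together with a versioned JSON
#' manifest (`manifest.json`) recording subject, seizure, sampling rate,
#' channel labels, array shape, the file name and a SHA-256 checksum per
#' segment. The raw-array format keeps fixtures plain and dependency-free;
#' EDF is supported as an input adapter only (see [read_edf()]).
#'
#' Samples are quantized to float32 on write, so a freshly generated
#' (float64) record round-trips to within single precision on the first
#' write/read cycle and bit-exactly on every cycle thereafter.
#'
#' @param records list of [seizure_record()] objects.
#' @param directory output directory (created if missing).
#' @return the manifest path, invisibly.
#' @seealso [read_dataset()]
#' @export
write_dataset <- function(records, directory) {
  if (inherits(records, "seizure_record")) records <- list(records)
  if (!length(records) || !all(vapply(records, inherits, TRUE, "seizure_record"))) {
    stop_param("records must be a non-empty list of seizure_record objects")
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  entries <- lapply(records, function(rec) {
    segs <- lapply(c("preictal", "interictal"), function(state) {
      fname <- sprintf("%s_sz%03d_%s.f32", rec$subject_id, rec$seizure_id, state)
      path <- file.path(directory, fname)
      con <- file(path, "wb")
      writeBin(as.vector(rec[[state]]), con, size = 4L, endian = "little")
      close(con)  # flush before checksumming
      list(state = state, file = fname,
           sha256 = digest::digest(path, algo = "sha256", file = TRUE))
    })
    names(segs) <- c("preictal", "interictal")
    list(
      subject_id = rec$subject_id,
      seizure_id = rec$seizure_id,
      fs = rec$fs,
      n_channels = nrow(rec$preictal),
      n_samples = ncol(rec$preictal),
      channel_labels = rec$channel_labels,
      segments = segs
    )
  })
  manifest <- list(schema_version = DATASET_SCHEMA_VERSION, records = entries)
  manifest_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest_path)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' Validates the manifest schema, the presence of every referenced array
#' file and its SHA-256 checksum before loading. The number of channels and
#' samples is taken from the manifest, not assumed.
#'
#' @param directory dataset directory containing `manifest.json`.
#' @return list of [seizure_record()] objects.
#' @export
read_dataset <- function(directory) {
  manifest_path <- file.path(directory, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_format("no manifest.json found in '%s'", directory)
  }
  manifest <- tryCatch(
    jsonlite::read_json(manifest_path),
    error = function(e) stop_format("corrupt manifest: %s", conditionMessage(e))
  )
  if (is.null(manifest$schema_version) ||
      manifest$schema_version != DATASET_SCHEMA_VERSION) {
    stop_format("unsupported or missing manifest schema_version")
  }
  if (!length(manifest$records)) stop_format("manifest lists no records")
  lapply(manifest$records, function(entry) {
    need <- c("subject_id", "seizure_id", "fs", "n_channels", "n_samples",
              "channel_labels", "segments")
    if (!all(need %in% names(entry))) {
      stop_format("manifest record is missing required fields")
    }
    nch <- entry$n_channels
    nsamp <- entry$n_samples
    segs <- lapply(c("preictal", "interictal"), function(state) {
      seg <- entry$segments[[state]]
      if (is.null(seg) || is.null(seg$file)) {
        stop_integrity("manifest record lacks a %s file entry", state)
      }
      path <- file.path(directory, seg$file)
      if (!file.exists(path)) {
        stop_integrity("segment file '%s' listed in manifest is missing",
                       seg$file)
      }
      sha <- digest::digest(path, algo = "sha256", file = TRUE)
      if (!identical(sha, seg$sha256)) {
        stop_integrity("checksum mismatch for '%s'", seg$file)
      }
      con <- file(path, "rb")
      on.exit(close(con))
      vals <- readBin(con, what = "numeric", n = nch * nsamp, size = 4L,
                      endian = "little")
      if (length(vals) != nch * nsamp) {
        stop_integrity("segment file '%s' is truncated", seg$file)
      }
      matrix(vals, nrow = nch, ncol = nsamp)
    })
    seizure_record(entry$subject_id, entry$seizure_id, segs[[1L]], segs[[2L]],
                   entry$fs, unlist(entry$channel_labels))
  })
}
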