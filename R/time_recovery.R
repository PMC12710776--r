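# Acquisition-time recovery.
#
# FFA analysis needs seconds post-injection per frame. Sources are tried in a
# configured order — embedded metadata first, then filename patterns, sidecar
# tables, and finally burned-in timestamp OCR — and the first success wins,
# so recovered times never depend on file-discovery order.

#' Time-source specifications
#'
#' Constructors for the source list consumed by [recover_time()].
#'
#' * `time_from_metadata()` — use time captured at decode: a TIFF description
#'   tag `t_acq=<s>`, or DICOM `AcquisitionTime` minus the configured
#'   injection clock time (`HHMMSS`).
#' * `time_from_filename(pattern)` — first capture group of `pattern` applied
#'   to the basename, interpreted as seconds.
#' * `time_from_sidecar(table)` — lookup in a `filename,seconds` table (CSV
#'   path or data frame).
#' * `time_from_overlay(roi, atlas)` — template-matching OCR of a burned-in
#'   `mm:ss` clock; see [ocr_timestamp()].
#'
#' @param pattern Regular expression with one numeric capture group.
#' @param table Data frame or CSV path with columns `filename`, `seconds`.
#' @param roi Overlay region (list with `row`, `col`, `height`, `width`).
#' @param atlas Glyph atlas; defaults to the packaged one.
#' @param injection_time Injection clock time `"HHMMSS"` for DICOM sources.
#' @name time_sources
NULL

#' @rdname time_sources
#' @export
time_from_metadata <- function(injection_time = NULL) {
  list(type = "metadata", injection_time = injection_time)
}

#' @rdname time_sources
#' @export
time_from_filename <- function(pattern = "t(\\d+)") {
  list(type = "filename", pattern = pattern)
}

#' @rdname time_sources
#' @export
time_from_sidecar <- function(table) {
  if (is.character(table)) table <- utils::read.csv(table, stringsAsFactors = FALSE)
  stopifnot(all(c("filename", "seconds") %in% names(table)))
  list(type = "sidecar", table = table)
}

#' @rdname time_sources
#' @export
time_from_overlay <- function(roi, atlas = glyph_atlas()) {
  list(type = "overlay", roi = roi, atlas = atlas)
}

hhmmss_to_seconds <- function(x) {
  x <- sub("\\..*$", "", trimws(x))
  if (!grepl("^[0-9]{6}$", x)) return(NA_real_)
  as.numeric(substr(x, 1, 2)) * 3600 + as.numeric(substr(x, 3, 4)) * 60 +
    as.numeric(substr(x, 5, 6))
}

try_source <- function(frame, src) {
  switch(src$type,
    metadata = {
      if (!is.null(frame$meta$t_acq)) return(frame$meta$t_acq)
      at <- frame$meta$acquisition_time
      if (!is.null(at) && !is.na(at) && !is.null(src$injection_time)) {
        t <- hhmmss_to_seconds(at) - hhmmss_to_seconds(src$injection_time)
        if (!is.na(t) && t >= 0) return(t)
      }
      NA_real_
    },
    filename = {
      base <- basename(frame$source_path %||% "")
      m <- regmatches(base, regexec(src$pattern, base))[[1]]
      if (length(m) >= 2) as.numeric(m[2]) else NA_real_
    },
    sidecar = {
      base <- basename(frame$source_path %||% "")
      hit <- src$table$seconds[src$table$filename == base]
      if (length(hit) >= 1) as.numeric(hit[1]) else NA_real_
    },
    overlay = {
      tryCatch(
        ocr_timestamp(frame$pixels, src$roi, src$atlas),
        ffa_time_ambiguity_error = function(e) stop(e),
        error = function(e) NA_real_
      )
    },
    abort(sprintf("Unknown time source type '%s'.", src$type),
          class = "ffa_parameter_error")
  )
}

#' Recover the acquisition time of a frame
#'
#' Tries each configured source in order and returns the first recovered
#' seconds-post-injection value. Ambiguous overlay OCR propagates as an
#' error; a frame for which no source yields a time raises a missing-time
#' error carrying the frame's path.
#'
#' @param frame `ffa_frame`.
#' @param sources List of time-source specs (see [time_sources]).
#' @return The frame with `t_acq` set.
#' @export
recover_time <- function(frame, sources) {
  if (length(sources) == 0) {
    abort("At least one time source must be configured.",
          class = "ffa_parameter_error")
  }
  for (src in sources) {
    t <- try_source(frame, src)
    if (!is.na(t)) {
      frame$t_acq <- as.numeric(t)
      frame$meta$time_source <- src$type
      return(frame)
    }
  }
  abort(sprintf("No configured source recovered a time for %s",
                frame$source_path),
        class = "ffa_missing_time_error")
}
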