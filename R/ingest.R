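# Study ingestion: discover image files, decode, recover times, and sort
# frames into per-(subject, eye, session) series.

SUPPORTED_EXT <- c("tif", "tiff", "png", "jpg", "jpeg", "bmp", "dcm")

#' Construct a series key
#'
#' @param subject_id Subject identifier (non-empty).
#' @param eye `"OS"` (left) or `"OD"` (right).
#' @param session `"AM"` or `"PM"`.
#' @param species `"mouse"`, `"nhp"` or `"human"`; dictates the registration
#'   strategy and whether ETDRS segmentation applies.
#' @export
series_key <- function(subject_id, eye, session, species) {
  eye <- match.arg(eye, c("OS", "OD"))
  session <- match.arg(session, c("AM", "PM"))
  species <- match.arg(species, c("mouse", "nhp", "human"))
  if (!nzchar(subject_id)) {
    abort("`subject_id` must be non-empty.", class = "ffa_parameter_error")
  }
  structure(list(subject_id = subject_id, eye = eye, session = session,
                 species = species),
            class = "ffa_series_key")
}

#' @export
format.ffa_series_key <- function(x, ...) {
  paste(x$subject_id, x$eye, x$session, sep = "_")
}

#' @export
print.ffa_series_key <- function(x, ...) {
  cat("<ffa_series_key ", format(x), " (", x$species, ")>\n", sep = "")
  invisible(x)
}

#' Construct an image series (ordered frames for one session)
#'
#' Frames are sorted by acquisition time; duplicate times within a series are
#' an error (two frames cannot share a timepoint).
#'
#' @param key `ffa_series_key`.
#' @param frames List of timed `ffa_frame` objects (at least 2).
#' @export
image_series <- function(key, frames) {
  if (length(frames) < 2) {
    abort(sprintf("Series %s needs at least 2 timed frames.", format(key)),
          class = "ffa_series_error")
  }
  times <- vapply(frames, function(f) f$t_acq, numeric(1))
  if (any(is.na(times))) {
    abort("All frames in a series must carry an acquisition time.",
          class = "ffa_series_error")
  }
  dup <- duplicated(times)
  if (any(dup)) {
    t_dup <- times[dup][1]
    paths <- vapply(frames[times == t_dup], function(f) f$source_path, character(1))
    abort(sprintf("Duplicate frame time %gs in series %s: %s",
                  t_dup, format(key), paste(paths, collapse = ", ")),
          class = "ffa_duplicate_frame_error")
  }
  frames <- frames[order(times)]
  structure(list(key = key, frames = frames), class = "ffa_series")
}

#' @export
print.ffa_series <- function(x, ...) {
  cat(sprintf("<ffa_series %s: %d frames, t = %g..%g s>\n", format(x$key),
              length(x$frames), x$frames[[1]]$t_acq,
              x$frames[[length(x$frames)]]$t_acq))
  invisible(x)
}

#' Default study configuration
#'
#' One list drives ingestion and processing; stages read their own blocks.
#' Serialisable to/from YAML with [read_study_config()].
#'
#' @param species Study species.
#' @param dialect Hardware dialect tag.
#' @param key_pattern Regex with capture groups `(subject)(eye)(session)`
#'   applied to file basenames.
#' @param time_sources Ordered list of time sources (see [time_sources]).
#' @param ... Further per-stage settings merged into the config.
#' @export
study_config <- function(species = "mouse", dialect = "generic",
                         key_pattern = "^([A-Za-z0-9]+)_(OS|OD)_(AM|PM)_",
                         time_sources = list(time_from_metadata(),
                                             time_from_filename("t(\\d+)")),
                         ...) {
  utils::modifyList(
    list(species = species, dialect = dialect, key_pattern = key_pattern,
         time_sources = time_sources,
         max_dim = 1024, crop = NULL, element_radius = NULL,
         illumination = "registration",
         schedule = seq(30, 600, by = 30), bin_tolerance = 0.25,
         phase_windows = phase_windows(),
         etdrs_diameters_mm = c(1, 3, 6), pixel_scale = NULL,
         macula_center = NULL,
         vessel_scales = c(3, 5), vessel_quantile = 0.90,
         registration = list(fast_threshold = 0.04, ratio = 0.8,
                             ransac_iters = 2000, inlier_tol = 2,
                             max_residual = 3, min_peak_ratio = 1.5,
                             seed = 1L)),
    list(...)
  )
}

#' Read/write a study configuration as YAML
#' @param path YAML file path.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(study_config, raw[setdiff(names(raw), "time_sources")])
  if (!is.null(raw$time_sources)) {
    cfg$time_sources <- lapply(raw$time_sources, function(s) {
      switch(s$type,
             metadata = time_from_metadata(s$injection_time),
             filename = time_from_filename(s$pattern %||% "t(\\d+)"),
             sidecar = time_from_sidecar(s$table),
             overlay = time_from_overlay(s$roi),
             abort(sprintf("Unknown time source '%s' in config.", s$type),
                   class = "ffa_parameter_error"))
    })
  }
  cfg
}

parse_key <- function(base, config) {
  m <- regmatches(base, regexec(config$key_pattern, base))[[1]]
  if (length(m) < 4) return(NULL)
  series_key(m[2], m[3], m[4], config$species)
}

#' Ingest a study directory into per-session image series
#'
#' Recursively discovers supported image files under `root`, decodes each,
#' recovers its acquisition time, and groups frames into one series per
#' (subject, eye, session). Frames whose decode or time recovery fails are
#' skipped and accounted for; series left with fewer than two timed frames
#' are reported and dropped. A machine-readable ingest manifest is written to
#' `root/ingest_manifest.json`.
#'
#' @param root Study directory.
#' @param config Study configuration from [study_config()].
#' @param write_manifest Write the JSON manifest (default `TRUE`).
#' @return List with `series` (list of `ffa_series`), `manifest` (tibble of
#'   per-file dispositions) and `dropped` (keys of dropped series).
#' @export
ingest_study <- function(root, config = study_config(), write_manifest = TRUE) {
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  files <- files[tolower(tools::file_ext(files)) %in% SUPPORTED_EXT]
  files <- sort(files)
  if (length(files) == 0) {
    abort(sprintf("No supported image files found under %s", root),
          class = "ffa_empty_study_error")
  }
  # auto-attach a root sidecar table if present and none configured
  sources <- config$time_sources
  sidecar_path <- file.path(root, "timing.csv")
  if (file.exists(sidecar_path) &&
      !any(vapply(sources, function(s) s$type == "sidecar", logical(1)))) {
    sources <- c(sources, list(time_from_sidecar(sidecar_path)))
  }

  disposition <- character(length(files))
  detail <- character(length(files))
  frames_by_key <- list()
  keys <- list()
  for (i in seq_along(files)) {
    path <- files[i]
    key <- parse_key(basename(path), config)
    if (is.null(key)) {
      disposition[i] <- "skipped"; detail[i] <- "unparseable series key"
      next
    }
    fr <- tryCatch(read_frame(path, dialect = config$dialect),
                   error = function(e) e)
    if (inherits(fr, "error")) {
      disposition[i] <- "skipped"; detail[i] <- conditionMessage(fr)
      next
    }
    fr <- tryCatch(recover_time(fr, sources), error = function(e) e)
    if (inherits(fr, "error")) {
      disposition[i] <- "skipped"; detail[i] <- conditionMessage(fr)
      next
    }
    kid <- format(key)
    frames_by_key[[kid]] <- c(frames_by_key[[kid]], list(fr))
    keys[[kid]] <- key
    disposition[i] <- "ingested"; detail[i] <- sprintf("t=%gs", fr$t_acq)
  }

  series <- list()
  dropped <- character()
  for (kid in names(frames_by_key)) {
    frs <- frames_by_key[[kid]]
    if (length(frs) < 2) {
      dropped <- c(dropped, kid)
      inform(sprintf("Series %s dropped: fewer than 2 timed frames.", kid))
      next
    }
    series[[kid]] <- image_series(keys[[kid]], frs)
  }

  manifest <- tibble::tibble(file = files, disposition = disposition,
                             detail = detail)
  stopifnot(sum(manifest$disposition == "ingested") +
              sum(manifest$disposition == "skipped") == length(files))
  if (write_manifest) {
    jsonlite::write_json(
      list(root = root,
           n_discovered = length(files),
           n_ingested = sum(disposition == "ingested"),
           n_skipped = sum(disposition == "skipped"),
           dropped_series = as.list(dropped),
           files = manifest),
      file.path(root, "ingest_manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  list(series = series, manifest = manifest, dropped = dropped)
}
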