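# Batch pipeline: ingest -> preprocess -> register -> segment -> extract
# ("process"), then temporal metrics + statistics ("analyze").

#' Process an FFA study directory
#'
#' Runs ingestion, preprocessing (crop, optional resize, FOV detection,
#' illumination correction on the registration path), species-dispatched
#' registration, vessel masking and regional intensity extraction for every
#' series. Intensities are extracted from the registered *uncorrected*
#' frames: the white top-hat would subtract exactly the diffuse leakage
#' signal under study, so it only feeds feature detection.
#'
#' @param root Study directory.
#' @param config [study_config()].
#' @param qc Write QC artifacts (MIP PNG, montage PNG, aligned TIFF stack,
#'   registration report CSV) under `root/qc/`.
#' @return List of class `ffa_processed`: `intensities` (long tibble over
#'   all series), `registrations`, `mips`, `series_status` tibble, `config`.
#' @export
process_study <- function(root, config = study_config(), qc = FALSE) {
  ing <- ingest_study(root, config)
  if (length(ing$series) == 0) {
    abort("No usable series after ingest.", class = "ffa_empty_study_error")
  }
  qc_dir <- file.path(root, "qc")
  if (qc) dir.create(qc_dir, showWarnings = FALSE)

  all_int <- list()
  registrations <- list()
  mips <- list()
  status <- list()
  for (kid in names(ing$series)) {
    series <- ing$series[[kid]]
    res <- tryCatch(
      process_series(series, config, qc_dir = if (qc) qc_dir else NULL),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      status[[kid]] <- tibble::tibble(series = kid, status = "failed",
                                      detail = conditionMessage(res))
      next
    }
    all_int[[kid]] <- res$intensities
    registrations[[kid]] <- res$registration
    mips[[kid]] <- res$mip
    status[[kid]] <- tibble::tibble(
      series = kid, status = "processed",
      detail = sprintf("%d/%d frames registered",
                       sum(res$registration$report$status == "registered"),
                       nrow(res$registration$report)))
  }
  if (length(all_int) == 0) {
    abort("Every series failed processing.", class = "ffa_processing_error")
  }
  structure(list(intensities = dplyr::bind_rows(all_int),
                 registrations = registrations, mips = mips,
                 series_status = dplyr::bind_rows(status), config = config),
            class = "ffa_processed")
}

process_series <- function(series, config, qc_dir = NULL) {
  # preprocess every frame identically
  prep <- lapply(series$frames, function(fr) {
    if (!is.null(config$crop)) fr <- crop_info_panel(fr, config$crop)
    fr <- resize_frame(fr, max_dim = config$max_dim)$frame
    fr
  })
  series$frames <- prep
  # provisional FOV from the mean frame: used only to pick the reference
  mean_px <- Reduce(`+`, lapply(prep, `[[`, "pixels")) / length(prep)
  fov <- tryCatch(detect_fov_mask(new_frame(mean_px)),
                  ffa_fov_error = function(e) {
                    matrix(TRUE, nrow(mean_px), ncol(mean_px))
                  })
  # illumination-corrected copies feed registration only
  reg_series <- series
  if (identical(config$illumination, "registration")) {
    reg_series$frames <- lapply(prep, correct_illumination,
                                element_radius = config$element_radius)
  }
  reg <- register_series(reg_series, strategy = "auto", fov = fov,
                         params = config$registration)
  # resample the uncorrected frames through the estimated transforms
  for (i in seq_along(reg$aligned)) {
    if (is.null(reg$aligned[[i]])) next
    reg$aligned[[i]] <- if (i == reg$reference_index) {
      prep[[i]]$pixels
    } else {
      warp_frame(prep[[i]]$pixels, reg$transforms[[i]])
    }
  }
  mip <- max_intensity_projection(reg)
  # final FOV from the registered MIP: it lives in reference coordinates,
  # so it hugs the imaged disk exactly (a FOV from unregistered frames is
  # blurred by the jitter and lets dark rim pixels into the statistics)
  fov <- tryCatch(detect_fov_mask(new_frame(mip)),
                  ffa_fov_error = function(e) fov)
  reg$fov <- fov
  vmask <- suppressWarnings(
    compute_vessel_mask(mip, species = series$key$species,
                        scales = config$vessel_scales,
                        threshold = config$vessel_quantile, fov = fov)
  )
  grid <- NULL
  if (series$key$species != "mouse") {
    center <- config$macula_center
    if (is.null(center)) {
      abort(sprintf("Macula centre required for primate series %s.",
                    format(series$key)),
            class = "ffa_configuration_error")
    }
    grid <- build_etdrs_grid(center, dim = dim(mip),
                             pixel_scale = config$pixel_scale,
                             diameters_mm = config$etdrs_diameters_mm)
  }
  intensities <- extract_region_intensities(reg, grid = grid,
                                            vessel_mask = vmask)
  if (!is.null(qc_dir)) {
    kid <- format(series$key)
    write_png(mip, file.path(qc_dir, paste0(kid, "_mip.png")))
    write_png(montage(reg$aligned), file.path(qc_dir, paste0(kid, "_montage.png")))
    stack <- Filter(Negate(is.null), reg$aligned)
    tiff::writeTIFF(lapply(stack, function(m) { m[is.na(m)] <- 0; clamp(m) }),
                    file.path(qc_dir, paste0(kid, "_aligned.tif")),
                    bits.per.sample = 16L, compression = "none")
    utils::write.csv(reg$report,
                     file.path(qc_dir, paste0(kid, "_registration.csv")),
                     row.names = FALSE)
  }
  list(intensities = intensities, registration = reg, mip = mip,
       vessel_mask = vmask, grid = grid, fov = fov)
}

#' Tile aligned frames into a QC montage
#' @param aligned List of matrices (NULL and NA entries allowed).
#' @param ncol Tiles per row (default: square-ish).
#' @export
montage <- function(aligned, ncol = NULL) {
  frames <- Filter(Negate(is.null), aligned)
  n <- length(frames)
  if (n == 0) abort("Nothing to montage.", class = "ffa_empty_series_error")
  if (is.null(ncol)) ncol <- ceiling(sqrt(n))
  nrow_t <- ceiling(n / ncol)
  h <- nrow(frames[[1]]); w <- ncol(frames[[1]])
  out <- matrix(0, nrow_t * h, ncol * w)
  for (i in seq_len(n)) {
    r <- (i - 1) %/% ncol; c <- (i - 1) %% ncol
    m <- frames[[i]]; m[is.na(m)] <- 0
    out[r * h + 1:h, c * w + 1:w] <- m
  }
  out
}

#' Analyse a processed study: temporal metrics and gated statistics
#'
#' Bins intensities to the nominal schedule, computes phase summaries,
#' cumulative intensity over common timepoints, per-subject AM-versus-PM
#' percent change of the chosen metric, and runs the normality-gated paired
#' comparison per region (Sidak-adjusted within the family of regions).
#'
#' @param processed `ffa_processed` from [process_study()], or a raw
#'   intensity tibble.
#' @param config Study configuration (schedule, tolerance, phase windows).
#' @param metric `"late_phase_mean"` (default) or `"cumulative"`.
#' @return List of class `ffa_analysis`: `records` (binned), `phases`,
#'   `cumulative`, `pct_change`, `pct_summary`, `comparisons`
#'   (`ffa_comparison` tibble), `metric`.
#' @export
analyze_study <- function(processed, config = study_config(),
                          metric = c("late_phase_mean", "cumulative")) {
  metric <- match.arg(metric)
  records <- if (inherits(processed, "ffa_processed")) {
    processed$intensities
  } else {
    processed
  }
  records <- bin_to_nominal(records, schedule = config$schedule,
                            tolerance = config$bin_tolerance)
  phases <- phase_summary(records, windows = config$phase_windows)
  cum <- cumulative_intensity(records)
  values <- if (metric == "late_phase_mean") {
    phases |>
      dplyr::filter(.data$phase == "late", .data$n_frames > 0) |>
      dplyr::transmute(.data$subject, .data$eye, .data$session, .data$region,
                       value = .data$mean_intensity)
  } else {
    # cumulative is region-agnostic here: computed over each region's records
    records |>
      dplyr::filter(!is.na(.data$nominal_t)) |>
      dplyr::group_by(.data$subject, .data$eye, .data$session, .data$region) |>
      dplyr::summarise(value = sum(.data$mean_intensity), .groups = "drop")
  }
  pct <- percent_change(values)
  comparisons <- compare_family(values, metric = metric)
  structure(list(records = records, phases = phases, cumulative = cum,
                 pct_change = pct, pct_summary = summarise_pct_change(pct),
                 comparisons = comparisons, metric = metric),
            class = "ffa_analysis")
}

#' @export
print.ffa_analysis <- function(x, ...) {
  cat(sprintf("<ffa_analysis metric=%s>\n", x$metric))
  print(x$comparisons)
  invisible(x)
}

#' Write the analysis report bundle (CSV + JSON)
#'
#' @param analysis `ffa_analysis`.
#' @param dir Output directory.
#' @param grid Optional `ffa_etdrs_grid` for the leakage colour map.
#' @export
write_report <- function(analysis, dir, grid = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(analysis$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$pct_change, file.path(dir, "pct_change.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$phases, file.path(dir, "phase_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(analysis$records, file.path(dir, "intensity_records.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(metric = analysis$metric,
         comparisons = analysis$comparisons,
         pct_summary = analysis$pct_summary),
    file.path(dir, "results.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  if (!is.null(grid)) {
    pct <- setNames(analysis$pct_summary$mean_pct_change,
                    analysis$pct_summary$region)
    leakage_color_map(pct, grid, path = file.path(dir, "leakage_map.png"))
  }
  invisible(dir)
}
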