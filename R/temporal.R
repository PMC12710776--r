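# Temporal leakage metrics: nominal-time binning, cumulative intensity over
# common timepoints, angiographic phase summaries, decay profiles, and
# morning-versus-evening percent change.

#' Angiographic phase windows
#'
#' Defaults follow the conventional phases: early is the first minute
#' `[0, 60)`, intermediate 2--4 minutes `[120, 240]`, late beyond 4 minutes
#' `(240, end]`. The 60--120 s gap is deliberately unassigned.
#'
#' @param early `[lo, hi)` in seconds.
#' @param mid `[lo, hi]` in seconds.
#' @param late `(lo, hi]` in seconds.
#' @export
phase_windows <- function(early = c(0, 60), mid = c(120, 240),
                          late = c(240, Inf)) {
  w <- list(early = early, mid = mid, late = late)
  lims <- c(early[1], early[2], mid[1], mid[2], late[1], late[2])
  if (early[2] > mid[1] || mid[2] > late[1] || any(diff(c(early, mid, late)) < 0)) {
    abort("Phase windows must be non-overlapping and increasing.",
          class = "ffa_configuration_error")
  }
  structure(w, class = "ffa_phase_windows")
}

phase_of <- function(t, windows) {
  dplyr::case_when(
    t >= windows$early[1] & t < windows$early[2] ~ "early",
    t >= windows$mid[1] & t <= windows$mid[2] ~ "mid",
    t > windows$late[1] & t <= windows$late[2] ~ "late",
    TRUE ~ NA_character_
  )
}

#' Snap record times onto a nominal acquisition schedule
#'
#' Real timestamps jitter around the scheduled grid; each record is assigned
#' the nearest schedule time when within `tolerance * step` of it. If two
#' records of one series land on the same nominal time, the nearer is kept
#' and the other flagged `off_schedule`; records outside tolerance are
#' likewise flagged.
#'
#' @param records Intensity tibble (from [extract_region_intensities()]).
#' @param schedule Strictly increasing nominal times (s).
#' @param tolerance Fraction of the schedule step (in `(0, 0.5]`).
#' @return `records` with columns `nominal_t` (`NA` when off-schedule) and
#'   `off_schedule`.
#' @export
bin_to_nominal <- function(records, schedule = seq(30, 600, by = 30),
                           tolerance = 0.25) {
  if (length(schedule) == 0) {
    abort("`schedule` must be non-empty.", class = "ffa_parameter_error")
  }
  if (any(diff(schedule) <= 0)) {
    abort("`schedule` must be strictly increasing.", class = "ffa_parameter_error")
  }
  if (tolerance <= 0 || tolerance > 0.5) {
    abort("`tolerance` must lie in (0, 0.5].", class = "ffa_parameter_error")
  }
  step <- if (length(schedule) > 1) min(diff(schedule)) else schedule[1]
  idx <- vapply(records$t_sec, function(t) which.min(abs(schedule - t)), integer(1))
  nominal <- schedule[idx]
  off <- abs(records$t_sec - nominal) > tolerance * step
  records$nominal_t <- ifelse(off, NA_real_, nominal)
  records$off_schedule <- off
  # collision: two records of one series/region on the same nominal time
  records <- records |>
    dplyr::group_by(.data$subject, .data$eye, .data$session, .data$region,
                    .data$nominal_t) |>
    dplyr::mutate(
      .dist = abs(.data$t_sec - .data$nominal_t),
      .loser = !is.na(.data$nominal_t) & dplyr::n() > 1 &
        dplyr::row_number(.data$.dist) > 1
    ) |>
    dplyr::ungroup()
  n_coll <- sum(records$.loser)
  if (n_coll > 0) {
    inform(sprintf("%d record(s) displaced from an occupied nominal timepoint.", n_coll))
    records$nominal_t[records$.loser] <- NA_real_
    records$off_schedule[records$.loser] <- TRUE
  }
  dplyr::select(records, -".dist", -".loser")
}

#' Cumulative intensity over timepoints common to the whole cohort
#'
#' The common grid is the intersection of nominal timepoints present in
#' every series of the cohort; the cumulative intensity of a series is the
#' sum of its mean intensities over that grid.
#'
#' @param records Nominal-binned intensity tibble.
#' @param region Region to aggregate (default `"fov"` for mouse data).
#' @return Tibble with one row per (subject, eye, session): `cumulative` and
#'   `n_timepoints`; the common grid is attached as attribute
#'   `common_grid`.
#' @export
cumulative_intensity <- function(records, region = NULL) {
  r <- dplyr::filter(records, !is.na(.data$nominal_t))
  if (!is.null(region)) r <- dplyr::filter(r, .data$region == !!region)
  if (nrow(r) == 0) {
    abort("No on-schedule records to accumulate.", class = "ffa_parameter_error")
  }
  grids <- r |>
    dplyr::distinct(.data$subject, .data$eye, .data$session, .data$nominal_t)
  series_n <- dplyr::n_distinct(paste(grids$subject, grids$eye, grids$session))
  common <- grids |>
    dplyr::count(.data$nominal_t) |>
    dplyr::filter(.data$n == series_n) |>
    dplyr::pull(.data$nominal_t)
  if (length(common) == 0) {
    coverage <- grids |>
      dplyr::count(.data$subject, .data$eye, .data$session, name = "n_timepoints")
    abort(paste0("No timepoints common to all series. Coverage: ",
                 paste(sprintf("%s_%s_%s=%d", coverage$subject, coverage$eye,
                               coverage$session, coverage$n_timepoints),
                       collapse = ", ")),
          class = "ffa_no_common_timepoints_error")
  }
  out <- r |>
    dplyr::filter(.data$nominal_t %in% common) |>
    dplyr::group_by(.data$subject, .data$eye, .data$session) |>
    dplyr::summarise(cumulative = sum(.data$mean_intensity),
                     n_timepoints = dplyr::n(), .groups = "drop")
  attr(out, "common_grid") <- sort(common)
  out
}

#' Summarise intensities over angiographic phase windows
#'
#' Per (series, region, phase): the unweighted mean of frame-level region
#' means whose nominal time falls in the window. Cells with no frames are
#' reported explicitly with `n_frames = 0` and `NA` mean.
#'
#' @param records Nominal-binned intensity tibble.
#' @param windows [phase_windows()].
#' @return Tibble `subject, eye, session, species, region, phase,
#'   mean_intensity, n_frames`.
#' @export
phase_summary <- function(records, windows = phase_windows()) {
  r <- dplyr::filter(records, !is.na(.data$nominal_t))
  r$phase <- phase_of(r$nominal_t, windows)
  r <- dplyr::filter(r, !is.na(.data$phase))
  present <- r |>
    dplyr::group_by(.data$subject, .data$eye, .data$session, .data$species,
                    .data$region, .data$phase) |>
    dplyr::summarise(mean_intensity = mean(.data$mean_intensity),
                     n_frames = dplyr::n(), .groups = "drop")
  # make missing cells explicit
  frame <- tidyr::expand_grid(
    dplyr::distinct(records, .data$subject, .data$eye, .data$session,
                    .data$species, .data$region),
    phase = c("early", "mid", "late")
  )
  out <- dplyr::left_join(frame, present,
                          by = c("subject", "eye", "session", "species",
                                 "region", "phase"))
  out$n_frames[is.na(out$n_frames)] <- 0L
  out
}

#' Decay profile: intensity as percent of the series maximum
#'
#' Expresses a temporal profile as a percentage of its peak and reports the
#' peak time plus the first time the profile falls below a clearance
#' threshold (the fluorescein clearance readout).
#'
#' @param curve Tibble/data frame with columns `t` and `intensity`, or two
#'   vectors via `t` and `intensity` arguments.
#' @param clearance_threshold Percent-of-max below which the dye is
#'   considered cleared (default 50).
#' @return Tibble `t, pct_of_max` with attributes `t_peak` and
#'   `t_clearance` (`NA` when never reached).
#' @export
decay_profile <- function(curve, clearance_threshold = 50) {
  stopifnot(all(c("t", "intensity") %in% names(curve)))
  curve <- dplyr::arrange(tibble::as_tibble(curve), .data$t)
  if (nrow(curve) < 2) {
    abort("Decay profile needs at least 2 points.", class = "ffa_parameter_error")
  }
  m <- max(curve$intensity)
  if (m <= 0) {
    abort("Degenerate profile: all intensities are zero.",
          class = "ffa_degenerate_profile_error")
  }
  out <- tibble::tibble(t = curve$t, pct_of_max = 100 * curve$intensity / m)
  t_peak <- curve$t[which.max(curve$intensity)]
  after <- out[out$t >= t_peak & out$pct_of_max <= clearance_threshold, ]
  attr(out, "t_peak") <- t_peak
  attr(out, "t_clearance") <- if (nrow(after)) after$t[1] else NA_real_
  out
}

#' Morning-versus-evening percent change
#'
#' Pairs AM and PM values of a chosen metric per (subject, eye, region) and
#' computes the per-subject percent change `100 * (PM - AM) / AM`; the
#' cohort summary is the mean (and median) of per-subject changes.
#' Incomplete pairs and non-positive AM baselines are dropped with a
#' message.
#'
#' @param values Tibble with columns `subject`, `eye`, `region`, `session`
#'   and `value`.
#' @return Tibble with one row per (subject, eye, region): `am`, `pm`,
#'   `pct_change`; cohort summaries are attached by
#'   [summarise_pct_change()].
#' @export
percent_change <- function(values) {
  wide <- values |>
    dplyr::select("subject", "eye", "region", "session", "value") |>
    tidyr::pivot_wider(names_from = "session", values_from = "value")
  if (!all(c("AM", "PM") %in% names(wide))) {
    abort("Both AM and PM sessions are required.", class = "ffa_parameter_error")
  }
  incomplete <- is.na(wide$AM) | is.na(wide$PM)
  if (any(incomplete)) {
    inform(sprintf("%d incomplete AM/PM pair(s) dropped.", sum(incomplete)))
    wide <- wide[!incomplete, ]
  }
  bad <- wide$AM <= 0
  if (any(bad)) {
    inform(sprintf("%d pair(s) dropped: AM baseline <= 0.", sum(bad)))
    wide <- wide[!bad, ]
  }
  dplyr::transmute(wide, .data$subject, .data$eye, .data$region,
                   am = .data$AM, pm = .data$PM,
                   pct_change = 100 * (.data$PM - .data$AM) / .data$AM)
}

#' Cohort summary of per-subject percent changes
#' @param pct Output of [percent_change()].
#' @return Tibble per region: `n`, `mean_pct_change`, `median_pct_change`.
#' @export
summarise_pct_change <- function(pct) {
  pct |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_pct_change = mean(.data$pct_change),
                     median_pct_change = stats::median(.data$pct_change),
                     .groups = "drop")
}
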