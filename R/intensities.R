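# Regional intensity extraction from a registered series.

#' Extract per-frame regional mean intensities
#'
#' For every registered frame and every region, the arithmetic mean intensity
#' over `region & fov & !vessel_mask & !invalid` pixels, plus an
#' `"all_regions"` aggregate (the pixel-count-weighted mean, i.e. the mean
#' over the union of regions). Mice use the whole field of view as a single
#' `"fov"` region; primates use the ETDRS grid.
#'
#' @param registration `ffa_registration` from [register_series()].
#' @param grid `ffa_etdrs_grid`, or `NULL` to quantify the whole FOV (mouse).
#' @param vessel_mask Logical large-vessel mask (`TRUE` = excluded), or
#'   `NULL`.
#' @return Tibble with columns `subject`, `eye`, `session`, `species`,
#'   `region`, `t_sec`, `mean_intensity`, `n_pixels` (one row per
#'   frame x region).
#' @export
extract_region_intensities <- function(registration, grid = NULL,
                                       vessel_mask = NULL) {
  key <- registration$key
  fov <- registration$fov
  excl <- if (is.null(vessel_mask)) {
    matrix(FALSE, nrow(fov), ncol(fov))
  } else {
    vessel_mask
  }
  regions <- if (is.null(grid)) {
    list(fov = fov)
  } else {
    setNames(
      lapply(ETDRS_REGIONS, function(r) etdrs_region_mask(grid, r)),
      ETDRS_REGIONS
    )
  }
  base_valid <- fov & !excl

  rows <- list()
  for (i in seq_along(registration$aligned)) {
    px <- registration$aligned[[i]]
    if (is.null(px)) next      # excluded frame
    t_sec <- registration$report$t_acq[i]
    valid <- base_valid & !is.na(px)
    tot_sum <- 0; tot_n <- 0L
    for (rname in names(regions)) {
      sel <- regions[[rname]] & valid
      n <- sum(sel)
      if (n == 0L) {
        warn(sprintf("Region %s fully occluded in frame %d of %s; record omitted.",
                     rname, i, format(key)),
             class = "ffa_occlusion_warning")
        next
      }
      s <- sum(px[sel])
      tot_sum <- tot_sum + s; tot_n <- tot_n + n
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = key$subject_id, eye = key$eye, session = key$session,
        species = key$species, region = rname, t_sec = t_sec,
        mean_intensity = s / n, n_pixels = n)
    }
    if (tot_n > 0L && length(regions) > 1L) {
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject = key$subject_id, eye = key$eye, session = key$session,
        species = key$species, region = "all_regions", t_sec = t_sec,
        mean_intensity = tot_sum / tot_n, n_pixels = tot_n)
    }
  }
  dplyr::bind_rows(rows)
}
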