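# ETDRS macular grid construction.
#
# The grid partitions the macula into concentric regions around the macula
# centre: fovea (central disk), parafovea (inner annulus), perifovea (outer
# annulus) and extrafovea (everything beyond, inside the field of view).
# Standard ring diameters are 1, 3 and 6 mm; radii in pixels follow from the
# acquisition pixel scale.

ETDRS_REGIONS <- c("fovea", "parafovea", "perifovea", "extrafovea")

#' Build an ETDRS grid around the macula centre
#'
#' Region membership is decided by pixel centre: fovea `r < r1`, parafovea
#' `r1 <= r < r2`, perifovea `r2 <= r < r3`, extrafovea `r >= r3`, so the
#' regions partition the plane exactly and
#' fovea + parafovea + perifovea = disk(r3).
#'
#' @param center Macula centre `(x, y)` in pixels.
#' @param dim Image dimensions `c(h, w)`.
#' @param pixel_scale Pixel scale in um/px; `NULL` triggers the fractional
#'   fallback radii `(0.055, 0.165, 0.33) * image width` (flagged in the
#'   returned object).
#' @param diameters_mm Ring diameters in mm, increasing (default `c(1, 3, 6)`).
#' @return Object of class `ffa_etdrs_grid` with `center`, `radii_px`,
#'   `region` (factor matrix of labels) and `fallback` flag.
#' @export
build_etdrs_grid <- function(center, dim, pixel_scale = NULL,
                             diameters_mm = c(1, 3, 6)) {
  if (any(diff(diameters_mm) <= 0) || length(diameters_mm) != 3) {
    abort("`diameters_mm` must be three increasing diameters.",
          class = "ffa_parameter_error")
  }
  h <- dim[1]; w <- dim[2]
  fallback <- is.null(pixel_scale)
  if (fallback) {
    radii <- c(0.055, 0.165, 0.33) * w
    warn("Pixel scale unavailable: using fractional fallback ETDRS radii.",
         class = "ffa_configuration_warning")
  } else {
    if (pixel_scale <= 0) {
      abort("`pixel_scale` must be positive (um/px).", class = "ffa_parameter_error")
    }
    radii <- diameters_mm / 2 * 1000 / pixel_scale
  }
  if (center[1] - radii[1] < 1 || center[1] + radii[1] > w ||
      center[2] - radii[1] < 1 || center[2] + radii[1] > h) {
    abort("ETDRS grid placement error: foveal disk clipped by the image border.",
          class = "ffa_grid_placement_error")
  }
  g <- coord_grid(h, w)
  r <- sqrt((g$x - center[1])^2 + (g$y - center[2])^2)
  region <- matrix(ETDRS_REGIONS[4], h, w)
  region[r < radii[3]] <- ETDRS_REGIONS[3]
  region[r < radii[2]] <- ETDRS_REGIONS[2]
  region[r < radii[1]] <- ETDRS_REGIONS[1]
  structure(list(center = center, radii_px = radii, dim = c(h, w),
                 pixel_scale = pixel_scale, region = region,
                 fallback = fallback),
            class = "ffa_etdrs_grid")
}

#' @export
print.ffa_etdrs_grid <- function(x, ...) {
  cat(sprintf("<ffa_etdrs_grid centre (%.0f, %.0f), radii %.1f/%.1f/%.1f px%s>\n",
              x$center[1], x$center[2], x$radii_px[1], x$radii_px[2],
              x$radii_px[3], if (x$fallback) " [fallback radii]" else ""))
  invisible(x)
}

#' Logical mask for one grid region
#' @param grid `ffa_etdrs_grid`.
#' @param region One of `"fovea"`, `"parafovea"`, `"perifovea"`,
#'   `"extrafovea"`.
#' @export
etdrs_region_mask <- function(grid, region) {
  region <- match.arg(region, ETDRS_REGIONS)
  grid$region == region
}
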