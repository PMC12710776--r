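# Frame preparation: info-panel cropping, illumination correction, size
# bounding, and circular field-of-view detection.

#' Crop specification
#'
#' @param top,bottom,left,right Margins in pixels to remove.
#' @param auto If `TRUE`, margins are ignored and constant-intensity border
#'   strips (machine info panels) are detected and removed automatically.
#' @export
crop_spec <- function(top = 0, bottom = 0, left = 0, right = 0, auto = FALSE) {
  m <- c(top = top, bottom = bottom, left = left, right = right)
  if (any(m < 0)) abort("Crop margins must be non-negative.", class = "ffa_parameter_error")
  list(top = top, bottom = bottom, left = left, right = right, auto = auto)
}

#' Remove machine info panels from a frame
#'
#' Either fixed per-dialect margins or auto-detection of maximal full-height /
#' full-width border strips whose per-row/column intensity variance is below
#' `1e-6` (constant panels).
#'
#' @param frame `ffa_frame`.
#' @param spec [crop_spec()].
#' @return Cropped `ffa_frame`.
#' @export
crop_info_panel <- function(frame, spec = crop_spec(auto = TRUE)) {
  px <- frame$pixels
  h <- nrow(px); w <- ncol(px)
  if (isTRUE(spec$auto)) {
    col_var <- apply(px, 2, var)
    row_var <- apply(px, 1, var)
    run_from <- function(v) {         # length of constant run from each end
      flat <- v < 1e-6
      lead <- if (flat[1]) which.min(c(flat, FALSE)) - 1L else 0L
      trail <- if (flat[length(v)]) which.min(c(rev(flat), FALSE)) - 1L else 0L
      c(lead, trail)
    }
    cr <- run_from(col_var); rr <- run_from(row_var)
    spec <- crop_spec(top = rr[1], bottom = rr[2], left = cr[1], right = cr[2])
  }
  r0 <- 1 + spec$top; r1 <- h - spec$bottom
  c0 <- 1 + spec$left; c1 <- w - spec$right
  if (r1 - r0 + 1 < 64 || c1 - c0 + 1 < 64) {
    abort(sprintf("Crop would leave %dx%d (< 64x64).", r1 - r0 + 1, c1 - c0 + 1),
          class = "ffa_overcrop_error")
  }
  frame$pixels <- px[r0:r1, c0:c1, drop = FALSE]
  frame
}

#' Correct non-uniform background illumination (white top-hat)
#'
#' Subtracts the morphological opening of the frame with a disk structuring
#' element: structures wider than roughly twice the element radius (shadows,
#' slow illumination gradients) are suppressed while vasculature-scale
#' structure passes. Output is clipped to `[0, 1]`; it is everywhere at most
#' the input (opening is anti-extensive).
#'
#' @param frame `ffa_frame`.
#' @param element_radius Disk radius in pixels; default
#'   `ceiling(min(h, w) / 8)`, larger than the widest vessel.
#' @return Corrected `ffa_frame`.
#' @export
correct_illumination <- function(frame, element_radius = NULL) {
  px <- frame$pixels
  h <- nrow(px); w <- ncol(px)
  if (is.null(element_radius)) element_radius <- ceiling(min(h, w) / 8)
  if (element_radius < 1 || element_radius >= min(h, w) / 2) {
    abort(sprintf("element_radius %g out of range [1, min(h,w)/2).", element_radius),
          class = "ffa_parameter_error")
  }
  brush <- EBImage::makeBrush(2 * element_radius + 1, shape = "disc")
  # replicate-pad so the opening sees no artificial border step
  r <- element_radius
  padded <- px[c(rep(1, r), seq_len(h), rep(h, r)),
               c(rep(1, r), seq_len(w), rep(w, r))]
  opened <- as.matrix(EBImage::opening(padded, brush))[r + seq_len(h),
                                                      r + seq_len(w)]
  frame$pixels <- clamp(px - opened, 0, 1)
  frame
}

#' Bound frame size by isotropic area-averaged downscaling
#'
#' If the larger image dimension exceeds `max_dim`, the frame is downscaled
#' isotropically by exact area averaging (each output pixel is the mean of
#' the source rectangle it covers, with fractional edge weights) so that
#' `max(h, w) == max_dim`. Pixel-scale metadata (`meta$pixel_scale`, um/px)
#' is divided by the applied scale.
#'
#' @param frame `ffa_frame`.
#' @param max_dim Maximum allowed dimension in pixels (>= 64).
#' @return List with the resized `frame` and the applied `scale` (<= 1).
#' @export
resize_frame <- function(frame, max_dim = 1024) {
  if (max_dim < 64) abort("`max_dim` must be >= 64.", class = "ffa_parameter_error")
  px <- frame$pixels
  h <- nrow(px); w <- ncol(px)
  big <- max(h, w)
  if (big <= max_dim) return(list(frame = frame, scale = 1))
  scale <- max_dim / big
  h2 <- max(64L, round(h * scale)); w2 <- max(64L, round(w * scale))
  frame$pixels <- area_resample(px, h2, w2)
  if (!is.null(frame$meta$pixel_scale)) {
    frame$meta$pixel_scale <- frame$meta$pixel_scale / scale
  }
  list(frame = frame, scale = scale)
}

# exact box/area averaging via 1-D interval-overlap weight matrices:
# out = Wr %*% px %*% t(Wc), rows of W summing to 1
area_weights <- function(n_out, n_in) {
  W <- matrix(0, n_out, n_in)
  step <- n_in / n_out
  for (i in seq_len(n_out)) {
    a <- (i - 1) * step; b <- i * step
    j0 <- floor(a) + 1L; j1 <- ceiling(b)
    for (j in j0:min(j1, n_in)) {
      lo <- max(a, j - 1); hi <- min(b, j)
      if (hi > lo) W[i, j] <- (hi - lo) / step
    }
  }
  W
}

area_resample <- function(px, h_out, w_out) {
  Wr <- area_weights(h_out, nrow(px))
  Wc <- area_weights(w_out, ncol(px))
  Wr %*% px %*% t(Wc)
}

#' Detect the circular imaged field of view
#'
#' The fundus aperture leaves a dark surround; the FOV is recovered by Otsu
#' thresholding a heavily smoothed copy, keeping the largest connected
#' component and filling holes. A configured centred disk can override
#' auto-detection.
#'
#' @param frame `ffa_frame`.
#' @param override_radius If given, return a centred disk of this radius
#'   instead of detecting.
#' @param min_fraction Smallest admissible FOV area as a fraction of the
#'   image (default 0.2); below this a fov-detection error is raised.
#' @param circularize Replace the detected component by its best-fit disk
#'   (default `TRUE`): the imaged field is a circular hardware aperture, and
#'   an intensity isophote would bulge outward where vessels reach the rim,
#'   biasing regional statistics toward vessel-rich sectors.
#' @return Logical matrix (`TRUE` inside the field of view).
#' @export
detect_fov_mask <- function(frame, override_radius = NULL, min_fraction = 0.2,
                            circularize = TRUE) {
  px <- frame$pixels
  h <- nrow(px); w <- ncol(px)
  if (!is.null(override_radius)) {
    g <- coord_grid(h, w)
    return((g$x - (w + 1) / 2)^2 + (g$y - (h + 1) / 2)^2 <= override_radius^2)
  }
  # smooth hard enough that vasculature-scale structure is washed out and
  # only the aperture edge survives before thresholding
  sm <- gauss_smooth(px, sigma = max(2, min(h, w) / 16))
  rng <- range(sm)
  if (diff(rng) < 1e-6) {
    if (rng[1] > 0.5) return(matrix(TRUE, h, w))
    abort("FOV detection failed: frame has no bright field.",
          class = "ffa_fov_error")
  }
  thr <- EBImage::otsu(matrix(clamp(sm), h, w), range = c(0, 1))
  rough <- sm > thr
  if (!any(rough) || all(rough)) {
    abort("FOV detection failed: degenerate threshold.", class = "ffa_fov_error")
  }
  # refine on a lighter smoothing (curvature shrinkage ~sigma^2 / 2R of the
  # heavy kernel would bite into the rim); threshold low so dim vignetted
  # rim sectors stay inside and the component hugs the aperture all around
  sm2 <- gauss_smooth(px, sigma = max(2, min(h, w) / 64))
  mu_in <- mean(sm2[rough]); mu_out <- mean(sm2[!rough])
  bw <- sm2 > mu_out + 0.15 * (mu_in - mu_out)
  lab <- EBImage::bwlabel(bw)
  if (max(lab) == 0) {
    abort("FOV detection failed: no foreground component.", class = "ffa_fov_error")
  }
  sizes <- tabulate(lab[lab > 0])
  mask <- lab == which.max(sizes)
  mask <- EBImage::fillHull(mask) > 0
  if (mean(mask) < min_fraction) {
    abort(sprintf("FOV detection failed: largest component covers %.1f%% < %.0f%%.",
                  100 * mean(mask), 100 * min_fraction),
          class = "ffa_fov_error")
  }
  mask <- matrix(as.logical(mask), h, w)
  if (circularize && mean(mask) < 0.99) {
    # the imaged field is a hardware aperture, i.e. a circle: an intensity
    # isophote bulges outward in vessel-rich sectors and inward in dark
    # ones, biasing regional statistics toward vessel-rich sectors, so the
    # component is replaced by a disk at the aperture edge
    mask <- fit_disk(mask, sm2)
  }
  mask
}

# aperture disk: centre from the low-threshold component (which hugs the
# aperture in every sector), radius at the steepest descent of the
# azimuthally averaged radial profile (the aperture edge, independent of
# per-sector brightness)
fit_disk <- function(mask, sm) {
  h <- nrow(mask); w <- ncol(mask)
  g <- coord_grid(h, w)
  cx <- mean(g$x[mask]); cy <- mean(g$y[mask])
  r <- sqrt((g$x - cx)^2 + (g$y - cy)^2)
  rbin <- round(r)
  prof <- tapply(as.vector(sm), as.vector(rbin), mean)
  rr <- as.numeric(names(prof))
  keep <- rr <= min(min(cx, w - cx), min(cy, h - cy))  # full rings only
  prof <- prof[keep]; rr <- rr[keep]
  if (length(rr) < 8) return(r <= sqrt(sum(mask) / pi))
  # search only near the component radius: interior vessel rings also
  # produce steep azimuthal-mean gradients
  r0 <- sqrt(sum(mask) / pi)
  band <- rr >= 0.85 * r0 & rr <= 1.15 * r0
  if (!any(band[-length(band)])) return(r <= r0)
  grad <- diff(prof)
  grad[!band[-length(band)]] <- Inf
  r_edge <- rr[which.min(grad)]
  r <= r_edge
}
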