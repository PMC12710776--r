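# Species-specific large-vessel masking.
#
# Fluorescein renders vessels bright, so large vessels are located with a
# multi-scale bright-ridge (Hessian) filter evaluated only at the configured
# large-vessel scales: small-calibre microvasculature is deliberately left
# unmasked, since for mice the microvasculature *is* the analysis region and
# for primates parenchymal leakage must not be diluted by major vessels.

hessian_ridge <- function(img, sigma) {
  sm <- gauss_smooth(img, sigma)
  h <- nrow(sm); w <- ncol(sm)
  shift <- function(m, dx, dy) {
    out <- shift_mat(m, dx, dy)
    # replicate border values so derivatives stay finite at the frame edge
    out[is.na(out)] <- m[is.na(out)]
    out
  }
  dxx <- shift(sm, 1, 0) - 2 * sm + shift(sm, -1, 0)
  dyy <- shift(sm, 0, 1) - 2 * sm + shift(sm, 0, -1)
  dxy <- (shift(sm, 1, 1) - shift(sm, 1, -1) -
            shift(sm, -1, 1) + shift(sm, -1, -1)) / 4
  tr <- dxx + dyy
  det_rt <- sqrt(pmax((dxx - dyy)^2 + 4 * dxy^2, 0))
  lam2 <- (tr - det_rt) / 2          # most negative eigenvalue
  resp <- sigma^2 * pmax(-lam2, 0)   # bright-tube polarity, gamma = 2
  resp
}

#' Compute the large-vessel exclusion mask
#'
#' Multi-scale Hessian bright-ridge response on the maximum intensity
#' projection, taken at the configured large-vessel scales only, thresholded
#' at a quantile of the response inside the field of view and dilated by
#' 2 px. For mice the complement of this mask within the FOV is the
#' "microvasculature" analysis region; for primates the mask is subtracted
#' from the ETDRS regions before averaging.
#'
#' @param mip Intensity matrix (MIP of the registered series).
#' @param species Species tag (recorded on the mask).
#' @param scales Gaussian scales (px) spanning expected large-vessel
#'   half-widths (default `c(5, 8)`).
#' @param threshold Quantile of the in-FOV response above which a pixel is
#'   masked (default 0.98).
#' @param fov Logical FOV mask (default: full image).
#' @return Logical matrix of class `ffa_vessel_mask` (`TRUE` = large-vessel
#'   pixel) with attributes `species` and `fraction`.
#' @export
compute_vessel_mask <- function(mip, species = "mouse", scales = c(5, 8),
                                threshold = 0.98, fov = NULL) {
  if (is.null(fov)) fov <- matrix(TRUE, nrow(mip), ncol(mip))
  resp <- matrix(0, nrow(mip), ncol(mip))
  for (s in scales) resp <- pmax(resp, hessian_ridge(mip, s))
  vals <- resp[fov]
  if (max(vals) < 1e-10) {
    warn("Vessel masking: no ridge structure found; returning an empty mask.",
         class = "ffa_masking_warning")
    mask <- matrix(FALSE, nrow(mip), ncol(mip))
  } else {
    thr <- stats::quantile(vals, threshold, names = FALSE)
    mask <- resp > thr & fov
    mask <- EBImage::dilate(mask, EBImage::makeBrush(5, "disc")) > 0
    mask <- mask & fov
  }
  frac <- sum(mask) / max(sum(fov), 1)
  if (frac > 0.5) {
    abort(sprintf("Vessel mask covers %.0f%% of the FOV (> 50%%); lower the threshold.",
                  100 * frac),
          class = "ffa_parameter_error")
  }
  structure(matrix(as.logical(mask), nrow(mip), ncol(mip)),
            species = species, fraction = frac, class = "ffa_vessel_mask")
}
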