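# Frequency-domain (phase-correlation) registration.
#
# Translation between two frames is the argmax of the inverse transform of
# the normalised cross-power spectrum, refined to sub-pixel precision by a
# local matrix-multiply DFT upsampling of the correlation surface. The
# confidence readout is the ratio of the main peak to the second-highest
# non-adjacent peak.

raised_cosine_window <- function(h, w) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(h) - 1) / (h - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(w) - 1) / (w - 1))
  outer(wr, wc)
}

# correlation surface values at fractional shifts via explicit DFT kernels
upsampled_correlation <- function(cp, shifts_y, shifts_x) {
  h <- nrow(cp); w <- ncol(cp)
  ky <- c(0:floor((h - 1) / 2), -(ceiling((h - 1) / 2):1))
  kx <- c(0:floor((w - 1) / 2), -(ceiling((w - 1) / 2):1))
  Ey <- exp(2i * pi * outer(shifts_y, ky) / h)    # n_y x h
  Ex <- exp(2i * pi * outer(kx, shifts_x) / w)    # w x n_x
  Re(Ey %*% cp %*% Ex) / (h * w)
}

#' Register two frames by phase correlation (translation only)
#'
#' @param reference,moving `ffa_frame`s of identical shape.
#' @param upsample Sub-pixel refinement factor (default 50).
#' @return List with `transform` (pure translation, moving -> reference),
#'   `peak_ratio` and the integer-peak `response`.
#' @export
register_frequency <- function(reference, moving, upsample = 50) {
  ref <- reference$pixels; mov <- moving$pixels
  if (!all(dim(ref) == dim(mov))) {
    abort("Frames must share a shape for registration.", class = "ffa_parameter_error")
  }
  h <- nrow(ref); w <- ncol(ref)
  win <- raised_cosine_window(h, w)
  fr <- stats::fft(ref * win)
  fm <- stats::fft(mov * win)
  cross <- fr * Conj(fm)
  mag <- Mod(cross)
  if (!any(mag > 1e-12)) {
    abort("Degenerate input: cross-power spectrum is zero.",
          class = "ffa_degenerate_input_error")
  }
  cp <- cross / pmax(mag, 1e-12)
  corr <- Re(stats::fft(cp, inverse = TRUE)) / (h * w)
  peak <- which.max(corr)
  py <- (peak - 1) %% h + 1
  px <- (peak - 1) %/% h + 1
  # wrap to signed shifts
  dy <- py - 1; if (dy > h / 2) dy <- dy - h
  dx <- px - 1; if (dx > w / 2) dx <- dx - w

  # peak_ratio: main peak vs second-highest outside a radius-2 neighbourhood
  corr2 <- corr
  for (oy in -2:2) for (ox in -2:2) {
    corr2[(py - 1 + oy) %% h + 1, (px - 1 + ox) %% w + 1] <- -Inf
  }
  second <- max(corr2)
  peak_ratio <- if (second > 1e-12) corr[peak] / second else Inf

  # sub-pixel refinement on a +/-1 px neighbourhood
  gy <- dy + seq(-1, 1, length.out = 2 * upsample + 1)
  gx <- dx + seq(-1, 1, length.out = 2 * upsample + 1)
  up <- upsampled_correlation(cp, gy, gx)
  im <- which(up == max(up), arr.ind = TRUE)[1, ]
  dy_sub <- gy[im[1]]; dx_sub <- gx[im[2]]

  # corr peak at shift (dy, dx) means ref(r, c) ~ mov(r - dy, c - dx):
  # moving -> reference coordinates is a translation by (dx, dy)
  list(transform = transform2d(tx = dx_sub, ty = dy_sub),
       peak_ratio = peak_ratio,
       response = corr[peak])
}
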