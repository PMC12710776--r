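# Internal helpers shared across modules.

#' Evaluate code under a fixed RNG state, restoring the caller's state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a base seed and a stream label, staying in
#' 32-bit integer range.
#' @noRd
child_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(parts)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483563
  as.integer(h + 1L)
}

stopifnot_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "ffa_parameter_error")
  }
  invisible(x)
}

#' Clamp values into [lo, hi].
#' @noRd
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Bilinear sampling of matrix `img` at (x, y) (col, row; 1-based pixel
#' centres). Points outside the support return NA.
#' @noRd
bilinear_sample <- function(img, x, y) {
  h <- nrow(img); w <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0;  fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 + 1 <= w & y0 + 1 <= h
  # clamp indices so the arithmetic stays vectorised; mask afterwards
  xc <- pmin(pmax(x0, 1L), w - 1L)
  yc <- pmin(pmax(y0, 1L), h - 1L)
  i00 <- (xc - 1) * h + yc
  v <- (1 - fx) * (1 - fy) * img[i00] +
    fx * (1 - fy) * img[i00 + h] +
    (1 - fx) * fy * img[i00 + 1] +
    fx * fy * img[i00 + h + 1]
  v[!ok] <- NA_real_
  v
}

#' Row/column pixel-centre coordinate grids for an h x w image.
#' @noRd
coord_grid <- function(h, w) {
  list(
    x = matrix(rep(seq_len(w), each = h), h, w),
    y = matrix(rep(seq_len(h), times = w), h, w)
  )
}

#' Separable Gaussian smoothing that treats borders by renormalising the
#' kernel mass inside the image (no dark halo at the frame edge).
#' @noRd
gauss_smooth <- function(img, sigma) {
  if (sigma <= 0) return(img)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  ones <- matrix(1, nrow(img), ncol(img))
  conv1 <- function(m) {
    # filter columns then rows with the 1-D kernel, zero-padded
    pad <- function(v) c(rep(0, r), v, rep(0, r))
    apply_k <- function(mat) {
      h <- nrow(mat)
      out <- matrix(0, h, ncol(mat))
      padded <- rbind(matrix(0, r, ncol(mat)), mat, matrix(0, r, ncol(mat)))
      for (j in seq_along(k)) {
        out <- out + k[j] * padded[j:(j + h - 1), , drop = FALSE]
      }
      out
    }
    t(apply_k(t(apply_k(mat = m))))
  }
  conv1(img) / conv1(ones)
}

#' Write a matrix (or H x W x 3 array) in [0,1] as PNG.
#' @noRd
write_png <- function(img, path) {
  png::writePNG(clamp(img), path)
  invisible(path)
}
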