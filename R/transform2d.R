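# Rigid/similarity transforms in the image plane.
#
# Convention: points are (x, y) = (column, row), 1-based pixel centres.
# A transform maps moving-frame coordinates into reference-frame
# coordinates:  p' = s * R(theta) * p + (tx, ty),
# with R a counter-clockwise rotation by `rotation` degrees about the origin.

#' Create a 2-D similarity (or pure translation) transform
#'
#' @param tx,ty Translation in pixels.
#' @param rotation Rotation in degrees, counter-clockwise, about the origin.
#' @param scale Isotropic scale factor; must lie in (0.5, 2).
#' @param kind `"translation"` or `"similarity"`.
#' @return An object of class `ffa_transform`.
#' @export
transform2d <- function(tx = 0, ty = 0, rotation = 0, scale = 1,
                        kind = if (rotation == 0 && scale == 1) "translation" else "similarity") {
  kind <- match.arg(kind, c("translation", "similarity"))
  vals <- c(tx = tx, ty = ty, rotation = rotation, scale = scale)
  if (any(!is.finite(vals))) {
    abort("Transform parameters must be finite.", class = "ffa_parameter_error")
  }
  if (scale <= 0.5 || scale >= 2) {
    abort(sprintf("Transform scale %.4f outside the admissible range (0.5, 2).", scale),
          class = "ffa_parameter_error")
  }
  if (kind == "translation" && (rotation != 0 || scale != 1)) {
    abort("A translation transform cannot carry rotation or scale.",
          class = "ffa_parameter_error")
  }
  structure(list(kind = kind, tx = tx, ty = ty, rotation = rotation, scale = scale),
            class = "ffa_transform")
}

#' @export
print.ffa_transform <- function(x, ...) {
  cat(sprintf("<ffa_transform %s: tx=%.3f ty=%.3f rot=%.3f deg scale=%.4f>\n",
              x$kind, x$tx, x$ty, x$rotation, x$scale))
  invisible(x)
}

#' Identity transform
#' @export
tf_identity <- function() transform2d(0, 0, 0, 1)

# complex-number representation: p' = a * p + b with a = s e^{i theta}
tf_to_ab <- function(tf) {
  th <- tf$rotation * pi / 180
  list(a = complex(modulus = tf$scale, argument = th),
       b = complex(real = tf$tx, imaginary = tf$ty))
}

tf_from_ab <- function(a, b, kind = "similarity") {
  transform2d(Re(b), Im(b), Arg(a) * 180 / pi, Mod(a), kind = kind)
}

#' Apply a transform to points
#'
#' @param tf An `ffa_transform`.
#' @param xy Two-column matrix (or length-2 vector) of (x, y) points.
#' @return Matrix of transformed points.
#' @export
tf_apply <- function(tf, xy) {
  if (is.null(dim(xy))) xy <- matrix(xy, ncol = 2)
  ab <- tf_to_ab(tf)
  z <- complex(real = xy[, 1], imaginary = xy[, 2]) * ab$a + ab$b
  cbind(x = Re(z), y = Im(z))
}

#' Compose two transforms: `tf_compose(a, b)` applies `b` first, then `a`.
#' @param a,b `ffa_transform` objects.
#' @export
tf_compose <- function(a, b) {
  aa <- tf_to_ab(a); bb <- tf_to_ab(b)
  kind <- if (a$kind == "translation" && b$kind == "translation") "translation" else "similarity"
  tf_from_ab(aa$a * bb$a, aa$a * bb$b + aa$b, kind = kind)
}

#' Invert a transform
#' @param tf An `ffa_transform`.
#' @export
tf_invert <- function(tf) {
  ab <- tf_to_ab(tf)
  tf_from_ab(1 / ab$a, -ab$b / ab$a, kind = tf$kind)
}

#' Re-express a rotation/scale about an image centre as an origin-form
#' similarity (helper for simulating motion about the optical axis).
#' @param rotation Degrees CCW about `center`.
#' @param scale Isotropic scale about `center`.
#' @param tx,ty Additional translation applied after the rotation.
#' @param center `(x, y)` pivot.
#' @export
tf_about_center <- function(rotation = 0, scale = 1, tx = 0, ty = 0, center) {
  th <- rotation * pi / 180
  a <- complex(modulus = scale, argument = th)
  c0 <- complex(real = center[1], imaginary = center[2])
  b <- c0 - a * c0 + complex(real = tx, imaginary = ty)
  tf_from_ab(a, b, kind = if (rotation == 0 && scale == 1) "translation" else "similarity")
}

#' Resample a frame through a transform
#'
#' Produces the moving image expressed in reference coordinates: each output
#' pixel `q` is sampled from the input at `tf_invert(tf)(q)` with bilinear
#' interpolation. Pixels that fall outside the input canvas are returned as
#' `NA` (invalid) so downstream statistics can ignore them.
#'
#' @param pixels Numeric matrix.
#' @param tf `ffa_transform` mapping input (moving) coordinates to output
#'   (reference) coordinates.
#' @param dim_out Output dimensions `c(h, w)`; defaults to the input shape.
#' @return Numeric matrix with `NA` marking invalid pixels.
#' @export
warp_frame <- function(pixels, tf, dim_out = dim(pixels)) {
  h <- dim_out[1]; w <- dim_out[2]
  g <- coord_grid(h, w)
  inv <- tf_invert(tf)
  src <- tf_apply(inv, cbind(as.vector(g$x), as.vector(g$y)))
  matrix(bilinear_sample(pixels, src[, 1], src[, 2]), h, w)
}

#' Least-squares similarity transform from point correspondences
#'
#' Solves `dst ~ s R src + t` in closed form via the complex-linear model
#' `w = a z + b`.
#'
#' @param src,dst Two-column matrices of corresponding (x, y) points.
#' @return An `ffa_transform`.
#' @export
fit_similarity <- function(src, dst) {
  z <- complex(real = src[, 1], imaginary = src[, 2])
  w <- complex(real = dst[, 1], imaginary = dst[, 2])
  zm <- mean(z); wm <- mean(w)
  zc <- z - zm
  denom <- sum(Mod(zc)^2)
  if (denom < 1e-12) {
    abort("Degenerate correspondence set for similarity fit.",
          class = "ffa_degenerate_error")
  }
  a <- sum(Conj(zc) * (w - wm)) / denom
  b <- wm - a * zm
  tf_from_ab(a, b)
}
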