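# FAST corner detection (Features from Accelerated Segment Test).
#
# A pixel p is a corner iff at least `arc_length` contiguous pixels on the
# radius-3 Bresenham circle of 16 pixels are all brighter than p + threshold
# or all darker than p - threshold. The corner score is the maximum threshold
# at which p remains a corner. Implemented with whole-image shifted matrices
# so the segment test runs vectorised over every pixel at once.

# radius-3 Bresenham circle, clockwise from 12 o'clock; (dx, dy) = (col, row)
FAST_CIRCLE <- cbind(
  dx = c(0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3, -3, -3, -2, -1),
  dy = c(-3, -3, -2, -1, 0, 1, 2, 3, 3, 3, 2, 1, 0, -1, -2, -3)
)

# shift a matrix by (dx, dy) with NA padding: result[r, c] = m[r + dy, c + dx]
shift_mat <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_real_, h, w)
  sr <- max(1, 1 + dy):min(h, h + dy)
  sc <- max(1, 1 + dx):min(w, w + dx)
  out[sr - dy, sc - dx] <- m[sr, sc]
  out
}

#' Detect FAST keypoints
#'
#' @param image Numeric intensity matrix (at least 7x7).
#' @param threshold Intensity delta for the segment test (> 0).
#' @param arc_length Required contiguous arc length, 9--12.
#' @param cap Maximum keypoints retained (default 15000); when more survive
#'   non-maximum suppression, the highest-scoring are kept with ties broken
#'   by row-major position.
#' @return Tibble with columns `x`, `y` (column/row pixel coordinates) and
#'   `score` (corner response).
#' @export
detect_fast <- function(image, threshold = 0.06, arc_length = 9L, cap = 15000L) {
  if (nrow(image) < 7 || ncol(image) < 7) {
    abort("Image must be at least 7x7 for FAST.", class = "ffa_size_error")
  }
  if (threshold <= 0) abort("`threshold` must be > 0.", class = "ffa_parameter_error")
  if (!(arc_length %in% 9:12)) {
    abort("`arc_length` must be between 9 and 12.", class = "ffa_parameter_error")
  }
  if (cap < 1) abort("`cap` must be >= 1.", class = "ffa_parameter_error")
  h <- nrow(image); w <- ncol(image)

  # per-offset differences circle[k] - center
  diffs <- vector("list", 16)
  for (k in 1:16) {
    diffs[[k]] <- shift_mat(image, FAST_CIRCLE[k, 1], FAST_CIRCLE[k, 2]) - image
  }

  # score_bright(p) = max over 16 arc starts of min over the arc of diffs;
  # score_dark analogous with -diffs
  arc_score <- function(ds) {
    acc <- matrix(-Inf, h, w)
    for (s in 1:16) {
      m <- ds[[s]]
      for (j in 1:(arc_length - 1)) {
        m <- pmin(m, ds[[(s + j - 1) %% 16 + 1]])
      }
      acc <- pmax(acc, m)
    }
    acc
  }
  score <- pmax(arc_score(diffs), arc_score(lapply(diffs, function(d) -d)))
  score[is.na(score) | is.infinite(score)] <- -Inf
  corner <- score > threshold

  # longest contiguous passing arc at the given threshold: secondary key for
  # suppression (a true corner supports a longer arc than an edge point)
  max_run <- function(bools) {
    run <- matrix(0, h, w); best <- matrix(0, h, w)
    for (k in 1:32) {
      b <- bools[[(k - 1) %% 16 + 1]]
      run <- ifelse(b, run + 1, 0)
      best <- pmax(best, run)
    }
    pmin(best, 16)
  }
  bright_ok <- lapply(diffs, function(d) !is.na(d) & d > threshold)
  dark_ok <- lapply(diffs, function(d) !is.na(d) & -d > threshold)
  arc_len <- pmax(max_run(bright_ok), max_run(dark_ok))

  # 3x3 non-maximum suppression on (score, arc length, row-major position)
  if (any(corner)) {
    keep <- corner
    g <- coord_grid(h, w)
    rank_rm <- (g$y - 1) * w + g$x  # row-major position, final tie-break
    for (dy in -1:1) for (dx in -1:1) {
      if (dx == 0 && dy == 0) next
      ns <- shift_mat(score, dx, dy)
      nl <- shift_mat(arc_len, dx, dy)
      nr <- shift_mat(rank_rm, dx, dy)
      ns[is.na(ns)] <- -Inf
      beat <- score > ns |
        (score == ns & arc_len > nl) |
        (score == ns & arc_len == nl & rank_rm < nr)
      beat[is.na(beat)] <- TRUE
      keep <- keep & beat
    }
    corner <- keep
  }

  idx <- which(corner)
  if (length(idx) == 0) {
    return(tibble::tibble(x = integer(), y = integer(), score = numeric()))
  }
  ys <- (idx - 1) %% h + 1
  xs <- (idx - 1) %/% h + 1
  sc <- score[idx]
  ord <- order(-sc, (ys - 1) * w + xs)
  ord <- ord[seq_len(min(cap, length(ord)))]
  tibble::tibble(x = xs[ord], y = ys[ord], score = sc[ord])
}
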