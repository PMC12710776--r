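# ORB-style oriented binary descriptors and keypoint registration.
#
# Each FAST keypoint receives an intensity-centroid orientation over a
# radius-15 patch and a 256-bit binary descriptor: intensity comparisons at a
# fixed sampling pattern rotated by the keypoint orientation. Matches (by
# Hamming distance with a best/second-best ratio gate) feed a seeded RANSAC
# similarity estimate refined by least squares on the inliers.

ORB_PATCH_RADIUS <- 15L
ORB_N_BITS <- 256L

# Fixed 256-pair sampling pattern. Generated once per session from a frozen
# seed so descriptors are identical across machines and runs.
orb_pattern <- function() {
  if (!is.null(the$orb_pattern)) return(the$orb_pattern)
  pat <- with_seed(60320L, {
    draw <- function() {
      v <- round(rnorm(ORB_N_BITS * 2, sd = ORB_PATCH_RADIUS / 2.5))
      clamp(v, -(ORB_PATCH_RADIUS - 2), ORB_PATCH_RADIUS - 2)
    }
    list(a = matrix(draw(), ncol = 2), b = matrix(draw(), ncol = 2))
  })
  the$orb_pattern <- pat
  pat
}

#' Intensity-centroid orientations for keypoints
#'
#' @param image Intensity matrix.
#' @param kp Keypoint tibble from [detect_fast()].
#' @return `kp` with an `angle` column (radians).
#' @noRd
orb_orientation <- function(image, kp) {
  r <- ORB_PATCH_RADIUS
  offs <- expand.grid(dx = -r:r, dy = -r:r)
  offs <- offs[offs$dx^2 + offs$dy^2 <= r^2, ]
  h <- nrow(image)
  angle <- numeric(nrow(kp))
  for (i in seq_len(nrow(kp))) {
    xs <- kp$x[i] + offs$dx
    ys <- kp$y[i] + offs$dy
    v <- image[(xs - 1) * h + ys]
    angle[i] <- atan2(sum(offs$dy * v), sum(offs$dx * v))
  }
  kp$angle <- angle
  kp
}

#' Oriented binary descriptors for keypoints
#'
#' @param image Intensity matrix (smoothed copy is taken internally).
#' @param kp Keypoints with orientation.
#' @return Logical matrix `n_bits x n_keypoints`.
#' @noRd
orb_describe <- function(image, kp) {
  sm <- gauss_smooth(image, sigma = 2)
  pat <- orb_pattern()
  n <- nrow(kp)
  desc <- matrix(FALSE, ORB_N_BITS, n)
  for (i in seq_len(n)) {
    ca <- cos(kp$angle[i]); sa <- sin(kp$angle[i])
    rot <- function(p) cbind(ca * p[, 1] - sa * p[, 2],
                             sa * p[, 1] + ca * p[, 2])
    pa <- rot(pat$a); pb <- rot(pat$b)
    va <- bilinear_sample(sm, kp$x[i] + pa[, 1], kp$y[i] + pa[, 2])
    vb <- bilinear_sample(sm, kp$x[i] + pb[, 1], kp$y[i] + pb[, 2])
    desc[, i] <- !is.na(va) & !is.na(vb) & va < vb
  }
  desc
}

# Hamming distances between two logical descriptor matrices (bits x n),
# computed with two BLAS products: d = a'(1-b) + (1-a)'b
hamming_all <- function(a, b) {
  am <- matrix(as.numeric(a), nrow(a))
  bm <- matrix(as.numeric(b), nrow(b))
  crossprod(am, 1 - bm) + crossprod(1 - am, bm)
}

#' Match descriptors by Hamming distance with a ratio test
#' @return Tibble with `idx_ref`, `idx_mov`, `distance`.
#' @noRd
orb_match <- function(desc_ref, desc_mov, ratio = 0.8) {
  d <- hamming_all(desc_ref, desc_mov)   # n_ref x n_mov
  best <- apply(d, 2, which.min)
  n_mov <- ncol(d)
  bd <- d[cbind(best, seq_len(n_mov))]
  second <- vapply(seq_len(n_mov), function(j) {
    col <- d[, j]; col[best[j]] <- Inf; min(col)
  }, numeric(1))
  keep <- bd < ratio * second
  tibble::tibble(idx_ref = best[keep], idx_mov = which(keep),
                 distance = bd[keep])
}

#' RANSAC similarity estimation from matched points
#' @noRd
ransac_similarity <- function(src, dst, iters = 2000, tol = 2, seed = 1L) {
  n <- nrow(src)
  best_inl <- logical(n)
  best_count <- 0L
  with_seed(seed, {
    for (it in seq_len(iters)) {
      pick <- sample.int(n, 2L)
      if (sum((src[pick[1], ] - src[pick[2], ])^2) < 4) next
      tf <- tryCatch(fit_similarity(src[pick, , drop = FALSE],
                                    dst[pick, , drop = FALSE]),
                     error = function(e) NULL)
      if (is.null(tf)) next
      proj <- tf_apply(tf, src)
      err <- sqrt(rowSums((proj - dst)^2))
      inl <- err < tol
      if (sum(inl) > best_count) {
        best_count <- sum(inl)
        best_inl <- inl
      }
    }
  })
  if (best_count < 10) {
    abort(sprintf("RANSAC found only %d inliers (< 10).", best_count),
          class = "ffa_no_consensus_error")
  }
  tf <- fit_similarity(src[best_inl, , drop = FALSE], dst[best_inl, , drop = FALSE])
  proj <- tf_apply(tf, src)
  err <- sqrt(rowSums((proj - dst)^2))
  inl <- err < tol
  tf <- fit_similarity(src[inl, , drop = FALSE], dst[inl, , drop = FALSE])
  err <- sqrt(rowSums((tf_apply(tf, src[inl, , drop = FALSE]) -
                         dst[inl, , drop = FALSE])^2))
  list(transform = tf, n_inliers = sum(inl), mean_residual = mean(err))
}

#' Register a moving frame to a reference by oriented keypoints
#'
#' FAST keypoints on both frames receive intensity-centroid orientations and
#' rotated binary descriptors; matches pass a Hamming best/second-best ratio
#' gate and a seeded RANSAC fits a similarity transform, refined by least
#' squares on the inliers.
#'
#' @param reference,moving `ffa_frame`s of identical shape, preprocessed.
#' @param params List of `fast_threshold`, `ratio`, `ransac_iters`,
#'   `inlier_tol`, `seed`, `max_keypoints` (descriptor budget after scoring).
#' @return List with `transform` (moving -> reference coordinates) and
#'   quality metrics `n_keypoints`, `n_matches`, `n_inliers`,
#'   `mean_residual`.
#' @export
register_keypoint <- function(reference, moving,
                              params = list()) {
  p <- utils::modifyList(
    list(fast_threshold = 0.04, ratio = 0.8, ransac_iters = 2000,
         inlier_tol = 2, seed = 1L, max_keypoints = 1200L),
    params
  )
  ref <- reference$pixels; mov <- moving$pixels
  if (!all(dim(ref) == dim(mov))) {
    abort("Frames must share a shape for registration.", class = "ffa_parameter_error")
  }
  border <- ORB_PATCH_RADIUS + 2L
  grab <- function(img) {
    kp <- detect_fast(img, threshold = p$fast_threshold, cap = 15000L)
    kp <- kp[kp$x > border & kp$x <= ncol(img) - border &
               kp$y > border & kp$y <= nrow(img) - border, ]
    head(kp, p$max_keypoints)
  }
  kp_r <- grab(ref); kp_m <- grab(mov)
  if (nrow(kp_r) < 50 || nrow(kp_m) < 50) {
    abort(sprintf("Too few keypoints for registration (%d reference, %d moving; need 50).",
                  nrow(kp_r), nrow(kp_m)),
          class = "ffa_insufficient_features_error")
  }
  kp_r <- orb_orientation(ref, kp_r); kp_m <- orb_orientation(mov, kp_m)
  d_r <- orb_describe(ref, kp_r); d_m <- orb_describe(mov, kp_m)
  matches <- orb_match(d_r, d_m, ratio = p$ratio)
  if (nrow(matches) < 10) {
    abort(sprintf("Only %d descriptor matches (< 10).", nrow(matches)),
          class = "ffa_no_consensus_error")
  }
  src <- cbind(kp_m$x[matches$idx_mov], kp_m$y[matches$idx_mov])
  dst <- cbind(kp_r$x[matches$idx_ref], kp_r$y[matches$idx_ref])
  fit <- ransac_similarity(src, dst, iters = p$ransac_iters,
                           tol = p$inlier_tol, seed = p$seed)
  list(transform = fit$transform,
       n_keypoints = min(nrow(kp_r), nrow(kp_m)),
       n_matches = nrow(matches),
       n_inliers = fit$n_inliers,
       mean_residual = fit$mean_residual)
}
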