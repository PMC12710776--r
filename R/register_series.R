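# Series-level registration: reference-frame choice, species-dispatched
# per-frame alignment, quality gating, and the maximum intensity projection.

#' Register every frame of a series to a reference frame
#'
#' The reference is the frame with the highest mean intensity inside the
#' field of view (the early bright phase carries the most structure). The
#' strategy is species-dispatched: keypoints (similarity transform) for
#' primates, phase correlation (translation) for rodents. Frames that fail
#' registration or miss the quality gates are flagged `excluded` with a
#' reason code and omitted from quantification; aligned frames are resampled
#' with bilinear interpolation and out-of-canvas pixels are marked invalid
#' (`NA`).
#'
#' @param series `ffa_series` (preprocessed frames).
#' @param strategy `"keypoint"`, `"frequency"` or `"auto"` (mouse ->
#'   frequency, nhp/human -> keypoint).
#' @param fov Optional logical FOV mask (defaults to full image).
#' @param params Registration parameters (see [study_config()]'s
#'   `registration` block): thresholds, RANSAC settings, `max_residual`
#'   (keypoint gate, px), `min_peak_ratio` (frequency gate).
#' @return List of class `ffa_registration`: `reference_index`, `report`
#'   (tibble: one row per frame with status, metrics, reason), `transforms`,
#'   `aligned` (list of matrices with `NA` invalid pixels), `fov`.
#' @export
register_series <- function(series, strategy = c("auto", "keypoint", "frequency"),
                            fov = NULL, params = list()) {
  strategy <- match.arg(strategy)
  if (strategy == "auto") {
    strategy <- if (series$key$species == "mouse") "frequency" else "keypoint"
  }
  p <- utils::modifyList(
    list(fast_threshold = 0.04, ratio = 0.8, ransac_iters = 2000,
         inlier_tol = 2, seed = 1L, max_residual = 3, min_peak_ratio = 1.5),
    params
  )
  frames <- series$frames
  n <- length(frames)
  if (n < 2) abort("Series must have at least 2 frames.", class = "ffa_series_error")
  dims <- vapply(frames, function(f) dim(f$pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    abort("All frames of a series must share a shape.", class = "ffa_parameter_error")
  }
  if (is.null(fov)) fov <- matrix(TRUE, nrow(frames[[1]]$pixels), ncol(frames[[1]]$pixels))

  mean_in_fov <- vapply(frames, function(f) mean(f$pixels[fov]), numeric(1))
  ref_idx <- which.max(mean_in_fov)
  reference <- frames[[ref_idx]]

  rows <- vector("list", n)
  transforms <- vector("list", n)
  for (i in seq_len(n)) {
    if (i == ref_idx) {
      transforms[[i]] <- tf_identity()
      rows[[i]] <- tibble::tibble(
        frame = i, t_acq = frames[[i]]$t_acq, status = "registered",
        reason = NA_character_, n_keypoints = NA_integer_,
        n_matches = NA_integer_, n_inliers = NA_integer_,
        mean_residual = 0, peak_ratio = NA_real_)
      next
    }
    res <- tryCatch(
      if (strategy == "keypoint") {
        r <- register_keypoint(reference, frames[[i]], params = p)
        if (r$mean_residual > p$max_residual) {
          abort(sprintf("Mean residual %.2f px exceeds %.2f px.",
                        r$mean_residual, p$max_residual),
                class = "ffa_poor_registration_error")
        }
        r
      } else {
        r <- register_frequency(reference, frames[[i]])
        if (r$peak_ratio < p$min_peak_ratio) {
          abort(sprintf("Peak ratio %.2f below %.2f.", r$peak_ratio,
                        p$min_peak_ratio),
                class = "ffa_poor_registration_error")
        }
        r
      },
      error = function(e) e
    )
    if (inherits(res, "error")) {
      reason <- if (inherits(res, "ffa_insufficient_features_error")) {
        "insufficient-features"
      } else if (inherits(res, "ffa_no_consensus_error")) {
        "no-consensus"
      } else if (inherits(res, "ffa_poor_registration_error")) {
        "poor-quality"
      } else if (inherits(res, "ffa_degenerate_input_error")) {
        "degenerate-input"
      } else {
        "error"
      }
      transforms[[i]] <- NULL
      rows[[i]] <- tibble::tibble(
        frame = i, t_acq = frames[[i]]$t_acq, status = "excluded",
        reason = reason, n_keypoints = NA_integer_, n_matches = NA_integer_,
        n_inliers = NA_integer_, mean_residual = NA_real_,
        peak_ratio = NA_real_)
      next
    }
    transforms[[i]] <- res$transform
    rows[[i]] <- tibble::tibble(
      frame = i, t_acq = frames[[i]]$t_acq, status = "registered",
      reason = NA_character_,
      n_keypoints = res$n_keypoints %||% NA_integer_,
      n_matches = res$n_matches %||% NA_integer_,
      n_inliers = res$n_inliers %||% NA_integer_,
      mean_residual = res$mean_residual %||% NA_real_,
      peak_ratio = res$peak_ratio %||% NA_real_)
  }
  report <- dplyr::bind_rows(rows)
  n_excluded <- sum(report$status == "excluded")
  if (n_excluded > n / 2) {
    abort(sprintf("Registration failed for series %s: %d of %d frames excluded.",
                  format(series$key), n_excluded, n),
          class = "ffa_registration_failure_error")
  }
  aligned <- vector("list", n)
  for (i in seq_len(n)) {
    if (report$status[i] != "registered") next
    aligned[[i]] <- if (i == ref_idx) {
      frames[[i]]$pixels
    } else {
      warp_frame(frames[[i]]$pixels, transforms[[i]])
    }
  }
  structure(list(key = series$key, reference_index = ref_idx, report = report,
                 transforms = transforms, aligned = aligned, fov = fov,
                 strategy = strategy),
            class = "ffa_registration")
}

#' @export
print.ffa_registration <- function(x, ...) {
  cat(sprintf("<ffa_registration %s (%s): reference frame %d, %d/%d registered>\n",
              format(x$key), x$strategy, x$reference_index,
              sum(x$report$status == "registered"), nrow(x$report)))
  invisible(x)
}

#' Maximum intensity projection over registered frames
#'
#' Per-pixel maximum across the aligned frames, ignoring invalid (`NA`)
#' pixels; a pixel invalid in every frame is set to 0.
#'
#' @param aligned List of aligned matrices (with `NA` invalid pixels), or an
#'   `ffa_registration`.
#' @return Intensity matrix with attribute `coverage` (number of frames
#'   contributing per pixel).
#' @export
max_intensity_projection <- function(aligned) {
  if (inherits(aligned, "ffa_registration")) aligned <- aligned$aligned
  aligned <- Filter(Negate(is.null), aligned)
  if (length(aligned) == 0) {
    abort("No registered frames to project.", class = "ffa_empty_series_error")
  }
  mip <- aligned[[1]]
  cov <- !is.na(mip)
  mip[is.na(mip)] <- -Inf
  for (m in aligned[-1]) {
    cov <- cov + !is.na(m)
    m[is.na(m)] <- -Inf
    mip <- pmax(mip, m)
  }
  none <- !is.finite(mip)
  mip[none] <- 0
  attr(mip, "coverage") <- cov
  mip
}
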