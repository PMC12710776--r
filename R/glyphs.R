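# Packaged digit-glyph atlas for burned-in timestamps.
#
# Hardware overlays stamp an mm:ss clock into a corner of the frame. Rather
# than a general OCR engine, timestamps are decoded by normalised
# cross-correlation against this fixed 5x7 digit atlas — the same atlas the
# synthetic renderer stamps with, so decoding is exact by construction and
# testable without clinical data.

GLYPH_ROWS <- list(
  "0" = c("01110", "10001", "10011", "10101", "11001", "10001", "01110"),
  "1" = c("00100", "01100", "00100", "00100", "00100", "00100", "01110"),
  "2" = c("01110", "10001", "00001", "00110", "01000", "10000", "11111"),
  "3" = c("11111", "00010", "00100", "00010", "00001", "10001", "01110"),
  "4" = c("00010", "00110", "01010", "10010", "11111", "00010", "00010"),
  "5" = c("11111", "10000", "11110", "00001", "00001", "10001", "01110"),
  "6" = c("00110", "01000", "10000", "11110", "10001", "10001", "01110"),
  "7" = c("11111", "00001", "00010", "00100", "01000", "01000", "01000"),
  "8" = c("01110", "10001", "10001", "01110", "10001", "10001", "01110"),
  "9" = c("01110", "10001", "10001", "01111", "00001", "00010", "01100"),
  ":" = c("00000", "00100", "00100", "00000", "00100", "00100", "00000")
)

#' Glyph atlas as a list of 0/1 matrices
#'
#' @param scale Integer pixel-replication factor (glyphs are 5x7 at scale 1).
#' @return Named list of binary matrices.
#' @export
glyph_atlas <- function(scale = 2L) {
  key <- paste0("atlas", scale)
  if (!is.null(the[[key]])) return(the[[key]])
  atlas <- lapply(GLYPH_ROWS, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.integer(strsplit(r, "")[[1]])))
    m[rep(seq_len(nrow(m)), each = scale), rep(seq_len(ncol(m)), each = scale)]
  })
  the[[key]] <- atlas
  atlas
}

#' Stamp an mm:ss timestamp into a frame corner
#'
#' @param pixels Frame matrix (modified copy returned).
#' @param seconds Time to render, shown as `sprintf("%02d:%02d", m, s)`.
#' @param atlas Glyph atlas from [glyph_atlas()].
#' @param origin `(row, col)` of the overlay's top-left corner.
#' @param fg,bg Foreground/background intensity of the stamp.
#' @return List with the stamped matrix and the overlay ROI
#'   (`row`, `col`, `height`, `width`).
#' @export
render_timestamp <- function(pixels, seconds, atlas = glyph_atlas(),
                             origin = c(6L, 6L), fg = 1, bg = 0) {
  txt <- sprintf("%02d:%02d", seconds %/% 60, round(seconds) %% 60)
  gh <- nrow(atlas[[1]]); gw <- ncol(atlas[[1]])
  gap <- max(1L, gw %/% 5)
  chars <- strsplit(txt, "")[[1]]
  width <- length(chars) * gw + (length(chars) - 1) * gap
  r0 <- origin[1]; c0 <- origin[2]
  pixels[r0:(r0 + gh - 1), c0:(c0 + width - 1)] <- bg
  cc <- c0
  for (ch in chars) {
    g <- atlas[[ch]]
    block <- pixels[r0:(r0 + gh - 1), cc:(cc + gw - 1)]
    pixels[r0:(r0 + gh - 1), cc:(cc + gw - 1)] <- ifelse(g == 1, fg, block)
    cc <- cc + gw + gap
  }
  list(pixels = pixels,
       roi = list(row = r0, col = c0, height = gh, width = width))
}

# normalised cross-correlation of one template at every valid offset of `img`
ncc_map <- function(img, tpl) {
  th <- nrow(tpl); tw <- ncol(tpl)
  H <- nrow(img) - th + 1; W <- ncol(img) - tw + 1
  if (H < 1 || W < 1) return(matrix(numeric(0), 0, 0))
  tplc <- tpl - mean(tpl)
  tnorm <- sqrt(sum(tplc^2))
  out <- matrix(NA_real_, H, W)
  n <- th * tw
  for (i in seq_len(H)) {
    for (j in seq_len(W)) {
      win <- img[i:(i + th - 1), j:(j + tw - 1)]
      wc <- win - mean(win)
      wnorm <- sqrt(sum(wc^2))
      out[i, j] <- if (wnorm < 1e-12 || tnorm < 1e-12) 0 else sum(wc * tplc) / (wnorm * tnorm)
    }
  }
  out
}

#' Decode a burned-in mm:ss timestamp by template matching
#'
#' Each glyph template is correlated across the overlay region; detections
#' above correlation `min_corr` are non-maximum suppressed, ordered
#' left-to-right and parsed as `mm:ss`. If at one location the best and
#' second-best glyph correlations are within `ambiguity_gap`, decoding aborts
#' with an ambiguity error rather than guessing.
#'
#' @param pixels Frame matrix.
#' @param roi Overlay region: list with `row`, `col`, `height`, `width`.
#' @param atlas Glyph atlas used for rendering.
#' @param min_corr Per-digit correlation floor (default 0.7).
#' @param ambiguity_gap Minimum separation between best and runner-up glyph.
#' @return Seconds post-injection (numeric).
#' @export
ocr_timestamp <- function(pixels, roi, atlas = glyph_atlas(),
                          min_corr = 0.7, ambiguity_gap = 0.02) {
  pad <- 2L
  r0 <- max(1L, roi$row - pad); c0 <- max(1L, roi$col - pad)
  r1 <- min(nrow(pixels), roi$row + roi$height - 1 + pad)
  c1 <- min(ncol(pixels), roi$col + roi$width - 1 + pad)
  win <- pixels[r0:r1, c0:c1]
  gw <- ncol(atlas[[1]])
  hits <- list()
  for (name in names(atlas)) {
    m <- ncc_map(win, atlas[[name]])
    idx <- which(m > min_corr, arr.ind = TRUE)
    if (nrow(idx)) {
      hits[[name]] <- tibble::tibble(glyph = name, row = idx[, 1],
                                     col = idx[, 2], corr = m[idx])
    }
  }
  hits <- dplyr::bind_rows(hits)
  if (nrow(hits) == 0) {
    abort("No glyphs decoded from overlay region.", class = "ffa_time_error")
  }
  # group detections by horizontal slot, keep the best glyph per slot
  hits <- dplyr::arrange(hits, .data$col, dplyr::desc(.data$corr))
  slots <- list()
  for (k in seq_len(nrow(hits))) {
    hit <- hits[k, ]
    placed <- FALSE
    for (s in seq_along(slots)) {
      if (abs(slots[[s]]$col[1] - hit$col) < gw %/% 2 + 1) {
        slots[[s]] <- dplyr::bind_rows(slots[[s]], hit)
        placed <- TRUE
        break
      }
    }
    if (!placed) slots[[length(slots) + 1]] <- hit
  }
  decode_slot <- function(sl) {
    sl <- dplyr::arrange(sl, dplyr::desc(.data$corr))
    best <- sl$glyph[1]
    rival <- sl[sl$glyph != best, , drop = FALSE]
    if (nrow(rival) && sl$corr[1] - rival$corr[1] < ambiguity_gap) {
      abort(sprintf("Ambiguous glyph: '%s' vs '%s' within %.3f correlation.",
                    best, rival$glyph[1], ambiguity_gap),
            class = "ffa_time_ambiguity_error")
    }
    tibble::tibble(glyph = best, col = sl$col[1])
  }
  decoded <- dplyr::bind_rows(lapply(slots, decode_slot))
  decoded <- dplyr::arrange(decoded, .data$col)
  txt <- paste(decoded$glyph, collapse = "")
  m <- regmatches(txt, regexec("^([0-9]{1,2}):([0-9]{2})$", txt))[[1]]
  if (length(m) != 3) {
    abort(sprintf("Overlay decoded to '%s', not an mm:ss timestamp.", txt),
          class = "ffa_time_error")
  }
  as.numeric(m[2]) * 60 + as.numeric(m[3])
}
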