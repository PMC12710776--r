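# Circadian leakage colour maps.
#
# The ETDRS rings are filled with a white-to-dark-red ramp scaled by the
# regional evening-versus-morning percent change: progressively darker red
# means greater vessel leakage in the evening; zero or negative change
# renders uncoloured. Output is a deterministic RGB raster with an embedded
# numeric legend (digits drawn from the packaged glyph atlas).

ramp_red <- function(frac) {
  # frac in [0,1]: white (0) to dark red (1)
  frac <- clamp(frac)
  cbind(r = 1 - 0.45 * frac, g = 1 - frac, b = 1 - frac)
}

draw_digits <- function(img, text, row, col, atlas = glyph_atlas(1L),
                        value = 0) {
  gh <- nrow(atlas[[1]]); gw <- ncol(atlas[[1]])
  cc <- col
  for (ch in strsplit(text, "")[[1]]) {
    g <- atlas[[ch]]
    if (is.null(g)) { cc <- cc + gw + 1; next }
    rows <- row:(row + gh - 1); cols <- cc:(cc + gw - 1)
    if (max(rows) <= dim(img)[1] && max(cols) <= dim(img)[2]) {
      for (k in 1:3) {
        plane <- img[, , k]
        block <- plane[rows, cols]
        block[g == 1] <- value
        plane[rows, cols] <- block
        img[, , k] <- plane
      }
    }
    cc <- cc + gw + 1
  }
  img
}

#' Render a circadian leakage colour map
#'
#' @param pct_by_region Named numeric vector of percent changes, names in
#'   `c("fovea", "parafovea", "perifovea", "extrafovea")` (missing regions
#'   render blank).
#' @param grid `ffa_etdrs_grid`.
#' @param max_pct Top of the colour ramp; defaults to the largest positive
#'   change (minimum 1) so the darkest red marks the leakiest region.
#' @param background Optional grayscale matrix (e.g. the MIP) under the
#'   rings.
#' @param path Optional PNG output path; rendering is deterministic, so two
#'   renders of identical input are byte-identical.
#' @return `h x w x 3` RGB array in `[0, 1]`.
#' @export
leakage_color_map <- function(pct_by_region, grid, max_pct = NULL,
                              background = NULL, path = NULL) {
  h <- grid$dim[1]; w <- grid$dim[2]
  legend_w <- 40L
  img <- array(1, dim = c(h, w + legend_w, 3))
  if (!is.null(background)) {
    for (k in 1:3) img[, seq_len(w), k] <- clamp(background)
  }
  pos <- pct_by_region[pct_by_region > 0]
  if (is.null(max_pct)) max_pct <- max(c(pos, 1), na.rm = TRUE)
  for (rname in intersect(names(pct_by_region), ETDRS_REGIONS)) {
    v <- pct_by_region[[rname]]
    if (is.na(v) || v <= 0) next
    mask <- etdrs_region_mask(grid, rname)
    col <- ramp_red(v / max_pct)
    for (k in 1:3) {
      plane <- img[, seq_len(w), k]
      plane[mask] <- col[k]
      img[, seq_len(w), k] <- plane
    }
  }
  # ring outlines
  g <- coord_grid(h, w)
  r <- sqrt((g$x - grid$center[1])^2 + (g$y - grid$center[2])^2)
  outline <- Reduce(`|`, lapply(grid$radii_px, function(rad) abs(r - rad) < 0.75))
  for (k in 1:3) {
    plane <- img[, seq_len(w), k]
    plane[outline] <- 0.25
    img[, seq_len(w), k] <- plane
  }
  # legend: vertical ramp with numeric ticks at 0 and max_pct
  bar_rows <- round(seq(0.15 * h, 0.85 * h))
  bar_cols <- (w + 8):(w + 20)
  fr <- rev(seq(0, 1, length.out = length(bar_rows)))
  col <- ramp_red(fr)
  for (k in 1:3) img[bar_rows, bar_cols, k] <- col[, k]
  img <- draw_digits(img, sprintf("%d", round(max_pct)),
                     row = bar_rows[1] - 2L, col = w + 23L)
  img <- draw_digits(img, "0", row = bar_rows[length(bar_rows)] - 5L,
                     col = w + 23L)
  if (!is.null(path)) png::writePNG(clamp(img), path)
  img
}
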