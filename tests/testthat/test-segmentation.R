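test_that("ETDRS grid converts standard diameters to pixel radii and partitions exactly", {
  grid <- build_etdrs_grid(c(512, 512), dim = c(1024, 1024), pixel_scale = 10)
  expect_equal(grid$radii_px, c(50, 150, 300))
  # every pixel belongs to exactly one region
  counts <- table(grid$region)
  expect_equal(sum(counts), 1024 * 1024)
  # ring counts equal the disk counts exactly
  g <- ffaquant:::coord_grid(1024, 1024)
  r <- sqrt((g$x - 512)^2 + (g$y - 512)^2)
  expect_equal(sum(grid$region == "fovea"), sum(r < 50))
  inner3 <- sum(grid$region %in% c("fovea", "parafovea", "perifovea"))
  expect_equal(inner3, sum(r < 300))
  # rasterized areas within 2% of the analytic annuli
  expect_lt(abs(sum(grid$region == "fovea") - pi * 50^2) / (pi * 50^2), 0.02)
  expect_lt(abs(sum(grid$region == "parafovea") - pi * (150^2 - 50^2)) /
              (pi * (150^2 - 50^2)), 0.02)
  expect_lt(abs(sum(grid$region == "perifovea") - pi * (300^2 - 150^2)) /
              (pi * (300^2 - 150^2)), 0.02)
})

test_that("grid placement and configuration errors are raised", {
  expect_error(build_etdrs_grid(c(30, 512), dim = c(1024, 1024), pixel_scale = 10),
               class = "ffa_grid_placement_error")
  expect_error(build_etdrs_grid(c(512, 512), dim = c(1024, 1024),
                                pixel_scale = 10, diameters_mm = c(3, 1, 6)),
               class = "ffa_parameter_error")
  expect_warning(
    grid <- build_etdrs_grid(c(128, 128), dim = c(256, 256), pixel_scale = NULL),
    class = "ffa_configuration_warning"
  )
  expect_true(grid$fallback)
  expect_equal(grid$radii_px, c(0.055, 0.165, 0.33) * 256)
})

test_that("vessel mask separates wide from thin vessels at large-vessel scales", {
  h <- 256; w <- 256
  segs <- tibble::tibble(
    x0 = c(40, seq(20, 236, by = 24)),
    y0 = c(128, rep(30, 10)),
    x1 = c(216, seq(20, 236, by = 24) + 6),
    y1 = c(128, rep(226, 10)),
    width = c(12, rep(2, 10)), depth = 1L)
  img <- ffaquant:::render_tubes(segs, h, w) * 0.8 + 0.1
  vm <- compute_vessel_mask(img, scales = c(5, 8), threshold = 0.98)
  cl <- centerline_points(segs)
  frac_masked <- function(pts) {
    idx <- cbind(pmin(pmax(round(pts$y), 1), h), pmin(pmax(round(pts$x), 1), w))
    mean(vm[idx])
  }
  expect_gte(frac_masked(cl[cl$width == 12, ]), 0.90)
  expect_lte(frac_masked(cl[cl$width == 2, ]), 0.05)
  expect_lte(attr(vm, "fraction"), 0.5)
})

test_that("vessel masking is empty (with a warning) on structureless input", {
  expect_warning(vm <- compute_vessel_mask(matrix(0.5, 128, 128)),
                 class = "ffa_masking_warning")
  expect_equal(sum(vm), 0)
})

test_that("region intensity extraction matches brute-force pixel accounting", {
  # minimal registration-like object around known frames
  key <- series_key("s01", "OS", "AM", "human")
  h <- 256; w <- 256
  grid <- build_etdrs_grid(c(128, 128), dim = c(h, w), pixel_scale = 40)
  fov <- matrix(TRUE, h, w)

  wrap_reg <- function(frames, times) {
    structure(list(
      key = key, reference_index = 1L,
      report = tibble::tibble(frame = seq_along(frames), t_acq = times,
                              status = "registered"),
      transforms = rep(list(tf_identity()), length(frames)),
      aligned = frames, fov = fov), class = "ffa_registration")
  }

  # constant field: every region mean is the constant
  rec <- extract_region_intensities(wrap_reg(list(matrix(0.4, h, w)), 30),
                                    grid = grid)
  expect_equal(rec$mean_intensity, rep(0.4, nrow(rec)))

  # indicator field: 1 inside the foveal disk, 0 elsewhere
  ind <- ifelse(etdrs_region_mask(grid, "fovea"), 1, 0)
  rec2 <- extract_region_intensities(wrap_reg(list(ind), 30), grid = grid)
  expect_equal(rec2$mean_intensity[rec2$region == "fovea"], 1)
  expect_equal(rec2$mean_intensity[rec2$region == "parafovea"], 0)

  # checkerboard: means match hand-counted pixel sums per region
  g <- ffaquant:::coord_grid(h, w)
  checker <- matrix(as.numeric((g$x + g$y) %% 2 == 0), h, w)
  vmask <- structure(matrix(FALSE, h, w), class = "ffa_vessel_mask")
  vmask[1:64, ] <- TRUE
  rec3 <- extract_region_intensities(wrap_reg(list(checker), 30), grid = grid,
                                     vessel_mask = vmask)
  for (rg in c("fovea", "parafovea", "perifovea", "extrafovea")) {
    sel <- etdrs_region_mask(grid, rg) & !vmask
    expect_equal(rec3$mean_intensity[rec3$region == rg],
                 sum(checker[sel]) / sum(sel))
    expect_equal(rec3$n_pixels[rec3$region == rg], sum(sel))
  }
  # all-regions aggregate is the pixel-weighted mean
  agg <- rec3[rec3$region == "all_regions", ]
  parts <- rec3[rec3$region != "all_regions", ]
  expect_equal(agg$mean_intensity,
               sum(parts$mean_intensity * parts$n_pixels) / sum(parts$n_pixels),
               tolerance = 1e-9)

  # enlarging the vessel mask never increases any region count
  vmask2 <- vmask; vmask2[1:96, ] <- TRUE
  rec4 <- extract_region_intensities(wrap_reg(list(checker), 30), grid = grid,
                                     vessel_mask = vmask2)
  joined <- merge(as.data.frame(rec3), as.data.frame(rec4), by = "region")
  expect_true(all(joined$n_pixels.y <= joined$n_pixels.x))

  # partition: region counts (minus extrafovea) equal disk(r3) minus exclusions
  r <- sqrt((g$x - 128)^2 + (g$y - 128)^2)
  disk3 <- r < grid$radii_px[3] & !vmask
  expect_equal(sum(parts$n_pixels[parts$region != "extrafovea"]), sum(disk3))
})

test_that("grid placement is equivariant to joint integer translation", {
  h <- 200; w <- 200
  set.seed(11)
  img <- ffaquant:::gauss_smooth(matrix(runif(h * w), h), 2)
  key <- series_key("s", "OS", "AM", "human")
  make_rec <- function(img, center) {
    grid <- build_etdrs_grid(center, dim = c(h, w), pixel_scale = 80)
    reg <- structure(list(
      key = key, reference_index = 1L,
      report = tibble::tibble(frame = 1L, t_acq = 30, status = "registered"),
      transforms = list(tf_identity()), aligned = list(img),
      fov = matrix(TRUE, h, w)), class = "ffa_registration")
    extract_region_intensities(reg, grid = grid)
  }
  base <- make_rec(img, c(100, 100))
  shifted_img <- matrix(0.5, h, w)
  shifted_img[11:h, 16:w] <- img[1:(h - 10), 1:(w - 15)]
  shifted <- make_rec(shifted_img, c(100 + 15, 100 + 10))
  # all_regions and extrafovea depend on the image border, which moves;
  # the three rings are fully determined by the jointly translated content
  inner <- base$region %in% c("fovea", "parafovea", "perifovea")
  expect_equal(shifted$mean_intensity[inner], base$mean_intensity[inner],
               tolerance = 1e-12)
})

test_that("fully occluded regions are omitted with a warning", {
  h <- 256; w <- 256
  grid <- build_etdrs_grid(c(128, 128), dim = c(h, w), pixel_scale = 40)
  vmask <- structure(etdrs_region_mask(grid, "fovea"), class = "ffa_vessel_mask")
  reg <- structure(list(
    key = series_key("s", "OS", "AM", "human"), reference_index = 1L,
    report = tibble::tibble(frame = 1L, t_acq = 30, status = "registered"),
    transforms = list(tf_identity()), aligned = list(matrix(0.5, h, w)),
    fov = matrix(TRUE, h, w)), class = "ffa_registration")
  expect_warning(
    rec <- extract_region_intensities(reg, grid = grid, vessel_mask = vmask),
    class = "ffa_occlusion_warning"
  )
  expect_false("fovea" %in% rec$region)
})
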