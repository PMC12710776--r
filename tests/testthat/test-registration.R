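test_that("FAST finds no corners in a constant image and validates inputs", {
  expect_equal(nrow(detect_fast(matrix(0.5, 64, 64))), 0)
  expect_error(detect_fast(matrix(0.5, 5, 5)), class = "ffa_size_error")
  expect_error(detect_fast(matrix(0.5, 64, 64), threshold = 0),
               class = "ffa_parameter_error")
  expect_error(detect_fast(matrix(0.5, 64, 64), arc_length = 8L),
               class = "ffa_parameter_error")
})

test_that("FAST locates the corners of a bright square within a pixel", {
  img <- matrix(0, 64, 64)
  img[30:34, 30:34] <- 1
  kp <- detect_fast(img, threshold = 0.1)
  true_corners <- rbind(c(30, 30), c(30, 34), c(34, 30), c(34, 34))
  for (i in seq_len(nrow(true_corners))) {
    d <- sqrt((kp$x - true_corners[i, 2])^2 + (kp$y - true_corners[i, 1])^2)
    expect_lte(min(d), sqrt(2))   # within 1 px in each direction
  }
  expect_lte(nrow(kp), 8)
})

test_that("FAST keypoint cap retains exactly the highest-scoring corners", {
  set.seed(20)
  noise <- matrix(runif(200 * 200), 200)
  all_kp <- detect_fast(noise, threshold = 0.01, cap = 10^7)
  expect_gt(nrow(all_kp), 500)
  capped <- detect_fast(noise, threshold = 0.01, cap = 500L)
  expect_equal(nrow(capped), 500L)
  expect_equal(capped$score, head(all_kp$score, 500))
})

test_that("keypoint registration is near-identity on self and recovers known motion", {
  sc <- make_scene_pair(31)
  self <- register_keypoint(sc$ref, sc$ref)
  expect_lt(sqrt(self$transform$tx^2 + self$transform$ty^2), 0.1)
  expect_lt(abs(self$transform$rotation), 0.05)
  expect_equal(self$transform$scale, 1, tolerance = 1e-3)

  tf <- tf_about_center(rotation = 3, tx = 12, ty = -7, center = c(96.5, 96.5))
  sc2 <- make_scene_pair(32, motion = tf)
  est <- register_keypoint(sc2$ref, sc2$mov)$transform
  truth <- tf_invert(tf)
  centre_err <- sqrt(sum((tf_apply(est, c(96.5, 96.5)) -
                            tf_apply(truth, c(96.5, 96.5)))^2))
  expect_lt(centre_err, 0.5)
  expect_lt(abs(est$rotation - truth$rotation), 0.2)
})

test_that("near-black frames raise insufficient-features", {
  sc <- make_scene_pair(33)
  dark <- new_frame(matrix(pmax(rnorm(192 * 192, 0.01, 0.002), 0), 192))
  expect_error(register_keypoint(sc$ref, dark),
               class = "ffa_insufficient_features_error")
})

test_that("phase correlation is exact on self and sub-pixel on known shifts", {
  sc <- make_scene_pair(34)
  self <- register_frequency(sc$ref, sc$ref)
  expect_equal(c(self$transform$tx, self$transform$ty), c(0, 0),
               tolerance = 1e-6)
  expect_gt(self$peak_ratio, 5)

  tf <- transform2d(tx = 5, ty = -3)
  sc2 <- make_scene_pair(35, motion = tf)
  est <- register_frequency(sc2$ref, sc2$mov)$transform
  expect_lt(abs(est$tx - (-5)), 0.25)
  expect_lt(abs(est$ty - 3), 0.25)

  expect_error(register_frequency(new_frame(matrix(0, 64, 64) + 0),
                                  new_frame(matrix(0, 64, 64))),
               class = "ffa_degenerate_input_error")
})

test_that("independent noise frames yield unreliable peak ratios", {
  prs <- vapply(1:25, function(s) {
    set.seed(s)
    a <- new_frame(matrix(runif(128 * 128), 128))
    b <- new_frame(matrix(runif(128 * 128), 128))
    register_frequency(a, b)$peak_ratio
  }, numeric(1))
  expect_lt(max(prs), 1.5)
})

test_that("series registration gates corrupt frames and aligns the rest", {
  key <- series_key("s01", "OS", "AM", "mouse")
  tree <- generate_vessel_tree(seed = 40, size = c(192, 192))
  tex <- background_texture(40, c(192, 192))
  kin <- kinetic_params()
  times <- seq(30, 240, by = 30)
  frames <- lapply(seq_along(times), function(i) {
    motion <- transform2d(tx = runif(1, -10, 10), ty = runif(1, -10, 10))
    f <- render_frame(times[i], tree, kin, motion = motion, texture = tex,
                      seed = 40 + i)$frame
    f$t_acq <- times[i]
    f
  })
  set.seed(41)
  # replace one frame by a blink (near-black)
  frames[[5]]$pixels <- matrix(pmax(rnorm(192 * 192, 0.01, 0.002), 0), 192)
  ser <- image_series(key, frames)
  reg <- register_series(ser, strategy = "frequency")
  expect_equal(sum(reg$report$status == "excluded"), 1)
  expect_equal(reg$report$status[5], "excluded")
  expect_true(all(reg$report$status[-5] == "registered"))
  expect_s3_class(reg$report, "tbl_df")
  # reference carries the identity
  ri <- reg$reference_index
  expect_equal(reg$transforms[[ri]]$tx, 0)

  # zero jitter: every transform is identity within tolerance
  frames0 <- lapply(seq_along(times), function(i) {
    f <- render_frame(times[i], tree, kin, texture = tex, seed = 80 + i)$frame
    f$t_acq <- times[i]
    f
  })
  reg0 <- register_series(image_series(key, frames0), strategy = "frequency")
  for (tf in reg0$transforms) {
    expect_lt(sqrt(tf$tx^2 + tf$ty^2), 0.2)
  }

  # a series that is mostly blinks fails outright
  for (i in c(2, 3, 4, 6, 7)) {
    frames[[i]]$pixels <- matrix(pmax(rnorm(192 * 192, 0.01, 0.002), 0), 192)
  }
  expect_error(register_series(image_series(key, frames), strategy = "frequency"),
               class = "ffa_registration_failure_error")
})

test_that("pairwise registrations compose consistently", {
  tree <- generate_vessel_tree(seed = 42, size = c(192, 192))
  tex <- background_texture(42, c(192, 192))
  kin <- kinetic_params()
  tf_b <- transform2d(tx = 6, ty = -4)
  tf_c <- transform2d(tx = -9, ty = 5)
  fa <- render_frame(40, tree, kin, texture = tex, seed = 1)$frame
  fb <- render_frame(40, tree, kin, motion = tf_b, texture = tex, seed = 2)$frame
  fc <- render_frame(40, tree, kin, motion = tf_c, texture = tex, seed = 3)$frame
  ab <- register_frequency(fb, fa)$transform   # a -> b coordinates
  bc <- register_frequency(fc, fb)$transform   # b -> c coordinates
  ac <- register_frequency(fc, fa)$transform   # a -> c directly
  composed <- tf_compose(bc, ab)
  pts <- cbind(runif(20, 40, 150), runif(20, 40, 150))
  err <- sqrt(rowSums((tf_apply(composed, pts) - tf_apply(ac, pts))^2))
  expect_lt(max(err), 1)
})

test_that("maximum intensity projection ignores invalid pixels and frame order", {
  a <- matrix(0.2, 32, 32); b <- matrix(0.5, 32, 32)
  expect_error(max_intensity_projection(list(NULL, NULL)),
               class = "ffa_empty_series_error")
  m <- max_intensity_projection(list(a, b))
  expect_equal(unique(as.vector(m)), 0.5)
  single <- max_intensity_projection(list(a))
  expect_equal(matrix(single, 32, 32), a, ignore_attr = TRUE)
  # disjoint bright spots: union
  s1 <- matrix(0, 32, 32); s1[5, 5] <- 1
  s2 <- matrix(0, 32, 32); s2[20, 20] <- 1
  mu <- max_intensity_projection(list(s1, s2))
  expect_equal(mu[5, 5], 1); expect_equal(mu[20, 20], 1)
  # permutation invariance, with NAs
  s1[1:3, ] <- NA
  m1 <- max_intensity_projection(list(s1, s2))
  m2 <- max_intensity_projection(list(s2, s1))
  expect_equal(matrix(m1, 32, 32), matrix(m2, 32, 32), ignore_attr = TRUE)
  # pixel invalid in all frames -> 0
  s2[1, 1] <- NA; s1[1, 1] <- NA
  expect_equal(max_intensity_projection(list(s1, s2))[1, 1], 0)
})
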