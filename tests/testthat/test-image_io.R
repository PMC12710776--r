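make_gradient <- function(h = 64, w = 64) {
  matrix(seq(0, 1, length.out = h * w), h, w)
}

test_that("decoding normalises by bit depth across containers", {
  tmp <- withr::local_tempdir()
  px <- make_gradient()
  px[1, 1] <- 1  # ensure max pixel maps to full scale

  p8 <- file.path(tmp, "a.png")
  png::writePNG(px, p8)
  fr <- read_frame(p8)
  expect_equal(max(fr$pixels), 1, tolerance = 1e-2)
  expect_true(all(fr$pixels >= 0 & fr$pixels <= 1))

  t16 <- file.path(tmp, "a.tif")
  tiff::writeTIFF(px, t16, bits.per.sample = 16L)
  fr16 <- read_frame(t16)
  expect_equal(fr16$pixels, px, tolerance = 1 / 65535)

  z <- file.path(tmp, "zero.tif")
  tiff::writeTIFF(matrix(0, 64, 64), z, bits.per.sample = 16L)
  expect_equal(max(read_frame(z)$pixels), 0)
})

test_that("frame writing round-trips pixels through 16-bit TIFF", {
  tmp <- withr::local_tempdir()
  fr <- new_frame(make_gradient(), t_acq = 90, dialect = "spectralis")
  path <- file.path(tmp, "rt.tif")
  write_frame(fr, path)
  back <- read_frame(path, dialect = "spectralis")
  expect_lt(max(abs(back$pixels - fr$pixels)), 1 / 65535)
})

test_that("colour input reduces to green channel under fundus dialects, mean otherwise", {
  tmp <- withr::local_tempdir()
  arr <- array(0, dim = c(64, 64, 3))
  arr[, , 1] <- 0.2; arr[, , 2] <- make_gradient(); arr[, , 3] <- 0.8
  jp <- file.path(tmp, "rgb.jpg")
  jpeg::writeJPEG(arr, jp, quality = 1)
  fr <- read_frame(jp, dialect = "spectralis")
  expect_equal(fr$pixels, make_gradient(), tolerance = 0.02)
  fr2 <- read_frame(jp, dialect = "generic")
  expect_equal(mean(fr2$pixels), mean((0.2 + make_gradient() + 0.8) / 3),
               tolerance = 0.02)
})

test_that("BMP and DICOM codecs round-trip synthetic frames", {
  tmp <- withr::local_tempdir()
  px <- make_gradient()
  bp <- file.path(tmp, "a.bmp")
  ffaquant:::write_bmp(px, bp)
  expect_equal(read_frame(bp)$pixels, px, tolerance = 1 / 255)

  dp <- file.path(tmp, "a.dcm")
  ffaquant:::write_dicom(px, dp, acquisition_time = "080130")
  fr <- read_frame(dp)
  expect_equal(fr$pixels, px, tolerance = 1 / 255)
  expect_equal(fr$meta$acquisition_time, "080130")
})

test_that("unsupported and corrupt files raise typed errors", {
  tmp <- withr::local_tempdir()
  bad <- file.path(tmp, "a.xyz")
  writeLines("nope", bad)
  expect_error(read_frame(bad), class = "ffa_format_error")
  corrupt <- file.path(tmp, "b.png")
  writeBin(as.raw(1:32), corrupt)
  expect_error(read_frame(corrupt), class = "ffa_decode_error")
  expect_error(read_frame(file.path(tmp, "missing.png")),
               class = "ffa_decode_error")
})

test_that("time recovery honours source order and reports failures", {
  fr <- new_frame(make_gradient(), source_path = "subj01_OS_AM_t090.png")
  out <- recover_time(fr, list(time_from_filename("t(\\d+)")))
  expect_equal(out$t_acq, 90)

  sidecar <- data.frame(filename = "frame_003.tif", seconds = 180)
  fr2 <- new_frame(make_gradient(), source_path = "frame_003.tif")
  out2 <- recover_time(fr2, list(time_from_filename("t(\\d+)"),
                                 time_from_sidecar(sidecar)))
  expect_equal(out2$t_acq, 180)
  expect_equal(out2$meta$time_source, "sidecar")

  # metadata beats filename when both present
  fr3 <- new_frame(make_gradient(), source_path = "x_t045.png",
                   meta = list(t_acq = 120))
  out3 <- recover_time(fr3, list(time_from_metadata(), time_from_filename()))
  expect_equal(out3$t_acq, 120)

  expect_error(recover_time(fr2, list(time_from_filename("t(\\d+)"))),
               class = "ffa_missing_time_error")
  expect_error(recover_time(fr, list()), class = "ffa_parameter_error")
})

test_that("DICOM acquisition time minus injection time yields seconds post-injection", {
  fr <- new_frame(make_gradient(), meta = list(acquisition_time = "080230"))
  out <- recover_time(fr, list(time_from_metadata(injection_time = "080000")))
  expect_equal(out$t_acq, 150)
})

test_that("burned-in timestamps decode by template matching, ambiguity is refused", {
  px <- matrix(0.3, 96, 96)
  st <- render_timestamp(px, 150)
  expect_equal(ocr_timestamp(st$pixels, st$roi), 150)
  # full round trip through recover_time
  fr <- new_frame(st$pixels)
  out <- recover_time(fr, list(time_from_overlay(st$roi)))
  expect_equal(out$t_acq, 150)
  # several times across the session
  for (s in c(30, 90, 305, 599)) {
    st2 <- render_timestamp(px, s)
    expect_equal(ocr_timestamp(st2$pixels, st2$roi), s)
  }
  # unreadable overlay: constant region has no glyphs
  expect_error(ocr_timestamp(px, st$roi), class = "ffa_time_error")
})

test_that("ingest groups frames into series, conserves files, rejects duplicates", {
  tmp <- withr::local_tempdir()
  for (sid in c("s01", "s02")) {
    for (session in c("AM", "PM")) {
      for (t in c(30, 60, 90)) {
        png::writePNG(make_gradient(),
                      file.path(tmp, sprintf("%s_OS_%s_t%03d.png", sid, session, t)))
      }
    }
  }
  cfg <- study_config(species = "mouse")
  res <- ingest_study(tmp, cfg)
  expect_length(res$series, 4)
  expect_true(all(vapply(res$series, function(s) length(s$frames), integer(1)) == 3))
  expect_true(file.exists(file.path(tmp, "ingest_manifest.json")))
  # conservation
  expect_equal(sum(res$manifest$disposition %in% c("ingested", "skipped")),
               nrow(res$manifest))

  # one unreadable file among them: skipped but everything else survives
  writeBin(as.raw(1:16), file.path(tmp, "s01_OS_AM_t120.png"))
  res2 <- ingest_study(tmp, cfg, write_manifest = FALSE)
  expect_equal(sum(res2$manifest$disposition == "skipped"), 1)
  expect_length(res2$series, 4)

  # duplicate (key, t): explicit error
  file.remove(file.path(tmp, "s01_OS_AM_t120.png"))
  dup_dir <- file.path(tmp, "sub")
  dir.create(dup_dir)
  png::writePNG(make_gradient(), file.path(dup_dir, "s01_OS_AM_t030.png"))
  expect_error(ingest_study(tmp, cfg, write_manifest = FALSE),
               class = "ffa_duplicate_frame_error")
})

test_that("frames sort by time and series need two timed frames", {
  key <- series_key("s01", "OS", "AM", "mouse")
  frames <- lapply(c(90, 30, 60), function(t) {
    new_frame(make_gradient(), t_acq = t, source_path = sprintf("t%d.png", t))
  })
  ser <- image_series(key, frames)
  expect_equal(vapply(ser$frames, function(f) f$t_acq, numeric(1)),
               c(30, 60, 90))
  expect_error(image_series(key, frames[1]), class = "ffa_series_error")
})

test_that("recovered times do not depend on discovery order", {
  tmp <- withr::local_tempdir()
  times <- c(30, 60, 90, 120)
  for (t in times) {
    png::writePNG(make_gradient(),
                  file.path(tmp, sprintf("s01_OS_AM_t%03d.png", t)))
  }
  res <- ingest_study(tmp, study_config(), write_manifest = FALSE)
  got <- vapply(res$series[[1]]$frames, function(f) f$t_acq, numeric(1))
  expect_equal(got, sort(times))
})
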