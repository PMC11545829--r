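test_that("DICOM round trip applies the rescale calibration and sorts by position", {
  d <- withr::local_tempdir()
  px <- matrix(1024, 8, 8)
  write_dicom_slice(px, file.path(d, "s.dcm"), slope = 1, intercept = -1024)
  img <- read_dicom_series(d)
  expect_true(img$is_hu)
  expect_equal(unname(img$pixels[1, 1]), 0)

  # several (slope, intercept) pairs on generated fixtures
  for (cal in list(c(1, -1024), c(2, -2048), c(0.5, 100))) {
    d2 <- withr::local_tempdir()
    set.seed(5)
    raw <- matrix(sample(0:3000, 36), 6, 6)
    write_dicom_slice(raw, file.path(d2, "x.dcm"), slope = cal[1], intercept = cal[2])
    got <- read_dicom_series(d2)
    expect_equal(got$pixels, cal[1] * raw + cal[2])
  }

  # shuffled filenames, increasing positions -> slices ordered by position
  d3 <- withr::local_tempdir()
  set.seed(6)
  slices <- lapply(1:3, function(i) matrix(sample(0:500, 16), 4, 4))
  write_dicom_slice(slices[[3]], file.path(d3, "a.dcm"), position_z = 7.5)
  write_dicom_slice(slices[[1]], file.path(d3, "z.dcm"), position_z = 2.5)
  write_dicom_slice(slices[[2]], file.path(d3, "m.dcm"), position_z = 5.0)
  vol <- read_dicom_series(d3)
  expect_equal(dim(vol$pixels)[3], 3)
  for (i in 1:3) expect_equal(vol$pixels[, , i], slices[[i]] - 1024)
  expect_equal(vol$spacing_mm[3], 2.5)
})

test_that("DICOM reader rejects empty and unreadable inputs with typed errors", {
  expect_error(read_dicom_series(file.path(tempdir(), "nope-dir")),
               class = "lungscreen_io_error")
  d <- withr::local_tempdir()
  expect_error(read_dicom_series(d), class = "lungscreen_io_error")
  writeLines("not dicom at all", file.path(d, "junk.txt"))
  expect_error(read_dicom_series(d), class = "lungscreen_format_error")
})

test_that("2D raster reading round-trips and converts color to luminance", {
  f <- withr::local_tempfile(fileext = ".png")
  write_image2d(matrix(7, 10, 12), f)
  img <- read_image2d(f)
  expect_false(img$is_hu)
  expect_true(all(img$pixels == 7))

  set.seed(3)
  x <- matrix(sample(0:255, 64 * 64, TRUE), 64, 64)
  write_image2d(x, f)
  expect_equal(read_image2d(f)$pixels, x)

  frgb <- withr::local_tempfile(fileext = ".png")
  png::writePNG(array(runif(5 * 5 * 3), c(5, 5, 3)), frgb)
  expect_warning(rgb <- read_image2d(frgb), "luminance")
  expect_equal(length(dim(rgb$pixels)), 2)

  expect_error(read_image2d("no/such/file.png"), class = "lungscreen_io_error")
})

test_that("display rescaling is a monotone window map with optional tone curve", {
  expect_error(rescale_for_display(matrix(0, 2, 2), window_width = 0),
               class = "lungscreen_parameter_error")
  expect_true(all(rescale_for_display(matrix(5, 3, 3)) ==
                  rescale_for_display(matrix(5, 3, 3))[1]))
  # window equal to [min, max], linear: affine map with endpoints 0 and 255
  x <- matrix(seq(-1000, 400, length.out = 50), 5, 10)
  got <- rescale_for_display(x, window_center = -300, window_width = 1400)
  expect_equal(min(got), 0)
  expect_equal(max(got), 255)
  expect_equal(got, (x + 1000) / 1400 * 255)
  # inverse-log tone curve on a linear ramp
  r <- matrix(seq(0, 1, length.out = 11), 1)
  toned <- rescale_for_display(r, window_center = 0.5, window_width = 1,
                               inverse_log = TRUE, base = 10)
  expect_equal(toned, (10^r - 1) / 9 * 255)
  # monotone non-decreasing for random windows
  set.seed(8)
  for (i in 1:5) {
    v <- sort(runif(20, -1000, 1000))
    out <- rescale_for_display(matrix(v, 1), window_center = runif(1, -500, 500),
                               window_width = runif(1, 10, 2000))
    expect_true(all(diff(as.vector(out)) >= 0))
  }
})

test_that("candidate CSV round-trips field-wise", {
  f <- withr::local_tempfile(fileext = ".csv")
  empty <- measure_candidates(structure(array(0L, c(4, 4)), n_components = 0L),
                              matrix(0, 4, 4), matrix(0, 4, 4))
  write_candidates_csv(empty, f)
  expect_equal(length(readLines(f)), 1)

  one <- data.frame(id = 1, x_mm = 1.5, y_mm = 2.5, z_mm = 0, area_mm2 = 80,
                    volume_mm3 = 0, elongation = 1.25, overlap = 1,
                    solid = TRUE, score = 0.8)
  write_candidates_csv(one, f)
  expect_equal(length(readLines(f)), 2)

  set.seed(4)
  many <- data.frame(id = 1:10, x_mm = runif(10, 0, 250), y_mm = runif(10, 0, 250),
                     z_mm = 0, area_mm2 = runif(10, 10, 700), volume_mm3 = 0,
                     elongation = runif(10, 1, 3), overlap = runif(10),
                     solid = sample(c(TRUE, FALSE), 10, TRUE), score = runif(10))
  write_candidates_csv(many, f)
  back <- read_candidates_csv(f)
  for (cl in c("x_mm", "y_mm", "area_mm2", "elongation", "overlap", "score"))
    expect_equal(back[[cl]], many[[cl]], tolerance = 1e-6)
  expect_identical(back$solid, many$solid)

  expect_error(write_candidates_csv(many, file.path(tempdir(), "no", "dir", "x.csv")),
               class = "lungscreen_io_error")
})

test_that("ct_image validates pixel and spacing invariants", {
  expect_error(ct_image(matrix(c(1, NA), 1, 2)), class = "lungscreen_format_error")
  expect_error(ct_image(matrix(1, 2, 2), spacing_mm = c(1, -1)),
               class = "lungscreen_parameter_error")
  expect_error(ct_image(array(1, c(2, 2, 2, 2))), class = "lungscreen_format_error")
  img <- ct_image(array(0, c(4, 5, 6)), spacing_mm = c(1, 1, 2))
  expect_equal(dim(img), c(4, 5, 6))
})
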