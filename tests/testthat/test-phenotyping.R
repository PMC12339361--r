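test_that("z-collapse is the pixelwise mean", {
  one <- matrix(1:9, 3)
  expect_identical(collapse_z(list(one)), one * 1)
  expect_equal(collapse_z(list(2 * one, matrix(0, 3, 3))), one)
  withr::with_seed(4, {
    planes <- lapply(1:3, function(i) matrix(rnorm(16), 4))
  })
  expect_equal(collapse_z(planes),
               (planes[[1]] + planes[[2]] + planes[[3]]) / 3)
  expect_error(collapse_z(list(one, matrix(0, 2, 2))), "shape")
})

test_that("local background subtraction removes flats and keeps impulses", {
  p <- pipeline_params()
  expect_true(all(local_background_subtract(matrix(7, 96, 96), p) == 0))

  img <- matrix(20, 96, 96)
  img[48, 48] <- 520                           # impulse of height 500
  out <- local_background_subtract(img, p)
  expect_equal(out[48, 48], 500, tolerance = 0.1 * 500)
  expect_lt(mean(out[img == 20]), 1e-9)

  ramp <- matrix(rep(seq(0, 100, length.out = 96), each = 96), 96)
  rout <- local_background_subtract(ramp, p)
  expect_true(all(rout >= 0))
  expect_true(all(rout <= ramp + 1e-9))        # never increases a pixel
})

test_that("background subtraction matches a literal re-implementation", {
  withr::with_seed(8, img <- matrix(rexp(64 * 80, 1 / 50), 64, 80))
  p <- pipeline_params()
  got <- local_background_subtract(img, p)
  # direct oracle: loop over full-resolution pixels
  ds <- nisseq:::block_downsample(img, 8L)
  want <- img
  for (r in seq_len(64)) {
    for (cc in seq_len(80)) {
      br <- (r - 1) %/% 8 + 1; bc <- (cc - 1) %/% 8 + 1
      rr <- max(1, br - 4):min(nrow(ds), br + 4)
      cs <- max(1, bc - 4):min(ncol(ds), bc + 4)
      want[r, cc] <- max(img[r, cc] - min(ds[rr, cs]), 0)
    }
  }
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("translocation correlation separates planted localisations", {
  cells <- label_image_from_points(rows = c(40, 40), cols = c(40, 110),
                                   radius = 18, dim = c(80L, 150L))
  nuclear <- matrix(0, 80, 150)
  nuclear <- nisseq:::add_gaussian(nuclear, 40, 40, 6, 100)
  nuclear <- nisseq:::add_gaussian(nuclear, 40, 110, 6, 100)
  expect_equal(translocation_score(cells, nuclear,
                                   nuclear)$translocation_r, c(1, 1),
               ignore_attr = TRUE)
  # anti-correlated reporter
  anti <- max(nuclear) - nuclear
  expect_true(all(translocation_score(cells, nuclear,
                                      anti)$translocation_r < 0))
  # translocated cell (reporter = nuclear pattern) vs cytosolic cell
  # (reporter = ring)
  reporter <- matrix(0, 80, 150)
  reporter <- nisseq:::add_gaussian(reporter, 40, 40, 6, 100)  # nuclear
  reporter <- nisseq:::add_gaussian(reporter, 40, 110, 14, 100)
  reporter <- nisseq:::add_gaussian(reporter, 40, 110, 6, -90) # ring
  ts <- translocation_score(cells, nuclear, pmax(reporter, 0))
  expect_gt(ts$translocation_r[1], ts$translocation_r[2])
  # affine invariance of the metric
  ts2 <- translocation_score(cells, nuclear, pmax(reporter, 0) * 3 + 17)
  expect_equal(ts$translocation_r, ts2$translocation_r, tolerance = 1e-9)
  # degenerate: flat reporter has no defined correlation
  flat <- translocation_score(cells, nuclear, matrix(5, 80, 150))
  expect_true(all(is.na(flat$translocation_r)))
})

test_that("speck ratio separates punctate from diffuse cells", {
  p <- pipeline_params(expression_percentile = 0)
  cells <- label_image_from_points(rows = c(50, 50), cols = c(50, 150),
                                   radius = 20, dim = c(100L, 200L))
  flat <- matrix(0, 100, 200)
  flat <- nisseq:::add_gaussian(flat, 50, 50, 25, 200)
  flat <- nisseq:::add_gaussian(flat, 50, 150, 25, 200)
  specked <- nisseq:::add_gaussian(flat, 50, 150, 1.2, 8000)
  s <- speck_score(cells, specked, p)
  expect_gt(s$speck_ratio[2], 10 * max(s$speck_ratio[1], 1e-3))
  # invariance under reporter rescaling
  s2 <- speck_score(cells, specked * 5, p)
  expect_equal(s$speck_ratio, s2$speck_ratio, tolerance = 1e-9)
})

test_that("speck populations are perfectly ranked on noiseless scenes", {
  n_side <- 4L
  centers <- expand.grid(row = seq(40, 280, by = 80),
                         col = seq(40, 280, by = 80))
  cells <- label_image_from_points(centers$row, centers$col, radius = 25,
                                   dim = c(320L, 320L))
  img <- matrix(0, 320, 320)
  specked <- rep(c(TRUE, FALSE), length.out = nrow(centers))
  for (i in seq_len(nrow(centers))) {
    img <- nisseq:::add_gaussian(img, centers$row[i], centers$col[i], 28, 150)
    if (specked[i]) {
      img <- nisseq:::add_gaussian(img, centers$row[i] + 5,
                                   centers$col[i] - 3, 1.2, 1500)
    }
  }
  s <- speck_score(cells, img, pipeline_params(expression_percentile = 0))
  # AUROC = 1: every specked cell outranks every clean cell
  expect_gt(min(s$speck_ratio[specked]), max(s$speck_ratio[!specked]))
})

test_that("low-expression cells are flagged for exclusion", {
  cells <- label_image_from_points(rows = c(30, 30, 30), cols = c(30, 90, 150),
                                   radius = 10, dim = c(60L, 180L))
  img <- matrix(0, 60, 180)
  img <- nisseq:::add_gaussian(img, 30, 30, 12, 500)
  img <- nisseq:::add_gaussian(img, 30, 90, 12, 480)
  img <- nisseq:::add_gaussian(img, 30, 150, 12, 5)    # dim cell
  s <- speck_score(cells, img, pipeline_params(expression_percentile = 40))
  expect_identical(s$excluded_low_expression, c(FALSE, FALSE, TRUE))
})
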