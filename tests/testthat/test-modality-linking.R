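test_that("identical images at one stage position pair with zero shift", {
  set.seed(3)
  img <- matrix(runif(256 * 256), 256)
  p <- pipeline_params()
  pheno <- tibble::tibble(fov = "p1", image = list(img),
                          stage_x = 0, stage_y = 0)
  nis <- tibble::tibble(fov = c("n1", "n2"),
                        image = list(img, matrix(runif(256 * 256), 256)),
                        stage_x = c(0, 5000), stage_y = c(0, 0))
  pr <- pair_fovs(pheno, nis, p)
  expect_equal(pr$nis_fov, "n1")
  expect_equal(c(pr$dy, pr$dx), c(0L, 0L))
  expect_gt(pr$corr, 0.9)
})

test_that("a downscaled, shifted phenotype image maps back within 2 px", {
  lib <- toy_library(n = 8L, L = 8L)
  cfg <- sim_config(dim = c(512L, 512L), n_nuclei = 40L, n_cycles = 1L,
                    noise_sd = 10, seed = 6L)
  scene <- render_nis_scene(lib, cfg)
  nis_img <- scene$stack$cycles[[1]]$nuclear
  # phenotype modality at half resolution (e.g. x10 vs x20), field moved
  shifted <- nisseq:::shift_image(nis_img, 16, -8)
  ph_img <- nisseq:::block_downsample(shifted, 2L)
  p <- pipeline_params(pixel_size_um = c(nis = 0.325, pheno = 0.65))
  pr <- pair_fovs(tibble::tibble(fov = "p", image = list(ph_img),
                                 stage_x = 0, stage_y = 0),
                  tibble::tibble(fov = "n", image = list(nis_img),
                                 stage_x = 0, stage_y = 0), p)
  expect_equal(pr$scale, 2)
  # the recorded shift maps phenotype coordinates into the sequencing
  # frame, i.e. it undoes the planted (16, -8) displacement
  expect_lte(abs(pr$dy - (-16)), 2)
  expect_lte(abs(pr$dx - 8), 2)
  # consistency check: a nucleus at (r, c) in the shifted phenotype frame
  # lands on its sequencing position under the recorded transform
  r_ph <- (200 + 16) / 2; c_ph <- (300 - 8) / 2
  expect_lte(abs(r_ph * pr$scale + pr$dy - 200), 2)
  expect_lte(abs(c_ph * pr$scale + pr$dx - 300), 2)
})

test_that("candidate order does not change the chosen pair", {
  set.seed(9)
  imgs <- lapply(1:3, function(i) matrix(runif(128 * 128), 128))
  p <- pipeline_params()
  pheno <- tibble::tibble(fov = "p", image = imgs[2],
                          stage_x = 0, stage_y = 0)
  for (ord in list(1:3, 3:1, c(2, 1, 3))) {
    nis <- tibble::tibble(fov = paste0("n", ord), image = imgs[ord],
                          stage_x = 0, stage_y = 0)
    expect_equal(pair_fovs(pheno, nis, p)$nis_fov, "n2")
  }
})

test_that("out-of-range phenotype fields are reported unpaired", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64)
  p <- pipeline_params()
  pr <- pair_fovs(tibble::tibble(fov = "p", image = list(img),
                                 stage_x = 0, stage_y = 0),
                  tibble::tibble(fov = "n", image = list(img),
                                 stage_x = 9000, stage_y = 0), p)
  expect_true(is.na(pr$nis_fov))
})

identity_pair <- tibble::tibble(pheno_fov = "p", nis_fov = "n", scale = 1,
                                dy = 0L, dx = 0L, corr = 1)

test_that("identical nuclei match one-to-one at distance zero", {
  li <- label_image_from_points(rows = c(40, 100, 160),
                                cols = c(40, 100, 160),
                                radius = 10, dim = c(200L, 200L))
  m <- match_nuclei(li, li, identity_pair, pipeline_params())
  expect_equal(nrow(m), 3L)
  expect_equal(m$distance_um, rep(0, 3))
  expect_equal(m$pheno_label, m$nis_label)
  expect_false(any(duplicated(m$nis_label)))
})

test_that("the 11.1 um movement gate rejects a 12 um displacement", {
  p <- pipeline_params()                       # 0.325 um/px
  px12 <- 12 / 0.325
  nis <- label_image_from_points(rows = 100, cols = 100, radius = 10,
                                 dim = c(220L, 220L))
  near <- label_image_from_points(rows = 100 + 10 / 0.325, cols = 100,
                                  radius = 10, dim = c(220L, 220L))
  far <- label_image_from_points(rows = 100 + px12, cols = 100,
                                 radius = 10, dim = c(220L, 220L))
  expect_equal(nrow(match_nuclei(near, nis, identity_pair, p)), 1L)
  expect_equal(nrow(match_nuclei(far, nis, identity_pair, p)), 0L)
})

test_that("the two-fold area gate rejects size-mismatched nuclei", {
  p <- pipeline_params()
  nis <- label_image_from_points(rows = 60, cols = 60, radius = 10,
                                 dim = c(120L, 120L))
  small <- label_image_from_points(rows = 60, cols = 60, radius = 6,
                                   dim = c(120L, 120L))
  expect_equal(nrow(match_nuclei(small, nis, identity_pair, p)), 0L)
  # but magnification is corrected first: the same small nuclei at
  # half-resolution (scale 2 -> area x4) match a radius-12 partner
  nis2 <- label_image_from_points(rows = 120, cols = 120, radius = 12,
                                  dim = c(240L, 240L))
  pair2 <- dplyr::mutate(identity_pair, scale = 2)
  expect_equal(nrow(match_nuclei(small, nis2, pair2, p)), 1L)
})

test_that("duplicate claims exclude every nucleus involved", {
  p <- pipeline_params()
  # two phenotype nuclei both nearest to the single nis nucleus
  ph <- label_image_from_points(rows = c(95, 105), cols = c(100, 100),
                                radius = 8, dim = c(200L, 200L))
  nis <- label_image_from_points(rows = 100, cols = 100, radius = 8,
                                 dim = c(200L, 200L))
  expect_equal(nrow(match_nuclei(ph, nis, identity_pair, p)), 0L)
  # a phenotype nucleus with two near-equidistant nis partners is ambiguous
  ph2 <- label_image_from_points(rows = 100, cols = 100, radius = 8,
                                 dim = c(200L, 200L))
  nis2 <- label_image_from_points(rows = c(95, 106), cols = c(100, 100),
                                  radius = 8, dim = c(200L, 200L))
  expect_equal(nrow(match_nuclei(ph2, nis2, identity_pair, p)), 0L)
})

test_that("jittered scenes recover essentially all true pairs", {
  lib <- toy_library(n = 10L, L = 8L)
  cfg <- sim_config(dim = c(512L, 512L), n_nuclei = 50L, n_cycles = 1L,
                    noise_sd = 0, seed = 12L)
  scene <- render_nis_scene(lib, cfg)
  nis_li <- label_image_from_points(scene$nuclei$row, scene$nuclei$col,
                                    scene$nuclei$radius_px,
                                    dim = c(512L, 512L))
  p <- pipeline_params()
  withr::with_seed(13, {
    ang <- runif(50, 0, 2 * pi)
    rad <- 5 * sqrt(runif(50)) / 0.325        # <= 5 um jitter
  })
  ph_li <- label_image_from_points(scene$nuclei$row + rad * sin(ang),
                                   scene$nuclei$col + rad * cos(ang),
                                   scene$nuclei$radius_px,
                                   dim = c(512L, 512L))
  m <- match_nuclei(ph_li, nis_li, identity_pair, p)
  expect_gte(nrow(m), 49L)
  expect_true(all(m$pheno_label == m$nis_label))  # no false pairs
})
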