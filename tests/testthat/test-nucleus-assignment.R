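# Hand-built scene: two disc nuclei, spots placed by hand. Intensities are
# encoded in 1x3 "unmixed" matrices so total spot intensity is their
# positive sum.
make_spot <- function(row, col, status, guide, gene = "G",
                      intensity = 1e6) {
  tibble::tibble(
    spot_id = NA_integer_, row = row, col = col,
    unmixed = list(matrix(c(intensity, 0, 0), 1, 3)),
    max_unmixed = intensity, status = status,
    guide_id = if (status %in% c("exact", "corrected")) guide
               else NA_character_,
    gene = if (status %in% c("exact", "corrected")) gene
           else NA_character_)
}

two_nuclei <- label_image_from_points(rows = c(30, 30), cols = c(30, 90),
                                      radius = 10, dim = c(60L, 120L))

test_that("single bright spots assign with dominance 1", {
  spots <- make_spot(30, 30, "exact", "g1")
  calls <- assign_spots_to_nuclei(spots, two_nuclei, pipeline_params())
  a <- calls[calls$label == 1L, ]
  expect_equal(a$status, "assigned")
  expect_equal(a$guide_id, "g1")
  expect_equal(a$dominance, 1)
  expect_equal(calls$status[calls$label == 2L], "no_spot")
})

test_that("the two-thirds dominance gate splits 80/30 from 60/40", {
  p <- pipeline_params()
  s_pass <- dplyr::bind_rows(make_spot(30, 30, "exact", "gA", intensity = 80e5),
                             make_spot(32, 30, "exact", "gB", intensity = 30e5))
  a <- assign_spots_to_nuclei(s_pass, two_nuclei, p)[1, ]
  expect_equal(a$dominance, 80 / 110, tolerance = 1e-12)
  expect_equal(a$status, "assigned")
  expect_equal(a$guide_id, "gA")

  s_fail <- dplyr::bind_rows(make_spot(30, 30, "exact", "gA", intensity = 60e5),
                             make_spot(32, 30, "exact", "gB", intensity = 40e5))
  b <- assign_spots_to_nuclei(s_fail, two_nuclei, p)[1, ]
  expect_equal(b$dominance, 0.6, tolerance = 1e-12)
  expect_equal(b$status, "not_dominant")
})

test_that("the per-nucleus intensity threshold gates assignment", {
  p <- pipeline_params()                       # threshold 7e5
  dim_spot <- make_spot(30, 30, "exact", "g1", intensity = 5e5)
  a <- assign_spots_to_nuclei(dim_spot, two_nuclei, p)[1, ]
  expect_equal(a$status, "below_intensity")
  # the low-signal preset admits the same nucleus
  p2 <- pipeline_params(nucleus_intensity_threshold = 2e5)
  b <- assign_spots_to_nuclei(dim_spot, two_nuclei, p2)[1, ]
  expect_equal(b$status, "assigned")
  # monotonicity: raising the threshold never increases assignments
  n_assigned <- vapply(c(2e5, 7e5, 2e6), function(thr) {
    pp <- pipeline_params(nucleus_intensity_threshold = thr)
    sum(assign_spots_to_nuclei(dim_spot, two_nuclei, pp)$status ==
          "assigned")
  }, numeric(1))
  expect_true(all(diff(n_assigned) <= 0))
})

test_that("ambiguous spots dilute dominance but never win a nucleus", {
  p <- pipeline_params()
  spots <- dplyr::bind_rows(
    make_spot(30, 30, "exact", "gA", intensity = 50e5),
    make_spot(32, 30, "ambiguous", NA, intensity = 40e5))
  a <- assign_spots_to_nuclei(spots, two_nuclei, p)[1, ]
  expect_equal(a$dominance, 50 / 90, tolerance = 1e-12)
  expect_equal(a$status, "not_dominant")

  only_amb <- make_spot(30, 90, "ambiguous", NA)
  b <- assign_spots_to_nuclei(only_amb, two_nuclei, p)
  expect_equal(b$status[b$label == 2L], "ambiguous")
})

test_that("background spots are discarded and intensity is conserved", {
  p <- pipeline_params()
  spots <- dplyr::bind_rows(
    make_spot(30, 30, "exact", "gA"),
    make_spot(2, 60, "exact", "gB"),              # on background
    make_spot(30, 90, "exact", "gC"))
  calls <- assign_spots_to_nuclei(spots, two_nuclei, p)
  expect_equal(sum(calls$n_spots), 2L)            # each in-nucleus spot once
  expect_equal(calls$guide_id[calls$label == 1L], "gA")
  expect_equal(calls$guide_id[calls$label == 2L], "gC")
  expect_error(
    assign_spots_to_nuclei(make_spot(500, 500, "exact", "g"), two_nuclei, p),
    "outside")
})

test_that("mapping summaries report status fractions and per-guide counts", {
  p <- pipeline_params()
  spots <- make_spot(30, 30, "exact", "g1")
  calls <- assign_spots_to_nuclei(spots, two_nuclei, p)
  s <- mapping_summary(calls)
  expect_equal(s$mapped_fraction, 0.5)
  expect_equal(sort(s$by_status$status), c("assigned", "no_spot"))
  expect_equal(s$by_status$fraction, c(0.5, 0.5))
  lib <- barcode_library(data.frame(guide_id = c("g1", "g2"), gene = "G",
                                    spacer = c("ACGT", "GGTT")))
  pg <- mapping_summary(calls, lib)$per_guide
  expect_equal(pg$n_nuclei[pg$guide_id == "g1"], 1L)
  expect_equal(pg$n_nuclei[pg$guide_id == "g2"], 0L)
})
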