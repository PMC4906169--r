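test_that("a blank image yields no objects", {
  expect_identical(nrow(segment_objects(matrix(3, 50, 50))), 0L)
})

test_that("a single synthetic solid object is segmented at its true centre", {
  im <- generate_golgi_image(golgi_population_spec(1, 1, seed = 2),
                             quiet_imaging(background = 0))
  segs <- segment_objects(im$image)
  expect_identical(nrow(segs), 1L)
  px <- imaging_params()$pixel_size
  expect_lt(abs(segs$x_nm - im$truth$x_nm), px)
  expect_lt(abs(segs$y_nm - im$truth$y_nm), px)
})

test_that("well-separated objects are segmented individually", {
  im <- generate_golgi_image(golgi_population_spec(3, 1, seed = 8),
                             quiet_imaging(background = 0))
  expect_identical(nrow(segment_objects(im$image)), 3L)
})

test_that("transects through constant images are constant", {
  prof <- extract_cross_section(matrix(4.5, 40, 40), c(20, 20), 0.7,
                                length_nm = 1500)
  expect_true(all(prof$intensity == 4.5))
})

test_that("transect sampling follows the half-pixel-step rule", {
  prof <- extract_cross_section(matrix(0, 64, 64), c(32, 32), 0,
                                length_nm = 2000, pixel_size = 133)
  expect_identical(nrow(prof), as.integer(floor(2000 / 66.5)) + 1L)
  expect_equal(unique(round(diff(prof$position_nm), 9)), 66.5)
  expect_equal(mean(prof$position_nm), 0)
})

test_that("a transect through a noiseless ring straddles its diameter", {
  spec <- golgi_population_spec(1, 0, ring_diameter_mean = 600,
                                ring_diameter_sd = 0, seed = 4)
  im <- generate_golgi_image(spec, quiet_imaging(background = 0))
  segs <- segment_objects(im$image)
  prof <- extract_cross_section(im$image, c(segs$x_px, segs$y_px), 0,
                                length_nm = 1800)
  pk <- find_profile_peaks(prof)
  expect_identical(nrow(pk), 2L)
  expect_lt(abs(diff(pk$position_nm) - 600), 66.5 + 2 * 113^2 / 600)
})

test_that("transects that leave the image are refused by name", {
  expect_error(
    extract_cross_section(matrix(0, 20, 20), c(2, 2), 0, length_nm = 2000,
                          source_id = "edge_case"),
    "edge_case")
})
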