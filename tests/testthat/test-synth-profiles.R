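test_that("solid-only noiseless populations give single-maximum profiles", {
  sim <- generate_profile_population(
    golgi_population_spec(10, solid_fraction = 1, seed = 1),
    quiet_imaging())
  for (id in unique(sim$profiles$source_id)) {
    y <- sim$profiles$intensity[sim$profiles$source_id == id]
    n_max <- sum(diff(sign(diff(y))) < 0)
    expect_identical(n_max, 1L)
  }
  expect_true(all(sim$truth$class == "solid"))
})

test_that("generation is bit-reproducible for a fixed seed", {
  spec <- golgi_population_spec(15, 0.4, seed = 7)
  a <- generate_profile_population(spec, imaging_params())
  b <- generate_profile_population(spec, imaging_params())
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$truth, b$truth)
})

test_that("noiseless ring argmaxima sit one sampling step from the true diameter", {
  # brute-force argmax oracle on the generated arrays
  spec <- golgi_population_spec(5, 0, ring_diameter_mean = 600,
                                ring_diameter_sd = 0, seed = 2)
  sim <- generate_profile_population(spec, quiet_imaging())
  step <- imaging_params()$pixel_size / 2
  for (id in unique(sim$profiles$source_id)) {
    block <- sim$profiles[sim$profiles$source_id == id, ]
    y <- block$intensity
    locmax <- which(diff(sign(diff(y))) < 0) + 1L
    expect_length(locmax, 2L)
    sep <- diff(block$position_nm[locmax])
    expect_lte(abs(sep - 600), step + 1e-9)
  }
})

test_that("noise perturbs intensities but never the ground truth", {
  spec <- golgi_population_spec(20, 0.5, seed = 11)
  noisy <- generate_profile_population(spec, imaging_params())
  clean <- generate_profile_population(spec, quiet_imaging())
  expect_identical(noisy$truth, clean$truth)
  expect_false(identical(noisy$profiles$intensity, clean$profiles$intensity))
})

test_that("invalid population specs are rejected by field name", {
  expect_error(golgi_population_spec(10, 1.5), "solid_fraction")
  expect_error(golgi_population_spec(-1, 0.5), "n_objects")
  expect_error(
    generate_profile_population(
      golgi_population_spec(5, 0, ring_diameter_mean = 200, seed = 1),
      imaging_params()),
    "resolvable")
})
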