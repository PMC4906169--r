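test_that("a pure solid population is classified entirely solid", {
  sim <- generate_profile_population(
    golgi_population_spec(100, solid_fraction = 1, seed = 1),
    quiet_imaging())
  pop <- analyze_population(sim$profiles)
  expect_equal(glance(pop)$fraction_solid, 1)
  expect_identical(nrow(tidy(pop)), 100L) # one row per object
})

test_that("noiseless classification agrees with ground truth for resolvable rings", {
  # rings at least twice the PSF FWHM wide
  sim <- generate_profile_population(
    golgi_population_spec(100, solid_fraction = 0.4,
                          ring_diameter_mean = 700, ring_diameter_sd = 80,
                          seed = 3),
    quiet_imaging())
  pop <- analyze_population(sim$profiles)
  merged <- dplyr::inner_join(tidy(pop), sim$truth, by = "source_id",
                              suffix = c("_pred", "_true"))
  scored <- merged[merged$class_pred != "rejected", ]
  accuracy <- mean(scored$class_pred == scored$class_true)
  expect_gte(accuracy, 0.99)
})

test_that("recovered ring diameters match truth plus the PSF broadening", {
  # generated separation D plus two fitted FWHMs: expected mean diameter is
  # D_mean + 2 * fwhm = 800 + 532.2 nm on this moderate-noise population
  sim <- generate_profile_population(
    golgi_population_spec(60, solid_fraction = 0,
                          ring_diameter_mean = 800, ring_diameter_sd = 150,
                          seed = 5),
    imaging_params()) # SNR ~ 10
  pop <- analyze_population(sim$profiles)
  expected <- mean(sim$truth$true_diameter_nm) + 2 * 266
  expect_lt(abs(glance(pop)$mean_diameter_nm - expected) / expected, 0.05)
})

test_that("an all-rejected population warns and reports zero fractions", {
  flat <- purrr::map(1:3, function(i) {
    p <- make_profile(b = 5, A1 = 0, id = paste0("f", i))
    p
  }) |> purrr::list_rbind()
  expect_warning(pop <- analyze_population(flat), "rejected")
  expect_identical(glance(pop)$n_ring + glance(pop)$n_solid, 0L)
})

test_that("group comparison is null for identical samples and symmetric in sign", {
  x <- c(3.1, 4.5, 2.2, 5.0, 3.3)
  same <- compare_groups(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 7)
  ab <- compare_groups(a, b); ba <- compare_groups(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)
})

test_that("the pooled t on the textbook example matches hand computation", {
  a <- c(1, 2, 3, 4, 5); b <- c(2, 3, 4, 5, 6)
  res <- compare_groups(a, b)
  expect_identical(res$method, "student_pooled")
  expect_equal(res$statistic, -1, tolerance = 1e-12)
  expect_equal(res$p_value, 0.3466, tolerance = 1e-4)
})

test_that("comparison matches the textbook formulas on random samples", {
  for (s in 1:100) {
    ab <- withr::with_seed(s, {
      list(a = rnorm(sample(5:30, 1), 0, runif(1, 0.5, 3)),
           b = rnorm(sample(5:30, 1), runif(1, -1, 1), runif(1, 0.5, 3)))
    })
    res <- compare_groups(ab$a, ab$b)
    expect_equal(res$variance_test_p, f_test_oracle(ab$a, ab$b), tolerance = 1e-10)
    oracle <- t_test_oracle(ab$a, ab$b, pooled = res$method == "student_pooled")
    expect_equal(res$statistic, oracle$t, tolerance = 1e-10)
    expect_equal(res$df, oracle$df, tolerance = 1e-10)
    expect_equal(res$p_value, oracle$p, tolerance = 1e-10)
  }
})

test_that("degenerate samples are refused", {
  expect_error(compare_groups(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(compare_groups(1, c(1, 2, 3)), "two finite")
})
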