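test_that("free-mode fitting exactly recovers noiseless parameters", {
  # generate-then-fit oracle
  prof <- make_profile(b = 10, A1 = 100, mu1 = -300, s1 = 113,
                       A2 = 100, mu2 = 300, s2 = 113)
  fit <- fit_double_gaussian(prof, "free")
  expect_true(fit$converged)
  rel <- function(est, truth) abs(est - truth) / abs(truth)
  expect_lt(rel(fit$baseline, 10), 1e-4)
  expect_lt(rel(fit$A1, 100), 1e-4)
  expect_lt(rel(fit$A2, 100), 1e-4)
  expect_lt(rel(fit$mu1, -300), 1e-4)
  expect_lt(rel(fit$mu2, 300), 1e-4)
  expect_lt(rel(fit$sigma1, 113), 1e-4)
  expect_lt(rel(fit$sigma2, 113), 1e-4)
})

test_that("fixed mode pins the separation to the resolution limit", {
  prof <- make_profile(A1 = 100, mu1 = 50, s1 = 113)
  fit <- fit_double_gaussian(prof, "fixed", R = 266)
  expect_true(fit$converged)
  expect_lt(abs((fit$mu2 - fit$mu1) - 266) / 266, 1e-6)
})

test_that("the fixed-separation constraint holds on noisy profiles too", {
  for (s in 1:20) {
    withr::with_seed(s, {
      prof <- make_profile(A1 = runif(1, 50, 150), mu1 = runif(1, -200, 200),
                           s1 = runif(1, 90, 140))
      prof$intensity <- prof$intensity + rnorm(nrow(prof), 0, 5)
    })
    fit <- fit_double_gaussian(prof, "fixed", R = 266)
    expect_lt(abs((fit$mu2 - fit$mu1) - 266) / 266, 1e-6)
  }
})

test_that("an all-zero profile converges to the zero solution", {
  prof <- make_profile(b = 0, A1 = 0)
  fit <- fit_double_gaussian(prof, "free")
  expect_true(fit$converged)
  expect_equal(fit$baseline, 0, tolerance = 1e-10)
  expect_equal(fit$A1 + fit$A2, 0, tolerance = 1e-10)
})

test_that("diameters follow the separation-plus-widths definition exactly", {
  prof <- make_profile(A1 = 100, mu1 = -200, s1 = 100, A2 = 100, mu2 = 200,
                       s2 = 100)
  fit <- fit_double_gaussian(prof, "free")
  d <- object_diameter(fit, "fwhm")
  # mu = +/-200, sigma = 100: 400 + 2 * 235.482 = 870.964
  expect_equal(d$diameter_nm, 400 + 2 * 2 * sqrt(2 * log(2)) * 100,
               tolerance = 1e-4)
  expect_equal(d$diameter_nm, d$separation_nm + d$w1_nm + d$w2_nm) # additivity

  d2 <- object_diameter(fit, "two_sigma")
  expect_equal(d$diameter_nm - d2$diameter_nm,
               (2 * sqrt(2 * log(2)) - 2) * (fit$sigma1 + fit$sigma2))
})

test_that("fixed-mode diameter arithmetic matches the closed form", {
  fit <- fit_double_gaussian(make_profile(A1 = 100, mu1 = 0, s1 = 113),
                             "fixed", R = 266)
  # the arithmetic of the definition at sigma1 = sigma2 = 113:
  # 266 + 2 * 2 sqrt(2 ln 2) * 113 = 798.19
  fit$sigma1 <- 113; fit$sigma2 <- 113
  d <- object_diameter(fit)
  expect_equal(d$separation_nm, 266, tolerance = 1e-6)
  expect_equal(d$diameter_nm, 798.19, tolerance = 1e-4)
})

test_that("diameter additivity holds across random converged fits", {
  for (s in 1:15) {
    prof <- withr::with_seed(s, {
      p <- make_profile(b = runif(1, 0, 20), A1 = runif(1, 50, 150),
                        mu1 = runif(1, -400, -100), s1 = runif(1, 90, 140),
                        A2 = runif(1, 50, 150), mu2 = runif(1, 100, 400),
                        s2 = runif(1, 90, 140))
      p$intensity <- p$intensity + rnorm(nrow(p), 0, 3)
      p
    })
    fit <- fit_double_gaussian(prof, "free")
    if (fit$converged) {
      d <- object_diameter(fit)
      expect_identical(d$diameter_nm, d$separation_nm + d$w1_nm + d$w2_nm)
    }
  }
})

test_that("non-converged fits refuse to yield a diameter", {
  prof <- make_profile()
  fit <- fit_double_gaussian(prof, "free")
  fit$converged <- FALSE
  expect_error(object_diameter(fit), "non-converged")
})

test_that("tidiers expose the parameter table and fit summary", {
  fit <- fit_double_gaussian(make_profile(), "fixed")
  td <- generics::tidy(fit)
  expect_identical(td$term[4:5], c("mu1", "mu2"))
  gl <- generics::glance(fit)
  expect_equal(gl$separation_nm, 266, tolerance = 1e-6)
  expect_true(gl$converged)
})
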