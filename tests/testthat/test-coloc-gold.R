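test_that("identical channels are fully co-localized", {
  a <- matrix(0, 30, 30); a[10:14, 10:14] <- 100
  res <- manders(a, a, threshold_a = 10, threshold_b = 10)
  expect_equal(res$M1, 1)
  expect_equal(res$M2, 1)
})

test_that("disjoint channels are fully un-co-localized", {
  a <- matrix(0, 30, 30); a[2:6, 2:6] <- 100
  b <- matrix(0, 30, 30); b[20:24, 20:24] <- 100
  res <- manders(a, b, threshold_a = 10, threshold_b = 10)
  expect_equal(res$M1, 0)
  expect_equal(res$M2, 0)
})

test_that("half-overlap pairs match the pixel-sum oracle near 0.5", {
  pair <- generate_coloc_pair(
    40, 0.5, quiet_imaging(background = 0, field_size = c(40, 40)), seed = 2)
  res <- manders(pair$channel_a, pair$channel_b, threshold_a = 1, threshold_b = 1)
  oracle <- manders_oracle(pair$channel_a, pair$channel_b, 1, 1)
  expect_equal(res$M1, oracle$M1)
  expect_equal(res$M2, oracle$M2)
  expect_lt(abs(res$M1 - 0.5), 0.02)
  expect_lt(abs(res$M2 - 0.5), 0.02)
})

test_that("Manders coefficients are bounded, symmetric and scale-invariant", {
  for (s in 1:5) {
    pair <- generate_coloc_pair(
      20, withr::with_seed(s, runif(1)),
      imaging_params(field_size = c(30, 30)), seed = s)
    a <- pair$channel_a; b <- pair$channel_b
    res <- manders(a, b, threshold_a = 30, threshold_b = 30)
    expect_true(res$M1 >= 0 && res$M1 <= 1)
    expect_true(res$M2 >= 0 && res$M2 <= 1)
    swapped <- manders(b, a, threshold_a = 30, threshold_b = 30)
    expect_equal(res$M1, swapped$M2)
    expect_equal(res$M2, swapped$M1)
    scaled <- manders(a * 3, b, threshold_a = 90, threshold_b = 30)
    expect_equal(scaled$M1, res$M1)
    expect_equal(scaled$M2, res$M2)
  }
})

test_that("channels without signal give NA coefficients with a warning", {
  a <- matrix(0, 10, 10); b <- matrix(0, 10, 10); b[3, 3] <- 50
  expect_warning(res <- manders(a, b, threshold_a = 10, threshold_b = 10),
                 "undefined")
  expect_true(is.na(res$M1))
})

test_that("gold distances hit the centre and end anchors", {
  p <- tibble::tibble(particle_id = 1:3, position_nm = c(500, 0, 1000))
  d <- gold_relative_distance(p, axis_length = 1000)
  expect_equal(d$d_rel, c(0, 0.5, 0.5))
})

test_that("the gold statistic is rigid-motion invariant", {
  pts <- withr::with_seed(3, tibble::tibble(
    x_nm = runif(50, 0, 1200), y_nm = rnorm(50, 0, 40)))
  axis <- matrix(c(0, 0, 1200, 0), 2, 2, byrow = TRUE)
  d0 <- gold_relative_distance(pts, axis = axis)
  th <- 0.83; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  xy <- as.matrix(pts) %*% t(R)
  pts2 <- tibble::tibble(x_nm = xy[, 1] + 500, y_nm = xy[, 2] - 300)
  axis2 <- axis %*% t(R) + matrix(c(500, -300), 2, 2, byrow = TRUE)
  d1 <- gold_relative_distance(pts2, axis = axis2)
  expect_equal(d1$d_rel, d0$d_rel, tolerance = 1e-9)
})

test_that("particles far off the axis are flagged as out of bounds", {
  p <- tibble::tibble(x_nm = 2000, y_nm = 0)
  axis <- matrix(c(0, 0, 1000, 0), 2, 2, byrow = TRUE)
  expect_error(gold_relative_distance(p, axis = axis), "outside")
})

test_that("distribution summaries use type-7 quantiles and flag degeneracy", {
  s <- summarize_distribution(c(0.1, 0.2, 0.3))
  expect_equal(s$stats$median, 0.2)
  const <- summarize_distribution(rep(2, 10))
  expect_true(const$stats$degenerate)
  expect_null(const$density)
  for (k in 1:100) {
    x <- withr::with_seed(k, runif(sample(5:50, 1)))
    st <- summarize_distribution(x)$stats
    expect_equal(st$q25, quantile7_oracle(x, 0.25), tolerance = 1e-12)
    expect_equal(st$median, quantile7_oracle(x, 0.5), tolerance = 1e-12)
    expect_equal(st$q75, quantile7_oracle(x, 0.75), tolerance = 1e-12)
  }
})
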