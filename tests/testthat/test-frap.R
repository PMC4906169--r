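test_that("a movie with no foci yields no events", {
  sim <- generate_frap_movie(frap_spec(0, decoy_density = 0, duration = 120,
                                       seed = 1),
                             quiet_imaging(field_size = c(10, 10)))
  ev <- detect_insertion_events(sim$movie, 5)
  expect_identical(nrow(ev$events), 0L)
})

test_that("decoy-only movies score zero events", {
  # one-frame flashes fail the persistence criterion by construction
  sim <- generate_frap_movie(frap_spec(0, decoy_density = 8, duration = 300,
                                       seed = 2),
                             quiet_imaging(field_size = c(15, 15)))
  expect_gt(nrow(sim$decoys), 0)
  ev <- detect_insertion_events(sim$movie, 5)
  expect_identical(nrow(ev$events), 0L)
})

test_that("noise-free insertions in the scorable window are all recovered", {
  sim <- generate_frap_movie(frap_spec(3, decoy_density = 0, duration = 300,
                                       seed = 5),
                             quiet_imaging(field_size = c(15, 15)))
  ev <- detect_insertion_events(sim$movie, 5)
  w <- sim$field_um[1]; h <- sim$field_um[2]
  scorable <- sim$truth[
    sim$truth$x_um > 0.2 * w & sim$truth$x_um < 0.8 * w &
      sim$truth$y_um > 0.2 * h & sim$truth$y_um < 0.8 * h &
      sim$truth$first_frame >= 3 & sim$truth$first_frame <= sim$n_frames - 4, ]
  # each scorable truth event matches a detected event within 300 nm, unless
  # an earlier focus had drifted into its exclusion neighbourhood (the
  # devoid-region criterion then rejects it, correctly)
  speed_um_s <- 255 / 1000 / 60
  matched <- vapply(seq_len(nrow(scorable)), function(i) {
    any(ev$events$frame == scorable$first_frame[i] &
          sqrt((ev$events$x_um - scorable$x_um[i])^2 +
                 (ev$events$y_um - scorable$y_um[i])^2) < 0.3)
  }, logical(1))
  occluded <- vapply(seq_len(nrow(scorable)), function(i) {
    earlier <- sim$truth[sim$truth$first_frame < scorable$first_frame[i], ]
    if (nrow(earlier) == 0) return(FALSE)
    t_f <- (scorable$first_frame[i] - 1) * 5
    dt <- t_f - earlier$time_s
    x <- earlier$x_um + speed_um_s * dt * cos(earlier$direction_rad)
    y <- earlier$y_um + speed_um_s * dt * sin(earlier$direction_rad)
    min(sqrt((x - scorable$x_um[i])^2 + (y - scorable$y_um[i])^2)) < 0.65
  }, logical(1))
  expect_true(all(matched | occluded))
  # and nothing is detected that is not near a truth event
  false_pos <- vapply(seq_len(nrow(ev$events)), function(i) {
    min(sqrt((sim$truth$x_um - ev$events$x_um[i])^2 +
               (sim$truth$y_um - ev$events$y_um[i])^2)) > 0.3
  }, logical(1))
  expect_identical(sum(false_pos), 0L)
})

test_that("delivery-rate arithmetic is exact", {
  r <- delivery_rate(12, area_um2 = 25, duration_s = 1800)
  expect_equal(r$rate_per_um2_h, 0.96)
  expect_equal(delivery_rate(0, area_um2 = 10, duration_s = 600)$rate_per_um2_h, 0)
  expect_error(delivery_rate(3, area_um2 = -1, duration_s = 10), "area_um2")
})

test_that("the rate estimator is unbiased over repeated movies", {
  rate <- 4.8
  est <- vapply(1:50, function(s) {
    sim <- generate_frap_movie(
      frap_spec(rate, decoy_density = 1, seed = 1000 + s),
      imaging_params(field_size = c(8, 8)))
    delivery_rate(detect_insertion_events(sim$movie, 5))$rate_per_um2_h
  }, numeric(1))
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - rate), 3 * se)
})

test_that("doubling the duration leaves the expected estimate unchanged", {
  est <- function(duration, seeds) {
    mean(vapply(seeds, function(s) {
      sim <- generate_frap_movie(
        frap_spec(4, duration = duration, seed = s),
        imaging_params(field_size = c(8, 8)))
      delivery_rate(detect_insertion_events(sim$movie, 5))$rate_per_um2_h
    }, numeric(1)))
  }
  short <- est(300, 1:8)
  long <- est(600, 1:8)
  expect_lt(abs(long - short) / 4, 0.25) # both are noisy estimates of 4
})

test_that("too-short movies are refused", {
  m <- array(0, c(20, 20, 4))
  expect_error(detect_insertion_events(m, 5), "frames")
})
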