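test_that("focus detection handles empty, single and paired spots", {
  expect_identical(nrow(detect_foci(matrix(0, 32, 32))), 0L)

  img <- matrix(0, 40, 40)
  img <- golgiring:::stamp_spot(img, 20.3, 17.6, 100, 1.7)
  det <- detect_foci(img, sigma_px = 1.7)
  expect_identical(nrow(det), 1L)
  expect_lt(abs(det$x_px - 20.3), 0.25)
  expect_lt(abs(det$y_px - 17.6), 0.25)

  img2 <- golgiring:::stamp_spot(img, 30.0, 17.6, 100, 1.7)
  expect_identical(nrow(detect_foci(img2, sigma_px = 1.7)), 2L)
})

test_that("a single moving focus links into one full-length track", {
  sim <- generate_track_set(track_spec(1, 300, 0, loc_noise_sd = 0, seed = 1))
  tracks <- link_trajectories(sim$detections)
  expect_identical(dplyr::n_distinct(tracks$track_id), 1L)
  expect_identical(nrow(tracks), 30L)
})

test_that("parallel tracks keep their identities", {
  det <- dplyr::bind_rows(
    tibble::tibble(frame = 1:20, x_nm = 100 * (1:20), y_nm = 0, truth = 1L),
    tibble::tibble(frame = 1:20, x_nm = 100 * (1:20), y_nm = 3000, truth = 2L)
  )
  tracks <- link_trajectories(det, d_max_nm = 400)
  purity <- tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(p = dplyr::n_distinct(truth))
  expect_identical(nrow(purity), 2L)
  expect_true(all(purity$p == 1L))
})

test_that("detections beyond the step limit never form tracks", {
  det <- tibble::tibble(frame = 1:10, x_nm = 1000 * (1:10), y_nm = 0)
  expect_identical(nrow(link_trajectories(det, d_max_nm = 400)), 0L)
})

test_that("track recovery is near-perfect at low density", {
  sim <- generate_track_set(track_spec(100, 255, 128, loc_noise_sd = 20,
                                       density = 0.02, seed = 7))
  # linking ignores true_track_id but carries it through for the audit
  tracks <- link_trajectories(sim$detections)
  purity <- tracks |>
    dplyr::group_by(track_id) |>
    dplyr::summarise(ids = dplyr::n_distinct(true_track_id), n = dplyr::n())
  full <- purity[purity$n == 30 & purity$ids == 1, ]
  expect_gte(nrow(full), 95)
})

test_that("slope speeds match the constant-velocity arithmetic", {
  traj <- tibble::tibble(frame = 1:10, x_nm = 50 * (0:9), y_nm = 0)
  expect_equal(trajectory_speed(traj, 5)$speed_nm_min, 600)
  expect_equal(trajectory_speed(traj, 5, "stepwise")$speed_nm_min, 600)
  # noiseless: both estimators agree
  diag <- tibble::tibble(frame = 1:12, x_nm = 30 * (0:11), y_nm = 40 * (0:11))
  expect_equal(trajectory_speed(diag, 5)$speed_nm_min,
               trajectory_speed(diag, 5, "stepwise")$speed_nm_min,
               tolerance = 1e-9)
  still <- tibble::tibble(frame = 1:8, x_nm = 5, y_nm = 5)
  expect_equal(trajectory_speed(still, 5)$speed_nm_min, 0)
  expect_error(trajectory_speed(traj[1:3, ], 5), "at least")
})

test_that("slope speed is unbiased under localization noise, stepwise is not", {
  sim <- generate_track_set(track_spec(500, 255, 128, loc_noise_sd = 50,
                                       seed = 11))
  tracks <- link_trajectories(sim$detections)
  slope <- track_speeds(tracks, 5, method = "slope")
  stepwise <- track_speeds(tracks, 5, method = "stepwise")
  truth_mean <- mean(sim$truth$true_speed_nm_min)
  expect_lt(abs(mean(slope$speed_nm_min) - truth_mean) / truth_mean, 0.03)
  # stepwise mean displacement inflates badly at this noise level: the
  # per-step noise (~ 50 sqrt(2) nm) dwarfs the ~21 nm true step
  expect_gt(mean(stepwise$speed_nm_min), 2 * truth_mean)
})

test_that("time averaging is the per-pixel mean", {
  m <- array(rnorm(16 * 16 * 5), c(16, 16, 5))
  avg <- time_average(m)
  expect_equal(avg[3, 4], mean(m[3, 4, ]))
  expect_equal(mean(avg), mean(m))
  one <- array(1:9, c(3, 3, 1))
  expect_equal(time_average(one), matrix(1:9, 3, 3) * 1.0)
})
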