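noise_free <- function(seed = 1, ...) {
  sim_config(accel_noise_sd = 0, position_noise_sd = 0, cycle_jitter = 0,
             seed = seed, ...)
}

test_that("trajectories realize the specified geometry and counts", {
  cfg <- noise_free()
  # horizontal: 0.40 m peak-to-peak on x before noise
  tr <- generate_trajectory(movement_spec("horizontal"), cfg)
  expect_equal(diff(range(tr$position[, 1])), 0.40, tolerance = 1e-6)
  expect_equal(diff(range(tr$position[, 2])), 0)     # y constant
  # vertical: 0.50 m on z
  tr <- generate_trajectory(movement_spec("vertical"), cfg)
  expect_equal(diff(range(tr$position[, 3])), 0.50, tolerance = 1e-6)
  # 10 cycles x 2 s x 200 Hz: 4000 samples, 11 boundaries
  expect_length(tr$timestamps, 4000)
  expect_length(attr(tr, "boundaries"), 11)
  expect_equal(attr(tr, "boundaries"), c(seq(1, 3601, by = 400), 4001))
  expect_error(movement_spec("horizontal", cycle_duration = -1), "cycle_duration")
})

test_that("analytic acceleration matches the differentiated closed form", {
  cfg <- noise_free()
  spec <- movement_spec("elliptical")   # semi-axes 0.1125 / 0.0755
  tr <- generate_trajectory(spec, cfg)
  acc <- attr(tr, "accel_true")
  # at t = 0 the ellipse sits at x = a, all acceleration on x: |a| = a (2 pi / T)^2
  expect_equal(sqrt(sum(acc[1, ]^2)), 0.1125 * (2 * pi / 2)^2, tolerance = 1e-9)
  # numerical second difference of noise-free positions agrees in the interior
  num <- (tr$position[3:4000, ] - 2 * tr$position[2:3999, ] + tr$position[1:3998, ]) * 200^2
  expect_equal(max(abs(num - acc[2:3999, ])), 0, tolerance = 2e-3)
})

test_that("simulate_imu applies orientation, gravity, lag and markers correctly", {
  cfg <- noise_free()
  tr <- generate_trajectory(movement_spec("horizontal"), cfg)
  acc <- attr(tr, "accel_true")
  # identity orientation, gravity off, zero lag: device accel == world accel
  cfg0 <- noise_free(gravity = 0)
  imu <- simulate_imu(tr, cfg0)
  expect_equal(imu$accel[1:4000, ], acc, tolerance = 1e-12, ignore_attr = TRUE)
  # 90 deg about world z: world (1,0,0) appears as (0,-1,0) in the device frame
  cfg_rot <- noise_free(gravity = 0,
                        device_orientation = c(sqrt(0.5), 0, 0, sqrt(0.5)))
  imu_rot <- simulate_imu(tr, cfg_rot)
  expect_equal(imu_rot$accel[1:4000, 2], -acc[, 1], tolerance = 1e-9)
  # gravity on: a resting device reads +g on world z rotated into device frame
  imu_g <- simulate_imu(tr, noise_free(lag_samples = 5))
  expect_equal(imu_g$accel[1, ], c(0, 0, 9.81), tolerance = 1e-12,
               ignore_attr = TRUE)
  # markers: boundaries shifted by the lag
  expect_equal(imu_g$markers, attr(tr, "boundaries") + 5L)
  # downstream recovery of an injected lag through the real pipeline
  cfg7 <- sim_config(seed = 2, lag_samples = 7)
  tr7 <- generate_trajectory(movement_spec("horizontal"), cfg7)
  imu7 <- simulate_imu(tr7, cfg7)
  expect_equal(process_pair(imu7, tr7)$lag, 7)
  expect_error(simulate_imu(tr, sim_config(device_orientation = c(1, 1, 0, 0))),
               "deviates")
})

test_that("round-trip identity: device accel rotated back equals world truth", {
  set.seed(9)
  for (i in 1:5) {
    q <- random_quaternion()
    cfg <- noise_free(gravity = 0, device_orientation = q)
    tr <- generate_trajectory(movement_spec("figure_eight"), cfg)
    imu <- simulate_imu(tr, cfg)
    back <- quat_rotate(imu$accel, q)
    expect_lt(max(abs(back[1:4000, ] - attr(tr, "accel_true"))), 1e-9)
  }
})

test_that("generate_dataset reproduces the study design reproducibly", {
  specs <- tiny_specs(c("horizontal", "vertical"), n_cycles = 3L)
  ds1 <- generate_dataset(2L, specs, sim_config(seed = 11))
  ds2 <- generate_dataset(2L, specs, sim_config(seed = 11))
  expect_identical(ds1, ds2)                     # same seed, identical bytes
  expect_length(ds1, 4L)                         # 2 participants x 2 types
  # 1 participant x 1 type x 1 cycle -> a single cycle record
  ds <- generate_dataset(1L, tiny_specs("horizontal", n_cycles = 1L),
                         sim_config(seed = 3), lag_range = c(0L, 10L))
  pr <- process_pair(ds[[1]]$imu, ds[[1]]$mocap, max_lag = 20L)
  expect_equal(n_cycles(pr$kid), 1L)
  # per-participant randomization: orientations differ across participants
  q1 <- ds1[[1]]$imu$quat[1, ]
  q3 <- ds1[[3]]$imu$quat[1, ]
  expect_gt(max(abs(q1 - q3)), 1e-6)
})

test_that("boundaries partition the recording into the requested cycles", {
  cfg <- sim_config(seed = 5)                    # default jitter on
  tr <- generate_trajectory(movement_spec("horizontal"), cfg)
  b <- attr(tr, "boundaries")
  expect_length(b, 11)
  expect_true(all(diff(b) > 0))
  expect_equal(b[1], 1L)
  expect_equal(b[11], length(tr$timestamps) + 1L)
  # without jitter all cycles have identical length
  trj <- generate_trajectory(movement_spec("horizontal"), noise_free())
  expect_equal(unique(diff(attr(trj, "boundaries"))), 400L)
})
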