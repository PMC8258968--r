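test_that("estimate_lag recovers shifts and matches the brute-force oracle", {
  set.seed(31)
  x <- as.numeric(stats::filter(rnorm(600), rep(1 / 5, 5), sides = 2))
  x[is.na(x)] <- 0
  expect_equal(estimate_lag(x, x, max_lag = 50), 0)
  q <- c(rnorm(7, sd = 0.1), x)                  # delayed by 7
  expect_equal(estimate_lag(x, q, max_lag = 50), 7)
  expect_equal(estimate_lag(x, q, max_lag = 50), oracle_lag(x, q, 50))
  expect_error(estimate_lag(rep(1, 100), rnorm(100), 10), "constant")
})

test_that("white-noise lag recovery succeeds in at least 19 of 20 replicates", {
  set.seed(32)
  hits <- 0L
  for (i in 1:20) {
    lag <- sample(0:30, 1)
    ref <- rnorm(500)
    query <- c(rnorm(lag), ref + rnorm(500, sd = 0.3))
    if (estimate_lag(ref, query, max_lag = 60) == lag) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("align_and_trim cuts the lag and equalizes lengths", {
  mk <- function(n, src) world_accel(rnorm(n), rnorm(n), rnorm(n), 200, src)
  set.seed(33)
  kid <- mk(4007, "kid"); moc <- mk(4000, "mocap")
  out <- align_and_trim(kid, moc, 7)
  expect_length(out$kid$ax, 4000)
  expect_length(out$mocap$ax, 4000)
  expect_equal(out$kid$ax, kid$ax[8:4007])
  # lag 0, equal lengths: unchanged
  out0 <- align_and_trim(moc, moc, 0)
  expect_equal(out0$kid$ax, moc$ax)
  expect_error(align_and_trim(kid, moc, 5000), "lag")
})

test_that("the estimated lag maximizes post-alignment correlation", {
  cfg <- sim_config(seed = 34, lag_samples = 12)
  tr <- generate_trajectory(movement_spec("figure_eight"), cfg)
  imu <- simulate_imu(tr, cfg)
  wk <- to_world_frame(imu)
  wm <- differentiate_position(tr)
  lag <- estimate_lag(wm$am, wk$am, max_lag = 60)
  r_at <- function(L) {
    n <- min(length(wm$am), length(wk$am) - L)
    cor(wm$am[seq_len(n)], wk$am[L + seq_len(n)])
  }
  rs <- vapply(0:60, r_at, numeric(1))
  expect_equal(which.max(rs) - 1L, lag)
  expect_true(all(rs[lag + 1] >= rs))
})

test_that("segmentation follows half-open boundaries and conserves samples", {
  set.seed(35)
  s <- world_accel(rnorm(400), rnorm(400), rnorm(400), 200, "kid")
  cyc <- segment_cycles(s, c(1, 201, 401))
  expect_length(cyc, 2)
  expect_length(cyc[[1]]$ax, 200)
  expect_equal(c(cyc[[1]]$ax, cyc[[2]]$ax), s$ax)  # conservation
  expect_length(segment_cycles(s, c(101, 301))[[1]]$ax, 200)  # single interval
  expect_error(segment_cycles(s, c(201, 1)), "increasing")
  expect_error(segment_cycles(s, c(1, 500)), "outside")
  # remainder before/after boundaries plus cycles reproduces the input length
  cyc2 <- segment_cycles(s, c(51, 151, 351))
  expect_equal(50 + sum(lengths(lapply(cyc2, `[[`, "ax"))) + 50, 400)
})

test_that("binning averages contiguous blocks and preserves means", {
  expect_equal(resample_bins(rep(2.5, 100), 10), rep(2.5, 10))
  # linear ramp 0..199: bin means 9.5, 29.5, ..., 189.5
  expect_equal(resample_bins(0:199, 10), seq(9.5, 189.5, by = 20))
  # 200 samples, 10 bins: each bin the mean of 20 consecutive samples
  set.seed(36)
  x <- rnorm(200)
  expect_equal(resample_bins(x, 10),
               colMeans(matrix(x, nrow = 20)))
  # mean preservation when divisible
  expect_equal(mean(resample_bins(x, 10)), mean(x))
  # remainder goes to the earliest bins
  expect_equal(resample_bins(c(1, 1, 2, 3), 3), c(1, 2, 3))
  expect_error(resample_bins(1:5, 10), "shorter")
})

test_that("pipeline lag recovery is exact for most injected lags", {
  set.seed(37)
  hits <- 0L; total <- 0L
  for (mt in c("horizontal", "figure_eight")) {
    for (i in 1:5) {
      lag <- sample(0:50, 1)
      cfg <- sim_config(device_orientation = random_quaternion(),
                        lag_samples = lag)
      tr <- generate_trajectory(movement_spec(mt), cfg)
      pr <- process_pair(simulate_imu(tr, cfg), tr)
      total <- total + 1L
      hits <- hits + (pr$lag == lag)
      expect_equal(n_cycles(pr$kid), 10L)      # never lose a cycle
    }
  }
  expect_gte(hits, total - 1L)
})
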