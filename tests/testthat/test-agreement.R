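worked_table <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8), ncol = 2, byrow = TRUE)

test_that("the worked 4x2 table reproduces the hand-computed ANOVA", {
  ms <- two_way_mean_squares(worked_table)
  expect_equal(ms$MSR, 40 / 3)
  expect_equal(ms$MSC, 2)
  expect_equal(ms$MSE, 0)
  expect_equal(icc_consistency(ms), 1.0)
  expect_equal(icc_absolute_agreement(ms), (40 / 3) / (40 / 3 + 2 / 4))
  expect_equal(icc_absolute_agreement(ms), 0.9639, tolerance = 1e-4)
  # MSE = 0 is the degenerate F case
  sig <- icc_significance(ms, "consistency")
  expect_true(sig$degenerate)
  expect_equal(sig$F, Inf)
  expect_equal(sig$p, 0)
})

test_that("degenerate and reduced cases behave per the formulas", {
  flat <- matrix(5, 4, 2)
  ms <- two_way_mean_squares(flat)
  expect_equal(c(ms$MSR, ms$MSC, ms$MSE), c(0, 0, 0))
  expect_error(icc_consistency(ms), "MSR")
  # identical columns: perfect consistency and agreement
  tab <- cbind(1:6, 1:6)
  ms2 <- two_way_mean_squares(tab)
  expect_equal(icc_consistency(ms2), 1.0)
  expect_equal(icc_absolute_agreement(ms2), 1.0)
  # hand-built mean squares: MSR = MSE gives ICC 0, F = 1, p well above 0.05
  ms3 <- structure(list(MSR = 10, MSC = 3, MSE = 10, n = 50, k = 2),
                   class = "mean_squares")
  expect_equal(icc_consistency(ms3), 0)
  sig <- icc_significance(ms3, "consistency")
  expect_equal(sig$F, 1)
  expect_gt(sig$p, 0.05)
  # when MSC = MSE the two ICC formulas coincide
  ms4 <- structure(list(MSR = 12, MSC = 4, MSE = 4, n = 30, k = 2),
                   class = "mean_squares")
  expect_equal(icc_absolute_agreement(ms4), icc_consistency(ms4))
  expect_error(two_way_mean_squares(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  # discordant columns: negative ICC is reported as computed, with a warning
  ms5 <- two_way_mean_squares(cbind(c(1, 2, 3, 10), c(4, 3, 2, 1)))
  expect_warning(val <- icc_consistency(ms5), "negative")
  expect_lt(val, 0)
})

test_that("both ICC formulas agree with the brute-force ANOVA on random tables", {
  set.seed(41)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    tab <- matrix(rnorm(2 * n, mean = 5), n, 2)
    tab[, 2] <- tab[, 2] + rnorm(1)            # random device offset
    ms <- two_way_mean_squares(tab)
    or <- oracle_two_way(tab)
    expect_equal(ms$MSR, or$MSR, tolerance = 1e-10)
    expect_equal(ms$MSC, or$MSC, tolerance = 1e-10)
    expect_equal(ms$MSE, or$MSE, tolerance = 1e-10)
    # random tables can fall below zero, which warns by design; silence here
    expect_equal(suppressWarnings(icc_consistency(ms)),
                 (or$MSR - or$MSE) / or$MSR, tolerance = 1e-10)
    expect_equal(suppressWarnings(icc_absolute_agreement(ms)),
                 (or$MSR - or$MSE) / (or$MSR + (or$MSC - or$MSE) / n),
                 tolerance = 1e-10)
    # decomposition identity
    grand <- mean(tab)
    sst <- sum((tab - grand)^2)
    expect_equal((n - 1) * ms$MSR + ms$MSC + (n - 1) * ms$MSE, sst,
                 tolerance = 1e-9)
  }
})

test_that("a constant offset lowers agreement but not consistency", {
  set.seed(42)
  base <- rnorm(40, mean = 3)
  tab <- cbind(base + rnorm(40, sd = 0.2), base + rnorm(40, sd = 0.2))
  shifted <- tab
  shifted[, 2] <- shifted[, 2] + 1.5
  ms0 <- two_way_mean_squares(tab)
  ms1 <- two_way_mean_squares(shifted)
  expect_equal(icc_consistency(ms1), icc_consistency(ms0), tolerance = 1e-12)
  expect_lt(icc_absolute_agreement(ms1), icc_absolute_agreement(ms0))
})

test_that("bonferroni follows min(1, m p)", {
  expect_equal(bonferroni(0.01, 8), 0.08)
  expect_equal(bonferroni(0.4, 8), 1.0)
  expect_equal(bonferroni(c(0.2, 0.5), 1), c(0.2, 0.5))
  expect_error(bonferroni(1.5, 2), "p")
})

test_that("agreement tables have the participant-by-bin layout", {
  cyc <- tiny_cycles(n_participants = 3, types = "horizontal", seed = 43)
  tab <- build_agreement_table(cyc$kid, cyc$mocap, "horizontal")
  expect_equal(dim(tab), c(30L, 2L))             # 3 participants x 10 bins
  expect_equal(colnames(tab), c("kid", "mocap"))
  # near-noise-free simulation: device columns nearly coincide
  cycq <- tiny_cycles(n_participants = 1, types = "horizontal", seed = 44,
                      accel_noise_sd = 1e-4, position_noise_sd = 1e-6)
  tabq <- build_agreement_table(cycq$kid, cycq$mocap, "horizontal")
  expect_lt(max(abs(tabq[, 1] - tabq[, 2])), 0.05)
  expect_error(build_agreement_table(cyc$kid, cyc$mocap, "vertical"), "no cycles")
})

test_that("full agreement analysis returns one row per type with adjustment", {
  cyc <- tiny_cycles(n_participants = 2, types = c("horizontal", "vertical"),
                     seed = 45)
  res <- agreement_analysis(cyc$kid, cyc$mocap, bonferroni_m = 8)
  expect_equal(nrow(res), 2L)
  expect_true(all(res$consistency > 0.9))
  expect_equal(res$p_consistency_bonf, pmin(1, 8 * res$p_consistency))
  expect_true(all(res$agreement <= res$consistency + 1e-12))
})
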