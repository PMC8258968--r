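test_that("feature tables concatenate the three axes in fixed order", {
  cyc <- tiny_cycles(n_participants = 2, types = c("horizontal", "vertical"),
                     seed = 61)
  ft <- build_features(cyc$kid)
  expect_equal(dim(ft$X), c(40L, 30L))          # 2 x 2 x 10 cycles, 3 x 10 bins
  expect_equal(colnames(ft$X)[c(1, 11, 21)], c("ax_b1", "ay_b1", "az_b1"))
  expect_equal(as.numeric(ft$X[1, 1:10]), as.numeric(cyc$kid$data[1, , 1]))
  # a zero cycle gives a zero row
  z <- cycle_set(array(0, c(1, 10, 4)),
                 data.frame(participant_id = "P", movement_type = "horizontal",
                            cycle_index = 1L, source = "kid"))
  expect_equal(as.numeric(build_features(z)$X), rep(0, 30))
})

test_that("structured folds hold one cycle per participant-type stratum", {
  cyc <- tiny_cycles(n_participants = 2, types = c("horizontal", "vertical"),
                     seed = 62)
  ft <- build_features(cyc$kid)
  folds <- make_structured_folds(ft, n_folds = 10, seed = 1)
  expect_equal(sort(unique(folds)), 1:10)
  expect_true(all(table(folds) == 4))           # 2 participants x 2 types
  # disjoint cover by construction; per-stratum exactly one cycle per fold
  for (f in 1:10) {
    sel <- folds == f
    expect_true(all(table(ft$groups[sel], ft$y[sel]) == 1))
  }
  # determinism and seed sensitivity
  expect_identical(folds, make_structured_folds(ft, 10, seed = 1))
  expect_false(identical(folds, make_structured_folds(ft, 10, seed = 2)))
  # indivisible designs are rejected with the stratum named
  bad <- ft
  bad$y[1] <- "vertical"                        # 9 vs 11 cycles in P1's strata
  expect_error(make_structured_folds(bad, 10), "not divisible")
})

test_that("nested CV separates well-separated synthetic movements", {
  cyc <- tiny_cycles(n_participants = 2,
                     types = c("horizontal", "vertical", "elliptical",
                               "figure_eight"), seed = 63)
  ft <- build_features(cyc$kid)
  res <- nested_cv_svm(ft, n_folds = 10, seed = 1)
  expect_gte(res$mean_accuracy, 0.97)
  expect_length(res$fold_accuracies, 10)
  expect_equal(res$mean_accuracy, mean(res$fold_accuracies))
  expect_equal(dim(res$confusion), c(4L, 4L))
  expect_equal(as.numeric(rowSums(res$confusion)), rep(100, 4), tolerance = 1e-9)
  # determinism: identical seed, identical result
  res2 <- nested_cv_svm(ft, n_folds = 10, seed = 1)
  expect_identical(res$fold_accuracies, res2$fold_accuracies)
  expect_identical(res$chosen_C, res2$chosen_C)
})

test_that("no leakage: each fold's model is a function of training rows only", {
  cyc <- tiny_cycles(n_participants = 2, types = c("horizontal", "vertical"),
                     seed = 64)
  ft <- build_features(cyc$kid)
  folds <- make_structured_folds(ft, 10, seed = 5)
  res <- nested_cv_svm(ft, folds = folds, C_fixed = 1, seed = 5)
  # rebuild fold 3's scaler and SVM from the training rows alone and
  # reproduce the reported held-out accuracy exactly: nothing about the
  # test rows can have entered the fitted parameters
  for (f in c(3L, 7L)) {
    tr <- folds != f
    sc <- kidmotion:::fit_scaler(ft$X[tr, , drop = FALSE])
    fit <- linear_svm(kidmotion:::apply_scaler(ft$X[tr, , drop = FALSE], sc),
                      ft$y[tr], C = 1, seed = 5 + f)
    pred <- predict(fit, kidmotion:::apply_scaler(ft$X[!tr, , drop = FALSE], sc))
    expect_identical(mean(pred == ft$y[!tr]), res$fold_accuracies[f])
    # and the scaler itself ignores test rows by construction
    expect_identical(sc, kidmotion:::fit_scaler(ft$X[tr, , drop = FALSE]))
  }
})

test_that("a perfectly predictive feature gives accuracy 1", {
  set.seed(65)
  n_p <- 2
  y <- rep(rep(c("horizontal", "vertical"), each = 10), n_p)
  X <- matrix(rnorm(length(y) * 30), ncol = 30)
  X[, 1] <- ifelse(y == "horizontal", 10, -10) + rnorm(length(y), sd = 0.1)
  ft <- structure(list(X = X, y = factor(y),
                       groups = rep(c("P1", "P2"), each = 20),
                       cycle_index = rep(1:10, 4), source = "kid"),
                  class = "feature_table")
  res <- nested_cv_svm(ft, n_folds = 10, seed = 1)
  expect_equal(res$mean_accuracy, 1.0)
})

test_that("cross-classification matches within-source on noise-free pairs", {
  cyc <- tiny_cycles(n_participants = 2,
                     types = c("horizontal", "vertical", "elliptical",
                               "figure_eight"),
                     seed = 66, accel_noise_sd = 1e-6, position_noise_sd = 1e-9)
  ft_kid <- build_features(cyc$kid)
  ft_moc <- build_features(cyc$mocap)
  res_within <- nested_cv_svm(ft_kid, seed = 2)
  res_cross <- cross_classify(ft_moc, ft_kid, seed = 2)
  expect_lt(abs(res_cross$mean_accuracy - res_within$mean_accuracy), 0.01 + 1e-9)
  # test set identical to training set: resubstitution >= CV accuracy
  res_self <- cross_classify(ft_kid, ft_kid, seed = 2)
  expect_gte(res_self$mean_accuracy, res_within$mean_accuracy - 1e-9)
  # mismatched cycles rejected
  ft_bad <- ft_moc
  ft_bad$cycle_index <- rev(ft_bad$cycle_index)
  expect_error(cross_classify(ft_bad, ft_kid, seed = 2), "same cycles")
})

test_that("permutation p-values follow the add-one formula and chance level", {
  cyc <- tiny_cycles(n_participants = 2, types = c("horizontal", "vertical"),
                     seed = 67)
  ft <- build_features(cyc$kid)
  pt_hi <- permutation_test(ft, observed_accuracy = 1.01, n_perm = 5,
                            seed = 1, retune = FALSE)
  expect_equal(pt_hi$p, 1 / 6)                   # observed above every null
  pt_lo <- permutation_test(ft, observed_accuracy = -1, n_perm = 5,
                            seed = 1, retune = FALSE)
  expect_equal(pt_lo$p, 1.0)                     # observed below every null
  # chance level for 2 balanced classes is ~0.5
  expect_gt(mean(pt_hi$null_distribution), 0.3)
  expect_lt(mean(pt_hi$null_distribution), 0.7)
})

test_that("shuffled 4-class labels converge to chance accuracy", {
  cyc <- tiny_cycles(n_participants = 2,
                     types = c("horizontal", "vertical", "elliptical",
                               "figure_eight"), seed = 68)
  ft <- build_features(cyc$kid)
  pt <- permutation_test(ft, observed_accuracy = 1, n_perm = 20, seed = 9,
                         retune = FALSE, C_fixed = 1)
  expect_gte(mean(pt$null_distribution), 0.20)
  expect_lte(mean(pt$null_distribution), 0.30)
})
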