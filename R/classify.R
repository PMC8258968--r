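#' Build the classification feature table from a cycle set
#'
#' One row per movement cycle: the three world-axis bin vectors concatenated
#' in fixed order (Ax bins 1..n, then Ay, then Az). The magnitude channel is
#' excluded; with 10 bins this gives the 30 tri-axial features used for
#' movement-type classification.
#'
#' @param cycles a [cycle_set()].
#' @return object of class `feature_table`: list with `X` (cycle x feature
#'   matrix), `y` (movement-type factor), `groups` (participant ids),
#'   `cycle_index`, `source`.
#' @export
build_features <- function(cycles) {
  stopifnot(inherits(cycles, "cycle_set"))
  d <- dim(cycles$data)
  nb <- d[2L]
  X <- cbind(matrix(cycles$data[, , 1L], d[1L]),
             matrix(cycles$data[, , 2L], d[1L]),
             matrix(cycles$data[, , 3L], d[1L]))
  colnames(X) <- c(paste0("ax_b", seq_len(nb)), paste0("ay_b", seq_len(nb)),
                   paste0("az_b", seq_len(nb)))
  structure(list(X = X,
                 y = factor(cycles$labels$movement_type),
                 groups = cycles$labels$participant_id,
                 cycle_index = cycles$labels$cycle_index,
                 source = cycles$labels$source[1L]),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table:%s> %d cycles x %d features, %d classes\n",
              x$source, nrow(x$X), ncol(x$X), nlevels(x$y)))
  invisible(x)
}

#' Participant- and type-structured cross-validation folds
#'
#' Assigns cycles to folds so that every fold holds exactly the same number
#' of cycles from each participant x movement-type stratum (one each, for
#' the 10-cycle / 10-fold design): each test fold then contains one cycle
#' per participant per movement type (80 cycles in the full design). The
#' within-stratum assignment is randomized by `seed`.
#'
#' @param table a [build_features()] table.
#' @param n_folds number of folds (default 10).
#' @param seed RNG seed for the within-stratum shuffling.
#' @return integer vector of fold ids (1..n_folds), one per cycle.
#' @export
make_structured_folds <- function(table, n_folds = 10L, seed = 1L) {
  stopifnot(inherits(table, "feature_table"))
  n_folds <- as.integer(n_folds)
  set.seed(seed)
  folds <- integer(nrow(table$X))
  strata <- split(seq_len(nrow(table$X)),
                  list(table$groups, table$y), drop = TRUE)
  for (nm in names(strata)) {
    idx <- strata[[nm]]
    if (length(idx) %% n_folds != 0L) {
      stop(sprintf("stratum '%s' has %d cycles, not divisible into %d folds",
                   nm, length(idx), n_folds))
    }
    folds[idx] <- sample(rep(seq_len(n_folds), length(idx) %/% n_folds))
  }
  folds
}

# z-score standardization fit on training rows only (no leakage)
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2L, stats::sd)
  sd[sd == 0 | !is.finite(sd)] <- 1
  list(mu = mu, sd = sd)
}

apply_scaler <- function(X, sc) sweep(sweep(X, 2L, sc$mu), 2L, sc$sd, `/`)

# mean validation accuracy over the given inner folds for each C; returns the
# best C (smallest on ties)
tune_C <- function(X, y, inner_folds, C_grid, seed) {
  accs <- vapply(C_grid, function(C) {
    fold_ids <- sort(unique(inner_folds))
    mean(vapply(fold_ids, function(v) {
      tr <- inner_folds != v
      if (nlevels(droplevels(y[tr])) < nlevels(droplevels(y))) {
        stop("a class is absent from an inner training fold")
      }
      sc <- fit_scaler(X[tr, , drop = FALSE])
      fit <- linear_svm(apply_scaler(X[tr, , drop = FALSE], sc), y[tr],
                        C = C, seed = seed)
      pred <- predict(fit, apply_scaler(X[!tr, , drop = FALSE], sc))
      mean(pred == y[!tr])
    }, numeric(1)))
  }, numeric(1))
  C_grid[which.max(accs)]                    # which.max: first (smallest C) on ties
}

confusion_percent <- function(truth, pred) {
  tab <- table(truth = truth, pred = pred)
  100 * sweep(tab, 1L, pmax(rowSums(tab), 1L), `/`)
}

new_classification_result <- function(fold_acc, truth, pred, chosen_C,
                                      label = "within-source") {
  structure(list(fold_accuracies = fold_acc,
                 mean_accuracy = mean(fold_acc),
                 sem = stats::sd(fold_acc) / sqrt(length(fold_acc)),
                 confusion = confusion_percent(truth, pred),
                 chosen_C = chosen_C,
                 label = label,
                 null_distribution = NULL, p_perm = NA_real_),
            class = "classification_result")
}

#' @export
print.classification_result <- function(x, ...) {
  cat(sprintf("<classification_result> %s: accuracy %.3f +/- %.3f SEM (%d folds)\n",
              x$label, x$mean_accuracy, x$sem, length(x$fold_accuracies)))
  if (!is.na(x$p_perm)) {
    cat(sprintf("  permutation p = %.4f (%d permutations)\n",
                x$p_perm, length(x$null_distribution)))
  }
  invisible(x)
}

#' Nested cross-validated linear SVM
#'
#' Outer loop: structured 10-fold split (each test fold = one cycle per
#' participant per movement type). Inner loop: on each reduced training set,
#' the cost parameter C is tuned by validating on each of the remaining
#' structured folds in turn. Features are z-scored with parameters fit on
#' the training rows only; the model is refit on the full training set with
#' the chosen C and evaluated on the held-out fold.
#'
#' @param table a [build_features()] table.
#' @param n_folds outer folds (default 10).
#' @param C_grid candidate cost values (default `10^(-3:3)`).
#' @param seed RNG seed controlling fold assignment and solver shuffling.
#' @param folds optional precomputed fold ids (overrides the structured
#'   assignment; used by the permutation test to keep the design folds while
#'   labels are shuffled).
#' @param C_fixed optional fixed cost; skips inner tuning when given.
#' @return a `classification_result` with per-fold accuracies, mean, SEM,
#'   pooled row-normalized confusion matrix (percent) and per-fold chosen C.
#' @export
nested_cv_svm <- function(table, n_folds = 10L, C_grid = 10^(-3:3), seed = 1L,
                          folds = NULL, C_fixed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  if (is.null(folds)) folds <- make_structured_folds(table, n_folds, seed)
  fold_ids <- sort(unique(folds))
  truth_all <- factor(character(0), levels = levels(table$y))
  pred_all <- truth_all
  fold_acc <- numeric(length(fold_ids))
  chosen <- numeric(length(fold_ids))
  for (f in seq_along(fold_ids)) {
    te <- folds == fold_ids[f]
    tr <- !te
    if (nlevels(droplevels(table$y[tr])) < nlevels(table$y)) {
      stop(sprintf("a class is absent from the training data of fold %d", f))
    }
    C_best <- if (is.null(C_fixed)) {
      tune_C(table$X[tr, , drop = FALSE], table$y[tr], folds[tr], C_grid,
             seed = seed + f)
    } else C_fixed
    sc <- fit_scaler(table$X[tr, , drop = FALSE])
    fit <- linear_svm(apply_scaler(table$X[tr, , drop = FALSE], sc),
                      table$y[tr], C = C_best, seed = seed + f)
    pred <- predict(fit, apply_scaler(table$X[te, , drop = FALSE], sc))
    fold_acc[f] <- mean(pred == table$y[te])
    chosen[f] <- C_best
    truth_all <- c(truth_all, table$y[te])
    pred_all <- c(pred_all, pred)
  }
  new_classification_result(fold_acc, truth_all, pred_all, chosen,
                            label = sprintf("nested CV (%s)", table$source))
}

#' Cross-device cross-classification
#'
#' Tunes C by structured cross-validation within the training source, refits
#' on all training-source cycles, and evaluates on the other source's cycles
#' fold-by-fold (same structured folds) so the SEM is comparable to the
#' within-source analysis. The two tables must describe the same cycles
#' (matched participant, movement type and cycle index).
#'
#' @param train,test [build_features()] tables from the two sources.
#' @param C_grid candidate cost values.
#' @param n_folds folds for tuning and fold-wise evaluation.
#' @param seed RNG seed.
#' @return a `classification_result`.
#' @export
cross_classify <- function(train, test, C_grid = 10^(-3:3), n_folds = 10L,
                           seed = 1L) {
  stopifnot(inherits(train, "feature_table"), inherits(test, "feature_table"))
  if (!identical(paste(train$groups, train$y, train$cycle_index),
                 paste(test$groups, test$y, test$cycle_index))) {
    stop("training and test tables do not describe the same cycles")
  }
  folds <- make_structured_folds(train, n_folds, seed)
  C_best <- tune_C(train$X, train$y, folds, C_grid, seed = seed)
  sc <- fit_scaler(train$X)
  fit <- linear_svm(apply_scaler(train$X, sc), train$y, C = C_best, seed = seed)
  fold_ids <- sort(unique(folds))
  truth_all <- factor(character(0), levels = levels(test$y))
  pred_all <- truth_all
  fold_acc <- numeric(length(fold_ids))
  for (f in seq_along(fold_ids)) {
    te <- folds == fold_ids[f]
    pred <- predict(fit, apply_scaler(test$X[te, , drop = FALSE], sc))
    fold_acc[f] <- mean(pred == test$y[te])
    truth_all <- c(truth_all, test$y[te])
    pred_all <- c(pred_all, pred)
  }
  new_classification_result(fold_acc, truth_all, pred_all, C_best,
                            label = sprintf("cross-classification (%s -> %s)",
                                            train$source, test$source))
}

#' Permutation test of classification accuracy
#'
#' Builds the chance-level null by shuffling the movement-type labels across
#' all cycles and recomputing the full nested cross-validated accuracy for
#' each permutation; the design folds (fixed by participant and true cycle
#' slot) are kept so only the labels move. The p-value uses the add-one
#' convention `p = (1 + #{null >= observed}) / (1 + n_perm)`, whose smallest
#' attainable value with 100 permutations is 1/101.
#'
#' @param table a [build_features()] table.
#' @param observed_accuracy the accuracy to test (mean outer-fold accuracy).
#' @param n_perm number of permutations (default 100).
#' @param seed RNG seed.
#' @param n_folds,C_grid forwarded to [nested_cv_svm()].
#' @param retune if `TRUE` (default) hyperparameters are retuned within each
#'   permutation (conservative); if `FALSE`, `C_fixed` is used as a fast path.
#' @param C_fixed cost used when `retune = FALSE` (default 1).
#' @return list with `null_distribution` and `p`.
#' @export
permutation_test <- function(table, observed_accuracy, n_perm = 100L, seed = 1L,
                             n_folds = 10L, C_grid = 10^(-3:3),
                             retune = TRUE, C_fixed = 1) {
  stopifnot(inherits(table, "feature_table"), n_perm >= 1L)
  folds <- make_structured_folds(table, n_folds, seed)
  null_acc <- numeric(n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(seed + 1000L + i)
    perm <- sample(length(table$y))
    tab_p <- table
    tab_p$y <- table$y[perm]
    res <- nested_cv_svm(tab_p, n_folds = n_folds, C_grid = C_grid,
                         seed = seed + i, folds = folds,
                         C_fixed = if (retune) NULL else C_fixed)
    null_acc[i] <- res$mean_accuracy
  }
  list(null_distribution = null_acc,
       p = (1 + sum(null_acc >= observed_accuracy)) / (1 + n_perm))
}
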