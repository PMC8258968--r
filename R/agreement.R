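#' Build the per-movement-type agreement table
#'
#' For one movement type, averages the binned acceleration magnitude Am
#' across each participant's movement cycles, separately per device, and
#' stacks the participant x time-bin means into an `n x 2` table
#' (rows = participant-bin pairs, columns = KiD, MoCap). With the full
#' design this gives 20 participants x 10 bins = 200 rows.
#'
#' @param cycles_kid,cycles_mocap [cycle_set()]s with matching labels.
#' @param movement_type the movement type to extract.
#' @return numeric matrix with columns `kid` and `mocap`.
#' @export
build_agreement_table <- function(cycles_kid, cycles_mocap, movement_type) {
  stopifnot(inherits(cycles_kid, "cycle_set"), inherits(cycles_mocap, "cycle_set"))
  sel_k <- cycles_kid$labels$movement_type == movement_type
  sel_m <- cycles_mocap$labels$movement_type == movement_type
  if (!any(sel_k) || !any(sel_m)) stop(sprintf("no cycles for movement type '%s'", movement_type))
  lab_k <- cycles_kid$labels[sel_k, ]
  lab_m <- cycles_mocap$labels[sel_m, ]
  key_k <- paste(lab_k$participant_id, lab_k$cycle_index)
  key_m <- paste(lab_m$participant_id, lab_m$cycle_index)
  if (!identical(sort(key_k), sort(key_m))) {
    stop("participant/cycle labels do not match between devices")
  }
  participant_bin_means <- function(set, sel, labs) {
    am <- set$data[sel, , 4L, drop = FALSE]
    dim(am) <- dim(am)[1:2]
    parts <- sort(unique(labs$participant_id))
    do.call(rbind, lapply(parts, function(p) {
      colMeans(am[labs$participant_id == p, , drop = FALSE])
    }))
  }
  mk <- participant_bin_means(cycles_kid, sel_k, lab_k)
  mm <- participant_bin_means(cycles_mocap, sel_m, lab_m)
  out <- cbind(kid = as.numeric(t(mk)), mocap = as.numeric(t(mm)))
  rownames(out) <- NULL
  out
}

#' Two-way crossed mean squares
#'
#' Decomposes an `n x k` table (rows = observations, columns = devices) into
#' the two-way crossed ANOVA mean squares used by the intraclass correlation
#' coefficients: rows (MSR, df `n - 1`), columns (MSC, df `k - 1`) and
#' residual (MSE, df `(n - 1)(k - 1)`).
#'
#' @param table complete numeric `n x k` matrix, `n >= 2`, `k >= 2`.
#' @return object of class `mean_squares`: list with `MSR`, `MSC`, `MSE`,
#'   `n`, `k`.
#' @export
two_way_mean_squares <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table); k <- ncol(table)
  stopifnot(n >= 2L, k >= 2L)
  if (anyNA(table)) stop("agreement table has missing cells")
  grand <- mean(table)
  row_means <- rowMeans(table)
  col_means <- colMeans(table)
  ssr <- k * sum((row_means - grand)^2)
  ssc <- n * sum((col_means - grand)^2)
  sst <- sum((table - grand)^2)
  sse <- sst - ssr - ssc
  structure(list(MSR = ssr / (n - 1), MSC = ssc / (k - 1),
                 MSE = sse / ((n - 1) * (k - 1)), n = n, k = k),
            class = "mean_squares")
}

#' ICC for consistency
#'
#' `(MSR - MSE) / MSR`: the extent to which the two devices co-vary,
#' insensitive to a constant offset between them.
#'
#' @param ms a [two_way_mean_squares()] result.
#' @return numeric consistency coefficient (at most 1; may be negative for
#'   discordant columns, in which case a warning is raised).
#' @export
icc_consistency <- function(ms) {
  stopifnot(inherits(ms, "mean_squares"))
  if (ms$MSR <= 0) stop("MSR is zero: consistency undefined (no row variance)")
  val <- (ms$MSR - ms$MSE) / ms$MSR
  if (val < 0) warning("negative consistency ICC; reporting as computed")
  val
}

#' ICC for absolute agreement
#'
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)`: like consistency, but penalizing
#' systematic differences in absolute value between devices (the column
#' variance enters the denominator).
#'
#' @inheritParams icc_consistency
#' @return numeric absolute-agreement coefficient.
#' @export
icc_absolute_agreement <- function(ms) {
  stopifnot(inherits(ms, "mean_squares"))
  denom <- ms$MSR + (ms$MSC - ms$MSE) / ms$n
  if (denom <= 0) stop("non-positive denominator: absolute agreement undefined")
  val <- (ms$MSR - ms$MSE) / denom
  if (val < 0) warning("negative absolute-agreement ICC; reporting as computed")
  val
}

#' F-test of an ICC against zero
#'
#' Tests the null hypothesis ICC = 0. For both the consistency index and the
#' average-measure absolute-agreement index the null-hypothesis statistic is
#' `F = MSR / MSE`; for absolute agreement under a non-zero null value the
#' McGraw-Wong form `F = MSR / (a MSC + b MSE)` with Satterthwaite
#' denominator degrees of freedom is used (with `rho0 = 0` it reduces to
#' `MSR / MSE`).
#'
#' @param ms a [two_way_mean_squares()] result.
#' @param which `"consistency"` or `"agreement"`.
#' @param rho0 null ICC value (default 0).
#' @return list with `F`, `df1`, `df2`, `p`, and `degenerate` (`TRUE` when
#'   `MSE = 0`, where the statistic is infinite and `p` is reported as 0).
#' @export
icc_significance <- function(ms, which = c("consistency", "agreement"), rho0 = 0) {
  stopifnot(inherits(ms, "mean_squares"))
  which <- match.arg(which)
  n <- ms$n; k <- ms$k
  if (ms$MSE <= 0) {
    return(list(F = Inf, df1 = n - 1, df2 = (n - 1) * (k - 1), p = 0,
                degenerate = TRUE))
  }
  if (which == "consistency" || rho0 == 0) {
    Fstat <- ms$MSR / ms$MSE
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
  } else {
    a <- (k * rho0) / (n * (1 - rho0))
    b <- 1 + (k * rho0 * (n - 1)) / (n * (1 - rho0))
    denom <- a * ms$MSC + b * ms$MSE
    Fstat <- ms$MSR / denom
    df1 <- n - 1
    df2 <- denom^2 / ((a * ms$MSC)^2 / (k - 1) +
                        (b * ms$MSE)^2 / ((n - 1) * (k - 1)))
  }
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       degenerate = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p numeric p-values in `[0, 1]`.
#' @param m number of comparisons.
#' @return `pmin(1, m * p)`.
#' @export
bonferroni <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  pmin(1, m * p)
}

#' Full agreement analysis across movement types
#'
#' Computes both ICC indices, their F tests and Bonferroni-adjusted p-values
#' (default m = 8: four movement types x two indices) for every movement
#' type present in the cycle sets.
#'
#' @param cycles_kid,cycles_mocap [cycle_set()]s from the two devices.
#' @param bonferroni_m number of comparisons for the adjustment.
#' @return data frame with one row per movement type: `consistency`,
#'   `agreement`, F statistics, dfs, raw and adjusted p-values.
#' @export
agreement_analysis <- function(cycles_kid, cycles_mocap, bonferroni_m = 8) {
  types <- sort(unique(cycles_kid$labels$movement_type))
  rows <- lapply(types, function(mt) {
    tab <- build_agreement_table(cycles_kid, cycles_mocap, mt)
    ms <- two_way_mean_squares(tab)
    cons <- icc_consistency(ms)
    agr <- icc_absolute_agreement(ms)
    tc <- icc_significance(ms, "consistency")
    ta <- icc_significance(ms, "agreement")
    data.frame(movement_type = mt, n = ms$n,
               consistency = cons, agreement = agr,
               F_consistency = tc$F, df1_consistency = tc$df1,
               df2_consistency = tc$df2, p_consistency = tc$p,
               F_agreement = ta$F, df1_agreement = ta$df1,
               df2_agreement = ta$df2, p_agreement = ta$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_consistency_bonf <- bonferroni(out$p_consistency, bonferroni_m)
  out$p_agreement_bonf <- bonferroni(out$p_agreement, bonferroni_m)
  out
}
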