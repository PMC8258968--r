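#' Estimate the sample lag between two acceleration-magnitude series
#'
#' The optical (reference) series is kept fixed and the IMU (query) series is
#' shifted forward by 0, 1, ..., `max_lag` samples; the lag maximizing the
#' Pearson correlation over the overlapping region is returned. Only
#' non-negative integer lags are searched (the IMU stream starts earlier, so
#' its initial samples are the ones to discard); exact ties go to the
#' smallest lag.
#'
#' @param am_ref reference Am series (optical).
#' @param am_query query Am series (IMU), assumed delayed by the lag.
#' @param max_lag largest candidate lag in samples.
#' @return integer lag in samples.
#' @export
estimate_lag <- function(am_ref, am_query, max_lag = 400L) {
  max_lag <- as.integer(max_lag)
  stopifnot(length(am_ref) > 1L, length(am_query) > max_lag)
  if (stats::sd(am_ref) == 0 || stats::sd(am_query) == 0) {
    stop("cannot synchronize constant (zero-variance) series")
  }
  best_lag <- NA_integer_
  best_r <- -Inf
  for (lag in 0:max_lag) {
    n <- min(length(am_ref), length(am_query) - lag)
    if (n < 2L) break
    a <- am_ref[seq_len(n)]
    b <- am_query[lag + seq_len(n)]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    r <- stats::cor(a, b)
    if (r > best_r) {                        # strict: first (smallest) lag wins ties
      best_r <- r
      best_lag <- lag
    }
  }
  if (is.na(best_lag)) stop("no overlap between series at any candidate lag")
  best_lag
}

#' Align the IMU stream to the optical stream and trim to a common length
#'
#' Removes the first `lag` samples from every IMU channel, then truncates
#' the longer of the two streams so both have equal length.
#'
#' @param kid IMU-derived [world_accel()].
#' @param mocap optical-derived [world_accel()].
#' @param lag non-negative integer lag from [estimate_lag()].
#' @return list with elements `kid` and `mocap`, equal-length [world_accel()]s.
#' @export
align_and_trim <- function(kid, mocap, lag) {
  stopifnot(inherits(kid, "world_accel"), inherits(mocap, "world_accel"),
            lag >= 0, lag < length(kid$ax))
  keep <- (lag + 1L):length(kid$ax)
  n <- min(length(keep), length(mocap$ax))
  if (n < 1L) stop("alignment leaves no overlapping samples")
  kid_idx <- keep[seq_len(n)]
  moc_idx <- seq_len(n)
  out_kid <- world_accel(kid$ax[kid_idx], kid$ay[kid_idx], kid$az[kid_idx],
                         fs = kid$fs, source = kid$source,
                         participant_id = kid$participant_id,
                         movement_type = kid$movement_type)
  out_moc <- world_accel(mocap$ax[moc_idx], mocap$ay[moc_idx], mocap$az[moc_idx],
                         fs = mocap$fs, source = mocap$source,
                         participant_id = mocap$participant_id,
                         movement_type = mocap$movement_type)
  list(kid = out_kid, mocap = out_moc)
}

#' Segment a world-acceleration series into movement cycles
#'
#' Cycle `k` spans the half-open sample interval
#' `[boundaries[k], boundaries[k + 1])`; the last boundary may be one past
#' the final sample. Boundaries come from the event markers recorded during
#' acquisition (or from the simulator's ground truth), not from signal
#' periodicity.
#'
#' @param series a [world_accel()].
#' @param boundaries sorted integer sample indices, length >= 2.
#' @return list of cycles; each cycle is a list of numeric vectors
#'   `ax`, `ay`, `az`, `am`.
#' @export
segment_cycles <- function(series, boundaries) {
  stopifnot(inherits(series, "world_accel"), length(boundaries) >= 2L)
  boundaries <- as.integer(boundaries)
  if (is.unsorted(boundaries, strictly = TRUE)) stop("boundaries must be strictly increasing")
  n <- length(series$ax)
  if (min(boundaries) < 1L || max(boundaries) > n + 1L) {
    stop("boundaries fall outside the series")
  }
  lapply(seq_len(length(boundaries) - 1L), function(k) {
    idx <- boundaries[k]:(boundaries[k + 1L] - 1L)
    list(ax = series$ax[idx], ay = series$ay[idx],
         az = series$az[idx], am = series$am[idx])
  })
}

#' Time-normalize one cycle into percentage bins
#'
#' Partitions the cycle into `n_bins` contiguous, near-equal blocks of
#' samples (any remainder goes to the earliest bins) and averages within
#' each block, expressing the cycle on a normalized 0-100% timescale at
#' intervals of `100 / n_bins` percent.
#'
#' @param x numeric vector, one channel of one cycle.
#' @param n_bins number of time bins (default 10, i.e. 10% bins).
#' @return numeric vector of `n_bins` bin means.
#' @export
resample_bins <- function(x, n_bins = 10L) {
  n <- length(x)
  n_bins <- as.integer(n_bins)
  if (n < n_bins) stop(sprintf("cycle of %d samples is shorter than %d bins", n, n_bins))
  base <- n %/% n_bins
  extra <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, extra), rep(0L, n_bins - extra))
  grp <- rep(seq_len(n_bins), times = sizes)
  as.numeric(tapply(x, grp, mean))
}

#' Build a time-normalized cycle set from a segmented series
#'
#' @param series a [world_accel()].
#' @param boundaries cycle boundaries as in [segment_cycles()].
#' @param n_bins bins per cycle.
#' @return a [cycle_set()] with one row per cycle.
#' @export
build_cycle_set <- function(series, boundaries, n_bins = 10L) {
  cycles <- segment_cycles(series, boundaries)
  nc <- length(cycles)
  data <- array(NA_real_, c(nc, n_bins, 4L))
  for (k in seq_len(nc)) {
    data[k, , 1L] <- resample_bins(cycles[[k]]$ax, n_bins)
    data[k, , 2L] <- resample_bins(cycles[[k]]$ay, n_bins)
    data[k, , 3L] <- resample_bins(cycles[[k]]$az, n_bins)
    data[k, , 4L] <- resample_bins(cycles[[k]]$am, n_bins)
  }
  labels <- data.frame(participant_id = rep(series$participant_id, nc),
                       movement_type = rep(series$movement_type, nc),
                       cycle_index = seq_len(nc),
                       source = rep(series$source, nc),
                       stringsAsFactors = FALSE)
  cycle_set(data, labels)
}

#' Process one paired recording into aligned cycle sets
#'
#' Convenience wrapper for a single participant x movement series: converts
#' both streams to filtered world acceleration, estimates the lag on Am,
#' aligns and trims, shifts the recorded markers by the estimated lag, and
#' bins both streams with the shared boundaries.
#'
#' @param imu an [imu_recording()].
#' @param mocap a [marker_trajectory()].
#' @param gravity,cutoff,order preprocessing settings.
#' @param max_lag lag search range in samples.
#' @param n_bins bins per cycle.
#' @param sync_trim_s seconds trimmed from the edges of the reference Am
#'   copy (and from the start of the query copy) before the lag search, to
#'   keep onset and end-of-stream transients out of the correlation window.
#' @return list with `kid` and `mocap` [cycle_set()]s, plus `lag`.
#' @export
process_pair <- function(imu, mocap, gravity = 9.81, cutoff = 6, order = 2L,
                         max_lag = 400L, n_bins = 10L, sync_trim_s = 1) {
  wa_kid <- to_world_frame(imu, gravity = gravity, cutoff = cutoff, order = order)
  wa_moc <- differentiate_position(mocap, cutoff = cutoff, order = order)
  # Condition the Am copies used for the lag search only: drop the movement
  # onset (abrupt rest-to-motion transition) and the end-of-stream filter
  # transient from the reference, and smooth both copies at half the analysis
  # cutoff. This sharpens the integer-lag correlation peak for movements
  # whose Am modulation is weak; the aligned output streams are untouched.
  trim <- min(round(sync_trim_s * imu$fs),
              max(0L, (length(wa_moc$am) - 2L * max_lag) %/% 4L))
  am_ref <- wa_moc$am[(trim + 1L):(length(wa_moc$am) - trim)]
  am_query <- wa_kid$am[(trim + 1L):length(wa_kid$am)]
  if (!is.null(cutoff) && length(am_ref) > 4 * imu$fs / cutoff) {
    am_ref <- lowpass_filter(am_ref, cutoff / 2, imu$fs, order)
    am_query <- lowpass_filter(am_query, cutoff / 2, imu$fs, order)
  }
  lag <- estimate_lag(am_ref, am_query, max_lag = max_lag)
  aligned <- align_and_trim(wa_kid, wa_moc, lag)
  boundaries <- imu$markers - lag
  # a residual one-sample misalignment must not drop a whole cycle: clamp
  # boundaries into range, keeping them strictly increasing
  boundaries <- pmin(pmax(boundaries, 1L), length(aligned$kid$ax) + 1L)
  boundaries <- boundaries[!duplicated(boundaries)]
  if (length(boundaries) < 2L) stop("no usable cycle boundaries after alignment")
  list(kid = build_cycle_set(aligned$kid, boundaries, n_bins),
       mocap = build_cycle_set(aligned$mocap, boundaries, n_bins),
       lag = lag)
}
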