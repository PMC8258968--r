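#' Element-wise acceleration magnitude
#'
#' @param ax,ay,az equal-length numeric series.
#' @return numeric series of Euclidean norms.
#' @export
accel_magnitude <- function(ax, ay, az) {
  if (length(ax) != length(ay) || length(ay) != length(az)) {
    stop("acceleration channels have unequal lengths")
  }
  sqrt(ax^2 + ay^2 + az^2)
}

# central second difference with one-sided (forward/backward) endpoint
# formulas; exact on quadratics in the interior
second_difference <- function(pos, fs) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  if (n < 3L) stop("need at least 3 samples to differentiate")
  acc <- matrix(NA_real_, n, ncol(pos))
  i <- 2L:(n - 1L)
  acc[i, ] <- (pos[i + 1L, , drop = FALSE] - 2 * pos[i, , drop = FALSE] +
                 pos[i - 1L, , drop = FALSE]) * fs^2
  acc[1L, ] <- (pos[3L, ] - 2 * pos[2L, ] + pos[1L, ]) * fs^2
  acc[n, ] <- (pos[n, ] - 2 * pos[n - 1L, ] + pos[n - 2L, ]) * fs^2
  acc
}

#' Rotate an IMU recording into the world frame and remove gravity
#'
#' Applies the per-sample quaternion rotation `a_world = R(q_i) a_device_i`,
#' then subtracts the constant gravity reaction `(0, 0, +gravity)` so that
#' only motion acceleration remains, and finally low-pass filters each
#' channel. World axes follow the study convention: x mediolateral
#' (left-right), y anteroposterior (forward-backward), z vertical (up-down).
#'
#' @param rec an [imu_recording()].
#' @param gravity gravity magnitude to subtract from world z, m/s^2
#'   (default 9.81). Set to 0 if the stream is already gravity-free.
#' @param cutoff,order low-pass Butterworth settings passed to
#'   [lowpass_filter()]; `cutoff = NULL` skips filtering.
#' @return a [world_accel()] with `source = "kid"`.
#' @export
to_world_frame <- function(rec, gravity = 9.81, cutoff = 6, order = 2L) {
  stopifnot(inherits(rec, "imu_recording"))
  n <- nrow(rec$accel)
  constant_q <- n == 1L ||
    all(abs(sweep(rec$quat, 2L, rec$quat[1L, ])) < .Machine$double.eps)
  if (constant_q) {
    aw <- rec$accel %*% t(quat_to_rotation(rec$quat[1L, ]))
  } else {
    aw <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
      aw[i, ] <- quat_to_rotation(rec$quat[i, ]) %*% rec$accel[i, ]
    }
  }
  aw[, 3L] <- aw[, 3L] - gravity
  if (!is.null(cutoff)) aw <- lowpass_filter(aw, cutoff = cutoff, fs = rec$fs, order = order)
  world_accel(aw[, 1L], aw[, 2L], aw[, 3L], fs = rec$fs, source = "kid",
              participant_id = rec$participant_id,
              movement_type = rec$movement_type)
}

#' Differentiate an optical-marker trajectory into world acceleration
#'
#' Low-pass filters the position channels (differentiation amplifies
#' high-frequency noise, so smoothing must come first), then applies the
#' central second difference `a[i] = (p[i+1] - 2 p[i] + p[i-1]) * fs^2`, with
#' one-sided formulas at the two endpoints.
#'
#' @param traj a [marker_trajectory()].
#' @param cutoff,order Butterworth settings for the position pre-filter;
#'   `cutoff = NULL` skips filtering.
#' @param max_gap longest run of missing samples (camera drop-out) that will
#'   be linearly interpolated; longer gaps raise an error.
#' @return a [world_accel()] with `source = "mocap"`.
#' @export
differentiate_position <- function(traj, cutoff = 6, order = 2L, max_gap = 10L) {
  stopifnot(inherits(traj, "marker_trajectory"))
  pos <- traj$position
  if (anyNA(pos)) pos <- fill_gaps(pos, max_gap = max_gap)
  if (nrow(pos) < 3L) stop("trajectory too short to differentiate (need >= 3 samples)")
  if (!is.null(cutoff)) pos <- lowpass_filter(pos, cutoff = cutoff, fs = traj$fs, order = order)
  acc <- second_difference(pos, traj$fs)
  world_accel(acc[, 1L], acc[, 2L], acc[, 3L], fs = traj$fs, source = "mocap",
              participant_id = traj$participant_id,
              movement_type = traj$movement_type)
}

# linear interpolation of NA runs up to max_gap samples, per column
fill_gaps <- function(pos, max_gap = 10L) {
  for (j in seq_len(ncol(pos))) {
    miss <- is.na(pos[, j])
    if (!any(miss)) next
    runs <- rle(miss)
    if (max(runs$lengths[runs$values]) > max_gap) {
      stop(sprintf("marker gap longer than %d samples; cannot interpolate", max_gap))
    }
    if (miss[1L] || miss[length(miss)]) {
      stop("trajectory starts or ends with missing samples")
    }
    pos[, j] <- stats::approx(which(!miss), pos[!miss, j], xout = seq_len(nrow(pos)))$y
  }
  pos
}
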