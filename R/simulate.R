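#' Movement specification
#'
#' Geometry and timing of one sinusoidal arm-movement task. The four types
#' mirror the validation protocol: horizontal (left-right, ~40 cm peak-to-peak),
#' vertical (up-down, ~50 cm peak-to-peak), elliptical (template ellipse with
#' 22.5 cm major and 15.1 cm minor axis, traced in the frontal x-z plane) and
#' figure-eight (1:2 Lissajous in the same plane, same axis lengths).
#'
#' @param movement_type one of `"horizontal"`, `"vertical"`, `"elliptical"`,
#'   `"figure_eight"`.
#' @param amplitude for horizontal/vertical: full peak-to-peak extent in
#'   meters (defaults 0.40 and 0.50); for elliptical/figure_eight: length-2
#'   vector of semi-axes in meters (default `c(0.1125, 0.0755)`).
#' @param cycle_duration nominal duration of one movement cycle in seconds.
#'   The tempo was paced only approximately in the protocol; 2 s is this
#'   package's default, not a measured value.
#' @param n_cycles number of movement cycles (default 10).
#' @return object of class `movement_spec`.
#' @export
movement_spec <- function(movement_type = c("horizontal", "vertical",
                                            "elliptical", "figure_eight"),
                          amplitude = NULL, cycle_duration = 2, n_cycles = 10L) {
  movement_type <- match.arg(movement_type)
  if (is.null(amplitude)) {
    amplitude <- switch(movement_type,
      horizontal = 0.40, vertical = 0.50,
      elliptical = c(0.1125, 0.0755), figure_eight = c(0.1125, 0.0755))
  }
  stopifnot(all(amplitude > 0), cycle_duration > 0, n_cycles >= 1)
  if (movement_type %in% c("elliptical", "figure_eight") && length(amplitude) != 2L) {
    stop("elliptical and figure-eight movements need two semi-axis lengths")
  }
  structure(list(movement_type = movement_type, amplitude = amplitude,
                 cycle_duration = cycle_duration, n_cycles = as.integer(n_cycles)),
            class = "movement_spec")
}

#' Simulation configuration
#'
#' Parameters of the paired IMU / optical-marker simulator. Defaults state
#' the conditions the pipeline is validated under: 200 Hz sampling, white
#' accelerometer noise of 0.05 m/s^2, sub-millimeter optical position noise
#' (0.5 mm), gravity 9.81 m/s^2 along world -z, +/-5% uniform per-cycle
#' tempo jitter (the auditory pacing tone was only approximate).
#'
#' @param sampling_rate Hz (default 200).
#' @param accel_noise_sd accelerometer noise SD, m/s^2, in the device frame.
#' @param position_noise_sd optical marker noise SD, m.
#' @param device_orientation unit quaternion `(w, x, y, z)` rotating device
#'   vectors into the world frame; constant over a recording.
#' @param lag_samples non-negative integer delay of the IMU stream relative
#'   to the optical stream (the IMU starts recording earlier and idles in a
#'   rest pose).
#' @param gravity gravitational acceleration magnitude, m/s^2, acting along
#'   world -z; a resting accelerometer therefore reads +gravity on world z.
#' @param cycle_jitter half-width of the uniform per-cycle duration jitter,
#'   as a fraction of the nominal cycle duration.
#' @param seed integer RNG seed, or `NULL` to use the current RNG state.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 200, accel_noise_sd = 0.05,
                       position_noise_sd = 5e-4,
                       device_orientation = c(1, 0, 0, 0),
                       lag_samples = 0L, gravity = 9.81,
                       cycle_jitter = 0.05, seed = NULL) {
  stopifnot(sampling_rate > 0, accel_noise_sd >= 0, position_noise_sd >= 0,
            lag_samples >= 0, gravity >= 0,
            cycle_jitter >= 0, cycle_jitter < 1)
  device_orientation <- quat_normalize(device_orientation)
  structure(list(sampling_rate = sampling_rate, accel_noise_sd = accel_noise_sd,
                 position_noise_sd = position_noise_sd,
                 device_orientation = device_orientation,
                 lag_samples = as.integer(lag_samples), gravity = gravity,
                 cycle_jitter = cycle_jitter, seed = seed),
            class = "sim_config")
}

# closed-form position and its second time derivative at phase phi (radians,
# 2*pi per cycle), for angular rate omega = 2*pi / T of the current cycle
movement_curves <- function(spec, phi, omega) {
  n <- length(phi)
  pos <- matrix(0, n, 3L)
  acc <- matrix(0, n, 3L)
  # resting arm posture: hand in front of the trunk at shoulder height
  center <- c(0, 0.30, 1.00)
  switch(spec$movement_type,
    horizontal = {
      A <- spec$amplitude[1L] / 2
      pos[, 1L] <- A * sin(phi)
      acc[, 1L] <- -A * sin(phi) * omega^2
    },
    vertical = {
      A <- spec$amplitude[1L] / 2
      pos[, 3L] <- A * sin(phi)
      acc[, 3L] <- -A * sin(phi) * omega^2
    },
    elliptical = {
      a <- spec$amplitude[1L]; b <- spec$amplitude[2L]
      pos[, 1L] <- a * cos(phi); pos[, 3L] <- b * sin(phi)
      acc[, 1L] <- -a * cos(phi) * omega^2
      acc[, 3L] <- -b * sin(phi) * omega^2
    },
    figure_eight = {
      a <- spec$amplitude[1L]; b <- spec$amplitude[2L]
      pos[, 1L] <- a * sin(phi); pos[, 3L] <- b * sin(2 * phi)
      acc[, 1L] <- -a * sin(phi) * omega^2
      acc[, 3L] <- -4 * b * sin(2 * phi) * omega^2
    })
  pos <- sweep(pos, 2L, center, `+`)
  list(pos = pos, acc = acc)
}

#' Generate an optical-marker trajectory for one movement series
#'
#' Samples the closed-form movement curve at the configured rate, applies
#' per-cycle tempo jitter, and adds Gaussian position noise. The noise-free
#' analytic acceleration and the ground-truth cycle boundaries are attached
#' as attributes (`"accel_true"`, `"boundaries"`); the final boundary index
#' is `n + 1`, the exclusive end of the last cycle.
#'
#' @param spec a [movement_spec()].
#' @param cfg a [sim_config()]. `cfg$seed`, if set, seeds the RNG.
#' @param participant_id optional participant label carried on the output.
#' @return a [marker_trajectory()] with attributes `boundaries` (integer,
#'   length `n_cycles + 1`) and `accel_true` (n x 3 matrix, m/s^2).
#' @export
generate_trajectory <- function(spec, cfg, participant_id = NA_character_) {
  stopifnot(inherits(spec, "movement_spec"), inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  fs <- cfg$sampling_rate
  jit <- stats::runif(spec$n_cycles, -cfg$cycle_jitter, cfg$cycle_jitter)
  durations <- spec$cycle_duration * (1 + jit)
  ends <- cumsum(durations)
  starts <- c(0, ends[-length(ends)])
  n <- round(ends[spec$n_cycles] * fs)
  t <- (seq_len(n) - 1L) / fs
  cyc <- findInterval(t, ends) + 1L          # cycle index per sample
  cyc[cyc > spec$n_cycles] <- spec$n_cycles
  omega <- 2 * pi / durations[cyc]
  phi <- 2 * pi * (cyc - 1L) + (t - starts[cyc]) * omega
  curves <- movement_curves(spec, phi, omega)
  pos <- curves$pos
  if (cfg$position_noise_sd > 0) {
    pos <- pos + matrix(stats::rnorm(3L * n, sd = cfg$position_noise_sd), n, 3L)
  }
  boundaries <- as.integer(c(1L, round(ends * fs) + 1L))
  traj <- marker_trajectory(t, pos, fs, participant_id = participant_id,
                            movement_type = spec$movement_type)
  attr(traj, "boundaries") <- boundaries
  attr(traj, "accel_true") <- curves$acc
  traj
}

#' Simulate an IMU recording paired with a marker trajectory
#'
#' Builds the device-frame accelerometer stream the wearable would have
#' produced while tracing `traj`: the world-frame motion acceleration plus
#' the gravity reaction `(0, 0, +g)` is rotated into the device frame by the
#' inverse of the device orientation, white noise is added, and the stream is
#' delayed by `cfg$lag_samples` rest-pose samples (gravity only) to emulate
#' the IMU starting before the optical system. Event markers are emitted at
#' the true cycle boundaries, shifted by the lag.
#'
#' @param traj a trajectory from [generate_trajectory()] (must carry the
#'   `accel_true` attribute; otherwise the trajectory is numerically
#'   differentiated, which amplifies any position noise).
#' @param cfg a [sim_config()].
#' @return an [imu_recording()].
#' @export
simulate_imu <- function(traj, cfg) {
  stopifnot(inherits(traj, "marker_trajectory"), inherits(cfg, "sim_config"))
  acc_true <- attr(traj, "accel_true")
  if (is.null(acc_true)) {
    acc_true <- second_difference(traj$position, traj$fs)
  }
  n <- nrow(acc_true)
  lag <- cfg$lag_samples
  g_world <- c(0, 0, cfg$gravity)            # accelerometer gravity reaction
  f_world <- sweep(acc_true, 2L, g_world, `+`)
  rest <- matrix(0, nrow = lag, ncol = 3L)
  if (lag > 0L) rest <- sweep(rest, 2L, g_world, `+`)
  # one trailing rest sample so the final boundary MARK lands on a stored row
  f_world <- rbind(rest, f_world, g_world)
  a_dev <- quat_rotate(f_world, cfg$device_orientation, inverse = TRUE)
  if (cfg$accel_noise_sd > 0) {
    a_dev <- a_dev + matrix(stats::rnorm(length(a_dev), sd = cfg$accel_noise_sd),
                            nrow(a_dev), 3L)
  }
  nn <- n + lag + 1L
  quat <- matrix(rep(cfg$device_orientation, each = nn), nn, 4L)
  boundaries <- attr(traj, "boundaries")
  markers <- if (is.null(boundaries)) integer(0) else boundaries + lag
  imu_recording(timestamps = (seq_len(nn) - 1L) / traj$fs,
                accel = a_dev, quat = quat, fs = traj$fs, markers = markers,
                participant_id = traj$participant_id,
                movement_type = traj$movement_type)
}

#' Generate the full paired study design
#'
#' Simulates `n_participants` participants each performing every movement in
#' `movement_specs` (default: the four-task protocol, 10 cycles each),
#' producing one IMU recording and one optical trajectory per participant and
#' movement. Each participant gets a random device orientation (uniform on
#' SO(3)), a random IMU-vs-optical start lag, and fresh noise; cycle tempo is
#' jittered per cycle. Fully reproducible from `cfg$seed`.
#'
#' @param n_participants number of participants (default 20).
#' @param movement_specs list of [movement_spec()] objects.
#' @param cfg a [sim_config()]; `device_orientation` and `lag_samples` are
#'   ignored here and randomized per participant.
#' @param lag_range integer range to draw each participant's lag from,
#'   in samples (default 0 to 80, i.e. up to 0.4 s at 200 Hz).
#' @return object of class `paired_dataset`: a list of records, each with
#'   elements `participant_id`, `movement_type`, `imu`, `mocap`,
#'   `lag_true`, `boundaries`.
#' @export
generate_dataset <- function(n_participants = 20L,
                             movement_specs = default_movement_specs(),
                             cfg = sim_config(), lag_range = c(0L, 80L)) {
  stopifnot(n_participants >= 1)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  records <- list()
  for (p in seq_len(n_participants)) {
    pid <- sprintf("P%02d", p)
    q <- random_quaternion()
    lag <- sample(seq(lag_range[1L], lag_range[2L]), 1L)
    for (spec in movement_specs) {
      cfg_p <- cfg
      cfg_p$seed <- NULL                     # one seeding at dataset level
      cfg_p$device_orientation <- q
      cfg_p$lag_samples <- lag
      traj <- generate_trajectory(spec, cfg_p, participant_id = pid)
      imu <- simulate_imu(traj, cfg_p)
      records[[length(records) + 1L]] <-
        list(participant_id = pid, movement_type = spec$movement_type,
             imu = imu, mocap = traj, lag_true = lag,
             boundaries = attr(traj, "boundaries"))
    }
  }
  structure(records, class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d recordings (%d participants x %d movement types)\n",
              length(x), length(unique(vapply(x, `[[`, "", "participant_id"))),
              length(unique(vapply(x, `[[`, "", "movement_type")))))
  invisible(x)
}

#' Default four-movement protocol
#' @param cycle_duration nominal cycle duration in seconds.
#' @param n_cycles cycles per movement series.
#' @return list of four [movement_spec()] objects.
#' @export
default_movement_specs <- function(cycle_duration = 2, n_cycles = 10L) {
  lapply(c("horizontal", "vertical", "elliptical", "figure_eight"),
         movement_spec, cycle_duration = cycle_duration, n_cycles = n_cycles)
}
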