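# Shared fixtures. The full study design is expensive (~20 s), so the
# acceptance tests build it once and cache it for the whole test run.

tiny_specs <- function(types = c("horizontal", "vertical"), cycle_duration = 1,
                       n_cycles = 10L) {
  lapply(types, movement_spec, cycle_duration = cycle_duration,
         n_cycles = n_cycles)
}

# small paired dataset processed into cycle sets
tiny_cycles <- function(n_participants = 2L, types = c("horizontal", "vertical"),
                        n_cycles = 10L, seed = 1L, accel_noise_sd = 0.05,
                        position_noise_sd = 5e-4, n_bins = 10L) {
  ds <- generate_dataset(
    n_participants = n_participants,
    movement_specs = tiny_specs(types, n_cycles = n_cycles),
    cfg = sim_config(accel_noise_sd = accel_noise_sd,
                     position_noise_sd = position_noise_sd, seed = seed),
    lag_range = c(0L, 40L))
  pairs <- lapply(ds, function(r) {
    process_pair(r$imu, r$mocap, max_lag = 100L, n_bins = n_bins)
  })
  list(kid = bind_cycle_sets(lapply(pairs, `[[`, "kid")),
       mocap = bind_cycle_sets(lapply(pairs, `[[`, "mocap")),
       dataset = ds)
}

.acceptance_env <- new.env(parent = emptyenv())

# full 20 x 4 x 10 design at default (stated-world) noise, seed 1; processed
# once and reused by every acceptance criterion
acceptance_fixture <- function() {
  if (!is.null(.acceptance_env$fx)) return(.acceptance_env$fx)
  ds <- generate_dataset(n_participants = 20L,
                         movement_specs = default_movement_specs(),
                         cfg = sim_config(seed = 1L))
  pairs <- lapply(ds, function(r) process_pair(r$imu, r$mocap))
  fx <- list(
    dataset = ds,
    kid = bind_cycle_sets(lapply(pairs, `[[`, "kid")),
    mocap = bind_cycle_sets(lapply(pairs, `[[`, "mocap")),
    lags_est = vapply(pairs, `[[`, numeric(1), "lag"),
    lags_true = vapply(ds, `[[`, numeric(1), "lag_true"))
  .acceptance_env$fx <- fx
  fx
}
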