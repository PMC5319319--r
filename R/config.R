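#' Default run configuration
#'
#' The hierarchical configuration tying all pipeline blocks together. Every
#' tunable parameter of the flock, predator, tracker, trial protocol,
#' experimental design and analysis is addressable here; a flat YAML file
#' with any subset of these keys overrides the defaults.
#'
#' @return A nested list of class `run_config`.
#' @export
default_run_config <- function() {
  cfg <- list(
    seed = 1L,
    output_dir = ".",
    design = list(sizes = c(1, 50, 250, 1000, 5000),
                  densities = c("dense", "normal", "loose"),
                  practice_reps = 4L, experimental_reps = 15L,
                  participants = 25L),
    density_map = list(literal = FALSE),
    flock = list(k_neighbours = 7L, cruise_speed = 10, dt = 0.05,
                 reaction_dt = 0.05, w_sep = 12, w_ali = 4, w_coh = 2,
                 coh_sat = 1, w_spd = 2, w_alt = 0.4, w_alt_damp = 0.8,
                 pref_altitude = 50, v_min = 6, v_max = 14,
                 max_accel = 19.62, noise_sd = 0.4),
    predator = list(v_min = 4, v_max = 20, thrust_accel = 8,
                    roll_max = pi / 3, roll_rate_max = pi,
                    pitch_rate_max = pi / 2, gamma_max = pi / 3),
    tracker = list(h0 = 3e-4, theta = 0.02, decision_dt = 0.1,
                   jitter_sd = 0.2),
    controller = list(name = "pursuit", strike_radius = 0.5,
                      arm_distance = 3),
    trial = list(timeout = 30, start_distance = 100, start_altitude = 50,
                 trail_duration = 1, trail_fade_far = 40,
                 trail_fade_near = 20, dt = 0.05, flock_burn_in = 2,
                 record_trajectories = FALSE),
    analysis = list(max_error = 20, alpha = 0.05))
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration
#'
#' Reads a YAML file, validates every key against the documented schema
#' (unknown keys are rejected by name) and fills unset values with the
#' defaults. An empty or absent-block file yields [default_run_config()].
#' `save_config()` followed by `load_config()` round-trips losslessly.
#'
#' @param path YAML file.
#' @return A validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  defaults <- default_run_config()
  merged <- .merge_config(defaults, user, "")
  class(merged) <- "run_config"
  merged
}

.merge_config <- function(defaults, user, prefix) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("schema error: unknown config key(s): ",
         paste0(prefix, unknown, collapse = ", "), call. = FALSE)
  for (key in names(user)) {
    dv <- defaults[[key]]
    uv <- user[[key]]
    if (is.list(dv) && !is.list(uv))
      stop("schema error: key '", prefix, key, "' must be a block",
           call. = FALSE)
    if (is.list(dv)) {
      defaults[[key]] <- .merge_config(dv, uv, paste0(prefix, key, "."))
    } else {
      if (is.numeric(dv) && !is.numeric(uv) && !is.null(uv))
        stop("schema error: key '", prefix, key, "' must be numeric",
             call. = FALSE)
      defaults[[key]] <- if (is.integer(dv) && is.numeric(uv))
        as.integer(uv) else uv
    }
  }
  defaults
}

#' @rdname load_config
#' @param config A `run_config`.
#' @export
save_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' Build module objects from a run configuration
#'
#' Helpers expanding a `run_config` into the per-module configuration
#' objects.
#'
#' @param config A `run_config`.
#' @param flock_size,density For `config_trial`, the cell to instantiate.
#' @param seed Trial seed.
#' @return The corresponding module object.
#' @export
config_tracker <- function(config) {
  tracker_params(h0 = config$tracker$h0, theta = config$tracker$theta,
                 decision_dt = config$tracker$decision_dt)
}

#' @rdname config_tracker
#' @export
config_design <- function(config) {
  experiment_design(sizes = config$design$sizes,
                    densities = config$design$densities,
                    practice_reps = config$design$practice_reps,
                    experimental_reps = config$design$experimental_reps)
}

#' @rdname config_tracker
#' @export
config_trial <- function(config, flock_size, density, seed = config$seed) {
  tr <- config$trial
  trial_config(flock_size = flock_size, density = density, seed = seed,
               timeout = tr$timeout, start_distance = tr$start_distance,
               start_altitude = tr$start_altitude,
               trail_duration = tr$trail_duration,
               trail_fade_far = tr$trail_fade_far,
               trail_fade_near = tr$trail_fade_near, dt = tr$dt,
               flock_burn_in = tr$flock_burn_in,
               record_trajectories = tr$record_trajectories,
               flock = config$flock,
               density_map = density_labels(config$density_map$literal))
}

#' Write a results table as CSV
#'
#' @param table A `results_table`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results_csv()]
#'
#' @param path CSV file.
#' @return A `results_table`.
#' @export
read_results_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(tab) <- c("results_table", class(tab))
  tab
}

#' Export a flock trajectory as CSV
#'
#' One row per bird per sampled frame, columns time, bird_id, x, y, z, vx,
#' vy, vz.
#'
#' @param state A `flock_state` from [simulate_flock()] run with
#'   `record_every` set, or the trajectory data.frame itself.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_flock_csv <- function(state, path) {
  traj <- if (is.data.frame(state)) state else attr(state, "trajectory")
  if (is.null(traj))
    stop("no trajectory recorded; run simulate_flock(record_every = ...)",
         call. = FALSE)
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
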