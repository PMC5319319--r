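#' Trial configuration
#'
#' Parameters of one virtual-predation trial. The protocol constants default
#' to the experiment's: the predator starts exactly 100 m from a randomly
#' chosen target bird, both at 50 m altitude; the target is marked by a 1 s
#' trail that fades linearly between 40 m and 20 m predator-target distance;
#' the trial times out after 30 s.
#'
#' @param flock_size Number of birds.
#' @param density Density setting: a label (`"dense"`, `"normal"`,
#'   `"loose"`) or a target mean NND in metres.
#' @param seed Integer seed for the trial's randomness (flock initialisation,
#'   target choice, predator bearing, tracker decisions).
#' @param timeout Trial timeout, s.
#' @param start_distance Initial predator-target distance, m.
#' @param start_altitude Shared initial altitude, m.
#' @param trail_duration Length of the target trail, s.
#' @param trail_fade_far,trail_fade_near Distances (m) between which trail
#'   opacity ramps from 1 to 0.
#' @param dt Simulation step, s.
#' @param flock_burn_in Seconds of flock settling before the trial starts.
#' @param record_trajectories Keep full predator/target trajectories in the
#'   trial record?
#' @param flock Optional list of [flock_config()] overrides (e.g. a
#'   calibrated `separation_radius`).
#' @param density_map Label mapping, see [density_labels()].
#' @return An object of class `trial_config`.
#' @export
trial_config <- function(flock_size, density = "normal", seed = 1L,
                         timeout = 30, start_distance = 100,
                         start_altitude = 50, trail_duration = 1,
                         trail_fade_far = 40, trail_fade_near = 20,
                         dt = 0.05, flock_burn_in = 2,
                         record_trajectories = TRUE, flock = list(),
                         density_map = density_labels()) {
  if (timeout <= 0) stop("'timeout' must be positive", call. = FALSE)
  if (!(trail_fade_far > trail_fade_near && trail_fade_near > 0))
    stop("need trail_fade_far > trail_fade_near > 0", call. = FALSE)
  nnd <- resolve_density(density, density_map)
  cfg <- list(flock_size = as.integer(flock_size),
              density = nnd,
              density_label = if (is.character(density)) density else
                names(density_map)[match(nnd, density_map)],
              seed = as.integer(seed), timeout = timeout,
              start_distance = start_distance,
              start_altitude = start_altitude,
              trail_duration = trail_duration,
              trail_fade_far = trail_fade_far,
              trail_fade_near = trail_fade_near,
              dt = dt, flock_burn_in = flock_burn_in,
              record_trajectories = record_trajectories,
              flock = flock)
  class(cfg) <- "trial_config"
  cfg
}

.trial_flock_config <- function(config) {
  args <- list(n_birds = config$flock_size, target_nnd = config$density,
               dt = config$dt, reaction_dt = config$dt,
               pref_altitude = config$start_altitude)
  args[names(config$flock)] <- config$flock
  do.call(flock_config, args)
}

#' Initialise a trial
#'
#' Builds the starting world state: the flock at the configured size and
#' density (after a short settling run), a uniformly chosen target bird, and
#' the predator placed at a random azimuth so that its distance to the target
#' is exactly `start_distance`, both at `start_altitude`, heading at the
#' target.
#'
#' @param config A [trial_config()].
#' @return A list with `flock` (`flock_state`), `flock_config`, `target_id`,
#'   `predator` (`predator_state`) and `predator_config`.
#' @export
initialize_trial <- function(config) {
  stopifnot(inherits(config, "trial_config"))
  set.seed(config$seed)
  fcfg <- .trial_flock_config(config)
  fcfg$seed <- NULL   # RNG already seeded at trial level
  flock <- init_flock(fcfg, centre = c(0, 0, config$start_altitude))
  if (config$flock_burn_in > 0 && config$flock_size > 1L)
    flock <- simulate_flock(fcfg, config$flock_burn_in, state = flock)

  target_id <- if (config$flock_size == 1L) 1L else
    sample.int(config$flock_size, 1L)
  # shift the whole flock so the target sits exactly at start altitude
  flock$pos[, 3] <- flock$pos[, 3] +
    (config$start_altitude - flock$pos[target_id, 3])

  az <- stats::runif(1L, 0, 2 * pi)
  tp <- flock$pos[target_id, ]
  ppos <- tp + config$start_distance * c(cos(az), sin(az), 0)
  pcfg <- predator_config()
  pred <- predator_state(ppos, speed = 15,
                         heading = atan2(tp[2] - ppos[2], tp[1] - ppos[1]))
  list(flock = flock, flock_config = fcfg, target_id = target_id,
       predator = pred, predator_config = pcfg)
}

#' Trail opacity
#'
#' Opacity of the target's marker trail as a function of predator-target
#' distance: fully opaque at or beyond `trail_fade_far` (40 m), invisible at
#' or below `trail_fade_near` (20 m), linear in between.
#'
#' @param distance_to_target Distance(s) in metres (>= 0).
#' @param config A [trial_config()] (only the fade distances are used).
#' @return Opacity in \[0, 1\], vectorised over `distance_to_target`.
#' @export
trail_visibility <- function(distance_to_target,
                             config = trial_config(1)) {
  if (any(distance_to_target < 0))
    stop("distance must be non-negative", call. = FALSE)
  pmin(pmax((distance_to_target - config$trail_fade_near) /
              (config$trail_fade_far - config$trail_fade_near), 0), 1)
}

#' Feedback category for a targeting error
#'
#' The five qualitative feedback bands, with band edges belonging to the
#' better (smaller-error) band; errors beyond 10 m map to an out-of-range
#' label.
#'
#' @param error Targeting error(s), metres (>= 0).
#' @return Character label(s).
#' @export
feedback_category <- function(error) {
  if (any(is.na(error)) || any(error < 0))
    stop("invalid input: error must be non-negative", call. = FALSE)
  cut(error, c(-Inf, 0.005, 0.02, 1, 2, 10, Inf),
      labels = c("Direct hit!", "That was a catch!",
                 "That was nearly a catch!", "Somewhat close to the target",
                 "You missed your target", "Out of range"),
      right = TRUE) |> as.character()
}

#' Run one trial
#'
#' Steps the flock and predator on a common clock. Each tracker decision
#' interval the belief over the target may swap (the confusion surrogate);
#' the controller steers the predator towards the believed target and decides
#' when to "click". The trial ends at the click or at the timeout. The
#' targeting error is always measured to the true target.
#'
#' @param config A [trial_config()].
#' @param controller A controller function (see [pursuit_controller()]) or a
#'   registered controller name.
#' @param tracker A [tracker_params()] object, or `NULL` for perfect
#'   tracking.
#' @return A one-row data.frame of class `trial_record` with columns
#'   flock_size, density, density_label, seed, targeting_error_m,
#'   hunting_time_s, timed_out, swaps, movement_speed, approach_speed,
#'   feedback; when `config$record_trajectories` is `TRUE`, attributes
#'   `predator_trajectory` and `target_trajectory` (data.frames of time, x,
#'   y, z) and `trail_opacity`.
#' @export
run_trial <- function(config, controller = pursuit_controller(),
                      tracker = tracker_params()) {
  stopifnot(inherits(config, "trial_config"))
  if (is.character(controller)) controller <- get_controller(controller)
  world <- initialize_trial(config)
  flock <- world$flock
  fcfg <- world$flock_config
  pred <- world$predator
  pcfg <- world$predator_config
  target_id <- world$target_id
  belief <- tracker_belief(target_id)
  dt <- config$dt
  n_steps <- as.integer(ceiling(config$timeout / dt))
  decision_dt <- if (is.null(tracker)) Inf else tracker$decision_dt

  keep <- config$record_trajectories
  if (keep) {
    ptraj <- matrix(NA_real_, n_steps + 1L, 3L)
    ttraj <- matrix(NA_real_, n_steps + 1L, 3L)
    opac <- numeric(n_steps + 1L)
    ptraj[1L, ] <- pred$position
    ttraj[1L, ] <- flock$pos[target_id, ]
    opac[1L] <- trail_visibility(
      sqrt(sum((pred$position - flock$pos[target_id, ])^2)), config)
  }

  dist_to_target <- function() sqrt(sum((pred$position -
                                           flock$pos[target_id, ])^2))
  d_prev <- dist_to_target()
  move_len <- 0
  dist_drop <- 0
  clicked <- FALSE
  t_click <- NA_real_
  next_decision <- decision_dt
  time <- 0

  for (s in seq_len(n_steps)) {
    flock <- step_flock(flock, fcfg)
    if (!is.null(tracker) && time + dt >= next_decision - 1e-9) {
      belief <- confusable_tracker(belief, flock, pred, tracker)
      next_decision <- next_decision + decision_dt
    }
    bp <- flock$pos[belief$believed_id, ]
    bv <- flock$vel[belief$believed_id, ]
    act <- controller(pred, bp, pcfg, time, target_velocity = bv)
    p_old <- pred$position
    pred <- step_predator(pred, act$control, pcfg, dt)
    time <- time + dt

    move_len <- move_len + sqrt(sum((pred$position - p_old)^2))
    d_now <- dist_to_target()
    dist_drop <- dist_drop + (d_prev - d_now)
    d_prev <- d_now
    if (keep) {
      ptraj[s + 1L, ] <- pred$position
      ttraj[s + 1L, ] <- flock$pos[target_id, ]
      opac[s + 1L] <- trail_visibility(d_now, config)
    }
    if (isTRUE(act$click)) {
      clicked <- TRUE
      t_click <- time
      break
    }
  }

  timed_out <- !clicked
  hunting_time <- if (timed_out) config$timeout else t_click
  err <- if (timed_out) NA_real_ else d_prev
  elapsed <- if (timed_out) config$timeout else t_click
  rec <- data.frame(
    flock_size = config$flock_size,
    density = config$density,
    density_label = config$density_label %||% NA_character_,
    seed = config$seed,
    targeting_error_m = err,
    hunting_time_s = hunting_time,
    timed_out = timed_out,
    swaps = belief$swaps,
    movement_speed = move_len / elapsed,
    approach_speed = dist_drop / elapsed,
    feedback = if (timed_out) NA_character_ else feedback_category(err),
    stringsAsFactors = FALSE)
  class(rec) <- c("trial_record", class(rec))
  if (keep) {
    n_kept <- if (clicked) s + 1L else n_steps + 1L
    tt <- seq(0, by = dt, length.out = n_kept)
    attr(rec, "predator_trajectory") <- data.frame(
      time = tt, x = ptraj[1:n_kept, 1], y = ptraj[1:n_kept, 2],
      z = ptraj[1:n_kept, 3])
    attr(rec, "target_trajectory") <- data.frame(
      time = tt, x = ttraj[1:n_kept, 1], y = ttraj[1:n_kept, 2],
      z = ttraj[1:n_kept, 3])
    attr(rec, "trail_opacity") <- opac[1:n_kept]
  }
  rec
}
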