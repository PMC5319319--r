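#' Predator flight configuration
#'
#' The predator's flight mechanics are deliberately simpler than the birds':
#' the controller adjusts roll, pitch and thrust, each command in \[-1, 1\]
#' scaling linearly to a configured maximum rate. Turning is coordinated
#' (yaw rate = g tan(roll) / speed), the flight-path angle integrates the
#' pitch command, and thrust accelerates along the path. Speed is clamped to
#' `[v_min, v_max]`.
#'
#' @param v_min,v_max Speed bounds, m/s. The defaults make a lone starling
#'   (10 m/s) comfortably catchable from 100 m inside the 30 s timeout.
#' @param thrust_accel Longitudinal acceleration at full thrust, m/s^2.
#' @param roll_max Bank-angle limit, rad.
#' @param roll_rate_max Roll rate at full command, rad/s.
#' @param pitch_rate_max Flight-path-angle rate at full command, rad/s.
#' @param gamma_max Flight-path-angle limit, rad.
#' @param g Gravitational acceleration, m/s^2.
#' @return An object of class `predator_config`.
#' @export
predator_config <- function(v_min = 4, v_max = 20, thrust_accel = 8,
                            roll_max = pi / 3, roll_rate_max = pi,
                            pitch_rate_max = pi / 2, gamma_max = pi / 3,
                            g = 9.81) {
  stopifnot(v_min > 0, v_max >= v_min, thrust_accel > 0,
            roll_max > 0, roll_max < pi / 2, gamma_max > 0,
            gamma_max < pi / 2)
  cfg <- list(v_min = v_min, v_max = v_max, thrust_accel = thrust_accel,
              roll_max = roll_max, roll_rate_max = roll_rate_max,
              pitch_rate_max = pitch_rate_max, gamma_max = gamma_max, g = g)
  class(cfg) <- "predator_config"
  cfg
}

#' Predator state
#'
#' @param position Numeric length-3, metres.
#' @param speed m/s.
#' @param heading Yaw angle psi, rad (0 = +x).
#' @param gamma Flight-path (climb) angle, rad.
#' @param roll Bank angle, rad.
#' @return An object of class `predator_state`; `$velocity` is derived from
#'   speed, heading and gamma.
#' @export
predator_state <- function(position, speed = 15, heading = 0, gamma = 0,
                           roll = 0) {
  stopifnot(length(position) == 3L, all(is.finite(position)),
            is.finite(speed), speed > 0)
  st <- list(position = as.numeric(position), speed = speed,
             heading = heading, gamma = gamma, roll = roll)
  st$velocity <- .predator_velocity(st)
  class(st) <- "predator_state"
  st
}

.predator_velocity <- function(st) {
  st$speed * c(cos(st$gamma) * cos(st$heading),
               cos(st$gamma) * sin(st$heading),
               sin(st$gamma))
}

#' Control input
#'
#' Roll, pitch and thrust commands, each clamped to \[-1, 1\].
#'
#' @param roll,pitch,thrust Numeric commands.
#' @return An object of class `control_input`.
#' @export
control_input <- function(roll = 0, pitch = 0, thrust = 0) {
  v <- c(roll = roll, pitch = pitch, thrust = thrust)
  if (any(!is.finite(v)))
    stop("invalid control: commands must be finite", call. = FALSE)
  out <- as.list(pmin(pmax(v, -1), 1))
  class(out) <- "control_input"
  out
}

#' Advance the predator by one time step
#'
#' @param state A [predator_state()].
#' @param control A [control_input()] (or a bare list with roll/pitch/thrust).
#' @param config A [predator_config()].
#' @param dt Time step, s (> 0).
#' @return The advanced `predator_state`. With zero command the predator
#'   flies straight (given zero roll) at constant speed.
#' @export
step_predator <- function(state, control, config = predator_config(),
                          dt = 0.05) {
  stopifnot(inherits(state, "predator_state"), dt > 0)
  if (!inherits(control, "control_input"))
    control <- control_input(control$roll %||% 0, control$pitch %||% 0,
                             control$thrust %||% 0)
  state$roll <- min(max(state$roll + control$roll * config$roll_rate_max * dt,
                        -config$roll_max), config$roll_max)
  state$gamma <- min(max(state$gamma +
                           control$pitch * config$pitch_rate_max * dt,
                         -config$gamma_max), config$gamma_max)
  state$heading <- state$heading +
    config$g * tan(state$roll) / state$speed * dt
  state$speed <- min(max(state$speed +
                           control$thrust * config$thrust_accel * dt,
                         config$v_min), config$v_max)
  state$velocity <- .predator_velocity(state)
  state$position <- state$position + state$velocity * dt
  state
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Pure-pursuit steering
#'
#' Proportional guidance towards the line of sight to a target point: the
#' desired heading and climb angle are those of the line of sight; the roll
#' command drives the bank towards an angle proportional to the heading
#' error, the pitch command drives the climb angle, and thrust drives the
#' speed towards a distance-scheduled desired speed (fast when far, slowing
#' on the final approach so the turn radius shrinks enough to intercept).
#' Already-aligned geometry yields (near-)zero lateral commands.
#'
#' @param state A [predator_state()].
#' @param target_position Numeric length-3, metres.
#' @param config A [predator_config()].
#' @param gains List of proportional gains: `k_heading` (rad of bank per rad
#'   of heading error), `k_roll`, `k_pitch`, `k_thrust`.
#' @param target_velocity Optional target velocity (3-vector, m/s); the
#'   desired speed rides above the target's own speed.
#' @return A [control_input()].
#' @export
pure_pursuit <- function(state, target_position, config = predator_config(),
                         gains = list(k_heading = 2, k_roll = 4,
                                      k_pitch = 3, k_thrust = 1),
                         target_velocity = NULL) {
  stopifnot(all(is.finite(target_position)))
  los <- target_position - state$position
  d <- sqrt(sum(los^2))
  hd <- sqrt(los[1]^2 + los[2]^2)
  psi_d <- atan2(los[2], los[1])
  gamma_d <- atan2(los[3], hd)
  err_psi <- .wrap_angle(psi_d - state$heading)
  roll_d <- min(max(gains$k_heading * err_psi, -config$roll_max),
                config$roll_max)
  v_t <- if (is.null(target_velocity)) 0 else sqrt(sum(target_velocity^2))
  v_des <- min(config$v_max,
               max(config$v_min, v_t + 1.5 + 0.2 * max(0, d - 10)))
  control_input(
    roll = gains$k_roll * (roll_d - state$roll),
    pitch = gains$k_pitch * (gamma_d - state$gamma),
    thrust = gains$k_thrust * (v_des - state$speed)
  )
}

.wrap_angle <- function(a) atan2(sin(a), cos(a))

#' Tracker belief
#'
#' The scripted predator's belief about which bird is the target. The belief
#' starts on the true target and may swap to nearby distractors (the
#' confusion surrogate).
#'
#' @param believed_id Bird index (1-based).
#' @return An object of class `tracker_belief` with fields `believed_id`,
#'   `swaps` (count so far) and `time_since_last_swap` (s).
#' @export
tracker_belief <- function(believed_id) {
  st <- list(believed_id = as.integer(believed_id), swaps = 0L,
             time_since_last_swap = 0)
  class(st) <- "tracker_belief"
  st
}

#' Confusable-tracker parameters
#'
#' @param h0 Per-decision swap hazard contributed by each distractor.
#' @param theta Angular radius (rad) around the line of sight to the believed
#'   target within which other birds count as distractors.
#' @param decision_dt Interval between tracking decisions, s.
#' @return A list of class `tracker_params`.
#' @export
tracker_params <- function(h0 = 3e-4, theta = 0.02, decision_dt = 0.1) {
  stopifnot(h0 >= 0, theta > 0, decision_dt > 0)
  structure(list(h0 = h0, theta = theta, decision_dt = decision_dt),
            class = "tracker_params")
}

#' Confusable tracking decision
#'
#' One decision step of the confusion surrogate. Let m be the number of
#' non-target birds lying within angle `theta` of the line of sight to the
#' believed target, as seen from the predator. With probability
#' `min(1, h0 * m)` the belief swaps to one of those m distractors chosen
#' uniformly at random. A singleton flock (m = 0) never swaps. Uses the R
#' RNG, so it is reproducible under `set.seed()`.
#'
#' @param belief A [tracker_belief()].
#' @param flock A `flock_state` (or N x 3 position matrix).
#' @param predator A [predator_state()].
#' @param params A [tracker_params()].
#' @return The updated `tracker_belief`.
#' @export
confusable_tracker <- function(belief, flock, predator,
                               params = tracker_params()) {
  pos <- if (inherits(flock, "flock_state")) flock$pos else as.matrix(flock)
  n <- nrow(pos)
  if (belief$believed_id < 1L || belief$believed_id > n)
    stop("believed target is not a valid bird index", call. = FALSE)
  belief$time_since_last_swap <- belief$time_since_last_swap +
    params$decision_dt
  if (n < 2L || params$h0 <= 0) return(belief)

  rel <- sweep(pos, 2, predator$position)
  los <- rel[belief$believed_id, ]
  los_n <- sqrt(sum(los^2))
  if (los_n < 1e-9) return(belief)
  d <- sqrt(rowSums(rel^2))
  cosang <- (rel %*% los) / (d * los_n)
  distr <- which(cosang >= cos(params$theta))
  distr <- distr[distr != belief$believed_id]
  m <- length(distr)
  if (m == 0L) return(belief)
  if (stats::runif(1L) < min(1, params$h0 * m)) {
    belief$believed_id <- if (m == 1L) distr else sample(distr, 1L)
    belief$swaps <- belief$swaps + 1L
    belief$time_since_last_swap <- 0
  }
  belief
}

#' Controller registry
#'
#' Controllers are functions `(predator_state, believed_target_position,
#' predator_config, trial_time) -> list(control = control_input, click =
#' logical)`. They can be registered by name so configuration files can refer
#' to them.
#'
#' @param name Controller name.
#' @param fn Controller function (omit to look one up).
#' @return `register_controller` returns `fn` invisibly; `get_controller`
#'   returns the registered function.
#' @export
register_controller <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  .controllers[[name]] <- fn
  invisible(fn)
}

.controllers <- new.env(parent = emptyenv())

#' @rdname register_controller
#' @export
get_controller <- function(name) {
  fn <- .controllers[[name]]
  if (is.null(fn)) stop("no controller registered as '", name, "'",
                        call. = FALSE)
  fn
}

#' Scripted pursuit controller
#'
#' Pure pursuit of the believed target with a simple click policy: click when
#' the distance to the believed target is within `strike_radius`, or when the
#' predator starts moving away from it (negative time-to-closest-approach)
#' inside `arm_distance`.
#'
#' @param strike_radius Click distance, m.
#' @param arm_distance Distance inside which a receding target triggers a
#'   click, m.
#' @param close_speed Speed held during the final shadowing approach, m/s.
#'   Slightly above the prey's cruise speed: the predator transits fast,
#'   then decelerates to creep up on its target before clicking, as a
#'   careful participant would.
#' @param decel_slope Speed added per metre of distance above the shadowing
#'   zone (caps at the predator's maximum speed).
#' @param gains Passed to [pure_pursuit()].
#' @return A controller function suitable for [run_trial()].
#' @export
pursuit_controller <- function(strike_radius = 0.5, arm_distance = 3,
                               close_speed = 11, decel_slope = 0.3,
                               gains = NULL) {
  force(strike_radius); force(arm_distance); force(gains)
  force(close_speed); force(decel_slope)
  function(state, target_position, config, time, target_velocity = NULL) {
    ctl <- if (is.null(gains)) pure_pursuit(state, target_position, config)
    else pure_pursuit(state, target_position, config, gains)
    rel <- target_position - state$position
    d <- sqrt(sum(rel^2))
    # distance-scheduled speed: full speed far out, shadowing speed close in
    v_des <- min(config$v_max, close_speed + decel_slope * max(0, d - 10))
    ctl$thrust <- min(1, max(-1, v_des - state$speed))
    click <- d <= strike_radius
    if (!click && d <= arm_distance && !is.null(target_velocity)) {
      vrel <- target_velocity - state$velocity
      # time to closest approach of the linearly extrapolated encounter
      tca <- -sum(rel * vrel) / max(sum(vrel^2), 1e-12)
      click <- tca < 0
    }
    list(control = ctl, click = click)
  }
}
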