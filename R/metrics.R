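#' Trajectory constructor
#'
#' A trajectory is a data.frame of uniformly sampled positions: columns
#' `time`, `x`, `y`, `z`, with strictly increasing time and at least two
#' samples.
#'
#' @param time Sample times, s.
#' @param x,y,z Coordinates, m (z may be omitted for planar paths).
#' @return A `trajectory` data.frame.
#' @export
trajectory <- function(time, x, y, z = 0) {
  tr <- data.frame(time = time, x = x, y = y, z = z)
  .check_trajectory(tr)
  class(tr) <- c("trajectory", class(tr))
  tr
}

.check_trajectory <- function(tr) {
  if (nrow(tr) < 2L) stop("a trajectory needs >= 2 samples", call. = FALSE)
  if (any(diff(tr$time) <= 0))
    stop("trajectory time must be strictly increasing", call. = FALSE)
  invisible(tr)
}

#' Normalize targeting errors against the singleton baseline
#'
#' Subtracts, per participant, the participant's mean error in singleton
#' (flock size 1) trials from every error. This removes the individual
#' component of error due to the mechanical difficulty of the task, so
#' remaining non-zero error reflects group size and density. After
#' normalization each participant's singleton trials average zero.
#'
#' @param table A results table with columns `participant`,
#'   `flock_size` and the error column.
#' @param error_col Name of the error column.
#' @return The table with an added `<error_col>_norm` column.
#' @export
normalize_error <- function(table, error_col = "targeting_error_m") {
  stopifnot(error_col %in% names(table))
  err <- table[[error_col]]
  base <- tapply(err[table$flock_size == 1L],
                 table$participant[table$flock_size == 1L],
                 mean, na.rm = TRUE)
  missing <- setdiff(unique(table$participant), names(base)[!is.na(base)])
  if (length(missing) > 0)
    stop("missing singleton baseline for participant(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  table[[paste0(error_col, "_norm")]] <-
    as.numeric(err - unname(base[as.character(table$participant)]))
  table
}

#' Approach speed
#'
#' Mean per-frame reduction in the predator-target distance over a trial.
#' By telescoping this equals (first distance - last distance) divided by
#' elapsed time.
#'
#' @param predator,target `trajectory` objects sharing identical timestamps.
#' @return Approach speed, m/s (positive = closing).
#' @export
approach_speed <- function(predator, target) {
  .check_trajectory(predator); .check_trajectory(target)
  if (nrow(predator) != nrow(target) ||
      any(abs(predator$time - target$time) > 1e-9))
    stop("alignment error: trajectories must share timestamps",
         call. = FALSE)
  d <- sqrt((predator$x - target$x)^2 + (predator$y - target$y)^2 +
              (predator$z - target$z)^2)
  dt <- diff(predator$time)
  mean(-diff(d) / dt)   # mean per-frame distance-reduction rate
}

#' Movement speed
#'
#' Mean magnitude of the per-frame displacement rate along a trajectory.
#'
#' @param traj A `trajectory`.
#' @return Mean speed, m/s.
#' @export
movement_speed <- function(traj) {
  .check_trajectory(traj)
  step <- sqrt(diff(traj$x)^2 + diff(traj$y)^2 + diff(traj$z)^2)
  mean(step / diff(traj$time))
}

#' Trajectory kinematics summary
#'
#' Speed (from first differences), tangential acceleration (rate of change
#' of speed) and curvature kappa = |v x a| / |v|^3 with velocity and
#' acceleration from central differences; means, variances and standard
#' deviations over frames. Frames with (near-)zero speed have undefined
#' curvature and are excluded from the curvature summary.
#'
#' @param traj A `trajectory` with >= 3 samples.
#' @param zero_speed_tol Speed below which curvature is marked missing, m/s.
#' @return A list of class `kinematics_summary` with elements `speed`,
#'   `accel` and `curvature`, each a named vector (mean, var, sd, n), plus
#'   the per-frame series in `$frames`.
#' @export
kinematics_summary <- function(traj, zero_speed_tol = 1e-8) {
  .check_trajectory(traj)
  n <- nrow(traj)
  if (n < 3L) stop("kinematics need >= 3 samples", call. = FALSE)
  p <- as.matrix(traj[, c("x", "y", "z")])
  t <- traj$time
  dt <- diff(t)

  # speed from first differences (frame-to-frame displacement rate)
  speed_fd <- sqrt(rowSums((p[-1L, , drop = FALSE] -
                              p[-n, , drop = FALSE])^2)) / dt

  # central differences on interior samples
  i <- 2:(n - 1L)
  h <- t[i + 1L] - t[i - 1L]
  v <- (p[i + 1L, , drop = FALSE] - p[i - 1L, , drop = FALSE]) / h
  a <- (p[i + 1L, , drop = FALSE] - 2 * p[i, , drop = FALSE] +
          p[i - 1L, , drop = FALSE]) / (dt[i] * dt[i - 1L])
  vnorm <- sqrt(rowSums(v^2))
  # tangential acceleration: central difference of the speed series
  accel <- (speed_fd[i] - speed_fd[i - 1L]) / ((dt[i] + dt[i - 1L]) / 2)
  cross <- cbind(v[, 2] * a[, 3] - v[, 3] * a[, 2],
                 v[, 3] * a[, 1] - v[, 1] * a[, 3],
                 v[, 1] * a[, 2] - v[, 2] * a[, 1])
  kappa <- sqrt(rowSums(cross^2)) / vnorm^3
  kappa[vnorm < zero_speed_tol] <- NA_real_

  summ <- function(x) {
    x <- x[is.finite(x)]
    c(mean = mean(x), var = stats::var(x), sd = stats::sd(x), n = length(x))
  }
  out <- list(speed = summ(speed_fd), accel = summ(accel),
              curvature = summ(kappa),
              frames = data.frame(time = t[i], speed = speed_fd[i],
                                  accel = accel, curvature = kappa))
  class(out) <- "kinematics_summary"
  out
}

#' @export
print.kinematics_summary <- function(x, ...) {
  cat("<kinematics_summary>\n")
  m <- rbind(speed = x$speed, accel = x$accel, curvature = x$curvature)
  print(signif(m, 4))
  invisible(x)
}

#' Per-trial kinematics of the target bird
#'
#' Convenience wrapper applying [kinematics_summary()] to the target
#' trajectory attached to a [run_trial()] record.
#'
#' @param record A `trial_record` with trajectories attached.
#' @return A `kinematics_summary`.
#' @export
target_kinematics <- function(record) {
  tt <- attr(record, "target_trajectory")
  if (is.null(tt))
    stop("trial record has no trajectories (record_trajectories = FALSE?)",
         call. = FALSE)
  kinematics_summary(tt)
}
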