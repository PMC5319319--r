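#' Factorial experiment design
#'
#' The default design crosses flock sizes 1, 50, 250, 1000, 5000 with the
#' three density settings; every cell appears 4 times in the practice phase
#' and 15 times in the experimental phase.
#'
#' @param sizes Flock sizes.
#' @param densities Density settings (labels or NND values).
#' @param practice_reps,experimental_reps Repetitions per size x density
#'   cell in each phase.
#' @return A list of class `experiment_design`.
#' @export
experiment_design <- function(sizes = c(1, 50, 250, 1000, 5000),
                              densities = c("dense", "normal", "loose"),
                              practice_reps = 4L,
                              experimental_reps = 15L) {
  stopifnot(length(sizes) >= 1, length(densities) >= 1,
            practice_reps >= 0, experimental_reps >= 0)
  structure(list(sizes = sizes, densities = densities,
                 practice_reps = as.integer(practice_reps),
                 experimental_reps = as.integer(experimental_reps)),
            class = "experiment_design")
}

#' Generate a participant's randomized trial schedule
#'
#' The multiset of size x density cells is exact per phase; the order of
#' trials is a seeded permutation drawn independently per participant, and
#' every trial receives a distinct seed derived from the participant seed.
#'
#' @param participant_seed Integer seed for this participant.
#' @param design An [experiment_design()].
#' @param participant Participant identifier stored in the schedule.
#' @return A data.frame of class `experiment_schedule` with columns
#'   participant, phase ("practice"/"experimental"), trial (order within
#'   phase), flock_size, density (label or value as given) and seed.
#' @export
generate_schedule <- function(participant_seed, design = experiment_design(),
                              participant = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  set.seed(as.integer(participant_seed))
  cells <- expand.grid(flock_size = design$sizes,
                       density = design$densities,
                       stringsAsFactors = FALSE)
  one_phase <- function(phase, reps) {
    if (reps == 0L || nrow(cells) == 0L) return(NULL)
    idx <- rep(seq_len(nrow(cells)), each = reps)
    idx <- sample(idx)                       # seeded permutation
    out <- cells[idx, , drop = FALSE]
    out$phase <- phase
    out$trial <- seq_len(nrow(out))
    out
  }
  sched <- rbind(one_phase("practice", design$practice_reps),
                 one_phase("experimental", design$experimental_reps))
  if (is.null(sched))
    sched <- data.frame(flock_size = numeric(), density = character(),
                        phase = character(), trial = integer())
  rownames(sched) <- NULL
  sched$participant <- rep(participant, nrow(sched))
  sched$seed <- sample.int(.Machine$integer.max, nrow(sched))
  sched <- sched[, c("participant", "phase", "trial", "flock_size",
                     "density", "seed")]
  class(sched) <- c("experiment_schedule", class(sched))
  sched
}

#' Run a scheduled experiment
#'
#' Executes every trial in one or more schedules and binds the trial records
#' into a long results table. Practice trials are flagged, not dropped
#' (exclusion happens at analysis time). A trial that errors is recorded as a
#' failed row and the run continues.
#'
#' @param schedule An `experiment_schedule` (or several rbind-ed together).
#' @param controller Controller for [run_trial()].
#' @param tracker [tracker_params()] shared by all trials, or a function
#'   `(participant) -> tracker_params` for per-participant variation.
#' @param trial_options Named list of [trial_config()] overrides (e.g.
#'   `record_trajectories = FALSE`).
#' @param progress Print per-trial progress to stderr?
#' @return A `results_table` data.frame: one row per trial with participant,
#'   phase, trial, flock_size, density, density_label, seed,
#'   targeting_error_m, hunting_time_s, timed_out, swaps, movement_speed,
#'   approach_speed, feedback, failed.
#' @export
run_experiment <- function(schedule, controller = pursuit_controller(),
                           tracker = tracker_params(),
                           trial_options = list(record_trajectories = FALSE),
                           progress = FALSE) {
  if (is.null(schedule) || nrow(schedule) == 0L) {
    out <- data.frame()
    class(out) <- c("results_table", class(out))
    return(out)
  }
  rows <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    row <- schedule[i, ]
    trk <- if (is.function(tracker)) tracker(row$participant) else tracker
    args <- c(list(flock_size = row$flock_size, density = row$density,
                   seed = row$seed), trial_options)
    rec <- tryCatch({
      r <- run_trial(do.call(trial_config, args), controller, trk)
      r$failed <- FALSE
      r
    }, error = function(e) {
      data.frame(flock_size = row$flock_size,
                 density = resolve_density(row$density),
                 density_label = if (is.character(row$density)) row$density
                 else NA_character_,
                 seed = row$seed, targeting_error_m = NA_real_,
                 hunting_time_s = NA_real_, timed_out = NA, swaps = NA_integer_,
                 movement_speed = NA_real_, approach_speed = NA_real_,
                 feedback = NA_character_, failed = TRUE,
                 stringsAsFactors = FALSE)
    })
    rec$participant <- row$participant
    rec$phase <- row$phase
    rec$trial <- row$trial
    rows[[i]] <- as.data.frame(rec)
    if (progress)
      message(sprintf("trial %d/%d (participant %s, N=%d)", i,
                      nrow(schedule), row$participant, row$flock_size))
  }
  out <- do.call(rbind, rows)
  front <- c("participant", "phase", "trial")
  out <- out[, c(front, setdiff(names(out), front))]
  class(out) <- c("results_table", class(out))
  out
}

#' Run the full multi-participant experiment
#'
#' Generates an independent randomized schedule per participant (seeds
#' derived from `seed`) and runs it. Individual differences are mimicked by
#' jittering each participant's tracker hazard multiplicatively.
#'
#' @param participants Number of synthetic participants (the study used 25).
#' @param seed Global seed.
#' @param design An [experiment_design()].
#' @param base_tracker [tracker_params()] around which participants vary.
#' @param jitter_sd Standard deviation of the log-normal hazard jitter
#'   (0 disables individual differences).
#' @param ... Passed to [run_experiment()].
#' @return A `results_table` covering all participants.
#' @export
run_full_experiment <- function(participants = 25L, seed = 1L,
                                design = experiment_design(),
                                base_tracker = tracker_params(),
                                jitter_sd = 0.2, ...) {
  set.seed(as.integer(seed))
  pseeds <- sample.int(.Machine$integer.max, participants)
  jit <- exp(stats::rnorm(participants, 0, jitter_sd))
  out <- vector("list", participants)
  for (p in seq_len(participants)) {
    sched <- generate_schedule(pseeds[p], design, participant = p)
    trk <- tracker_params(h0 = base_tracker$h0 * jit[p],
                          theta = base_tracker$theta,
                          decision_dt = base_tracker$decision_dt)
    out[[p]] <- run_experiment(sched, tracker = trk, ...)
  }
  res <- do.call(rbind, out)
  class(res) <- c("results_table", class(res))
  res
}
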