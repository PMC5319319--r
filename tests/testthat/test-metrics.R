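test_that("error normalization subtracts the singleton baseline", {
  tab <- data.frame(
    participant = c(1, 1, 1, 2, 2),
    flock_size = c(1, 1, 50, 1, 50),
    targeting_error_m = c(1.5, 2.5, 4.5, 1.0, 3.0))
  out <- normalize_error(tab)
  # participant 1 singleton mean 2.0: raw 4.5 -> 2.5; singleton rows centre 0
  expect_equal(out$targeting_error_m_norm, c(-0.5, 0.5, 2.5, 0, 2))
  expect_equal(mean(out$targeting_error_m_norm[out$flock_size == 1 &
                                                 out$participant == 1]), 0)

  # random tables: group-by-hand loop matches the vectorized path exactly
  set.seed(14)
  big <- data.frame(participant = sample(1:6, 300, TRUE),
                    flock_size = sample(c(1, 50, 250), 300, TRUE),
                    targeting_error_m = rexp(300, 1 / 3))
  big <- rbind(big, data.frame(participant = 1:6, flock_size = 1,
                               targeting_error_m = runif(6)))
  got <- normalize_error(big)$targeting_error_m_norm
  want <- numeric(nrow(big))
  for (i in seq_len(nrow(big))) {
    p <- big$participant[i]
    base <- mean(big$targeting_error_m[big$participant == p &
                                         big$flock_size == 1])
    want[i] <- big$targeting_error_m[i] - base
  }
  expect_equal(got, want)

  # missing singleton baseline is an explicit error
  expect_error(normalize_error(data.frame(participant = 1, flock_size = 50,
                                          targeting_error_m = 2)),
               "missing singleton baseline")
})

test_that("normalization preserves within-participant contrasts", {
  set.seed(3)
  tab <- data.frame(participant = rep(1:4, each = 20),
                    flock_size = rep(c(1, 50, 250, 1000, 5000), 16),
                    targeting_error_m = rexp(80))
  out <- normalize_error(tab)
  for (p in 1:4) {
    sub <- out[out$participant == p, ]
    raw_diff <- diff(tapply(sub$targeting_error_m, sub$flock_size, mean))
    norm_diff <- diff(tapply(sub$targeting_error_m_norm, sub$flock_size,
                             mean))
    expect_equal(unname(raw_diff), unname(norm_diff))
  }
})

test_that("approach speed equals the telescoped distance change", {
  # stationary pair
  tt <- seq(0, 2, by = 0.1)
  p0 <- trajectory(tt, 0 * tt, 0 * tt, 0 * tt)
  p1 <- trajectory(tt, 0 * tt + 3, 0 * tt, 0 * tt)
  expect_equal(approach_speed(p0, p1), 0)

  # constant head-on closure at 5 m/s
  pr <- trajectory(tt, 5 * tt, 0 * tt, 0 * tt)
  tg <- trajectory(tt, 0 * tt + 100, 0 * tt, 0 * tt)
  expect_equal(approach_speed(pr, tg), 5)

  # property: telescoping identity on random trajectories
  for (rep in 1:10) {
    set.seed(rep)
    a <- random_traj(40)
    b <- random_traj(40)
    d <- sqrt((a$x - b$x)^2 + (a$y - b$y)^2 + (a$z - b$z)^2)
    expect_equal(approach_speed(a, b),
                 (d[1] - d[40]) / (a$time[40] - a$time[1]),
                 tolerance = 1e-12)
  }

  expect_error(approach_speed(p0, trajectory(tt + 0.05, 0 * tt, 0, 0)),
               "alignment error")
})

test_that("movement speed recovers analytic path speeds", {
  tt <- seq(0, 2, by = 0.01)
  expect_equal(movement_speed(trajectory(tt, 0 * tt, 0 * tt, 0 * tt)), 0)
  expect_equal(movement_speed(trajectory(tt, 5 * tt, 0 * tt, 0 * tt)), 5)
  # circle at constant speed v, any radius: mean chord rate ~ v
  for (r in c(2, 10)) {
    v <- 7
    w <- v / r
    tr <- trajectory(tt, r * cos(w * tt), r * sin(w * tt), 0 * tt)
    expect_equal(movement_speed(tr), v, tolerance = 1e-3)
  }
})

test_that("kinematics summaries match differential-geometry closed forms", {
  # straight line at constant speed: zero curvature, zero acceleration
  line <- traj_from_fn(function(t) c(3 * t, 4 * t, 0), 5, 0.02)
  ks <- kinematics_summary(line)
  expect_equal(unname(ks$speed["mean"]), 5, tolerance = 1e-9)
  expect_equal(unname(ks$curvature["mean"]), 0, tolerance = 1e-9)
  expect_equal(unname(ks$accel["mean"]), 0, tolerance = 1e-9)

  # circle radius 10: curvature 1/10
  circ <- traj_from_fn(function(t) c(10 * cos(t), 10 * sin(t), 0),
                       2 * pi, 0.01)
  kc <- kinematics_summary(circ)
  expect_equal(unname(kc$curvature["mean"]), 0.1, tolerance = 1e-3)
  expect_equal(unname(kc$accel["mean"]), 0, tolerance = 1e-6)

  # helix radius r, pitch c: curvature r / (r^2 + c^2)
  r <- 4; cc <- 2
  helix <- traj_from_fn(function(t) c(r * cos(t), r * sin(t), cc * t),
                        4 * pi, 0.01)
  kh <- kinematics_summary(helix)
  expect_equal(unname(kh$curvature["mean"]), r / (r^2 + cc^2),
               tolerance = 1e-3)
})

test_that("kinematics are invariant under rigid motion", {
  set.seed(8)
  tr <- random_traj(60)
  # random rotation (QR of a gaussian matrix) + translation
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  p <- as.matrix(tr[, c("x", "y", "z")]) %*% t(R)
  tr2 <- trajectory(tr$time, p[, 1] + 5, p[, 2] - 3, p[, 3] + 100)
  a <- kinematics_summary(tr)
  b <- kinematics_summary(tr2)
  expect_equal(a$speed, b$speed, tolerance = 1e-9)
  expect_equal(a$accel, b$accel, tolerance = 1e-9)
  expect_equal(a$curvature, b$curvature, tolerance = 1e-9)
})

test_that("degenerate zero-speed frames are excluded from curvature", {
  tt <- seq(0, 1, by = 0.1)
  stuck <- trajectory(tt, c(rep(0, 6), seq(0.1, 0.5, 0.1)), 0 * tt, 0 * tt)
  ks <- kinematics_summary(stuck)
  expect_true(any(is.na(ks$frames$curvature)))
  expect_true(all(is.finite(stats::na.omit(ks$frames$curvature))))
  expect_true(ks$curvature[["n"]] < nrow(ks$frames))
})

test_that("trajectory validation rejects malformed inputs", {
  expect_error(trajectory(c(0, 0.1, 0.1), 1:3, 1:3, 1:3), "increasing")
  expect_error(trajectory(0, 1, 1, 1), ">= 2 samples")
  expect_error(kinematics_summary(trajectory(c(0, 1), c(0, 1), c(0, 0),
                                             c(0, 0))), ">= 3 samples")
})

test_that("trial records expose target kinematics", {
  rec <- run_trial(trial_config(10, "normal", seed = 21))
  ks <- target_kinematics(rec)
  expect_gt(ks$speed[["mean"]], 5)
  expect_lt(ks$speed[["mean"]], 15)
  norec <- run_trial(trial_config(5, "normal", seed = 3,
                                  record_trajectories = FALSE))
  expect_error(target_kinematics(norec), "no trajectories")
})
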