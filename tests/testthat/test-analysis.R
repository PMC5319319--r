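make_table <- function(...) simulate_results_table(...)

test_that("trial filtering applies the exclusion rules and is idempotent", {
  tab <- data.frame(
    participant = 1,
    phase = c("practice", rep("experimental", 5)),
    flock_size = c(50, 1, 50, 50, 50, 50),
    density = 1.3,
    targeting_error_m = c(1, 2, 25, 19.9, NA, 3),
    timed_out = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE))
  out <- filter_trials(tab)
  expect_equal(nrow(out), 3L)             # keeps rows 2, 4, 6
  expect_false(any(out$targeting_error_m > 20, na.rm = TRUE))
  expect_false(any(out$phase == "practice"))
  expect_false(any(out$timed_out))
  counts <- attr(out, "filter_counts")
  expect_equal(counts$over_max_error, 1L)
  expect_equal(counts$practice, 1L)
  expect_equal(counts$timed_out, 1L)
  # idempotent on the retained rows
  again <- filter_trials(out)
  expect_equal(as.data.frame(again), as.data.frame(out),
               ignore_attr = TRUE)
  expect_equal(attr(again, "filter_counts")$retained, counts$retained)
})

test_that("flock size transforms to its natural logarithm", {
  tab <- data.frame(flock_size = c(1, exp(1), 5000))
  out <- transform_size(tab)
  expect_equal(out$log_size, c(0, 1, log(5000)))
  # library-independent check: exp inverts the transform
  expect_equal(exp(out$log_size), tab$flock_size)
  expect_error(transform_size(data.frame(flock_size = 0.5)), "invalid")
})

test_that("ML mixed fits recover known generating parameters", {
  # matches the full study size: 25 participants x 225 trials
  tab <- make_table(participants = 25, reps = 15,
                    effects = list(targeting_error_m = list(
                      b0 = 1, b_size = 0.4, b_dens = 0.8,
                      sd_participant = 0.5, sd_resid = 1)),
                    seed = 42)
  tab <- transform_size(tab)
  fit <- fit_mixed("targeting_error_m", tab, size_degree = 1L,
                   density_degree = 1L, interaction = FALSE)
  # recover raw-scale slopes from the orthogonal basis via model prediction
  fe <- lme4::fixef(fit$model)
  Xs <- poly(tab$log_size, 1)
  slope_size <- fe[2] * (max(Xs) - min(Xs)) /
    (max(tab$log_size) - min(tab$log_size))
  Xd <- poly(tab$density, 1)
  slope_dens <- fe[3] * (max(Xd) - min(Xd)) /
    (max(tab$density) - min(tab$density))
  sfit <- summary(fit$model)
  se <- sfit$coefficients[2:3, "Std. Error"]
  se_size <- se[1] * (max(Xs) - min(Xs)) / (max(tab$log_size) -
                                              min(tab$log_size))
  se_dens <- se[2] * (max(Xd) - min(Xd)) / (max(tab$density) -
                                              min(tab$density))
  expect_lt(abs(slope_size - 0.4), 2 * se_size)
  expect_lt(abs(slope_dens - 0.8), 2 * se_dens)
})

test_that("a constant response yields null slopes and the null deviance", {
  tab <- make_table(participants = 6, reps = 2,
                    effects = list(targeting_error_m = list(
                      b0 = 3, sd_participant = 0, sd_resid = 0)))
  tab$targeting_error_m <- 3          # exactly constant
  tab <- transform_size(tab)
  # a zero-variance response is degenerate for lme4; convergence chatter
  # is expected, the point is the fitted slopes
  fit <- suppressWarnings(fit_mixed("targeting_error_m", tab, 1L, 1L,
                                    FALSE))
  expect_lt(max(abs(lme4::fixef(fit$model)[-1])), 1e-6)
})

test_that("adding terms never increases the ML deviance", {
  tab <- transform_size(make_table(participants = 8, reps = 3, seed = 5))
  fits <- list(
    fit_mixed("targeting_error_m", tab, 0L, 0L, FALSE),
    fit_mixed("targeting_error_m", tab, 1L, 0L, FALSE),
    fit_mixed("targeting_error_m", tab, 1L, 1L, FALSE),
    fit_mixed("targeting_error_m", tab, 2L, 1L, FALSE),
    fit_mixed("targeting_error_m", tab, 2L, 2L, TRUE))
  dev <- vapply(fits, function(f) f$deviance, numeric(1))
  expect_true(all(diff(dev) <= 1e-6))
})

test_that("the LRT handles identical fits and matches the chi-square tail", {
  tab <- transform_size(make_table(participants = 6, reps = 2, seed = 2))
  fit <- fit_mixed("targeting_error_m", tab, 1L, 1L, FALSE)
  self <- lrt(fit, fit)
  expect_equal(self$chi_square, 0)
  expect_equal(self$p_value, 1)

  # chi2 = 3.84 on 1 df sits at p ~ 0.05
  fake_s <- structure(list(deviance = 103.84, n_par = 4, nobs = 50),
                      class = "mixed_fit")
  fake_c <- structure(list(deviance = 100, n_par = 5, nobs = 50),
                      class = "mixed_fit")
  cmp <- lrt(fake_s, fake_c)
  expect_equal(cmp$chi_square, 3.84)
  expect_equal(cmp$df, 1L)
  expect_equal(cmp$p_value, 0.05, tolerance = 1e-3)

  bad <- structure(list(deviance = 90, n_par = 6, nobs = 49),
                   class = "mixed_fit")
  expect_error(lrt(fake_s, bad), "comparison refused")
})

test_that("lrt agrees with lme4's own nested-model comparison", {
  tab <- transform_size(make_table(participants = 10, reps = 4,
                                   effects = list(targeting_error_m = list(
                                     b0 = 1, b_size = 0.2,
                                     sd_participant = 0.3, sd_resid = 1)),
                                   seed = 9))
  f0 <- fit_mixed("targeting_error_m", tab, 0L, 1L, FALSE)
  f1 <- fit_mixed("targeting_error_m", tab, 1L, 1L, FALSE)
  ours <- lrt(f0, f1)
  ref <- anova(f0$model, f1$model)
  expect_equal(ours$chi_square, ref$Chisq[2], tolerance = 1e-8)
  expect_equal(ours$df, ref$Df[2])
  expect_equal(ours$p_value, ref$`Pr(>Chisq)`[2], tolerance = 1e-8)
})

test_that("the full decision tree runs and reports every comparison", {
  set.seed(1)
  tab <- make_table(participants = 8, reps = 4,
                    effects = list(
                      targeting_error_m = list(b0 = 1, b_size = 0.3,
                                               b_dens = 0.5, b_int = 0.15,
                                               sd_participant = 0.3,
                                               sd_resid = 0.6),
                      hunting_time_s = list(b0 = 12, b_size = -0.5,
                                            sd_participant = 1,
                                            sd_resid = 1.5)),
                    seed = 31)
  prepared <- prepare_results(tab)
  rep <- run_paper_analysis(prepared,
                            responses = c(
                              targeting_error = "targeting_error_m_norm",
                              hunting_time = "hunting_time_s"))
  expect_s3_class(rep, "confusion_report")
  te <- rep$targeting_error
  expect_true(all(c("size_poly_test", "density_poly_test",
                    "interaction_test") %in% names(te)))
  # generated interaction should surface either as the interaction LRT or
  # the per-density breakdown
  expect_true(!is.null(te$size_by_density) || !is.null(te$size_main_test))
  ht <- rep$hunting_time
  if (!is.null(ht$size_main_test)) {
    expect_lt(ht$size_main_test$p_value, 0.001)  # strong generated effect
    expect_equal(ht$size_main_test$df, ht$size_degree)
  }
  # JSON report round-trip
  tf <- tempfile(fileext = ".json")
  write_report(rep, tf)
  back <- jsonlite::read_json(tf)
  expect_true("targeting_error" %in% names(back))
  unlink(tf)
})

test_that("an interaction built into the generator is detected with power", {
  hits <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    tab <- make_table(participants = 10, reps = 5,
                      sizes = c(1, 50, 250, 1000, 5000),
                      effects = list(targeting_error_m = list(
                        b0 = 1, b_size = 0.3, b_dens = 0.4, b_int = 0.12,
                        sd_participant = 0.3, sd_resid = 0.8)),
                      seed = 400 + r)
    tab <- transform_size(filter_trials(tab))
    m1 <- fit_mixed("targeting_error_m", tab, 1L, 1L, TRUE)
    m0 <- fit_mixed("targeting_error_m", tab, 1L, 1L, FALSE)
    if (lrt(m0, m1)$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 19L)   # >= 95% detection at this effect size
})

test_that("null density effects reject at about the nominal rate", {
  hits <- 0L
  n_rep <- 60L
  for (r in seq_len(n_rep)) {
    tab <- make_table(participants = 12, reps = 2,
                      effects = list(hunting_time_s = list(
                        b0 = 10, b_size = -0.4, sd_participant = 1,
                        sd_resid = 1)),
                      seed = 7000 + r)
    tab <- transform_size(tab)
    m1 <- fit_mixed("hunting_time_s", tab, 1L, 1L, FALSE)
    m0 <- fit_mixed("hunting_time_s", tab, 1L, 0L, FALSE)
    if (lrt(m0, m1)$p_value < 0.05) hits <- hits + 1L
  }
  # 3 expected under the null; allow a generous binomial band
  expect_lte(hits, 10L)
})

test_that("LRT chi-square is invariant to per-participant constant shifts", {
  tab <- transform_size(make_table(participants = 6, reps = 3,
                                   effects = list(targeting_error_m = list(
                                     b0 = 2, b_size = 0.3,
                                     sd_participant = 0.5, sd_resid = 1)),
                                   seed = 77))
  shifted <- tab
  offs <- rnorm(6, 0, 5)
  shifted$targeting_error_m <- shifted$targeting_error_m +
    offs[shifted$participant]
  cmp <- function(t) {
    m1 <- fit_mixed("targeting_error_m", t, 1L, 1L, FALSE)
    m0 <- fit_mixed("targeting_error_m", t, 0L, 1L, FALSE)
    lrt(m0, m1)$chi_square
  }
  expect_equal(cmp(tab), cmp(shifted), tolerance = 0.05)
})

test_that("the tolerant participant-data reader maps columns and fails loudly", {
  tf <- tempfile(fileext = ".txt")
  writeLines(c("Subject\tGroupSize\tDensity\tError\tTime",
               "1\t50\t0.8\t2.5\t12.1",
               "1\t1\t1.3\t1.0\t15.0",
               "2\t250\t1.8\t4.0\t9.7"), tf)
  tab <- read_participant_data(tf)
  expect_true(all(c("participant", "flock_size", "density",
                    "targeting_error_m", "hunting_time_s") %in% names(tab)))
  expect_equal(tab$flock_size, c(50, 1, 250))
  unlink(tf)

  bad <- tempfile(fileext = ".txt")
  writeLines(c("a,b,c", "1,2,3"), bad)
  expect_error(read_participant_data(bad), "schema error")
  unlink(bad)
})

test_that("within-subject intervals centre on condition means", {
  tab <- make_table(participants = 8, reps = 6,
                    sizes = c(1, 50), densities = c(0.8, 1.8),
                    effects = list(targeting_error_m = list(
                      b0 = 2, b_size = 0.5, sd_participant = 2,
                      sd_resid = 0.3)),
                    seed = 10)
  ci <- within_subject_ci(tab)
  expect_equal(nrow(ci), 4L)
  expect_true(all(ci$lower < ci$mean & ci$mean < ci$upper))
  # removing participant offsets should give narrower intervals than the
  # raw between-subject spread implies
  raw_se <- tapply(tab$targeting_error_m,
                   interaction(tab$flock_size, tab$density),
                   function(x) sd(x) / sqrt(length(x)))
  expect_lt(mean(ci$upper - ci$mean), mean(2.2 * raw_se))
})
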