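test_that("behaviour process validates its transition structure", {
  expect_error(behaviourSpec(c("a", "b"), matrix(c(0.9, 0.2, 0.1, 0.9), 2, 2,
                                                 byrow = TRUE)),
               "sum to 1")
  expect_error(behaviourSpec(c("a", "b"), matrix(c(1.1, -0.1, 0.1, 0.9), 2, 2,
                                                 byrow = TRUE)),
               "\\[0, 1\\]")
  spec <- behaviourSpecFromBouts(c(slow = 60, fast = 20))
  expect_equal(rowSums(spec$transition_matrix), c(1, 1))
  expect_equal(spec$transition_matrix[1, 1], 1 - 1 / 60)
  # stationary initial law satisfies delta P = delta
  expect_equal(as.numeric(spec$initial_distribution %*%
                            spec$transition_matrix),
               spec$initial_distribution, tolerance = 1e-12)
})

test_that("an absorbing identity chain never leaves its initial behaviour", {
  spec <- behaviourSpec(c("stationary", "travelling"), diag(2),
                        initial_distribution = c(1, 0))
  s <- simulateBehaviourSequence(spec, 200, seed = 4)
  expect_true(all(s == "stationary"))
})

test_that("simulated dwell times follow the geometric closed form", {
  p <- 0.9
  spec <- behaviourSpec(c("a", "b"),
                        matrix(c(p, 1 - p, 1 - p, p), 2, 2, byrow = TRUE))
  s <- simulateBehaviourSequence(spec, 1e5, seed = 123)
  r <- rle(s)
  lens <- r$lengths[-length(r$lengths)]  # last run is right-censored
  expected <- 1 / (1 - p)
  se <- sd(lens) / sqrt(length(lens))
  expect_lt(abs(mean(lens) - expected), 3 * se)
})

test_that("the behaviour sequence is a pure function of the seed", {
  spec <- defaultBehaviourSpec()
  expect_identical(simulateBehaviourSequence(spec, 500, seed = 9),
                   simulateBehaviourSequence(spec, 500, seed = 9))
})

test_that("zero speed and zero GPS error give a constant position", {
  kin <- kinematicsSpec("stationary", speed_mean = 0, speed_sd = 1,
                        turn_concentration = 0, gps_error_sd = 0)
  tr <- simulateTrack(rep("stationary", 50), kin, seed = 1)
  expect_true(all(tr$x == tr$x[1]) && all(tr$y == tr$y[1]))
})

test_that("missing kinematics for a behaviour is a keyed error", {
  kin <- defaultKinematics()
  expect_error(simulateTrack(c("stationary", "flying"), kin, seed = 1),
               "flying")
})

test_that("mean per-tick displacement obeys the law of large numbers", {
  kin <- kinematicsSpec("travelling", speed_mean = 0.05, speed_sd = 0.025,
                        turn_concentration = 1, gps_error_sd = 0)
  n <- 50000
  tr <- simulateTrack(rep("travelling", n), kin, seed = 21)
  d_km <- sqrt(diff(tr$x_true)^2 + diff(tr$y_true)^2) / 1000
  se <- 0.025 / sqrt(n)
  expect_lt(abs(mean(d_km) - 0.05), 3 * se)
})

test_that("large turn concentration drives circular variance to zero", {
  kin <- kinematicsSpec("travelling", speed_mean = 0.05, speed_sd = 0.025,
                        turn_concentration = 200, gps_error_sd = 0)
  tr <- simulateTrack(rep("travelling", 20000), kin, seed = 8)
  heading <- atan2(diff(tr$y_true), diff(tr$x_true))
  turns <- wrapAngle(diff(heading))
  circ_var <- 1 - sqrt(mean(cos(turns))^2 + mean(sin(turns))^2)
  expect_lt(circ_var, 0.01)
})

test_that("fix emission respects the schedule and the daylight window", {
  spec <- behaviourSpec("s", matrix(1, 1, 1), initial_distribution = 1)
  kin <- kinematicsSpec("s", 0.01, 0.01, 0, gps_error_sd = 0)
  tr <- simulateTrack(rep("s", 61), kin, seed = 1)
  out <- emitFixesAndClips(tr, spec, 20, daylight_window = c(0, 24))
  expect_equal(nrow(out$fixes), 4)  # minutes 0, 20, 40, 60
  expect_equal(as.numeric(diff(out$fixes$timestamp), units = "mins"),
               rep(20, 3))

  tr2 <- simulateTrack(rep("s", 2880), kin, seed = 1)
  out2 <- emitFixesAndClips(tr2, spec, 20, daylight_window = c(6, 22))
  hrs <- as.numeric(format(out2$fixes$timestamp, "%H")) +
    as.numeric(format(out2$fixes$timestamp, "%M")) / 60
  expect_true(all(hrs >= 6 & hrs <= 22))

  spec5 <- behaviourSpec("s", matrix(1, 1, 1), initial_distribution = 1,
                         fine_step_minutes = 5)
  expect_error(emitFixesAndClips(tr, spec5, 7), "multiple")
})

test_that("clip labels equal the true fine state at the fix tick", {
  sim <- simulateDataset(n_individuals = 2, n_days = 2, seed = 5,
                         raw_labels = FALSE)
  start <- as.POSIXct(sim$provenance$start_time,
                      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  for (i in 1:2) {
    cl <- sim$clips[sim$clips$id == sprintf("ind%02d", i), ]
    tick <- as.numeric(cl$timestamp - start, units = "mins") + 1
    expect_identical(cl$label, sim$true_fine_states[[i]][tick])
  }
})

test_that("coarser fix intervals straddle more behaviour switches", {
  spec <- defaultBehaviourSpec()  # bouts of ~20-60 min at 1-min ticks
  s <- simulateBehaviourSequence(spec, 1440 * 30, seed = 77)
  frac_switch <- function(interval) {
    starts <- seq(1, length(s) - interval, by = interval)
    mean(vapply(starts, function(k)
      length(unique(s[k:(k + interval)])) > 1, logical(1)))
  }
  f <- vapply(c(20, 60, 120), frac_switch, numeric(1))
  expect_true(all(diff(f) > 0))
})

test_that("the whole dataset is reproducible from the master seed", {
  a <- simulateDataset(n_individuals = 2, n_days = 1, seed = 3)
  b <- simulateDataset(n_individuals = 2, n_days = 1, seed = 3)
  expect_identical(a$fixes, b$fixes)
  expect_identical(a$clips, b$clips)
  c <- simulateDataset(n_individuals = 2, n_days = 1, seed = 4)
  expect_false(identical(a$fixes, c$fixes))
})

test_that("model-exact generation matches its declared state kinematics", {
  p <- hmmParams(step_mean = c(0.05, 1), step_sd = c(0.05, 0.8),
                 angle_concentration = c(0.5, 3),
                 transition_matrix = matrix(c(.9, .1, .1, .9), 2, 2))
  d <- simulateHMMData(p, 4000, seed = 10)
  for (i in 1:2) {
    x <- d$steps$step_km[d$states == i]
    expect_lt(abs(mean(x) - p$step_mean[i]),
              3 * p$step_sd[i] / sqrt(length(x)))
  }
  expect_true(is.na(d$steps$turn_rad[1]))
})
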