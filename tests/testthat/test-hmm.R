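twoStateParams <- function() {
  hmmParams(step_mean = c(0.05, 1), step_sd = c(0.05, 0.8),
            angle_concentration = c(0.5, 3),
            transition_matrix = matrix(c(.9, .1, .1, .9), 2, 2))
}

test_that("parameter validation enforces the stochastic constraints", {
  expect_error(hmmParams(c(0.1, 1), c(0.1, 1),
                         matrix(c(.9, .2, .1, .9), 2, 2, byrow = TRUE),
                         c(1, 1)),
               "sum to 1")
  expect_error(hmmParams(c(0.1, 1), c(0.1, 1),
                         matrix(c(.9, .1, .1, .9), 2, 2),
                         c(1, 1), initial_law = c(0.9, 0.1)),
               "stationary")
  p <- twoStateParams()
  expect_equal(as.numeric(p$initial_law %*% p$transition_matrix),
               p$initial_law, tolerance = 1e-10)
})

test_that("emission density reduces to known closed forms", {
  # kappa = 0: the angle factor is the circular uniform 1/(2*pi)
  p0 <- hmmParams(0.5, 0.5, matrix(1, 1, 1), angle_concentration = 0)
  with_angle <- emissionLogdensity(makeSteps(0.7, 1.3), p0)
  without <- emissionLogdensity(makeSteps(0.7, NA), p0)
  expect_equal(with_angle[1, 1] - without[1, 1], -log(2 * pi))

  # shape-1 gamma (mean = sd) is exponential: at x = mu the log-density of
  # the length factor is -log(mu) - 1
  mu <- 0.4
  pe <- hmmParams(mu, mu, matrix(1, 1, 1), angle_concentration = 0)
  ld <- emissionLogdensity(makeSteps(mu, NA), pe)
  expect_equal(ld[1, 1], -log(mu) - 1)

  # a missing angle contributes only the length factor
  p <- twoStateParams()
  both <- emissionLogdensity(makeSteps(c(0.1, 0.1), c(NA, 0.4)), p)
  expect_equal(both[1, ],
               dgamma(0.1, shape = (p$step_mean / p$step_sd)^2,
                      rate = p$step_mean / p$step_sd^2, log = TRUE))
})

test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(101)
  inst <- randomInstance(2, 6)
  ld <- oracleLogdens(inst$steps, inst$params)
  brute <- bruteLoglikBurst(ld, inst$params$transition_matrix,
                            inst$params$initial_law)
  expect_equal(forwardLoglik(inst$steps, inst$params), brute,
               tolerance = 1e-8)
})

test_that("a one-state chain reduces to the sum of emission densities", {
  p <- hmmParams(0.5, 0.4, matrix(1, 1, 1), angle_concentration = 1.2)
  s <- makeSteps(rgamma(20, 2, 4))
  expect_equal(forwardLoglik(s, p), sum(emissionLogdensity(s, p)))
  v <- viterbiPath(s, p)
  expect_true(all(v$state == 1))
})

test_that("log-likelihood is additive over bursts", {
  p <- twoStateParams()
  s1 <- makeSteps(rgamma(8, 2, 4))
  s2 <- s1
  s2$burst <- 2L
  both <- rbind(s1, s2)
  class(both) <- class(s1)
  expect_equal(forwardLoglik(both, p), 2 * forwardLoglik(s1, p),
               tolerance = 1e-12)
})

test_that("Viterbi matches exhaustive enumeration and breaks ties low", {
  set.seed(102)
  inst <- randomInstance(2, 6)
  ld <- oracleLogdens(inst$steps, inst$params)
  brute <- bruteViterbiBurst(ld, inst$params$transition_matrix,
                             inst$params$initial_law)
  v <- viterbiPath(inst$steps, inst$params)
  expect_equal(v$state, brute)

  # identical emissions in every state + sticky symmetric transitions:
  # every constant path is tied, the tie rule picks state 1 throughout
  p_tie <- hmmParams(step_mean = c(0.5, 0.5), step_sd = c(0.4, 0.4),
                     angle_concentration = c(1, 1),
                     transition_matrix = matrix(c(.8, .2, .2, .8), 2, 2))
  v_tie <- viterbiPath(makeSteps(rgamma(10, 2, 4)), p_tie)
  expect_true(all(v_tie$state == 1))
})

test_that("the analytic score matches central finite differences", {
  set.seed(103)
  p <- hmmParams(step_mean = c(0.05, 0.3, 1), step_sd = c(0.05, 0.2, 0.8),
                 angle_concentration = c(0.5, 1, 3),
                 angle_mean = c(0.3, -1, 0.1), zero_mass = c(0.1, 0.05, 0),
                 transition_matrix = matrix(c(.8, .1, .1, .2, .7, .1,
                                              .15, .15, .7), 3, 3,
                                            byrow = TRUE))
  d <- simulateHMMData(p, 150, n_bursts = 2, seed = 55)
  d$steps$step_km[3] <- 0  # exercise the zero-mass branch
  sv <- movescale:::stepVectors(d$steps)
  for (est_theta in c(TRUE, FALSE)) {
    w <- movescale:::packParams(p, TRUE, est_theta)
    sc <- movescale:::hmmScore(w, sv, 3, TRUE, est_theta)
    num <- vapply(seq_along(w), function(k) {
      h <- 1e-6
      wp <- w; wp[k] <- w[k] + h
      wm <- w; wm[k] <- w[k] - h
      (movescale:::hmmScore(wp, sv, 3, TRUE, est_theta)$loglik -
         movescale:::hmmScore(wm, sv, 3, TRUE, est_theta)$loglik) / (2 * h)
    }, numeric(1))
    expect_equal(sc$grad, num, tolerance = 1e-5)
  }
})

test_that("fitting is deterministic given data and seed", {
  d <- simulateHMMData(twoStateParams(), 800, seed = 6)
  f1 <- fitHMM(d$steps, 2, n_starts = 3, seed = 17)
  f2 <- fitHMM(d$steps, 2, n_starts = 3, seed = 17)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$log_likelihood, f2$log_likelihood)
})

test_that("a one-state fit reduces to the iid gamma MLE", {
  set.seed(104)
  x <- rgamma(600, shape = 2.5, rate = 5)
  s <- makeSteps(x, turn_rad = rep(NA_real_, 600))
  f <- fitHMM(s, 1, n_starts = 3, seed = 2, estimate_angle_mean = FALSE)
  ref <- fitdistrplus::fitdist(x, "gamma",
                               control = list(reltol = 1e-12))
  ref_mean <- unname(ref$estimate["shape"] / ref$estimate["rate"])
  ref_sd <- unname(sqrt(ref$estimate["shape"]) / ref$estimate["rate"])
  expect_equal(f$params$step_mean, ref_mean, tolerance = 1e-4)
  expect_equal(f$params$step_sd, ref_sd, tolerance = 1e-4)
})

test_that("the kept model dominates every converged start and is a fixed point", {
  d <- simulateHMMData(twoStateParams(), 1200, seed = 7)
  f <- fitHMM(d$steps, 2, n_starts = 5, seed = 19)
  expect_true(all(f$log_likelihood >= f$start_loglik[f$converged]))
  # restarting from the optimum reproduces it
  sv <- movescale:::stepVectors(d$steps)
  w <- movescale:::packParams(f$params, f$settings$zero_inflation, TRUE)
  refit <- optim(w, function(v)
    -movescale:::hmmScore(v, sv, 2, FALSE, TRUE)$loglik,
    function(v) -movescale:::hmmScore(v, sv, 2, FALSE, TRUE)$grad,
    method = "BFGS", control = list(maxit = 10000, reltol = 1e-10))
  expect_equal(-refit$value, f$log_likelihood, tolerance = 1e-6)
})

test_that("state relabelling makes fits permutation-invariant across seeds", {
  d <- simulateHMMData(twoStateParams(), 1500, seed = 8)
  fa <- fitHMM(d$steps, 2, n_starts = 5, seed = 1)
  fb <- fitHMM(d$steps, 2, n_starts = 5, seed = 99)
  expect_true(!is.unsorted(fa$params$step_mean))
  expect_true(!is.unsorted(fb$params$step_mean))
  expect_equal(fa$params$step_mean, fb$params$step_mean, tolerance = 1e-4)
  expect_equal(fa$log_likelihood, fb$log_likelihood, tolerance = 1e-6)
})

test_that("step-mean bias shrinks as the sample grows (model-matched data)", {
  p <- twoStateParams()
  d_small <- simulateHMMData(p, 500, seed = 9)
  d_big <- simulateHMMData(p, 5000, seed = 9)
  f_small <- fitHMM(d_small$steps, 2, n_starts = 5, seed = 3)
  f_big <- fitHMM(d_big$steps, 2, n_starts = 5, seed = 3)
  err <- function(f) abs(f$params$step_mean - p$step_mean) / p$step_mean
  expect_true(all(err(f_big) < 0.1))
  expect_lt(mean(err(f_big)), mean(err(f_small)))
})

test_that("too few steps for the parameter count is an error", {
  d <- simulateHMMData(twoStateParams(), 50, seed = 10)
  expect_error(fitHMM(d$steps, 3, seed = 1), "not enough steps")
})

test_that("state summaries carry nominal labels in step-mean order", {
  d <- simulateHMMData(twoStateParams(), 1000, seed = 12)
  f <- fitHMM(d$steps, 2, n_starts = 5, seed = 4)
  sm <- stateSummaries(f)
  expect_equal(sm$label, c("stationary", "travelling"))
  expect_true(!is.unsorted(sm$step_mean_km))
  expect_equal(stateLabels(3), c("stationary", "foraging", "travelling"))
})

test_that("decoding accuracy degrades as the fix interval coarsens", {
  sim <- simulateDataset(n_individuals = 6, n_days = 10, seed = 42,
                         raw_labels = FALSE)
  base <- splitBursts(sim$fixes, 20)
  acc <- vapply(c(1, 3, 6), function(f) {
    steps <- computeSteps(resampleBursts(base, f))
    fit <- fitHMM(steps, 2, n_starts = 5, seed = 7)
    dec <- viterbiPath(steps, fit$params)
    truth <- sim$clips
    truth$category <- ifelse(truth$label == "travelling", "travelling",
                             "stationary")
    mr <- matchStatesToVideo(dec, truth)
    mr$overall_accuracy
  }, numeric(1))
  expect_true(all(diff(acc) < 0))
})
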