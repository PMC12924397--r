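# Independent brute-force oracles for the HMM recursions: enumerate every
# state path explicitly. Only feasible for tiny N and T, which is the point.

# log-density matrix for given steps under params, computed independently of
# the package's compiled kernel (base R dgamma + explicit von Mises formula)
oracleLogdens <- function(steps, params) {
  N <- params$n_states
  Tn <- nrow(steps)
  out <- matrix(0, Tn, N)
  shape <- (params$step_mean / params$step_sd)^2
  rate <- params$step_mean / params$step_sd^2
  for (i in seq_len(N)) {
    x <- steps$step_km
    ld <- ifelse(x == 0,
                 ifelse(params$zero_mass[i] > 0, log(params$zero_mass[i]),
                        -Inf),
                 dgamma(x, shape = shape[i], rate = rate[i], log = TRUE) +
                   log(1 - params$zero_mass[i]))
    a <- steps$turn_rad
    va <- ifelse(is.na(a), 0,
                 params$angle_concentration[i] * cos(a - params$angle_mean[i]) -
                   log(2 * pi * besselI(params$angle_concentration[i], 0,
                                        expon.scaled = TRUE)) -
                   params$angle_concentration[i])
    out[, i] <- ld + va
  }
  out
}

# all N^T state paths for one burst
allPaths <- function(N, Tn) {
  as.matrix(expand.grid(rep(list(seq_len(N)), Tn)))
}

# log-likelihood by exhaustive path enumeration (single burst)
bruteLoglikBurst <- function(logdens, Gamma, delta) {
  Tn <- nrow(logdens)
  N <- ncol(logdens)
  paths <- allPaths(N, Tn)
  lp <- apply(paths, 1, function(s) {
    v <- log(delta[s[1]]) + logdens[1, s[1]]
    if (Tn > 1) for (t in 2:Tn)
      v <- v + log(Gamma[s[t - 1], s[t]]) + logdens[t, s[t]]
    v
  })
  m <- max(lp)
  m + log(sum(exp(lp - m)))
}

# most probable path by exhaustive enumeration (single burst; assumes the
# maximum is unique, which holds a.s. for continuous random emissions)
bruteViterbiBurst <- function(logdens, Gamma, delta) {
  Tn <- nrow(logdens)
  N <- ncol(logdens)
  paths <- allPaths(N, Tn)
  lp <- apply(paths, 1, function(s) {
    v <- log(delta[s[1]]) + logdens[1, s[1]]
    if (Tn > 1) for (t in 2:Tn)
      v <- v + log(Gamma[s[t - 1], s[t]]) + logdens[t, s[t]]
    v
  })
  as.integer(paths[which.max(lp), ])
}

# random small HMM instance: params plus a short random step table
randomInstance <- function(N, Tn) {
  mu <- sort(exp(runif(N, -3, 0.5)))
  sg <- mu * runif(N, 0.4, 1.2)
  kp <- runif(N, 0, 4)
  th <- runif(N, -pi, pi - 1e-9)
  G <- matrix(runif(N * N, 0.05, 1), N, N)
  G <- G / rowSums(G)
  params <- hmmParams(step_mean = mu, step_sd = sg, transition_matrix = G,
                      angle_concentration = kp, angle_mean = th)
  steps <- data.frame(
    id = "a", burst = 1L,
    t_start = as.POSIXct("2018-06-01", tz = "UTC") + 60 * seq_len(Tn),
    step_km = rgamma(Tn, 2, 4),
    turn_rad = c(NA, runif(Tn - 1, -pi, pi)))
  class(steps) <- c("stepTable", "data.frame")
  attr(steps, "interval_minutes") <- 20
  list(params = params, steps = steps)
}

# quick step-table constructor for hand-built cases
makeSteps <- function(step_km, turn_rad = NULL, burst = 1L) {
  n <- length(step_km)
  if (is.null(turn_rad)) turn_rad <- c(NA, runif(n - 1, -pi, pi))
  d <- data.frame(id = "a", burst = rep_len(burst, n),
                  t_start = as.POSIXct("2018-06-01", tz = "UTC") +
                    1200 * seq_len(n),
                  step_km = step_km, turn_rad = turn_rad)
  class(d) <- c("stepTable", "data.frame")
  attr(d, "interval_minutes") <- 20
  d
}

# state-sequence constructor for evaluation tests
makeStateSeq <- function(labels, interval = 20, id = "a", burst = 1L,
                         t0 = as.POSIXct("2018-06-01 06:00:00", tz = "UTC")) {
  lv <- c("stationary", "foraging", "travelling")
  d <- data.frame(id = id, burst = rep_len(burst, length(labels)),
                  t_start = t0 + 60 * interval * (seq_along(labels) - 1),
                  state = match(labels, lv), label = labels,
                  stringsAsFactors = FALSE)
  class(d) <- c("stateSequence", "data.frame")
  attr(d, "interval_minutes") <- interval
  d
}
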