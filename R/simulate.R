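#' Specify the fine-scale behaviour-switching process
#'
#' Defines a first-order Markov chain over behaviours on a fine simulation
#' tick (default 1 minute), the scale at which real animals actually switch
#' between resting, foraging and travelling — typically much finer than the
#' GPS fix interval, which is exactly the mismatch this package is built to
#' study.
#'
#' @param behaviours character vector of behaviour names, in state order.
#' @param transition_matrix row-stochastic matrix over `behaviours` at tick
#'   scale; row `i` gives transition probabilities out of behaviour `i` per
#'   tick.
#' @param initial_distribution probability vector over `behaviours`; defaults
#'   to the stationary distribution of `transition_matrix`.
#' @param fine_step_minutes tick length in minutes (positive integer).
#' @return object of class `behaviourSpec`.
#' @seealso [behaviourSpecFromBouts()] to build the matrix from mean bout
#'   durations, [simulateBehaviourSequence()].
#' @export
behaviourSpec <- function(behaviours, transition_matrix,
                          initial_distribution = NULL,
                          fine_step_minutes = 1L) {
  stopifnot(is.character(behaviours), length(behaviours) >= 1,
            !anyDuplicated(behaviours))
  fine_step_minutes <- as.integer(fine_step_minutes)
  if (is.na(fine_step_minutes) || fine_step_minutes < 1)
    stop("fine_step_minutes must be a positive integer")
  transition_matrix <- as.matrix(transition_matrix)
  checkStochasticMatrix(transition_matrix, length(behaviours))
  if (is.null(initial_distribution))
    initial_distribution <- stationaryDistribution(transition_matrix)
  stopifnot(length(initial_distribution) == length(behaviours),
            all(initial_distribution >= 0),
            abs(sum(initial_distribution) - 1) < 1e-12)
  structure(list(behaviours = behaviours,
                 transition_matrix = unname(transition_matrix),
                 initial_distribution = unname(initial_distribution),
                 fine_step_minutes = fine_step_minutes),
            class = "behaviourSpec")
}

checkStochasticMatrix <- function(P, n) {
  if (!is.matrix(P) || nrow(P) != n || ncol(P) != n)
    stop("transition matrix must be ", n, "x", n)
  if (any(!is.finite(P)) || any(P < 0) || any(P > 1))
    stop("transition probabilities must lie in [0, 1]")
  if (any(abs(rowSums(P) - 1) > 1e-12))
    stop("transition matrix rows must sum to 1 (tolerance 1e-12)")
  invisible(P)
}

#' Stationary distribution of a transition matrix
#'
#' Solves `delta %*% P = delta` subject to `sum(delta) = 1` by a direct
#' linear solve.
#'
#' @param P row-stochastic matrix.
#' @return probability vector.
#' @export
stationaryDistribution <- function(P) {
  n <- nrow(P)
  A <- rbind(t(diag(n) - P), rep(1, n))
  b <- c(rep(0, n), 1)
  delta <- as.vector(qr.solve(A, b))
  delta[delta < 0] <- 0
  delta / sum(delta)
}

#' Build a behaviour process from mean bout durations
#'
#' Converts mean bout durations (minutes) into per-tick stay probabilities
#' `1 - tick/mean` (the geometric dwell-time identity) and splits each row's
#' leave probability across the other behaviours in proportion to
#' `switch_weights`.
#'
#' @param mean_bout_minutes named numeric vector of mean bout durations, one
#'   per behaviour; names define the behaviours.
#' @param switch_weights square matrix of relative switch propensities
#'   (diagonal ignored); defaults to uniform.
#' @inheritParams behaviourSpec
#' @return a `behaviourSpec`.
#' @export
#' @examples
#' behaviourSpecFromBouts(c(stationary = 60, foraging = 30, travelling = 20))
behaviourSpecFromBouts <- function(mean_bout_minutes, switch_weights = NULL,
                                   fine_step_minutes = 1L) {
  stopifnot(!is.null(names(mean_bout_minutes)),
            all(mean_bout_minutes > fine_step_minutes))
  behaviours <- names(mean_bout_minutes)
  n <- length(behaviours)
  if (is.null(switch_weights)) switch_weights <- matrix(1, n, n)
  stay <- 1 - fine_step_minutes / mean_bout_minutes
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    w <- switch_weights[i, ]
    w[i] <- 0
    if (n > 1) P[i, ] <- (1 - stay[i]) * w / sum(w)
    P[i, i] <- stay[i]
  }
  behaviourSpec(behaviours, P, fine_step_minutes = fine_step_minutes)
}

#' Per-behaviour movement kinematics at tick scale
#'
#' One row per behaviour: gamma-distributed per-tick speed (km per tick) and
#' von Mises heading increments. `gps_error_sd` (metres) is isotropic
#' Gaussian noise added to *reported* positions only, so a stationary animal
#' still shows apparent movement — the main reason real stationary fixes have
#' non-zero step lengths.
#'
#' @param behaviours character vector matching the behaviour process.
#' @param speed_mean,speed_sd per-tick displacement mean and sd (km), `> 0`.
#' @param turn_concentration von Mises concentration of heading increments,
#'   `>= 0` (0 = uniform re-orientation each tick).
#' @param turn_mean mean heading increment, radians in `(-pi, pi]`.
#' @param gps_error_sd GPS noise sd in metres, `>= 0`.
#' @return object of class `kinematicsSpec` (a data.frame).
#' @export
kinematicsSpec <- function(behaviours, speed_mean, speed_sd,
                           turn_concentration, turn_mean = 0,
                           gps_error_sd = 15) {
  n <- length(behaviours)
  turn_mean <- rep_len(turn_mean, n)
  gps_error_sd <- rep_len(gps_error_sd, n)
  stopifnot(length(speed_mean) == n, length(speed_sd) == n,
            length(turn_concentration) == n,
            all(speed_mean >= 0), all(speed_sd[speed_mean > 0] > 0),
            all(turn_concentration >= 0), all(gps_error_sd >= 0),
            all(turn_mean > -pi & turn_mean <= pi))
  structure(data.frame(behaviour = behaviours, speed_mean = speed_mean,
                       speed_sd = speed_sd,
                       turn_concentration = turn_concentration,
                       turn_mean = turn_mean, gps_error_sd = gps_error_sd,
                       stringsAsFactors = FALSE),
            class = c("kinematicsSpec", "data.frame"))
}

#' Default behaviour process and kinematics
#'
#' The reference simulation scenario: three behaviours (stationary, foraging,
#' travelling) switching at 1-minute ticks with mean bouts of 60, 30 and 20
#' minutes — fine-scale dwell times of the order field studies report for
#' large herbivores — and kinematics giving partial overlap between foraging
#' and its neighbours: near-zero stationary speed (apparent movement is GPS
#' error), slow tortuous foraging, fast directed travelling.
#'
#' @return `defaultBehaviourSpec()`: a [behaviourSpec()];
#'   `defaultKinematics()`: a [kinematicsSpec()].
#' @export
defaultBehaviourSpec <- function() {
  w <- matrix(c(0, 0.6, 0.4,
                0.5, 0, 0.5,
                0.3, 0.7, 0), 3, 3, byrow = TRUE)
  behaviourSpecFromBouts(
    c(stationary = 60, foraging = 30, travelling = 20),
    switch_weights = w)
}

#' @rdname defaultBehaviourSpec
#' @export
defaultKinematics <- function() {
  kinematicsSpec(
    behaviours = c("stationary", "foraging", "travelling"),
    speed_mean = c(0.0005, 0.010, 0.050),   # km per 1-min tick
    speed_sd = c(0.0005, 0.008, 0.025),
    turn_concentration = c(0, 0.8, 8),
    turn_mean = 0,
    gps_error_sd = 15)
}

#' Simulate a fine-scale behaviour sequence
#'
#' Draws `n_ticks` behaviours from the Markov chain in `spec`. Uses R's RNG
#' stream, so results are reproducible under `set.seed()` / the `seed`
#' argument.
#'
#' @param spec a [behaviourSpec()].
#' @param n_ticks number of ticks (`>= 1`).
#' @param seed optional integer seed applied before drawing.
#' @return character vector of behaviour labels, length `n_ticks`.
#' @export
simulateBehaviourSequence <- function(spec, n_ticks, seed = NULL) {
  stopifnot(inherits(spec, "behaviourSpec"), n_ticks >= 1)
  if (!is.null(seed)) set.seed(seed)
  idx <- .markovSimCpp(spec$transition_matrix, spec$initial_distribution,
                       as.integer(n_ticks))
  spec$behaviours[idx]
}

#' Simulate a movement track from a behaviour sequence
#'
#' First-order directed walk at tick scale: the heading evolves by a von
#' Mises increment drawn with the current behaviour's concentration, the
#' per-tick displacement length is gamma with the behaviour's speed mean/sd,
#' and the position is the cumulative vector sum. Reported positions add
#' isotropic Gaussian GPS error; underlying positions do not. Note this
#' generator is deliberately *not* the fitted HMM observation model — see
#' [simulateHMMData()] for model-exact generation.
#'
#' @param states character vector of behaviours, one per tick.
#' @param kin a [kinematicsSpec()] covering every behaviour in `states`.
#' @param seed optional integer seed.
#' @param x0,y0 starting position (metres).
#' @return data.frame with per-tick columns `x`, `y` (reported, metres),
#'   `x_true`, `y_true`, and `state`. Row `k` is the position after `k-1`
#'   ticks (row 1 is the start).
#' @export
simulateTrack <- function(states, kin, seed = NULL, x0 = 0, y0 = 0) {
  stopifnot(inherits(kin, "kinematicsSpec"), length(states) >= 1)
  missing_kin <- setdiff(unique(states), kin$behaviour)
  if (length(missing_kin))
    stop("no kinematics for behaviour(s): ", paste(missing_kin, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  n <- length(states)
  ki <- match(states, kin$behaviour)
  # per-tick displacement lengths, gamma(mean, sd) per behaviour, in km
  shp <- ifelse(kin$speed_mean > 0, (kin$speed_mean / kin$speed_sd)^2, 1)
  rte <- ifelse(kin$speed_mean > 0, kin$speed_mean / kin$speed_sd^2, 1)
  len_km <- rgamma(n, shape = shp[ki], rate = rte[ki])
  len_km[kin$speed_mean[ki] == 0] <- 0   # degenerate at rest
  # heading increments: von Mises per behaviour (vectorized per behaviour)
  turn <- numeric(n)
  for (b in unique(ki)) {
    sel <- which(ki == b)
    turn[sel] <- rvonmises(length(sel), mu = kin$turn_mean[b],
                           kappa = kin$turn_concentration[b])
  }
  heading <- runif(1, -pi, pi) + cumsum(turn)
  dx <- 1000 * len_km * cos(heading)
  dy <- 1000 * len_km * sin(heading)
  x_true <- x0 + cumsum(c(0, dx))[seq_len(n)]
  y_true <- y0 + cumsum(c(0, dy))[seq_len(n)]
  err_sd <- kin$gps_error_sd[ki]
  data.frame(x = x_true + rnorm(n, 0, err_sd),
             y = y_true + rnorm(n, 0, err_sd),
             x_true = x_true, y_true = y_true,
             state = states, stringsAsFactors = FALSE)
}

#' Emit GPS fixes and instantaneous behaviour "clips"
#'
#' Thins a tick-level track to a regular fix schedule restricted to a daily
#' daylight window (collar cameras cannot film in the dark, so real
#' schedules have overnight gaps). Each emitted fix carries the behaviour at
#' exactly that tick, standing in for a ~10-second video clip.
#'
#' @param track data.frame from [simulateTrack()].
#' @param spec the [behaviourSpec()] used (supplies the tick length).
#' @param fix_interval_minutes fix spacing; must be a multiple of the tick.
#' @param daylight_window numeric length-2, start/end hour of day (24h
#'   clock); fixes outside `[start, end]` are suppressed. Use `c(0, 24)` for
#'   no gap.
#' @param start_time POSIXct of tick 1 (UTC).
#' @param id individual identifier stamped on every row.
#' @return list with `fixes` (id, timestamp, x, y) and `clips`
#'   (id, timestamp, label), both data.frames.
#' @export
emitFixesAndClips <- function(track, spec, fix_interval_minutes,
                              daylight_window = c(6, 22),
                              start_time = as.POSIXct("2018-06-01 00:00:00",
                                                      tz = "UTC"),
                              id = "ind1") {
  stopifnot(inherits(spec, "behaviourSpec"))
  tick <- spec$fine_step_minutes
  if (fix_interval_minutes %% tick != 0)
    stop("fix_interval_minutes must be a multiple of the fine tick (",
         tick, " min)")
  n <- nrow(track)
  minutes <- (seq_len(n) - 1) * tick
  tod0 <- as.numeric(format(start_time, "%H", tz = "UTC")) * 60 +
    as.numeric(format(start_time, "%M", tz = "UTC"))
  tod <- (tod0 + minutes) %% 1440
  in_window <- tod >= daylight_window[1] * 60 & tod <= daylight_window[2] * 60
  on_schedule <- minutes %% fix_interval_minutes == 0
  keep <- which(in_window & on_schedule)
  ts <- start_time + 60 * minutes[keep]
  list(fixes = data.frame(id = id, timestamp = ts,
                          x = track$x[keep], y = track$y[keep],
                          stringsAsFactors = FALSE),
       clips = data.frame(id = id, timestamp = ts,
                          label = track$state[keep],
                          stringsAsFactors = FALSE))
}

# Raw single-label video records consistent with a true behaviour category.
# Mimics how a human scorer would code a clip: a stationary animal may be
# ruminating, alert or napping; a foraging animal is eating (usually
# standing, sometimes drifting forward); a travelling animal walks or runs.
sampleRawLabels <- function(true_labels) {
  n <- length(true_labels)
  behaviour <- character(n)
  locomotion <- character(n)
  st <- which(true_labels == "stationary")
  if (length(st)) {
    behaviour[st] <- sample(c("ruminating", "stationary awake", "napping"),
                            length(st), replace = TRUE,
                            prob = c(0.4, 0.3, 0.3))
    locomotion[st] <- ifelse(behaviour[st] == "napping", "napping",
                             "stationary awake")
  }
  fo <- which(true_labels == "foraging")
  if (length(fo)) {
    behaviour[fo] <- "eating"
    locomotion[fo] <- sample(c("stationary awake", "walking"), length(fo),
                             replace = TRUE, prob = c(0.7, 0.3))
  }
  tr <- which(true_labels == "travelling")
  if (length(tr)) {
    behaviour[tr] <- "travelling"
    locomotion[tr] <- sample(c("walking", "running"), length(tr),
                             replace = TRUE, prob = c(0.8, 0.2))
  }
  data.frame(behaviour = behaviour, locomotion = locomotion,
             stringsAsFactors = FALSE)
}

#' Simulate a full multi-individual tracking dataset
#'
#' Runs the behaviour process and directed walk for each individual on an
#' independent, deterministically derived RNG stream, emits daylight-only
#' fixes and clip labels, and (optionally) dresses each clip in raw
#' single-label video codes so the label-binning stage is exercised
#' end-to-end. The whole object is a pure function of the specs and `seed`.
#'
#' @param behaviour a [behaviourSpec()].
#' @param kinematics a [kinematicsSpec()].
#' @param n_individuals,n_days number of animals and full days per animal.
#' @param fix_interval_minutes base GPS schedule (default 20 min).
#' @param daylight_window see [emitFixesAndClips()].
#' @param seed master integer seed.
#' @param raw_labels attach raw single-label video codes to the clips.
#' @param start_time POSIXct origin (UTC midnight recommended).
#' @return object of class `simData`: list with `fixes`, `clips`,
#'   `true_fine_states` (list per individual), and `provenance`.
#' @export
simulateDataset <- function(behaviour = defaultBehaviourSpec(),
                            kinematics = defaultKinematics(),
                            n_individuals = 30, n_days = 60,
                            fix_interval_minutes = 20,
                            daylight_window = c(6, 22),
                            seed = 1, raw_labels = TRUE,
                            start_time = as.POSIXct("2018-06-01 00:00:00",
                                                    tz = "UTC")) {
  stopifnot(n_individuals >= 1, n_days >= 1)
  ticks_per_day <- as.integer(1440 / behaviour$fine_step_minutes)
  n_ticks <- ticks_per_day * n_days
  fixes <- vector("list", n_individuals)
  clips <- vector("list", n_individuals)
  states <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    set.seed(deriveSeed(seed, i))
    s <- simulateBehaviourSequence(behaviour, n_ticks)
    tr <- simulateTrack(s, kinematics)
    out <- emitFixesAndClips(tr, behaviour, fix_interval_minutes,
                             daylight_window, start_time,
                             id = sprintf("ind%02d", i))
    if (raw_labels)
      out$clips <- cbind(out$clips, sampleRawLabels(out$clips$label))
    fixes[[i]] <- out$fixes
    clips[[i]] <- out$clips
    states[[i]] <- s
  }
  structure(list(fixes = do.call(rbind, fixes),
                 clips = do.call(rbind, clips),
                 true_fine_states = states,
                 provenance = list(behaviour = behaviour,
                                   kinematics = as.data.frame(kinematics),
                                   n_individuals = n_individuals,
                                   n_days = n_days,
                                   fix_interval_minutes = fix_interval_minutes,
                                   daylight_window = daylight_window,
                                   seed = seed,
                                   start_time = format(start_time,
                                                       "%Y-%m-%dT%H:%M:%SZ"))),
            class = "simData")
}

# Independent per-individual stream from one master seed (kept < 2^31).
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

#' @export
print.simData <- function(x, ...) {
  cat("Simulated tracking dataset\n")
  cat("  individuals:", x$provenance$n_individuals,
      " days:", x$provenance$n_days,
      " fix interval:", x$provenance$fix_interval_minutes, "min\n")
  cat("  fixes:", nrow(x$fixes), "  clips:", nrow(x$clips), "\n")
  cat("  behaviours:", paste(x$provenance$behaviour$behaviours,
                             collapse = ", "), "\n")
  invisible(x)
}

#' Simulate observations directly from an HMM ("model-exact" generator)
#'
#' Draws hidden states from the transition matrix and emits step lengths and
#' turn angles from the fitted gamma / von Mises families at fix scale. This
#' is the generation mode in which the fitted model is correctly specified,
#' so parameter-recovery tests are exact rather than confounded with model
#' mismatch.
#'
#' @param params an [hmmParams()] object.
#' @param n_steps steps per burst.
#' @param n_bursts number of independent bursts.
#' @param seed optional integer seed.
#' @param interval_minutes nominal relocation interval stamped on the output.
#' @return list with `steps` (a step table usable by [fitHMM()]) and
#'   `states` (true state index per step).
#' @export
simulateHMMData <- function(params, n_steps, n_bursts = 1, seed = NULL,
                            interval_minutes = 20) {
  stopifnot(inherits(params, "hmmParams"), n_steps >= 1, n_bursts >= 1)
  if (!is.null(seed)) set.seed(seed)
  N <- params$n_states
  shp <- (params$step_mean / params$step_sd)^2
  rte <- params$step_mean / params$step_sd^2
  all_steps <- vector("list", n_bursts)
  all_states <- vector("list", n_bursts)
  t0 <- as.POSIXct("2018-06-01 06:00:00", tz = "UTC")
  for (b in seq_len(n_bursts)) {
    s <- .markovSimCpp(params$transition_matrix, params$initial_law,
                       as.integer(n_steps))
    len <- rgamma(n_steps, shape = shp[s], rate = rte[s])
    if (any(params$zero_mass > 0)) {
      z <- runif(n_steps) < params$zero_mass[s]
      len[z] <- 0
    }
    ang <- numeric(n_steps)
    for (i in seq_len(N)) {
      sel <- which(s == i)
      if (length(sel))
        ang[sel] <- rvonmises(length(sel), params$angle_mean[i],
                              params$angle_concentration[i])
    }
    ang[1] <- NA_real_  # first step of a burst has no previous heading
    all_steps[[b]] <- data.frame(
      id = "sim", burst = b,
      t_start = t0 + 60 * interval_minutes * (seq_len(n_steps) - 1) +
        86400 * (b - 1),
      step_km = len, turn_rad = ang, stringsAsFactors = FALSE)
    all_states[[b]] <- s
  }
  steps <- do.call(rbind, all_steps)
  attr(steps, "interval_minutes") <- interval_minutes
  class(steps) <- c("stepTable", "data.frame")
  list(steps = steps, states = unlist(all_states))
}

#' Serialize a simulation specification to YAML
#'
#' @param sim a `simData` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSimSpec <- function(sim, path) {
  stopifnot(inherits(sim, "simData"))
  prov <- sim$provenance
  prov$behaviour <- list(
    behaviours = prov$behaviour$behaviours,
    fine_step_minutes = prov$behaviour$fine_step_minutes,
    transition_matrix = apply(prov$behaviour$transition_matrix, 1, as.list),
    initial_distribution = prov$behaviour$initial_distribution)
  yaml::write_yaml(prov, path)
  invisible(path)
}
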