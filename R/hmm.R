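#' HMM parameter set for movement data
#'
#' Parameters of an N-state hidden Markov model whose state-dependent
#' distributions are gamma (step length, parameterized by mean and sd, the
#' form movement ecologists report) with an optional point mass at exactly
#' zero, and von Mises (turn angle). The initial law defaults to the
#' stationary distribution of the transition matrix, the standard
#' movement-HMM choice.
#'
#' @param step_mean,step_sd per-state gamma mean and sd of step length (km),
#'   `> 0`.
#' @param transition_matrix N x N row-stochastic matrix (rows sum to 1
#'   within 1e-10).
#' @param angle_concentration per-state von Mises concentration, `>= 0`.
#' @param angle_mean per-state von Mises mean, in `(-pi, pi]`.
#' @param zero_mass per-state probability of a step of exactly 0 km, in
#'   `[0, 1)`.
#' @param initial_law optional probability vector; must satisfy
#'   `initial_law %*% transition_matrix == initial_law` within 1e-8. Default:
#'   the stationary distribution.
#' @return object of class `hmmParams`.
#' @export
#' @examples
#' hmmParams(step_mean = c(0.05, 1), step_sd = c(0.05, 0.8),
#'           angle_concentration = c(0.5, 3),
#'           transition_matrix = matrix(c(.9, .1, .1, .9), 2, 2))
hmmParams <- function(step_mean, step_sd, transition_matrix,
                      angle_concentration, angle_mean = 0, zero_mass = 0,
                      initial_law = NULL) {
  N <- length(step_mean)
  angle_mean <- rep_len(angle_mean, N)
  zero_mass <- rep_len(zero_mass, N)
  stopifnot(N >= 1, length(step_sd) == N, length(angle_concentration) == N,
            all(step_mean > 0), all(step_sd > 0),
            all(angle_concentration >= 0),
            all(angle_mean > -pi & angle_mean <= pi),
            all(zero_mass >= 0 & zero_mass < 1))
  transition_matrix <- as.matrix(transition_matrix)
  if (!is.matrix(transition_matrix) || any(dim(transition_matrix) != N))
    stop("transition_matrix must be ", N, "x", N)
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-10))
    stop("transition_matrix rows must sum to 1 (tolerance 1e-10)")
  if (is.null(initial_law)) {
    initial_law <- stationaryDistribution(transition_matrix)
  } else {
    stopifnot(length(initial_law) == N, all(initial_law >= 0))
    if (max(abs(initial_law %*% transition_matrix - initial_law)) > 1e-8)
      stop("initial_law is not stationary for transition_matrix (tol 1e-8)")
  }
  structure(list(n_states = N,
                 step_mean = as.numeric(step_mean),
                 step_sd = as.numeric(step_sd),
                 zero_mass = as.numeric(zero_mass),
                 angle_mean = as.numeric(angle_mean),
                 angle_concentration = as.numeric(angle_concentration),
                 transition_matrix = unname(transition_matrix),
                 initial_law = as.numeric(initial_law)),
            class = "hmmParams")
}

#' @export
print.hmmParams <- function(x, ...) {
  cat(x$n_states, "-state movement HMM parameters\n", sep = "")
  tab <- data.frame(step_mean = x$step_mean, step_sd = x$step_sd,
                    zero_mass = x$zero_mass, angle_mean = x$angle_mean,
                    angle_conc = x$angle_concentration,
                    stationary = x$initial_law)
  rownames(tab) <- paste0("state", seq_len(x$n_states))
  print(round(tab, 4))
  cat("transition matrix:\n")
  print(round(x$transition_matrix, 4))
  invisible(x)
}

# gamma (mean, sd) -> (shape, rate)
gammaShapeRate <- function(mean, sd) {
  list(shape = (mean / sd)^2, rate = mean / sd^2)
}

stepVectors <- function(steps) {
  stopifnot(is.data.frame(steps), all(c("step_km", "turn_rad") %in% names(steps)))
  if (!all(is.finite(steps$step_km)) || any(steps$step_km < 0))
    stop("step lengths must be finite and non-negative")
  if (any(!is.na(steps$turn_rad) & !is.finite(steps$turn_rad)))
    stop("turn angles must be finite or NA")
  bl <- if ("burst" %in% names(steps)) {
    as.integer(table(factor(steps$burst, levels = unique(steps$burst))))
  } else nrow(steps)
  list(step = steps$step_km, angle = steps$turn_rad, burst_len = bl)
}

#' State-dependent emission log-densities
#'
#' For each step and state, the log of the joint density of step length
#' (gamma with optional zero mass) and turn angle (von Mises). A missing
#' angle contributes only the step-length factor — the angle is marginalized
#' out, so first-of-burst steps and steps adjacent to zero-length steps stay
#' in the likelihood.
#'
#' @param steps a `stepTable` (or any data.frame with `step_km`,
#'   `turn_rad`).
#' @param params an [hmmParams()].
#' @return numeric matrix, one row per step, one column per state.
#' @export
emissionLogdensity <- function(steps, params) {
  stopifnot(inherits(params, "hmmParams"))
  sv <- stepVectors(steps)
  sr <- gammaShapeRate(params$step_mean, params$step_sd)
  .emissionLogdensCpp(sv$step, sv$angle, sr$shape, sr$rate,
                      params$zero_mass, params$angle_concentration,
                      params$angle_mean,
                      logBesselI0(params$angle_concentration) + log(2 * pi))
}

#' Forward-algorithm log-likelihood
#'
#' Total log-likelihood of the step data under the HMM, summed over bursts;
#' the initial law restarts at every burst. Computed with a scaled forward
#' recursion in compiled code, so long bursts do not underflow.
#'
#' @inheritParams emissionLogdensity
#' @return scalar log-likelihood.
#' @export
forwardLoglik <- function(steps, params) {
  stopifnot(inherits(params, "hmmParams"))
  sv <- stepVectors(steps)
  if (length(sv$step) < 1) stop("need at least one step")
  ld <- emissionLogdensity(steps, params)
  .forwardLoglikCpp(ld, params$transition_matrix, params$initial_law,
                    sv$burst_len)
}

#' Viterbi decoding
#'
#' The jointly most probable state path per burst under the fitted
#' parameters, ties broken toward the lower state index. Each state is
#' attached to the START location of its step (`t_start`), the convention
#' whose validity against instantaneous observed behaviour this package
#' exists to probe.
#'
#' @inheritParams emissionLogdensity
#' @param labels optional character vector of state labels (default: nominal
#'   labels from [stateLabels()] when the states are ordered by ascending
#'   step mean, as [fitHMM()] guarantees).
#' @return a `stateSequence`: data.frame `(id, burst, t_start, state,
#'   label)` with `attr(, "interval_minutes")` carried over from `steps`.
#' @export
viterbiPath <- function(steps, params, labels = NULL) {
  stopifnot(inherits(params, "hmmParams"))
  sv <- stepVectors(steps)
  if (length(sv$step) < 1) stop("need at least one step")
  ld <- emissionLogdensity(steps, params)
  st <- .viterbiCpp(ld, params$transition_matrix, params$initial_law,
                    sv$burst_len)
  if (is.null(labels)) labels <- stateLabels(params$n_states)
  out <- data.frame(
    id = if ("id" %in% names(steps)) steps$id else "all",
    burst = if ("burst" %in% names(steps)) steps$burst else 1L,
    t_start = if ("t_start" %in% names(steps)) steps$t_start else
      seq_along(st),
    state = st, label = labels[st], stringsAsFactors = FALSE)
  attr(out, "interval_minutes") <- attr(steps, "interval_minutes")
  class(out) <- c("stateSequence", "data.frame")
  out
}

#' Nominal behaviour labels for ordered states
#'
#' With states sorted by ascending step mean, two-state models are read as
#' stationary/travelling and three-state models as
#' stationary/foraging/travelling — the conventional post-hoc biological
#' reading of slow-tortuous vs. intermediate vs. fast-directed movement.
#'
#' @param n_states number of states.
#' @return character vector of labels.
#' @export
stateLabels <- function(n_states) {
  switch(as.character(n_states),
         "1" = "state1",
         "2" = c("stationary", "travelling"),
         "3" = c("stationary", "foraging", "travelling"),
         paste0("state", seq_len(n_states)))
}

## ---- working-scale parameterization -------------------------------------
##
## Unconstrained vector w:
##   log step_mean (N), log step_sd (N),
##   [logit zero_mass (N)]                      if zero-inflated
##   angle block: (u_i, v_i) planar 2-vector with kappa = |(u,v)|,
##                theta = atan2(v, u)           if angle mean estimated
##            or  log kappa (N)                 if angle mean fixed at 0
##   transition logits eta_ij, j != i, row-wise, diagonal as reference.

packParams <- function(params, est_zero, est_theta) {
  N <- params$n_states
  w <- c(log(params$step_mean), log(params$step_sd))
  if (est_zero) {
    z <- pmin(pmax(params$zero_mass, 1e-8), 1 - 1e-8)
    w <- c(w, log(z / (1 - z)))
  }
  if (est_theta) {
    k <- pmax(params$angle_concentration, 1e-8)
    w <- c(w, rbind(k * cos(params$angle_mean), k * sin(params$angle_mean)))
  } else {
    w <- c(w, log(pmax(params$angle_concentration, 1e-8)))
  }
  if (N > 1) {
    G <- pmin(pmax(params$transition_matrix, 1e-12), 1)
    eta <- log(G / diag(G))
    w <- c(w, t(eta)[t(!diag(N))])  # row-wise off-diagonals
  }
  w
}

unpackParams <- function(w, N, est_zero, est_theta) {
  i <- 0
  take <- function(k) { out <- w[i + seq_len(k)]; i <<- i + k; out }
  mu <- exp(take(N)); sg <- exp(take(N))
  zt <- if (est_zero) stats::plogis(take(N)) else rep(0, N)
  if (est_theta) {
    uv <- matrix(take(2 * N), 2, N)
    kp <- sqrt(colSums(uv^2))
    th <- ifelse(kp > 0, atan2(uv[2, ], uv[1, ]), 0)
  } else {
    kp <- exp(take(N))
    th <- rep(0, N)
  }
  if (N > 1) {
    eta <- matrix(0, N, N)
    eta[t(!diag(N))] <- take(N * (N - 1))
    eta <- t(eta)
    eta <- eta - apply(eta, 1, max)      # stable softmax, rows have 0 reference
    G <- exp(eta) / rowSums(exp(eta))
  } else G <- matrix(1, 1, 1)
  delta <- stationaryDistribution(G)
  list(step_mean = mu, step_sd = sg, zero_mass = zt,
       angle_concentration = kp, angle_mean = th,
       transition_matrix = G, initial_law = delta)
}

asHmmParams <- function(p) {
  hmmParams(step_mean = p$step_mean, step_sd = p$step_sd,
            transition_matrix = p$transition_matrix,
            angle_concentration = p$angle_concentration,
            angle_mean = wrapAngle(p$angle_mean), zero_mass = p$zero_mass,
            initial_law = p$initial_law)
}

emissionLogdensRaw <- function(sv, p) {
  sr <- gammaShapeRate(p$step_mean, p$step_sd)
  .emissionLogdensCpp(sv$step, sv$angle, sr$shape, sr$rate, p$zero_mass,
                      p$angle_concentration, p$angle_mean,
                      logBesselI0(p$angle_concentration) + log(2 * pi))
}

# Score of the log-likelihood on the working scale via the Fisher identity:
# one forward-backward pass yields the posterior state probabilities and
# expected transition counts, from which every partial derivative follows in
# closed form. The initial law's dependence on the transition matrix (it is
# the stationary distribution) is propagated by exact central differences of
# the small stationary-distribution map.
hmmScore <- function(w, sv, N, est_zero, est_theta) {
  p <- unpackParams(w, N, est_zero, est_theta)
  ld <- emissionLogdensRaw(sv, p)
  fb <- .forwardBackwardCpp(ld, p$transition_matrix, p$initial_law,
                            sv$burst_len)
  gam <- fb$gamma
  x <- sv$step
  pos <- x > 0
  lx <- ifelse(pos, log(pmax(x, .Machine$double.xmin)), 0)
  sr <- gammaShapeRate(p$step_mean, p$step_sd)
  g_mu <- g_sg <- g_z <- numeric(N)
  ang_ok <- !is.na(sv$angle)
  a_use <- sv$angle[ang_ok]
  g_k <- g_th <- numeric(N)
  for (s in seq_len(N)) {
    a <- sr$shape[s]; b <- sr$rate[s]
    gi <- gam[, s]
    G <- log(b) - digamma(a) + lx[pos]
    H <- a - b * x[pos]
    gp <- gi[pos]
    g_mu[s] <- sum(gp * (2 * a * G + H))
    g_sg[s] <- sum(gp * (-2 * a * G - 2 * H))
    if (est_zero) {
      z <- p$zero_mass[s]
      g_z[s] <- sum(gi[!pos]) * (1 - z) - sum(gp) * z
    }
    if (any(ang_ok)) {
      ga <- gi[ang_ok]
      dk <- cos(a_use - p$angle_mean[s]) -
        besselRatioA1(p$angle_concentration[s])
      g_k[s] <- sum(ga * dk)
      g_th[s] <- p$angle_concentration[s] * sum(ga * sin(a_use - p$angle_mean[s]))
    }
  }
  grad <- c(g_mu, g_sg)
  if (est_zero) grad <- c(grad, g_z)
  if (est_theta) {
    kp <- pmax(p$angle_concentration, 1e-12)
    cu <- cos(p$angle_mean); sv_ <- sin(p$angle_mean)
    g_u <- g_k * cu - g_th * sv_ / kp
    g_v <- g_k * sv_ + g_th * cu / kp
    grad <- c(grad, rbind(g_u, g_v))
  } else {
    grad <- c(grad, g_k * p$angle_concentration)
  }
  if (N > 1) {
    Xi <- fb$xi_sum
    dEta <- Xi - p$transition_matrix * rowSums(Xi)   # softmax chain rule
    # initial-law term: dL/ddelta %*% ddelta/deta by central differences of
    # the stationary-distribution map (an N x N linear solve per component)
    eta_idx <- which(t(!diag(N)))  # positions in row-wise order
    g_eta <- as.vector(t(dEta))[eta_idx]
    dld <- fb$dldelta
    if (any(dld != 0)) {
      eta0 <- matrix(0, N, N)
      eta0[t(!diag(N))] <- w[(length(w) - N * (N - 1) + 1):length(w)]
      eta0 <- t(eta0)
      h <- 1e-6
      for (k in seq_along(g_eta)) {
        rc <- etaPosition(k, N)
        ep <- eta0; ep[rc[1], rc[2]] <- eta0[rc[1], rc[2]] + h
        em <- eta0; em[rc[1], rc[2]] <- eta0[rc[1], rc[2]] - h
        dp <- stationaryDistribution(exp(ep) / rowSums(exp(ep)))
        dm <- stationaryDistribution(exp(em) / rowSums(exp(em)))
        g_eta[k] <- g_eta[k] + sum(dld * (dp - dm) / (2 * h))
      }
    }
    grad <- c(grad, g_eta)
  }
  list(loglik = fb$loglik, grad = grad)
}

# (row, col) of the k-th row-wise off-diagonal entry of an N x N matrix
etaPosition <- function(k, N) {
  pos <- which(t(!diag(N)))[k]   # index into t(M), i.e. column-major of t
  c(((pos - 1) %/% (N)) + 1, ((pos - 1) %% N) + 1)
}

## ---- multi-start fitting -------------------------------------------------

#' Random starting values from the observed step distribution
#'
#' Draws per-state step-mean starts from disjoint quantile bands of the
#' observed positive step lengths (a reproducible stand-in for choosing
#' starts by eye from histograms), concentration starts uniform on
#' `[0.1, 5]`, and a mildly sticky random transition matrix.
#'
#' @param step_km observed step lengths.
#' @param n_states number of states.
#' @param quantile_bands optional list of length-2 probability bands, one
#'   per state; defaults depend on `n_states` (e.g. (5-40), (40-80),
#'   (80-98) percentiles for three states).
#' @return a function of no arguments returning an [hmmParams()] draw (the
#'   draw consumes the current RNG stream).
#' @export
startGenerator <- function(step_km, n_states, quantile_bands = NULL) {
  pos <- step_km[step_km > 0]
  if (is.null(quantile_bands))
    quantile_bands <- defaultQuantileBands(n_states)
  stopifnot(length(quantile_bands) == n_states)
  zprop <- mean(step_km == 0)
  function() {
    mu <- vapply(quantile_bands, function(b)
      as.numeric(quantile(pos, runif(1, b[1], b[2]))), numeric(1))
    mu <- pmax(sort(mu), 1e-6)
    sg <- mu * runif(n_states, 0.5, 1.5)
    kp <- runif(n_states, 0.1, 5)
    G <- randomStickyMatrix(n_states)
    hmmParams(step_mean = mu, step_sd = sg, transition_matrix = G,
              angle_concentration = kp, angle_mean = 0,
              zero_mass = rep(min(zprop, 0.99), n_states))
  }
}

defaultQuantileBands <- function(n_states) {
  switch(as.character(n_states),
         "1" = list(c(.05, .95)),
         "2" = list(c(.05, .40), c(.60, .98)),
         "3" = list(c(.05, .40), c(.40, .80), c(.80, .98)),
         lapply(seq_len(n_states), function(i)
           c((i - 1) / n_states, i / n_states) * 0.93 + 0.05))
}

randomStickyMatrix <- function(N) {
  if (N == 1) return(matrix(1, 1, 1))
  G <- matrix(0, N, N)
  for (i in seq_len(N)) {
    d <- runif(1, 0.7, 0.95)
    off <- runif(N - 1)
    G[i, -i] <- (1 - d) * off / sum(off)
    G[i, i] <- d
  }
  G
}

#' Fit a movement HMM by multi-start maximum likelihood
#'
#' Maximizes the forward log-likelihood over an unconstrained working scale
#' with BFGS and an analytic score (from forward-backward recursions), from
#' `n_starts` random starting-parameter draws; the fit with the highest
#' converged log-likelihood is kept. States are relabelled by ascending
#' fitted step mean, which makes fits comparable across starts and seeds.
#'
#' @param steps a `stepTable` from [computeSteps()] (or
#'   [simulateHMMData()]).
#' @param n_states number of hidden states (2 or 3 in the headline
#'   analysis; any N >= 1 works).
#' @param n_starts number of random starting-parameter sets (default 10).
#' @param seed integer seed for the starting draws (the fit itself is
#'   deterministic given the starts).
#' @param estimate_angle_mean estimate the von Mises means (default) or fix
#'   them at 0.
#' @param zero_inflation estimate a point mass at zero step length. Default
#'   `NULL`: engaged exactly when zero steps are present in the data (they
#'   otherwise have no density under the gamma).
#' @param quantile_bands see [startGenerator()].
#' @param maxit,reltol BFGS iteration cap and relative convergence
#'   tolerance.
#' @return object of class `hmmFit`: list with elements `params` (an
#'   [hmmParams()], states ordered by ascending step mean),
#'   `log_likelihood`, `n_starts`, `best_start_index`, `converged` (logical
#'   per start), `start_loglik`, `state_order`, `n_steps`, `seed`,
#'   `settings`.
#' @export
fitHMM <- function(steps, n_states, n_starts = 10, seed = 1,
                   estimate_angle_mean = TRUE, zero_inflation = NULL,
                   quantile_bands = NULL, maxit = 10000, reltol = 1e-8) {
  sv <- stepVectors(steps)
  Tn <- length(sv$step)
  est_zero <- if (is.null(zero_inflation)) any(sv$step == 0) else
    isTRUE(zero_inflation)
  est_theta <- isTRUE(estimate_angle_mean)
  n_free <- n_states * (2 + est_zero + 1 + est_theta) +
    n_states * (n_states - 1)
  if (Tn <= 10 * n_free)
    stop("not enough steps (", Tn, ") for ", n_free,
         " free parameters; need more than ", 10 * n_free)
  if (any(sv$step == 0) && !est_zero)
    stop("data contain zero step lengths; zero_inflation must not be FALSE")

  set.seed(seed)
  gen <- startGenerator(sv$step, n_states, quantile_bands)
  starts <- replicate(n_starts, gen(), simplify = FALSE)

  negll <- function(w) {
    ll <- tryCatch({
      p <- unpackParams(w, n_states, est_zero, est_theta)
      ld <- emissionLogdensRaw(sv, p)
      .forwardLoglikCpp(ld, p$transition_matrix, p$initial_law,
                        sv$burst_len)
    }, error = function(e) NA_real_)
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  neggrad <- function(w) {
    g <- tryCatch(-hmmScore(w, sv, n_states, est_zero, est_theta)$grad,
                  error = function(e) rep(NA_real_, length(w)))
    g[!is.finite(g)] <- 0
    g
  }

  results <- vector("list", n_starts)
  for (k in seq_len(n_starts)) {
    w0 <- packParams(starts[[k]], est_zero, est_theta)
    opt <- tryCatch(
      optim(w0, fn = negll, gr = neggrad, method = "BFGS",
            control = list(maxit = maxit, reltol = reltol)),
      error = function(e) e)
    if (inherits(opt, "error")) {
      results[[k]] <- list(ok = FALSE, message = conditionMessage(opt))
      next
    }
    gnorm <- max(abs(neggrad(opt$par)))
    rel_gnorm <- gnorm / (1 + abs(opt$value))
    results[[k]] <- list(ok = TRUE, par = opt$par, value = opt$value,
                         converged = opt$convergence == 0 &&
                           is.finite(rel_gnorm) && rel_gnorm < 1e-4,
                         grad_norm = gnorm)
  }
  ok <- vapply(results, function(r) isTRUE(r$ok), logical(1))
  conv <- vapply(results, function(r) isTRUE(r$converged), logical(1))
  ll_all <- vapply(results, function(r)
    if (isTRUE(r$ok)) -r$value else NA_real_, numeric(1))
  usable <- if (any(conv)) conv else ok
  if (!any(usable)) {
    msgs <- vapply(seq_len(n_starts), function(k)
      paste0("start ", k, ": ",
             if (isTRUE(results[[k]]$ok)) "optimizer failure" else
               results[[k]]$message), character(1))
    stop("all starting values failed:\n", paste(msgs, collapse = "\n"))
  }
  best <- which(usable)[which.max(ll_all[usable])]
  p <- unpackParams(results[[best]]$par, n_states, est_zero, est_theta)
  ord <- order(p$step_mean)
  params <- asHmmParams(reorderStates(p, ord))
  structure(list(params = params,
                 log_likelihood = ll_all[best],
                 n_starts = n_starts,
                 best_start_index = best,
                 converged = conv,
                 start_loglik = ll_all,
                 state_order = ord,
                 n_steps = Tn,
                 seed = seed,
                 settings = list(estimate_angle_mean = est_theta,
                                 zero_inflation = est_zero,
                                 maxit = maxit, reltol = reltol)),
            class = "hmmFit")
}

reorderStates <- function(p, ord) {
  list(step_mean = p$step_mean[ord], step_sd = p$step_sd[ord],
       zero_mass = p$zero_mass[ord],
       angle_concentration = p$angle_concentration[ord],
       angle_mean = p$angle_mean[ord],
       transition_matrix = p$transition_matrix[ord, ord, drop = FALSE],
       initial_law = p$initial_law[ord])
}

#' @export
print.hmmFit <- function(x, ...) {
  cat(x$params$n_states, "-state movement HMM fit\n", sep = "")
  cat("  log-likelihood:", format(x$log_likelihood, digits = 10),
      " (best of", x$n_starts, "starts,", sum(x$converged), "converged)\n")
  cat("  steps:", x$n_steps, "\n")
  print(stateSummaries(x))
  invisible(x)
}

#' Per-state summaries of a fitted HMM
#'
#' The fitted state-dependent distributions as a labelled table: gamma mean
#' and sd of step length, zero mass, von Mises mean and concentration, and
#' the stationary probability of each state. States are ordered by
#' ascending step mean and carry the nominal behaviour labels of
#' [stateLabels()].
#'
#' @param fit an `hmmFit` (or an `hmmParams` already ordered by step mean).
#' @return data.frame, one row per state.
#' @export
stateSummaries <- function(fit) {
  p <- if (inherits(fit, "hmmFit")) fit$params else fit
  stopifnot(inherits(p, "hmmParams"))
  data.frame(state = seq_len(p$n_states),
             label = stateLabels(p$n_states),
             step_mean_km = p$step_mean,
             step_sd_km = p$step_sd,
             zero_mass = p$zero_mass,
             angle_mean_rad = p$angle_mean,
             angle_concentration = p$angle_concentration,
             stationary_prob = p$initial_law,
             stringsAsFactors = FALSE)
}

#' Serialize a fit to JSON
#'
#' @param fit an `hmmFit`.
#' @param path output file.
#' @export
writeFitResult <- function(fit, path) {
  stopifnot(inherits(fit, "hmmFit"))
  p <- fit$params
  obj <- list(n_states = p$n_states, step_mean = p$step_mean,
              step_sd = p$step_sd, zero_mass = p$zero_mass,
              angle_mean = p$angle_mean,
              angle_concentration = p$angle_concentration,
              transition_matrix = p$transition_matrix,
              initial_law = p$initial_law,
              log_likelihood = fit$log_likelihood,
              n_starts = fit$n_starts,
              best_start_index = fit$best_start_index,
              converged = fit$converged,
              start_loglik = fit$start_loglik,
              n_steps = fit$n_steps, seed = fit$seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a decoded state sequence as CSV
#'
#' @param states a `stateSequence`.
#' @param path output file.
#' @export
writeStateSequence <- function(states, path) {
  out <- as.data.frame(states)
  out$t_start <- format(out$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
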