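#' von Mises density
#'
#' Density of the von Mises distribution on the circle, the standard
#' turn-angle emission distribution in movement HMMs. At `kappa = 0` it
#' reduces to the circular uniform density `1/(2*pi)`.
#'
#' @param x angles in radians (any real; the density is 2*pi-periodic).
#' @param mu mean direction in radians.
#' @param kappa concentration parameter, `>= 0`.
#' @param log if `TRUE`, return the log-density.
#' @return numeric vector of (log-)densities.
#' @export
#' @examples
#' dvonmises(0, 0, 2)
#' integrate(dvonmises, -pi, pi, mu = 0.5, kappa = 3)  # ~1
dvonmises <- function(x, mu = 0, kappa = 1, log = FALSE) {
  stopifnot(kappa >= 0, is.finite(mu))
  ld <- kappa * cos(x - mu) - logBesselI0(kappa) - log(2 * pi)
  if (log) ld else exp(ld)
}

# log I0(kappa), exponentially scaled for numerical stability at large kappa
logBesselI0 <- function(kappa) {
  log(besselI(kappa, 0, expon.scaled = TRUE)) + kappa
}

# A(kappa) = I1(kappa)/I0(kappa): mean resultant length, used in the score
besselRatioA1 <- function(kappa) {
  ifelse(kappa == 0, 0,
         besselI(kappa, 1, expon.scaled = TRUE) /
           besselI(kappa, 0, expon.scaled = TRUE))
}

#' Draw from a von Mises distribution
#'
#' Best–Fisher (1979) wrapped-Cauchy envelope rejection sampler, vectorized.
#' `kappa = 0` draws from the circular uniform on `(-pi, pi]`.
#'
#' @param n number of draws.
#' @inheritParams dvonmises
#' @return angles in `(-pi, pi]`.
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  stopifnot(n >= 0, kappa >= 0)
  if (n == 0) return(numeric(0))
  if (kappa == 0) {
    th <- runif(n, -pi, pi)
  } else {
    a <- 1 + sqrt(1 + 4 * kappa^2)
    b <- (a - sqrt(2 * a)) / (2 * kappa)
    r <- (1 + b^2) / (2 * b)
    th <- numeric(n)
    todo <- seq_len(n)
    while (length(todo)) {
      m <- length(todo)
      u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
      z <- cos(pi * u1)
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
      th[todo[ok]] <- sign(u3[ok] - 0.5) * acos(f[ok])
      todo <- todo[!ok]
    }
  }
  wrapAngle(th + mu)
}

#' Wrap angles to (-pi, pi]
#'
#' @param x angles in radians.
#' @return wrapped angles.
#' @export
wrapAngle <- function(x) {
  w <- x - 2 * pi * floor((x + pi) / (2 * pi))
  # floor puts the boundary at -pi; the convention here is (-pi, pi]
  w[w <= -pi] <- pi
  w
}
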