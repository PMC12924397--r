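#' Split a fix table into constant-interval bursts
#'
#' A burst is a maximal run of fixes at an exactly constant sampling
#' interval for one individual. Daylight-only collar schedules produce an
#' overnight gap every day, so each day typically becomes (at least) one
#' burst; no movement step is ever computed across a gap.
#'
#' @param fixes data.frame with columns `id`, `timestamp` (POSIXct),
#'   `x`, `y` (metres, projected plane).
#' @param expected_interval_minutes the nominal fix interval; gaps differing
#'   from it (compared in whole minutes) start a new burst.
#' @return a `burstSet`: data.frame `(id, burst, timestamp, x, y)` with the
#'   interval recorded in `attr(, "interval_minutes")`. Singleton bursts are
#'   retained (they simply yield no steps).
#' @export
splitBursts <- function(fixes, expected_interval_minutes) {
  stopifnot(all(c("id", "timestamp", "x", "y") %in% names(fixes)),
            expected_interval_minutes >= 1)
  if (nrow(fixes) == 0)
    return(emptyBurstSet(expected_interval_minutes))
  fixes <- fixes[order(fixes$id, fixes$timestamp), , drop = FALSE]
  if (anyDuplicated(fixes[, c("id", "timestamp")]))
    stop("duplicate timestamps within an individual")
  gap_min <- round(c(NA, diff(as.numeric(fixes$timestamp)) / 60))
  new_ind <- c(TRUE, fixes$id[-1] != fixes$id[-nrow(fixes)])
  new_burst <- new_ind | gap_min != expected_interval_minutes
  new_burst[is.na(new_burst)] <- TRUE
  burst <- cumsum(new_burst)
  out <- data.frame(id = fixes$id, burst = burst,
                    timestamp = fixes$timestamp,
                    x = fixes$x, y = fixes$y, stringsAsFactors = FALSE)
  attr(out, "interval_minutes") <- expected_interval_minutes
  class(out) <- c("burstSet", "data.frame")
  out
}

emptyBurstSet <- function(interval_minutes) {
  out <- data.frame(id = character(0), burst = integer(0),
                    timestamp = as.POSIXct(character(0), tz = "UTC"),
                    x = numeric(0), y = numeric(0))
  attr(out, "interval_minutes") <- interval_minutes
  class(out) <- c("burstSet", "data.frame")
  out
}

#' Thin bursts to a coarser relocation interval
#'
#' Within each burst, retains the fixes at indices 1, 1+n, 1+2n, ... and
#' multiplies the interval by `n`. Because only every nth location is
#' retained (never interpolated), the retained set at a coarser scale is by
#' construction a subset of every finer scale's set, which is what makes
#' behavioural states comparable at the same physical locations across
#' temporal scales.
#'
#' @param bursts a `burstSet` from [splitBursts()].
#' @param n positive integer thinning factor (`n = 1` is the identity;
#'   `n = 3` turns a 20-min schedule into 60 min).
#' @return a `burstSet` at interval `n * interval_minutes`.
#' @export
resampleBursts <- function(bursts, n) {
  stopifnot(inherits(bursts, "burstSet"))
  n <- as.integer(n)
  if (is.na(n) || n < 1) stop("resample factor n must be a positive integer")
  if (n == 1 || nrow(bursts) == 0) {
    attr(bursts, "interval_minutes") <- attr(bursts, "interval_minutes") * n
    return(bursts)
  }
  pos <- stats::ave(seq_len(nrow(bursts)), bursts$burst,
                    FUN = seq_along)
  keep <- (pos - 1L) %% n == 0L
  out <- bursts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "interval_minutes") <- attr(bursts, "interval_minutes") * n
  class(out) <- c("burstSet", "data.frame")
  out
}

#' Step lengths and turn angles from bursts
#'
#' Step `k` links relocation `k` to `k+1` within a burst; its length is the
#' planar Euclidean distance in kilometres. The turn angle of step `k`
#' (`k >= 2`) is the signed heading change from step `k-1` to step `k`,
#' counter-clockwise positive, wrapped to `(-pi, pi]`; the first step of
#' each burst has no previous heading and its angle is missing. A
#' zero-length step has an undefined heading, so the angles that depend on
#' it are also set missing (they are marginalized out of the HMM
#' likelihood).
#'
#' @param bursts a `burstSet`.
#' @return a `stepTable`: data.frame `(id, burst, t_start, step_km,
#'   turn_rad)`, one row per step, with the relocation interval in
#'   `attr(, "interval_minutes")`. `t_start` is the timestamp of the step's
#'   START location — the convention under which decoded states are later
#'   compared to observed behaviours.
#' @export
computeSteps <- function(bursts) {
  stopifnot(inherits(bursts, "burstSet"))
  pieces <- lapply(split(seq_len(nrow(bursts)), bursts$burst), function(ix) {
    L <- length(ix)
    if (L < 2) return(NULL)
    x <- bursts$x[ix]; y <- bursts$y[ix]
    dx <- diff(x); dy <- diff(y)
    len_km <- sqrt(dx^2 + dy^2) / 1000
    heading <- atan2(dy, dx)
    heading[len_km == 0] <- NA_real_
    turn <- c(NA_real_, wrapAngle(diff(heading)))
    data.frame(id = bursts$id[ix[1]], burst = bursts$burst[ix[1]],
               t_start = bursts$timestamp[ix[-L]],
               step_km = len_km, turn_rad = turn, stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  out <- if (length(pieces)) do.call(rbind, pieces) else
    data.frame(id = character(0), burst = integer(0),
               t_start = as.POSIXct(character(0), tz = "UTC"),
               step_km = numeric(0), turn_rad = numeric(0))
  rownames(out) <- NULL
  attr(out, "interval_minutes") <- attr(bursts, "interval_minutes")
  class(out) <- c("stepTable", "data.frame")
  out
}

#' Read / write fix tables as CSV
#'
#' Fix tables are CSV with columns `id, timestamp, x, y`; timestamps are
#' ISO-8601 UTC, coordinates metres in a projected plane. (Projection from
#' lon/lat is upstream of this package: the analysis needs linear
#' distances.)
#'
#' @param path file path.
#' @return `readFixes`: a data.frame with parsed POSIXct timestamps.
#' @export
readFixes <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "timestamp", "x", "y") %in% names(d)))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                           "%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS"))
  if (anyNA(d$timestamp)) stop("unparseable timestamps in ", path)
  d
}

#' @rdname readFixes
#' @param fixes data.frame with `id, timestamp, x, y`.
#' @export
writeFixes <- function(fixes, path) {
  out <- fixes[, c("id", "timestamp", "x", "y")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Write a step table as CSV
#'
#' @param steps a `stepTable`.
#' @param path file path.
#' @export
writeSteps <- function(steps, path) {
  out <- as.data.frame(steps)
  out$t_start <- format(out$t_start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
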