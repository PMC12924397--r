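#' Match decoded states to binned video behaviours
#'
#' Joins each step's START-location timestamp to a binned video behaviour
#' for the same individual within `join_tolerance_minutes`, drops EXCLUDED
#' and unmatched records (counting them), and tabulates agreement. The
#' reference is the video category; the prediction is the HMM state label.
#' Overall accuracy (percent match) is the proportion of joined
#' observations where the two coincide.
#'
#' @param states a `stateSequence` from [viterbiPath()].
#' @param binned a clip table with a `category` column from
#'   [binBehaviours()] (extra columns such as raw labels are carried into
#'   the joined table).
#' @param join_tolerance_minutes maximum |clip time - step start| for a
#'   join (default 1; schedules are meant to coincide exactly, the
#'   tolerance only absorbs clock jitter).
#' @return object of class `matchResult`: list with `confusion` (prediction
#'   rows x reference columns), `overall_accuracy` (in `[0, 1]`), `n_used`,
#'   `n_excluded`, `n_unmatched`, and `joined` (the row-level joined
#'   table).
#' @export
matchStatesToVideo <- function(states, binned, join_tolerance_minutes = 1) {
  stopifnot(inherits(states, "stateSequence"),
            all(c("id", "timestamp", "category") %in% names(binned)))
  tol <- as.integer(join_tolerance_minutes)
  skey_min <- round(as.numeric(states$t_start) / 60)
  ckey_min <- round(as.numeric(binned$timestamp) / 60)
  sidx <- integer(0); cidx <- integer(0)
  for (off in seq(-tol, tol)) {
    skey <- paste(states$id, skey_min + off)
    ckey <- paste(binned$id, ckey_min)
    m <- match(skey, ckey)
    hit <- which(!is.na(m))
    sidx <- c(sidx, hit); cidx <- c(cidx, m[hit])
  }
  if (anyDuplicated(sidx))
    stop("duplicate video joins for at least one fix; ",
         "shrink join_tolerance_minutes")
  excl <- binned$category[cidx] == "EXCLUDED"
  n_excluded <- sum(excl)
  n_unmatched <- nrow(states) - length(sidx)
  keep <- !excl
  if (!any(keep))
    stop("no usable observations (n_excluded = ", n_excluded, ")")
  joined <- cbind(states[sidx[keep], c("id", "t_start", "state", "label")],
                  binned[cidx[keep],
                         setdiff(names(binned), c("id", "timestamp")),
                         drop = FALSE])
  rownames(joined) <- NULL
  cats <- sort(unique(c(joined$label, joined$category)))
  confusion <- table(prediction = factor(joined$label, levels = cats),
                     reference = factor(joined$category, levels = cats))
  structure(list(confusion = confusion,
                 overall_accuracy = sum(diag(confusion)) / sum(confusion),
                 n_used = sum(confusion),
                 n_excluded = n_excluded,
                 n_unmatched = n_unmatched,
                 joined = joined),
            class = "matchResult")
}

#' @export
print.matchResult <- function(x, ...) {
  cat("HMM state vs video behaviour match\n")
  cat("  overall accuracy:", sprintf("%.1f%%", 100 * x$overall_accuracy),
      " (n =", x$n_used, "; excluded =", x$n_excluded,
      "; unmatched =", x$n_unmatched, ")\n")
  print(x$confusion)
  invisible(x)
}

#' Composition of raw video behaviours within each decoded state
#'
#' For each HMM state label, the distribution of raw (pre-binning) video
#' behaviours among the joined locations — the table behind
#' variable-width composition bar charts, where column mass is proportional
#' to the number of locations decoded into each state.
#'
#' @param joined the `joined` element of a [matchStatesToVideo()] result.
#' @param raw_col name of the raw-label column (default `"behaviour"`).
#' @return tidy data.frame `(state_label, raw_label, n, proportion,
#'   state_n)`; proportions sum to 1 within each state.
#' @export
compositionByState <- function(joined, raw_col = "behaviour") {
  stopifnot(nrow(joined) > 0, raw_col %in% names(joined))
  tab <- table(state_label = joined$label, raw_label = joined[[raw_col]])
  df <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(df)[3] <- "n"
  state_n <- rowSums(tab)
  df$proportion <- df$n / state_n[df$state_label]
  df$state_n <- as.integer(state_n[df$state_label])
  df <- df[df$state_n > 0, ]
  df <- df[order(df$state_label, -df$proportion, df$raw_label), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Agreement between state sequences at two temporal scales
#'
#' Restricts the finer-scale sequence to the coarser sequence's step-start
#' locations (guaranteed to be a subset when the coarse track was obtained
#' with [resampleBursts()]) and computes the proportion of shared locations
#' whose inferred state labels agree.
#'
#' @param fine,coarse `stateSequence` objects decoded at a finer and a
#'   coarser relocation interval of the same underlying track.
#' @return list with `proportion_match`, `n_shared`, and the two intervals.
#' @export
crossScaleMatch <- function(fine, coarse) {
  stopifnot(inherits(fine, "stateSequence"), inherits(coarse, "stateSequence"))
  fkey <- paste(fine$id, round(as.numeric(fine$t_start) / 60))
  ckey <- paste(coarse$id, round(as.numeric(coarse$t_start) / 60))
  m <- match(ckey, fkey)
  if (anyNA(m))
    stop("coarse step-start locations are not a subset of fine ones (",
         sum(is.na(m)), " missing); sequences are not nested resamples")
  list(proportion_match = mean(fine$label[m] == coarse$label),
       n_shared = length(m),
       fine_interval = attr(fine, "interval_minutes"),
       coarse_interval = attr(coarse, "interval_minutes"))
}

#' Mean behavioural bout durations from a decoded sequence
#'
#' A bout is a maximal run of identical states within a burst (runs never
#' span burst boundaries — there is no evidence about what happened across
#' a gap). Its duration is the run length multiplied by the relocation
#' interval; the per-state mean of these durations is the usual
#' "average time spent in a state before switching" summary.
#'
#' @param states a `stateSequence`.
#' @param interval_minutes relocation interval; defaults to the attribute
#'   carried on `states`.
#' @return object of class `boutSummary`: data.frame `(label, n_bouts,
#'   mean_bout_minutes, total_minutes)`.
#' @export
boutDurations <- function(states, interval_minutes = NULL) {
  stopifnot(inherits(states, "stateSequence"), nrow(states) > 0)
  if (is.null(interval_minutes))
    interval_minutes <- attr(states, "interval_minutes")
  stopifnot(is.numeric(interval_minutes), interval_minutes > 0)
  runs <- do.call(rbind, lapply(split(states$label, states$burst),
                                function(lab) {
    r <- rle(as.character(lab))
    data.frame(label = r$values, len = r$lengths, stringsAsFactors = FALSE)
  }))
  agg <- do.call(rbind, lapply(split(runs$len, runs$label), function(l)
    data.frame(n_bouts = length(l), mean_len = mean(l), total_len = sum(l))))
  out <- data.frame(label = rownames(agg),
                    n_bouts = agg$n_bouts,
                    mean_bout_minutes = agg$mean_len * interval_minutes,
                    total_minutes = agg$total_len * interval_minutes,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "interval_minutes") <- interval_minutes
  class(out) <- c("boutSummary", "data.frame")
  out
}
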