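## Label vocabularies and precedence rules. The same structure is shipped as
## a versioned YAML (inst/extdata/binning_rules.yaml) so the mapping is
## auditable outside R; binningRules() reads that file.

FMCH_BEHAVIOURS <- c("eating", "ruminating", "travelling", "stationary awake",
                     "napping", "other")
FMCH_LOCOMOTION <- c("napping", "stationary awake", "running",
                     "wading/swimming", "walking")
RFCH_LABELS <- c("eating", "foraging", "drinking", "laying", "walking",
                 "ruminating", "vigilant", "running", "swimming", "other")
RFCH_MOVING <- c("walking", "running", "swimming")
RFCH_STATIONARY2 <- c("eating", "drinking", "laying", "ruminating",
                      "vigilant", "foraging")
RFCH_LOWMOVE3 <- c("laying", "vigilant", "ruminating")
RFCH_FEEDING3 <- c("eating", "drinking", "foraging")

#' The binning vocabularies and precedence rules
#'
#' Reads the versioned rule file shipped with the package. This is the
#' single auditable statement of which raw video labels map to which broad
#' category under each dialect and scheme.
#'
#' @return nested list mirroring the YAML.
#' @export
binningRules <- function() {
  yaml::read_yaml(system.file("extdata", "binning_rules.yaml",
                              package = "movescale"))
}

#' Bin single-label (FMCH-dialect) video records
#'
#' Reduces mutually exclusive behaviour/locomotion codes to the broad
#' category matching an HMM state scheme. The two-state scheme reads the
#' locomotion code (napping / stationary awake -> stationary; running /
#' wading-swimming / walking -> travelling). The three-state scheme reads
#' the behaviour code (ruminating / stationary awake / napping ->
#' stationary; eating -> foraging; travelling -> travelling). Records whose
#' behaviour is "other" are EXCLUDED, as are three-state records whose
#' behaviour has no mapping.
#'
#' @param behaviour,locomotion character vectors of raw codes; a record
#'   whose read field is `NA` (unscored) is EXCLUDED.
#' @param scheme `"two_state"` or `"three_state"`.
#' @return character vector of categories (`stationary`, `foraging`,
#'   `travelling`, or `EXCLUDED`).
#' @export
binFMCH <- function(behaviour, locomotion, scheme = c("two_state",
                                                      "three_state")) {
  scheme <- match.arg(scheme)
  n <- max(length(behaviour), length(locomotion))
  behaviour <- rep_len(as.character(behaviour), n)
  locomotion <- rep_len(as.character(locomotion), n)
  bad_b <- !is.na(behaviour) & !(behaviour %in% FMCH_BEHAVIOURS)
  bad_l <- !is.na(locomotion) & !(locomotion %in% FMCH_LOCOMOTION)
  if (any(bad_b))
    stop("unknown FMCH behaviour label(s): ",
         paste(unique(behaviour[bad_b]), collapse = ", "))
  if (any(bad_l))
    stop("unknown FMCH locomotion label(s): ",
         paste(unique(locomotion[bad_l]), collapse = ", "))
  out <- if (scheme == "two_state") {
    ifelse(is.na(locomotion), "EXCLUDED",
           ifelse(locomotion %in% c("napping", "stationary awake"),
                  "stationary", "travelling"))
  } else {
    m <- c(ruminating = "stationary", "stationary awake" = "stationary",
           napping = "stationary", eating = "foraging",
           travelling = "travelling")
    cat_ <- unname(m[as.character(behaviour)])
    cat_[is.na(cat_)] <- "EXCLUDED"   # unmapped or locomotion-only record
    cat_
  }
  out[!is.na(behaviour) & behaviour == "other"] <- "EXCLUDED"
  out
}

#' Bin multi-label (RFCH-dialect) video records
#'
#' Applies the deterministic precedence rules for label sets. Two-state:
#' any moving label (walking, running, swimming) forces `travelling`,
#' overriding concurrent stationary labels; otherwise any of eating,
#' drinking, laying, ruminating, vigilant, foraging gives `stationary`.
#' Three-state, in order with later rules overriding earlier: low-movement
#' labels (laying, vigilant, ruminating) give `stationary`; locomotion
#' labels give `travelling`; feeding labels (eating, drinking, foraging)
#' give `foraging` — so walking-with-eating ends up `foraging` while
#' locomotion without feeding stays `travelling`. Any set containing
#' "other" is EXCLUDED. The result does not depend on the order of the
#' labels within a set.
#'
#' @param labels a list of character vectors (one set per record), or a
#'   character vector of pipe-delimited label strings. "vigilance" is
#'   accepted as an alias of "vigilant".
#' @inheritParams binFMCH
#' @return character vector of categories.
#' @export
binRFCH <- function(labels, scheme = c("two_state", "three_state")) {
  scheme <- match.arg(scheme)
  if (is.character(labels)) labels <- strsplit(labels, "|", fixed = TRUE)
  stopifnot(is.list(labels))
  vapply(labels, function(ls) {
    ls <- trimws(as.character(ls))
    ls[ls == "vigilance"] <- "vigilant"
    if (length(ls) == 0 || all(ls == ""))
      stop("empty RFCH label set")
    unknown <- setdiff(ls, RFCH_LABELS)
    if (length(unknown))
      stop("unknown RFCH label(s): ", paste(unknown, collapse = ", "))
    if ("other" %in% ls) return("EXCLUDED")
    if (scheme == "two_state") {
      if (any(ls %in% RFCH_MOVING)) return("travelling")
      if (any(ls %in% RFCH_STATIONARY2)) return("stationary")
      stop("RFCH record matches no two-state rule: ",
           paste(ls, collapse = ", "))
    }
    cat_ <- NA_character_
    if (any(ls %in% RFCH_LOWMOVE3)) cat_ <- "stationary"
    if (any(ls %in% RFCH_MOVING)) cat_ <- "travelling"
    if (any(ls %in% RFCH_FEEDING3)) cat_ <- "foraging"
    if (is.na(cat_))
      stop("RFCH record matches no three-state rule: ",
           paste(ls, collapse = ", "))
    cat_
  }, character(1))
}

#' Bin a clip table
#'
#' Data-frame front end over [binFMCH()] / [binRFCH()]: adds `scheme` and
#' `category` columns to a clip table. FMCH tables need `behaviour` and
#' `locomotion` columns; RFCH tables need a `labels` column (pipe-delimited
#' strings or a list column).
#'
#' @param clips data.frame of video records (typically the `clips` element
#'   of a [simulateDataset()] or read with [readClips()]).
#' @param dialect `"FMCH"` (single-label) or `"RFCH"` (multi-label).
#' @inheritParams binFMCH
#' @return `clips` with `scheme` and `category` columns appended.
#' @export
binBehaviours <- function(clips, dialect = c("FMCH", "RFCH"),
                          scheme = c("two_state", "three_state")) {
  dialect <- match.arg(dialect)
  scheme <- match.arg(scheme)
  category <- if (dialect == "FMCH") {
    stopifnot(all(c("behaviour", "locomotion") %in% names(clips)))
    binFMCH(clips$behaviour, clips$locomotion, scheme)
  } else {
    stopifnot("labels" %in% names(clips))
    binRFCH(clips$labels, scheme)
  }
  clips$scheme <- scheme
  clips$category <- category
  clips
}

#' Read / write clip label tables as CSV
#'
#' CSV with columns `id, timestamp, dialect` plus either
#' `behaviour, locomotion` (FMCH) or pipe-delimited `labels` (RFCH).
#'
#' @param path file path.
#' @export
readClips <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("id", "timestamp") %in% names(d)))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%OSZ",
                                           "%Y-%m-%dT%H:%M:%OS",
                                           "%Y-%m-%d %H:%M:%OS"))
  d
}

#' @rdname readClips
#' @param clips clip table.
#' @export
writeClips <- function(clips, path) {
  out <- as.data.frame(clips)
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
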