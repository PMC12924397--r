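#' Configuration for a full simulate-fit-evaluate experiment
#'
#' Bundles the simulation scenario, the grid of relocation intervals and
#' state counts, the fit settings and the output location into one
#' validated object. The grid is fully crossed: every resample factor is
#' analysed with every state count, mirroring a herd-level study design
#' (e.g. 3 intervals x 2 state counts = 6 cells).
#'
#' @param behaviour a [behaviourSpec()].
#' @param kinematics a [kinematicsSpec()].
#' @param n_individuals,n_days simulated sampling effort.
#' @param base_interval_minutes base GPS schedule (minutes).
#' @param resample_factors positive integers; factor 1 is the base scale.
#' @param n_states integer vector of state counts to fit (e.g. `c(2, 3)`).
#' @param n_starts random starting-parameter sets per fit.
#' @param dialect video-label dialect for binning (`"FMCH"` single-label or
#'   `"RFCH"` multi-label).
#' @param daylight_window start/end hour of the daily collar-on window.
#' @param join_tolerance_minutes see [matchStatesToVideo()].
#' @param out_dir output directory (created if needed).
#' @param seed master seed; every stage derives its stream from it.
#' @return object of class `experimentConfig`.
#' @export
experimentConfig <- function(behaviour = defaultBehaviourSpec(),
                             kinematics = defaultKinematics(),
                             n_individuals = 30, n_days = 60,
                             base_interval_minutes = 20,
                             resample_factors = c(1, 3, 6),
                             n_states = c(2, 3),
                             n_starts = 10,
                             dialect = "FMCH",
                             daylight_window = c(6, 22),
                             join_tolerance_minutes = 1,
                             out_dir = tempfile("movescale_run_"),
                             seed = 1) {
  stopifnot(inherits(behaviour, "behaviourSpec"),
            inherits(kinematics, "kinematicsSpec"),
            n_individuals >= 1, n_days >= 1, base_interval_minutes >= 1,
            length(resample_factors) >= 1, length(n_states) >= 1,
            n_starts >= 1)
  if (any(resample_factors != round(resample_factors)) ||
      any(resample_factors < 1))
    stop("resample_factors must be positive integers")
  if (any(n_states < 1)) stop("n_states must be >= 1")
  if (!dialect %in% c("FMCH", "RFCH")) stop("unknown dialect: ", dialect)
  if (base_interval_minutes %% behaviour$fine_step_minutes != 0)
    stop("base interval must be a multiple of the fine tick")
  structure(list(behaviour = behaviour, kinematics = kinematics,
                 n_individuals = n_individuals, n_days = n_days,
                 base_interval_minutes = base_interval_minutes,
                 resample_factors = sort(unique(as.integer(resample_factors))),
                 n_states = sort(unique(as.integer(n_states))),
                 n_starts = n_starts, dialect = dialect,
                 daylight_window = daylight_window,
                 join_tolerance_minutes = join_tolerance_minutes,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "experimentConfig")
}

stageTry <- function(stage, cell, expr) {
  tryCatch(expr, error = function(e)
    stop("experiment stage '", stage, "' failed",
         if (nzchar(cell)) paste0(" for cell [", cell, "]"), ": ",
         conditionMessage(e), call. = FALSE))
}

#' Run the full experiment grid
#'
#' Simulates the dataset, preprocesses it into bursts and steps at every
#' relocation interval, fits an HMM per (interval, state-count) cell on the
#' pooled bursts of all individuals, decodes states, bins the clip labels,
#' and evaluates video match, cross-scale match and bout durations. All
#' artifacts are written under `config$out_dir` and listed (with md5
#' hashes and the seed) in `manifest.json`; rerunning with the same config
#' reproduces identical files.
#'
#' @param config an [experimentConfig()].
#' @return invisibly, a list with `manifest` (artifact table), `fits`,
#'   `matches`, `bouts`, `cross_scale`, `compositions` and `config`.
#' @export
runExperiment <- function(config) {
  stopifnot(inherits(config, "experimentConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  od <- function(...) file.path(config$out_dir, ...)
  artifacts <- character(0)
  log <- list()

  sim <- stageTry("simulate", "", simulateDataset(
    behaviour = config$behaviour, kinematics = config$kinematics,
    n_individuals = config$n_individuals, n_days = config$n_days,
    fix_interval_minutes = config$base_interval_minutes,
    daylight_window = config$daylight_window, seed = config$seed))
  writeFixes(sim$fixes, od("fixes.csv"))
  writeClips(sim$clips, od("clips.csv"))
  writeSimSpec(sim, od("sim_spec.yaml"))
  artifacts <- c(artifacts, od("fixes.csv"), od("clips.csv"),
                 od("sim_spec.yaml"))
  log$n_fixes <- nrow(sim$fixes)

  base_bursts <- stageTry("preprocess", "",
                          splitBursts(sim$fixes, config$base_interval_minutes))
  log$n_bursts_base <- length(unique(base_bursts$burst))

  fits <- list(); matches <- list(); bouts <- list()
  seqs <- list(); compositions <- list()
  binned <- list()
  for (K in config$n_states) {
    scheme <- if (K >= 3) "three_state" else "two_state"
    binned[[as.character(K)]] <- stageTry(
      "bin", paste0("scheme=", scheme),
      binBehaviours(sim$clips, config$dialect, scheme))
  }

  for (f in config$resample_factors) {
    interval <- config$base_interval_minutes * f
    cell_f <- paste0(interval, "min")
    bursts <- stageTry("resample", cell_f, resampleBursts(base_bursts, f))
    steps <- stageTry("steps", cell_f, computeSteps(bursts))
    for (K in config$n_states) {
      cell <- paste0(K, "state_", interval, "min")
      fit_seed <- deriveSeed(config$seed, 1000 * f + K)
      fit <- stageTry("fit", cell,
                      fitHMM(steps, n_states = K, n_starts = config$n_starts,
                             seed = fit_seed))
      dec <- stageTry("decode", cell, viterbiPath(steps, fit$params))
      writeFitResult(fit, od(paste0("fit_", cell, ".json")))
      writeStateSequence(dec, od(paste0("states_", cell, ".csv")))
      artifacts <- c(artifacts, od(paste0("fit_", cell, ".json")),
                     od(paste0("states_", cell, ".csv")))
      fits[[cell]] <- fit
      seqs[[cell]] <- dec

      mr <- stageTry("evaluate", cell,
                     matchStatesToVideo(dec, binned[[as.character(K)]],
                                        config$join_tolerance_minutes))
      matches[[cell]] <- mr
      jsonlite::write_json(
        list(cell = cell,
             overall_accuracy = mr$overall_accuracy,
             n_used = mr$n_used, n_excluded = mr$n_excluded,
             n_unmatched = mr$n_unmatched,
             confusion = as.data.frame(mr$confusion)),
        od(paste0("match_", cell, ".json")), auto_unbox = TRUE, digits = NA)
      artifacts <- c(artifacts, od(paste0("match_", cell, ".json")))

      if ("behaviour" %in% names(mr$joined)) {
        comp <- compositionByState(mr$joined)
        compositions[[cell]] <- comp
        write.csv(comp, od(paste0("composition_", cell, ".csv")),
                  row.names = FALSE)
        artifacts <- c(artifacts, od(paste0("composition_", cell, ".csv")))
      }

      bs <- stageTry("bouts", cell, boutDurations(dec))
      bouts[[cell]] <- bs
      write.csv(as.data.frame(bs), od(paste0("bouts_", cell, ".csv")),
                row.names = FALSE)
      artifacts <- c(artifacts, od(paste0("bouts_", cell, ".csv")))
    }
  }

  cross <- list()
  fs <- config$resample_factors
  if (length(fs) >= 2) {
    for (K in config$n_states) {
      for (i in seq_len(length(fs) - 1)) for (j in seq(i + 1, length(fs))) {
        fine_cell <- paste0(K, "state_",
                            config$base_interval_minutes * fs[i], "min")
        coarse_cell <- paste0(K, "state_",
                              config$base_interval_minutes * fs[j], "min")
        nm <- paste0(K, "state_", config$base_interval_minutes * fs[i],
                     "v", config$base_interval_minutes * fs[j], "min")
        cross[[nm]] <- stageTry("crossscale", nm,
                                crossScaleMatch(seqs[[fine_cell]],
                                                seqs[[coarse_cell]]))
      }
    }
    jsonlite::write_json(cross, od("cross_scale.json"), auto_unbox = TRUE,
                         digits = NA)
    artifacts <- c(artifacts, od("cross_scale.json"))
  }

  manifest <- data.frame(
    file = basename(artifacts),
    md5 = unname(tools::md5sum(artifacts)),
    stringsAsFactors = FALSE)
  jsonlite::write_json(list(seed = config$seed,
                            n_individuals = config$n_individuals,
                            n_days = config$n_days,
                            base_interval_minutes = config$base_interval_minutes,
                            resample_factors = config$resample_factors,
                            n_states = config$n_states,
                            dialect = config$dialect,
                            log = log,
                            artifacts = manifest),
                       od("manifest.json"), auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)

  invisible(list(manifest = manifest, fits = fits, matches = matches,
                 bouts = bouts, cross_scale = cross,
                 compositions = compositions, sequences = seqs,
                 config = config, sim = sim))
}
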