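# End-to-end orchestration: synthesize or read a cohort, compute section
# statistics and the model table, run the evaluation, write artifacts.

#' Standard data-enhancement groups
#'
#' The seven (EEG length, window, step) presets used for sliding-window
#' data enhancement, with the per-segment fragment count
#' `N = (L - W)/step + 1` and the cohort input size at 71 usable segments.
#'
#' @return `data.frame` with columns `group`, `eeg_length_s`, `window_s`,
#'   `step_s`, `fragments_per_segment`, `input_n_71_segments`.
#' @examples
#' enhancementGroups()
#' @export
enhancementGroups <- function() {
  g <- data.frame(group = 1:7,
                  eeg_length_s = c(30, 30, 30, 60, 60, 60, 60),
                  window_s = c(2, 4, 6, 2, 4, 6, 8),
                  step_s = c(1, 2, 3, 1, 2, 3, 4))
  g$fragments_per_segment <- mapply(fragmentCount, g$eeg_length_s,
                                    g$window_s, g$step_s)
  g$input_n_71_segments <- 71L * g$fragments_per_segment
  g
}

#' Assemble and validate a pipeline configuration
#'
#' @param synth A [SynthConfig-class] (or `NULL` when reading recordings
#'   from `inputDir`).
#' @param inputDir Directory of `.csv`/`.edf` recordings with JSON sidecars
#'   (labels are taken from the sidecars). Ignored when `synth` is given.
#' @param group Enhancement-group preset 1-7 (see [enhancementGroups()]);
#'   sets `modelLengthS`, `windowS`, `stepS`.
#' @param sectionLengthS Section length for the contrast stage (30 or 60).
#' @param contrasts Contrast names to test.
#' @param estimator Estimator name for the LOSO evaluation, or `NULL` to
#'   skip single-model evaluation.
#' @param stacking A [stackingSpec()] or `NULL` to skip stacking.
#' @param alpha Significance level of the contrast selection.
#' @param seed Master seed (overrides `synth@seed`).
#' @param outDir Run directory to create.
#' @return A validated config (list), serializable to YAML.
#' @export
pipelineConfig <- function(synth = synthConfig(), inputDir = NULL,
                           group = 1L, sectionLengthS = 30,
                           contrasts = c("begin_end", "pre_post", "pre_end"),
                           estimator = "LGBM", stacking = NULL,
                           alpha = 0.05, seed = 1L, outDir = "relaxeeg_run") {
  if (!sectionLengthS %in% c(30, 60))
    stop("sectionLengthS must be 30 or 60", call. = FALSE)
  g <- enhancementGroups()
  if (!group %in% g$group) stop("group must be in 1..7", call. = FALSE)
  contrasts <- match.arg(contrasts, .CONTRAST_NAMES, several.ok = TRUE)
  if (!is.null(synth)) {
    synth@seed <- as.integer(seed)
    validObject(synth)
  } else if (is.null(inputDir)) {
    stop("either synth or inputDir must be given", call. = FALSE)
  }
  list(synth = synth, inputDir = inputDir, group = as.integer(group),
       modelLengthS = g$eeg_length_s[group], windowS = g$window_s[group],
       stepS = g$step_s[group], sectionLengthS = sectionLengthS,
       contrasts = contrasts, estimator = estimator, stacking = stacking,
       alpha = alpha, seed = as.integer(seed), outDir = outDir)
}

.configAsYamlList <- function(config) {
  out <- config
  if (!is.null(out$synth)) {
    s <- out$synth
    out$synth <- list(nParticipants = s@nParticipants,
                      scenes = as.list(stats::setNames(s@scenes$duration_s,
                                                       s@scenes$name)),
                      fs = s@fs, channels = s@channels,
                      restDurationS = s@restDurationS,
                      bandResponse = as.list(s@bandResponse),
                      asymmetryResponse = s@asymmetryResponse,
                      noiseFloor = s@noiseFloor,
                      labelNoiseSd = s@labelNoiseSd,
                      segmentDropout = s@segmentDropout, seed = s@seed)
  }
  if (!is.null(out$stacking)) {
    st <- out$stacking
    out$stacking <- list(base = vapply(st@base, slot, "", "name"),
                         meta = st@meta@name, scheme = st@scheme)
  }
  out
}

.writeHashedCsv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_md5: ", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
}

#' Run the full pipeline
#'
#' Stages: acquire the cohort (synthesize or read), build the section-level
#' statistics table and test the configured contrasts, build the
#' fragment-level model table with the configured enhancement group, run the
#' leave-one-subject-out evaluation (single estimator and/or stacking), and
#' write a deterministic artifact tree into `config$outDir`:
#' `features.csv`, `contrasts.csv`, `cv_result.json`, `predictions.csv`,
#' `run.log`, `config.lock.yaml`. Tables carry the lock-file MD5 as a `#`
#' comment line. Re-running an identical config reproduces identical
#' numbers.
#'
#' @param config From [pipelineConfig()].
#' @return The run directory path, invisibly.
#' @export
runPipeline <- function(config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "run.log")
  logLines <- character()
  say <- function(...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    logLines <<- c(logLines, line)
    writeLines(logLines, logPath)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      say("ERROR in stage ", name, ": ", conditionMessage(e))
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  lockPath <- file.path(config$outDir, "config.lock.yaml")
  yaml::write_yaml(.configAsYamlList(config), lockPath)
  hash <- unname(tools::md5sum(lockPath))
  say("config hash ", hash)

  cohort <- stage("acquire", {
    if (!is.null(config$synth)) {
      say("synthesizing cohort (seed ", config$seed, ")")
      generateExperiment(config$synth)
    } else {
      files <- list.files(config$inputDir, "\\.(csv|edf)$", full.names = TRUE,
                          ignore.case = TRUE)
      if (!length(files)) stop("no recordings found in ", config$inputDir)
      recs <- lapply(files, readRecording)
      labs <- do.call(rbind, lapply(recs, function(r) {
        l <- attr(r, "labels")
        data.frame(segment_id = r@segmentId, participant_id = r@participantId,
                   scene = r@sceneId,
                   r_state = as.numeric(l$r_state %||% NA),
                   usable = r@usable, stringsAsFactors = FALSE)
      }))
      names(recs) <- labs$segment_id
      list(recordings = recs, labels = labs)
    }
  })
  say(length(cohort$recordings), " segments read, ",
      sum(!cohort$labels$usable), " flagged unusable")

  contrastsDf <- stage("stats", {
    statsTab <- buildFeatureTable(cohort$recordings, cohort$labels,
                                  level = "section", featureSet = "stats",
                                  sectionLengthS = config$sectionLengthS)
    res <- do.call(rbind, lapply(config$contrasts,
                                 function(cn) pairedContrast(statsTab, cn)))
    say("contrasts: ", nrow(res), " feature tests; ",
        sum(res$p_value < config$alpha), " at p < ", config$alpha)
    res
  })
  .writeHashedCsv(contrastsDf, file.path(config$outDir, "contrasts.csv"), hash)

  modelTab <- stage("features", {
    tab <- buildFeatureTable(cohort$recordings, cohort$labels,
                             level = "fragment",
                             modelLengthS = config$modelLengthS,
                             windowS = config$windowS, stepS = config$stepS)
    say("model table: ", ncol(tab), " fragments x ", nrow(tab),
        " features (group ", config$group, ": ", config$modelLengthS, "/",
        config$windowS, "/", config$stepS, ")")
    tab
  })
  featDf <- cbind(fragmentInfo(modelTab), as.data.frame(featureMatrix(modelTab)))
  .writeHashedCsv(featDf, file.path(config$outDir, "features.csv"), hash)

  cvOut <- list(config_md5 = hash, group = config$group)
  predDf <- NULL
  if (!is.null(config$estimator)) {
    cv <- stage("train", {
      fitPredictLoso(modelTab, estimatorSpec(config$estimator,
                                             seed = config$seed))
    })
    say(sprintf("%s LOSO: mean MAE %.5f, mean ACC %.5f",
                config$estimator, meanMae(cv), meanAcc(cv)))
    cvOut$estimator <- list(name = config$estimator, mean_mae = meanMae(cv),
                            mean_acc = meanAcc(cv),
                            fold_metrics = foldMetrics(cv))
    predDf <- predictions(cv)
    predDf$model <- config$estimator
  }
  if (!is.null(config$stacking)) {
    scv <- stage("stack", stackFitPredict(modelTab, config$stacking))
    say(sprintf("stacking (%s): mean MAE %.5f, mean ACC %.5f",
                config$stacking@scheme, meanMae(scv), meanAcc(scv)))
    cvOut$stacking <- list(scheme = config$stacking@scheme,
                           meta = config$stacking@meta@name,
                           mean_mae = meanMae(scv), mean_acc = meanAcc(scv),
                           fold_metrics = foldMetrics(scv))
    sp <- predictions(scv)
    sp$model <- "stacking"
    predDf <- rbind(predDf, sp)
  }
  jsonlite::write_json(cvOut, file.path(config$outDir, "cv_result.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  if (is.null(predDf))
    predDf <- data.frame(participant_id = character(), segment_id = character(),
                         r_state = numeric(), predicted = numeric(),
                         model = character())
  .writeHashedCsv(predDf, file.path(config$outDir, "predictions.csv"), hash)
  say("done")
  invisible(config$outDir)
}
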