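#' Default experiment configuration
#'
#' A small "demo" configuration: a 20-cell healthy-like retina, 5 minutes of
#' binary white noise at 30 Hz on a 20 x 20 px canvas, LN model fits, noise
#' estimation and a flash-count decoding experiment. Any part can be
#' overridden by the supplied list (or a YAML file with the same keys).
#'
#' @param overrides named list (possibly nested) merged over the defaults.
#' @return Configuration list.
#' @export
defaultConfig <- function(overrides = list()) {
  base <- list(
    experiment = "demo",
    seed = 1L,
    stages = c("stim", "simulate", "sta", "fit", "noise", "decode"),
    stimulus = list(frames = 9000L, height = 20L, width = 20L,
                    frame_rate = 30, p_bright = 0.5, pixel_pitch = 60,
                    modality = "visual"),
    population = list(preset = "demo", n_cells = NULL, noise_ratio = NULL),
    fit = list(model = "ln", max_cells = 5L),
    noise = list(nr_grid = seq(0, 1, by = 0.2), n_seeds = 2L),
    decode = list(axis = "n_flashes", grid = c(1L, 2L, 4L),
                  n_trials = 500L, c_size_px = 14, k = 200L))
  modifyList(base, overrides)
}

readConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- defaultConfig(config)
  # YAML sequences with mixed integer/double entries arrive as lists
  cfg$stages <- as.character(unlist(cfg$stages))
  cfg$noise$nr_grid <- as.numeric(unlist(cfg$noise$nr_grid))
  cfg$decode$grid <- as.numeric(unlist(cfg$decode$grid))
  cfg
}

#' Run the analysis pipeline end to end
#'
#' Executes the requested stages in dependency order: stimulus generation,
#' population simulation, STA/selection summaries, encoding-model fits,
#' noise-ratio estimation and ensemble decoding. Artifacts are written as CSV
#' under \code{outDir} together with a JSON manifest recording the
#' configuration, per-stage seeds and output file hashes; re-running the same
#' configuration reproduces the hashes bit for bit.
#'
#' @param config configuration list or YAML file path (see
#'   \code{\link{defaultConfig}}).
#' @param outDir output directory (created if needed).
#' @param seed optional master-seed override.
#' @return The manifest list, invisibly.
#' @export
runPipeline <- function(config = list(), outDir = tempfile("retfidelity"),
                        seed = NULL) {
  cfg <- readConfig(if (is.character(config)) config else as.list(config))
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  stages <- cfg$stages
  files <- character()
  log <- function(...) message(sprintf(...))

  needs <- function(stage, dep, obj) {
    if (is.null(obj))
      stop(sprintf("stage '%s' requires '%s' to have run first", stage, dep))
    obj
  }
  movie <- NULL; cells <- NULL; trains <- NULL; stas <- NULL; summary <- NULL

  if ("stim" %in% stages) {
    s <- cfg$stimulus
    log("stage stim: %d frames %dx%d @ %g Hz", s$frames, s$height, s$width,
        s$frame_rate)
    movie <- generateWhiteNoise(c(s$frames, s$height, s$width),
                                frameRate = s$frame_rate,
                                pBright = s$p_bright,
                                pixelPitch = s$pixel_pitch,
                                modality = s$modality,
                                seed = subSeed(cfg$seed, "stim"))
    f <- file.path(outDir, "stimulus_summary.csv")
    utils::write.csv(data.frame(
      frames = s$frames, height = s$height, width = s$width,
      frame_rate = s$frame_rate, bright_fraction = mean(stimFrames(movie)),
      modality = s$modality), f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("simulate" %in% stages) {
    movie <- needs("simulate", "stim", movie)
    p <- cfg$population
    cells <- buildPopulation(p$preset, canvas = dim(stimFrames(movie))[2:3],
                             nCells = p$n_cells, noiseRatio = p$noise_ratio,
                             frameRate = frameRate(movie),
                             seed = subSeed(cfg$seed, "population"))
    log("stage simulate: %d cells (%s preset)", length(cells), p$preset)
    trains <- simulatePopulation(cells, movie,
                                 seed = subSeed(cfg$seed, "simulate"))
    f <- file.path(outDir, "spikes.csv")
    writeSpikesCSV(trains, f)
    files <- c(files, f)
  }
  if ("sta" %in% stages) {
    trains <- needs("sta", "simulate", trains)
    log("stage sta: %d cells", length(trains))
    stas <- lapply(trains, computeSTA, stimulus = movie)
    summary <- do.call(rbind, lapply(names(stas), function(id) {
      tc <- extractTimeCourse(stas[[id]])
      data.frame(cell_id = id, n_spikes = nSpikes(trains[[id]]),
                 snr = tc@snr,
                 polarity = classifyPolarity(tc, modality(movie)),
                 contamination = estimateContamination(trains[[id]]))
    }))
    f <- file.path(outDir, "sta_summary.csv")
    utils::write.csv(summary, f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("fit" %in% stages) {
    stas <- needs("fit", "sta", stas)
    ids <- names(trains)[seq_len(min(cfg$fit$max_cells, length(trains)))]
    log("stage fit: %s model on %d cells", cfg$fit$model, length(ids))
    rows <- lapply(ids, function(id) {
      sp <- trainTestSplit(nFrames(movie))
      r <- tryCatch({
        m <- fitLN(movie, trains[[id]], split = sp)
        evaluateModel(predictRate(m, movie), trains[[id]],
                      frameRate(movie), segment = sp$test)
      }, error = function(e) NA_real_)
      data.frame(cell_id = id, model = "ln", split = "holdout", r = r)
    })
    f <- file.path(outDir, "model_eval.csv")
    utils::write.csv(do.call(rbind, rows), f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("noise" %in% stages) {
    stas <- needs("noise", "sta", stas)
    log("stage noise: CCC/AUC for %d cells", length(trains))
    curves <- lapply(names(trains), function(id)
      tryCatch(computeCCC(trains[[id]], movie,
                          cropBox = stas[[id]]@cropBox),
               error = function(e) NULL))
    names(curves) <- names(trains)
    aucs <- vapply(curves, function(cc)
      if (is.null(cc)) NA_real_ else cc@auc, numeric(1L))
    refId <- selectReferenceCell(aucs, names(trains))
    fam <- buildNoiseFamily(trains[[refId]], movie,
                            nrGrid = cfg$noise$nr_grid,
                            nSeeds = cfg$noise$n_seeds,
                            seed = subSeed(cfg$seed, "noise"))
    est <- vapply(curves, function(cc)
      if (is.null(cc) || is.na(cc@auc)) NA_real_
      else suppressWarnings(matchNoiseRatio(cc, fam)), numeric(1L))
    f <- file.path(outDir, "noise_estimates.csv")
    utils::write.csv(data.frame(cell_id = names(trains), auc = aucs,
                                nr_estimate = est,
                                reference = refId), f, row.names = FALSE)
    files <- c(files, f)
  }
  if ("decode" %in% stages) {
    stas <- needs("decode", "sta", stas)
    d <- cfg$decode
    log("stage decode: axis %s over [%s]", d$axis,
        paste(d$grid, collapse = ", "))
    kernels <- lapply(stas, function(s) s@kernel - s@stimulusMean)
    exp <- runExperiment(kernels, trains, movie, axis = d$axis,
                         grid = d$grid, nTrials = d$n_trials,
                         seed = subSeed(cfg$seed, "decode"),
                         cSizePx = d$c_size_px, k = d$k)
    f <- file.path(outDir, sprintf("accuracy_%s.csv", d$axis))
    utils::write.csv(exp$summary, f, row.names = FALSE)
    files <- c(files, f)
  }

  manifest <- list(
    experiment = cfg$experiment,
    seed = cfg$seed,
    stages = stages,
    config = cfg,
    files = as.list(stats::setNames(unname(tools::md5sum(files)),
                                    basename(files))),
    outDir = outDir)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

#' Summarize pipeline artifacts
#'
#' Reads whatever artifact tables a manifest lists and returns summary
#' tables: per-cell model correlations, the AUC / noise-ratio distribution,
#' and accuracy-versus-axis curves. Missing sections are skipped; an empty
#' manifest yields an empty report.
#'
#' @param manifest a manifest list from \code{\link{runPipeline}} or the path
#'   to a \code{manifest.json}.
#' @return Named list of data.frames (possibly empty).
#' @export
reportPipeline <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest,
                                                              simplifyVector = TRUE)
  out <- list()
  fetch <- function(name) {
    f <- file.path(manifest$outDir, name)
    if (file.exists(f)) utils::read.csv(f, stringsAsFactors = FALSE) else NULL
  }
  me <- fetch("model_eval.csv")
  if (!is.null(me)) out$modelTable <- me
  ne <- fetch("noise_estimates.csv")
  if (!is.null(ne)) {
    out$noiseEstimates <- ne
    out$noiseSummary <- data.frame(
      mean_auc = mean(ne$auc, na.rm = TRUE),
      mean_nr = mean(ne$nr_estimate, na.rm = TRUE),
      sd_nr = stats::sd(ne$nr_estimate, na.rm = TRUE))
  }
  for (f in names(manifest$files)) {
    if (startsWith(f, "accuracy_")) {
      acc <- fetch(f)
      if (!is.null(acc)) out[[sub("\\.csv$", "", f)]] <- acc
    }
  }
  out
}
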