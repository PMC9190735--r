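#' Default (demo-scale) run configuration
#'
#' A nested list mirroring the YAML config consumed by [runPipeline()].
#' The analysis constants are the canonical ones (3 super-trials, SVM
#' cost 1, alpha 0.05, chance 50%); the simulation itself is demo-scale
#' (12 participants, a reduced stimulus set and run count, reduced
#' repetitions and permutations) so a complete run finishes in minutes.
#' Full-scale values (48 objects, 8 auditory / 6 visual runs, 100
#' repetitions, 10000 permutations) can be set field by field.
#'
#' @return a nested configuration list.
#' @export
defaultRunConfig <- function() {
  list(
    participants = 12L,
    seed = 1L,
    design = list(
      nObjects = 8L, nDims = 3L,
      runsPerModality = list(auditory = 2L, visual = 2L),
      repsPerStimPerRun = 3L, onebackFraction = 0.20,
      epochWindow = c(-200, 800), fsRaw = 200, fsTarget = 200,
      nChannels = 32L),
    signal = list(
      objectOnsetMs = 75, categoryOnsetMs = 305, rampMs = 20,
      snr = 1.5, modalityCoding = "orthogonal",
      noiseRho = 0.3, noiseSd = 1),
    preprocess = list(zThreshold = 20),
    analysis = list(
      schemes = c("object", "category", "crossmodal"),
      nRepetitions = 20L, nGroups = 3L, cost = 1),
    inference = list(
      nPermutations = 1000L, nBootstrap = 1000L,
      alpha = 0.05, chance = 50))
}

#' Read a run configuration from a YAML file
#'
#' Fields missing from the file fall back to [defaultRunConfig()].
#'
#' @param path YAML file path.
#' @return a nested configuration list.
#' @export
readRunConfig <- function(path) {
  user <- yaml::read_yaml(path)
  merge2 <- function(def, usr) {
    if (!is.list(def) || !is.list(usr)) return(usr)
    for (k in names(usr)) def[[k]] <- merge2(def[[k]], usr[[k]])
    def
  }
  merge2(defaultRunConfig(), user)
}

configDesign <- function(cfg) {
  d <- cfg$design
  designSpec(nObjects = d$nObjects, nDims = d$nDims,
             runsPerModality = unlist(d$runsPerModality),
             repsPerStimPerRun = d$repsPerStimPerRun,
             onebackFraction = d$onebackFraction,
             epochWindow = unlist(d$epochWindow),
             fsRaw = d$fsRaw, fsTarget = d$fsTarget,
             nChannels = d$nChannels)
}

epochPath <- function(dir, p, modality)
  file.path(dir, "epochs", sprintf("participant%02d_%s.rds", p, modality))

# simulate, preprocess and store epochs for every participant x modality
stageSimulate <- function(cfg, outputDir) {
  design <- configDesign(cfg)
  stimset <- buildStimulusSet(design@nObjects, design@nDims,
                              seed = childSeed(cfg$seed, 1L))
  dir.create(file.path(outputDir, "epochs"), recursive = TRUE,
             showWarnings = FALSE)
  modalities <- names(design@runsPerModality)
  rejection <- list()
  for (p in seq_len(cfg$participants)) {
    model <- signalModel(
      stimset, design,
      objectOnsetMs = cfg$signal$objectOnsetMs,
      categoryOnsetMs = cfg$signal$categoryOnsetMs,
      rampMs = cfg$signal$rampMs, snr = cfg$signal$snr,
      modalityCoding = cfg$signal$modalityCoding,
      noiseRho = cfg$signal$noiseRho, noiseSd = cfg$signal$noiseSd,
      seed = childSeed(cfg$seed, 3L, p))
    for (mi in seq_along(modalities)) {
      m <- modalities[mi]
      trials <- generateTrialSequence(design, m,
                                      seed = childSeed(cfg$seed, 4L, p, mi))
      ep <- simulateEpochs(trials, stimset, model, design,
                           seed = childSeed(cfg$seed, 5L, p, mi),
                           participantId = sprintf("participant%02d", p))
      ep <- dropOneBack(ep)
      rej <- rejectArtifacts(ep, cfg$preprocess$zThreshold)
      rejection[[sprintf("p%02d_%s", p, m)]] <- rej$fraction
      ep <- downsampleEpochs(rej$epochs, design@fsTarget)
      saveEpochs(ep, epochPath(outputDir, p, m))
    }
  }
  saveRDS(stimset, file.path(outputDir, "epochs", "stimulus_set.rds"))
  exportTrialTable(
    generateTrialSequence(design, modalities[1],
                          seed = childSeed(cfg$seed, 4L, 1L, 1L)),
    file.path(outputDir, "trials_example.tsv"))
  rejection
}

# run the configured decoding schemes and write accuracy tables
stageDecode <- function(cfg, outputDir) {
  design <- configDesign(cfg)
  stimset <- readRDS(file.path(outputDir, "epochs", "stimulus_set.rds"))
  modalities <- names(design@runsPerModality)
  an <- cfg$analysis
  schemes <- an$schemes
  out <- list()
  perPart <- function(fn)
    bindParticipants(lapply(seq_len(cfg$participants), fn))
  loadp <- function(p, m) loadEpochs(epochPath(outputDir, p, m))
  normFor <- function(ep) fitNoiseNormalizer(ep)
  for (m in modalities) {
    if ("object" %in% schemes) {
      acc <- perPart(function(p) {
        ep <- loadp(p, m)
        pairwiseDecode(ep, an$nRepetitions, an$nGroups, an$cost,
                       normalizer = normFor(ep),
                       seed = childSeed(cfg$seed, 21L, p, match(m, modalities)))
      })
      acc@scheme <- paste0("object_", m)
      out[[acc@scheme]] <- acc
    }
    if ("category" %in% schemes) {
      acc <- perPart(function(p) {
        ep <- loadp(p, m)
        categoryDecode(ep, stimset, an$nRepetitions, an$nGroups,
                       an$cost, normalizer = normFor(ep),
                       seed = childSeed(cfg$seed, 22L, p, match(m, modalities)))
      })
      acc@scheme <- paste0("category_", m)
      out[[acc@scheme]] <- acc
    }
  }
  if (length(modalities) >= 2L && "crossmodal" %in% schemes) {
    acc <- perPart(function(p) {
      epA <- loadp(p, modalities[1])
      epB <- loadp(p, modalities[2])
      crossmodalDecode(epA, epB, stimset, an$nRepetitions, an$nGroups,
                       an$cost, normalizerA = normFor(epA),
                       normalizerB = normFor(epB),
                       seed = childSeed(cfg$seed, 23L, p))
    })
    acc@scheme <- "crossmodal"
    out[["crossmodal"]] <- acc
  }
  if (length(modalities) >= 2L && "generalization" %in% schemes) {
    acc <- perPart(function(p) {
      epA <- loadp(p, modalities[1])
      epB <- loadp(p, modalities[2])
      temporalGeneralization(epA, epB, stimset, an$nRepetitions,
                             an$nGroups, an$cost,
                             normalizerA = normFor(epA),
                             normalizerB = normFor(epB),
                             seed = childSeed(cfg$seed, 23L, p))
    })
    acc@scheme <- "generalization"
    out[["generalization"]] <- acc
  }
  for (nm in names(out))
    exportAccuracy(out[[nm]],
                   file.path(outputDir, sprintf("accuracy_%s.tsv", nm)))
  out
}

# group inference on the accuracy tables
stageStats <- function(cfg, outputDir) {
  inf <- cfg$inference
  files <- list.files(outputDir, pattern = "^accuracy_.*\\.tsv$")
  schemes <- sub("^accuracy_(.*)\\.tsv$", "\\1", files)
  accs <- lapply(seq_along(files), function(i)
    readAccuracy(file.path(outputDir, files[i]), scheme = schemes[i]))
  names(accs) <- schemes
  clusterResults <- list()
  for (nm in schemes) {
    if (length(dim(accs[[nm]]@values)) != 2L) next
    res <- clusterPermutationTest(
      accs[[nm]], chance = inf$chance,
      nPermutations = inf$nPermutations, alpha = inf$alpha,
      seed = childSeed(cfg$seed, 31L, match(nm, schemes)))
    clusterResults[[nm]] <- res
    exportClusterTable(res, file.path(outputDir,
                                      sprintf("clusters_%s.tsv", nm)))
  }
  peaks <- list()
  peakMods <- unique(sub("^object_", "",
                         grep("^object_", schemes, value = TRUE)))
  for (i in seq_along(peakMods)) {
    m <- peakMods[i]
    onm <- paste0("object_", m)
    cnm <- paste0("category_", m)
    if (!(onm %in% schemes && cnm %in% schemes)) next
    pk <- bootstrapPeakLatencyDifference(
      accs[[onm]], accs[[cnm]], nBootstrap = inf$nBootstrap,
      seed = childSeed(cfg$seed, 32L, i),
      alternative = "greater")
    peaks[[m]] <- pk
    df <- data.frame(modality = m,
                     peak_object_ms = pk@peakMsA,
                     peak_category_ms = pk@peakMsB,
                     p_object_later = pk@pOneTailed,
                     n_bootstrap = pk@nBootstrap,
                     degenerate = pk@degenerate)
    utils::write.table(
      df, file.path(outputDir, sprintf("peak_latency_%s.tsv", m)),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(diff_ms = pk@bootDifferences),
      file.path(outputDir, sprintf("peak_bootstrap_%s.tsv", m)),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(clusters = clusterResults, peaks = peaks)
}

#' Run the complete decoding pipeline
#'
#' Orchestrates synthesize -> preprocess -> super-trials/normalize ->
#' decode -> group inference from a single configuration, writing
#' per-scheme accuracy tables, cluster-inference tables, peak-latency
#' tests and a JSON manifest (config echo, seed, package version, stage
#' timings) into `outputDir`. Re-running with the same configuration
#' reproduces all numbers exactly; existing outputs are never silently
#' overwritten.
#'
#' @param config a configuration list (see [defaultRunConfig()]) or the
#'   path to a YAML file ([readRunConfig()]).
#' @param outputDir output directory (created if needed).
#' @param overwrite allow writing into a directory that already holds a
#'   manifest.
#' @param stages subset of c("simulate", "decode", "stats") to run;
#'   later stages read the earlier stages' outputs from `outputDir`.
#' @return invisibly, a list with elements `accuracies`, `clusters`,
#'   `peaks`, `rejection` and `manifest`.
#' @export
runPipeline <- function(config = defaultRunConfig(),
                        outputDir = "mvpatime_run",
                        overwrite = FALSE,
                        stages = c("simulate", "decode", "stats")) {
  cfg <- if (is.character(config)) readRunConfig(config) else config
  stages <- match.arg(stages, several.ok = TRUE)
  manifestPath <- file.path(outputDir, "manifest.json")
  if (file.exists(manifestPath) && !overwrite)
    stop("outputDir already contains a run; use overwrite = TRUE")
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  timings <- c()
  res <- list()
  for (st in stages) {
    t0 <- proc.time()[["elapsed"]]
    out <- switch(st,
      simulate = stageSimulate(cfg, outputDir),
      decode = stageDecode(cfg, outputDir),
      stats = stageStats(cfg, outputDir))
    timings[st] <- round(proc.time()[["elapsed"]] - t0, 2)
    res[[st]] <- out
  }
  manifest <- list(
    config = cfg,
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("mvpatime")),
    stages = stages,
    timings_s = as.list(timings),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(list(accuracies = res$decode,
                 clusters = res$stats$clusters,
                 peaks = res$stats$peaks,
                 rejection = res$simulate,
                 manifest = manifest))
}

#' Summarize a completed pipeline run
#'
#' Reads the tables a [runPipeline()] call wrote to disk and prints a
#' human-readable report: per scheme the significant time intervals
#' (onset/offset), the group-mean peak latency, and the peak-latency
#' comparison between object- and category-level decoding.
#'
#' @param outputDir directory of a completed run.
#' @param file connection or path passed to [cat()] (default: console).
#' @return invisibly, a list of the per-scheme summary rows.
#' @export
summarizeRun <- function(outputDir, file = "") {
  manifestPath <- file.path(outputDir, "manifest.json")
  if (!file.exists(manifestPath))
    stop(sprintf("no manifest found in '%s'", outputDir))
  files <- list.files(outputDir, pattern = "^accuracy_.*\\.tsv$")
  if (!length(files)) stop("no accuracy tables found")
  lines <- character()
  out <- list()
  for (f in files) {
    nm <- sub("^accuracy_(.*)\\.tsv$", "\\1", f)
    acc <- readAccuracy(file.path(outputDir, f), scheme = nm)
    if (length(dim(acc@values)) != 2L) {
      lines <- c(lines, sprintf(
        "%s: temporal generalization matrix, grand mean %.2f%%",
        nm, mean(acc@values)))
      next
    }
    gm <- colMeans(acc@values)
    peak <- acc@timeMs[which.max(gm)]
    cpath <- file.path(outputDir, sprintf("clusters_%s.tsv", nm))
    cl <- if (file.exists(cpath))
      utils::read.table(cpath, header = TRUE, sep = "\t")
    else data.frame()
    sig <- cl[which(cl$significant), , drop = FALSE]
    intervals <- if (nrow(sig))
      paste(sprintf("%g-%g ms (p=%.4g)", sig$start_ms, sig$end_ms,
                    sig$p), collapse = ", ")
    else "no significant timepoints"
    lines <- c(lines, sprintf(
      "%s: grand mean %.2f%%, peak %.2f%% at %g ms; significant: %s",
      nm, mean(gm), max(gm), peak, intervals))
    out[[nm]] <- list(peak_ms = peak, intervals = sig)
  }
  for (f in list.files(outputDir, pattern = "^peak_latency_.*\\.tsv$")) {
    pk <- utils::read.table(file.path(outputDir, f), header = TRUE,
                            sep = "\t")
    lines <- c(lines, sprintf(
      "peak latency (%s): object %g ms vs category %g ms, one-tailed p(object later) = %.4g%s",
      pk$modality, pk$peak_object_ms, pk$peak_category_ms,
      pk$p_object_later,
      if (isTRUE(pk$degenerate)) " [degenerate]" else ""))
    out[[paste0("peaks_", pk$modality)]] <- pk
  }
  cat(paste(lines, collapse = "\n"), "\n", sep = "", file = file)
  invisible(out)
}

#' Plot a group accuracy time course
#'
#' Group mean with a between-participant standard-error band and an
#' optional significance raster from a cluster test.
#'
#' @param acc an [AccuracyTimecourse-class] (participants x timepoints).
#' @param cluster optional [ClusterInferenceResult-class] for the raster.
#' @param chance chance level reference line.
#' @param ... passed to [plot()].
#' @return invisibly, NULL.
#' @export
plotTimecourse <- function(acc, cluster = NULL, chance = 50, ...) {
  stopifnot(is(acc, "AccuracyTimecourse"),
            length(dim(acc@values)) == 2L)
  gm <- colMeans(acc@values)
  se <- apply(acc@values, 2, stats::sd) / sqrt(nrow(acc@values))
  graphics::plot(acc@timeMs, gm, type = "l", lwd = 2,
                 xlab = "time (ms)", ylab = "decoding accuracy (%)",
                 ylim = range(c(gm - se, gm + se, chance)), ...)
  graphics::polygon(c(acc@timeMs, rev(acc@timeMs)),
                    c(gm + se, rev(gm - se)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::abline(h = chance, lty = 2)
  graphics::abline(v = 0, lty = 3)
  if (!is.null(cluster) && any(cluster@significantMask)) {
    y <- graphics::par("usr")[3] + 0.02 * diff(graphics::par("usr")[3:4])
    graphics::points(acc@timeMs[cluster@significantMask],
                     rep(y, sum(cluster@significantMask)),
                     pch = 15, cex = 0.4)
  }
  invisible(NULL)
}
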