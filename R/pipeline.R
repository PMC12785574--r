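# End-to-end orchestration: simulate -> preprocess -> stats -> report,
# driven by one YAML config. Every stage reads and writes plain files
# (imzML + CSV), so any stage can be fed real data in place of synthetic,
# and re-running with the same config reproduces all CSVs bit-identically.

#' Default pipeline configuration
#'
#' The nested list mirroring the YAML schema accepted by
#' \code{\link{runPipeline}}; every generator, preprocessing, statistics
#' and reporting default is overridable from the file.
#'
#' @return Nested list of defaults.
#' @export
defaultConfig <- function() {
  list(
    seed = 1L,
    out_dir = "simsdiff_run",
    ions = NULL,
    design = list(
      groups = c("LEAN", "P1", "P2"),
      animals_per_group = list(LEAN = 4L, P1 = 8L, P2 = 8L),
      technical_replicates = 3L,
      image_width_px = 128L,
      image_height_px = 128L,
      field_of_view_um = 250),
    noise = list(
      tic_per_pixel_mean = 2000,
      tic_cv = 0.05,
      texture_length_um = 30,
      texture_cv = 0.08,
      drift_ppm = 0,
      animal_cv = 0.10),
    preprocess = list(
      roi_size_um = 150,
      window = 0.05,
      window_mode = "absolute",
      calibrate = TRUE,
      replicate_policy = "average"),
    stats = list(
      alpha = 0.05,
      family = "class",
      roles = list(lean = "LEAN", reference = "P1", treated = "P2")),
    report = list(
      top_k = 40L,
      fc_threshold = 0.6,
      p_threshold = 0.05,
      ion_maps = c(241.043, 281.253, 89.03, 180.05)))
}

# merge user config over the defaults, complaining about unknown keys
mergeConfig <- function(user, defaults = defaultConfig(), path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults) && !path %in% c("design.animals_per_group",
                                                  "stats.roles"))
      stop("unknown config key '", full, "'")
    defaults[[key]] <-
      if (is.list(defaults[[key]]) && is.list(user[[key]]) &&
          !is.null(names(defaults[[key]])))
        mergeConfig(user[[key]], defaults[[key]], full)
      else user[[key]]
  }
  defaults
}

validateConfig <- function(cfg) {
  fail <- function(key, what) stop("config key '", key, "': ", what)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num1(cfg$seed)) fail("seed", "must be a single integer")
  d <- cfg$design
  if (anyDuplicated(d$groups)) fail("design.groups", "names must be unique")
  if (!all(d$groups %in% names(d$animals_per_group)))
    fail("design.animals_per_group", "must name every group")
  for (k in c("technical_replicates", "image_width_px", "image_height_px"))
    if (!num1(d[[k]]) || d[[k]] < 1) fail(paste0("design.", k), "must be >= 1")
  if (!num1(d$field_of_view_um) || d$field_of_view_um <= 0)
    fail("design.field_of_view_um", "must be positive")
  for (k in setdiff(names(cfg$noise), "drift_ppm"))
    if (!num1(cfg$noise[[k]]) || cfg$noise[[k]] < 0)
      fail(paste0("noise.", k), "must be a non-negative number")
  p <- cfg$preprocess
  if (!num1(p$roi_size_um) || p$roi_size_um <= 0)
    fail("preprocess.roi_size_um", "must be positive")
  if (!p$window_mode %in% c("absolute", "ppm"))
    fail("preprocess.window_mode", "must be 'absolute' or 'ppm'")
  if (!p$replicate_policy %in% c("average", "pool"))
    fail("preprocess.replicate_policy", "must be 'average' or 'pool'")
  if (!num1(cfg$stats$alpha) || cfg$stats$alpha <= 0 || cfg$stats$alpha >= 1)
    fail("stats.alpha", "must lie in (0, 1)")
  if (!cfg$stats$family %in% c("class", "global"))
    fail("stats.family", "must be 'class' or 'global'")
  if (!all(c("lean", "reference", "treated") %in% names(cfg$stats$roles)))
    fail("stats.roles", "must name 'lean', 'reference' and 'treated'")
  invisible(cfg)
}

configDesign <- function(cfg) {
  d <- cfg$design
  StudyDesign(groups = unlist(d$groups),
              animalsPerGroup = unlist(d$animals_per_group)[unlist(d$groups)],
              technicalReplicates = d$technical_replicates,
              imageWidthPx = d$image_width_px,
              imageHeightPx = d$image_height_px,
              fieldOfViewUm = d$field_of_view_um, seed = cfg$seed)
}

configNoise <- function(cfg) {
  n <- cfg$noise
  NoiseModel(ticPerPixelMean = n$tic_per_pixel_mean, ticCv = n$tic_cv,
             textureLengthUm = n$texture_length_um, textureCv = n$texture_cv,
             driftPpm = n$drift_ppm, animalCv = n$animal_cv)
}

configIons <- function(cfg) {
  if (is.null(cfg$ions)) referenceIons() else referenceIons(path = cfg$ions)
}

#' Write differential results to CSV
#'
#' Column layout mirrors the published summary tables (m/z, annotation,
#' trend, group means, the two log2 fold changes, q) plus the full
#' diagnostic set.
#'
#' @param results \code{\link{runDifferential}} output.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writeResults <- function(results, path) {
  utils::write.csv(as.data.frame(results), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the pipeline stages described by a config
#'
#' Stages: \code{simulate} (synthetic study written as imzML + sample
#' metadata CSV), \code{preprocess} (imzML to replicate- and animal-level
#' peak-table CSVs plus a calibration report), \code{stats} (differential
#' results CSV), \code{report} (volcano, heatmap, boxplot and ion-map data
#' CSVs, with PNG renderings for the ion maps). Each stage consumes the
#' previous stage's files, so partial runs are resumable per stage; a
#' missing input is an error naming the expected file. The run directory
#' keeps a versioned copy of the effective config and a log, and is fully
#' regenerable from config + seed.
#'
#' @param config path to a YAML config, or a nested list (see
#'   \code{\link{defaultConfig}}); partial configs are completed with the
#'   defaults.
#' @param stages subset of \code{c("simulate", "preprocess", "stats",
#'   "report")}, or \code{"all"}.
#' @param outDir overrides \code{out_dir} from the config.
#' @param quiet suppress console log messages.
#' @return Invisibly, the run directory path.
#' @export
runPipeline <- function(config = list(), stages = "all", outDir = NULL,
                        quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- validateConfig(mergeConfig(config))
  if (!is.null(outDir)) cfg$out_dir <- outDir
  if (identical(stages, "all"))
    stages <- c("simulate", "preprocess", "stats", "report")
  stages <- match.arg(stages, c("simulate", "preprocess", "stats", "report"),
                      several.ok = TRUE)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(cfg, file.path(out, "config.yaml"))
  logFile <- file.path(out, "run.log")
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    paste0(...))
    cat(line, "\n", file = logFile, append = TRUE)
    if (!quiet) message(line)
  }
  imagesDir <- file.path(out, "images")
  peaksReplicates <- file.path(out, "peaks_replicates.csv")
  peaksAnimals <- file.path(out, "peaks_animals.csv")
  resultsCsv <- file.path(out, "results.csv")
  ions <- configIons(cfg)

  if ("simulate" %in% stages) {
    note("simulate: generating study (seed ", cfg$seed, ")")
    study <- generateStudy(configDesign(cfg), ions, configNoise(cfg))
    writeStudy(study, imagesDir)
    note("simulate: wrote ", length(study$images), " images to ", imagesDir)
  }
  if ("preprocess" %in% stages) {
    if (!file.exists(file.path(imagesDir, "samples.csv")))
      stop("preprocess stage input missing: expected file ",
           file.path(imagesDir, "samples.csv"))
    note("preprocess: calibrating, cropping ROI and integrating peaks")
    p <- cfg$preprocess
    pt <- preprocessStudy(imagesDir, ions, roiSizeUm = p$roi_size_um,
                          window = p$window, windowMode = p$window_mode,
                          calibrate = p$calibrate)
    writePeakTable(pt, peaksReplicates)
    cal <- S4Vectors::metadata(pt)$calibration
    if (!is.null(cal))
      utils::write.csv(cal, file.path(out, "calibration_report.csv"),
                       row.names = FALSE)
    writePeakTable(aggregateReplicates(pt, p$replicate_policy), peaksAnimals)
    note("preprocess: wrote ", peaksReplicates, " and ", peaksAnimals)
  }
  if ("stats" %in% stages) {
    if (!file.exists(peaksAnimals))
      stop("stats stage input missing: expected file ", peaksAnimals)
    note("stats: per-ion ANOVA / Tukey / BH")
    pt <- readPeakTable(peaksAnimals)
    res <- runDifferential(pt, alpha = cfg$stats$alpha,
                           family = cfg$stats$family,
                           roles = unlist(cfg$stats$roles))
    writeResults(res, resultsCsv)
    note("stats: wrote ", resultsCsv, " (", nrow(res), " ions, ",
         sum(res$significant), " significant)")
  }
  if ("report" %in% stages) {
    if (!file.exists(resultsCsv))
      stop("report stage input missing: expected file ", resultsCsv)
    if (!file.exists(peaksAnimals))
      stop("report stage input missing: expected file ", peaksAnimals)
    note("report: volcano / clustering / boxplot / ion-map tables")
    res <- utils::read.csv(resultsCsv, stringsAsFactors = FALSE)
    rownames(res) <- formatMz(res$mz)
    pt <- readPeakTable(peaksAnimals)
    r <- cfg$report
    for (ctr in c("LEAN_vs_P1", "P2_vs_P1")) {
      v <- volcanoData(res, ctr, r$fc_threshold, r$p_threshold)
      utils::write.csv(v, file.path(out, paste0("volcano_", ctr, ".csv")),
                       row.names = FALSE)
    }
    cl <- tryCatch(zscoreCluster(pt, topK = r$top_k, results = res),
                   error = function(e) NULL)
    if (!is.null(cl)) {
      utils::write.csv(data.frame(ion = rownames(cl$z), cl$z,
                                  check.names = FALSE),
                       file.path(out, "heatmap_z.csv"), row.names = FALSE)
      writeLines(c(paste(rownames(cl$z)[cl$rowOrder], collapse = ","),
                   paste(colnames(cl$z)[cl$colOrder], collapse = ",")),
                 file.path(out, "heatmap_order.txt"))
    }
    bx <- boxplotSummaries(pt, intersect(r$ion_maps,
                                         SummarizedExperiment::rowData(pt)$mz))
    utils::write.csv(bx$summary, file.path(out, "boxplot_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(bx$points, file.path(out, "boxplot_points.csv"),
                     row.names = FALSE)
    samplesCsv <- file.path(imagesDir, "samples.csv")
    if (file.exists(samplesCsv)) {
      samples <- utils::read.csv(samplesCsv, stringsAsFactors = FALSE)
      firstPerGroup <- samples[!duplicated(samples$group), ]
      for (mzv in r$ion_maps) {
        maps <- lapply(seq_len(nrow(firstPerGroup)), function(i)
          ionMap(readImzML(file.path(imagesDir, firstPerGroup$file[i])),
                 mz = mzv, scale = "auto"))
        shared <- range(unlist(lapply(maps, function(m)
          range(m$raster, na.rm = TRUE))))
        for (i in seq_along(maps)) {
          g <- firstPerGroup$group[i]
          base <- sprintf("ionmap_%s_%s", formatMz(mzv), g)
          utils::write.csv(maps[[i]]$raster,
                           file.path(out, paste0(base, ".csv")),
                           row.names = FALSE)
          ionMap(readImzML(file.path(imagesDir, firstPerGroup$file[i])),
                 mz = mzv, scale = "fixed", fixedRange = shared,
                 file = file.path(out, paste0(base, ".png")))
        }
      }
    } else {
      note("report: image directory absent, skipping ion maps")
    }
    note("report: done")
  }
  invisible(out)
}
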