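# End-to-end orchestration: synthetic or directory input, per-core
# quantification, cohort statistics, and a run manifest that records the
# config fingerprint and every realised threshold so each number in the
# output is traceable.

# permissive tissue footprint: heavy smoothing of the summed channels,
# then a low automatic cut. Defines the tissue area used for densities.
tissueMask <- function(image, sigma = 10) {
  s <- Reduce(`+`, lapply(channelNames(image), function(m) getChannel(image, m)))
  s <- smoothChannel(s, sigma, pixelSize(image))
  ot <- otsuThreshold(s)
  if (is.na(ot)) return(BinaryMask(matrix(TRUE, nrow(s), ncol(s)),
                                   pixelSize = pixelSize(image),
                                   provenance = list(rule = "constant frame")))
  BinaryMask(s > 0.5 * ot, pixelSize = pixelSize(image),
             provenance = list(rule = "tissue (0.5 x Otsu on smoothed sum)",
                               threshold = 0.5 * ot))
}

#' Quantify one tissue core
#'
#' Runs the full single-core battery: tissue area, neutrophil and NET
#' detection with the MPO/S100A8 overlap report, lectin vessel
#' segmentation and size classification, per-class lectin intensity,
#' vascular compartment assignment, pathology association, and the MPO
#' load partition.
#'
#' @param image a [MultiChannelImage-class]; MPO and S100A8 are required,
#'   CitH3 / lectin / abeta / ptau are used when present
#' @param segConfig a [SegmentationConfig-class]
#' @param vesselCfg a [VesselConfig-class]
#' @return list: `core` (one-row data.frame of per-core readouts),
#'   `cells` (cell table), `vessels` (vessel records), `load`
#'   ([MpoLoadResult-class] or NULL), `thresholds` (realised thresholds)
#' @export
quantifyCore <- function(image, segConfig = segmentationConfig(),
                         vesselCfg = vesselConfig()) {
  px <- pixelSize(image)
  tmask <- tissueMask(image)
  areaMm2 <- sum(maskArray(tmask)) * px^2 / 1e6
  thresholds <- list(tissue = provenance(tmask)$threshold)

  cs <- if ("CitH3" %in% channelNames(image))
    detectNets(image, segConfig, tissue = tmask)
  else detectNeutrophils(image, segConfig, tissue = tmask)
  cells <- cellTable(cs)
  ov <- overlapSummary(overlapSummary(cs))

  vrec <- NULL; vmask <- NULL
  lectinByClass <- list(perClass = data.frame())
  if ("lectin" %in% channelNames(image)) {
    vobj <- segmentVessels(image, "lectin", segConfig, tissue = tmask)
    vrec <- classifyVesselSize(vobj, cutoff = vesselCfg@cutoffLectin,
                               boundaryRule = vesselCfg@boundaryRule,
                               sourceMarker = "lectin")
    vmask <- vesselMask(vobj, segConfig@vesselMaskDilation)
    lectinByClass <- meanIntensityByClass(image, vobj, vrec, "lectin")
    cs <- assignCompartment(cs, vmask)
    cells <- cellTable(cs)
  }

  # MPO load over all intense-MPO structures (no large-object exclusion)
  loadObj <- segmentMarker(image, "MPO", "intense", segConfig,
                           minArea = segConfig@cellAreaMin, maxArea = Inf,
                           tissue = tmask)
  assoc <- NULL
  if (all(c("abeta", "ptau") %in% channelNames(image))) {
    plaques <- segmentMarker(image, "abeta", "intense", segConfig,
                             minArea = segConfig@cellAreaMin, maxArea = Inf,
                             tissue = tmask)
    tangles <- segmentMarker(image, "ptau", "intense", segConfig,
                             minArea = segConfig@cellAreaMin, maxArea = Inf,
                             tissue = tmask)
    assoc <- associatePathology(loadObj, plaques, tangles, segConfig)
  }
  load <- if (!is.null(vmask))
    mpoLoad(image, loadObj, vmask, assoc, measure = segConfig@loadMeasure)
  else NULL

  nphil <- cells$class %in% c("neutrophil", "NET")
  nNeut <- sum(nphil)
  nNet <- sum(cells$class == "NET")
  vascFrac <- if (nNeut > 0 && "lectin" %in% channelNames(image))
    mean(cells$compartment[nphil] == "vascular") else NA_real_
  pc <- lectinByClass$perClass
  meanSmall <- if (nrow(pc)) pc$mean_intensity[pc$size_class == "small"] else NA_real_
  meanLarge <- if (nrow(pc)) pc$mean_intensity[pc$size_class == "large"] else NA_real_

  core <- data.frame(
    tissue_area_mm2 = areaMm2,
    n_neutrophils = nNeut,
    neutrophil_density_mm2 = objectDensity(nNeut, areaMm2),
    n_nets = nNet,
    net_fraction = if (nNeut > 0) nNet / nNeut else NA_real_,
    net_positive = nNet > 0,
    vascular_fraction = vascFrac,
    n_mpo_objects = ov$a_only + ov$co_labelled,
    colabel_fraction = ov$fraction_a_colabelled,
    mpo_vascular_share = if (!is.null(load)) vascularShare(load) else NA_real_,
    mean_lectin_small = meanSmall,
    mean_lectin_large = meanLarge,
    n_vessels = if (is.null(vrec)) 0L else nrow(vrec))
  list(core = core, cells = cells, vessels = vrec, load = load,
       thresholds = thresholds)
}

#' Pipeline run configuration
#'
#' Exactly one input mode: `"synthetic"` (a [CohortSpec-class]) or
#' `"directory"` (a tree written by [writeCohort()] or equivalent, with a
#' design.csv). In blinded directory mode, group labels are withheld from
#' the quantification stages and joined only for the statistics.
#'
#' @slot mode `"synthetic"` or `"directory"`
#' @slot cohort [CohortSpec-class] (synthetic mode) or NULL
#' @slot inputDir input directory (directory mode)
#' @slot outDir output directory
#' @slot segConfig [SegmentationConfig-class]
#' @slot vesselConfig [VesselConfig-class]
#' @slot measures per-core columns compared between groups
#' @slot seed integer seed
#' @slot strict fail hard on a bad core (TRUE) or skip with a recorded
#'   warning (FALSE)
#' @slot blinded withhold group labels during quantification
#' @export
setClass("RunConfig",
  representation(mode = "character", cohort = "ANY", inputDir = "character",
                 outDir = "character", segConfig = "SegmentationConfig",
                 vesselConfig = "VesselConfig", measures = "character",
                 seed = "integer", strict = "logical", blinded = "logical"))

#' Construct a RunConfig
#' @param mode `"synthetic"` or `"directory"`
#' @param cohort a [CohortSpec-class] (synthetic mode)
#' @param inputDir input directory (directory mode)
#' @param outDir output directory
#' @param segConfig,vesselCfg stage configurations
#' @param measures per-core readouts compared between groups
#' @param seed integer seed
#' @param strict hard-fail on a bad core
#' @param blinded withhold group labels during quantification
#' @return a [RunConfig-class]
#' @export
runConfig <- function(mode = c("synthetic", "directory"), cohort = NULL,
                      inputDir = NA_character_, outDir = tempfile("nqrun"),
                      segConfig = segmentationConfig(),
                      vesselCfg = vesselConfig(),
                      measures = c("neutrophil_density_mm2", "n_nets",
                                   "vascular_fraction", "mpo_vascular_share",
                                   "mean_lectin_small", "mean_lectin_large"),
                      seed = 1L, strict = FALSE, blinded = TRUE) {
  mode <- match.arg(mode)
  new("RunConfig", mode = mode, cohort = cohort, inputDir = inputDir,
      outDir = outDir, segConfig = segConfig, vesselConfig = vesselCfg,
      measures = measures, seed = as.integer(seed), strict = strict,
      blinded = blinded)
}

#' Validate a run configuration
#'
#' Checks every invariant of the nested configurations and reports
#' violations without side effects. An empty result means the config is
#' runnable; the report also echoes key realised parameters (e.g. the
#' vessel cutoffs) for audit.
#'
#' @param config a [RunConfig-class]
#' @return list: `violations` data.frame (field, problem), `echo` named
#'   list of key parameters
#' @export
validateConfig <- function(config) {
  v <- data.frame(field = character(), problem = character())
  addv <- function(field, problem)
    v <<- rbind(v, data.frame(field = field, problem = problem))
  for (obj in list(config@segConfig, config@vesselConfig)) {
    msg <- validObject(obj, test = TRUE)
    if (is.character(msg))
      for (m in msg) addv(class(obj), m)
  }
  if (config@mode == "synthetic") {
    if (is.null(config@cohort)) addv("cohort", "synthetic mode needs a CohortSpec")
    else {
      msg <- validObject(config@cohort, test = TRUE)
      if (is.character(msg)) for (m in msg) addv("cohort", m)
    }
  } else {
    if (is.na(config@inputDir) || !dir.exists(config@inputDir))
      addv("inputDir", "input directory does not exist")
    else if (!file.exists(file.path(config@inputDir, "design.csv")))
      addv("inputDir", "design.csv not found in input directory")
  }
  list(violations = v,
       echo = list(cutoff_lectin_um = config@vesselConfig@cutoffLectin,
                   cutoff_collagenIV_um = config@vesselConfig@cutoffCollagenIV,
                   rolling_ball_um = config@segConfig@rollingBallRadius,
                   smoothing_sigma_um = config@segConfig@smoothingSigma,
                   vessel_mask_dilation_um = config@segConfig@vesselMaskDilation,
                   seed = config@seed))
}

#' Run the full pipeline
#'
#' Orchestrates generation/loading, per-core quantification and cohort
#' statistics. Deterministic given (inputs, config, seed). The manifest
#' (config fingerprint, software version, realised thresholds, row
#' counts, warnings) is written even when a stage fails.
#'
#' @param config a [RunConfig-class]
#' @return list: `cores` per-core table, `stats` cohort report, `manifest`
#' @export
runPipeline <- function(config) {
  val <- validateConfig(config)
  if (nrow(val$violations))
    stop("invalid config: ",
         paste(val$violations$field, val$violations$problem,
               sep = ": ", collapse = "; "))
  dir.create(config@outDir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(fingerprint = fnvHash(config),
                   version = as.character(utils::packageVersion("neutroquant")),
                   seed = config@seed, parameters = val$echo,
                   warnings = list(), cores = list())
  coreRows <- list(); cellRows <- list(); vesselRows <- list()
  status <- "ok"

  finish <- function() {
    jsonlite::write_json(manifest, file.path(config@outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  res <- tryCatch({
    if (config@mode == "synthetic") {
      scenes <- generateCohort(config@cohort, render = "image")
      inputs <- lapply(scenes, function(sc)
        list(id = sc$coreId, group = sc$group, image = sc$image))
    } else {
      design <- utils::read.csv(file.path(config@inputDir, "design.csv"))
      inputs <- lapply(seq_len(nrow(design)), function(i)
        list(id = design$core_id[i], group = design$group[i],
             path = file.path(config@inputDir, design$core_id[i], "image.tif")))
    }
    for (inp in inputs) {
      q <- tryCatch({
        img <- if (!is.null(inp$image)) inp$image
               else readMultiChannelImage(inp$path)
        quantifyCore(img, config@segConfig, config@vesselConfig)
      }, error = function(e) e)
      if (inherits(q, "error")) {
        msg <- paste0("core ", inp$id, ": ", conditionMessage(q))
        if (config@strict) stop(msg)
        manifest$warnings[[length(manifest$warnings) + 1L]] <-
          list(core = inp$id, message = conditionMessage(q), skipped = TRUE)
        next
      }
      row <- cbind(data.frame(core_id = inp$id), q$core)
      coreRows[[inp$id]] <- row
      if (nrow(q$cells))
        cellRows[[inp$id]] <- cbind(data.frame(core_id = inp$id), q$cells)
      if (!is.null(q$vessels) && nrow(q$vessels))
        vesselRows[[inp$id]] <- cbind(data.frame(core_id = inp$id), q$vessels)
      manifest$cores[[inp$id]] <- list(thresholds = q$thresholds,
                                        n_cells = nrow(q$cells))
    }
    cores <- do.call(rbind, coreRows)
    rownames(cores) <- NULL
    # group labels joined only now (quantification above never saw them)
    groups <- vapply(inputs, `[[`, "", "group")
    names(groups) <- vapply(inputs, `[[`, "", "id")
    cores$group <- unname(groups[cores$core_id])

    measures <- intersect(config@measures, names(cores))
    measures <- measures[vapply(measures, function(m)
      sum(!is.na(cores[[m]])) >= 4, TRUE)]
    stats <- if (length(unique(cores$group)) == 2L && length(measures))
      cohortReport(cores, measures = measures, group = "group")
    else list(tidy = data.frame(), reports = list(), descriptives = NULL)

    utils::write.csv(cores, file.path(config@outDir, "cores.csv"),
                     row.names = FALSE)
    if (length(cellRows))
      utils::write.csv(do.call(rbind, cellRows),
                       file.path(config@outDir, "cells.csv"), row.names = FALSE)
    if (length(vesselRows))
      utils::write.csv(do.call(rbind, vesselRows),
                       file.path(config@outDir, "vessels.csv"),
                       row.names = FALSE)
    if (nrow(stats$tidy))
      utils::write.csv(stats$tidy, file.path(config@outDir, "stats.csv"),
                       row.names = FALSE)
    list(cores = cores, stats = stats)
  }, error = function(e) {
    manifest$status <<- paste("failed:", conditionMessage(e))
    finish()
    stop(e)
  })
  manifest$status <- status
  manifest$n_cores <- length(coreRows)
  finish()
  c(res, list(manifest = manifest))
}
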