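# Reading and writing: multi-page TIFF images with a JSON channel-map
# sidecar, ground-truth and results tables as CSV. TIFF pages are stored
# in [0, 1] (the tiff package's float range) with a per-channel scale
# recorded in the sidecar, so intensities round-trip exactly up to float
# precision.

#' Write a MultiChannelImage as multi-page TIFF plus sidecar
#'
#' @param image a [MultiChannelImage-class]
#' @param path output TIFF path; the sidecar is written next to it as
#'   `<path basename>_channels.json`
#' @return invisibly, the sidecar path
#' @export
writeMultiChannelImage <- function(image, path) {
  stopifnot(is(image, "MultiChannelImage"))
  mks <- channelNames(image)
  pages <- vector("list", length(mks))
  scales <- numeric(length(mks))
  for (i in seq_along(mks)) {
    ch <- getChannel(image, mks[i])
    scales[i] <- max(ch, 1e-12)
    pages[[i]] <- ch / scales[i]
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  sidecar <- sub("\\.tiff?$", "", path)
  sidecar <- paste0(sidecar, "_channels.json")
  jsonlite::write_json(
    list(pixel_size_um = pixelSize(image),
         channels = data.frame(marker = mks, page = seq_along(mks),
                               scale = scales)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read a MultiChannelImage from multi-page TIFF plus sidecar
#'
#' @param path TIFF path written by [writeMultiChannelImage()] (or any
#'   multi-page TIFF accompanied by a compatible sidecar)
#' @param sidecar channel-map JSON; defaults to `<path>_channels.json`
#' @return a [MultiChannelImage-class]
#' @export
readMultiChannelImage <- function(path, sidecar = NULL) {
  if (is.null(sidecar))
    sidecar <- paste0(sub("\\.tiff?$", "", path), "_channels.json")
  if (!file.exists(path)) stop("image not found: ", path)
  if (!file.exists(sidecar)) stop("channel-map sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  chans <- list()
  for (i in seq_len(nrow(meta$channels))) {
    p <- pages[[meta$channels$page[i]]]
    if (length(dim(p)) == 3L) p <- p[, , 1]
    chans[[meta$channels$marker[i]]] <- p * meta$channels$scale[i]
  }
  MultiChannelImage(chans, pixelSize = meta$pixel_size_um)
}

#' Write the ground truth of a synthetic scene as CSV
#'
#' @param truth a [GroundTruth-class]
#' @param dir output directory (created if needed)
#' @return invisibly, the directory
#' @export
writeGroundTruth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(truth@objects, file.path(dir, "truth_objects.csv"),
                   row.names = FALSE)
  utils::write.csv(truth@vessels, file.path(dir, "truth_vessels.csv"),
                   row.names = FALSE)
  utils::write.csv(truth@pathology, file.path(dir, "truth_pathology.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(core_area_mm2 = truth@coreAreaMm2,
                            core_radius_um = truth@coreRadiusUm,
                            pixel_size_um = truth@pixelSize),
                       file.path(dir, "truth_core.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Materialise a synthetic cohort as a directory tree
#'
#' One folder per core with the multi-channel TIFF, its channel-map
#' sidecar and the ground-truth CSVs, plus a top-level `design.csv`
#' (core_id, group).
#'
#' @param cohort a [CohortSpec-class]
#' @param dir output directory
#' @return invisibly, the design data.frame
#' @export
writeCohort <- function(cohort, dir) {
  scenes <- generateCohort(cohort, render = "image")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- data.frame(core_id = vapply(scenes, `[[`, "", "coreId"),
                       group = vapply(scenes, `[[`, "", "group"))
  for (sc in scenes) {
    cdir <- file.path(dir, sc$coreId)
    dir.create(cdir, showWarnings = FALSE)
    writeMultiChannelImage(sc$image, file.path(cdir, "image.tif"))
    writeGroundTruth(sc$truth, cdir)
  }
  utils::write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  invisible(design)
}
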