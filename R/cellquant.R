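# Neutrophil / NET / MPO-deposit detection, marker colocalisation by
# object touching, vascular compartment assignment, pathology association
# and MPO load partitioning.

#' Colocalise two labelled object sets by touching
#'
#' A pair (a, b) is colocalised iff their footprints overlap or lie within
#' `maxGap` background pixels of each other, under the given connectivity
#' (Chebyshev distance for 8, Manhattan for 4). `maxGap = 0` is strict
#' touching: overlap or pixel adjacency. The relation is symmetric:
#' a touches b iff b touches a.
#'
#' @param objectsA,objectsB [LabeledObjects-class] from the same frame
#' @param maxGap tolerated background gap in pixels (>= 0)
#' @param connectivity 4 or 8
#' @param markerA,markerB names recorded in the result
#' @return a [ColocalisationResult-class]
#' @export
touchingColocalise <- function(objectsA, objectsB, maxGap = 0L,
                               connectivity = 8L,
                               markerA = "A", markerB = "B") {
  stopifnot(is(objectsA, "LabeledObjects"), is(objectsB, "LabeledObjects"))
  if (!identical(dim(labelImage(objectsA)), dim(labelImage(objectsB))))
    stop("object sets come from frames of different shapes")
  pr <- touching_pairs(labelImage(objectsA), labelImage(objectsB),
                       as.integer(maxGap) + 1L, as.integer(connectivity))
  pairs <- data.frame(a = pr[, 1], b = pr[, 2])
  nA <- nObjects(objectsA); nB <- nObjects(objectsB)
  co <- length(unique(pairs$a))
  new("ColocalisationResult", markerA = markerA, markerB = markerB,
      nA = as.integer(nA), nB = as.integer(nB), pairs = pairs,
      aOnly = as.integer(nA - co),
      bOnly = as.integer(nB - length(unique(pairs$b))),
      coLabelled = as.integer(co))
}

#' Detect neutrophils by intense MPO and S100A8 co-staining
#'
#' Both channels are rolling-ball background subtracted, smoothed and
#' thresholded at the intense (bright staining) level; objects outside the
#' cell size window are excluded. An MPO object touching an S100A8 object
#' is a neutrophil; MPO objects without S100A8 contact are retained as
#' class `mpo_deposit` so the MPO-only / S100A8-only / co-labelled
#' overlap report stays complete.
#'
#' @param image a [MultiChannelImage-class] with MPO and S100A8 channels
#' @param config a [SegmentationConfig-class]
#' @param tissue optional tissue-footprint [BinaryMask-class]; computed
#'   automatically from the image when NULL (automatic thresholds are
#'   searched within tissue so the core/glass contrast is ignored)
#' @return a [CellSet-class]; `overlapSummary()` gives the overlap report
#' @export
detectNeutrophils <- function(image, config = segmentationConfig(),
                              tissue = NULL) {
  for (mk in c("MPO", "S100A8"))
    if (!mk %in% channelNames(image))
      stop("channel '", mk, "' is missing from the channel map")
  if (is.null(tissue)) tissue <- tissueMask(image)
  mpoObj <- segmentMarker(image, "MPO", "intense", config,
                          config@cellAreaMin, config@cellAreaMax,
                          tissue = tissue)
  s100Obj <- segmentMarker(image, "S100A8", "intense", config,
                           config@cellAreaMin, config@cellAreaMax,
                           tissue = tissue)
  coloc <- touchingColocalise(mpoObj, s100Obj,
                              maxGap = if (config@positivityRule == "overlap")
                                -1L else config@maxGap,
                              connectivity = config@connectivity,
                              markerA = "MPO", markerB = "S100A8")
  tab <- objectTable(mpoObj)
  s100pos <- tab$id %in% pairTable(coloc)$a
  cells <- data.frame(
    id = tab$id,
    class = ifelse(s100pos, "neutrophil", "mpo_deposit"),
    mpo_pos = rep(TRUE, nrow(tab)), s100a8_pos = s100pos,
    cith3_pos = rep(FALSE, nrow(tab)),
    compartment = rep(NA_character_, nrow(tab)),
    pathology_association = rep("none", nrow(tab)),
    cx = tab$cx, cy = tab$cy, area_um2 = tab$area_um2)
  new("CellSet", cells = cells, objects = mpoObj, overlap = coloc)
}

#' Detect NETs by CitH3 / S100A8 / MPO triple positivity
#'
#' Runs [detectNeutrophils()] and additionally segments the CitH3 channel
#' at the intense level. A neutrophil (MPO+, S100A8+) whose object touches
#' a CitH3 object is reclassified as a NET; CitH3-negative MPO/S100A8
#' objects remain neutrophils, so every NET satisfies the neutrophil
#' marker pair by construction.
#'
#' @param image a [MultiChannelImage-class] with MPO, S100A8 and CitH3
#' @param config a [SegmentationConfig-class]
#' @param tissue optional tissue-footprint [BinaryMask-class] (see
#'   [detectNeutrophils()])
#' @return a [CellSet-class] containing both neutrophil and NET records
#' @export
detectNets <- function(image, config = segmentationConfig(), tissue = NULL) {
  if (!"CitH3" %in% channelNames(image))
    stop("channel 'CitH3' is missing from the channel map")
  if (is.null(tissue)) tissue <- tissueMask(image)
  cs <- detectNeutrophils(image, config, tissue = tissue)
  citObj <- segmentMarker(image, "CitH3", "intense", config,
                          config@cellAreaMin, config@cellAreaMax,
                          tissue = tissue)
  coloc <- touchingColocalise(cs@objects, citObj,
                              maxGap = if (config@positivityRule == "overlap")
                                -1L else config@maxGap,
                              connectivity = config@connectivity,
                              markerA = "MPO", markerB = "CitH3")
  cells <- cs@cells
  citpos <- cells$id %in% pairTable(coloc)$a
  cells$cith3_pos <- citpos
  cells$class <- ifelse(cells$class == "neutrophil" & citpos, "NET",
                        cells$class)
  new("CellSet", cells = cells, objects = cs@objects, overlap = cs@overlap)
}

#' Assign cells to the vascular or extravascular compartment
#'
#' A cell is vascular iff its object footprint intersects the (dilated)
#' vessel mask in at least one pixel; otherwise it is extravascular. Every
#' cell is assigned exactly once, so vascular + extravascular counts equal
#' the total on any input.
#'
#' @param cells a [CellSet-class]
#' @param vmask a [BinaryMask-class] from [vesselMask()]
#' @return the [CellSet-class] with the compartment column filled
#' @export
assignCompartment <- function(cells, vmask) {
  stopifnot(is(cells, "CellSet"), is(vmask, "BinaryMask"))
  lab <- labelImage(cells)
  if (!identical(dim(lab), dim(maskArray(vmask))))
    stop("vessel mask shape does not match the cell frame")
  vascIds <- unique(lab[maskArray(vmask) & lab > 0L])
  tab <- cells@cells
  tab$compartment <- ifelse(tab$id %in% vascIds, "vascular", "extravascular")
  new("CellSet", cells = tab, objects = cells@objects, overlap = cells@overlap)
}

#' Associate MPO objects with plaques and tangles by touching
#'
#' Each MPO object is labelled plaque-associated, tangle-associated or
#' unassociated under the touching rule. An object touching both classes
#' is counted once, under the configured precedence (plaque by default).
#'
#' @param mpoObjects [LabeledObjects-class] of MPO-positive structures
#' @param plaques,tangles [LabeledObjects-class] of thresholded
#'   amyloid-beta and pTau structures (same frame)
#' @param config a [SegmentationConfig-class] (touching gap, connectivity,
#'   precedence)
#' @return data.frame (id, association) with one row per MPO object
#' @export
associatePathology <- function(mpoObjects, plaques, tangles,
                               config = segmentationConfig()) {
  stopifnot(is(mpoObjects, "LabeledObjects"))
  touch <- function(other) {
    if (is.null(other) || nObjects(other) == 0L) return(integer())
    unique(pairTable(touchingColocalise(mpoObjects, other,
                                        maxGap = config@maxGap,
                                        connectivity = config@connectivity))$a)
  }
  inPlaque <- touch(plaques)
  inTangle <- touch(tangles)
  ids <- objectTable(mpoObjects)$id
  first <- config@pathologyPrecedence
  second <- setdiff(c("plaque", "tangle"), first)
  hitFirst <- if (first == "plaque") inPlaque else inTangle
  hitSecond <- if (first == "plaque") inTangle else inPlaque
  assoc <- ifelse(ids %in% hitFirst, first,
                  ifelse(ids %in% hitSecond, second, "none"))
  data.frame(id = ids, association = assoc)
}

#' Partition total MPO load into compartments
#'
#' The total MPO-positive load -- pixel area in um^2 by default, or
#' integrated intensity -- is split exactly into a vascular share (pixels
#' inside the vessel mask) and an extravascular share, the latter broken
#' down by the pathology association of the owning object. The partition
#' is computed per pixel, so objects straddling the mask boundary
#' contribute to both compartments and the shares always sum exactly.
#'
#' @param image a [MultiChannelImage-class] (used for the intensity
#'   measure; may be NULL for the area measure)
#' @param mpoObjects [LabeledObjects-class] of MPO-positive structures
#' @param vmask [BinaryMask-class] vessel mask
#' @param associations data.frame (id, association) from
#'   [associatePathology()], or NULL for no pathology breakdown
#' @param measure `"area"` or `"integrated_intensity"`
#' @return an [MpoLoadResult-class]; with zero total load the shares are
#'   reported absent via [vascularShare()] (NA), never 0/0
#' @export
mpoLoad <- function(image, mpoObjects, vmask, associations = NULL,
                    measure = c("area", "integrated_intensity")) {
  measure <- match.arg(measure)
  stopifnot(is(mpoObjects, "LabeledObjects"), is(vmask, "BinaryMask"))
  lab <- labelImage(mpoObjects)
  if (!identical(dim(lab), dim(maskArray(vmask))))
    stop("vessel mask shape does not match the object frame")
  idx <- which(lab > 0L)
  w <- if (measure == "area") {
    rep(pixelSize(mpoObjects)^2, length(idx))
  } else {
    if (is.null(image)) stop("intensity measure needs the source image")
    getChannel(image, "MPO")[idx]
  }
  inVessel <- maskArray(vmask)[idx]
  total <- sum(w)
  vascular <- sum(w[inVessel])
  extw <- w[!inVessel]
  extLab <- lab[idx][!inVessel]
  assocOf <- rep("none", max(nObjects(mpoObjects), 1L))
  if (!is.null(associations) && nrow(associations))
    assocOf[associations$id] <- associations$association
  extAssoc <- if (length(extLab)) assocOf[extLab] else character()
  new("MpoLoadResult", measure = measure, total = total,
      vascular = vascular, extravascular = total - vascular,
      plaqueAssociated = sum(extw[extAssoc == "plaque"]),
      tangleAssociated = sum(extw[extAssoc == "tangle"]),
      unassociated = sum(extw[extAssoc == "none"]))
}
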