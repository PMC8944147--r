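#' Multi-channel calibrated fluorescence image
#'
#' Container for a 2D multi-channel immunofluorescence image with a
#' marker-to-channel map and a physical pixel size. All geometric
#' quantities downstream are reported in micrometres via `pixelSize`.
#'
#' @slot pixels numeric 3D array `(nx, ny, n_channels)`; finite, >= 0
#' @slot channelMap named integer vector, marker name -> channel index
#' @slot pixelSize micrometres per pixel (> 0)
#' @export
setClass("MultiChannelImage",
  representation(pixels = "array", channelMap = "integer",
                 pixelSize = "numeric"))

setValidity("MultiChannelImage", function(object) {
  p <- object@pixels
  msg <- character()
  if (length(dim(p)) != 3L) msg <- c(msg, "pixels must be a 3D array (x, y, channel)")
  if (any(!is.finite(p))) msg <- c(msg, "pixel intensities must be finite")
  else if (any(p < 0)) msg <- c(msg, "pixel intensities must be >= 0")
  cm <- object@channelMap
  if (is.null(names(cm)) || any(names(cm) == ""))
    msg <- c(msg, "channelMap must be a fully named integer vector")
  if (anyDuplicated(names(cm))) msg <- c(msg, "channelMap marker names must be unique")
  if (anyDuplicated(cm)) msg <- c(msg, "channelMap must be injective")
  if (length(dim(p)) == 3L && length(cm) &&
      (any(cm < 1L) || any(cm > dim(p)[3L])))
    msg <- c(msg, "channelMap indices outside channel range")
  if (length(object@pixelSize) != 1L || !is.finite(object@pixelSize) ||
      object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiChannelImage
#'
#' @param pixels 3D numeric array `(nx, ny, n_channels)`, or a named list of
#'   equally sized matrices (names become the channel map)
#' @param channelMap named integer vector mapping marker names to channel
#'   indices; derived from list names when `pixels` is a list
#' @param pixelSize micrometres per pixel
#' @return a [MultiChannelImage-class] object
#' @examples
#' img <- MultiChannelImage(list(MPO = matrix(0, 8, 8)), pixelSize = 1)
#' channelNames(img)
#' @export
MultiChannelImage <- function(pixels, channelMap = NULL, pixelSize = 1) {
  if (is.list(pixels)) {
    stopifnot(!is.null(names(pixels)))
    channelMap <- structure(seq_along(pixels), names = names(pixels))
    pixels <- array(unlist(pixels, use.names = FALSE),
                    dim = c(dim(pixels[[1L]]), length(pixels)))
  }
  if (is.null(channelMap))
    channelMap <- structure(seq_len(dim(pixels)[3L]),
                            names = paste0("ch", seq_len(dim(pixels)[3L])))
  new("MultiChannelImage", pixels = pixels,
      channelMap = structure(as.integer(channelMap), names = names(channelMap)),
      pixelSize = as.numeric(pixelSize))
}

#' Binary mask with provenance
#'
#' A thresholded structure mask. `provenance` records the marker, the
#' threshold rule and its realised parameters so every mask is auditable.
#'
#' @slot mask logical matrix
#' @slot pixelSize micrometres per pixel
#' @slot provenance list: marker, rule, realised threshold, parameters
#' @export
setClass("BinaryMask",
  representation(mask = "matrix", pixelSize = "numeric", provenance = "list"))

setValidity("BinaryMask", function(object) {
  msg <- character()
  if (!is.logical(object@mask)) msg <- c(msg, "mask must be a logical matrix")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Construct a BinaryMask
#' @param mask logical matrix
#' @param pixelSize micrometres per pixel
#' @param provenance list describing how the mask was made
#' @return a [BinaryMask-class] object
#' @export
BinaryMask <- function(mask, pixelSize = 1, provenance = list()) {
  storage.mode(mask) <- "logical"
  new("BinaryMask", mask = mask, pixelSize = as.numeric(pixelSize),
      provenance = provenance)
}

#' Labelled connected components with per-object measurements
#'
#' Connected components of a binary mask together with per-object geometry
#' (area, centroid, bounding box, equivalent-ellipse axes) and, when a
#' source image is supplied, per-channel mean intensities
#' (columns `mean_<marker>`). Lengths are micrometres, areas square
#' micrometres.
#'
#' @slot labels integer matrix, 0 = background, objects labelled 1..n
#' @slot table data.frame with one row per object
#' @slot pixelSize micrometres per pixel
#' @export
setClass("LabeledObjects",
  representation(labels = "matrix", table = "data.frame",
                 pixelSize = "numeric"))

setValidity("LabeledObjects", function(object) {
  msg <- character()
  tab <- object@table
  n <- max(0L, object@labels)
  if (nrow(tab) != n) msg <- c(msg, "table rows must match number of labels")
  if (nrow(tab) && !identical(tab$id, seq_len(n)))
    msg <- c(msg, "object ids must be contiguous from 1")
  if (nrow(tab) && any(tab$area_um2 <= 0)) msg <- c(msg, "areas must be > 0")
  if (nrow(tab) &&
      any(tab$minor_axis_um > tab$major_axis_um + 1e-9, na.rm = TRUE))
    msg <- c(msg, "minor axis cannot exceed major axis")
  if (length(msg)) msg else TRUE
})

#' Segmentation configuration
#'
#' All tunable preprocessing and segmentation parameters, in physical
#' units. None of these are dictated by the analysis design itself, so all
#' are exposed here, logged per run, and stamped into mask provenance.
#'
#' @slot rollingBallRadius rolling-ball background radius, um
#' @slot smoothingSigma Gaussian smoothing sigma, um
#' @slot intenseMultiplier multiplier applied to the automatic (Otsu)
#'   threshold for the "intense" rule
#' @slot allVesselFactor multiplier (< 1) applied to the Otsu threshold for
#'   the permissive "all_vessel" rule
#' @slot cellAreaMin,cellAreaMax cell object size window, um^2
#' @slot vesselAreaMin,vesselAreaMax vessel object size window, um^2
#' @slot connectivity pixel connectivity, 4 or 8
#' @slot vesselMaskDilation vessel mask dilation radius, um
#' @slot maxGap pixel gap tolerated by the touching rule (0 = strict)
#' @slot keepBorderObjects retain objects touching the frame border
#' @slot positivityRule "touching" or "overlap" semantics for marker
#'   positivity of an object
#' @slot loadMeasure "area" or "integrated_intensity" for MPO load
#' @slot pathologyPrecedence association precedence on double contact,
#'   "plaque" or "tangle"
#' @export
setClass("SegmentationConfig",
  representation(rollingBallRadius = "numeric", smoothingSigma = "numeric",
                 intenseMultiplier = "numeric", allVesselFactor = "numeric",
                 cellAreaMin = "numeric", cellAreaMax = "numeric",
                 vesselAreaMin = "numeric", vesselAreaMax = "numeric",
                 connectivity = "integer", vesselMaskDilation = "numeric",
                 maxGap = "integer", keepBorderObjects = "logical",
                 positivityRule = "character", loadMeasure = "character",
                 pathologyPrecedence = "character"))

setValidity("SegmentationConfig", function(object) {
  msg <- character()
  if (object@rollingBallRadius <= 0) msg <- c(msg, "rollingBallRadius must be > 0")
  if (object@smoothingSigma < 0) msg <- c(msg, "smoothingSigma must be >= 0")
  if (object@allVesselFactor <= 0) msg <- c(msg, "allVesselFactor must be > 0")
  if (object@intenseMultiplier <= 0) msg <- c(msg, "intenseMultiplier must be > 0")
  if (object@cellAreaMin < 0 || object@vesselAreaMin < 0)
    msg <- c(msg, "minimum areas must be >= 0")
  if (object@cellAreaMin >= object@cellAreaMax)
    msg <- c(msg, "cellAreaMin must be < cellAreaMax")
  if (object@vesselAreaMin >= object@vesselAreaMax)
    msg <- c(msg, "vesselAreaMin must be < vesselAreaMax")
  if (!object@connectivity %in% c(4L, 8L)) msg <- c(msg, "connectivity must be 4 or 8")
  if (object@vesselMaskDilation < 0) msg <- c(msg, "vesselMaskDilation must be >= 0")
  if (object@maxGap < 0L) msg <- c(msg, "maxGap must be >= 0")
  if (!object@positivityRule %in% c("touching", "overlap"))
    msg <- c(msg, "positivityRule must be 'touching' or 'overlap'")
  if (!object@loadMeasure %in% c("area", "integrated_intensity"))
    msg <- c(msg, "loadMeasure must be 'area' or 'integrated_intensity'")
  if (!object@pathologyPrecedence %in% c("plaque", "tangle"))
    msg <- c(msg, "pathologyPrecedence must be 'plaque' or 'tangle'")
  if (length(msg)) msg else TRUE
})

#' Construct a SegmentationConfig
#'
#' Defaults: rolling-ball radius 25 um (well above the cell scale, below
#' the vessel scale), smoothing sigma 1 um, intense threshold = Otsu,
#' all-vessel threshold = 0.5 x Otsu, cell size window 20-200 um^2,
#' vessel size window 20-50000 um^2, 8-connectivity, vessel mask dilation
#' 2 um, strict touching (gap 0), border objects kept.
#'
#' @param rollingBallRadius,smoothingSigma,intenseMultiplier,allVesselFactor
#'   see [SegmentationConfig-class]
#' @param cellAreaMin,cellAreaMax,vesselAreaMin,vesselAreaMax size windows, um^2
#' @param connectivity,vesselMaskDilation,maxGap,keepBorderObjects see class doc
#' @param positivityRule,loadMeasure,pathologyPrecedence see class doc
#' @return a [SegmentationConfig-class] object
#' @export
segmentationConfig <- function(rollingBallRadius = 25, smoothingSigma = 1,
                               intenseMultiplier = 1, allVesselFactor = 0.5,
                               cellAreaMin = 20, cellAreaMax = 200,
                               vesselAreaMin = 20, vesselAreaMax = 50000,
                               connectivity = 8L, vesselMaskDilation = 2,
                               maxGap = 0L, keepBorderObjects = TRUE,
                               positivityRule = "touching",
                               loadMeasure = "area",
                               pathologyPrecedence = "plaque") {
  new("SegmentationConfig",
      rollingBallRadius = rollingBallRadius, smoothingSigma = smoothingSigma,
      intenseMultiplier = intenseMultiplier, allVesselFactor = allVesselFactor,
      cellAreaMin = cellAreaMin, cellAreaMax = cellAreaMax,
      vesselAreaMin = vesselAreaMin, vesselAreaMax = vesselAreaMax,
      connectivity = as.integer(connectivity),
      vesselMaskDilation = vesselMaskDilation, maxGap = as.integer(maxGap),
      keepBorderObjects = keepBorderObjects, positivityRule = positivityRule,
      loadMeasure = loadMeasure, pathologyPrecedence = pathologyPrecedence)
}

#' Vessel size-classification configuration
#'
#' Minor-axis cutoffs separating small from large vessels: 12 um for
#' lectin-segmented vessels, 15 um for collagen IV. A vessel whose minor
#' axis equals the cutoff exactly is assigned per `boundaryRule`
#' ("large" by default).
#'
#' @slot cutoffLectin um
#' @slot cutoffCollagenIV um
#' @slot boundaryRule "large" or "small"
#' @export
setClass("VesselConfig",
  representation(cutoffLectin = "numeric", cutoffCollagenIV = "numeric",
                 boundaryRule = "character"))

setValidity("VesselConfig", function(object) {
  msg <- character()
  if (object@cutoffLectin <= 0 || object@cutoffCollagenIV <= 0)
    msg <- c(msg, "cutoffs must be > 0")
  if (!object@boundaryRule %in% c("large", "small"))
    msg <- c(msg, "boundaryRule must be 'large' or 'small'")
  if (length(msg)) msg else TRUE
})

#' Construct a VesselConfig
#' @param cutoffLectin minor-axis cutoff for lectin vessels, um
#' @param cutoffCollagenIV minor-axis cutoff for collagen IV vessels, um
#' @param boundaryRule class assigned at an exact tie
#' @return a [VesselConfig-class] object
#' @export
vesselConfig <- function(cutoffLectin = 12, cutoffCollagenIV = 15,
                         boundaryRule = "large") {
  new("VesselConfig", cutoffLectin = cutoffLectin,
      cutoffCollagenIV = cutoffCollagenIV, boundaryRule = boundaryRule)
}

#' Object-level colocalisation by touching
#'
#' Result of pairing two labelled object sets under the touching rule.
#'
#' @slot markerA,markerB marker names (informational)
#' @slot nA,nB object counts
#' @slot pairs data.frame (a, b) of touching label pairs
#' @slot aOnly,bOnly,coLabelled counts; `aOnly + coLabelled == nA`
#' @export
setClass("ColocalisationResult",
  representation(markerA = "character", markerB = "character",
                 nA = "integer", nB = "integer", pairs = "data.frame",
                 aOnly = "integer", bOnly = "integer", coLabelled = "integer"))

setValidity("ColocalisationResult", function(object) {
  msg <- character()
  if (object@aOnly + object@coLabelled != object@nA)
    msg <- c(msg, "aOnly + coLabelled must equal nA")
  if (length(msg)) msg else TRUE
})

#' Detected cells with marker positivity and compartment
#'
#' Cell records detected from marker masks. `cells` has one row per
#' detected object: id, class (neutrophil / NET / mpo_deposit), positivity
#' flags per marker, compartment (vascular / extravascular / NA before
#' assignment), pathology association, centroid and area. `objects` keeps
#' the underlying label image so compartments and loads can be computed at
#' pixel level.
#'
#' @slot cells data.frame of cell records
#' @slot objects [LabeledObjects-class] backing the records (ids match)
#' @slot overlap [ColocalisationResult-class] MPO vs S100A8 overlap report
#' @export
setClass("CellSet",
  representation(cells = "data.frame", objects = "LabeledObjects",
                 overlap = "ColocalisationResult"))

setValidity("CellSet", function(object) {
  msg <- character()
  cl <- object@cells
  if (nrow(cl)) {
    bad <- cl$class == "NET" & !(cl$mpo_pos & cl$s100a8_pos & cl$cith3_pos)
    if (any(bad)) msg <- c(msg, "NET records must be MPO+, S100A8+ and CitH3+")
    bad2 <- cl$class == "neutrophil" & !(cl$mpo_pos & cl$s100a8_pos)
    if (any(bad2)) msg <- c(msg, "neutrophil records must be MPO+ and S100A8+")
    if (!all(cl$compartment %in% c("vascular", "extravascular", NA)))
      msg <- c(msg, "compartment must be vascular, extravascular or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Partition of MPO load into compartments
#'
#' Total MPO-positive load (pixel area in um^2, or integrated intensity)
#' split exactly into vascular and extravascular shares, the latter broken
#' down by pathology association. `vascular + extravascular == total`.
#'
#' @slot measure "area" or "integrated_intensity"
#' @slot total,vascular,extravascular load values
#' @slot plaqueAssociated,tangleAssociated,unassociated extravascular breakdown
#' @export
setClass("MpoLoadResult",
  representation(measure = "character", total = "numeric",
                 vascular = "numeric", extravascular = "numeric",
                 plaqueAssociated = "numeric", tangleAssociated = "numeric",
                 unassociated = "numeric"))

setValidity("MpoLoadResult", function(object) {
  msg <- character()
  tol <- 1e-8 * max(1, object@total)
  if (abs(object@vascular + object@extravascular - object@total) > tol)
    msg <- c(msg, "vascular + extravascular must equal total")
  br <- object@plaqueAssociated + object@tangleAssociated + object@unassociated
  if (abs(br - object@extravascular) > tol)
    msg <- c(msg, "extravascular breakdown must sum to the extravascular share")
  if (length(msg)) msg else TRUE
})

#' Statistical test report
#'
#' One statistical comparison in the cohort battery: the test run, its
#' estimate(s), statistic, degrees of freedom, p-value, any post-hoc table,
#' the normality pre-check, and outliers flagged by the 2-SD screen.
#'
#' @slot test test name
#' @slot estimate named numeric estimates (e.g. group means)
#' @slot statistic named numeric test statistic(s)
#' @slot df degrees of freedom (possibly vector)
#' @slot pValue p-value(s)
#' @slot posthoc post-hoc table (data.frame) or NULL
#' @slot normality per-group Shapiro-Wilk results (list)
#' @slot outliers outlier screen output (list)
#' @slot details anything else worth auditing (list)
#' @export
setClass("StatReport",
  representation(test = "character", estimate = "numeric",
                 statistic = "numeric", df = "numeric", pValue = "numeric",
                 posthoc = "ANY", normality = "list", outliers = "list",
                 details = "list"))

setValidity("StatReport", function(object) {
  msg <- character()
  if (length(object@pValue) && any(!is.na(object@pValue) &
      (object@pValue < 0 | object@pValue > 1)))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})
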