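# Vessel segmentation, minor-axis size classification, per-class mean
# intensity (the glycocalyx readout), and the vessel mask used for
# compartment assignment.

#' Segment vessels from a lectin or collagen IV channel
#'
#' Lectin vessels are segmented with the permissive "all_vessel" threshold
#' (to keep mid- and low-intensity vessels) after rolling-ball background
#' subtraction; collagen IV vessels use the high "intense" threshold.
#' Large and small objects are then filtered out by the vessel size
#' window.
#'
#' @param image a [MultiChannelImage-class]
#' @param sourceMarker `"lectin"` or `"collagenIV"` (must be present in
#'   the channel map)
#' @param config a [SegmentationConfig-class]
#' @param tissue optional tissue-footprint [BinaryMask-class]; computed
#'   from the image when NULL
#' @return a [LabeledObjects-class] of vessel objects
#' @export
segmentVessels <- function(image, sourceMarker = c("lectin", "collagenIV"),
                           config = segmentationConfig(), tissue = NULL) {
  sourceMarker <- match.arg(sourceMarker)
  if (!sourceMarker %in% channelNames(image))
    stop("marker '", sourceMarker, "' is missing from the channel map")
  if (is.null(tissue)) tissue <- tissueMask(image)
  rule <- if (sourceMarker == "lectin") "all_vessel" else "intense"
  # no smoothing on the vessel route: background subtraction only, so the
  # permissive threshold does not grow a halo around crisp vessel walls
  segmentMarker(image, sourceMarker, rule, config,
                minArea = config@vesselAreaMin, maxArea = config@vesselAreaMax,
                smooth = FALSE, tissue = tissue)
}

#' Classify vessels into small and large by minor axis length
#'
#' The minor axis of each object's moment-equivalent ellipse is compared
#' to the cutoff (12 um for lectin, 15 um for collagen IV). Below the
#' cutoff is small, above is large; an exact tie goes to the class named
#' by `boundaryRule`. Every object is classified exactly once.
#'
#' @param objects a [LabeledObjects-class] from [segmentVessels()]
#' @param cutoff minor-axis cutoff in um
#' @param boundaryRule class at an exact tie, `"large"` (default) or
#'   `"small"`
#' @param sourceMarker recorded in the output
#' @return data.frame of vessel records: id, source_marker,
#'   minor_axis_um, size_class, area_um2, plus any mean_* intensity
#'   columns carried from `objects`
#' @export
classifyVesselSize <- function(objects, cutoff = 12, boundaryRule = "large",
                               sourceMarker = NA_character_) {
  stopifnot(is(objects, "LabeledObjects"), cutoff > 0,
            boundaryRule %in% c("large", "small"))
  tab <- objectTable(objects)
  # 1e-9 slack so an exact tie computed through sqrt() is not pushed to
  # the wrong side by floating-point rounding
  big <- if (boundaryRule == "large") tab$minor_axis_um >= cutoff - 1e-9
         else tab$minor_axis_um > cutoff + 1e-9
  rec <- data.frame(id = tab$id, source_marker = sourceMarker,
                    minor_axis_um = tab$minor_axis_um,
                    size_class = ifelse(big, "large", "small"),
                    area_um2 = tab$area_um2)
  for (cn in grep("^mean_", names(tab), value = TRUE)) rec[[cn]] <- tab[[cn]]
  rec
}

#' Mean marker intensity per vessel and per size class
#'
#' Measures each vessel's mean intensity of `marker` over the vessel's own
#' pixels, then summarises per size class as the unweighted mean of
#' per-vessel means (vessel-weighted, not pixel-pooled, so large vessels
#' do not dominate the class summary). An empty class is reported as
#' absent (`present = FALSE`, mean NA), never as zero.
#'
#' @param image a [MultiChannelImage-class]
#' @param objects the [LabeledObjects-class] whose footprints to measure
#' @param records vessel records from [classifyVesselSize()] (ids must
#'   match `objects`)
#' @param marker marker whose intensity to read out (may differ from the
#'   segmentation marker, e.g. lectin intensity inside collagen IV vessels)
#' @param backgroundSubtract measure on the rolling-ball-subtracted channel
#'   (default); additive tissue autofluorescence would otherwise compress
#'   between-group intensity ratios
#' @param ballRadius rolling-ball radius for the background correction, um
#' @return list with `perVessel` (id, size_class, mean_intensity) and
#'   `perClass` (size_class, n, mean_intensity, present)
#' @export
meanIntensityByClass <- function(image, objects, records, marker,
                                 backgroundSubtract = TRUE, ballRadius = 25) {
  if (!marker %in% channelNames(image))
    stop("marker '", marker, "' is missing from the channel map")
  stopifnot(is(objects, "LabeledObjects"))
  ch <- getChannel(image, marker)
  if (backgroundSubtract) {
    # ball background estimated on a lightly smoothed copy: the grayscale
    # opening of raw shot noise is dominated by the minimum of the noise
    # (about zero), which would make the correction a no-op
    sm <- smoothChannel(ch, 2, pixelSize(image))
    m <- max(sm)
    if (m > 0) {
      rPx <- umToPx(ballRadius, pixelSize(image))
      bg <- asMatrix(EBImage::opening(sm / m, makeDisc(rPx))) * m
      ch <- pmax(ch - bg, 0)
    }
  }
  lab <- labelImage(objects)
  n <- nObjects(objects)
  perVessel <- data.frame(id = integer(), size_class = character(),
                          mean_intensity = numeric())
  if (n > 0) {
    idx <- which(lab > 0L)
    l <- lab[idx]
    m <- rowsum(ch[idx], l)[, 1] / tabulate(l, n)
    perVessel <- data.frame(id = seq_len(n),
                            size_class = records$size_class[match(seq_len(n),
                                                                  records$id)],
                            mean_intensity = m)
  }
  perClass <- do.call(rbind, lapply(c("small", "large"), function(cl) {
    v <- perVessel$mean_intensity[perVessel$size_class %in% cl]
    data.frame(size_class = cl, n = length(v),
               mean_intensity = meanOrNA(v), present = length(v) > 0)
  }))
  list(perVessel = perVessel, perClass = perClass)
}

#' Build the (dilated) vessel mask
#'
#' Union of all vessel object footprints, dilated by a physical radius.
#' This is the mask that defines the vascular compartment: cells and MPO
#' pixels inside it are vascular, outside parenchymal.
#'
#' @param objects a [LabeledObjects-class] of vessels
#' @param dilationRadius dilation radius in um (>= 0; 0 keeps the raw
#'   footprint)
#' @return a [BinaryMask-class]
#' @export
vesselMask <- function(objects, dilationRadius = 2) {
  stopifnot(is(objects, "LabeledObjects"))
  m <- labelImage(objects) > 0L
  dilateMask(BinaryMask(m, pixelSize = pixelSize(objects),
                        provenance = list(source = "vessel objects",
                                          n_vessels = nObjects(objects))),
             radius = dilationRadius)
}
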