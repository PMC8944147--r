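# Preprocessing and segmentation primitives shared by the vessel and cell
# quantification stages. EBImage provides the morphology and filtering
# engines; the threshold rules and measurement conventions live here.

asMatrix <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  as.matrix(x)
}

#' Rolling-ball background subtraction
#'
#' Estimates the background of a fluorescence channel by grayscale
#' morphological opening with a flat disc of the given physical radius and
#' subtracts it. The output is everywhere >= 0 and <= the input; a constant
#' image maps to zero.
#'
#' @param channel 2D numeric intensity matrix
#' @param radius ball radius in um; must be at least one pixel, otherwise
#'   the correction would be a no-op
#' @param pixelSize um per pixel
#' @return background-subtracted matrix, same shape
#' @examples
#' ch <- matrix(50, 16, 16); ch[8, 8] <- 150
#' range(rollingBallSubtract(ch, radius = 3, pixelSize = 1))
#' @export
rollingBallSubtract <- function(channel, radius, pixelSize = 1) {
  stopifnot(is.matrix(channel))
  if (!is.numeric(radius) || radius <= 0)
    stop("rolling-ball radius must be > 0")
  rPx <- umToPx(radius, pixelSize)
  if (rPx < 1)
    stop("rolling-ball radius (", radius, " um) is smaller than one pixel (",
         pixelSize, " um); background estimation would be a no-op")
  m <- max(channel)
  if (m <= 0) return(channel)
  # EBImage grayscale morphology clips outside [0, 1]; rescale around it
  bg <- asMatrix(EBImage::opening(channel / m, makeDisc(rPx))) * m
  pmax(channel - bg, 0)
}

#' Gaussian smoothing with a physical sigma
#'
#' Convolves with a normalised Gaussian kernel of standard deviation
#' `sigma` micrometres (truncated at 3 sigma), replicating edge pixels at
#' the boundary so constant images are preserved exactly. `sigma = 0`
#' returns the input unchanged.
#'
#' @param channel 2D numeric intensity matrix
#' @param sigma Gaussian sigma in um (>= 0)
#' @param pixelSize um per pixel
#' @return smoothed matrix, same shape
#' @export
smoothChannel <- function(channel, sigma, pixelSize = 1) {
  stopifnot(is.matrix(channel))
  if (!is.numeric(sigma) || sigma < 0) stop("smoothing sigma must be >= 0")
  if (sigma == 0) return(channel)
  sPx <- umToPx(sigma, pixelSize)
  r <- ceiling(3 * sPx)
  g1 <- exp(-((-r:r)^2) / (2 * sPx^2))
  kern <- outer(g1, g1)
  kern <- kern / sum(kern)
  asMatrix(EBImage::filter2(channel, kern, boundary = "replicate"))
}

# Otsu threshold by exhaustive between-class variance maximisation over a
# fixed binning of the observed range.
otsuThreshold <- function(channel, levels = 256L) {
  channel <- as.matrix(channel)
  rg <- range(channel)
  if (diff(rg) <= 0) return(NA_real_)
  as.numeric(EBImage::otsu(channel, range = rg, levels = levels))
}

#' Threshold a channel into a binary mask
#'
#' Three rules are supported. `"intense"` targets bright, strongly stained
#' structures: an automatic bimodal (Otsu) split of the preprocessed
#' channel, scaled by `intenseMultiplier`. `"all_vessel"` is the permissive
#' low cut used to keep mid- and low-intensity vessels: the Otsu threshold
#' scaled down by `allVesselFactor`. `"fixed"` applies a literal intensity
#' value. Pixels strictly above the realised threshold are foreground. The
#' rule and realised threshold are recorded in the mask provenance.
#'
#' If the Otsu split would call more than a quarter of the (tissue) pixels
#' foreground -- the degenerate outcome when bright structures are too
#' sparse for a bimodal split -- the automatic rules fall back to a robust
#' background ceiling (median + 5 MAD) before the multiplier is applied;
#' the provenance records which base was used.
#'
#' @param channel 2D numeric intensity matrix (already preprocessed as the
#'   pipeline configures)
#' @param rule one of `"intense"`, `"all_vessel"`, `"fixed"`
#' @param value literal threshold, required for `rule = "fixed"`
#' @param pixelSize um per pixel, carried into the mask
#' @param config a [SegmentationConfig-class] supplying the multipliers
#' @param marker marker name recorded in provenance
#' @param within optional logical matrix; automatic thresholds are
#'   computed from the pixels inside it (e.g. the tissue footprint of a
#'   TMA core, so the core-versus-glass contrast does not hijack the
#'   bimodal split). The mask itself is still applied to the whole frame.
#' @return a [BinaryMask-class]
#' @export
thresholdChannel <- function(channel, rule = c("intense", "all_vessel", "fixed"),
                             value = NULL, pixelSize = 1,
                             config = segmentationConfig(),
                             marker = NA_character_, within = NULL) {
  rule <- match.arg(rule)
  stopifnot(is.matrix(channel))
  if (rule == "fixed") {
    if (is.null(value)) stop("rule 'fixed' needs a threshold value")
    thr <- value
    base <- "fixed"
  } else {
    vals <- if (is.null(within)) channel else channel[within]
    ot <- otsuThreshold(vals)
    if (is.na(ot)) {
      warning("channel is constant; automatic '", rule,
              "' threshold has no bimodality to exploit - returning empty mask")
      return(BinaryMask(matrix(FALSE, nrow(channel), ncol(channel)),
                        pixelSize = pixelSize,
                        provenance = list(marker = marker, rule = rule,
                                          threshold = NA_real_,
                                          note = "constant channel")))
    }
    # When bright structures are very sparse the between-class optimum
    # degenerates to a split inside the background mode, marking most of
    # the tissue as foreground. Guard: if the Otsu split calls more than
    # 25% of the (tissue) pixels foreground, fall back to a robust
    # background ceiling, median + 5 MAD.
    auto <- ot
    base <- "otsu"
    if (mean(vals > ot) > 0.25) {
      auto <- stats::median(vals) + 5 * stats::mad(vals)
      base <- "robust background (median + 5 MAD)"
    }
    thr <- if (rule == "intense") auto * config@intenseMultiplier
           else auto * config@allVesselFactor
  }
  BinaryMask(channel > thr, pixelSize = pixelSize,
             provenance = list(marker = marker, rule = rule, threshold = thr,
                               base = base))
}

# per-object geometry (and optional per-channel intensity) measurements
measureObjects <- function(lab, pixelSize, image = NULL) {
  n <- max(lab, 0L)
  if (n == 0L) {
    tab <- data.frame(id = integer(), area_um2 = numeric(), cx = numeric(),
                      cy = numeric(), xmin = integer(), xmax = integer(),
                      ymin = integer(), ymax = integer(),
                      minor_axis_um = numeric(), major_axis_um = numeric(),
                      on_border = logical())
    return(tab)
  }
  idx <- which(lab > 0L)
  l <- lab[idx]
  nr <- nrow(lab); nc <- ncol(lab)
  x <- ((idx - 1L) %% nr) + 1L
  y <- ((idx - 1L) %/% nr) + 1L
  npx <- tabulate(l, n)
  cx <- rowsum(as.numeric(x), l)[, 1] / npx
  cy <- rowsum(as.numeric(y), l)[, 1] / npx
  dx <- x - cx[l]; dy <- y - cy[l]
  mxx <- rowsum(dx * dx, l)[, 1] / npx
  myy <- rowsum(dy * dy, l)[, 1] / npx
  mxy <- rowsum(dx * dy, l)[, 1] / npx
  tr <- mxx + myy
  disc <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
  l1 <- (tr + disc) / 2
  l2 <- pmax((tr - disc) / 2, 0)
  tab <- data.frame(
    id = seq_len(n),
    area_um2 = npx * pixelSize^2,
    cx = cx, cy = cy,
    xmin = as.integer(tapply(x, l, min)), xmax = as.integer(tapply(x, l, max)),
    ymin = as.integer(tapply(y, l, min)), ymax = as.integer(tapply(y, l, max)),
    # moment-based width/length: sqrt(12 * (lambda + 1/12)), the uniform-
    # profile convention with pixel-variance correction; exact for
    # axis-aligned rectangles (a d-pixel-wide tube measures d), within 13%
    # of the ellipse convention for elliptical objects
    minor_axis_um = sqrt(12 * (l2 + 1 / 12)) * pixelSize,
    major_axis_um = sqrt(12 * (l1 + 1 / 12)) * pixelSize,
    on_border = as.logical(tapply(x == 1L | x == nr | y == 1L | y == nc, l, any)))
  if (!is.null(image)) {
    for (mk in channelNames(image)) {
      ch <- getChannel(image, mk)
      tab[[paste0("mean_", mk)]] <- rowsum(ch[idx], l)[, 1] / npx
    }
  }
  rownames(tab) <- NULL
  tab
}

#' Label connected components and measure them
#'
#' Connected-component labelling of a binary mask under 4- or
#' 8-connectivity, with per-object geometry (area in um^2, centroid,
#' bounding box, equivalent-ellipse minor/major axis in um) and, when the
#' source image is given, per-channel mean intensities.
#'
#' @param mask a [BinaryMask-class] or logical matrix
#' @param connectivity 4 or 8
#' @param image optional [MultiChannelImage-class] for intensity readouts
#' @param pixelSize um per pixel (taken from `mask` when it is a BinaryMask)
#' @return a [LabeledObjects-class]
#' @export
labelObjects <- function(mask, connectivity = 8L, image = NULL, pixelSize = NULL) {
  if (is(mask, "BinaryMask")) {
    if (is.null(pixelSize)) pixelSize <- mask@pixelSize
    mask <- mask@mask
  } else if (is.null(pixelSize)) pixelSize <- 1
  storage.mode(mask) <- "logical"
  lab <- cc_label(mask, as.integer(connectivity))
  new("LabeledObjects", labels = lab,
      table = measureObjects(lab, pixelSize, image), pixelSize = pixelSize)
}

# keep a subset of object ids and relabel contiguously from 1
subsetObjects <- function(objects, keepIds) {
  keepIds <- sort(unique(keepIds))
  map <- integer(max(nObjects(objects), 1L))
  map[keepIds] <- seq_along(keepIds)
  lab <- objects@labels
  sel <- lab > 0L
  lab[sel] <- map[lab[sel]]
  tab <- objects@table[objects@table$id %in% keepIds, , drop = FALSE]
  if (nrow(tab)) tab$id <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  new("LabeledObjects", labels = lab, table = tab, pixelSize = objects@pixelSize)
}

#' Filter labelled objects by area
#'
#' Retains objects whose area lies in `[minArea, maxArea]` (um^2) and
#' relabels the survivors contiguously. This implements the size exclusion
#' applied to both cell detections (large-object exclusion) and vessel
#' segmentation (large and small objects filtered out).
#'
#' @param objects a [LabeledObjects-class]
#' @param minArea,maxArea inclusive area bounds in um^2
#' @return a [LabeledObjects-class] with the survivors
#' @export
filterBySize <- function(objects, minArea = 0, maxArea = Inf) {
  stopifnot(is(objects, "LabeledObjects"), minArea <= maxArea)
  tab <- objects@table
  keep <- tab$id[tab$area_um2 >= minArea & tab$area_um2 <= maxArea]
  subsetObjects(objects, keep)
}

#' Dilate a binary mask by a physical radius
#'
#' Morphological dilation with a disc of the given radius in um. Radius 0
#' is the identity; the output is always a superset of the input.
#'
#' @param mask a [BinaryMask-class] or logical matrix
#' @param radius dilation radius in um (>= 0)
#' @param pixelSize um per pixel (taken from the BinaryMask when given)
#' @return a [BinaryMask-class]
#' @export
dilateMask <- function(mask, radius, pixelSize = NULL) {
  prov <- list()
  if (is(mask, "BinaryMask")) {
    if (is.null(pixelSize)) pixelSize <- mask@pixelSize
    prov <- mask@provenance
    mask <- mask@mask
  } else if (is.null(pixelSize)) pixelSize <- 1
  if (!is.numeric(radius) || radius < 0) stop("dilation radius must be >= 0")
  rPx <- umToPx(radius, pixelSize)
  out <- if (rPx < 0.5 || !any(mask)) mask
         else asMatrix(EBImage::dilate(mask * 1, makeDisc(rPx))) > 0.5
  BinaryMask(out, pixelSize = pixelSize,
             provenance = c(prov, list(dilated_um = radius)))
}

# rolling ball + smoothing, the standard preprocessing for one marker
preprocessChannel <- function(image, marker, config) {
  ch <- getChannel(image, marker)
  ch <- rollingBallSubtract(ch, config@rollingBallRadius, pixelSize(image))
  smoothChannel(ch, config@smoothingSigma, pixelSize(image))
}

# full single-marker segmentation: preprocess, threshold, label, size-filter.
# `tissue` (BinaryMask or NULL) restricts the automatic threshold search to
# tissue pixels so the core/glass contrast cannot hijack the bimodal split.
segmentMarker <- function(image, marker, rule, config,
                          minArea = 0, maxArea = Inf, smooth = TRUE,
                          tissue = NULL) {
  ch <- getChannel(image, marker)
  ch <- rollingBallSubtract(ch, config@rollingBallRadius, pixelSize(image))
  if (smooth) ch <- smoothChannel(ch, config@smoothingSigma, pixelSize(image))
  mask <- thresholdChannel(ch, rule, pixelSize = pixelSize(image),
                           config = config, marker = marker,
                           within = if (is.null(tissue)) NULL
                                    else maskArray(tissue))
  obj <- labelObjects(mask, connectivity = config@connectivity, image = image)
  if (!config@keepBorderObjects && nObjects(obj) > 0)
    obj <- subsetObjects(obj, obj@table$id[!obj@table$on_border])
  filterBySize(obj, minArea, maxArea)
}
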