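# Synthetic tissue-microarray-core generator with exact ground truth.
# Emulates the statistical structure the quantification stages assume:
# tubular vessels with a tunable lectin intensity factor (glycocalyx
# stand-in), bright MPO/S100A8 co-positive neutrophils placed inside
# vessels or in parenchyma, a CitH3-positive NET sub-population, amyloid
# plaques and pTau tangles with optional diffuse MPO deposits, and a
# Poisson-Gaussian noise model -- all inside a circular tissue core so
# densities are well defined.

DEFAULT_CHANNELS <- c("DAPI", "MPO", "S100A8", "CitH3", "lectin",
                      "collagenIV", "abeta", "ptau")

# default peak intensities (arbitrary units) per cell class
CELL_INTENSITY_DEFAULTS <- list(
  neutrophil     = c(MPO = 100, S100A8 = 100, DAPI = 60),
  NET            = c(MPO = 70, S100A8 = 70, CitH3 = 70, DAPI = 40),
  mpo_deposit    = c(MPO = 45),
  microglial_mpo = c(MPO = 35, DAPI = 60))

LECTIN_PEAK <- 100       # lectin vessel amplitude at intensity factor 1
ABETA_PEAK <- 80         # plaque amplitude in the amyloid-beta channel
PTAU_PEAK <- 80          # tangle amplitude in the pTau channel
DEPOSIT_PEAK <- 40       # diffuse MPO amplitude under pathology deposits

#' Synthetic scene specification
#'
#' Full description of one synthetic tissue core: frame geometry, vessels,
#' cells, pathology, noise model and seed. Built with [sceneSpec()];
#' entries with [vesselSpec()], [cellSpec()] and [pathologySpec()].
#'
#' @slot imageShape integer (nx, ny) in pixels
#' @slot pixelSize um per pixel
#' @slot coreRadius tissue core radius in um (signal is zero outside)
#' @slot vessels list of vessel entries
#' @slot cells list of cell entries
#' @slot pathology list of pathology entries
#' @slot noise list: gaussianSd, poissonScale, background
#' @slot channels marker channels to render
#' @slot seed integer seed governing all randomness of the scene
#' @export
setClass("SceneSpec",
  representation(imageShape = "integer", pixelSize = "numeric",
                 coreRadius = "numeric", vessels = "list", cells = "list",
                 pathology = "list", noise = "list", channels = "character",
                 seed = "integer"))

setValidity("SceneSpec", function(object) {
  msg <- character()
  if (length(object@imageShape) != 2L || any(object@imageShape < 16L))
    msg <- c(msg, "imageShape must be two pixel counts >= 16")
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (object@coreRadius <= 0) msg <- c(msg, "coreRadius must be > 0")
  for (i in seq_along(object@vessels)) {
    v <- object@vessels[[i]]
    if (v$diameter <= 0)
      msg <- c(msg, sprintf("vessel_specs[%d]: diameter must be > 0", i))
    if (v$lectinFactor <= 0 || v$lectinFactor > 1)
      msg <- c(msg, sprintf("vessel_specs[%d]: lectinFactor must be in (0, 1]", i))
  }
  for (i in seq_along(object@cells)) {
    cl <- object@cells[[i]]
    if (cl$radius <= 0)
      msg <- c(msg, sprintf("cell_specs[%d]: radius must be > 0", i))
    if (!cl$class %in% names(CELL_INTENSITY_DEFAULTS))
      msg <- c(msg, sprintf("cell_specs[%d]: unknown class '%s'", i, cl$class))
    if (!cl$compartment %in% c("intravascular", "parenchymal"))
      msg <- c(msg, sprintf("cell_specs[%d]: unknown compartment '%s'",
                            i, cl$compartment))
  }
  for (i in seq_along(object@pathology)) {
    p <- object@pathology[[i]]
    if (p$radius <= 0)
      msg <- c(msg, sprintf("pathology_specs[%d]: radius must be > 0", i))
    if (!p$class %in% c("plaque", "tangle"))
      msg <- c(msg, sprintf("pathology_specs[%d]: unknown class '%s'", i, p$class))
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a synthetic scene
#'
#' @slot objects data.frame of true cells: id, class, compartment,
#'   centroid (cx, cy in px), radius_um, marker positivity flags,
#'   vessel_id, pathology_id
#' @slot vessels data.frame of true vessels: id, diameter_um, size_class
#'   (at the 12 um cutoff), lectin_factor, collagen_intensity
#' @slot pathology data.frame of plaques/tangles
#' @slot coreAreaMm2 tissue core area in mm^2
#' @slot coreCentre core centre (px)
#' @slot coreRadiusUm core radius (um)
#' @slot pixelSize um per pixel
#' @export
setClass("GroundTruth",
  representation(objects = "data.frame", vessels = "data.frame",
                 pathology = "data.frame", coreAreaMm2 = "numeric",
                 coreCentre = "numeric", coreRadiusUm = "numeric",
                 pixelSize = "numeric"))

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@objects), "cells,",
      nrow(object@vessels), "vessels,", nrow(object@pathology),
      "pathology objects; core", round(object@coreAreaMm2, 4), "mm^2\n")
})

#' Vessel entry for a synthetic scene
#'
#' A constant-diameter tube along a polyline centerline.
#'
#' @param polyline n x 2 matrix of (x, y) pixel coordinates, n >= 2
#' @param diameter tube diameter in um
#' @param lectinFactor lectin intensity factor in (0, 1]; 1 = intact
#'   glycocalyx, lower values emulate glycocalyx loss
#' @param collagenIntensity collagen IV amplitude (arbitrary units)
#' @return a list entry for [sceneSpec()]
#' @export
vesselSpec <- function(polyline, diameter, lectinFactor = 1,
                       collagenIntensity = 80) {
  polyline <- as.matrix(polyline)
  stopifnot(ncol(polyline) == 2L, nrow(polyline) >= 2L)
  list(polyline = polyline, diameter = diameter, lectinFactor = lectinFactor,
       collagenIntensity = collagenIntensity)
}

#' Cell entry for a synthetic scene
#'
#' Cells are rendered as 2D Gaussian-profiled discs (sigma = radius / 2)
#' in the channels named by the intensity map.
#'
#' @param centre (x, y) pixel coordinates of the centroid
#' @param radius cell radius in um (neutrophil scale is 4-6 um)
#' @param class one of `"neutrophil"`, `"NET"`, `"mpo_deposit"`,
#'   `"microglial_mpo"`
#' @param compartment `"intravascular"` or `"parenchymal"`
#' @param intensity named numeric of peak amplitudes per marker; defaults
#'   depend on `class` (NETs are larger, dimmer, CitH3-positive)
#' @return a list entry for [sceneSpec()]
#' @export
cellSpec <- function(centre, radius = 5, class = "neutrophil",
                     compartment = "parenchymal", intensity = NULL) {
  if (is.null(intensity)) intensity <- CELL_INTENSITY_DEFAULTS[[class]]
  list(centre = as.numeric(centre), radius = radius, class = class,
       compartment = compartment, intensity = intensity)
}

#' Pathology entry for a synthetic scene
#'
#' @param centre (x, y) pixel coordinates
#' @param radius object radius in um
#' @param class `"plaque"` (amyloid-beta channel) or `"tangle"` (pTau)
#' @param mpoDeposit if TRUE, a diffuse MPO deposit is rendered at the
#'   same location (so the two objects touch by construction)
#' @return a list entry for [sceneSpec()]
#' @export
pathologySpec <- function(centre, radius = 15, class = "plaque",
                          mpoDeposit = FALSE) {
  list(centre = as.numeric(centre), radius = radius, class = class,
       mpoDeposit = isTRUE(mpoDeposit))
}

#' Construct a SceneSpec
#'
#' @param imageShape (nx, ny) in pixels
#' @param pixelSize um per pixel
#' @param vessels,cells,pathology lists built with [vesselSpec()],
#'   [cellSpec()], [pathologySpec()]
#' @param noise list with `gaussianSd` (additive read noise SD),
#'   `poissonScale` (photons per intensity unit; 0 disables shot noise)
#'   and `background` (tissue autofluorescence level inside the core)
#' @param coreRadius tissue core radius in um; defaults to 90% of the
#'   half-frame so the core sits inside the frame
#' @param channels marker channels to render
#' @param seed integer seed
#' @return a [SceneSpec-class]
#' @examples
#' sp <- sceneSpec(imageShape = c(128, 128), seed = 1,
#'                 cells = list(cellSpec(c(64, 64))))
#' @export
sceneSpec <- function(imageShape = c(400L, 400L), pixelSize = 1,
                      vessels = list(), cells = list(), pathology = list(),
                      noise = list(), coreRadius = NA_real_,
                      channels = DEFAULT_CHANNELS, seed = 1L) {
  noise <- utils::modifyList(
    list(gaussianSd = 2, poissonScale = 1, background = 10), noise)
  if (is.na(coreRadius))
    coreRadius <- 0.45 * min(imageShape) * pixelSize
  new("SceneSpec", imageShape = as.integer(imageShape),
      pixelSize = as.numeric(pixelSize), coreRadius = as.numeric(coreRadius),
      vessels = vessels, cells = cells, pathology = pathology, noise = noise,
      channels = channels, seed = as.integer(seed))
}

# distance from every pixel of a frame window to a polyline (min over
# segments); returns matrix of distances for pixels in rows rx, cols ry
distToPolyline <- function(rx, ry, poly) {
  g <- expand.grid(x = rx, y = ry)
  d2 <- rep(Inf, nrow(g))
  for (s in seq_len(nrow(poly) - 1L)) {
    p0 <- poly[s, ]; p1 <- poly[s + 1L, ]
    v <- p1 - p0
    L2 <- sum(v^2)
    if (L2 == 0) {
      dd <- (g$x - p0[1])^2 + (g$y - p0[2])^2
    } else {
      t <- pmin(pmax(((g$x - p0[1]) * v[1] + (g$y - p0[2]) * v[2]) / L2, 0), 1)
      dd <- (g$x - p0[1] - t * v[1])^2 + (g$y - p0[2] - t * v[2])^2
    }
    d2 <- pmin(d2, dd)
  }
  matrix(sqrt(d2), length(rx), length(ry))
}

# rasterise one vessel tube; returns linear pixel indices of the footprint
vesselFootprint <- function(v, shape, pixelSize, coreMask) {
  rad <- (v$diameter / 2) / pixelSize
  xr <- range(v$polyline[, 1]); yr <- range(v$polyline[, 2])
  rx <- max(1L, floor(xr[1] - rad - 1)):min(shape[1], ceiling(xr[2] + rad + 1))
  ry <- max(1L, floor(yr[1] - rad - 1)):min(shape[2], ceiling(yr[2] + rad + 1))
  d <- distToPolyline(rx, ry, v$polyline)
  sel <- which(d <= rad, arr.ind = TRUE)
  if (!nrow(sel)) return(integer())
  ix <- rx[sel[, 1]]; iy <- ry[sel[, 2]]
  idx <- (iy - 1L) * shape[1] + ix
  idx[coreMask[idx]]
}

# add a Gaussian-profiled disc to a channel matrix (in place semantics via
# return); sigma and cut radius in pixels
addBlob <- function(ch, centre, sigmaPx, amp, cut = 3) {
  shape <- dim(ch)
  r <- ceiling(cut * sigmaPx)
  rx <- max(1L, floor(centre[1] - r)):min(shape[1], ceiling(centre[1] + r))
  ry <- max(1L, floor(centre[2] - r)):min(shape[2], ceiling(centre[2] + r))
  dx <- rx - centre[1]; dy <- ry - centre[2]
  d2 <- outer(dx^2, dy^2, "+")
  ch[rx, ry] <- ch[rx, ry] + amp * exp(-d2 / (2 * sigmaPx^2)) * (d2 <= r^2)
  ch
}

coreMaskOf <- function(shape, centrePx, radiusPx) {
  dx2 <- (seq_len(shape[1]) - centrePx[1])^2
  dy2 <- (seq_len(shape[2]) - centrePx[2])^2
  outer(dx2, dy2, "+") <= radiusPx^2
}

#' Generate one synthetic tissue core
#'
#' Rasterises the vessels, cells and pathology of a [SceneSpec-class] into
#' a multi-channel image, applies the Poisson-Gaussian noise model, and
#' returns the image together with its exact ground truth. The output is a
#' pure function of the spec (including its seed): identical spec, identical
#' scene.
#'
#' @param spec a [SceneSpec-class]
#' @return list with elements `image` ([MultiChannelImage-class]) and
#'   `truth` ([GroundTruth-class])
#' @examples
#' sc <- generateScene(sceneSpec(imageShape = c(96, 96), seed = 7,
#'   cells = list(cellSpec(c(48, 48)))))
#' sc$truth
#' @export
generateScene <- function(spec) {
  validObject(spec)
  shape <- spec@imageShape
  px <- spec@pixelSize
  centrePx <- (shape + 1) / 2
  coreRadPx <- spec@coreRadius / px
  coreMask <- coreMaskOf(shape, centrePx, coreRadPx)

  # vessel footprints (linear pixel indices), clipped to the core
  feet <- lapply(spec@vessels, vesselFootprint, shape = shape,
                 pixelSize = px, coreMask = coreMask)

  # intravascular cells must sit inside their vessel's rasterised footprint
  vesselIds <- rep(NA_integer_, length(spec@cells))
  for (i in seq_along(spec@cells)) {
    cl <- spec@cells[[i]]
    if (cl$compartment != "intravascular") next
    cpix <- (round(cl$centre[2]) - 1L) * shape[1] + round(cl$centre[1])
    hit <- which(vapply(feet, function(f) cpix %in% f, logical(1)))
    if (!length(hit))
      stop("cell_specs[", i, "]: intravascular cell centroid (",
           cl$centre[1], ", ", cl$centre[2],
           ") lies outside every vessel footprint")
    vesselIds[i] <- hit[1L]
  }

  chans <- lapply(spec@channels, function(m) matrix(0, shape[1], shape[2]))
  names(chans) <- spec@channels
  addTo <- function(name, idx, val) {
    if (name %in% names(chans) && length(idx))
      chans[[name]][idx] <<- chans[[name]][idx] + val
  }

  for (k in seq_along(spec@vessels)) {
    v <- spec@vessels[[k]]
    addTo("lectin", feet[[k]], v$lectinFactor * LECTIN_PEAK)
    addTo("collagenIV", feet[[k]], v$collagenIntensity)
  }
  for (cl in spec@cells) {
    sigmaPx <- (cl$radius / 2) / px
    for (mk in names(cl$intensity)) {
      if (!mk %in% names(chans)) next
      chans[[mk]] <- addBlob(chans[[mk]], cl$centre, sigmaPx, cl$intensity[[mk]])
    }
  }
  pathMpoIdx <- integer(0)
  for (i in seq_along(spec@pathology)) {
    p <- spec@pathology[[i]]
    sigmaPx <- (p$radius / 2) / px
    target <- if (p$class == "plaque") "abeta" else "ptau"
    amp <- if (p$class == "plaque") ABETA_PEAK else PTAU_PEAK
    if (target %in% names(chans))
      chans[[target]] <- addBlob(chans[[target]], p$centre, sigmaPx, amp)
    if (p$mpoDeposit && "MPO" %in% names(chans))
      chans[["MPO"]] <- addBlob(chans[["MPO"]], p$centre, sigmaPx, DEPOSIT_PEAK)
  }

  # zero signal outside the circular core, then noise
  withSeed(spec@seed, {
    for (m in names(chans)) {
      ch <- chans[[m]]
      ch[!coreMask] <- 0
      base <- ch + spec@noise$background * coreMask
      if (spec@noise$poissonScale > 0)
        base <- stats::rpois(length(base), spec@noise$poissonScale * base) /
          spec@noise$poissonScale
      if (spec@noise$gaussianSd > 0)
        base <- base + stats::rnorm(length(base), 0, spec@noise$gaussianSd)
      chans[[m]] <- matrix(pmax(base, 0), shape[1], shape[2])
    }
  })

  img <- MultiChannelImage(chans, pixelSize = px)
  list(image = img, truth = truthFromSpec(spec, feet))
}

#' Cohort specification for synthetic scenes
#'
#' Group-level effect sizes for a two-group synthetic cohort: neutrophil
#' density (cells per mm^2 of core tissue), NET prevalence (fraction of
#' neutrophils that are CitH3-positive), vascular fraction of neutrophils,
#' lectin intensity factor (glycocalyx effect), and plaque/tangle
#' densities. Per-scene cell counts are Poisson with mean density x core
#' area.
#'
#' @slot nPerGroup scenes per group (>= 1)
#' @slot groups two group labels
#' @slot density,netPrevalence,vascularFraction,lectinFactor named numeric
#'   per group
#' @slot plaqueDensity,tangleDensity named numeric per group (per mm^2)
#' @slot mpoDepositProb probability a pathology object carries an MPO deposit
#' @slot nVessels vessels per scene
#' @slot imageShape,pixelSize,coreRadius,noise,channels scene frame defaults
#' @slot seed integer seed governing the whole cohort
#' @export
setClass("CohortSpec",
  representation(nPerGroup = "integer", groups = "character",
                 density = "numeric", netPrevalence = "numeric",
                 vascularFraction = "numeric", lectinFactor = "numeric",
                 plaqueDensity = "numeric", tangleDensity = "numeric",
                 mpoDepositProb = "numeric", nVessels = "integer",
                 imageShape = "integer", pixelSize = "numeric",
                 coreRadius = "numeric", noise = "list",
                 channels = "character", seed = "integer"))

setValidity("CohortSpec", function(object) {
  msg <- character()
  if (object@nPerGroup < 1L) msg <- c(msg, "nPerGroup must be >= 1")
  if (length(object@groups) != 2L) msg <- c(msg, "exactly two groups required")
  for (s in c("density", "netPrevalence", "vascularFraction", "lectinFactor",
              "plaqueDensity", "tangleDensity")) {
    v <- slot(object, s)
    if (!all(object@groups %in% names(v)))
      msg <- c(msg, paste0(s, " must be named by group"))
  }
  if (any(object@density < 0) || any(object@plaqueDensity < 0) ||
      any(object@tangleDensity < 0))
    msg <- c(msg, "densities must be >= 0")
  if (any(object@netPrevalence < 0 | object@netPrevalence > 1) ||
      any(object@vascularFraction < 0 | object@vascularFraction > 1))
    msg <- c(msg, "fractions must lie in [0, 1]")
  if (any(object@lectinFactor <= 0 | object@lectinFactor > 1))
    msg <- c(msg, "lectinFactor must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a CohortSpec
#'
#' Defaults emulate a two-group contrast with a 3x neutrophil density
#' effect, higher NET prevalence, glycocalyx loss (lectin factor 0.6) and
#' pathology only in the disease group, with most neutrophils vascular in
#' both groups.
#'
#' @param nPerGroup scenes per group
#' @param groups two group labels
#' @param density,netPrevalence,vascularFraction,lectinFactor per-group
#'   effect sizes (named or in group order)
#' @param plaqueDensity,tangleDensity per-group pathology densities per mm^2
#' @param mpoDepositProb probability a pathology object has an MPO deposit
#' @param nVessels vessels per scene
#' @param imageShape,pixelSize,coreRadius,noise,channels scene frame
#'   defaults (see [sceneSpec()])
#' @param seed integer seed
#' @return a [CohortSpec-class]
#' @export
cohortSpec <- function(nPerGroup = 10L, groups = c("control", "AD"),
                       density = c(15, 45), netPrevalence = c(0.1, 0.3),
                       vascularFraction = c(0.8, 0.8),
                       lectinFactor = c(1, 0.6), plaqueDensity = c(0, 3),
                       tangleDensity = c(0, 2), mpoDepositProb = 0.5,
                       nVessels = 5L, imageShape = c(400L, 400L),
                       pixelSize = 1, coreRadius = NA_real_,
                       noise = list(), channels = DEFAULT_CHANNELS,
                       seed = 1L) {
  nm <- function(v) {
    if (is.null(names(v))) names(v) <- groups
    v[groups]
  }
  noise <- utils::modifyList(
    list(gaussianSd = 2, poissonScale = 1, background = 10), noise)
  if (is.na(coreRadius)) coreRadius <- 0.45 * min(imageShape) * pixelSize
  new("CohortSpec", nPerGroup = as.integer(nPerGroup), groups = groups,
      density = nm(density), netPrevalence = nm(netPrevalence),
      vascularFraction = nm(vascularFraction), lectinFactor = nm(lectinFactor),
      plaqueDensity = nm(plaqueDensity), tangleDensity = nm(tangleDensity),
      mpoDepositProb = mpoDepositProb, nVessels = as.integer(nVessels),
      imageShape = as.integer(imageShape), pixelSize = pixelSize,
      coreRadius = coreRadius, noise = noise, channels = channels,
      seed = as.integer(seed))
}

# near-straight chord across the core with mild curvature; scenes draw
# near-parallel lanes (one base angle, evenly spread offsets) so vessels
# rarely cross and stay measurable as individual tubes
randomVesselPolyline <- function(centrePx, coreRadPx, theta = NULL,
                                 offset = NULL) {
  if (is.null(theta)) theta <- stats::runif(1, 0, pi)
  if (is.null(offset)) offset <- stats::runif(1, -0.6, 0.6) * coreRadPx
  half <- sqrt(max(coreRadPx^2 - offset^2, 1)) * 1.05
  dirv <- c(cos(theta), sin(theta))
  nrm <- c(-sin(theta), cos(theta))
  p0 <- centrePx + offset * nrm - half * dirv
  p1 <- centrePx + offset * nrm + half * dirv
  mid <- (p0 + p1) / 2 + stats::runif(1, -0.015, 0.015) * 2 * half * nrm
  rbind(p0, mid, p1)
}

# bimodal vessel diameter, clear of the 12 um cutoff band
randomVesselDiameter <- function() {
  if (stats::runif(1) < 0.5) stats::runif(1, 5, 9.5)
  else stats::runif(1, 14.5, 24)
}

# sample a point uniformly inside the core, optionally avoiding / hitting
# the vessel footprint (linear indices on the frame)
samplePoint <- function(shape, centrePx, coreRadPx, vesselIdx, inVessel) {
  if (inVessel) {
    if (!length(vesselIdx)) stop("no vessel pixels to place a vascular cell")
    i <- vesselIdx[sample.int(length(vesselIdx), 1L)]
    return(c(((i - 1L) %% shape[1]) + 1L, ((i - 1L) %/% shape[1]) + 1L))
  }
  for (tries in 1:200) {
    r <- coreRadPx * 0.92 * sqrt(stats::runif(1))
    a <- stats::runif(1, 0, 2 * pi)
    p <- centrePx + r * c(cos(a), sin(a))
    i <- (round(p[2]) - 1L) * shape[1] + round(p[1])
    if (!length(vesselIdx) || !(i %in% vesselIdx)) return(p)
  }
  p  # give up avoiding vessels; extremely dense vasculature
}

#' Generate a synthetic two-group cohort
#'
#' Draws `2 * nPerGroup` scenes. Per-scene neutrophil counts are Poisson
#' with mean `density x core area`; each cell is vascular with the group's
#' vascular fraction and a NET with the group's NET prevalence; vessels
#' carry the group's lectin intensity factor; plaques and tangles follow
#' the group's pathology densities. Fully reproducible from the cohort
#' seed.
#'
#' @param cohort a [CohortSpec-class]
#' @param render `"image"` renders full images; `"truth"` skips channel
#'   rasterisation and returns ground truth only (fast path for
#'   statistical calibration studies)
#' @return list of per-core lists with elements `image`
#'   ([MultiChannelImage-class] or NULL), `truth` ([GroundTruth-class]),
#'   `group`, `coreId`
#' @export
generateCohort <- function(cohort, render = c("image", "truth")) {
  render <- match.arg(render)
  validObject(cohort)
  shape <- cohort@imageShape
  px <- cohort@pixelSize
  centrePx <- (shape + 1) / 2
  coreRadPx <- cohort@coreRadius / px
  coreArea <- pi * (cohort@coreRadius / 1000)^2
  nTot <- 2L * cohort@nPerGroup
  groupOf <- rep(cohort@groups, each = cohort@nPerGroup)

  withSeed(cohort@seed, {
    seeds <- sample.int(.Machine$integer.max, nTot)
    out <- vector("list", nTot)
    coreMask <- coreMaskOf(shape, centrePx, coreRadPx)
    for (i in seq_len(nTot)) {
      g <- groupOf[i]
      nV <- cohort@nVessels
      baseTheta <- stats::runif(1, 0, pi)
      offsets <- if (nV > 0)
        ((seq_len(nV) - (nV + 1) / 2) / max(nV, 1) * 1.2 +
           stats::runif(nV, -0.06, 0.06)) * coreRadPx
      else numeric()
      vessels <- lapply(seq_len(nV), function(k)
        vesselSpec(randomVesselPolyline(centrePx, coreRadPx,
                                        theta = baseTheta +
                                          stats::runif(1, -0.12, 0.12),
                                        offset = offsets[k]),
                   diameter = randomVesselDiameter(),
                   lectinFactor = cohort@lectinFactor[[g]]))
      feet <- lapply(vessels, vesselFootprint, shape = shape,
                     pixelSize = px, coreMask = coreMask)
      allVesselIdx <- unique(unlist(feet))
      # parenchymal cells keep a 10 um clearance from vessel walls so the
      # ground-truth compartment is unambiguous under mask dilation
      avoidIdx <- allVesselIdx
      if (length(allVesselIdx)) {
        vm <- matrix(FALSE, shape[1], shape[2])
        vm[allVesselIdx] <- TRUE
        dl <- asMatrix(EBImage::dilate(vm * 1, makeDisc(10 / px))) > 0.5
        avoidIdx <- which(dl)
      }

      nCells <- stats::rpois(1, cohort@density[[g]] * coreArea)
      cells <- vector("list", nCells)
      if (nCells > 0) for (j in seq_len(nCells)) {
        vascular <- stats::runif(1) < cohort@vascularFraction[[g]] &&
          length(allVesselIdx) > 0
        isNet <- stats::runif(1) < cohort@netPrevalence[[g]]
        p <- samplePoint(shape, centrePx, coreRadPx,
                         if (vascular) allVesselIdx else avoidIdx, vascular)
        cells[[j]] <- cellSpec(
          centre = p,
          radius = if (isNet) stats::runif(1, 6, 8) else stats::runif(1, 4, 6),
          class = if (isNet) "NET" else "neutrophil",
          compartment = if (vascular) "intravascular" else "parenchymal")
      }

      pathology <- list()
      for (pc in c("plaque", "tangle")) {
        dens <- if (pc == "plaque") cohort@plaqueDensity[[g]]
                else cohort@tangleDensity[[g]]
        nP <- stats::rpois(1, dens * coreArea)
        if (nP > 0) for (j in seq_len(nP)) {
          p <- samplePoint(shape, centrePx, coreRadPx, allVesselIdx, FALSE)
          pathology[[length(pathology) + 1L]] <- pathologySpec(
            centre = p, radius = if (pc == "plaque") 15 else 8, class = pc,
            mpoDeposit = stats::runif(1) < cohort@mpoDepositProb)
        }
      }

      spec <- sceneSpec(imageShape = shape, pixelSize = px,
                        vessels = vessels, cells = cells,
                        pathology = pathology, noise = cohort@noise,
                        coreRadius = cohort@coreRadius,
                        channels = cohort@channels, seed = seeds[i])
      if (render == "image") {
        sc <- generateScene(spec)
      } else {
        sc <- list(image = NULL, truth = truthFromSpec(spec, feet))
      }
      out[[i]] <- list(image = sc$image, truth = sc$truth, group = g,
                       coreId = sprintf("core_%03d", i))
    }
    out
  })
}

# ground truth straight from a spec (no rasterisation of channels);
# vessel footprints are supplied so intravascular references are resolved
truthFromSpec <- function(spec, feet) {
  shape <- spec@imageShape
  vesselIds <- rep(NA_integer_, length(spec@cells))
  for (i in seq_along(spec@cells)) {
    cl <- spec@cells[[i]]
    if (cl$compartment != "intravascular") next
    cpix <- (round(cl$centre[2]) - 1L) * shape[1] + round(cl$centre[1])
    hit <- which(vapply(feet, function(f) cpix %in% f, logical(1)))
    vesselIds[i] <- if (length(hit)) hit[1L] else NA_integer_
  }
  sc <- spec
  # reuse generateScene's table-building by constructing tables directly
  vtab <- data.frame(
    id = seq_along(sc@vessels),
    diameter_um = vapply(sc@vessels, `[[`, numeric(1), "diameter"),
    lectin_factor = vapply(sc@vessels, `[[`, numeric(1), "lectinFactor"),
    collagen_intensity = vapply(sc@vessels, `[[`, numeric(1),
                                "collagenIntensity"))
  vtab$size_class <- ifelse(vtab$diameter_um >= 12, "large", "small")
  otab <- if (length(sc@cells)) data.frame(
    id = seq_along(sc@cells),
    class = vapply(sc@cells, `[[`, character(1), "class"),
    compartment = vapply(sc@cells, `[[`, character(1), "compartment"),
    cx = vapply(sc@cells, function(cl) cl$centre[1], numeric(1)),
    cy = vapply(sc@cells, function(cl) cl$centre[2], numeric(1)),
    radius_um = vapply(sc@cells, `[[`, numeric(1), "radius"),
    mpo_pos = vapply(sc@cells, function(cl)
      "MPO" %in% names(cl$intensity), logical(1)),
    s100a8_pos = vapply(sc@cells, function(cl)
      "S100A8" %in% names(cl$intensity), logical(1)),
    cith3_pos = vapply(sc@cells, function(cl)
      "CitH3" %in% names(cl$intensity), logical(1)),
    vessel_id = vesselIds,
    pathology_id = NA_integer_)
  else data.frame(id = integer(), class = character(),
                  compartment = character(), cx = numeric(), cy = numeric(),
                  radius_um = numeric(), mpo_pos = logical(),
                  s100a8_pos = logical(), cith3_pos = logical(),
                  vessel_id = integer(), pathology_id = integer())
  ptab <- if (length(sc@pathology)) data.frame(
    id = seq_along(sc@pathology),
    class = vapply(sc@pathology, `[[`, character(1), "class"),
    cx = vapply(sc@pathology, function(p) p$centre[1], numeric(1)),
    cy = vapply(sc@pathology, function(p) p$centre[2], numeric(1)),
    radius_um = vapply(sc@pathology, `[[`, numeric(1), "radius"),
    has_mpo_deposit = vapply(sc@pathology, `[[`, logical(1), "mpoDeposit"))
  else data.frame(id = integer(), class = character(), cx = numeric(),
                  cy = numeric(), radius_um = numeric(),
                  has_mpo_deposit = logical())
  new("GroundTruth", objects = otab, vessels = vtab, pathology = ptab,
      coreAreaMm2 = pi * (sc@coreRadius / 1000)^2,
      coreCentre = (shape + 1) / 2, coreRadiusUm = sc@coreRadius,
      pixelSize = sc@pixelSize)
}
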