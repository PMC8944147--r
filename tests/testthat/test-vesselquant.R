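# Vessel segmentation, size classification and the glycocalyx readout.

threeTubeScene <- function(lectinFactor = 1, seed = 2) {
  generateScene(noiselessScene(
    imageShape = c(200, 200), seed = seed,
    vessels = list(hTube(50, 8, 20, 180, lectinFactor),
                   hTube(100, 16, 20, 180, lectinFactor),
                   hTube(150, 20, 20, 180, lectinFactor))))
}

test_that("noiseless tubes are recovered one-to-one", {
  sc <- threeTubeScene()
  vo <- segmentVessels(sc$image, "lectin")
  expect_equal(nObjects(vo), 3L)

  # a single-pixel speckle below the minimum area is filtered out
  img <- sc$image
  ch <- getChannel(img, "lectin"); ch[5, 5] <- 200
  chans <- lapply(channelNames(img), function(m)
    if (m == "lectin") ch else getChannel(img, m))
  names(chans) <- channelNames(img)
  img2 <- MultiChannelImage(chans, pixelSize = 1)
  expect_equal(nObjects(segmentVessels(img2, "lectin")), 3L)

  expect_error(segmentVessels(flatImage("MPO"), "lectin"), "missing")
})

test_that("threshold adapts to uniform dimming; intensities scale", {
  sc1 <- threeTubeScene(lectinFactor = 1)
  sc2 <- threeTubeScene(lectinFactor = 0.5)
  v1 <- segmentVessels(sc1$image, "lectin")
  v2 <- segmentVessels(sc2$image, "lectin")
  expect_equal(nObjects(v1), nObjects(v2))
  expect_equal(objectTable(v1)$area_um2, objectTable(v2)$area_um2)
  r1 <- classifyVesselSize(v1); r2 <- classifyVesselSize(v2)
  m1 <- meanIntensityByClass(sc1$image, v1, r1, "lectin")
  m2 <- meanIntensityByClass(sc2$image, v2, r2, "lectin")
  expect_equal(m2$perVessel$mean_intensity / m1$perVessel$mean_intensity,
               rep(0.5, 3), tolerance = 1e-6)
})

test_that("minor axis width matches the brute-force moment oracle", {
  set.seed(23)
  m <- matrix(FALSE, 60, 60)
  m[10:40, 5:12] <- TRUE        # 8-wide rectangle
  m[45:52, 20:50] <- TRUE       # 8-tall rectangle
  d2 <- outer((1:60 - 30)^2, (1:60 - 45)^2, "+"); m[d2 <= 36] <- TRUE  # disc
  lo <- labelsFrom(m)
  tab <- objectTable(lo)
  for (i in tab$id) {
    w <- oracleWidths(labelImage(lo), i)
    expect_equal(tab$minor_axis_um[tab$id == i], w[1], tolerance = 1e-9)
    expect_equal(tab$major_axis_um[tab$id == i], w[2], tolerance = 1e-9)
  }
  # the rectangles measure exactly their pixel width
  expect_equal(sort(tab$minor_axis_um)[1:2], c(8, 8), tolerance = 1e-9)
})

test_that("straight aligned tubes recover their diameter within 10%", {
  for (d in c(6, 8, 10, 14, 16, 20)) {
    # integer-centre placement for odd widths, half-integer for even, so
    # rasterisation quantisation does not add a spurious pixel
    y0 <- if (d %% 2 == 0) 60.5 else 60
    sc <- generateScene(noiselessScene(imageShape = c(140, 140),
                                       vessels = list(hTube(y0, d, 15, 125))))
    vo <- segmentVessels(sc$image, "lectin")
    expect_equal(nObjects(vo), 1L)
    expect_equal(objectTable(vo)$minor_axis_um, d, tolerance = 0.1)
  }
})

test_that("size classification follows the cutoff and boundary rule", {
  mk <- function(w) {
    m <- matrix(FALSE, 60, 40); m[10:50, 10 + seq_len(w) - 1] <- TRUE
    labelsFrom(m)
  }
  expect_equal(classifyVesselSize(mk(8), cutoff = 12)$size_class, "small")
  expect_equal(classifyVesselSize(mk(20), cutoff = 12)$size_class, "large")
  # a 12-px-wide rectangle measures exactly 12: tie goes large by default
  tie <- mk(12)
  expect_equal(objectTable(tie)$minor_axis_um, 12, tolerance = 1e-9)
  expect_equal(classifyVesselSize(tie, cutoff = 12)$size_class, "large")
  expect_equal(classifyVesselSize(tie, cutoff = 12,
                                  boundaryRule = "small")$size_class, "small")

  # partition: every object classified exactly once
  sc <- threeTubeScene()
  vo <- segmentVessels(sc$image, "lectin")
  rec <- classifyVesselSize(vo, cutoff = 12)
  expect_equal(sum(rec$size_class == "small") +
               sum(rec$size_class == "large"), nObjects(vo))
})

test_that("tubes clear of the cutoff are classified 100% correctly", {
  ds <- c(5, 7, 9, 10, 14, 15, 18, 22)
  for (i in seq_along(ds)) {
    sc <- generateScene(sceneSpec(imageShape = c(140, 140), seed = 40 + i,
                                  vessels = list(hTube(60, ds[i], 15, 125))))
    vo <- segmentVessels(sc$image, "lectin")
    expect_equal(nObjects(vo), 1L)
    rec <- classifyVesselSize(vo, cutoff = 12)
    expect_equal(rec$size_class, ifelse(ds[i] >= 12, "large", "small"),
                 info = paste("diameter", ds[i]))
  }
})

test_that("per-class summaries are vessel-weighted and flag empty classes", {
  # one vessel of constant intensity 100
  m <- matrix(FALSE, 60, 40); m[10:50, 10:17] <- TRUE
  lo <- labelsFrom(m)
  img <- flatImage("lectin", c(60, 40), 0)
  ch <- getChannel(img, "lectin"); ch[m] <- 100
  img <- MultiChannelImage(list(lectin = ch), pixelSize = 1)
  rec <- classifyVesselSize(lo, cutoff = 12)
  out <- meanIntensityByClass(img, lo, rec, "lectin")
  expect_equal(out$perVessel$mean_intensity, 100)
  expect_equal(out$perClass$mean_intensity[out$perClass$size_class == "small"],
               100)
  # the empty large class is absent, not zero
  largeRow <- out$perClass[out$perClass$size_class == "large", ]
  expect_false(largeRow$present)
  expect_true(is.na(largeRow$mean_intensity))

  # two small vessels with means 10 and 30 -> class mean 20 (unweighted)
  m2 <- matrix(FALSE, 60, 60)
  m2[5:45, 5:10] <- TRUE     # 6 x 41
  m2[5:55, 30:37] <- TRUE    # 8 x 51 (more pixels)
  lo2 <- labelsFrom(m2)
  ch2 <- matrix(0, 60, 60); ch2[5:45, 5:10] <- 10; ch2[5:55, 30:37] <- 30
  img2 <- MultiChannelImage(list(lectin = ch2), pixelSize = 1)
  rec2 <- classifyVesselSize(lo2, cutoff = 12)
  out2 <- meanIntensityByClass(img2, lo2, rec2, "lectin")
  expect_equal(sort(out2$perVessel$mean_intensity), c(10, 30))
  expect_equal(out2$perClass$mean_intensity[
    out2$perClass$size_class == "small"], 20)
})

test_that("intensity readout is exactly linear in the channel", {
  sc <- threeTubeScene()
  vo <- segmentVessels(sc$image, "lectin")
  rec <- classifyVesselSize(vo)
  base <- meanIntensityByClass(sc$image, vo, rec, "lectin")$perVessel
  k <- 3.7
  chans <- lapply(channelNames(sc$image), function(m) {
    ch <- getChannel(sc$image, m)
    if (m == "lectin") ch * k else ch
  })
  names(chans) <- channelNames(sc$image)
  scaled <- MultiChannelImage(chans, pixelSize = 1)
  got <- meanIntensityByClass(scaled, vo, rec, "lectin")$perVessel
  expect_equal(got$mean_intensity, base$mean_intensity * k, tolerance = 1e-12)
})

test_that("lectin intensity factor is recovered inside collagen IV vessels", {
  mk <- function(f, seed) generateScene(sceneSpec(
    imageShape = c(200, 200), seed = seed,
    vessels = list(hTube(50, 9, 20, 180, f), hTube(100, 16, 20, 180, f),
                   hTube(150, 12, 20, 180, f))))
  scA <- mk(1, 51); scB <- mk(0.6, 52)
  readout <- function(sc) {
    vo <- segmentVessels(sc$image, "collagenIV")
    rec <- classifyVesselSize(vo, cutoff = 15, sourceMarker = "collagenIV")
    mean(meanIntensityByClass(sc$image, vo, rec, "lectin")$perVessel$mean_intensity)
  }
  expect_equal(readout(scB) / readout(scA), 0.6, tolerance = 0.05)
})

test_that("the vessel mask is the dilated union of footprints", {
  # zero vessels -> empty mask
  empty <- labelsFrom(matrix(FALSE, 30, 30))
  expect_false(any(maskArray(vesselMask(empty, 2))))

  sc <- generateScene(noiselessScene(imageShape = c(128, 128),
                                     vessels = list(hTube(64, 10, 20, 108))))
  vo <- segmentVessels(sc$image, "lectin")
  foot <- labelImage(vo) > 0
  m0 <- vesselMask(vo, 0)
  expect_identical(maskArray(m0), foot)
  m2 <- vesselMask(vo, 2)
  expect_gt(sum(maskArray(m2)), sum(foot))
  # bounded by the oracle disc dilation of the footprint
  expect_true(all(maskArray(m2) <= (oracleDilate(foot * 1, 2) > 0)))
  expect_true(all(foot <= maskArray(m2)))
})
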