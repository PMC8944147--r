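# Preprocessing and segmentation primitives.

test_that("rolling-ball subtraction removes flat background and keeps peaks", {
  flat <- matrix(50, 20, 20)
  expect_true(all(rollingBallSubtract(flat, radius = 5) == 0))

  # isolated bright pixel survives almost intact
  img <- matrix(0, 11, 11); img[6, 6] <- 100
  out <- rollingBallSubtract(img, radius = 5, pixelSize = 1)
  expect_equal(out[6, 6], 100, tolerance = 1e-8)
  expect_true(all(out[-61] == 0))

  # plane + small blob: blob retained, background gone
  img2 <- matrix(20, 41, 41)
  img2[20:22, 20:22] <- img2[20:22, 20:22] + 80
  out2 <- rollingBallSubtract(img2, radius = 10, pixelSize = 1)
  expect_gt(max(out2), 0.95 * 80)
  expect_lte(max(out2[img2 == 20]), 2)

  expect_error(rollingBallSubtract(flat, radius = 0.5, pixelSize = 1),
               "smaller than one pixel")
  expect_error(rollingBallSubtract(flat, radius = -1), "> 0")
})

test_that("rolling-ball subtraction equals input minus brute-force opening", {
  set.seed(42)
  for (k in 1:100) {
    r <- sample(1:4, 1)
    img <- matrix(runif(16 * 16, 0, 100), 16, 16)
    got <- rollingBallSubtract(img, radius = r, pixelSize = 1)
    want <- img - oracleOpening(img, r)
    expect_equal(got, want, tolerance = 1e-8)
    expect_true(all(got >= 0) && all(got <= img + 1e-12))
  }
})

test_that("smoothing has a physical sigma and conserves what it should", {
  img <- matrix(runif(100), 10, 10)
  expect_identical(smoothChannel(img, 0), img)
  expect_error(smoothChannel(img, -1), ">= 0")

  # delta impulse reproduces the sampled (normalised) Gaussian kernel
  d <- matrix(0, 31, 31); d[16, 16] <- 1
  got <- smoothChannel(d, sigma = 2, pixelSize = 1)
  r <- ceiling(3 * 2)
  g1 <- exp(-((-r:r)^2) / (2 * 4))
  kern <- outer(g1, g1); kern <- kern / sum(kern)
  expect_equal(got[(16 - r):(16 + r), (16 - r):(16 + r)], kern,
               tolerance = 1e-6)
  expect_equal(sum(got), 1, tolerance = 1e-6)

  # constants are preserved exactly, including at the boundary
  flat <- matrix(7, 15, 15)
  expect_equal(smoothChannel(flat, 2), flat, tolerance = 1e-9)

  # physical sigma: same result at half pixel size and doubled pixel sigma
  expect_equal(smoothChannel(d, sigma = 1, pixelSize = 0.5),
               smoothChannel(d, sigma = 2, pixelSize = 1), tolerance = 1e-12)
})

test_that("threshold rules split bimodal images and record provenance", {
  set.seed(7)
  ch <- matrix(c(rnorm(300, 10, 1), rnorm(100, 200, 5)), 20, 20)
  m <- thresholdChannel(ch, "intense")
  expect_identical(maskArray(m), ch > provenance(m)$threshold)
  # the intense mask covers exactly the bright-mode pixels
  expect_identical(maskArray(m), ch > 100)
  expect_identical(provenance(m)$rule, "intense")

  # the permissive all-vessel cut sits below the intense cut
  mv <- thresholdChannel(ch, "all_vessel")
  expect_lt(provenance(mv)$threshold, provenance(m)$threshold)
  expect_true(all(maskArray(m) <= maskArray(mv)))

  # fixed rule is literal
  fx <- matrix(c(50, 150, 50, 150), 2, 2)
  expect_identical(maskArray(thresholdChannel(fx, "fixed", value = 100)),
                   fx > 100)

  # constant channel: automatic rule warns and returns an empty mask
  expect_warning(e <- thresholdChannel(matrix(3, 5, 5), "intense"),
                 "constant")
  expect_false(any(maskArray(e)))
  expect_false(any(maskArray(
    thresholdChannel(matrix(0, 5, 5), "fixed", value = 1))))

  # monotone: raising a fixed threshold never adds pixels
  ch2 <- matrix(runif(400, 0, 10), 20, 20)
  m1 <- maskArray(thresholdChannel(ch2, "fixed", value = 3))
  m2 <- maskArray(thresholdChannel(ch2, "fixed", value = 6))
  expect_true(all(m2 <= m1))
})

test_that("automatic thresholds can be restricted to a tissue window", {
  # frame = dark glass + tissue plateau + bright blob; full-frame Otsu
  # splits glass vs tissue, tissue-restricted Otsu finds the blob
  ch <- matrix(0, 40, 40)
  tissue <- matrix(FALSE, 40, 40); tissue[12:29, 12:29] <- TRUE
  ch[tissue] <- 50
  ch[19:21, 19:21] <- 120
  mFull <- thresholdChannel(ch, "intense")
  mTissue <- thresholdChannel(ch, "intense", within = tissue)
  expect_gt(sum(maskArray(mFull)), 300)          # grabbed the whole island
  expect_identical(maskArray(mTissue), ch > 85)  # just the bright blob
})

test_that("connected-component labelling matches flood fill and EBImage", {
  # two disjoint squares
  m <- matrix(FALSE, 20, 20); m[2:6, 2:6] <- TRUE; m[10:14, 10:14] <- TRUE
  lo <- labelsFrom(m)
  expect_equal(nObjects(lo), 2L)
  expect_equal(objectTable(lo)$area_um2, c(25, 25))

  # diagonal touch: one object at 8-connectivity, two at 4
  d <- matrix(FALSE, 5, 5); d[2, 2] <- TRUE; d[3, 3] <- TRUE
  expect_equal(nObjects(labelsFrom(d, 8)), 1L)
  expect_equal(nObjects(labelsFrom(d, 4)), 2L)

  # empty mask
  expect_equal(nObjects(labelsFrom(matrix(FALSE, 4, 4))), 0L)

  # random masks agree with the flood-fill oracle under both connectivities
  set.seed(11)
  for (k in 1:50) {
    conn <- sample(c(4, 8), 1)
    mk <- randomMask(15, 15, runif(1, 0.2, 0.5))
    lab <- labelImage(labelsFrom(mk, conn))
    ref <- oracleLabel(mk, conn)
    expect_equal(max(lab), max(ref))
    # identical partition (labels may only differ by renaming)
    expect_true(all(tapply(ref[mk], lab[mk], function(v) length(unique(v))) == 1))
  }

  # 4-connectivity cross-check against EBImage::bwlabel (which joins only
  # edge-adjacent pixels)
  set.seed(12)
  for (k in 1:20) {
    mk <- randomMask(25, 25, 0.4)
    lab <- labelImage(labelsFrom(mk, 4))
    bw <- EBImage::imageData(EBImage::bwlabel(mk * 1))
    expect_equal(max(lab), max(bw))
    expect_true(all(tapply(bw[mk], lab[mk], function(v) length(unique(v))) == 1))
  }
})

test_that("size filtering keeps the window and relabels consistently", {
  m <- matrix(FALSE, 40, 120)
  m[2:4, 2:4] <- TRUE                 # ~9 um^2
  m[10:19, 10:19] <- TRUE             # 100 um^2
  m[25:39, 30:110] <- TRUE            # >1000 um^2
  lo <- labelsFrom(m)
  expect_equal(nObjects(lo), 3L)

  f <- filterBySize(lo, 20, 1000)
  expect_equal(nObjects(f), 1L)
  expect_equal(objectTable(f)$area_um2, 100)
  expect_equal(objectTable(f)$id, 1L)
  expect_equal(sort(unique(c(labelImage(f)))), c(0L, 1L))

  # identity bounds and idempotence
  all1 <- filterBySize(lo, 0, Inf)
  expect_equal(objectTable(all1), objectTable(lo))
  f2 <- filterBySize(f, 20, 1000)
  expect_equal(objectTable(f2), objectTable(f))

  # everything filtered out -> empty table and empty label image
  none <- filterBySize(lo, 1e6, Inf)
  expect_equal(nObjects(none), 0L)
  expect_true(all(labelImage(none) == 0L))
})

test_that("mask dilation uses a physical disc and is extensive", {
  m <- matrix(FALSE, 15, 15); m[8, 8] <- TRUE
  b <- BinaryMask(m, pixelSize = 1)
  expect_identical(maskArray(dilateMask(b, 0)), m)

  d3 <- dilateMask(b, 3)
  expect_equal(sum(maskArray(d3)), 37)   # disc of radius 3 px
  off <- oracleDisc(3)
  want <- matrix(FALSE, 15, 15)
  want[cbind(8 + off$dx, 8 + off$dy)] <- TRUE
  expect_identical(maskArray(d3), want)

  full <- BinaryMask(matrix(TRUE, 10, 10))
  expect_identical(maskArray(dilateMask(full, 4)), maskArray(full))

  # extensive and increasing in radius
  set.seed(5)
  mk <- BinaryMask(randomMask(20, 20, 0.1))
  d1 <- maskArray(dilateMask(mk, 1)); d2 <- maskArray(dilateMask(mk, 2))
  expect_true(all(maskArray(mk) <= d1))
  expect_true(all(d1 <= d2))
  expect_error(dilateMask(mk, -1), ">= 0")
})

test_that("physical measurements are stable under pixel-size re-expression", {
  # same disc at 1 um/px and upsampled 0.5 um/px: areas in um^2 agree
  img1 <- paintDisc(flatImage("MPO", c(64, 64), 0), "MPO", c(32, 32), 8, 100)
  m1 <- labelObjects(BinaryMask(getChannel(img1, "MPO") > 50, pixelSize = 1))
  img2 <- paintDisc(flatImage("MPO", c(128, 128), 0, pixelSize = 0.5), "MPO",
                    c(64, 64), 16, 100)
  m2 <- labelObjects(BinaryMask(getChannel(img2, "MPO") > 50, pixelSize = 0.5))
  expect_equal(objectTable(m1)$area_um2, objectTable(m2)$area_um2,
               tolerance = 0.05)
  expect_equal(objectTable(m1)$minor_axis_um, objectTable(m2)$minor_axis_um,
               tolerance = 0.05)
})
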