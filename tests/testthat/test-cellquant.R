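# Cell detection, touching colocalisation, compartments, pathology
# association and MPO load.

oneCellScene <- function(cells, seed = 5, shape = c(160, 160), ...) {
  generateScene(sceneSpec(imageShape = shape, seed = seed, cells = cells, ...))
}

test_that("touching colocalisation implements the gap rule symmetrically", {
  A <- matrix(FALSE, 20, 20); A[5:8, 5:8] <- TRUE
  B <- matrix(FALSE, 20, 20); B[8:11, 8:11] <- TRUE   # overlaps A at (8, 8)
  r <- touchingColocalise(labelsFrom(A), labelsFrom(B))
  expect_equal(nrow(pairTable(r)), 1L)
  expect_equal(r@coLabelled, 1L)

  # separated by >= 2 background pixels: not colocalised at maxGap 1
  C <- matrix(FALSE, 20, 20); C[11:14, 5:8] <- TRUE   # rows 9, 10 empty
  expect_equal(nrow(pairTable(
    touchingColocalise(labelsFrom(A), labelsFrom(C), maxGap = 1))), 0L)
  # ... but a single-pixel gap is bridged by maxGap 1
  D <- matrix(FALSE, 20, 20); D[10:13, 5:8] <- TRUE   # row 9 empty
  expect_equal(nrow(pairTable(
    touchingColocalise(labelsFrom(A), labelsFrom(D), maxGap = 1))), 1L)
  expect_equal(nrow(pairTable(
    touchingColocalise(labelsFrom(A), labelsFrom(D), maxGap = 0))), 0L)

  expect_error(touchingColocalise(labelsFrom(A),
                                  labelsFrom(matrix(FALSE, 10, 10))),
               "different shapes")
})

test_that("pair lists agree with the all-pairs distance oracle", {
  set.seed(33)
  for (k in 1:100) {
    conn <- sample(c(4L, 8L), 1)
    gap <- sample(0:2, 1)
    la <- labelImage(labelsFrom(randomMask(18, 18, 0.15), conn))
    lb <- labelImage(labelsFrom(randomMask(18, 18, 0.15), conn))
    got <- pairTable(touchingColocalise(
      labelObjects(BinaryMask(la > 0), conn),
      labelObjects(BinaryMask(lb > 0), conn), maxGap = gap,
      connectivity = conn))
    # relabel through the same path so ids are comparable
    laa <- labelImage(labelsFrom(la > 0, conn))
    lbb <- labelImage(labelsFrom(lb > 0, conn))
    want <- oraclePairs(laa, lbb, reach = gap + 1, connectivity = conn)
    gotm <- as.matrix(got); dimnames(gotm) <- NULL
    if (is.null(want)) {
      expect_equal(nrow(gotm), 0L)
    } else {
      expect_identical(gotm[order(gotm[, 1], gotm[, 2]), , drop = FALSE],
                       want[order(want[, 1], want[, 2]), , drop = FALSE])
    }
    # symmetry: swapping the sets transposes the pair list
    rev <- pairTable(touchingColocalise(
      labelObjects(BinaryMask(lb > 0), conn),
      labelObjects(BinaryMask(la > 0), conn), maxGap = gap,
      connectivity = conn))
    expect_identical(nrow(rev), nrow(got))
  }
})

test_that("neutrophils require both MPO and S100A8", {
  # co-expressing cell -> one neutrophil
  sc <- oneCellScene(list(cellSpec(c(80, 80))))
  cs <- detectNeutrophils(sc$image)
  expect_equal(sum(cellTable(cs)$class == "neutrophil"), 1L)

  # diffuse MPO-only deposit -> no neutrophil, one MPO-only object
  sc2 <- oneCellScene(list(cellSpec(c(80, 80), radius = 6,
                                    class = "mpo_deposit")))
  cs2 <- detectNeutrophils(sc2$image)
  expect_equal(sum(cellTable(cs2)$class == "neutrophil"), 0L)
  ov <- overlapSummary(overlapSummary(cs2))
  expect_equal(ov$a_only, 1L)
  expect_equal(ov$co_labelled, 0L)

  expect_error(detectNeutrophils(flatImage("MPO")), "S100A8")
})

test_that("NET calls need triple positivity and stay neutrophil-positive", {
  sc <- oneCellScene(list(cellSpec(c(50, 50), class = "NET", radius = 6),
                          cellSpec(c(110, 110))))
  cs <- detectNets(sc$image)
  tab <- cellTable(cs)
  expect_equal(sum(tab$class == "NET"), 1L)
  expect_equal(sum(tab$class == "neutrophil"), 1L)
  # every NET record carries the neutrophil marker pair
  nets <- tab[tab$class == "NET", ]
  expect_true(all(nets$mpo_pos & nets$s100a8_pos & nets$cith3_pos))

  # CitH3 without MPO/S100A8 is neither class
  sc2 <- oneCellScene(list(cellSpec(c(80, 80), class = "neutrophil",
                                    intensity = c(CitH3 = 90))))
  cs2 <- detectNets(sc2$image)
  expect_equal(nrow(cellTable(cs2)), 0L)

  expect_error(detectNets(flatImage(c("MPO", "S100A8"))), "CitH3")
})

test_that("compartment assignment intersects the vessel mask and conserves", {
  sc <- generateScene(sceneSpec(
    imageShape = c(200, 200), seed = 6,
    vessels = list(hTube(100, 14, 20, 180)),
    cells = list(cellSpec(c(60, 100), compartment = "intravascular"),
                 cellSpec(c(60, 40)), cellSpec(c(140, 160)))))
  cs <- detectNeutrophils(sc$image)
  vo <- segmentVessels(sc$image, "lectin")
  vm <- vesselMask(vo, 2)
  cs2 <- assignCompartment(cs, vm)
  tab <- cellTable(cs2)
  expect_equal(sum(tab$compartment == "vascular"), 1L)
  expect_equal(sum(tab$compartment == "vascular") +
               sum(tab$compartment == "extravascular"), nrow(tab))

  expect_error(assignCompartment(cs, BinaryMask(matrix(FALSE, 10, 10))),
               "shape")
})

test_that("pathology association follows touching with plaque precedence", {
  mpo <- matrix(FALSE, 30, 30); mpo[5:8, 5:8] <- TRUE; mpo[20:23, 20:23] <- TRUE
  pla <- matrix(FALSE, 30, 30); pla[8:12, 8:12] <- TRUE   # touches MPO 1
  tan <- matrix(FALSE, 30, 30); tan[4:6, 9:12] <- TRUE    # also touches MPO 1
  mo <- labelsFrom(mpo); po <- labelsFrom(pla); to <- labelsFrom(tan)
  a <- associatePathology(mo, po, to)
  a <- a[order(a$id), ]
  expect_equal(a$association, c("plaque", "none"))

  cfgT <- segmentationConfig(pathologyPrecedence = "tangle")
  expect_equal(associatePathology(mo, po, to, cfgT)$association[1], "tangle")

  # isolated deposit
  none <- associatePathology(labelsFrom(mpo), labelsFrom(matrix(FALSE, 30, 30)),
                             labelsFrom(matrix(FALSE, 30, 30)))
  expect_true(all(none$association == "none"))
})

test_that("MPO load partitions exactly and matches per-pixel counting", {
  # all objects inside the mask -> 100% vascular
  mpo <- matrix(FALSE, 30, 30); mpo[10:14, 10:14] <- TRUE
  vm <- BinaryMask(matrix(TRUE, 30, 30))
  r <- mpoLoad(NULL, labelsFrom(mpo), vm)
  expect_equal(vascularShare(r), 1)

  # two equal-area objects, one in, one out -> 50%
  mpo2 <- matrix(FALSE, 40, 40); mpo2[5:8, 5:8] <- TRUE; mpo2[30:33, 30:33] <- TRUE
  vm2 <- matrix(FALSE, 40, 40); vm2[1:20, ] <- TRUE
  r2 <- mpoLoad(NULL, labelsFrom(mpo2), BinaryMask(vm2))
  expect_equal(vascularShare(r2), 0.5)
  expect_equal(r2@vascular + r2@extravascular, r2@total)

  # zero total load: share reported absent, not 0/0
  r0 <- mpoLoad(NULL, labelsFrom(matrix(FALSE, 20, 20)),
                BinaryMask(matrix(TRUE, 20, 20)))
  expect_true(is.na(vascularShare(r0)))

  # random scenes against the per-pixel oracle
  set.seed(77)
  for (k in 1:100) {
    mm <- randomMask(20, 20, 0.25)
    vv <- randomMask(20, 20, 0.4)
    lo <- labelsFrom(mm)
    r3 <- mpoLoad(NULL, lo, BinaryMask(vv))
    msk <- labelImage(lo) > 0
    expect_equal(r3@total, sum(msk))
    expect_equal(r3@vascular, sum(msk & vv))
    expect_equal(r3@extravascular, sum(msk & !vv))
  }
})

test_that("extravascular load splits by association and sums exactly", {
  mpo <- matrix(FALSE, 40, 40)
  mpo[5:8, 5:8] <- TRUE      # will touch plaque
  mpo[20:23, 20:23] <- TRUE  # unassociated
  mpo[30:33, 5:8] <- TRUE    # inside vessel mask
  pla <- matrix(FALSE, 40, 40); pla[8:10, 8:10] <- TRUE
  vm <- matrix(FALSE, 40, 40); vm[28:36, 3:10] <- TRUE
  lo <- labelsFrom(mpo)
  assoc <- associatePathology(lo, labelsFrom(pla),
                              labelsFrom(matrix(FALSE, 40, 40)))
  r <- mpoLoad(NULL, lo, BinaryMask(vm), assoc)
  expect_equal(r@plaqueAssociated, 16)
  expect_equal(r@unassociated, 16)
  expect_equal(r@vascular, 16)
  expect_equal(r@plaqueAssociated + r@tangleAssociated + r@unassociated,
               r@extravascular)
})

test_that("growing the vessel mask never decreases the vascular share", {
  sc <- generateScene(sceneSpec(
    imageShape = c(200, 200), seed = 55,
    vessels = list(hTube(70, 10, 20, 180), hTube(140, 18, 20, 180)),
    cells = list(cellSpec(c(60, 70), compartment = "intravascular"),
                 cellSpec(c(100, 30)), cellSpec(c(160, 170)))))
  tm <- neutroquant:::tissueMask(sc$image)
  cfg <- segmentationConfig()
  lo <- neutroquant:::segmentMarker(sc$image, "MPO", "intense", cfg,
                                    20, Inf, tissue = tm)
  vo <- segmentVessels(sc$image, "lectin", cfg, tissue = tm)
  shares <- vapply(c(0, 1, 2, 4, 8), function(rad)
    vascularShare(mpoLoad(NULL, lo, vesselMask(vo, rad))), 0)
  expect_true(all(diff(shares) >= 0))
})
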