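diskMask <- function(radiusPx, cx = radiusPx + 3, cy = radiusPx + 3,
                     side = 2 * radiusPx + 6) {
  xs <- matrix(rep(seq_len(side) - 0.5, each = side), side)
  ys <- matrix(rep(seq_len(side) - 0.5, times = side), side)
  (xs - cx)^2 + (ys - cy)^2 <= radiusPx^2
}

test_that("area and ECD follow their defining formulas", {
  expect_equal(areaNm2(100, 0.5), 25)
  expect_equal(areaNm2(1, 1), 1)
  expect_equal(areaNm2(84, 0.5), 21)
  expect_equal(ecd(pi), 2)
  expect_equal(ecd(21.1), 5.18318, tolerance = 1e-6)
  expect_error(ecd(0), "positive")
  expect_error(ecd(-3), "positive")
})

test_that("moment ellipse fit is exact on rectangles and round on disks", {
  # solid 40 x 10 px rectangle: axis ratio equals the side ratio exactly
  rect <- matrix(FALSE, 20, 50)
  rect[6:15, 6:45] <- TRUE
  f <- fitEllipse(rect)
  expect_equal(f$b / f$a, 0.25, tolerance = 1e-12)
  expect_equal(f$orientation, 0)
  # area-preserving normalization
  expect_equal(pi * (f$a / 2) * (f$b / 2), 400, tolerance = 1e-9)
  # digitized disk: nearly unit axis ratio
  f2 <- fitEllipse(diskMask(12))
  expect_gte(f2$b / f2$a, 0.99)
  # one pixel: both axes equal the ECD of a single pixel
  one <- matrix(c(TRUE), 1, 1)
  f3 <- fitEllipse(one, nmPerPx = 2)
  expect_equal(f3$a, ecd(4))
  expect_equal(f3$b, ecd(4))
})

test_that("ellipse fit is equivariant under 90-degree rotation", {
  set.seed(21)
  mask <- randomRegion(21, 40)
  rot <- t(mask)[, nrow(mask):1, drop = FALSE]  # rotate 90 degrees
  f <- fitEllipse(mask); fr <- fitEllipse(rot)
  expect_equal(fr$a, f$a, tolerance = 1e-12)
  expect_equal(fr$b, f$b, tolerance = 1e-12)
  shift <- abs(fr$orientation - f$orientation) %% pi
  expect_equal(min(shift, pi - shift), pi / 2, tolerance = 1e-9)
})

test_that("Feret diameter equals the exact hull caliper on known shapes", {
  one <- matrix(TRUE, 1, 1)
  expect_equal(feretMax(one), sqrt(2))
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  expect_equal(feretMax(sq), 10 * sqrt(2))
  line <- matrix(FALSE, 5, 24); line[3, 3:22] <- TRUE
  expect_equal(feretMax(line, nmPerPx = 0.5), sqrt(10^2 + 0.5^2))
})

test_that("rotating calipers equals brute-force pairwise maximum exactly", {
  for (seed in 1:40) {
    mask <- randomRegion(seed)
    corners <- pixelCorners(mask)
    expect_identical(feretMax(mask), bruteFeretPx(corners))
  }
})

test_that("ratios validate their domains", {
  expect_equal(rar(10, 6.4), 0.64)
  expect_equal(rar(7, 7), 1)
  expect_error(rar(10, 0), "a >= b > 0")
  expect_error(rar(5, 6), "a >= b > 0")
  expect_equal(fmr(13.7, 10), 1.37)
  expect_error(fmr(10, 0), "major axis")
  expect_error(fmr(0, 10), "Feret")
})

test_that("shape classes tile (0.12, 1] with upper-inclusive boundaries", {
  expect_equal(as.character(classifyShape(0.64)), "rounded")
  expect_equal(as.character(classifyShape(0.79)), "very rounded")
  expect_equal(as.character(classifyShape(1.0)), "very rounded")
  # a printed boundary belongs to the lower class
  expect_equal(as.character(classifyShape(c(0.17, 0.25, 0.35, 0.49, 0.70))),
               c("very angular", "angular", "sub-angular", "sub-rounded",
                 "rounded"))
  expect_equal(as.character(classifyShape(0.12)), "out of scale")
  expect_equal(as.character(classifyShape(0.05)), "out of scale")
  expect_error(classifyShape(0), "\\(0, 1]")
  expect_error(classifyShape(1.2), "\\(0, 1]")
  tab <- shapeClassTable()
  expect_equal(nrow(tab), 6)
  expect_equal(tab$rar_min[-1], tab$rar_max[-6])  # touching bounds
})

test_that("morphometrics scale correctly with the calibration", {
  set.seed(31)
  mask <- randomRegion(31, 48)
  cfg <- segmentationConfig(50, minAreaPx = 1, excludeEdges = FALSE)
  t1 <- particleTable(measureParticles(extractParticles(
    maskMicrograph(mask, 1), cfg, mask = mask)))
  tk <- particleTable(measureParticles(extractParticles(
    maskMicrograph(mask, 2.5), cfg, mask = mask)))
  k <- 2.5
  expect_equal(tk$ecd_nm, t1$ecd_nm * k)
  expect_equal(tk$a_nm, t1$a_nm * k)
  expect_equal(tk$b_nm, t1$b_nm * k)
  expect_equal(tk$feret_nm, t1$feret_nm * k)
  expect_equal(tk$area_nm2, t1$area_nm2 * k^2)
  expect_equal(tk$rar, t1$rar)
  expect_equal(tk$fmr, t1$fmr)
  expect_identical(tk$shape_class, t1$shape_class)
})

test_that("FMR of digitized disks stays at or above one", {
  cfg <- segmentationConfig(50, minAreaPx = 1, excludeEdges = FALSE)
  for (r in c(5, 10, 15, 20)) {
    mask <- diskMask(r)
    tab <- particleTable(measureParticles(extractParticles(
      maskMicrograph(mask), cfg, mask = mask)))
    expect_gte(tab$fmr, 1)
    # corner-caliper excess shrinks with size for well-resolved disks
    if (r >= 15) expect_lte(tab$fmr, 1.05)
  }
  # elongated blocky shapes are the documented exception: the area-preserving
  # moment ellipse's major axis can exceed the hull caliper
  rect <- matrix(FALSE, 20, 40); rect[5:14, 5:34] <- TRUE
  tab <- particleTable(measureParticles(extractParticles(
    maskMicrograph(rect), cfg, mask = rect)))
  expect_equal(tab$fmr, tab$feret_nm / tab$a_nm)
  expect_gte(tab$fmr, 0.9)
})

test_that("measured ECD satisfies the area identity on real extractions", {
  sc <- diskGridScene(runif(9, 3, 6), pitchNm = 25, noiseSd = 4, seed = 14,
                      perRow = 3L)
  r <- renderScene(sc, 0.5, seed = 15)
  ps <- measureParticles(extractParticles(
    r$micrograph, segmentationConfig(suggestThreshold(r$micrograph),
                                     minAreaPx = 20)))
  tab <- particleTable(ps)
  expect_gt(nrow(tab), 0)
  expect_equal(tab$ecd_nm, sqrt(4 * tab$area_nm2 / pi), tolerance = 1e-9)
  expect_equal(pi * (tab$a_nm / 2) * (tab$b_nm / 2), tab$area_nm2,
               tolerance = 1e-6)
})
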