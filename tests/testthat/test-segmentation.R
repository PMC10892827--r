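test_that("percentile thresholding follows the histogram definition", {
  # two-level image: half gray 0, half gray 255; TH 50 selects the dark half
  px <- matrix(c(rep(0, 50), rep(255, 50)), 10, 10)
  m <- Micrograph(px, 1)
  mask <- thresholdMask(m, 50, "dark")
  expect_identical(mask, px == 0)
  # TH 100 marks everything; a constant image is all-foreground for any TH
  expect_true(all(thresholdMask(m, 100, "dark")))
  flat <- Micrograph(matrix(128, 8, 8), 1)
  expect_true(all(thresholdMask(flat, 1, "dark")))
  expect_true(all(thresholdMask(flat, 60, "dark")))
  # light polarity mirrors the rule
  expect_identical(thresholdMask(m, 50, "light"), px == 255)
  expect_error(thresholdMask(Micrograph(matrix(0, 0, 0), 1), 50),
               "empty image")
  expect_error(thresholdMask(m, 0), "\\(0, 100]")
})

test_that("foreground pixel count is nondecreasing in the threshold", {
  set.seed(13)
  m <- Micrograph(matrix(sample(0:255, 900, replace = TRUE), 30, 30), 1)
  counts <- vapply(c(1, 5, 10, 25, 50, 75, 100),
                   function(th) sum(thresholdMask(m, th)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("a clean interior square survives extraction intact", {
  mask <- matrix(FALSE, 30, 30)
  mask[10:19, 8:17] <- TRUE
  m <- maskMicrograph(mask)
  ps <- extractParticles(m, segmentationConfig(50, minAreaPx = 50),
                         mask = mask)
  tab <- particleTable(ps)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$pixel_count, 100)
  expect_equal(tab$cx_nm, 12)  # columns 8..17, centers 7.5..16.5
  expect_equal(tab$cy_nm, 14)
  expect_false(tab$touches_edge)
})

test_that("include-holes absorbs interior background into the region", {
  mask <- matrix(FALSE, 15, 15)
  mask[4:12, 4:12] <- TRUE   # 9x9 square
  mask[8:10, 8:10] <- FALSE  # 3x3 hole
  m <- maskMicrograph(mask)
  cfg <- segmentationConfig(50, minAreaPx = 10)
  tab <- particleTable(extractParticles(m, cfg, mask = mask))
  expect_equal(tab$pixel_count, 81)
  expect_equal(tab$holes_filled_px, 9)
  noFill <- segmentationConfig(50, minAreaPx = 10, includeHoles = FALSE)
  expect_equal(particleTable(extractParticles(m, noFill,
                                              mask = mask))$pixel_count, 72)
})

test_that("components touching the border are excluded when configured", {
  mask <- matrix(FALSE, 20, 20)
  mask[1:5, 3:7] <- TRUE     # touches row 1
  mask[10:14, 10:14] <- TRUE # interior
  m <- maskMicrograph(mask)
  cfg <- segmentationConfig(50, minAreaPx = 1)
  ps <- extractParticles(m, cfg, mask = mask)
  expect_equal(nrow(particleTable(ps)), 1)
  expect_false(any(particleTable(ps)$touches_edge))
  lab <- labelMatrix(ps)
  expect_true(all(lab[1, ] == 0) && all(lab[, 1] == 0) &&
              all(lab[20, ] == 0) && all(lab[, 20] == 0))
  keepAll <- segmentationConfig(50, minAreaPx = 1, excludeEdges = FALSE)
  expect_equal(nrow(particleTable(extractParticles(m, keepAll,
                                                   mask = mask))), 2)
})

test_that("connectivity setting separates or joins diagonal neighbors", {
  mask <- matrix(FALSE, 8, 8)
  mask[3, 3] <- TRUE; mask[4, 4] <- TRUE
  m <- maskMicrograph(mask)
  n8 <- nrow(particleTable(extractParticles(
    m, segmentationConfig(50, minAreaPx = 1, connectivity = 8),
    mask = mask)))
  n4 <- nrow(particleTable(extractParticles(
    m, segmentationConfig(50, minAreaPx = 1, connectivity = 4),
    mask = mask)))
  expect_equal(n8, 1)
  expect_equal(n4, 2)
})

test_that("component labeling agrees with brute-force flood fill", {
  for (seed in 1:12) {
    set.seed(seed)
    ny <- sample(5:64, 1); nx <- sample(5:64, 1)
    mask <- matrix(runif(ny * nx) < runif(1, 0.2, 0.6), ny, nx)
    for (conn in c(4L, 8L)) {
      got <- nanoPSD:::labelComponents(mask, conn)
      want <- floodLabel(mask, conn)
      expect_equal(max(got), max(want))
      expect_identical(labelPartition(got), labelPartition(want))
    }
  }
})

test_that("every surviving foreground pixel belongs to exactly one region", {
  set.seed(77)
  mask <- matrix(runif(64 * 64) < 0.4, 64, 64)
  m <- maskMicrograph(mask)
  cfg <- segmentationConfig(50, minAreaPx = 3)
  ps <- extractParticles(m, cfg, mask = mask)
  lab <- labelMatrix(ps)
  tab <- particleTable(ps)
  expect_equal(sum(lab > 0), sum(tab$pixel_count))
  expect_equal(tabulate(lab[lab > 0], nrow(tab)), tab$pixel_count)
  # ids are row-major by centroid
  expect_false(is.unsorted(order(tab$cy_nm, tab$cx_nm)))
})

test_that("region ids are ordered row-major by centroid", {
  mask <- matrix(FALSE, 20, 40)
  mask[12:14, 3:5] <- TRUE   # lower-left
  mask[3:5, 30:32] <- TRUE   # upper-right
  mask[3:5, 10:12] <- TRUE   # upper-left
  tab <- particleTable(extractParticles(
    maskMicrograph(mask), segmentationConfig(50, minAreaPx = 1),
    mask = mask))
  expect_equal(tab$cy_nm, sort(tab$cy_nm))
  expect_lt(tab$cx_nm[1], tab$cx_nm[2])
})

test_that("restriction sweep counts inclusively and is monotone", {
  areas <- c(10, 30, 50, 200)
  sw <- restrictionSweep(areas, list(c(26, 160), c(0, Inf), c(30, 160),
                                     c(40, 160)))
  expect_equal(sw$hit_count, c(2, 4, 2, 1))
  expect_equal(sw$ids[[1]], c(2, 3))
  # inclusive bounds
  expect_equal(restrictionSweep(c(26, 160), list(c(26, 160)))$hit_count, 2)
  # nested intervals can never gain hits
  set.seed(4)
  av <- runif(60, 0, 300)
  nests <- list(c(26, 160), c(30, 160), c(40, 160), c(40, 120))
  hits <- restrictionSweep(av, nests)$hit_count
  expect_true(all(diff(hits) <= 0))
  expect_error(restrictionSweep(areas, list(c(160, 26))),
               "invalid interval \\(160, 26\\)")
})
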