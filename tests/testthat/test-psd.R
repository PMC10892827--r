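test_that("summary statistics match the two-point closed form", {
  sm <- summarizePSD(c(2, 4), metric = "ecd_nm")
  expect_equal(sm@n, 2L)
  expect_equal(sm@mean, 3)
  expect_equal(sm@se, 1)  # sd sqrt(2) / sqrt(2)
  expect_equal(sum(sm@counts), 2)
})

test_that("histogram bookkeeping holds on random populations", {
  for (seed in 1:6) {
    set.seed(seed)
    v <- rlnorm(sample(3:200, 1), meanlog = 1.2, sdlog = 0.5)
    sm <- summarizePSD(v, metric = "ecd_nm", binWidth = runif(1, 0.3, 2))
    expect_equal(sum(sm@counts), length(v))
    expect_false(is.unsorted(sm@cumulativePercent))
    expect_equal(sm@cumulativePercent[length(sm@cumulativePercent)], 100)
    # brute-force two-pass mean / SE
    expect_equal(sm@mean, sum(v) / length(v))
    expect_equal(sm@se,
                 sqrt(sum((v - mean(v))^2) / (length(v) - 1)) /
                   sqrt(length(v)))
    p <- sm@percentiles
    expect_false(is.unsorted(p[c("p10", "p25", "p75", "p90")]))
    # every value lands in the half-open bin containing it
    idx <- findInterval(v, sm@breaks)
    expect_true(all(idx >= 1 & idx <= length(sm@counts)))
  }
})

test_that("degenerate populations are flagged, not fatal", {
  e <- summarizePSD(numeric(0), metric = "rar")
  expect_equal(e@n, 0L)
  expect_true("empty" %in% e@flags)
  s1 <- summarizePSD(5.2, metric = "ecd_nm")
  expect_equal(s1@se, 0)
  expect_true("single-particle-se" %in% s1@flags)
  expect_error(summarizePSD(1:3, metric = "volume"), "'arg' should be one of")
  expect_error(summarizePSD(1:3, metric = "rar", binWidth = 0), "positive")
})

test_that("identical noiseless disks give a one-bin distribution", {
  sc <- diskGridScene(rep(2.5, 25), pitchNm = 15, seed = 5, perRow = 5L)
  r <- renderScene(sc, 0.5, seed = 6)
  ps <- measureParticles(extractParticles(
    r$micrograph, segmentationConfig(suggestThreshold(r$micrograph),
                                     minAreaPx = 20)))
  sm <- summarizePSD(ps, metric = "ecd_nm", binWidth = 1)
  expect_equal(sm@n, 25L)
  # identical particles on an integer pixel grid digitize identically
  expect_lte(sum(sm@counts > 0), 2)
  expect_lte(sm@se, 0.1)
})

test_that("shape breakdown percentages cover the six classes", {
  b <- shapeBreakdown(rep("very rounded", 4))
  expect_equal(unname(b$percent["very rounded"]), 100)
  expect_equal(sum(b$percent), 100)
  b2 <- shapeBreakdown(c("rounded", "rounded", "very rounded", "sub-rounded"))
  expect_equal(unname(b2$percent[c("rounded", "very rounded", "sub-rounded")]),
               c(50, 25, 25))
  expect_equal(sum(b2$percent), 100)
  b3 <- shapeBreakdown(character(0))
  expect_true(b3$empty)
  expect_equal(sum(b3$percent), 0)
  # out-of-scale values are excluded from the six-class percentages
  b4 <- shapeBreakdown(c("rounded", "out of scale"))
  expect_equal(unname(b4$percent["rounded"]), 100)
  expect_equal(b4$out_of_scale, 1L)
  expect_error(shapeBreakdown("roundish"), "unknown shape class")
})

test_that("a whole-image window reproduces the global segmentation", {
  sc <- diskGridScene(runif(9, 2, 4), pitchNm = 25, seed = 8, perRow = 3L)
  r <- renderScene(sc, 0.5, seed = 9)
  m <- r$micrograph
  th <- suggestThreshold(m)
  cfg <- segmentationConfig(th, minAreaPx = 20)
  globalTab <- particleTable(measureParticles(extractParticles(m, cfg)))
  d <- dim(pixels(m)) * nmPerPx(m)
  res <- localPSD(m, list(localWindow(c(0, 0), d[2], d[1])), cfg)
  expect_equal(res[[1]]$particles, globalTab, tolerance = 1e-12)
})

test_that("windows report their own particle sets and echo run fields", {
  radii <- c(rep(2.5, 4), rep(3.5, 2))
  set.seed(2)
  parts <- c(
    lapply(1:4, function(i) diskParticle(10 + 20 * ((i - 1) %% 2),
                                         15 + 20 * ((i - 1) %/% 2), 2.5)),
    lapply(1:2, function(i) diskParticle(70 + 15 * i, 30, 3.5)))
  sc <- buildScene(sceneSpec(120, 70, parts, noiseSd = 0,
    background = backgroundSpec(gradientAmplitude = 0, textureAmplitude = 0)))
  r <- renderScene(sc, 0.5, seed = 3)
  # fixed low TH: the noiseless two-level histogram puts the cutoff on the
  # fully covered particle gray both globally and inside every window
  cfg <- segmentationConfig(1, minAreaPx = 20)
  wins <- list(localWindow(c(0, 0), 55, 55),
               localWindow(c(60, 10), 55, 40, minAreaPx = 30))
  res <- localPSD(r$micrograph, wins, cfg)
  expect_equal(res[[1]]$n, 4L)
  expect_equal(res[[2]]$n, 2L)
  expect_equal(res[[2]]$min_area_px, 30L)
  tab <- localPSDTable(res)
  expect_equal(tab$n, c(4L, 2L))
  expect_equal(tab$x_nm, c(0, 60))
  # particle metrics agree with the global run for wholly contained particles
  globalTab <- particleTable(measureParticles(extractParticles(
    r$micrograph, cfg)))
  w1 <- res[[1]]$particles
  for (i in seq_len(nrow(w1))) {
    j <- which(abs(globalTab$cx_nm - w1$cx_nm[i]) < 1e-9 &
               abs(globalTab$cy_nm - w1$cy_nm[i]) < 1e-9)
    expect_length(j, 1)
    for (col in c("area_nm2", "ecd_nm", "a_nm", "b_nm", "feret_nm", "rar",
                  "fmr"))
      expect_equal(w1[[col]][i], globalTab[[col]][j], tolerance = 1e-9)
  }
})

test_that("an empty window yields a valid n = 0 summary", {
  sc <- buildScene(sceneSpec(100, 100, list(diskParticle(80, 80, 4)),
    noiseSd = 0,
    background = backgroundSpec(gradientAmplitude = 0, textureAmplitude = 0)))
  r <- renderScene(sc, 0.5, seed = 1)
  cfg <- segmentationConfig(suggestThreshold(r$micrograph), minAreaPx = 20)
  res <- localPSD(r$micrograph, list(localWindow(c(0, 0), 40, 40)), cfg)
  expect_equal(res[[1]]$n, 0L)
  expect_true("empty" %in% res[[1]]$summary@flags)
  expect_error(
    localPSD(r$micrograph, list(localWindow(c(80, 80), 50, 50)), cfg),
    "window at \\(80, 80\\) nm.*outside")
})

test_that("random window sampling is reproducible and in-bounds", {
  m <- Micrograph(matrix(128, 100, 200), 10)  # 2000 x 1000 nm
  w1 <- sampleWindows(m, count = 5, sizeNm = 500, seed = 42)
  w2 <- sampleWindows(m, count = 5, sizeNm = 500, seed = 42)
  expect_identical(w1, w2)
  for (w in w1) {
    expect_gte(w$originNm[1], 0)
    expect_lte(w$originNm[1] + w$widthNm, 2000)
    expect_lte(w$originNm[2] + w$heightNm, 1000)
  }
  expect_error(sampleWindows(m, sizeNm = 5000), "exceeds")
})
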