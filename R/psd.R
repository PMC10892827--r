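# Global and windowed particle-size distributions and shape-class breakdowns.

defaultBinWidth <- function(metric) {
  switch(metric, ecd_nm = 1, area_nm2 = 10, rar = 0.05, fmr = 0.05,
         stop("unknown metric: ", metric))
}

#' Summarize a particle metric into a PSD
#'
#' Builds the distribution report used for particle populations: count N,
#' arithmetic mean, standard error of the mean (sample standard deviation,
#' n - 1 denominator, divided by sqrt(n)), a histogram over half-open bins
#' [lo, lo + w), the per-bin cumulative percentage, and the 10/25/75/90th
#' percentiles (linear interpolation).
#'
#' @param x a measured [ParticleSet-class] or a numeric vector of metric
#'   values.
#' @param metric one of \code{"ecd_nm"}, \code{"area_nm2"}, \code{"rar"},
#'   \code{"fmr"} (ignored when \code{x} is numeric, except as a label).
#' @param binWidth histogram bin width; defaults: 1 nm for ECD, 10 nm^2 for
#'   area, 0.05 for RAR/FMR.
#' @return A [PSDSummary-class]. An empty input yields a valid summary
#'   flagged \code{"empty"}; a single particle reports SE 0 with flag
#'   \code{"single-particle-se"} so report tables stay rectangular.
#' @examples
#' summarizePSD(c(2, 4), metric = "ecd_nm")  # mean 3, SE 1
#' @export
summarizePSD <- function(x, metric = c("ecd_nm", "area_nm2", "rar", "fmr"),
                         binWidth = NULL) {
  metric <- match.arg(metric)
  v <- if (is(x, "ParticleSet")) {
    tab <- particleTable(x)
    if (!metric %in% names(tab))
      stop("metric ", metric, " not present; run measureParticles() first")
    tab[[metric]]
  } else as.numeric(x)
  if (is.null(binWidth)) binWidth <- defaultBinWidth(metric)
  if (binWidth <= 0) stop("binWidth must be positive")
  n <- length(v)
  if (n == 0)
    return(new("PSDSummary", metric = metric, n = 0L, mean = NA_real_,
               se = NA_real_, breaks = numeric(0), counts = integer(0),
               cumulativePercent = numeric(0),
               percentiles = c(p10 = NA_real_, p25 = NA_real_,
                               p75 = NA_real_, p90 = NA_real_),
               flags = "empty"))
  lo <- floor(min(v) / binWidth) * binWidth
  hi <- floor(max(v) / binWidth) * binWidth + binWidth
  breaks <- seq(lo, hi, by = binWidth)
  counts <- tabulate(findInterval(v, breaks), length(breaks) - 1L)
  flags <- character(0)
  se <- if (n >= 2) stats::sd(v) / sqrt(n) else {
    flags <- "single-particle-se"
    0
  }
  q <- stats::quantile(v, c(0.10, 0.25, 0.75, 0.90), type = 7, names = FALSE)
  new("PSDSummary", metric = metric, n = as.integer(n), mean = mean(v),
      se = se, breaks = breaks, counts = as.integer(counts),
      cumulativePercent = cumsum(counts) / n * 100,
      percentiles = c(p10 = q[1], p25 = q[2], p75 = q[3], p90 = q[4]),
      flags = flags)
}

#' Shape-class breakdown
#'
#' Percentages over the six roundness classes. Out-of-scale values (RAR at or
#' below 0.12) are excluded from the six percentages and reported separately;
#' for nonempty in-scale input the six percentages sum to 100.
#'
#' @param classes factor/character vector of shape classes (see
#'   [classifyShape()]), or a measured [ParticleSet-class].
#' @return \code{list(percent, counts, n, out_of_scale, empty)}: named
#'   six-class percentage and count vectors, the in-scale count, the
#'   out-of-scale count, and an empty flag.
#' @export
shapeBreakdown <- function(classes) {
  if (is(classes, "ParticleSet")) {
    tab <- particleTable(classes)
    if (!"shape_class" %in% names(tab))
      stop("run measureParticles() first")
    classes <- tab$shape_class
  }
  cls <- factor(as.character(classes),
                levels = c(shapeClassLevels, "out of scale"))
  if (anyNA(cls)) stop("unknown shape class label")
  counts <- table(cls)
  oos <- as.integer(counts[["out of scale"]])
  counts <- counts[shapeClassLevels]
  n <- sum(counts)
  pct <- if (n > 0) 100 * as.numeric(counts) / n else rep(0, 6)
  names(pct) <- shapeClassLevels
  list(percent = pct, counts = stats::setNames(as.integer(counts),
                                               shapeClassLevels),
       n = as.integer(n), out_of_scale = oos, empty = n == 0)
}

#' Define a local analysis window
#'
#' @param originNm window top-left corner (x, y) in scene nm coordinates.
#' @param widthNm,heightNm window extent, nm (default 500 x 500).
#' @param thPercent optional threshold override for this window; by default
#'   the window is re-thresholded with the base configuration's TH on its own
#'   local histogram.
#' @param minAreaPx optional lower particle limit override.
#' @return A window specification list.
#' @export
localWindow <- function(originNm, widthNm = 500, heightNm = 500,
                        thPercent = NULL, minAreaPx = NULL) {
  stopifnot(length(originNm) == 2, widthNm > 0, heightNm > 0)
  list(originNm = as.numeric(originNm), widthNm = widthNm,
       heightNm = heightNm, thPercent = thPercent, minAreaPx = minAreaPx)
}

#' Randomly placed square windows
#'
#' Reproducible stand-in for manually chosen analysis regions: samples
#' \code{count} window origins uniformly such that each window lies inside
#' the micrograph.
#'
#' @param m a [Micrograph-class].
#' @param count number of windows.
#' @param sizeNm window side length, nm (default 500).
#' @param seed integer seed.
#' @return List of [localWindow()] specifications.
#' @export
sampleWindows <- function(m, count = 5, sizeNm = 500, seed = 1L) {
  d <- dim(pixels(m)) * nmPerPx(m)  # (height, width) nm
  if (sizeNm > d[2] || sizeNm > d[1])
    stop("window size exceeds the micrograph extent")
  withSeed(seed, {
    xs <- stats::runif(count, 0, d[2] - sizeNm)
    ys <- stats::runif(count, 0, d[1] - sizeNm)
  })
  off <- offsetNm(m)
  lapply(seq_len(count), function(i)
    localWindow(c(off[1] + xs[i], off[2] + ys[i]), sizeNm, sizeNm))
}

# nm-space window -> pixel index ranges of the pixels fully inside it
windowToPx <- function(m, win) {
  npp <- nmPerPx(m)
  off <- offsetNm(m)
  d <- dim(pixels(m))
  eps <- 1e-9 * npp
  x0 <- win$originNm[1] - off[1]; y0 <- win$originNm[2] - off[2]
  ix0 <- floor(x0 / npp + eps) + 1L
  ix1 <- floor((x0 + win$widthNm) / npp + eps)
  iy0 <- floor(y0 / npp + eps) + 1L
  iy1 <- floor((y0 + win$heightNm) / npp + eps)
  if (x0 < -eps || y0 < -eps || ix1 > d[2] || iy1 > d[1] || ix0 > ix1 ||
      iy0 > iy1)
    stop(sprintf(
      "window at (%g, %g) nm of %g x %g nm lies outside the micrograph",
      win$originNm[1], win$originNm[2], win$widthNm, win$heightNm))
  list(ix = ix0:ix1, iy = iy0:iy1)
}

#' Local (windowed) particle-size distributions
#'
#' Crops each window out of the micrograph, segments it with the base
#' configuration (threshold recomputed on the window's own gray histogram,
#' with optional per-window TH and lower-pixel-limit overrides), measures the
#' particles, and summarizes the chosen metric. Edge exclusion applies to the
#' window borders, so particles straddling a window edge are dropped.
#'
#' @param m a [Micrograph-class].
#' @param windows list of [localWindow()] specifications.
#' @param cfg base [segmentationConfig()].
#' @param metric,binWidth summary metric and bin width, see [summarizePSD()].
#' @return List with one entry per window:
#'   \code{list(window, th_percent, min_area_px, n, mean, se, summary,
#'   particles)} where \code{particles} is the measured per-window particle
#'   table (nm coordinates scene-absolute) and \code{summary} a
#'   [PSDSummary-class].
#' @export
localPSD <- function(m, windows, cfg, metric = "area_nm2", binWidth = NULL) {
  stopifnot(is(m, "Micrograph"), inherits(cfg, "SegmentationConfig"))
  lapply(seq_along(windows), function(i) {
    win <- windows[[i]]
    px <- windowToPx(m, win)
    sub <- preprocess(m, crop = c(px$ix[1] - 1L, px$iy[1] - 1L,
                                  length(px$ix), length(px$iy)))
    wcfg <- cfg
    if (!is.null(win$thPercent)) wcfg$thPercent <- win$thPercent
    if (!is.null(win$minAreaPx)) wcfg$minAreaPx <- as.integer(win$minAreaPx)
    ps <- measureParticles(extractParticles(sub, wcfg))
    sm <- summarizePSD(ps, metric = metric, binWidth = binWidth)
    list(window = win, th_percent = wcfg$thPercent,
         min_area_px = wcfg$minAreaPx, n = sm@n, mean = sm@mean, se = sm@se,
         summary = sm, particles = particleTable(ps))
  })
}

#' One-row-per-window report table for local PSDs
#'
#' Echoes the fields reported alongside windowed distributions: threshold,
#' mean with standard error, particle count, lower pixel limit, and the
#' window's (x, y) origin.
#'
#' @param results return value of [localPSD()].
#' @return data.frame with one row per window.
#' @export
localPSDTable <- function(results) {
  do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(window = i, x_nm = r$window$originNm[1],
               y_nm = r$window$originNm[2], width_nm = r$window$widthNm,
               height_nm = r$window$heightNm, th_percent = r$th_percent,
               min_area_px = r$min_area_px, n = r$n, mean = r$mean,
               se = r$se)
  }))
}
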