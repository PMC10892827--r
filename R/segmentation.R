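# Micrograph -> particle regions: percentile thresholding, connected
# components under 4- or 8-connectivity, hole inclusion, edge exclusion, and
# area restriction.

#' Segmentation configuration
#'
#' @param thPercent threshold percentage in (0, 100]; see [thresholdMask()].
#' @param polarity \code{"dark"} (particles darker than background; the
#'   bright-field TEM case) or \code{"light"}.
#' @param connectivity 4 or 8 (default 8, the usual particle-analysis
#'   convention for contiguous pixels).
#' @param includeHoles fill interior background holes of each region
#'   (default TRUE).
#' @param excludeEdges drop regions touching the image border (default TRUE).
#' @param minAreaPx discard components below this pixel count (default 50,
#'   the lower particle limit used for automatic runs; set smaller for
#'   coarse calibrations where real particles cover few pixels).
#' @param minAreaNm2,maxAreaNm2 optional inclusive physical-area restriction
#'   in nm^2 (e.g. the 26-160 nm^2 band used to separate small particles from
#'   cellular components of similar gray value).
#' @return A validated configuration list of class \code{SegmentationConfig}.
#' @export
segmentationConfig <- function(thPercent, polarity = c("dark", "light"),
                               connectivity = 8L, includeHoles = TRUE,
                               excludeEdges = TRUE, minAreaPx = 50L,
                               minAreaNm2 = NULL, maxAreaNm2 = NULL) {
  polarity <- match.arg(polarity)
  if (length(thPercent) != 1 || !is.finite(thPercent) ||
      thPercent <= 0 || thPercent > 100)
    stop("thPercent must lie in (0, 100]")
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  if (minAreaPx < 0) stop("minAreaPx must be >= 0")
  if (!is.null(minAreaNm2) && !is.null(maxAreaNm2) &&
      minAreaNm2 >= maxAreaNm2)
    stop("minAreaNm2 must be below maxAreaNm2")
  structure(list(
    thPercent = thPercent, polarity = polarity,
    connectivity = as.integer(connectivity),
    includeHoles = isTRUE(includeHoles), excludeEdges = isTRUE(excludeEdges),
    minAreaPx = as.integer(minAreaPx),
    minAreaNm2 = minAreaNm2, maxAreaNm2 = maxAreaNm2
  ), class = "SegmentationConfig")
}

#' @export
print.SegmentationConfig <- function(x, ...) {
  cat(sprintf(
    "SegmentationConfig: TH %.3g%% (%s), conn %d, holes %s, edges %s, min %d px",
    x$thPercent, x$polarity, x$connectivity,
    if (x$includeHoles) "filled" else "kept",
    if (x$excludeEdges) "excluded" else "kept", x$minAreaPx))
  if (!is.null(x$minAreaNm2) || !is.null(x$maxAreaNm2))
    cat(sprintf(", area [%s, %s] nm2",
                if (is.null(x$minAreaNm2)) "0" else x$minAreaNm2,
                if (is.null(x$maxAreaNm2)) "Inf" else x$maxAreaNm2))
  cat("\n")
  invisible(x)
}

#' Percentile threshold of a micrograph
#'
#' The threshold percentage TH selects foreground through the gray histogram:
#' for dark polarity the cutoff is the smallest gray value whose cumulative
#' histogram fraction reaches TH/100, and a pixel is foreground iff its gray
#' value is at or below that cutoff. TH = 100 marks every pixel; on a constant
#' image every pixel equals the cutoff and is marked for any TH. Light
#' polarity mirrors the rule on the bright side of the histogram.
#'
#' @param m a [Micrograph-class].
#' @param thPercent threshold percentage in (0, 100].
#' @param polarity \code{"dark"} or \code{"light"} foreground.
#' @return Logical matrix, TRUE = foreground.
#' @export
thresholdMask <- function(m, thPercent, polarity = c("dark", "light")) {
  polarity <- match.arg(polarity)
  px <- pixels(m)
  if (length(px) == 0) stop("cannot threshold an empty image")
  if (thPercent <= 0 || thPercent > 100) stop("thPercent must lie in (0, 100]")
  if (polarity == "dark") {
    cutoff <- stats::quantile(px, thPercent / 100, type = 1, names = FALSE)
    px <= cutoff
  } else {
    cutoff <- -stats::quantile(-px, thPercent / 100, type = 1, names = FALSE)
    px >= cutoff
  }
}

# Connected-component labeling via row runs and union-find.
# Returns an integer matrix; labels are arbitrary but consecutive from 1.
labelComponents <- function(mask, connectivity = 8L) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (!any(mask)) return(lab)
  delta <- if (connectivity == 8L) 1L else 0L
  parent <- integer(0)
  findRoot <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  runRow <- integer(0); runS <- integer(0); runE <- integer(0)
  runLab <- integer(0)
  prevIdx <- integer(0)  # indices (into run vectors) of previous row's runs
  for (r in seq_len(ny)) {
    row <- mask[r, ]
    if (!any(row)) { prevIdx <- integer(0); next }
    rl <- rle(row)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    fg <- which(rl$values)
    curIdx <- integer(length(fg))
    for (j in seq_along(fg)) {
      s <- starts[fg[j]]; e <- ends[fg[j]]
      hit <- prevIdx[runS[prevIdx] <= e + delta & runE[prevIdx] >= s - delta]
      if (length(hit) == 0) {
        newLab <- length(parent) + 1L
        parent[newLab] <- newLab
        labHere <- newLab
      } else {
        roots <- unique(vapply(runLab[hit], findRoot, integer(1)))
        labHere <- min(roots)
        for (rt in roots) parent[rt] <- labHere
      }
      k <- length(runRow) + 1L
      runRow[k] <- r; runS[k] <- s; runE[k] <- e; runLab[k] <- labHere
      curIdx[j] <- k
    }
    prevIdx <- curIdx
  }
  roots <- vapply(seq_along(parent), findRoot, integer(1))
  remap <- integer(length(parent))
  remap[sort(unique(roots))] <- seq_along(unique(roots))
  for (k in seq_along(runRow))
    lab[runRow[k], runS[k]:runE[k]] <- remap[roots[runLab[k]]]
  lab
}

# Fill interior holes: background components (under the complement
# connectivity) not reachable from the image border are assigned to the
# unique adjacent foreground region. Returns the updated label matrix plus
# filled-pixel counts per region label.
fillRegionHoles <- function(lab, connectivity = 8L) {
  nlab <- max(lab)
  filled <- integer(nlab)
  if (nlab == 0) return(list(lab = lab, filled = filled))
  bgConn <- if (connectivity == 8L) 4L else 8L
  bg <- labelComponents(lab == 0L, bgConn)
  ny <- nrow(bg); nx <- ncol(bg)
  borderLabs <- unique(c(bg[1, ], bg[ny, ], bg[, 1], bg[, nx]))
  isHole <- bg > 0L & !(bg %in% borderLabs)
  if (!any(isHole)) return(list(lab = lab, filled = filled))
  idx <- which(isHole)
  r <- (idx - 1L) %% ny + 1L
  c <- (idx - 1L) %/% ny + 1L
  # per-pixel minimum positive 4-neighbor region label
  nbMin <- rep(Inf, length(idx))
  gather <- function(rr, cc) {
    v <- rep(Inf, length(idx))
    ok <- which(rr >= 1 & rr <= ny & cc >= 1 & cc <= nx)
    lv <- lab[cbind(rr[ok], cc[ok])]
    pos <- lv > 0L
    v[ok[pos]] <- lv[pos]
    v
  }
  nbMin <- pmin(nbMin, gather(r - 1L, c), gather(r + 1L, c),
                gather(r, c - 1L), gather(r, c + 1L))
  holeId <- bg[idx]
  # each hole is surrounded by one region; min label is the deterministic
  # owner if several regions ever border the same cavity
  owner <- tapply(nbMin, holeId, min)
  lab[idx] <- as.integer(owner[as.character(holeId)])
  add <- table(factor(lab[idx], levels = seq_len(nlab)))
  filled <- filled + as.integer(add)
  list(lab = lab, filled = filled)
}

#' Extract particle regions from a micrograph
#'
#' Thresholds the micrograph (unless a mask is supplied), labels connected
#' components under the configured connectivity, fills interior holes
#' (\code{includeHoles}), removes components touching the image border
#' (\code{excludeEdges}), and applies the pixel- and nm^2-area restrictions
#' (inclusive bounds, areas taken after hole filling). Surviving regions are
#' ordered row-major by centroid (y, then x) with ids consecutive from 1.
#'
#' @param m a [Micrograph-class].
#' @param cfg a [segmentationConfig()].
#' @param mask optional precomputed logical foreground mask.
#' @return A [ParticleSet-class]; an empty result is valid.
#' @export
extractParticles <- function(m, cfg, mask = NULL) {
  stopifnot(is(m, "Micrograph"), inherits(cfg, "SegmentationConfig"))
  if (is.null(mask)) mask <- thresholdMask(m, cfg$thPercent, cfg$polarity)
  if (!all(dim(mask) == dim(pixels(m))))
    stop("mask dimensions do not match the micrograph")
  lab <- labelComponents(mask, cfg$connectivity)
  nlab <- max(lab)
  holesFilled <- integer(nlab)
  if (cfg$includeHoles && nlab > 0) {
    fh <- fillRegionHoles(lab, cfg$connectivity)
    lab <- fh$lab
    holesFilled <- fh$filled
  }
  npp <- nmPerPx(m)
  emptyTab <- data.frame(
    id = integer(), pixel_count = integer(), cx_px = numeric(),
    cy_px = numeric(), cx_nm = numeric(), cy_nm = numeric(),
    touches_edge = logical(), holes_filled_px = integer())
  if (nlab == 0)
    return(new("ParticleSet", labelMatrix = lab, table = emptyTab,
               nmPerPx = npp, offsetNm = offsetNm(m), config = unclass(cfg)))
  idx <- which(lab > 0L)
  lv <- lab[idx]
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  counts <- tabulate(lv, nlab)
  cx <- rowsum(cols - 0.5, lv)[, 1] / counts
  cy <- rowsum(rows - 0.5, lv)[, 1] / counts
  onEdge <- rows == 1L | rows == nrow(lab) | cols == 1L | cols == ncol(lab)
  touches <- as.logical(rowsum(as.integer(onEdge), lv)[, 1] > 0)
  keep <- rep(TRUE, nlab)
  if (cfg$excludeEdges) keep <- keep & !touches
  keep <- keep & counts >= cfg$minAreaPx
  areaNm2v <- counts * npp^2
  if (!is.null(cfg$minAreaNm2)) keep <- keep & areaNm2v >= cfg$minAreaNm2
  if (!is.null(cfg$maxAreaNm2)) keep <- keep & areaNm2v <= cfg$maxAreaNm2
  kept <- which(keep)
  ord <- kept[order(cy[kept], cx[kept])]
  remap <- integer(nlab)
  remap[ord] <- seq_along(ord)
  lab[idx] <- remap[lv]
  off <- offsetNm(m)
  tab <- if (length(ord) == 0) emptyTab else data.frame(
    id = seq_along(ord),
    pixel_count = counts[ord],
    cx_px = cx[ord], cy_px = cy[ord],
    cx_nm = cx[ord] * npp + off[1], cy_nm = cy[ord] * npp + off[2],
    touches_edge = touches[ord],
    holes_filled_px = holesFilled[ord])
  rownames(tab) <- NULL
  new("ParticleSet", labelMatrix = lab, table = tab, nmPerPx = npp,
      offsetNm = off, config = unclass(cfg))
}

#' Area-restriction sweep
#'
#' Counts, for each candidate (min, max) nm^2 interval, how many particles
#' fall inside it (inclusive bounds) - the procedure used to settle a size
#' restriction that separates genuine particles from similar-gray cellular
#' components. A narrower interval can never gain hits.
#'
#' @param x a [ParticleSet-class] (measured or not) or a numeric vector of
#'   particle areas in nm^2.
#' @param intervals list of \code{c(min, max)} nm^2 pairs (use \code{Inf} for
#'   an open upper end).
#' @param nmPerPx calibration, only needed when \code{x} is a ParticleSet
#'   without measured areas (taken from the set itself by default).
#' @return data.frame with columns \code{min_nm2}, \code{max_nm2},
#'   \code{hit_count} and a list column \code{ids} of surviving particle ids.
#' @export
restrictionSweep <- function(x, intervals, nmPerPx = NULL) {
  if (is(x, "ParticleSet")) {
    tab <- particleTable(x)
    areas <- if ("area_nm2" %in% names(tab)) tab$area_nm2
    else tab$pixel_count * (if (is.null(nmPerPx)) nmPerPx(x) else nmPerPx)^2
    ids <- tab$id
  } else {
    areas <- as.numeric(x)
    ids <- seq_along(areas)
  }
  res <- lapply(intervals, function(iv) {
    if (length(iv) != 2 || iv[1] >= iv[2])
      stop(sprintf("invalid interval (%s, %s): min must be below max",
                   format(iv[1]), format(iv[2])))
    hit <- areas >= iv[1] & areas <= iv[2]
    list(min = iv[1], max = iv[2], n = sum(hit), ids = ids[hit])
  })
  out <- data.frame(
    min_nm2 = vapply(res, `[[`, numeric(1), "min"),
    max_nm2 = vapply(res, `[[`, numeric(1), "max"),
    hit_count = vapply(res, `[[`, numeric(1), "n"))
  out$ids <- lapply(res, `[[`, "ids")
  out
}
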