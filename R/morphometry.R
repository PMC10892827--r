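# Per-particle size and shape descriptors: area, equivalent circular diameter
# (ECD), moment-fitted ellipse axes, maximum Feret diameter, reciprocal aspect
# ratio (RAR = b/a), Feret major axis ratio (FMR = Df/a), and the six-class
# roundness classification.
#
# Conventions: a and b are FULL axis lengths (so a perfect ellipse has
# FMR ~ 1); the ellipse comes from the region's second central moments with
# area-preserving normalization; the Feret diameter is the maximum caliper
# distance over the convex hull of the region's pixel OUTER corners (a single
# pixel therefore has Feret sqrt(2) px).

#' Physical area of a region
#'
#' @param pixelCount number of pixels in the region (after hole filling).
#' @param nmPerPx calibration.
#' @return Area in nm^2: \code{pixelCount * nmPerPx^2}.
#' @export
areaNm2 <- function(pixelCount, nmPerPx) {
  stopifnot(all(pixelCount >= 1), nmPerPx > 0)
  pixelCount * nmPerPx^2
}

#' Equivalent circular diameter
#'
#' Diameter of the circle with the same area as the particle, assuming a
#' perfectly round particle: \code{ECD = sqrt(4 A / pi)}.
#'
#' @param A particle area(s) in nm^2; must be positive.
#' @return ECD in nm.
#' @examples
#' ecd(pi)  # 2
#' @export
ecd <- function(A) {
  if (any(A <= 0)) stop("area must be positive to define an ECD")
  sqrt(4 * A / pi)
}

#' Reciprocal aspect ratio and Feret major axis ratio
#'
#' \code{RAR = b / a} of the fitted ellipse, in (0, 1] with 1 a perfect
#' circle; \code{FMR = Df / a}, slightly above 1 for regular convex particles
#' and growing with outline irregularity.
#'
#' @param a,b full major and minor ellipse axes (same units); \code{a >= b > 0}.
#' @param feret maximum Feret diameter (same units as \code{a}).
#' @return Numeric ratio(s).
#' @export
rar <- function(a, b) {
  if (any(b <= 0) || any(a < b)) stop("ellipse axes must satisfy a >= b > 0")
  b / a
}

#' @rdname rar
#' @export
fmr <- function(feret, a) {
  if (any(a <= 0)) stop("major axis must be positive")
  if (any(feret <= 0)) stop("Feret diameter must be positive")
  feret / a
}

shapeClassLevels <- c("very angular", "angular", "sub-angular",
                      "sub-rounded", "rounded", "very rounded")
shapeClassBreaks <- c(0.12, 0.17, 0.25, 0.35, 0.49, 0.70, 1.00)

#' The six roundness classes
#'
#' RAR intervals tiling (0.12, 1.00]: boundaries are lower-exclusive and
#' upper-inclusive, so a RAR exactly on a printed boundary (e.g. 0.70) belongs
#' to the lower class.
#'
#' @return data.frame with columns class, rar_min (exclusive), rar_max
#'   (inclusive).
#' @export
shapeClassTable <- function() {
  data.frame(class = shapeClassLevels,
             rar_min = shapeClassBreaks[-7],
             rar_max = shapeClassBreaks[-1])
}

#' Classify particle shape from the reciprocal aspect ratio
#'
#' Values at or below the scale's lower bound 0.12 (never observed for
#' compact nanoparticles) are tagged \code{"out of scale"} rather than
#' raising an error; they are excluded from six-class breakdowns but kept in
#' particle tables.
#'
#' @param rarValues RAR value(s) in (0, 1].
#' @return Factor with the six class levels plus \code{"out of scale"}.
#' @examples
#' classifyShape(c(0.64, 0.79, 1.0))
#' @export
classifyShape <- function(rarValues) {
  if (any(rarValues <= 0 | rarValues > 1 + 1e-12))
    stop("RAR must lie in (0, 1]")
  rarValues <- pmin(rarValues, 1)
  cls <- as.character(cut(rarValues, shapeClassBreaks,
                          labels = shapeClassLevels, right = TRUE))
  cls[rarValues <= shapeClassBreaks[1]] <- "out of scale"
  factor(cls, levels = c(shapeClassLevels, "out of scale"))
}

# second-central-moment covariance of a pixel set (centers + the 1/12
# per-pixel term, so e.g. a solid n-px-wide rectangle gets variance n^2/12)
pixelCovariance <- function(cols, rows) {
  x <- cols - 0.5; y <- rows - 0.5
  mx <- mean(x); my <- mean(y)
  list(vxx = mean((x - mx)^2) + 1 / 12,
       vyy = mean((y - my)^2) + 1 / 12,
       vxy = mean((x - mx) * (y - my)),
       cx = mx, cy = my)
}

#' Fit an ellipse to a region by its second central moments
#'
#' Orientation and axis ratio come from the eigendecomposition of the pixel
#' covariance (pixel centers plus the 1/12 single-pixel term); the axes are
#' then scaled so that \code{pi * (a/2) * (b/2)} equals the region's area
#' exactly. A single pixel yields \code{a = b =} the ECD of one pixel.
#'
#' @param mask logical matrix covering one region (TRUE = member pixel).
#' @param nmPerPx calibration (default 1: axes in px units).
#' @return \code{list(a, b, orientation, cx, cy)}: full axes in nm,
#'   major-axis angle in radians from +x toward +y (y down), centroid in
#'   pixel units.
#' @export
fitEllipse <- function(mask, nmPerPx = 1) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("region is empty")
  pc <- pixelCovariance(idx[, 2], idx[, 1])
  ax <- axesFromCovariance(pc$vxx, pc$vyy, pc$vxy, nrow(idx))
  list(a = ax$a * nmPerPx, b = ax$b * nmPerPx, orientation = ax$orientation,
       cx = pc$cx, cy = pc$cy)
}

#' Outer corners of a region's boundary pixels
#'
#' Every boundary pixel (a member pixel with fewer than four 4-neighbors in
#' the region) contributes its four corners; pixel (ix, iy) spans
#' [ix-1, ix] x [iy-1, iy] in pixel units.
#'
#' @param mask logical matrix covering one region.
#' @return Two-column matrix of unique (x, y) corner coordinates in px units.
#' @export
pixelCorners <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("region is empty")
  ny <- nrow(mask); nx <- ncol(mask)
  inReg <- function(r, c) {
    ok <- r >= 1 & r <= ny & c >= 1 & c <= nx
    res <- logical(length(r))
    res[ok] <- mask[cbind(r[ok], c[ok])]
    res
  }
  r <- idx[, 1]; c <- idx[, 2]
  interior <- inReg(r - 1L, c) & inReg(r + 1L, c) &
    inReg(r, c - 1L) & inReg(r, c + 1L)
  b <- idx[!interior, , drop = FALSE]
  x <- c(b[, 2] - 1, b[, 2], b[, 2] - 1, b[, 2])
  y <- c(b[, 1] - 1, b[, 1] - 1, b[, 1], b[, 1])
  unique(cbind(x = x, y = y))
}

# maximum pairwise distance over a point set via convex hull + rotating
# calipers (antipodal pairs); exact on digitized shapes
rotatingCalipers <- function(pts) {
  pts <- unique(pts)
  n <- nrow(pts)
  if (n == 1) return(0)
  if (n == 2) return(sqrt(sum((pts[1, ] - pts[2, ])^2)))
  h <- grDevices::chull(pts)
  P <- pts[h, , drop = FALSE]
  m <- nrow(P)
  if (m == 1) return(0)
  if (m == 2) return(sqrt(sum((P[1, ] - P[2, ])^2)))
  # orient counter-clockwise (positive signed area)
  x <- P[, 1]; y <- P[, 2]
  if (sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) < 0)
    P <- P[m:1, , drop = FALSE]
  d2 <- function(i, j) sum((P[i, ] - P[j, ])^2)
  nxt <- function(i) if (i == m) 1L else i + 1L
  best <- 0
  j <- 2L
  for (i in seq_len(m)) {
    i2 <- nxt(i)
    repeat {
      j2 <- nxt(j)
      # advance the caliper while the support distance to edge (i, i2) grows
      adv <- (P[i2, 1] - P[i, 1]) * (P[j2, 2] - P[j, 2]) -
             (P[i2, 2] - P[i, 2]) * (P[j2, 1] - P[j, 1])
      if (adv > 0) j <- j2 else break
    }
    best <- max(best, d2(i, j), d2(i2, j))
  }
  sqrt(best)
}

#' Maximum Feret diameter of a region
#'
#' Maximum caliper distance over the convex hull of the region's boundary
#' pixel corners (rotating calipers), equal to the maximum pairwise corner
#' distance.
#'
#' @param mask logical matrix covering one region.
#' @param nmPerPx calibration (default 1: result in px units).
#' @return Feret diameter in nm.
#' @examples
#' m <- matrix(FALSE, 12, 12); m[2:11, 2:11] <- TRUE
#' feretMax(m)  # 10 * sqrt(2)
#' @export
feretMax <- function(mask, nmPerPx = 1) {
  rotatingCalipers(pixelCorners(mask)) * nmPerPx
}

#' Measure all particles of a ParticleSet
#'
#' Appends the morphometric columns to the particle table: \code{area_nm2},
#' \code{ecd_nm}, full ellipse axes \code{a_nm}, \code{b_nm},
#' \code{orientation}, \code{feret_nm}, \code{rar}, \code{fmr} and
#' \code{shape_class}.
#'
#' @param ps a [ParticleSet-class] from [extractParticles()].
#' @return The ParticleSet with a measured table.
#' @export
measureParticles <- function(ps) {
  stopifnot(is(ps, "ParticleSet"))
  tab <- particleTable(ps)
  n <- nrow(tab)
  npp <- nmPerPx(ps)
  lab <- labelMatrix(ps)
  a <- b <- orient <- feret <- numeric(n)
  idxAll <- which(lab > 0L)
  lv <- lab[idxAll]
  rowsAll <- (idxAll - 1L) %% nrow(lab) + 1L
  colsAll <- (idxAll - 1L) %/% nrow(lab) + 1L
  for (i in seq_len(n)) {
    sel <- lv == i
    r <- rowsAll[sel]; c <- colsAll[sel]
    # work on a local bounding-box mask
    r0 <- min(r) - 1L; c0 <- min(c) - 1L
    sub <- matrix(FALSE, max(r) - r0, max(c) - c0)
    sub[cbind(r - r0, c - c0)] <- TRUE
    pc <- pixelCovariance(c, r)
    ax <- axesFromCovariance(pc$vxx, pc$vyy, pc$vxy, length(r))
    a[i] <- ax$a * npp; b[i] <- ax$b * npp; orient[i] <- ax$orientation
    feret[i] <- feretMax(sub, npp)
  }
  tab$area_nm2 <- areaNm2(tab$pixel_count, npp)
  tab$ecd_nm <- if (n) ecd(tab$area_nm2) else numeric(0)
  tab$a_nm <- a; tab$b_nm <- b; tab$orientation <- orient
  tab$feret_nm <- feret
  tab$rar <- if (n) rar(a, b) else numeric(0)
  tab$fmr <- if (n) fmr(feret, a) else numeric(0)
  tab$shape_class <- if (n) as.character(classifyShape(tab$rar))
  else character(0)
  initialize(ps, table = tab)
}
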