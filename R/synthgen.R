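# Synthetic TEM-like micrographs with exact ground truth.
#
# Scenes are specified in nm. Geometry (including the random harmonic
# realization of amorphous blobs) is fixed at buildScene() time from the scene
# seed, so the nm-space truth is identical no matter at which nm/px a scene is
# later rendered; render() only draws background texture and pixel noise.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores \code{.Random.seed} so package functions do not disturb
#' the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthetic scene with realized geometry and exact ground truth
#'
#' @slot spec the validated scene specification (see [sceneSpec()]).
#' @slot truth nm-space ground-truth table: one row per particle with columns
#'   id, family, cx_nm, cy_nm, true_area_nm2, true_ecd_nm, true_a_nm,
#'   true_b_nm, contrast.
#' @slot geometry per-particle realized geometry (harmonic phases for blobs),
#'   used by [renderScene()].
#' @export
setClass("Scene",
  representation(spec = "list", truth = "data.frame", geometry = "list")
)

setMethod("show", "Scene", function(object) {
  cat(sprintf("Scene: %g x %g nm, %d particle(s), noise sd %g, seed %d\n",
              object@spec$widthNm, object@spec$heightNm,
              nrow(object@truth), object@spec$noiseSd, object@spec$seed))
  if (nrow(object@truth) > 0)
    cat(sprintf("  true ECD range: %.2f - %.2f nm\n",
                min(object@truth$true_ecd_nm), max(object@truth$true_ecd_nm)))
})

#' Particle specifications for synthetic scenes
#'
#' Particles are dark against the bright-field background, so \code{contrast}
#' (gray-level offset added where the particle covers a pixel) must be
#' negative unless the scene is built with inverted polarity for robustness
#' tests.
#'
#' @param cxNm,cyNm particle centroid in scene coordinates, nm.
#' @param radiusNm disk radius / blob base radius, nm.
#' @param aNm,bNm full (not semi-) major and minor ellipse axes, nm.
#' @param orientation major-axis angle in radians, measured from +x toward +y
#'   (image convention, y down).
#' @param amplitude total relative radial perturbation of a blob boundary
#'   (default 0.20, i.e. up to 20 percent of the base radius).
#' @param harmonics number of low-order harmonics in the blob boundary.
#' @param contrast gray offset versus local background (negative = darker).
#' @return A particle specification list consumed by [sceneSpec()].
#' @seealso [sceneSpec()], [buildScene()]
#' @export
diskParticle <- function(cxNm, cyNm, radiusNm, contrast = -80) {
  stopifnot(radiusNm > 0)
  list(family = "disk", cx = cxNm, cy = cyNm, radius = radiusNm,
       contrast = contrast)
}

#' @rdname diskParticle
#' @export
ellipseParticle <- function(cxNm, cyNm, aNm, bNm, orientation = 0,
                            contrast = -80) {
  stopifnot(aNm >= bNm, bNm > 0)
  list(family = "ellipse", cx = cxNm, cy = cyNm, a = aNm, b = bNm,
       orientation = orientation, contrast = contrast)
}

#' @rdname diskParticle
#' @export
blobParticle <- function(cxNm, cyNm, radiusNm, amplitude = 0.20,
                         harmonics = 5L, contrast = -60) {
  stopifnot(radiusNm > 0, amplitude >= 0, amplitude < 0.9, harmonics >= 1)
  list(family = "amorphous-blob", cx = cxNm, cy = cyNm, radius = radiusNm,
       amplitude = amplitude, harmonics = as.integer(harmonics),
       contrast = contrast)
}

#' Background specification for synthetic scenes
#'
#' Emulates the cell interior of a bright-field TEM micrograph: a base gray
#' level, a shallow horizontal illumination gradient, a correlated "cell
#' texture" field (some of which can reach particle gray values, as real
#' cellular components do), and optionally a dark vertical membrane band.
#'
#' @param baseGray base gray level, 0-255.
#' @param gradientAmplitude peak-to-peak gray amplitude of a left-to-right
#'   linear gradient.
#' @param textureAmplitude standard deviation (gray levels) of the correlated
#'   texture field; 0 disables it.
#' @param textureCorrelationNm correlation length of the texture, nm.
#' @param membrane optional \code{list(positionNm, widthNm, darkness)}: a dark
#'   vertical band of the given FWHM centered at \code{positionNm}.
#' @return A background specification list.
#' @export
backgroundSpec <- function(baseGray = 180, gradientAmplitude = 10,
                           textureAmplitude = 8, textureCorrelationNm = 30,
                           membrane = NULL) {
  stopifnot(baseGray >= 0, baseGray <= 255, gradientAmplitude >= 0,
            textureAmplitude >= 0, textureCorrelationNm > 0)
  if (!is.null(membrane))
    stopifnot(is.list(membrane), membrane$widthNm > 0, membrane$darkness >= 0)
  list(baseGray = baseGray, gradientAmplitude = gradientAmplitude,
       textureAmplitude = textureAmplitude,
       textureCorrelationNm = textureCorrelationNm, membrane = membrane)
}

#' Specify a synthetic scene
#'
#' @param widthNm,heightNm scene extent, nm.
#' @param particles list of particle specifications ([diskParticle()],
#'   [ellipseParticle()], [blobParticle()]).
#' @param background a [backgroundSpec()].
#' @param noiseSd per-pixel Gaussian gray-noise standard deviation.
#' @param seed integer seed fixing the scene's random geometry (blob
#'   harmonics); rendering takes its own seed for noise.
#' @param invertPolarity render particles brighter than background (for
#'   robustness tests); particle contrasts must then be positive.
#' @return A scene specification list for [buildScene()].
#' @export
sceneSpec <- function(widthNm, heightNm, particles = list(),
                      background = backgroundSpec(), noiseSd = 4,
                      seed = 1L, invertPolarity = FALSE) {
  stopifnot(widthNm > 0, heightNm > 0, noiseSd >= 0)
  for (p in particles) {
    want <- if (invertPolarity) p$contrast > 0 else p$contrast < 0
    if (!want)
      stop("particle contrast must be ",
           if (invertPolarity) "positive" else "negative",
           " (dark particles on a bright-field background)")
  }
  list(widthNm = widthNm, heightNm = heightNm, particles = particles,
       background = background, noiseSd = noiseSd, seed = as.integer(seed),
       invertPolarity = isTRUE(invertPolarity))
}

# polygon area / centroid / central second moments by Green's theorem;
# vertices counter-clockwise, (n x 2) matrix
polygonMoments <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  x2 <- c(x[-1], x[1]); y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  A <- sum(cr) / 2
  cx <- sum((x + x2) * cr) / (6 * A)
  cy <- sum((y + y2) * cr) / (6 * A)
  ixx <- sum((x^2 + x * x2 + x2^2) * cr) / 12
  iyy <- sum((y^2 + y * y2 + y2^2) * cr) / 12
  ixy <- sum((x * y2 + 2 * x * y + 2 * x2 * y2 + x2 * y) * cr) / 24
  list(area = abs(A),
       cx = cx, cy = cy,
       # central second moments normalized by area (covariance of the lamina)
       vxx = ixx / A - cx^2, vyy = iyy / A - cy^2, vxy = ixy / A - cx * cy)
}

# full ellipse axes (area preserving) from a covariance matrix and an area
axesFromCovariance <- function(vxx, vyy, vxy, area) {
  tr <- vxx + vyy
  disc <- sqrt(max(0, (vxx - vyy)^2 / 4 + vxy^2))
  l1 <- tr / 2 + disc
  l2 <- max(tr / 2 - disc, .Machine$double.eps * tr)
  ratio <- sqrt(l1 / l2)
  semiB <- sqrt(area / (pi * ratio))
  semiA <- semiB * ratio
  theta <- 0.5 * atan2(2 * vxy, vxx - vyy)
  list(a = 2 * semiA, b = 2 * semiB, orientation = theta)
}

blobRadius <- function(geom, theta) {
  r <- rep(1, length(theta))
  for (j in seq_along(geom$k))
    r <- r + geom$amps[j] * cos(geom$k[j] * theta + geom$phases[j])
  geom$radius * r
}

#' Build a scene: realize geometry and compute exact ground truth
#'
#' Disk and ellipse truth areas are analytic; an amorphous blob's truth area is
#' the polygon area of its (densely sampled) perturbed boundary. For every
#' particle \code{true_ecd_nm = sqrt(4 * true_area_nm2 / pi)} exactly.
#'
#' @param spec a [sceneSpec()].
#' @return A [Scene-class].
#' @examples
#' sc <- buildScene(sceneSpec(100, 100,
#'   particles = list(diskParticle(50, 50, radiusNm = 5))))
#' sceneTruth(sc)$true_ecd_nm  # 10 nm
#' @export
buildScene <- function(spec) {
  stopifnot(is.list(spec), !is.null(spec$widthNm))
  np <- length(spec$particles)
  geometry <- vector("list", np)
  rows <- vector("list", np)
  withSeed(spec$seed, {
    for (i in seq_len(np)) {
      p <- spec$particles[[i]]
      if (p$cx < 0 || p$cx > spec$widthNm || p$cy < 0 || p$cy > spec$heightNm)
        stop(sprintf("particle %d centroid (%g, %g) lies outside the scene",
                     i, p$cx, p$cy))
      g <- p
      if (p$family == "disk") {
        area <- pi * p$radius^2
        aFull <- 2 * p$radius; bFull <- 2 * p$radius
      } else if (p$family == "ellipse") {
        area <- pi * (p$a / 2) * (p$b / 2)
        aFull <- p$a; bFull <- p$b
      } else if (p$family == "amorphous-blob") {
        K <- p$harmonics
        # harmonics k >= 2 so the perturbation does not translate the shape
        g$k <- seq(2L, 1L + K)
        u <- stats::runif(K, 0.5, 1)
        g$amps <- p$amplitude * u / sum(u)
        g$phases <- stats::runif(K, 0, 2 * pi)
        theta <- seq(0, 2 * pi, length.out = 1441L)[-1441L]
        r <- blobRadius(g, theta)
        poly <- cbind(p$cx + r * cos(theta), p$cy + r * sin(theta))
        pm <- polygonMoments(poly)
        area <- pm$area
        ax <- axesFromCovariance(pm$vxx, pm$vyy, pm$vxy, area)
        aFull <- ax$a; bFull <- ax$b
      } else stop("unknown particle family: ", p$family)
      geometry[[i]] <- g
      rows[[i]] <- data.frame(
        id = i, family = p$family, cx_nm = p$cx, cy_nm = p$cy,
        true_area_nm2 = area, true_ecd_nm = sqrt(4 * area / pi),
        true_a_nm = aFull, true_b_nm = bFull, contrast = p$contrast,
        stringsAsFactors = FALSE
      )
    }
  })
  truth <- if (np > 0) do.call(rbind, rows) else
    data.frame(id = integer(), family = character(), cx_nm = numeric(),
               cy_nm = numeric(), true_area_nm2 = numeric(),
               true_ecd_nm = numeric(), true_a_nm = numeric(),
               true_b_nm = numeric(), contrast = numeric(),
               stringsAsFactors = FALSE)
  new("Scene", spec = spec, truth = truth, geometry = geometry)
}

#' @describeIn buildScene ground-truth table accessor
#' @param object a \code{Scene}
#' @export
setGeneric("sceneTruth", function(object) standardGeneric("sceneTruth"))

#' @export
setMethod("sceneTruth", "Scene", function(object) object@truth)

# fractional pixel coverage of one particle over its bounding box,
# by ss x ss subpixel sampling of the analytic inside test
particleCoverage <- function(g, nmPerPx, nx, ny, ss = 4L) {
  rmax <- switch(g$family,
    disk = g$radius,
    ellipse = g$a / 2,
    "amorphous-blob" = g$radius * (1 + sum(abs(g$amps))))
  ix0 <- max(1L, floor((g$cx - rmax) / nmPerPx))
  ix1 <- min(nx, ceiling((g$cx + rmax) / nmPerPx) + 1L)
  iy0 <- max(1L, floor((g$cy - rmax) / nmPerPx))
  iy1 <- min(ny, ceiling((g$cy + rmax) / nmPerPx) + 1L)
  if (ix0 > ix1 || iy0 > iy1) return(NULL)
  ix <- ix0:ix1; iy <- iy0:iy1
  off <- (seq_len(ss) - 0.5) / ss
  cov <- matrix(0, length(iy), length(ix))
  for (oy in off) {
    ynm <- (iy - 1 + oy) * nmPerPx
    for (ox in off) {
      xnm <- (ix - 1 + ox) * nmPerPx
      dx <- outer(rep(1, length(iy)), xnm - g$cx)
      dy <- outer(ynm - g$cy, rep(1, length(ix)))
      inside <- switch(g$family,
        disk = dx^2 + dy^2 <= g$radius^2,
        ellipse = {
          co <- cos(g$orientation); si <- sin(g$orientation)
          u <- dx * co + dy * si
          v <- -dx * si + dy * co
          (u / (g$a / 2))^2 + (v / (g$b / 2))^2 <= 1
        },
        "amorphous-blob" = {
          rr <- sqrt(dx^2 + dy^2)
          rr <= blobRadius(g, atan2(dy, dx))
        })
      cov <- cov + inside
    }
  }
  list(ix = ix, iy = iy, coverage = cov / ss^2)
}

#' Render a scene at a given pixel calibration
#'
#' Pixel gray = background (base + gradient + correlated texture + optional
#' membrane band) + sum of particle contrasts weighted by fractional pixel
#' coverage (area-coverage antialiasing at particle boundaries) + Gaussian
#' noise, clamped and quantized to 8-bit. Texture and noise are drawn from a
#' single RNG stream seeded once per render, after all geometry is fixed, so
#' two renders with the same (scene, nmPerPx, seed) are byte-identical.
#'
#' @param scene a [Scene-class] from [buildScene()].
#' @param nmPerPx rendering calibration, nm per pixel; the rendered image must
#'   be at least 16 x 16 px.
#' @param seed integer seed for texture and noise.
#' @return \code{list(micrograph, truth)}: the [Micrograph-class] and the
#'   ground-truth table augmented with pixel coordinates (\code{cx_px},
#'   \code{cy_px}) and an \code{under_1px} flag marking particles whose true
#'   area covers less than one pixel at this calibration.
#' @export
renderScene <- function(scene, nmPerPx, seed = 1L) {
  stopifnot(is(scene, "Scene"), nmPerPx > 0)
  spec <- scene@spec
  nx <- as.integer(round(spec$widthNm / nmPerPx))
  ny <- as.integer(round(spec$heightNm / nmPerPx))
  if (nx < 16 || ny < 16)
    stop(sprintf("rendered image would be %d x %d px; at least 16 x 16 required",
                 nx, ny))
  bg <- spec$background
  xc <- (seq_len(nx) - 0.5) * nmPerPx
  yc <- (seq_len(ny) - 0.5) * nmPerPx
  img <- matrix(bg$baseGray, ny, nx)
  if (bg$gradientAmplitude > 0)
    img <- img + matrix(bg$gradientAmplitude * (xc / spec$widthNm - 0.5),
                        ny, nx, byrow = TRUE)
  if (!is.null(bg$membrane)) {
    sig <- bg$membrane$widthNm / 2.355  # FWHM -> sigma
    band <- bg$membrane$darkness * exp(-0.5 * ((xc - bg$membrane$positionNm) / sig)^2)
    img <- img - matrix(band, ny, nx, byrow = TRUE)
  }
  withSeed(seed, {
    if (bg$textureAmplitude > 0) {
      # iid normals on a grid at the correlation length, bilinearly upsampled
      gpx <- max(2, bg$textureCorrelationNm / nmPerPx)
      ngx <- ceiling(nx / gpx) + 2L
      ngy <- ceiling(ny / gpx) + 2L
      gv <- matrix(stats::rnorm(ngx * ngy, 0, bg$textureAmplitude), ngy, ngx)
      fx <- (seq_len(nx) - 0.5) / gpx + 1
      fy <- (seq_len(ny) - 0.5) / gpx + 1
      ix <- pmin(floor(fx), ngx - 1L); tx <- fx - ix
      iy <- pmin(floor(fy), ngy - 1L); ty <- fy - iy
      w00 <- outer(1 - ty, 1 - tx); w10 <- outer(ty, 1 - tx)
      w01 <- outer(1 - ty, tx);     w11 <- outer(ty, tx)
      img <- img + gv[cbind(rep(iy, nx), rep(ix, each = ny))] * w00 +
        gv[cbind(rep(iy + 1L, nx), rep(ix, each = ny))] * w10 +
        gv[cbind(rep(iy, nx), rep(ix + 1L, each = ny))] * w01 +
        gv[cbind(rep(iy + 1L, nx), rep(ix + 1L, each = ny))] * w11
    }
    for (g in scene@geometry) {
      pc <- particleCoverage(g, nmPerPx, nx, ny)
      if (!is.null(pc))
        img[pc$iy, pc$ix] <- img[pc$iy, pc$ix] + g$contrast * pc$coverage
    }
    if (spec$noiseSd > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noiseSd)
  })
  img <- round(pmin(pmax(img, 0), 255))
  truth <- scene@truth
  if (nrow(truth) > 0) {
    truth$cx_px <- truth$cx_nm / nmPerPx
    truth$cy_px <- truth$cy_nm / nmPerPx
    truth$under_1px <- truth$true_area_nm2 < nmPerPx^2
    if (any(truth$under_1px))
      warning(sprintf("%d particle(s) cover less than one pixel at %g nm/px",
                      sum(truth$under_1px), nmPerPx))
  }
  m <- Micrograph(img, nmPerPx, label = sprintf("%g nm/px", nmPerPx),
                  provenance = "synthetic")
  list(micrograph = m, truth = truth)
}

#' Write a micrograph / ground-truth table to disk
#'
#' Format follows the file extension: \code{.png} or \code{.tif}/\code{.tiff},
#' always 8-bit grayscale. Ground truth is written as CSV with the columns
#' id, family, cx_nm, cy_nm, true_area_nm2, true_ecd_nm, true_a_nm, true_b_nm,
#' contrast (plus pixel coordinates and the under_1px flag when present).
#'
#' @param m a [Micrograph-class].
#' @param truth a ground-truth data.frame from [renderScene()] / [buildScene()].
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeMicrograph <- function(m, path) {
  stopifnot(is(m, "Micrograph"))
  img01 <- pixels(m) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(img01, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(img01, where = path, bits.per.sample = 8L)
  } else stop("unsupported image extension: ", ext)
  invisible(path)
}

#' @rdname writeMicrograph
#' @export
writeGroundTruth <- function(truth, path) {
  lead <- c("id", "family", "cx_nm", "cy_nm", "true_area_nm2", "true_ecd_nm",
            "true_a_nm", "true_b_nm", "contrast")
  truth <- truth[, c(lead, setdiff(names(truth), lead)), drop = FALSE]
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
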