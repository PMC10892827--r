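#' @import methods
NULL

#' Calibrated grayscale micrograph
#'
#' A \code{Micrograph} holds an 8-bit grayscale pixel grid together with its
#' physical calibration (nm per pixel) and an nm-space origin offset that keeps
#' coordinates scene-absolute after cropping or when several renderings of one
#' specimen region are registered against each other.
#'
#' Pixel convention: the matrix is indexed \code{[row = y, col = x]} with the
#' origin at the top-left; pixel \code{(ix, iy)} (1-based) has its center at
#' \code{((ix - 0.5), (iy - 0.5))} in pixel units, and nm coordinates are
#' \code{center_px * nmPerPx + offsetNm}.
#'
#' @slot pixels numeric matrix of gray values in [0, 255] (rows are y).
#' @slot nmPerPx physical length of one pixel side, nm.
#' @slot label free-text tag (e.g. a magnification label).
#' @slot provenance source path or \code{"synthetic"}.
#' @slot offsetNm length-2 numeric, nm-space (x, y) position of the image's
#'   top-left corner.
#'
#' @export
setClass("Micrograph",
  representation(
    pixels = "matrix",
    nmPerPx = "numeric",
    label = "character",
    provenance = "character",
    offsetNm = "numeric"
  )
)

setValidity("Micrograph", function(object) {
  msg <- character()
  if (!is.numeric(object@pixels)) {
    msg <- c(msg, "pixels must be a numeric matrix")
  } else if (length(object@pixels) > 0) {
    rng <- range(object@pixels)
    if (!is.finite(rng[1]) || rng[1] < 0 || rng[2] > 255) {
      msg <- c(msg, "gray values must lie in [0, 255]")
    }
  }
  if (length(object@nmPerPx) != 1 || !is.finite(object@nmPerPx) ||
      object@nmPerPx <= 0) {
    msg <- c(msg, "nmPerPx must be a single positive number")
  }
  if (length(object@offsetNm) != 2 || any(!is.finite(object@offsetNm))) {
    msg <- c(msg, "offsetNm must be a length-2 finite numeric")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Micrograph
#'
#' @param pixels numeric matrix of gray values in [0, 255], rows are y.
#' @param nmPerPx positive nm-per-pixel calibration (see [calibrate()]).
#' @param label free-text tag.
#' @param provenance source description.
#' @param offsetNm nm-space (x, y) of the image top-left corner.
#' @return A [Micrograph-class] object.
#' @examples
#' m <- Micrograph(matrix(128, 32, 32), nmPerPx = 0.5)
#' nmPerPx(m)
#' @export
Micrograph <- function(pixels, nmPerPx, label = "", provenance = "in-memory",
                       offsetNm = c(0, 0)) {
  new("Micrograph",
    pixels = pixels, nmPerPx = as.numeric(nmPerPx),
    label = as.character(label), provenance = as.character(provenance),
    offsetNm = as.numeric(offsetNm)
  )
}

#' @describeIn Micrograph-class gray-value matrix accessor
#' @param object,x a \code{Micrograph}
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @export
setMethod("pixels", "Micrograph", function(object) object@pixels)

#' @describeIn Micrograph-class calibration accessor (nm per pixel)
#' @export
setGeneric("nmPerPx", function(object) standardGeneric("nmPerPx"))

#' @export
setMethod("nmPerPx", "Micrograph", function(object) object@nmPerPx)

#' @describeIn Micrograph-class nm-space origin offset accessor
#' @export
setGeneric("offsetNm", function(object) standardGeneric("offsetNm"))

#' @export
setMethod("offsetNm", "Micrograph", function(object) object@offsetNm)

setMethod("show", "Micrograph", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "Micrograph: %d x %d px @ %g nm/px (%.0f x %.0f nm)\n",
    d[2], d[1], object@nmPerPx, d[2] * object@nmPerPx, d[1] * object@nmPerPx
  ))
  if (nzchar(object@label)) cat("  label:", object@label, "\n")
  cat("  provenance:", object@provenance,
      sprintf(" offset: (%g, %g) nm\n", object@offsetNm[1], object@offsetNm[2]))
})

#' Detected particle regions of one micrograph
#'
#' A \code{ParticleSet} couples a labeled pixel matrix (0 = background,
#' k = particle k) with a per-particle table. Directly after
#' [extractParticles()] the table holds the region bookkeeping columns
#' (\code{id}, \code{pixel_count}, \code{cx_px}, \code{cy_px}, \code{cx_nm},
#' \code{cy_nm}, \code{touches_edge}, \code{holes_filled_px});
#' [measureParticles()] appends the morphometric columns (\code{area_nm2},
#' \code{ecd_nm}, \code{a_nm}, \code{b_nm}, \code{orientation},
#' \code{feret_nm}, \code{rar}, \code{fmr}, \code{shape_class}).
#'
#' @slot labelMatrix integer matrix of region labels.
#' @slot table per-particle data.frame, one row per region, ids consecutive
#'   from 1 in row-major centroid order.
#' @slot nmPerPx calibration of the source micrograph.
#' @slot offsetNm nm-space origin of the source micrograph.
#' @slot config the [segmentationConfig()] used.
#'
#' @export
setClass("ParticleSet",
  representation(
    labelMatrix = "matrix",
    table = "data.frame",
    nmPerPx = "numeric",
    offsetNm = "numeric",
    config = "list"
  )
)

setValidity("ParticleSet", function(object) {
  msg <- character()
  n <- nrow(object@table)
  if (n > 0 && !identical(object@table$id, seq_len(n)))
    msg <- c(msg, "particle ids must be consecutive from 1")
  lab <- object@labelMatrix
  if (length(lab) && max(lab) > n)
    msg <- c(msg, "labelMatrix contains labels beyond the particle table")
  if (n > 0 && any(object@table$pixel_count < 1))
    msg <- c(msg, "every region must contain at least one pixel")
  if (object@nmPerPx <= 0) msg <- c(msg, "nmPerPx must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn ParticleSet-class per-particle table accessor
#' @param object a \code{ParticleSet}
#' @export
setGeneric("particleTable", function(object) standardGeneric("particleTable"))

#' @export
setMethod("particleTable", "ParticleSet", function(object) object@table)

#' @describeIn ParticleSet-class label-matrix accessor
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' @export
setMethod("labelMatrix", "ParticleSet", function(object) object@labelMatrix)

#' @export
setMethod("nmPerPx", "ParticleSet", function(object) object@nmPerPx)

#' @export
setMethod("offsetNm", "ParticleSet", function(object) object@offsetNm)

setMethod("length", "ParticleSet", function(x) nrow(x@table))

setMethod("show", "ParticleSet", function(object) {
  cat(sprintf("ParticleSet: %d particle(s) @ %g nm/px\n",
              nrow(object@table), object@nmPerPx))
  if ("ecd_nm" %in% names(object@table) && nrow(object@table) > 0) {
    cat(sprintf("  ECD range: %.2f - %.2f nm\n",
                min(object@table$ecd_nm), max(object@table$ecd_nm)))
  } else if (nrow(object@table) > 0) {
    cat("  (unmeasured; run measureParticles())\n")
  }
})

#' Particle-size-distribution summary
#'
#' Summary statistics of one per-particle metric over a particle population:
#' count N, arithmetic mean, standard error of the mean (sample sd / sqrt(N)),
#' a half-open-bin histogram with per-bin cumulative percentages, and the
#' 10/25/75/90th percentiles used for box-plot reporting.
#'
#' @slot metric which metric was summarized.
#' @slot n particle count.
#' @slot mean,se mean and standard error (NA / flagged for n < 2).
#' @slot breaks histogram bin edges; bin i is [breaks[i], breaks[i+1]).
#' @slot counts per-bin counts, sum equals n.
#' @slot cumulativePercent running percentage per bin, ends at 100 for n > 0.
#' @slot percentiles named numeric: p10, p25, p75, p90.
#' @slot flags character vector, e.g. "empty" or "single-particle-se".
#'
#' @export
setClass("PSDSummary",
  representation(
    metric = "character",
    n = "integer",
    mean = "numeric",
    se = "numeric",
    breaks = "numeric",
    counts = "integer",
    cumulativePercent = "numeric",
    percentiles = "numeric",
    flags = "character"
  )
)

setValidity("PSDSummary", function(object) {
  msg <- character()
  if (object@n > 0) {
    if (sum(object@counts) != object@n)
      msg <- c(msg, "histogram counts must sum to n")
    cp <- object@cumulativePercent
    if (length(cp) && (is.unsorted(cp) ||
                       abs(cp[length(cp)] - 100) > 1e-9))
      msg <- c(msg, "cumulative percent must be nondecreasing and end at 100")
    p <- object@percentiles
    if (is.unsorted(p[c("p10", "p25", "p75", "p90")]))
      msg <- c(msg, "percentiles must be ordered p10 <= p25 <= p75 <= p90")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PSDSummary", function(object) {
  if (object@n == 0) {
    cat(sprintf("PSDSummary[%s]: empty\n", object@metric))
    return(invisible(NULL))
  }
  cat(sprintf("PSDSummary[%s]: N = %d, mean = %.4g, SE = %.4g\n",
              object@metric, object@n, object@mean, object@se))
  cat(sprintf("  %d bins over [%g, %g); p10/p25/p75/p90 = %s\n",
              length(object@counts), object@breaks[1],
              object@breaks[length(object@breaks)],
              paste(signif(object@percentiles, 4), collapse = "/")))
})

#' Cross-magnification quality-control report
#'
#' Per-particle equivalent circular diameters (ECD) of matched particles at
#' each magnification, their signed deviations from a reference magnification,
#' and the maximum absolute deviation per magnification. Rows whose reference
#' ECD falls below \code{minEcdNm} (or is missing) are kept in the table but
#' excluded from the deviation maxima.
#'
#' @slot ecd numeric matrix, particles x magnifications.
#' @slot deviations \code{ecd} minus its reference column.
#' @slot reference reference magnification label (column name).
#' @slot maxAbsDeviation per-magnification maximum |deviation| over unexcluded
#'   rows.
#' @slot excluded integer row indices excluded from the maxima.
#'
#' @export
setClass("QCReport",
  representation(
    ecd = "matrix",
    deviations = "matrix",
    reference = "character",
    maxAbsDeviation = "numeric",
    excluded = "integer"
  )
)

setValidity("QCReport", function(object) {
  msg <- character()
  if (!(object@reference %in% colnames(object@ecd)))
    msg <- c(msg, "reference must name a column of the ECD matrix")
  else {
    ref <- object@deviations[, object@reference]
    ok <- is.na(ref) | abs(ref) < 1e-12
    if (!all(ok))
      msg <- c(msg, "reference column must have zero self-deviation")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn QCReport-class signed deviation matrix accessor
#' @param object a \code{QCReport}
#' @export
setGeneric("deviations", function(object) standardGeneric("deviations"))

#' @export
setMethod("deviations", "QCReport", function(object) object@deviations)

#' @describeIn QCReport-class per-magnification maximum absolute deviation
#' @export
setGeneric("maxAbsDeviation",
           function(object) standardGeneric("maxAbsDeviation"))

#' @export
setMethod("maxAbsDeviation", "QCReport",
          function(object) object@maxAbsDeviation)

setMethod("show", "QCReport", function(object) {
  cat(sprintf("QCReport: %d matched particle(s), reference = %s\n",
              nrow(object@ecd), object@reference))
  cat("  max |ECD deviation| per magnification:\n")
  print(round(object@maxAbsDeviation, 3))
  if (length(object@excluded))
    cat(sprintf("  (%d row(s) excluded from maxima)\n",
                length(object@excluded)))
})
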