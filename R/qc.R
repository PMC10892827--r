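# Quality control: cross-magnification particle matching, ECD deviation
# tables against a reference magnification, and threshold-sensitivity runs.

#' Define a magnification series
#'
#' Several micrographs of the same specimen region at different
#' magnifications (nm/px calibrations), registered in a shared nm coordinate
#' frame through each micrograph's \code{offsetNm} (supplied by the user for
#' real images; exact for synthetic renders of one scene).
#'
#' @param entries list of \code{list(micrograph, label, thPercent = NULL,
#'   minAreaPx = NULL)}; at least two entries. \code{thPercent} defaults to
#'   [suggestThreshold()] of that image; \code{minAreaPx} overrides the base
#'   configuration's lower pixel limit (coarser calibrations need a smaller
#'   one since the same particle covers fewer pixels).
#' @return A validated list of class \code{MagnificationSeries}.
#' @export
magnificationSeries <- function(entries) {
  if (length(entries) < 2) stop(">= 2 magnifications required")
  labels <- vapply(entries, function(e) as.character(e$label), character(1))
  if (anyDuplicated(labels)) stop("magnification labels must be unique")
  for (e in entries) stopifnot(is(e$micrograph, "Micrograph"))
  structure(list(entries = entries, labels = labels),
            class = "MagnificationSeries")
}

#' @export
print.MagnificationSeries <- function(x, ...) {
  cat(sprintf("MagnificationSeries: %d entries (%s)\n",
              length(x$entries), paste(x$labels, collapse = ", ")))
  invisible(x)
}

# segment + measure every entry of a series -> named list of particle tables
measureSeries <- function(series, baseCfg) {
  stopifnot(inherits(series, "MagnificationSeries"))
  out <- lapply(series$entries, function(e) {
    cfg <- baseCfg
    cfg$thPercent <- if (is.null(e$thPercent))
      suggestThreshold(e$micrograph) else e$thPercent
    if (!is.null(e$minAreaPx)) cfg$minAreaPx <- as.integer(e$minAreaPx)
    particleTable(measureParticles(extractParticles(e$micrograph, cfg)))
  })
  names(out) <- series$labels
  out
}

# greedy one-to-one matching of one table against the reference by nearest
# scene-coordinate centroid; ties broken by lower reference id, then lower
# candidate id
greedyMatch <- function(refTab, tab, toleranceNm) {
  nr <- nrow(refTab); nt <- nrow(tab)
  match <- rep(NA_integer_, nr)
  if (nr == 0 || nt == 0) return(match)
  dx <- outer(refTab$cx_nm, tab$cx_nm, "-")
  dy <- outer(refTab$cy_nm, tab$cy_nm, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= toleranceNm, arr.ind = TRUE)
  if (nrow(cand) == 0) return(match)
  ord <- order(d[cand], refTab$id[cand[, 1]], tab$id[cand[, 2]])
  usedRef <- logical(nr); usedTab <- logical(nt)
  for (k in ord) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!usedRef[i] && !usedTab[j]) {
      match[i] <- j
      usedRef[i] <- TRUE
      usedTab[j] <- TRUE
    }
  }
  match
}

#' Match particles across a magnification series
#'
#' Segments and measures every entry (or takes pre-measured particle tables),
#' then matches particles greedily by nearest scene-coordinate centroid
#' within a tolerance, one-to-one against the reference entry. Equidistant
#' candidates are resolved deterministically by lower particle id.
#'
#' @param x a [magnificationSeries()] or a named list of measured particle
#'   tables (columns \code{id}, \code{cx_nm}, \code{cy_nm}, \code{ecd_nm}).
#' @param cfg base [segmentationConfig()] (series input only).
#' @param reference label of the reference entry; default the finest
#'   calibration (series input) or the first table.
#' @param toleranceNm matching tolerance; default two pixels of the coarsest
#'   image, in nm.
#' @return \code{list(ecd, ids, unmatched, reference, tables)}: \code{ecd}
#'   and \code{ids} are reference-particle x magnification matrices (NA
#'   where unmatched), \code{unmatched} lists per label the particle ids not
#'   matched to any reference particle.
#' @export
matchParticles <- function(x, cfg = NULL, reference = NULL,
                           toleranceNm = NULL) {
  if (inherits(x, "MagnificationSeries")) {
    npps <- vapply(x$entries, function(e) nmPerPx(e$micrograph), numeric(1))
    if (is.null(reference)) reference <- x$labels[which.min(npps)]
    if (is.null(toleranceNm)) toleranceNm <- 2 * max(npps)
    if (is.null(cfg)) stop("a base segmentationConfig is required")
    tables <- measureSeries(x, cfg)
  } else {
    tables <- x
    if (is.null(names(tables)) || any(!nzchar(names(tables))))
      stop("particle tables must be named by magnification label")
    if (is.null(reference)) reference <- names(tables)[1]
    if (is.null(toleranceNm))
      stop("toleranceNm is required for table input")
  }
  if (toleranceNm <= 0) stop("toleranceNm must be positive")
  if (!reference %in% names(tables))
    stop("reference label not present: ", reference)
  labels <- names(tables)
  refTab <- tables[[reference]]
  nr <- nrow(refTab)
  ecdM <- idM <- matrix(NA_real_, nr, length(labels),
                        dimnames = list(NULL, labels))
  unmatched <- stats::setNames(vector("list", length(labels)), labels)
  for (lb in labels) {
    if (lb == reference) {
      ecdM[, lb] <- refTab$ecd_nm
      idM[, lb] <- refTab$id
      unmatched[[lb]] <- integer(0)
      next
    }
    tab <- tables[[lb]]
    mt <- greedyMatch(refTab, tab, toleranceNm)
    ok <- !is.na(mt)
    ecdM[ok, lb] <- tab$ecd_nm[mt[ok]]
    idM[ok, lb] <- tab$id[mt[ok]]
    unmatched[[lb]] <- setdiff(tab$id, tab$id[mt[ok]])
  }
  list(ecd = ecdM, ids = idM, unmatched = unmatched, reference = reference,
       tables = tables)
}

#' Cross-magnification ECD deviation table
#'
#' Signed per-particle ECD deviation of every magnification against the
#' reference magnification, plus the maximum absolute deviation per
#' magnification. Accepts either the output of [matchParticles()] or a plain
#' particle x magnification ECD matrix / data.frame (e.g. a pre-measured
#' published table).
#'
#' @param matched [matchParticles()] result, or a numeric matrix/data.frame
#'   of ECDs with magnification labels as column names.
#' @param reference reference column label; defaults to the matching
#'   reference (or the first column for plain input).
#' @param minEcdNm rows whose reference ECD is below this are kept in the
#'   table but excluded from the deviation maxima (default 3.5 nm, the usual
#'   cutoff below which automatic runs disregard values); set 0 to disable.
#' @return A [QCReport-class].
#' @examples
#' ecds <- cbind("150k" = c(10.2, 3.3, 5.0),
#'               "10k"  = c(11.3, 4.0, 6.0))
#' deviations(deviationTable(ecds, reference = "150k"))
#' @export
deviationTable <- function(matched, reference = NULL, minEcdNm = 3.5) {
  ecdM <- if (is.list(matched) && !is.data.frame(matched) &&
              !is.null(matched$ecd)) {
    if (is.null(reference)) reference <- matched$reference
    matched$ecd
  } else as.matrix(matched)
  if (is.null(colnames(ecdM))) stop("ECD columns must carry labels")
  if (is.null(reference)) reference <- colnames(ecdM)[1]
  if (!reference %in% colnames(ecdM))
    stop("reference label not present: ", reference)
  ref <- ecdM[, reference]
  dev <- ecdM - ref
  excluded <- which(is.na(ref) | ref < minEcdNm)
  use <- setdiff(seq_len(nrow(ecdM)), excluded)
  mad <- apply(abs(dev[use, , drop = FALSE]), 2,
               function(col) if (all(is.na(col))) NA_real_
               else max(col, na.rm = TRUE))
  new("QCReport", ecd = ecdM, deviations = dev, reference = reference,
      maxAbsDeviation = mad, excluded = as.integer(excluded))
}

#' Threshold-sensitivity analysis
#'
#' Re-runs segmentation and morphometry of one micrograph over a list of
#' threshold percentages and reports the particle count per threshold plus
#' the ECD of particles matched (by centroid) to the first threshold's
#' particle set, as a function of TH.
#'
#' @param m a [Micrograph-class].
#' @param cfg base [segmentationConfig()] (its own thPercent is ignored).
#' @param thList threshold percentages, each in (0, 100].
#' @param toleranceNm matching tolerance; default two pixels in nm.
#' @return \code{list(counts, ecd)}: a data.frame (th_percent, n) and a
#'   matched-particle x threshold ECD matrix.
#' @export
thresholdSensitivity <- function(m, cfg, thList, toleranceNm = NULL) {
  if (length(thList) == 0) stop("thList must be nonempty")
  if (any(thList <= 0 | thList > 100)) stop("thresholds must lie in (0, 100]")
  if (is.null(toleranceNm)) toleranceNm <- 2 * nmPerPx(m)
  tables <- lapply(thList, function(th) {
    cfg$thPercent <- th
    particleTable(measureParticles(extractParticles(m, cfg)))
  })
  names(tables) <- make.unique(sprintf("TH_%g", thList))
  counts <- data.frame(th_percent = thList,
                       n = vapply(tables, nrow, integer(1)))
  rownames(counts) <- NULL
  mt <- matchParticles(tables, toleranceNm = toleranceNm)
  list(counts = counts, ecd = mt$ecd)
}
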