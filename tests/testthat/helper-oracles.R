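# Independent oracles and small fixture builders used across the suite.

# brute-force connected-component labeling by depth-first flood fill
floodLabel <- function(mask, connectivity = 8L) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  if (connectivity == 8L) {
    dr <- c(-1, -1, -1, 0, 0, 1, 1, 1)
    dc <- c(-1, 0, 1, -1, 1, -1, 0, 1)
  } else {
    dr <- c(-1, 1, 0, 0); dc <- c(0, 0, -1, 1)
  }
  cur <- 0L
  stackR <- integer(ny * nx); stackC <- integer(ny * nx)
  for (c0 in seq_len(nx)) for (r0 in seq_len(ny)) {
    if (!mask[r0, c0] || lab[r0, c0] > 0L) next
    cur <- cur + 1L
    sp <- 1L
    stackR[1] <- r0; stackC[1] <- c0
    lab[r0, c0] <- cur
    while (sp > 0L) {
      r <- stackR[sp]; c <- stackC[sp]; sp <- sp - 1L
      for (k in seq_along(dr)) {
        rr <- r + dr[k]; cc <- c + dc[k]
        if (rr >= 1 && rr <= ny && cc >= 1 && cc <= nx &&
            mask[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- cur
          sp <- sp + 1L
          stackR[sp] <- rr; stackC[sp] <- cc
        }
      }
    }
  }
  lab
}

# canonical partition of a label matrix: list of sorted pixel-index sets,
# ordered by their smallest member (label-permutation invariant)
labelPartition <- function(lab) {
  grp <- split(which(lab > 0L), lab[lab > 0L])
  grp <- unname(lapply(grp, sort))
  grp[order(vapply(grp, `[`, numeric(1), 1))]
}

# brute-force maximum pairwise distance over a corner set
bruteFeretPx <- function(corners) {
  dx <- outer(corners[, 1], corners[, 1], "-")
  dy <- outer(corners[, 2], corners[, 2], "-")
  sqrt(max(dx^2 + dy^2))
}

# random connected region inside maxSide x maxSide: largest flood-fill
# component of a thresholded smooth noise field
randomRegion <- function(seed, maxSide = 64L) {
  set.seed(seed)
  ny <- sample(8:maxSide, 1); nx <- sample(8:maxSide, 1)
  field <- matrix(rnorm(ny * nx), ny, nx)
  k <- matrix(1, 3, 3) / 9
  field <- as.matrix(EBImage::filter2(field, k, boundary = "replicate"))
  mask <- field > quantile(field, runif(1, 0.55, 0.9))
  lab <- floodLabel(mask, 8L)
  if (max(lab) == 0) return(randomRegion(seed + 10000L, maxSide))
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

# published cross-magnification ECD comparison of two CeNP triplets
# (particles 1-3 and 4-6; reference = highest magnification)
table2ECD <- function() {
  cbind("150000" = c(3.0, 11.8, 5.3, 10.2, 3.3, 5.0),
        "100000" = c(3.1, 11.0, 4.8, 9.5, 3.3, 4.6),
        "10000"  = c(2.4, 11.6, 5.4, 11.3, 4.0, 6.0))
}

# flat-background scene of dark disks on a jittered grid
diskGridScene <- function(radiiNm, pitchNm = 20, contrast = -60, noiseSd = 0,
                          seed = 1L, jitterNm = 0, perRow = 10L,
                          background = backgroundSpec(gradientAmplitude = 0,
                                                     textureAmplitude = 0)) {
  n <- length(radiiNm)
  set.seed(seed)
  parts <- lapply(seq_len(n), function(i) {
    gx <- (i - 1) %% perRow; gy <- (i - 1) %/% perRow
    diskParticle(pitchNm + gx * pitchNm + runif(1, -jitterNm, jitterNm),
                 pitchNm + gy * pitchNm + runif(1, -jitterNm, jitterNm),
                 radiiNm[i], contrast = contrast)
  })
  rows <- ceiling(n / perRow)
  buildScene(sceneSpec(pitchNm * (min(n, perRow) + 1), pitchNm * (rows + 1),
                       parts, background = background, noiseSd = noiseSd,
                       seed = seed))
}

# binary micrograph with the given foreground mask (dark pixels on bright)
maskMicrograph <- function(mask, nmPerPx = 1, dark = 0, bright = 255) {
  px <- matrix(bright, nrow(mask), ncol(mask))
  px[mask] <- dark
  Micrograph(px, nmPerPx)
}

# match a measured table against scene truth by nearest centroid
matchToTruth <- function(tab, truth, toleranceNm) {
  matchParticles(list(
    truth = data.frame(id = truth$id, cx_nm = truth$cx_nm,
                       cy_nm = truth$cy_nm, ecd_nm = truth$true_ecd_nm),
    measured = tab), toleranceNm = toleranceNm)
}
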