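# Shell-ROI quantification of nuclear immunofluorescence.

#' NucleusImage accessors
#' @param x A [NucleusImage-class].
#' @name NucleusImage-accessors
NULL

#' @rdname NucleusImage-accessors
#' @export
setMethod("pixelSize", "NucleusImage", function(x) x@pixelSize)

#' @rdname NucleusImage-accessors
#' @export
setMethod("nucleusMask", "NucleusImage", function(x) x@nucleusMask)

#' @rdname NucleusImage-accessors
#' @export
setMethod("nucleolusMask", "NucleusImage", function(x) x@nucleolusMask)

#' @rdname NucleusImage-accessors
#' @export
setMethod("intensityValues", "NucleusImage", function(x) x@intensity)

#' @rdname NucleusImage-accessors
#' @export
setMethod("roiMask", "ShellROI", function(x) x@mask)

setMethod("show", "NucleusImage", function(object) {
  cat("NucleusImage", paste(dim(object@intensity), collapse = "x"),
      "px @", object@pixelSize, "nm;",
      sum(object@nucleusMask), "nucleus px,",
      sum(object@nucleolusMask), "nucleolus px\n")
})

setMethod("show", "ShellROI", function(object) {
  cat("ShellROI (", object@origin, "):", sum(object@mask), "px, depth",
      object@depthNm, "nm =", object@depthPx, "px\n")
})

#' Build a fixed-depth shell region of interest
#'
#' The lamina shell holds the nucleus pixels within `depthNm` (inward,
#' Euclidean on the physical grid) of the nuclear boundary; the
#' perinucleolar shell the nucleus pixels outside the nucleolus within
#' `depthNm` (outward) of the nucleolar boundary. The physical depth is
#' rounded to whole pixels (240 nm at 80.25 nm pixels gives 3 px). The
#' two shells are not forced to be exclusive. 2D sections only.
#'
#' @param image A [NucleusImage-class] (2D).
#' @param origin "lamina" or "perinucleolar".
#' @param depthNm Shell depth in nm (default 240).
#' @return A [ShellROI-class].
#' @export
shellROI <- function(image, origin = c("lamina", "perinucleolar"),
                     depthNm = 240) {
  origin <- match.arg(origin)
  if (length(dim(image@intensity)) != 2)
    stop("shell ROIs are defined on 2D sections")
  depthPx <- as.integer(round(depthNm / pixelSize(image)))
  nuc <- nucleusMask(image)
  empty <- array(FALSE, dim(nuc))
  if (depthPx <= 0)
    return(new("ShellROI", mask = empty, origin = origin,
               depthNm = depthNm, depthPx = depthPx))
  if (origin == "lamina") {
    if (!any(nuc)) {
      warning("empty nucleus mask; empty shell")
      return(new("ShellROI", mask = empty, origin = origin,
                 depthNm = depthNm, depthPx = depthPx))
    }
    d <- EBImage::distmap(EBImage::Image(nuc * 1), metric = "euclidean")
    mask <- nuc & as.matrix(d) <= depthPx
  } else {
    nlo <- nucleolusMask(image)
    if (!any(nlo)) {
      warning("empty nucleolus mask; empty shell")
      return(new("ShellROI", mask = empty, origin = origin,
                 depthNm = depthNm, depthPx = depthPx))
    }
    d <- EBImage::distmap(EBImage::Image((!nlo) * 1), metric = "euclidean")
    mask <- nuc & !nlo & as.matrix(d) <= depthPx
  }
  new("ShellROI", mask = mask, origin = origin,
      depthNm = depthNm, depthPx = depthPx)
}

#' Intensity statistics of a region of interest
#'
#' Computes (i) the ROI's fraction of total nuclear fluorescence,
#' (ii) the heterogeneity of the staining inside the ROI as the
#' coefficient of variation (sd / mean), and (iii) the share of bright
#' nuclear pixels falling inside the ROI. "Bright" defaults to pixels at
#' or above 90 percent of the maximal nuclear intensity
#' (`brightMode = "threshold90"`); `"decile"` instead takes the top 10
#' percent of nuclear pixels by rank. All three metrics are invariant to
#' multiplying the image by a positive constant.
#'
#' @param image A [NucleusImage-class].
#' @param roi A [ShellROI-class] or a logical mask inside the nucleus.
#' @param brightMode "threshold90" or "decile".
#' @return One-row data.frame: region, intensity_fraction, cv,
#'   bright_fraction (NaN sentinels where undefined).
#' @export
roiIntensityStats <- function(image, roi,
                              brightMode = c("threshold90", "decile")) {
  brightMode <- match.arg(brightMode)
  m <- if (is(roi, "ShellROI")) roiMask(roi) else roi
  region <- if (is(roi, "ShellROI")) roi@origin else "custom"
  nuc <- nucleusMask(image)
  if (any(m & !nuc)) stop("ROI extends outside the nucleus mask")
  I <- intensityValues(image)
  tot <- sum(I[nuc])
  v <- I[m]
  frac <- if (tot > 0) sum(v) / tot else NaN
  cv <- if (length(v) && mean(v) > 0) sd(v) / mean(v) else NaN
  nucVals <- I[nuc]
  bright <- if (brightMode == "threshold90") {
    I >= 0.9 * max(nucVals) & nuc
  } else {
    thr <- quantile(nucVals, 0.9, names = FALSE)
    I >= thr & nuc
  }
  nb <- sum(bright)
  bf <- if (nb > 0) sum(bright & m) / nb else NaN
  data.frame(region = region, intensity_fraction = frac, cv = cv,
             bright_fraction = bf)
}

#' Quantify both shells of a nucleus in one call
#'
#' @param image A [NucleusImage-class].
#' @param depthNm Shell depth in nm.
#' @param brightMode Passed to [roiIntensityStats()].
#' @return data.frame with one row per region (lamina, perinucleolar,
#'   nucleus).
#' @export
quantifyShells <- function(image, depthNm = 240,
                           brightMode = "threshold90") {
  lam <- shellROI(image, "lamina", depthNm)
  per <- shellROI(image, "perinucleolar", depthNm)
  rows <- rbind(roiIntensityStats(image, lam, brightMode),
                roiIntensityStats(image, per, brightMode),
                roiIntensityStats(image, nucleusMask(image), brightMode))
  rows$region <- c("lamina", "perinucleolar", "nucleus")
  rows
}

#' Label connected components of a boolean mask
#'
#' Frontier-vectorized flood fill with 8-connectivity in 2D and
#' 26-connectivity in 3D.
#'
#' @param mask Logical array (2D or 3D).
#' @return Integer array of the same shape; 0 is background, objects are
#'   numbered from 1.
#' @export
labelComponents <- function(mask) {
  d <- dim(mask)
  nd <- length(d)
  stopifnot(nd %in% c(2, 3), is.logical(mask))
  lab <- array(0L, d)
  remaining <- which(mask)
  if (!length(remaining)) return(lab)
  # neighbor offsets in linear index space, guarded against wrap-around
  if (nd == 2) {
    steps <- expand.grid(dx = -1:1, dy = -1:1)
    steps <- steps[!(steps$dx == 0 & steps$dy == 0), ]
    steps$dz <- 0L
  } else {
    steps <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
    steps <- steps[!(steps$dx == 0 & steps$dy == 0 & steps$dz == 0), ]
  }
  nx <- d[1]; ny <- d[2]; nz <- if (nd == 3) d[3] else 1L
  toXYZ <- function(idx) {
    idx0 <- idx - 1L
    cbind(x = idx0 %% nx + 1L,
          y = (idx0 %/% nx) %% ny + 1L,
          z = idx0 %/% (nx * ny) + 1L)
  }
  inMask <- array(FALSE, c(nx, ny, nz))
  inMask[seq_along(mask)] <- mask
  labv <- array(0L, c(nx, ny, nz))
  nextLab <- 0L
  seen <- array(FALSE, c(nx, ny, nz))
  for (seedIdx in remaining) {
    if (seen[seedIdx]) next
    nextLab <- nextLab + 1L
    frontier <- seedIdx
    seen[seedIdx] <- TRUE
    while (length(frontier)) {
      labv[frontier] <- nextLab
      xyz <- toXYZ(frontier)
      cand <- integer(0)
      for (s in seq_len(nrow(steps))) {
        x <- xyz[, 1] + steps$dx[s]
        y <- xyz[, 2] + steps$dy[s]
        z <- xyz[, 3] + steps$dz[s]
        ok <- x >= 1 & x <= nx & y >= 1 & y <= ny & z >= 1 & z <= nz
        if (!any(ok)) next
        idx <- (z[ok] - 1L) * nx * ny + (y[ok] - 1L) * nx + x[ok]
        cand <- c(cand, idx[inMask[idx] & !seen[idx]])
      }
      cand <- unique(cand)
      seen[cand] <- TRUE
      frontier <- cand
    }
  }
  lab[seq_along(lab)] <- labv[seq_len(length(lab))]
  lab
}

#' Count mask objects and measure their volumes
#'
#' Connected components (8-connectivity in 2D, 26-connectivity in 3D)
#' with per-object voxel counts and volumes in cubic micrometers
#' (voxel count times voxel volume). When a reference mask is given
#' (e.g. the nucleus for a nucleolus mask) the total volume ratio is
#' reported too.
#'
#' @param mask Logical array.
#' @param voxelSize Physical voxel edge lengths in micrometers (length 2
#'   or 3 matching the mask).
#' @param refMask Optional logical reference mask of the same shape.
#' @return List: count, voxels (per object), volumes (um^3 per object),
#'   totalVolume, and volumeRatio when `refMask` is given.
#' @export
countObjectsAndVolumes <- function(mask, voxelSize, refMask = NULL) {
  stopifnot(length(voxelSize) == length(dim(mask)), all(voxelSize > 0))
  lab <- labelComponents(mask)
  voxVol <- prod(voxelSize)
  if (!any(mask)) {
    out <- list(count = 0L, voxels = integer(0), volumes = numeric(0),
                totalVolume = 0)
  } else {
    tb <- tabulate(lab[lab > 0])
    out <- list(count = length(tb), voxels = tb, volumes = tb * voxVol,
                totalVolume = sum(tb) * voxVol)
  }
  if (!is.null(refMask)) {
    stopifnot(identical(dim(refMask), dim(mask)))
    refVol <- sum(refMask) * voxVol
    out$volumeRatio <- if (refVol > 0) out$totalVolume / refVol else NaN
  }
  out
}
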