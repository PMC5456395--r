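#' Simulate a nucleus immunofluorescence image with known shell fractions
#'
#' Builds a circular nucleus with disjoint nucleolar disks, then deposits
#' fluorescence so that exactly the requested fractions of total nuclear
#' intensity fall into the lamina shell and the perinucleolar shell
#' (fixed physical depth, default 240 nm). Within each region the signal
#' is uniform plus optional Gaussian bright foci, and the per-region
#' totals are rescaled to the target budgets, so the deposited fractions
#' are exact before noise. Multiplicative lognormal noise (mean 1) is
#' applied last. A 3D stack mode builds spherical masks with uniform
#' intensity for object counting and volumetry.
#'
#' @param imageShape Pixels per side (length-2 for 2D sections).
#' @param pixelSize xy pixel edge, nm.
#' @param nucleusRadius Nucleus radius, nm.
#' @param nucleolusRadii Nucleolus radii, nm (length = `nNucleoli`,
#'   recycled).
#' @param nNucleoli Number of nucleoli.
#' @param laminaFraction,perinucleolarFraction Target fractions of total
#'   nuclear intensity deposited in the two shells (sum <= 1). Defaults
#'   are typical proliferating-fibroblast medians for H3K9me3.
#' @param focusCount,focusBrightness,focusSigmaPx Bright-focus model:
#'   number of Gaussian foci, peak amplitude relative to the uniform
#'   level, and focus width in pixels.
#' @param noiseSd sdlog of the multiplicative lognormal noise (0 = none).
#' @param shellDepthNm Shell depth, nm.
#' @param stack If TRUE, return a 3D stack (masks + uniform intensity)
#'   instead of a 2D section.
#' @param nSlices,zStep Stack depth and z step (nm), 3D mode only.
#' @param seed Integer seed.
#' @return List with `image` (a [NucleusImage-class]) and `truth`
#'   (targets, realized per-region intensity fractions and CVs computed
#'   by direct summation over the deposited regions, focus positions; in
#'   3D mode per-nucleolus voxel counts and volumes).
#' @export
simulateNucleusImage <- function(imageShape = c(160L, 160L),
                                 pixelSize = 80.25,
                                 nucleusRadius = 5500,
                                 nucleolusRadii = c(1600, 1200, 1000),
                                 nNucleoli = 3L,
                                 laminaFraction = 0.095,
                                 perinucleolarFraction = 0.052,
                                 focusCount = 6L, focusBrightness = 4,
                                 focusSigmaPx = 2, noiseSd = 0.02,
                                 shellDepthNm = 240,
                                 stack = FALSE, nSlices = 25L, zStep = 500,
                                 seed = 1L) {
  stopifnot(laminaFraction >= 0, perinucleolarFraction >= 0,
            laminaFraction + perinucleolarFraction <= 1,
            nucleusRadius > 0, pixelSize > 0)
  set.seed(seed)
  nNucleoli <- as.integer(nNucleoli)
  radiiPx <- rep_len(nucleolusRadii, max(nNucleoli, 1L)) / pixelSize
  Rpx <- nucleusRadius / pixelSize
  nx <- imageShape[1]; ny <- imageShape[2]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  if (cx - Rpx < 1.5 || cy - Rpx < 1.5)
    stop("nucleus does not fit inside the image")

  ix <- matrix(seq_len(nx), nx, ny)
  iy <- matrix(rep(seq_len(ny), each = nx), nx, ny)
  rad2 <- (ix - cx)^2 + (iy - cy)^2
  nucleus <- rad2 <= Rpx^2

  # nucleolus centers on a ring, evenly spaced in angle
  nucleolus <- matrix(FALSE, nx, ny)
  centers <- NULL
  if (nNucleoli > 0) {
    ringR <- 0.45 * Rpx
    ang <- 2 * pi * (seq_len(nNucleoli) - 1) / nNucleoli + runif(1, 0, 2 * pi)
    ccx <- cx + ringR * cos(ang); ccy <- cy + ringR * sin(ang)
    for (k in seq_len(nNucleoli)) {
      if (sqrt((ccx[k] - cx)^2 + (ccy[k] - cy)^2) + radiiPx[k] > Rpx - 1)
        stop("nucleolus ", k, " extends outside the nucleus")
      nucleolus <- nucleolus |
        ((ix - ccx[k])^2 + (iy - ccy[k])^2 <= radiiPx[k]^2)
    }
    centers <- cbind(x = ccx, y = ccy, radiusPx = radiiPx[seq_len(nNucleoli)])
  }

  if (stack) {
    nz <- as.integer(nSlices)
    zC <- (nz + 1) / 2
    Rz <- nucleusRadius / zStep
    nuc3 <- array(FALSE, c(nx, ny, nz))
    nlo3 <- array(FALSE, c(nx, ny, nz))
    for (z in seq_len(nz)) {
      dz <- (z - zC)
      nuc3[, , z] <- (rad2 / Rpx^2 + dz^2 / Rz^2) <= 1
      if (nNucleoli > 0) for (k in seq_len(nNucleoli)) {
        rk <- centers[k, "radiusPx"]
        rkz <- rk * pixelSize / zStep
        nlo3[, , z] <- nlo3[, , z] |
          (((ix - centers[k, "x"])^2 + (iy - centers[k, "y"])^2) / rk^2 +
             dz^2 / rkz^2) <= 1
      }
    }
    nlo3 <- nlo3 & nuc3
    img <- new("NucleusImage", intensity = array(as.numeric(nuc3), dim(nuc3)),
               nucleusMask = nuc3, nucleolusMask = nlo3,
               pixelSize = pixelSize, zStep = zStep)
    voxVol <- (pixelSize / 1000)^2 * (zStep / 1000)
    return(list(image = img,
                truth = list(nNucleoli = nNucleoli,
                             nucleusVoxels = sum(nuc3),
                             nucleusVolume = sum(nuc3) * voxVol,
                             nucleolusVoxels = sum(nlo3),
                             nucleolusVolume = sum(nlo3) * voxVol)))
  }

  img0 <- new("NucleusImage",
              intensity = array(as.numeric(nucleus), c(nx, ny)),
              nucleusMask = nucleus, nucleolusMask = nucleolus,
              pixelSize = pixelSize, zStep = NA_real_)
  lamina <- roiMask(shellROI(img0, "lamina", shellDepthNm))
  perinu <- roiMask(shellROI(img0, "perinucleolar", shellDepthNm)) & !lamina
  rest <- nucleus & !lamina & !perinu

  # uniform base plus bright foci, then per-region rescaling to budgets
  pattern <- array(0, c(nx, ny))
  pattern[nucleus] <- 1
  foci <- NULL
  if (focusCount > 0) {
    cand <- which(nucleus)
    pick <- sample(cand, focusCount)
    fx <- ((pick - 1) %% nx) + 1
    fy <- ((pick - 1) %/% nx) + 1
    for (k in seq_len(focusCount))
      pattern <- pattern + focusBrightness *
        exp(-((ix - fx[k])^2 + (iy - fy[k])^2) / (2 * focusSigmaPx^2))
    pattern[!nucleus] <- 0
    foci <- cbind(x = fx, y = fy)
  }
  budget <- c(lamina = laminaFraction, perinucleolar = perinucleolarFraction,
              rest = 1 - laminaFraction - perinucleolarFraction)
  total <- 1000
  intensity <- array(0, c(nx, ny))
  for (rg in names(budget)) {
    m <- switch(rg, lamina = lamina, perinucleolar = perinu, rest = rest)
    s <- sum(pattern[m])
    if (s > 0) intensity[m] <- pattern[m] * (budget[[rg]] * total / s)
  }
  if (noiseSd > 0)
    intensity[nucleus] <- intensity[nucleus] *
      exp(rnorm(sum(nucleus), 0, noiseSd) - noiseSd^2 / 2)

  img <- new("NucleusImage", intensity = intensity,
             nucleusMask = nucleus, nucleolusMask = nucleolus,
             pixelSize = pixelSize, zStep = NA_real_)
  regionStats <- function(m) {
    v <- intensity[m]
    c(fraction = sum(v) / sum(intensity[nucleus]),
      cv = if (length(v) && mean(v) > 0) sd(v) / mean(v) else NA_real_)
  }
  truth <- list(targets = budget,
                realized = rbind(lamina = regionStats(lamina),
                                 perinucleolar = regionStats(perinu),
                                 rest = regionStats(rest)),
                shellDepthNm = shellDepthNm,
                foci = foci,
                nucleolusCenters = centers)
  list(image = img, truth = truth)
}
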