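#' Specification of a synthetic nucleus image
#'
#' Describes the analytic geometry and rendering parameters of a single
#' nucleus-centred field: an ellipsoidal chromatin-filled nucleus with a thin
#' lamina shell, a perinuclear tubulin band with tunable tip-biased
#' enrichment, optional tip chromatin protrusion (with a local lamina gap),
#' and punctate perinuclear foci. Rendering is geometric: blur and noise are
#' optional post-processing, and the analytic ground truth is recorded
#' before either is applied.
#'
#' @param dimensionality 2 (mid-plane, default) or 3.
#' @param voxelSize micrometres per voxel; defaults to 0.1 (2-D) or 0.25
#'   (3-D).
#' @param gridShape integer vector of grid sides, or NULL to size the grid
#'   automatically so the cytoplasmic reference band fits.
#' @param semiAxes nucleus semi-axes in micrometres, c(major, minor); in 3-D
#'   the nucleus is a prolate spheroid unless a third value is given.
#' @param orientation radians, major-axis angle in the image plane.
#' @param chromatinLevel,laminaLevel,cytLevel arbitrary intensity units.
#' @param laminaThickness micrometres.
#' @param protrusionProb per-image probability of a tip chromatin
#'   protrusion; ignored when \code{protrusionPresent} is TRUE/FALSE.
#' @param protrusionPresent logical or NA (draw from \code{protrusionProb}).
#' @param protrusionRadius micrometres, radius of the protruding blob.
#' @param protrusionOffset micrometres, distance of the blob centre beyond
#'   the nuclear tip.
#' @param protrusionTipSign +1, -1 or NA (random tip).
#' @param laminaCoverage fraction of the lamina retained over the
#'   protrusion; below 1 a local gap is opened.
#' @param enrichmentFactor target perinuclear/cytoplasmic tubulin ratio
#'   (1 = no cage).
#' @param ringWidth micrometres, width of the rendered tubulin band.
#' @param tipBoost tip-to-side tubulin level ratio within the band; levels
#'   are normalized so the band mean still equals
#'   \code{enrichmentFactor * cytLevel}.
#' @param nuclearTubulinLevel residual tubulin level inside the nucleus.
#' @param fociRate Poisson mean of perinuclear foci per image; ignored when
#'   \code{fociCenters} is given.
#' @param fociCenters optional matrix of focus centres (micrometres, image
#'   coordinates centred on the nucleus).
#' @param fociRadius,fociLevel micrometres and intensity of each focus.
#' @param fociBandWidth micrometres, foci are planted within this distance
#'   outside the nuclear border.
#' @param psfSigma micrometres, Gaussian blur applied after rendering
#'   (0 = none).
#' @param noiseModel "gaussian" or "poisson-gaussian".
#' @param noiseSD additive noise standard deviation, intensity units.
#' @param genotype label carried through to cohort tables.
#' @param seed integer.
#' @return A validated list of class \code{ImageSpec}.
#' @export
imageSpec <- function(dimensionality = 2, voxelSize = NULL, gridShape = NULL,
                      semiAxes = c(5.45, 2.6), orientation = 0,
                      chromatinLevel = 1, laminaThickness = 0.15,
                      laminaLevel = 1, protrusionProb = 0,
                      protrusionPresent = NA, protrusionRadius = 0.8,
                      protrusionOffset = 0.3, protrusionTipSign = NA,
                      laminaCoverage = 0.5, cytLevel = 0.6,
                      enrichmentFactor = 2, ringWidth = 1.5, tipBoost = 1,
                      nuclearTubulinLevel = 0.09, fociRate = 0,
                      fociCenters = NULL, fociRadius = 0.25, fociLevel = 1.5,
                      fociBandWidth = 0.9, psfSigma = 0,
                      noiseModel = c("gaussian", "poisson-gaussian"),
                      noiseSD = 0, genotype = "custom", seed = 1L) {
  noiseModel <- match.arg(noiseModel)
  if (is.null(voxelSize)) voxelSize <- if (dimensionality == 2) 0.1 else 0.25
  a <- semiAxes[1]
  b <- semiAxes[2]
  if (a < b) stop("semiAxes must be ordered major, minor")
  if (is.null(gridShape)) {
    nx <- 2L * as.integer(ceiling((a + 5.5) / voxelSize)) + 1L
    ny <- 2L * as.integer(ceiling((b + 5.5) / voxelSize)) + 1L
    gridShape <- if (dimensionality == 2) {
      if (abs(orientation) > 1e-9) c(nx, nx) else c(nx, ny)
    } else c(nx, ny, ny)
  }
  s <- list(dimensionality = dimensionality, voxelSize = voxelSize,
            gridShape = as.integer(gridShape), semiAxes = semiAxes,
            orientation = orientation, chromatinLevel = chromatinLevel,
            laminaThickness = laminaThickness, laminaLevel = laminaLevel,
            protrusionProb = protrusionProb,
            protrusionPresent = protrusionPresent,
            protrusionRadius = protrusionRadius,
            protrusionOffset = protrusionOffset,
            protrusionTipSign = protrusionTipSign,
            laminaCoverage = laminaCoverage, cytLevel = cytLevel,
            enrichmentFactor = enrichmentFactor, ringWidth = ringWidth,
            tipBoost = tipBoost, nuclearTubulinLevel = nuclearTubulinLevel,
            fociRate = fociRate, fociCenters = fociCenters,
            fociRadius = fociRadius, fociLevel = fociLevel,
            fociBandWidth = fociBandWidth, psfSigma = psfSigma,
            noiseModel = noiseModel, noiseSD = noiseSD, genotype = genotype,
            seed = as.integer(seed))
  class(s) <- "ImageSpec"
  validateImageSpec(s)
  s
}

validateImageSpec <- function(s) {
  if (!s$dimensionality %in% c(2, 3))
    stop("dimensionality must be 2 or 3")
  half <- s$gridShape * s$voxelSize / 2
  a <- s$semiAxes[1]
  b <- s$semiAxes[2]
  ext <- if (abs(s$orientation) > 1e-9) rep(a, 2) else c(a, b)
  if (s$dimensionality == 3) ext <- c(ext, if (length(s$semiAxes) >= 3)
    s$semiAxes[3] else b)
  if (any(ext + 2 > half))
    stop("geometry error: nucleus must fit in the grid with a 2 um margin")
  if (s$enrichmentFactor < 0) stop("enrichmentFactor must be >= 0")
  if (s$ringWidth <= 0) stop("ringWidth must be positive")
  if (s$laminaThickness >= b) stop("laminaThickness must be below the minor",
                                   " semi-axis")
  invisible(TRUE)
}

## Pixel-centre coordinate matrices (um), origin at the grid centre.
.gridCoords2d <- function(gridShape, voxelSize) {
  nx <- gridShape[1]; ny <- gridShape[2]
  x <- (seq_len(nx) - (nx + 1) / 2) * voxelSize
  y <- (seq_len(ny) - (ny + 1) / 2) * voxelSize
  list(X = matrix(x, nx, ny), Y = matrix(y, nx, ny, byrow = TRUE))
}

#' Render a synthetic nucleus image
#'
#' @param spec an \code{\link{imageSpec}}.
#' @return A \linkS4class{NucleusImage} with channels chromatin, tubulin,
#'   foci, lamina and the analytic ground truth.
#' @examples
#' img <- generateNucleusImage(imageSpec(enrichmentFactor = 2, seed = 7))
#' img
#' @export
generateNucleusImage <- function(spec) {
  stopifnot(inherits(spec, "ImageSpec"))
  validateImageSpec(spec)
  set.seed(spec$seed)
  if (spec$dimensionality == 2) .renderNucleus2d(spec) else
    .renderNucleus3d(spec)
}

.renderNucleus2d <- function(spec) {
  v <- spec$voxelSize
  a <- spec$semiAxes[1]; b <- spec$semiAxes[2]
  g <- .gridCoords2d(spec$gridShape, v)
  ct <- cos(spec$orientation); st <- sin(spec$orientation)
  Xe <- g$X * ct + g$Y * st        # ellipse-frame coordinates
  Ye <- -g$X * st + g$Y * ct
  rho2 <- (Xe / a)^2 + (Ye / b)^2
  mask <- rho2 <= 1

  ## random draws in fixed order for seeded reproducibility
  protr <- spec$protrusionPresent
  if (is.na(protr)) protr <- stats::runif(1) < spec$protrusionProb
  tipSign <- spec$protrusionTipSign
  if (is.na(tipSign)) tipSign <- sample(c(-1, 1), 1)
  if (is.null(spec$fociCenters)) {
    nFoci <- stats::rpois(1, spec$fociRate)
    th <- stats::runif(nFoci, 0, 2 * pi)
    dd <- stats::runif(nFoci, 0.08, spec$fociBandWidth)
  } else {
    nFoci <- nrow(spec$fociCenters)
  }

  chromatin <- spec$chromatinLevel * mask
  protrArea <- 0
  protrCenter <- NULL
  if (isTRUE(protr)) {
    cx <- tipSign * (a + spec$protrusionOffset)
    blob <- (Xe - cx)^2 + Ye^2 <= spec$protrusionRadius^2
    ## chromatin is continuous with the nucleus: a neck of half the blob
    ## radius bridges the tip and the blob centre
    xlo <- min(tipSign * (a - 0.2), cx)
    xhi <- max(tipSign * (a - 0.2), cx)
    neck <- Xe >= xlo & Xe <= xhi &
      abs(Ye) <= 0.5 * spec$protrusionRadius
    blob <- blob | neck
    chromatin[blob] <- spec$chromatinLevel
    protrArea <- sum(blob & !mask) * v^2
    protrCenter <- c(cx * ct, cx * st)
  }

  innerA <- a - spec$laminaThickness
  innerB <- b - spec$laminaThickness
  lamina <- spec$laminaLevel *
    (mask & ((Xe / innerA)^2 + (Ye / innerB)^2 > 1))
  if (isTRUE(protr) && spec$laminaCoverage < 1) {
    gap <- (Xe - tipSign * (a + spec$protrusionOffset))^2 + Ye^2 <=
      spec$protrusionRadius^2
    lamina[gap] <- 0
  }

  ## tubulin: band within ringWidth of the border, tip-boosted, normalized
  ## so the band mean equals enrichmentFactor * cytLevel exactly
  dOut <- .distanceOutside(mask) * v
  ring <- !mask & dOut <= spec$ringWidth
  tipSector <- abs(cos(atan2(Ye, Xe))) >= cos(pi / 6)
  tubulin <- matrix(spec$cytLevel, nrow(mask), ncol(mask))
  nt <- sum(ring & tipSector); ns <- sum(ring & !tipSector)
  if (nt + ns > 0) {
    Ls <- spec$enrichmentFactor * spec$cytLevel * (nt + ns) /
      (ns + spec$tipBoost * nt)
    tubulin[ring & !tipSector] <- Ls
    tubulin[ring & tipSector] <- spec$tipBoost * Ls
  }
  tubulin[mask] <- spec$nuclearTubulinLevel

  foci <- matrix(0, nrow(mask), ncol(mask))
  centers <- matrix(numeric(0), 0, 2)
  if (nFoci > 0) {
    if (is.null(spec$fociCenters)) {
      bx <- a * cos(th); by <- b * sin(th)
      nrm <- cbind(bx / a^2, by / b^2)
      nrm <- nrm / sqrt(rowSums(nrm^2))
      ce <- cbind(bx, by) + dd * nrm          # ellipse frame
      centers <- cbind(ce[, 1] * ct - ce[, 2] * st,
                       ce[, 1] * st + ce[, 2] * ct)
    } else centers <- spec$fociCenters
    for (k in seq_len(nrow(centers)))
      foci[(g$X - centers[k, 1])^2 + (g$Y - centers[k, 2])^2 <=
             spec$fociRadius^2] <- spec$fociLevel
  }

  channels <- list(chromatin = chromatin, tubulin = tubulin, foci = foci,
                   lamina = lamina)
  channels <- lapply(channels, .blurNoise, spec = spec)

  gt <- list(nuclearLength = 2 * a, nuclearWidth = 2 * b, aspectRatio = a / b,
             area = pi * a * b, protrusionPresent = isTRUE(protr),
             protrusionArea = protrArea, protrusionCenter = protrCenter,
             enrichmentFactor = spec$enrichmentFactor, fociCount = nFoci,
             fociCenters = centers, orientation = spec$orientation,
             tipSign = tipSign)
  new("NucleusImage", channels = channels, voxelSize = v, groundTruth = gt,
      seed = spec$seed)
}

.renderNucleus3d <- function(spec) {
  v <- spec$voxelSize
  a <- spec$semiAxes[1]; b <- spec$semiAxes[2]
  cc <- if (length(spec$semiAxes) >= 3) spec$semiAxes[3] else b
  sh <- spec$gridShape
  x <- (seq_len(sh[1]) - (sh[1] + 1) / 2) * v
  y <- (seq_len(sh[2]) - (sh[2] + 1) / 2) * v
  z <- (seq_len(sh[3]) - (sh[3] + 1) / 2) * v
  X <- array(rep(x, times = sh[2] * sh[3]), sh)
  Y <- array(rep(rep(y, each = sh[1]), times = sh[3]), sh)
  Z <- array(rep(z, each = sh[1] * sh[2]), sh)
  rho <- sqrt((X / a)^2 + (Y / b)^2 + (Z / cc)^2)
  mask <- rho <= 1

  protr <- spec$protrusionPresent
  if (is.na(protr)) protr <- stats::runif(1) < spec$protrusionProb
  tipSign <- spec$protrusionTipSign
  if (is.na(tipSign)) tipSign <- sample(c(-1, 1), 1)

  chromatin <- spec$chromatinLevel * mask
  protrVol <- 0
  if (isTRUE(protr)) {
    cx <- tipSign * (a + spec$protrusionOffset)
    blob <- (X - cx)^2 + Y^2 + Z^2 <= spec$protrusionRadius^2
    xlo <- min(tipSign * (a - 0.2), cx)
    xhi <- max(tipSign * (a - 0.2), cx)
    blob <- blob | (X >= xlo & X <= xhi &
                      sqrt(Y^2 + Z^2) <= 0.5 * spec$protrusionRadius)
    chromatin[blob] <- spec$chromatinLevel
    protrVol <- sum(blob & !mask) * v^3
  }

  innerRho <- sqrt((X / (a - spec$laminaThickness))^2 +
                   (Y / (b - spec$laminaThickness))^2 +
                   (Z / (cc - spec$laminaThickness))^2)
  lamina <- spec$laminaLevel * (mask & innerRho > 1)

  ## band distance approximated by (rho - 1) * minor semi-axis: an
  ## underestimate of the true distance, so the band is a superset of the
  ## true euclidean shell (enrichment analysis is 2-D mid-plane only)
  dApprox <- (rho - 1) * min(b, cc)
  ring <- !mask & dApprox <= spec$ringWidth
  tubulin <- array(spec$cytLevel, sh)
  tubulin[ring] <- spec$enrichmentFactor * spec$cytLevel
  tubulin[mask] <- spec$nuclearTubulinLevel

  foci <- array(0, sh)
  nFoci <- if (is.null(spec$fociCenters)) stats::rpois(1, spec$fociRate) else
    nrow(spec$fociCenters)
  centers <- matrix(numeric(0), 0, 3)
  if (nFoci > 0) {
    th <- stats::runif(nFoci, 0, 2 * pi)
    dd <- stats::runif(nFoci, 0.08, spec$fociBandWidth)
    bx <- a * cos(th); by <- b * sin(th)
    nrm <- cbind(bx / a^2, by / b^2)
    nrm <- nrm / sqrt(rowSums(nrm^2))
    centers <- cbind(cbind(bx, by) + dd * nrm, 0)
    for (k in seq_len(nFoci))
      foci[(X - centers[k, 1])^2 + (Y - centers[k, 2])^2 +
             (Z - centers[k, 3])^2 <= spec$fociRadius^2] <- spec$fociLevel
  }

  channels <- lapply(list(chromatin = chromatin, tubulin = tubulin,
                          foci = foci, lamina = lamina),
                     .blurNoise, spec = spec)
  gt <- list(nuclearLength = 2 * a, nuclearWidth = 2 * b, aspectRatio = a / b,
             volume = 4 / 3 * pi * a * b * cc,
             protrusionPresent = isTRUE(protr), protrusionArea = protrVol,
             enrichmentFactor = spec$enrichmentFactor, fociCount = nFoci,
             fociCenters = centers, orientation = 0, tipSign = tipSign)
  new("NucleusImage", channels = channels, voxelSize = v, groundTruth = gt,
      seed = spec$seed)
}

## euclidean distance (pixels) of background pixels to the mask
.distanceOutside <- function(mask) {
  d <- EBImage::distmap(EBImage::Image(1 - mask))
  as.matrix(EBImage::imageData(d))
}

.blurNoise <- function(x, spec) {
  isMat <- is.matrix(x)
  x <- x * 1.0
  if (spec$psfSigma > 0) {
    sigmaPx <- spec$psfSigma / spec$voxelSize
    x <- as.array(EBImage::imageData(
      EBImage::gblur(EBImage::Image(x), sigma = sigmaPx)))
  }
  if (spec$noiseSD > 0) {
    if (spec$noiseModel == "poisson-gaussian") {
      gain <- 100
      x[] <- stats::rpois(length(x), pmax(x, 0) * gain) / gain
    }
    x <- x + stats::rnorm(length(x), 0, spec$noiseSD)
  }
  if (isMat && !is.matrix(x)) x <- matrix(x, dim(x)[1], dim(x)[2])
  x
}

#' Write a nucleus image as multi-page TIFF with a JSON ground-truth sidecar
#'
#' Channels are written in the order chromatin, tubulin, foci, lamina; the
#' voxel size and ground truth go to \code{<file>.json}.
#'
#' @param img a \linkS4class{NucleusImage}.
#' @param file output TIFF path.
#' @export
writeNucleusImage <- function(img, file) {
  stopifnot(is(img, "NucleusImage"))
  ch <- img@channels[c("chromatin", "tubulin", "foci", "lamina")]
  arr <- simplify2array(lapply(ch, function(x) x / max(max(unlist(ch)), 1)))
  EBImage::writeImage(EBImage::Image(arr), file, type = "tiff")
  side <- img@groundTruth
  side$fociCenters <- if (length(side$fociCenters)) unclass(side$fociCenters)
    else NULL
  side$voxelSize <- img@voxelSize
  side$seed <- img@seed
  jsonlite::write_json(side, paste0(file, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(file)
}
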