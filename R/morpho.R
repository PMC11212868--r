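#' Ring geometry for perinuclear measurements
#'
#' Defines the perinuclear band (within \code{pnWidth} outside the nuclear
#' boundary), the cytoplasmic reference band (between \code{cytInner} and
#' \code{cytOuter} outside the boundary) and the half-angle of the tip
#' sectors around the major axis.
#'
#' @param pnWidth micrometres; 1.0 is the perinuclear ring used both for
#'   tubulin enrichment and for perinuclear foci.
#' @param cytInner,cytOuter micrometres.
#' @param tipHalfAngle degrees.
#' @export
ringGeometry <- function(pnWidth = 1, cytInner = 2, cytOuter = 4,
                         tipHalfAngle = 30) {
  if (!(pnWidth > 0 && pnWidth <= cytInner && cytInner < cytOuter))
    stop("require 0 < pnWidth <= cytInner < cytOuter")
  structure(list(pnWidth = pnWidth, cytInner = cytInner,
                 cytOuter = cytOuter, tipHalfAngle = tipHalfAngle),
            class = "RingGeometry")
}

.otsuMask <- function(x) {
  rng <- range(x)
  if (diff(rng) <= .Machine$double.eps)
    stop("segmentation error: image has no contrast")
  xn <- (x - rng[1]) / diff(rng)
  thr <- EBImage::otsu(EBImage::Image(matrix(xn, ncol = 1)), range = c(0, 1))
  array(xn > thr, dim(x))
}

#' Segment the nucleus from a chromatin channel
#'
#' Global Otsu threshold, largest connected component, hole fill (2-D). In
#' 3-D the thresholded foreground is used directly (the field is assumed to
#' contain a single dominant nucleus).
#'
#' @param chromatin numeric matrix or 3-D array.
#' @param voxelSize micrometres per voxel (carried through to the result).
#' @return list with \code{mask} (logical array), \code{boundary} (logical
#'   array of mask edge pixels) and \code{voxelSize}.
#' @export
segmentNucleus <- function(chromatin, voxelSize) {
  mask <- .otsuMask(chromatin)
  if (!any(mask)) stop("segmentation error: empty mask")
  if (length(dim(chromatin)) == 2) {
    lab <- EBImage::bwlabel(EBImage::Image(mask * 1))
    tab <- tabulate(as.integer(EBImage::imageData(lab)))
    mask <- as.matrix(EBImage::imageData(lab)) == which.max(tab)
    mask <- as.matrix(EBImage::imageData(
      EBImage::fillHull(EBImage::Image(mask * 1)))) > 0
  }
  if (sum(mask) < 10) stop("segmentation error: mask below 10 pixels")
  er <- EBImage::erode(EBImage::Image(mask * 1),
                       EBImage::makeBrush(3, "box"))
  boundary <- mask & !(as.array(EBImage::imageData(er)) > 0)
  list(mask = mask, boundary = boundary, voxelSize = voxelSize)
}

## centroid, principal-axis directions and moment-based semi-axes of a mask
.maskMoments <- function(mask, voxelSize) {
  idx <- which(mask, arr.ind = TRUE)
  P <- (idx - rep(colMeans(idx), each = nrow(idx))) * voxelSize
  C <- crossprod(P) / nrow(P)
  e <- eigen(C, symmetric = TRUE)
  list(centroid = colMeans(idx), axes = e$vectors, lambda = e$values,
       npix = nrow(idx))
}

#' Nuclear dimensions from a segmented mask
#'
#' Length and width are moment-based axis extents: for a solid ellipse the
#' eigenvalues \eqn{\lambda_i} of the pixel-coordinate covariance satisfy
#' semi-axis \eqn{= 2\sqrt{\lambda_i}}, which is sub-pixel accurate and
#' stable under rotation.
#'
#' @param seg result of \code{\link{segmentNucleus}} (or a logical mask, in
#'   which case \code{voxelSize} must be given).
#' @param voxelSize micrometres per voxel.
#' @return list: \code{length}, \code{width} (micrometres),
#'   \code{aspectRatio}, and \code{area} (2-D, um^2) or \code{volume}
#'   (3-D, um^3).
#' @export
nuclearDimensions <- function(seg, voxelSize = NULL) {
  mask <- if (is.list(seg)) seg$mask else seg
  v <- if (is.list(seg)) seg$voxelSize else voxelSize
  if (sum(mask) < 10) stop("degenerate mask: fewer than 10 pixels")
  m <- .maskMoments(mask, v)
  len <- 4 * sqrt(m$lambda[1])
  wid <- 4 * sqrt(m$lambda[2])
  out <- list(length = len, width = wid, aspectRatio = len / wid)
  if (length(dim(mask)) == 2) out$area <- m$npix * v^2 else
    out$volume <- m$npix * v^3
  out
}

## distance (um) of every pixel outside the mask to the mask, plus the
## angular offset of each pixel from the mask's major axis
.ringFields <- function(mask, voxelSize) {
  dOut <- .distanceOutside(mask) * voxelSize
  m <- .maskMoments(mask, voxelSize)
  idx1 <- slice.index(mask, 1) - m$centroid[1]
  idx2 <- slice.index(mask, 2) - m$centroid[2]
  axial <- idx1 * m$axes[1, 1] + idx2 * m$axes[2, 1]
  perp <- sqrt(pmax(idx1^2 + idx2^2 - axial^2, 0))
  list(dOut = dOut, tipAngle = atan2(perp, abs(axial)), moments = m)
}

#' Perinuclear-to-cytoplasmic tubulin enrichment
#'
#' Mean tubulin intensity in the perinuclear band divided by the mean in the
#' cytoplasmic reference band, overall and split into tip and side sectors
#' around the nuclear major axis.
#'
#' @param tubulin numeric matrix (mid-plane channel).
#' @param seg result of \code{\link{segmentNucleus}}.
#' @param rings a \code{\link{ringGeometry}}.
#' @return list: \code{overall}, \code{tips}, \code{sides} PN/Cyt ratios.
#' @export
perinuclearEnrichment <- function(tubulin, seg, rings = ringGeometry()) {
  stopifnot(inherits(rings, "RingGeometry"))
  mask <- seg$mask
  rf <- .ringFields(mask, seg$voxelSize)
  pn <- !mask & rf$dOut <= rings$pnWidth
  cyt <- rf$dOut > rings$cytInner & rf$dOut <= rings$cytOuter
  if (!any(cyt)) stop("empty cytoplasmic band: nucleus too close to the ",
                      "image edge")
  tip <- rf$tipAngle <= rings$tipHalfAngle * pi / 180
  cytMean <- mean(tubulin[cyt])
  list(overall = mean(tubulin[pn]) / cytMean,
       tips = mean(tubulin[pn & tip]) / cytMean,
       sides = mean(tubulin[pn & !tip]) / cytMean)
}

#' Detect a tip chromatin protrusion
#'
#' Fits the moment ellipse to the nuclear mask and collects mask pixels
#' lying beyond the fitted ellipse (plus a sub-pixel guard margin), within
#' the tip sectors, and connected to the nucleus. A protrusion is called
#' when their total area reaches \code{minArea}.
#'
#' @param seg result of \code{\link{segmentNucleus}} on the chromatin
#'   channel (the mask includes any protruding chromatin).
#' @param tipHalfAngle degrees around the major axis.
#' @param minArea um^2, minimum residual area to call a protrusion.
#' @param margin micrometres added to the fitted semi-axes to suppress
#'   pixelation fringe.
#' @param refits robust refit iterations: pixels beyond the current ellipse
#'   are excluded and the ellipse refitted, so a protruding blob does not
#'   inflate the fit it is measured against.
#' @return list: \code{present}, \code{area} (um^2).
#' @export
detectProtrusion <- function(seg, tipHalfAngle = 30, minArea = 1,
                             margin = 0.1, refits = 2) {
  mask <- seg$mask
  v <- seg$voxelSize
  ellipseResidual <- function(fitMask) {
    m <- .maskMoments(fitMask, v)
    a <- 2 * sqrt(m$lambda[1]) + margin
    b <- 2 * sqrt(m$lambda[2]) + margin
    idx1 <- (slice.index(mask, 1) - m$centroid[1]) * v
    idx2 <- (slice.index(mask, 2) - m$centroid[2]) * v
    axial <- idx1 * m$axes[1, 1] + idx2 * m$axes[2, 1]
    perp2 <- pmax(idx1^2 + idx2^2 - axial^2, 0)
    list(outside = (axial / a)^2 + perp2 / b^2 > 1,
         tip = atan2(sqrt(perp2), abs(axial)) <= tipHalfAngle * pi / 180)
  }
  fit <- mask
  for (i in seq_len(refits)) {
    r <- ellipseResidual(fit)
    fit <- mask & !r$outside
  }
  r <- ellipseResidual(fit)
  area <- sum(mask & r$outside & r$tip) * v^2
  list(present = area >= minArea, area = area)
}

#' Detect punctate foci in or around the nucleus
#'
#' Candidate pixels exceed the channel mean by \code{k} standard deviations;
#' connected components are filtered by area and kept when their centroid
#' lies in the admissible zone: the nucleus plus the perinuclear ring
#' (\code{mode = "perinuclear"}, rupture-reporter foci within 1 um of the
#' border) or the nuclear interior (\code{mode = "nuclear"}, DNA-damage
#' foci).
#'
#' @param fociChannel numeric matrix.
#' @param seg result of \code{\link{segmentNucleus}}.
#' @param rings a \code{\link{ringGeometry}}; \code{pnWidth} is the
#'   admissible distance outside the border.
#' @param mode "perinuclear" or "nuclear".
#' @param k threshold in standard deviations over the channel mean.
#' @param minArea,maxArea um^2 component-area bounds.
#' @return list: \code{count}, \code{areas} (um^2 per kept focus).
#' @export
detectFoci <- function(fociChannel, seg, rings = ringGeometry(),
                       mode = c("perinuclear", "nuclear"), k = 3,
                       minArea = 0.05, maxArea = 5) {
  mode <- match.arg(mode)
  mask <- seg$mask
  v <- seg$voxelSize
  thr <- mean(fociChannel) + k * stats::sd(fociChannel)
  cand <- fociChannel > thr
  if (!any(cand)) return(list(count = 0L, areas = numeric(0)))
  lab <- as.matrix(EBImage::imageData(
    EBImage::bwlabel(EBImage::Image(cand * 1))))
  dOut <- .distanceOutside(mask) * v
  admissible <- if (mode == "perinuclear") mask | dOut <= rings$pnWidth else
    mask
  areas <- numeric(0)
  for (l in seq_len(max(lab))) {
    px <- which(lab == l, arr.ind = TRUE)
    area <- nrow(px) * v^2
    if (area < minArea || area > maxArea) next
    cen <- round(colMeans(px))
    if (admissible[cen[1], cen[2]]) areas <- c(areas, area)
  }
  list(count = length(areas), areas = areas)
}

#' Full morphometry of one synthetic nucleus image
#'
#' Segments the chromatin channel and reports shape, enrichment, protrusion
#' and foci metrics for a single nucleus.
#'
#' @param img a \linkS4class{NucleusImage}.
#' @param rings a \code{\link{ringGeometry}}.
#' @param ... passed to \code{\link{detectProtrusion}}.
#' @return one-row data.frame.
#' @export
measureNucleus <- function(img, rings = ringGeometry(), ...) {
  stopifnot(is(img, "NucleusImage"))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  dims <- nuclearDimensions(seg)
  if (length(dim(seg$mask)) == 3)
    return(data.frame(nuclear_length = dims$length,
                      nuclear_width = dims$width,
                      aspect_ratio = dims$aspectRatio, volume = dims$volume))
  enr <- perinuclearEnrichment(img@channels$tubulin, seg, rings)
  pro <- detectProtrusion(seg, ...)
  foc <- detectFoci(img@channels$foci, seg, rings)
  data.frame(nuclear_length = dims$length, nuclear_width = dims$width,
             aspect_ratio = dims$aspectRatio, area = dims$area,
             enrichment_overall = enr$overall, enrichment_tips = enr$tips,
             enrichment_sides = enr$sides, protrusion_present = pro$present,
             protrusion_area = pro$area, foci_count = foc$count)
}

#' Score a cohort of nucleus images
#'
#' Applies the morphometry pipeline to every image and summarizes either the
#' protrusion prevalence, mean foci count, or mean shape metrics, with a
#' seeded bootstrap percentile confidence interval.
#'
#' @param images list of \linkS4class{NucleusImage}.
#' @param mode "protrusion", "foci" or "shape".
#' @param rings a \code{\link{ringGeometry}}.
#' @param nBoot bootstrap resamples.
#' @param level confidence level.
#' @param seed bootstrap seed.
#' @return list: \code{table} (per-nucleus data.frame), \code{estimate},
#'   \code{ci} (percentile interval), \code{n}.
#' @export
scoreCohort <- function(images, mode = c("protrusion", "foci", "shape"),
                        rings = ringGeometry(), nBoot = 2000, level = 0.95,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (!length(images)) stop("empty cohort")
  tab <- do.call(rbind, lapply(images, measureNucleus, rings = rings))
  tab <- cbind(image_id = seq_len(nrow(tab)), tab)
  stat <- switch(mode,
    protrusion = as.numeric(tab$protrusion_present),
    foci = tab$foci_count,
    shape = tab$aspect_ratio)
  est <- mean(stat)
  set.seed(seed)
  boot <- vapply(seq_len(nBoot), function(i)
    mean(stat[sample.int(length(stat), replace = TRUE)]), 0)
  alpha <- (1 - level) / 2
  list(table = tab, estimate = est,
       ci = unname(stats::quantile(boot, c(alpha, 1 - alpha))),
       n = nrow(tab))
}
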