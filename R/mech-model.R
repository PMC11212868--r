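#' Geometry of the axisymmetric cardiomyocyte model
#'
#' The stress-free reference configuration is a cylinder of radius
#' \code{cellRadius} and half-length \code{cellHalfLength} containing a
#' round nucleus of radius \code{nucleusRadius} at its centre. The nucleus
#' is split into nucleoplasm and a thin envelope-plus-lamina layer of
#' thickness \code{laminaThickness}. The perinuclear microtubule cage is the
#' region inside a prolate ellipsoid with semi-axes \code{cageSemiAxes}
#' (radial, axial) but outside the nucleus, so it is thin at the equator and
#' thick over the nuclear tips where microtubules accumulate. Symmetry about
#' the mid-plane is exploited: only z >= 0 is meshed.
#'
#' @param cellRadius,cellHalfLength micrometres.
#' @param nucleusRadius micrometres (round in the stress-free state).
#' @param cageSemiAxes micrometres, c(radial, axial) outer ellipsoid.
#' @param laminaThickness micrometres.
#' @param meshFine target edge length near the nucleus, micrometres; must
#'   resolve the lamina with at least two elements through its thickness.
#' @param meshCoarse target edge length at the cell ends.
#' @export
mechGeometry <- function(cellRadius = 9, cellHalfLength = 35,
                         nucleusRadius = 2.7, cageSemiAxes = c(3.3, 5.8),
                         laminaThickness = 0.1, meshFine = 0.05,
                         meshCoarse = 2.5) {
  g <- list(cellRadius = cellRadius, cellHalfLength = cellHalfLength,
            nucleusRadius = nucleusRadius, cageSemiAxes = cageSemiAxes,
            laminaThickness = laminaThickness, meshFine = meshFine,
            meshCoarse = meshCoarse)
  if (!(nucleusRadius < cageSemiAxes[1] && cageSemiAxes[1] < cellRadius &&
        cageSemiAxes[2] < cellHalfLength))
    stop("geometry must nest: nucleus inside cage inside cell")
  if (laminaThickness >= nucleusRadius / 5)
    stop("laminaThickness must be below nucleusRadius/5")
  if (meshFine > laminaThickness / 2)
    stop("meshFine must resolve the lamina with >= 2 elements ",
         "through its thickness")
  class(g) <- "MechGeometry"
  g
}

#' Material moduli of the model regions
#'
#' Compressible neo-Hookean in every region, parameterized by Young modulus
#' (kPa) and Poisson ratio. Defaults are calibrated so the wild-type probe
#' stresses land in the physiological ranges (myofibril diastolic tension
#' 2-3 kPa, microtubule axial compression 1-1.8 kPa); the mutant lamina is
#' softened to 10 kPa.
#'
#' @param E named numeric, kPa, for cytoplasm, cage, lamina, nucleoplasm.
#' @param nu named numeric Poisson ratios.
#' @export
mechMaterials <- function(E = c(cytoplasm = 1.2, cage = 8, lamina = 25,
                                nucleoplasm = 0.25),
                          nu = c(cytoplasm = 0.3, cage = 0.3, lamina = 0.3,
                                 nucleoplasm = 0.49)) {
  need <- c("cytoplasm", "cage", "lamina", "nucleoplasm")
  if (!all(need %in% names(E)) || !all(need %in% names(nu)))
    stop("E and nu must name all four regions")
  if (any(E <= 0)) stop("all moduli must be positive")
  structure(list(E = E[need], nu = nu[need]), class = "MechMaterials")
}

#' Active-stress state and loading schedule
#'
#' Myofibril contractility is an active Cauchy stress in the cytoplasm:
#' isotropic with magnitude \code{rho0} during the initial ramp, then
#' polarized along the local maximum-principal-stress direction n as
#' \eqn{\rho_p [\lambda n n^T + (1-\lambda)(I - n n^T)/2]}. The microtubule
#' cage carries an isotropic compressive stress \code{-sigmaMT I}. Both are
#' ramped simultaneously from zero (the stress-free configuration).
#'
#' @param rho0 kPa, isotropic contractility magnitude at the end of the
#'   isotropic ramp.
#' @param sigmaMT kPa, cage compressive stress magnitude.
#' @param rhoPolar kPa, polarized contractility magnitude (the fibre-aligned
#'   state the isotropic field matures into).
#' @param lambda fraction of the polarized stress along the fibre direction.
#' @param rampSteps load increments for the isotropic ramp.
#' @param blendSteps increments for the isotropic-to-polarized transition.
#' @param polarizationIterations fibre-field updates: 1 freezes the
#'   directions computed from the isotropic prestress; larger values
#'   fixed-point iterate (recompute directions from the polarized solution
#'   and re-solve), letting the fibres wrap the nucleus as myofibrils do.
#' @param voidScale myofibrils do not populate the perinuclear space at
#'   the nuclear poles (the microtubule cage fills it); cytoplasm inside
#'   the cage ellipsoid scaled by this factor carries no contractility.
#'   1 limits the void to the cage itself.
#' @export
activeState <- function(rho0 = 0.8, sigmaMT = 1.4, rhoPolar = 4.5,
                        lambda = 0.6, rampSteps = 8, blendSteps = 10,
                        polarizationIterations = 2, voidScale = 1.1) {
  if (sigmaMT < 0) stop("sigmaMT must be >= 0")
  structure(list(rho0 = rho0, sigmaMT = sigmaMT, rhoPolar = rhoPolar,
                 lambda = lambda, rampSteps = as.integer(rampSteps),
                 blendSteps = as.integer(blendSteps),
                 polarizationIterations =
                   as.integer(polarizationIterations),
                 voidScale = voidScale),
            class = "ActiveState")
}

## graded 1-D node sequence from a to b, spacing h0 at a growing to h1
.gradeSeq <- function(a, b, h0, h1, ratio = 1.3) {
  xs <- a
  h <- h0
  while (xs[length(xs)] < b - 1e-9) {
    xs <- c(xs, min(xs[length(xs)] + h, b))
    h <- min(h * ratio, h1)
  }
  xs
}

#' Assemble the axisymmetric finite-element model
#'
#' Builds a graded tensor-product triangulation of the (r, z) half-domain,
#' labels elements by region from their centroids, and precomputes the
#' element kinematic operators. Boundary conditions: u_r = 0 on the axis,
#' u_z = 0 on the mid-plane (symmetry) and on the cell end face; the
#' lateral surface is traction-free.
#'
#' @param geometry a \code{\link{mechGeometry}}.
#' @param materials a \code{\link{mechMaterials}}.
#' @param active an \code{\link{activeState}}.
#' @return A \linkS4class{MechModel}.
#' @export
buildModel <- function(geometry = mechGeometry(),
                       materials = mechMaterials(),
                       active = activeState()) {
  stopifnot(inherits(geometry, "MechGeometry"),
            inherits(materials, "MechMaterials"),
            inherits(active, "ActiveState"))
  g <- geometry
  fineR <- g$nucleusRadius + 0.4
  fineZ <- g$cageSemiAxes[2] + 0.4
  ## snap to nm precision so graded and uniform sections join cleanly
  rs <- sort(unique(round(c(seq(0, fineR, by = g$meshFine), fineR,
                            .gradeSeq(fineR, g$cellRadius, g$meshFine,
                                      g$meshCoarse)), 9)))
  zs <- sort(unique(round(c(seq(0, g$nucleusRadius + 0.4, by = g$meshFine),
                            .gradeSeq(g$nucleusRadius + 0.4, fineZ,
                                      g$meshFine, 3 * g$meshFine),
                            .gradeSeq(fineZ, g$cellHalfLength,
                                      3 * g$meshFine, g$meshCoarse)), 9)))
  nr <- length(rs); nz <- length(zs)
  nodes <- cbind(r = rep(rs, times = nz), z = rep(zs, each = nr))
  nid <- function(i, j) (j - 1L) * nr + i
  ii <- rep(seq_len(nr - 1), times = nz - 1)
  jj <- rep(seq_len(nz - 1), each = nr - 1)
  n00 <- nid(ii, jj); n10 <- nid(ii + 1, jj)
  n01 <- nid(ii, jj + 1); n11 <- nid(ii + 1, jj + 1)
  ## alternate the quad diagonal for isotropy
  flip <- (ii + jj) %% 2 == 0
  tri <- rbind(
    cbind(n00, n10, ifelse(flip, n11, n01)),
    cbind(ifelse(flip, n00, n10), n11, n01))
  tri <- matrix(as.integer(tri), ncol = 3)

  P1 <- nodes[tri[, 1], ]; P2 <- nodes[tri[, 2], ]; P3 <- nodes[tri[, 3], ]
  cen <- (P1 + P2 + P3) / 3
  detJ <- (P2[, 1] - P1[, 1]) * (P3[, 2] - P1[, 2]) -
    (P3[, 1] - P1[, 1]) * (P2[, 2] - P1[, 2])
  area <- abs(detJ) / 2
  ## shape-function gradients of the linear triangle
  dNdR <- cbind(P2[, 2] - P3[, 2], P3[, 2] - P1[, 2], P1[, 2] - P2[, 2]) /
    detJ
  dNdZ <- cbind(P3[, 1] - P2[, 1], P1[, 1] - P3[, 1], P2[, 1] - P1[, 1]) /
    detJ

  rhoN <- sqrt(cen[, 1]^2 + cen[, 2]^2)
  inCage <- (cen[, 1] / g$cageSemiAxes[1])^2 +
    (cen[, 2] / g$cageSemiAxes[2])^2 <= 1
  region <- rep("cytoplasm", nrow(tri))
  region[inCage & rhoN > g$nucleusRadius] <- "cage"
  region[rhoN <= g$nucleusRadius] <- "lamina"
  region[rhoN <= g$nucleusRadius - g$laminaThickness] <- "nucleoplasm"
  region <- factor(region,
                   levels = c("cytoplasm", "cage", "lamina", "nucleoplasm"))

  nNodes <- nrow(nodes)
  fixedR <- which(abs(nodes[, 1]) < 1e-9)
  fixedZ <- which(abs(nodes[, 2]) < 1e-9 |
                    abs(nodes[, 2] - g$cellHalfLength) < 1e-9)
  fixed <- c(2L * fixedR - 1L, 2L * fixedZ)
  free <- setdiff(seq_len(2L * nNodes), fixed)

  edof <- cbind(2L * tri[, 1] - 1L, 2L * tri[, 2] - 1L, 2L * tri[, 3] - 1L,
                2L * tri[, 1], 2L * tri[, 2], 2L * tri[, 3])
  Ki <- matrix(0L, nrow(tri), 36)
  Kj <- matrix(0L, nrow(tri), 36)
  for (a in 1:6) for (b in 1:6) {
    Ki[, (a - 1) * 6 + b] <- edof[, a]
    Kj[, (a - 1) * 6 + b] <- edof[, b]
  }

  lame <- function(E, nu) c(mu = E / (2 * (1 + nu)),
                            lam = E * nu / ((1 + nu) * (1 - 2 * nu)))
  lm <- t(vapply(levels(region), function(rg)
    lame(materials$E[rg], materials$nu[rg]), c(mu = 0, lam = 0)))
  mu <- lm[as.integer(region), "mu"]
  lam <- lm[as.integer(region), "lam"]

  mesh <- list(nodes = nodes, tri = tri, region = region, area = area,
               centroid = cen, dNdR = dNdR, dNdZ = dNdZ,
               Rc = cen[, 1], weight = 2 * pi * cen[, 1] * area,
               mu = mu, lam = lam, edof = edof, Ki = as.vector(t(Ki)),
               Kj = as.vector(t(Kj)), fixed = fixed, free = free,
               nNodes = nNodes)
  new("MechModel", mesh = mesh, geometry = unclass(g),
      materials = unclass(materials), active = unclass(active))
}
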