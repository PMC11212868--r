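#' @import methods
NULL

#' Contraction time series for a single cardiomyocyte
#'
#' Per-cell recordings of sarcomere length, nuclear length and nuclear width
#' during paced contraction, sampled on a uniform time grid. The first sample
#' is taken at diastole so that it can serve as the resting baseline.
#'
#' @slot time numeric, seconds; strictly increasing and uniformly spaced.
#' @slot sarcomereLength numeric, micrometres.
#' @slot nuclearLength numeric, micrometres.
#' @slot nuclearWidth numeric, micrometres.
#' @slot cellId character scalar.
#' @slot genotype character scalar, experimental-group label.
#' @slot pacingFrequency numeric scalar, Hz.
#'
#' @exportClass ContractionTrace
setClass("ContractionTrace",
  representation(
    time = "numeric",
    sarcomereLength = "numeric",
    nuclearLength = "numeric",
    nuclearWidth = "numeric",
    cellId = "character",
    genotype = "character",
    pacingFrequency = "numeric"
  )
)

setValidity("ContractionTrace", function(object) {
  n <- length(object@time)
  msgs <- character()
  if (length(object@sarcomereLength) != n ||
      length(object@nuclearLength) != n ||
      length(object@nuclearWidth) != n)
    msgs <- c(msgs, "all four series must have equal length")
  if (n >= 2) {
    dt <- diff(object@time)
    if (any(dt <= 0)) msgs <- c(msgs, "time must be strictly increasing")
    if (diff(range(dt)) > 1e-8 * mean(dt))
      msgs <- c(msgs, "time must be uniformly sampled")
  }
  if (any(object@sarcomereLength <= 0) || any(object@nuclearLength <= 0) ||
      any(object@nuclearWidth <= 0))
    msgs <- c(msgs, "all lengths must be positive")
  if (length(object@pacingFrequency) != 1 || object@pacingFrequency <= 0)
    msgs <- c(msgs, "pacingFrequency must be a positive scalar")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ContractionTrace", function(object) {
  cat("ContractionTrace '", object@cellId, "' (", object@genotype, ")\n",
      sep = "")
  cat(sprintf("  %d samples over %.2f s at %.1f Hz pacing\n",
              length(object@time), diff(range(object@time)),
              object@pacingFrequency))
  cat(sprintf("  SL %.3f-%.3f um, NL %.3f-%.3f um, NW %.3f-%.3f um\n",
              min(object@sarcomereLength), max(object@sarcomereLength),
              min(object@nuclearLength), max(object@nuclearLength),
              min(object@nuclearWidth), max(object@nuclearWidth)))
})

#' Strain time series derived from a contraction trace
#'
#' Strains in percent relative to the diastolic baseline,
#' \eqn{\epsilon = 100 (x - x_0)/x_0}; compression is negative.
#'
#' @slot time numeric, seconds.
#' @slot sarcomereStrain numeric, percent.
#' @slot nuclearLengthStrain numeric, percent.
#' @slot nuclearWidthStrain numeric, percent.
#' @slot baselines named numeric: SL0, NL0, NW0 in micrometres.
#' @slot pacingFrequency numeric scalar, Hz.
#'
#' @exportClass StrainTrace
setClass("StrainTrace",
  representation(
    time = "numeric",
    sarcomereStrain = "numeric",
    nuclearLengthStrain = "numeric",
    nuclearWidthStrain = "numeric",
    baselines = "numeric",
    pacingFrequency = "numeric"
  )
)

setValidity("StrainTrace", function(object) {
  n <- length(object@time)
  msgs <- character()
  if (length(object@sarcomereStrain) != n ||
      length(object@nuclearLengthStrain) != n ||
      length(object@nuclearWidthStrain) != n)
    msgs <- c(msgs, "strain series must match time length")
  if (!all(c("SL0", "NL0", "NW0") %in% names(object@baselines)))
    msgs <- c(msgs, "baselines must be named SL0, NL0, NW0")
  else if (any(object@baselines[c("SL0", "NL0", "NW0")] <= 0))
    msgs <- c(msgs, "baselines must be positive")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "StrainTrace", function(object) {
  cat("StrainTrace:", length(object@time), "samples\n")
  cat(sprintf("  peak sarcomere strain %.2f%%, peak nuclear length strain %.2f%%\n",
              object@sarcomereStrain[which.max(abs(object@sarcomereStrain))],
              object@nuclearLengthStrain[which.max(abs(object@nuclearLengthStrain))]))
})

#' Cycle phase indices for a strain trace
#'
#' For each pacing cycle, the sample indices of contraction onset, peak
#' systole, and the end of relaxation (return of sarcomere strain below the
#' onset threshold, or the end of the pacing period).
#'
#' @slot onset integer vector, one per cycle.
#' @slot peak integer vector.
#' @slot relaxEnd integer vector.
#' @slot onsetThreshold numeric scalar, percent strain.
#'
#' @exportClass CyclePhases
setClass("CyclePhases",
  representation(
    onset = "integer",
    peak = "integer",
    relaxEnd = "integer",
    onsetThreshold = "numeric"
  )
)

setValidity("CyclePhases", function(object) {
  if (length(object@onset) != length(object@peak) ||
      length(object@peak) != length(object@relaxEnd))
    return("phase vectors must have equal length (one entry per cycle)")
  if (any(!(object@onset < object@peak & object@peak <= object@relaxEnd)))
    return("phases must satisfy onset < peak <= relaxEnd in every cycle")
  if (length(object@onset) > 1 &&
      any(object@onset[-1] <= object@relaxEnd[-length(object@relaxEnd)] - 1))
    return("cycle phases must not overlap")
  TRUE
})

setMethod("show", "CyclePhases", function(object) {
  cat("CyclePhases:", length(object@onset), "cycle(s), onset threshold",
      object@onsetThreshold, "%\n")
})

#' Sarcomere-nuclear coupling metrics for one cell
#'
#' Peak strain magnitudes, systolic/diastolic dampening areas, integrated
#' nuclear strain, and the cycle-averaged strain coupling path.
#'
#' @slot peakSarcomereCompression numeric, percent (positive magnitude).
#' @slot peakNuclearCompression numeric, percent (positive magnitude).
#' @slot peakWidthExpansion numeric, percent (positive magnitude).
#' @slot systolicDampening numeric, percent-squared area.
#' @slot diastolicDampening numeric, percent-squared area.
#' @slot integratedNuclearStrain numeric, percent-seconds.
#' @slot couplingPath data.frame with columns eps_s, eps_n, limb.
#' @slot cellId character scalar.
#' @slot genotype character scalar.
#'
#' @exportClass CouplingResult
setClass("CouplingResult",
  representation(
    peakSarcomereCompression = "numeric",
    peakNuclearCompression = "numeric",
    peakWidthExpansion = "numeric",
    systolicDampening = "numeric",
    diastolicDampening = "numeric",
    integratedNuclearStrain = "numeric",
    couplingPath = "data.frame",
    cellId = "character",
    genotype = "character"
  )
)

setMethod("show", "CouplingResult", function(object) {
  cat("CouplingResult '", object@cellId, "' (", object@genotype, ")\n",
      sep = "")
  cat(sprintf("  peak compression: sarcomere %.2f%%, nucleus %.2f%%; width expansion %.2f%%\n",
              object@peakSarcomereCompression, object@peakNuclearCompression,
              object@peakWidthExpansion))
  cat(sprintf("  dampening: systolic %.3f %%^2, diastolic %.3f %%^2; integrated nuclear strain %.3f %%.s\n",
              object@systolicDampening, object@diastolicDampening,
              object@integratedNuclearStrain))
})

#' Synthetic multi-channel nucleus image with analytic ground truth
#'
#' Channels are chromatin, tubulin, foci and lamina, rendered on a common
#' pixel/voxel grid. Ground truth is recorded from the analytic geometry
#' before blur and noise are applied.
#'
#' @slot channels list of numeric arrays (2-D matrices or 3-D arrays), named
#'   chromatin, tubulin, foci, lamina.
#' @slot voxelSize numeric scalar, micrometres per pixel/voxel.
#' @slot groundTruth list: nuclearLength, nuclearWidth, aspectRatio,
#'   area (2-D) or volume (3-D), protrusionPresent, protrusionArea,
#'   enrichmentFactor, fociCount, fociCenters.
#' @slot seed integer scalar.
#'
#' @exportClass NucleusImage
setClass("NucleusImage",
  representation(
    channels = "list",
    voxelSize = "numeric",
    groundTruth = "list",
    seed = "integer"
  )
)

setValidity("NucleusImage", function(object) {
  need <- c("chromatin", "tubulin", "foci", "lamina")
  if (!all(need %in% names(object@channels)))
    return("channels must contain chromatin, tubulin, foci, lamina")
  dims <- lapply(object@channels[need], dim)
  if (length(unique(vapply(dims, paste, "", collapse = "x"))) != 1)
    return("all channels must share the same grid")
  if (object@voxelSize <= 0) return("voxelSize must be positive")
  TRUE
})

setMethod("show", "NucleusImage", function(object) {
  d <- dim(object@channels$chromatin)
  cat("NucleusImage:", paste(d, collapse = " x "), "voxels at",
      object@voxelSize, "um/voxel\n")
  gt <- object@groundTruth
  cat(sprintf("  truth: %.1f x %.1f um nucleus (AR %.2f), enrichment %.2f, protrusion %s, %d foci\n",
              gt$nuclearLength, gt$nuclearWidth, gt$aspectRatio,
              gt$enrichmentFactor, gt$protrusionPresent, gt$fociCount))
})

#' Continuous two-segment (breakpoint) regression fit
#'
#' Fit of a continuous piecewise-linear model y = a + b1 x + b2 (x - c)+ with
#' breakpoint c chosen by grid search, plus per-segment slope inference and an
#' optional loess overlay.
#'
#' @slot breakpoint numeric, x units.
#' @slot slopeBelow,slopeAbove numeric, y per x unit.
#' @slot intercept numeric, fitted y at x = 0 for the lower segment.
#' @slot slopeSE named numeric (below, above).
#' @slot slopePValues named numeric (below, above), t-test of slope = 0
#'   against segment-local residual variance.
#' @slot residualSD numeric.
#' @slot nPoints integer.
#' @slot flatAbove logical: upper-segment slope not distinguishable from zero
#'   (p > 0.05).
#' @slot loessCurve data.frame (x, fitted, se) or empty.
#'
#' @exportClass BiphasicFit
setClass("BiphasicFit",
  representation(
    breakpoint = "numeric",
    slopeBelow = "numeric",
    slopeAbove = "numeric",
    intercept = "numeric",
    slopeSE = "numeric",
    slopePValues = "numeric",
    residualSD = "numeric",
    nPoints = "integer",
    flatAbove = "logical",
    loessCurve = "data.frame"
  )
)

setMethod("show", "BiphasicFit", function(object) {
  cat("BiphasicFit on", object@nPoints, "points\n")
  cat(sprintf("  breakpoint %.3f; slope below %.3f (p=%.3g), slope above %.3f (p=%.3g)%s\n",
              object@breakpoint, object@slopeBelow,
              object@slopePValues["below"], object@slopeAbove,
              object@slopePValues["above"],
              if (object@flatAbove) " [flat]" else ""))
})

#' Axisymmetric finite-element model of a resting cardiomyocyte
#'
#' Assembled mesh, region labels, materials and active-stress state for the
#' half-domain (r, z), z >= 0, exploiting symmetry about the mid-plane.
#'
#' @slot mesh list: nodes (n x 2 matrix, columns r and z), tri (m x 3 integer
#'   matrix), region (factor per element: cytoplasm, cage, lamina,
#'   nucleoplasm), area, centroid.
#' @slot geometry list of geometric parameters (micrometres).
#' @slot materials list: E and nu per region (kPa, dimensionless).
#' @slot active list: rho0, sigmaMT (kPa), rampSteps, polarization parameters.
#'
#' @exportClass MechModel
setClass("MechModel",
  representation(
    mesh = "list",
    geometry = "list",
    materials = "list",
    active = "list"
  )
)

setMethod("show", "MechModel", function(object) {
  cat("MechModel:", nrow(object@mesh$nodes), "nodes,",
      nrow(object@mesh$tri), "elements\n")
  print(table(object@mesh$region))
})

#' Solution of the axisymmetric mechanics model
#'
#' @slot model MechModel the solution belongs to.
#' @slot U numeric matrix (n x 2): nodal displacements u_r, u_z in um.
#' @slot stress numeric matrix (m x 4): Cauchy components s_rr, s_zz, s_rz,
#'   s_tt per element, kPa.
#' @slot nuclearAspectRatio numeric.
#' @slot nuclearVolumeChange numeric, percent versus the stress-free state.
#' @slot probes named numeric, kPa: myofibril tension at the cage short and
#'   long tips, MT axial compression at the nucleus long and short tips.
#' @slot laminaStressLocation numeric in [0, 1]: normalized arc coordinate of
#'   the maximum principal stress on the lamina (0 equator, 1 tip).
#' @slot tipInstability logical.
#' @slot converged logical.
#' @slot loadFactor numeric, fraction of the full (rho0, sigmaMT) load.
#'
#' @exportClass MechSolution
setClass("MechSolution",
  representation(
    model = "MechModel",
    U = "matrix",
    stress = "matrix",
    nuclearAspectRatio = "numeric",
    nuclearVolumeChange = "numeric",
    probes = "numeric",
    laminaStressLocation = "numeric",
    tipInstability = "logical",
    converged = "logical",
    loadFactor = "numeric"
  )
)

setMethod("show", "MechSolution", function(object) {
  cat(sprintf("MechSolution (load factor %.2f, %s)\n", object@loadFactor,
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  nuclear AR %.3f, volume change %.2f%%\n",
              object@nuclearAspectRatio, object@nuclearVolumeChange))
  cat(sprintf("  lamina max-principal-stress location s = %.2f%s\n",
              object@laminaStressLocation,
              if (object@tipInstability) " [tip instability]" else ""))
  if (length(object@probes)) {
    cat("  probes (kPa):\n")
    for (nm in names(object@probes))
      cat(sprintf("    %-28s %8.3f\n", nm, object@probes[nm]))
  }
})
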