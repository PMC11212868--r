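## Condition presets. Each non-default value is calibrated to a printed group
## value; see the methods vignette for the provenance of every number.

.tracePresets <- list(
  # Adult rat, 1 Hz pacing at 90 fps: 11.4% peak sarcomere compression with
  # the nuclear length following at 6.6% (dampened first-order lag).
  WT_rat = list(peakSarcomereStrain = -11.4, peakNuclearStrain = -6.6,
                relaxationTime = 0.15, nuclearTimeConstant = 0.06),
  AdV_empty = list(peakSarcomereStrain = -11.4, peakNuclearStrain = -6.6,
                   relaxationTime = 0.15, nuclearTimeConstant = 0.06),
  # Acute LINC disruption: subtly increased sarcomere contractility with
  # slightly decreased nuclear compression (larger systolic dampening).
  AdV_DNKASH = list(peakSarcomereStrain = -12.2, peakNuclearStrain = -5.8,
                    relaxationTime = 0.15, nuclearTimeConstant = 0.06),
  DMSO = list(peakSarcomereStrain = -11.4, peakNuclearStrain = -6.6,
              relaxationTime = 0.15, nuclearTimeConstant = 0.06),
  # Microtubule depolymerization: moderately increased contraction with
  # accelerated sarcomere relaxation while nuclear relaxation does not keep
  # up (diastolic hysteresis).
  colch = list(peakSarcomereStrain = -12.6, peakNuclearStrain = -7.4,
               relaxationTime = 0.10, nuclearTimeConstant = 0.12),
  WT_mouse = list(peakSarcomereStrain = -10.0, peakNuclearStrain = -5.5,
                  relaxationTime = 0.15, nuclearTimeConstant = 0.06),
  csDNKASH = list(peakSarcomereStrain = -10.0, peakNuclearStrain = -5.5,
                  relaxationTime = 0.15, nuclearTimeConstant = 0.06),
  # Lamin A/C N195K: more deformable nucleus; 30% larger integrated nuclear
  # strain than WT_mouse (the lag is linear in the gain, so the 1.30 ratio
  # of peak targets carries over exactly to the integrated strain).
  N195K = list(peakSarcomereStrain = -10.0, peakNuclearStrain = -7.15,
               relaxationTime = 0.15, nuclearTimeConstant = 0.06),
  N195K_csDNKASH = list(peakSarcomereStrain = -10.0, peakNuclearStrain = -7.15,
                        relaxationTime = 0.15, nuclearTimeConstant = 0.06)
)

.imagePresets <- list(
  # WT mouse nucleus ~10.9 x 5.2 um (AR 2.1); dense tip-biased MT cage with
  # perinuclear/cytoplasmic enrichment ~2.2; protrusions essentially absent.
  WT_mouse = list(semiAxes = c(5.45, 2.6), enrichmentFactor = 2.2,
                  tipBoost = 1.4, protrusionProb = 0.02, fociRate = 0.2,
                  noiseSD = 0.05),
  # Chronic LINC disruption: cage lost (enrichment ~1.4, uniform residual),
  # elongated nucleus (+36% aspect ratio).
  csDNKASH = list(semiAxes = c(6.2, 2.175), enrichmentFactor = 1.4,
                  tipBoost = 1.0, protrusionProb = 0.02, fociRate = 0.2,
                  noiseSD = 0.05),
  # N195K: shape comparable to WT at high resolution, cage intact, 20% of
  # nuclei with tip chromatin protrusions, more perinuclear rupture foci.
  N195K = list(semiAxes = c(5.45, 2.6), enrichmentFactor = 2.1,
               tipBoost = 1.4, protrusionProb = 0.20, fociRate = 1.5,
                  noiseSD = 0.05),
  # Combined: cage lost, strongly elongated (+63% AR), protrusions rescued.
  N195K_csDNKASH = list(semiAxes = c(6.65, 1.945), enrichmentFactor = 1.4,
                        tipBoost = 1.0, protrusionProb = 0.03, fociRate = 0.3,
                  noiseSD = 0.05),
  # Cardiac-specific lamin A/C depletion: ~40% protrusion prevalence.
  Lmna_cKO = list(semiAxes = c(5.45, 2.6), enrichmentFactor = 2.1,
                  tipBoost = 1.4, protrusionProb = 0.40, fociRate = 1.2,
                  noiseSD = 0.05),
  # Rat presets for the acute perturbations.
  AdV_empty = list(semiAxes = c(5.45, 2.6), enrichmentFactor = 2.5,
                   tipBoost = 1.4, protrusionProb = 0.01, fociRate = 0.2,
                  noiseSD = 0.05),
  AdV_DNKASH = list(semiAxes = c(5.6, 2.75), enrichmentFactor = 1.7,
                    tipBoost = 1.1, protrusionProb = 0.01, fociRate = 0.2,
                  noiseSD = 0.05),
  DMSO = list(semiAxes = c(5.45, 2.6), enrichmentFactor = 2.2,
              tipBoost = 1.4, protrusionProb = 0.02, fociRate = 1.5,
                  noiseSD = 0.05),
  colch = list(semiAxes = c(6.0, 2.3), enrichmentFactor = 1.0,
               tipBoost = 1.0, protrusionProb = 0.02, fociRate = 0.5,
                  noiseSD = 0.05)
)

#' Calibrated condition presets
#'
#' Returns a fully populated parameter object for a named experimental
#' condition: a \code{\link{traceParams}} object (\code{type = "trace"}) or
#' an \code{\link{imageSpec}} (\code{type = "image"}). Values not listed in
#' the preset tables take the constructor defaults; \code{...} overrides any
#' field (typically \code{seed} or \code{noiseSD}).
#'
#' @param name preset name. Trace presets: WT_rat, AdV_empty, AdV_DNKASH,
#'   DMSO, colch, WT_mouse, csDNKASH, N195K, N195K_csDNKASH. Image presets
#'   additionally include Lmna_cKO.
#' @param type "trace" or "image".
#' @param ... overrides passed to the constructor.
#' @export
genotypePreset <- function(name, type = c("trace", "image"), ...) {
  type <- match.arg(type)
  tab <- if (type == "trace") .tracePresets else .imagePresets
  if (!name %in% names(tab))
    stop("unknown ", type, " preset '", name, "'; available: ",
         paste(names(tab), collapse = ", "))
  args <- tab[[name]]
  dots <- list(...)
  args[names(dots)] <- dots
  if (type == "trace") {
    if (is.null(args$genotype)) args$genotype <- name
    do.call(traceParams, args)
  } else {
    if (is.null(args$genotype)) args$genotype <- name
    do.call(imageSpec, args)
  }
}

#' Parameters of the biphasic aspect-ratio/enrichment cohort generator
#'
#' Defaults encode the pooled-data relationship between nuclear aspect ratio
#' and perinuclear microtubule-cage enrichment: a deflection point at
#' enrichment 1.9 with slope -2.1 below it and a flat segment above.
#'
#' @param nPoints cohort size.
#' @param breakpoint enrichment units.
#' @param slopeBelow,slopeAbove aspect-ratio change per enrichment unit.
#' @param arAtBreakpoint aspect ratio at the deflection point.
#' @param enrichmentRange length-2 numeric spanning the breakpoint.
#' @param noiseSD Gaussian noise on aspect ratio.
#' @param seed integer.
#' @export
cohortSpec <- function(nPoints = 300, breakpoint = 1.9, slopeBelow = -2.1,
                       slopeAbove = 0, arAtBreakpoint = 2.1,
                       enrichmentRange = c(0.8, 3.2), noiseSD = 0.15,
                       seed = 1L) {
  s <- list(nPoints = as.integer(nPoints), breakpoint = breakpoint,
            slopeBelow = slopeBelow, slopeAbove = slopeAbove,
            arAtBreakpoint = arAtBreakpoint,
            enrichmentRange = enrichmentRange, noiseSD = noiseSD,
            seed = as.integer(seed))
  if (s$nPoints < 10) stop("nPoints must be at least 10")
  if (length(enrichmentRange) != 2 ||
      enrichmentRange[1] >= enrichmentRange[2])
    stop("enrichmentRange must be an increasing pair")
  if (breakpoint <= enrichmentRange[1] || breakpoint >= enrichmentRange[2])
    stop("enrichmentRange must span the breakpoint")
  class(s) <- "CohortSpec"
  s
}

#' Generate a synthetic (enrichment, aspect ratio) cohort
#'
#' Aspect ratio is piecewise linear in enrichment (continuous at the
#' breakpoint) plus Gaussian noise; enrichment values are uniform over the
#' configured range.
#'
#' @param spec a \code{\link{cohortSpec}}.
#' @return data.frame with columns \code{enrichment}, \code{aspect_ratio}.
#' @export
generateCohort <- function(spec = cohortSpec()) {
  stopifnot(inherits(spec, "CohortSpec"))
  set.seed(spec$seed)
  x <- stats::runif(spec$nPoints, spec$enrichmentRange[1],
                    spec$enrichmentRange[2])
  y <- spec$arAtBreakpoint +
    ifelse(x < spec$breakpoint,
           spec$slopeBelow * (x - spec$breakpoint),
           spec$slopeAbove * (x - spec$breakpoint))
  if (spec$noiseSD > 0) y <- y + stats::rnorm(spec$nPoints, 0, spec$noiseSD)
  data.frame(enrichment = x, aspect_ratio = y)
}
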