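.scenarioNames <- c("WT", "LMNA_mut", "csDNKASH", "LMNA_mut_csDNKASH")

#' Resolve scenario parameters
#'
#' WT uses the calibrated defaults. LMNA_mut softens the envelope-plus-
#' lamina layer to \code{mutantLaminaE} (10 kPa). csDNKASH scales the cage
#' compressive stress and cage modulus down by the configured fractions
#' (the microtubule cage is lost with LINC complex disruption). The
#' combined scenario applies both.
#'
#' @param name scenario name.
#' @param geometry,materials,active base parameter objects.
#' @param mutantLaminaE kPa.
#' @param cageStressFraction,cageStiffnessFraction csDNKASH scalings.
#' @return list(geometry, materials, active).
#' @export
scenarioParams <- function(name, geometry = mechGeometry(),
                           materials = mechMaterials(),
                           active = activeState(), mutantLaminaE = 10,
                           cageStressFraction = 0.25,
                           cageStiffnessFraction = 0.25) {
  if (!name %in% .scenarioNames)
    stop("unknown scenario '", name, "'; available: ",
         paste(.scenarioNames, collapse = ", "))
  if (name %in% c("LMNA_mut", "LMNA_mut_csDNKASH"))
    materials$E["lamina"] <- mutantLaminaE
  if (name %in% c("csDNKASH", "LMNA_mut_csDNKASH")) {
    active$sigmaMT <- active$sigmaMT * cageStressFraction
    materials$E["cage"] <- materials$E["cage"] * cageStiffnessFraction
  }
  list(geometry = geometry, materials = materials, active = active)
}

.standardLegs <- function(active) {
  list(list(target = c(active$rho0, 0, active$sigmaMT),
            nSteps = active$rampSteps),
       list(target = c(0, active$rhoPolar, active$sigmaMT),
            nSteps = active$blendSteps))
}

#' Run a named scenario to its physiological configuration
#'
#' Ramps isotropic contractility and cage compression simultaneously from
#' the stress-free state, then matures the contractility into the polarized
#' (fibre-aligned) field, and returns the converged solution.
#'
#' @param name one of WT, LMNA_mut, csDNKASH, LMNA_mut_csDNKASH.
#' @param ... passed to \code{\link{scenarioParams}}.
#' @return A \linkS4class{MechSolution}.
#' @examples
#' \donttest{
#' sol <- runScenario("WT", geometry = mechGeometry(meshFine = 0.15,
#'                                                  laminaThickness = 0.3))
#' sol
#' }
#' @export
runScenario <- function(name, ...) {
  sp <- scenarioParams(name, ...)
  model <- buildModel(sp$geometry, mechMaterials(sp$materials$E,
                                                 sp$materials$nu),
                      sp$active)
  legs <- .standardLegs(sp$active)
  sol <- solveSchedule(model, legs)
  for (i in seq_len(max(sp$active$polarizationIterations - 1, 0)))
    sol <- solveSchedule(model, legs,
                         polarDirs = .principalDirs(sol@stress))
  sol
}

#' Sweep microtubule enrichment and record nuclear aspect ratio
#'
#' Enrichment E maps linearly onto the cage loading: the cage stress and
#' cage modulus are scaled by E / refEnrichment relative to the base
#' scenario. Solver failures at a grid point are flagged and the sweep
#' continues.
#'
#' @param enrichmentGrid numeric vector of enrichment values.
#' @param name base scenario.
#' @param refEnrichment enrichment assigned to the base (WT) cage state.
#' @param minCageE kPa floor for the scaled cage modulus (a vanishing-
#'   stiffness region would degenerate).
#' @param ... passed to \code{\link{scenarioParams}}.
#' @return data.frame: enrichment, aspect_ratio, volume_change, instability,
#'   converged.
#' @export
sweepEnrichment <- function(enrichmentGrid, name = "WT",
                            refEnrichment = 2.2, minCageE = 0.05, ...) {
  base <- scenarioParams(name, ...)
  rows <- lapply(enrichmentGrid, function(E) {
    sc <- E / refEnrichment
    mat <- base$materials
    mat$E["cage"] <- max(mat$E["cage"] * sc, minCageE)
    act <- base$active
    act$sigmaMT <- act$sigmaMT * sc
    sol <- tryCatch({
      model <- buildModel(base$geometry, mechMaterials(mat$E, mat$nu), act)
      solveSchedule(model, .standardLegs(act))
    }, error = function(e) NULL)
    if (is.null(sol))
      data.frame(enrichment = E, aspect_ratio = NA, volume_change = NA,
                 instability = NA, converged = FALSE)
    else
      data.frame(enrichment = E, aspect_ratio = sol@nuclearAspectRatio,
                 volume_change = sol@nuclearVolumeChange,
                 instability = sol@tipInstability, converged = TRUE)
  })
  do.call(rbind, rows)
}

#' Detect the tip instability under increasing cage compression
#'
#' Ramps the cage stress through increasing levels after the physiological
#' configuration and tracks the location of the maximum principal stress on
#' the lamina. The instability is flagged at the first level where the
#' location crosses s > 0.8 (a jump from the nuclear middle to the tips);
#' the critical stress is interpolated between the bracketing levels. With
#' \code{rescue = TRUE} the cage stress is subsequently reduced (simulated
#' LINC complex disruption) and the post-rescue solution returned, so the
#' return of the stress location to the nuclear middle and the accompanying
#' elongation can be checked.
#'
#' @param sigmaMTLevels increasing cage stress magnitudes (kPa), at least 5.
#' @param name base scenario (instability requires a softened lamina).
#' @param rescue logical.
#' @param rescueFraction cage stress scaling applied after instability.
#' @param sThreshold arc-coordinate threshold for calling the jump; on
#'   coarse meshes the discrete element positions quantize the arc
#'   coordinate, so mesh-resolution studies may lower it.
#' @param ... passed to \code{\link{scenarioParams}}.
#' @return list: \code{critical} (kPa or NA), \code{instability} (logical),
#'   \code{locations}, \code{aspectRatios}, \code{levels}, and with rescue
#'   \code{rescueSolution}.
#' @export
detectTipInstability <- function(sigmaMTLevels, name = "LMNA_mut",
                                 rescue = FALSE, rescueFraction = 0.25,
                                 sThreshold = 0.8, ...) {
  if (length(sigmaMTLevels) < 5) stop("need at least 5 load levels")
  if (is.unsorted(sigmaMTLevels)) stop("levels must be increasing")
  sp <- scenarioParams(name, ...)
  act <- sp$active
  model <- buildModel(sp$geometry, mechMaterials(sp$materials$E,
                                                 sp$materials$nu), act)
  ## fibre directions are frozen at the physiological configuration: the
  ## cage overload does not instantly remodel the myofibril lattice
  physLegs <- list(list(target = c(act$rho0, 0, act$sigmaMT),
                        nSteps = act$rampSteps),
                   list(target = c(0, act$rhoPolar, act$sigmaMT),
                        nSteps = act$blendSteps))
  phys <- solveSchedule(model, physLegs)
  for (i in seq_len(max(act$polarizationIterations - 1, 0)))
    phys <- solveSchedule(model, physLegs,
                          polarDirs = .principalDirs(phys@stress))
  dirs <- .principalDirs(phys@stress)
  legs <- c(physLegs,
            lapply(sigmaMTLevels, function(sm)
              list(target = c(0, act$rhoPolar, sm), nSteps = 3)))
  sols <- solveSchedule(model, legs, polarDirs = dirs, keep = "legs")
  sols <- sols[-(1:2)]                  # drop ramp and blend legs
  locs <- vapply(sols, function(s) s@laminaStressLocation, 0)
  ars <- vapply(sols, function(s) s@nuclearAspectRatio, 0)
  hit <- which(locs > sThreshold)
  critical <- NA_real_
  if (length(hit)) {
    k <- hit[1]
    if (any(diff(locs[seq_len(k)]) < -0.25))
      warning("non-monotone stress-location trace; no critical value ",
              "reported")
    else critical <- if (k == 1) sigmaMTLevels[1] else
      stats::approx(locs[c(k - 1, k)], sigmaMTLevels[c(k - 1, k)],
                    xout = sThreshold)$y
  }
  out <- list(critical = critical, instability = length(hit) > 0,
              locations = locs, aspectRatios = ars,
              levels = sigmaMTLevels,
              physAspectRatio = phys@nuclearAspectRatio)
  if (rescue && length(hit)) {
    ## simulated LINC complex disruption after the instability: cage
    ## stress and stiffness both reduced; the response is hyperelastic,
    ## so the rescued equilibrium is solved directly
    mat <- sp$materials
    mat$E["cage"] <- mat$E["cage"] * rescueFraction
    resModel <- buildModel(sp$geometry, mechMaterials(mat$E, mat$nu), act)
    smRes <- sigmaMTLevels[length(sigmaMTLevels)] * rescueFraction
    resLegs <- list(list(target = c(act$rho0, 0, smRes),
                         nSteps = act$rampSteps),
                    list(target = c(0, act$rhoPolar, smRes),
                         nSteps = act$blendSteps))
    res <- solveSchedule(resModel, resLegs)
    for (i in seq_len(max(act$polarizationIterations - 1, 0)))
      res <- solveSchedule(resModel, resLegs,
                           polarDirs = .principalDirs(res@stress))
    out$rescueSolution <- res
  }
  out
}

#' Load mechanics parameters from a YAML scenario config
#'
#' Recognized top-level blocks: \code{geometry}, \code{materials} (maps
#' \code{E} and \code{nu} per region), \code{active}, and \code{scenario}
#' options passed to \code{\link{scenarioParams}}.
#'
#' @param file YAML path.
#' @return list of arguments for \code{\link{scenarioParams}}.
#' @export
readMechConfig <- function(file) {
  cfg <- yaml::read_yaml(file)
  out <- list()
  if (!is.null(cfg$geometry))
    out$geometry <- do.call(mechGeometry, cfg$geometry)
  if (!is.null(cfg$materials))
    out$materials <- mechMaterials(E = unlist(cfg$materials$E),
                                   nu = unlist(cfg$materials$nu))
  if (!is.null(cfg$active)) out$active <- do.call(activeState, cfg$active)
  if (!is.null(cfg$scenario)) out <- c(out, cfg$scenario)
  out
}

#' Export a solution's fields as per-element CSV
#'
#' Writes element centroids, region labels, Cauchy stress components and
#' centroid displacements; readable by any unstructured-grid viewer.
#'
#' @param solution a \linkS4class{MechSolution}.
#' @param file output path.
#' @export
writeSolutionFields <- function(solution, file) {
  mesh <- solution@model@mesh
  Uc <- (solution@U[mesh$tri[, 1], ] + solution@U[mesh$tri[, 2], ] +
           solution@U[mesh$tri[, 3], ]) / 3
  df <- data.frame(r = mesh$centroid[, 1], z = mesh$centroid[, 2],
                   region = as.character(mesh$region),
                   u_r = Uc[, 1], u_z = Uc[, 2],
                   s_rr = solution@stress[, "rr"],
                   s_zz = solution@stress[, "zz"],
                   s_rz = solution@stress[, "rz"],
                   s_tt = solution@stress[, "tt"])
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
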