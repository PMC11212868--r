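test_that("model assembly reproduces the analytic region volumes", {
  m <- buildModel(testGeometry(), testMaterials(), activeState())
  vol <- tapply(m@mesh$weight, m@mesh$region, sum)
  g <- m@geometry
  vNuc <- 2 / 3 * pi * g$nucleusRadius^3        # half-domain z >= 0
  vCage <- 2 / 3 * pi * g$cageSemiAxes[1]^2 * g$cageSemiAxes[2] - vNuc
  vCell <- pi * g$cellRadius^2 * g$cellHalfLength
  expect_equal(unname(vol["lamina"] + vol["nucleoplasm"]), vNuc,
               tolerance = 0.02)
  expect_equal(unname(vol["cage"]), vCage, tolerance = 0.02)
  expect_equal(unname(sum(vol)), vCell, tolerance = 1e-6)
  ## at the default (fine) resolution the staircase error is below 1%
  mFine <- buildModel(mechGeometry(), mechMaterials(), activeState())
  volF <- tapply(mFine@mesh$weight, mFine@mesh$region, sum)
  gF <- mFine@geometry
  expect_equal(unname(volF["lamina"] + volF["nucleoplasm"]),
               2 / 3 * pi * gF$nucleusRadius^3, tolerance = 0.01)
  ## refinement reduces the nuclear-volume discretization error
  m2 <- buildModel(testGeometry(meshFine = 0.1), testMaterials(),
                   activeState())
  vol2 <- tapply(m2@mesh$weight, m2@mesh$region, sum)
  err1 <- abs(vol["lamina"] + vol["nucleoplasm"] - vNuc)
  err2 <- abs(vol2["lamina"] + vol2["nucleoplasm"] - vNuc)
  expect_lt(unname(err2), unname(err1))
  ## invariant violations
  expect_error(mechGeometry(laminaThickness = 1), "nucleusRadius/5")
  expect_error(mechGeometry(meshFine = 0.2, laminaThickness = 0.3),
               "2 elements")
  expect_error(mechGeometry(nucleusRadius = 4, cageSemiAxes = c(3.5, 6)),
               "nest")
})

test_that("the unloaded model is exactly undeformed", {
  m <- buildModel(testGeometry(), testMaterials(), activeState())
  sol <- solveSchedule(m, list(list(target = c(0, 0, 0), nSteps = 1)))
  expect_identical(max(abs(sol@U)), 0)
  expect_equal(sol@nuclearAspectRatio, 1)
  expect_true(all(abs(sol@probes) < 1e-12))
})

test_that("small-load response matches the constrained-cylinder solution", {
  ## homogeneous material, no cage stress, tiny isotropic contractility:
  ## closed form e = -rho / (2 (lambda + mu)), u_z = 0
  geo <- mechGeometry(nucleusRadius = 0.5, cageSemiAxes = c(0.7, 0.9),
                      laminaThickness = 0.09, meshFine = 0.045,
                      meshCoarse = 2)
  E0 <- 5; nu0 <- 0.3; rho <- 0.01
  mat <- mechMaterials(E = c(cytoplasm = E0, cage = E0, lamina = E0,
                             nucleoplasm = E0),
                       nu = c(cytoplasm = nu0, cage = nu0, lamina = nu0,
                              nucleoplasm = nu0))
  m <- buildModel(geo, mat, activeState(voidScale = 0))
  sol <- solveSchedule(m, list(list(target = c(rho, 0, 0), nSteps = 1)))
  mu <- E0 / (2 * (1 + nu0))
  lam <- E0 * nu0 / ((1 + nu0) * (1 - 2 * nu0))
  eExp <- -rho / (2 * (lam + mu))
  nodes <- m@mesh$nodes
  far <- which(nodes[, 1] > 0.98 * geo$cellRadius)
  eFE <- mean(sol@U[far, 1] / nodes[far, 1])
  expect_equal(eFE, eExp, tolerance = 0.02)
  ## u_z vanishes except for the local perturbation of the (inactive)
  ## inclusion regions near the origin
  expect_lt(max(abs(sol@U[, 2])), 1e-3)
})

test_that("boundary conditions hold: axis, mid-plane and cell ends", {
  sol <- testScenario("WT")
  m <- sol@model
  nodes <- m@mesh$nodes
  expect_lt(max(abs(sol@U[nodes[, 1] < 1e-9, 1])), 1e-12)
  ends <- abs(nodes[, 2]) < 1e-9 |
    abs(nodes[, 2] - m@geometry$cellHalfLength) < 1e-9
  ## cell length constant through the ramp
  expect_lt(max(abs(sol@U[ends, 2])) / m@geometry$cellHalfLength, 1e-8)
})

test_that("the wild-type prestressed state shows the physiological field
           pattern", {
  sol <- testScenario("WT")
  expect_true(sol@converged)
  m <- sol@model
  nodes <- m@mesh$nodes
  ## cytoplasm contracts radially while cell length is fixed
  lat <- which(nodes[, 1] > 0.98 * m@geometry$cellRadius)
  expect_lt(max(sol@U[lat, 1]), 0)
  ## nucleus elongates axially from the round stress-free shape
  expect_gt(sol@nuclearAspectRatio, 1.2)
  ## myofibril tension: maximum at the cage short tip, minimum at the
  ## long tip, both within the physiological 2-3 kPa band
  expect_gt(sol@probes["myofibril_tension_cage_short_tip"],
            sol@probes["myofibril_tension_cage_long_tip"])
  expect_gt(sol@probes["myofibril_tension_cage_short_tip"], 2)
  expect_lt(sol@probes["myofibril_tension_cage_short_tip"], 3)
  ## axial microtubule load: the long-tip site carries more compression
  ## (less tension) than the short-tip site
  expect_gt(sol@probes["mt_axial_compression_nucleus_long_tip"],
            sol@probes["mt_axial_compression_nucleus_short_tip"])
  ## the maximum principal stress on the lamina sits at the nuclear middle
  expect_lt(sol@laminaStressLocation, 0.3)
})

test_that("scenario aspect ratios reproduce the group ordering", {
  arWT <- testScenario("WT")@nuclearAspectRatio
  arCS <- testScenario("csDNKASH")@nuclearAspectRatio
  arMut <- testScenario("LMNA_mut")@nuclearAspectRatio
  arBoth <- testScenario("LMNA_mut_csDNKASH")@nuclearAspectRatio
  expect_lt(arWT, arCS)
  expect_lt(arCS, arBoth)
  ## intact cage: mutant lamina alone barely changes the shape
  expect_lt(abs(arMut - arWT) / arWT, 0.15)
  ## determinism: a rerun is bit-identical
  again <- runScenario("csDNKASH", geometry = testGeometry(),
                       materials = testMaterials(),
                       mutantLaminaE = testMutantLamina)
  expect_identical(again@U, testScenario("csDNKASH")@U)
  expect_error(runScenario("not_a_scenario"), "unknown scenario")
})

test_that("nuclear aspect ratio is non-increasing in cage stress over the
           physiological range", {
  ars <- vapply(c(0, 0.7, 1.4), function(sMT) {
    act <- activeState(sigmaMT = sMT)
    runScenario("WT", geometry = testGeometry(),
                materials = testMaterials(),
                active = act)@nuclearAspectRatio
  }, 0)
  expect_true(all(diff(ars) <= 1e-6))
})

test_that("enrichment sweep recovers the restriction of elongation by the
           cage", {
  grid <- c(0.3, 0.8, 1.3, 1.9, 2.4, 3.0)
  sw <- sweepEnrichment(grid, geometry = testGeometry(),
                        materials = testMaterials(),
                        active = activeState(blendSteps = 6))
  expect_true(all(sw$converged))
  ## depleted cage: maximal elongation; AR falls as enrichment grows
  expect_equal(which.max(sw$aspect_ratio), 1L)
  fit <- stats::lm(aspect_ratio ~ enrichment, sw)
  expect_lt(stats::coef(fit)[2], 0)
  ## the top of the grid approaches a plateau: the last point is within
  ## 5% of the mean of the top three
  expect_lt(abs(sw$aspect_ratio[6] - mean(sw$aspect_ratio[4:6])) /
              mean(sw$aspect_ratio[4:6]), 0.05)
  ## two-point grid bookkeeping
  sw2 <- sweepEnrichment(c(1, 2), geometry = testGeometry(),
                         materials = testMaterials(),
                         active = activeState(blendSteps = 6))
  expect_identical(nrow(sw2), 2L)
})

test_that("tip stress localization appears under cage overload only with a
           softened lamina, and cage reduction rescues it", {
  act <- activeState(rhoPolar = 2.5)
  levels <- c(1.8, 2.2, 2.6, 2.9, 3.2)
  ## the coarse test mesh quantizes the lamina arc coordinate; 0.6 is the
  ## first tip-region element band
  mut <- detectTipInstability(levels, "LMNA_mut", rescue = TRUE,
                              sThreshold = 0.6, geometry = testGeometry(),
                              materials = testMaterials(), active = act,
                              mutantLaminaE = testMutantLamina)
  wt <- detectTipInstability(levels, "WT", sThreshold = 0.6,
                             geometry = testGeometry(),
                             materials = testMaterials(), active = act)
  expect_true(mut$instability)
  expect_false(wt$instability)
  expect_false(is.na(mut$critical))
  ## softer lamina destabilizes earlier than the wild type anywhere in the
  ## tested range
  expect_true(all(wt$locations < 0.5))
  ## rescue: reducing cage stress and stiffness returns the maximum
  ## principal stress to the nuclear middle and elongates the nucleus
  ## relative to its physiological (pre-overload) configuration
  expect_lt(mut$rescueSolution@laminaStressLocation, 0.5)
  expect_gt(mut$rescueSolution@nuclearAspectRatio, mut$physAspectRatio)
  expect_error(detectTipInstability(c(1, 2)), "5 load levels")
})
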