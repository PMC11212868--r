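test_that("strain computation matches closed forms", {
  n <- 90
  ## constant length: zero strain
  s <- computeStrain(makeTrace(rep(1.80, n)), baselineRule = "first_sample")
  expect_equal(s@sarcomereStrain, rep(0, n))
  ## arithmetic check: 1.800 -> 1.5948 um is -11.4%
  sl <- rep(1.800, n); sl[45] <- 1.5948
  s <- computeStrain(makeTrace(sl), baselineRule = "first_sample")
  expect_equal(min(s@sarcomereStrain), -11.4)
  ## linear ramp: strain linear in time with the closed-form slope
  sl <- 1.8 * (1 - 0.001 * (seq_len(n) - 1))
  s <- computeStrain(makeTrace(sl), baselineRule = "first_sample")
  slope <- diff(s@sarcomereStrain) / diff(s@time)
  expect_lt(max(abs(slope - (-0.1 * 90))), 1e-9)
  ## strains invariant under unit rescaling of lengths
  s2 <- computeStrain(makeTrace(1000 * sl, nl = rep(11500, n),
                                nw = rep(5800, n)),
                      baselineRule = "first_sample")
  expect_equal(s2@sarcomereStrain, s@sarcomereStrain)
})

test_that("cycle segmentation finds onset, peak and relaxation end", {
  p <- genotypePreset("WT_rat", noiseSD = 0, nCycles = 3)
  tr <- generateTraces(p)[[1]]
  s <- computeStrain(tr)
  ph <- segmentCycles(s, onsetThreshold = 0.5)
  expect_length(ph@onset, 3)
  ## closed-form onset: raised cosine crosses 0.5% at
  ## t0 + (tau_c/pi) acos(1 - 2 thr/|A|)
  tOn <- 0.1 + (0.2 / pi) * acos(1 - 2 * 0.5 / 11.4)
  expect_lt(abs(s@time[ph@onset[1]] - tOn), 1 / 90 + 1e-12)
  ## peak at the sampled waveform extremum
  expect_equal(s@time[ph@peak[1]], 0.3)
  ## identical cycles: per-cycle offsets equal within one frame
  expect_lt(max(abs(diff(ph@onset) - 90)), 1.5)
  expect_lt(max(abs(diff(ph@peak) - 90)), 1.5)
  ## flat trace: no contraction detected
  sFlat <- computeStrain(makeTrace(rep(1.8, 90)),
                         baselineRule = "first_sample")
  expect_error(segmentCycles(sFlat), "no contraction")
})

test_that("identity coupling lies on the identity line with zero dampening", {
  n <- 90
  sl <- 1.8 * (1 + cardionuc:::sarcomereWave((seq_len(n) - 1) / 90, -10,
                                             0.1, 0.2, 0.15, 1) / 100)
  nl <- 11.5 * sl / 1.8
  tr <- makeTrace(sl, nl = nl)
  s <- computeStrain(tr, baselineRule = "first_sample")
  ph <- segmentCycles(s)
  path <- couplingPath(s, ph)
  expect_lt(max(abs(path$eps_n - path$eps_s)), 1e-9)
  expect_lt(systolicDampening(path), 1e-9)
  expect_lt(diastolicDampening(path), 1e-9)
})

test_that("systolic dampening matches a brute-force quadrature oracle", {
  ## parabolic contraction limb sampled at 200 points, peak -10%
  xs <- seq(0, -10, length.out = 200)
  path <- makePath(xs, xs^2 / 10)
  d <- systolicDampening(path)
  ## oracle: 1e5-point trapezoid quadrature
  xf <- seq(0, -10, length.out = 1e5)
  f <- xf^2 / 10 - xf
  oracle <- abs(sum((f[-1] + f[-1e5]) / 2 * diff(xf)))
  expect_equal(d, oracle, tolerance = 1e-3)
  expect_error(systolicDampening(path[1:2, ]), "insufficient")
})

test_that("diastolic dampening uses the shifted unit-slope reference", {
  ## relaxation limb retracing the unit-slope line through end systole: 0
  con <- makePath(seq(0, -10, length.out = 50),
                  seq(0, -6, length.out = 50))
  rel <- data.frame(eps_s = seq(-10, 0, length.out = 50),
                    eps_n = seq(-10, 0, length.out = 50) + 4,
                    limb = "relaxation")
  path <- rbind(con, rel)
  expect_lt(diastolicDampening(path), 1e-9)
  ## a limb bulging below the reference has positive area; chord reference
  ## differs from the shifted one
  rel2 <- rel
  rel2$eps_n <- rel2$eps_n - 0.5 * sin(seq(0, pi, length.out = 50))
  path2 <- rbind(con, rel2)
  expect_gt(diastolicDampening(path2), 0)
  expect_false(isTRUE(all.equal(diastolicDampening(path2, "chord"),
                                diastolicDampening(path2, "shifted"))))
})

test_that("diastolic dampening grows with the nuclear lag time constant", {
  taus <- c(0.02, 0.05, 0.08, 0.12, 0.16)
  dd <- vapply(taus, function(tau) {
    p <- traceParams(nuclearGain = 0.6, peakNuclearStrain = NA,
                     nuclearTimeConstant = tau, noiseSD = 0)
    analyzeCoupling(generateTraces(p)[[1]])@diastolicDampening
  }, 0)
  expect_true(all(diff(dd) > 0))
})

test_that("integrated nuclear strain matches the triangle closed form", {
  ## triangular nuclear strain pulse: depth 6%, duration 0.5 s -> 1.5 %.s
  n <- 91
  tt <- (seq_len(n) - 1) / 90
  tri <- pmax(0, 1 - abs(tt - 0.35) / 0.25) * (-6)
  strain <- new("StrainTrace", time = tt[1:90],
                sarcomereStrain = tri[1:90],
                nuclearLengthStrain = tri[1:90],
                nuclearWidthStrain = rep(0, 90),
                baselines = c(SL0 = 1.8, NL0 = 11.5, NW0 = 5.8),
                pacingFrequency = 1)
  ph <- new("CyclePhases", onset = 10L, peak = 32L, relaxEnd = 55L,
            onsetThreshold = 0.5)
  ## 0.35 and 0.25 s align with the 90 fps grid only approximately; the
  ## trapezoid rule is exact between samples, so tolerance is one frame
  expect_equal(integratedNuclearStrain(strain, ph), 1.5, tolerance = 0.01)
  strain@nuclearLengthStrain <- rep(0, 90)
  expect_equal(integratedNuclearStrain(strain, ph), 0)
})

test_that("multi-cycle averaged path agrees with per-cycle brute force", {
  p <- genotypePreset("WT_rat", noiseSD = 0.02, nCycles = 4, seed = 11)
  tr <- generateTraces(p)[[1]]
  s <- computeStrain(tr)
  ph <- segmentCycles(s)
  path <- couplingPath(s, ph)
  ## brute force: interpolate each cycle's limb on the same grid and average
  con <- path[path$limb == "contraction", ]
  perCycle <- vapply(seq_along(ph@onset), function(k) {
    idx <- seq(ph@onset[k], ph@peak[k])
    stats::approx(s@sarcomereStrain[idx], s@nuclearLengthStrain[idx],
                  xout = con$eps_s, ties = mean, rule = 1)$y
  }, numeric(nrow(con)))
  ## compare on the grid section covered by the raw samples of every cycle
  ## (the implementation additionally interpolates the onset crossing)
  sel <- stats::complete.cases(perCycle)
  expect_gt(sum(sel), 150)
  expect_equal(con$eps_n[sel], rowMeans(perCycle)[sel], tolerance = 1e-6)
})

test_that("dampening areas are stable under path reparameterization and
           sampling-rate doubling", {
  tr90 <- generateTraces(genotypePreset("WT_rat", noiseSD = 0))[[1]]
  r90 <- analyzeCoupling(tr90)
  tr180 <- generateTraces(genotypePreset("WT_rat", noiseSD = 0,
                                         samplingRate = 180))[[1]]
  r180 <- analyzeCoupling(tr180)
  expect_equal(r90@systolicDampening, r180@systolicDampening,
               tolerance = 5e-3)
  expect_equal(r90@diastolicDampening, r180@diastolicDampening,
               tolerance = 5e-3)
  expect_equal(r90@integratedNuclearStrain, r180@integratedNuclearStrain,
               tolerance = 5e-3)
  ## inserting interpolated midpoints leaves the areas unchanged
  path <- r90@couplingPath
  con <- path[path$limb == "contraction", ]
  dense <- data.frame(
    eps_s = c(rbind(con$eps_s, con$eps_s + c(diff(con$eps_s) / 2, 0))),
    eps_n = c(rbind(con$eps_n, con$eps_n + c(diff(con$eps_n) / 2, 0))),
    limb = "contraction")
  dense <- dense[seq_len(2 * nrow(con) - 1), ]
  ## identical up to the spline refinement of the path integral (the
  ## inserted points are linear, the original samples lie on a smooth path)
  expect_equal(systolicDampening(dense), systolicDampening(con),
               tolerance = 2e-3)
})

test_that("perturbation presets reproduce the printed group orderings", {
  res <- sapply(c("WT_rat", "AdV_DNKASH", "DMSO", "colch"), function(g)
    couplingTable(analyzeCoupling(
      generateTraces(genotypePreset(g, noiseSD = 0))[[1]]))[1, ],
    simplify = FALSE)
  ## LINC disruption increases systolic dampening
  expect_gt(res$AdV_DNKASH$d_sys, res$WT_rat$d_sys)
  ## microtubule disruption increases diastolic hysteresis
  expect_gt(res$colch$d_dia, res$DMSO$d_dia)
  ## lamin mutant: ~30% larger integrated nuclear strain than WT mouse
  insWT <- analyzeCoupling(generateTraces(
    genotypePreset("WT_mouse", noiseSD = 0))[[1]])@integratedNuclearStrain
  insMut <- analyzeCoupling(generateTraces(
    genotypePreset("N195K", noiseSD = 0))[[1]])@integratedNuclearStrain
  expect_equal(insMut / insWT, 1.30, tolerance = 0.02 / 1.30)
})

test_that("group summaries report mean, SE and n", {
  ## identical cells: SE = 0
  g <- summarizeGroup(list(makeResult(10), makeResult(10)))
  expect_true(all(g$se == 0))
  expect_true(all(g$n == 2))
  ## two cells with peaks 10 and 12: mean 11, SE 1
  g <- summarizeGroup(list(makeResult(10), makeResult(12)))
  expect_equal(g$mean[g$metric == "peak_ns"], 11)
  expect_equal(g$se[g$metric == "peak_ns"], 1)
  expect_error(summarizeGroup(list(makeResult(10)), grouping = NA),
               "empty group")
  ## Monte-Carlo: the noisy ensemble mean of the integrated nuclear strain
  ## (an integral metric, unbiased to first order unlike a peak of a noisy
  ## series) is within 3 SE of the noiseless value
  set.seed(1)
  cells <- generateTraces(genotypePreset("WT_rat", noiseSD = 0.02,
                                         seed = 3), 50)
  res <- lapply(cells, analyzeCoupling)
  g <- summarizeGroup(res)
  noiseless <- analyzeCoupling(generateTraces(
    genotypePreset("WT_rat", noiseSD = 0))[[1]])
  row <- g[g$metric == "int_ns", ]
  expect_lt(abs(row$mean - noiseless@integratedNuclearStrain), 3 * row$se)
})
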