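test_that("wild-type rat preset reproduces the calibrated peak strains", {
  tr <- generateTraces(genotypePreset("WT_rat", noiseSD = 0))[[1]]
  strain <- computeStrain(tr)
  expect_equal(min(strain@sarcomereStrain), -11.4, tolerance = 0.1 / 11.4)
  expect_equal(min(strain@nuclearLengthStrain), -6.6, tolerance = 0.1 / 6.6)
  ## opposing width expansion
  expect_gt(max(strain@nuclearWidthStrain), 0)
})

test_that("null contraction leaves all three series at baseline", {
  p <- traceParams(peakSarcomereStrain = 0, nuclearGain = 0.6,
                   peakNuclearStrain = NA, noiseSD = 0)
  tr <- generateTraces(p)[[1]]
  expect_equal(tr@sarcomereLength, rep(1.80, length(tr@time)))
  expect_equal(tr@nuclearLength, rep(11.5, length(tr@time)))
  expect_equal(tr@nuclearWidth, rep(5.8, length(tr@time)))
})

test_that("unit-gain, zero-lag nuclear response equals the sarcomere strain", {
  p <- traceParams(nuclearGain = 1, peakNuclearStrain = NA,
                   nuclearTimeConstant = 0, noiseSD = 0)
  tr <- generateTraces(p)[[1]]
  s <- computeStrain(tr, baselineRule = "first_sample")
  expect_lt(max(abs(s@nuclearLengthStrain - s@sarcomereStrain)), 1e-6)
})

test_that("the exponential-integrator lag matches fine-step integration", {
  ## independent oracle: forward Euler at 1000x finer resolution
  p <- traceParams(nuclearGain = 0.7, peakNuclearStrain = NA,
                   nuclearTimeConstant = 0.08, noiseSD = 0)
  tr <- generateTraces(p)[[1]]
  s <- computeStrain(tr, baselineRule = "first_sample")
  fs <- 90 * 1000
  tt <- (seq_len(fs) - 1) / fs
  forcing <- 0.7 * cardionuc:::sarcomereWave(tt, -11.4, 0.1, 0.2, 0.15, 1)
  tau <- 0.08
  y <- 0
  ## run several periods so the Euler trace reaches the periodic state
  for (rep in 1:8) {
    ys <- numeric(fs)
    for (k in seq_len(fs)) {
      y <- y + (1 / fs) * (forcing[k] - y) / tau
      ys[k] <- y
    }
  }
  oracle <- ys[seq(1, fs, by = 1000)] - ys[1]
  expect_lt(max(abs(s@nuclearLengthStrain - oracle)), 0.02)
})

test_that("noiseless traces are exactly periodic across cycles", {
  for (preset in c("WT_rat", "colch", "N195K")) {
    tr <- generateTraces(genotypePreset(preset, noiseSD = 0,
                                        nCycles = 3))[[1]]
    nPer <- length(tr@time) / 3
    m <- matrix(tr@nuclearLength, nPer)
    expect_lt(max(abs(m - m[, 1])), 1e-9)
    m <- matrix(tr@sarcomereLength, nPer)
    expect_lt(max(abs(m - m[, 1])), 1e-9)
  }
})

test_that("nuclear strain is dampened whenever the gain is at most one", {
  for (gain in c(0.3, 0.7, 1.0)) {
    p <- traceParams(nuclearGain = gain, peakNuclearStrain = NA, noiseSD = 0)
    tr <- generateTraces(p)[[1]]
    s <- computeStrain(tr, baselineRule = "first_sample")
    expect_lte(max(abs(s@nuclearLengthStrain)),
               max(abs(s@sarcomereStrain)) + 1e-9)
  }
})

test_that("same seed gives byte-identical traces, and presets validate", {
  a <- generateTraces(genotypePreset("WT_rat", seed = 7, noiseSD = 0.05), 3)
  b <- generateTraces(genotypePreset("WT_rat", seed = 7, noiseSD = 0.05), 3)
  expect_identical(a, b)
  expect_error(genotypePreset("not_a_genotype"), "unknown")
  ## infeasible calibration: target beyond the gain ceiling
  expect_error(generateTraces(traceParams(peakNuclearStrain = -20)),
               "calibration error")
  ## invariant violations
  expect_error(traceParams(relaxationTime = 2), "period")
  expect_error(traceParams(samplingRate = 1), "twice")
  expect_error(traceParams(noiseSD = -1), "non-negative")
})

test_that("trace CSV round-trips through the documented schema", {
  traces <- generateTraces(genotypePreset("colch", noiseSD = 0.03,
                                          seed = 2), 2)
  f <- tempfile(fileext = ".csv")
  writeTraces(traces, f)
  back <- readTraces(f)
  expect_equal(length(back), 2)
  expect_equal(back[[1]]@nuclearLength, traces[[1]]@nuclearLength)
  expect_equal(back[[2]]@genotype, "colch")
  header <- readLines(f, n = 1)
  expect_match(header, "time_s.*sarcomere_length_um.*nuclear_length_um")
})
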