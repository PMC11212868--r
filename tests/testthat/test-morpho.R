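test_that("segmentation recovers the noiseless ellipse", {
  img <- generateNucleusImage(imageSpec(seed = 1))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  truth <- with(img@groundTruth, {
    g <- cardionuc:::.gridCoords2d(dim(img@channels$chromatin),
                                   img@voxelSize)
    (g$X / (nuclearLength / 2))^2 + (g$Y / (nuclearWidth / 2))^2 <= 1
  })
  dice <- 2 * sum(seg$mask & truth) / (sum(seg$mask) + sum(truth))
  expect_gte(dice, 0.99)
  ## determinism
  seg2 <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  expect_identical(seg$mask, seg2$mask)
  ## degenerate input
  expect_error(segmentNucleus(matrix(0.5, 50, 50), 0.1), "segmentation")
})

test_that("nuclear dimensions are accurate and rotation invariant", {
  ## sphere: AR 1
  img <- generateNucleusImage(imageSpec(semiAxes = c(3.5, 3.5), seed = 1))
  d <- nuclearDimensions(segmentNucleus(img@channels$chromatin, 0.1))
  expect_equal(d$aspectRatio, 1, tolerance = 0.02)
  ## 7 x 3.5 um ellipse: AR 2, dimensions recovered
  img <- generateNucleusImage(imageSpec(semiAxes = c(3.5, 1.75), seed = 1))
  d <- nuclearDimensions(segmentNucleus(img@channels$chromatin, 0.1))
  expect_equal(d$aspectRatio, 2, tolerance = 0.05 / 2)
  expect_equal(d$length, 7, tolerance = 0.03)
  expect_equal(d$area, pi * 3.5 * 1.75, tolerance = 0.02)
  ## rotation sweep: unbiased within 2%, 37 degrees within 0.02
  ars <- vapply(seq(0, 165, by = 15), function(deg) {
    img <- generateNucleusImage(imageSpec(semiAxes = c(3.5, 1.75),
                                          orientation = deg * pi / 180,
                                          seed = 1))
    nuclearDimensions(segmentNucleus(img@channels$chromatin,
                                     0.1))$aspectRatio
  }, 0)
  expect_lt(max(abs(ars - 2)) / 2, 0.02)
  img37 <- generateNucleusImage(imageSpec(semiAxes = c(3.5, 1.75),
                                          orientation = 37 * pi / 180,
                                          seed = 1))
  ar37 <- nuclearDimensions(segmentNucleus(img37@channels$chromatin,
                                           0.1))$aspectRatio
  expect_lt(abs(ar37 - ars[1]), 0.02)
  expect_error(nuclearDimensions(matrix(FALSE, 10, 10), 0.1), "degenerate")
})

test_that("perinuclear enrichment recovers the generator truth", {
  ## uniform tubulin: all ratios 1
  img <- generateNucleusImage(imageSpec(enrichmentFactor = 1, seed = 2))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  e <- perinuclearEnrichment(img@channels$tubulin, seg)
  expect_equal(e$overall, 1, tolerance = 0.02)
  expect_equal(e$tips, 1, tolerance = 0.02)
  ## factor 2, noiseless
  img <- generateNucleusImage(imageSpec(enrichmentFactor = 2, seed = 2))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  e <- perinuclearEnrichment(img@channels$tubulin, seg)
  expect_equal(e$overall, 2, tolerance = 0.1 / 2)
  ## tip-biased cage: tips above sides
  img <- generateNucleusImage(imageSpec(enrichmentFactor = 2,
                                        tipBoost = 1.5, seed = 2))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  e <- perinuclearEnrichment(img@channels$tubulin, seg)
  expect_gt(e$tips, e$sides)
  expect_equal(e$overall, 2, tolerance = 0.05)
  ## recovery across factors at realistic noise (SNR >= 10)
  for (ef in c(1, 1.5, 2, 3)) {
    img <- generateNucleusImage(imageSpec(enrichmentFactor = ef,
                                          noiseSD = 0.05, seed = 30 + ef))
    seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
    e <- perinuclearEnrichment(img@channels$tubulin, seg)
    expect_lt(abs(e$overall - ef), 0.15)
  }
  ## ratios invariant to global intensity scaling
  img <- generateNucleusImage(imageSpec(enrichmentFactor = 1.6, seed = 3))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  e1 <- perinuclearEnrichment(img@channels$tubulin, seg)
  e2 <- perinuclearEnrichment(10 * img@channels$tubulin, seg)
  expect_equal(e1$overall, e2$overall)
  ## ring validation
  expect_error(ringGeometry(pnWidth = 3, cytInner = 2), "pnWidth")
})

test_that("csDNKASH image preset returns enrichment 1.4", {
  img <- generateNucleusImage(genotypePreset("csDNKASH", type = "image",
                                             seed = 8))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  e <- perinuclearEnrichment(img@channels$tubulin, seg)
  expect_equal(e$overall, 1.4, tolerance = 0.1 / 1.4)
})

test_that("protrusion detection calls tips and estimates area", {
  ## clean ellipsoid: no protrusion
  img <- generateNucleusImage(imageSpec(protrusionPresent = FALSE,
                                        seed = 4))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  expect_false(detectProtrusion(seg)$present)
  ## planted protrusion: detected, area within 25% of the analytic cap
  spec <- imageSpec(protrusionPresent = TRUE, protrusionRadius = 0.8,
                    protrusionOffset = 1, protrusionTipSign = 1, seed = 4)
  img <- generateNucleusImage(spec)
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  det <- detectProtrusion(seg)
  expect_true(det$present)
  expect_equal(det$area, img@groundTruth$protrusionArea, tolerance = 0.25)
})

test_that("protrusion prevalence is recovered on a seeded cohort", {
  n <- 80
  imgs <- lapply(seq_len(n), function(k)
    generateNucleusImage(genotypePreset("N195K", type = "image",
                                        seed = 600 + k, noiseSD = 0.05)))
  gt <- vapply(imgs, function(i) i@groundTruth$protrusionPresent, TRUE)
  sc <- scoreCohort(imgs, mode = "protrusion", nBoot = 200, seed = 1)
  ## detected prevalence within the exact binomial 95% CI of the truth
  ci <- stats::binom.test(sum(gt), n)$conf.int
  expect_gte(sc$estimate, ci[1])
  expect_lte(sc$estimate, ci[2])
})

test_that("foci detection respects the perinuclear admissibility zone", {
  ## no foci
  img <- generateNucleusImage(imageSpec(fociRate = 0, noiseSD = 0.02,
                                        seed = 5))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  expect_identical(detectFoci(img@channels$foci, seg)$count, 0L)
  ## three in-ring foci at high SNR: count 3, areas within 30% of pi r^2
  centers <- rbind(c(5.9, 0), c(0, 3.05), c(-5.9, 0))
  img <- generateNucleusImage(imageSpec(fociCenters = centers,
                                        fociRadius = 0.25,
                                        noiseSD = 0.02, seed = 5))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  det <- detectFoci(img@channels$foci, seg)
  expect_identical(det$count, 3L)
  expect_true(all(abs(det$areas - pi * 0.25^2) / (pi * 0.25^2) < 0.3))
  ## focus 2 um outside the border is excluded
  img <- generateNucleusImage(imageSpec(fociCenters = cbind(7.45, 0),
                                        noiseSD = 0.02, seed = 5))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  expect_identical(detectFoci(img@channels$foci, seg)$count, 0L)
  ## nuclear-interior mode keeps only interior foci
  centers <- rbind(c(0, 0), c(5.9, 0))
  img <- generateNucleusImage(imageSpec(fociCenters = centers,
                                        noiseSD = 0.02, seed = 5))
  seg <- segmentNucleus(img@channels$chromatin, img@voxelSize)
  expect_identical(detectFoci(img@channels$foci, seg,
                              mode = "nuclear")$count, 1L)
})

test_that("cohort scoring summarizes with bootstrap intervals", {
  imgs <- lapply(1:6, function(k)
    generateNucleusImage(imageSpec(protrusionPresent = FALSE, seed = 100)))
  sc <- scoreCohort(imgs, mode = "protrusion", nBoot = 100, seed = 2)
  expect_equal(sc$estimate, 0)
  expect_equal(unname(sc$ci), c(0, 0))
  expect_error(scoreCohort(list()), "empty cohort")
  ## determinism of the bootstrap
  sc2 <- scoreCohort(imgs, mode = "protrusion", nBoot = 100, seed = 2)
  expect_identical(sc$ci, sc2$ci)
})
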