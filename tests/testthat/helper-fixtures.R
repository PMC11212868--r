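## shared fixtures built in code

## a ContractionTrace from explicit length series on a uniform grid
makeTrace <- function(sl, nl = NULL, nw = NULL, fs = 90, pacing = 1,
                      id = "cell", genotype = "custom") {
  n <- length(sl)
  if (is.null(nl)) nl <- rep(11.5, n)
  if (is.null(nw)) nw <- rep(5.8, n)
  new("ContractionTrace", time = (seq_len(n) - 1) / fs,
      sarcomereLength = sl, nuclearLength = nl, nuclearWidth = nw,
      cellId = id, genotype = genotype, pacingFrequency = pacing)
}

## coupling path data.frame from explicit strain samples
makePath <- function(eps_s_con, eps_n_con, eps_s_rel = NULL,
                     eps_n_rel = NULL) {
  p <- data.frame(eps_s = eps_s_con, eps_n = eps_n_con,
                  limb = "contraction")
  if (!is.null(eps_s_rel))
    p <- rbind(p, data.frame(eps_s = eps_s_rel, eps_n = eps_n_rel,
                             limb = "relaxation"))
  p
}

## a CouplingResult carrying only the metrics needed by group summaries
makeResult <- function(peak_ns, id = "c", genotype = "g") {
  new("CouplingResult", peakSarcomereCompression = peak_ns + 4,
      peakNuclearCompression = peak_ns, peakWidthExpansion = 1,
      systolicDampening = 1, diastolicDampening = 1,
      integratedNuclearStrain = 1,
      couplingPath = data.frame(eps_s = 0, eps_n = 0, limb = "contraction"),
      cellId = id, genotype = genotype)
}

## small geometry for fast mechanics tests: a 3x thicker lamina so a 3x
## coarser mesh still resolves it with two elements through the thickness;
## lamina moduli are divided by 3 to preserve the shell stiffness
## (modulus x thickness) of the default configuration
testGeometry <- function(meshFine = 0.15)
  mechGeometry(meshFine = meshFine, laminaThickness = 0.3)

testMaterials <- function(lamina = 25 / 3)
  mechMaterials(E = c(cytoplasm = 1.2, cage = 8, lamina = lamina,
                      nucleoplasm = 0.25),
                nu = c(cytoplasm = 0.3, cage = 0.3, lamina = 0.3,
                       nucleoplasm = 0.49))

## mutant lamina at test scale: 10 kPa / 3
testMutantLamina <- 10 / 3

## one mechanics scenario at test scale, memoised across test files
testScenario <- local({
  cache <- list()
  function(name, ...) {
    key <- paste(name, deparse(list(...)), collapse = "_")
    if (is.null(cache[[key]]))
      cache[[key]] <<- runScenario(name, geometry = testGeometry(),
                                   materials = testMaterials(),
                                   mutantLaminaE = testMutantLamina, ...)
    cache[[key]]
  }
})
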