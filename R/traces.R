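#' Parameters for the contraction-trace generator
#'
#' Bundles the waveform, coupling and noise parameters that define one
#' experimental condition. The sarcomere strain waveform is a raised-cosine
#' shortening followed by an exponential re-lengthening (tapered so each
#' pacing cycle closes exactly at baseline); the nuclear length responds
#' through a first-order lag with gain \code{nuclearGain} and time constant
#' \code{nuclearTimeConstant}, and nuclear width strain is
#' \code{widthGain} times nuclear length strain (negative, so compression of
#' the length couples to expansion of the width).
#'
#' When \code{peakNuclearStrain} is given, \code{\link{generateTraces}}
#' calibrates \code{nuclearGain} so the realized peak nuclear length strain
#' matches it; the lag response is linear in the gain, so the calibration is
#' exact up to floating point.
#'
#' @param pacingFrequency Hz.
#' @param samplingRate frames per second.
#' @param nCycles number of pacing cycles.
#' @param baselineSL,baselineNL,baselineNW diastolic sarcomere length,
#'   nuclear length and nuclear width, micrometres.
#' @param peakSarcomereStrain percent; negative = compression.
#' @param onsetDelay seconds from the start of each pacing period to
#'   contraction onset.
#' @param contractionTime seconds, duration of the raised-cosine shortening.
#' @param relaxationTime seconds, exponential re-lengthening time constant.
#' @param nuclearGain dimensionless lag gain in [0, 1.5]; ignored when
#'   \code{peakNuclearStrain} is given.
#' @param peakNuclearStrain percent (negative) target peak nuclear length
#'   strain, or \code{NA} to use \code{nuclearGain} directly.
#' @param nuclearTimeConstant seconds, lag time constant (0 = instantaneous).
#' @param widthGain dimensionless, negative couples length compression to
#'   width expansion.
#' @param noiseSD micrometres, additive Gaussian measurement noise applied to
#'   each recorded length series.
#' @param genotype experimental-group label.
#' @param seed integer seed for the generator.
#'
#' @return A validated list of class \code{TraceParams}.
#' @seealso \code{\link{genotypePreset}} for the calibrated condition presets.
#' @export
traceParams <- function(pacingFrequency = 1, samplingRate = 90, nCycles = 1,
                        baselineSL = 1.80, baselineNL = 11.5,
                        baselineNW = 5.8, peakSarcomereStrain = -11.4,
                        onsetDelay = 0.1, contractionTime = 0.2,
                        relaxationTime = 0.15, nuclearGain = 0.6,
                        peakNuclearStrain = NA_real_,
                        nuclearTimeConstant = 0.06, widthGain = -0.35,
                        noiseSD = 0, genotype = "WT_rat", seed = 1L) {
  p <- list(pacingFrequency = pacingFrequency, samplingRate = samplingRate,
            nCycles = as.integer(nCycles), baselineSL = baselineSL,
            baselineNL = baselineNL, baselineNW = baselineNW,
            peakSarcomereStrain = peakSarcomereStrain,
            onsetDelay = onsetDelay, contractionTime = contractionTime,
            relaxationTime = relaxationTime, nuclearGain = nuclearGain,
            peakNuclearStrain = peakNuclearStrain,
            nuclearTimeConstant = nuclearTimeConstant,
            widthGain = widthGain, noiseSD = noiseSD, genotype = genotype,
            seed = as.integer(seed))
  class(p) <- "TraceParams"
  validateTraceParams(p)
  p
}

validateTraceParams <- function(p) {
  period <- 1 / p$pacingFrequency
  if (p$onsetDelay + p$contractionTime + p$relaxationTime >= period)
    stop("pacing period must exceed onset delay + contraction time + ",
         "relaxation time constant")
  if (p$samplingRate < 2 * p$pacingFrequency)
    stop("samplingRate must be at least twice the pacing frequency")
  if (p$baselineSL <= 0 || p$baselineNL <= 0 || p$baselineNW <= 0)
    stop("baseline lengths must be positive")
  if (p$noiseSD < 0) stop("noiseSD must be non-negative")
  if (p$nCycles < 1) stop("nCycles must be at least 1")
  if (is.na(p$peakNuclearStrain) &&
      (p$nuclearGain < 0 || p$nuclearGain > 1.5))
    stop("nuclearGain must lie in [0, 1.5]")
  invisible(TRUE)
}

## Sarcomere strain (percent) at within-cycle phase s in [0, period).
## Raised-cosine onset; exponential relaxation rescaled to end exactly at 0
## so that consecutive cycles join continuously at baseline.
sarcomereWave <- function(s, amplitude, onsetDelay, contractionTime,
                          relaxationTime, period) {
  eps <- numeric(length(s))
  rise <- s >= onsetDelay & s <= onsetDelay + contractionTime
  eps[rise] <- amplitude / 2 *
    (1 - cos(pi * (s[rise] - onsetDelay) / contractionTime))
  fall <- s > onsetDelay + contractionTime
  tail0 <- exp(-(period - onsetDelay - contractionTime) / relaxationTime)
  eps[fall] <- amplitude *
    (exp(-(s[fall] - onsetDelay - contractionTime) / relaxationTime) - tail0) /
    (1 - tail0)
  eps
}

## Exact update of tau * y' = f - y over one uniform step with piecewise
## linear forcing; exact also in the stiff limit tau -> 0.
lagFilter <- function(f, dt, tau, y0 = 0) {
  n <- length(f)
  if (tau <= 0) return(f)
  a <- exp(-dt / tau)
  m <- c(diff(f), 0) / dt
  y <- numeric(n)
  y[1] <- y0
  w <- dt - tau * (1 - a)
  for (k in seq_len(n - 1))
    y[k + 1] <- a * y[k] + f[k] * (1 - a) + m[k] * w
  y
}

## Periodic steady-state lag response to one cycle of forcing, anchored so
## the first sample is exactly zero (the anchoring shift is the residual
## carry-over of the previous cycle and is orders of magnitude below the
## strain amplitudes).
periodicLagResponse <- function(fCycle, dt, tau) {
  if (tau <= 0) return(fCycle)
  nT <- length(fCycle)
  y1 <- lagFilter(c(fCycle, fCycle[1]), dt, tau, y0 = 0)
  aTot <- exp(-nT * dt / tau)
  y0 <- y1[nT + 1] / (1 - aTot)
  y <- lagFilter(c(fCycle, fCycle[1]), dt, tau, y0 = y0)[seq_len(nT)]
  y - y[1]
}

#' Generate synthetic contraction traces
#'
#' Produces per-cell \linkS4class{ContractionTrace} objects under the
#' condition described by \code{params}. The nuclear response is the exact
#' periodic steady state of the first-order lag, so noiseless traces are
#' exactly periodic across cycles. When the parameters specify a target peak
#' nuclear strain, the gain is calibrated so the realized (sampled) peak
#' matches the target; a target that would require a gain above 1.5 is an
#' error.
#'
#' @param params a \code{\link{traceParams}} object or preset name accepted
#'   by \code{\link{genotypePreset}}.
#' @param nCells number of cells to generate.
#' @return A list of \linkS4class{ContractionTrace}.
#' @examples
#' tr <- generateTraces(genotypePreset("WT_rat", noiseSD = 0), nCells = 1)[[1]]
#' tr
#' @export
generateTraces <- function(params, nCells = 1) {
  if (is.character(params)) params <- genotypePreset(params)
  stopifnot(inherits(params, "TraceParams"), nCells >= 1)
  validateTraceParams(params)
  p <- params
  period <- 1 / p$pacingFrequency
  dt <- 1 / p$samplingRate
  nPer <- round(period / dt)
  time <- (seq_len(nPer * p$nCycles) - 1) * dt
  phase <- time %% period

  epsS <- sarcomereWave(phase, p$peakSarcomereStrain, p$onsetDelay,
                        p$contractionTime, p$relaxationTime, period)
  cyc <- sarcomereWave((seq_len(nPer) - 1) * dt, p$peakSarcomereStrain,
                       p$onsetDelay, p$contractionTime, p$relaxationTime,
                       period)
  unitLag <- periodicLagResponse(cyc, dt, p$nuclearTimeConstant)

  gain <- p$nuclearGain
  if (!is.na(p$peakNuclearStrain)) {
    unitPeak <- unitLag[which.max(abs(unitLag))]
    if (abs(unitPeak) < .Machine$double.eps)
      stop("calibration error: sarcomere waveform induces no nuclear strain")
    gain <- p$peakNuclearStrain / unitPeak
    if (gain < 0 || gain > 1.5)
      stop(sprintf(paste0("calibration error: target nuclear strain %.2f%% ",
                          "requires gain %.3f outside [0, 1.5]"),
                   p$peakNuclearStrain, gain))
  }
  epsN <- rep(gain * unitLag, p$nCycles)
  epsW <- p$widthGain * epsN

  set.seed(p$seed)
  lapply(seq_len(nCells), function(i) {
    sl <- p$baselineSL * (1 + epsS / 100)
    nl <- p$baselineNL * (1 + epsN / 100)
    nw <- p$baselineNW * (1 + epsW / 100)
    if (p$noiseSD > 0) {
      sl <- sl + rnorm(length(sl), 0, p$noiseSD * p$baselineSL / p$baselineNL)
      nl <- nl + rnorm(length(nl), 0, p$noiseSD)
      nw <- nw + rnorm(length(nw), 0, p$noiseSD)
    }
    new("ContractionTrace", time = time, sarcomereLength = sl,
        nuclearLength = nl, nuclearWidth = nw,
        cellId = sprintf("%s_cell%03d", p$genotype, i),
        genotype = p$genotype, pacingFrequency = p$pacingFrequency)
  })
}

#' Write and read contraction traces as CSV
#'
#' Long-format CSV with columns \code{time_s, sarcomere_length_um,
#' nuclear_length_um, nuclear_width_um, cell_id, genotype}.
#'
#' @param traces list of \linkS4class{ContractionTrace}.
#' @param file path.
#' @export
writeTraces <- function(traces, file) {
  if (inherits(traces, "ContractionTrace")) traces <- list(traces)
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(time_s = tr@time, sarcomere_length_um = tr@sarcomereLength,
               nuclear_length_um = tr@nuclearLength,
               nuclear_width_um = tr@nuclearWidth, cell_id = tr@cellId,
               genotype = tr@genotype)
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeTraces
#' @param pacingFrequency Hz, not stored in the CSV schema.
#' @export
readTraces <- function(file, pacingFrequency = 1) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_s), ]
    new("ContractionTrace", time = d$time_s,
        sarcomereLength = d$sarcomere_length_um,
        nuclearLength = d$nuclear_length_um,
        nuclearWidth = d$nuclear_width_um, cellId = d$cell_id[1],
        genotype = d$genotype[1], pacingFrequency = pacingFrequency)
  })
}
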