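#' Convert a contraction trace to strains
#'
#' Strains in percent relative to the diastolic baseline,
#' \eqn{\epsilon = 100 (x - x_0) / x_0}. The default baseline is the mean of
#' the five samples preceding the first contraction onset (robust to
#' single-frame noise); \code{"first_sample"} uses the first recorded sample.
#'
#' @param trace a \linkS4class{ContractionTrace}.
#' @param baselineRule "pre_onset_mean" or "first_sample".
#' @param onsetThreshold percent sarcomere strain used to locate the first
#'   onset for the pre-onset baseline window. The window is the 55 ms
#'   before the threshold crossing, excluding an 11 ms guard immediately
#'   before it (the guard skips the sub-threshold early rise of the
#'   contraction); at the reference 90 frames/s this is five frames with a
#'   one-frame guard.
#' @return A \linkS4class{StrainTrace}.
#' @export
computeStrain <- function(trace,
                          baselineRule = c("pre_onset_mean", "first_sample"),
                          onsetThreshold = 0.5) {
  stopifnot(is(trace, "ContractionTrace"))
  baselineRule <- match.arg(baselineRule)
  base <- c(SL0 = trace@sarcomereLength[1], NL0 = trace@nuclearLength[1],
            NW0 = trace@nuclearWidth[1])
  if (baselineRule == "pre_onset_mean") {
    eps0 <- 100 * (trace@sarcomereLength / base["SL0"] - 1)
    hit <- which(abs(eps0) > onsetThreshold)
    dt <- trace@time[2] - trace@time[1]
    guardN <- max(1L, round((1 / 90) / dt))
    winN <- max(1L, round((5 / 90) / dt))
    win <- if (length(hit) && hit[1] > guardN + 1)
      seq(max(1, hit[1] - guardN - winN), hit[1] - guardN - 1) else
        seq_len(min(winN, length(eps0)))
    base <- c(SL0 = mean(trace@sarcomereLength[win]),
              NL0 = mean(trace@nuclearLength[win]),
              NW0 = mean(trace@nuclearWidth[win]))
  }
  if (any(base <= 0)) stop("non-positive baseline")
  new("StrainTrace", time = trace@time,
      sarcomereStrain = 100 * (trace@sarcomereLength / base["SL0"] - 1),
      nuclearLengthStrain = 100 * (trace@nuclearLength / base["NL0"] - 1),
      nuclearWidthStrain = 100 * (trace@nuclearWidth / base["NW0"] - 1),
      baselines = base, pacingFrequency = trace@pacingFrequency)
}

#' Segment a strain trace into pacing-cycle phases
#'
#' Within each full pacing period, contraction onset is the first sample with
#' \eqn{|\epsilon_s|} above the threshold, peak systole is the extremum of
#' sarcomere strain, and relaxation end is the first post-peak return below
#' the threshold (or the period end).
#'
#' @param strain a \linkS4class{StrainTrace}.
#' @param onsetThreshold percent strain.
#' @return A \linkS4class{CyclePhases}.
#' @export
segmentCycles <- function(strain, onsetThreshold = 0.5) {
  stopifnot(is(strain, "StrainTrace"))
  dt <- strain@time[2] - strain@time[1]
  nPer <- round(1 / strain@pacingFrequency / dt)
  nCyc <- floor(length(strain@time) / nPer)
  if (nCyc < 1) stop("need at least one full pacing period")
  onset <- peak <- relaxEnd <- integer(nCyc)
  for (k in seq_len(nCyc)) {
    idx <- ((k - 1) * nPer + 1):(k * nPer)
    absS <- abs(strain@sarcomereStrain[idx])
    hit <- which(absS > onsetThreshold)
    if (!length(hit))
      stop("no contraction detected: |sarcomere strain| never exceeds ",
           onsetThreshold, "% in cycle ", k)
    onset[k] <- idx[1] + hit[1] - 1L
    peak[k] <- idx[1] + which.max(absS) - 1L
    post <- which(absS < onsetThreshold &
                    seq_along(absS) > (peak[k] - idx[1] + 1))
    relaxEnd[k] <- if (length(post)) idx[1] + post[1] - 1L else idx[nPer]
  }
  new("CyclePhases", onset = onset, peak = peak, relaxEnd = relaxEnd,
      onsetThreshold = onsetThreshold)
}

#' Cycle-averaged sarcomere-nuclear strain coupling path
#'
#' The ordered (sarcomere strain, nuclear length strain) path over one
#' contraction cycle, from onset through peak systole back to relaxation
#' end. The identity line is the lossless-coupling reference. With multiple
#' cycles, each limb is resampled to a uniform sarcomere-strain grid and
#' averaged across cycles; with a single cycle the raw samples are returned.
#'
#' @param strain a \linkS4class{StrainTrace}.
#' @param phases a \linkS4class{CyclePhases}.
#' @param nGrid resampling grid size per limb when averaging cycles.
#' @return data.frame with columns \code{eps_s}, \code{eps_n}, \code{limb}.
#' @export
couplingPath <- function(strain, phases, nGrid = 200) {
  stopifnot(is(strain, "StrainTrace"), is(phases, "CyclePhases"))
  nCyc <- length(phases@onset)
  thr <- phases@onsetThreshold
  ## interpolate the exact threshold crossing adjacent to an endpoint so
  ## the limb extent does not depend on the sampling grid to first order
  crossingBefore <- function(i) {
    a <- abs(strain@sarcomereStrain[i - 1]); b <- abs(strain@sarcomereStrain[i])
    if (i <= 1 || a > thr || b <= thr) return(NULL)
    w <- (thr - a) / (b - a)
    c(eps_s = (1 - w) * strain@sarcomereStrain[i - 1] +
        w * strain@sarcomereStrain[i],
      eps_n = (1 - w) * strain@nuclearLengthStrain[i - 1] +
        w * strain@nuclearLengthStrain[i])
  }
  crossingAfter <- function(i) {
    if (i >= length(strain@time)) return(NULL)
    a <- abs(strain@sarcomereStrain[i - 1]); b <- abs(strain@sarcomereStrain[i])
    if (a <= thr || b > thr) return(NULL)
    w <- (thr - a) / (b - a)
    c(eps_s = (1 - w) * strain@sarcomereStrain[i - 1] +
        w * strain@sarcomereStrain[i],
      eps_n = (1 - w) * strain@nuclearLengthStrain[i - 1] +
        w * strain@nuclearLengthStrain[i])
  }
  limbOf <- function(k, from, to) {
    idx <- seq(from[k], to[k])
    d <- data.frame(eps_s = strain@sarcomereStrain[idx],
                    eps_n = strain@nuclearLengthStrain[idx])
    if (identical(from, phases@onset)) {
      pre <- crossingBefore(from[k])
      if (!is.null(pre)) d <- rbind(pre, d)
    } else {
      ## end the limb exactly at the downward threshold crossing
      post <- crossingAfter(to[k])
      if (!is.null(post)) d[nrow(d), ] <- post
    }
    d
  }
  if (nCyc == 1) {
    con <- limbOf(1, phases@onset, phases@peak)
    rel <- limbOf(1, phases@peak, phases@relaxEnd)
    ## the end-systolic point belongs to both limbs so each limb integral
    ## covers its full extent
    return(rbind(cbind(con, limb = "contraction"),
                 cbind(rel, limb = "relaxation")))
  }
  avgLimb <- function(from, to, label) {
    limbs <- lapply(seq_len(nCyc), limbOf, from = from, to = to)
    x0 <- mean(vapply(limbs, function(d) d$eps_s[1], 0))
    x1 <- mean(vapply(limbs, function(d) d$eps_s[nrow(d)], 0))
    grid <- seq(x0, x1, length.out = nGrid)
    ynew <- rowMeans(vapply(limbs, function(d)
      stats::approx(d$eps_s, d$eps_n, xout = grid, ties = mean,
                    rule = 2)$y, numeric(nGrid)))
    data.frame(eps_s = grid, eps_n = ynew, limb = label)
  }
  rbind(avgLimb(phases@onset, phases@peak, "contraction"),
        avgLimb(phases@peak, phases@relaxEnd, "relaxation"))
}

.trapz <- function(x, y) sum(0.5 * (y[-1] + y[-length(y)]) * diff(x))

## Stieltjes integral along an ordered path: both coordinates are smooth
## functions of the (time-ordered) sample index, so cubic interpolation in
## the index before the trapezoid rule removes most of the sampling error
## where the path turns
.pathIntegral <- function(x, y, refine = 10) {
  n <- length(x)
  if (n < 4) return(.trapz(x, y))
  tt <- seq_len(n)
  tf <- seq(1, n, length.out = refine * (n - 1) + 1)
  xf <- stats::spline(tt, x, xout = tf)$y
  yf <- stats::spline(tt, y, xout = tf)$y
  .trapz(xf, yf)
}

#' Systolic strain dampening
#'
#' Area between the contraction limb of the coupling path and the identity
#' (lossless) line:
#' \eqn{D_{sys} = |\int (\epsilon_{nL} - \epsilon_s)\, d\epsilon_s|}
#' over the contraction limb, by the trapezoid rule along the
#' time-parameterized path. Zero iff coupling is linear and lossless.
#'
#' @param path a coupling path from \code{\link{couplingPath}}.
#' @return numeric, percent-squared area.
#' @export
systolicDampening <- function(path) {
  p <- path[path$limb == "contraction", ]
  if (nrow(p) < 3) stop("insufficient data: contraction limb shorter than ",
                        "3 samples")
  abs(.pathIntegral(p$eps_s, p$eps_n - p$eps_s))
}

#' Diastolic strain dampening
#'
#' Area between the relaxation limb of the coupling path and a linear
#' reference. The default reference is the unit-slope line through the
#' end-systolic point \eqn{(\epsilon_s^*, \epsilon_{nL}^*)};
#' \code{reference = "chord"} uses the chord from the end-systolic point to
#' the origin instead.
#'
#' @param path a coupling path from \code{\link{couplingPath}}.
#' @param reference "shifted" (unit slope through end systole) or "chord".
#' @return numeric, percent-squared area.
#' @export
diastolicDampening <- function(path, reference = c("shifted", "chord")) {
  reference <- match.arg(reference)
  p <- path[path$limb == "relaxation", ]
  con <- path[path$limb == "contraction", ]
  if (nrow(p) < 3) stop("insufficient data: relaxation limb shorter than ",
                        "3 samples")
  sStar <- con$eps_s[nrow(con)]
  nStar <- con$eps_n[nrow(con)]
  ref <- if (reference == "shifted") p$eps_s + (nStar - sStar) else
    (nStar / sStar) * p$eps_s
  abs(.pathIntegral(p$eps_s, p$eps_n - ref))
}

#' Integrated nuclear strain over the contractile cycle
#'
#' \eqn{\int |\epsilon_{nL}(t)|\, dt} over one pacing period (trapezoid
#' rule); with several full cycles the per-cycle average is returned.
#'
#' @param strain a \linkS4class{StrainTrace}.
#' @param phases a \linkS4class{CyclePhases} (used for the cycle count).
#' @return numeric, percent-seconds.
#' @export
integratedNuclearStrain <- function(strain, phases) {
  stopifnot(is(strain, "StrainTrace"))
  dt <- strain@time[2] - strain@time[1]
  nPer <- round(1 / strain@pacingFrequency / dt)
  nCyc <- length(phases@onset)
  idx <- seq_len(nPer * nCyc)
  .trapz(strain@time[idx], abs(strain@nuclearLengthStrain[idx])) / nCyc
}

#' Full per-cell coupling analysis
#'
#' Runs strain computation, cycle segmentation, path construction and all
#' coupling metrics for one trace.
#'
#' @param trace a \linkS4class{ContractionTrace}.
#' @param baselineRule,onsetThreshold see \code{\link{computeStrain}} and
#'   \code{\link{segmentCycles}}.
#' @param diastolicReference see \code{\link{diastolicDampening}}.
#' @return A \linkS4class{CouplingResult}.
#' @examples
#' tr <- generateTraces(genotypePreset("WT_rat", noiseSD = 0))[[1]]
#' analyzeCoupling(tr)
#' @export
analyzeCoupling <- function(trace, baselineRule = "pre_onset_mean",
                            onsetThreshold = 0.5,
                            diastolicReference = "shifted") {
  strain <- computeStrain(trace, baselineRule, onsetThreshold)
  phases <- segmentCycles(strain, onsetThreshold)
  path <- couplingPath(strain, phases)
  new("CouplingResult",
      peakSarcomereCompression = abs(min(strain@sarcomereStrain)),
      peakNuclearCompression = abs(min(strain@nuclearLengthStrain)),
      peakWidthExpansion = max(strain@nuclearWidthStrain),
      systolicDampening = systolicDampening(path),
      diastolicDampening = diastolicDampening(path, diastolicReference),
      integratedNuclearStrain = integratedNuclearStrain(strain, phases),
      couplingPath = path, cellId = trace@cellId, genotype = trace@genotype)
}

#' Per-cell coupling metrics as a table
#'
#' @param results list of \linkS4class{CouplingResult}.
#' @return data.frame with columns \code{cell_id, genotype, peak_ss,
#'   peak_ns, peak_nw, d_sys, d_dia, int_ns}.
#' @export
couplingTable <- function(results) {
  if (is(results, "CouplingResult")) results <- list(results)
  do.call(rbind, lapply(results, function(r)
    data.frame(cell_id = r@cellId, genotype = r@genotype,
               peak_ss = r@peakSarcomereCompression,
               peak_ns = r@peakNuclearCompression,
               peak_nw = r@peakWidthExpansion,
               d_sys = r@systolicDampening, d_dia = r@diastolicDampening,
               int_ns = r@integratedNuclearStrain)))
}

#' Group summaries (mean, standard error, n) of coupling metrics
#'
#' @param results list of \linkS4class{CouplingResult}.
#' @param grouping optional character vector of group labels (defaults to
#'   each cell's genotype).
#' @return data.frame with one row per group and metric.
#' @export
summarizeGroup <- function(results, grouping = NULL) {
  tab <- couplingTable(results)
  if (is.null(grouping)) grouping <- tab$genotype
  if (length(grouping) != nrow(tab))
    stop("grouping must have one label per result")
  if (any(!nzchar(grouping)) || anyNA(grouping))
    stop("empty group label")
  metrics <- c("peak_ss", "peak_ns", "peak_nw", "d_sys", "d_dia", "int_ns")
  out <- do.call(rbind, lapply(split(tab, grouping), function(d) {
    data.frame(group = d$genotype[1], metric = metrics,
               mean = vapply(metrics, function(m) mean(d[[m]]), 0),
               se = vapply(metrics, function(m)
                 stats::sd(d[[m]]) / sqrt(nrow(d)), 0),
               n = nrow(d), row.names = NULL)
  }))
  out$group <- rep(names(split(tab, grouping)),
                   each = length(metrics))
  rownames(out) <- NULL
  out
}
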