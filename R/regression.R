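#' Loess smoothing with a pointwise error band
#'
#' Locally weighted linear regression (tricube weights, degree 1) evaluated
#' on a uniform grid, with a band of plus or minus one standard error from
#' the local fit variance.
#'
#' @param points data.frame with numeric columns x and y (the first two
#'   columns are used; cohort tables with \code{enrichment} and
#'   \code{aspect_ratio} work directly).
#' @param span loess span in (0, 1].
#' @param nGrid evaluation grid size.
#' @return data.frame with columns \code{x}, \code{fitted}, \code{se}.
#' @export
loessFit <- function(points, span = 0.75, nGrid = 100) {
  x <- points[[1]]; y <- points[[2]]
  if (length(x) < 10) stop("need at least 10 points")
  if (span <= 0 || span > 1) stop("span must be in (0, 1]")
  if (span * length(x) < 4)
    stop("span too small: local neighbourhoods below 4 points")
  fit <- stats::loess(y ~ x, data = data.frame(x = x, y = y), span = span,
                      degree = 1, family = "gaussian",
                      control = stats::loess.control(surface = "direct"))
  grid <- seq(min(x), max(x), length.out = nGrid)
  pr <- stats::predict(fit, newdata = data.frame(x = grid), se = TRUE)
  data.frame(x = grid, fitted = pr$fit, se = pr$se.fit)
}

## continuous two-segment least squares at a fixed breakpoint c:
## y = a + b1 x + b2 (x - c)+
.segRSS <- function(x, y, cp) {
  X <- cbind(1, x, pmax(x - cp, 0))
  f <- stats::lm.fit(X, y)
  list(coef = f$coefficients, rss = sum(f$residuals^2),
       residuals = f$residuals)
}

#' Continuous two-segment (breakpoint) regression
#'
#' Fits \eqn{y = a + b_1 x + b_2 (x - c)_+} with the breakpoint \eqn{c}
#' chosen by grid search over interior quantiles of x, minimizing the
#' residual sum of squares of the continuous two-segment least-squares fit.
#' Per-segment slopes are tested against zero with t statistics using
#' segment-local residual variance; the upper segment is flagged flat when
#' its p-value exceeds 0.05. An optional free-intercept (discontinuous)
#' variant drops the continuity constraint.
#'
#' @param points data.frame; first two columns are x and y.
#' @param continuity logical; FALSE fits the two segments independently at
#'   the selected breakpoint.
#' @param nCandidates breakpoint grid size across the 5th-95th percentile
#'   range of x (ties broken toward the smaller breakpoint).
#' @param minSegment minimum points per segment at the optimum; below this a
#'   warning is issued and the grid is widened to guarantee the minimum.
#' @param refine logical; polish the grid optimum by continuous
#'   minimization of the residual sum of squares between the neighbouring
#'   grid candidates (exact recovery on noiseless data).
#' @param span loess span for the overlaid smooth (NA skips it).
#' @return A \linkS4class{BiphasicFit}.
#' @examples
#' fit <- piecewiseLinearFit(generateCohort(cohortSpec(seed = 1)))
#' fit
#' @export
piecewiseLinearFit <- function(points, continuity = TRUE,
                               nCandidates = 200, minSegment = 4,
                               refine = TRUE, span = 0.75) {
  x <- points[[1]]; y <- points[[2]]
  n <- length(x)
  if (n < 10) stop("need at least 10 points")
  if (diff(range(x)) <= .Machine$double.eps)
    stop("all x values identical")
  grid <- seq(stats::quantile(x, 0.05), stats::quantile(x, 0.95),
              length.out = nCandidates)
  rss <- vapply(grid, function(cp) .segRSS(x, y, cp)$rss, 0)
  cp <- grid[which.min(rss)]   # which.min takes the first (smaller) tie
  if (min(sum(x < cp), sum(x >= cp)) < minSegment) {
    warning("fewer than ", minSegment, " points in a segment at the ",
            "optimal breakpoint; widening the search grid")
    xs <- sort(x)
    grid <- seq(xs[minSegment], xs[n - minSegment + 1],
                length.out = nCandidates)
    rss <- vapply(grid, function(cp) .segRSS(x, y, cp)$rss, 0)
    cp <- grid[which.min(rss)]
  }
  if (refine) {
    k <- which.min(abs(grid - cp))
    lo <- grid[max(k - 1, 1)]
    hi <- grid[min(k + 1, length(grid))]
    if (hi > lo)
      cp <- stats::optimize(function(c) .segRSS(x, y, c)$rss,
                            c(lo, hi), tol = 1e-9)$minimum
  }
  f <- .segRSS(x, y, cp)
  below <- x < cp
  if (continuity) {
    slopes <- c(below = unname(f$coef[2]),
                above = unname(f$coef[2] + f$coef[3]))
    intercept <- unname(f$coef[1])
    resid <- f$residuals
  } else {
    fb <- stats::lm(y[below] ~ x[below])
    fa <- stats::lm(y[!below] ~ x[!below])
    slopes <- c(below = unname(stats::coef(fb)[2]),
                above = unname(stats::coef(fa)[2]))
    intercept <- unname(stats::coef(fb)[1])
    resid <- numeric(n)
    resid[below] <- stats::residuals(fb)
    resid[!below] <- stats::residuals(fa)
  }
  segTest <- function(inSeg, slope) {
    xs <- x[inSeg]
    s2 <- sum(resid[inSeg]^2) / max(sum(inSeg) - 2, 1)
    se <- unname(sqrt(s2 / sum((xs - mean(xs))^2)))
    p <- unname(2 * stats::pt(-abs(slope / se), df = max(sum(inSeg) - 2, 1)))
    c(se = se, p = p)
  }
  tb <- segTest(below, slopes["below"])
  ta <- segTest(!below, slopes["above"])
  lo <- if (is.na(span)) data.frame(x = numeric(0), fitted = numeric(0),
                                    se = numeric(0)) else
    loessFit(data.frame(x = x, y = y), span = span)
  new("BiphasicFit", breakpoint = cp,
      slopeBelow = unname(slopes["below"]),
      slopeAbove = unname(slopes["above"]), intercept = intercept,
      slopeSE = c(below = unname(tb["se"]), above = unname(ta["se"])),
      slopePValues = c(below = unname(tb["p"]), above = unname(ta["p"])),
      residualSD = stats::sd(resid), nPoints = as.integer(n),
      flatAbove = unname(ta["p"]) > 0.05, loessCurve = lo)
}
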