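#' Evaluate stability against the lower limit
#'
#' Computes the mean regression line and its two-sided confidence band on
#' the natural-log scale — prediction +/- t(df) quantile times the
#' standard error of the predicted mean — then exponentiates back to the
#' original scale. Stability is satisfied ("pass") when the band's lower
#' bound stays at or above the lower limit over the whole evaluated
#' range; otherwise the earliest crossing time is located by bisection
#' (to 1e-6 grid units) on the continuous lower-bound function.
#'
#' For per-lot models (\code{reduced1}/\code{full}) the evaluation is the
#' conservative envelope across lots: the reported mean line and lower
#' bound are the pointwise worst (lowest) lot, the upper bound the
#' pointwise best. Each lot contributes to the envelope only over its own
#' observed time range — a lot assayed only to month 12 does not get its
#' line extrapolated to month 24, consistent with the no-extrapolation
#' rule applied to the overall grid.
#'
#' The band is for the mean response, the convention of shelf-life
#' evaluation; set \code{band = "prediction"} for a single-future-assay
#' prediction band instead.
#'
#' @param fit a \linkS4class{RegressionFit} on log content vs time.
#' @param grid evaluation times in the fit's time unit (months). Default:
#'   the observed timepoints plus a 101-point dense grid over the
#'   observed range.
#' @param lowerLimit the minimum acceptable potency, original scale.
#' @param level confidence level of the band.
#' @param band "confidence" (mean response, default) or "prediction".
#' @return a \linkS4class{StabilityEvaluation}.
#' @examples
#' f <- fitStability(simulateDataset(mockSimParams(seed = 5)), "RT")
#' evaluateStability(f, lowerLimit = 800)
#' @export
evaluateStability <- function(fit, grid = NULL, lowerLimit = 800,
                              level = 0.95,
                              band = c("confidence", "prediction")) {
  stopifnot(is(fit, "RegressionFit"))
  band <- match.arg(band)
  if (fit@dfResidual < 1L)
    stop("cannot form a confidence band with no residual degrees of freedom")
  stopifnot(level > 0, level < 1, lowerLimit > 0)
  rng <- range(fit@time)
  if (is.null(grid))
    grid <- sort(unique(c(fit@time, seq(rng[1], rng[2], length.out = 101))))
  if (min(grid) < rng[1] - 1e-9 || max(grid) > rng[2] + 0.25 * diff(rng))
    stop("grid extends well beyond the observed time range; ",
         "no silent extrapolation")
  tq <- stats::qt(1 - (1 - level) / 2, fit@dfResidual)
  s2 <- if (band == "prediction") fit@residualSD^2 else 0

  lots <- unique(fit@lot)
  predLot <- function(tt, lt) {
    nd <- data.frame(.time = tt, .lot = factor(lt, levels = lots))
    pr <- stats::predict(fit@model, newdata = nd, se.fit = TRUE)
    se <- sqrt(pr$se.fit^2 + s2)
    cbind(fit = pr$fit, lo = pr$fit - tq * se, hi = pr$fit + tq * se)
  }
  lotRange <- lapply(lots, function(lt) range(fit@time[fit@lot == lt]))
  names(lotRange) <- lots
  bandAt <- function(tt) {
    if (fit@modelType == "reduced2") return(predLot(tt, lots[1]))
    per <- lapply(lots, function(lt) {
      m <- predLot(tt, lt)
      r <- lotRange[[lt]]
      outside <- tt < r[1] - 1e-9 | tt > r[2] + 1e-9
      m[outside, ] <- NA_real_
      m
    })
    agg <- function(col, f) apply(
      do.call(cbind, lapply(per, function(m) m[, col])), 1,
      function(v) f(v, na.rm = TRUE))
    cbind(fit = agg("fit", min), lo = agg("lo", min), hi = agg("hi", max))
  }

  bb <- bandAt(grid)
  lower <- exp(bb[, "lo"])
  pass <- all(lower >= lowerLimit)
  first_fail <- NA_real_
  if (!pass) {
    lowAt <- function(tt) exp(bandAt(tt)[, "lo"]) - lowerLimit
    i <- which(lower < lowerLimit)[1]
    if (i == 1L) {
      first_fail <- grid[1]
    } else {
      lo_t <- grid[i - 1L]; hi_t <- grid[i]
      while (hi_t - lo_t > 1e-6) {
        mid <- (lo_t + hi_t) / 2
        if (lowAt(mid) < 0) hi_t <- mid else lo_t <- mid
      }
      first_fail <- hi_t
    }
  }
  new("StabilityEvaluation", grid = as.numeric(grid),
      meanLine = unname(exp(bb[, "fit"])), ciLower = unname(lower),
      ciUpper = unname(exp(bb[, "hi"])), lowerLimit = lowerLimit,
      level = level, pass = pass, firstFailureTime = first_fail)
}

#' Is a claimed storage duration supported?
#'
#' TRUE iff the evaluation passes (lower confidence bound at or above the
#' lower limit) at every evaluated time up to the claim. The claim must
#' lie within the evaluated grid: extrapolating a stability verdict
#' beyond the data is refused.
#'
#' @param evaluation a \linkS4class{StabilityEvaluation}.
#' @param claimTime claimed duration in the evaluation's time unit.
#' @return logical(1).
#' @export
shelfLifeSupported <- function(evaluation, claimTime) {
  stopifnot(is(evaluation, "StabilityEvaluation"))
  if (claimTime > max(evaluation@grid) + 1e-9 ||
      claimTime < min(evaluation@grid) - 1e-9)
    stop("claim ", claimTime, " lies outside the evaluated range [",
         min(evaluation@grid), ", ", max(evaluation@grid),
         "]; no silent extrapolation")
  if (evaluation@pass) return(TRUE)
  evaluation@firstFailureTime > claimTime
}

setMethod("show", "StabilityEvaluation", function(object) {
  cat(sprintf(
    "StabilityEvaluation over [%g, %g]: %s (LL = %g, %.0f%% band)\n",
    min(object@grid), max(object@grid),
    if (object@pass) "PASS" else
      sprintf("FAIL at t = %.4f", object@firstFailureTime),
    object@lowerLimit, 100 * object@level))
})
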