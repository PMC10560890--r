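#' Fit the three nested poolability models
#'
#' On the same observations, fits (1) the full model with per-lot slopes
#' and intercepts, (2) reduced model 1 with a common slope and per-lot
#' intercepts, and (3) reduced model 2, a single line. By construction
#' SSE(full) <= SSE(reduced1) <= SSE(reduced2).
#'
#' @inheritParams fitOLS
#' @return named list of \linkS4class{RegressionFit}s: \code{full},
#'   \code{reduced1}, \code{reduced2}.
#' @export
fitPoolModels <- function(time, logContent, lot) {
  if (length(unique(lot)) < 2L)
    stop("poolability needs at least 2 lots")
  list(full = fitOLS(time, logContent, lot, model = "full"),
       reduced1 = fitOLS(time, logContent, lot, model = "reduced1"),
       reduced2 = fitOLS(time, logContent, lot, model = "reduced2"))
}

#' Partial F-test of two nested OLS fits
#'
#' F = \[(SSE_r - SSE_f) / (df_r - df_f)\] / (SSE_f / df_f), with the
#' p-value from the F distribution on (df_r - df_f, df_f) degrees of
#' freedom. The models must be fitted on identical observations with the
#' reduced model nested in the full one.
#'
#' @param full,reduced \linkS4class{RegressionFit}s on the same data.
#' @return list with \code{statistic}, \code{p.value}, \code{df1},
#'   \code{df2}.
#' @export
partialFTest <- function(full, reduced) {
  stopifnot(is(full, "RegressionFit"), is(reduced, "RegressionFit"))
  if (full@n != reduced@n)
    stop("models were not fitted on the same observations")
  if (reduced@dfResidual <= full@dfResidual)
    stop("reduced model must have more residual degrees of freedom")
  if (reduced@sse < full@sse - 1e-8 * max(1, full@sse))
    stop("models are not nested: reduced SSE is below full SSE")
  df1 <- reduced@dfResidual - full@dfResidual
  df2 <- full@dfResidual
  ssdiff <- max(0, reduced@sse - full@sse)
  if (full@sse == 0) {
    # a saturated full model: any reduction in fit is infinitely
    # significant unless the reduced model is also exact
    f <- if (ssdiff == 0) 0 else Inf
  } else {
    f <- (ssdiff / df1) / (full@sse / df2)
  }
  list(statistic = f, p.value = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2)
}

#' The poolability decision rule at alpha = 0.25
#'
#' Sequential ICH Q1E-style criteria: if the slope-equality p-value is
#' <= alpha, lots keep separate slopes and intercepts ("not_parallel",
#' full model; the intercept test is not applicable). Otherwise a common
#' slope is imposed and the intercept-equality p-value decides between
#' separate intercepts ("parallel", reduced model 1, p <= alpha) and a
#' single line ("one_line", reduced model 2, p > alpha). A p-value of
#' exactly alpha is treated as significant (the pooled branch is not
#' taken).
#'
#' @param pSlope slope-equality p-value (full vs reduced1).
#' @param pIntercept intercept-equality p-value (reduced1 vs reduced2);
#'   required iff \code{pSlope > alpha}, ignored with a warning
#'   otherwise.
#' @param alpha significance level, default 0.25.
#' @return list with \code{decision} and \code{chosenModel}.
#' @examples
#' decidePoolability(0.20)               # not_parallel
#' decidePoolability(0.30, 0.20)         # parallel
#' decidePoolability(0.30, 0.30)         # one_line
#' @export
decidePoolability <- function(pSlope, pIntercept = NA_real_, alpha = 0.25) {
  stopifnot(pSlope >= 0, pSlope <= 1)
  if (pSlope <= alpha) {
    if (!is.na(pIntercept))
      warning("slope test is significant; the intercept test is not ",
              "applicable and pIntercept is ignored")
    return(list(decision = "not_parallel", chosenModel = "full"))
  }
  if (is.na(pIntercept))
    stop("pIntercept is required when pSlope > alpha")
  stopifnot(pIntercept >= 0, pIntercept <= 1)
  if (pIntercept <= alpha)
    list(decision = "parallel", chosenModel = "reduced1")
  else
    list(decision = "one_line", chosenModel = "reduced2")
}

#' Test batch poolability of a stability data slice
#'
#' Fits the three nested models, runs the sequential partial F-tests
#' (slope equality: full vs reduced1; intercept equality: reduced1 vs
#' reduced2) and applies [decidePoolability()].
#'
#' @param x a \linkS4class{StabilityDataset} or records data.frame.
#' @param condition "RT" or "ECTC".
#' @param conditioningMonths optional ECTC subset, see [fitStability()].
#' @param alpha poolability significance level.
#' @param monthDays days per month for ECTC time conversion.
#' @return a \linkS4class{PoolabilityResult}.
#' @examples
#' ds <- simulateDataset(mockSimParams(seed = 2))
#' testPoolability(ds, "RT")
#' @export
testPoolability <- function(x, condition = c("RT", "ECTC"),
                            conditioningMonths = NULL, alpha = 0.25,
                            monthDays = 30) {
  condition <- match.arg(condition)
  rec <- if (is(x, "StabilityDataset")) records(x) else as.data.frame(x)
  rec <- rec[rec$condition == condition, , drop = FALSE]
  if (condition == "ECTC" && !is.null(conditioningMonths))
    rec <- rec[rec$conditioning_months %in% conditioningMonths, ,
               drop = FALSE]
  if (!nrow(rec)) stop("no ", condition, " records to pool")
  tm <- if (condition == "RT") rec$time_value else rec$time_value / monthDays
  fits <- fitPoolModels(tm, log(rec$content), rec$lot_id)
  slope_test <- partialFTest(fits$full, fits$reduced1)
  p_slope <- slope_test$p.value
  p_int <- NA_real_
  if (p_slope > alpha)
    p_int <- partialFTest(fits$reduced1, fits$reduced2)$p.value
  dec <- decidePoolability(p_slope, p_int, alpha = alpha)
  new("PoolabilityResult", pSlope = p_slope, pIntercept = p_int,
      alpha = alpha, decision = dec$decision,
      chosenModel = dec$chosenModel, fits = fits)
}

setMethod("show", "PoolabilityResult", function(object) {
  cat(sprintf(
    "PoolabilityResult: p(slope) = %.4f, p(intercept) = %s -> %s (%s model)\n",
    object@pSlope,
    if (is.na(object@pIntercept)) "NA" else sprintf("%.4f", object@pIntercept),
    object@decision, object@chosenModel))
})
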