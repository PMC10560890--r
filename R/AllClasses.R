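#' @import methods
NULL

.CONDITIONS <- c("RT", "ECTC")
.TIME_UNITS <- c("month", "day")
.RECORD_COLUMNS <- c("lot_id", "condition", "conditioning_months",
                     "time_value", "time_unit", "replicate", "content")

#' StabilityDataset: a complete stability study
#'
#' Container for one stability study of a single stability-indicating
#' parameter (SIP), typically antigen content. Each row of \code{records}
#' is one assay result: a lot, a storage condition (\code{"RT"} for
#' real-time cold-chain storage at 2-8 degrees C, \code{"ECTC"} for
#' extended controlled temperature conditions at 40 degrees C), the months
#' of cold-chain conditioning before ECTC exposure started (0 for RT rows),
#' the time value in the condition's native unit (months for RT, days for
#' ECTC), a replicate index and the observed content on the original
#' (untransformed) assay scale.
#'
#' @slot records data.frame with columns \code{lot_id}, \code{condition},
#'   \code{conditioning_months}, \code{time_value}, \code{time_unit},
#'   \code{replicate}, \code{content}.
#' @slot sipName character(1), name of the stability-indicating parameter.
#' @slot unit character(1), assay unit of \code{content} (e.g. "LEU").
#' @slot lowerLimit numeric(1), the minimum acceptable potency (LL) on the
#'   original scale; must be positive.
#'
#' @seealso [readDataset()], [writeDataset()], [simulateDataset()]
#' @export
setClass("StabilityDataset",
  representation(records = "data.frame", sipName = "character",
                 unit = "character", lowerLimit = "numeric"),
  prototype(records = data.frame(), sipName = "antigen content",
            unit = "LEU", lowerLimit = 800))

.validRecords <- function(records) {
  missing <- setdiff(.RECORD_COLUMNS, names(records))
  if (length(missing))
    return(sprintf("records is missing column(s): %s",
                   paste(missing, collapse = ", ")))
  if (nrow(records) == 0L) return(TRUE)
  bad <- which(!records$condition %in% .CONDITIONS)
  if (length(bad))
    return(sprintf("unknown condition label %s in row %d",
                   dQuote(records$condition[bad[1]]), bad[1]))
  if (!is.numeric(records$content))
    return("content column must be numeric")
  bad <- which(!is.finite(records$content) | records$content <= 0)
  if (length(bad))
    return(sprintf("content must be positive and finite (row %d has %s)",
                   bad[1], format(records$content[bad[1]])))
  bad <- which(!is.finite(records$time_value) | records$time_value < 0)
  if (length(bad))
    return(sprintf("time_value must be non-negative (row %d)", bad[1]))
  bad <- which(records$conditioning_months < 0 |
               records$conditioning_months != floor(records$conditioning_months))
  if (length(bad))
    return(sprintf("conditioning_months must be a non-negative integer (row %d)",
                   bad[1]))
  bad <- which(records$replicate < 1 |
               records$replicate != floor(records$replicate))
  if (length(bad))
    return(sprintf("replicate must be a positive integer (row %d)", bad[1]))
  expected_unit <- ifelse(records$condition == "RT", "month", "day")
  bad <- which(records$time_unit != expected_unit)
  if (length(bad))
    return(sprintf(
      "row %d: condition %s requires time_unit %s, found %s",
      bad[1], records$condition[bad[1]], dQuote(expected_unit[bad[1]]),
      dQuote(records$time_unit[bad[1]])))
  TRUE
}

setValidity("StabilityDataset", function(object) {
  msgs <- character()
  v <- .validRecords(object@records)
  if (!isTRUE(v)) msgs <- c(msgs, v)
  if (length(object@lowerLimit) != 1L || !is.finite(object@lowerLimit) ||
      object@lowerLimit <= 0)
    msgs <- c(msgs, "lowerLimit must be a single positive number")
  if (length(msgs)) msgs else TRUE
})

#' DesignScheme: the sampling plan of a stability study
#'
#' Which (time, lot-count) cells are assayed under each condition.
#' RT cells are (month, number of lots); ECTC cells are
#' (conditioning month, day, number of lots). Each scheduled lot
#' contributes \code{replicatesPerSample} assay results per cell.
#'
#' @slot rtCells data.frame(month, n_lots), months strictly increasing.
#' @slot ectcCells data.frame(conditioning_month, day, n_lots), days
#'   strictly increasing within each conditioning month.
#' @slot replicatesPerSample integer(1) >= 1.
#'
#' @seealso [mockStudyDesign()]
#' @export
setClass("DesignScheme",
  representation(rtCells = "data.frame", ectcCells = "data.frame",
                 replicatesPerSample = "integer"),
  prototype(rtCells = data.frame(month = integer(), n_lots = integer()),
            ectcCells = data.frame(conditioning_month = integer(),
                                   day = integer(), n_lots = integer()),
            replicatesPerSample = 1L))

setValidity("DesignScheme", function(object) {
  msgs <- character()
  rt <- object@rtCells
  if (!all(c("month", "n_lots") %in% names(rt)))
    msgs <- c(msgs, "rtCells needs columns month, n_lots")
  else {
    if (any(rt$n_lots <= 0)) msgs <- c(msgs, "rtCells n_lots must be positive")
    if (is.unsorted(rt$month, strictly = TRUE))
      msgs <- c(msgs, "rtCells months must be strictly increasing")
  }
  ec <- object@ectcCells
  if (!all(c("conditioning_month", "day", "n_lots") %in% names(ec)))
    msgs <- c(msgs, "ectcCells needs columns conditioning_month, day, n_lots")
  else {
    if (any(ec$n_lots <= 0)) msgs <- c(msgs, "ectcCells n_lots must be positive")
    for (m in unique(ec$conditioning_month)) {
      d <- ec$day[ec$conditioning_month == m]
      if (is.unsorted(d, strictly = TRUE))
        msgs <- c(msgs, sprintf(
          "ectcCells days must be strictly increasing within conditioning month %s", m))
    }
  }
  if (object@replicatesPerSample < 1L)
    msgs <- c(msgs, "replicatesPerSample must be >= 1")
  if (length(msgs)) msgs else TRUE
})

#' SimulationParams: the generative model behind mock stability data
#'
#' Log-linear decay with lot-level release variability. For lot i with
#' random intercept a_i ~ N(0, lotInterceptSD^2):
#' \itemize{
#'   \item RT at month t: log content = logInterceptMean + a_i +
#'     rtSlope * t + eps, eps ~ N(0, rtResidualSD^2).
#'   \item ECTC for a lot conditioned m months, at day d: log content =
#'     logInterceptMean + a_i + rtSlope * m + ectcSlope * (d / monthDays)
#'     + eps, eps ~ N(0, ectcResidualSD^2).
#' }
#' Slopes are per month on the natural-log scale; the ECTC slope is
#' applied per day through \code{monthDays} (default 30 days/month).
#'
#' @slot logInterceptMean numeric(1), mean log release content.
#' @slot lotInterceptSD numeric(1) >= 0, SD of the lot random intercept.
#' @slot rtSlope numeric(1), decay slope at 2-8 degrees C (log units/month).
#' @slot ectcSlope numeric(1), decay slope at 40 degrees C (log units/month).
#' @slot rtResidualSD,ectcResidualSD numeric(1) >= 0, residual SDs.
#' @slot design DesignScheme.
#' @slot monthDays numeric(1) > 0, days per month for unit conversion.
#' @slot seed integer(1), RNG seed; identical seed gives identical data.
#'
#' @seealso [simParams()], [mockSimParams()], [simulateDataset()]
#' @export
setClass("SimulationParams",
  representation(logInterceptMean = "numeric", lotInterceptSD = "numeric",
                 rtSlope = "numeric", ectcSlope = "numeric",
                 rtResidualSD = "numeric", ectcResidualSD = "numeric",
                 design = "DesignScheme", monthDays = "numeric",
                 seed = "integer"))

setValidity("SimulationParams", function(object) {
  msgs <- character()
  if (object@lotInterceptSD < 0) msgs <- c(msgs, "lotInterceptSD must be >= 0")
  if (object@rtResidualSD < 0) msgs <- c(msgs, "rtResidualSD must be >= 0")
  if (object@ectcResidualSD < 0) msgs <- c(msgs, "ectcResidualSD must be >= 0")
  if (object@monthDays <= 0) msgs <- c(msgs, "monthDays must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' RegressionFit: one OLS fit on log-transformed content
#'
#' Summarises an ordinary least-squares fit of log content on time (in
#' months), optionally with per-lot intercepts and slopes. Slope and SE
#' are reported for the common time term when one exists
#' (\code{modelType} \code{"reduced2"} or \code{"reduced1"}); for the full
#' per-lot-slopes model the common-slope slots hold the reference lot's
#' time coefficient.
#'
#' @slot slope,slopeSE numeric(1), time coefficient (per month, log scale).
#' @slot intercept,interceptSE numeric(1), intercept (log scale).
#' @slot residualSD numeric(1), sqrt(SSE / df).
#' @slot sse numeric(1), residual sum of squares.
#' @slot dfResidual,n integer(1).
#' @slot residuals,fitted numeric, per observation, in input order.
#' @slot time numeric, per-observation time in months.
#' @slot lot character, per-observation lot label.
#' @slot modelType character(1): "reduced2" (single line), "reduced1"
#'   (common slope, per-lot intercepts) or "full" (per-lot lines).
#' @slot model the underlying \code{\link[stats]{lm}} object.
#' @export
setClass("RegressionFit",
  representation(slope = "numeric", slopeSE = "numeric",
                 intercept = "numeric", interceptSE = "numeric",
                 residualSD = "numeric", sse = "numeric",
                 dfResidual = "integer", n = "integer",
                 residuals = "numeric", fitted = "numeric",
                 time = "numeric", lot = "character",
                 modelType = "character", model = "ANY"))

setValidity("RegressionFit", function(object) {
  msgs <- character()
  if (object@n != length(object@residuals) ||
      object@n != length(object@fitted))
    msgs <- c(msgs, "n must equal length(residuals) and length(fitted)")
  if (abs(object@sse - sum(object@residuals^2)) >
      1e-8 * max(1, object@sse))
    msgs <- c(msgs, "sse inconsistent with residuals")
  if (!object@modelType %in% c("reduced2", "reduced1", "full"))
    msgs <- c(msgs, "modelType must be reduced2, reduced1 or full")
  if (length(msgs)) msgs else TRUE
})

#' DiagnosticsReport: the regression-assumption check battery
#'
#' Results of the five assumption checks run on a log-scale stability
#' fit: Shapiro-Wilk normality of residuals, Breusch-Pagan and White
#' heteroscedasticity tests, the Durbin-Watson autocorrelation statistic
#' with the 1.5 < d < 2.5 rule-of-thumb verdict, per-observation
#' influence measures, and the maximum deviation of a loess smooth from
#' the least-squares line through the partial residuals.
#'
#' @slot shapiroStat,shapiroP numeric(1).
#' @slot bpStat,bpP numeric(1), studentized (Koenker) Breusch-Pagan.
#' @slot whiteStat,whiteP numeric(1).
#' @slot dwStat numeric(1) in \[0, 4\].
#' @slot dwVerdict character(1), "ok" or "suspect".
#' @slot influence data.frame, see [influenceDiagnostics()].
#' @slot linearityMaxDev numeric(1) >= 0.
#' @export
setClass("DiagnosticsReport",
  representation(shapiroStat = "numeric", shapiroP = "numeric",
                 bpStat = "numeric", bpP = "numeric",
                 whiteStat = "numeric", whiteP = "numeric",
                 dwStat = "numeric", dwVerdict = "character",
                 influence = "data.frame", linearityMaxDev = "numeric"))

setValidity("DiagnosticsReport", function(object) {
  msgs <- character()
  ps <- c(object@shapiroP, object@bpP, object@whiteP)
  if (any(is.finite(ps) & (ps < 0 | ps > 1)))
    msgs <- c(msgs, "p-values must lie in [0, 1]")
  if (is.finite(object@dwStat) &&
      (object@dwStat < 0 || object@dwStat > 4))
    msgs <- c(msgs, "dwStat must lie in [0, 4]")
  if (!object@dwVerdict %in% c("ok", "suspect"))
    msgs <- c(msgs, "dwVerdict must be ok or suspect")
  if (length(msgs)) msgs else TRUE
})

#' PoolabilityResult: the ICH Q1E batch-poolability decision
#'
#' Holds the two sequential partial-F p-values (slope equality tested by
#' full vs reduced1; intercept equality by reduced1 vs reduced2 after
#' imposing a common slope) and the resulting decision at alpha = 0.25:
#' \code{"not_parallel"} (separate slopes and intercepts),
#' \code{"parallel"} (common slope, separate intercepts) or
#' \code{"one_line"} (common slope and intercept).
#'
#' @slot pSlope numeric(1) in \[0,1\].
#' @slot pIntercept numeric(1); NA when the slope test already failed
#'   (the intercept test is then not defined).
#' @slot alpha numeric(1), the poolability significance level.
#' @slot decision character(1).
#' @slot chosenModel character(1): "full", "reduced1" or "reduced2".
#' @slot fits named list of the three \linkS4class{RegressionFit}s.
#' @export
setClass("PoolabilityResult",
  representation(pSlope = "numeric", pIntercept = "numeric",
                 alpha = "numeric", decision = "character",
                 chosenModel = "character", fits = "list"))

setValidity("PoolabilityResult", function(object) {
  msgs <- character()
  if (object@pSlope < 0 || object@pSlope > 1)
    msgs <- c(msgs, "pSlope must lie in [0, 1]")
  if (!is.na(object@pIntercept) &&
      (object@pIntercept < 0 || object@pIntercept > 1))
    msgs <- c(msgs, "pIntercept must lie in [0, 1]")
  if (!object@decision %in% c("not_parallel", "parallel", "one_line"))
    msgs <- c(msgs, "unknown decision")
  ok <- switch(object@decision,
    not_parallel = object@pSlope <= object@alpha,
    parallel = object@pSlope > object@alpha &&
      !is.na(object@pIntercept) && object@pIntercept <= object@alpha,
    one_line = object@pSlope > object@alpha &&
      !is.na(object@pIntercept) && object@pIntercept > object@alpha)
  if (!isTRUE(ok))
    msgs <- c(msgs, "decision inconsistent with p-values at alpha")
  if (length(msgs)) msgs else TRUE
})

#' StabilityEvaluation: mean regression line, confidence band and verdict
#'
#' Predicted mean content with its two-sided confidence band, evaluated
#' on a time grid and compared against the lower limit. Stability is
#' satisfied when the band's lower bound (and hence the mean line) stays
#' at or above the lower limit over the whole evaluated range.
#'
#' @slot grid numeric, evaluation times (months for RT, days for ECTC).
#' @slot meanLine,ciLower,ciUpper numeric, original-scale predictions.
#' @slot lowerLimit numeric(1).
#' @slot level numeric(1), band confidence level.
#' @slot pass logical(1).
#' @slot firstFailureTime numeric(1), earliest grid-scale time at which
#'   the lower bound crosses below the limit; NA when pass.
#' @export
setClass("StabilityEvaluation",
  representation(grid = "numeric", meanLine = "numeric",
                 ciLower = "numeric", ciUpper = "numeric",
                 lowerLimit = "numeric", level = "numeric",
                 pass = "logical", firstFailureTime = "numeric"))

setValidity("StabilityEvaluation", function(object) {
  msgs <- character()
  if (length(object@grid) != length(object@meanLine) ||
      length(object@grid) != length(object@ciLower) ||
      length(object@grid) != length(object@ciUpper))
    msgs <- c(msgs, "grid, meanLine, ciLower, ciUpper lengths differ")
  if (any(object@ciLower > object@meanLine + 1e-12) ||
      any(object@meanLine > object@ciUpper + 1e-12))
    msgs <- c(msgs, "band must bracket the mean line pointwise")
  if (length(msgs)) msgs else TRUE
})

#' MRPScenario: one minimum-release-potency scenario
#'
#' A storage history: \code{t28} months in the cold chain followed by
#' \code{tEctcDays} days at 40 degrees C, evaluated against
#' \code{lowerLimit}. Days are converted to months with \code{monthDays}.
#'
#' @slot label character(1), e.g. "pooled" or "exposed_M12".
#' @slot t28 numeric(1) >= 0, months at 2-8 degrees C.
#' @slot tEctcDays numeric(1) >= 0, days at 40 degrees C.
#' @slot lowerLimit numeric(1) > 0.
#' @slot monthDays numeric(1) > 0.
#' @export
setClass("MRPScenario",
  representation(label = "character", t28 = "numeric",
                 tEctcDays = "numeric", lowerLimit = "numeric",
                 monthDays = "numeric"),
  prototype(label = "scenario", t28 = 24, tEctcDays = 14,
            lowerLimit = 800, monthDays = 30))

setValidity("MRPScenario", function(object) {
  msgs <- character()
  if (object@t28 < 0) msgs <- c(msgs, "t28 must be >= 0")
  if (object@tEctcDays < 0) msgs <- c(msgs, "tEctcDays must be >= 0")
  if (object@lowerLimit <= 0) msgs <- c(msgs, "lowerLimit must be > 0")
  if (object@monthDays <= 0) msgs <- c(msgs, "monthDays must be > 0")
  if (length(msgs)) msgs else TRUE
})

#' MRPResult: a minimum release potency with its inputs
#'
#' @slot scenario \linkS4class{MRPScenario}.
#' @slot b28,se28,s28 numeric(1), RT slope, its SE and residual SD.
#' @slot bEctc,seEctc,sEctc numeric(1), ECTC slope (per month), SE,
#'   residual SD; all zero/NA-free for RT-only scenarios.
#' @slot U numeric(1) >= 0, combined uncertainty (log scale).
#' @slot mrp numeric(1), the minimum release potency (original scale).
#' @slot slopesClamped logical(1), whether the clamp policy changed a slope.
#' @export
setClass("MRPResult",
  representation(scenario = "MRPScenario", b28 = "numeric",
                 se28 = "numeric", s28 = "numeric", bEctc = "numeric",
                 seEctc = "numeric", sEctc = "numeric", U = "numeric",
                 mrp = "numeric", slopesClamped = "logical"))

setValidity("MRPResult", function(object) {
  if (object@U < 0) "U must be >= 0" else TRUE
})

#' AnalysisConfig: tuning knobs of the full analysis pipeline
#'
#' @slot lowerLimit numeric(1) > 0, release lower limit (original scale).
#' @slot poolAlpha numeric(1) in (0,1), poolability significance level.
#' @slot ciLevel numeric(1) in (0,1), confidence level for stability bands.
#' @slot coverageK numeric(1) > 0, coverage factor of the combined
#'   uncertainty (1.645 = one-sided 95 percent normal).
#' @slot monthDays numeric(1) > 0, days per month.
#' @slot shelfLifeMonths numeric(1), labelled RT storage duration.
#' @slot ectcDays numeric, ECTC excursion durations to evaluate (days).
#' @slot clampPositiveSlopes logical(1), clamp improving slopes to zero.
#' @slot residualPolicy character(1): "pooled", "average", "rt" or "ectc".
#' @slot dwOrdering character(1), Durbin-Watson observation ordering.
#' @export
setClass("AnalysisConfig",
  representation(lowerLimit = "numeric", poolAlpha = "numeric",
                 ciLevel = "numeric", coverageK = "numeric",
                 monthDays = "numeric", shelfLifeMonths = "numeric",
                 ectcDays = "numeric", clampPositiveSlopes = "logical",
                 residualPolicy = "character", dwOrdering = "character"),
  prototype(lowerLimit = 800, poolAlpha = 0.25, ciLevel = 0.95,
            coverageK = 1.645, monthDays = 30, shelfLifeMonths = 24,
            ectcDays = c(3, 14), clampPositiveSlopes = TRUE,
            residualPolicy = "pooled", dwOrdering = "lot_time"))

setValidity("AnalysisConfig", function(object) {
  msgs <- character()
  if (object@poolAlpha <= 0 || object@poolAlpha >= 1)
    msgs <- c(msgs, "poolAlpha must lie in (0, 1)")
  if (object@ciLevel <= 0 || object@ciLevel >= 1)
    msgs <- c(msgs, "ciLevel must lie in (0, 1)")
  if (object@lowerLimit <= 0) msgs <- c(msgs, "lowerLimit must be > 0")
  if (object@coverageK <= 0) msgs <- c(msgs, "coverageK must be > 0")
  if (!object@residualPolicy %in% c("pooled", "average", "rt", "ectc"))
    msgs <- c(msgs, "residualPolicy must be pooled, average, rt or ectc")
  if (length(msgs)) msgs else TRUE
})
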