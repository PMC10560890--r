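#' Ordinary least squares on log content versus time
#'
#' The workhorse fit behind every analysis stage: OLS of natural-log
#' content on time in months, optionally with per-lot terms. Model types
#' follow the batch-poolability scheme:
#' \describe{
#'   \item{reduced2}{\code{log(content) ~ time} — one line.}
#'   \item{reduced1}{\code{log(content) ~ time + lot} — common slope,
#'     per-lot intercepts.}
#'   \item{full}{\code{log(content) ~ time * lot} — per-lot lines.}
#' }
#'
#' @param time numeric, time in months.
#' @param logContent numeric, natural-log content, same length.
#' @param lot character/factor lot labels; required for
#'   \code{"reduced1"}/\code{"full"}.
#' @param model one of \code{"reduced2"}, \code{"reduced1"}, \code{"full"}.
#' @return a \linkS4class{RegressionFit}. \code{residualSD} is
#'   \code{sqrt(sse / dfResidual)}; coefficient SEs come from the unscaled
#'   covariance matrix times the residual variance.
#' @examples
#' f <- fitOLS(c(0, 1, 2), c(0, 1, 2))
#' slopeOf(f)  # exactly 1
#' @export
fitOLS <- function(time, logContent, lot = NULL,
                   model = c("reduced2", "reduced1", "full")) {
  model <- match.arg(model)
  n <- length(time)
  if (length(logContent) != n)
    stop("time and logContent lengths differ")
  if (n < 3L) stop("need at least 3 observations, got ", n)
  if (length(unique(time)) < 2L)
    stop("need at least 2 distinct time values")
  if (is.null(lot)) lot <- rep("all", n)
  lot <- as.character(lot)
  if (model != "reduced2") {
    if (length(unique(lot)) < 2L)
      stop("model ", dQuote(model), " needs at least 2 lots")
    one_tp <- vapply(split(time, lot),
                     function(tt) length(unique(tt)) < 2L, logical(1))
    if (model == "full" && any(one_tp))
      stop("singular fit: lot ", dQuote(names(one_tp)[one_tp][1]),
           " has a single timepoint; its slope is not estimable")
  }
  dat <- data.frame(.time = time, .y = logContent, .lot = factor(lot))
  fm <- switch(model,
    reduced2 = .y ~ .time,
    reduced1 = .y ~ .time + .lot,
    full = .y ~ .time * .lot)
  obj <- stats::lm(fm, data = dat)
  cf <- stats::coef(obj)
  if (anyNA(cf))
    stop("singular fit: collinear term(s) ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(obj)
  se <- sm$coefficients[, "Std. Error"]
  res <- stats::residuals(obj)
  sse <- sum(res^2)
  dfres <- obj$df.residual
  new("RegressionFit",
      slope = unname(cf[".time"]), slopeSE = unname(se[".time"]),
      intercept = unname(cf["(Intercept)"]),
      interceptSE = unname(se["(Intercept)"]),
      residualSD = if (dfres > 0) sqrt(sse / dfres) else NA_real_,
      sse = sse, dfResidual = as.integer(dfres), n = as.integer(n),
      residuals = unname(res), fitted = unname(stats::fitted(obj)),
      time = as.numeric(time), lot = lot, modelType = model, model = obj)
}

#' Fit a stability regression on one condition of a dataset
#'
#' Slices a \linkS4class{StabilityDataset} down to one storage condition
#' (and, for ECTC, optionally a set of conditioning months), converts
#' time to months (ECTC days are divided by \code{monthDays}) and fits
#' [fitOLS()] on the natural-log contents, so slopes are always per
#' month on the log scale as in the MRP formula.
#'
#' @param x a \linkS4class{StabilityDataset} or a records data.frame.
#' @param condition "RT" or "ECTC".
#' @param conditioningMonths optional integer vector; keep only ECTC
#'   records whose conditioning month is in this set.
#' @param model passed to [fitOLS()].
#' @param monthDays days per month for the ECTC day-to-month conversion.
#' @return a \linkS4class{RegressionFit}.
#' @examples
#' ds <- simulateDataset(mockSimParams(seed = 1))
#' fitStability(ds, "RT")
#' @export
fitStability <- function(x, condition = c("RT", "ECTC"),
                         conditioningMonths = NULL,
                         model = "reduced2", monthDays = 30) {
  condition <- match.arg(condition)
  rec <- if (is(x, "StabilityDataset")) records(x) else as.data.frame(x)
  rec <- rec[rec$condition == condition, , drop = FALSE]
  if (condition == "ECTC" && !is.null(conditioningMonths))
    rec <- rec[rec$conditioning_months %in% conditioningMonths, ,
               drop = FALSE]
  if (!nrow(rec))
    stop("no ", condition, " records",
         if (!is.null(conditioningMonths))
           paste0(" at conditioning month(s) ",
                  paste(conditioningMonths, collapse = ", ")) else "")
  tm <- if (condition == "RT") rec$time_value else rec$time_value / monthDays
  fitOLS(tm, log(rec$content), lot = rec$lot_id, model = model)
}

#' @describeIn fitOLS Slope of the common time term (log units/month).
#' @param fit a \linkS4class{RegressionFit}.
#' @export
slopeOf <- function(fit) fit@slope

#' @describeIn fitOLS Standard error of the slope.
#' @export
slopeSE <- function(fit) fit@slopeSE

#' @describeIn fitOLS Residual standard deviation, sqrt(SSE/df).
#' @export
residualSD <- function(fit) fit@residualSD

setMethod("show", "RegressionFit", function(object) {
  cat(sprintf(
    "RegressionFit (%s): slope %.6f (SE %.6f) per month, residual SD %.4f, n = %d, df = %d\n",
    object@modelType, object@slope, object@slopeSE, object@residualSD,
    object@n, object@dfResidual))
})
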