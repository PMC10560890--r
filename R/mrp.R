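#' Reference estimates of the built-in mock stability study
#'
#' The fitted pooled-model coefficients of the package's reference mock
#' study: the RT row (24 lots, 0-24 months) and the ECTC rows (pooled
#' D0-D14 set and the subsets exposed after 0, 6, 12 and 24 months of
#' conditioning, each at 3 and 14 days of excursion). Slopes are per
#' month on the natural-log scale. The \code{U} and \code{mrp} columns
#' are the study's reported combined uncertainties and minimum release
#' potencies for a 24-month shelf-life followed by the given excursion;
#' they serve as regression references for [combinedUncertainty()] and
#' [computeMRP()].
#'
#' @return list with \code{rt} (1-row data.frame: slope, slopeSE,
#'   residualSD, U) and \code{ectc} (10-row data.frame: subset, days,
#'   slope, slopeSE, residualSD, U, mrp).
#' @examples
#' mockEstimates()$rt
#' @export
mockEstimates <- function() {
  rt <- data.frame(slope = -0.003723, slopeSE = 0.000377,
                   residualSD = 0.0271, U = 0.0469)
  sub <- data.frame(
    subset = c("pooled", "exposed_M0", "exposed_M6", "exposed_M12",
               "exposed_M24"),
    slope = c(-0.117480, -0.118629, -0.126544, -0.102528, -0.136440),
    slopeSE = c(0.009942, 0.018841, 0.018649, 0.017323, 0.034428),
    residualSD = c(0.0250, 0.0263, 0.0260, 0.0242, 0.0240))
  ec <- merge(sub, data.frame(days = c(3, 14)), by = NULL)
  ec <- ec[order(match(ec$subset, sub$subset), ec$days), ]
  ec$U <- c(0.0456, 0.0462, 0.0457, 0.0479, 0.0457, 0.0478,
            0.0470, 0.0488, 0.0460, 0.0527)
  ec$mrp <- c(924, 966, 925, 968, 925, 971, 923, 960, 926, 981)
  rownames(ec) <- NULL
  list(rt = rt, ectc = ec)
}

#' Combined uncertainty of the two-phase decay estimate
#'
#' The statistical allowance, on the natural-log scale, added to the
#' decay terms of the MRP formula. It is a coverage factor k times the
#' root sum of squares of the slope-estimation terms (duration times
#' slope SE, per storage phase) and one residual-variability term:
#'
#' \deqn{U = k \sqrt{(t_{2-8} \cdot se_{2-8})^2 +
#'   (t_{ECTC} \cdot se_{ECTC})^2 + s^2}}
#'
#' The residual term \eqn{s^2} follows \code{residualPolicy}:
#' \describe{
#'   \item{pooled (default)}{mean of the RT residual variance and a
#'     reference ECTC residual variance (\code{sEctcRef}, normally the
#'     pooled D0-D14 fit's residual SD). Residual scatter is assay-level
#'     noise, so the full ECTC set estimates it best even when the slope
#'     comes from a conditioning-month subset.}
#'   \item{average}{mean of the RT and the scenario's own ECTC residual
#'     variances.}
#'   \item{rt / ectc}{that single phase's residual variance.}
#' }
#' RT-only scenarios (\code{tEctcMonths = 0}) always use the RT residual
#' variance. \code{k = 1.645} is the one-sided 95 percent normal coverage
#' factor.
#'
#' @param t28 months at 2-8 degrees C.
#' @param se28 SE of the RT slope (per month, log scale).
#' @param s28 RT residual SD (log scale).
#' @param tEctcMonths months at 40 degrees C (days / monthDays).
#' @param seEctc SE of the ECTC slope (per month, log scale).
#' @param sEctc ECTC residual SD of the scenario's own fit.
#' @param k coverage factor.
#' @param residualPolicy see above.
#' @param sEctcRef reference ECTC residual SD for the "pooled" policy;
#'   defaults to \code{sEctc}.
#' @return U, a non-negative scalar on the log scale.
#' @examples
#' # RT-only, 24 months
#' combinedUncertainty(24, 0.000377, 0.0271)
#' @export
combinedUncertainty <- function(t28, se28, s28, tEctcMonths = 0,
                                seEctc = 0, sEctc = 0, k = 1.645,
                                residualPolicy = c("pooled", "average",
                                                   "rt", "ectc"),
                                sEctcRef = NULL) {
  residualPolicy <- match.arg(residualPolicy)
  vals <- c(t28 = t28, se28 = se28, s28 = s28, tEctcMonths = tEctcMonths,
            seEctc = seEctc, sEctc = sEctc, k = k)
  bad <- names(vals)[!is.finite(vals) | vals < 0]
  if (length(bad))
    stop("negative or non-finite input(s): ", paste(bad, collapse = ", "))
  if (k == 0) stop("coverage factor k must be > 0")
  if (is.null(sEctcRef)) sEctcRef <- sEctc
  s2 <- if (tEctcMonths == 0) s28^2 else switch(residualPolicy,
    pooled = (s28^2 + sEctcRef^2) / 2,
    average = (s28^2 + sEctc^2) / 2,
    rt = s28^2,
    ectc = sEctc^2)
  k * sqrt((t28 * se28)^2 + (tEctcMonths * seEctc)^2 + s2)
}

#' Construct an MRP scenario
#'
#' @param t28 months at 2-8 degrees C (normally the shelf-life).
#' @param tEctcDays days at 40 degrees C.
#' @param lowerLimit minimum acceptable potency, original scale.
#' @param label scenario name.
#' @param monthDays days per month.
#' @return an \linkS4class{MRPScenario}.
#' @export
mrpScenario <- function(t28 = 24, tEctcDays = 14, lowerLimit = 800,
                        label = "scenario", monthDays = 30) {
  new("MRPScenario", label = label, t28 = t28, tEctcDays = tEctcDays,
      lowerLimit = lowerLimit, monthDays = monthDays)
}

#' Minimum release potency
#'
#' The release-time potency required so that, after \code{t28} months in
#' the cold chain and \code{tEctcDays} days of excursion and allowing for
#' the combined uncertainty U, the content stays above the lower limit:
#'
#' \deqn{MRP = \exp[\log(LL) - (t_{2-8} b_{2-8} +
#'   t_{ECTC} b_{ECTC} - U)]}
#'
#' with \eqn{t_{ECTC}} in months (days / monthDays). Slopes first pass
#' through the clamp policy: \code{"positive"} (default) sets improving
#' (positive) slopes to zero so an apparent potency gain can never push
#' the release requirement below LL; \code{"negative"} sets decaying
#' slopes to zero instead; \code{"none"} uses both as estimated.
#'
#' @param scenario an \linkS4class{MRPScenario}.
#' @param b28 RT decay slope (per month, log scale).
#' @param bEctc ECTC decay slope (per month, log scale).
#' @param U combined uncertainty, see [combinedUncertainty()].
#' @param clampPolicy "positive", "negative" or "none".
#' @param se28,s28,seEctc,sEctc optional inputs echoed into the result.
#' @return an \linkS4class{MRPResult}.
#' @examples
#' computeMRP(mrpScenario(24, 14, 800), b28 = -0.003723,
#'            bEctc = -0.117480, U = 0.0462)
#' @export
computeMRP <- function(scenario, b28, bEctc = 0, U = 0,
                       clampPolicy = c("positive", "negative", "none"),
                       se28 = NA_real_, s28 = NA_real_,
                       seEctc = NA_real_, sEctc = NA_real_) {
  stopifnot(is(scenario, "MRPScenario"))
  validObject(scenario)
  clampPolicy <- match.arg(clampPolicy)
  if (!is.finite(U) || U < 0) stop("U must be a non-negative number")
  clamp <- function(b) switch(clampPolicy,
    positive = min(b, 0), negative = max(b, 0), none = b)
  b28c <- clamp(b28); bEctcC <- clamp(bEctc)
  clamped <- !identical(b28c, b28) || !identical(bEctcC, bEctc)
  decay <- scenario@t28 * b28c +
    (scenario@tEctcDays / scenario@monthDays) * bEctcC
  mrp <- exp(log(scenario@lowerLimit) - (decay - U))
  new("MRPResult", scenario = scenario, b28 = b28c, se28 = se28,
      s28 = s28, bEctc = bEctcC, seEctc = seEctc, sEctc = sEctc,
      U = U, mrp = mrp, slopesClamped = clamped)
}

.coefOf <- function(x) {
  if (is(x, "RegressionFit"))
    return(list(slope = x@slope, se = x@slopeSE, s = x@residualSD))
  x <- as.list(x)
  list(slope = x$slope, se = x$slopeSE, s = x$residualSD)
}

#' MRP scenario grid over ECTC subsets and excursion durations
#'
#' One MRP per (ECTC subset, excursion duration) pair, each with its
#' combined uncertainty. The RT duration is fixed at the shelf-life for
#' every scenario (the release specification must cover a full shelf
#' life followed by the excursion); override \code{t28} for what-if
#' analyses such as a 12-months-then-excursion reading.
#'
#' @param rt the RT fit: a \linkS4class{RegressionFit} or a list/1-row
#'   data.frame with \code{slope}, \code{slopeSE}, \code{residualSD}.
#' @param ectc named list (one element per subset) of
#'   \linkS4class{RegressionFit}s or coefficient lists as above.
#' @param days numeric, ECTC durations in days.
#' @param lowerLimit minimum acceptable potency.
#' @param k coverage factor for [combinedUncertainty()].
#' @param t28 months at 2-8 degrees C (default: 24-month shelf-life).
#' @param monthDays days per month.
#' @param residualPolicy passed to [combinedUncertainty()]; under the
#'   default "pooled" policy the reference ECTC residual SD is taken from
#'   the element of \code{ectc} named \code{"pooled"} when present,
#'   otherwise from each subset's own fit.
#' @param clampPolicy passed to [computeMRP()].
#' @return list of \linkS4class{MRPResult}, one per (subset, day), in
#'   subset-major order; see [mrpTable()] for a tabular view.
#' @examples
#' est <- mockEstimates()
#' ec <- est$ectc[!duplicated(est$ectc$subset), ]
#' fits <- split(ec[, c("slope", "slopeSE", "residualSD")], ec$subset)
#' grid <- scenarioGrid(est$rt, fits[unique(ec$subset)])
#' mrpTable(grid)
#' @export
scenarioGrid <- function(rt, ectc, days = c(3, 14), lowerLimit = 800,
                         k = 1.645, t28 = 24, monthDays = 30,
                         residualPolicy = "pooled",
                         clampPolicy = "positive") {
  if (is.null(names(ectc)) || any(!nzchar(names(ectc))))
    stop("ectc must be a named list of subset fits")
  rtc <- .coefOf(rt)
  sRef <- if ("pooled" %in% names(ectc)) .coefOf(ectc$pooled)$s else NULL
  out <- list()
  for (nm in names(ectc)) {
    ec <- .coefOf(ectc[[nm]])
    if (is.null(ec$slope))
      stop("configuration error: subset ", dQuote(nm),
           " has no slope estimate")
    for (d in days) {
      U <- combinedUncertainty(
        t28 = t28, se28 = rtc$se, s28 = rtc$s,
        tEctcMonths = d / monthDays, seEctc = ec$se, sEctc = ec$s,
        k = k, residualPolicy = residualPolicy, sEctcRef = sRef)
      out[[sprintf("%s_%gd", nm, d)]] <- computeMRP(
        mrpScenario(t28 = t28, tEctcDays = d, lowerLimit = lowerLimit,
                    label = nm, monthDays = monthDays),
        b28 = rtc$slope, bEctc = ec$slope, U = U,
        clampPolicy = clampPolicy, se28 = rtc$se, s28 = rtc$s,
        seEctc = ec$se, sEctc = ec$s)
    }
  }
  out
}

#' Tabulate a list of MRP results
#'
#' @param results list of \linkS4class{MRPResult} (e.g. from
#'   [scenarioGrid()]).
#' @param digits round the \code{mrp} column to this many decimals in the
#'   extra \code{mrp_rounded} column (release specifications are quoted
#'   as integers).
#' @return data.frame with columns subset, days, slope, slopeSE,
#'   residualSD, U, mrp, mrp_rounded.
#' @export
mrpTable <- function(results, digits = 0) {
  stopifnot(length(results) > 0)
  do.call(rbind, lapply(results, function(r) data.frame(
    subset = r@scenario@label, days = r@scenario@tEctcDays,
    slope = r@bEctc, slopeSE = r@seEctc, residualSD = r@sEctc,
    U = r@U, mrp = r@mrp, mrp_rounded = round(r@mrp, digits),
    row.names = NULL)))
}

setMethod("show", "MRPResult", function(object) {
  cat(sprintf(
    "MRPResult [%s]: %g months RT + %g days ECTC, LL = %g -> MRP = %.1f (U = %.4f%s)\n",
    object@scenario@label, object@scenario@t28, object@scenario@tEctcDays,
    object@scenario@lowerLimit, object@mrp, object@U,
    if (object@slopesClamped) ", slopes clamped" else ""))
})
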