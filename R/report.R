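#' Construct an analysis configuration
#'
#' Bundles every tunable decision of the pipeline so a full analysis is a
#' pure function of (dataset, config). Defaults: lower limit 800,
#' poolability alpha 0.25, 95 percent confidence bands, coverage factor
#' 1.645, 30-day months, 24-month shelf-life, 3- and 14-day excursions,
#' positive-slope clamping, "pooled" residual policy and within-lot
#' Durbin-Watson ordering.
#'
#' @param lowerLimit,poolAlpha,ciLevel,coverageK,monthDays numeric(1).
#' @param shelfLifeMonths claimed RT storage duration (months).
#' @param ectcDays ECTC excursion durations to evaluate (days).
#' @param clampPositiveSlopes logical(1).
#' @param residualPolicy "pooled", "average", "rt" or "ectc".
#' @param dwOrdering "lot_time" or "input".
#' @return an \linkS4class{AnalysisConfig}.
#' @export
analysisConfig <- function(lowerLimit = 800, poolAlpha = 0.25,
                           ciLevel = 0.95, coverageK = 1.645,
                           monthDays = 30, shelfLifeMonths = 24,
                           ectcDays = c(3, 14),
                           clampPositiveSlopes = TRUE,
                           residualPolicy = "pooled",
                           dwOrdering = "lot_time") {
  new("AnalysisConfig", lowerLimit = lowerLimit, poolAlpha = poolAlpha,
      ciLevel = ciLevel, coverageK = coverageK, monthDays = monthDays,
      shelfLifeMonths = shelfLifeMonths, ectcDays = ectcDays,
      clampPositiveSlopes = clampPositiveSlopes,
      residualPolicy = residualPolicy, dwOrdering = dwOrdering)
}

.fitAsList <- function(fit) list(
  model = fit@modelType, slope = fit@slope, slopeSE = fit@slopeSE,
  intercept = fit@intercept, interceptSE = fit@interceptSE,
  residualSD = fit@residualSD, sse = fit@sse, df = fit@dfResidual,
  n = fit@n)

.diagAsList <- function(rep) list(
  shapiro = list(statistic = rep@shapiroStat, p.value = rep@shapiroP),
  breusch_pagan = list(statistic = rep@bpStat, p.value = rep@bpP),
  white = list(statistic = rep@whiteStat, p.value = rep@whiteP),
  durbin_watson = list(statistic = rep@dwStat, verdict = rep@dwVerdict),
  n_flagged = sum(rep@influence$outlier | rep@influence$high_leverage |
                  rep@influence$influence_cooks |
                  rep@influence$influence_dffits),
  linearity_max_dev = rep@linearityMaxDev)

.poolAsList <- function(p) list(
  p_slope = p@pSlope, p_intercept = p@pIntercept, alpha = p@alpha,
  decision = p@decision, chosen_model = p@chosenModel)

#' Per-lot slope table of a fit
#'
#' For the full model, each lot's time slope and its SE (from the
#' coefficient covariance); for common-slope models a single row. Used
#' to carry worst-case lot slopes into the MRP stage when lots are not
#' poolable.
#'
#' @param fit a \linkS4class{RegressionFit}.
#' @return data.frame(lot, slope, se).
#' @export
lotSlopeTable <- function(fit) {
  stopifnot(is(fit, "RegressionFit"))
  if (fit@modelType != "full")
    return(data.frame(lot = "(common)", slope = fit@slope,
                      se = fit@slopeSE))
  obj <- fit@model
  cf <- stats::coef(obj)
  V <- stats::vcov(obj)
  lots <- levels(factor(fit@lot))
  out <- lapply(lots, function(lt) {
    v <- rep(0, length(cf)); names(v) <- names(cf)
    v[".time"] <- 1
    inter <- paste0(".time:.lot", lt)
    if (inter %in% names(cf)) v[inter] <- 1
    data.frame(lot = lt, slope = sum(v * cf),
               se = sqrt(drop(t(v) %*% V %*% v)))
  })
  do.call(rbind, out)
}

.finalFit <- function(x, condition, conditioningMonths, pool, monthDays) {
  fitStability(x, condition, conditioningMonths = conditioningMonths,
               model = pool@chosenModel, monthDays = monthDays)
}

#' Run the full stability analysis pipeline
#'
#' Deterministically chains every stage on one dataset: descriptive
#' summary, transformation check, assumption diagnostics, batch
#' poolability (RT; ECTC pooled and per conditioning month), stability
#' evaluation of the final models against the lower limit, and the MRP
#' scenario grid. When lots are not poolable, the MRP stage evaluates
#' every lot-slope combination and reports the worst-case (largest) MRP
#' per scenario — the conservative release rule.
#'
#' @param x a \linkS4class{StabilityDataset}.
#' @param config an \linkS4class{AnalysisConfig}.
#' @return a report bundle: a nested list with elements \code{header},
#'   \code{summary}, \code{mean_range}, \code{diagnostics},
#'   \code{poolability}, \code{evaluation}, \code{mrp} (data.frame
#'   replica of the scenario table) and \code{verdicts}. Identical
#'   (dataset, config) inputs give identical bundles.
#' @examples
#' ds <- simulateDataset(mockSimParams(seed = 11))
#' bundle <- runFullAnalysis(ds, analysisConfig())
#' bundle$verdicts
#' @export
runFullAnalysis <- function(x, config = analysisConfig()) {
  stopifnot(is(x, "StabilityDataset"), is(config, "AnalysisConfig"))
  validObject(config)
  rec <- records(x)
  if (!nrow(rec))
    stop("stage design-validation: dataset has no records")
  stage <- function(name, expr) tryCatch(expr, error = function(e)
    stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))

  header <- list(
    sip = sipName(x), unit = sipUnit(x), n_records = nrow(rec),
    lower_limit = config@lowerLimit, pool_alpha = config@poolAlpha,
    ci_level = config@ciLevel, coverage_k = config@coverageK,
    month_days = config@monthDays,
    shelf_life_months = config@shelfLifeMonths,
    ectc_days = config@ectcDays,
    clamp_positive_slopes = config@clampPositiveSlopes,
    residual_policy = config@residualPolicy,
    dw_ordering = config@dwOrdering)

  summary_tab <- stage("summary", contentSummary(x))
  mean_range <- stage("mean-range", {
    mr <- tryCatch(meanRangeTable(x, "RT"), error = function(e) NULL)
    if (is.null(mr)) NULL else list(slopes = mr$slopes,
                                    recommended = mr$recommended)
  })

  has_ectc <- any(rec$condition == "ECTC")
  cms <- if (has_ectc) sort(unique(rec$conditioning_months[
    rec$condition == "ECTC"])) else integer()

  pool_rt <- stage("poolability-RT",
    testPoolability(x, "RT", alpha = config@poolAlpha))
  pools_ectc <- if (has_ectc) stage("poolability-ECTC", {
    out <- list(pooled = testPoolability(
      x, "ECTC", alpha = config@poolAlpha, monthDays = config@monthDays))
    for (m in cms)
      out[[sprintf("exposed_M%d", m)]] <- testPoolability(
        x, "ECTC", conditioningMonths = m, alpha = config@poolAlpha,
        monthDays = config@monthDays)
    out
  }) else list()

  fit_rt <- stage("fit-RT",
    .finalFit(x, "RT", NULL, pool_rt, config@monthDays))
  fits_ectc <- if (has_ectc) stage("fit-ECTC", {
    out <- list(pooled = .finalFit(x, "ECTC", NULL, pools_ectc$pooled,
                                   config@monthDays))
    for (m in cms)
      out[[sprintf("exposed_M%d", m)]] <- .finalFit(
        x, "ECTC", m, pools_ectc[[sprintf("exposed_M%d", m)]],
        config@monthDays)
    out
  }) else list()

  diag_rt <- stage("diagnostics-RT",
    runDiagnostics(fit_rt, ordering = config@dwOrdering))
  diag_ectc <- if (has_ectc) stage("diagnostics-ECTC",
    runDiagnostics(fits_ectc$pooled, ordering = config@dwOrdering))
  else NULL

  eval_rt <- stage("evaluate-RT", evaluateStability(
    fit_rt, lowerLimit = config@lowerLimit, level = config@ciLevel))
  eval_ectc <- if (has_ectc) stage("evaluate-ECTC", evaluateStability(
    fits_ectc$pooled, lowerLimit = config@lowerLimit,
    level = config@ciLevel)) else NULL

  clampPolicy <- if (config@clampPositiveSlopes) "positive" else "none"
  mrp_tab <- if (has_ectc) stage("mrp", {
    rt_slopes <- lotSlopeTable(fit_rt)
    sRef <- fits_ectc$pooled@residualSD
    rows <- list()
    for (nm in names(fits_ectc)) {
      ec_fit <- fits_ectc[[nm]]
      ec_slopes <- lotSlopeTable(ec_fit)
      for (d in config@ectcDays) {
        best <- NULL
        for (i in seq_len(nrow(rt_slopes))) for (j in seq_len(nrow(ec_slopes))) {
          U <- combinedUncertainty(
            t28 = config@shelfLifeMonths, se28 = rt_slopes$se[i],
            s28 = fit_rt@residualSD, tEctcMonths = d / config@monthDays,
            seEctc = ec_slopes$se[j], sEctc = ec_fit@residualSD,
            k = config@coverageK, residualPolicy = config@residualPolicy,
            sEctcRef = sRef)
          r <- computeMRP(
            mrpScenario(config@shelfLifeMonths, d, config@lowerLimit,
                        label = nm, monthDays = config@monthDays),
            b28 = rt_slopes$slope[i], bEctc = ec_slopes$slope[j], U = U,
            clampPolicy = clampPolicy, se28 = rt_slopes$se[i],
            s28 = fit_rt@residualSD, seEctc = ec_slopes$se[j],
            sEctc = ec_fit@residualSD)
          if (is.null(best) || r@mrp > best@mrp) best <- r
        }
        rows[[sprintf("%s_%gd", nm, d)]] <- best
      }
    }
    mrpTable(rows)
  }) else NULL

  verdicts <- list(
    rt_shelf_life_supported = shelfLifeSupported(
      eval_rt, min(config@shelfLifeMonths, max(eval_rt@grid))),
    ectc_excursion_supported = if (has_ectc) shelfLifeSupported(
      eval_ectc, min(max(config@ectcDays) / config@monthDays,
                     max(eval_ectc@grid))) else NA)

  list(header = header,
       summary = summary_tab,
       mean_range = mean_range,
       fits = c(list(rt = .fitAsList(fit_rt)),
                lapply(fits_ectc, .fitAsList)),
       diagnostics = list(rt = .diagAsList(diag_rt),
                          ectc = if (has_ectc) .diagAsList(diag_ectc)),
       poolability = c(list(rt = .poolAsList(pool_rt)),
                       lapply(pools_ectc, .poolAsList)),
       evaluation = list(rt = eval_rt, ectc = eval_ectc),
       mrp = mrp_tab,
       verdicts = verdicts)
}

#' Serialise a report bundle to JSON
#'
#' Writes a machine-readable JSON report; evaluation bands are flattened
#' to (time, mean, lower, upper) tables. Output is byte-identical for
#' identical bundles.
#'
#' @param bundle result of [runFullAnalysis()].
#' @param path output JSON file.
#' @return the path, invisibly.
#' @export
writeReport <- function(bundle, path) {
  evalTab <- function(ev) if (is.null(ev)) NULL else data.frame(
    time = ev@grid, mean = ev@meanLine, lower = ev@ciLower,
    upper = ev@ciUpper)
  out <- bundle
  out$evaluation <- list(
    rt = evalTab(bundle$evaluation$rt),
    ectc = evalTab(bundle$evaluation$ectc))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
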