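#' Construct simulation parameters
#'
#' See \linkS4class{SimulationParams} for the generative model.
#'
#' @param logInterceptMean mean log release content (natural log).
#' @param lotInterceptSD SD of the lot-level random intercept (log scale).
#' @param rtSlope,ectcSlope decay slopes, log units per month.
#' @param rtResidualSD,ectcResidualSD residual SDs (log scale).
#' @param design a \linkS4class{DesignScheme}.
#' @param monthDays days per month used to apply the per-month ECTC slope
#'   per day.
#' @param seed integer RNG seed.
#' @return a \linkS4class{SimulationParams}.
#' @export
simParams <- function(logInterceptMean = log(1000), lotInterceptSD = 0.005,
                      rtSlope = -0.003723, ectcSlope = -0.117480,
                      rtResidualSD = 0.0271, ectcResidualSD = 0.0250,
                      design = mockStudyDesign(), monthDays = 30,
                      seed = 1L) {
  new("SimulationParams", logInterceptMean = logInterceptMean,
      lotInterceptSD = lotInterceptSD, rtSlope = rtSlope,
      ectcSlope = ectcSlope, rtResidualSD = rtResidualSD,
      ectcResidualSD = ectcResidualSD, design = design,
      monthDays = monthDays, seed = as.integer(seed))
}

#' The calibrated mock-study preset
#'
#' Parameters matching the package's reference mock stability study:
#' pooled RT slope -0.003723/month with residual SD 0.0271, pooled ECTC
#' slope -0.117480/month with residual SD 0.0250, the
#' [mockStudyDesign()] sampling plan, and a mean log release content of
#' log(1000) so trajectories sit comfortably above the 800 LEU lower
#' limit. Lot-level release variability defaults to SD 0.005 on the log
#' scale (about 0.5 percent CV), small enough that generated studies are
#' poolable across lots and their pooled-model residuals show no material
#' within-lot autocorrelation.
#'
#' @param seed integer RNG seed.
#' @param ... overrides passed on to [simParams()].
#' @return a \linkS4class{SimulationParams}.
#' @examples
#' ds <- simulateDataset(mockSimParams(seed = 7))
#' ds
#' @export
mockSimParams <- function(seed = 1L, ...) {
  simParams(seed = seed, ...)
}

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams: log intercept", format(object@logInterceptMean),
      "+/- lot SD", object@lotInterceptSD, "\n",
      " slopes (per month): RT", object@rtSlope, "| ECTC", object@ectcSlope,
      "\n  residual SDs: RT", object@rtResidualSD, "| ECTC",
      object@ectcResidualSD, "| seed", object@seed, "\n")
})

# Lot roster covering the largest cell of the design; lots are assigned
# to cells in roster order (first n_lots lots of each cell).
.lotRoster <- function(design) {
  n <- max(0L, design@rtCells$n_lots, design@ectcCells$n_lots)
  if (n == 0L) return(character())
  sprintf("L%02d", seq_len(n))
}

#' Generate a mock stability dataset
#'
#' Draws one study from the log-linear decay model of
#' \linkS4class{SimulationParams}: per-lot random intercepts, linear decay
#' in time on the natural-log scale, and iid Gaussian residual noise per
#' assay result. The ECTC starting level of a lot conditioned m months is
#' its noise-free RT trajectory at month m, so the two decay phases
#' compose exactly as the MRP formula assumes. Contents are emitted on
#' the original scale (exponentiated); an identical seed yields an
#' identical dataset, and the RNG state of the session is left untouched.
#'
#' @param params a \linkS4class{SimulationParams}.
#' @param lowerLimit lower limit recorded on the returned dataset.
#' @param sipName,unit metadata for the returned dataset.
#' @return a \linkS4class{StabilityDataset} whose record counts exactly
#'   match the design (empty design gives an empty dataset).
#' @export
simulateDataset <- function(params, lowerLimit = 800,
                            sipName = "antigen content", unit = "LEU") {
  stopifnot(is(params, "SimulationParams"))
  validObject(params)
  design <- params@design
  roster <- .lotRoster(design)
  empty <- StabilityDataset(
    data.frame(lot_id = character(), condition = character(),
               conditioning_months = integer(), time_value = numeric(),
               time_unit = character(), replicate = integer(),
               content = numeric()),
    sipName = sipName, unit = unit, lowerLimit = lowerLimit)
  if (!length(roster)) return(empty)

  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(params@seed)

  a <- stats::rnorm(length(roster), 0, params@lotInterceptSD)
  names(a) <- roster
  reps <- design@replicatesPerSample

  rt <- design@rtCells
  rt_rows <- if (nrow(rt)) do.call(rbind, lapply(seq_len(nrow(rt)), function(i) {
    lots <- roster[seq_len(rt$n_lots[i])]
    expand.grid(lot_id = lots, replicate = seq_len(reps),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
      , c("lot_id", "replicate")] |>
      transform(condition = "RT", conditioning_months = 0L,
                time_value = rt$month[i], time_unit = "month")
  })) else NULL

  ec <- design@ectcCells
  ec_rows <- if (nrow(ec)) do.call(rbind, lapply(seq_len(nrow(ec)), function(i) {
    lots <- roster[seq_len(ec$n_lots[i])]
    expand.grid(lot_id = lots, replicate = seq_len(reps),
                KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[
      , c("lot_id", "replicate")] |>
      transform(condition = "ECTC",
                conditioning_months = ec$conditioning_month[i],
                time_value = ec$day[i], time_unit = "day")
  })) else NULL

  rows <- rbind(rt_rows, ec_rows)
  if (is.null(rows) || !nrow(rows)) return(empty)

  mu <- params@logInterceptMean + a[rows$lot_id]
  is_rt <- rows$condition == "RT"
  mu[is_rt] <- mu[is_rt] + params@rtSlope * rows$time_value[is_rt]
  mu[!is_rt] <- mu[!is_rt] +
    params@rtSlope * rows$conditioning_months[!is_rt] +
    params@ectcSlope * rows$time_value[!is_rt] / params@monthDays
  sds <- ifelse(is_rt, params@rtResidualSD, params@ectcResidualSD)
  logc <- mu + stats::rnorm(nrow(rows), 0, sds)

  rows$content <- exp(logc)
  rows <- rows[, .RECORD_COLUMNS]
  StabilityDataset(rows, sipName = sipName, unit = unit,
                   lowerLimit = lowerLimit)
}
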