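#' Mean-range table for transformation selection
#'
#' For each candidate monotone transform, computes the per-timepoint mean
#' and range of the transformed contents and the OLS slope of range
#' against mean. A transform that stabilises the variance leaves the
#' range unrelated to the mean, so the recommended transform is the one
#' with the smallest absolute range-versus-mean slope. With
#' multiplicative (lognormal) assay noise this selects the log; with
#' purely additive noise it selects the identity.
#'
#' @param x a \linkS4class{StabilityDataset} or records data.frame.
#' @param condition which condition's timepoints to use.
#' @param transforms named list of monotone functions.
#' @return list with \code{cells} (data.frame: transform, time, n, mean,
#'   range), \code{slopes} (named numeric) and \code{recommended}
#'   (name of the winning transform).
#' @export
meanRangeTable <- function(x, condition = c("RT", "ECTC"),
                           transforms = list(identity = identity,
                                             log = log,
                                             sqrt = sqrt)) {
  condition <- match.arg(condition)
  rec <- if (is(x, "StabilityDataset")) records(x) else as.data.frame(x)
  rec <- rec[rec$condition == condition, , drop = FALSE]
  cells <- split(rec$content, rec$time_value)
  cells <- cells[vapply(cells, length, 1L) >= 2L]
  if (length(cells) < 2L)
    stop("mean-range needs >= 2 timepoints with >= 2 observations each")
  out <- lapply(names(transforms), function(nm) {
    f <- transforms[[nm]]
    data.frame(transform = nm,
               time = as.numeric(names(cells)),
               n = vapply(cells, length, 1L),
               mean = vapply(cells, function(v) mean(f(v)), 1),
               range = vapply(cells, function(v) diff(range(f(v))), 1))
  })
  tab <- do.call(rbind, out)
  rownames(tab) <- NULL
  slopes <- vapply(names(transforms), function(nm) {
    d <- tab[tab$transform == nm, ]
    if (stats::var(d$mean) == 0) return(0)
    unname(stats::coef(stats::lm(range ~ mean, data = d))["mean"])
  }, 1)
  list(cells = tab, slopes = slopes,
       recommended = names(slopes)[which.min(abs(slopes))])
}

.fitResiduals <- function(fit) {
  if (is(fit, "RegressionFit")) fit@residuals else as.numeric(fit)
}

#' Shapiro-Wilk normality test of residuals
#'
#' The null hypothesis is that the residual distribution is normal; a
#' significant p-value flags non-normality. Valid for 3 to 5000
#' observations (the standard published approximation).
#'
#' @param x a \linkS4class{RegressionFit} or a numeric residual vector.
#' @return list with \code{statistic} (W) and \code{p.value}.
#' @export
normalityTest <- function(x) {
  e <- .fitResiduals(x)
  if (length(e) < 3L)
    stop("Shapiro-Wilk needs at least 3 residuals, got ", length(e))
  if (length(e) > 5000L)
    stop("Shapiro-Wilk approximation is valid only up to 5000 residuals")
  if (stats::var(e) == 0)
    stop("residuals have zero variance; normality test undefined")
  sw <- stats::shapiro.test(e)
  list(statistic = unname(sw$statistic), p.value = sw$p.value)
}

.checkAuxiliary <- function(fit) {
  if (fit@dfResidual < 2L)
    stop("heteroscedasticity test needs >= 2 residual degrees of freedom")
  # numerically-zero residuals (an exact fit) leave nothing to regress
  scale2 <- max(1, mean(fit@fitted^2))
  if (stats::var(fit@residuals) <= .Machine$double.eps^2 * scale2)
    stop("residuals are constant; auxiliary regression is degenerate")
}

#' Breusch-Pagan heteroscedasticity test
#'
#' Tests whether the residual variance depends on the regressors, via the
#' LM statistic n R-squared of the auxiliary regression of (scaled)
#' squared residuals on the model regressors. The default is the
#' studentized (Koenker) form.
#'
#' @param fit a \linkS4class{RegressionFit}.
#' @param studentized use the Koenker scaling (default TRUE).
#' @return list with \code{statistic}, \code{p.value} and \code{df}.
#' @export
breuschPagan <- function(fit, studentized = TRUE) {
  stopifnot(is(fit, "RegressionFit"))
  .checkAuxiliary(fit)
  bp <- lmtest::bptest(fit@model, studentize = studentized)
  list(statistic = unname(bp$statistic), p.value = unname(bp$p.value),
       df = unname(bp$parameter))
}

#' White heteroscedasticity test
#'
#' Breusch-Pagan with the auxiliary regressors augmented by the squared
#' time term, sensitive to multiplicative variance patterns. Needs at
#' least 3 distinct time values (with 2, the squared term is collinear).
#'
#' @inheritParams breuschPagan
#' @return list with \code{statistic}, \code{p.value} and \code{df}.
#' @export
whiteTest <- function(fit, studentized = TRUE) {
  stopifnot(is(fit, "RegressionFit"))
  .checkAuxiliary(fit)
  if (length(unique(fit@time)) < 3L)
    stop("singular fit: time squared is collinear with time ",
         "(need >= 3 distinct time values)")
  dat <- data.frame(.time = fit@time)
  bp <- lmtest::bptest(fit@model, ~ .time + I(.time^2), data = dat,
                       studentize = studentized)
  list(statistic = unname(bp$statistic), p.value = unname(bp$p.value),
       df = unname(bp$parameter))
}

#' Durbin-Watson autocorrelation statistic
#'
#' d = sum of squared successive residual differences over the residual
#' sum of squares, computed after ordering the observations. Stability
#' data are a panel, so the default ordering is within-lot by time with
#' lots concatenated in lot-ID order. By the usual rule of thumb,
#' 1.5 < d < 2.5 indicates no material autocorrelation ("ok"); values
#' outside that range are flagged "suspect". An optional large-sample
#' normal approximation (d approximately N(2, 4/n) under independence)
#' provides a two-sided p-value.
#'
#' @param fit a \linkS4class{RegressionFit}, or a numeric vector of
#'   residuals already in analysis order.
#' @param ordering "lot_time" (default) or "input"; ignored for a plain
#'   residual vector, which is taken as ordered.
#' @param pvalue also return the normal-approximation p-value.
#' @return list with \code{statistic}, \code{verdict} and, if requested,
#'   \code{p.value}.
#' @export
durbinWatson <- function(fit, ordering = c("lot_time", "input"),
                         pvalue = FALSE) {
  ordering <- match.arg(ordering)
  if (is(fit, "RegressionFit")) {
    e <- fit@residuals
    if (ordering == "lot_time") e <- e[order(fit@lot, fit@time)]
  } else {
    e <- as.numeric(fit)
  }
  n <- length(e)
  if (n < 3L) stop("Durbin-Watson needs at least 3 observations")
  if (all(e == 0)) stop("all residuals are zero; d is undefined")
  d <- sum(diff(e)^2) / sum(e^2)
  out <- list(statistic = d,
              verdict = if (d > 1.5 && d < 2.5) "ok" else "suspect")
  if (pvalue) {
    z <- (d - 2) / sqrt(4 / n)
    out$p.value <- 2 * stats::pnorm(-abs(z))
  }
  out
}

#' Influence and outlier diagnostics
#'
#' Per-observation studentized (leave-one-out) residuals, leverages,
#' Cook's distances and DFFITS, with the conventional flag thresholds:
#' |studentized residual| > 3 (outlier), leverage > 2p/n, Cook's D > 4/n,
#' |DFFITS| > 2 sqrt(p/n), where p is the number of estimated
#' coefficients. Observations with leverage numerically equal to 1 have
#' no defined studentized residual and are flagged \code{exact_leverage}.
#' Flagged observations are reported, never removed: influential points
#' deserve scrutiny of the raw data, not silent deletion.
#'
#' @param fit a \linkS4class{RegressionFit} with \code{dfResidual >= 2}.
#' @return data.frame with columns \code{lot}, \code{time},
#'   \code{studentized}, \code{leverage}, \code{cooksD}, \code{dffits}
#'   and logical flags \code{outlier}, \code{high_leverage},
#'   \code{influence_cooks}, \code{influence_dffits},
#'   \code{exact_leverage}.
#' @export
influenceDiagnostics <- function(fit) {
  stopifnot(is(fit, "RegressionFit"))
  if (fit@dfResidual < 2L)
    stop("influence diagnostics need >= 2 residual degrees of freedom")
  obj <- fit@model
  n <- fit@n
  p <- n - fit@dfResidual
  h <- unname(stats::hatvalues(obj))
  exact <- h >= 1 - 1e-10
  rs <- rep(NA_real_, n)
  rs[!exact] <- unname(stats::rstudent(obj))[!exact]
  cd <- unname(stats::cooks.distance(obj))
  dff <- rep(NA_real_, n)
  dff[!exact] <- unname(stats::dffits(obj))[!exact]
  data.frame(
    lot = fit@lot, time = fit@time,
    studentized = rs, leverage = h, cooksD = cd, dffits = dff,
    outlier = !is.na(rs) & abs(rs) > 3,
    high_leverage = h > 2 * p / n,
    influence_cooks = cd > 4 / n,
    influence_dffits = !is.na(dff) & abs(dff) > 2 * sqrt(p / n),
    exact_leverage = exact)
}

#' Partial-residual linearity check
#'
#' Computes the component-plus-residual (partial residual) values for the
#' time term, smooths them with local regression (tricube-weighted loess
#' for span < 1) and reports the maximum absolute gap between the smooth
#' and the least-squares line over the observed time range. Noise-free
#' linear data give (numerically) zero; curvature inflates the deviation
#' with the size of the nonlinear component.
#'
#' @param fit a \linkS4class{RegressionFit}.
#' @param span loess span alpha controlling the degree of smoothing.
#' @return list with \code{maxDev} and \code{points} (data.frame: time,
#'   partial residual, smooth and linear values at the observed times).
#' @export
linearityCheck <- function(fit, span = 0.75) {
  stopifnot(is(fit, "RegressionFit"))
  ut <- unique(fit@time)
  if (length(ut) < 5L)
    stop("linearity check needs >= 5 distinct time values, got ",
         length(ut))
  pr <- fit@residuals + fit@slope * fit@time
  d <- data.frame(.time = fit@time, .pr = pr)
  lo <- stats::loess(.pr ~ .time, data = d, span = span, degree = 1,
                     family = "gaussian",
                     control = stats::loess.control(surface = "direct"))
  lin <- stats::lm(.pr ~ .time, data = d)
  grid <- data.frame(.time = sort(ut))
  smooth <- stats::predict(lo, newdata = grid)
  straight <- stats::predict(lin, newdata = grid)
  list(maxDev = max(abs(smooth - straight)),
       points = data.frame(time = grid$.time, smooth = smooth,
                           linear = straight))
}

#' Run the full diagnostics battery
#'
#' Applies all five regression-assumption checks to a log-scale
#' stability fit and assembles a \linkS4class{DiagnosticsReport}. The
#' linearity deviation is set to NA when fewer than 5 distinct times are
#' available.
#'
#' @param fit a \linkS4class{RegressionFit}.
#' @param span loess span for [linearityCheck()].
#' @param ordering Durbin-Watson ordering, see [durbinWatson()].
#' @return a \linkS4class{DiagnosticsReport}.
#' @examples
#' ds <- simulateDataset(mockSimParams(seed = 3))
#' runDiagnostics(fitStability(ds, "RT"))
#' @export
runDiagnostics <- function(fit, span = 0.75, ordering = "lot_time") {
  sw <- normalityTest(fit)
  bp <- breuschPagan(fit)
  wh <- whiteTest(fit)
  dw <- durbinWatson(fit, ordering = ordering)
  infl <- influenceDiagnostics(fit)
  lin <- if (length(unique(fit@time)) >= 5L)
    linearityCheck(fit, span = span)$maxDev else NA_real_
  new("DiagnosticsReport",
      shapiroStat = sw$statistic, shapiroP = sw$p.value,
      bpStat = bp$statistic, bpP = bp$p.value,
      whiteStat = wh$statistic, whiteP = wh$p.value,
      dwStat = dw$statistic, dwVerdict = dw$verdict,
      influence = infl, linearityMaxDev = lin)
}

setMethod("show", "DiagnosticsReport", function(object) {
  cat("DiagnosticsReport\n")
  cat(sprintf("  Shapiro-Wilk:  W = %.4f, p = %.4f\n",
              object@shapiroStat, object@shapiroP))
  cat(sprintf("  Breusch-Pagan: LM = %.4f, p = %.4f\n",
              object@bpStat, object@bpP))
  cat(sprintf("  White:         LM = %.4f, p = %.4f\n",
              object@whiteStat, object@whiteP))
  cat(sprintf("  Durbin-Watson: d = %.4f (%s)\n",
              object@dwStat, object@dwVerdict))
  cat(sprintf("  flagged observations: %d of %d\n",
              sum(object@influence$outlier | object@influence$high_leverage |
                  object@influence$influence_cooks |
                  object@influence$influence_dffits),
              nrow(object@influence)))
  if (is.finite(object@linearityMaxDev))
    cat(sprintf("  linearity max |smooth - line|: %.5f\n",
                object@linearityMaxDev))
})
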