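# Small in-code fixtures shared across test files.

# A tiny valid RT-only records table.
tinyRecords <- function(contents = c(1000, 990), months = c(0, 3),
                        lot = "A") {
  data.frame(lot_id = lot, condition = "RT", conditioning_months = 0L,
             time_value = months, time_unit = "month", replicate = 1L,
             content = contents)
}

# Noise-free two-lot RT data with chosen slopes/intercepts, in months 0..5.
twoLotLines <- function(slopeA, slopeB, interceptA = 7, interceptB = 7,
                        months = 0:5) {
  data.frame(
    lot = rep(c("A", "B"), each = length(months)),
    time = rep(months, 2),
    y = c(interceptA + slopeA * months, interceptB + slopeB * months))
}

# Independent OLS oracle: normal equations (X'X)^-1 X'y.
normalEquations <- function(X, y) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  list(beta = drop(beta), se = sqrt(diag(s2 * solve(XtX))),
       sse = sum(res^2), df = df)
}

# The reference mock-study coefficient table used throughout.
refEst <- ctcstab::mockEstimates()
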