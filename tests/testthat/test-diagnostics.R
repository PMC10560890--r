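test_that("fitOLS matches the normal-equations oracle on random inputs", {
  set.seed(11)
  for (i in 1:10) {
    n <- sample(6:15, 1)
    t <- sort(runif(n, 0, 24))
    y <- 7 - 0.01 * t + rnorm(n, 0, 0.05)
    f <- fitOLS(t, y)
    o <- normalEquations(cbind(1, t), y)
    expect_equal(f@intercept, unname(o$beta[1]), tolerance = 1e-8)
    expect_equal(slopeOf(f), unname(o$beta[2]), tolerance = 1e-8)
    expect_equal(slopeSE(f), unname(o$se[2]), tolerance = 1e-8)
    expect_equal(f@sse, o$sse, tolerance = 1e-8)
    expect_equal(f@dfResidual, o$df)
    expect_equal(residualSD(f), sqrt(o$sse / o$df), tolerance = 1e-10)
  }
})

test_that("fitOLS handles exact lines and refuses deficient designs", {
  f <- fitOLS(c(0, 1, 2), c(0, 1, 2))
  expect_equal(slopeOf(f), 1)
  expect_equal(f@intercept, 0)
  expect_equal(residualSD(f), 0)
  expect_error(fitOLS(c(0, 1), c(0, 1)), "3 observations")
  expect_error(fitOLS(c(1, 1, 1), c(0, 1, 2)), "distinct time")
  # a one-timepoint lot has no estimable slope in the full model
  d <- rbind(twoLotLines(1, 2), data.frame(lot = "C", time = 0, y = 7))
  expect_error(fitOLS(d$time, d$y, d$lot, model = "full"), "C")
})

test_that("mean-range ranking selects log for multiplicative and identity for additive noise", {
  set.seed(21)
  months <- rep(c(0, 6, 12, 18, 24), each = 6)
  mu <- 1000 * exp(-0.05 * months)
  mult <- tinyRecords(contents = mu * exp(rnorm(length(mu), 0, 0.05)),
                      months = months)
  mr <- meanRangeTable(StabilityDataset(mult),
                       transforms = list(identity = identity, log = log))
  expect_equal(mr$recommended, "log")
  expect_lt(abs(mr$slopes["log"]), abs(mr$slopes["identity"]))

  addv <- tinyRecords(contents = mu + rnorm(length(mu), 0, 20),
                      months = months)
  mr2 <- meanRangeTable(StabilityDataset(addv),
                        transforms = list(identity = identity, log = log))
  expect_equal(mr2$recommended, "identity")

  const <- tinyRecords(contents = rep(1000, 10), months = rep(c(0, 6), 5))
  mr3 <- meanRangeTable(StabilityDataset(const))
  expect_true(all(mr3$cells$range == 0))

  single <- tinyRecords(contents = c(1000, 990), months = c(0, 6))
  expect_error(meanRangeTable(StabilityDataset(single)), ">= 2")
})

test_that("Shapiro-Wilk is calibrated under the null and powered against skew", {
  expect_error(normalityTest(rep(0, 10)), "zero variance")
  expect_error(normalityTest(c(0.1, -0.1)), "at least 3")
  set.seed(31)
  p_null <- vapply(1:500, function(i)
    normalityTest(rnorm(100))$p.value, 1)
  expect_gte(mean(p_null > 0.05), 0.90)
  p_skew <- vapply(1:500, function(i)
    normalityTest(exp(rnorm(100)))$p.value, 1)
  expect_gte(mean(p_skew < 0.05), 0.95)
})

test_that("Breusch-Pagan equals the hand-computed auxiliary-regression LM statistic", {
  t <- c(0, 1, 2, 3, 4)
  y <- c(1.0, 1.4, 1.7, 2.5, 2.6)
  f <- fitOLS(t, y)
  bp <- breuschPagan(f, studentized = TRUE)
  # Koenker form by hand: n * R^2 of u^2 on the regressor
  u2 <- f@residuals^2
  aux <- lm(u2 ~ t)
  expect_equal(bp$statistic, 5 * summary(aux)$r.squared, tolerance = 1e-10)
  expect_equal(bp$p.value, pchisq(bp$statistic, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_error(breuschPagan(fitOLS(0:3, c(0, 1, 2, 3))), "constant")
})

test_that("heteroscedasticity tests are type-I calibrated and powered", {
  set.seed(41)
  n <- 200
  t <- rep(seq(0, 24, length.out = 10), each = n / 10)
  p_null <- t(vapply(1:1000, function(i) {
    f <- fitOLS(t, 7 + 0.01 * t + rnorm(n, 0, 0.05))
    c(breuschPagan(f)$p.value, whiteTest(f)$p.value)
  }, c(1, 1)))
  expect_gte(mean(p_null[, 1] < 0.05), 0.03)
  expect_lte(mean(p_null[, 1] < 0.05), 0.07)
  expect_gte(mean(p_null[, 2] < 0.05), 0.03)
  expect_lte(mean(p_null[, 2] < 0.05), 0.07)
  # variance growing with time: strong rejection
  p_het <- vapply(1:200, function(i) {
    f <- fitOLS(t, 7 + 0.01 * t + rnorm(n, 0, 0.01 + 0.01 * t))
    breuschPagan(f)$p.value
  }, 1)
  expect_gte(mean(p_het < 0.05), 0.8)
  # two distinct times: the squared term is collinear
  f2 <- fitOLS(rep(c(0, 1), 5), rnorm(10))
  expect_error(whiteTest(f2), "collinear")
})

test_that("Durbin-Watson matches the direct formula and its null expectation", {
  expect_equal(durbinWatson(c(1, -1, 1, -1))$statistic, 3)
  expect_equal(durbinWatson(c(1, -1, 1, -1))$verdict, "suspect")
  expect_equal(durbinWatson(c(1, 1, 1, -1))$statistic, 1)
  expect_equal(durbinWatson(c(1, 1, 1, -1))$verdict, "suspect")
  expect_error(durbinWatson(rep(0, 5)), "zero")

  set.seed(51)
  d <- vapply(1:500, function(i) {
    f <- fitOLS(rep(0:9, 3), rnorm(30))
    durbinWatson(f, ordering = "input")$statistic
  }, 1)
  expect_gt(mean(d), 1.9); expect_lt(mean(d), 2.1)

  # agreement with the reference implementation on a clean fit
  set.seed(52)
  f <- fitOLS(1:20, rnorm(20))
  dw_ref <- lmtest::dwtest(f@model)
  expect_equal(durbinWatson(f, ordering = "input")$statistic,
               unname(dw_ref$statistic), tolerance = 1e-10)
})

test_that("influence measures match leave-one-out oracles and flag planted points", {
  set.seed(61)
  t <- c(0:8, 24)
  y <- 7 - 0.01 * t + rnorm(10, 0, 0.02)
  y[10] <- y[10] + 10 * 0.02  # displaced far point
  f <- fitOLS(t, y)
  infl <- influenceDiagnostics(f)

  # Cook's D against the explicit leave-one-out refit formula
  X <- cbind(1, t)
  beta <- normalEquations(X, y)$beta
  s2 <- f@sse / f@dfResidual
  for (i in c(1, 5, 10)) {
    bi <- normalEquations(X[-i, ], y[-i])$beta
    db <- beta - bi
    D_oracle <- drop(t(db) %*% crossprod(X) %*% db) / (2 * s2)
    expect_equal(infl$cooksD[i], D_oracle, tolerance = 1e-8)
  }
  expect_true(infl$outlier[10] || infl$influence_cooks[10])
  expect_true(infl$high_leverage[10])
  expect_true(infl$influence_dffits[10])

  # hat-matrix trace identity: sum of leverages = number of coefficients
  expect_equal(sum(infl$leverage), 2, tolerance = 1e-10)

  # balanced symmetric design with equal residual magnitudes: no flags
  fb <- fitOLS(rep(0:4, 2), rep(c(1, -1), 5) * 0.01 + 5)
  ib <- influenceDiagnostics(fb)
  expect_false(any(ib$outlier | ib$influence_cooks))
})

test_that("linearity deviation is zero for lines and grows with curvature", {
  t <- rep(seq(0, 24, by = 3), each = 2)
  f_lin <- fitOLS(t, 7 - 0.01 * t)
  expect_lt(linearityCheck(f_lin)$maxDev, 1e-8)

  devs <- vapply(c(0.001, 0.003, 0.01), function(q) {
    f <- fitOLS(t, 7 - 0.01 * t + q * t^2)
    linearityCheck(f)$maxDev
  }, 1)
  expect_true(all(diff(devs) > 0))

  f_few <- fitOLS(rep(c(0, 6, 12), 2), rnorm(6))
  expect_error(linearityCheck(f_few), "5 distinct")

  # noise-only: deviation small relative to the residual SD
  set.seed(71)
  dev_null <- vapply(1:200, function(i) {
    f <- fitOLS(t, 7 + rnorm(length(t), 0, 0.05))
    linearityCheck(f)$maxDev / residualSD(f)
  }, 1)
  expect_lt(median(dev_null), 1.5)
})
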