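test_that("a flat noise-free line passes with a collapsed band", {
  rec <- tinyRecords(contents = rep(c(1000.0001, 999.9999), 4),
                     months = rep(c(0, 6, 12, 24), each = 2))
  f <- fitStability(StabilityDataset(rec), "RT")
  ev <- evaluateStability(f, lowerLimit = 800)
  expect_true(ev@pass)
  expect_true(all(abs(ev@meanLine - 1000) < 0.01))
  expect_true(all(ev@ciUpper - ev@ciLower < 0.01))
  expect_true(is.na(ev@firstFailureTime))
})

test_that("a crossing mean line fails at the closed-form crossing time", {
  # steep noise-free decay: content = 1000 exp(-0.02 t) crosses 900
  # (as a mean line with a negligible band) at t = log(1000/900)/0.02
  months <- rep(seq(0, 24, by = 3), each = 2)
  set.seed(121)
  contents <- 1000 * exp(-0.02 * months) * exp(rnorm(length(months), 0, 1e-6))
  f <- fitStability(StabilityDataset(tinyRecords(contents, months)), "RT")
  ev <- evaluateStability(f, lowerLimit = 900)
  expect_false(ev@pass)
  expect_equal(ev@firstFailureTime, log(1000 / 900) / 0.02, tolerance = 1e-3)
  expect_true(shelfLifeSupported(ev, 3))
  expect_false(shelfLifeSupported(ev, 24))
})

test_that("band geometry: bracketing, hyperbolic width, level monotonicity", {
  set.seed(131)
  months <- rep(seq(0, 24, by = 3), each = 2)
  contents <- 1000 * exp(-0.005 * months + rnorm(length(months), 0, 0.03))
  f <- fitStability(StabilityDataset(tinyRecords(contents, months)), "RT")
  ev <- evaluateStability(f, lowerLimit = 800)
  expect_true(all(ev@ciLower <= ev@meanLine + 1e-12))
  expect_true(all(ev@meanLine <= ev@ciUpper + 1e-12))
  # log-scale width grows with distance from the mean observation time
  w <- log(ev@ciUpper) - log(ev@ciLower)
  dist <- abs(ev@grid - mean(f@time))
  expect_true(all(diff(w[order(dist)]) > -1e-12))
  # wider level, wider band; level -> 0 collapses onto the mean line
  ev99 <- evaluateStability(f, lowerLimit = 800, level = 0.99)
  expect_true(all(log(ev99@ciUpper) - log(ev99@ciLower) >= w - 1e-12))
  ev0 <- evaluateStability(f, lowerLimit = 800, level = 1e-9)
  expect_true(all(abs(ev0@ciLower - ev0@meanLine) < 1e-6))
  # log- and original-scale verdicts agree by monotonicity of exp
  expect_equal(ev@pass, all(log(ev@ciLower) >= log(800)))
})

test_that("prediction bands are wider than mean-response bands", {
  set.seed(141)
  months <- rep(seq(0, 24, by = 3), each = 2)
  contents <- 1000 * exp(rnorm(length(months), 0, 0.03))
  f <- fitStability(StabilityDataset(tinyRecords(contents, months)), "RT")
  evc <- evaluateStability(f, lowerLimit = 800)
  evp <- evaluateStability(f, lowerLimit = 800, band = "prediction")
  expect_true(all(evp@ciLower < evc@ciLower))
  expect_true(all(evp@ciUpper > evc@ciUpper))
})

test_that("extrapolation is refused, for grids and for claims", {
  rec <- tinyRecords(contents = rep(1000, 8),
                     months = rep(c(0, 6, 12, 24), each = 2))
  f <- fitStability(StabilityDataset(rec), "RT")
  expect_error(evaluateStability(f, grid = seq(0, 48, by = 1)),
               "beyond the observed")
  ev <- evaluateStability(f)
  expect_error(shelfLifeSupported(ev, 36), "outside the evaluated")
})

test_that("mock-preset RT studies pass the 24-month evaluation", {
  passes <- vapply(1:40, function(s) {
    ds <- simulateDataset(mockSimParams(seed = 1000 + s))
    ev <- evaluateStability(fitStability(ds, "RT"), lowerLimit = 800)
    ev@pass && shelfLifeSupported(ev, 24)
  }, NA)
  expect_gte(mean(passes), 0.95)
})
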