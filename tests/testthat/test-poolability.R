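test_that("nested model SSEs are monotone on any input", {
  set.seed(81)
  for (i in 1:10) {
    d <- twoLotLines(runif(1, -0.1, 0), runif(1, -0.1, 0),
                     interceptA = 7, interceptB = 7 + runif(1, -0.2, 0.2))
    d$y <- d$y + rnorm(nrow(d), 0, 0.05)
    fits <- fitPoolModels(d$time, d$y, d$lot)
    expect_lte(fits$full@sse, fits$reduced1@sse + 1e-12)
    expect_lte(fits$reduced1@sse, fits$reduced2@sse + 1e-12)
  }
})

test_that("identical lots collapse the three models; distinct slopes separate them", {
  same <- twoLotLines(-0.01, -0.01)
  fits <- fitPoolModels(same$time, same$y, same$lot)
  expect_equal(fits$full@sse, 0, tolerance = 1e-20)
  expect_equal(fits$reduced2@sse, 0, tolerance = 1e-20)

  diff <- twoLotLines(1, 2)
  fd <- fitPoolModels(diff$time, diff$y, diff$lot)
  expect_equal(fd$full@sse, 0, tolerance = 1e-16)
  expect_gt(fd$reduced1@sse, 0)
  expect_gt(fd$reduced2@sse, fd$reduced1@sse)
})

test_that("the partial F statistic equals the SSE formula on a 12-point fixture", {
  set.seed(91)
  d <- twoLotLines(-0.02, -0.05, interceptA = 7, interceptB = 7.1)
  d$y <- d$y + round(rnorm(12, 0, 0.03), 4)
  fits <- fitPoolModels(d$time, d$y, d$lot)
  ft <- partialFTest(fits$full, fits$reduced1)
  f_hand <- ((fits$reduced1@sse - fits$full@sse) /
             (fits$reduced1@dfResidual - fits$full@dfResidual)) /
            (fits$full@sse / fits$full@dfResidual)
  expect_equal(ft$statistic, f_hand, tolerance = 1e-10)
  expect_equal(ft$p.value,
               pf(f_hand, 1, fits$full@dfResidual, lower.tail = FALSE),
               tolerance = 1e-12)
  # against the reference ANOVA decomposition
  av <- anova(fits$reduced1@model, fits$full@model)
  expect_equal(ft$statistic, av$F[2], tolerance = 1e-10)
  expect_equal(ft$p.value, av$`Pr(>F)`[2], tolerance = 1e-10)

  # equal SSEs give F = 0, p = 1
  same <- twoLotLines(-0.01, -0.01)
  same$y <- same$y + rep(c(-0.01, 0.01), 6)
  fs <- fitPoolModels(same$time, same$y, same$lot)
  if (abs(fs$full@sse - fs$reduced1@sse) < 1e-12) {
    ft0 <- partialFTest(fs$full, fs$reduced1)
    expect_equal(ft0$p.value, 1, tolerance = 1e-6)
  }
  expect_error(partialFTest(fits$reduced1, fits$full), "degrees of freedom")
})

test_that("the decision rule reproduces all three criteria rows and the boundary", {
  expect_equal(decidePoolability(0.20)$decision, "not_parallel")
  expect_equal(decidePoolability(0.20)$chosenModel, "full")
  expect_equal(decidePoolability(0.30, 0.20)$decision, "parallel")
  expect_equal(decidePoolability(0.30, 0.20)$chosenModel, "reduced1")
  expect_equal(decidePoolability(0.30, 0.30)$decision, "one_line")
  expect_equal(decidePoolability(0.30, 0.30)$chosenModel, "reduced2")
  # p exactly alpha is significant: the pooled branch is not taken
  expect_equal(decidePoolability(0.25)$decision, "not_parallel")
  expect_equal(decidePoolability(0.30, 0.25)$decision, "parallel")
  # intercept p-value with a significant slope test: ignored with warning
  expect_warning(out <- decidePoolability(0.10, 0.50), "ignored")
  expect_equal(out$decision, "not_parallel")
  expect_error(decidePoolability(0.30), "pIntercept")
  # purity: same inputs, same output
  expect_identical(decidePoolability(0.30, 0.30),
                   decidePoolability(0.30, 0.30))
})

test_that("a strong batch slope effect is detected with high power", {
  set.seed(111)
  months <- rep(0:5 * 4, each = 2)
  hits <- vapply(1:200, function(i) {
    d <- rbind(
      data.frame(lot = "A", time = months,
                 y = 7 - 0.010 * months + rnorm(12, 0, 0.02)),
      data.frame(lot = "B", time = months,
                 y = 7 - 0.014 * months + rnorm(12, 0, 0.02)))
    fits <- fitPoolModels(d$time, d$y, d$lot)
    partialFTest(fits$full, fits$reduced1)$p.value < 0.25
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("testPoolability wires fits, tests and decision together", {
  ds <- simulateDataset(mockSimParams(seed = 5))
  p <- testPoolability(ds, "RT")
  expect_s4_class(p, "PoolabilityResult")
  expect_true(p@decision %in% c("not_parallel", "parallel", "one_line"))
  expect_equal(names(p@fits), c("full", "reduced1", "reduced2"))
  # ECTC per conditioning-month subsets also run
  p24 <- testPoolability(ds, "ECTC", conditioningMonths = 24)
  expect_equal(p24@fits$reduced2@n, 18L)
})
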