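test_that("combined uncertainty degenerates and validates correctly", {
  expect_equal(combinedUncertainty(0, 0, 0, k = 1.645), 0)
  expect_error(combinedUncertainty(24, -0.001, 0.03), "negative")
  # RT-only: U = k sqrt((t se)^2 + s^2)
  expect_equal(combinedUncertainty(24, 0.000377, 0.0271),
               1.645 * sqrt((24 * 0.000377)^2 + 0.0271^2),
               tolerance = 1e-12)
})

test_that("residual policies select the documented variance term", {
  base <- function(policy, ...) combinedUncertainty(
    24, 0.001, 0.03, tEctcMonths = 0.5, seEctc = 0.01, sEctc = 0.02,
    k = 1, residualPolicy = policy, ...)
  rss <- function(s2) sqrt((24 * 0.001)^2 + (0.5 * 0.01)^2 + s2)
  expect_equal(base("average"), rss((0.03^2 + 0.02^2) / 2))
  expect_equal(base("rt"), rss(0.03^2))
  expect_equal(base("ectc"), rss(0.02^2))
  expect_equal(base("pooled", sEctcRef = 0.025), rss((0.03^2 + 0.025^2) / 2))
  # without a reference, pooled falls back to the scenario residual
  expect_equal(base("pooled"), base("average"))
})

test_that("the MRP formula is exact in its closed-form special cases", {
  sc <- mrpScenario(24, 14, 800)
  expect_equal(computeMRP(sc, b28 = 0, bEctc = 0, U = 0)@mrp, 800)
  # log-scale additivity
  r <- computeMRP(sc, b28 = -0.003723, bEctc = -0.117480, U = 0.0462)
  expect_equal(log(r@mrp) - log(800),
               -(24 * -0.003723 + 14 / 30 * -0.117480 - 0.0462),
               tolerance = 1e-12)
})

test_that("MRP is monotone in uncertainty and in decay", {
  sc <- mrpScenario(24, 14, 800)
  m <- function(b28, be, U) computeMRP(sc, b28, be, U)@mrp
  expect_true(all(diff(sapply(c(0, 0.02, 0.05), function(U)
    m(-0.004, -0.12, U))) > 0))
  expect_true(all(diff(sapply(c(-0.002, -0.004, -0.006), function(b)
    m(b, -0.12, 0.05))) > 0))
  expect_true(all(diff(sapply(c(-0.10, -0.12, -0.14), function(b)
    m(-0.004, b, 0.05))) > 0))
})

test_that("clamping keeps an improving slope from undercutting the lower limit", {
  sc <- mrpScenario(24, 14, 800)
  r <- computeMRP(sc, b28 = 0.01, bEctc = 0.02, U = 0)
  expect_true(r@slopesClamped)
  expect_equal(r@mrp, 800)
  r2 <- computeMRP(sc, b28 = 0.01, bEctc = 0.02, U = 0,
                   clampPolicy = "none")
  expect_lt(r2@mrp, 800)
  # the "negative" reading zeroes decaying slopes instead
  r3 <- computeMRP(sc, b28 = -0.004, bEctc = -0.12, U = 0.05,
                   clampPolicy = "negative")
  expect_equal(r3@mrp, 800 * exp(0.05))
  # with non-positive slopes and U >= 0, MRP never drops below LL
  set.seed(151)
  for (i in 1:20) {
    r4 <- computeMRP(sc, b28 = -runif(1, 0, 0.01),
                     bEctc = -runif(1, 0, 0.2), U = runif(1, 0, 0.1))
    expect_gte(r4@mrp, 800)
  }
})

test_that("the scenario grid replicates the reference coefficient table", {
  est <- refEst
  ec <- est$ectc[!duplicated(est$ectc$subset), ]
  fits <- split(ec[, c("slope", "slopeSE", "residualSD")], ec$subset)
  fits <- fits[unique(ec$subset)]
  grid <- scenarioGrid(est$rt, fits, days = c(3, 14))
  expect_length(grid, 10L)
  tab <- mrpTable(grid)
  expect_equal(tab$subset, est$ectc$subset)
  expect_equal(tab$days, est$ectc$days)
  # internal consistency: recomputing MRP from the table's own columns
  # reproduces its MRP column exactly
  redo <- vapply(seq_len(nrow(tab)), function(i)
    computeMRP(mrpScenario(24, tab$days[i], 800),
               b28 = est$rt$slope, bEctc = tab$slope[i], U = tab$U[i])@mrp,
    1)
  expect_equal(redo, tab$mrp, tolerance = 1e-12)

  # single subset, single day
  one <- scenarioGrid(est$rt, fits["pooled"], days = 14)
  expect_length(one, 1L)
  expect_error(scenarioGrid(est$rt, unname(fits)), "named")
})

test_that("an end-to-end simulated study lands near the reference MRP grid", {
  # generate -> fit pooled models per subset -> scenario grid, mirroring
  # how the reference estimates themselves were derived (pooled fits)
  ds <- simulateDataset(mockSimParams(seed = 9))
  rtFit <- fitStability(ds, "RT")
  subsets <- list(pooled = NULL, exposed_M0 = 0, exposed_M6 = 6,
                  exposed_M12 = 12, exposed_M24 = 24)
  fits <- lapply(subsets, function(m)
    fitStability(ds, "ECTC", conditioningMonths = m))
  tab <- mrpTable(scenarioGrid(rtFit, fits))
  expect_equal(nrow(tab), 10L)
  ref <- refEst$ectc
  for (i in seq_len(nrow(ref))) {
    row <- tab[tab$subset == ref$subset[i] & tab$days == ref$days[i], ]
    expect_equal(row$mrp, ref$mrp[i], tolerance = 0.05)
  }
})
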