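shortRun <- function(tEnd = 60, repeats = 4, dose = 2, seed = 1, ...) {
  runSimulation(simulationConfig("B",
                                 damage = list(type = "photon", dose = dose),
                                 tEnd = tEnd, repeats = repeats,
                                 masterSeed = seed, ...))
}

test_that("recruitment curves peak at 1 inside their window", {
  r <- shortRun()
  for (p in c("Ku", "DNA-PKcs", "CtIP", "EXO1", "Artemis")) {
    cur <- recruitmentCurve(r, p)
    win <- if (p == "Artemis") 60 else 30
    expect_equal(max(cur@mean[cur@times <= win]), 1)
    expect_true(all(cur@mean >= 0))
    expect_equal(cur@quantity, p)
  }
  expect_error(recruitmentCurve(r, "BRCA1"), "unknown protein")
  expect_error(recruitmentCurve(r, "Ku", normWindow = 0), "normWindow")
})

test_that("Ku loading is monotone early and DNA-PKcs counts both branches", {
  r <- shortRun(repeats = 6)
  ku <- recruitmentCurve(r, "Ku")
  early <- ku@mean[ku@times <= 30]
  expect_true(all(diff(early) >= -1e-9))  # no unloading before ligation
  # DNA-PKcs includes the post-resection loading: with a long horizon the
  # slow branch contributes pk_artemis_slow entries
  r2 <- shortRun(tEnd = 2000, repeats = 3)
  ev <- events(r2)
  expect_gt(sum(ev$to == "pk_artemis_slow"), 0)
  pk <- recruitmentCurve(r2, "DNA-PKcs", times = c(1, 10, 100, 1500))
  ct <- recruitmentCurve(r2, "CtIP", times = c(1, 10, 100, 1500))
  expect_true(all(is.finite(pk@mean)))
  # CtIP unloads once resection completes, so its curve falls at late times
  expect_lt(ct@mean[4], max(ct@mean))
})

test_that("repair curves report mean and SEM of unrepaired counts", {
  r <- shortRun(tEnd = 600, repeats = 4)
  rc <- repairCurve(r, times = c(0, 300, 600))
  expect_equal(rc@mean[1], mean(nSites(r)))
  expect_true(all(diff(rc@mean) <= 0))
  # single repeat: SEM reported as zero
  r1 <- shortRun(tEnd = 60, repeats = 1)
  rc1 <- repairCurve(r1, times = c(0, 60))
  expect_equal(rc1@sem, c(0, 0))
  # zero dose: flat zero curve
  r0 <- shortRun(tEnd = 60, repeats = 2, dose = 0)
  expect_true(all(repairCurve(r0, times = c(0, 30, 60))@mean == 0))
})

test_that("reduced chi-square matches hand evaluation and scales correctly", {
  simC <- kineticsCurve(c(0, 10), c(10, 5), c(0, 0), 1)
  expD <- data.frame(time_s = c(0, 10), value = c(12, 6), sem = c(2, 1))
  expect_equal(reducedChiSquare(simC, expD), 1.0)
  # simulation equal to experiment everywhere: statistic 0
  expSame <- data.frame(time_s = c(0, 5, 10), value = c(10, 7.5, 5),
                        sem = c(1, 1, 1))
  expect_equal(reducedChiSquare(simC, expSame), 0)
  # doubling the SEMs divides the statistic by 4
  exp2 <- expD; exp2$sem <- 2 * exp2$sem
  expect_equal(reducedChiSquare(simC, exp2), 0.25)
  # zero SEM cannot weight the statistic
  bad <- expD; bad$sem[1] <- 0
  expect_error(reducedChiSquare(simC, bad), "SEM")
  # times outside the simulated range are refused
  out <- data.frame(time_s = 20, value = 1, sem = 1)
  expect_error(reducedChiSquare(simC, out), "range")
})

test_that("interpolated values are bounded by the interval endpoints", {
  simC <- kineticsCurve(c(0, 10, 20), c(10, 4, 6), c(0, 0, 0), 1)
  expD <- data.frame(time_s = c(3, 12), value = c(0, 0), sem = c(1, 1))
  y <- approx(simC@times, simC@mean, xout = expD$time_s)$y
  expect_true(all(y >= 4 & y <= 10))
})

test_that("chi-square aggregation returns mean, best and worst", {
  expect_equal(aggregateChiSquare(1.0), list(mean = 1, best = 1, worst = 1))
  expect_equal(aggregateChiSquare(c(0.5, 1.5, 4.0)),
               list(mean = 2.0, best = 0.5, worst = 4.0))
  expect_equal(aggregateChiSquare(c(4.0, 0.5, 1.5)),
               aggregateChiSquare(c(0.5, 1.5, 4.0)))
  expect_error(aggregateChiSquare(numeric(0)), "at least one")
})

test_that("the residual-vs-LET fit is exact on collinear input", {
  fit <- residualVsLet(c(1, 2, 3), c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(sum(fit$residuals), 0, tolerance = 1e-10)
  # order invariance
  fit2 <- residualVsLet(c(3, 1, 2), c(6, 2, 4))
  expect_equal(fit2$slope, fit$slope)
  expect_equal(fit2$intercept, fit$intercept)
  expect_error(residualVsLet(1, 2), "distinct LET")
  expect_error(residualVsLet(c(1, 2), c(1, 2, 3)), "length")
})
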