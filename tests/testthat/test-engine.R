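quickCfg <- function(modelId = "B", dose = 1, tEnd = 600, repeats = 3,
                     seed = 1, ...) {
  simulationConfig(modelId, damage = list(type = "photon", dose = dose),
                   tEnd = tEnd, repeats = repeats, masterSeed = seed, ...)
}

test_that("zero dose yields an empty simulation", {
  r <- runSimulation(quickCfg(dose = 0, tEnd = 60, repeats = 2))
  expect_equal(nrow(events(r)), 0L)
  expect_equal(countUnrepaired(r, 60), c(0L, 0L))
  expect_true(all(samples(r)$unrepaired == 0L))
})

test_that("the same master seed reproduces event logs exactly", {
  r1 <- runSimulation(quickCfg(seed = 7))
  r2 <- runSimulation(quickCfg(seed = 7))
  expect_identical(events(r1), events(r2))
  expect_identical(complexes(r1), complexes(r2))
  r3 <- runSimulation(quickCfg(seed = 8))
  expect_false(identical(events(r1), events(r3)))
})

test_that("end conservation holds at every sampled time", {
  r <- runSimulation(quickCfg(dose = 2, tEnd = 3600, repeats = 3))
  sm <- samples(r)
  total <- 2L * nSites(r)[sm$rep]
  expect_true(all(sm$free_ends + sm$ends_in_complex + sm$ends_ligated ==
                  total))
  expect_true(all(sm$stalled_ends <= sm$free_ends))
})

test_that("the ligated count is monotone and unrepaired is non-increasing", {
  r <- runSimulation(quickCfg(dose = 2, tEnd = 7200, repeats = 3))
  for (k in 1:3) {
    sm <- samples(r)[samples(r)$rep == k, ]
    expect_true(all(diff(sm$ends_ligated) >= 0))
    expect_true(all(diff(sm$unrepaired) <= 0))
  }
})

test_that("synapsis pairing respects radius and branch rules", {
  mA <- buildModel("A"); mB <- buildModel("B")
  twoEnds <- function(d, st1, st2, br1, br2, sites = c(1, 2)) {
    data.frame(end_id = 1:2, site_id = sites, state = c(st1, st2),
               branch = c(br1, br2), x = c(0, d), y = 0, z = 0)
  }
  # two DNA-PK-loaded ends 20 nm apart pair under both models
  for (m in list(mA, mB)) {
    cx <- attemptSynapsis(twoEnds(20, "pk_fast", "pk_fast", "fast", "fast"),
                          m)
    expect_equal(nrow(cx), 1L)
    expect_true(cx$cross_origin)
  }
  # mixed branches 10 nm apart: refused by model A, allowed by model B
  mixed <- twoEnds(10, "pk_fast", "blunt_slow", "fast", "slow")
  expect_equal(nrow(attemptSynapsis(mixed, mA)), 0L)
  expect_equal(nrow(attemptSynapsis(mixed, mB)), 1L)
  # 30 nm apart: outside the capture radius for everyone
  far <- twoEnds(30, "pk_fast", "pk_fast", "fast", "fast")
  expect_equal(nrow(attemptSynapsis(far, mA)), 0L)
  expect_equal(nrow(attemptSynapsis(far, mB)), 0L)
  # resection-stage ends are eligible only in the entwined model
  res <- twoEnds(10, "pk_fast", "resected_awaiting_pk", "fast", "slow")
  expect_equal(nrow(attemptSynapsis(res, mA)), 0L)
  expect_equal(nrow(attemptSynapsis(res, mB)), 1L)
  # same-site pairs are not flagged cross-origin
  same <- twoEnds(5, "pk_fast", "pk_fast", "fast", "fast", sites = c(3, 3))
  expect_false(attemptSynapsis(same, mB)$cross_origin)
})

test_that("greedy matching pairs nearest ends first and each end only once", {
  m <- buildModel("B")
  ends <- data.frame(end_id = 1:3, site_id = 1:3, state = "pk_fast",
                     branch = "fast", x = c(0, 8, 24), y = 0, z = 0)
  cx <- attemptSynapsis(ends, m)
  expect_equal(nrow(cx), 1L)     # middle end pairs with its nearest; the
  expect_setequal(c(cx$end1, cx$end2), c(1L, 2L))  # third is left out
})

test_that("unrepaired counts follow conservation arithmetic", {
  # 10 sites; exactly 2 complexes ligated -> (20 - 4)/2 = 8 DSB equivalents
  r <- runSimulation(quickCfg(dose = 2, tEnd = 5400, repeats = 4))
  for (k in 1:4) {
    cx <- complexes(r)
    ligk <- sum(cx$rep == k & cx$status == "ligated")
    expect_equal(countUnrepaired(r, 5400)[k], nSites(r)[k] - ligk)
  }
  expect_equal(countUnrepaired(r, 0), nSites(r))
  expect_error(countUnrepaired(r, -1), "within")
  expect_error(countUnrepaired(r, 1e9), "within")
})

test_that("slow-branch commitment matches the race closed form when ungated", {
  cfg <- simulationConfig("B", damage = list(type = "photon", dose = 4),
                          tEnd = 120, repeats = 10, masterSeed = 3)
  r <- runSimulation(cfg)
  f <- slowBranchFraction(r)
  p <- raceWinProb(7.0, 1.2)
  nEnds <- 2 * sum(nSites(r))
  expect_lt(abs(f - p), 3 * sqrt(p * (1 - p) / nEnds))
})

test_that("ends that recruit CtIP stall without Artemis", {
  cfg <- simulationConfig("B", damage = list(type = "photon", dose = 2),
                          knockouts = knockoutConfig(artemisDeficient = TRUE),
                          tEnd = 300, repeats = 3, masterSeed = 2)
  r <- runSimulation(cfg)
  ev <- events(r)
  ctip <- unique(paste(ev$rep, ev$end_id)[ev$to == "ku_ctip"])
  stalled <- unique(paste(ev$rep, ev$end_id)[ev$to == "stalled"])
  expect_gt(length(ctip), 0L)
  expect_setequal(stalled, ctip)
  # and the stall happens from the resected state
  expect_true(all(ev$from[ev$to == "stalled"] == "resected_awaiting_pk"))
})

test_that("invalid damage sources are rejected before any work", {
  expect_error(simulationConfig("B", damage = list(type = "photon")), "dose")
  expect_error(simulationConfig("B", damage = list(type = "track", let = 5)),
               "nPrimaries")
  expect_error(simulationConfig("B", damage = list(foo = 1)), "type")
})

test_that("an explicit DamageSet is reused across repeats", {
  d <- fixedDamage(matrix(c(0, 0, 0, 1000, 0, 0), 2, 3, byrow = TRUE))
  cfg <- simulationConfig("B", damage = d, tEnd = 60, repeats = 3,
                          masterSeed = 1)
  r <- runSimulation(cfg)
  expect_equal(nSites(r), c(2L, 2L, 2L))
})
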