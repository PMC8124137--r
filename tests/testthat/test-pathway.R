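test_that("wild-type graphs carry every time constant exactly once", {
  for (id in c("A", "B")) {
    m <- buildModel(id)
    tr <- transitions(m)
    expect_setequal(tr$label, c("ku_recruit", "ku_inhibition", "ku_release",
                                "pk_fast", "ctip", "exo1", "resection_entry",
                                "artemis_pk_slow", "blunt"))
    expect_equal(tr$mean_time[tr$label == "ku_recruit"], 1.1)
    expect_equal(tr$mean_time[tr$label == "ku_inhibition"], 0.85)
    expect_equal(tr$mean_time[tr$label == "ku_release"], 3.8)
    expect_equal(tr$mean_time[tr$label == "pk_fast"], 1.2)
    expect_equal(tr$mean_time[tr$label == "ctip"], 7.0)
    expect_equal(tr$mean_time[tr$label == "exo1"], 1.2)
    expect_equal(tr$mean_time[tr$label == "artemis_pk_slow"], 500)
    expect_equal(m@stabilisationTime, 250)
    expect_equal(m@dissociationTime, 400)
    expect_equal(m@baseLesionTime, 300)
    expect_equal(m@ssbTime, 900)
    expect_equal(m@synapsisRadius, 25)
    # every non-terminal state that is reachable has an outgoing transition
    reach <- unique(c("naked", tr$to))
    nonterm <- setdiff(reach, c("ligated", "stalled",
                                "pk_fast", "blunt_slow"))
    expect_true(all(nonterm %in% tr$from))
  }
  a <- buildModel("A"); b <- buildModel("B")
  expect_equal(a@ligationTimeFast, 1200); expect_equal(a@ligationTimeSlow, 8000)
  expect_equal(b@ligationTimeFast, 3000); expect_equal(b@ligationTimeSlow, 3000)
  expect_equal(a@bluntTime, 60); expect_equal(b@bluntTime, 400)
  expect_false(a@crossPathwaySynapsis); expect_true(b@crossPathwaySynapsis)
  expect_false(a@slowBranchDissociation); expect_true(b@slowBranchDissociation)
  expect_error(buildModel("C"), "modelId")
})

test_that("knockouts delete or retime exactly the stated transitions", {
  mArt <- buildModel("B", knockoutConfig(artemisDeficient = TRUE))
  out <- availableTransitions("resected_awaiting_pk", list(), mArt)
  expect_equal(nrow(out), 0L)   # resected ends stall without Artemis
  # all other states keep their transitions
  expect_equal(nrow(transitions(mArt)), nrow(transitions(buildModel("B"))) - 1L)

  mX <- buildModel("B", knockoutConfig(xlfDeficient = TRUE))
  expect_equal(mX@dissociationTime, 11.0)
  expect_identical(transitions(mX), transitions(buildModel("B")))

  mC <- buildModel("B", knockoutConfig(ctipInhibited = TRUE))
  kb <- availableTransitions("ku_bound", list(), mC)
  expect_identical(kb$label, "pk_fast")

  # CtIP co-inhibition removes the stalling path of the Artemis knockout
  mRescue <- buildModel("B", knockoutConfig(artemisDeficient = TRUE,
                                            ctipInhibited = TRUE))
  expect_false("ctip" %in% transitions(mRescue)$label)
  expect_identical(availableTransitions("ku_bound", list(), mRescue)$label,
                   "pk_fast")
})

test_that("chromatin gating restricts ku_bound exits per chromatin label", {
  m <- buildModel("A", gating = chromatinGating(enabled = TRUE))
  eu <- availableTransitions("ku_bound", list(chromatin = "euchromatin"), m)
  expect_identical(eu$label, "pk_fast")
  hcYes <- availableTransitions(
    "ku_bound", list(chromatin = "heterochromatin", pkEligible = TRUE), m)
  expect_identical(hcYes$label, "pk_fast")
  hcNo <- availableTransitions(
    "ku_bound", list(chromatin = "heterochromatin", pkEligible = FALSE), m)
  expect_identical(hcNo$label, "ctip")
  # gating disabled: the full race is on regardless of chromatin
  m0 <- buildModel("A")
  both <- availableTransitions("ku_bound", list(chromatin = "euchromatin"), m0)
  expect_setequal(both$label, c("pk_fast", "ctip"))
})

test_that("terminal states have no transitions and empty races stall", {
  m <- buildModel("B")
  expect_equal(nrow(availableTransitions("ligated", list(), m)), 0L)
  expect_equal(nrow(availableTransitions("stalled", list(), m)), 0L)
  expect_error(sampleTransition(transitions(m)[0, ]), "stall")
})

test_that("exponential races reproduce their closed-form win frequencies", {
  m <- buildModel("B")
  drawWinner <- function(cands, n) {
    vapply(seq_len(n), function(i) sampleTransition(cands)$transition$label,
           character(1))
  }
  set.seed(1)
  # single transition: sample mean equals the time constant
  one <- transitions(m)[transitions(m)$label == "ctip", ]
  w <- vapply(1:20000, function(i) sampleTransition(one)$waitingTime,
              numeric(1))
  expect_lt(abs(mean(w) - 7.0) / 7.0, 0.03)
  expect_true(all(w > 0))

  # DNA-PKcs vs CtIP: P(ctip) = (1/7)/(1/1.2 + 1/7) ~ 0.146
  kb <- availableTransitions("ku_bound", list(), m)
  n <- 50000
  winners <- drawWinner(kb, n)
  p <- raceWinProb(7.0, 1.2)
  expect_lt(abs(mean(winners == "ctip") - p), 3 * sqrt(p * (1 - p) / n))

  # recruitment vs inhibition: P(recruit) = (1/1.1)/(1/1.1 + 1/0.85) ~ 0.436
  nk <- availableTransitions("naked", list(), m)
  winners <- drawWinner(nk, n)
  p <- raceWinProb(1.1, 0.85)
  expect_lt(abs(mean(winners == "ku_recruit") - p), 3 * sqrt(p * (1 - p) / n))

  # XLF-deficient synapsis race: P(dissociate) = (1/11)/(1/11 + 1/250) ~ 0.958
  race <- data.frame(from = "x", to = c("d", "s"), mean_time = c(11, 250),
                     label = c("dissoc", "stab"))
  winners <- drawWinner(race, n)
  p <- raceWinProb(11, 250)
  expect_lt(abs(mean(winners == "dissoc") - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("the zero-mean bookkeeping step always wins immediately", {
  m <- buildModel("B")
  cands <- availableTransitions("ku_ctip_exo1", list(), m)
  res <- sampleTransition(cands)
  expect_equal(res$waitingTime, 0)
  expect_equal(res$transition$to, "resected_awaiting_pk")
})
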