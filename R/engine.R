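## Coupled motion + state-transition simulation engine. Each DSB site is split
## into two independently moving ends that progress through the pathway graph
## by exponential races; synapsis-eligible ends within the capture radius pair
## into complexes that race stabilisation vs dissociation and then ligate.
## In the entwined model (B) resection-stage ends are already eligible and
## Artemis end-processing continues inside the complex; ligation waits until
## both ends are ligatable (fast ends with cleaned lesions, or blunt ends).

.SC <- stats::setNames(seq_along(.STATES), .STATES)

#' Create a simulation configuration
#'
#' @param modelId "A" or "B".
#' @param damage either a \linkS4class{DamageSet} (the same damage is reused
#'   in every repeat) or a generator parameter list redrawn per repeat:
#'   \code{list(type = "photon", dose, dsbPerGy = 25, hcFraction = 0,
#'   complexity = list(baseMean = 0.5, ssbMean = 0.3))} or
#'   \code{list(type = "track", let, nPrimaries, hcFraction = 0)}.
#' @param knockouts a \linkS4class{KnockoutConfig}.
#' @param gating a \linkS4class{ChromatinGating}.
#' @param tEnd horizon in s (default 24 h).
#' @param repeats number of repeats (default 70).
#' @param motion a \linkS4class{CTRWParams}.
#' @param masterSeed integer; repeat k runs under \code{masterSeed + k}, so
#'   keep \code{masterSeed + repeats} below 2^31.
#' @param sampleTimes sampling grid (s); the default is a dense 0-60 s grid
#'   (0.5 s spacing, for recruitment curves) plus the usual foci time points
#'   (0.25, 0.5, 1, 2, 4, 6, 8, 24 h), truncated to \code{tEnd}.
#' @param nucleus a \linkS4class{Nucleus}.
#' @param tickEarly,tickGrowth,tickMax,tickSwitch motion/reaction tick
#'   schedule: fixed \code{tickEarly} until \code{tickSwitch}, then geometric
#'   growth by factor \code{tickGrowth} capped at \code{tickMax}.
#' @return A \linkS4class{SimulationConfig}.
#' @examples
#' simulationConfig("B", damage = list(type = "photon", dose = 1),
#'                  tEnd = 60, repeats = 2, masterSeed = 1)
#' @export
simulationConfig <- function(modelId = "B",
                             damage = list(type = "photon", dose = 2),
                             knockouts = knockoutConfig(),
                             gating = chromatinGating(),
                             tEnd = 86400, repeats = 70L,
                             motion = ctrwParams(), masterSeed = 1L,
                             sampleTimes = NULL, nucleus = .defaultNucleus(),
                             tickEarly = 0.1, tickGrowth = 1.05,
                             tickMax = 10, tickSwitch = 100) {
  if (is.null(sampleTimes)) {
    sampleTimes <- sort(unique(c(
      seq(0, min(60, tEnd), by = 0.5),
      c(900, 1800, 3600, 7200, 14400, 21600, 28800, 86400), tEnd
    )))
    sampleTimes <- sampleTimes[sampleTimes <= tEnd]
  }
  if (is.list(damage) && !is(damage, "DamageSet")) {
    if (is.null(damage$type) || !damage$type %in% c("photon", "track")) {
      stop("damage generator list must have type 'photon' or 'track'")
    }
    if (damage$type == "photon" && is.null(damage$dose)) {
      stop("photon damage source needs a dose")
    }
    if (damage$type == "track" &&
        (is.null(damage$let) || is.null(damage$nPrimaries))) {
      stop("track damage source needs let and nPrimaries")
    }
  }
  new("SimulationConfig", modelId = modelId, knockouts = knockouts,
      gating = gating, damage = damage, tEnd = as.numeric(tEnd),
      repeats = as.integer(repeats), motion = motion,
      masterSeed = as.integer(masterSeed),
      sampleTimes = as.numeric(sampleTimes), nucleus = nucleus,
      tickEarly = tickEarly, tickGrowth = tickGrowth, tickMax = tickMax,
      tickSwitch = tickSwitch)
}

## Synapsis-eligible pathway states. Model A pairs only fully prepared ends
## (DNA-PK-loaded fast ends, blunt slow ends); in the entwined model B ends
## in the resection stages (EXO1 loaded onward) may also join complexes.
.eligStates <- function(model) {
  base <- c("pk_fast", "blunt_slow")
  if (model@crossPathwaySynapsis) {
    base <- c(base, "ku_ctip_exo1", "resected_awaiting_pk", "pk_artemis_slow")
  }
  unname(.SC[base])
}

## Greedy nearest-pair matching among synapsis-eligible ends. pos: m x 3,
## branch: integer (1 fast, 2 slow), site: site ids. Returns a matrix with
## columns i, j (row indices into the inputs), d, cross.
.pairEligible <- function(pos, branch, site, radius, sameBranchOnly) {
  m <- nrow(pos)
  if (m < 2L) return(NULL)
  dmat <- as.matrix(stats::dist(pos))
  dmat[upper.tri(dmat, diag = TRUE)] <- Inf
  ok <- which(dmat <= radius, arr.ind = TRUE)
  if (nrow(ok) == 0L) return(NULL)
  if (sameBranchOnly) {
    keep <- branch[ok[, 1]] == branch[ok[, 2]]
    ok <- ok[keep, , drop = FALSE]
    if (nrow(ok) == 0L) return(NULL)
  }
  d <- dmat[ok]
  ord <- order(d, ok[, 2], ok[, 1])
  used <- logical(m)
  out <- matrix(0, nrow = 0, ncol = 4,
                dimnames = list(NULL, c("i", "j", "d", "cross")))
  for (k in ord) {
    i <- ok[k, 1]; j <- ok[k, 2]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    out <- rbind(out, c(i, j, d[k], as.numeric(site[i] != site[j])))
  }
  out
}

#' Attempt synapsis among free eligible ends
#'
#' Pairs any two synapsis-eligible ends lying within the model's capture
#' radius (25 nm), by greedy nearest-distance matching; each end joins at
#' most one complex. Eligible states are \code{pk_fast} and \code{blunt_slow}
#' in model A, which additionally requires both ends to be on the same
#' branch. Model B allows cross-branch pairing and also admits ends in the
#' resection stages (\code{ku_ctip_exo1}, \code{resected_awaiting_pk},
#' \code{pk_artemis_slow}), whose end-processing then completes inside the
#' complex.
#'
#' @param freeEnds data.frame with columns \code{end_id}, \code{site_id},
#'   \code{state}, \code{branch} ("fast"/"slow"), \code{x}, \code{y},
#'   \code{z}.
#' @param model a \linkS4class{PathwayModel}.
#' @return data.frame of complexes formed (\code{end1}, \code{end2},
#'   \code{distance}, \code{cross_origin}); zero rows if none.
#' @examples
#' ends <- data.frame(end_id = 1:2, site_id = c(1, 1),
#'                    state = "pk_fast", branch = "fast",
#'                    x = c(0, 10), y = 0, z = 0)
#' attemptSynapsis(ends, buildModel("B"))
#' @export
attemptSynapsis <- function(freeEnds, model) {
  stopifnot(is.data.frame(freeEnds), is(model, "PathwayModel"))
  elig <- .SC[freeEnds$state] %in% .eligStates(model)
  fe <- freeEnds[elig, , drop = FALSE]
  empty <- data.frame(end1 = integer(0), end2 = integer(0),
                      distance = numeric(0), cross_origin = logical(0))
  if (nrow(fe) < 2L) return(empty)
  br <- ifelse(fe$branch == "fast", 1L, 2L)
  pr <- .pairEligible(as.matrix(fe[, c("x", "y", "z")]), br, fe$site_id,
                      model@synapsisRadius, !model@crossPathwaySynapsis)
  if (is.null(pr)) return(empty)
  data.frame(end1 = fe$end_id[pr[, "i"]], end2 = fe$end_id[pr[, "j"]],
             distance = pr[, "d"], cross_origin = pr[, "cross"] > 0)
}

## Precompute, per (state, gating-variant), the outgoing candidate sets as
## plain vectors, by calling availableTransitions once per combination.
.candidateTable <- function(model) {
  asCand <- function(df) list(to = unname(.SC[df$to]), mean = df$mean_time)
  tbl <- vector("list", length(.STATES))
  for (s in seq_along(.STATES)) {
    st <- .STATES[s]
    if (st == "ku_bound") next
    tbl[[s]] <- asCand(availableTransitions(st, list(), model))
  }
  ku <- list(
    ungated = asCand({
      m2 <- model; m2@gating@enabled <- FALSE
      availableTransitions("ku_bound", list(), m2)
    }),
    eu = asCand(availableTransitions(
      "ku_bound", list(chromatin = "euchromatin"), model)),
    hc_pk = asCand(availableTransitions(
      "ku_bound", list(chromatin = "heterochromatin", pkEligible = TRUE),
      model)),
    hc_ctip = asCand(availableTransitions(
      "ku_bound", list(chromatin = "heterochromatin", pkEligible = FALSE),
      model))
  )
  list(states = tbl, ku = ku)
}

## One repeat of the coupled simulation. All randomness comes from the
## ambient RNG stream (the caller seeds it).
.runRepeat <- function(damage, model, cfg) {
  s <- damage@sites
  n <- nrow(s)
  nEnds <- 2L * n
  sampleTimes <- cfg@sampleTimes
  motion <- cfg@motion
  nuc <- cfg@nucleus

  ## --- end state ---
  ## `state` is the pathway position; synaptic membership is tracked
  ## separately so that end-processing can continue inside a complex.
  site <- rep(seq_len(n), each = 2L)
  state <- rep.int(.SC[["naked"]], nEnds)
  branch <- integer(nEnds)                 # 0 none, 1 fast, 2 slow
  hc <- rep(s$chromatin == "heterochromatin", each = 2L)
  pkElig <- stats::runif(nEnds) < model@gating@pkRecruitProbabilityHC
  baseN <- as.integer(rbind(s$lesions_a_base, s$lesions_b_base))
  ssbN <- as.integer(rbind(s$lesions_a_ssb, s$lesions_b_ssb))
  pos <- matrix(0, nEnds, 3)
  if (n > 0L) {
    pos[, 1] <- rep(s$x, each = 2L)
    pos[, 2] <- rep(s$y, each = 2L)
    pos[, 3] <- rep(s$z, each = 2L)
  }
  trap <- sampleWaitTime(nEnds, motion)
  refr <- rep.int(-Inf, nEnds)
  inCx <- integer(nEnds)
  nextT <- rep.int(Inf, nEnds)
  nextTo <- integer(nEnds)
  baseClock <- vector("list", nEnds)
  ssbClock <- vector("list", nEnds)

  cand <- .candidateTable(model)
  kuVariant <- if (!model@gating@enabled) rep.int(1L, nEnds) else
    ifelse(!hc, 2L, ifelse(pkElig, 3L, 4L))
  kuCands <- list(cand$ku$ungated, cand$ku$eu, cand$ku$hc_pk,
                  cand$ku$hc_ctip)
  eligSet <- .eligStates(model)

  S_KU <- .SC[["ku_bound"]]; S_CTIP <- .SC[["ku_ctip"]]
  S_PKF <- .SC[["pk_fast"]]; S_BLUNT <- .SC[["blunt_slow"]]
  S_SYN <- .SC[["in_synapsis"]]; S_STAB <- .SC[["stable_synapsis"]]
  S_LIG <- .SC[["ligated"]]; S_STALL <- .SC[["stalled"]]

  ## --- event log (growable) ---
  logCap <- max(256L, 16L * nEnds)
  logT <- numeric(logCap); logE <- integer(logCap)
  logFrom <- integer(logCap); logTo <- integer(logCap)
  nLog <- 0L
  logEvent <- function(t, e, from, to) {
    if (nLog == logCap) {
      logCap <<- 2L * logCap
      length(logT) <<- logCap; length(logE) <<- logCap
      length(logFrom) <<- logCap; length(logTo) <<- logCap
    }
    nLog <<- nLog + 1L
    logT[nLog] <<- t; logE[nLog] <<- e
    logFrom[nLog] <<- from; logTo[nLog] <<- to
  }

  ## --- complexes (growable parallel vectors) ---
  cxCap <- max(8L, nEnds)
  cE1 <- integer(cxCap); cE2 <- integer(cxCap); cCross <- logical(cxCap)
  cStage <- integer(cxCap)                  # 0 dissolved 1 formed 2 stable 3 ligated
  cTF <- numeric(cxCap); cTS <- rep.int(NA_real_, cxCap)
  cTL <- rep.int(NA_real_, cxCap); cTD <- rep.int(NA_real_, cxCap)
  cNextT <- rep.int(Inf, cxCap); cNextType <- integer(cxCap)  # 1 resolve 2 ligate
  cDissWins <- logical(cxCap)
  cLigT <- rep.int(NA_real_, cxCap)          # sampled ligation clock
  cPos <- matrix(0, cxCap, 3); cTrap <- numeric(cxCap)
  nCx <- 0L
  growCx <- function() {
    cxCap2 <- 2L * cxCap
    length(cE1) <<- cxCap2; length(cE2) <<- cxCap2; length(cCross) <<- cxCap2
    length(cStage) <<- cxCap2; length(cTF) <<- cxCap2; length(cTS) <<- cxCap2
    length(cTL) <<- cxCap2; length(cTD) <<- cxCap2
    cNextT2 <- rep.int(Inf, cxCap2); cNextT2[seq_len(cxCap)] <- cNextT
    cNextT <<- cNextT2
    length(cNextType) <<- cxCap2; length(cDissWins) <<- cxCap2
    length(cLigT) <<- cxCap2
    cPos2 <- matrix(0, cxCap2, 3); cPos2[seq_len(cxCap), ] <- cPos
    cPos <<- cPos2
    length(cTrap) <<- cxCap2
    cxCap <<- cxCap2
  }

  ## mean ligation time for a complex given its member branches
  ligMean <- function(b1, b2) {
    if (b1 == 1L && b2 == 1L) model@ligationTimeFast else
      model@ligationTimeSlow   # slow-slow, or mixed (model B only, 3000 s)
  }
  ## an end is ready for ligation once fully prepared and lesion-free
  endReady <- function(e) {
    (state[e] == S_PKF || state[e] == S_BLUNT)
  }
  lesionReady <- function(id) {
    max(0, unlist(baseClock[c(cE1[id], cE2[id])]),
        unlist(ssbClock[c(cE1[id], cE2[id])]))
  }
  armLigation <- function(id, tNow) {
    if (endReady(cE1[id]) && endReady(cE2[id])) {
      cNextT[id] <<- max(cLigT[id], tNow, lesionReady(id))
    } else {
      cNextT[id] <<- Inf      # re-armed when the lagging end becomes ready
    }
    cNextType[id] <<- 2L
  }

  scheduleEnd <- function(i, te) {
    cnd <- if (state[i] == S_KU) kuCands[[kuVariant[i]]] else
      cand$states[[state[i]]]
    k <- length(cnd$mean)
    if (k == 0L) {                      # stall: no path forward
      logEvent(te, i, state[i], S_STALL)
      state[i] <<- S_STALL
      nextT[i] <<- Inf
      return(invisible())
    }
    zero <- which(cnd$mean == 0)
    if (length(zero)) {
      w <- 0; j <- zero[1L]
    } else {
      ts <- stats::rexp(k, rate = 1 / cnd$mean)
      j <- which.min(ts); w <- ts[j]
    }
    nextT[i] <<- te + w
    nextTo[i] <<- cnd$to[j]
  }

  applyEndEvent <- function(i) {
    te <- nextT[i]; to <- nextTo[i]
    logEvent(te, i, state[i], to)
    state[i] <<- to
    if (to == S_PKF) {
      branch[i] <<- 1L
      nextT[i] <<- Inf
    } else if (to == S_BLUNT) {
      baseN[i] <<- 0L; ssbN[i] <<- 0L   # resection leaves a clean blunt end
      nextT[i] <<- Inf
      id <- inCx[i]                      # end matured inside its complex:
      if (id > 0L && cStage[id] == 2L) armLigation(id, te)
    } else {
      if (to == S_CTIP) branch[i] <<- 2L
      scheduleEnd(i, te)
    }
  }

  formComplex <- function(i, j, tNow) {
    if (nCx == cxCap) growCx()
    nCx <<- nCx + 1L; id <- nCx
    cE1[id] <<- i; cE2[id] <<- j
    cCross[id] <<- site[i] != site[j]
    cStage[id] <<- 1L; cTF[id] <<- tNow
    cTS[id] <<- NA_real_; cTL[id] <<- NA_real_; cTD[id] <<- NA_real_
    cLigT[id] <<- NA_real_
    mid <- (pos[i, ] + pos[j, ]) / 2
    cPos[id, ] <<- mid
    cTrap[id] <<- tNow + sampleWaitTime(1L, motion)
    inCx[i] <<- id; inCx[j] <<- id
    logEvent(tNow, i, state[i], S_SYN); logEvent(tNow, j, state[j], S_SYN)
    ## stabilisation vs dissociation race (dissociation disabled for
    ## model-A slow-slow complexes)
    dissocAllowed <- model@slowBranchDissociation ||
      !(branch[i] == 2L && branch[j] == 2L)
    tStab <- tNow + stats::rexp(1L, 1 / model@stabilisationTime)
    tDiss <- if (dissocAllowed)
      tNow + stats::rexp(1L, 1 / model@dissociationTime) else Inf
    cDissWins[id] <<- tDiss < tStab
    cNextT[id] <<- min(tStab, tDiss); cNextType[id] <<- 1L
    ## lesion-removal clocks on fast-branch ends
    for (e in c(i, j)) {
      if (branch[e] == 1L) {
        if (baseN[e] > 0L) {
          baseClock[[e]] <<- tNow +
            stats::rexp(baseN[e], 1 / model@baseLesionTime)
        }
        if (ssbN[e] > 0L) {
          ssbClock[[e]] <<- tNow + stats::rexp(ssbN[e], 1 / model@ssbTime)
        }
      }
    }
    invisible(id)
  }

  applyComplexEvent <- function(id, tickEnd) {
    tc <- cNextT[id]
    i <- cE1[id]; j <- cE2[id]
    if (cNextType[id] == 1L && cDissWins[id]) {       # dissociation
      cStage[id] <<- 0L; cTD[id] <<- tc; cNextT[id] <<- Inf
      for (e in c(i, j)) {
        logEvent(tc, e, S_SYN, state[e])
        inCx[e] <<- 0L
        pos[e, ] <<- cPos[id, ]
        trap[e] <<- tc + sampleWaitTime(1L, motion)
        refr[e] <<- tickEnd              # one-tick refractory period
        ## lesions whose clocks completed are gone; the rest stay pending
        bc <- baseClock[[e]]; sc <- ssbClock[[e]]
        if (!is.null(bc)) { baseN[e] <<- sum(bc > tc); baseClock[e] <<- list(NULL) }
        if (!is.null(sc)) { ssbN[e] <<- sum(sc > tc); ssbClock[e] <<- list(NULL) }
      }
    } else if (cNextType[id] == 1L) {                  # stabilisation
      cStage[id] <<- 2L; cTS[id] <<- tc
      logEvent(tc, i, S_SYN, S_STAB); logEvent(tc, j, S_SYN, S_STAB)
      cLigT[id] <<- tc + stats::rexp(1L, 1 / ligMean(branch[i], branch[j]))
      armLigation(id, tc)
    } else {                                           # ligation
      cStage[id] <<- 3L; cTL[id] <<- cNextT[id]
      logEvent(cNextT[id], i, S_STAB, S_LIG)
      logEvent(cNextT[id], j, S_STAB, S_LIG)
      state[i] <<- S_LIG; state[j] <<- S_LIG
      nextT[i] <<- Inf; nextT[j] <<- Inf
      baseN[i] <<- 0L; ssbN[i] <<- 0L; baseN[j] <<- 0L; ssbN[j] <<- 0L
      baseClock[i] <<- list(NULL); ssbClock[i] <<- list(NULL)
      baseClock[j] <<- list(NULL); ssbClock[j] <<- list(NULL)
      cNextT[id] <<- Inf
    }
  }

  ## --- sampling ---
  nsamp <- length(sampleTimes)
  smFree <- integer(nsamp); smStalled <- integer(nsamp)
  smInCx <- integer(nsamp); smLig <- integer(nsamp); smUnrep <- integer(nsamp)
  recordSample <- function(k) {
    st <- cStage[seq_len(nCx)]
    lig2 <- 2L * sum(st == 3L)
    act2 <- 2L * sum(st == 1L | st == 2L)
    smFree[k] <<- nEnds - lig2 - act2
    smStalled[k] <<- sum(state == S_STALL & inCx == 0L)
    smInCx[k] <<- act2
    smLig[k] <<- lig2
    smUnrep[k] <<- n - lig2 %/% 2L
  }
  sampleIdx <- 1L
  while (sampleIdx <= nsamp && sampleTimes[sampleIdx] <= 0) {
    recordSample(sampleIdx); sampleIdx <- sampleIdx + 1L
  }

  ## initial end scheduling
  for (i in seq_len(nEnds)) scheduleEnd(i, 0)

  now <- 0; dt <- cfg@tickEarly
  while (now < cfg@tEnd && n > 0L) {
    tickEnd <- min(now + dt, cfg@tEnd)

    ## end- and complex-level events (chains may fire repeatedly in a tick,
    ## and an end event may arm a complex event or vice versa)
    changed <- FALSE
    repeat {
      due <- which(nextT <= tickEnd)
      dueC <- which(cNextT[seq_len(nCx)] <= tickEnd)
      if (length(due) == 0L && length(dueC) == 0L) break
      changed <- TRUE
      if (length(due)) for (i in due[order(nextT[due])]) applyEndEvent(i)
      dueC <- which(cNextT[seq_len(nCx)] <= tickEnd)
      if (length(dueC)) {
        for (id in dueC[order(cNextT[dueC])]) applyComplexEvent(id, tickEnd)
      }
    }

    ## motion: free non-terminal ends and active complexes
    mvE <- which(inCx == 0L & state != S_LIG & state != S_STALL &
                 trap <= tickEnd)
    if (length(mvE)) {
      changed <- TRUE
      pos[mvE, ] <- .reflectInside(
        pos[mvE, , drop = FALSE] + jumpDisplacement(length(mvE), motion), nuc)
      trap[mvE] <- tickEnd + sampleWaitTime(length(mvE), motion)
    }
    actC <- which(cStage[seq_len(nCx)] == 1L | cStage[seq_len(nCx)] == 2L)
    mvC <- actC[cTrap[actC] <= tickEnd]
    if (length(mvC)) {
      cPos[mvC, ] <- .reflectInside(
        cPos[mvC, , drop = FALSE] + jumpDisplacement(length(mvC), motion),
        nuc)
      cTrap[mvC] <- tickEnd + sampleWaitTime(length(mvC), motion)
    }

    ## synapsis attempts among eligible free ends (re-check also when a
    ## refractory period from a dissociation has just expired)
    elig <- which(inCx == 0L & state %in% eligSet & refr < tickEnd)
    if (length(elig) >= 2L && (changed || any(refr[elig] >= now))) {
      pr <- .pairEligible(pos[elig, , drop = FALSE], branch[elig],
                          site[elig], model@synapsisRadius,
                          !model@crossPathwaySynapsis)
      if (!is.null(pr)) {
        for (r in seq_len(nrow(pr))) {
          formComplex(elig[pr[r, "i"]], elig[pr[r, "j"]], tickEnd)
        }
      }
    }

    ## record samples falling in this tick
    while (sampleIdx <= nsamp && sampleTimes[sampleIdx] <= tickEnd) {
      recordSample(sampleIdx); sampleIdx <- sampleIdx + 1L
    }

    now <- tickEnd
    if (now >= cfg@tickSwitch) dt <- min(dt * cfg@tickGrowth, cfg@tickMax)

    ## early exit when the state can no longer change: no pending end or
    ## complex events and no possible new pairing
    if (all(cNextT[seq_len(nCx)] == Inf) && all(nextT == Inf)) {
      eligNow <- which(inCx == 0L & state %in% eligSet)
      pairPossible <- if (model@crossPathwaySynapsis) {
        length(eligNow) >= 2L
      } else {
        sum(branch[eligNow] == 1L) >= 2L || sum(branch[eligNow] == 2L) >= 2L
      }
      if (!pairPossible) break
    }
  }
  while (sampleIdx <= nsamp) { recordSample(sampleIdx); sampleIdx <- sampleIdx + 1L }

  idx <- seq_len(nLog)
  cxIdx <- seq_len(nCx)
  statusLab <- c("dissolved", "formed", "stable", "ligated")
  list(
    events = data.frame(t = logT[idx], end_id = logE[idx],
                        from = .STATES[logFrom[idx]],
                        to = .STATES[logTo[idx]], stringsAsFactors = FALSE),
    complexes = data.frame(
      complex_id = cxIdx, end1 = cE1[cxIdx], end2 = cE2[cxIdx],
      cross_origin = cCross[cxIdx], t_formed = cTF[cxIdx],
      t_stable = cTS[cxIdx], t_ligated = cTL[cxIdx],
      t_dissolved = cTD[cxIdx],
      status = statusLab[cStage[cxIdx] + 1L], stringsAsFactors = FALSE),
    samples = data.frame(t = sampleTimes, free_ends = smFree,
                         stalled_ends = smStalled, ends_in_complex = smInCx,
                         ends_ligated = smLig, unrepaired = smUnrep),
    ends = data.frame(end_id = seq_len(nEnds), site_id = site,
                      chromatin = ifelse(hc, "heterochromatin",
                                         "euchromatin"),
                      pk_eligible = pkElig,
                      lesions_base = as.integer(rbind(s$lesions_a_base,
                                                      s$lesions_b_base)),
                      lesions_ssb = as.integer(rbind(s$lesions_a_ssb,
                                                     s$lesions_b_ssb)),
                      stringsAsFactors = FALSE),
    nSites = n
  )
}

.damageForRepeat <- function(cfg) {
  d <- cfg@damage
  if (is(d, "DamageSet")) return(d)
  if (d$type == "photon") {
    dmg <- generatePhotonDamage(
      dose = d$dose, nucleus = cfg@nucleus,
      dsbPerGy = if (is.null(d$dsbPerGy)) 25 else d$dsbPerGy,
      complexity = if (is.null(d$complexity))
        list(baseMean = 0.5, ssbMean = 0.3) else d$complexity)
  } else {
    dmg <- generateTrackDamage(let = d$let, nPrimaries = d$nPrimaries,
                               nucleus = cfg@nucleus)
  }
  hcf <- if (is.null(d$hcFraction)) 0 else d$hcFraction
  if (hcf > 0) dmg <- assignChromatin(dmg, hcf)
  dmg
}

#' Run the repair simulation
#'
#' Runs \code{repeats} independent repeats of the coupled motion +
#' state-transition simulation from the configured damage source to
#' \code{tEnd}. Both ends of each DSB start co-located at the site position.
#' Repeat k is seeded with \code{masterSeed + k}, so a master seed fully
#' reproduces the result.
#'
#' @param config a \linkS4class{SimulationConfig}.
#' @return A \linkS4class{SimulationResult}.
#' @examples
#' cfg <- simulationConfig("B", damage = list(type = "photon", dose = 0.5),
#'                         tEnd = 30, repeats = 2, masterSeed = 1)
#' runSimulation(cfg)
#' @export
runSimulation <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  model <- buildModel(config@modelId, config@knockouts, config@gating)
  evL <- cxL <- smL <- enL <- vector("list", config@repeats)
  nS <- integer(config@repeats)
  for (k in seq_len(config@repeats)) {
    set.seed(config@masterSeed + k)
    dmg <- .damageForRepeat(config)
    r <- .runRepeat(dmg, model, config)
    r$events$rep <- rep.int(k, nrow(r$events))
    r$complexes$rep <- rep.int(k, nrow(r$complexes))
    r$samples$rep <- rep.int(k, nrow(r$samples))
    r$ends$rep <- rep.int(k, nrow(r$ends))
    evL[[k]] <- r$events; cxL[[k]] <- r$complexes; smL[[k]] <- r$samples
    enL[[k]] <- r$ends; nS[k] <- r$nSites
  }
  new("SimulationResult",
      events = do.call(rbind, evL), complexes = do.call(rbind, cxL),
      samples = do.call(rbind, smL), ends = do.call(rbind, enL),
      nSites = nS, config = config)
}

#' Count unrepaired DSB equivalents at a time point
#'
#' The number of DSB ends not yet in a ligated complex, divided by two,
#' evaluated per repeat from the exact ligation timestamps.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param t time in s, within [0, tEnd].
#' @return Integer vector of unrepaired DSB equivalents, one per repeat.
#' @examples
#' cfg <- simulationConfig("B", damage = list(type = "photon", dose = 0.5),
#'                         tEnd = 30, repeats = 2, masterSeed = 1)
#' countUnrepaired(runSimulation(cfg), 30)
#' @export
countUnrepaired <- function(result, t) {
  stopifnot(is(result, "SimulationResult"), length(t) == 1L)
  if (!is.finite(t) || t < 0 || t > result@config@tEnd) {
    stop("t must lie within [0, tEnd]")
  }
  cx <- result@complexes
  lig <- cx[cx$status == "ligated" & !is.na(cx$t_ligated) & cx$t_ligated <= t,
            , drop = FALSE]
  nLig <- tabulate(lig$rep, nbins = result@config@repeats)
  result@nSites - nLig
}
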