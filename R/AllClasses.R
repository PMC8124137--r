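#' @import methods
NULL

## Repair-state vocabulary shared by the pathway and engine code. Order matters
## only for compact integer coding inside the engine; names are the contract.
.STATES <- c(
  "naked", "inhibited", "ku_bound", "ku_ctip", "ku_ctip_exo1",
  "resected_awaiting_pk", "pk_artemis_slow", "blunt_slow", "pk_fast",
  "in_synapsis", "stable_synapsis", "ligated", "stalled"
)
.TERMINAL_STATES <- c("ligated", "stalled")
.ELIGIBLE_STATES <- c("pk_fast", "blunt_slow")
.PROTEINS <- c("Ku", "DNA-PKcs", "CtIP", "EXO1", "Artemis")

#' Spherical cell nucleus
#'
#' Container for the simulation volume: a sphere of given radius (nm) centred
#' at \code{centre}. All damage positions and all diffusing objects are kept
#' strictly inside this sphere.
#'
#' @slot radius numeric(1), nucleus radius in nm.
#' @slot centre numeric(3), centre coordinates in nm.
#' @export
setClass("Nucleus", representation(radius = "numeric", centre = "numeric"))

setValidity("Nucleus", function(object) {
  if (length(object@radius) != 1L || !is.finite(object@radius) ||
      object@radius <= 0) {
    return("radius must be a single positive number (nm)")
  }
  if (length(object@centre) != 3L || any(!is.finite(object@centre))) {
    return("centre must be a finite 3-vector (nm)")
  }
  TRUE
})

#' Create a nucleus
#'
#' @param radius nucleus radius in nm; the default 5000 nm corresponds to a
#'   10 micron diameter G0/G1 nucleus.
#' @param centre centre of the sphere in nm.
#' @return A \linkS4class{Nucleus} object.
#' @examples
#' nucleus()
#' @export
nucleus <- function(radius = 5000, centre = c(0, 0, 0)) {
  new("Nucleus", radius = as.numeric(radius), centre = as.numeric(centre))
}

#' Set of initial DSB sites
#'
#' One row of \code{sites} per double-strand break: spatial position (nm,
#' Cartesian, nucleus centred at the origin), chromatin label and the extra
#' lesion load carried by each of the two ends (additional base lesions and
#' single-strand breaks beyond the break itself).
#'
#' @slot sites data.frame with columns \code{site_id}, \code{x}, \code{y},
#'   \code{z}, \code{chromatin} ("heterochromatin"/"euchromatin"),
#'   \code{lesions_a_base}, \code{lesions_a_ssb}, \code{lesions_b_base},
#'   \code{lesions_b_ssb}.
#' @slot dose absorbed dose in Gy.
#' @slot quality radiation quality label, "photon" or "proton-like".
#' @slot let linear energy transfer in keV/um (NA for photons).
#' @slot seed integer seed used by the generator (NA if generated from the
#'   ambient RNG stream).
#' @slot nucleus the \linkS4class{Nucleus} the positions live in.
#' @export
setClass("DamageSet", representation(
  sites = "data.frame", dose = "numeric", quality = "character",
  let = "numeric", seed = "integer", nucleus = "Nucleus"
))

.SITE_COLS <- c(
  "site_id", "x", "y", "z", "chromatin",
  "lesions_a_base", "lesions_a_ssb", "lesions_b_base", "lesions_b_ssb"
)

setValidity("DamageSet", function(object) {
  s <- object@sites
  if (!all(.SITE_COLS %in% names(s))) {
    return(paste("sites must contain columns:", paste(.SITE_COLS, collapse = ", ")))
  }
  if (length(object@dose) != 1L || is.na(object@dose) || object@dose < 0) {
    return("dose must be a single non-negative number (Gy)")
  }
  if (!object@quality %in% c("photon", "proton-like")) {
    return("quality must be 'photon' or 'proton-like'")
  }
  if (nrow(s) > 0) {
    if (!all(s$chromatin %in% c("heterochromatin", "euchromatin"))) {
      return("chromatin labels must be 'heterochromatin' or 'euchromatin'")
    }
    les <- as.matrix(s[, c("lesions_a_base", "lesions_a_ssb",
                           "lesions_b_base", "lesions_b_ssb")])
    if (any(les < 0) || any(les != round(les))) {
      return("lesion counts must be non-negative integers")
    }
    r <- sqrt((s$x - object@nucleus@centre[1])^2 +
              (s$y - object@nucleus@centre[2])^2 +
              (s$z - object@nucleus@centre[3])^2)
    if (any(r >= object@nucleus@radius)) {
      return("all site positions must lie strictly inside the nucleus")
    }
  }
  TRUE
})

#' Knockout / deficiency configuration
#'
#' Protein deficiencies are modelled by deleting or retiming single pathway
#' transitions: Artemis deficiency deletes the 500 s resection-completion step,
#' CtIP inhibition deletes the slow-branch entry, and XLF deficiency shortens
#' the synapsis dissociation time constant to 11 s.
#'
#' @slot artemisDeficient logical(1).
#' @slot ctipInhibited logical(1).
#' @slot xlfDeficient logical(1).
#' @slot xlfDissociationTime numeric(1), seconds; used only when
#'   \code{xlfDeficient} is TRUE.
#' @export
setClass("KnockoutConfig", representation(
  artemisDeficient = "logical", ctipInhibited = "logical",
  xlfDeficient = "logical", xlfDissociationTime = "numeric"
))

#' @rdname KnockoutConfig-class
#' @param artemisDeficient,ctipInhibited,xlfDeficient logical flags.
#' @param xlfDissociationTime dissociation time constant (s) under XLF
#'   deficiency.
#' @return A \linkS4class{KnockoutConfig}.
#' @examples
#' knockoutConfig(artemisDeficient = TRUE)
#' @export
knockoutConfig <- function(artemisDeficient = FALSE, ctipInhibited = FALSE,
                           xlfDeficient = FALSE, xlfDissociationTime = 11.0) {
  new("KnockoutConfig",
      artemisDeficient = artemisDeficient, ctipInhibited = ctipInhibited,
      xlfDeficient = xlfDeficient,
      xlfDissociationTime = as.numeric(xlfDissociationTime))
}

#' Chromatin gating of pathway entry
#'
#' When enabled, the local chromatin label of a break gates slow/fast branch
#' entry: CtIP recruitment is blocked in euchromatin, and in heterochromatin
#' each end independently has probability \code{pkRecruitProbabilityHC} of
#' being DNA-PKcs-eligible (in which case the abundant kinase outcompetes CtIP
#' and the end takes the fast branch); otherwise the end recruits CtIP. The
#' eligibility roll is made once per end when Ku loads and is not re-rolled.
#'
#' @slot enabled logical(1).
#' @slot blockCtipInEuchromatin logical(1).
#' @slot pkRecruitProbabilityHC numeric(1) in [0, 1].
#' @export
setClass("ChromatinGating", representation(
  enabled = "logical", blockCtipInEuchromatin = "logical",
  pkRecruitProbabilityHC = "numeric"
))

setValidity("ChromatinGating", function(object) {
  p <- object@pkRecruitProbabilityHC
  if (length(p) != 1L || is.na(p) || p < 0 || p > 1) {
    return("pkRecruitProbabilityHC must be a probability in [0, 1]")
  }
  TRUE
})

#' @rdname ChromatinGating-class
#' @param enabled turn gating on or off.
#' @param blockCtipInEuchromatin whether CtIP entry is blocked for euchromatic
#'   ends when gating is enabled.
#' @param pkRecruitProbabilityHC per-end probability of DNA-PKcs recruitment in
#'   heterochromatin.
#' @return A \linkS4class{ChromatinGating}.
#' @examples
#' chromatinGating(enabled = TRUE)
#' @export
chromatinGating <- function(enabled = FALSE, blockCtipInEuchromatin = TRUE,
                            pkRecruitProbabilityHC = 0.4) {
  new("ChromatinGating", enabled = enabled,
      blockCtipInEuchromatin = blockCtipInEuchromatin,
      pkRecruitProbabilityHC = as.numeric(pkRecruitProbabilityHC))
}

#' NHEJ pathway model
#'
#' A state-transition graph over DSB-end repair states with per-transition mean
#' times (exponential-race semantics) plus the complex-level time constants
#' (synapsis stabilisation, dissociation, ligation, lesion cleaning). Two
#' topologies exist: model "A" ("parallel"; slow and fast branches fully
#' separated, no cross-branch synapsis, no dissociation of slow-branch
#' complexes, branch-specific ligation times 1200/8000 s) and model "B"
#' ("entwined"; cross-branch synapsis allowed, all complexes may dissociate,
#' single ligation time 3000 s).
#'
#' @slot modelId "A" or "B".
#' @slot transitions data.frame of end-level transitions (\code{from},
#'   \code{to}, \code{mean_time} in s, \code{label}).
#' @slot crossPathwaySynapsis logical; can ends from different branches join?
#' @slot slowBranchDissociation logical; can slow-slow complexes dissociate?
#' @slot ligationTimeFast,ligationTimeSlow seconds.
#' @slot synapsisRadius nm.
#' @slot dissociationTime,stabilisationTime,bluntTime seconds.
#' @slot baseLesionTime,ssbTime per-lesion removal time constants, seconds.
#' @slot kuInhibitionTime,kuReleaseTime,kuRecruitTime seconds.
#' @slot pkFastTime,ctipTime,exo1Time,artemisPkSlowTime seconds.
#' @slot knockouts the \linkS4class{KnockoutConfig} the graph was built with.
#' @slot gating the \linkS4class{ChromatinGating} attached to the graph.
#' @export
setClass("PathwayModel", representation(
  modelId = "character", transitions = "data.frame",
  crossPathwaySynapsis = "logical", slowBranchDissociation = "logical",
  ligationTimeFast = "numeric", ligationTimeSlow = "numeric",
  synapsisRadius = "numeric", dissociationTime = "numeric",
  stabilisationTime = "numeric", bluntTime = "numeric",
  baseLesionTime = "numeric", ssbTime = "numeric",
  kuInhibitionTime = "numeric", kuReleaseTime = "numeric",
  kuRecruitTime = "numeric", pkFastTime = "numeric", ctipTime = "numeric",
  exo1Time = "numeric", artemisPkSlowTime = "numeric",
  knockouts = "KnockoutConfig", gating = "ChromatinGating"
))

setValidity("PathwayModel", function(object) {
  if (!object@modelId %in% c("A", "B")) return("modelId must be 'A' or 'B'")
  tr <- object@transitions
  if (!all(c("from", "to", "mean_time", "label") %in% names(tr))) {
    return("transitions must have columns from, to, mean_time, label")
  }
  if (any(!tr$from %in% .STATES) || any(!tr$to %in% .STATES)) {
    return("transition endpoints must be known repair states")
  }
  if (any(tr$mean_time < 0)) return("transition mean times must be >= 0")
  if (anyDuplicated(tr[, c("from", "to")])) {
    return("at most one transition per (from, to) pair")
  }
  if (object@modelId == "A" &&
      (object@crossPathwaySynapsis || object@slowBranchDissociation)) {
    return("model A must have crossPathwaySynapsis and slowBranchDissociation FALSE")
  }
  consts <- c(object@ligationTimeFast, object@ligationTimeSlow,
              object@synapsisRadius, object@dissociationTime,
              object@stabilisationTime, object@bluntTime,
              object@baseLesionTime, object@ssbTime, object@kuInhibitionTime,
              object@kuReleaseTime, object@kuRecruitTime, object@pkFastTime,
              object@ctipTime, object@exo1Time, object@artemisPkSlowTime)
  if (any(!is.finite(consts)) || any(consts <= 0)) {
    return("all model time constants and the synapsis radius must be > 0")
  }
  TRUE
})

#' Continuous-time random walk parameters
#'
#' Sub-diffusive end motion is modelled as instantaneous Gaussian jumps
#' separated by heavy-tailed (Pareto-type) trapping times: after each jump an
#' object is trapped, with trap durations whose tail exponent
#' \code{waitTimeExponent} < 1 produces ensemble MSD growing as
#' t^\code{waitTimeExponent}.
#'
#' @slot jumpDiffusionCoefficient nm^2/s governing the per-jump displacement
#'   variance (2 D tau per axis over the jump duration tau).
#' @slot waitTimeExponent tail exponent alpha in (0, 1).
#' @slot waitTimeScale scale (s) of the trapping-time law.
#' @slot jumpDuration duration (s) of a single jump burst.
#' @export
setClass("CTRWParams", representation(
  jumpDiffusionCoefficient = "numeric", waitTimeExponent = "numeric",
  waitTimeScale = "numeric", jumpDuration = "numeric"
))

setValidity("CTRWParams", function(object) {
  if (object@jumpDiffusionCoefficient < 0) {
    return("jumpDiffusionCoefficient must be >= 0")
  }
  a <- object@waitTimeExponent
  if (length(a) != 1L || is.na(a) || a <= 0 || a >= 1) {
    return("waitTimeExponent must lie strictly in (0, 1)")
  }
  if (object@waitTimeScale <= 0 || object@jumpDuration < 0) {
    return("waitTimeScale must be > 0 and jumpDuration >= 0")
  }
  TRUE
})

#' @rdname CTRWParams-class
#' @param jumpDiffusionCoefficient jump diffusion coefficient, nm^2/s.
#' @param waitTimeExponent heavy-tail exponent alpha of trap times.
#' @param waitTimeScale trap-time scale, s.
#' @param jumpDuration duration of one jump, s.
#' @return A \linkS4class{CTRWParams}.
#' @examples
#' ctrwParams()
#' @export
ctrwParams <- function(jumpDiffusionCoefficient = 6.0e10,
                       waitTimeExponent = 0.5, waitTimeScale = 5,
                       jumpDuration = 4e-10) {
  new("CTRWParams",
      jumpDiffusionCoefficient = as.numeric(jumpDiffusionCoefficient),
      waitTimeExponent = as.numeric(waitTimeExponent),
      waitTimeScale = as.numeric(waitTimeScale),
      jumpDuration = as.numeric(jumpDuration))
}

#' Simulation configuration
#'
#' Everything needed to run a repeated repair simulation: the pathway model id
#' and its variants, the damage source (either an explicit
#' \linkS4class{DamageSet}, reused in every repeat, or generator parameters,
#' redrawn per repeat), the horizon, the motion parameters, the master seed and
#' the output sampling grid.
#'
#' @slot modelId "A" or "B".
#' @slot knockouts \linkS4class{KnockoutConfig}.
#' @slot gating \linkS4class{ChromatinGating}.
#' @slot damage a \linkS4class{DamageSet} or a list of generator parameters
#'   (see \code{\link{simulationConfig}}).
#' @slot tEnd simulated horizon, s.
#' @slot repeats number of independent repeats.
#' @slot motion \linkS4class{CTRWParams}.
#' @slot masterSeed integer master seed; repeat k runs under masterSeed + k.
#' @slot sampleTimes times (s) at which state tallies are recorded.
#' @slot nucleus \linkS4class{Nucleus}.
#' @slot tickEarly,tickGrowth,tickMax,tickSwitch motion/reaction coupling tick
#'   schedule: fixed \code{tickEarly} (s) until \code{tickSwitch} (s), then
#'   geometric growth by \code{tickGrowth} capped at \code{tickMax} (s).
#' @export
setClass("SimulationConfig", representation(
  modelId = "character", knockouts = "KnockoutConfig",
  gating = "ChromatinGating", damage = "ANY", tEnd = "numeric",
  repeats = "integer", motion = "CTRWParams", masterSeed = "integer",
  sampleTimes = "numeric", nucleus = "Nucleus", tickEarly = "numeric",
  tickGrowth = "numeric", tickMax = "numeric", tickSwitch = "numeric"
))

setValidity("SimulationConfig", function(object) {
  if (object@tEnd <= 0) return("tEnd must be > 0")
  if (object@repeats < 1L) return("repeats must be >= 1")
  if (any(object@sampleTimes < 0) || any(object@sampleTimes > object@tEnd)) {
    return("sampleTimes must lie in [0, tEnd]")
  }
  if (is.unsorted(object@sampleTimes, strictly = TRUE)) {
    return("sampleTimes must be strictly increasing")
  }
  if (object@tickEarly <= 0 || object@tickMax < object@tickEarly ||
      object@tickGrowth < 1) {
    return("invalid tick schedule")
  }
  ok <- is(object@damage, "DamageSet") ||
    (is.list(object@damage) && !is.null(object@damage$type))
  if (!ok) return("damage must be a DamageSet or a generator parameter list")
  TRUE
})

#' Result of a repeated repair simulation
#'
#' @slot events data.frame of end-level state transitions (\code{rep},
#'   \code{t}, \code{end_id}, \code{from}, \code{to}).
#' @slot complexes data.frame of synaptic complexes (\code{rep},
#'   \code{complex_id}, \code{end1}, \code{end2}, \code{cross_origin},
#'   \code{t_formed}, \code{t_stable}, \code{t_ligated}, \code{t_dissolved},
#'   \code{status}); a dissociated-and-reformed pairing appears as a new row.
#' @slot samples data.frame of per-sample-time tallies (\code{rep}, \code{t},
#'   \code{free_ends}, \code{stalled_ends}, \code{ends_in_complex},
#'   \code{ends_ligated}, \code{unrepaired}).
#' @slot ends data.frame of per-end static attributes (\code{rep},
#'   \code{end_id}, \code{site_id}, \code{chromatin}, \code{pk_eligible},
#'   \code{lesions_base}, \code{lesions_ssb}).
#' @slot nSites integer vector: initial DSB count per repeat.
#' @slot config the \linkS4class{SimulationConfig} that produced the result.
#' @export
setClass("SimulationResult", representation(
  events = "data.frame", complexes = "data.frame", samples = "data.frame",
  ends = "data.frame", nSites = "integer", config = "SimulationConfig"
))

#' Time-indexed kinetics curve
#'
#' Mean and SEM (over repeats) of a simulated quantity: unrepaired DSB
#' equivalents or the loaded fraction of a repair protein.
#'
#' @slot times sampling times, s (strictly increasing).
#' @slot mean,sem mean and standard error over repeats.
#' @slot n number of repeats.
#' @slot quantity label, e.g. "unrepaired_dsb" or "Ku".
#' @slot normalisation free-text descriptor of the normalisation applied.
#' @export
setClass("KineticsCurve", representation(
  times = "numeric", mean = "numeric", sem = "numeric", n = "integer",
  quantity = "character", normalisation = "character"
))

setValidity("KineticsCurve", function(object) {
  if (length(object@times) != length(object@mean) ||
      length(object@mean) != length(object@sem)) {
    return("times, mean and sem must have equal length")
  }
  if (is.unsorted(object@times, strictly = TRUE)) {
    return("times must be strictly increasing")
  }
  if (any(object@sem < 0)) return("sem must be >= 0")
  TRUE
})

#' @rdname KineticsCurve-class
#' @param times,mean,sem,n,quantity,normalisation see the corresponding slots.
#' @return A \linkS4class{KineticsCurve}.
#' @export
kineticsCurve <- function(times, mean, sem, n, quantity = "unrepaired_dsb",
                          normalisation = "none") {
  new("KineticsCurve", times = as.numeric(times), mean = as.numeric(mean),
      sem = as.numeric(sem), n = as.integer(n), quantity = quantity,
      normalisation = normalisation)
}

## Default 10-um-diameter nucleus, used in function signatures where an
## argument is itself named `nucleus`.
.defaultNucleus <- function() new("Nucleus", radius = 5000, centre = c(0, 0, 0))
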