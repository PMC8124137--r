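## The two NHEJ pathway topologies as state-transition graphs with
## exponential-race semantics.

.MODEL_CONSTANTS <- list(
  A = list(ligationFast = 1200, ligationSlow = 8000, blunt = 60,
           cross = FALSE, slowDissoc = FALSE),
  B = list(ligationFast = 3000, ligationSlow = 3000, blunt = 400,
           cross = TRUE, slowDissoc = TRUE)
)

#' Build an NHEJ pathway model
#'
#' Constructs the validated state-transition graph for pathway model "A"
#' ("parallel") or "B" ("entwined"), applying knockout and chromatin-gating
#' variants. The wild-type end-level graph is:
#' \preformatted{
#'   naked        -> race { ku_bound (1.1 s) | inhibited (0.85 s) }
#'   inhibited    -> naked (release, 3.8 s; the end re-enters the race)
#'   ku_bound     -> race { pk_fast (1.2 s) | ku_ctip (7.0 s) }
#'   ku_ctip      -> ku_ctip_exo1 (EXO1, 1.2 s)
#'   ku_ctip_exo1 -> resected_awaiting_pk (bookkeeping, immediate)
#'   resected_awaiting_pk -> pk_artemis_slow (resection + Artemis:DNA-PKcs,
#'                                            500 s)
#'   pk_artemis_slow -> blunt_slow (60 s model A / 400 s model B)
#' }
#' \code{pk_fast} and \code{blunt_slow} ends are synapsis-eligible; complex
#' formation, stabilisation (250 s), dissociation (400 s) and ligation are
#' handled at the complex level by the engine. Artemis deficiency deletes the
#' 500 s step (resected ends stall); CtIP inhibition deletes the slow-branch
#' entry; XLF deficiency sets the dissociation time constant to 11 s.
#'
#' @param modelId "A" or "B".
#' @param knockouts a \linkS4class{KnockoutConfig}.
#' @param gating a \linkS4class{ChromatinGating}.
#' @return A \linkS4class{PathwayModel}.
#' @examples
#' buildModel("B")
#' buildModel("A", gating = chromatinGating(enabled = TRUE))
#' @export
buildModel <- function(modelId, knockouts = knockoutConfig(),
                       gating = chromatinGating()) {
  if (length(modelId) != 1L || !modelId %in% c("A", "B")) {
    stop("modelId must be 'A' or 'B'")
  }
  mc <- .MODEL_CONSTANTS[[modelId]]
  tr <- data.frame(
    from = c("naked", "naked", "inhibited", "ku_bound", "ku_bound",
             "ku_ctip", "ku_ctip_exo1", "resected_awaiting_pk",
             "pk_artemis_slow"),
    to = c("ku_bound", "inhibited", "naked", "pk_fast", "ku_ctip",
           "ku_ctip_exo1", "resected_awaiting_pk", "pk_artemis_slow",
           "blunt_slow"),
    mean_time = c(1.1, 0.85, 3.8, 1.2, 7.0, 1.2, 0, 500, mc$blunt),
    label = c("ku_recruit", "ku_inhibition", "ku_release", "pk_fast", "ctip",
              "exo1", "resection_entry", "artemis_pk_slow", "blunt"),
    stringsAsFactors = FALSE
  )
  if (knockouts@artemisDeficient) {
    tr <- tr[tr$label != "artemis_pk_slow", , drop = FALSE]
  }
  if (knockouts@ctipInhibited) {
    tr <- tr[tr$label != "ctip", , drop = FALSE]
  }
  dissoc <- if (knockouts@xlfDeficient) knockouts@xlfDissociationTime else 400
  new("PathwayModel",
      modelId = modelId, transitions = tr,
      crossPathwaySynapsis = mc$cross, slowBranchDissociation = mc$slowDissoc,
      ligationTimeFast = mc$ligationFast, ligationTimeSlow = mc$ligationSlow,
      synapsisRadius = 25, dissociationTime = dissoc,
      stabilisationTime = 250, bluntTime = mc$blunt,
      baseLesionTime = 300, ssbTime = 900,
      kuInhibitionTime = 0.85, kuReleaseTime = 3.8, kuRecruitTime = 1.1,
      pkFastTime = 1.2, ctipTime = 7.0, exo1Time = 1.2,
      artemisPkSlowTime = 500,
      knockouts = knockouts, gating = gating)
}

#' Transitions available to an end in a given state
#'
#' Returns the outgoing transitions of \code{state}, filtered by knockouts
#' (already absent from the graph) and by chromatin gating. With gating
#' enabled, a euchromatic end at \code{ku_bound} keeps only the fast DNA-PKcs
#' entry, while a heterochromatic end keeps the fast entry only if its one-off
#' DNA-PKcs eligibility roll succeeded (probability 0.4 by default) and
#' otherwise keeps only the CtIP entry. Terminal states return an empty set.
#'
#' @param state a repair-state name.
#' @param endContext list with elements \code{chromatin}
#'   ("heterochromatin"/"euchromatin") and \code{pkEligible} (logical, the
#'   per-end roll; only consulted for heterochromatic ends under gating).
#' @param model a \linkS4class{PathwayModel}.
#' @return data.frame of transitions (possibly zero rows).
#' @examples
#' m <- buildModel("B")
#' availableTransitions("ku_bound", list(chromatin = "euchromatin"), m)
#' @export
availableTransitions <- function(state, endContext, model) {
  stopifnot(state %in% .STATES)
  if (state %in% .TERMINAL_STATES) {
    return(model@transitions[0, , drop = FALSE])
  }
  tr <- model@transitions[model@transitions$from == state, , drop = FALSE]
  g <- model@gating
  if (g@enabled && state == "ku_bound") {
    if (identical(endContext$chromatin, "euchromatin")) {
      if (g@blockCtipInEuchromatin) tr <- tr[tr$label != "ctip", , drop = FALSE]
    } else {
      if (isTRUE(endContext$pkEligible)) {
        tr <- tr[tr$label != "ctip", , drop = FALSE]
      } else {
        tr <- tr[tr$label != "pk_fast", , drop = FALSE]
      }
    }
  }
  tr
}

#' Sample the winner of an exponential race
#'
#' Draws an exponential waiting time for every candidate transition (rate =
#' 1 / mean) and selects the shortest. A zero-mean transition is a
#' deterministic immediate step and always wins (ties broken by lowest row
#' index). An empty candidate set signals a stall, which the caller converts
#' into the terminal \code{stalled} state.
#'
#' @param transitions data.frame of candidate transitions (as returned by
#'   \code{\link{availableTransitions}}).
#' @return list with elements \code{transition} (the winning row) and
#'   \code{waitingTime} (s), or an error of class \code{"nhejsimStall"} if
#'   the candidate set is empty.
#' @examples
#' m <- buildModel("B")
#' sampleTransition(availableTransitions("naked", list(), m))
#' @export
sampleTransition <- function(transitions) {
  n <- nrow(transitions)
  if (n == 0L) {
    stop(structure(class = c("nhejsimStall", "error", "condition"),
                   list(message = "no available transitions: end stalls",
                        call = sys.call())))
  }
  times <- ifelse(transitions$mean_time == 0, 0,
                  stats::rexp(n, rate = 1 / transitions$mean_time))
  i <- which.min(times)  # which.min takes the lowest index on exact ties
  list(transition = transitions[i, , drop = FALSE], waitingTime = times[i])
}
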