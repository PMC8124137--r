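#' Accessors
#'
#' @param x a package object.
#' @name accessors
NULL

#' @describeIn accessors data.frame of DSB sites in a \linkS4class{DamageSet}.
#' @export
setGeneric("sites", function(x) standardGeneric("sites"))

#' @rdname accessors
#' @export
setMethod("sites", "DamageSet", function(x) x@sites)

#' @describeIn accessors absorbed dose (Gy).
#' @export
setGeneric("dose", function(x) standardGeneric("dose"))

#' @rdname accessors
#' @export
setMethod("dose", "DamageSet", function(x) x@dose)

#' @describeIn accessors number of DSB sites.
#' @export
setGeneric("nSites", function(x) standardGeneric("nSites"))

#' @rdname accessors
#' @export
setMethod("nSites", "DamageSet", function(x) nrow(x@sites))

#' @rdname accessors
#' @export
setMethod("nSites", "SimulationResult", function(x) x@nSites)

#' @describeIn accessors model identifier ("A" or "B").
#' @export
setGeneric("modelId", function(x) standardGeneric("modelId"))

#' @rdname accessors
#' @export
setMethod("modelId", "PathwayModel", function(x) x@modelId)

#' @describeIn accessors edge list of a \linkS4class{PathwayModel} (data.frame
#'   with from, to, mean_time, label), suitable for inspection or export.
#' @export
setGeneric("transitions", function(x) standardGeneric("transitions"))

#' @rdname accessors
#' @export
setMethod("transitions", "PathwayModel", function(x) x@transitions)

#' @describeIn accessors per-repeat event log of a simulation.
#' @export
setGeneric("events", function(x) standardGeneric("events"))

#' @rdname accessors
#' @export
setMethod("events", "SimulationResult", function(x) x@events)

#' @describeIn accessors synaptic-complex table of a simulation.
#' @export
setGeneric("complexes", function(x) standardGeneric("complexes"))

#' @rdname accessors
#' @export
setMethod("complexes", "SimulationResult", function(x) x@complexes)

#' @describeIn accessors per-sample-time tallies of a simulation.
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))

#' @rdname accessors
#' @export
setMethod("samples", "SimulationResult", function(x) x@samples)

#' @rdname accessors
#' @param object object to display.
#' @export
setMethod("show", "Nucleus", function(object) {
  cat(sprintf("Nucleus: radius %.0f nm, centre (%g, %g, %g)\n",
              object@radius, object@centre[1], object@centre[2],
              object@centre[3]))
})

#' @rdname accessors
#' @export
setMethod("show", "DamageSet", function(object) {
  cat(sprintf("DamageSet: %d DSB site(s), %.3g Gy %s", nrow(object@sites),
              object@dose, object@quality))
  if (!is.na(object@let)) cat(sprintf(", LET %.3g keV/um", object@let))
  cat("\n")
  if (nrow(object@sites) > 0) {
    hc <- mean(object@sites$chromatin == "heterochromatin")
    cat(sprintf("  heterochromatic fraction: %.3f\n", hc))
  }
})

#' @rdname accessors
#' @export
setMethod("show", "PathwayModel", function(object) {
  lab <- if (object@modelId == "A") "parallel" else "entwined"
  cat(sprintf("PathwayModel %s (%s): %d transitions\n", object@modelId, lab,
              nrow(object@transitions)))
  cat(sprintf("  cross-pathway synapsis: %s; slow-branch dissociation: %s\n",
              object@crossPathwaySynapsis, object@slowBranchDissociation))
  cat(sprintf("  synapsis radius %g nm; dissociation %g s; ligation %g/%g s\n",
              object@synapsisRadius, object@dissociationTime,
              object@ligationTimeFast, object@ligationTimeSlow))
  ko <- object@knockouts
  flags <- c(if (ko@artemisDeficient) "Artemis-" ,
             if (ko@ctipInhibited) "CtIP-inhibited",
             if (ko@xlfDeficient) "XLF-")
  if (length(flags)) cat("  knockouts:", paste(flags, collapse = ", "), "\n")
  if (object@gating@enabled) {
    cat(sprintf("  chromatin gating on (P[DNA-PKcs | HC] = %.2f)\n",
                object@gating@pkRecruitProbabilityHC))
  }
})

#' @rdname accessors
#' @export
setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: model %s, %d repeat(s), %g s horizon\n",
              object@config@modelId, object@config@repeats,
              object@config@tEnd))
  cat(sprintf("  initial DSBs per repeat: mean %.1f\n", mean(object@nSites)))
  lig <- object@complexes[object@complexes$status == "ligated", , drop = FALSE]
  cat(sprintf("  ligated complexes: %d (%d cross-origin)\n", nrow(lig),
              sum(lig$cross_origin)))
})

#' @rdname accessors
#' @export
setMethod("show", "KineticsCurve", function(object) {
  cat(sprintf("KineticsCurve '%s': %d points over [%g, %g] s, n = %d\n",
              object@quantity, length(object@times), min(object@times),
              max(object@times), object@n))
  cat(sprintf("  normalisation: %s\n", object@normalisation))
})

#' Coerce a kinetics curve to a data.frame
#'
#' @param x a \linkS4class{KineticsCurve}.
#' @param row.names,optional,... ignored; present for generic compatibility.
#' @return data.frame with columns time_s, value, sem.
#' @export
setMethod("as.data.frame", "KineticsCurve",
          function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(time_s = x@times, value = x@mean, sem = x@sem)
})
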