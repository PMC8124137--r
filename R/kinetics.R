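## Turning simulation results into reported quantities: recruitment curves,
## repair curves, residual-vs-LET fits and reduced chi-square comparisons.

## Protein load intervals inferred from state occupancy: a protein is "loaded"
## from first entry into its loading state until the state boundary where the
## pathway removes it (ligation for Ku/DNA-PKcs/Artemis; completion of the
## 500 s resection step for CtIP/EXO1). Returns per-end (start, end) times.
.loadIntervals <- function(ev, protein) {
  firstEntry <- function(stateNames) {
    sel <- ev[ev$to %in% stateNames, c("end_id", "t")]
    if (nrow(sel) == 0L) return(numeric(0))
    tapply(sel$t, sel$end_id, min)
  }
  ligT <- firstEntry("ligated")
  endAt <- function(starts, ends) {
    out <- rep.int(Inf, length(starts))
    m <- match(names(starts), names(ends))
    hit <- !is.na(m)
    out[hit] <- ends[m[hit]]
    out
  }
  switch(protein,
    "Ku" = {
      st <- firstEntry("ku_bound")
      list(start = as.numeric(st), end = endAt(st, ligT))
    },
    "DNA-PKcs" = ,
    "Artemis" = {
      st <- firstEntry(c("pk_fast", "pk_artemis_slow"))
      list(start = as.numeric(st), end = endAt(st, ligT))
    },
    "CtIP" = {
      st <- firstEntry("ku_ctip")
      list(start = as.numeric(st), end = endAt(st, firstEntry("pk_artemis_slow")))
    },
    "EXO1" = {
      st <- firstEntry("resected_awaiting_pk")
      list(start = as.numeric(st), end = endAt(st, firstEntry("pk_artemis_slow")))
    },
    stop("unknown protein: ", protein)
  )
}

#' Protein recruitment curve
#'
#' Counts, at each sampling time, the DSB ends whose state implies the given
#' protein is currently loaded. Per repeat the count is normalised to the
#' initial number of DSBs, the repeats are averaged, and the averaged curve is
#' rescaled so that its maximum within \code{normWindow} equals 1 (30 s for
#' Ku/DNA-PKcs/CtIP/EXO1, 60 s for Artemis, matching how fluorescence
#' recruitment data are normalised). DNA-PKcs counts both its fast loading and
#' its post-resection loading with Artemis.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param protein one of "Ku", "DNA-PKcs", "CtIP", "EXO1", "Artemis".
#' @param normWindow normalisation window in s (> 0); default 60 for Artemis,
#'   30 otherwise.
#' @param times sampling grid; defaults to the configured sample times.
#' @return A \linkS4class{KineticsCurve} (values may exceed 1 after the
#'   normalisation window).
#' @examples
#' cfg <- simulationConfig("B", damage = list(type = "photon", dose = 1),
#'                         tEnd = 30, repeats = 3, masterSeed = 1)
#' recruitmentCurve(runSimulation(cfg), "Ku")
#' @export
recruitmentCurve <- function(result, protein,
                             normWindow = if (protein == "Artemis") 60 else 30,
                             times = NULL) {
  stopifnot(is(result, "SimulationResult"))
  if (!protein %in% .PROTEINS) {
    stop("unknown protein: ", protein, " (expected one of ",
         paste(.PROTEINS, collapse = ", "), ")")
  }
  if (normWindow <= 0) stop("normWindow must be > 0")
  if (is.null(times)) times <- result@config@sampleTimes
  reps <- result@config@repeats
  frac <- matrix(0, nrow = reps, ncol = length(times))
  for (k in seq_len(reps)) {
    ev <- result@events[result@events$rep == k, , drop = FALSE]
    iv <- .loadIntervals(ev, protein)
    loaded <- findInterval(times, sort(iv$start)) -
      findInterval(times, sort(iv$end[is.finite(iv$end)]))
    frac[k, ] <- loaded / max(1L, result@nSites[k])
  }
  m <- colMeans(frac)
  sem <- if (reps > 1) apply(frac, 2, stats::sd) / sqrt(reps) else
    rep.int(0, length(times))
  inWin <- times <= normWindow
  peak <- max(m[inWin])
  if (peak <= 0) peak <- 1
  kineticsCurve(times, m / peak, sem / peak, reps, quantity = protein,
                normalisation = sprintf(
                  "per-repeat fraction of initial DSBs, rescaled to max in %g s",
                  normWindow))
}

#' Repair kinetics curve
#'
#' Mean and SEM over repeats of the number of unrepaired DSB equivalents at
#' each sampling time.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @param times sampling grid; defaults to the configured sample times.
#' @return A \linkS4class{KineticsCurve} with quantity "unrepaired_dsb".
#' @examples
#' cfg <- simulationConfig("B", damage = list(type = "photon", dose = 1),
#'                         tEnd = 60, repeats = 3, masterSeed = 1)
#' repairCurve(runSimulation(cfg))
#' @export
repairCurve <- function(result, times = NULL) {
  stopifnot(is(result, "SimulationResult"))
  if (is.null(times)) times <- result@config@sampleTimes
  reps <- result@config@repeats
  cx <- result@complexes
  lig <- cx[cx$status == "ligated", , drop = FALSE]
  counts <- matrix(0, nrow = reps, ncol = length(times))
  for (k in seq_len(reps)) {
    tl <- sort(lig$t_ligated[lig$rep == k])
    counts[k, ] <- result@nSites[k] - findInterval(times, tl)
  }
  m <- colMeans(counts)
  sem <- if (reps > 1) apply(counts, 2, stats::sd) / sqrt(reps) else
    rep.int(0, length(times))
  kineticsCurve(times, m, sem, reps, quantity = "unrepaired_dsb",
                normalisation = "none")
}

#' Reduced chi-square between a simulated curve and experimental data
#'
#' \eqn{\chi^2 / DF = \sum_i ((sim(t_i) - y_i) / \sigma_i)^2 / N}, where the
#' simulated curve is linearly interpolated at the experimental times, the
#' weights are the experimental SEMs, and DF is the number of experimental
#' points (no parameters are fitted at comparison time).
#'
#' @param sim a \linkS4class{KineticsCurve}.
#' @param exp data.frame with columns \code{time_s}, \code{value}, \code{sem}
#'   (all SEMs > 0); experimental times must lie within the simulated range.
#' @return The reduced chi-square statistic (numeric scalar).
#' @examples
#' simC <- kineticsCurve(c(0, 10), c(10, 5), c(0, 0), 1)
#' expD <- data.frame(time_s = c(0, 10), value = c(12, 6), sem = c(2, 1))
#' reducedChiSquare(simC, expD)  # (1 + 1) / 2 = 1
#' @export
reducedChiSquare <- function(sim, exp) {
  stopifnot(is(sim, "KineticsCurve"), is.data.frame(exp))
  need <- c("time_s", "value", "sem")
  if (!all(need %in% names(exp))) {
    stop("experimental series must have columns time_s, value, sem")
  }
  if (nrow(exp) == 0L) stop("experimental series is empty")
  if (any(exp$sem <= 0)) {
    stop("all experimental SEMs must be > 0 to weight the chi-square")
  }
  if (any(exp$time_s < min(sim@times)) || any(exp$time_s > max(sim@times))) {
    stop("experimental times must lie within the simulated time range")
  }
  y <- stats::approx(sim@times, sim@mean, xout = exp$time_s)$y
  sum(((y - exp$value) / exp$sem)^2) / nrow(exp)
}

#' Aggregate reduced chi-square statistics
#'
#' Unweighted arithmetic mean over datasets, plus the best (smallest) and
#' worst (largest) single-dataset statistics.
#'
#' @param stats numeric vector of reduced chi-square values (non-empty).
#' @return list with elements \code{mean}, \code{best}, \code{worst}.
#' @examples
#' aggregateChiSquare(c(0.5, 1.5, 4.0))
#' @export
aggregateChiSquare <- function(stats) {
  if (length(stats) == 0L) stop("need at least one chi-square statistic")
  list(mean = mean(stats), best = min(stats), worst = max(stats))
}

#' Linear fit of residual damage versus LET
#'
#' Ordinary least-squares line through (LET, mean unrepaired DSBs at the end
#' of the simulation), as used to summarise residual damage across radiation
#' qualities.
#'
#' @param lets numeric vector of LET values (>= 2 distinct values).
#' @param residuals either a numeric vector of mean residual counts (same
#'   length) or a list of \linkS4class{SimulationResult} objects, whose mean
#'   residual at their horizon is used.
#' @return list with \code{slope}, \code{intercept}, \code{residuals}
#'   (per-point fit residuals) and \code{points} (the fitted data).
#' @examples
#' residualVsLet(c(1, 2, 3), c(2, 4, 6))
#' @export
residualVsLet <- function(lets, residuals) {
  if (is.list(residuals) && all(vapply(residuals, is, logical(1),
                                       "SimulationResult"))) {
    residuals <- vapply(residuals, function(r) {
      mean(countUnrepaired(r, r@config@tEnd))
    }, numeric(1))
  }
  if (length(lets) != length(residuals)) {
    stop("lets and residuals must have the same length")
  }
  if (length(unique(lets)) < 2L) {
    stop("need at least two distinct LET values")
  }
  fit <- stats::lm(residuals ~ lets)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residuals = unname(stats::residuals(fit)),
       points = data.frame(let = lets, residual = residuals))
}

#' Fraction of ends committing to the resection-dependent branch
#'
#' Measured from event logs: the fraction of ends that entered the CtIP
#' state among all ends that committed to either branch (entered
#' \code{pk_fast} or \code{ku_ctip}). In the ungated wild-type this matches
#' the closed-form race probability
#' (1/7.0) / (1/1.2 + 1/7.0) = 0.146.
#'
#' @param result a \linkS4class{SimulationResult}.
#' @return Fraction in [0, 1].
#' @export
slowBranchFraction <- function(result) {
  stopifnot(is(result, "SimulationResult"))
  ev <- result@events
  slow <- unique(paste(ev$rep, ev$end_id)[ev$to == "ku_ctip"])
  fast <- unique(paste(ev$rep, ev$end_id)[ev$to == "pk_fast" &
                                          ev$from == "ku_bound"])
  committed <- length(slow) + length(fast)
  if (committed == 0L) return(NA_real_)
  length(slow) / committed
}
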