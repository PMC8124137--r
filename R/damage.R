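## Synthetic damage generators: photon-like (Poisson yield, uniform positions)
## and a simplified track-like generator for LET sweeps.

.setSeed <- function(seed) {
  if (!is.null(seed) && !is.na(seed)) set.seed(as.integer(seed))
}

## Uniform points strictly inside a sphere: direction from an isotropic
## Gaussian, radius from the volume-uniform law r = R * U^(1/3).
.uniformSphere <- function(n, nucleus) {
  if (n == 0L) {
    return(matrix(numeric(0), ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z"))))
  }
  g <- matrix(stats::rnorm(3L * n), ncol = 3)
  nrm <- sqrt(rowSums(g^2))
  nrm[nrm == 0] <- 1
  r <- nucleus@radius * stats::runif(n)^(1 / 3)
  p <- g / nrm * r
  p <- sweep(p, 2, nucleus@centre, "+")
  colnames(p) <- c("x", "y", "z")
  p
}

.makeSites <- function(pos, chromatin, complexity) {
  n <- nrow(pos)
  ## low-level data.frame construction: this sits in tight per-seed loops
  structure(list(
    site_id = seq_len(n),
    x = unname(pos[, 1]), y = unname(pos[, 2]), z = unname(pos[, 3]),
    chromatin = rep_len(chromatin, n),
    lesions_a_base = stats::rpois(n, complexity$baseMean),
    lesions_a_ssb = stats::rpois(n, complexity$ssbMean),
    lesions_b_base = stats::rpois(n, complexity$baseMean),
    lesions_b_ssb = stats::rpois(n, complexity$ssbMean)
  ), class = "data.frame", row.names = c(NA_integer_, -n))
}

#' Strand-break induction probability
#'
#' Linear ramp between the energy depositions bounding strand-break induction:
#' probability 0 at or below 5.0 eV, 1 at or above 37.5 eV, linear in between.
#'
#' @param energy deposited energy in eV (vectorised, must be >= 0).
#' @param eMin,eMax ramp endpoints in eV.
#' @return Probabilities in [0, 1], same length as \code{energy}.
#' @examples
#' strandBreakProbability(c(5, 21.25, 37.5))
#' @export
strandBreakProbability <- function(energy, eMin = 5.0, eMax = 37.5) {
  if (any(!is.finite(energy)) || any(energy < 0)) {
    stop("energy must be finite and >= 0 (eV)")
  }
  pmin(1, pmax(0, (energy - eMin) / (eMax - eMin)))
}

#' Cluster strand breaks into DSB sites
#'
#' Strand breaks on opposite strands separated by at most
#' \code{maxSeparationBp} base pairs are paired into double-strand-break
#' sites; unpaired breaks are returned as isolated damage. When one break
#' could pair with several opposite-strand breaks, pairing is greedy
#' left-to-right by genomic position, taking the nearest available partner
#' (leftmost on ties), which is deterministic after sorting.
#'
#' @param breaks data.frame with columns \code{genomic_pos} (integer >= 0,
#'   0-based) and \code{strand} (1 or 2); optional columns \code{x}, \code{y},
#'   \code{z} (nm) are averaged into the site position.
#' @param maxSeparationBp maximum opposite-strand separation (bp).
#' @return list with elements \code{sites} (data.frame: site_id, bp_a, bp_b,
#'   and x/y/z when available) and \code{isolated} (the unpaired rows of
#'   \code{breaks}).
#' @examples
#' sb <- data.frame(genomic_pos = c(100, 105), strand = c(1, 2))
#' clusterStrandBreaks(sb)
#' @export
clusterStrandBreaks <- function(breaks, maxSeparationBp = 10L) {
  stopifnot(is.data.frame(breaks))
  if (nrow(breaks) == 0L) {
    return(list(sites = data.frame(site_id = integer(0), bp_a = integer(0),
                                   bp_b = integer(0)),
                isolated = breaks))
  }
  if (!all(breaks$strand %in% c(1L, 2L))) stop("strand must be 1 or 2")
  if (any(breaks$genomic_pos < 0)) stop("genomic_pos must be >= 0")
  ord <- order(breaks$genomic_pos, breaks$strand)
  b <- breaks[ord, , drop = FALSE]
  n <- nrow(b)
  partner <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(partner[i])) next
    cand <- which(is.na(partner) & b$strand != b$strand[i] &
                  abs(b$genomic_pos - b$genomic_pos[i]) <= maxSeparationBp)
    cand <- cand[cand != i]
    if (length(cand) == 0L) next
    d <- abs(b$genomic_pos[cand] - b$genomic_pos[i])
    j <- cand[order(d, cand)][1L]
    partner[i] <- j
    partner[j] <- i
  }
  first <- which(!is.na(partner) & partner > seq_len(n))
  sites <- data.frame(
    site_id = seq_along(first),
    bp_a = b$genomic_pos[first],
    bp_b = b$genomic_pos[partner[first]]
  )
  if (all(c("x", "y", "z") %in% names(b)) && length(first) > 0) {
    sites$x <- (b$x[first] + b$x[partner[first]]) / 2
    sites$y <- (b$y[first] + b$y[partner[first]]) / 2
    sites$z <- (b$z[first] + b$z[partner[first]]) / 2
  }
  list(sites = sites, isolated = b[is.na(partner), , drop = FALSE])
}

#' Generate photon-like damage
#'
#' Draws a Poisson number of DSB sites (mean \code{dose * dsbPerGy}) placed
#' independently and uniformly inside the nucleus, with per-end extra lesion
#' loads drawn from the configured complexity distribution. Sites are labelled
#' euchromatic; use \code{\link{assignChromatin}} to label heterochromatin.
#'
#' @param dose absorbed dose in Gy (>= 0).
#' @param nucleus a \linkS4class{Nucleus}.
#' @param dsbPerGy mean DSB yield per Gy per cell (default 25).
#' @param seed integer seed for reproducibility; NULL uses the ambient RNG
#'   stream (as the simulation engine does).
#' @param complexity list with \code{baseMean} and \code{ssbMean}: Poisson
#'   means of extra base lesions and extra single-strand breaks per end.
#' @return A \linkS4class{DamageSet}.
#' @examples
#' generatePhotonDamage(1, seed = 1)
#' @export
generatePhotonDamage <- function(dose, nucleus = .defaultNucleus(), dsbPerGy = 25,
                                 seed = NULL,
                                 complexity = list(baseMean = 0.5,
                                                   ssbMean = 0.3)) {
  if (!is.finite(dose) || dose < 0) stop("dose must be >= 0 (Gy)")
  .setSeed(seed)
  n <- stats::rpois(1L, dose * dsbPerGy)
  pos <- .uniformSphere(n, nucleus)
  new("DamageSet",
      sites = .makeSites(pos, "euchromatin", complexity),
      dose = as.numeric(dose), quality = "photon", let = NA_real_,
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nucleus = nucleus)
}

#' Generate simplified track-like damage
#'
#' Places DSB sites along straight chords through the nucleus, one chord per
#' primary particle. The per-track linear DSB density and the per-end lesion
#' complexity both increase monotonically with LET through configurable
#' functions, which is sufficient to exercise LET sweeps of residual damage;
#' no track-structure physics is modelled.
#'
#' @param let linear energy transfer in keV/um (> 0).
#' @param nPrimaries number of primary tracks (>= 0).
#' @param nucleus a \linkS4class{Nucleus}.
#' @param seed integer seed, or NULL for the ambient stream.
#' @param densityPerUm function of LET giving mean DSBs per um of chord.
#' @param complexityMean function of LET giving the Poisson mean of extra
#'   lesions (base and SSB pooled mean split 60/40) per end.
#' @return A \linkS4class{DamageSet} with quality "proton-like".
#' @examples
#' generateTrackDamage(10, nPrimaries = 5, seed = 1)
#' @export
generateTrackDamage <- function(let, nPrimaries, nucleus = .defaultNucleus(),
                                seed = NULL,
                                densityPerUm = function(l) 0.05 * l,
                                complexityMean = function(l) 0.2 + 0.02 * l) {
  if (!is.finite(let) || let <= 0) stop("let must be > 0 (keV/um)")
  if (nPrimaries < 0) stop("nPrimaries must be >= 0")
  .setSeed(seed)
  R <- nucleus@radius
  posL <- vector("list", nPrimaries)
  for (k in seq_len(nPrimaries)) {
    ## random chord: two independent uniform points on the sphere surface
    a <- stats::rnorm(3); a <- a / sqrt(sum(a^2)) * R
    bdir <- stats::rnorm(3); bdir <- bdir / sqrt(sum(bdir^2)) * R
    chordLenUm <- sqrt(sum((bdir - a)^2)) / 1000
    m <- stats::rpois(1L, densityPerUm(let) * chordLenUm)
    if (m > 0L) {
      ## strictly interior fractions along the chord
      f <- stats::runif(m)
      posL[[k]] <- cbind(a[1] + f * (bdir[1] - a[1]),
                         a[2] + f * (bdir[2] - a[2]),
                         a[3] + f * (bdir[3] - a[3]))
    }
  }
  pos <- do.call(rbind, c(posL, list(matrix(numeric(0), ncol = 3))))
  pos <- sweep(pos, 2, nucleus@centre, "+")
  colnames(pos) <- c("x", "y", "z")
  cm <- complexityMean(let)
  new("DamageSet",
      sites = .makeSites(pos, "euchromatin",
                         list(baseMean = 0.6 * cm, ssbMean = 0.4 * cm)),
      dose = 0, quality = "proton-like", let = as.numeric(let),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
      nucleus = nucleus)
}

#' Assign chromatin labels
#'
#' Labels each DSB site heterochromatic independently with the given
#' probability (Bernoulli assignment). The fractions used in practice are 0.48
#' (methylation-based assignment) and 0.25 (literature value).
#'
#' @param damage a \linkS4class{DamageSet}.
#' @param heterochromatinFraction probability in [0, 1].
#' @param seed integer seed, or NULL for the ambient stream.
#' @return The relabelled \linkS4class{DamageSet}.
#' @examples
#' d <- generatePhotonDamage(1, seed = 1)
#' assignChromatin(d, 0.48, seed = 2)
#' @export
assignChromatin <- function(damage, heterochromatinFraction, seed = NULL) {
  stopifnot(is(damage, "DamageSet"))
  p <- heterochromatinFraction
  if (!is.finite(p) || p < 0 || p > 1) {
    stop("heterochromatinFraction must lie in [0, 1]")
  }
  .setSeed(seed)
  n <- nrow(damage@sites)
  hc <- stats::runif(n) < p
  damage@sites$chromatin <- ifelse(hc, "heterochromatin", "euchromatin")
  damage
}
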