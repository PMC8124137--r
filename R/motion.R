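## CTRW sub-diffusive motion: Gaussian jump bursts separated by heavy-tailed
## trapping times, confined to the nucleus by reflection.

#' Sample CTRW trapping times
#'
#' Pareto-type (Lomax) heavy-tailed waits with
#' \eqn{P(W > w) = (1 + w/s)^{-\alpha}}, drawn by inversion as
#' \eqn{W = s (U^{-1/\alpha} - 1)}. The infinite-mean tail
#' (\eqn{\alpha < 1}) is what produces sub-linear ensemble mean-squared
#' displacement, growing as \eqn{t^{\alpha}} at times beyond the scale
#' \eqn{s}.
#'
#' @param n number of waits to draw.
#' @param params a \linkS4class{CTRWParams}.
#' @return numeric vector of waiting times (s), all > 0.
#' @examples
#' summary(sampleWaitTime(100, ctrwParams()))
#' @export
sampleWaitTime <- function(n, params) {
  stopifnot(is(params, "CTRWParams"))
  u <- stats::runif(n)
  params@waitTimeScale * (u^(-1 / params@waitTimeExponent) - 1)
}

#' Sample jump displacements
#'
#' Isotropic Gaussian jump: each axis is N(0, 2 D tau) with D the jump
#' diffusion coefficient and tau the jump duration.
#'
#' @param n number of jumps.
#' @param params a \linkS4class{CTRWParams}.
#' @return n x 3 matrix of displacements (nm).
#' @examples
#' colMeans(jumpDisplacement(1000, ctrwParams()))
#' @export
jumpDisplacement <- function(n, params) {
  stopifnot(is(params, "CTRWParams"))
  sd <- sqrt(2 * params@jumpDiffusionCoefficient * params@jumpDuration)
  matrix(stats::rnorm(3L * n, sd = sd), ncol = 3,
         dimnames = list(NULL, c("x", "y", "z")))
}

## Reflect positions (n x 3 matrix) back inside the sphere. Radial reflection
## about the surface, iterated for (rare) jumps larger than the diameter.
.reflectInside <- function(pos, nucleus) {
  ctr <- nucleus@centre
  R <- nucleus@radius
  for (iter in 1:50) {
    d <- sweep(pos, 2, ctr, "-")
    r <- sqrt(rowSums(d^2))
    out <- which(r >= R)
    if (length(out) == 0L) return(pos)
    rr <- r[out]
    fac <- (2 * R - rr) / rr
    fac[fac < 0] <- -fac[fac < 0]  # beyond 2R: fold back towards the centre
    pos[out, ] <- sweep(d[out, , drop = FALSE] * fac, 2, ctr, "+")
  }
  ## pathological jump: clamp just inside
  d <- sweep(pos, 2, ctr, "-")
  r <- sqrt(rowSums(d^2))
  out <- which(r >= R)
  if (length(out)) {
    pos[out, ] <- sweep(d[out, , drop = FALSE] * (0.999 * R / r[out]), 2,
                        ctr, "+")
  }
  pos
}

#' Advance mobile objects by one motion tick
#'
#' Every object whose trap has expired by the end of the tick performs one
#' Gaussian jump and draws a new trapping time; trapped objects do not move.
#' Positions are reflected at the nuclear boundary so that all objects remain
#' strictly inside the sphere. A synaptic complex is a single mobile object;
#' the engine moves the complex and keeps both member ends at its position.
#'
#' @param objects list with elements \code{position} (n x 3 matrix, nm) and
#'   \code{trappedUntil} (numeric vector, s).
#' @param now current simulation time (s).
#' @param dt tick length (s), > 0.
#' @param nucleus a \linkS4class{Nucleus}.
#' @param params a \linkS4class{CTRWParams}.
#' @return The updated \code{objects} list.
#' @examples
#' obj <- list(position = matrix(0, 2, 3), trappedUntil = c(0, 1e6))
#' stepMotion(obj, now = 0, dt = 0.5, nucleus(), ctrwParams())
#' @export
stepMotion <- function(objects, now, dt, nucleus, params) {
  if (dt <= 0) stop("dt must be > 0")
  tEndTick <- now + dt
  mv <- which(objects$trappedUntil <= tEndTick)
  if (length(mv)) {
    disp <- jumpDisplacement(length(mv), params)
    objects$position[mv, ] <- objects$position[mv, , drop = FALSE] + disp
    objects$position <- .reflectInside(objects$position, nucleus)
    objects$trappedUntil[mv] <- tEndTick + sampleWaitTime(length(mv), params)
  }
  objects
}
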