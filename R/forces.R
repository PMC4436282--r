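#' Social forces
#'
#' The three social forces acting on a focal bird, each computed from its
#' per-behaviour topological neighbour set. Weights are in newtons; the
#' returned vectors are forces in world coordinates.
#'
#' `separationForce()` pushes the focal bird away from each avoided
#' neighbour with weight `g(d)`: 1 inside the hard sphere (`d <= rH`),
#' decaying to 0 at the separation radius `rSep`. Contributions are
#' *averaged* over the avoided set, so avoiding several neighbours on
#' different sides partially cancels -- the mechanism by which avoiding a
#' single closest neighbour produces a longer avoidance displacement than
#' compromising between 6 or 7 of them.
#'
#' @param focalPosition length-3 position of the focal bird (m).
#' @param avoidPositions M x 3 matrix of avoided neighbours (may have 0 rows).
#' @param rH hard-sphere radius (m).
#' @param rSep separation radius (m).
#' @param wSep separation weight (N).
#' @param sepDecay `"linear"` or `"smoothstep"` decay between `rH` and `rSep`.
#' @param coincidentDirection unit vector used if a neighbour coincides with
#'   the focal position (the engine draws it from the world RNG stream).
#' @return length-3 force vector (N).
#' @examples
#' # one neighbour directly ahead at the hard-sphere radius: full backward push
#' separationForce(c(0, 0, 0), rbind(c(0.2, 0, 0)), rH = 0.2, rSep = 1, wSep = 2)
#' @export
separationForce <- function(focalPosition, avoidPositions, rH, rSep, wSep,
                            sepDecay = "linear",
                            coincidentDirection = c(1, 0, 0)) {
  if (is.null(avoidPositions) || NROW(avoidPositions) == 0) return(c(0, 0, 0))
  avoidPositions <- matrix(as.numeric(avoidPositions), ncol = 3)
  rel <- matrix(focalPosition, nrow(avoidPositions), 3, byrow = TRUE) - avoidPositions
  d <- sqrt(rowSums(rel^2))
  g <- sepRampWeight(d, rH, rSep, sepDecay)
  u <- rel / ifelse(d > 0, d, 1)
  coincident <- d == 0
  if (any(coincident))
    u[coincident, ] <- matrix(coincidentDirection, sum(coincident), 3, byrow = TRUE)
  wSep * colSums(u * g) / nrow(avoidPositions)
}

sepRampWeight <- function(d, rH, rSep, sepDecay = "linear") {
  u <- pmin(pmax((rSep - d) / (rSep - rH), 0), 1)
  if (sepDecay == "smoothstep") u <- u * u * (3 - 2 * u)
  ifelse(d <= rH, 1, ifelse(d >= rSep, 0, u))
}

#' @describeIn separationForce steers the focal heading toward the
#'   normalized mean forward direction of its alignment set; zero if the
#'   set is empty or its mean heading degenerates to zero length.
#' @param focalForward length-3 unit forward direction of the focal bird.
#' @param neighborForwards M x 3 matrix of neighbour forward directions.
#' @param wAlign alignment weight (N).
#' @export
alignmentForce <- function(focalForward, neighborForwards, wAlign) {
  if (is.null(neighborForwards) || NROW(neighborForwards) == 0) return(c(0, 0, 0))
  neighborForwards <- matrix(as.numeric(neighborForwards), ncol = 3)
  m <- colMeans(neighborForwards)
  n <- sqrt(sum(m^2))
  if (n < 1e-12) return(c(0, 0, 0))
  wAlign * (m / n - focalForward)
}

#' @describeIn separationForce unit-vector attraction toward the centroid
#'   of the cohesion set; zero if the set is empty or the focal bird sits at
#'   the centroid.
#' @param coherePositions M x 3 matrix of cohesion-set positions (m).
#' @param wCohere cohesion weight (N).
#' @export
cohesionForce <- function(focalPosition, coherePositions, wCohere) {
  if (is.null(coherePositions) || NROW(coherePositions) == 0) return(c(0, 0, 0))
  coherePositions <- matrix(as.numeric(coherePositions), ncol = 3)
  rel <- colMeans(coherePositions) - focalPosition
  n <- sqrt(sum(rel^2))
  if (n < 1e-12) return(c(0, 0, 0))
  wCohere * rel / n
}

#' @describeIn separationForce scalar thrust/brake along the forward axis
#'   relaxing the speed exponentially toward the cruise speed with time
#'   constant `tau`.
#' @param speed current speed (m/s).
#' @param cruiseSpeed cruise speed (m/s).
#' @param mass body mass (kg).
#' @param tau relaxation time constant (s).
#' @export
speedControlForce <- function(speed, cruiseSpeed, mass, tau) {
  stopifnot(tau > 0)
  mass * (cruiseSpeed - speed) / tau
}

# Level (unbanked) lateral/up axes for a forward direction: ez0 is world up
# projected perpendicular to ex, ey0 = ez0 x ex is the sideward axis.
levelFrame <- function(ex) {
  up <- c(0, 0, 1)
  e <- up - sum(up * ex) * ex
  n <- sqrt(sum(e^2))
  if (n < 1e-8) {
    ref <- c(1, 0, 0)
    e <- ref - sum(ref * ex) * ex
    n <- sqrt(sum(e^2))
  }
  ez0 <- e / n
  ey0 <- c(ez0[2] * ex[3] - ez0[3] * ex[2],
           ez0[3] * ex[1] - ez0[1] * ex[3],
           ez0[1] * ex[2] - ez0[2] * ex[1])
  list(ey0 = ey0, ez0 = ez0)
}

#' Banked-turn roll update
#'
#' Rolls the body frame about the forward axis toward the bank angle at
#' which the lateral component of the lift balances the lateral component
#' of the steering force, `beta* = atan(F_lat / (m g))`. The roll rate is
#' limited: at most `rollInRate` while the bank magnitude grows and
#' `rollOutRate` while it shrinks (birds roll into turns faster than they
#' roll out), and the bank is clamped at `maxRoll`. With zero lateral
#' steering the bank decays back to level flight.
#'
#' @param heading length-3 unit forward direction.
#' @param bank current bank angle (rad); the sign follows the sideward axis.
#' @param steeringForce length-3 steering force (N).
#' @param params a [FlockParams-class] (uses mass and the roll limits).
#' @param dt time step (s).
#' @return list with the new `bank` (rad) and the banked orthonormal frame
#'   `ex`, `ey`, `ez`.
#' @export
applyBanking <- function(heading, bank, steeringForce, params, dt) {
  stopifnot(dt > 0)
  lf <- levelFrame(heading)
  fLat <- sum(steeringForce * lf$ey0)
  target <- atan2(fLat, params@mass * 9.81)
  target <- min(max(target, -params@maxRoll), params@maxRoll)
  delta <- target - bank
  rate <- if (abs(target) > abs(bank)) params@rollInRate else params@rollOutRate
  delta <- min(max(delta, -rate * dt), rate * dt)
  bank <- bank + delta
  ey <- cos(bank) * lf$ey0 - sin(bank) * lf$ez0
  ez <- sin(bank) * lf$ey0 + cos(bank) * lf$ez0
  list(bank = bank, ex = heading, ey = ey, ez = ez)
}
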