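#' @import methods
NULL

#' Flocking model parameters
#'
#' Bundles the social-force parameters (separation, alignment, cohesion on
#' topological neighbour sets) and the flight parameters (cruise-speed
#' control and banked-turn dynamics) of a single bird. All values are SI.
#'
#' @slot rH hard-sphere radius (m): inside this distance the avoidance
#'   weight is maximal (1).
#' @slot rSep separation radius (m): beyond this distance no avoidance
#'   force acts.
#' @slot kAvoid number of closest neighbours avoided.
#' @slot kTopo topological range for alignment and cohesion (6-7 in
#'   starlings; default 7).
#' @slot wSep,wAlign,wCohere force weights (N).
#' @slot centralityGain fraction of the cohesion weight modulated by
#'   centrality (0 = plain unit-vector attraction for every bird, 1 =
#'   attraction proportional to how one-sided the neighbour distribution
#'   is, i.e. acting mainly on peripheral birds).
#' @slot wNoise behavioural-noise coefficient (N per metre of
#'   nearest-neighbour distance).
#' @slot reactionTime behavioural reaction interval (s); social forces are
#'   held between reaction updates.
#' @slot kTopoMix draw the alignment/cohesion range as "kTopo - 1 or kTopo"
#'   per bird per reaction (the empirical "6 or 7" rule).
#' @slot alignVelocity alignment as velocity matching (TRUE) or pure
#'   heading matching (FALSE).
#' @slot cruiseSpread quenched fractional spread of individual cruise
#'   speeds.
#' @slot cohereSpring cohesion as a spring to the perceived centre (TRUE)
#'   or constant-magnitude attraction (FALSE).
#' @slot fovHalfAngle field-of-view half-angle (rad); `pi` disables the
#'   filter.
#' @slot sepDecay decay of the avoidance weight between `rH` and `rSep`:
#'   `"linear"` or `"smoothstep"`.
#' @slot cruiseSpeed cruise speed (m/s).
#' @slot mass body mass (kg).
#' @slot speedTau speed relaxation time constant (s).
#' @slot rollInRate,rollOutRate maximum roll rate into and out of a banked
#'   turn (rad/s); birds roll into turns faster than they roll out.
#' @slot maxRoll bank-angle clamp (rad).
#' @slot pitchGain level-flight pitch restoring gain (1/s).
#'
#' @seealso [flockParams()]
#' @export
setClass("FlockParams", representation(
  rH = "numeric", rSep = "numeric",
  kAvoid = "integer", kTopo = "integer",
  wSep = "numeric", wAlign = "numeric", wCohere = "numeric",
  centralityGain = "numeric", wNoise = "numeric",
  reactionTime = "numeric", kTopoMix = "logical",
  alignVelocity = "logical", cruiseSpread = "numeric",
  cohereSpring = "logical",
  fovHalfAngle = "numeric", sepDecay = "character",
  cruiseSpeed = "numeric", mass = "numeric", speedTau = "numeric",
  rollInRate = "numeric", rollOutRate = "numeric",
  maxRoll = "numeric", pitchGain = "numeric"
))

setValidity("FlockParams", function(object) {
  msg <- character()
  if (!(object@rH > 0)) msg <- c(msg, "rH must be > 0")
  if (!(object@rSep > object@rH)) msg <- c(msg, "rSep must exceed rH")
  if (object@kAvoid < 1L) msg <- c(msg, "kAvoid must be >= 1")
  if (object@kTopo < 1L) msg <- c(msg, "kTopo must be >= 1")
  if (any(c(object@wSep, object@wAlign, object@wCohere) < 0))
    msg <- c(msg, "force weights must be >= 0")
  if (object@centralityGain < 0 || object@centralityGain > 1)
    msg <- c(msg, "centralityGain must be in [0, 1]")
  if (object@wNoise < 0) msg <- c(msg, "wNoise must be >= 0")
  if (!(object@reactionTime > 0)) msg <- c(msg, "reactionTime must be > 0")
  if (object@cruiseSpread < 0 || object@cruiseSpread >= 1)
    msg <- c(msg, "cruiseSpread must be in [0, 1)")
  if (!(object@fovHalfAngle > 0 && object@fovHalfAngle <= pi))
    msg <- c(msg, "fovHalfAngle must be in (0, pi]")
  if (!object@sepDecay %in% c("linear", "smoothstep"))
    msg <- c(msg, "sepDecay must be 'linear' or 'smoothstep'")
  flight <- c(object@cruiseSpeed, object@mass, object@speedTau,
              object@rollInRate, object@rollOutRate, object@maxRoll,
              object@pitchGain)
  if (any(!is.finite(flight)) || any(flight <= 0))
    msg <- c(msg, "flight parameters must be strictly positive")
  if (object@rollInRate < object@rollOutRate)
    msg <- c(msg, "rollInRate must be >= rollOutRate")
  if (length(msg)) msg else TRUE
})

#' Flock world state
#'
#' The complete simulation state: bird positions, forward directions (body
#' x-axes), speeds and bank angles, the model parameters and the RNG seed
#' stream. Velocity of bird i is `speeds[i] * headings[i, ]`.
#'
#' @slot time current simulation time (s).
#' @slot positions N x 3 matrix (m).
#' @slot headings N x 3 matrix of unit forward vectors.
#' @slot speeds length-N vector (m/s).
#' @slot banks length-N vector of bank angles (rad).
#' @slot params a [FlockParams-class].
#' @slot seed integer seed from which all stochastic draws derive.
#' @slot draws number of engine RNG draws consumed so far (coincident-pair
#'   escapes), so continuation runs stay reproducible.
#'
#' @export
setClass("FlockWorld", representation(
  time = "numeric", positions = "matrix", headings = "matrix",
  speeds = "numeric", banks = "numeric", params = "FlockParams",
  seed = "numeric", draws = "numeric"
))

setValidity("FlockWorld", function(object) {
  n <- nrow(object@positions)
  msg <- character()
  if (n < 2) msg <- c(msg, "a flock needs at least 2 birds")
  if (!all(is.finite(object@positions))) msg <- c(msg, "non-finite positions")
  if (!identical(dim(object@positions), dim(object@headings)))
    msg <- c(msg, "positions and headings must have identical shape")
  if (length(object@speeds) != n || length(object@banks) != n)
    msg <- c(msg, "speeds/banks length must equal bird count")
  hn <- sqrt(rowSums(object@headings^2))
  if (any(abs(hn - 1) > 1e-6)) msg <- c(msg, "headings must be unit vectors")
  if (length(msg)) msg else TRUE
})

#' Flock trajectory
#'
#' Time-indexed positions and forward directions of every bird, sampled at a
#' uniform interval. This is the input type of all internal-dynamics metrics
#' (neighbour stability, centre-of-mass diffusion, polarization, voxel
#' volume).
#'
#' @slot times sampling times (s), uniformly spaced.
#' @slot positions T x N x 3 array (m).
#' @slot forwards T x N x 3 array of unit forward vectors.
#'
#' @seealso [neighborStability()], [meanSquareDisplacement()],
#'   [polarization()], [voxelVolume()]
#' @export
setClass("FlockTrajectory", representation(
  times = "numeric", positions = "array", forwards = "array"
))

setValidity("FlockTrajectory", function(object) {
  msg <- character()
  dt <- diff(object@times)
  if (length(object@times) != dim(object@positions)[1])
    msg <- c(msg, "times length must match first array dimension")
  if (length(dt) > 0 && any(abs(dt - dt[1]) > 1e-9))
    msg <- c(msg, "sampling must be uniform")
  if (!identical(dim(object@positions), dim(object@forwards)))
    msg <- c(msg, "positions and forwards must have identical shape")
  if (length(dim(object@positions)) != 3 || dim(object@positions)[3] != 3)
    msg <- c(msg, "arrays must be T x N x 3")
  if (length(object@forwards) > 0) {
    fn <- sqrt(rowSums(matrix(object@forwards, ncol = 3)^2))
    if (any(abs(fn - 1) > 1e-6))
      msg <- c(msg, "forwards must be unit vectors")
  }
  if (length(msg)) msg else TRUE
})

#' Power-law diffusion fit
#'
#' Result of fitting `msd = D * t^alpha` by ordinary least squares of
#' log10(msd) on log10(t). `alpha` = 1 is normal (Brownian) diffusion,
#' `alpha` > 1 super-diffusion, `alpha` = 2 ballistic relative motion.
#'
#' @slot D diffusion coefficient (m^2 s^-alpha).
#' @slot alpha anomalous diffusion exponent.
#' @slot fitWindow `(t_min, t_max)` of the fitted range (s).
#' @slot rSquared goodness of fit on the log-log scale.
#' @slot nPoints number of points used.
#'
#' @seealso [fitPowerLaw()]
#' @export
setClass("DiffusionFit", representation(
  D = "numeric", alpha = "numeric", fitWindow = "numeric",
  rSquared = "numeric", nPoints = "integer"
))

setValidity("DiffusionFit", function(object) {
  msg <- character()
  if (!(object@D > 0)) msg <- c(msg, "D must be positive")
  if (object@nPoints < 5L) msg <- c(msg, "fit needs >= 5 points")
  if (length(msg)) msg else TRUE
})

#' Flock-event preset
#'
#' One row of the study design: an empirically observed flock event (labels
#' like "28-10") with its flock size, per-condition separation radii,
#' hard-sphere radius, target nearest-neighbour distance and the measurement
#' protocol times.
#'
#' @slot eventId event label.
#' @slot n flock size.
#' @slot rSepSingle separation radius when a single neighbour is avoided (m).
#' @slot rSepMulti separation radius when 6-7 neighbours are avoided (m).
#' @slot rH hard-sphere radius (m).
#' @slot targetNnd target mean nearest-neighbour distance (m).
#' @slot acclimatizationS settle time before measurement (s).
#' @slot diffusionWindowS short measurement window for stability/diffusion (s).
#' @slot longWindowS long window for polarization/volume (s).
#' @slot sampleDtS sampling interval of the short window (s).
#'
#' @seealso [loadPreset()], [runFlockEvent()]
#' @export
setClass("FlockEventPreset", representation(
  eventId = "character", n = "integer",
  rSepSingle = "numeric", rSepMulti = "numeric", rH = "numeric",
  targetNnd = "numeric", acclimatizationS = "numeric",
  diffusionWindowS = "numeric", longWindowS = "numeric", sampleDtS = "numeric"
))

setValidity("FlockEventPreset", function(object) {
  msg <- character()
  if (object@n < 2L) msg <- c(msg, "n must be >= 2")
  if (!(object@rH < object@rSepSingle && object@rH < object@rSepMulti))
    msg <- c(msg, "rH must be below both separation radii")
  if (!(object@targetNnd > 0)) msg <- c(msg, "targetNnd must be positive")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FlockParams", function(object) {
  cat("FlockParams\n")
  cat(sprintf("  social : rH=%.3g m, rSep=%.3g m, kAvoid=%d, kTopo=%d (%s decay)\n",
              object@rH, object@rSep, object@kAvoid, object@kTopo, object@sepDecay))
  cat(sprintf("  weights: wSep=%.3g, wAlign=%.3g, wCohere=%.3g N\n",
              object@wSep, object@wAlign, object@wCohere))
  cat(sprintf("  flight : cruise=%.3g m/s, mass=%.3g kg, tau=%.3g s, roll in/out=%.3g/%.3g rad/s, maxRoll=%.2f rad\n",
              object@cruiseSpeed, object@mass, object@speedTau,
              object@rollInRate, object@rollOutRate, object@maxRoll))
  invisible(object)
})

setMethod("show", "FlockWorld", function(object) {
  cat(sprintf("FlockWorld: %d birds at t = %.2f s (seed %s)\n",
              nrow(object@positions), object@time, format(object@seed)))
  invisible(object)
})

setMethod("show", "FlockTrajectory", function(object) {
  d <- dim(object@positions)
  dt <- if (length(object@times) > 1) diff(object@times)[1] else NA_real_
  cat(sprintf("FlockTrajectory: %d frames x %d birds, dt = %s s, span [%.2f, %.2f] s\n",
              d[1], d[2], format(dt), min(object@times), max(object@times)))
  invisible(object)
})

setMethod("show", "DiffusionFit", function(object) {
  cat(sprintf("DiffusionFit: msd = D t^alpha, D = %.3g m^2 s^-alpha, alpha = %.3f (R^2 = %.4f, %d points in [%.3g, %.3g] s)\n",
              object@D, object@alpha, object@rSquared, object@nPoints,
              object@fitWindow[1], object@fitWindow[2]))
  invisible(object)
})

setMethod("show", "FlockEventPreset", function(object) {
  cat(sprintf("FlockEventPreset %s: N=%d, rSep single/multi = %.2f/%.2f m, rH = %.2f m, target NND = %.2f m\n",
              object@eventId, object@n, object@rSepSingle, object@rSepMulti,
              object@rH, object@targetNnd))
  invisible(object)
})
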