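#' Construct flocking model parameters
#'
#' Default values describe a starling-like bird (mass 80 g, cruise speed
#' 10 m/s) flocking with a topological range of 7 neighbours for alignment
#' and cohesion while avoiding only its single closest neighbour. The force
#' weights are free parameters of the model, set so that the default
#' flock-event presets produce cohesive, highly polarized flocks.
#'
#' @param rH hard-sphere radius (m), avoidance weight 1 inside.
#' @param rSep separation radius (m), avoidance 0 beyond.
#' @param kAvoid number of closest neighbours avoided.
#' @param kTopo topological range for alignment and cohesion.
#' @param wSep,wAlign,wCohere force weights (N).
#' @param centralityGain fraction of the cohesion weight modulated by
#'   centrality; 0 applies the plain unit-vector attraction uniformly,
#'   1 concentrates attraction on peripheral birds.
#' @param wNoise behavioural-noise coefficient (N per metre): each bird
#'   feels an isotropic random force of magnitude `wNoise` times its
#'   current nearest-neighbour distance (perceptual error grows with the
#'   distance at which neighbours are tracked; capped at `rSep`), redrawn
#'   at each reaction update.
#' @param reactionTime behavioural reaction interval (s): the social force
#'   of each bird is re-evaluated at this rate (staggered across birds) and
#'   held constant in between, while flight dynamics integrate at `dt`.
#'   Values at or below the integration step mean reaction every step.
#' @param kTopoMix starlings attend to "6 or 7" neighbours: when `TRUE`
#'   each bird redraws its alignment/cohesion range between `kTopo - 1`
#'   and `kTopo` at every reaction update.
#' @param alignVelocity when `TRUE` alignment matches the mean
#'   neighbour velocity, `wAlign * (v_mean - v) / cruiseSpeed`, damping
#'   relative motion; `FALSE` (default) uses the pure heading form
#'   `wAlign * (unit mean heading - e_x)`.
#' @param cruiseSpread quenched individual variation of the preferred
#'   cruise speed, as a half-width fraction (each bird's cruise speed is
#'   fixed for the whole run, uniform within `+/- cruiseSpread`).
#' @param cohereSpring when `TRUE` cohesion is a spring toward
#'   the perceived centre, `wCohere` newton per metre of centroid offset;
#'   `FALSE` (default) uses the constant-magnitude unit-vector attraction.
#' @param fovHalfAngle field-of-view half-angle (rad); `pi` disables it.
#' @param sepDecay `"linear"` (default) or `"smoothstep"` decay of the
#'   avoidance weight between `rH` and `rSep`.
#' @param cruiseSpeed cruise speed (m/s).
#' @param mass body mass (kg).
#' @param speedTau speed relaxation time (s).
#' @param rollInRate,rollOutRate roll rate limits into/out of a turn (rad/s).
#' @param maxRoll maximum bank angle (rad).
#' @param pitchGain level-flight pitch restoring gain (1/s).
#' @return a [FlockParams-class] object.
#' @examples
#' p <- flockParams(kAvoid = 1, rSep = 1.75)
#' p
#' @export
flockParams <- function(rH = 0.2, rSep = 1.75, kAvoid = 1L, kTopo = 7L,
                        wSep = 1.0, wAlign = 1.0, wCohere = 0.5,
                        centralityGain = 1.0, wNoise = 0.26,
                        reactionTime = 0.15, kTopoMix = FALSE,
                        alignVelocity = FALSE, cruiseSpread = 0.01,
                        cohereSpring = FALSE,
                        fovHalfAngle = pi, sepDecay = "linear",
                        cruiseSpeed = 10, mass = 0.08, speedTau = 0.15,
                        rollInRate = 6.0, rollOutRate = 3.0,
                        maxRoll = 1.222, pitchGain = 2.0) {
  if (kAvoid > kTopo)
    warning("kAvoid exceeds kTopo: avoidance uses more neighbours than alignment/cohesion")
  new("FlockParams",
      rH = as.numeric(rH), rSep = as.numeric(rSep),
      kAvoid = as.integer(kAvoid), kTopo = as.integer(kTopo),
      wSep = as.numeric(wSep), wAlign = as.numeric(wAlign),
      wCohere = as.numeric(wCohere),
      centralityGain = as.numeric(centralityGain),
      wNoise = as.numeric(wNoise),
      reactionTime = as.numeric(reactionTime),
      kTopoMix = isTRUE(kTopoMix), alignVelocity = isTRUE(alignVelocity),
      cruiseSpread = as.numeric(cruiseSpread),
      cohereSpring = isTRUE(cohereSpring),
      fovHalfAngle = as.numeric(fovHalfAngle), sepDecay = sepDecay,
      cruiseSpeed = as.numeric(cruiseSpeed), mass = as.numeric(mass),
      speedTau = as.numeric(speedTau),
      rollInRate = as.numeric(rollInRate), rollOutRate = as.numeric(rollOutRate),
      maxRoll = as.numeric(maxRoll), pitchGain = as.numeric(pitchGain))
}

# flat list consumed by the C++ engine
paramsAsList <- function(p) {
  list(rH = p@rH, rSep = p@rSep, kAvoid = p@kAvoid, kTopo = p@kTopo,
       wSep = p@wSep, wAlign = p@wAlign, wCohere = p@wCohere,
       centralityGain = p@centralityGain, wNoise = p@wNoise,
       reactionTime = p@reactionTime, kTopoMix = p@kTopoMix,
       alignVelocity = p@alignVelocity, cruiseSpread = p@cruiseSpread,
       cohereSpring = p@cohereSpring,
       fovHalfAngle = p@fovHalfAngle, sepDecay = p@sepDecay,
       cruiseSpeed = p@cruiseSpeed, mass = p@mass, speedTau = p@speedTau,
       rollInRate = p@rollInRate, rollOutRate = p@rollOutRate,
       maxRoll = p@maxRoll, pitchGain = p@pitchGain)
}

#' @describeIn flockParams replace named parameters, returning a new object.
#' @param params a [FlockParams-class] object.
#' @param ... name = value pairs of slots to replace.
#' @export
updateParams <- function(params, ...) {
  stopifnot(is(params, "FlockParams"))
  repl <- list(...)
  args <- paramsAsList(params)
  unknown <- setdiff(names(repl), names(args))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
  args[names(repl)] <- repl
  do.call(flockParams, args)
}

#' Accessors for flock objects
#'
#' @param x a [FlockWorld-class] or [FlockTrajectory-class].
#' @return `nBirds()` the bird count; `positions()` an N x 3 matrix (world)
#'   or T x N x 3 array (trajectory); `forwards()` likewise for the unit
#'   forward directions; `frameTimes()` the sampling times of a trajectory;
#'   `params()` the [FlockParams-class] of a world.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nBirds", function(x) standardGeneric("nBirds"))
#' @rdname accessors
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))
#' @rdname accessors
#' @export
setGeneric("forwards", function(x) standardGeneric("forwards"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("params", function(x) standardGeneric("params"))

#' @rdname accessors
setMethod("nBirds", "FlockWorld", function(x) nrow(x@positions))
#' @rdname accessors
setMethod("nBirds", "FlockTrajectory", function(x) dim(x@positions)[2])
#' @rdname accessors
setMethod("positions", "FlockWorld", function(x) x@positions)
#' @rdname accessors
setMethod("positions", "FlockTrajectory", function(x) x@positions)
#' @rdname accessors
setMethod("forwards", "FlockWorld", function(x) x@headings)
#' @rdname accessors
setMethod("forwards", "FlockTrajectory", function(x) x@forwards)
#' @rdname accessors
setMethod("frameTimes", "FlockTrajectory", function(x) x@times)
#' @rdname accessors
setMethod("params", "FlockWorld", function(x) x@params)

#' Number of frames in a trajectory
#' @param traj a [FlockTrajectory-class].
#' @export
nFrames <- function(traj) dim(traj@positions)[1]

#' Build a trajectory object from raw arrays
#'
#' @param times sampling times (s), uniformly spaced.
#' @param positions T x N x 3 array of positions (m).
#' @param forwards T x N x 3 array of unit forward vectors; if missing, unit
#'   +x is used for every bird (metrics that need headings then see a fully
#'   polarized flock).
#' @return a [FlockTrajectory-class].
#' @export
flockTrajectory <- function(times, positions, forwards = NULL) {
  if (is.null(forwards)) {
    forwards <- array(0, dim(positions))
    forwards[, , 1] <- 1
  }
  new("FlockTrajectory", times = as.numeric(times),
      positions = positions, forwards = forwards)
}
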