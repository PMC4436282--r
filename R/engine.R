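#' Initialize a flock
#'
#' Places `n` birds uniformly at random in a sphere whose radius is chosen
#' so that the expected mean nearest-neighbour distance approximates
#' `targetNnd` (using the Poisson-process relation
#' `NND = 0.5540 * density^(-1/3)`), with headings along +x perturbed by a
#' small Gaussian angle (sd 0.1 rad) and all speeds at the cruise speed.
#' Fully reproducible from `seed`.
#'
#' @param n number of birds (>= 2).
#' @param targetNnd target mean nearest-neighbour distance (m).
#' @param params a [FlockParams-class]; its cruise speed sets initial speeds.
#' @param seed integer seed.
#' @param headingSd sd of the heading perturbation (rad).
#' @return a [FlockWorld-class] at time 0.
#' @examples
#' w <- initializeFlock(50, targetNnd = 0.8, seed = 1)
#' w
#' @export
initializeFlock <- function(n, targetNnd, params = flockParams(), seed = 1L,
                            headingSd = 0.1) {
  stopifnot(n >= 2, targetNnd > 0)
  n <- as.integer(n)
  rho <- (0.5540 / targetNnd)^3          # birds per m^3
  radius <- (3 * n / (4 * pi * rho))^(1 / 3)
  rs <- .rngScope(seed)
  # uniform in a sphere
  u <- matrix(stats::rnorm(3L * n), n, 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius * stats::runif(n)^(1 / 3)
  pos <- u * r
  # headings: +x rotated by small Gaussian lateral components
  head <- cbind(1, stats::rnorm(n, 0, headingSd), stats::rnorm(n, 0, headingSd))
  head <- head / sqrt(rowSums(head^2))
  .rngRestore(rs)
  new("FlockWorld", time = 0, positions = pos, headings = head,
      speeds = rep(params@cruiseSpeed, n), banks = rep(0, n),
      params = params, seed = as.numeric(seed), draws = 0)
}

# run a seeded block of R RNG without disturbing the caller's stream
.rngScope <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed) %% .Machine$integer.max)
  old
}
.rngRestore <- function(old) {
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Advance a flock through time
#'
#' Integrates the model with a fixed-step explicit Euler scheme: per step
#' and bird, topological neighbour sets are recomputed on a fresh spatial
#' index, the social forces (separation over the `kAvoid` closest,
#' alignment and cohesion over the `kTopo` closest) are summed, speed
#' relaxes toward cruise under the forward force component, and turning is
#' produced by rolling toward the bank angle whose lateral lift component
#' matches the lateral steering demand (vertical steering passes through a
#' level-flight pitch term). Velocity is always `speed * forward`. The run
#' is deterministic given the world (including its seed).
#'
#' @param world a [FlockWorld-class].
#' @param duration simulated time to advance (s).
#' @param dt integration step (s); default 0.01.
#' @param recordEvery record one frame every this many seconds (must be a
#'   multiple of `dt`); `NULL` records nothing (fast settle runs).
#' @param recordInitial include the starting state as frame 0.
#' @return list with `world` (the advanced [FlockWorld-class]) and
#'   `trajectory` (a [FlockTrajectory-class], or `NULL` when not recording).
#' @examples
#' w <- initializeFlock(30, targetNnd = 0.8, seed = 2)
#' out <- simulateFlock(w, duration = 1, recordEvery = 0.1)
#' out$trajectory
#' @export
simulateFlock <- function(world, duration, dt = 0.01, recordEvery = dt,
                          recordInitial = TRUE) {
  stopifnot(is(world, "FlockWorld"), duration > 0, dt > 0)
  nSteps <- as.integer(round(duration / dt))
  record <- !is.null(recordEvery)
  if (record) {
    every <- as.integer(round(recordEvery / dt))
    if (abs(every * dt - recordEvery) > 1e-9)
      stop("recordEvery must be a multiple of dt")
  } else {
    every <- nSteps + 1L
    recordInitial <- FALSE
  }
  res <- .simulate_cpp(world@positions, world@headings, world@speeds,
                       world@banks, paramsAsList(world@params), dt, nSteps,
                       every, isTRUE(recordInitial),
                       world@seed * 2^16 + (world@time * 100) %% 2^16 + 1,
                       world@seed + 1)
  newWorld <- new("FlockWorld", time = world@time + nSteps * dt,
                  positions = res$finalPositions, headings = res$finalHeadings,
                  speeds = as.numeric(res$finalSpeeds),
                  banks = as.numeric(res$finalBanks),
                  params = world@params, seed = world@seed,
                  draws = world@draws + res$coincidentEvents)
  traj <- NULL
  if (record && length(res$times) > 0) {
    if (res$coincidentEvents > 0)
      message(res$coincidentEvents,
              " coincident-position escape direction(s) drawn from the world RNG")
    traj <- new("FlockTrajectory", times = world@time + res$times,
                positions = res$positions, forwards = res$forwards)
  }
  list(world = newWorld, trajectory = traj)
}

#' @describeIn simulateFlock advance exactly one integration step and
#'   return the new [FlockWorld-class].
#' @export
stepFlock <- function(world, dt = 0.01) {
  simulateFlock(world, duration = dt, dt = dt, recordEvery = NULL)$world
}
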