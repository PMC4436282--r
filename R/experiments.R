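#' Run one flock-event measurement protocol
#'
#' Initializes a flock from the preset, lets it settle for the
#' acclimatization time (unrecorded), records the short diffusion window
#' (default 2 s at 0.01 s) for neighbour stability and centre-of-mass
#' diffusion, then continues recording a long window for polarization and
#' volume. The summary aggregates every internal-dynamics measure.
#'
#' @param preset a [FlockEventPreset-class] (see [loadPreset()]).
#' @param kAvoid number of closest neighbours avoided.
#' @param seed integer seed; the run is fully reproducible from it.
#' @param stabilityM neighbourhood sizes for the stability curves.
#' @param t0Every spacing of the start-time offsets Q and dr2 average over (s).
#' @param fitWindow power-law fit window (s).
#' @param longSampleDt sampling interval of the long window (s); volume and
#'   polarization vary slowly, so 0.5 s keeps memory modest.
#' @param longWindow `TRUE` to run the long polarization/volume window;
#'   `FALSE` measures polarization and volume on the diffusion window only.
#' @param ... overrides forwarded to [flockParams()] via [presetParams()].
#' @return list with `diffusionTrajectory`, `longTrajectory` (or `NULL`)
#'   and `summary`, a list carrying `D`, `alpha`, `rSquared`, the `Q`
#'   curves, `phiGlobal`, `phiLocal`, `volumeM3`, `nndM`, `fission` and the
#'   run configuration.
#' @examples
#' \donttest{
#' pre <- loadPreset("28-10")
#' run <- runFlockEvent(pre, kAvoid = 1, seed = 1)
#' run$summary$D
#' }
#' @export
runFlockEvent <- function(preset, kAvoid, seed, stabilityM = c(4L, 6L, 10L),
                          t0Every = 0.1, fitWindow = c(0.05, 1.0),
                          longSampleDt = 0.5, longWindow = TRUE, ...) {
  stopifnot(is(preset, "FlockEventPreset"), kAvoid >= 1)
  par <- presetParams(preset, kAvoid = kAvoid, ...)
  world <- initializeFlock(preset@n, preset@targetNnd, par, seed = seed)
  dt <- preset@sampleDtS

  settled <- simulateFlock(world, preset@acclimatizationS, dt = dt,
                           recordEvery = NULL)$world
  diff <- simulateFlock(settled, preset@diffusionWindowS, dt = dt,
                        recordEvery = dt, recordInitial = TRUE)
  diffTraj <- diff$trajectory

  span <- preset@diffusionWindowS
  t0s <- seq(0, span / 2, by = t0Every)
  tValues <- seq(dt, span / 2, by = dt)
  msd <- meanSquareDisplacement(diffTraj, tValues, t0s)
  fit <- fitPowerLaw(msd$t_s, msd$msd_m2, fitWindow)
  qT <- seq(0.1, min(1, span / 2), by = 0.1)
  qCurves <- lapply(stabilityM, function(M)
    neighborStability(diffTraj, M, qT, t0s))
  names(qCurves) <- paste0("M", stabilityM)

  longTraj <- NULL
  if (isTRUE(longWindow) && preset@longWindowS > preset@diffusionWindowS) {
    long <- simulateFlock(diff$world,
                          preset@longWindowS - preset@diffusionWindowS,
                          dt = dt, recordEvery = longSampleDt,
                          recordInitial = FALSE)
    longTraj <- long$trajectory
    orderTraj <- longTraj
  } else {
    orderTraj <- diffTraj
  }

  lastPos <- function(tr, f) tr@positions[f, , ]
  # order/volume statistics vary slowly; sample at ~0.1 s when the source
  # trajectory is finer
  stride <- max(1L, as.integer(round(0.1 / (orderTraj@times[2] - orderTraj@times[1]))))
  tIdx <- seq(1L, nFrames(orderTraj), by = stride)
  phi <- mean(vapply(tIdx, function(f)
    polarization(orderTraj@forwards[f, , ]), numeric(1)))
  vol <- mean(vapply(tIdx, function(f)
    voxelVolume(lastPos(orderTraj, f), preset@targetNnd), numeric(1)))
  finalFrame <- nFrames(orderTraj)
  phiLocal <- localPolarization(lastPos(orderTraj, finalFrame),
                                orderTraj@forwards[finalFrame, , ],
                                par@kTopo)
  nnd <- mean(vapply(tIdx, function(f)
    measureNnd(lastPos(orderTraj, f)), numeric(1)))
  fission <- flagFission(lastPos(orderTraj, finalFrame), par@rSep)

  summary <- list(
    eventId = preset@eventId, kAvoid = as.integer(kAvoid), seed = seed,
    n = preset@n, rSep = par@rSep,
    D = fit@D, alpha = fit@alpha, rSquared = fit@rSquared,
    msd = msd, qCurves = qCurves,
    phiGlobal = phi, phiLocal = phiLocal,
    volumeM3 = vol, nndM = nnd, cellSizeM = preset@targetNnd,
    fission = fission)
  list(diffusionTrajectory = diffTraj, longTrajectory = longTraj,
       summary = summary)
}

# a flock has fissioned if any bird is farther than 10 * rSep from every other
flagFission <- function(positions, rSep) {
  nn <- .frameNeighborSets(as.matrix(positions), 1L)[, 1]
  d <- sqrt(rowSums((positions - positions[nn, , drop = FALSE])^2))
  any(d > 10 * rSep)
}

#' Sweep the number of avoided neighbours
#'
#' Runs the diffusion-window protocol for each `kAvoid` in `kValues` and
#' each seed, reporting per run the neighbour stability of the 4 closest at
#' a 1 s lag, the diffusion fit (D, alpha) and the polarization. This is
#' the saturation-curve experiment: D and the stability deficit saturate as
#' more neighbours are avoided.
#'
#' @param preset a [FlockEventPreset-class].
#' @param kValues numbers of avoided neighbours (default 1:7).
#' @param nSeeds seeds per condition (1..nSeeds).
#' @param ... forwarded to [runFlockEvent()].
#' @return data.frame with one row per (kAvoid, seed): `Q4_1s`, `D`,
#'   `alpha`, `phi`, `volumeM3`, `nndM`.
#' @export
sweepKAvoid <- function(preset, kValues = 1:7, nSeeds = 3, ...) {
  stopifnot(length(kValues) >= 1)
  rows <- list()
  for (k in kValues) {
    for (s in seq_len(nSeeds)) {
      run <- runFlockEvent(preset, kAvoid = k, seed = s,
                           longWindow = FALSE, ...)
      sm <- run$summary
      q4 <- sm$qCurves$M4
      rows[[length(rows) + 1L]] <- data.frame(
        kAvoid = k, seed = s,
        Q4_1s = q4$Q[which.min(abs(q4$t_s - 1))],
        D = sm$D, alpha = sm$alpha, phi = sm$phiGlobal,
        volumeM3 = sm$volumeM3, nndM = sm$nndM)
    }
  }
  do.call(rbind, rows)
}

#' Flock volume versus flock size at fixed density
#'
#' For each flock size, calibrates the separation radius so that the mean
#' nearest-neighbour distance matches the fixed target, runs the long-window
#' protocol and reports the time-averaged voxelised volume. At a fixed NND
#' the occupied volume grows with flock size, and avoiding a single
#' neighbour yields larger flocks than avoiding 6-7.
#'
#' @param sizes flock sizes (each >= 2).
#' @param kAvoid number of neighbours avoided.
#' @param targetNnd the fixed nearest-neighbour distance (m), also the voxel
#'   cell size.
#' @param seeds seeds to average over.
#' @param referenceEvent preset supplying radii and protocol: an event id
#'   (default `"28-10"`) or a [FlockEventPreset-class].
#' @param calibrate bisect the separation radius per size (`TRUE`) or reuse
#'   the reference-event radius (`FALSE`, faster).
#' @param ... forwarded to [runFlockEvent()].
#' @return data.frame with one row per (size, seed): `n`, `seed`, `rSep`,
#'   `volumeM3`, `nndM`.
#' @export
volumeVsSize <- function(sizes, kAvoid, targetNnd = NULL, seeds = 1L,
                         referenceEvent = "28-10", calibrate = FALSE, ...) {
  stopifnot(all(sizes >= 2))
  if (is(referenceEvent, "FlockEventPreset")) {
    base <- referenceEvent
    if (!is.null(targetNnd)) base@targetNnd <- as.numeric(targetNnd)
  } else {
    base <- loadPreset(referenceEvent, targetNnd = targetNnd)
  }
  rows <- list()
  for (n in sizes) {
    pre <- base
    pre@n <- as.integer(n)
    rSep <- presetRSep(pre, kAvoid)
    if (isTRUE(calibrate)) {
      rSep <- tryCatch(
        calibrateRSep(pre, targetNnd = pre@targetNnd, kAvoid = kAvoid),
        error = function(e) {
          warning("calibration failed for N = ", n, ": ", conditionMessage(e))
          NA_real_
        })
      if (is.na(rSep)) next
    }
    for (s in seeds) {
      run <- runFlockEvent(pre, kAvoid = kAvoid, seed = s, rSep = rSep, ...)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, seed = s, rSep = rSep,
        volumeM3 = run$summary$volumeM3, nndM = run$summary$nndM)
    }
  }
  do.call(rbind, rows)
}

#' Calibrate the separation radius to a target nearest-neighbour distance
#'
#' Bisection on `rSep` over `[rH, 10 * targetNnd]`: each evaluation
#' simulates the flock for `settleS` seconds and measures the time-averaged
#' NND over the last `measureS` seconds. Stops when the relative error is
#' within `tolerance` (default 5%) or after `maxIter` iterations (with a
#' warning). NND is assumed non-decreasing in `rSep`; the assumption is
#' checked on the evaluated points and a violation raises an error carrying
#' the evaluated pairs.
#'
#' @param preset a [FlockEventPreset-class] (supplies N and rH).
#' @param targetNnd target mean NND (m), must exceed rH.
#' @param kAvoid avoidance condition being calibrated.
#' @param tolerance relative NND tolerance.
#' @param maxIter bisection iteration cap.
#' @param settleS,measureS simulated settle and measurement times (s).
#' @param seed seed for the evaluation runs.
#' @param ... forwarded to [flockParams()].
#' @return calibrated `rSep` (m), with attribute `nnd` (the achieved NND).
#' @export
calibrateRSep <- function(preset, targetNnd, kAvoid = 1L, tolerance = 0.05,
                          maxIter = 12L, settleS = 30, measureS = 5,
                          seed = 1L, ...) {
  stopifnot(targetNnd > preset@rH)
  evalNnd <- function(rSep) {
    par <- flockParams(rH = preset@rH, rSep = rSep,
                       kAvoid = as.integer(kAvoid), ...)
    w <- initializeFlock(preset@n, targetNnd, par, seed = seed)
    w <- simulateFlock(w, settleS - measureS, recordEvery = NULL)$world
    tr <- simulateFlock(w, measureS, recordEvery = 0.5,
                        recordInitial = FALSE)$trajectory
    mean(vapply(seq_len(nFrames(tr)),
                function(f) measureNnd(tr@positions[f, , ]), numeric(1)))
  }
  lo <- preset@rH; hi <- 10 * targetNnd
  evaluated <- data.frame(rSep = numeric(), nnd = numeric())
  note <- function(r, v) evaluated[nrow(evaluated) + 1L, ] <<- c(r, v)
  best <- NULL
  for (it in seq_len(maxIter)) {
    mid <- (lo + hi) / 2
    v <- evalNnd(mid)
    note(mid, v)
    if (is.null(best) || abs(v - targetNnd) < abs(attr(best, "nnd") - targetNnd)) {
      best <- mid
      attr(best, "nnd") <- v
    }
    if (abs(v - targetNnd) / targetNnd <= tolerance) {
      ord <- order(evaluated$rSep)
      if (is.unsorted(evaluated$nnd[ord] + 1e-9 * seq_along(ord) * 0)) {
        # tolerate small stochastic wiggles only
        if (any(diff(evaluated$nnd[ord]) < -0.2 * targetNnd))
          stop("NND not monotone in rSep over evaluated points: ",
               paste(sprintf("(%.3f, %.3f)", evaluated$rSep[ord],
                             evaluated$nnd[ord]), collapse = " "))
      }
      out <- mid
      attr(out, "nnd") <- v
      return(out)
    }
    if (v < targetNnd) lo <- mid else hi <- mid
  }
  warning("calibration hit the iteration cap; returning the best evaluated rSep")
  best
}
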