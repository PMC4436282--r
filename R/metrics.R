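#' Centre-of-mass frame of a trajectory
#'
#' Subtracts the instantaneous flock centroid from every position, removing
#' the global translation of the flock. Internal-dynamics measures
#' (diffusion) are computed in this frame.
#'
#' @param traj a [FlockTrajectory-class].
#' @return T x N x 3 array of relative positions; each frame sums to zero.
#' @export
comFrame <- function(traj) {
  pos <- traj@positions
  com <- apply(pos, c(1, 3), mean)           # T x 3
  sweep(pos, c(1, 3), com, "-")
}

.frameIndex <- function(traj, t, what = "time") {
  times <- traj@times
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  idx <- round((t - times[1]) / dt) + 1
  if (any(idx < 1 | idx > length(times)))
    stop(what, " outside the trajectory span [",
         format(times[1]), ", ", format(times[length(times)]), "] s")
  as.integer(idx)
}

# nearest-M neighbour sets (N x M matrix) for one frame
.frameNeighborSets <- function(pos, M) {
  if (M == 1L || nrow(pos) <= 60) {
    res <- vapply(seq_len(nrow(pos)),
                  function(i) findTopologicalNeighbors(pos, i, M),
                  integer(M))
    matrix(res, ncol = M, byrow = TRUE)
  } else {
    knnAll(pos, M)
  }
}

#' Neighbour stability (neighbour overlap) curve
#'
#' For each lag `t`, the fraction of a bird's `M` nearest neighbours at a
#' start time `t0` that are still among its `M` nearest at `t0 + t`,
#' averaged over birds and over the supplied start offsets:
#' `Q_M(t) = (1/N) sum_i M_i(t) / M`. `Q_M(0) = 1` exactly, and a rigidly
#' moving flock keeps `Q_M = 1` at all lags.
#'
#' @param traj a [FlockTrajectory-class].
#' @param M neighbourhood size (<= N - 1).
#' @param tValues lags (s) at which to evaluate.
#' @param t0Offsets start times (s), relative to the first frame, to average
#'   over; default the single offset 0.
#' @return data.frame with columns `t_s` and `Q`; attribute `M`.
#' @export
neighborStability <- function(traj, M, tValues, t0Offsets = 0) {
  n <- nBirds(traj)
  stopifnot(M >= 1, M <= n - 1)
  M <- as.integer(M)
  t0Idx <- .frameIndex(traj, traj@times[1] + t0Offsets, "t0")
  lagIdx <- as.integer(round(tValues / (traj@times[2] - traj@times[1])))
  needed <- sort(unique(c(t0Idx, rep(t0Idx, each = length(lagIdx)) +
                            rep(lagIdx, length(t0Idx)))))
  if (any(needed > nFrames(traj)))
    stop("t0 + t outside the trajectory span")
  sets <- lapply(needed, function(f) .frameNeighborSets(traj@positions[f, , ], M))
  names(sets) <- as.character(needed)
  # per-bird overlap, vectorized by encoding (bird, neighbour) pairs
  rowKey <- rep(seq_len(n), M) * (n + 1L)
  Q <- vapply(lagIdx, function(lag) {
    mean(vapply(t0Idx, function(f0) {
      k0 <- as.vector(sets[[as.character(f0)]]) + rowKey
      k1 <- as.vector(sets[[as.character(f0 + lag)]]) + rowKey
      sum(k1 %in% k0) / (n * M)
    }, numeric(1)))
  }, numeric(1))
  out <- data.frame(t_s = tValues, Q = Q)
  attr(out, "M") <- M
  out
}

#' Mean-square displacement in the centre-of-mass frame
#'
#' The group-level diffusion measure: for each lag `t`,
#' `dr2(t) = (1/N) sum_i || r_i(t0 + t) - r_i(t0) ||^2` with `r_i` the
#' position relative to the instantaneous centre of mass, averaged over the
#' supplied start offsets. Rigid global translation contributes nothing.
#'
#' @inheritParams neighborStability
#' @param tValues lags (s).
#' @return data.frame with columns `t_s` and `msd_m2`.
#' @export
meanSquareDisplacement <- function(traj, tValues, t0Offsets = 0) {
  rel <- comFrame(traj)
  t0Idx <- .frameIndex(traj, traj@times[1] + t0Offsets, "t0")
  dt <- traj@times[2] - traj@times[1]
  lagIdx <- as.integer(round(tValues / dt))
  if (any(max(t0Idx) + lagIdx > nFrames(traj)))
    stop("t0 + t outside the trajectory span")
  msd <- vapply(lagIdx, function(lag) {
    mean(vapply(t0Idx, function(f0) {
      d <- rel[f0 + lag, , ] - rel[f0, , ]
      mean(rowSums(d^2))
    }, numeric(1)))
  }, numeric(1))
  data.frame(t_s = tValues, msd_m2 = msd)
}

#' Fit a power law to a mean-square-displacement curve
#'
#' Ordinary least squares of `log10(msd)` on `log10(t)` inside the fit
#' window: the slope is the anomalous diffusion exponent `alpha` and the
#' intercept `log10(D)`, i.e. `msd = D t^alpha`. The default window
#' 0.05-1.0 s excludes both the first samples and the late-time saturation
#' bend that appears once birds have explored the whole flock volume.
#'
#' @param tValues lags (s).
#' @param msd mean-square displacements (m^2), same length.
#' @param fitWindow `(t_min, t_max)` (s).
#' @return a [DiffusionFit-class].
#' @examples
#' t <- seq(0.05, 1, by = 0.05)
#' fitPowerLaw(t, 4 * t)   # D = 4, alpha = 1
#' @export
fitPowerLaw <- function(tValues, msd, fitWindow = c(0.05, 1.0)) {
  keep <- tValues >= fitWindow[1] & tValues <= fitWindow[2] & tValues > 0
  if (sum(keep) < 5) stop("fewer than 5 points inside the fit window")
  if (any(msd[keep] <= 0)) stop("non-positive msd inside the fit window")
  x <- log10(tValues[keep]); y <- log10(msd[keep])
  fit <- stats::lm.fit(cbind(1, x), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  new("DiffusionFit", D = 10^fit$coefficients[[1]],
      alpha = fit$coefficients[[2]],
      fitWindow = as.numeric(fitWindow), rSquared = r2,
      nPoints = as.integer(sum(keep)))
}

#' Polarization order parameter
#'
#' The average correspondence between each bird's forward direction and the
#' flock's mean forward direction: `Phi = (1/N) sum_i e_xi . ebar`, with
#' `ebar` the normalized mean heading, which equals the length of the mean
#' forward vector. 1 = perfectly aligned; 0 for balanced opposite headings.
#'
#' @param forwards N x 3 matrix of unit forward vectors (one frame).
#' @return Phi in [0, 1].
#' @export
polarization <- function(forwards) {
  forwards <- matrix(as.numeric(forwards), ncol = 3)
  min(sqrt(sum(colMeans(forwards)^2)), 1)
}

#' @describeIn polarization mean over birds of the polarization of the set
#'   formed by each bird and its `kTopo` nearest neighbours; reduces to the
#'   global value at `kTopo = N - 1`.
#' @param positions N x 3 matrix of positions (m) for the same frame.
#' @param kTopo neighbourhood size.
#' @export
localPolarization <- function(positions, forwards, kTopo) {
  n <- nrow(positions)
  stopifnot(kTopo >= 1, kTopo <= n - 1)
  nn <- .frameNeighborSets(as.matrix(positions), as.integer(kTopo))
  acc <- forwards
  for (j in seq_len(ncol(nn))) acc <- acc + forwards[nn[, j], , drop = FALSE]
  acc <- acc / (ncol(nn) + 1)
  mean(pmin(sqrt(rowSums(acc^2)), 1))
}

#' Voxelised flock volume
#'
#' Estimates flock volume by mapping positions onto a cubic lattice of edge
#' `cellSize` (anchored at the frame's minimum corner, so the measure is
#' translation invariant) and counting occupied cells:
#' `volume = cellSize^3 * #occupied`. The cell size convention is the
#' average "standard" nearest-neighbour distance of the reference flock
#' event.
#'
#' @param positions N x 3 matrix (m), one frame.
#' @param cellSize lattice constant (m).
#' @return occupied volume (m^3).
#' @examples
#' voxelVolume(rbind(c(0, 0, 0)), cellSize = 2) # 8
#' @export
voxelVolume <- function(positions, cellSize) {
  stopifnot(cellSize > 0, NROW(positions) >= 1)
  positions <- matrix(as.numeric(positions), ncol = 3)
  idx <- floor(sweep(positions, 2, apply(positions, 2, min), "-") / cellSize)
  side <- max(idx) + 1
  key <- idx[, 1] + side * (idx[, 2] + side * idx[, 3])
  cellSize^3 * length(unique(key))
}

#' Mean nearest-neighbour distance
#'
#' Mean over birds of the distance to their single closest neighbour (NND),
#' the standard flock density measure.
#'
#' @param positions N x 3 matrix (m), one frame.
#' @return mean NND (m).
#' @export
measureNnd <- function(positions) {
  positions <- matrix(as.numeric(positions), ncol = 3)
  n <- nrow(positions)
  stopifnot(n >= 2)
  nn <- .frameNeighborSets(positions, 1L)[, 1]
  mean(sqrt(rowSums((positions - positions[nn, , drop = FALSE])^2)))
}
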