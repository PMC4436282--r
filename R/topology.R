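#' Topological (k-nearest) neighbours of one bird
#'
#' Returns the `k` birds closest to the focal bird in Euclidean distance,
#' ordered closest first. This is the "topological range" interaction rule:
#' a fixed number of closest neighbours, independent of metric distance.
#' Distance ties are broken by lower index, so the result is deterministic.
#'
#' @param positions N x 3 matrix of positions (m).
#' @param focal index of the focal bird (1-based).
#' @param k number of neighbours.
#' @return integer vector of `k` indices, ascending by distance.
#' @examples
#' pos <- cbind(0:3, 0, 0)
#' findTopologicalNeighbors(pos, focal = 1, k = 2) # 2, 3
#' @export
findTopologicalNeighbors <- function(positions, focal, k) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (k < 1) stop("k must be >= 1")
  if (k >= n) stop("k must be below the number of birds")
  if (!all(is.finite(positions))) stop("non-finite coordinates in positions")
  d2 <- colSums((t(positions) - positions[focal, ])^2)
  ord <- order(d2, seq_len(n))
  ord <- ord[ord != focal]
  ord[seq_len(k)]
}

#' Restrict candidate neighbours to a field of view
#'
#' Keeps the candidates whose bearing from the focal bird's forward
#' direction is at most `halfAngle`, preserving input order. A half-angle of
#' `pi` is the identity filter (full spherical view). A candidate exactly at
#' the focal position has no defined bearing and is kept.
#'
#' @param focalPosition length-3 position of the focal bird (m).
#' @param focalForward length-3 unit forward direction.
#' @param candidateIds indices of candidate neighbours.
#' @param positions N x 3 matrix of all positions (m).
#' @param halfAngle view-cone half-angle (rad), in (0, pi].
#' @return the subset of `candidateIds` inside the cone, input order kept.
#' @export
filterFieldOfView <- function(focalPosition, focalForward, candidateIds,
                              positions, halfAngle) {
  nrm <- sqrt(sum(focalForward^2))
  if (nrm < 1e-12) stop("focal forward direction has zero length")
  if (!(halfAngle > 0 && halfAngle <= pi)) stop("halfAngle must be in (0, pi]")
  if (halfAngle >= pi || length(candidateIds) == 0) return(candidateIds)
  fwd <- focalForward / nrm
  rel <- positions[candidateIds, , drop = FALSE] -
    matrix(focalPosition, length(candidateIds), 3, byrow = TRUE)
  dn <- sqrt(rowSums(rel^2))
  keep <- dn == 0 | (rel %*% fwd)[, 1] >= cos(halfAngle) * dn
  candidateIds[keep]
}

#' Per-behaviour neighbour sets of a focal bird
#'
#' Computes the ordered topological neighbour sets used by each behaviour:
#' the `kAvoid` closest neighbours are avoided while the `kTopo` closest are
#' used for alignment and cohesion. The same field-of-view filter applies to
#' all behaviours, so the avoided set is always a prefix of the alignment
#' set when `kAvoid <= kTopo`. If fewer than `k` candidates survive the
#' filter the sets are shorter, never padded.
#'
#' @param positions N x 3 matrix (m).
#' @param forwards N x 3 matrix of unit forward directions.
#' @param focal focal bird index.
#' @param kAvoid number of neighbours avoided.
#' @param kTopo topological range for alignment/cohesion.
#' @param fovHalfAngle field-of-view half-angle (rad), `pi` = no filter.
#' @return list with ordered integer vectors `avoid`, `align`, `cohere`.
#' @export
neighborSets <- function(positions, forwards, focal, kAvoid, kTopo,
                         fovHalfAngle = pi) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 2) stop("a flock needs at least 2 birds")
  if (!(kAvoid >= 1)) stop("kAvoid must be >= 1")
  if (kAvoid > kTopo)
    warning("kAvoid exceeds kTopo: avoidance uses more neighbours than alignment/cohesion")
  kMax <- min(max(kAvoid, kTopo), n - 1L)
  candidates <- findTopologicalNeighbors(positions, focal, n - 1L)
  candidates <- filterFieldOfView(positions[focal, ], forwards[focal, ],
                                  candidates, positions, fovHalfAngle)
  topo <- candidates[seq_len(min(kTopo, length(candidates)))]
  avoid <- candidates[seq_len(min(kAvoid, length(candidates)))]
  list(avoid = avoid, align = topo, cohere = topo)
}

#' k-nearest neighbours of every bird at once
#'
#' Grid-accelerated exact kNN over the whole flock (the same spatial index
#' the simulation engine uses). Ordering and tie-breaking are identical to
#' [findTopologicalNeighbors()].
#'
#' @param positions N x 3 matrix (m).
#' @param k neighbours per bird.
#' @return N x k integer matrix; row i holds the neighbours of bird i,
#'   ascending by distance.
#' @export
knnAll <- function(positions, k) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  n <- nrow(positions)
  if (k < 1 || k >= n) stop("k must be in [1, N-1]")
  span <- apply(positions, 2, function(x) diff(range(x)))
  vol <- max(prod(pmax(span, 1e-6)), 1e-9)
  cell <- max(0.05, 1.5 * (vol / n)^(1 / 3))
  .knn_all_cpp(positions, as.integer(k), cell)
}
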