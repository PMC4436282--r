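# Independent brute-force oracles used across the metric and topology tests.
# These deliberately use the most direct formulation available (full pairwise
# distance matrices, per-element loops) and never call the package's
# accelerated code paths.

bruteKnn <- function(positions, focal, k) {
  d <- sqrt(colSums((t(positions) - positions[focal, ])^2))
  ord <- order(d, seq_len(nrow(positions)))
  ord <- ord[ord != focal]
  ord[seq_len(k)]
}

bruteFov <- function(focalPos, fwd, ids, positions, halfAngle) {
  keep <- vapply(ids, function(j) {
    v <- positions[j, ] - focalPos
    nv <- sqrt(sum(v^2))
    if (nv == 0) return(TRUE)
    acos(pmin(pmax(sum(v * fwd) / nv, -1), 1)) <= halfAngle + 1e-12
  }, logical(1))
  ids[keep]
}

bruteMsd <- function(positions, lag, t0 = 1) {
  # positions: T x N x 3; centre-of-mass frame computed longhand
  tN <- dim(positions)[1]
  rel <- positions
  for (f in seq_len(tN)) {
    com <- colMeans(positions[f, , ])
    rel[f, , ] <- sweep(positions[f, , ], 2, com)
  }
  d <- rel[t0 + lag, , ] - rel[t0, , ]
  mean(rowSums(d^2))
}

bruteVoxelCount <- function(positions, a) {
  idx <- floor(sweep(positions, 2, apply(positions, 2, min)) / a)
  length(unique(apply(idx, 1, paste, collapse = ",")))
}

randomCloud <- function(n, spread = 5, seed = 1) {
  set.seed(seed)
  matrix(runif(3 * n, 0, spread), n, 3)
}

randomHeadings <- function(n, seed = 1) {
  set.seed(seed)
  h <- matrix(rnorm(3 * n), n, 3)
  h / sqrt(rowSums(h^2))
}

# small flock-event preset for fast experiment-module tests
tinyPreset <- function(n = 60, acclimatization = 3, diffusion = 2,
                       longWindow = 4, targetNnd = 0.7) {
  methods::new("FlockEventPreset", eventId = "tiny", n = as.integer(n),
               rSepSingle = 1.0, rSepMulti = 1.2, rH = 0.2,
               targetNnd = targetNnd, acclimatizationS = acclimatization,
               diffusionWindowS = diffusion, longWindowS = longWindow,
               sampleDtS = 0.01)
}

quietParams <- function(...) {
  # parameters with every stochastic/held-force feature disabled, for
  # closed-form flight-dynamics checks
  flockParams(wSep = 0, wAlign = 0, wCohere = 0, wNoise = 0,
              cruiseSpread = 0, reactionTime = 0.01, ...)
}
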