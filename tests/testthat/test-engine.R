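# One integration step recomputed longhand in R, used as the independent
# reference for the compiled engine (reaction every step, no stochastic
# features, no field of view).
rReferenceStep <- function(world, dt) {
  p <- world@params
  n <- nrow(world@positions)
  pos <- world@positions; ex <- world@headings
  spd <- world@speeds; bank <- world@banks
  newEx <- ex; newPos <- pos; newSpd <- spd; newBank <- bank
  force <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    ns <- neighborSets(pos, ex, i, p@kAvoid, p@kTopo, p@fovHalfAngle)
    fSep <- separationForce(pos[i, ], pos[ns$avoid, , drop = FALSE],
                            p@rH, p@rSep, p@wSep, p@sepDecay)
    fAli <- alignmentForce(ex[i, ], ex[ns$align, , drop = FALSE], p@wAlign)
    # engine cohesion: centrality-scaled unit attraction
    rel <- pos[ns$cohere, , drop = FALSE] -
      matrix(pos[i, ], length(ns$cohere), 3, byrow = TRUE)
    dn <- sqrt(rowSums(rel^2))
    theta <- sqrt(sum(colSums(rel / dn)^2)) / length(ns$cohere)
    scale <- 1 - p@centralityGain + p@centralityGain * theta
    cen <- colMeans(pos[ns$cohere, , drop = FALSE])
    dvec <- cen - pos[i, ]
    fCoh <- if (sqrt(sum(dvec^2)) > 1e-12)
      p@wCohere * scale * dvec / sqrt(sum(dvec^2)) else c(0, 0, 0)
    force[i, ] <- fSep + fAli + fCoh
  }
  for (i in seq_len(n)) {
    lf <- murmuration:::levelFrame(ex[i, ])
    st <- applyBanking(ex[i, ], bank[i], force[i, ], p, dt)
    newBank[i] <- st$bank
    sp <- max(spd[i], 0.5)
    aLat <- 9.81 * tan(st$bank)
    aUp <- sum(force[i, ] * lf$ez0) / p@mass - p@pitchGain * sp * ex[i, 3]
    e <- ex[i, ] + (lf$ey0 * aLat + lf$ez0 * aUp) * dt / sp
    newEx[i, ] <- e / sqrt(sum(e^2))
    newSpd[i] <- spd[i] + dt * ((p@cruiseSpeed - spd[i]) / p@speedTau +
                                  sum(force[i, ] * ex[i, ]) / p@mass)
  }
  for (i in seq_len(n)) newPos[i, ] <- pos[i, ] + newSpd[i] * dt * newEx[i, ]
  list(positions = newPos, headings = newEx, speeds = newSpd, banks = newBank)
}

test_that("one compiled step matches the longhand R reference step", {
  par <- flockParams(kAvoid = 2, kTopo = 5, wSep = 1.2, wAlign = 0.8,
                     wCohere = 0.6, wNoise = 0, cruiseSpread = 0,
                     reactionTime = 0.01)
  w <- initializeFlock(40, targetNnd = 0.8, par, seed = 11)
  ref <- rReferenceStep(w, 0.01)
  got <- stepFlock(w, 0.01)
  expect_equal(got@positions, ref$positions, tolerance = 1e-12)
  expect_equal(got@headings, ref$headings, tolerance = 1e-12)
  expect_equal(got@speeds, ref$speeds, tolerance = 1e-12)
  expect_equal(got@banks, ref$banks, tolerance = 1e-12)
})

test_that("two distant aligned birds fly straight at cruise speed", {
  par <- quietParams(rSep = 1)
  pos <- rbind(c(0, 0, 0), c(100, 0, 0))
  head <- rbind(c(1, 0, 0), c(1, 0, 0))
  w <- methods::new("FlockWorld", time = 0, positions = pos, headings = head,
                    speeds = c(10, 10), banks = c(0, 0), params = par,
                    seed = 1, draws = 0)
  out <- simulateFlock(w, 1, dt = 0.01, recordEvery = NULL)$world
  expect_equal(out@positions,
               pos + matrix(c(10, 0, 0), 2, 3, byrow = TRUE),
               tolerance = 1e-9)
  expect_equal(out@headings, head, tolerance = 1e-12)
  expect_equal(out@speeds, c(10, 10), tolerance = 1e-12)
})

test_that("identical seeds give bit-identical trajectories", {
  par <- flockParams()
  w1 <- initializeFlock(60, 0.7, par, seed = 5)
  w2 <- initializeFlock(60, 0.7, par, seed = 5)
  t1 <- simulateFlock(w1, 1, recordEvery = 0.1)$trajectory
  t2 <- simulateFlock(w2, 1, recordEvery = 0.1)$trajectory
  expect_identical(t1@positions, t2@positions)
  expect_identical(t1@forwards, t2@forwards)
  w3 <- initializeFlock(60, 0.7, par, seed = 6)
  t3 <- simulateFlock(w3, 1, recordEvery = 0.1)$trajectory
  expect_false(identical(t1@positions, t3@positions))
})

test_that("with social forces off, speed follows the exponential closed form", {
  par <- quietParams(cruiseSpeed = 10, speedTau = 1)
  pos <- rbind(c(0, 0, 0), c(50, 0, 0))
  head <- rbind(c(1, 0, 0), c(1, 0, 0))
  w <- methods::new("FlockWorld", time = 0, positions = pos, headings = head,
                    speeds = c(8, 8), banks = c(0, 0), params = par,
                    seed = 1, draws = 0)
  out <- simulateFlock(w, 5, dt = 0.01, recordEvery = NULL)$world
  expected <- 10 + (8 - 10) * exp(-5 / 1)
  expect_equal(out@speeds, rep(expected, 2), tolerance = 0.01)
})

test_that("bird count and parameters are conserved; paths are pairwise independent at zero weights", {
  par <- quietParams()
  w <- initializeFlock(20, 0.7, par, seed = 3)
  out <- simulateFlock(w, 0.5, recordEvery = NULL)$world
  expect_identical(nBirds(out), 20L)
  expect_identical(params(out), par)
  # removing other birds does not change a bird's path when weights are zero
  w2 <- methods::new("FlockWorld", time = 0,
                     positions = w@positions[1:2, ], headings = w@headings[1:2, ],
                     speeds = w@speeds[1:2], banks = w@banks[1:2],
                     params = par, seed = w@seed, draws = 0)
  out2 <- simulateFlock(w2, 0.5, recordEvery = NULL)$world
  expect_equal(out2@positions, out@positions[1:2, ], tolerance = 1e-10)
})

test_that("dynamics are invariant under global translation and yaw rotation", {
  # noise off: the stream's random vectors are world-fixed, so they would
  # break equivariance even though the deterministic dynamics respect it
  par <- flockParams(wNoise = 0, cruiseSpread = 0)
  w <- initializeFlock(40, 0.7, par, seed = 7)
  base <- simulateFlock(w, 1, recordEvery = 1)$trajectory

  shift <- c(100, -50, 20)
  wT <- w; wT@positions <- sweep(w@positions, 2, -shift)
  outT <- simulateFlock(wT, 1, recordEvery = 1)$trajectory
  expect_equal(sweep(outT@positions[2, , ], 2, shift),
               base@positions[2, , ], tolerance = 1e-6)

  # rotation about the vertical axis (gravity singles out z)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  wR <- w
  wR@positions <- w@positions %*% t(R)
  wR@headings <- w@headings %*% t(R)
  outR <- simulateFlock(wR, 1, recordEvery = 1)$trajectory
  expect_equal(outR@positions[2, , ], base@positions[2, , ] %*% t(R),
               tolerance = 1e-5)
})

test_that("body frames from bank and heading stay orthonormal through a run", {
  par <- flockParams()
  w <- initializeFlock(50, 0.6, par, seed = 2)
  out <- simulateFlock(w, 2, recordEvery = NULL)$world
  expect_true(all(abs(sqrt(rowSums(out@headings^2)) - 1) < 1e-9))
  for (i in c(1, 25, 50)) {
    st <- applyBanking(out@headings[i, ], out@banks[i], c(0, 0, 0), par, 1e-9)
    M <- rbind(st$ex, st$ey, st$ez)
    expect_equal(M %*% t(M), diag(3), tolerance = 1e-9)
  }
})

test_that("averaged avoidance weakens with more avoided neighbours (direction compromise)", {
  # Monte-Carlo inequality over crowded configurations: the mean separation
  # force magnitude with k_avoid = 1 strictly exceeds k_avoid = 7
  set.seed(42)
  mag <- function(k) {
    vapply(1:200, function(rep) {
      nb <- matrix(rnorm(21, sd = 0.5), 7, 3)
      ord <- order(sqrt(rowSums(nb^2)))
      f <- separationForce(c(0, 0, 0), nb[ord[seq_len(k)], , drop = FALSE],
                           rH = 0.2, rSep = 1.5, wSep = 1)
      sqrt(sum(f^2))
    }, numeric(1))
  }
  expect_gt(mean(mag(1)), mean(mag(7)))
})

test_that("initialization hits the target density and is reproducible", {
  w1 <- initializeFlock(1246, targetNnd = 0.63, seed = 4)
  w2 <- initializeFlock(1246, targetNnd = 0.63, seed = 4)
  expect_identical(w1@positions, w2@positions)
  nnd <- measureNnd(w1@positions)
  expect_lt(abs(nnd - 0.63) / 0.63, 0.2)
  expect_gt(polarization(w1@headings), 0.95)
  w3 <- initializeFlock(2, targetNnd = 1, seed = 1)
  expect_false(all(w3@positions[1, ] == w3@positions[2, ]))
})

test_that("non-finite states abort naming the offending bird", {
  par <- murmuration:::paramsAsList(quietParams())
  pos <- rbind(c(0, 0, 0), c(NaN, 0, 0))
  head <- rbind(c(1, 0, 0), c(1, 0, 0))
  expect_error(
    murmuration:::.simulate_cpp(pos, head, c(10, 10), c(0, 0), par,
                                0.01, 10L, 1L, FALSE, 1, 1),
    "non-finite position for bird")
})
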