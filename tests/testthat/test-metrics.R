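test_that("centre-of-mass frame removes global motion", {
  tr <- makeFixture("rigid_translation", list(n = 8, nFrames = 20), seed = 2)
  rel <- comFrame(tr)
  for (f in c(1, 10, 20))
    expect_equal(colSums(rel[f, , ]), c(0, 0, 0), tolerance = 1e-9)
  # rigid translation leaves the relative frame static
  expect_equal(rel[20, , ], rel[1, , ], tolerance = 1e-9)
  # two-bird closed form
  tr2 <- flockTrajectory(0, array(c(0, 2, 0, 0, 0, 0), c(1, 2, 3)))
  expect_equal(comFrame(tr2)[1, , ], rbind(c(-1, 0, 0), c(1, 0, 0)))
})

test_that("neighbour stability is 1 for static flocks and matches the swap enumeration", {
  tr <- makeFixture("static", list(n = 12, nFrames = 30), seed = 3)
  q <- neighborStability(tr, M = 3, tValues = c(0, 0.5, 1, 2))
  expect_equal(q$Q, rep(1, 4))

  # hand enumeration: birds on a line at x = (0, 1, 2.1), ends swapped.
  # before: NN sets {2}, {1}, {2}; after: {2}, {3}, {2}; overlaps 1, 0, 1
  tr <- makeFixture("swap", list(nFrames = 11, dt = 0.1), seed = 1)
  q <- neighborStability(tr, M = 1, tValues = 1)
  expect_equal(q$Q, 2 / 3)
  expect_equal(neighborStability(tr, M = 1, tValues = 0)$Q, 1)

  # M = N - 1: the neighbourhood is everyone, always stable
  trb <- makeFixture("brownian", list(n = 6, nFrames = 20, sigma = 0.5), seed = 5)
  expect_equal(neighborStability(trb, M = 5, tValues = c(0.5, 1))$Q, c(1, 1))

  expect_error(neighborStability(trb, 2, tValues = 100), "span")
})

test_that("neighbour stability is invariant under rigid motions and bounded", {
  trb <- makeFixture("brownian", list(n = 15, nFrames = 25, sigma = 0.3), seed = 7)
  q1 <- neighborStability(trb, 4, tValues = c(0.4, 0.8, 1.6), t0Offsets = c(0, 0.4))
  expect_true(all(q1$Q >= 0 & q1$Q <= 1))
  # rotate + translate every frame identically
  th <- 1.1
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  pos2 <- trb@positions
  for (f in seq_len(nFrames(trb)))
    pos2[f, , ] <- trb@positions[f, , ] %*% t(R) +
      matrix(c(5, -3, 2), nBirds(trb), 3, byrow = TRUE)
  tr2 <- flockTrajectory(trb@times, pos2)
  q2 <- neighborStability(tr2, 4, tValues = c(0.4, 0.8, 1.6), t0Offsets = c(0, 0.4))
  expect_equal(q2$Q, q1$Q)
})

test_that("mean-square displacement matches closed forms and the brute-force oracle", {
  # rigid translation: zero at all lags
  tr <- makeFixture("rigid_translation", list(n = 10, nFrames = 21), seed = 4)
  msd <- meanSquareDisplacement(tr, c(0.5, 1, 2))
  expect_equal(msd$msd_m2, c(0, 0, 0), tolerance = 1e-18)

  # two birds separating symmetrically at v each: dr2(t) = (v t)^2
  v <- 1.5
  times <- seq(0, 2, 0.1)
  pos <- array(0, c(length(times), 2, 3))
  pos[, 1, 1] <- -v * times
  pos[, 2, 1] <- v * times
  tr2 <- flockTrajectory(times, pos)
  msd2 <- meanSquareDisplacement(tr2, c(0.5, 1, 2))
  expect_equal(msd2$msd_m2, (v * c(0.5, 1, 2))^2, tolerance = 1e-12)
  fit <- fitPowerLaw(seq(0.1, 2, 0.1),
                     meanSquareDisplacement(tr2, seq(0.1, 2, 0.1))$msd_m2,
                     fitWindow = c(0.1, 2))
  expect_equal(fit@alpha, 2, tolerance = 1e-9)
  expect_equal(fit@D, v^2, tolerance = 1e-9)

  # brownian cloud vs the independent longhand implementation
  trb <- makeFixture("brownian", list(n = 20, nFrames = 40, sigma = 0.2), seed = 9)
  got <- meanSquareDisplacement(trb, c(0.3, 1.2), t0Offsets = 0)
  expect_equal(got$msd_m2,
               c(bruteMsd(trb@positions, 3), bruteMsd(trb@positions, 12)),
               tolerance = 1e-12)
  expect_equal(meanSquareDisplacement(trb, 0)$msd_m2, 0)
})

test_that("brownian motion fits alpha near 1 with the expected D scale", {
  sigma <- 0.2; dt <- 0.1; n <- 60
  tr <- makeFixture("brownian",
                    list(n = n, nFrames = 201, dt = dt, sigma = sigma),
                    seed = 12)
  lags <- seq(0.2, 6, 0.2)
  msd <- meanSquareDisplacement(tr, lags, t0Offsets = seq(0, 12, 1))
  fit <- fitPowerLaw(lags, msd$msd_m2, fitWindow = c(0.2, 6))
  expect_equal(fit@alpha, 1, tolerance = 0.1)
  # per-step variance 3 sigma^2 per bird, reduced by the COM constraint
  expect_equal(fit@D, 3 * sigma^2 / dt * (1 - 1 / n), tolerance = 0.15)
})

test_that("power-law fit is exact on noiseless input and robust to mild noise", {
  t <- seq(0.05, 1, by = 0.05)
  f1 <- fitPowerLaw(t, 4 * t)
  expect_equal(f1@D, 4, tolerance = 1e-12)
  expect_equal(f1@alpha, 1, tolerance = 1e-12)
  expect_equal(f1@rSquared, 1)
  f2 <- fitPowerLaw(t, t^2)
  expect_equal(f2@D, 1, tolerance = 1e-12)
  expect_equal(f2@alpha, 2, tolerance = 1e-12)

  set.seed(31)
  t50 <- seq(0.02, 1, length.out = 50)
  noisy <- 2.5 * t50^1.7 * exp(rnorm(50, 0, 0.01))
  f3 <- fitPowerLaw(t50, noisy, fitWindow = c(0.02, 1))
  expect_equal(f3@alpha, 1.7, tolerance = 0.05)

  expect_error(fitPowerLaw(t[1:4], 4 * t[1:4], c(0, 1)), "fewer than 5")
  expect_error(fitPowerLaw(t, c(-1, (4 * t)[-1]), c(0, 1)), "non-positive")
})

test_that("polarization closed forms and invariances hold", {
  e <- c(1, 0, 0)
  expect_equal(polarization(rbind(e, e, e)), 1)
  expect_equal(polarization(rbind(e, -e)), 0)
  expect_equal(polarization(rbind(c(1, 0, 0), c(0, 1, 0))), sqrt(2) / 2)
  h <- randomHeadings(40, seed = 3)
  phi <- polarization(h)
  expect_true(phi >= 0 && phi <= 1)
  th <- 0.8
  R <- rbind(c(cos(th), 0, sin(th)), c(0, 1, 0), c(-sin(th), 0, cos(th)))
  expect_equal(polarization(h %*% t(R)), phi, tolerance = 1e-12)
})

test_that("local polarization matches brute force and reduces to global", {
  pos <- randomCloud(30, seed = 21)
  h <- randomHeadings(30, seed = 22)
  got <- localPolarization(pos, h, 6)
  brute <- mean(vapply(1:30, function(i) {
    nn <- bruteKnn(pos, i, 6)
    polarization(h[c(i, nn), ])
  }, numeric(1)))
  expect_equal(got, brute, tolerance = 1e-12)
  expect_equal(localPolarization(pos, h, 29), polarization(h), tolerance = 1e-12)
  aligned <- matrix(rep(c(1, 0, 0), each = 30), 30, 3)
  expect_equal(localPolarization(pos, aligned, 6), 1)
})

test_that("voxel volume counts occupied lattice cells", {
  expect_equal(voxelVolume(rbind(c(7, -3, 2)), cellSize = 2), 8)
  # ten birds inside one cell
  cl <- matrix(runif(30, 0, 0.9), 10, 3)
  expect_equal(voxelVolume(cl, cellSize = 1), 1)
  # 500 uniform points vs the hash-set oracle
  pts <- randomCloud(500, spread = 10, seed = 8)
  expect_equal(voxelVolume(pts, 1), bruteVoxelCount(pts, 1))
  # translation invariance from the min-corner anchor
  expect_equal(voxelVolume(sweep(pts, 2, c(-100, 55, 7)), 1),
               voxelVolume(pts, 1))
  # dilation monotonicity at fixed cell size
  vols <- vapply(c(1, 1.5, 2, 3), function(s) voxelVolume(pts * s, 1),
                 numeric(1))
  expect_true(all(diff(vols) >= 0))
})

test_that("mean nearest-neighbour distance matches the pairwise oracle", {
  expect_equal(measureNnd(rbind(c(0, 0, 0), c(3, 0, 0))), 3)
  # interior of a unit cubic lattice
  g <- as.matrix(expand.grid(0:3, 0:3, 0:3))
  expect_equal(measureNnd(g), 1)
  pts <- randomCloud(50, seed = 13)
  brute <- mean(vapply(1:50, function(i) {
    d <- sqrt(colSums((t(pts) - pts[i, ])^2))
    min(d[-i])
  }, numeric(1)))
  expect_equal(measureNnd(pts), brute, tolerance = 1e-12)
})
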