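test_that("separation force follows the hard-sphere ramp and averages over neighbours", {
  # single neighbour at the hard-sphere radius straight ahead: full backward push
  f <- separationForce(c(0, 0, 0), rbind(c(0.2, 0, 0)), rH = 0.2, rSep = 1,
                       wSep = 2)
  expect_equal(f, c(-2, 0, 0))

  # four equidistant neighbours at 90 degree spacing inside r_h cancel
  ring <- rbind(c(0.1, 0, 0), c(-0.1, 0, 0), c(0, 0.1, 0), c(0, -0.1, 0))
  expect_equal(separationForce(c(0, 0, 0), ring, 0.2, 1, 2), c(0, 0, 0))

  # hand evaluation of the linear ramp: neighbours at (r_h+r_sep)/2 and r_sep
  rH <- 0.2; rSep <- 1; wSep <- 3
  pos <- rbind(c((rH + rSep) / 2, 0, 0), c(rSep, 0, 0))
  f <- separationForce(c(0, 0, 0), pos, rH, rSep, wSep)
  expect_equal(sqrt(sum(f^2)), 0.25 * wSep, tolerance = 1e-12)
  expect_equal(f / sqrt(sum(f^2)), c(-1, 0, 0))

  expect_equal(separationForce(c(0, 0, 0), NULL, 0.2, 1, 2), c(0, 0, 0))
  # coincident neighbour uses the supplied escape direction at full weight
  f0 <- separationForce(c(1, 1, 1), rbind(c(1, 1, 1)), 0.2, 1, 2,
                        coincidentDirection = c(0, 0, 1))
  expect_equal(f0, c(0, 0, 2))
})

test_that("alignment force steers toward the mean heading and degenerates to zero", {
  ex <- c(1, 0, 0)
  expect_equal(alignmentForce(ex, rbind(ex, ex, ex), 2), c(0, 0, 0))
  nbr <- c(0, 1, 0)
  expect_equal(alignmentForce(ex, rbind(nbr), 1.5), 1.5 * (nbr - ex))
  # two opposite headings: degenerate zero mean
  expect_equal(alignmentForce(ex, rbind(c(0, 1, 0), c(0, -1, 0)), 1),
               c(0, 0, 0))
  expect_equal(alignmentForce(ex, NULL, 1), c(0, 0, 0))
})

test_that("cohesion force is the unit pull toward the centroid", {
  expect_equal(cohesionForce(c(0, 0, 0), rbind(c(0, 5, 0)), 1.2),
               c(0, 1.2, 0))
  # focal at the centroid: zero
  ring <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0))
  expect_equal(cohesionForce(c(0, 0, 0), ring, 1), c(0, 0, 0))
  # random cloud vs explicit centroid recomputation
  set.seed(4)
  nb <- matrix(rnorm(21), 7, 3)
  cen <- colMeans(nb)
  expect_equal(cohesionForce(c(0.3, -0.2, 0.1), nb, 2),
               2 * (cen - c(0.3, -0.2, 0.1)) / sqrt(sum((cen - c(0.3, -0.2, 0.1))^2)))
})

test_that("speed control is linear in the speed error", {
  expect_equal(speedControlForce(10, 10, 0.08, 1), 0)
  expect_equal(speedControlForce(8, 10, 0.08, 1), 0.16)
  expect_error(speedControlForce(8, 10, 0.08, 0))
})

test_that("banking converges to the lift-balance angle with asymmetric rates", {
  par <- flockParams(rollInRate = 2, rollOutRate = 1, maxRoll = 1.3)
  ex <- c(1, 0, 0)
  # zero lateral steering, level frame: fixed point
  st <- applyBanking(ex, 0, c(0, 0, 0), par, 0.01)
  expect_equal(st$bank, 0)
  expect_equal(st$ey, c(0, 1, 0))    # sideward axis of a level +x frame
  expect_equal(st$ez, c(0, 0, 1))

  # constant lateral steering: bank converges to atan(F_lat / (m g))
  fLat <- 0.5
  force <- c(0, fLat, 0)             # along the sideward axis
  target <- atan2(fLat, par@mass * 9.81)
  bank <- 0
  for (i in 1:400) bank <- applyBanking(ex, bank, force, par, 0.01)$bank
  expect_equal(bank, target, tolerance = 1e-9)

  # frame stays orthonormal at the converged bank
  st <- applyBanking(ex, bank, force, par, 0.01)
  M <- rbind(st$ex, st$ey, st$ez)
  expect_equal(M %*% t(M), diag(3), tolerance = 1e-12)

  # roll-in twice as fast as roll-out: time into the turn is half the time out
  stepsTo <- function(from, to, force) {
    bank <- from; n <- 0
    repeat {
      n <- n + 1
      bank <- applyBanking(ex, bank, force, par, 0.01)$bank
      if (abs(bank - to) < 1e-9 || n > 1e4) break
    }
    n
  }
  nIn <- stepsTo(0, target, force)                  # rate-limited ascent
  nOut <- stepsTo(target, 0, c(0, 0, 0))            # decay back to level
  expect_equal(nOut / nIn, 2, tolerance = 0.05)

  # clamp at maxRoll
  big <- c(0, 50, 0)
  bank <- 0
  for (i in 1:1000) bank <- applyBanking(ex, bank, big, par, 0.01)$bank
  expect_equal(bank, par@maxRoll)
})
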