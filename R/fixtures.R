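#' Analytic trajectory fixtures
#'
#' Generates small trajectories with known closed-form metric values, used
#' to validate the internal-dynamics measures:
#'
#' * `"static"` -- no motion: Q = 1, dr2 = 0, volume constant.
#' * `"ballistic"` -- constant distinct per-bird velocities: fitted
#'   diffusion exponent alpha = 2.
#' * `"brownian"` -- independent Gaussian steps of sd `sigma` per frame:
#'   alpha near 1.
#' * `"rigid_translation"` -- one shared velocity: dr2 identically 0.
#' * `"swap"` -- three birds on a line at x = (0, 1, 2.1) whose end birds
#'   exchange positions linearly over the span: a hand-checkable
#'   neighbour-stability scenario (enumerating the three nearest-neighbour
#'   sets before and after gives Q_1 = 2/3 at the full lag).
#'
#' @param kind one of the fixture families above.
#' @param params named list; recognised entries `n` (birds), `nFrames`,
#'   `dt` (s), `spread` (m, initial cloud scale), `speed` (m/s, ballistic),
#'   `sigma` (m, brownian step sd).
#' @param seed integer seed for the random families.
#' @return a [FlockTrajectory-class].
#' @examples
#' tr <- makeFixture("swap", list(nFrames = 11), seed = 1)
#' neighborStability(tr, M = 1, tValues = 1)  # Q_1 = 2/3
#' @export
makeFixture <- function(kind, params = list(), seed = 1L) {
  p <- utils::modifyList(list(n = 10L, nFrames = 51L, dt = 0.1,
                              spread = 5, speed = 1, sigma = 0.1), params)
  n <- as.integer(p$n); tN <- as.integer(p$nFrames)
  times <- (seq_len(tN) - 1) * p$dt
  rs <- .rngScope(seed)
  on.exit(.rngRestore(rs))
  base <- matrix(stats::runif(3L * n, 0, p$spread), n, 3)
  pos <- array(0, c(tN, n, 3))
  fwd <- NULL
  switch(kind,
    static = {
      for (f in seq_len(tN)) pos[f, , ] <- base
    },
    ballistic = {
      vel <- matrix(stats::rnorm(3L * n, 0, p$speed), n, 3)
      for (f in seq_len(tN)) pos[f, , ] <- base + times[f] * vel
    },
    brownian = {
      steps <- array(stats::rnorm((tN - 1) * n * 3, 0, p$sigma), c(tN - 1, n, 3))
      pos[1, , ] <- base
      for (f in 2:tN) pos[f, , ] <- pos[f - 1, , ] + steps[f - 1, , ]
    },
    rigid_translation = {
      vel <- stats::rnorm(3, 0, p$speed)
      for (f in seq_len(tN))
        pos[f, , ] <- base + matrix(times[f] * vel, n, 3, byrow = TRUE)
    },
    swap = {
      start <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.1, 0, 0))
      end <- start[c(3, 2, 1), ]
      end[, 2] <- c(1, 0, 1)   # ends pass beside the middle bird
      n <- 3L
      pos <- array(0, c(tN, 3L, 3L))
      for (f in seq_len(tN)) {
        u <- (f - 1) / (tN - 1)
        pos[f, , ] <- (1 - u) * start + u * end
      }
      pos[tN, , 2] <- 0        # arrive exactly on the swapped line positions
    },
    stop("unknown fixture kind '", kind, "'")
  )
  flockTrajectory(times, pos, fwd)
}
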