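# Shared full-protocol runs for the acceptance suite. The four flock events
# are simulated once per condition (3 seeds each) and the summaries cached,
# so every criterion tests the same ensemble. Single-neighbour avoidance
# uses the separation radius calibrated to the event's target NND; the
# multi-neighbour condition uses the preset's 6-or-7 column.

.protocolCache <- new.env(parent = emptyenv())

protocolSeeds <- 1:3

diffusionEnsemble <- function() {
  if (!is.null(.protocolCache$diffusion)) return(.protocolCache$diffusion)
  rows <- list()
  for (ev in listPresets()) {
    pre <- loadPreset(ev)
    rs1 <- as.numeric(calibrateRSep(pre, targetNnd = pre@targetNnd,
                                    kAvoid = 1, seed = 1))
    for (k in c(1L, 7L)) for (s in protocolSeeds) {
      run <- if (k == 1L)
        runFlockEvent(pre, kAvoid = 1, seed = s, rSep = rs1,
                      longWindow = FALSE)
      else
        runFlockEvent(pre, kAvoid = 7, seed = s, longWindow = FALSE)
      sm <- run$summary
      rows[[length(rows) + 1L]] <- list(
        ev = ev, k = k, seed = s, n = pre@n, D = sm$D, alpha = sm$alpha,
        phi = sm$phiGlobal, vol = sm$volumeM3, nnd = sm$nndM,
        Q4_1s = tail(sm$qCurves$M4$Q, 1),
        Q6_1s = tail(sm$qCurves$M6$Q, 1))
    }
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  .protocolCache$diffusion <- out
  out
}

# long-window (2 min) runs of event 28-10 at matched nearest-neighbour
# distance for both avoidance conditions (polarization / volume contrast)
longEnsemble2810 <- function() {
  if (!is.null(.protocolCache$long)) return(.protocolCache$long)
  pre <- loadPreset("28-10")
  rs <- list(
    `1` = as.numeric(calibrateRSep(pre, pre@targetNnd, kAvoid = 1, seed = 1)),
    `7` = as.numeric(calibrateRSep(pre, pre@targetNnd, kAvoid = 7, seed = 1)))
  rows <- list()
  for (k in c(1L, 7L)) for (s in protocolSeeds) {
    sm <- runFlockEvent(pre, kAvoid = k, seed = s, rSep = rs[[as.character(k)]],
                        longWindow = TRUE)$summary
    rows[[length(rows) + 1L]] <- list(
      k = k, seed = s, phi = sm$phiGlobal, phiLocal = sm$phiLocal,
      vol = sm$volumeM3, nnd = sm$nndM, fission = sm$fission)
  }
  out <- do.call(rbind, lapply(rows, as.data.frame))
  .protocolCache$long <- out
  out
}

eventMeans <- function(df, k) {
  sub <- df[df$k == k, ]
  aggregate(cbind(D, alpha, phi, vol, Q4_1s, Q6_1s) ~ ev, sub, mean)
}
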