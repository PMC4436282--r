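# murmuration

An agent-based simulator of three-dimensional starling flocks in which the
number of **topological** interaction partners differs per behaviour, plus
the measurement suite for a flock's internal dynamics. Starlings coordinate
with a fixed number of closest neighbours (6 or 7); this package implements
and tests the hypothesis that collision *avoidance* works best against the
**single closest neighbour**, while alignment and attraction keep the full
topological range. Escaping one neighbour produces a full-length avoidance
vector; compromising between 6-7 neighbours on different sides averages the
escape directions away. That single change propagates, by self-organisation,
into four measurable signatures of the flock's interior.

It is written for researchers in collective animal behaviour who want a
reproducible, scriptable flocking testbed in R with the standard
internal-dynamics measurements built in.

## The model and the measures

Each bird flies at a cruise speed with banked turns (the lateral lift
component `m g tan(bank)` supplies the steering force, with asymmetric
roll-rate limits), reacts to its neighbours at a behavioural reaction
interval, and feels three topological social forces: separation averaged
over the `k_avoid` closest neighbours with a hard-sphere/linear-ramp
weight, alignment toward the mean heading of the 7 closest, and
centrality-weighted cohesion toward their centroid. From the resulting
trajectories the package computes:

- **neighbour stability** `Q_M(t) = (1/N) * sum_i M_i(t) / M` — the fraction
  of each bird's `M` nearest neighbours still present after a lag `t`;
- **group-level diffusion** in the centre-of-mass frame,
  `dr^2(t) = (1/N) * sum_i [r_i(t0+t) - r_i(t0)]^2`, fitted as the power law
  `dr^2 = D t^alpha` (`alpha > 1` is super-diffusion);
- **polarization** `Phi = |mean forward direction|`, global and local;
- **voxelised volume**: occupied cubic-lattice cells times the cell volume.

## Worked example

Run the full measurement protocol (60 s acclimatization, then a 2 s window
sampled at 0.01 s) for flock event 28-10 — 1246 birds — under both
avoidance conditions:

```r
library(murmuration)

pre  <- loadPreset("28-10")          # N = 1246, tabulated radii, protocol times
run1 <- runFlockEvent(pre, kAvoid = 1, seed = 42, rSep = 1.06,  # calibrated radius
                      longWindow = FALSE)
run7 <- runFlockEvent(pre, kAvoid = 7, seed = 42, longWindow = FALSE)

for (r in list(run1, run7)) with(r$summary, cat(sprintf(
  "k_avoid=%d: D=%.2f alpha=%.2f phi=%.3f Q4(1s)=%.2f nnd=%.2f vol=%.0f\n",
  kAvoid, D, alpha, phiGlobal, tail(qCurves$M4$Q, 1), nndM, volumeM3)))
#> k_avoid=1: D=2.10 alpha=1.87 phi=0.987 Q4(1s)=0.40 nnd=0.66 vol=292
#> k_avoid=7: D=0.26 alpha=1.87 phi=0.998 Q4(1s)=0.64 nnd=0.76 vol=306
```

Avoiding only the closest neighbour makes the flock interior an order of
magnitude more diffusive (`D` 2.10 vs 0.26 m²·s⁻ᵅ, both super-diffusive),
much less stable (only 40% of a bird's four closest neighbours survive a
one-second lag, versus 64%), and slightly less polarized. The separation
radius for the single-avoidance condition comes from `calibrateRSep()`,
which bisects until the settled flock matches the event's target
nearest-neighbour distance — the same calibration semantics as the
tabulated per-event radii used by the multi-avoidance condition.

Other entry points: `sweepKAvoid()` (the 1..7 avoided-neighbour saturation
curves), `volumeVsSize()` (volume against flock size at fixed density),
`makeFixture()` (analytic trajectories with known metric values),
`writeTrajectory()`/`exportTrajectoryCsv()` (persistence), and a thin
command-line front end in `inst/cli/flock.R`.

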