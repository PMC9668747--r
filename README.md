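# ec3btsp

Models and analysis tools for studying how entorhinal cortex layer 3
(EC3) shapes hippocampal CA1 place-cell maps through
behavioural-timescale synaptic plasticity (BTSP).

## The problem

When a mouse learns a reward location on a circular treadmill belt,
initially silent CA1 pyramidal neurons acquire place fields abruptly —
often in a single lap — and the density of new fields becomes elevated
around the reward.  Field formation is driven by dendritic Ca²⁺ plateau
potentials in the apical tuft, where EC3 axons terminate; BTSP then
potentiates inputs active in the seconds around the plateau, so the new
field sits *backward* (against the running direction) of the plateau
site, and its width grows with the animal's running speed on the
induction lap.

This package provides, for computational neuroscientists working on
hippocampal learning:

* a **two-state Markov-chain simulator** of EC3 persistent activity.
  Each chain activates with per-step probability `P01·Δt` and
  inactivates with `P10·Δt` (Δt = 0.1 s), giving exponential active /
  inactive periods (τ_off = 1/P01 = 25 s at the default P01 = 0.04 s⁻¹)
  and a stationary active fraction P01/(P01+P10).  Spatial tuning comes
  from a recurring 1-s window per lap in which P01 is boosted
  (0.04 → 0.20 in 1400 of 2000 chains for the cue-rich environment A;
  0.04 → 0.28 in 1850 chains with phase density concentrated at the cue
  for environment B);
* a **plateau-threshold model**: each of 10 000 model CA1 neurons sums
  100 randomly chosen chains (5 % of the input population) minus
  feedforward inhibition (0.05 × the population sum); a plateau is an
  upward threshold crossing of the net drive
  `d_j(t) = Σ_{i∈S_j} s_i(t) − 0.05 Σ_i s_i(t)`,
  with the threshold calibrated so 20–25 % of neurons cross at least
  once per session.  Crossings per spatial bin (via a dwell-time
  mapping) predict place-field density across space;
* the complete **calcium-imaging place-cell pipeline**: ΔF/F with a
  mode-of-distribution baseline, 3σ significant-transient detection,
  noise-correlation merging of axonal ROIs (threshold 0.45, size-weighted
  averaging), reward-aligned 50-bin activity maps (running frames only,
  circular boxcar), spatial information
  `SI = Σ_i P_i λ_i log2(λ_i/λ)` with a circular-shift + chunk-permutation
  shuffle test, induction-lap detection (2-of-5 confirmation rule), and
  BTSP signature metrics (backward peak shift, width–velocity relation);
* a seeded **synthetic-data generator** (behaviour, CA1 somata, EC3
  axonal ROIs) with ground truth, so the whole pipeline is testable
  without any recording.

## Worked example

Simulate the environment-A chain population, calibrate the plateau
threshold, and ask how a doubled reward-zone dwell time shapes plateau
initiation across the belt:

```r
library(ec3btsp)

cfg <- chainConfig("A")
cfg
#> ChainConfig: env A - 2000 chains ( 1400 modulated, 600 homogeneous ), 50 laps x 100 steps, dt 0.1 s
#>   P01 base 0.04/s, P10 0.25/s

pop <- simulateChains(cfg, seed = 1)
pop
#> ChainPopulation: 2000 chains x 5000 steps, env A ; mean active fraction 0.168

drives <- simulatePopulationDrive(pop, nNeurons = 10000, seed = 2)
cal <- calibrateThreshold(drives)        # aim: 20-25% of neurons recruited

zone <- zoneBinsAround(90)               # +/- 18 cm around the reward at 90 cm
dwell <- rep(0.2, 50); dwell[zone] <- 0.4   # dwell time doubled in the zone
result <- crossingProfile(drives, cal$threshold, spaceMapping(dwell))
result
#> PlateauResult: 10000 model neurons, 100 inputs each; threshold 13.75 -> recruited fraction 0.218

p <- crossingProfileOf(result)
enrichment <- (sum(p[zone]) / length(zone)) /
              (sum(p[-zone]) / (50 - length(zone)))
round(enrichment, 2)
#> [1] 2.03
```

Reading the output: the calibrated threshold (13.75 drive units)
recruits 21.8 % of model neurons, inside the observed 20–25 % band of
CA1 cells gaining a field per session; and doubling the time spent in
the reward zone doubles (2.03×) the per-bin plateau rate there relative
to the rest of the track — dwell time alone produces a twofold
over-representation, before any change in EC3 tuning.

The full synthetic pipeline (behaviour → traces → maps → place cells →
model comparison) runs with:

```r
res <- runEndToEnd(defaultRunConfig(), "run1")
reportSummary("run1")
```

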