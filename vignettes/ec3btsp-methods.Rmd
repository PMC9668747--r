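---
title: "Modelling entorhinal drive and plateau-triggered place-field formation"
author: "ec3btsp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling entorhinal drive and plateau-triggered place-field formation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ec3btsp)
```

## Scientific setting

During spatial learning on a circular treadmill belt (180 cm), initially
silent CA1 pyramidal neurons acquire place fields abruptly — often in a
single lap — through behavioural-timescale synaptic plasticity (BTSP).
BTSP is triggered by long dendritic Ca^2+^ plateau potentials in the
apical tuft, where axons from entorhinal cortex layer 3 (EC3) terminate.
This package implements the computational machinery for studying that
pathway end to end:

1. a **two-state Markov-chain model** of EC3 persistent activity, with
   environment-specific spatial tuning;
2. a **plateau-threshold model** in which each model CA1 neuron sums a
   random subset of EC3 chains, subtracts feedforward inhibition, and
   initiates a plateau when the net drive crosses a calibrated threshold;
3. the full **calcium-imaging place-cell pipeline** (dF/F conversion,
   significant-transient detection, noise-correlation merging of axonal
   ROIs, reward-aligned 50-bin activity maps, spatial-information shuffle
   testing, induction-lap detection, BTSP signature metrics);
4. a **synthetic-data generator** that produces seeded behaviour and
   fluorescence with known ground truth, so every stage is testable
   without any recording.

## The EC3 chain model

Each EC3 axon is abstracted as a two-state Markov chain: inactive (0) or
active (1), emulating the seconds-long persistent firing characteristic of
EC3 neurons.  With time step $\Delta t = 0.1$ s, a chain activates with
per-step probability $P_{01}\Delta t$ and inactivates with probability
$P_{10}\Delta t$, yielding exponentially distributed inactive and active
periods with means $\tau_{\mathrm{off}} = 1/P_{01}$ and
$\tau_{\mathrm{on}} = 1/P_{10}$ and a stationary active fraction
$P_{01}/(P_{01}+P_{10})$.  Defaults: $P_{01} = 0.04\,\mathrm{s^{-1}}$
(mean inactive period 25 s).  The inactivation rate is not recoverable
from the published text; the package fixes $P_{10} = 0.25\,\mathrm{s^{-1}}$
(mean active period 4 s), in the seconds-scale persistent-firing regime,
and exposes it as a parameter.

A session is 50 laps of 10 s (100 steps per lap, 5100 steps simulated,
the first lap discarded as burn-in).  Spatial tuning enters through a
recurring 1-s *boost window* at a fixed within-lap phase in which
$P_{01}$ is stepped up:

* **uniform**: no boosts — a fully homogeneous population;
* **environment A** (cue-rich belt): 1400 of 2000 chains boosted
  $0.04 \to 0.20$, phases tiling the lap uniformly at 14 chains per step,
  600 chains homogeneous;
* **environment B** (single predictive cue at 40 cm): 1850 chains boosted
  $0.04 \to 0.28$ with phase density $1 + A\,e^{-d^2/2\sigma^2}$
  ($\sigma = 10$ cm about the cue; $A = 25$, calibrated once so that the
  cue-zone fraction of chain activity peaks is about threefold the uniform
  configuration, then frozen), 150 homogeneous;
* **enhanced tuning** (optional): the ~100 modulated chains nearest the
  salient location further boosted (to 0.68 in A; to $3\times$ the env-B
  boost in B), emulating the elevated tuning observed around reward/cue.

**Window placement.** The mean-state occupancy of a chain rises during its
boost window and decays afterwards with time constant
$\approx 1/(P_{01}+P_{10})$, so the occupancy bump peaks at the window
*end*.  Boost windows are therefore placed to end at the chain's nominal
preferred step; otherwise every peak histogram would sit one window length
(18 cm) forward of its nominal position.

Time is mapped to the 50 spatial bins (3.6 cm) through a dwell-time
profile (`spaceMapping`): steps are assigned to bins by cumulative dwell,
so a bin holding twice the time receives twice the steps; constant speed
(18 cm/s) gives exactly 2 steps per bin.  Per-lap bin averages are
smoothed with a circular three-point boxcar.

## The plateau-threshold model

Each of 10 000 model CA1 neurons receives 100 of the 2000 chains
(5% of the input population, drawn without replacement per neuron) as
excitation, minus feedforward inhibition equal to the sum of all 2000
chains scaled by 0.05:

$$d_j(t) = \sum_{i \in S_j} s_i(t) \; - \; 0.05 \sum_{i=1}^{2000} s_i(t).$$

A plateau is proxied by an *upward crossing* of a threshold by $d_j(t)$.
The threshold is calibrated by bisection so that the fraction of neurons
with at least one crossing per session falls in the observed band of CA1
place-field recruitment, 20–25% (aiming at 0.225).  Crossings are
assigned to spatial bins via the dwell mapping; the crossing profile
(crossings per bin / neurons) is the model's prediction of place-field
density across space.  Counting *events* (not time above threshold) is
the default because a plateau is an initiation event; the time-above
variant can be derived from the drives if needed.

Two model predictions follow directly: under uniform input and constant
speed the profile is flat in expectation; and doubling the dwell time in
the reward zone (what the animals actually do) doubles the zone's
crossing rate relative to the rest of the track.

**A note on profile flatness at finite size.**  With the threshold
calibrated to 20–25% recruitment, a session yields on the order of
$-\ln(0.775) \times 10^4 \approx 3$–$4\times10^3$ crossing events in
total (an extreme-value identity, insensitive to the chain parameters),
i.e. ~80 per bin.  Poisson sampling noise alone then makes the max/min
bin ratio of one simulated session ~1.4–1.6 even though the profile is
flat in expectation; resolving flatness to a ratio below 1.2 would
require roughly four times more model neurons.  The package reports the
profile as simulated and leaves the sampling noise visible.

## Calcium-trace processing

* **dF/F**: $(F - F_0)/F_0$ per ROI, $F_0$ the mode of the fluorescence
  distribution.  The default mode estimator is the half-sample mode
  (shortest-half recursion) on the 1st–99th percentile of $F$: its
  precision scales with the baseline noise, whereas a fixed 100-bin
  histogram (available as `method = "histogram"`) becomes coarse relative
  to the baseline noise once large transients stretch the range, and the
  resulting percent-level baseline offset corrupts every downstream
  3-sigma threshold.
* **Significant transients**: frames belonging to excursions above
  $2\sigma_{\mathrm{noise}}$ whose peak exceeds $3\sigma_{\mathrm{noise}}$
  and lasting at least 2 frames;
  $\sigma_{\mathrm{noise}}$ is the standard deviation of negative dF/F
  values mirrored about zero (robust to transients).  The onset level and
  minimum duration guard single-frame shot noise; both are parameters.
* **Axon merging** (EC3 ROIs only): Pearson correlations between full
  dF/F traces; pairs at or above 0.45 (midpoint of the 0.4–0.5 range used
  for such data) are linked; connected components become axons, with the
  merged trace the pixel-size-weighted mean of members.  Correlation on
  raw (not event-excluded) traces is used because the shared axonal
  signal dominates; the threshold is a parameter.
* **Activity maps**: 50 bins of 3.6 cm; only running frames
  (velocity > 2 cm/s) contribute; empty bins are filled by circular
  linear interpolation before a circular three-point boxcar per lap; maps
  are rotated so the reward sits in bin 26 (environment A) or 24
  (environment B).  Bins are half-open, internally 1-based.

## Place-cell identification

For each unit: the *eventual field* is the maximal circularly contiguous
run of bins above 20% of the peak smoothed mean dF/F that contains the
global peak (one field per unit; ties broken toward the lower bin).  The
*induction lap* is the earliest lap with significant field activity
confirmed in at least 2 of the 5 following laps; if the field then
disappears for more than 20 consecutive laps the search resumes after the
gap.  (The window is five laps; the count is the primary quantity, and
the window size is a parameter.)  Only post-induction laps enter the
classification: spatial information

$$\mathrm{SI} = \sum_i P_i\, \lambda_i \log_2 \frac{\lambda_i}{\lambda},
\qquad \lambda = \sum_i P_i \lambda_i,$$

with $P_i$ the running-frame occupancy probability and $\lambda_i$ the
smoothed mean dF/F of bin $i$, is compared against 100 shuffles (circular
shift by at least 500 frames, then six equal chunks permuted, identity
excluded; chunking applied after the shift).  Taking $\lambda$ as the
occupancy-weighted mean guarantees $\mathrm{SI} \ge 0$ (Jensen); a flag
switches to the unweighted mean.  Negative bin means (baseline noise) are
clamped to zero.  A unit is a place cell when its SI exceeds the 95th
percentile (linear interpolation) of its shuffles and it shows
significant field activity in more than 30% of post-induction laps.

BTSP signatures: the field peak shift (established-field peak minus
induction-lap peak, minimal circular displacement, negative = backward
relative to running) and the field width versus mean induction-lap
running velocity (5 cm/s bins, least-squares line on bin means, Pearson
R).

## The synthetic-data generator

The generator defines the study conditions for every test:

* **Behaviour**: 30 Hz frame grid (behaviour and imaging share one clock,
  removing resampling ambiguity without affecting any statistic); base
  speed 18 cm/s, halved within ±18 cm of the reward so dwell time doubles
  there; lap-to-lap lognormal speed multiplier (sd 0.2) — this is what
  spreads induction velocities across the width–velocity axis; smooth
  within-lap AR(1) speed noise (sd 0.05); with probability 0.3 per lap a
  1-s stop just before the reward (velocity 0.5 cm/s, below the running
  threshold, so the running filter has frames to remove); licking is a
  state-dependent point process peaking in the 20 cm before the reward.
* **CA1 units**: a fraction (default 40%) are place cells, the rest split
  between silent and noise-only (spatially random transients) units.
  A place cell is silent until its induction lap, then fires on every
  traversal: width = 2 s × induction velocity (measured as the
  20%-of-peak extent), field centre displaced backward from the plateau
  position by 0.5 s × induction velocity, lap amplitudes lognormal
  (sigma 0.3) around a 1.5 dF/F peak.  Activity drives are convolved with
  a fast-indicator kernel (50 ms rise, 300 ms exponential decay) on a
  lognormal baseline with additive Gaussian noise (sd 0.05 dF/F).
  Because the kernel smears fluorescence forward in time — hence forward
  in space by roughly decay × speed — the drive centre is advanced
  against running by that amount each lap, so the ground-truth field
  centre describes the *fluorescence* field the analysis actually sees.
* **EC3 ROIs**: each chain is a parent axon; its state sequence is mapped
  onto the behaviour frame grid lap by lap, convolved with the same
  kernel, and split into 1–3 ROIs sharing the signal with independent
  noise (sd 0.1) and lognormal pixel sizes — the substrate for the
  noise-correlation merge, with ground-truth axon identities retained.

No published forward model of the fluorescence exists; these kernel and
noise choices are fixture conventions, not claims about the data.  What
passing tests show is that the *analysis* recovers known ground truth
under a realistic forward model; they cannot certify performance on real
recordings, which add motion artefacts, neuropil contamination,
drift, and non-Poisson behaviour that the generator deliberately omits
(segmentation and motion correction are upstream of this package's
scope).

## Numerical choices and degenerate inputs

* Transition sampling uses continuous uniform draws with
  $p = P_{01}\Delta t$ (equivalent to integer sampling from 1–1000 at
  1/1000 granularity, without requiring $100 P_{01}$ to be integral).
* A calibration threshold is searched by bisection and accepted anywhere
  in the 20–25% band; with granular drives the band is reachable because
  drive values move in steps of 0.05.
* Dwell profiles with zero-time bins are filled by circular interpolation
  (with a warning) before step assignment.
* A 1e-9 cm guard in spatial binning absorbs floating-point boundary
  error when frame positions are exactly commensurate with bin edges.
* Degenerate traces fail loudly: non-positive F0, zero noise estimate,
  all-zero maps, too-short traces for the 500-frame shuffle shift.
* Period statistics exclude censored first/last runs; because long
  periods are preferentially censored, session-length runs would bias
  the mean inactive period by about $\tau^2/T$ (5% at 500 s), so
  closed-form checks use longer simulations (500 chains × 500 laps),
  where the bias is ~0.5%.

## Problem sizes

Default analyses run at the published operating points: 2000 chains,
10 000 model neurons, 200-unit imaging sessions of 60 laps, 100 shuffles
per unit.  The package's own validation (tests and the acceptance
script) uses these sizes directly; only auxiliary oracle checks use
smaller populations where the property under test is size-free.

## Known limitations

* The inactivation rate $P_{10}$ and the exact env-B density profile are
  not recoverable from the published material; defaults are fixed,
  documented choices with the stated calibration targets.
* Real-data ingestion is via plain CSV/JSON containers (one matrix per
  file); there is no HDF5 reader in this build.
* Group-comparison statistics between experimental arms (drug/opsin
  versus control) are out of scope; the package reports estimates and
  correlations, not treatment contrasts.
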