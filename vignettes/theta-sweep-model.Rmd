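---
title: "A behavior-dependent theta-sweep model of hippocampal place cells"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A behavior-dependent theta-sweep model of hippocampal place cells}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thetasweeps)
```

## The model

`thetasweeps` simulates a one-dimensional continuous attractor network of
`n = 250` rate units ("place cells") whose activation `r` obeys

    tau_r dr/dt = -r + i_theta + W_rec ((1 - d) * f * sigma_r(r)) + i_init + i_ext

with `tau_r = 5 ms` and a logistic activation `sigma_r(x) = 1/(1 +
exp(-alpha_r (x - x_r)))` (`alpha_r = 6`, `x_r = 0.5`). Four mechanisms
shape the dynamics:

* **Rhythmic theta drive.** All units share `i_theta(theta) =
  -(i_max - i_min) exp(kappa cos theta)/exp(kappa) + i_max` with
  `kappa = 12`, `i_max = 1.6`, `i_min = -1`, driven by the phase of an 8 Hz
  oscillation. Inhibition is maximal at `theta = 0` and shuts the network
  down between cycles; for most of the cycle the drive sits near `i_max`.

* **Asymmetric recurrent connectivity.** `W_rec[i, j] = 3.3 *
  exp(-(i - j - delta)^2 / (2 sigma_rec^2)) - 2.8` with `delta = 0.6`,
  `sigma_rec = 5`. The global negative baseline makes the network
  winner-take-all (a single activity bump); the offset `delta` makes the
  bump travel towards higher unit indices.

* **Short-term synaptic facilitation and depression.** Presynaptic
  efficacy is `(1 - d) f`, with `tau_f df/dt = -f + (1 - f) sigma_r(r) + f0`
  (`tau_f = 0.32 s`, `f0 = 0.14`) and `tau_d dd/dt = -d + sigma_r(r)`
  (`tau_d = 0.06 s`). Depression pushes the bump forward within a theta
  cycle; the slower facilitation, combined with fast recovery from
  depression during the inhibited troughs, makes each new bump form
  slightly ahead of where the previous one formed. The network therefore
  generates sequences that advance both within and across theta cycles,
  entirely on its own.

* **Gated spatial input with Hebbian anchoring.** 128 frozen,
  weakly-spatially-tuned features `s(x)` project onto the units through
  plastic weights `W_s` (initialized to 0):
  `i_ext = beta_max * beta_theta * sigma_s(W_s s)` with `beta_max = 0.4`
  and a steep dendritic nonlinearity (`alpha_s = 12`, `x_s = 0.7`). The
  gate `beta_theta = exp(kappa_s sin theta)/exp(kappa_s)` (`kappa_s = 2`)
  peaks at `theta = pi/2`, early in the cycle, and also gates the weight
  update `tau_w dW_s/dt = beta_theta (sigma_r(r) - i_ext) (x) s`
  (`tau_w = 20 s`). Units active in the input window become associated
  with the features of the rat's current position; the subtraction of
  `i_ext` stops growth once the input reproduces the unit's gated activity.

At the beginning of each lap `r` and `d` are reset to 0, `f` to `f0`, and
the first five units receive `i_init = beta_theta` for one theta cycle,
seeding the sequence; `W_s` persists across laps. Because sequences advance
at a pace set by the network while the rat moves at a position-dependent
speed, neighboring units become anchored to positions spaced proportionally
to the local typical speed — the elastic-mapping principle that produces
larger place fields, shallower phase precession and longer theta sweeps
where the animal typically runs faster.

## What the generator emulates

The trajectory generator emulates a rat running laps on a 200 cm linear
track at 1 ms resolution: a triangular target-speed profile (15 cm/s at the
ends, 80 cm/s in the middle), multiplied by a smooth noise factor (white
Gaussian noise convolved with a 2 s Gaussian kernel, affinely scaled to
[0.5, 1.5] over the session) to create lap-to-lap speed variability. At the
track end the rat is teleported back to 0; theta runs freely across laps
(no phase reset is applied at lap starts). The
feature bank emulates a mixture of weakly spatially modulated entorhinal
inputs (border/grid/object cells) as frozen smoothed noise over 1 cm bins,
each feature rescaled to the range [-1, 1] with the range midpoint at 0,
smoothing widths drawn uniformly from 2–20 cm (a continuous-uniform
reading; a discrete set would work equally).

What the generator does *not* emulate: pauses, reversals and grooming
bouts; 2-D environments; speed-dependent theta frequency; spiking
variability (units are deterministic rate units — the only stochasticity is
the behavior and the frozen features). Tests passing on this generator
therefore certify the mechanism and the analysis pipeline, not robustness
to spike noise or real behavioral statistics.

## Numerical choices

* **Integration** is forward Euler at `dt = 1 ms` for `r`, `f`, `d` and
  `W_s` (the step size is prescribed; the integrator is not). Within a
  step: drives are computed from the current phase and position, `r` is
  updated with pre-update `f`, `d`, `sigma_r(r)`, then `f` and `d` advance
  with the pre-update activation, then `W_s` with the post-update
  activation. Any consistent order is O(dt)-equivalent; a step-halving test
  bounds the error of each unit's cycle-integrated activation below 1%,
  with the clean first-order convergence ratio. Pointwise traces are not
  the right yardstick here: in a marginally stable attractor a sub-ms shift
  in bump-formation timing displaces the bump slightly, so pointwise
  differences are much larger even when the dynamics are accurate, and the
  emergent pace of the sequence itself moves by a few percent under step
  halving.
* **Session-length coupling.** The speed-noise factor must be scaled to
  [0.5, 1.5] over exactly the steps the session uses, but the session
  length itself depends on the scaled factor. The generator resolves this
  by fixed-point iteration on the scaling window (converges in a few
  rounds). A zero-variance noise series maps to the constant 1.
* **Smoothing** always uses a normalized Gaussian kernel truncated at 4 sd
  with reflective boundaries (edge transients would otherwise contaminate
  the speed factor and the track ends of the maps); summed activation is
  conserved to well under 1%.
* **Maps.** Activation maps average `sigma_r(r)` (or `i_ext` for true
  fields) in 2 cm occupancy bins after discarding the first 80 s of each
  session, then smooth with a 3 cm kernel. Unvisited bins (possible in
  speed-conditioned subsets) are interpolated for smoothing support and
  flagged.
* **Fields.** Peaks are the global map maximum per unit (parabolically
  refined below bin size); units with peaks under 0.2, or not dropping
  below 50% of peak on both sides, are discarded; sizes are 10%-of-peak
  extents with linearly interpolated crossings. The absolute 0.2 threshold
  is not applied to the input-defined (true) maps: `i_ext` is bounded by
  `beta_max` times the cycle-average of the gate (≈ 0.12), so an absolute
  unit-activation threshold would discard every unit; instead true fields
  are computed for units whose measured field was retained, with the same
  relative criteria.
* **Phase precession** is fit on position-by-phase bin centers (2 cm,
  20 degrees) within the field extent, thresholded at 10% of the in-field
  maximum and weighted by activation, using weighted total least squares
  (orthogonal distances — the reason steep clouds at the track ends keep
  their steep slopes). Since phase is circular, the fit is repeated for
  every 360-degree relabeling cut and the smallest orthogonal residual
  wins; circular-linear regression is deliberately not used.
* **Decoding** correlates each step's population vector with each spatial
  bin's template (the smoothed measured activation map, for internal
  consistency with the field analyses); ties take the lowest-index bin;
  steps with no unit above 0.1 or zero variance are invalid. Theta cycles
  are segmented at `theta = 0` (the inhibition peak) so each cycle holds
  one contiguous active epoch; sweep endpoints are the first and last
  36-degree bin (anchored at cycle start) containing a valid step. Cycles
  decoding the first or last track bin anywhere, straddling a lap
  teleport, or lacking valid steps are excluded.
* **Seeds.** A master seed is split into independent per-run streams, and
  within a run into separate streams for speed noise and features; features
  are regenerated per run, so each run is an independent track.

## Problem sizes

The package's own test suite runs the full 250-unit model: an 18-lap
session for the dynamics properties, three pooled 30-lap runs for the
field/sweep statistics, and one 45-lap run for the instantaneous-speed
invariance ratios (longer so that both speed conditions sample every bin).
The reference experiment (`run_experiment(default_config())`) pools ten
30-lap runs; `analyze_run()` on one run takes on the order of half a minute
on a laptop core, dominated by the map computations rather than the
compiled network loop.

## Emergent scales, and a known quantitative discrepancy

Two quantities are emergent rather than set: the pace `u0` at which the
sequence advances across cycles in unit space (units/s), and the
within-cycle sweep extent `S` (units). They determine the headline
statistics — at a location with typical speed `v`, field size scales with
`(S/u0) * v`, the onset-to-true-peak look-ahead is about `S/u0` seconds,
and the measured-vs-true peak shift is the (smaller) backward offset of the
averaged activation profile.

With the reference parameters this implementation measures `u0 ≈ 23`
units/s before anchoring (about 2.9 units per cycle, so a typical lap uses
roughly half of the 250 units) and `S ≈ 23` units, giving a pooled backward
field shift of ≈ 380–400 ms and an onset look-ahead of ≈ 1.0 s — larger
than the ≈ 160 ms / ≈ 600 ms scales the model family is known for, and the
value is stable over longer sessions (no warm-up effect). The
speed-dependence and invariance properties (field size, precession slope,
sweep metrics, instantaneous-speed ratios) hold regardless, since they
depend on the elastic mapping rather than on the absolute sweep scale. Two
downstream statistics do inherit the scale, however: fields near the slow
track ends become wide enough to be removed by the cut-off filter, which
suppresses field counts within ~20 cm of the walls and lets a linear fit
beat the hyperbolic (1/v) fit of density against speed that holds over the
interior; and the decoded look-behind saturates at roughly half the
(oversized) field shift instead of matching it one-to-one. A
single-parameter sensitivity analysis shows the discrepancy is governed by
the facilitation/depression balance between theta cycles: halving `tau_f`
to 0.16 s roughly doubles `u0` (a lap then spans nearly all 250 units) and
yields ≈ 130–160 ms and ≈ 450–600 ms; the packaged defaults nevertheless
remain the reference values, and the discrepancy is documented
rather than tuned away.

## A worked example

```{r example, eval = FALSE}
cfg <- default_config(master_seed = 1, n_runs = 3)
res <- run_experiment(cfg, outdir = "experiment_out")
rep <- summarize_experiment(res$pooled, track_spec())
str(rep)
```

The report lists the pooled mean backward shift and onset look-ahead (ms),
the regression statistics of field size and inverse precession slope
against mean speed, the linear-vs-hyperbolic density fits, the sweep
trends, and the shift-vs-look-behind comparison. The same quantities are
written as CSV/JSON artifacts when `outdir` is given, and
`scripts/acceptance.R` recomputes the two headline means from a fresh
10-run experiment.

## Limitations

* One-dimensional tracks only; extending to 2-D requires stitching
  sequences and is out of scope.
* Rate units without intrinsic noise; no spike-based statistics (rate maps
  in Hz, circular-linear correlations) are produced.
* The optional dependence of the within-cycle propagation speed on
  instantaneous running speed (which would make field sizes exactly
  invariant) is not implemented; the invariance ratios are accordingly
  slightly below 1.
* Theta frequency is fixed at 8 Hz; compensatory speed-theta interactions
  are not modeled.
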