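---
title: "A chaotic recurrent-network model of barcode-mediated cache memory"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A chaotic recurrent-network model of barcode-mediated cache memory}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(barcodeRNN)
```

## The model

Food-caching birds store and recall hundreds of precise spatial memories.
Hippocampal recordings in chickadees show that, during each caching event,
the population produces a sparse, high-dimensional activity pattern — a
"barcode" — that is unique to that cache, uncorrelated between nearby
sites, and reactivated when the cache is later retrieved; the same neurons
simultaneously carry ordinary place tuning. `barcodeRNN` implements a rate
model of this phenomenon and the analyses used to characterize it.

The network holds `N_x` rectified-linear rate units. Unit activity `x =
max(v, 0)` evolves by explicit Euler integration of

    dv/dt = -(alpha/N_x) * sum(x) * v  +  r * J %*% x  +  G * p  +  s * j_in

The leak is *divisive*: proportional to mean population activity, a shunting
normalization that keeps total activity bounded however strong the
recurrence. `J` is the recurrent matrix, `r` a global recurrence gain, `p`
the place input (exponential tuning `exp(-d/nu)` around each unit's
preferred location on a circular track of `N_s = 100` discrete states), `G`
a fixed input gain, and `s` a scalar "seed" input entering through fixed
standard-normal weights `j_in`.

Three protocols use the same network:

* **visit** (`r = 0`): purely input-driven; activity is exactly proportional
  to the place input, so the population carries a smooth place code.
* **caching** (`r = 1`): chaotic recurrence scrambles the place input into a
  sparse, location-decorrelated pattern (the barcode); the seed input is
  pulsed during the final `t_s` steps; the final snapshot is then stored by
  Hebbian plasticity.
* **recall** (`r = 1`, seed input held at the *search strength* `s`):
  pattern-completion dynamics; readouts report whether a stored attractor
  was reached and which place field it carries.

Storage binds the snapshot three ways: into the recurrent weights with
`Delta J = (eta/N_x)(x x^T + beta * x 1^T)` (the negative `beta` weakens
synapses of units inactive at storage, suppressing spurious recall), into a
seed readout (`w_seed += x`), and into a place readout (`J_place += p x^T`).
The seed output `y_s` and the place output `y_p` are linear readouts of the
recall activity; `y_s > kappa = 0.5` is the Cache Presence decision, and the
Cache Location decision additionally requires the place-output peak to fall
within a window of the nearest cache.

## Parameters and their defaults

| parameter | default | meaning |
|---|---|---|
| `nu` | 0.2 | place-field spatial scale (fraction of the track) |
| `N_p = N_x = N_y` | 5000 | layer sizes (inputs wired one-to-one) |
| `N_s` | 100 | track states; 8 states = one cache-site distance |
| `mu`, `sigma` | −40, 7 | weight mean/sd scales: entries `N(mu/N, sigma²/N)` |
| `dt`, `T_dyn` | 0.1, 100 | Euler step; length of dynamics (time units) |
| `t_s`, `lam` | 5, 3.0 | seed-pulse length (steps) and strength at caching |
| `eta`, `beta` | 40, −0.35 | Hebbian rate and inhibitory bias |
| `kappa` | 0.5 | seed-output decision threshold |
| `k_spike`, `K_offset` | 2, 0.2 | Poisson spike scales (analysis / display) |
| `gamma, rho, delta_off, D` | 0.99, 0.075, −0.015, 300 | successor-representation matrix |
| `input_gain` | 4 | gain of the place drive (calibration, below) |
| `storage_norm` | 0.15 | mean-square amplitude of the stored snapshot |
| `readout_gain` | 3 | fixed gain of both readouts |

With `sigma = 1` the network is input-dominated (activity correlations track
the inputs); with `sigma = 20` recurrence destroys spatial correlation; the
default `sigma = 7` is the interesting mixed regime in which activity keeps
a smooth place component *and* a strong state-specific barcode component.

## Calibration choices (and why they exist)

Three numerical choices in this package are calibrations rather than free
model structure. They were fixed once, from single-cache behaviour, before
any multi-cache evaluation was run, and are exposed as config fields:

* **`input_gain = 4`.** With a unit-peak exponential place drive, `sigma =
  7` recurrence fully decorrelates activity — no residual place component
  survives and place-cued recall cannot find stored attractors. A modest
  feedforward gain moves the operating point into the mixed regime described
  above. The gain multiplies only the place drive; the seed pathway drive is
  used as printed.
* **`storage_norm = 0.15`.** The attractor strength created by one Hebbian
  update is `(eta/N) * ||x||^2`, and the squared norm of a raw chaotic
  snapshot fluctuates severalfold between realizations; unnormalized storage
  therefore produces either runaway amplification (non-finite voltages) or
  patterns too weak to recall. Normalizing each stored snapshot to a fixed
  mean-square amplitude pins the attractor gain at `eta * storage_norm ≈ 6`,
  comparable to the chaotic gain `sigma = 7`: strong enough to capture the
  cued trajectory, weak enough not to capture neighbouring states.
* **`k_spike = 2`.** The Poisson scale for the correlation analyses is,
  by its definition, a calibration: it is chosen so that simulated spike
  counts have the statistics of the recorded data. At this package's rate
  amplitudes (active visit rates ≈ 0.3, cache rates ≈ 0.8), `k = 2` gives
  expected counts of order one for active units — the same operating point
  the original choice achieves at larger rate amplitudes — so spiking
  attenuates correlations uniformly instead of drowning them in sampling
  noise.
* **`readout_gain = 3`.** The readouts are normalized per neuron
  (`y = gain * w.x / N_x`), so a converged recall reads out ≈ 1 and
  uncaptured activity ≈ 0.05–0.4, with the decision threshold
  `kappa = 0.5` between the two.

Two interpretation choices: `T_dyn = 100` is read in *time units* (1000
Euler steps at `dt = 0.1`) — the snapshot is the rate vector at `t = 100`,
and the shorter 100-step transient leaves attractor convergence incomplete
— while `t_s = 5` is read in *steps*, since the seed pulse is specified on
the step grid; both readings are available via `t_unit`.

## What the tasks measure

`run_three_cache_task()` stores caches at 20%, 35% and 70% of the track and
probes recall everywhere. *Cache Presence* (correct-reject at uncached
states, especially midpoints between nearby caches) measures memory
precision: because barcodes for nearby caches are uncorrelated, the model
can reject a midpoint only one site distance (8 states) from two caches.
*Cache Location* (place-output peak at the nearest cache) measures recall
robustness; raising the search strength `s` widens the retrieval radius at
the cost of presence precision. The ablations dissociate the two codes:
`place_only` (no random recurrence) merges nearby memories and cannot
reject midpoints; `barcode_only` (uncorrelated inputs, `nu = 1e-3`) detects
presence but cannot retrieve remote caches because no proximity structure
exists.

`correlation_profile()` reproduces the in-silico version of the
electrophysiological signature: Poisson spikes (`k = 0.2`) drawn from
visit, cache and retrieval activity; population Pearson correlations binned
by site distance and normalized by the distance-0 visit-visit value. The
same-site cache-retrieval value exceeding 1 is the barcode-reinstatement
boost; at one site distance it falls back to the visit-visit curve.

`code_projection()` analyses the hybrid model (`J = B + M` with `M` a
circulant successor-representation matrix for a deterministic clockwise
walk). Sweeping the recurrence gain decomposes activity into place,
predictive and barcode components: place projection maximal at `r = 0`,
predictive peaking near `r = 0.4`, barcode at `r = 1`. The predictive
reference is the place pattern one state clockwise, orthogonalized against
the local place pattern. Projections are taken on the unit-normalized
population direction: total activity grows with the recurrence gain, and
raw-magnitude projections inherit that amplitude trend, flattening the
predictive curve into a near-degenerate plateau across `r = 0.3`–`0.4`;
the direction-based statistic gives a stable interior peak (the raw option
remains available). With a single cache stored, the hybrid model's supra-threshold
seed output extends farther on the approach side than past the cache: prior
experience skews recall.

## Synthetic data and problem sizes

Everything is generated internally; there is no external data. The
generator's defaults are the study conditions: three caches at 20%/35%/70%,
35 replicate seeds with 99% binomial confidence intervals, 20 simulated
correlation experiments with 5 cached sites each, spike scale `k = 0.2`.
One master seed fans out into named streams (weights, seed pathway, noise,
spikes, inputs, task) so that toggling one source of randomness leaves the
others unchanged.

The test-suite and acceptance-script runs use reduced networks — 700–2000
units instead of 5000, chosen so the full suite completes on a single CPU —
with `scale_config()` preserving the dynamical regime: weight statistics
scale automatically through the `mu/N`, `sigma^2/N` parameterization, and
the successor-representation matrix is rescaled (`gamma^(5000/n)`,
`rho * 5000/n`, `delta * 5000/n`, `D * n/5000`) so its action on smooth
activity profiles is unchanged. Finite-size effects at these sizes mainly
inflate seed-to-seed variability of the recall readout around the
threshold; quantities that are averages over states or units (correlation
profiles, projection curves) are stable.

What passing tests do **not** show about real data: inputs here are
noiseless and stationary, the track is 1-D, every cache stores the same
seed content, and retrieval never modifies stored memories (no forgetting
or overwriting, no multiple caches per site). Dynamics and static noise
hooks exist (`noise_dynamic`, `noise_static`) but default to zero because
no noise magnitudes are part of the study conditions.

## Numerical notes, degenerate inputs, limitations

* Explicit Euler at `dt = 0.1` is marginal for the strongest recurrence
  (`sigma = 20`): eigenvalues of order `sigma` put `dt*lambda` near the
  stability edge, and the strong-recurrence steady state retains a residual
  input-driven correlation (~0.3) rather than decorrelating completely.
  Where that matters the relevant test states it.
* Any non-finite voltage raises an error naming the step; nothing is
  silently clipped.
* Zero activity is an exact fixed point; storing an all-zero snapshot is an
  error (amplitude normalization would divide by zero).
* The midpoint between caches at even spacing falls between two states; the
  floor state is probed.
* Ties in the feedforward thresholds leave tied units at zero, so the
  active fraction can undershoot `theta` by at most one unit.
* The GP input bank draws one process realization and shifts it circularly
  with the state, giving stationary spatially-correlated inputs with random
  irregular tuning curves; drawing independent profiles per state would
  destroy the spatial proximity structure the tasks rely on.
* Amplitude-normalized storage changes the character of the `place_only`
  ablation: a dense place pattern's Hebbian self-excitation
  (`eta * storage_norm`) barely exceeds its `beta` inhibition (which scales
  with the pattern's mean rather than its mean square), so the place-only
  model under-recalls rather than over-recalling (merging) nearby memories.
  The ablation still demonstrates that place-code-only storage cannot
  support the tasks, but by the opposite failure mode.
* Because the stored patterns carry their place component at a share well
  below one, the cache-retrieval correlation profile is approximately a
  scaled-down copy of the visit-visit profile away from distance zero (plus
  the same-site reinstatement boost), rather than coinciding with it.
* One-site-distance midpoint rejection is the most finite-size-fragile
  quantity in the package: at a few thousand units the chaotic trajectories
  that implement pattern separation occasionally wander into a stored
  attractor's basin, so rejection rates at 4-state distances sit below the
  near-perfect rates expected of the full-size network.
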