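---
title: "Methods: simulating and scoring heterogeneous diffusion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and scoring heterogeneous diffusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fbmbench)
```

This vignette is the package's own account of its science: the stochastic
model underneath every simulator, the conventions we had to fix where the
mathematics leaves room, the numerical choices, and what the synthetic
data can and cannot tell you about real experiments.

## The diffusion model

All trajectories are two-dimensional fractional Brownian motion (FBM):
`X(t)` and `Y(t)` are independent Gaussian processes with stationary,
correlated increments. A *diffusive state* is the pair `(K, alpha)` — the
generalized diffusion coefficient (pixel²/frame^α) and the anomalous
exponent, related to the Hurst exponent by `alpha = 2H`. The per-axis
increments are unit-variance fractional Gaussian noise (fGn) with
autocovariance

    gamma(k) = 1/2 * (|k+1|^alpha - 2|k|^alpha + |k-1|^alpha),

rescaled by `sqrt(2 * K * dt^alpha)`, so the unconstrained ensemble MSD is
`4 K t^alpha`. At the package's sampling interval `dt = 1` this is the
familiar per-step variance `2 K dt`; we use the self-similar `dt^alpha`
scaling so the MSD law survives a change of sampling interval.
`alpha < 1` gives anti-persistent (subdiffusive) increments, `alpha = 1`
Brownian motion, `alpha > 1` persistent (superdiffusive) motion.

**Generation.** Long blocks use Davies–Harte circulant embedding: the
covariance of `n` increments embeds in a `2n` circulant whose eigenvalues
come from one FFT; sampling is exact whenever those eigenvalues are
non-negative, which holds analytically for fGn (tiny numerical negatives
are clamped; a genuine failure would fall back to the Hosking /
Durbin–Levinson recursion, which is exact at `O(n²)`). Blocks of 64 steps
or fewer instead draw through a cached Cholesky factor of the Toeplitz
covariance — segment-wise simulation generates thousands of short blocks,
and the factorization cache makes them cheap. All three paths are tested
against the analytic covariance. `alpha` is clipped to `[0.01, 1.99]`
before generation: the covariance matrix becomes numerically singular at
the open-interval endpoints. `K` draws live on `[1e-12, 1e6]`, with
`K = 0` reserved for the exactly immobile (trapped) state.

**Seeds.** One root seed per experiment; per-FOV and per-noise-stream
children are derived with a small multiplicative hash (`derive_seed()`)
and logged in the dataset manifest, so a manifest reproduces a dataset
bit for bit.

## Interaction models and their conventions

State switching is driven by five models. Where a rule is not forced by
the definitions, the convention we chose is stated here and implemented
exactly once.

* **SSM** — one `(K, alpha)` per trajectory, drawn from the state's
  Gaussian hyper-parameters (sd 0 means a point mass; draws are redrawn
  up to 100 times, then clamped, to respect the supports). No
  changepoints: the negative control for false-positive rates.
* **MSM** — a Markov chain over `S` states with row-stochastic `M`;
  each trajectory draws its own `S` parameter pairs. The expected
  residence time is `1/(1 - M_ii)`. *Convention:* the initial state is
  uniform over states.
* **DIM** — particles of radius `r`; a free, "eligible" pair at distance
  `< 2r` binds with probability `P_b` per step, moves with *identical*
  displacements drawn from the dimeric state, and unbinds with `P_u` per
  step. *Conventions:* per step the order is unbind → bind → move;
  particles that just unbound cannot re-bind within the same step; only
  pairs form (collisions with a dimer are inert); each binding event
  draws fresh dimeric parameters.
* **TCM** — `N_c` non-overlapping circular compartments (rejection
  sampling, bounded attempts). Boundaries are osmotic: entry from
  outside always succeeds, an exit attempt succeeds with probability
  `transmittance`, otherwise the step is specularly reflected about the
  tangent at the crossing point (and projected back inside if numerics
  leave it outside). Transmittance is tested once per crossing attempt.
  Inside and outside use the trajectory's two parameter draws.
* **QTM** — `N_t` circular traps (may overlap). A free particle within
  `r_t` of a trap center binds with `P_b` per step and is exactly
  immobilized (`K = 0, alpha = 0`); release happens with `P_u` per step,
  and the released particle steps immediately — so it cannot be
  re-trapped before taking a new step.

**Memory at changepoints.** Every state change starts a fresh fGn block
with the new state's parameters: positions are continuous, increment
memory is not. For the spatially-triggered models, whose segment
durations are unknown a priori, streams are (re)generated for the
remaining horizon at each switch. This "reset" convention is a modelling
choice — conditioning the new segment on the old increments would be the
alternative — and it matches segment-wise generation of the time-driven
models exactly.

**Boundaries.** The box `[0, L]²` reflects: a proposed position is folded
by mirror reflection about the violated wall(s), repeatedly for steps
longer than the box.

**Ground-truth labels.** Per-frame state labels are smoothed with a
centered window-5 majority filter (ties keep the current label). One pass
does not guarantee a minimum run length on adversarial sequences, so the
filter iterates to a fixed point and any surviving run shorter than
`t_min = 3` frames is absorbed into its longer neighbour; the spec of the
data format — every segment at least `t_min` frames — then holds by
construction. After relabeling, each run's `(K, alpha)` are refilled from
frames whose raw label matches the run. Diffusion-type identifiers per
frame: 0 immobile (trapped, or `alpha < 0.05`), 1 confined (inside a
compartment), 2 free (`0.05 <= alpha < 1.9`), 3 directed
(`alpha >= 1.9`).

**Field of view.** The FOV is the centered square of side `L_FOV`. Each
maximal in-FOV visit of at least `T_min = 20` frames becomes a new
trajectory with a fresh id (re-entries are separate trajectories);
changepoints and segments are re-derived on the cropped support. Frames
keep the recording time base (0-based, up to `T = 200`).

## The imaging model

Videos render each particle as an Airy disk of FWHM 2.1 px centered at
its sub-pixel position (pixel centers at integer coordinates), scaled by
a per-particle intensity: base `~ Uniform[I_min, I_max]`, per-frame
fluctuation `~ Normal(base, sigma_I)` clipped at zero. A flat background
of 100 counts is added and every pixel is Poisson-corrupted. The PSF is
truncated at its third dark ring and renormalized by the encircled energy
inside that radius, so a rendered spot integrates to its particle's
intensity to better than 1% — without the renormalization the truncation
would silently discard ~6% of the photons. 8-bit conversion clips at 255
with no rescaling (counts are already detector units); the clipped
fraction is reported so `I_max` can be adjusted. The peak-count and SNR
conveniences follow `I_peak = I_tot * 4 ln 2 / (pi FWHM²)` and
`SNR = I_peak / sqrt(I_peak + I_bg)`. Motion blur, blinking and
photobleaching are deliberately out of scope. VIP label maps fill a disk
of one FWHM (configurable) around each VIP's first-frame position with
the particle index, nearest-center where disks overlap.

Trajectory-track tables instead add i.i.d. Gaussian localization noise
(`sigma_N`, default 0.12 px — a typical sub-pixel localization precision)
to the reported coordinates only; ground truth is stored separately.

## Scoring

**Changepoints.** For one trajectory, the gated distance
`d_ij = min(|t_gt − t_pred|, eps_cp)` feeds a rectangular minimum-cost
assignment (Hungarian; solved by `clue::solve_LSAP`, checked in the test
suite against exhaustive enumeration). Unmatched ground-truth CPs charge
the full gate. Then `alpha_cp = 1 − d_cp/d_cp_max` with
`d_cp_max = M_GT * eps_cp`, and
`beta_cp = (d_cp_max − d_cp)/(d_cp_max + d_bar)` where `d_bar` charges
`eps_cp` per unassigned prediction. Pairs closer than the gate are TPs;
gate-saturated or unmatched predictions FPs; unmatched truths FNs. JSC
(`TP/(TP+FP+FN)`, with 0/0 defined as 1) and the RMSE of TP pairs
aggregate over the whole experiment.

Conventions worth stating: `eps_cp` defaults to 10 frames (5% of the
recording; configurable and reported with every score). Trajectories with
no ground-truth CPs are excluded from the `alpha_cp`/`beta_cp` averages
(their `d_cp_max` is 0) but still contribute false positives to JSC. The
RMSE normalizer counts TP pairs, not trajectories, which would be
undefined for CP-free trajectories; with zero TPs the worst-value
sentinel `eps_cp` is reported unless nothing was contested at all, which
scores a perfect 0.

**Segments.** Predicted CPs define predicted segments; ground-truth and
predicted segments pair one-to-one by maximizing the summed temporal
Jaccard index. Only paired segments enter
`MSLE = mean((log(K_gt+1) − log(K_pred+1))²)` (natural log) and
`MAE = mean(|alpha_gt − alpha_pred|)`, normalized by the number of paired
segments in the experiment. Type classification uses micro-averaged F1;
unpaired ground-truth segments count as FNs of their class and unpaired
predictions as FPs. Trajectories missing from a submission score worst
everywhere: `alpha_cp = beta_cp = 0`, their CPs become FNs, each segment
contributes the support-width maxima (MAE term 2; MSLE term
`log(1e6+1)²`).

**Ensembles.** A prediction is a model label (scored correct/wrong), a
state count (absolute error), and per-state `(weight, mean, sd)` for `K`
and `alpha`. The mixture CDFs — Gaussian components untruncated, sd-0
components as Heaviside steps — are compared by
`W1 = ∫ |CDF_P − CDF_Q| dx` over the parameter support. Quadrature:
trapezoidal on 2001 uniform points over `(0, 2)` for `alpha`; for `K`,
6001 points uniform in `log10` over `[1e-12, 1e6]` integrated in the
linear variable (a uniform linear grid over 18 decades resolves nothing
near `K ≈ 1`). Nodes are inserted at every point mass, making the rule
exact for step CDFs; doubling either grid changes W1 by less than 0.1% in
the convergence tests. W1 deliberately carries no penalty for
over-splitting into many states — the state-count error is reported
alongside, never mixed in.

**Ranking.** Methods are ranked per metric (ties share the average rank —
the aggregate is silent on ties, so this is declared here) and summarized
by the mean reciprocal rank. The single-trajectory ranking uses JSC,
RMSE, MSLE and MAE; the ensemble ranking uses model correctness and the
two W1 distances.

## The MSD baseline

For each trajectory the overlapping-window TA-MSD is fit over the first
quarter of lags (a standard short-lag window; configurable): `K` from the
linear slope divided by 4, keeping an intercept so static localization
noise does not bias the slope; `alpha` from the log–log slope, clipped to
`[0.01, 1.99]`. Types come from the identifier thresholds with an
immobility cut at `K < 1e-3` (the baseline has no confinement detector,
so type 1 is never emitted — a documented limitation). It predicts no
changepoints, giving a false-positive rate of exactly zero on
single-state data, and its ensemble summary is the length-weighted
one-state pool of the per-trajectory estimates. It is a floor, not a
method.

## Default study conditions

Values the simulator needs but the data format does not pin down were
fixed once, before any benchmarking, at what we consider realistic
single-molecule regimes: box `L = 192` px around the 128-px FOV (large
enough that boundary reflections are rare in-FOV), `N = 100` particles
per FOV, `sigma_N = 0.12` px, intensities `I_min = 400`, `I_max = 600`,
`sigma_I = 20` counts (peak SNR ≈ 7), and the per-model presets in
`inst/presets/` (e.g. two-state MSM with ~50-frame dwells; dimeric state
subdiffusive at `alpha = 0.5`; traps of radius 1 px at `P_u = 0.05`).
All are configuration, not constants.

The test suite's statistical checks state their problem sizes explicitly:
ensemble-MSD recovery uses 10⁴ trajectories of length 200 (slope within
±0.03, prefactor within 5%); residence-time recovery uses >10⁴
uncensored sojourns (within 5%; sojourns touching the recording edges are
discarded to avoid censoring bias); geometric dwell checks for binding
and trapping run at a few hundred events with proportionally wider
tolerances.

## What passing tests do and do not show

The generator emulates the benchmark's data model faithfully — piecewise
FBM, the five interaction mechanisms, sub-pixel localization error, shot
noise — but real data differ in ways the synthetic suite cannot certify:
localization error is not i.i.d. Gaussian (it depends on photon counts
and background), motion blur couples position error to motion, detectors
add gain and read noise on top of Poisson statistics, linking errors
create identity switches that the gap-free tables exclude by
construction, and real interaction kinetics need not be Markovian.
Metric-suite results, by contrast, are exact properties of the formulas
and transfer to any data. Known limitations: the specular-reflection
geometry at compartment boundaries is one of several defensible choices
("reflected back inside" underdetermines it); the FBM memory reset at
changepoints is a convention; and W1's blindness to over-splitting means
ensemble scores should always be read next to the state-count error.
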