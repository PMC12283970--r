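# fbmbench

Simulation and benchmarking of heterogeneous single-particle diffusion.

Single-particle tracking experiments routinely produce trajectories whose
diffusive behaviour switches along the way: a membrane receptor dimerizes
and slows down, a protein falls into a chromatin trap, a lipid gets caught
in a cortical corral. Methods that segment such trajectories — finding the
changepoints (CPs), estimating each segment's generalized diffusion
coefficient *K* and anomalous exponent *α*, and classifying the motion
type — need ground-truthed data to be trained and compared on.
`fbmbench` provides the full loop for that comparison:

* **Simulate.** 2-D fractional Brownian motion (FBM) with per-state
  parameters: the increments of each coordinate are fractional Gaussian
  noise with autocovariance
  `γ(k) = ½(|k+1|^α − 2|k|^α + |k−1|^α)` (Hurst exponent `H = α/2`),
  scaled so the unconstrained ensemble MSD is `MSD(t) = 4 K t^α`.
  Switching between diffusive states is driven by five interaction models:
  single-state (SSM), multi-state Markov (MSM, transition matrix `M`,
  residence time `τᵢ = 1/(1 − Mᵢᵢ)`), transient dimerization (DIM),
  transient confinement in osmotic compartments (TCM) and quenched traps
  (QTM, immobilized at `K = 0, α = 0`).
* **Render.** Fields of view become realistic fluorescence videos: Airy
  PSF (FWHM 2.1 px), per-particle intensities, 100-count background,
  Poisson shot noise, 8-bit multi-frame TIFF, plus a VIP label map of the
  first frame. Trajectory tables get Gaussian localization noise instead.
* **Score.** The benchmark metric suite: gated Hungarian CP pairing
  (`α_CP`, `β_CP`), experiment-wide Jaccard similarity and RMSE of CPs,
  temporal-Jaccard segment pairing feeding MSLE(*K*), MAE(*α*) and a
  micro-averaged F1 on the type labels; for ensemble predictions, model
  classification, state-count error and the first Wasserstein distance
  `W₁(P, Q) = ∫ |CDF_P − CDF_Q| dx` between Gaussian-mixture state
  distributions; mean reciprocal rank to aggregate methods.
* **Baseline.** A non-learned MSD-fit predictor (linear fit for *K*,
  log-log fit for *α*, no changepoints) that exercises the whole pipeline
  and marks the floor any real method must beat.

## Worked example

Simulate a two-state Markov experiment, crop to the field of view, corrupt
the observed coordinates with localization noise, run the MSD baseline,
and score it against the ground truth:

```r
library(fbmbench)
library(dplyr)

cfg <- experiment_config("msm", N = 50, seed = 7)
exp <- simulate_experiment(cfg)
exp
#> <fbm_experiment> model=msm  particles=50  frames=200

fov <- crop_to_fov(exp)        # 35 trajectories >= 20 frames in the FOV
gt  <- derive_segments(fov)
head(gt, 5)
#> # A tibble: 5 × 7
#>    traj segment start   end      K alpha  type
#>   <int>   <int> <int> <int>  <dbl> <dbl> <int>
#> 1     1       1    73    79 0.965  1.27      2
#> 2     1       2    80    90 0.0400 0.775     2
#> 3     1       3    91   122 0.965  1.27      2
#> 4     2       1     0    18 0.972  1.18      2
#> 5     2       2    19    81 0.0587 0.875     2

noisy <- add_localization_noise(fov, sigma_N = 0.12, seed = 8)
pred  <- baseline_predict(noisy)
score_trajectories(gt, pred, eps_cp = 10) |> select(alpha_cp:f1)
#> # A tibble: 1 × 7
#>   alpha_cp beta_cp   jsc  rmse   msle   mae    f1
#>      <dbl>   <dbl> <dbl> <dbl>  <dbl> <dbl> <dbl>
#> 1        0       0     0    10 0.0844 0.201 0.470
```

The baseline predicts no changepoints, so every CP metric sits at its
floor (`α_CP = β_CP = JSC = 0`, RMSE at the gate `ε_CP = 10` frames) while
its segment-level parameter errors are respectable (MSLE 0.084 on *K*,
MAE 0.20 on *α*) — exactly the benchmark contrast the scorer is meant to
expose. Pooling the per-trajectory fits into a one-state ensemble summary
and scoring against the generating mixture:

```r
truth <- ensemble_truth(exp, fov)
score_ensemble(baseline_ensemble(pred, model = "ssm"), truth)
#> # A tibble: 1 × 4
#>   model_correct state_count_err  w1_K w1_alpha
#>           <dbl>           <int> <dbl>    <dbl>
#> 1             0               1 0.301   0.0813
```

Full datasets in the challenge layout (`track_2/EXP_n/FOV_m.csv`,
optional `track_1` videos, hidden `ground_truth/` sidecars, a seed
manifest) are produced by `write_challenge_dataset()` or from the shell:

```sh
inst/cli/fbmbench generate --config inst/presets/benchmark.yaml --out data/ --seed 1
inst/cli/fbmbench baseline --data data/ --out preds/msd
inst/cli/fbmbench score    --data data/ --pred preds/msd
```

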