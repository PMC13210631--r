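# ethosim

Sensor-aware generative simulation of rodent trajectories: a framework for
*in silico ethology* that separates what the animal does from what the
sensor reports.

## The problem

Long behavioral recordings of rodents are central to phenotyping, but real
cohorts are costly and the measurement process is never neutral.
Ultra-wideband (UWB) positioning distorts trajectories differently under
line-of-sight (LoS) and non-line-of-sight (NLoS) propagation — systematic
bias, heavier-tailed errors, intermittent outliers — which shifts every
downstream kinematic feature. `ethosim` models the trajectory as

```
z_t  →  x_t  →  x̃_t          x̃_t = x_t + e_t
```

where `z_t ∈ {exploring, feeding, burrowing}` is the behavioral state,
`x_t` the latent planar position (meters, 10 Hz), and `e_t` an additive
distortion conditioned on state and sensing regime. The latent layer is a
run-level semi-Markov process (zero-diagonal transition matrix, empirical
dwell-time distributions, occupancy-calibrated exploring exits) driving
state-conditioned step-length/turning-angle priors with 0.995-quantile
Winsorization caps. The observation channel is a per-(state, regime)
Gaussian/Student-t mixture, `e = μ + u`,
`u ~ (1−ρ)·N(0,Σ) + ρ·T₄(0,Λ)`, fitted by EM on proxy-referenced residuals
(observed minus a rolling-median-then-mean reference, window 21 samples
under LoS, 41 under NLoS) with hierarchical pooling for sparse bins and
0.999-quantile magnitude caps.

The package ships the full evaluation stack from the study design it
implements: a "statistical Turing test" (occupancy error, state-conditioned
and occupancy-weighted KL divergence, residual-domain KL/KS),
mean-squared-displacement curves with RMSE summaries, a ground-truth
fixture generator, and a domain-shift robustness benchmark comparing a
sensor-aware classifier (regime as covariate) against condition-agnostic
baselines under LoS↔NLoS transfer.

## Worked example

```r
library(ethosim)

# 1. ground-truth fixture sessions standing in for real recordings
real <- make_real_like_sessions(n_los = 2, n_nlos = 2, T = 3000, seed = 7)
real[[1]]
#> <ethosim_session> 3000 frames (300.0 s) under LoS
#>   occupancy: exploring 0.798, feeding 0.058, burrowing 0.144
#>   latent: yes, reference: no

# 2. calibrate the full model bundle
bundle <- calibrate_model(real)
bundle
#> <ethosim_bundle>
#>   calibrated exploring exits: alpha = (0.489, 0.511), objective = 2.79e-06
#>   target occupancy: 0.810, 0.063, 0.126
#>   channel bins: 1.LoS, 2.LoS, 3.LoS, 1.NLoS, 2.NLoS, 3.NLoS

# 3. synthesize an ensemble and check realism under NLoS
synth <- synthesize_ensemble(bundle, n = 20, regime = "NLoS", base_seed = 100)
real_nlos <- Filter(function(s) s$regime == "NLoS", real)
turing_report(real_nlos, synth, config = bundle$config)
#> <ethosim_turing> regime NLoS
#>   occupancy error: +0.0080 +0.0055 -0.0135
#>   weighted KL: step 0.0435, turn 0.0143 nats
#>   residual KL 0.0260 nats, residual KS 0.0100

rmse_msd(mean_msd(real_nlos, K = 300), mean_msd(synth, K = 300))
#> [1] 0.4389952

# 4. domain-shift benchmark (one replicate per setting)
run_benchmark(bundle, "sensor_aware_mixed", seed = 20250)
#> <ethosim_benchmark> sensor_aware_mixed: AUC 0.993, accuracy 0.967, balanced accuracy 0.967 (n=300/300)
run_benchmark(bundle, "agnostic_nlos_to_los", seed = 20250)
#> <ethosim_benchmark> agnostic_nlos_to_los: AUC 0.998, accuracy 0.687, balanced accuracy 0.687 (n=300/300)
```

Reading the numbers: the calibrated exploring-exit distribution `alpha`
makes the model's induced frame occupancy match the sessions' empirical
occupancy (squared error 2.8e-6); the synthetic NLoS ensemble reproduces
occupancy within 0.014 per state and the residual-magnitude distribution
almost exactly (KS = 0.010); and a classifier that knows the sensing regime
keeps both AUC and its decision threshold intact on mixed-regime data,
whereas the condition-agnostic baseline trained on NLoS still *ranks* LoS
sessions well (AUC 0.998) but its fixed 0.5 threshold collapses (balanced
accuracy 0.687, and 0.500 in the opposite direction) — the
threshold-miscalibration failure mode that sensor awareness removes.

A command-line front-end wrapping the same functions
(`fixtures`, `calibrate`, `generate`, `evaluate`, `benchmark`, `pipeline`)
is installed at `system.file("cli/ethosim", package = "ethosim")`.

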