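---
title: "Sensor-aware simulation of rodent trajectories: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sensor-aware simulation of rodent trajectories: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Quantitative rodent phenotyping needs long, well-controlled trajectory
cohorts, but real cohorts are expensive and the sensing process is never
neutral: an ultra-wideband (UWB) positioning system distorts the observed
track differently under line-of-sight (LoS) and non-line-of-sight (NLoS)
propagation — bias, heavier tails, and intermittent outliers under NLoS.
Treating that distortion as a nuisance conflates behavior with measurement.
`ethosim` instead factorizes trajectory generation into a latent behavioral
process and an explicit observation channel,

$$z_t \rightarrow x_t \rightarrow \tilde{x}_t, \qquad
\tilde{x}_t = x_t + e_t,$$

where $z_t \in \{\text{exploring}, \text{feeding}, \text{burrowing}\}$ is
the behavioral state, $x_t \in \mathbb{R}^2$ the latent planar position
(meters), and $e_t$ an additive distortion conditioned on the state and on
the session's sensing regime $c \in \{\text{LoS}, \text{NLoS}\}$. Frames
arrive at $\Delta t = 0.1$ s.

## The latent behavioral layer

**Runs and the semi-Markov chain.** Frame labels are collapsed into runs
$(s_k, d_k)$ (state, duration in frames). Run-to-run succession is a
first-order Markov chain with maximum-likelihood transition probabilities
$\hat{P}_{ij} = N_{ij} / \sum_{j'} N_{ij'}$; self-transitions are
structurally removed ($\hat{P}_{ii} = 0$) because persistence is carried
entirely by the per-state empirical dwell-time distributions $D_i$ with
means $m_i$. A state never exited in the data has an undefined row; we fill
it uniformly over the other states and flag it degenerate — the
maximum-entropy choice, which affects synthesis only, never the reported
counts.

**Occupancy calibration.** Run dynamics induce the frame-level occupancy

$$\pi_i = \frac{\mu_i m_i}{\sum_\ell \mu_\ell m_\ell},$$

with $\mu$ the stationary distribution of the run chain. Because the
dominant exploring state exits rarely, its outgoing row is the least stable
estimate, so calibration replaces only that row with
$(0, \alpha_2, \alpha_3)$, $\alpha_2 + \alpha_3 = 1$, keeps the renormalized
empirical structure of the other rows, and minimizes
$\lVert \pi(\alpha) - \pi^{\text{real}} \rVert_2^2$ by exhaustive grid
search. The constraint makes the problem one-dimensional; we use a grid step
of 0.001 (1001 candidates), which is exact to the resolution anyone would
report and fully reproducible. The stationary distribution is solved by the
left eigenvector of the $3 \times 3$ chain (validated in the tests against
power iteration) rather than iteratively — exactness is free at this size.

**Kinematic priors.** Step lengths $\ell_t$, headings $\phi_t$, and wrapped
turning angles $\theta_t \in (-\pi, \pi]$ are extracted from a smoothed
reference trajectory and pooled per *arrival* state $z_t$ into empirical
sample sets. Synthesis draws i.i.d. bootstrap samples from these sets — the
priors are the empirical distributions themselves, with no parametric
family imposed — and Winsorizes each draw at the state's
$p_\ell = p_\theta = 0.995$ quantile caps (type-7 quantiles throughout)
before integrating

$$\phi_t = \phi_{t-1} + \theta_t^{\text{cap}}, \qquad
x_t = x_{t-1} + \ell_t^{\text{cap}} (\cos \phi_t, \sin \phi_t).$$

Because runs shorter than one frame of feeding are artifacts of run-based
synthesis, a deterministic pass reassigns isolated single-frame feeding
events to the longer neighboring run (ties to the preceding run) before any
kinematics are drawn.

## The observation channel

There is no external ground truth in UWB-only recordings, so the reference
trajectory is a *proxy*: a centered rolling median followed by a centered
rolling mean, window $w = 21$ samples under LoS and $w = 41$ under NLoS. At
the series boundaries the window shrinks symmetrically (down to a single
sample) so a reference — and hence a residual $e_t = \tilde{x}_t - x_t$ —
exists at every frame. Residuals are therefore deviations from a denoised
proxy, not true localization errors; this caveat is inherited by everything
downstream and is documented rather than modeled.

Per (state, regime) bin the residuals follow a location-plus-mixture model

$$e_t = \mu_{i,c} + u_t, \qquad
u_t \sim (1 - \rho_{i,c})\, \mathcal{N}(0, \Sigma_{i,c})
      + \rho_{i,c}\, T_\nu(0, \Lambda_{i,c}),$$

with the Student-t degrees of freedom fixed at $\nu = 4$. Fitting is by EM
with the Student-t handled through its Gamma scale-mixture augmentation, so
each sweep is closed-form and the observed-data log-likelihood is provably
non-decreasing (asserted in the tests). Choices the estimator needs but the
model does not pin down: initialization at the sample mean and covariance
with $\rho = 0.05$; convergence at relative log-likelihood change below
$10^{-8}$ or 200 iterations; diagonal regularization of $10^{-9}$ m$^2$ on
every covariance/scale update; $\rho$ clipped to $[10^{-4}, 1 - 10^{-4}]$
during iteration to avoid component death. The location update solves the
exact precision-weighted system over both components rather than a scalar
approximation.

Bins with fewer than $N_{\min} = 5$ residuals fall back hierarchically —
regime-pooled parameters $\Psi_c$, then a single global fit — so every
(state, regime) query resolves; the provenance is recorded per bin.
Distortion-magnitude caps are the $p_e = 0.999$ quantile of
$\lVert e_t \rVert_2$ per bin and follow the same pooling chain when a bin
is sparse. Sampled distortions are rescaled to
$\lVert e^{\text{cap}} \rVert_2 = \min(\lVert e \rVert_2, q_e)$ with
direction preserved.

## Realism evaluation

The "statistical Turing test" compares a synthetic session set against real
sessions of the same regime:

* occupancy error $\pi^{\text{synth}} - \pi^{\text{real}}$ per state;
* state-conditioned KL divergence (nats, natural log) of step-length and
  turning-angle histograms with $B = 50$ bins, additive smoothing
  $\epsilon = 10^{-12}$, and shared edges taken from the pooled range of
  both sources — pooling the edge range prevents out-of-support zero bins
  from dominating the divergence;
* the occupancy-weighted summary
  $D_{\text{WKL}} = \sum_i \pi_i^{\text{real}} D_{\text{KL},i}$, which stops
  rare-state divergences (which are variance-limited at low support) from
  dominating;
* KL and the two-sample Kolmogorov–Smirnov statistic on residual magnitudes
  pooled across states within the regime.

Temporal structure beyond marginals is probed by the mean-squared
displacement $\text{MSD}(k) = \frac{1}{T-k} \sum_t \lVert x_{t+k} - x_t
\rVert_2^2$ over lags $k = 1, \dots, 300$ frames (0.1–30 s), averaged
across sessions within a group, and summarized by the RMSE between the real
and synthetic mean curves. Regime comparisons use observed trajectories;
latent curves are available behind a flag.

## The domain-shift benchmark

A balanced cohort of 600 synthetic sessions (300 per class, $T = 3000$)
contrasts unperturbed sessions with sessions carrying a mild
disease-inspired perturbation: one speed-reduction factor
$u \sim U[0.02, 0.12]$ applied to the latent displacement increments (the
original distortion is re-added, because the perturbation targets the motion
model, not the sensor), a fraction $U[0.003, 0.012]$ of exploring frames
relabeled as feeding (uniformly without replacement; feeding smoothing is
not re-applied), and observed-coordinate jitter with standard deviation
$U[0.001, 0.006]$ m. Each session is summarized by 15 deterministic
features (occupancy; step mean/sd/median/p95; mean and sd of $|\theta|$;
proxy-residual mean/sd/p99; observed MSD at 1, 5, 10 s), plus a 0/1 regime
indicator in the sensor-aware setting.

The classifier is an L2-regularized logistic regression (`glmnet`,
$\lambda = 1/n_{\text{train}}$, i.e. unit inverse regularization strength)
on features z-scored by training statistics; AUC is computed from decision
scores and accuracy/balanced accuracy at the fixed 0.5 probability
threshold — the canonical fixed operating point, which deliberately exposes
threshold miscalibration under covariate shift. Sensor-aware settings train
on a 50/50 LoS/NLoS mix; condition-agnostic settings train on one regime
and test on the other. Train and test splits use disjoint per-session seed
ranges (`base + index`), asserted at run time.

## The fixture generator

Because the original recordings are not bundled, `default_ground_truth()`
defines a fully known generative truth and `make_real_like_sessions()`
draws "real-like" sessions from it by exactly the mechanism the model
assumes. Defaults describe a caged mouse at 10 Hz: an exploring-dominant
chain (outgoing exploring row 0.55/0.45), shifted negative-binomial dwell
laws with means 120/15/40 frames (size 2, giving realistic overdispersion),
gamma step laws with means 8/2/4 mm per frame (0.08 m/s while exploring),
and wrapped-normal turn laws with sd 0.1/1.5/1.0 rad — persistent heading
while exploring, near-isotropic dithering during stationary behaviors. The
LoS channel has a 3.6 mm bias, 1.5 cm Gaussian noise, and 4% outliers
(t-scale 4 cm); the NLoS channel has a 4.5 cm bias, 3.5 cm noise, and 15%
outliers (t-scale 10 cm), reproducing the qualitative LoS/NLoS asymmetry of
UWB propagation.

Two aspects deserve emphasis. First, the kinematic defaults are chosen so
that the truth is *recoverable through the proxy reference*: with faster or
jerkier motion the 21/41-sample smoother cannot track the latent path, the
residuals become motion-curvature-dominated, and the channel fit no longer
estimates the sensor — which would test the fixture, not the method. The
slow, heading-persistent defaults keep the proxy error well below the
channel noise, so end-to-end calibration recovers the per-regime outlier
probabilities within 0.05. Second, the fixture is an idealization: i.i.d.
increments given state, wholly LoS or NLoS sessions, no arena boundaries,
no temporally correlated or burst-like NLoS artifacts, no subject-specific
style. Tests passing on fixtures therefore demonstrate internal consistency
of the machinery under the model's own assumptions, not fidelity to any
particular real dataset.

## Numerical choices and degenerate inputs

* Quantiles are type-7 (linear interpolation) everywhere, fixed for
  reproducibility.
* Angle wrapping maps onto exactly $(-\pi, \pi]$ and is $2\pi$-periodic.
* The calibration grid search takes the first minimum on ties, making the
  reported optimum deterministic; the objective is evaluated exhaustively,
  so the minimum is global over the grid.
* Reducible candidate chains during calibration are skipped; if every
  candidate is reducible, calibration errors out rather than guessing.
* Empty histogram inputs yield the uniform all-$\epsilon$ pmf with a
  warning; empty prior sets for any state abort bundle construction
  (pooling is defined for the observation channel, not for kinematic
  priors).
* The final synthesis run is truncated, never rejected, so sessions land on
  exactly $T$ frames.
* Per-session determinism: one RNG stream per session, seeded
  `base + index`, consumed in a fixed order (state sequence, initial
  heading, per-state kinematic draws, per-state distortion draws).

## Problem sizes used in the shipped checks

The packaged tests and the acceptance script calibrate on 2 LoS + 2 NLoS
fixture sessions of 3000 frames, close the occupancy loop on a $10^6$-frame
simulation, check EM recovery on 20 seeded residual sets of $n = 20000$,
close the realism loop on 50 seeded sessions of $T = 3000$, and run the
classifier benchmark at the full 600-session scale with 10 replicate seeds
per setting. These sizes keep every stage's Monte-Carlo error comfortably
inside the tolerance it is checked against.

## Known limitations

The i.i.d. increment assumption discards longer-range temporal dependence
and motion motifs; rare-state divergences are variance-limited at realistic
session lengths; the observation channel is temporally white and spatially
homogeneous; arena geometry is not modeled; and all residual-domain
statements are proxy-referenced. On the benchmark side, which cross-regime
transfer direction degrades more — and how far balanced accuracy collapses
at the fixed threshold — depends on the relative scale of channel distortion
and motion in the calibrated model, so cross-domain numbers should be read
as properties of the study conditions, not constants of the method.
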