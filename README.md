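# mrnpwalk

Quantitative analysis of messenger ribonucleoprotein (mRNP) transport in
neuronal dendrites, for single-particle-tracking data read off kymographs.

mRNP granules are carried along dendritic microtubules by motor proteins in
a stop-and-go fashion: ballistic **runs** at roughly constant speed
(~1 μm/s, anterograde or retrograde) alternate with static **rests**. Both
sojourn times are heavy tailed, so the motion is an **aging Lévy walk with
rests**: rest durations follow the power law

ψ_rest(t) = α (t + 1)^(−1−α),

and run durations the exponentially truncated power law

ψ_run(t) = N⁻¹ e^(−t/τ_r) (t + 1)^(−1−η),   N = e^(1/τ_r) Γ(−η, 1/τ_r) / τ_r^η,

with α ≈ 0.24, η ≈ 0.18, τ_r ≈ 12.6 s for dendritic β-actin and Arc mRNPs.
Because α < 1 the mean rest time diverges and the process **ages**: what you
observe depends on the lag t_a between transport initiation and the start of
the recording. The fraction of trajectories that never run during the
observation window grows with t_a, which turns that fraction into an
estimator of the mean aging time — and, via two-population mixtures, of the
ratio of newly synthesized to pre-existing mRNPs.

The package provides the full toolchain:

* **Simulation** — exact event-level generator of the aging Lévy walk
  (`simulate_trajectories()`, `simulate_mixture()`), localization-noise
  models, and the stationary-fraction curve (`no_run_fraction_curve()`).
* **Segmentation** — iterative bilateral velocity filtering
  (`bilateral_filter()`) and run/rest thresholding (`segment_phases()`,
  `segment_ensemble()`, `run_statistics()`).
* **Sojourn-time fitting** — least-squares fits of the rest and run laws
  under finite-window and time-resolution corrections (`fit_rest()`,
  `fit_run()`, `apply_observation_correction()`).
* **Diagnostics** — time- and ensemble-averaged MSD (`ta_msd()`,
  `ea_msd()`, `msd_exponent()`), aged displacement distributions
  (`aged_displacement_pdf()`) and ergodicity-breaking amplitude scatter
  (`amplitude_scatter()`).
* **Inference** — aging-time estimation (`estimate_aging_time()`) and
  two-population mixture selection (`select_ratio()`).
* **smFISH statistics** — nearest-neighbor colocalization and linear spot
  densities (`nearest_neighbor_distances()`, `coloc_fraction()`,
  `linear_density()`).
* **Synthetic data** — fully seeded generators with ground truth
  (`make_trajectory_dataset()`, `make_fish_dataset()`) and plain-text I/O.

## Worked example

```r
library(mrnpwalk)
set.seed(42)

params <- mrnp_preset("arc")
params
#> Aging Levy walk parameters (arc preset)
#>   rest law : alpha_rest = 0.24
#>   run law  : eta_run = 0.18, tau_r = 12.6 s
#>   velocity : +1.3 / -1.1 um/s, P(anterograde) = 0.54
#>   sampling : dt = 0.2 s

# simulate a recorded ensemble: 2000 particles, 60 s window, aged 30 s
ens <- simulate_trajectories(params, 2000, aging_time = 30, window = 60)

# segment into run/rest phases and summarize the run velocities
segs <- segment_ensemble(ens)
stats <- run_statistics(segs)
#> anterograde 1.16 um/s, retrograde -0.98 um/s, 56% anterograde runs

# fit the rest-time law from fully observed rests
rests <- segs[segs$kind == "rest" & !segs$left_censored & !segs$right_censored, ]
fit_rest(rests$duration)
#> Corrected rest-time least-squares fit (n = 718 durations)
#>   alpha_rest 0.2832
#>   weighted SSE (log residuals): 1.585 over 30 bins in [1.3, 45.9] s

# anomalous transport: TA MSD exponent on 1-10 s lags
tam <- ta_msd(ens, lags = 0.2 * (1:150))
msd_exponent(tam, c(1, 10))
#> [1] 1.81

# invert the stationary fraction: 68% of trajectories never run
set.seed(7)
estimate_aging_time(0.68, levy_walk_params(), n_traj = 20000)
#> Aging-time estimate: ta = 38 s (observed stationary fraction 0.68)
#>   Monte-Carlo 95% interval: [36.6, 39.6] s
```

The segmentation recovers the preset's velocities and directional bias; the
fitted rest exponent sits near the generating α = 0.24 (n = 2000 particles
is a small sample — the closed-loop tests use 20 000); the short-lag MSD is
strongly superdiffusive; and a stationary fraction of 0.68 inverts to an
aging time of a few tens of seconds.

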