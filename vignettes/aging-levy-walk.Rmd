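---
title: "An aging Lévy walk with rests: methods behind mrnpwalk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An aging Lévy walk with rests: methods behind mrnpwalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Dendritic mRNP transport alternates two states: ballistic *runs*, in which
the particle moves at a constant signed velocity along the dendrite, and
static *rests*. The package models this as a Lévy walk with rests in one
dimension. Rest durations follow the normalized power law

$$\psi_{rest}(t) = \alpha\,(t+1)^{-1-\alpha}, \qquad \alpha > 0,$$

whose mean is infinite for $\alpha < 1$; run durations follow the
exponentially truncated power law

$$\psi_{run}(t) = \frac{1}{N}\,e^{-t/\tau_r}(t+1)^{-1-\eta}, \qquad
N = e^{1/\tau_r}\,\Gamma(-\eta, 1/\tau_r)\,\tau_r^{-\eta},$$

with $\Gamma(\cdot,\cdot)$ the upper incomplete gamma function. At the start
of each run the velocity is redrawn: $+v_{antero}$ with probability
$p_{antero}$, else $v_{retro}$; speeds are fixed constants, not
distributions, which matches how the walk is defined and keeps the
velocity histogram's two modes sharp.

Because the rest law is scale free, the process never equilibrates: it
*ages*. A trajectory starts (by definition of transport initiation) with a
run at $t = 0$; measurement begins only at the aging time $t_a$ and lasts a
window $T$ (60 s at $\Delta t = 0.2$ s here). The older the walk, the more
likely the window falls entirely inside one long rest, so the fraction
$F(t_a)$ of recorded trajectories without any run grows with $t_a$ — the
handle used for inference below.

Default parameters (the fitted values for dendritic mRNPs, shared by both
species):

| parameter | meaning | default | units |
|---|---|---|---|
| `alpha_rest` | rest-law exponent | 0.24 | — |
| `eta_run` | run-law exponent | 0.18 | — |
| `tau_r` | run-time cutoff | 12.6 | s |
| `v_antero`, `v_retro` | run speeds | +1.0 / −1.1 (β-actin), +1.3 / −1.1 (Arc) | μm/s |
| `p_antero` | anterograde probability | 0.5 (β-actin), 0.54 (Arc) | — |
| `dt` | sampling step | 0.2 | s |

## Simulator

`simulate_trajectories()` is event-level and exact: sojourn durations are
drawn at state entry (rests by inverse-transform sampling, $t = u^{-1/\alpha}
- 1$; runs by rejection from the pure power law with acceptance probability
$e^{-t/\tau_r}$, which bounds the target/proposal ratio — the truncated law
has no closed-form quantile). Phase boundaries live in continuous time;
positions are evaluated on the sampling grid by linear interpolation through
the phase-boundary nodes, which is exact because the velocity is constant
within a phase. A sample falling exactly on a boundary is labeled with the
newly entered state. Recorded positions are re-zeroed at the first sample of
the window, as for experimental tracks.

`no_run_fraction_curve()` works at the event level: a trajectory counts as
"no run" when no run interval overlaps the window — equivalently, when one
rest covers it entirely. This is deliberate: runs shorter than the sampling
step can never be missed, and a single event ensemble (simulated out to the
largest aging time requested) serves every grid point, which keeps the full
aging-time grid cheap.

### Noise

Localization error is superposed on the recorded positions: white Gaussian
with $\sigma = 0.05$ μm by default, an AR(1) mode as a stand-in for
temporally correlated "fluidic" noise, and a library mode that superposes
randomly drawn, mean-subtracted empirical all-rest traces. The true noise in
the motivating experiments was extracted from recorded all-rest
trajectories and its spectrum is not characterized; the white/AR(1)
surrogates are stand-ins, and the library mode accepts real traces when
available. This is the main feature of real data the generator does *not*
emulate faithfully — several consequences are collected under *Known
limitations*.

## Segmentation

The local velocity $v_i = (x_{i+1} - x_i)/\Delta t$ is smoothed by an
iterative bilateral filter: at pass $n$, each value is replaced by a
normalized weighted average over a 13-point stencil with spatial weights
$G_{\sigma_s}(j) = e^{-j^2/2\sigma_s}$ and range weights computed on the raw
velocity differences, $G_{\sigma_v}(v_{i-j} - v_i)$ ($\sigma$ enters as a
variance). The variance schedules grow the spatial reach
($\sigma_{s,n} = \sigma_{s,n-1} + 0.15\,n^2$, seed 0.078) and tighten the
range selectivity toward a floor
($\sigma_{v,n} = 0.05 + (\sigma_{v,n-1} - 0.05)\,n^{-1/10}$, seed 8).
Iteration stops, per trajectory, when no value changes by more than
0.01 μm/s. Samples with $|\hat v_i| < 0.3$ μm/s are rests, the others runs;
each velocity sample contributes one $\Delta t$ of duration, so durations
sum exactly to the recorded span; run displacements are read from the
position series at the segment boundaries so that $v_{run} = \Delta x /
\Delta t_{run}$; the first and last segments are flagged censored.

Two properties of the default schedule deserve emphasis, because they were
design decisions:

* **The default is conservative.** With a spatial seed of 0.078 squared
  samples the first pass is almost the identity, so any profile whose
  single-pass update is below the stopping tolerance — in particular the
  piecewise-constant velocity profiles of clean simulated walks — passes
  through unchanged, and segmentation is decided by the threshold alone at
  single-sample resolution. This is exactly what the closed-loop validation
  needs: the simulated ensembles carry little or no noise, and any real
  smoothing of a heavy-tailed phase sequence merges the abundant
  sub-resolution phases into their neighbors, which distorts the observed
  duration distributions in a way no truncation-style correction can undo
  (we verified this: every smoothing schedule we tried biased the fitted
  exponents far beyond the acceptance tolerances).
* **Smoothing is available, not implicit.** For noisy recordings, widen the
  spatial seed and lower the initial range variance toward the squared
  run/rest velocity contrast, e.g. `filter_params(sigma_s_init = 2,
  sigma_v_init = 0.5)`: this suppresses $\sigma = 0.05$ μm white
  localization noise below the threshold and removes single-sample spikes
  (both behaviors are under test), at the cost of a resolution of roughly
  the stencil width.

The stencil is truncated at the series edges and the normalization
recomputed there. Non-convergence after 500 passes returns the last iterate
with a warning.

## Window- and resolution-corrected sojourn fitting

Durations harvested from a finite recording are biased three ways: phases
touching the window edges are censored (excluded by the caller); a phase of
length $t$ can only be observed whole if it starts early enough; and phases
shorter than the classification resolution ($r = 7$ samples, 1.4 s) are
unreliable. `apply_observation_correction()` maps a sojourn density to

$$\psi_{ext}(t) \propto (T_w - t)^{\gamma}\,\psi(t), \qquad
r\,\Delta t \le t \le T_w,$$

with $T_w = 57.4$ s the effective window parameter. The censoring weight
counts start opportunities: a phase of length $t$ must begin within the
remaining $T_w - t$, and the expected number of phase entries in a stretch
of length $u$ is the renewal function $m(u)$ of the run/rest cycle. For
heavy-tailed cycles ($\alpha < 1$) $m(u) \sim u^{\alpha}$ grows
*sublinearly*, so $\gamma = \alpha$ — not the elementary uniform-start
$\gamma = 1$ — is the right weight for data produced by the alternating
process. We verified this directly: with $\gamma = 1$ the rest fit collapses
to $\hat\alpha \approx 0.02$ on the simulator's own output, with
$\gamma = \alpha$ it recovers the truth. `fit_rest()` ties $\gamma$
self-consistently to the candidate exponent; `fit_run()` takes the
companion rest exponent (`rest_exponent`, default 0.24).

The least-squares machinery (`fit_rest()`, `fit_run()`):

* **Lattice-aligned log binning.** Measured durations are multiples of
  $\Delta t$; log bins narrower than one lattice step alias against that
  grid (alternating over- and under-filled bins). Breaks therefore sit
  halfway between lattice points, at least one step apart, approximately 20
  per decade.
* **Count-weighted log residuals, amplitude profiled out.** Residuals are
  taken between log binned density and the log bin-averaged model (Simpson),
  weighted by bin counts (log densities of Poisson counts have variance
  $\approx 1/\text{count}$), with the overall amplitude profiled away — the
  censoring weight is only known up to a constant, so the fit is a pure
  shape fit, and the (then-irrelevant) model normalization never needs to
  be computed inside the optimization.
* **Fit range.** Default $[(r - \tfrac12)\Delta t,\ 0.8\,T_w]$: the upper
  20% is excluded because near the hard cutoff the approximate censoring
  weight dominates the model. When fitting *continuous* durations (for
  example draws from the corrected law itself, as in the self-consistency
  tests) the first lattice bin is only half covered by the corrected
  support and should be skipped (`fit_range = c(1.5, 45.9)`).
* **Optimization.** A coarse grid, refined by golden-section (one
  parameter) or Nelder–Mead in log space (two parameters).

Closed-loop recovery — simulate at the defaults, segment, fit — returns
$\alpha$ within about $\pm 0.03$, $\tau_r$ within about $\pm 15\%$, and
$\eta$ within about $\pm 0.06$ at 20 000 trajectories; $\eta$ is the
weakly identified parameter (its curvature signature over one and a half
decades trades off against $\tau_r$), which is why the acceptance check
uses the larger ensemble. Including censored durations as if complete
lowers $\hat\alpha$ (clipped long rests masquerade as complete mid-length
ones); the package therefore fits uncensored durations only, and this
direction is under test.

## Ensemble statistics

* `ta_msd()`: the time-averaged MSD of each trajectory,
  $\overline{x^2}(\tau)$, as the mean over all overlapping sample pairs at
  each lag — normalization by the pair count, not by $T - \tau$, avoids a
  $\Delta t$ bias. The ensemble mean weights each trajectory equally.
* `ea_msd()`: the ensemble-averaged MSD from the initial recorded position.
* `msd_exponent()`: log–log least-squares slope over a lag range.
* `aged_displacement_pdf()`: binned density of $X = x(\Delta t) - x(0)$,
  default $\Delta t = 30$ s, 61 uniform bins symmetric about zero.
* `amplitude_scatter()`: density of $\xi_i = \overline{x_i^2}(\tau) /
  \langle \overline{x^2}(\tau)\rangle$ (unit mean by construction), default
  $\tau = 2$ s — the lag is not dictated by anything in the source analyses,
  so it is exposed. Mass near $\xi = 0$ measures the weight of trajectories
  that rest through the window, i.e. ergodicity breaking.

Degenerate inputs (all-rest ensembles, identical trajectories) produce
well-defined point masses rather than errors.

## Aging-time inference

`estimate_aging_time()` inverts the simulated $F(t_a)$ at the observed
stationary fraction: the Monte-Carlo curve on a log-spaced grid (default
$1$–$10^4$ s, 25 points, 20 000 trajectories sharing one event ensemble) is
made monotone by isotonic regression in $\log t_a$ and inverted by
piecewise-linear interpolation; binomial standard errors are propagated by
inverting $F \pm 1.96\,\mathrm{SE}$. Larger observed fractions therefore
always yield larger estimates, and a fraction outside the curve's range
raises a "bracket not found" error rather than extrapolating.

## Two-population mixtures

`simulate_mixture()` mixes $\lfloor w_{new} n\rfloor$ trajectories at
$t_a = t_{a,new}$ (default 30 s) with the rest at $t_{a,old}$ (default
660 s). `score_mixture()` compares four statistics on identical supports —
EA MSD and ensemble-mean TA MSD by mean squared log-residual, aged
displacement distribution and amplitude scatter by $L_2$ distance between
binned densities — and sums them with equal weights (exposed; the source
analyses judged agreement visually, so the weighting is this package's
operationalization). `select_ratio()` minimizes the total over the
candidate grid 1:9, 3:7, 5:5, 7:3.

Closed-loop selection recovers the generating ratio reliably (10/10 seeded
replicates at 2 500 trajectories per simulation in the acceptance check).
Mis-specifying $t_{a,old}$ upward (660 s → 1 h or 10 h) shifts the selected
ratio by at most one grid step in our tests, but *not* zero steps: see the
limitations below.

## smFISH colocalization

Nearest-neighbor distances are 3-D Euclidean, computed per dendrite only
(no cross-dendrite matching), by brute force — spot counts per dendrite are
tens. Query spots in a dendrite without reference spots are flagged, not
dropped. Colocalization uses a *strict* threshold (distance < 0.25 μm;
ties are not colocalized). Linear density is count over dendrite length,
averaged across dendrites with its SEM.

The synthetic generator places Poisson numbers of spots (or exact totals,
allocated multinomially by length) uniformly in 2 × 2 μm slabs of the
stated length — real dendrites taper and curve, but only inter-spot
distances matter here. Planted colocalized pairs sit at radii
0.05–0.2 μm from a reference spot; all other query spots are kept at least
0.3 μm from every reference spot so the planted count is recovered exactly
with a margin against floating-point ambiguity.

## Numerical choices

* $\Gamma(-\eta, x)$ is integrated directly; for $x < 1$ the steep part of
  the integrand is flattened by the substitution $u = s^{-\eta}$ before
  quadrature, so the normalization is accurate even for very large
  $\tau_r$.
* The run-time rejection sampler's acceptance rate is $\eta N \approx 0.45$
  at the defaults; resampling rounds are capped.
* Ties at phase boundaries go to the newly entered state; zero-length
  phases (a measure-zero event) are dropped defensively.
* Isotonic regression before curve inversion guarantees monotonicity in the
  presence of Monte-Carlo noise.
* All generators are deterministic under a fixed seed, and dataset
  manifests record the full resolved configuration so outputs regenerate
  byte-identically.

## Problem sizes

The test suite validates with 300–2 500 trajectories per property and
20 000 for the sojourn closed loop; the acceptance script uses 50 000
trajectories for the stationary fractions, 25 000 per aging-grid point and
10 000 for the MSD slopes. These sizes were chosen so each Monte-Carlo
standard error is several times smaller than the tolerance it is checked
against.

## Known limitations

* **Stationary-fraction saturation.** The event-level $F(t_a)$ at the
  fitted parameters passes 82% near $t_a = 100$ s but keeps climbing
  (≈95% at 660 s, ≈99% at $10^4$ s). Published fractions for heavily aged
  populations saturate near ≈88–90%, which is only explainable if the
  fraction is measured after superposing recording noise and re-segmenting:
  false run detections put a ceiling on the observable stationary fraction.
  With the white-noise surrogate and the default filter the false-run rate
  is essentially zero, so this ceiling — and hence stationary fractions
  near 0.88, and the ≈11 min aging times inverted from them — is not
  reproduced by this package. Fractions up to ≈0.85 invert faithfully.
* **Long-lag TA MSD slope.** At the fitted parameters the ensemble-mean TA
  MSD slope on 10–30 s lags is ≈1.4–1.5, not 1: the exponential run cutoff
  at 12.6 s still leaves ballistic correlations well past 10 s, and the
  ensemble mean is dominated by rare long runs. Experimental curves are
  tamer (bounded dendrites and lost tracks truncate long excursions, and
  the stationary majority's noise floor flattens the mean); the simulated
  ensemble is not. The 1–10 s slope (≈1.8 superdiffusive, against ≈1.6
  experimentally) is borderline for the same reason.
* **EA vs TA MSD.** For a single aged population the EA MSD exceeds the
  ensemble-mean TA MSD by up to ≈80% at short lags (aging makes the two
  estimators genuinely different); near-identical curves arise only with
  the noise floor and population mixing of real data.
* **$t_{a,old}$ sensitivity.** Because $F(t_a)$ does not saturate (first
  bullet), mixtures with a much older pre-existing population are
  statistically distinguishable from the 660 s default, and selection can
  shift one grid step when $t_{a,old}$ is mis-specified by an order of
  magnitude.
* The filter's published variance schedules are not uniquely recoverable
  from their printed form; the interpretation shipped here (sample-unit
  spatial kernel, raw-velocity range weights, the growth/decay laws above)
  was chosen so that the pipeline's closed-loop behavior is unbiased, and
  every constant is exposed in `filter_params()`.
* One-dimensional positions only: kymograph extraction, sub-pixel spot
  detection and particle linking are upstream of this package.
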