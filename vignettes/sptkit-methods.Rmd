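---
title: "Models and methods behind sptkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sptkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

sptkit analyzes single-molecule tracking (SMT) data from membrane diffusion
experiments — trajectories of individual fluorescent lipid or protein probes
followed across video frames — and simulates such data under known
conditions so that every estimator in the package can be validated against a
ground truth. This vignette documents the models, the estimators, the
numerical choices, and the limits of what the simulations can show.

## Monte-Carlo simulation

### Step law

All simulators draw per-frame displacements independently per axis from a
zero-mean Gaussian with variance $2D\Delta t$, the exact propagator of 2-D
Brownian motion with diffusion coefficient $D$ over a frame interval
$\Delta t$. A trajectory of $N$ steps has $N+1$ localizations on frames
$0..N$. Localization noise of standard deviation $\sigma$ is added to every
*reported* coordinate and re-drawn each frame; the true positions propagate
noise-free, so noise inflates the MSD intercept by $4\sigma^2$ without
touching its slope.

Three modes are provided:

* **simple** — each particle keeps one coefficient for its lifetime; with
  probability `fraction1` it belongs to population 1 ($D_1$), otherwise to
  population 2 ($D_2$). The assignment is an independent Bernoulli draw per
  trajectory, so the realized fraction fluctuates binomially around
  `fraction1` — an irreducible part of any finite experiment that the CPD
  analysis below is expected to track, not correct.
* **switch** — a two-state Markov chain: a particle in the fast state
  (rate $k_{1\to2}$ out) or slow state (rate $k_{2\to1}$ out) leaves its
  state between consecutive frames with probability $1-e^{-k\Delta t}$.
  This is the exact discretization of exponential dwell times and remains
  valid for large $k\Delta t$, where the naive $k\Delta t$ probability
  would exceed 1. The initial state is drawn from the equilibrium occupancy
  $k_{2\to1}/(k_{1\to2}+k_{2\to1})$, which removes transient bias from
  occupancy estimates. The displacement over a frame uses the state at the
  frame's start.
* **domains** — immobile slow or obstructing regions, either circles
  (Poisson-distributed centers, Gaussian diameters truncated positive,
  overlaps allowed) or a binary raster imported from a PNG/TIFF. The step
  is drawn with the coefficient of the current region ($D_1$ outside,
  $D_2$ inside). A candidate step that crosses a boundary is accepted with
  probability $\min(1, k\Delta t)$ — $k_{1\to2}$ entering, $k_{2\to1}$
  leaving; this gates a *proposed move*, unlike the dwell discretization
  above, which is why the two formulas differ. On rejection the step is
  re-drawn, up to 10 attempts, after which the particle stays put for that
  frame; re-drawing keeps the distribution of accepted non-crossing steps
  unbiased, where simply truncating the step would not. The box is
  periodic; reported coordinates are continuous (unwrapped) so the periodic
  topology never corrupts displacement statistics, and circle membership
  uses minimum-image distances. Setting $k_{1\to2}=0$ makes domains
  impermeable obstacles (anomalous subdiffusion); $k_{2\to1}=0$ makes them
  traps (confined diffusion).

### Reproducibility

A run seed initializes a master stream that only derives one sub-seed per
trajectory; all draws for trajectory $i$ (population, states, steps, noise)
come from its own substream. Identical configurations are bit-identical,
and growing `n_traj` appends trajectories without reshuffling existing
ones.

### What the generator does not emulate

Localizations are instantaneous samples: no motion blur (analyses of
simulated data must use blur coefficient $R=0$), no photophysics (blinking,
bleaching, variable spot intensity), no detection or linking errors, no 3-D
excursions, no mobile domains. Passing recovery tests therefore validates
the *estimators* under ideal sampling; they say nothing about tracker
artifacts in real data, which is exactly what the exclusion-criteria
filtering stage exists for.

## MSD analysis

The time-averaged MSD at frame lag $n$ pools all overlapping displacement
pairs $(\mathbf r_{i+n}-\mathbf r_i)$, matched on frame-index difference so
gapped trajectories contribute only genuine $n$-frame pairs. Overlapping
pairs are serially correlated, so the per-lag standard error uses the
non-overlapping pair count: $\mathrm{sem} = \mathrm{sd}/\sqrt{n_\mathrm{indep}}$,
$n_\mathrm{indep} = \sum_\mathrm{traj} \lfloor (L-1)/n \rfloor$. The same
reasoning makes $1/\mathrm{sem}^2$ the weight of choice for weighted fits
(weighting by the raw dispersion would ignore how many independent pairs
support each lag).

Four models are fitted:

| model | form | free parameters |
|---|---|---|
| brownian | $\langle r^2\rangle = a + bt$, $D = b/4$ | $a, b$ |
| anomalous | $\Gamma t^\alpha$ | $\Gamma, \alpha$ |
| flow | $4Dt + (vt)^2$ | $D, v$ |
| confined | $R_\infty^2 (1 - e^{-4Dt/R_\infty^2})$ | $R_\infty^2, D$ |

The anomalous form deliberately omits a separate $4D$ factor — $\Gamma$ and
$D$ would be unidentifiable as a pair — and reports an apparent
$D_\mathrm{app} = \Gamma/4$ for convenience. The confined model is the
single-exponential saturation to a plateau $R_\infty^2$. Nonlinear models
are solved by Levenberg–Marquardt from analytic starts (the log–log line
for the anomalous model, slope-based starts otherwise); non-convergence
returns a flagged result with diagnostics, never an error.

The Brownian model is solved in closed form. For *weighted* fits the
parameter covariance is the known-variance generalized-least-squares form
$(X^\top W X)^{-1}$ with $W = \mathrm{diag}(1/\mathrm{sem}^2)$ rather than a
residual-rescaled covariance: the per-lag sems are genuine variance
estimates, and the optimal number of lags (below) is frequently 2, where a
residual-based error would be undefined. Unweighted fits keep ordinary
least-squares errors.

### Localization errors and optimal lags

With the motion-blur coefficient $R = t_E/(6\Delta t)$ for uniform exposure
$t_E$ ($1/6$ at full-frame exposure, $0$ for instantaneous sampling, hence
for all simulated data), the intercept decomposes as
$a = 4\sigma_\mathrm{static}^2 - 8RD\Delta t$, giving

* dynamic (apparent) error $\sigma_\mathrm{dyn} = \sqrt a/2$ for $a>0$;
* static error $\sigma_\mathrm{static} = \sqrt{a/4 + 2RD\Delta t}$;
* reduced error $x = \sigma_\mathrm{static}^2/(D\Delta t) - 2R$;
* optimal lag counts $p_b = \max(2, \lfloor 2 + 2.3x^{0.52}\rfloor)$ for
  the slope and $p_a = \max(2, \lfloor 2 + 2.7x^{0.5}\rfloor)$ for the
  intercept — standard calibrations, overridable via arguments.

Because $x$ depends on the fit and the fit on the lag counts, the weighted
fit is re-run until the counts stabilize (at most 10 rounds; estimation
noise can push $x$ slightly below its theoretical floor, where it is
clamped at 0 before the fractional power). `sigma_D` is the slope error of
the final weighted fit over $p_b$ lags, divided by 4.

## CPD population decomposition

At a fixed lag the squared displacements of a single Brownian population
are exponentially distributed, so a mixture of $k$ populations has the
cumulative distribution
$$P(r^2) = 1 - \sum_{i=1}^{k} F_i\, e^{-r^2 / r_i^2}, \qquad \sum F_i = 1 .$$
The empirical CPD uses plotting positions $i/n$ on the sorted values, every
point up to a deterministic even subsample of $10^4$ points per lag (pure
speed measure; the subsample preserves the full-sample quantiles).
$r_i^2$ absorbs the localization-error offset $4\sigma^2$; the offset then
reappears as the intercept of the per-population line below, which is why
no separate error term is fitted per lag.

Fits run on log-scales (positivity for free) with stick-breaking fractions
(each auxiliary parameter in $[0,1]$, fractions always summing to 1), by
Levenberg–Marquardt from a deterministic multi-start around the mean
squared displacement $m$: order 1 starts at $m$; order 2 at
$(4m, m/4, F_1{=}0.7)$ and $(2m, m/2, F_1{=}0.5)$; order 3 inserts the
geometric-middle scale. The first convergent start with the lowest residual
sum of squares wins, and populations are reported fast to slow.

Per-population coefficients come from an unweighted line of $r_i^2$ against
lag time over lags 1–10 (configurable): $D_i$ is the slope over 4 with the
slope's standard error over 4, and the fast fraction is the mean of the
per-lag $F_1$ with its standard error across lags — the per-lag $F_1$ are
nearly independent summaries, and their scatter is an honest error measure.

### Model-order selection

An order-$k$ mixture has $2k-1$ free parameters. The classical nested
F-test
$$F = \frac{(\mathrm{rss}_l - \mathrm{rss}_h)/(df_l - df_h)}{\mathrm{rss}_h/df_h},
\qquad df = n - \mathrm{parameters},$$
is available as `compare_models_ftest()` (with $F$ clamped at 0 when the
higher order fits worse, or when the lower-order fit is already at
numerical precision). Its p-value, however, assumes independent residuals —
and empirical-CDF residuals are anything but: the empirical process is a
Brownian bridge, so neighboring residuals are strongly correlated and a
spare mixture component can always absorb a large share of the smooth
sampling wiggle. On clean two-population simulations the naive test
produces $F$ in the thousands for order 2 vs 3 and would split a
*single*-population dataset just as confidently. `cpd_analysis()` therefore
calibrates the same statistic by parametric bootstrap: it re-simulates the
squared-displacement sample from the fitted lower-order mixture, refits
both orders, and accepts the higher order only when the observed $F$
exceeds every one of the 19 null replicates (a rank test at level 0.05).
The dataset-level order is the highest order accepted on a strict majority
of lags. Fixing `order` skips selection entirely — the right choice when
the model order is already established and only the parameters are wanted.

## Import and filtering

Two dialects are read: Mosaic Particle Tracker text reports (`%% Trajectory
N` blocks, pixel coordinates scaled by the pixel size on read, the `m0`
moment taken as intensity and normalized by the dataset mean) and a generic
`trajectory,frame,x,y[,intensity]` table in micrometres. Serialization uses
17 significant digits, so a write/read round trip is exact.

Per-trajectory quick estimates fit an unweighted line to the MSD over lags
1–4 by default — short-lag fits are the least biased by noise and
confinement, and four points is the shortest fit that still leaves a
meaningful $R^2$. Negative slopes clamp to $D = 0$ (a diffusion coefficient
is nonnegative; such trajectories are then removed by any positive
`min_D`). Trajectories too short for the requested lags carry `NA`
estimates and fail whichever criteria need those estimates, rather than
erroring the batch. The four exclusion criteria — minimum length, $D$
bounds, minimum fit $R^2$, intensity bounds on the mean-normalized mean
spot intensity — are each optional; a trajectory must pass every set
criterion, and the report counts failures per criterion (a trajectory may
count under several). Filtering is idempotent and monotone in each
threshold.

## Arrhenius analysis

Diffusion coefficients over a temperature series are fitted as
$\ln D$ against $1/T$; the effective activation energy is
$E_a = -\mathrm{slope} \times R_\mathrm{gas}$ ($R_\mathrm{gas} =
8.314\,\mathrm{J\,mol^{-1}K^{-1}}$), reported in kJ/mol. When $D$ errors
are supplied the fit weights by the inverse squared fractional error
($\sigma_{\ln D} = \sigma_D/D$); equal weights reproduce the unweighted
fit. Celsius inputs convert via $T + 273.15$. Two points give the exact
line with errors flagged undefined.

## Numerical choices and degenerate inputs

* Zero-variance MSD (stationary trajectory): $D = 0$, $R^2$ undefined and
  flagged `NA`.
* A weighted fit encountering a zero sem falls back to unweighted with a
  diagnostic flag.
* All-zero squared displacements make a CPD fit impossible and raise an
  error naming the cause; lags with fewer than 10 displacements are
  skipped with a warning.
* Raster domain maps imported from an all-background or all-foreground
  image are valid and produce a notice.
* Ties in CPD scale parameters are broken by the fast-to-slow sort order;
  fractions are renormalized only through the stick-breaking transform,
  never post hoc.

## Problem sizes used by the test suite

The package's tests validate estimator recovery at sizes chosen to keep
each statistical check inside a comfortable sampling budget while leaving
3-standard-error margins meaningful: 100 trajectories × 1000 steps for
single-population MSD recovery, 500 × 200 for two-population CPD recovery,
60 × 400 for the obstructed-diffusion physics, and 19-replicate bootstraps
for order selection. The same sizes are used by `scripts/acceptance.R`.

## Known limitations

* No covariance-based estimator of $D$ and no per-trajectory confinement
  classification; the MSD and CPD estimators are ensemble methods.
* The CPD model assumes each population is Brownian at every lag; strongly
  anomalous populations bend the $r_i^2$-vs-time line and are better
  diagnosed on the MSD models.
* Intensity-based filtering presumes the tracker exports a spot
  brightness; without one, intensity criteria are skipped with a warning.
* The bootstrap order selection tests one comparison per lag; it controls
  the per-lag error rate, not a family-wise rate across lags (the majority
  vote is the guard against isolated false acceptances).
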