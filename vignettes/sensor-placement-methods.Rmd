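---
title: "Optimal surface-sensor placement for a schooling follower: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optimal surface-sensor placement for a schooling follower: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schoolsense)
```

## The sensing problem

A follower swimmer trails a school of leaders and must infer, from
measurements on its own skin, either the relative position `r = (x, y)` of
the school's centre of mass or the number of leaders `nf`. This mimics the
fish lateral line: superficial neuromasts read wall shear stress,
sub-surface canal neuromasts read pressure gradients along the body.
`schoolsense` frames the question "where should such sensors sit?" as
Bayesian optimal experimental design: a design `s` (an ordered set of
midline stations, each expanding to a mirrored pair of skin locations) is
scored by its expected information gain

$$U(s) = \mathbb{E}_{y \mid s}\,
  D_{\mathrm{KL}}\!\left(p(\vartheta \mid y, s)\,\|\,p(\vartheta)\right),$$

the prior-predictive average of the Kullback–Leibler divergence between
posterior and prior, in nats. Sensors are then placed greedily, one pair at
a time, by grid search.

## Swimmer geometry, kinematics and controllers

The body is a slender profile of length `L = 0.1` (domain units) with
half-width `w(s)`: an elliptic head `sqrt(2*wh*s - s^2)` up to `sb`, a
linear taper to `wt` at `st = 0.95 L`, and a linear tail. Defaults
`wh = sb = 0.04 L`, `wt = 0.01 L` make the profile continuous at both
breakpoints; the square-root head reading is the unique one that meets the
taper continuously at `sb` when `sb = wh`. Anguilliform propulsion is a
travelling curvature wave `k(s,t) = A(s) sin(2*pi*t/Tp - 2*pi*s/L)` with
`Tp = 1` and a linear amplitude envelope from `0.82/L` at the head to
`5.7/L` at the tail. Midlines are reconstructed from curvature by
integrating the planar Frenet–Serret relations with a fixed-step midpoint
rule on a uniform 1000-point grid (second-order accurate; the polyline
arclength is exactly `L` by construction).

Schooling formation is maintained by two closed-loop controllers. The
period controller `Tp_i = Tp (1 - dx_i)` speeds up a swimmer that lags its
streamwise station (`dx` is the deviation normalised by `L`; the sign
convention is a flag because the deviation can be defined either way). The
steering controller adds a uniform curvature combining sign-gated products
of the lateral offset, the heading deflection and their exponential moving
averages (weight `dt/Tp`, first sample initialises the average to avoid
start-up bias); the gate `[a,b] = |a| b` fires only when the two deviations
disagree in sign. Deviations are measured against the straight schooling
lane through the initial formation, advected with the mean school speed —
the reference frame had to be fixed somewhere, and the lane is the only
frame the formation itself defines.

## Reduced-fidelity flow solver

`simulate_school()` couples the bodies to the 2D incompressible
Navier–Stokes equations with Brinkman penalization: each swimmer carries a
mollified characteristic field `chi` (linear ramp of half-width `2h` across
the surface, giving a second-order accurate body area) and a body velocity
field composed of rigid translation, rotation and the midline deformation
velocity; the penalty coefficient is `1/dt`, so the explicit term replaces
the flow inside the body by the body velocity in one step. Momentum returns
to the body by projecting the penalized flow field onto the rigid modes
inside `chi`. The deformation is registered so it carries neither linear
nor angular momentum in the body frame, and the undulation amplitude ramps
up linearly over one period at start-up — an impulsive full-amplitude start
otherwise produces a violent, unphysical recoil.

Numerics: second-order centred finite differences; conservative face-flux
advection with a small Rusanov-type blending (`beta = 0.1` by default;
momentum is conserved to round-off for any `beta` because the fluxes
telescope); explicit Euler in time with advective and diffusive step-size
checks on every step. The pressure projection inverts the composite
central-difference divergence-of-gradient operator exactly with FFTs
(periodic box, or periodic-x/free-slip-y "channel" via even extension).
That operator decouples into parity sublattices whose means are its null
space; the body-divergence correction switches the divergence source off
inside bodies (`(1 - chi) div(u)/dt`), and the compatibility excess is
absorbed inside the bodies on each sublattice, so the projected field is
divergence-free to round-off wherever `chi = 0`. Surface pressure and
near-wall tangential velocities are read by bilinear interpolation;
pressure gradients come from a smoothing-spline derivative along the
surface and shear from the two nearest wall-normal samples
(`nu (u2 - u1)/(n2 - n1)`, exact for linear shear, O(h) biased otherwise).
Points beyond `0.95 L` are excluded everywhere: the sharp tail generates
large spurious gradients.

The solver is a desk-scale demonstrator. Production studies of this
problem use thousands of grid points per domain length at `Re = 2000`; the
package validates its building blocks (Taylor–Green decay, projection
exactness, penalization residuals, mirror equivariance of a swimming body)
at resolutions of 64–256 points per direction and makes no claim of
converged schooling hydrodynamics. The utility analyses therefore run on a
synthetic surrogate instead of solver output.

## The synthetic signal surrogate

`generate_signal()` stands in for the expensive forward map
`F(theta; s)`. Each leader contributes a potential-flow dipole of strength
`mu` oriented along the swimming axis plus a short wake of three
counter-rotating point-vortex pairs (spacing `wake_wavelength = 0.1`, the
stride length; half-width `0.02`; circulation `2e-3` decaying by 0.7 per
pair and alternating in sign). Pressure uses the Bernoulli relation
linearised about the coasting cruise stream (`U0 = 0.1 = L/Tp`), so every
signal is exactly linear in the leader strengths; pressure gradients are
exact tangential derivatives of the complex potential; shear is the
boundary-layer scaling `nu u_t / delta` with `delta = 0.01 L`. Scales were
chosen once on dimensional grounds (`mu ~ U0 L^2`, circulation
`~ 0.2 U0 L`); the inference itself is invariant to the overall amplitude
because the noise scale is calibrated from the same signals.

The surrogate reproduces the structure the analysis assumes — smoothness
in `s`, injectivity over the prior support, amplitude decay with distance,
and exact mirror equivariance (vortex *pairs* rather than a staggered
single street; a staggered street would break the mirror symmetry that a
symmetric school must exhibit). It does not reproduce time-resolved
high-Reynolds wakes, intermittency, or solver noise; passing tests
demonstrate the statistical machinery, not fidelity to real fish flows.

Leaders sit on a staggered lattice with `0.15` spacing in both directions.
`configuration_catalogue()` enumerates arrangements deterministically
(windows of a canonical ordering of lattice sites, re-centred on the
school's centre of mass, de-duplicated); the default counts
`(1, 2, 4, 6, 9, 11, 13, 15)` give 61 configurations with equal prior mass
`1/61`. The counts are configurable — they reflect the published total, not
a published per-size breakdown.

## Measurement model

Measurements are `y = F(theta; s) + eps` with `eps ~ N(0, Sigma(s))`.
`Sigma` is block diagonal over the two body sides: channels on the same
side correlate as `sigma^2 exp(-d/ell)` in the Euclidean distance `d` of
their skin locations (`ell = 0.1 L`), opposite sides are independent. For
distinct channels closer than `1e-7 * ell` (including exact duplicates) the
exponent is floored at `1e-7`, keeping off-diagonals strictly below
`sigma^2`; this both preserves positive definiteness and penalises sensor
clustering, which is what pushes the greedy search away from re-selecting
a station. The distance is floored rather than the entry negated because
only `exp(-1e-7)` (just under 1) keeps the matrix positive definite.
Near-duplicates are floored too, for continuity. Factorisations are
Cholesky with a single `1e-12 sigma^2` jitter retry (logged when
triggered).

The noise scale follows the calibration `sigma = (1/(n N_theta))
sum_j sum_i |F(theta_i; s_j)|` — twice the mean absolute signal. Because
this expression depends on the stations `s_j`, calibrating per candidate
design would change the noise model mid-search; `sigma` is therefore
calibrated once per experiment on a dense 64-station reference grid, and
separately for the school-size and relative-position experiments (and per
sub-experiment for the 1-, 4- and 7-leader position studies).

## Information-gain estimators

For a continuous unknown the prior is the uniform 21 × 31 grid on
`[0.6, 0.8] × [0.1, 0.4]` (ahead distance × lateral offset). The nested
Monte Carlo estimator averages, over every grid node (deterministic
stratification — using each node once removes a layer of Monte Carlo noise
at identical forward-model cost) and `Ny` Gaussian draws per node,
`log p(y|theta_i) - log mean_k p(y|theta_k)`. The inner prior-predictive
average reuses the same forward signals, so the cost is `N_theta` forward
evaluations regardless of `Ny`. For the school size, each size's likelihood
is an equal-weight Gaussian mixture over its catalogued arrangements;
draws pick an arrangement uniformly, and the estimator weights sizes by
`p(theta_i)`. The outer weighting defaults to uniform-over-configurations
(`n_i / N_tot`, matching equal per-configuration mass) with
uniform-over-sizes available as an option. All likelihood arithmetic is
done in the log domain on whitened signals with log-sum-exp; ratios are
never exponentiated directly. `Ny` defaults to 1000 (tests and the
acceptance script use 100–4000 depending on the problem); the reported
standard error treats the per-draw gains as independent, which is exact
across nodes and a mild approximation within a node.

Because the outer average enumerates the full discretised prior, both
estimators are unbiased for the discrete-prior expected utility; the
acceptance suite checks them against deterministic nested quadrature on
one-channel toys, against the `ln 2` two-hypothesis separation limit, and
against the `0 <= U <= H(prior)` information bounds on randomised
problems.

## Placement, posteriors and the recovery protocol

`place_sensors_sequential()` fixes the first `k - 1` optima and grid
searches the k-th station over 101 uniform candidates on `[0, 0.95 L]`
(the published search interval has no stated resolution; 101 stations
resolve the utility curves at the surrogate's scale). All candidates
within a step share one seed — common random numbers, so the argmax is not
dominated by Monte Carlo noise — and steps get fresh seeds. Ties break to
the smallest `s`. `sense = "min"` yields the per-phase worst design used
as a control. Utility curves are re-estimated whenever the sensor prefix
changes, because extending the design changes the covariance.

Posteriors are computed by Bayes' rule on the prior grid (or over sizes
with mixture likelihoods), in the log domain, and normalise to 1 within
`1e-12`. The recovery demonstrations follow the coasting-snapshot
protocol: the measurement is the noise-free forward signal of the true
configuration, and the calibrated-`sigma` likelihood shapes the posterior.
This mirrors how the inference is demonstrated in studies of this kind; a
single noisy snapshot at the calibrated noise level (twice the mean
absolute signal) carries provably too little information to localise one
cell out of 651 — the typical whitened per-channel signal-to-noise is at
most about one half by construction, whatever the forward model — so noisy
single-snapshot trials would say nothing about sensor placement. Under the
snapshot protocol, informative three-sensor designs place the posterior
mode within one grid cell of off-grid truths in essentially all trials,
while per-phase-worst designs fail in a substantial fraction: degenerate
stations project distinct positions onto nearly identical signals, and the
mode wanders along the resulting level sets. For the school size, the
one-arrangement-per-size catalogue is identified exactly, and enlarging
the catalogue demonstrably lowers the posterior mass on the true size —
the hard case is harder.

## Problem sizes and determinism

Test and acceptance-script runs use: the full 21 × 31 prior and
61-arrangement catalogue; `Ny` between 100 and 4000; 31 or 21 candidate
stations and up to 3 placed sensor pairs; 50 recovery trials per design;
Taylor–Green validation at 256²; schooling-simulation checks at 96–128
points per direction over a fraction of a tail-beat period. These sizes
were chosen so the full analysis reruns comfortably on a single CPU while
exercising every code path at the study's stated conditions. Every
stochastic routine takes an explicit integer seed and restores the
caller's RNG state; identical seeds reproduce estimates, placements and
archives bit for bit.

## Known limitations

- The solver is reduced fidelity: thin bodies are marginally resolved at
  desk resolutions, the splitting is first order in time, and no claim is
  made about converged schooling forces. Solver output feeds the
  signal-processing operators but not the design analyses.
- The surrogate's injectivity and decay are built in, not emergent; real
  wake signals may alias distinct configurations far more severely.
- The greedy search is a heuristic; the acceptance suite measures its
  agreement with exhaustive search only on small instances.
- The expected-utility estimators enumerate the discretised prior, so
  their cost grows linearly with the grid; finer priors need either
  subsampling or variance-reduction schemes that are out of scope here.
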