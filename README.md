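# schoolsense

Bayesian optimal sensor placement for a fish-like follower that senses a
leading school through its own skin.

Fish keep station in schools even without vision, reading the flow with
their lateral line: canal neuromasts sense pressure gradients along the
body, superficial neuromasts sense wall shear stress. `schoolsense` asks
the engineering version of that question for a 2D artificial swimmer: **if
a follower may place `n` mirrored sensor pairs on its body, where should
they go so that a single snapshot of surface signals tells it the most
about the school ahead?** The unknown θ is either the relative position
`r = (x, y)` of the school's centre of mass (uniform prior on
`[0.6, 0.8] × [0.1, 0.4]`, discretised 21 × 31) or the school size
`nf ∈ {1, …, 8}` with a catalogue of 61 staggered arrangements.

A design `s` (midline stations of the sensor pairs) is scored by its
expected information gain,

```
U(s) = E_{y|s} [ D_KL( p(θ | y, s) || p(θ) ) ],
```

with measurements `y = F(θ; s) + ε`, `ε ~ N(0, Σ(s))`. Σ is exponentially
correlated along each body side (`σ² exp(−d/ℓ)`, `ℓ = 0.1 L`), independent
across sides, with a `1e-7` floor on the exponent that keeps duplicated
sensors positive definite and penalises clustering; σ is calibrated to
twice the mean absolute signal. `U(s)` is estimated by nested Monte Carlo
(continuous θ) or by a Gaussian-mixture estimator over arrangements
(discrete θ), and sensors are placed greedily, one pair at a time, by grid
search — with common random numbers across candidates within each step.

The package provides, as composable tibble-first functions:

- slender-body geometry, anguilliform midline kinematics and the
  schooling controllers (`swimmer_shape()`, `midline_at()`,
  `period_control()`, `steering_curvature()`);
- a reduced-fidelity 2D Navier–Stokes solver with Brinkman penalization
  for self-propelled swimmers (`simulate_school()`, `taylor_green()`,
  `pressure_projection()`), plus the surface signal-processing operators
  (`smooth_pressure_gradient()`, `shear_from_velocity()`);
- a potential-flow surrogate generator for surface signals with the
  statistical structure the analysis assumes (`surrogate_model()`,
  `generate_signal()`, `configuration_catalogue()`);
- the correlated-Gaussian measurement model (`sensor_array()`,
  `build_covariance()`, `calibrate_sigma()`, `log_likelihood()`);
- expected-information-gain estimators and design search
  (`expected_utility_continuous()`, `expected_utility_discrete()`,
  `place_sensors_sequential()`, `plateau_diagnostic()`);
- posterior inference and orchestration (`posterior_continuous()`,
  `posterior_discrete()`, `run_experiment()`), with `tidy()`, `glance()`
  and `autoplot()` methods throughout.

## Worked example

Place three pressure-gradient sensor pairs for the relative-position task
with one leader, then invert a coasting snapshot of an off-grid school:

```r
library(schoolsense)
shape <- swimmer_shape()                 # L = 0.1, lateral-line-like body
model <- surrogate_model()               # dipole + vortex-pair wake per leader
prior <- prior_position_grid(nx = 11, ny = 11)
tab   <- generate_signal_table(model, prior, shape, nf = 1)
fn    <- utility_functional_continuous(tab, shape, Ny = 200)
pl    <- place_sensors_sequential(fn, seq(0, 0.095, length.out = 20),
                                  m = 3, seed = 1)
tidy(pl)
#> # A tibble: 3 × 4
#>    step     s utility std.error
#>   <int> <dbl>   <dbl>     <dbl>
#> 1     1 0.005   0.131   0.00302
#> 2     2 0       0.263   0.00426
#> 3     3 0.035   0.319   0.00457
```

The first two sensor pairs land at the head (`s = 0.005` and `s = 0`,
i.e. within the first 5% of the body) — the utility curve peaks at the
snout, where the signal varies most across school positions — and the
expected gain grows from 0.13 to 0.32 nats as pairs are added. Inverting a
noise-free snapshot from a school at `r = (0.72, 0.23)`:

```r
sens  <- sensor_array(pl$s_opt, shape)
ref   <- sensor_array(seq(0, 0.095, length.out = 64), shape)
cv    <- covariance_model(calibrate_sigma(tab, ref), 0.1 * shape$L)
truth <- school_configuration("continuous", r = c(0.72, 0.23))
y     <- signals_at_sensors(generate_signal(model, truth, shape), sens)
post  <- posterior_continuous(y, sens, build_covariance(sens, cv), tab)
glance(post)
#> # A tibble: 1 × 4
#>   mode_x mode_y entropy kl_from_prior
#>    <dbl>  <dbl>   <dbl>         <dbl>
#> 1   0.72   0.22    4.75        0.0470
```

The posterior mode lands on the grid node nearest the true position
(`0.72, 0.22` on this 11 × 11 grid against a truth of `0.72, 0.23`).
`autoplot(pl)` draws the per-step utility curves, `autoplot(post)` the
posterior map; `run_experiment()` wraps the whole pipeline (including the
worst-design control and a CSV/JSON archive) for both experiments.

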