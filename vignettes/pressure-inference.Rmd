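---
title: "Physics-informed pressure inference in the pulmonary artery bifurcation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-informed pressure inference in the pulmonary artery bifurcation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Mean pulmonary arterial pressure (mPAP) is the key quantity for diagnosing
pulmonary hypertension, but its gold-standard measurement — right heart
catheterization — is invasive. 4D Flow MRI, in contrast, yields
time-resolved velocity fields and vessel cross-sections non-invasively,
but no pressure. `pulsepinn` closes that gap for the main pulmonary
artery bifurcation: given sparse time series of cross-sectional area
`A(t)` and axial velocity `u(t)` at the ends of the parent vessel and its
two daughter branches, it infers the full pressure field `p(x, t)` by
constraining three small neural networks (one per vessel) with a
reduced-order model of pulsatile blood flow.

## The governing model

Each vessel is a straight, elastic 1D segment carrying the
cross-section-averaged mass and momentum balance

```
dA/dt + A du/dx + u dA/dx                                   = 0
du/dt + a u du/dx + (u/A) d[(a-1) u A]/dx + (1/rho) dp/dx - KR u/A = 0
```

closed by the elastic wall law

```
p = pext + beta (sqrt(A) - sqrt(A0)),     beta = sqrt(pi) h0 E / ((1 - nu^2) A0)
```

with `A0` the equilibrium (diastolic) area, `h0` the wall thickness, `E`
the Young's modulus, `nu` the Poisson ratio and `pext` the external
tissue pressure. In the large pulmonary arteries the Womersley number is
high, the velocity profile nearly flat, and viscous losses over the short
straight segments negligible, so the defaults are a momentum correction
factor `alpha = 1` and friction `KR = 0` (both remain configurable, and
the residual operators implement the general forms). At the Y-junction
the three vessels are coupled by volume-flux conservation
`A1 u1 = A2 u2 + A3 u3` and continuity of total pressure
`p + rho u^2 / 2` between the parent and each daughter, assuming lossless
merging flow.

Small-amplitude disturbances of this system travel at
`c = sqrt(beta sqrt(A) / (2 rho))`, which ties the lumped stiffness
`beta` to the measurable pulse wave velocity — the basis of the
image-derived mechanics chain below.

## Image-derived wall mechanics

`estimate_wall_mechanics()` reproduces the full clinical stiffness chain:

1. mean-velocity waveforms at two points a known centerline distance
   apart are smoothed by **second-order Lagrange interpolation**
   (`smooth_series()`), implemented as a sliding three-point window with
   the quadratic centred on the knot nearest each query time and
   one-sided windows at the range ends — the interpolant is exact at
   every original sample and reproduces quadratics exactly;
2. a single **Gaussian pulse** `a exp(-(t-m)^2/(2 s^2)) + b` is fitted to
   each curve by Levenberg–Marquardt (`minpack.lm`), initialised from the
   peak, the FWHM and the baseline, with a bounded number of jittered
   restarts;
3. the **transit time** is the lag maximising the cross-correlation of
   the two *fitted* pulses, evaluated analytically on a 10^4-point grid
   spanning both pulses, with parabolic sub-grid peak refinement and
   ties broken toward the smallest |lag|;
4. the pulse wave velocity `c = distance / time_shift` is rounded to
   2 decimal places — the precision at which PWV is conventionally
   reported — before deriving `E = 2 rho c^2 / (h0/R0)`; this makes the
   derived mechanics exactly reproducible from the reported wave speed
   (`pwv_digits = NULL` keeps full precision);
5. `beta = sqrt(pi) h0 E / ((1-nu^2) A0)` per vessel, with the defaults
   `h0 = 0.1 R0` and `nu = 0.5` (incompressible wall).

For the reference case (distance 0.0621 m, transit time 0.0155 s,
`rho = 1060`), the chain yields `c = 4.01 m/s`, `E = 340,898.12 Pa` and a
main-segment `beta = 2.32586e6 Pa/m`.

The maximum area of each vessel section is read from the images; the
minimum (equilibrium) area follows the physiological assumption of a
roughly 10% peak-to-trough pulsation, `A_min = 0.9 A_max`
(`min_area_from_max()`).

## Non-dimensionalisation and normalization

The networks operate on z-scored dimensionless coordinates. The package
convention (`normalization_scales()`):

* `A* = A / A_ref` with `A_ref` the **parent** equilibrium area, shared
  by all three vessels so the interface flow residual is consistent;
* `u* = u / U_char` with `U_char` the peak measured speed, also shared;
* `p* = p / p_ref` with `p_ref = rho U_char^2`, which makes the
  dimensionless total pressure exactly `p* + u*^2/2` — this resolves the
  otherwise ambiguous mixing of a dimensional density with dimensionless
  velocities in the interface condition;
* `x* = x / L` per vessel, and `t* = t / T_char` with the advective
  default `T_char = L / U_char`. Under this choice the dimensionless
  residuals carry only the `1/sigma` normalization factors in front of
  the derivatives; a general time coefficient `lambda_t = L/(U T_char)`
  is carried in the residual code so any other `T_char` remains correct.
* coordinates are finally z-scored with the exact moments of the uniform
  distribution on the space–time rectangle (`sigma = range/sqrt(12)`),
  matching how collocation points are drawn.

The unknowns are normalized too. Each network carries an affine output
map set from the boundary-data statistics: `A*` and `u*` are z-scored
with the mean and standard deviation of their measured series, and the
pressure statistics are propagated from the area spread through the wall
law (`mu_p = wall(mu_A)`, `s_p = b1 s_A / (2 sqrt(mu_A))` with
`b1 = beta sqrt(A_ref)/p_ref`). Every output therefore works at unit
scale regardless of its physical amplitude, and training starts at the
measured mean state with a correctly pinned pressure gauge. This
matters: `b1` is of order 10^2 at physiological velocity scales, so in
raw starred units the area pulse is a few percent while the pressure
pulse is of order 10 — a pathological spread for a gradient optimiser.

The wall-law residual is measured in the same normalized pressure unit:
`rp = (p* - [pext + beta(sqrt(A_ref A*) - sqrt(A0))]/p_ref) / s_p`,
which gives `rp` order-1 sensitivity to both z-scored outputs. Without
this normalization `rp`'s sensitivity to `A*` dwarfs every other
residual and the optimiser stalls in a stiff valley; the zero set — the
physics actually enforced — is unchanged. Because `rp` contains `p*`
itself (not only derivatives), it pins the pressure gauge; without it
pressure would be identifiable only up to a constant. (Outside a
training assembly, where no data statistics exist, `rp` falls back to
normalization by the wall-law stiffness `b1` itself.)
Inside the loss, `sqrt(A*)` uses a C1 linear extension below `A* = 1e-4`
so that residual and gradient stay finite while an untrained network
still emits non-positive areas; physical areas are orders of magnitude
above the threshold, so the extension is inactive at any trained state.

## The networks and the composite loss

One fully connected `tanh` network per vessel maps `(x_hat, t_hat)` to
`(A*, u*, p*)`; the reference architecture is 7 hidden layers of 100
neurons, Glorot-initialised. The spatial and temporal derivatives
entering the residuals are the networks' *exact* derivatives, computed by
forward-mode tangent propagation through the same pass that evaluates the
outputs (verified against central finite differences to 1e-5 relative in
the test suite). The total loss is the unweighted sum

```
L = sum_j [ L_physics_j + L_data_j ] + L_interface
```

* `L_physics_j`: mean squared `rA`, `ru`, `rp` over the collocation set
  (2000 points per vessel by default, sampled once, uniformly, before
  training — a fixed set keeps runs reproducible);
* `L_data_j`: mean squared mismatch of `u*` and `A*` against the
  boundary measurements, interpolated to 101 uniform times at each
  vessel end via the same quadratic Lagrange smoother; the zero
  initial-velocity condition `u(x, 0) = 0` joins the data loss as an
  additional squared term over 101 x-points. Pressure is never a data
  target — it is the quantity being inferred;
* `L_interface`: mean squared junction flow residual plus the two
  dimensionless total-pressure residuals over 101 shared interface
  times.

Per-term weights are exposed in `training_control()` for
stiffness-dominated cases but default to 1, matching the unweighted
composite loss.

Training uses Adam at a fixed learning rate of 0.001 for 50,000 epochs
(defaults). The inner loop is compiled (RcppArmadillo); one epoch
evaluates all three networks on their full batches, accumulates the
adjoints of every loss term, and backpropagates — including the
second-order `tanh` terms that arise because the loss depends on the
networks' input derivatives. All randomness flows from explicit seeds;
runs are bit-reproducible on one platform (not across BLAS builds).

**Initialisation.** Weights are Glorot-uniform with the standard `tanh`
gain of 5/3; biases start at zero, so through the affine output map each
network begins exactly at its vessel's measured mean state. From a raw
random start (no output normalization) the optimiser can settle into a
self-consistent but wrongly gauged state — the wall law amplifies area
error into pressure error roughly 200-fold — while from the normalized
start it converges reliably toward the measured waveforms.

## The reference solver (synthetic ground truth)

Clinical images cannot ship with a package, so `solve_bifurcation()`
provides the ground truth that makes every stage testable: a two-step
(Richtmyer) Lax–Wendroff scheme on the conservative variables `(A, Q)`
per vessel — with the elastic pressure term integrated exactly into the
flux as `beta A^{3/2} / (3 rho)` — coupled at the junction every step by
a Newton solve of flow continuity, the two total-pressure continuities,
and the three outgoing characteristic invariants `u ± 4c`. The parent
inlet imposes a velocity waveform (area follows the outgoing invariant);
daughter outlets are non-reflecting. Default grid: 28 cells per vessel,
CFL 0.8; runs cover 3 cardiac cycles so the returned last cycle is
periodic. The solver stores junction states at every step; in the test
suite their flow residual stays below 1e-8 of peak flow and the
total-pressure residuals below 1e-6 of peak pressure, and a
small-amplitude pulse propagates within 5% of the analytic
`c = sqrt(beta sqrt(A0)/(2 rho))`.

**What the synthetic data emulate.** `waveform_spec()` defaults describe
a healthy adult: cycle 0.89 s, 34 frames per cycle (the clinical frame
rate), a Gaussian systolic pulse peaking at 0.25 of the cycle with width
0.07 cycles, and a peak inlet velocity of 0.45 m/s. That peak was chosen
once, on physiological grounds: with the reference vessel parameters the
induced pulse pressure is roughly `rho c u_peak`, giving a natural area
pulsation `dA/A0 ≈ u_peak/c` close to the assumed 10% — so the emitted
areas match the clinical processing assumption without distortion.
`make_clinical_like_dataset()` samples the solved fields at the vessel
ends at 34 frames, optionally adds multiplicative noise, and by default
rescales each area series affinely so its peak-to-trough variation is
exactly 10%, mirroring how the clinical areas are constructed from a
measured maximum.

**What they do not emulate:** imaging noise structure and partial-volume
bias, breathing and beat-to-beat variability, segmentation error in the
vessel geometry, curvature and 3D junction flow. Passing the recovery
tests therefore demonstrates correctness of the inference machinery on
model-consistent data, not clinical accuracy.

## Scaled-down study sizes

The packaged tests run a reduced configuration — 3x64 networks, 500
collocation points, 41 boundary/interface times, 5,000 epochs — which
one CPU trains in a few minutes per seed; the recovery check accepts
2 of 3 fixed seeds to allow for optimisation variability at this reduced
size. The defaults (7x100, 2000 points, 101 times, 50,000 epochs) remain
those of the full configuration. At the reduced size the narrow systolic
peak is the last feature the networks learn (spectral bias of `tanh`
networks under a fixed small learning rate), so midpoint pressure
recovery keeps improving well beyond 5,000 epochs; the loss history and
the junction-continuity diagnostics indicate how converged a given run
is.

## Numerical choices and degenerate inputs

* Junction Newton: analytic 6x6 Jacobian, tolerance 1e-12 on scaled
  residuals, warm-started from the previous step; equilibrium is an
  exact fixed point.
* Negative areas anywhere in the solver abort with a diagnostic rather
  than silently continuing.
* `fit_gaussian_pulse()` refuses constant (pulse-free) series;
  `time_shift_crosscorr()` refuses grids coarser than a quarter of the
  narrower pulse width.
* `area_from_pressure()` guards the wall-law collapse limit
  (`sqrt(A0) + (p - pext)/beta <= 0`).
* `predict_fields()` flags extrapolation outside the trained space-time
  domain instead of refusing it.

## Known limitations

* The interface model ignores energy losses and secondary flow at the
  junction; total pressure is conserved exactly.
* `beta` is constant per vessel (no tapering, no viscoelasticity).
* The PINN inherits the usual soft-constraint caveat: conservation holds
  only as well as the residuals are minimised, so junction continuity of
  a trained model is approximate (the tests bound it by 5% of peak
  flow).
* With friction enabled (`KR > 0`) the residual keeps the sign
  convention of the governing equations as stated; at the default
  `KR = 0` the term vanishes.

## A worked example

```{r example}
library(pulsepinn)

# 1. reference hemodynamics and clinical-like measurements
problem <- pa_problem()
sol <- solve_bifurcation(problem, waveform_spec(), solver_grid())
ds <- make_clinical_like_dataset(sol, noise = 0, seed = 1)

# 2. attach measurements and train a reduced model
prob <- bifurcation_problem(problem$vessels[[1]], problem$vessels[[2]],
                            problem$vessels[[3]], problem$fluid,
                            measurements = ds$measurements)
model <- train_pinn(prob, network_spec(3, 64),
                    training_control(epochs = 5000, n_collocation = 500,
                                     n_boundary = 41, seed = 1))

# 3. inspect
pressure_summary(model)
ggplot2::autoplot(model)
plot_field_surface(predict_fields(model, "parent",
                                  seq(0, 0.01763, length.out = 21),
                                  seq(0, 0.89, length.out = 81)))
```
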