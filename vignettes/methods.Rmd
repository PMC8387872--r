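---
title: "Constitutive models, calibration and evaluation for the spinal cord-pia complex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constitutive models, calibration and evaluation for the spinal cord-pia complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scpmech)
```

## The model

`scpmech` represents spinal cord parenchyma as a quasi-linear viscoelastic
(QLV) solid whose instantaneous elasticity is a one-term Ogden model, and
pia mater as a purely hyperelastic single-term Ogden membrane.

**Ogden elasticity.** The strain energy density in principal stretches is

$$W = \sum_i \frac{\mu_i}{\alpha_i}\left({\lambda_1^*}^{\alpha_i} +
{\lambda_2^*}^{\alpha_i} + {\lambda_3^*}^{\alpha_i} - 3\right) +
\tfrac{1}{2}K(J-1)^2,$$

with deviatoric stretches $\lambda_k^* = \lambda_k J^{-1/3}$ and bulk
modulus $K$ derived from the small-strain shear modulus
$G_0 = \sum_i \mu_i\alpha_i/2$ and the Poisson ratio. For homogeneous
uniaxial loading the package works with the incompressible idealization
($\nu = 0.499 \approx 0.5$), whose closed-form nominal stress is

$$P(\lambda) = \sum_i \mu_i\left(\lambda^{\alpha_i-1} -
\lambda^{-\alpha_i/2-1}\right).$$

The compressible energy is retained and used only as an independent oracle:
the test suite checks $P = dW/d\lambda$ on the isochoric restriction by
central finite differences to $10^{-6}$ relative.

**Quasi-linear viscoelasticity.** The relaxation function separates into a
strain part $\sigma^E(\varepsilon)$ (the Ogden stress) and a time part
$g(t)$, combined in the hereditary integral
$\sigma(t) = \int_0^t g(t-\tau)\, \dot\sigma^E(\tau)\, d\tau$. The time
part is a Prony series. As commonly printed, a bare sum
$\sum G_i e^{-\beta_i t}$ decays to zero and leaves no equilibrium stress,
which contradicts both the normalization language ("normalized shear
moduli") and the constraint $\sum G_i < 1$ used during fitting. The package
therefore adopts the standard normalized form

$$g(t) = \left(1 - \sum_i G_i\right) + \sum_i G_i e^{-\beta_i t},
\qquad g(0) = 1,$$

so the instantaneous response equals $\sigma^E$ and infinitely slow loading
tends to $(1-\sum G_i)\,\sigma^E$. Because the original explicit-solver
implementation could equally have added the viscous overstress on top of
the full hyperelastic stress (making the *quasi-static* response equal
$\sigma^E$), both formulations are exposed through
`qlv_stress(formulation = "normalized" | "overstress")`. The normalized
form is the default, and the generator and the fitter always share one
formulation, so all recovery results are self-consistent regardless of
which reading matches the original solver.

**Discretization.** The convolution is evaluated by a per-term exponential
internal-variable recurrence with a midpoint kernel,
$h_i^{k+1} = e^{-\beta_i\Delta t}h_i^k + G_i e^{-\beta_i\Delta t/2}\,
\Delta\sigma^E$, which is second-order accurate. Histories are resampled
internally so that $\max(\beta_i)\,\Delta t \le 0.1$ with at least 2000
samples per ramp. The suite verifies the recurrence against an independent
trapezoidal (endpoint-averaged) quadrature of the same integral to 0.1%
on 100 random piecewise-linear histories.

## Reference parameters

The shipped reference parameter sets (`reference_cord_material()`,
`reference_pia_model()`) are the fitted continuum values for the cord-pia
complex: cord $\mu = 209$ Pa, $\alpha = 7.52$, $\nu = 0.499$,
$G = (0.033, 0.296, 0.406)$, $\beta = (2, 13, 406)$ s⁻¹ (so
$G_\infty = 0.265$ and $G_0 = 785.8$ Pa); pia $\mu = 42$ kPa,
$\alpha = 12.58$, $\nu = 0.49$ ($G_0 = 264.2$ kPa — the familiar two to
three orders of magnitude stiffness contrast between membrane and
parenchyma). These parameters are the "truth" of every recovery study; the
package never fits the original digitized experimental curves, which are
not redistributable.

## Calibration

`fit_cord_qlv()` reproduces the published identification protocol on
synthetic data:

- one homogeneous single-element compression ramp per experimental rate
  (0.32, 2.83, 25.44, 77.22 s⁻¹, to 40% strain);
- a multi-objective equal-weighted sum of per-rate curve discrepancies;
- normalized Prony moduli constrained by $\sum G_i < 1$ with initial
  guesses of 0.25 and a maximum of 1;
- convergence declared at a relative curve difference below 0.5%.

The proprietary "curve mapping" metric of the original optimization
software is replaced by a documented hybrid: the normalized absolute
area difference between the curves and a normalized pointwise L2 term,
averaged 50/50 on a 200-point common strain grid. Because generator and
fitter are self-consistent, the substitution is fully testable: the global
minimum of the objective on noise-free data is exactly the generating
parameter set.

**Constraint handling.** $G_i$ are parameterized on the open simplex,
$G_i = e^{z_i}/(1+\sum_j e^{z_j})$, so *no optimizer iterate can violate*
$G_i \in (0,1)$, $\sum G_i < 1$; infeasible initial guesses (e.g.
$\sum G = 1.2$) are projected inside before optimization. $\mu$ and
$\alpha$ are optimized in log space.

**Optimizer.** The staged protocol (slowest rate anchors $(\mu,\alpha)$,
then the moduli against all rates) initializes a joint refinement by
bounded quasi-Newton (`nlminb`) from a deterministic three-point
multistart, with a Nelder–Mead escape pass re-polished by `nlminb`
whenever the objective remains above $10^{-6}$. The escape pass matters:
the slow Prony modulus ($\beta_1 = 2$ s⁻¹) trades off against its
neighbour along a shallow valley in which gradient descent can stall with
$G_1 \to 0$. With the full strategy, a 20-seed ±30% perturbed-start study
recovered all five parameters within 10% in 20/20 runs during development;
the shipped test suite runs a 6-seed version of the same study to stay
inside its time budget.

**Stage-1 ambiguity.** Whether the original quasi-static fit corrected for
the relaxation already present at 0.32 s⁻¹ is not stated. Both readings
are available (`stage1 = "viscoelastic"` or `"hyperelastic"`). The
hyperelastic reading treats the slowest curve as $\sigma^E$ and therefore
absorbs its relaxed fraction into $\mu$, biasing it low by roughly
$\times 0.35$ — measured ≈70 Pa against the 209 Pa truth. This is a
property of that reading, not an implementation defect; the default
pipeline uses the viscoelastic stage plus joint refinement, which removes
the bias.

`fit_pia_ogden()` maximizes $R^2$ of the closed-form uniaxial stress. For
a fixed exponent the optimal $\mu$ is a linear least-squares solution, so
the search is one-dimensional in $\alpha$ (coarse grid then golden
section) and fully deterministic; this also yields the exact scaling
property that multiplying all stresses by $c$ multiplies $\mu$ by $c$ and
leaves $\alpha$ unchanged.

## The impact surrogate

The 3-D explicit finite-element impact model is out of scope. In its place
`simulate_pellet_impact()` integrates a single-degree-of-freedom pellet
(default 7 g, 4.5 m/s, 314 mm² contact area) against a nonlinear
foundation: transverse engineering strain $u/h$ drives the QLV cord stress
over the pellet area, plus a pia membrane term modelled as two inclined
tension strips of width one pellet diameter anchored one cord dimension
from the pellet edge, carrying the closed-form Ogden tension on their
stretched arcs with an 8% axial prestretch offset and a geometric sine
factor. Contact is non-adhesive (force clamped at zero; the pellet
separates on rebound). Integration is semi-implicit (symplectic) Euler at
a fixed $10^{-6}$ s step; halving the step moves the peak by under 0.5%,
and kinetic energy plus cumulative contact work is conserved within 1%.

The transverse cord dimension is not printed in the source material;
`cord_height = 10` mm was chosen once as a realistic bovine cervical
anterior–posterior dimension and is not tuned. With the reference
materials the surrogate peaks near 8 mm (~79% compression) in ~2 ms —
the same regime as the reference experiments — but **no quantitative
surrogate output is acceptance-tested**. Only orderings and conservation
are asserted: smaller pellet area ⇒ deeper peak; higher velocity ⇒ deeper
peak; removing the pia ⇒ deeper peak; non-zero pia thicknesses cluster
while absence of the membrane matters most. That is precisely what a green
surrogate test establishes, and nothing more: the surrogate has no
contact mechanics, no 3-D kinematics, no wave propagation, and a rigid
support.

## Kinematics

Pellet trajectories are segmented into loading, rebound and unloading.
The boundary rules are the package's own documented choice (the source
procedure does not define them): loading ends when the smoothed
central-difference velocity drops below 20% of its early median; rebound
ends at the first run of three consecutive negative-velocity samples after
the peak; thresholds are configurable. Averaging follows the published
recipe — degree-1 least squares on loading and unloading, degree-3 on
rebound, continuity deliberately not enforced across boundaries, pointwise
mean on a common 4,500 Hz grid. Within each phase the fit basis is time
normalized to $[0,1]$; raw powers of millisecond-scale times are
numerically near-collinear. Initial pellet velocity is the slope of a
linear fit to the first 25% of loading samples, mirroring how the
experimental velocities were derived.

## Metrics

$R^2 = 1 - RSS/TSS$ and RMSE follow their definitions. The CORA rating is
the two-component variant actually described for this application: size
$= \min(A_r, A_c)/\max(A_r, A_c)$ with $A = \int |y|\,dt$ on the common
window, shape $=$ the maximum normalized cross-correlation of the two
derivative signals over shifts within ±10% of the window, clamped to
$[0,1]$, total $= 0.5\,\text{size} + 0.5\,\text{shape}$. ISO-style
corridors and sub-interval weighting are intentionally absent, and the
published FE CORA ratings (0.747–0.858) are excluded from acceptance since
they require the FE model. Richardson extrapolation from three
systematically refined meshes returns the observed order
$p = \ln|(f_1-f_2)/(f_2-f_3)|/\ln r$ and limit
$f_3 + (f_3-f_2)/(r^p-1)$; oscillatory convergence is flagged and the
extrapolation withheld, constant series are flagged degenerate.

## Synthetic data: the stated world

Generators are bit-reproducible functions of (parameters, seed) and leave
the global RNG stream untouched. Stress curves carry multiplicative
log-normal noise (tissue scatter scales with stress level), mean-corrected
so the expected noisy curve equals the clean one; displacement records
carry additive Gaussian noise plus optional per-replicate velocity jitter
emulating pellet-to-pellet spread. Specimen-to-specimen independence is
assumed; the real covariance structure is unreported. A green recovery
test therefore establishes that the estimator inverts *this* noise model
at *these* parameter values — not that it would recover parameters from
the original tissue data, whose artefacts (toe-region irregularity,
specimen geometry variation, digitization error) are not emulated.

## Numerical choices and edge cases

- Ogden powers guard $|\alpha \ln\lambda| \le 700$ and raise a domain
  error rather than silently clamping.
- `reduced_relaxation` at $t = 0$ returns 1 by construction; the QLV trace
  starts at exactly zero stress.
- A constant observed vector makes $R^2$ undefined — an error, not NaN.
- Degenerate (constant-stress) curves yield non-converged fit results, not
  exceptions; unsegmentable trajectories are skipped with a warning during
  averaging and fatal only when fewer than two members remain.
- One spec-level property was re-interpreted after measurement: a
  compression ramp at an engineering strain rate of $\beta_{\min}/100$
  (0.02 s⁻¹) does *not* sit within 2% of the equilibrium curve — the slow
  mode is still relaxing through most of the ramp (2.1% at the ramp end,
  far worse at small strains). The test instead uses a loading duration of
  100 slowest relaxation times and compares at strains ≥ 0.1, where the
  equilibrium property holds with margin. This is a statement about the
  model's time constants, not about the integrator.

## Limitations

Isotropic, homogeneous, damage-free tissue models fitted over strains up
to 40% and rates up to 77.22 s⁻¹; extrapolation beyond either range is
unvalidated. No 3-D stress states beyond homogeneous uniaxial loading. The
impact surrogate is a reduced-order stand-in, never a substitute for the
FE validation it emulates qualitatively. Gray and white matter are lumped,
as in the continuum model this package supports.
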