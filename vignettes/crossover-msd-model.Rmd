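---
title: "The crossover MSD model: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The crossover MSD model: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fractalmsd)
```

## The model

A tracked particle moves along straight segments of mean length
$\lambda$ (the mean free path), each traversed in the Brownian step time
$\tau$ at speed $v_0 = \lambda/\tau$. Seen on scales below $\lambda$ the
trajectory is a line; on large scales it is a fractal curve with
dimension $D_w = 2/\alpha$, where $\alpha$ is the anomalous diffusion
exponent of the long-time law $\langle r^2\rangle = 4\Gamma t^\alpha$
(two dimensions). The model interpolates the trajectory's fractal
dimension between the two regimes with a single crossover scale
$k\Lambda$ ($\Lambda = \sqrt{3/2}\,\lambda$ is the 3D mean free path):

$$D_w(s) = D_w - \frac{D_w - 1}{1 + s/(k\Lambda)}.$$

Integrating the fractal length relation
$\mathrm{d}\ln L/\mathrm{d}\ln s = 1 - D_w(s)$ and equating the contour
length with $v_0 t$ yields one implicit equation connecting MSD and time
at *every* stage of the motion. In the dimensionless variables
$x = \sqrt{\langle r^2\rangle}/\lambda$, $n = t/\tau$:

$$x\,(k + x)^{(2-\alpha)/\alpha} = k^{(2-\alpha)/\alpha}\, n .$$

Its two limits are the ballistic law $x = n$ and the anomalous power law
$x^2 = k^{2-\alpha} n^\alpha$. The crossover between them spans roughly
three decades of $t/\tau$ — much wider than in fractional-Langevin
solutions — which matters because real single-particle-tracking windows
usually sit inside it.

**Why $k = 2$.** The crossover constant is kept as an explicit field of
`walk_params()` because the generalized dimension profile is the core of
the model and its behaviour at other $k$ should remain testable. But only
$k = 2$ makes the $\alpha = 1$ limit reproduce the standard Brownian
result $\langle r^2\rangle = 4Dt$ with $D = \lambda^2/2\tau$; every
derived coefficient therefore assumes it:

$$\Gamma = 2^{-\alpha}\lambda^2/\tau^\alpha,\qquad
  \Gamma/D = (2\tau)^{1-\alpha},\qquad
  v_0 = 2D/\lambda = 2\sqrt{D}\,(\Gamma/D)^{1/(2(\alpha-1))},$$

and the universal collapse $\Gamma/D\cdot\tau^{\alpha-1} = 2^{1-\alpha}$.
`msd_longtime()` uses the $k$-general asymptote
$k^{2-\alpha}\lambda^2 n^\alpha$ so that limit checks remain valid for
any $k$; at $k=2$ it equals $4\Gamma t^\alpha$ exactly.

The model solution also satisfies, exactly and at every time, the
partition identity

$$\Big(\frac{\sqrt{\langle r^2\rangle}}{v_0 t}\Big)^{\alpha/(2-\alpha)}
 + \Big(\frac{\langle r^2\rangle}{4\Gamma t^\alpha}\Big)^{1/(2-\alpha)} = 1,$$

which splits the motion into its ballistic and diffusive shares and is
used both as a regression surface (`fit_free()`) and as a test oracle.

## Parameters

| parameter | meaning | units | constraint | default |
|---|---|---|---|---|
| `lambda` | mean free path (2D) | length (µm conventional) | > 0 | — |
| `tau` | Brownian step time | time (s conventional) | > 0 | — |
| `alpha` | anomalous exponent | — | $[0.05, 2]$ | 1 |
| `k` | crossover constant | — | > 0 | 2 |

The core is unit-agnostic: the caller must use one consistent
length/time pairing throughout. $\alpha = 2$ is handled as the exact
ballistic branch (the exponent $(2-\alpha)/\alpha$ vanishes, so no
$0^0$-style evaluation ever occurs). Values of $\alpha$ below 0.05 are
rejected: there the exponent $(2-\alpha)/\alpha$ exceeds 39 and the
equation ceases to be numerically meaningful, while no physical system in
scope approaches it.

## Numerics

**Root solve.** The left-hand side of the implicit equation is strictly
increasing in $x$, so the root is unique. Displacement cannot exceed
contour length, giving $x \le n$; substituting $x \le$ the power-law
bound gives $x \le k^{(2-\alpha)/2} n^{\alpha/2}$; pushing the smaller of
those back through the equation yields a guaranteed lower bound. The
solver works on $\log x$ — where the equation is well conditioned at both
extremes — with `stats::uniroot()` at absolute tolerance $10^{-14}$ on
$\log x$ (i.e. relative on $x$), 200 iterations maximum. Deep in either
asymptotic regime the two bracket ends agree to within $10^{-12}$ in the
log and their midpoint is returned directly. $t = 0$ returns 0 without
invoking the solver. The $\alpha = 1$ closed form
$x = -1 + \sqrt{1 + 2n}$ is **not** used by the implementation; it
serves as an independent oracle in the tests, which require agreement to
$10^{-10}$ relative over $t/\tau \in [10^{-3}, 10^{6}]$.

**Dimensionality.** The canonical internal space is 2D. 3D rescales by
$\langle R^2\rangle = \tfrac{3}{2}\langle r^2\rangle$; 1D by the isotropy
factor $\langle x^2\rangle = \tfrac{1}{2}\langle r^2\rangle$, consistent
with the $2\Gamma t^\alpha$ (1D) versus $4\Gamma t^\alpha$ (2D)
conventions. These factors are fixed constants, not options.

## Estimators and fitting choices

**Calibration.** `estimate_lambda_two_point()` inverts the
ordinary-diffusion ($\alpha=1$) crossover equation written at two times;
dividing the two copies eliminates $\tau$, leaving a closed form for
$\lambda$. It is exact on model-consistent data, not an asymptotic
approximation — a property the tests verify over random parameter draws.
Two failure modes are distinguished: points implying pure ballistic
scaling (the denominator vanishes; $\lambda$ unidentifiable) and points
implying a non-positive $\lambda$ (data inconsistent with sub-ballistic
ordinary diffusion). `calibrate_lambda_tau()` then recovers $\tau$
exactly from the closed-form solution at the first point.

**Objective function.** The fitting criterion is relative least squares,
$\sum_i (\hat m_i/m_i - 1)^2$ — equivalent to least squares on
$\log$-MSD to first order — because MSD values span decades and an
absolute criterion would let the largest time dominate. The four
observation times of a typical tracking experiment are weighted equally.
The criterion is a package choice; it is implemented in one place
(`fit_alpha_gamma()`) and easy to swap.

**Γ is not a free parameter in calibrated fits.** With $(\lambda, \tau)$
fixed, the closure $\Gamma = 2^{-\alpha}\lambda^2/\tau^\alpha$ ties the
transport coefficient to the exponent, so `alpha_from_single_point()` and
`fit_alpha_gamma()` return pairs lying exactly on the
$\Gamma = D(2\tau)^{1-\alpha}$ curve. This is the point of the method:
one calibration plus short-time data determine both anomalous transport
variables.

**Grid pre-scan.** Monotonicity of the single-point objective in
$\alpha$ is not guaranteed a priori, so both calibrated estimators scan
$\alpha \in [0.05, 2]$ at step 0.05 before refining (bisection for the
root, `stats::optimize()` to $10^{-8}$ for the least-squares optimum).
An optimum pinned at either end of the range is flagged
(`at_boundary`), not silently returned as interior.

**Free fit.** `fit_free()` needs only the unobstructed $D$. Each
candidate $(\alpha, \Gamma)$ implies
$\tau = (\Gamma/D)^{1/(1-\alpha)}/2$ and
$v_0 = 2\sqrt{D}(\Gamma/D)^{1/(2(\alpha-1))}$; the objective is the
squared residual of the partition identity evaluated at the observed
displacements. The search is a profile: for each $\alpha$ an inner 1-D
minimization over $\log\Gamma$ (started from the naive power-law
regression), with the outer search run separately on the sub- and
super-diffusive branches because the velocity relation is singular at
$\alpha = 1$; a band of $\pm 10^{-3}$ around 1 is excluded. Data that
are ordinary diffusion belong with the $\lambda/\tau$ estimators, not
with `fit_free()`. A near-flat profile is reported via
`flat_objective`. The fitted pair also implies a step time
(`tau_implied`), useful as a cross-check against an independent
calibration.

**Ratio estimators.** `tau_from_anomalous_ratio()` and
`gamma_over_D_from_ratio()` require the anomalous and normal MSDs *at
the same time* for the same species; the CLI takes a single `--time`
flag rather than interpolating two series, to avoid inventing an
interpolation scheme.

**Short-time bias of the naive power law.** The full model's MSD is
strictly below $4\Gamma t^\alpha$ at finite time (the advancement
$\langle r^2\rangle/4\Gamma t^\alpha < 1$). Data generated from the
asymptotic law alone, at times inside the crossover, therefore sit above
the model and force a calibrated fit to inflate $\alpha$ — the test
suite demonstrates this bias direction explicitly. This is the
quantitative argument for fitting the full equation, never the power
law, to short-period data.

## The synthetic-data module

`generate_msd_series()` is the forward model times lognormal
multiplicative noise with mean 1 and a specified coefficient of
variation. Lognormal (rather than additive Gaussian) noise keeps every
simulated MSD positive at any CV, preserving the invariants the rest of
the package relies on. A single integer seed, applied through
`withr::with_seed()`, makes every fixture reproducible without touching
the caller's RNG stream.

`generate_trajectory()` is explicitly a **stand-in**: the theory is a
statement about MSD and defines no microscopic update rule. The stand-in
walks equal segments of length $\lambda$ (one per $\tau$, optionally
sampled inside segments via `samples_per_step`) and couples successive
headings by a mixture: with probability $|\alpha - 1|$ the heading
repeats ($\alpha > 1$) or reverses ($\alpha < 1$), otherwise it is drawn
uniformly. Exactly two anchors are faithful — $\alpha = 2$ gives a
perfectly collinear path and $\alpha = 1$ an uncorrelated flight — and
the tests assert only those, plus the time-averaged-MSD estimator
against a brute-force double loop. At intermediate $\alpha$ the mixture
only pushes the moderate-lag exponent toward $\alpha$; its long-lag
diffusivity does not match the model's prefactor (an uncorrelated unit
flight has $\langle r^2\rangle = \lambda^2 n$, the model's Brownian
limit $2\lambda^2 n$). Consequently the end-to-end
trajectory-to-$\lambda$ recovery test calibrates on lags in the early
crossover ($0.2\tau$ and $2\tau$), where the segment walk and the model
agree; the two-point estimator recovers $\lambda$ to within 15% there on
$10^4$-step walks.

**What passing tests show about real data — and what they do not.** The
simulated noise is independent across lag times. Real time-averaged MSDs
from a single trajectory have strongly correlated errors across lags,
heterogeneous localization noise, and possible non-ergodicity
(time-averages differing from ensemble averages). Parameter-recovery
results under the synthetic model (median $|\hat\alpha - \alpha| <
0.03$ at 5% CV over 100 seeds) therefore demonstrate correctness of the
estimator under the model's own assumptions, not expected accuracy on
arbitrary experimental data.

## Problem sizes used by the test suite

The suite is dimensioned to run in well under a minute: the
closed-form-oracle grids use 25–60 log-spaced points; the recovery study
uses 4 exponents × 100 seeds × 16 time points (8 per decade over 2
decades at 5% CV); the noise-calibration check uses $10^4$ single-point
replicates; trajectory checks use $10^4$ steps. These sizes are the
package's chosen compromise between statistical resolution and suite
runtime.

## Known limitations

* Ergodicity analysis (time- versus ensemble-averaged MSD) and Bayesian
  motion-type classification are out of scope.
* No mechanistic simulation of obstacles, traps, CTRW waiting times,
  Lévy flights or fractional Brownian motion is provided; the
  trajectory generator is a labelled stand-in.
* The calibrated estimators presume $(\lambda, \tau)$ measured under
  ordinary diffusion for the *same* species and geometry; the closure
  $\Gamma/D = (2\tau)^{1-\alpha}$ inherits any calibration error.
* Monotonicity of the advancement $\langle r^2\rangle/4\Gamma t^\alpha$
  in time for $\alpha > 1$ is verified numerically across the tested
  grid, not proven.
* Confined diffusion and directed motion beyond the $\alpha = 2$ limit
  are not modelled.
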