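---
title: "Fractional impedance models: equations, fitting, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fractional impedance models: equations, fitting, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fracz)
```

This vignette is the package's own account of the model family it
implements: the equations and their reduction structure, the meaning and
defaults of every tunable parameter, the numerical decisions taken where
the design was genuinely open, and the limits of what the synthetic-data
tests establish.

## 1. The model family

### Constant phase element and Cole dispersion

The constant phase element (CPE) is the fractional-order circuit
primitive: its impedance

$$Z_{CPE}(\omega) = \frac{1}{C_\alpha (j\omega)^\alpha}, \qquad
  0 \le \alpha \le 1,$$

has a frequency-independent phase $-\alpha\pi/2$.  $\alpha = 0$ is a
pure resistance $1/C_\alpha$, $\alpha = 1$ an ideal capacitor.  Placing
a CPE in parallel with a resistance increment $\Delta R$ (a *reduced
Cole element*) and in series with a high-frequency resistance
$R_\infty$ yields the Cole dispersion

$$Z(\omega) = R_\infty + \frac{R_0 - R_\infty}{1 + (j\omega\tau)^\alpha},$$

whose locus in the $(\mathrm{Re}\,Z, -\mathrm{Im}\,Z)$ plane is a
depressed circular arc.  Serial models sum $n$ reduced elements,

$$Z(\omega) = R_\infty + \sum_{k=1}^n
  \frac{\Delta R_k}{1 + (j\omega\tau_k)^{\alpha_k}},
  \qquad \Delta R_k = p_k (R_0 - R_\infty),$$

with dispersion weights $p_k$ that sum to one for purely classic
circuits, so the DC resistance equals $R_0$.

### Generalized scaling and remnant memory

The generalization replaces the constant exponent by a five-term
partial Maclaurin series in the principal complex logarithm of the
dimensionless frequency:

$$s(\omega) = (j\omega\tau)^{E(\omega)}, \qquad
  E(\omega) = \alpha + \sum_{m=1}^{5} c_m z^m, \qquad
  z = \mathrm{Log}(p \cdot j\omega\tau),$$

with $c = (\beta, \gamma, \delta, \epsilon, \zeta)$ of unrestricted
sign.  The first coefficient $\beta$ encodes *remnant memory* — partial
temporal irreversibility of the underlying relaxation processes — and
bends the impedance locus away from the circular arc.  The reduction
chain is exact and is enforced to $10^{-12}$ relative by property
tests: all five coefficients zero gives the Cole model for **any** $p$
(the base of the power is $(j\omega\tau)$, not $(p\, j\omega\tau)$,
precisely so that this holds); $\gamma=\delta=\epsilon=\zeta=0$ gives
the single-$\beta$ generalized element.

The concrete form above is the package's own rendering of this model
class, pinned down by three requirements: the exact reduction contracts
just stated, the principal-branch logarithm convention used throughout,
and the structure of the reference fitted-parameter tables shipped as
fixtures (global $R_0/R_\infty$ per model, $p$ listed for every
non-Maclaurin element with classic weights summing to exactly one, no
$p$ for the Maclaurin-extended model, and at most ten fitted parameters
per model).

### Circuit labels

| label | elements | free parameters |
|-------|----------|-----------------|
| C1, C2, C3 | 1–3 classic | 4, 7, 10 |
| GC1 | one generalized | 6 |
| GC2 | two generalized | 10 |
| C1GC1 / GC1C1 | generalized + classic (both orders) | 10 |
| GGC1 | one Maclaurin-extended ($p \equiv 1$) | 9 |

Element order never affects the impedance (series addition commutes);
it only selects the label.

## 2. Parameters, units, defaults

| parameter | meaning | unit | admissible | notes |
|-----------|---------|------|------------|-------|
| $R_0$ | zero-frequency scale resistance | ohm | $> R_\infty$ | table-facing unit MΩ |
| $R_\infty$ | high-frequency series resistance | ohm | $\ge 0$ | table-facing unit kΩ |
| $\alpha$ | fractional order | – | $(0, 1]$ | distribution of relaxation times |
| $\tau$ | relaxation time | s | $> 0$ | |
| $p$ | scaling constant / dispersion weight | – | $\ge 0$ | $\Delta R_k = p_k(R_0-R_\infty)$; log-reference of $z$ |
| $\beta,\gamma,\delta,\epsilon,\zeta$ | Maclaurin memory coefficients | – | any sign | all zero = memoryless |

For generalized models the low-frequency limit is *not* $R_0$ — the
leading terms change their asymptotics whenever any memory coefficient
is nonzero — so `dc_limit()` reports it numerically at a configurable
small frequency (default $10^{-6}$ Hz) instead of asserting it.
A grid frequency of exactly zero is rejected everywhere: the models are
defined for $\omega > 0$.

### The self-consistent scaling constant

`solve_p()` implements the self-consistency condition that the
generalized factor, with log-reference $p$, has modulus $p$ at the
fixed dimensionless frequency $\omega\tau = e$:

$$p = \left|(j e)^{\alpha + \beta\,\mathrm{Log}(p\, j e)}\right|
  \iff \ln p = \alpha + \beta(1 + \ln p) - \beta\pi^2/4 .$$

For $\beta = 0$ the logarithmic correction disappears and
$p = e^\alpha$.  The root is found by safeguarded bracketing with a
final residual below $10^{-10}$ and is cross-checked in the tests
against a dense bisection oracle.  Because the condition is imposed at
a fixed value of $\omega\tau$, $\tau$ cancels; it stays in the
signature for interface stability.  Following the fitted tables —
which list $p$ as a fitted quantity — evaluation and fitting treat $p$
as a free parameter and `solve_p()` is a consistency diagnostic only.

## 3. Fitting

### Objective and conventions

A real-valued Levenberg–Marquardt solver minimises the stacked
residual vector
$[\mathrm{Re}(Z_{model}-Z_{data});\ \mathrm{Im}(Z_{model}-Z_{data})]$
of length $2N$, computed on the per-frequency mean of the replicate
sweeps (joint replicate fitting is available as an option; weighting is
off by default, matching the plain $L_2$ norm).  The optimisation runs
in megaohm units for conditioning.  The mean square error is

$$mse = \frac{1}{N}\sum_f |Z_{model}(f) - Z_{data}(f)|^2,$$

reported in ohm², in MΩ², and — matching the table convention — as
MΩ² × 10⁷ (`mse_scaled`).  The normalization is this package's
declared convention; the "(·10⁷)" footer of the reference tables does
not pin a normalization, so one had to be chosen.

Positivity and range constraints are enforced by transforms rather
than a constrained solver: resistances, $\tau$ and $p$ on the log
scale, $\alpha$ through a logistic map onto $(0,1)$ (the upper bound
is approached asymptotically; boundary-saturated stage-one estimates
are pulled back to the interior before reseeding), memory coefficients
unconstrained.  Convergence tolerances are $10^{-12}$ for cost, step
and gradient with at most 5000 iterations; the damping is
Marquardt-scaled (proportional to the diagonal curvature), which
matters because the sensitivity of the model to $\zeta$ exceeds that to
$\alpha$ by roughly $|{\ln \omega\tau}|^5 \sim 10^5$ at the sweep ends.
Every fit is deterministic: identical inputs give bit-identical
estimates, and solver divergence returns a flagged result instead of
raising.

### Staged protocol

`staged_fit()` follows the two-step initialization protocol: stage one
fits the classic counterpart (Cole for GC1/GGC1, C2 for the two-element
generalized models) from data-driven heuristics — several deterministic
relaxation-time spreads are tried and the best classic fit kept —
and stage two seeds the generalized model with the stage-one estimates,
sets every memory coefficient's initial value to 0.01, and refits.

### One exactly flat direction

For single-$\beta$ generalized elements the parameterization has an
exact gauge: the data depend on $(\alpha, p, R_0-R_\infty)$ only
through $\alpha + \beta\ln p$ and $p(R_0 - R_\infty)$.  Consequently
$R_0$, $p$ and $\alpha$ are not individually identifiable for GC1, GC2
and the mixed models — refits reach machine-zero residuals anywhere on
the ridge — while $R_\infty$, $\tau_k$, $\beta_k$, the increments
$\Delta R_k$ and the combination $\alpha_k + \beta_k \ln p_k$ are sharp.
The reference tables show the same signature (the generalized $R_0$
columns equal their classic stage-one values almost exactly), which is
consistent with a fit that simply stayed where the staged
initialization put the gauge.  The test suite therefore asserts
recovery of the identifiable combinations for these models, and full
per-parameter recovery for the classic and Maclaurin-extended models,
where no gauge exists ($p$ tied by the sum-to-one weight constraint,
respectively fixed at 1).

### Global search for the Maclaurin-extended model

The five-coefficient exponent makes the GGC1 least-squares surface
multimodal with a basin of attraction of only a few percent around the
optimum; from the all-0.01 protocol seed, plain LM reliably parks in an
adjacent local minimum even on noiseless self-generated data.  The
package exploits the model's structure instead of brute force: writing
$u = \mathrm{Log}(j\omega)$,

$$\log s(\omega) = Q(u)$$

is a degree-six polynomial with $Q(-\ln\tau) = 0$.  On the band where
$s = \Delta R/(Z - R_\infty) - 1$ is numerically resolvable and its
phase can be unwrapped unambiguously, $Q$ follows by *linear* least
squares; $\tau$ is recovered as a real root of $Q$, the exponent
coefficients by a Taylor shift to that root, and $R_\infty, \Delta R$
re-enter linearly.  A dense deterministic screening grid over
$R_\infty$ feeds this projection, the best few candidates are polished
with the full LM fit, and the projection is iterated at the winner's
nuisance values until the cost stops improving.  The search uses only
the data, is fully deterministic, and runs after the protocol seed;
the lower-cost fit wins.  With it, both reference Maclaurin-extended
parameter columns are recovered from their own noiseless spectra to
machine precision.

### Model comparison

`compare_models()` runs the staged protocol per label and ranks by
ascending mse; ties rank the model with fewer free parameters first,
non-converged fits rank last and are flagged.  On noiseless nested
data the richer model never fits worse — this monotonicity is part of
the acceptance suite.  Comparison is by mse only; information criteria
are out of scope.

## 4. The operator module

The Weyl fractional derivative of a $2\pi$-periodic function multiplies
Fourier coefficients by $(jk)^\alpha$ (principal branch), the integral
by $(jk)^{-\alpha}$; the generalized operator uses the symbol
$(jk\tau)^{\alpha+\beta\,\mathrm{Log}(jk\tau)}$, which for $\beta = 0$
and $\tau = 1$ is the classical Weyl symbol.  All statements are
exercised on truncated Fourier series — every property in scope is
coefficient-wise, so finite trigonometric polynomials lose nothing —
and the convolution-kernel route is deliberately not implemented; the
coefficient multiplication is the single source of truth.  The mean
term $c_0$ must be exactly zero (a structural exclusion, not a
tolerance).  Identity, composition $W^\alpha W^\beta = W^{\alpha+\beta}$,
inverse pairs and linearity hold numerically to $10^{-10}$ on random
polynomials, and driving the fractional circuit relation
$v + \tau^\alpha D^\alpha v = R_0\, i + R_\infty \tau^\alpha D^\alpha i$
with a unit sinusoid reproduces the closed-form Cole and generalized
impedances to $10^{-8}$ — the package's cross-check that the circuit
derivation and the closed forms agree.

## 5. Synthetic data

`simulate_spectrum()` emulates the acquisition protocol behind the
fitted tables: 61 log-spaced frequencies from 0.1 Hz to 100 kHz
(endpoints exact, constant ratio), 20 replicate sweeps, and instrument
error below 0.1%, modeled as independent multiplicative complex
Gaussian noise $Z(1 + \sigma(\varepsilon_1 + j\varepsilon_2))$ with
$\sigma = 10^{-3}$ per frequency and replicate.  Draws are reproducible
from the seed and leave the caller's RNG state untouched.

What the generator does *not* emulate: the source does not state how
its 61 frequencies were spaced (logarithmic spacing is the standard
choice for a six-decade sweep and is adopted here); the noise model has
no frequency correlation, no electrode-polarization artifact, and no
electrode-geometry dependence — the fixtures differ only by their
printed parameter columns.  A green recovery test therefore
establishes that the estimation machinery inverts the stated model
under the stated acquisition; it says nothing about instrument
systematics.  The mean-square errors originally obtained against
laboratory skin measurements are not reproducible here because those
raw spectra are not available; the fixtures carry only the fitted
parameter columns.

## 6. Numerical choices and degenerate inputs

* Complex powers use the principal branch throughout:
  $(j\omega)^\alpha = \omega^\alpha e^{j\alpha\pi/2}$ for
  $\omega > 0$; with the $e^{+j\omega t}$ time convention capacitive
  behaviour gives $\mathrm{Im}\,Z < 0$ and Cole plots are drawn as
  $(\mathrm{Re}\,Z, -\mathrm{Im}\,Z)$.
* Model equations take $\omega = 2\pi f$; all files and the CLI use
  $f$ in Hz.
* The ×1.2 multiplicative initialization of the recovery experiments
  would push $\alpha = 0.851$ above its admissible bound; perturbed
  fractional orders are capped at 0.995.
* $p = 0$ with a nonzero memory coefficient is a domain error (log of
  zero reference); $\tau = 0$ likewise for the operator symbol.
* Classic-element weights are parameterized by a softmax (sum to one);
  the last weight is derived, which is what makes $R_0$ identifiable
  for classic serial models.
* Tie-break in model comparison: fewer free parameters first.

## 7. Known limitations

* The generalized closed forms are a reconstruction under documented
  constraints, not a verbatim transcription (see Section 1).
* $R_0$, $p$, $\alpha$ of single-$\beta$ generalized elements are
  identifiable only as gauge-invariant combinations (Section 3).
* The structured global search covers single-element
  Maclaurin-extended models; multi-element models rely on the staged
  protocol alone, which suffices for the single-$\beta$ surfaces.
* Dielectric (permittivity) modelling, electrode-geometry corrections
  and Kramers–Kronig validation are out of scope by design.
* Uncertainty reporting is limited to the LM covariance proxy implicit
  in the residuals; no confidence intervals or information criteria.
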