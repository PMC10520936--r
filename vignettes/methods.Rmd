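---
title: "Methods: coupled electroporation and pump-energetics model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled electroporation and pump-energetics model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thzpore)
```

This vignette records the model, the numerical scheme, the parameter
choices and the design decisions behind `thzpore`, in enough detail that
a maintainer can judge (and re-derive) each one. No number quoted here is
asserted beyond what the test suite and `scripts/acceptance.R` compute at
run time.

## 1. The physical picture

A spherical cell (radius $R = 3.3\ \mu m$) sits in a conducting bath
(outer radius $3R$) and is driven by a unipolar picosecond pulse train:
rectangular same-sign field pulses of amplitude $5\times10^7$ V/m at a
repetition frequency of 0.1–1.2 THz with duty cycle 0.5, applied along
the polar axis for 1.1–1.2 ns. Because every pulse pushes in the same
direction, the membrane integrates the drive: the induced membrane
voltage ramps up over hundreds of picoseconds until electroporation
ignites, after which the open pore area clamps the voltage, large ion
fluxes flow, and the Na⁺,K⁺-ATPase works (and dissipates ATP energy)
against the disturbance.

## 2. Potential solve and membrane charging

Both media are uniform ohmic conductors and the drive is quasi-static at
these frequencies, so at each instant $\nabla^2\Phi = 0$ in both regions
with three conditions: a prescribed jump $\Phi_i - \Phi_o = V_m(\theta)$
across the (thin) membrane, continuity of normal conduction current
through it, and the applied-field Dirichlet value
$\Phi = -E(t)\, r\cos\theta$ on the outer sphere.

**Design decision — spectral rather than finite-difference solve.** In an
axisymmetric spherical shell each Legendre mode $P_\ell(\cos\theta)$
decouples, and the three boundary conditions reduce to a $3\times3$
linear system per mode. The map from $(V_m(\theta), E)$ to the normal
membrane current $J_n(\theta)$ is therefore linear and is precomputed
once as a dense $N_\theta \times N_\theta$ matrix plus a vector
(`field_operator()`); each time step then costs one small matrix–vector
product instead of an iterative Laplace solve. The solution satisfies the
PDE exactly mode by mode (the test suite verifies the residual with an
independent finite-difference stencil) and the growing/decaying radial
branches are normalised at opposite boundaries so the mode systems stay
well conditioned at any order.

The membrane charges explicitly:
$C_m\,\mathrm{d}V_m/\mathrm{d}t = J_n - g_1 (V_m - V_{rest}) - I_p$. The
default grid places $N_\theta = 13$ nodes uniformly on $[0, \pi]$ so the
seven reportable angles $0, \pi/6, \dots, \pi$ are nodes; membrane
elements are the conical bands around each node (areas sum exactly to
$4\pi R^2$).

**Known bias.** With the Dirichlet outer boundary at $3R$ the static
plateau of the induced voltage is $\tfrac{81}{55} E R\cos\theta$ rather
than the unbounded-medium $\tfrac{3}{2} E R \cos\theta$ — a 1.8%
truncation bias, deliberately matching the finite simulated bath. The
charging validation budgets for it: the numeric solution is required to
track the classical closed form (`schwan_reference()`, time constant
$\tau = R C_m (1/\sigma_i + 1/(2\sigma_o))$) within 2% of the plateau at
the seven reportable angles.

## 3. Electroporation

Pore density per angle follows the asymptotic nucleation law
(`density_rate()`), and each pore's radius the force-balance ODE
(`radius_rate()`), with the whole-cell effective tension
(`effective_tension()`) coupling all pores through the total open area.
Parameters default to the standard literature set for this model family
($\alpha = 10^9\,\mathrm{m^{-2}s^{-1}}$, $V_{ep} = 0.258$ V,
$N_0 = 1.5\times10^9\,\mathrm{m^{-2}}$, $r_* = 0.51$ nm, $r_m = 0.8$ nm,
$D_p = 5\times10^{-14}\,\mathrm{m^2/s}$, …), every one overridable from
configuration; the exponent in $q_p = (r_m/r_*)^{q}$ defaults to $q = 2$,
with $q = 1$ available as a config switch.

**Numerics.**

* The density ODE is advanced with the *exact* exponential update
  $N' = N - (N_{eq} - N)\,\mathrm{expm1}(-\alpha e^{u} \Delta t/N_{eq})$
  ($u = (V_m/V_{ep})^2$), which is unconditionally stable through the
  activation burst, reduces to the Euler increment when the relaxation is
  slow, and — written through `expm1` — is immune to the catastrophic
  cancellation that the naive form suffers when $N_{eq}/N > 2^{53}$.
* Discrete pores are tracked as deterministic per-angle *cohorts*
  (radius, count). Positive density increments accumulate into a pending
  count that spawns a cohort at the minimum radius $r_*$; density
  decreases scale all cohort counts down uniformly, so
  $\Sigma\,\mathrm{counts} + \mathrm{pending} = N A_\theta$ holds as an
  exact identity (tested). Because all cohorts at one angle follow the
  same first-order ODE their radii never cross; columns stay
  birth-ordered, newborn cohorts within a relative tolerance of $r_*$
  merge into the youngest cohort, and a cap (default 64 per angle) is
  enforced by merging the nearest-radius adjacent pair with
  count-weighted radius (open area is preserved exactly by the merge).
* The subsystem depends on $V_m$ only through $V_m^2$, so its evenness
  under $V_m \to -V_m$ is structural and is asserted bit-for-bit.
* $(V_m/V_{ep})^2$ is capped (default 250, with a warning) purely as an
  overflow guard; in practice the membrane never exceeds $\sim$2 V
  because poration clamps it.

## 4. Pore transport and concentration bookkeeping

Fluxes through open pore area use the steric-corrected drift–diffusion
law with two-point differences across the membrane thickness
($\nabla\Phi \approx -V_m/d_{mem}$,
$\nabla c \approx (c_o - c_i)/d_{mem}$, mid-membrane concentration the
arithmetic mean), scaled by the fractional open area $f_p(\theta)$; the
pore current density is the exact charge–flux identity
$I_p = F\sum_j z_j J_j$. No partition or hindrance factor is applied
inside pores.

Each angle owns a conical intracellular sector and a matching
extracellular shell sector (finite bath by default; an infinite-bath
clamp is available). The explicit update moves
$J\,A_\theta\,\Delta t$ moles across, conserving total moles to
round-off.

**Degenerate inputs.** The mid-membrane-mean discretisation can keep
exporting a species from a sector whose concentration has reached zero
(intracellular Ca²⁺ at the depolarised pole drains within the first
nanosecond — its basal store is four orders below the bath). The
orchestrator first retries the whole physics step at half the step; when
halving cannot cure the sign (a genuinely drained donor), it switches to
the *donor-limited* update, which transfers at most the donor
compartment's content — exactly mass-conserving, never negative. This
fallback is permanent once engaged because it is identical to the plain
update whenever nothing would go negative.

Lateral (angle-to-angle) bulk diffusion is off: over $\le 80$ ns the
diffusion displacement $\sqrt{D t} \sim 10$ nm is negligible against the
micrometre sector size.

## 5. The pump: cycle model, energetics, fitting

The four-state cycle uses cubic (Na) and quadratic (K) saturating binding
with voltage partition coefficients, MgATP saturation, MgADP linearity
and the $c_P\,10^{3-pH}$ phosphate term; the closed-form steady-state
cycle rate is verified against an independent stationary-distribution
(King–Altman style) linear-algebra oracle to $10^{-10}$ relative on 1000
random rate vectors. Stoichiometry ($3$ Na⁺ out, $2$ K⁺ in per cycle) is
exact by construction. The pump responds instantaneously to $V_m$ and
concentrations (steady-state cycle approximation); it is evaluated
per angle from the local membrane voltage and sector concentrations, with
each angle carrying its area fraction of the whole-cell current.

**Power accounting.** The ATP consumption rate is $I/q_{ele}$ molecules
per second, so the physical wattage is $P = Q_{ATP}\, I/q_{ele}$ with
$Q_{ATP} = 10\,k_B T$ per molecule (`pump_power(mode = "per_molecule")`,
what the simulator records). A second, "literal" mode divides by
$N_A$ as well — it is retained because that algebraic form appears in
print for this model, but it is per-mole-scaled and sits ~24 orders of
magnitude below the physical value; the two modes differ by exactly
$N_A$ (tested). All $10^{-11}$ W-level statements refer to the
per-molecule mode.

**Parameter provenance.** The exact fitted cycle constants for the two
preparations live in supplementary tables that are not shipped here, so
the package carries literature-style defaults chosen once to reproduce
the *described* qualitative behaviour: for the rat neostriatal set, a
current–voltage curve that is near zero below rest, rises as the membrane
depolarises, and is inhibited at overlarge positive excursions; for the
guinea-pig ventricular set, a narrower curve shifted toward more negative
potentials, with the whole-cell current scale $F_c$ set from the
preparation's typical ~1 pA/pF pump current on ~150 pF of membrane.
Supplying the fitted tables through a configuration file recovers exact
reproduction without code changes.

**Fitting.** `fit_iv()` is seeded multi-start Levenberg–Marquardt
weighted least squares with box positivity constraints; it reports
marginal standard errors and a practical-identifiability warning when the
scaled Jacobian cross-product is near singular. The synthetic I-V
fixture's default protocol spans $-120$ to $+200$ mV deliberately: a
protocol confined to the rising limb leaves $\{F_c, k_{d,Nao}^0,
k_{d,Ko}^0\}$ practically non-identifiable (the warning fires), whereas
covering the peak and the inhibited limb makes the three-parameter
recovery study well posed (recovery within 3 SE at 5% noise across 20
seeds is part of the acceptance suite).

## 6. Time stepping and problem sizes

Operator splitting per step: stimulus → potential solve → membrane
charging → pore step → pore fluxes → pump → concentration update (ion
flow and concentrations alternate). During stimulation
$\Delta t = $ pulse width$/20$ (50 fs at 0.5 THz); afterwards the step
grows geometrically (factor 1.05) to a cap of $100\times$ the
stimulation step, so the post-stimulation tail is resolved with ample
margin against the explicit stability bound declared by the field
operator. Self-convergence (halving $\Delta t$ moves the activation time
by $<5\%$ and the averaged power series by $<5\%$) is part of the test
suite.

The shipped study plans are: the 12.3 ns reference run (1.2 ns on), an
81.1 ns long run (1.1 ns on) for the pump-closure question, and a
frequency sweep at fixed duty and amplitude with a no-stimulus control.
The test suite and acceptance script run the sweep at three
representative frequencies (0.1, 0.5, 1.2 THz) to keep the default runs
inside a desktop-scale budget; `frequency_sweep()` takes any list.

## 7. What the synthetic fixtures do and do not show

The generator-side fixtures (`make_iv_dataset()`,
`schwan_reference()`, `cycle_steady_state_oracle()`, `mini_config()`)
make every stage testable without external data: fitting is tested by
parameter recovery from noisy synthetic curves with known truth, the
potential/charging solver against a classical closed form, and the
cycle algebra against an independent linear solve. Passing these shows
internal correctness of the implementation under the stated model — it
does *not* validate the model against wet-lab measurements, and the
synthetic I-V noise model (Gaussian, fraction-of-maximum scale) is an
assumption, not a measured error structure.

## 8. Known limitations and open outcomes

* **Pump closure.** Two descriptions of the source system are mutually
  inconsistent under any single four-state parameterisation: forward
  pumping at rest requires the I-V curve to be positive at
  $V_{rest}$, while "the pump closes as the membrane voltage decays
  toward zero" requires it to vanish near 0 mV. This package keeps the
  rest-directionality property (it is the physically grounded one). The
  measured consequence, recomputed by the acceptance script, is that
  after stimulation the membrane settles in a range where the pump
  current is an $O(1)$ fraction of its post-stimulation peak, and closure
  at the default $10^{-4}$ relative threshold does not occur within
  81 ns. The threshold and horizon are configuration, so a
  supplementary-table parameterisation that does close can be evaluated
  unchanged.
* **K⁺ frequency invariance.** The accumulated $\Delta[\mathrm{Na^+}]_i$
  is frequency-invariant at the percent level, but
  $\Delta[\mathrm{K^+}]_i$ is a small residual of nearly cancelling
  import and export flows and inherits tens-of-percent sensitivity on
  this coarse grid; the acceptance suite reports both spreads rather
  than hiding the second.
* **Ca²⁺ accumulation** depends linearly on the assumed extracellular
  Ca²⁺ (literature default 2 mol/m³) and on the open-area history, so
  its fold change is reproduced at the "factor-of-two scale" rather than
  tightly.
* No dielectric dispersion, no electro-osmotic water flux, no
  sub-THz protein-vibration coupling, no non-axisymmetric geometry; the
  bulk media are charge-neutral ohmic conductors and $V_{rest}$ enters
  only as an initial/leak reference.
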