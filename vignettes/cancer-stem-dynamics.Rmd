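---
title: "Cancer stem cell population dynamics: model, noise, and therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cancer stem cell population dynamics: model, noise, and therapy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(csmsim)
```

## The model

`csmsim` simulates a minimal dynamical description of tumor heterogeneity
under the cancer stem cell hypothesis. The tumor is a mixture of cancer
stem cells (density $S$), differentiated cancer cells (density $D$) and
inert cells ($1 - S - D$); two chemical fields close the feedback loops:
the stem-division activator $a$ and the plasticity activator $m$. The
dynamics are

$$
\begin{aligned}
\dot S &= (2p(D,a) - 1)\,\Upsilon\,\lambda S + q(m)\,D,\\
\dot D &= 2\,(1 - p(D,a))\,\Upsilon\,\lambda S - (d + q(m))\,D,\\
\dot a &= a\!\left(\frac{\beta S a}{1 + a} - \alpha_a\right),\\
\dot m &= \gamma\, e^{-S/S_0} - \alpha_m m,
\end{aligned}
$$

with

$$
p(D,a) = \frac{\eta a}{(1+\eta a)(1+\psi D)},\qquad
q(m) = \frac{q_0}{2}\Big[1 + \tanh\frac{m - m_0}{s_q}\Big],\qquad
\Upsilon = \tanh\frac{1 - S - D}{s_l}.
$$

Only stem cells divide (rate $\lambda$, the unit of time: one day is one
mean stem division). A division yields two stem cells with probability
$p$, two differentiated cells with probability $1 - p$, so
$\dot S + \dot D = \Upsilon\lambda S - dD$ holds identically: one net cell
per division, and differentiated-cell death ($d$) is the only loss.
Plasticity — de-differentiation of $D$ back to the stem state — switches
on through the step $q(m)$ when the plasticity activator crosses $m_0$;
$m$ itself is produced only while the stem density is below the scale
$S_0$. The saturation factor $\Upsilon$ suppresses all mitosis as the
tumor approaches confluence and confines trajectories to the simplex
$S + D \le 1$.

### Reading of the activator equation

The activator production is autocatalytic and linear in $S$, with a
partial saturation factor $a/(1+a)$: written out,
$\dot a = \beta S a^2/(1+a) - \alpha_a a$. For small $a$ the production is
quadratic and decay dominates ($\partial \dot a/\partial a = -\alpha_a$ at
the origin, and $a = 0$ is invariant); for large $a$ production grows
linearly in $a$, so whenever $\beta S > \alpha_a$ persists the activator
grows without bound. This runaway is an essential regime of the model —
it is what the divergence event detector monitors, and what therapy can
accidentally trigger (the tumor growth paradox below). A reading without
the autocatalytic prefactor would bound $a$ by $\beta/\alpha_a$ and
remove the runaway regime entirely, contradicting the phenomenology the
model is built to display; we therefore implement the autocatalytic form.

### Parameters

All rates are per day. The constants fixed across every packaged regime
are $\lambda = 1$, $\psi = 1$, $S_0 = 0.038$, $m_0 = 0.5$, $s_q = 0.01$,
$s_l = 0.1$; the step widths must stay small for $q$ and $\Upsilon$ to act
as switches (the constructor warns above 0.5). The regime-specific
constants ($\alpha_a$, $\alpha_m$, $\beta$, $\gamma$, $\eta$, $\psi$, $d$,
$q_0$) are tabulated per scenario:

```{r}
head(list_scenarios())
```

## Rest states and stability

The system has up to three rest states, analyzed — as is standard for
this model — with the saturation factor approximated by
$\Upsilon \approx 1$ (it deviates from 1 only within
$\mathcal{O}(s_l)$ of confluence):

* **F1**, extinction: $(0, 0, 0, \gamma/\alpha_m)$, always exists.
* **F2**, the plasticity-sustained dormant colony: $a = 0$,
  $m_2 = m_0 + s_q\,\mathrm{artanh}(2d/q_0 - 1)$,
  $S_2 = -S_0\log(\alpha_m m_2/\gamma)$, $D_2 = \lambda S_2/d$; exists
  iff $0 < d < q_0$ and $m_2 < \gamma/\alpha_m$. The ordering matters
  numerically: $m_2$ first, then its existence test, then $S_2$.
* **F3**, the only rest state with $a \neq 0$: no closed form. We locate
  it by a damped-Newton multi-start search of the $\Upsilon = 1$ field
  seeded along the activator nullcline $S = \alpha_a(1+a)/(\beta a)$,
  rather than re-deriving the unstated cubic; the approximate existence
  condition is $d > \psi\alpha_a/\beta$. The search domain is *not*
  restricted to the simplex: combining the nullcline with the interior
  division balance $p = 1/2$ often forces $S + D > 1$ (for the `fig5d`
  regime, $S + D \ge 1.25$), so F3 can be a formal rest state of the
  analytic system just outside the physical region — consistent with its
  role as the unstable ridge between regression and runaway growth.
  `fixed_point_f3()` reports this through `in_simplex`.

Stability comes from the eigenvalues of the Jacobian evaluated in the
same $\Upsilon = 1$ approximation (`csm_jacobian()`, with a full-field
finite-difference mode as a cross-check): all real parts negative is
stable, mixed signs a saddle, and any real part within $10^{-10}$ of zero
is refused as non-hyperbolic rather than guessed. When F2 exists it is
the attractor and F1 is a saddle; otherwise F1 is stable; F3, when it
exists, is always a saddle.

```{r}
fps <- csm_fixed_points(get_scenario("fig1b")$model)
fps$F2
```

## Deterministic simulation

`simulate_csm()` integrates the system with deSolve's `lsodar` (adaptive,
with root finding) at `rtol = 1e-8`, `atol = 1e-10` on a 0.02-day output
grid. The integrator's root function halts the run when the activator
crosses a configurable ceiling (default $10^6$) and records a
`divergence` event; a first passage of $S + D$ below $10^{-6}$ records a
(non-terminal) `extinction` event. These two thresholds are package
choices — the model itself only distinguishes "grows without bound" from
"decays". `lsodar` was chosen over an explicit Runge–Kutta pair because
event termination on the divergence manifold requires built-in root
finding; an `"ode45"` method remains selectable for cross-checks, and the
test suite verifies that halving the tolerances moves end states by less
than $10^{-4}$. Solver states with components in $[-10^{-9}, 0)$ are
clipped to zero before the auxiliary functions are evaluated; larger
violations raise an error rather than being silently repaired.

## Stochastic parameters

Environmental and intrinsic variability enter as white noise on one rate
constant at a time: the noised parameter $X$ follows $dX_t = \rho\,dW_t$,
a pure Wiener process started at the base value (primary targets: the
mitotic rate, the death rate $d$, the plasticity amplitude $q_0$).
Realistic relative amplitudes are 5–20% of the base value;
`noise_spec()` warns outside that range. Because the noise is independent
of the state, the joint system can be integrated by sampling the
parameter path exactly on the step grid and advancing the state through
each step with a classical RK4 step holding the parameter at its
left-endpoint (Itô) value. The default step is $0.005$ d; the suite's
zero-noise equivalence check runs at $0.001$ d, where the fixed-step
truncation error is below $10^{-6}$ against the adaptive reference. The
test suite also cross-checks full stochastic runs against an independent
route: freeze the sampled path, hand the resulting non-autonomous ODE to
the adaptive deterministic solver, and compare end states.

A parameter path that leaves $(0,\infty)$ is biologically meaningless;
the default policy is to *flag* the trajectory (`nonphysical_parameter`)
and keep simulating the literal model, with `clamp` and `resample`
policies available but off by default — pre-selecting trajectories would
silently bias ensemble statistics.

Bundles (`simulate_bundle()`, seeds `base_seed + index`) share one output
grid, so the ensemble dispersion is well defined. The bundle width
$\sigma(t)$ per variable is the unbinned Gaussian maximum-likelihood fit
of the cross-trajectory distribution, which is closed-form: the fitted
mean is the sample mean and the fitted $\sigma$ is the biased ($1/N$) RMS
deviation. Near the attractor F2, widths grow linearly within the
relaxation window $t \lesssim 10$ d; `width_growth_check()` fits the
slope and flags super-linear breakout by anchoring a linear fit on the
first half of the window and testing the second half against it (25%
relative excess plus three RMSE — a diagnostic convention, not a claim of
optimality). The activator $a$ is excluded from width fits by default
since it is a numerical zero in the fixed-point regimes where widths are
studied.

## Pharmacology

Drug level $\chi(t)$ follows one-compartment kinetics with periodic
administration: infusion at rate $\zeta$ for a duration $\tau$ each
period $T$, first-order clearance $\alpha_d$ throughout. The analytic
piecewise-exponential solution (with the closed-form geometric recursion
for the start-of-period level) is used everywhere; the suite checks it
against direct integration to $10^{-8}$ over ten periods. The dose is
specified either as $\zeta$ or as a target peak via
$\zeta(\chi_{\max}) = \chi_{\max}\alpha_d/(1 - e^{-\alpha_d\tau})$. The
reference schedule ($\chi_{\max} = 1$, $\alpha_d = 10$/d, $T = 1$ d,
$\tau = 0.08$ d) leaves $\chi(T)/\chi(\tau) = e^{-9.2}$ — no inter-dose
accumulation, which the schedule constructor warns about if violated.

The drug acts through the sigmoidal response
$\Omega(\chi) = \tfrac{\Omega_0}{2}[\tanh((\chi - \chi_0)/s_\chi) + 1]$
(reference: $\Omega_0 = 1$, $\chi_0 = 0.2$, $s_\chi = 0.05$), applied to
a model rate by one of four couplings:

* **cytotoxic** — $d(t) = d + \Omega$ (kills differentiated cells);
* **cytostatic** — $\lambda(t) = \lambda - \Omega$, clamped at 0 by
  default (a negative mitotic rate is nonphysical; the clamp can be
  disabled to study the literal model);
* **anti-plasticity** — $q_0(t) = q_0 - \Omega$, clamped likewise;
* **combined differentiation + cytotoxic** — the plasticity *term*
  becomes $q(m) - \Omega_{\rm diff}(\chi)$, deliberately *not* clamped
  (its negative excursion acts as an induced stem-cell death rate, which
  is the point of forced differentiation), together with
  $d(t) = d + \Omega_{\rm cyto}(\chi)$. Implemented literally as a shift
  of the $q(m)$ term; whether the forced-differentiation flux should
  instead be proportional to $S$ is a modeling ambiguity we document and
  do not resolve.

Dosing starts at the simulation start by default ($\chi(0) = 0$, no
pre-existing drug). Because the infusion switch makes the right-hand side
discontinuous at every $nT$ and $nT + \tau$, `simulate_with_therapy()`
restarts the integrator on each phase boundary so no step straddles a
discontinuity.

## Scenarios and their initial conditions

Every published parameter regime is packaged as a named scenario
(`get_scenario()`, `list_scenarios()`, `run_scenario()`). The regimes
come without initial states, so the defaults are package choices, fixed
once during scenario design so that each scenario exhibits its catalogued
outcome class, and recorded in each scenario's `notes`:

* convergence scenarios start from a small seeded tumor
  $(S, D, a, m) = (0.01, 0.1, 0.5, 0.1)$ (`fig1b` family) or an
  activator-primed state $(0.05, 0.02, 1, 0.1)$ that produces the
  overshoot of the extinction regime (`fig1a`);
* the plasticity-bump demonstration (`fig2c`) starts at
  $(0.15, 0.3, 0.3, 0.1)$: both cell densities fall until $m$ crosses
  $m_0$ near $t \approx 3$ d, then de-differentiation re-ignites the
  colony;
* the width-growth study (`fig3a`) starts exactly at F2;
* the paradox (`fig5d`, $(0.1, 0.5, 20, 0.1)$, 30 d) and rescue
  (`fig6a`/`fig8b`, $(0.02, 0.05, 5, 0.1)$) scenarios sit inside
  deliberately narrow windows in $(D_0, a_0)$ where treatment flips the
  outcome class — the windows are narrow because they straddle the
  stable manifold of the F3 saddle;
* `fig6b` starts at $(0.05, 0.02, 3, 0.1)$ so the untreated tumor
  overshoots and regresses spontaneously; `fig7a`/`fig8a` start at
  $(0.05, 0.1, 0.1, 0.6)$ with plasticity already active.

Horizons are 20 d for convergence and therapy runs (30 d where regression
or the paradox needs longer), 10 d for stochastic width studies — the
linear-growth window. Bundle sizes are 20 (trajectory illustrations) and
100 (width fits), with ensembles of 1000 exact Wiener paths used where
only the parameter law itself is tested.

What the generator does *not* emulate: measurement noise, cell-count
discreteness (densities are continuum averages), spatial structure, and
any memory in the environmental fluctuations (the noise is Markovian by
construction). Passing tests therefore validate the dynamical claims of
the implementation, not the biological fidelity of white-noise forcing.

## Known limitations

* The fixed-point analysis (including F3 and all eigenvalues) lives in
  the $\Upsilon \approx 1$ approximation; near confluence the analytic
  Jacobian and the full field disagree at the $10^{-3}$ level, which is
  why the cross-validation tests sample states with $S + D \lesssim 0.4$.
* Fixed-step RK4 for the stochastic layer trades adaptivity for exact
  reproducibility of the seed ladder; very stiff excursions (large noised
  $d$ pushing trajectories against the simplex boundary) are handled by
  the flag policy, not by step control.
* Therapy outcomes in the paradox/rescue scenarios depend sensitively on
  the initial state by design; they are regime demonstrations, not
  dose-response predictions.
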