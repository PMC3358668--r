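---
title: "Verifying temporal properties of SDE models with biased sampling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying temporal properties of SDE models with biased sampling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdemc)
```

## The problem

Stochastic differential equation (SDE) models of biological systems —
tumor growth under immune surveillance, chemotherapy response, gene
expression noise — often have their most interesting behaviour in their
tails: oncogenesis, escape from immune control, extinction. Plain Monte
Carlo answers questions like *"does the tumor burden reach $10^{11}$
cells within 10 time units with probability at least 1%?"* by sampling
trajectories i.i.d. and counting, which is hopeless when the behaviour of
interest has probability $10^{-3}$ or less: the expected number of
simulations needed just to *see* the event once is the reciprocal of its
probability.

`sdemc` implements statistical model checking for SDEs built from three
parts:

1. an **Euler–Maruyama simulator** that can draw trajectories under
   *randomly perturbed* probability measures, with the exact
   change-of-measure weight of every path tracked through the Girsanov
   exponential martingale;
2. a **bounded linear temporal logic (BLTL) monitor** that decides, for
   each finite trace, whether it satisfies the behavioural specification;
3. a **Bayesian sequential hypothesis test** on the resulting stream of
   Bernoulli outcomes, whose Bayes factor is conservatively corrected for
   the non-i.i.d. sampling.

The pipeline decides between the composite hypotheses
$H_0 : \rho \ge \theta_0$ and $H_1 : \rho < \theta_0$, where $\rho$ is
the unknown probability that a trajectory satisfies the BLTL formula.

## The model class and the integration scheme

Models are Itô systems $dX = b(t, X)\,dt + v(t, X)\,dW$ with one
independent Brownian motion per equation (`sde_model()`). The simulator
is the fixed-step Euler–Maruyama scheme
$$X_{k+1} = X_k + b(t_k, X_k)\,\Delta t + v(t_k, X_k)\,\Delta \hat W_k,$$
i.e. exactly the discrete difference scheme whose limit defines the SDE;
no adaptive stepping is attempted. Two representational choices are worth
stating explicitly:

* **Per-equation (diagonal) noise.** The diffusion coefficient of
  equation $i$ multiplies that equation's own $dW_i$; it may depend on
  the whole state. Both bundled tumor models have this form, and
  restricting to it (rather than a general $d \times m$ diffusion
  matrix) lets the engine vectorise across whole blocks of trajectories
  in pure R, which is what makes $10^5$-path validation runs practical.
  Correlated noise across equations is out of scope.
* **State clamping.** Population states are clamped at zero after every
  step when `positive = TRUE` (the bundled tumor models do this);
  clamping events are counted on each trajectory. The underlying
  continuous models keep populations non-negative through state-dependent
  coefficients, but the discretised scheme can overshoot.

Every trajectory is a deterministic function of
`(model, grid, perturbation, seed)`. Seeds for trajectory $i$ of a run
are derived from the run's root seed by a counter-based integer mixer
(`rng_substream()`), so any single sample can be regenerated in
isolation and batched simulation is bit-identical to sequential
simulation.

## Perturbing the measure: what is drawn and why

The sampling algorithm exposes rare behaviour by giving each trajectory
its own drift-shifted Brownian motion: increments
$\Delta\hat W_k = \Delta W_k + \theta\,\Delta t$. The theory places no
structure on the perturbation process $\theta_t$ beyond the Novikov
condition, so the package makes a deliberate, documented choice: **each
trajectory uses a constant shift $\theta$, drawn independently and
uniformly from $[-\theta_{\max}, \theta_{\max}]$ per Brownian
component** (`perturb_policy(theta_max, "symmetric_uniform")`).

Rationale:

* constants satisfy the Novikov condition trivially and make the
  Radon–Nikodym weight available in closed form,
  $\log Z_T = -\theta\, W_T - \tfrac{1}{2}\theta^2 T$
  (`girsanov_log_weight()`), which in turn makes the martingale property
  $\mathbb{E}[Z_T] = 1$ testable;
* the symmetric draw biases *towards* the event as often as *against*
  it, which is the constructive approximation of long-run fairness this
  package relies on for SDE sampling, where the per-sample implied
  change of measure is not computable.

One subtlety the discrete fixtures expose (see below): even a perfectly
direction-symmetric policy does **not** drive the geometric mean of the
realised per-sample derivatives to one. Under sampling measure $\mu_i$
the expected log derivative is $\mathrm{KL}(\mu_i \| \mu) > 0$, so the
realised geometric mean concentrates slightly *above* one. The asserted
fairness bound $\eta$ must absorb this offset; it is a property of the
perturbation policy's strength, not of its symmetry alone.

## The sequential test and the $\eta^{2n}$ correction

With $x$ satisfying traces out of $n$ and a Beta$(\alpha,\beta)$ prior
on $\rho$, the Bayes factor of $H_0$ against $H_1$ is the ratio of
prior-weighted likelihood integrals above and below $\theta_0$, which
reduces to $(1 - I)/I$ with
$I = I_{\theta_0}(\alpha + x,\ \beta + n - x)$ the regularised
incomplete beta function. Two implementation notes:

* This is the **posterior-odds form** — it is *not* divided by the
  prior odds. With a uniform
  prior and $\theta_0 = 0.5$ it coincides with the Jeffreys Bayes
  factor; for small $\theta_0$ it starts at the prior odds
  $(1-\theta_0)/\theta_0$, which is why thresholds $T$ below that value
  decide very quickly. Users comparing against prior-odds-normalised
  Bayes factors must divide accordingly.
* All arithmetic is on the log scale through `pbeta(log.p = TRUE)`, so
  the test survives $n$ in the thousands; posteriors beyond double
  precision saturate to $\pm\infty$ sentinels instead of erroring.

Sampling stops when the **adjusted** Bayes factor leaves $(1/T, T)$,
strict inequalities (ties keep sampling). The adjustment for non-i.i.d.
sampling divides $B$ by $\eta^{2n}$ when $B > 1$ and multiplies it by
$\eta^{2n}$ when $B < 1$ — equivalently, shrinks $|\log B|$ by
$2n\log\eta$. Applied literally, a large correction could cross zero and
flip the sign, letting the correction itself manufacture a (wrong)
decision; `adjust_log_bf()` therefore **clamps at zero**, the maximally
non-committal value. The order within an iteration is: draw, update
counts, compute the raw Bayes factor, adjust, then test.

$\eta$ is a *user-asserted* bound. For the discrete toy fixtures the
implied derivatives are explicit and `check_fairness()` can audit a
history; for SDE sampling they are not computable, and the assertion
rests on the symmetry and strength of the perturbation policy.
`eventually_fair()` implements the termination condition
$\eta^4 < e^b$, with the posterior-concentration constant $b$ supplied
by the user — the package does not compute $b$.

Defaults: Beta$(1,1)$ prior (non-informative), $T = 100$, $\eta = 1$,
`max_samples = 1e6`. `eta = 1` *is* i.i.d. mode; configurations with the
perturbation policy off force it.

## BLTL semantics on finite traces

Formulas are atoms $x \sim v$ ($\sim \in \{<, >, =\}$), Boolean
connectives, and the time-bounded Until $\varphi_1\,U^t\,\varphi_2$;
$F^t$ and $G^t$ are sugar. A trace is the finite sequence of simulated
states with durations: every state carries the integration step
$\Delta t$, except the last, which carries 0. Decisions that were
genuinely open and how they were fixed:

* **Elapsed time counts states strictly before the witness.** The Until
  at start $k$ needs a witness $k+i$ with
  $\sum_{0 \le l < i} \Delta_{k+l} \le t$: the witness state's own
  duration does not count. This is the literal reading of the index
  range in the defining rule, applied consistently in both evaluators.
* **Finite-trace semantics.** A bounded Until with no witness inside the
  trace is false — there is no third truth value. `sde_sampler()` warns
  when the formula's time bound exceeds the simulated horizon, since
  verdicts can then be artifacts of truncation.
* **Equality atoms compare exactly** (tolerance 0). Users needing a
  tolerance can write a conjunction of `<` and `>`.
* Grammar precedence is `!` over `&` over `|`; Until is non-associative
  and requires parentheses.

The production monitor (`bltl_satisfies()`) evaluates bottom-up over the
whole trace with two-pointer windows, $O(\text{trace} \times
\text{formula})$; a deliberately naive recursive transcription of the
semantic rules (`bltl_satisfies_naive()`) is kept as an independent
oracle and the test suite checks exact agreement on $10^4$ random
formula/trace pairs.

## Bundled models and what the defaults mean

**Tumor growth under immune surveillance and chemotherapy**
(`lefever_garay()`): logistic growth, saturating immune kill
$\beta x^2/(1+x^2)$, periodic chemotherapy forcing $A_0\cos(\omega t)$,
and multiplicative noise $x(1 - x/K)\,dW$. The equation is often written
in Langevin form with a trailing white-noise term; this package reads
that term as the diffusion coefficient of an Itô SDE, consistent with
the general form above, and an Itô (not Stratonovich) interpretation is
assumed throughout. **The numeric defaults are this package's
placeholders, not the parameter values of the original studies of this
model.** They were chosen once to make the deterministic part bistable
at desk scale (stable equilibria near $x \approx 0.46$ and
$x \approx 5.84$, unstable threshold near $x \approx 3.69$ for the
defaults). Consequently no quantitative result published for a specific
parameterisation of these models is a reproduction target here; the
validation checks are property-based instead.

**Immunogenic tumor model** (`immunogenic()`): immune effectors $x$ and
tumor cells $y$, with noise proportional to the displacement from the
stochastic equilibrium $(x_1, y_1)$. Same placeholder status; the
defaults put an interior equilibrium at $(1.5, 1)$. The bundled headline
property `immuno_rare` monitors `x > 3.3` — the variable the property is
conventionally stated over — although the tumor population is $y$ in the
equations; the discrepancy is preserved deliberately and documented in
the preset's description. Monitor `y` by passing your own formula.

**Analytic benchmarks**: `brownian_barrier(a, t)` pairs $dX = dW$ with
$F^t(x > a)$ and the reflection-principle probability
$2(1 - \Phi(a/\sqrt{t}))$, giving the whole pipeline a ground truth.
Discrete-time monitoring only sees grid points, so crossing estimates
undercount by $O(\sqrt{\Delta t})$ — the validation tolerance (0.02
absolute at $\Delta t = 10^{-4}$) covers this known bias.

**Discrete fixture with explicit measures**: `toy_fixture(c, p_rare)`
has a single rare satisfying outcome whose mass the biased measure
multiplies by $c$ (capped at $1/2$). Because an outcome-level constant
derivative cancels from the Beta-posterior ratio, the *posterior*
distortion bound is exercised through an odds-multiplier bias map
$h(u) = cu/(1 + (c-1)u)$, whose implied derivative lies in $[1/c, c]$
uniformly in $u$ (success: $c/(1+(c-1)u)$; failure: $1/(1+(c-1)u)$).
`biased_posterior_below()` integrates this biased posterior numerically,
and the tests verify the $c^{\pm 2n}$ sandwich around the unbiased
posterior on every sampled path — the inequality that licenses the
$\eta^{2n}$ correction.

## Validation experiments and the problem sizes used

The acceptance suite (`tests/testthat/test-acceptance.R`) and
`scripts/acceptance.R` recompute, at fixed seeds:

* closed-form vs quadrature Bayes factors over all $x$ for
  $n \in \{0..10, 25, 50, 100, 150, 200\}$, $\theta_0 \in \{0.01, 0.1,
  0.5, 0.9\}$ and Beta priors $(1,1), (2,5), (0.5,0.5)$, at $10^{-9}$
  relative tolerance (cells beyond double-precision underflow are
  excluded — quadrature cannot represent them);
* the analytic stopping time $n = 459$ for an all-failure stream at
  $\theta_0 = 0.01$, $T = 100$;
* the Girsanov martingale mean over $10^5$ paths
  ($\theta \in \{0.5, 1\}$, $\Delta t = 10^{-3}$), within 4 standard
  errors of 1;
* the barrier-crossing probability from $10^5$ paths at
  $\Delta t = 10^{-4}$, within 0.02 of $2(1-\Phi(1)) \approx 0.3173$;
* wrong-decision rates $\le 5\%$ over 500 Bernoulli replicates per
  setting ($p \in \{0.2, 0.001\}$ vs $\theta_0 = 0.01$);
* the rare-event advantage on `brownian_barrier(3, 1)` (crossing
  probability $\approx 2.7 \times 10^{-3}$; $\approx 2.2\times10^{-3}$
  as seen by the discrete monitor at $\Delta t = 10^{-2}$): 50 paired
  runs per threshold over $T \in \{10^4, 10^5, 10^6\}$ with
  $\theta_0 = 10^{-4}$, $\theta_{\max} = 6$, $\eta = 1.1$. Both samplers
  accept the (true) $H_0$; the biased sampler's median cost stays nearly
  flat while the i.i.d. median grows with $\log T$, so the gap widens —
  the qualitative signature of rare-event exposure. The experiment
  constants were fixed analytically before running: the i.i.d.
  log-Bayes-factor drift is a few $10^{-3}$ per sample at these rates
  while the biased drift is $\approx \mathrm{KL}(\theta_0 \| q) -
  2\log\eta \approx 0.09$ per sample for a boosted success rate
  $q \approx 0.25$;
* the reversal for a non-rare property ($p = 0.6$ vs $\theta_0 = 0.2$):
  the $\eta$-corrected biased tester is never faster in the median than
  the i.i.d. one.

## What the synthetic benchmarks do and do not show

The validation models (Brownian barrier, Bernoulli and toy streams) have
exactly known satisfaction probabilities and exactly known changes of
measure; they validate the *machinery* — integrator bias, weight
bookkeeping, monitor semantics, test calibration, the conservativeness
of the correction. They do not establish that any particular asserted
$\eta$ is honest for a real biological SDE under a given perturbation
policy: that judgement remains the user's, and a dishonestly small
$\eta$ can make the biased test converge quickly to the biased answer.
Nor do the placeholder tumor parameterisations reproduce the
quantitative results of the original studies. Passing tests mean the
algorithm does what it claims under its stated assumptions, not that
those assumptions hold for an arbitrary model.

## Numerical choices and degenerate inputs

* Grids cover the horizon with `n_steps = ceiling(t_end/dt)`;
  `dt > t_end` is rejected.
* Non-finite states abort with the offending step index rather than
  propagating `NaN`s; the usual causes are too-large `dt` for stiff
  drifts.
* `max_samples = 0` returns `undecided` at the prior state.
* An empty fairness history is vacuously fair, with a warning.
* Elapsed-time comparisons in the monitor are exact; with
  durations equal to a floating-point `dt`, a witness exactly at the
  bound can land on either side of rounding. At the trace lengths and
  bounds used here this is far below every tolerance of interest.

## A worked example

```{r example, eval = FALSE}
library(sdemc)

bb <- brownian_barrier(a = 3, horizon = 1) # rare: p ~ 0.0027
grid <- sim_grid(t_end = 1, dt = 0.01)

spec <- test_spec(theta0 = 1e-4, bayes_threshold = 1e4, eta = 1.1,
                  max_samples = 20000)
sampler <- sde_sampler(
  bb$model, bb$formula, grid,
  perturb_policy(theta_max = 6, mode = "symmetric_uniform"),
  seed = 1
)
res <- sequential_verify(sampler, spec, keep_history = TRUE)
glance(res)
autoplot(res)
```
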