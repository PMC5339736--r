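---
title: "Methods: a stochastic birth–death model of irrigated commons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a stochastic birth–death model of irrigated commons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(irristoch)
```

## The model and its assumptions

`irristoch` models an irrigation community as a one-dimensional birth–death
process for the irrigator population $N$, coupled to two exogenous annual
drivers: water availability $W$ and the tax fraction $T$ levied on
water-derived income to maintain the shared infrastructure. The core
assumptions:

* **Water is rival.** Each irrigator draws $a$ water units, so available
  water is $W(N) = \max(0, W - aN)$ — never negative, exactly zero once
  $N \ge W/a$.
* **Infrastructure is funded by taxes and responds instantaneously.**
  Tax revenue $x = T N h W(N)$ (with $h$ the income per person per unit of
  available water) feeds a performance function
  $g(x) = z/(z+\kappa)$, $z = \max(0, x - x_0)$: inoperative below the
  maintenance threshold $x_0$, saturating above it with half-saturation
  $\kappa$. Infrastructure has no memory; its state is a function of this
  year's funding. Dynamic infrastructure (degradation, repair lags) is out
  of scope.
* **Migration follows incentives.** Per-capita payoff inside the system is
  $\pi(N; W, T) = (1-T)\,h\,W(N)\,g(x)$. Both entry and exit carry a
  demographic floor $m$ (births, deaths, background migration); the side
  favoured by the gap against the outside option $\pi_o$ gains an
  incentive term $rN\,|\pi - \pi_o|$. At $N = 0$, only entry is possible
  ($b(0) = m$, $d(0) = 0$).
* **Time scales separate.** A step is $dt = 5\times10^{-5}$ yr (about 26
  minutes, 20{,}000 steps/yr) during which $N$ changes by at most one;
  drivers change only at year boundaries and are constant within a year.

Because $\pi = 0$ wherever water is exhausted while $\pi_o > 0$, there is
always a population size at which exit dominates; no driver condition makes
entry dominate everywhere, while drought or confiscatory/absent taxation
makes exit dominate everywhere. This asymmetry is what makes collapse a
one-way trap, and it is asserted as a property test over a dense sample of
driver conditions.

## Calibration

The functional form of $g$ carries three free constants $(x_0, \kappa,
\pi_o)$ that the published description of the model does not fix
numerically. They are pinned by the three landmarks of the payoff
landscape at baseline drivers $(\bar W, \bar T) = (1, 0.2)$:
$\tilde N = 727$ (largest population with inoperative infrastructure),
$N_M = 3{,}333$ (payoff maximum), $N^* = 7{,}015$ (payoff parity with the
outside option). Concretely, `calibrate_payoff()` sets

* $x_0 = x(\tilde N)$ — so performance is exactly zero at $\tilde N$ and
  positive at $\tilde N + 1$;
* $\kappa$ from the first-order condition of the payoff maximum at $N_M$,
  $a\,z_M(z_M + \kappa) = (\bar W - a N_M)\,\kappa\,x'(N_M)$, which is
  linear in $\kappa$ and solved in closed form (an error is raised if the
  root is nonpositive, i.e. the anchors are inconsistent with this
  functional family);
* $\pi_o = \pi(N^*)$, evaluated through the *same floating-point code
  path* as `per_capita_payoff()`, so the comparison $\pi \ge \pi_o$
  recovers $N^*$ bitwise, without tolerance.

This yields $x_0 \approx 1.3483$, $\kappa \approx 7.1018$,
$\pi_o \approx 6.821\times10^{-4}$, and `compute_thresholds()` on the
calibrated defaults returns the anchors exactly (integer equality, a
round-trip asserted for two independent anchor sets). Calibration is done
once at baseline and the constants are held fixed in every experiment,
including payoff surfaces over $T$.

The lower parity crossing $N_\mathrm{low} = 1{,}199$ (smallest $N$ with
$\pi \ge \pi_o$) is computed and named although the source description
names only the other three landmarks: it delimits the attraction basin and
is the natural "re-entry" line for recovery detection.

## Parameters

| Parameter | Meaning | Units | Default |
|---|---|---|---|
| `m` | baseline entry/exit rate | events·yr⁻¹ | 1 |
| `h` | income per person per unit available water | payoff·water⁻¹ | 0.01 |
| `r` | responsiveness of migration to payoff gap | persons·payoff⁻¹·yr⁻¹ per person | 1 |
| `a` | per-capita water usage | water·person⁻¹ | 10⁻⁴ |
| `W_bar`, `T_bar` | driver means | water, fraction | 1, 0.2 |
| `dt` | step length | yr | 5×10⁻⁵ |
| `x0`, `kappa`, `pi_o` | calibrated payoff constants | funding, funding, payoff | 1.3483, 7.1018, 6.821×10⁻⁴ |

`r` and `m` set the separation between incentive-driven drift (up to
$rN|\pi-\pi_o| \sim 3$ events/yr in the basin) and demographic noise; `a`
sets the hard carrying capacity $W/a = 10{,}000$ at mean water.

## Two transition schemes

The per-step transition rule admits two readings, and the package ships
both:

* **`jump`** (default): every step is a forced ±1 move with probabilities
  $b/(b+d)$ and $d/(b+d)$. This is the literal reading of the transition
  probabilities, and it produces the fast within-year crashes seen in the
  collapse experiments: in a year where $\pi < \pi_o$ at every $N$, the
  per-step downward bias is order $(d-b)/(b+d) \approx 0.7$, i.e. a drop
  of thousands of persons within one 20{,}000-step year.
* **`bernoulli`**: rate-thinned moves with probabilities $b\,dt$, $d\,dt$
  and a stay probability. This reading respects the rates as continuous-
  time intensities; the chain then moves only $\sim(b+d)\,dt \cdot 20{,}000
  \approx 2$ times per year, and its relaxation time around the attractor
  is hundreds of model years.

Which scheme the original runs used is not decidable from the description;
both are tested against their own exact stationary laws. The `jump` default
is the package's design choice: it matches the sharp published collapse
phenomenology and equilibrates on simulable horizons.

## Exact stationary oracles and their verification

At fixed $(W, T)$ the chain is a birth–death process, so its invariant law
has the classical product form $\mu(N) \propto \prod_{n=1}^N b(n-1)/d(n)$
(for the jump chain, the same product reweighted by the total rate
$b+d$). `stationary_product_form()` accumulates it in log space: the
valley between the collapsed state and the viable basin spans thousands of
orders of magnitude, far beyond double-precision mass, so modes and
barrier depths are always assessed on `log_mass`. Two independent checks
guard this oracle:

* a dense linear-algebra stationary solve of the full transition matrix on
  a scaled-down calibrated model (state space 0..120), agreeing to
  $10^{-10}$ for both schemes;
* Monte Carlo occupation measures of the simulator itself, within total
  variation 0.02 of the product form. For the jump scheme a 100-year run
  (2×10⁶ steps) suffices. For the bernoulli scheme it cannot: with ~200
  moves per 2×10⁶ steps and a ~400-year relaxation time, no 100-year run
  equilibrates, whatever the sampler. The equivalence is therefore checked
  over 2×10¹¹ steps using an exact accelerated sampler
  (`occupation_distribution()`) that aggregates the geometric holding
  times between moves — distributionally identical to the literal walk,
  cheaper by the factor $1/((b+d)dt) \approx 10^4$.

Numerical conventions: integer argmax ties break toward smaller $N$;
parity crossings are found by integer bisection on the monotone branches
of the unimodal payoff (verified against exhaustive scans over random
driver draws); stationary supports are truncated at $1.2\,\bar W/a =
12{,}000$ with a hard check that tail mass is below $10^{-10}$; the
simulator's guard cap adapts to the wettest drawn year
($1.2\max_t W_t/a$), since under $CV_W = 0.2$ wet years routinely push the
attractor past the baseline cap.

## The synthetic drivers: what they emulate and what they do not

Annual driver series are i.i.d. draws, moment-matched to a fixed mean and
a chosen CV: lognormal for water (positive support, right-skewed — wet
outliers and dry years), beta for taxation (confined to $[0,1]$; at
$CV_T = 0.8$ the distribution piles up near zero, emulating frequent
tax-collection failures). $CV = 0$ is handled as an exact constant so the
fixed-driver benchmark uses the same code path. The published CV levels
(0.02/0.1/0.2 for water, 0.1/0.3/0.8 for taxation) are the generator's
stated world.

Deliberately **not** emulated: temporal autocorrelation (droughts come in
runs in real basins), trends, and any dependence between water and
taxation — the model studies each driver's stochasticity in isolation, and
no joint law is specified. A green collapse test therefore establishes the
regime-shift mechanism under i.i.d. annual shocks, not a calibrated
collapse risk for any real system.

## Experiment defaults

The stochasticity-sweep and trap experiments need horizons and replicate
counts that the source description does not state. They were fixed once,
from the physics of the calibrated landscape, before the acceptance tests
were frozen:

* **Sweep (fig3 preset): 30 years × 20 replicates.** The probability that
  a year is *nonviable* ($\max_N \pi < \pi_o$) is $\sim 10^{-5}$ at the
  weakest CV levels and 0.1–0.4 at the strongest, so 30 years keeps the
  weakest levels collapse-free while the strongest collapse in a majority
  of replicates.
* **Trap (fig4 preset): calm 10 / storm 20 / calm 30 years**, storm at
  the strongest published CVs on both drivers ($CV_W = 0.2$,
  $CV_T = 0.8$). Under the storm, $P(\text{nonviable year}) \approx 0.39$
  (and $P(\pi \equiv 0) \approx 0.22$, i.e. taxation below the level that
  can fund any maintenance), so 20 storm years make first passage below
  $\tilde N$ near-certain; 30 calm years then demonstrate non-recovery.

Collapse is operationalized as first passage below $\tilde N$, not
extinction at $N = 0$: below $\tilde N$ payoff is identically zero and
drift is negative at every positive $N$, so the decline is effectively
irreversible ("recovery" is re-entry above $N_\mathrm{low}$, and a
replicate that never collapsed counts as vacuously recovered).

## Known limitations

* The published model's displayed equations are not available; the payoff
  family implemented here reproduces all printed landmarks and the
  qualitative claims, but not necessarily the exact curve shape. The
  clearest trace: the benchmark distribution's CV at fixed drivers is
  ≈ 0.0029 here versus the printed 0.0062 — same order, different
  curvature of $\pi$ near $N^*$. The package reports this CV and asserts
  it only at order of magnitude.
* Relatedly, the published claim that $N^*$ is least sensitive to $T$
  near $T = 0.5$ is not guaranteed by this family and is not asserted.
* $\pi_o$ is never printed; it is recovered purely through the $N^*$
  anchor.
* Bit-level reproducibility of seeded runs is promised within this
  implementation only (R's Mersenne–Twister stream, recorded in every run
  manifest), not across reimplementations.
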