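# irristoch

Stochastic population dynamics of irrigated social-ecological systems.

Irrigation communities couple people, water, and shared infrastructure:
irrigators earn income from the water they can harvest, pay a tax that funds
canal maintenance, and enter or leave the system depending on whether
farming inside it beats outside opportunities. `irristoch` implements a
stylized stochastic model of this feedback loop for researchers studying
commons governance, regime shifts, and population viability: a
discrete-time birth–death process for the irrigator population *N*, driven
by annually fluctuating water availability *W* and tax fraction *T*.

## The model

Per-capita payoff inside the system:

    π(N; W, T) = (1 − T) · h · W(N) · g(x)

with

* `W(N) = max(0, W − aN)` — water left after per-capita usage `a`,
* `x = T · N · h · W(N)` — tax revenue funding infrastructure maintenance,
* `g(x) = z / (z + κ)`, `z = max(0, x − x₀)` — infrastructure performance,
  zero below the maintenance threshold `x₀`, saturating above it.

Entry and exit rates carry a demographic floor `m` plus an incentive term
proportional to the payoff gap against the outside option `π_o`:

    π ≥ π_o:  b(N) = m + r·N·(π − π_o),   d(N) = m
    π < π_o:  b(N) = m,                   d(N) = m + r·N·(π_o − π)

with the boundary `b(0) = m`, `d(0) = 0`. Each time step (`dt = 5·10⁻⁵` yr,
about 26 minutes; 20,000 steps per year) the population moves by ±1 with
probabilities `b/(b+d)` and `d/(b+d)` (the default `jump` scheme; a
rate-thinned `bernoulli` scheme with stay probability `1 − (b+d)dt` is also
provided). *W* and *T* are redrawn once per year from moment-matched
lognormal and beta distributions with fixed means (1 and 0.2) and tunable
coefficients of variation.

At the published constants (`m = 1`, `h = 0.01`, `r = 1`, `a = 10⁻⁴`) the
free constants `(x₀, κ, π_o)` are calibrated so the landscape has its three
landmarks at Ñ = 727 (largest population that cannot maintain the
infrastructure), N_M = 3,333 (payoff maximum), and N* = 7,015 (payoff
parity with the outside option — the stochastic attractor). The landscape
is bistable: a collapsed state near 0 and a viable basin around N*,
separated by a probability valley hundreds of orders of magnitude deep.
Because π ≡ 0 for N ≥ W/a while π_o > 0, exit can dominate at *every*
population size but entry never can — collapse is a one-way trap.

## Worked example

```r
library(irristoch)
params <- irristoch_params()   # published constants, calibrated payoff
compute_thresholds(params)
#> Population landmarks at W = 1 , T = 0.2
#>   N_tilde = 727  (maintenance threshold)
#>   N_low   = 1199  (lower payoff-parity crossing)
#>   N_M     = 3333  (payoff maximum, pi_max = 0.001619)
#>   N_star  = 7015  (attractor: inside payoff = outside)

# exact stationary distribution at fixed drivers (the analytic oracle)
stationary_product_form(params)
#> Distribution over N = 0..12000 (jump)
#>   mean = 7014.94, sd = 20.116, cv = 0.002868, mode = 7015

# collapse probability vs water stochasticity: 20 replicates x 30 years
run_cv_sweep(params, driver = "W", base_seed = 42)
#>   driver   cv n_reps n_collapsed collapse_fraction
#> 1      W 0.02     20           0              0.00
#> 2      W 0.10     20           1              0.05
#> 3      W 0.20     20          17              0.85

# the collapse trap: calm / storm / calm, starting at the attractor
trap <- collapse_trap_protocol(params, seed = 42)
trap$storm_report
#> COLLAPSED: fell below N_tilde = 727 in year 3 (min N = 1)
trap$recovered
#> [1] FALSE
```

The sweep shows the regime shift: with mild water fluctuation (CV = 0.02)
the population sits indefinitely near N* (intrinsic CV ≈ 0.003); at
CV = 0.2 most replicates hit a year in which payoff falls below π_o at
every N, the population crashes through Ñ within that year, and — as the
trap protocol shows — calmer conditions afterwards do not bring it back:
below N_low ≈ 1,199 drift is negative everywhere, so the remnant population
hovers near zero.

## Command line

```sh
CLI=$(Rscript -e 'cat(system.file("cli/irristoch.R", package = "irristoch"))')
Rscript $CLI thresholds --out run1
Rscript $CLI simulate --config cfg.yaml --seed 7 --out run2
Rscript $CLI fig3 --seed 1 --out sweep
```

Subcommands: `calibrate`, `thresholds`, `surface`, `simulate`,
`stationary`, `fig2`, `fig3`, `trap`. Every run writes its outputs as CSV
(17 significant digits) plus a `manifest.json` (config snapshot, seeds, RNG
identity, file inventory) sufficient to reproduce it exactly.

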