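# splitcost

**What does it cost to cut a continuous predictor into categories?**

Ecologists, ethologists and evolutionary biologists routinely measure
variables continuously — body mass in kg, breeding dates in day of year,
elevation in m — and then analyse them as categories ("early" vs "late",
"high" vs "low"). `splitcost` is a simulation laboratory that makes the
price of that habit measurable. It is aimed at quantitative ecologists and
at teachers of biological statistics who want a reproducible, fully coded
demonstration rather than an appeal to authority.

## The model at the core

The laboratory generates paired data (reproductive timing *d* in day of
year, body mass *m* in kg) from a Gamma GLM with log link:

    m | d  ~  Gamma(k, μ(d)/k),      log μ(d) = β₀ + d·log(ρ)

with defaults ρ = 0.985 (each day of breeding delay multiplies expected
mass by 0.985 — a 1.5 %/day cost, 43 kg at day 55 down to ~37 kg at day
65), β₀ = log 43 − 55·log 0.985, a right-skewed shifted-Gamma timing
distribution with percentiles ≈ 55/57/60/63/65 days, and shape k
calibrated so the continuous fit's median McFadden pseudo-R² at n = 120
is ≈ 0.65. A nonlinear variant swaps in a smooth unimodal log-mean curve.

It then applies the breakpoint schemes catalogued from the literature —
median split, uneven (25/75) split, quartiles, fixed-width intervals,
bimodal "natural break" splits — refits the same Gamma likelihood with
categorical predictors, and compares: AIC, McFadden pseudo-R²
(1 − ℓ₁/ℓ₀), back-transformed marginal means exp(η̂ ± 1.96·se) with
compact letter displays, and Monte-Carlo power/efficiency. A penalized
cubic B-spline smoother (`gamma_smooth()`) covers the nonlinear case
without pre-binning. The Gamma IRLS engine, profile-ML shape, marginal
means, letter displays and spline machinery are implemented in the
package and cross-checked in the tests against independent oracles
(`stats::glm`, brute-force likelihood maximization, exhaustive
letter-cover search).

## Worked example

```r
library(splitcost)

d <- simulate_dataset(sim_config(n = 120, seed = 1))
run_comparison(d)
```

```
Model comparison on n = 120 observations

      model n_par    loglik      aic delta_aic pseudo_r2
 continuous     2 -110.5482 227.0965    0.0000    0.5763
     median     2 -217.4364 440.8728  213.7763    0.1667
     uneven     3 -181.2541 370.5082  143.4117    0.3053
   interval     5 -173.3432 358.6864  131.5899    0.3356

median marginal means (kg):
    at  mean lower upper span letters
 early 41.69 41.30 42.08 0.78       a
  late 38.63 38.27 38.99 0.72       b

uneven marginal means (kg):
    at  mean lower upper span letters
 early 42.41 42.00 42.83 0.83       a
   mid 40.44 40.16 40.72 0.56       b
  late 37.35 36.98 37.71 0.73       c

interval marginal means (kg):
    at  mean lower upper span letters
 50–55 43.28 42.40 44.18 1.77       a
 55–60 41.33 41.07 41.59 0.51       b
 60–65 38.77 38.46 39.07 0.61       c
 65–70 35.60 34.93 36.28 1.35       d
 70–75 34.41 32.72 36.17 3.45       d
```

Reading it: the continuous model fits best by a wide AIC margin
(ΔAIC ≥ 130 for every categorized rival) and explains the most variance
(0.58 vs 0.17–0.34). Every extra category widens the confidence spans of
the sparse outer groups (compare the earliest-category spans 0.78 →
0.83 → 1.77 kg across median → uneven → interval), and the letter
displays show interval categories "65–70" and "70–75" are statistically
indistinguishable — the categorized analysis cannot say where in the
season the mass cost accrues, only that late is worse than early.

The power cost of a median split, in its classical Gaussian setting:

```r
dichotomization_efficiency(n = 1000, reps = 2000, seed = 1)
```

```
Dichotomization efficiency experiment
  family: gaussian   n = 1000   reps = 2000   effect = 0.1
  estimated fraction of data lost: 0.364 (MC se 0.0075)
  analytic value for a median split of a normal predictor: 1 - 2/pi = 0.363
```

Dichotomizing at the median discards about a third of your sample.

Other entry points: `sample_size_study()` (same timing range, n = 120 /
80 / 20), `replicate_study()` (seeded Monte Carlo over all of the above),
`gamma_smooth()` + `smooth_curve()` (penalized-spline fits),
`tally_review()` (literature-audit tallies), and CSV/YAML/JSON I/O in
`write_dataset()` / `read_run_config()` / `write_provenance()`.

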