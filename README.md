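# divergesize

Why are dietary specialists over-represented among the smallest and the
largest terrestrial mammals, and scarce at intermediate body sizes?
`divergesize` packages both halves of the answer for ecologists and
macroevolutionary biologists:

1. **A consumer-resource competition model.** A specialist $x_1$ and an
   equal-sized generalist $x_2$ compete over two resources,

   $$\dot r_1 = R_1 - g r_1 x_1 - \alpha g r_1 x_2, \qquad
     \dot r_2 = R_2 - \alpha g r_2 x_2,$$
   $$\dot x_1 = \kappa g r_1 x_1 - m_1 x_1, \qquad
     \dot x_2 = \kappa \alpha g (r_1 + r_2) x_2 - m_2 x_2,$$

   with per-capita mortality $m_i = b^{k_i} d(b)$ combining an allometric
   home range $h_i = b^{k_i}$ ($k_1 > k_2$: the specialist's slope is
   steeper) and an S-shaped per-area death rate
   $d(b) = 1 - e^{-\gamma e^{-b^\beta}}$. The equilibrium specialist
   frequency $f^*$ has a closed form in which $d(b)$ and $\kappa$ cancel;
   the package provides the closed-form equilibria, Jacobian stability,
   stiff integration of quasi-stable transients spanning up to ~1e12 time
   units, body-mass and parameter sweeps, and a three-consumer extension
   (meat and plant specialists plus a generalist).

2. **An empirical macroecology pipeline.** Diet-breadth and primary-diet
   classification from ten EltonTraits-style diet categories, body-mass
   quantile bins with Clopper-Pearson (or Wilson) binomial confidence
   intervals flagged against pooled or realm-specific null expectations,
   one-sided Kolmogorov-Smirnov comparisons between diet groups,
   median-split size covariates, and a closed-form phylogenetic GLS with
   Brownian covariance as a frequentist analogue of Bayesian phylogenetic
   multilevel regressions.

A synthetic trait-table generator (skewed mass spectrum over seven orders
of magnitude, U-shaped specialist probability with configurable amplitude,
realm occupancy, Yule trees with tunable phylogenetic signal in mass)
makes the entire pipeline testable offline with known ground truth.

## Worked example

```r
library(divergesize)

p <- model_params(b = 100)            # 100 g competitors, reference defaults
specialist_equilibrium_frequency(p)
#> [1] 0.1640294
coexistence_boundary_mass(p)          # specialist persists only below this
#> [1] 411.5226
frequency_at_time(p, t_query = 1e3)   # numerical ODE solution agrees
#> [1] 0.1640294
time_to_equilibrium(p, t_max = 1e5)$t_eq
#> [1] 14.74397

eq <- coexistence_equilibrium(p)
jacobian_stability(p, eq)$stable
#> [1] TRUE
```

At 100 g the specialist settles at 16.4% of total consumer abundance; the
same call at `b = 1e4` returns 0 (exclusion), yet `frequency_at_time()`
at `t = 1e3` for `b = 3e6` still returns ~0.58 — the quasi-stable
coexistence of very large specialists, whose exclusion takes ~10 decades
longer than at squirrel size.

The empirical half, on a synthetic table with a built-in U-shape:

```r
synth <- generate_trait_table(synth_config(n_species = 3487, seed = 1))
mean(classify_specialist(synth$traits) == "specialist")
#> [1] 0.340694
bins <- bin_specialist_proportions(synth$traits, n_bins = 20)
head(bins[, c("bin_index", "n_species", "proportion",
              "ci_low", "ci_high", "deviation")], 4)
#>   bin_index n_species proportion ci_low ci_high deviation
#> 1         1       175      0.549  0.472   0.624     above
#> 2         2       174      0.385  0.312   0.462      none
#> 3         3       175      0.309  0.241   0.383      none
#> 4         4       174      0.408  0.334   0.485      none
```

The smallest-mass bin is flagged `above` the pooled null (34.1% here):
its 95% interval lies entirely above it, exactly the diverging pattern
the generator planted. `run_replication()` writes the full set of
analysis tables (global bins, per-realm bins, diet-group bins, KS table,
mass sweep, timescales) as CSVs with a version-and-seed header. Real
trait tables enter through `read_trait_table()`, with a column map for
EltonTraits-style exports.

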