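---
title: "Specialist-generalist coexistence across the body size spectrum: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specialist-generalist coexistence across the body size spectrum: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divergesize)
```

## The scientific question

Terrestrial mammals span about seven orders of magnitude in body mass, and
the proportion of dietary specialists (species consuming a single one of
the ten standard diet categories) is not uniform across that spectrum: it
is comparatively high among the smallest and largest species and low at
intermediate sizes. `divergesize` implements the two complementary tools
needed to study this pattern: a mechanistic consumer-resource model that
explains *why* specialists fare better at extreme sizes, and an empirical
pipeline that quantifies the pattern in trait data.

## The competition model

Two resources and two consumers of equal body mass $b$ interact through

$$
\begin{aligned}
\dot r_1 &= R_1 - g r_1 x_1 - \alpha g r_1 x_2, &
\dot r_2 &= R_2 - \alpha g r_2 x_2,\\
\dot x_1 &= \kappa g r_1 x_1 - m_1 x_1, &
\dot x_2 &= \kappa \alpha g (r_1 + r_2) x_2 - m_2 x_2,
\end{aligned}
$$

where $x_1$ is the specialist (only resource 1, at rate $g$) and $x_2$ the
generalist (both resources, at the discounted rate $\alpha g$,
$0<\alpha<1$). Mortality couples the system to body mass through two
allometries: home range $h_i = b^{k_i}$ with a steeper slope for the
specialist ($k_1 > k_2$), and an S-shaped per-unit-area death rate
$d(b) = 1 - e^{-\gamma e^{-b^\beta}}$ that falls from ~1 for tiny animals
to ~0 for giants. Per-capita mortality is their product,
$m_i = b^{k_i} d(b)$.

Time, resources and abundances carry arbitrary units throughout; only $b$
has a unit (grams). The reference parameterization is
$k_1 = 0.9$, $k_2 = 0.7$, $\alpha = 0.2$, $\beta = 0.25$, $\gamma = 100$,
$g = 1$, $\kappa = 100$, $R_1 = 1$, $R_2 = 0.5$ — the defaults of
`model_params()`.

### Equilibria and what cancels out

Setting the rates to zero yields two closed-form equilibria
(`generalist_only_equilibrium()`, `coexistence_equilibrium()`). The
coexistence equilibrium exists when
$b^{k_2} R_1 > \alpha\, b^{k_1} (R_1 + R_2)$
(`coexistence_condition()`), i.e. below the boundary mass
$b^* = (\alpha (R_1+R_2)/R_1)^{1/(k_2-k_1)}$, about 411.5 g under the
defaults. The equilibrium specialist frequency

$$
f^* = \frac{b^{k_2} R_1 - \alpha b^{k_1}(R_1+R_2)}
           {b^{k_2} R_1 - \alpha b^{k_1}(R_1+R_2) + b^{k_1} R_2}
$$

depends on neither $\beta$, $\gamma$ nor $\kappa$: both consumers share
the same body mass, so the per-area death rate and the conversion
efficiency cancel. The package treats this as a tested invariant — the
mortality-shape parameters move only the *timescale* of competition, and
the allometric $\kappa(b) = C_0 b^{b_0} C_1 b^{b_1}/(C_0 b^{b_0} + C_1
b^{b_1})$ alters transients but never $f^*$. No canonical values for
$C_0, b_0, C_1, b_1$ ship with the package; they are user-supplied.

```{r}
p <- model_params(b = 100)
specialist_equilibrium_frequency(p)
coexistence_boundary_mass(p)
```

Where the coexistence condition fails, `specialist_equilibrium_frequency()`
returns exactly 0 (the specialist is excluded);
`specialist_frequency_raw()` exposes the untruncated — possibly negative —
closed-form value for diagnostics. Local stability is classified from the
analytic Jacobian (`jacobian_matrix()`, validated against central finite
differences in the test suite); analytic partials avoid finite-difference
step-size fragility across seven orders of magnitude of $b$.

## Numerics: stiff transients and quasi-stability

`integrate_dynamics()` wraps `deSolve::ode(method = "lsoda")` on a
logarithmically spaced output grid. That choice is essential: near the
large-mass end ($b \sim 3\times10^6$ g) mortality rates fall to
$\sim 10^{-12}$ while resource turnover remains $O(1)$, so the system
mixes timescales separated by more than twenty orders of magnitude and
exclusion takes $\sim 10^{11}$ time units. Default tolerances are
`rtol = 1e-8`, `atol = 1e-12` (both configurable); halving them moves the
frequency at $t = 10^3$ by less than $10^{-6}$. Abundances that undershoot
zero by round-off (beyond $-10^{-8}$ a warning is raised) are clipped to
zero. The per-area death rate uses `-expm1(...)` so that rates as small as
$10^{-42}$ survive double precision instead of rounding to zero.

`time_to_equilibrium()` reports the first output-grid time from which the
specialist frequency stays within $\varepsilon$ of its analytic target for
the rest of the horizon. The equilibrium criterion is not canonical, so
$\varepsilon$ is a first-class knob (default $10^{-3}$ on frequency) and
every result carries the $\varepsilon$ used. Under the defaults the
time-to-equilibrium curve is S-shaped in mass: minimal near $10^3$ g and
about ten decades longer for elephant-sized ($3\times10^6$ g) than
squirrel-sized (300 g) competitors — which is why large specialists,
although doomed at equilibrium, persist at nearly constant frequency for
ecologically unbounded times (quasi-stability).

Initial conditions default to resources at their replenishment rates and a
total consumer abundance of 1 split by `init_freq` (default 0.5).
Equilibrium outcomes are initial-condition independent; the test suite
asserts that the time to equilibrium moves by less than 20% across a
100-fold change in initial total abundance.

### The three-consumer extension

`integrate_extended()` adds a second specialist so that a meat-based and a
plant-based resource each have a dedicated consumer alongside the shared
generalist. The construction mirrors the core model (strategy-specific
home-range exponents, shared $d(b)$); with the plant specialist absent it
reduces exactly to the two-consumer system, a reduction the tests verify
to solver tolerance. The combined specialist frequency reproduces the same
extremes-over-middle pattern at quasi-stability.

## The empirical pipeline

The pipeline consumes a trait table (one row per species: body mass in
grams, ten EltonTraits-style diet-share columns, eleven realm occupancy
flags, optional taxonomic order; `read_trait_table()` adapts foreign
headers through a column map). Classification follows the field's binary
convention: a species is a *specialist* when exactly one diet category has
a share strictly above zero (`count_diet_types()` exposes a minimum-share
cutoff as a sensitivity knob, since trait databases do not state one), and
the *primary diet* is carnivore/herbivore/omnivore according to which side
of the animal/plant divide is consumed.

`bin_specialist_proportions()` partitions species into body-mass quantile
bins (20 bins of 5% for global analyses, 10 bins of 10% for regional
ones). Species are ranked by (log10 mass, species name) with a stable
sort, and bins are contiguous rank blocks differing in size by at most
one; the name tie-break makes the binning deterministic under row
permutation despite heavy mass ties in real databases. Each bin gets a
binomial confidence interval — Clopper-Pearson by default, matching the
exact binomial-test convention, Wilson as an option, the method recorded
in the output — and a deviation flag relative to a null expectation: the
pooled specialist proportion of the table (or of each realm subset for
regional runs). A bin is `above`/`below` when its interval excludes the
null. With the pooled null, the abundance-weighted mean of bin proportions
equals the null exactly, which the tests assert.

One-sided Kolmogorov-Smirnov comparisons between diet groups use the
statistic $D = \sup_t [F_x(t) - F_y(t)]$ evaluated over pooled sample
points, with the caller stating which sample is hypothesized
stochastically smaller; the p-value uses the one-sided asymptotic formula
$e^{-2D^2 nm/(n+m)}$. The implementation is checked against both a
brute-force double loop and `stats::ks.test`. Island-dominated realms
(Oceanian, Madagascan) can be excluded for continental comparisons via
`exclude_island_only()`; `median_split_covariates()` builds the body-size
covariates (absolute deviation from the median log mass, with ties
assigned to the lower half).

## The phylogenetic regression analogue

Body size carries strong phylogenetic signal, so naive regressions of diet
breadth on size covariates are confounded by shared ancestry. The package
provides a deliberately frequentist treatment: `brownian_vcv()` builds the
Brownian-motion covariance (shared root-to-MRCA path lengths) from a tree,
and `gls_fit()` solves the generalized-least-squares problem in closed
form under that fixed covariance ($\lambda = 1$), reporting 5-95%
intervals from the asymptotic covariance. This is an *analogue* of a
Bayesian multilevel phylogenetic regression, not a reproduction of any
posterior: the scientific content — the sign and interval of the
coefficient — is what the design targets, and pinning the package to one
MCMC engine would buy no additional insight. There is consequently no
Pagel's-lambda optimization and no sampler. Near-singular covariance
matrices (e.g. from zero-length branches) receive a $10^{-10}$ diagonal
ridge when the smallest eigenvalue drops below $10^{-12}$.
`gls_fit_trees()` repeats a fit over a collection of trees (mirroring
validation against posterior tree samples), and `phylo_signal_variance()`
summarizes signal as the ratio of Brownian-scaled to raw residual
standard deviation.

## The synthetic generator: what it emulates, and what it does not

`generate_trait_table()` produces trait tables with the statistical
structure the pipeline assumes, so every stage is testable with no
download:

* **Mass spectrum.** A skew-normal marginal on log10 mass (location 0.9,
  scale 1.6, shape 5), clipped to [1.75, 3.9e6] g. These values were
  chosen once so that a ~3,500-species draw has its median near 100 g and
  spans roughly seven orders of magnitude with only light clipping at the
  bounds, mirroring the published mammalian spectrum.
* **Phylogenetic signal.** A Yule tree (`ape::rphylo`) plus Brownian
  motion, blended with independent noise by a `signal_strength` weight and
  rank-mapped (copula-style) onto the skewed marginal. Rank-mapping makes
  tip ranks invariant to the Brownian rate, so a mixing weight — not a
  rate — is the honest control of signal strength; it also decouples
  marginal shape from tree structure, which real data do not guarantee.
* **Specialization.** Specialist status is drawn per species with
  probability $p(q) = p_{mid} + A(2q-1)^2$ of its mass quantile $q$. The
  defaults $p_{mid} = 0.25$, $A = 0.25$ give a pooled expectation of
  $p_{mid} + A/3 = 1/3$, matching the observed pooled specialist
  proportion of about a third.
* **Diets.** Specialists place 100% in one category; generalists spread a
  positive integer composition of 100 over 2-6 categories. The
  carnivore/herbivore/omnivore weights are *overall* target margins
  (default 0.276/0.336/0.388, the observed composition): because
  specialists cannot be omnivores, the generalist mixture is solved so the
  realized composition matches the margins in expectation.
* **Realms.** Independent Bernoulli occupancy with per-realm
  probabilities loosely tracking published realm richness; species drawing
  no realm are resampled, which inflates realized richness by a known
  ~30% relative factor (the tests bound it).

A single integer seed drives all stages: stage sub-seeds are drawn once
from it, so a configuration is byte-reproducible. What the generator does
*not* emulate: real taxonomic names, realm geometry, correlation between
mass and realm membership, and clade-structured diet or order membership
(synthetic order labels are random). Pipeline tests passing on synthetic
tables therefore demonstrate the *machinery* — binning, intervals, flags,
GLS — under known ground truth; they do not certify any empirical claim
about mammals, which requires the real trait dataset as input.

## Problem sizes and reproducibility

The test-suite and acceptance computations use: long integrations to
$t = 10^6$ for equilibrium agreement (to $10^{14}$ horizon for
time-to-equilibrium); a 40-point log-mass grid for the timescale curve; a
100-point (25 masses x 4 $\alpha$) stability grid; 50 generator seeds at
3,500 species for U-shape recovery; 100 replicates at 200 tips for GLS
coverage. `run_replication()` writes every stage as CSV with a
version-and-seed header; the model half is deterministic and reruns are
byte-identical.

## Known limitations

* The model treats a single body mass per scenario; competition between
  unequal-sized consumers is out of scope, as are stochastic
  (demographic-noise) and spatially explicit variants.
* Equilibria come from the closed forms; there is no bifurcation
  continuation, which is adequate because the system has only the two
  equilibria used.
* The GLS analogue fixes the Brownian correlation ($\lambda = 1$); traits
  with weaker-than-Brownian structure will get conservative intervals.
* Realm membership is consumed as input flags; no GIS intersection of
  range maps is performed, and taxonomy reconciliation beyond normalized
  string matching is out of scope.
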