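---
title: "Neighbourhood species mingling by tree size: models, null models, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neighbourhood species mingling by tree size}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(treemingle)
```

## The question and the two statistics

Negative conspecific density dependence predicts that as trees grow, their
surviving neighbourhoods become more heterospecific: crowded conspecific
recruits die preferentially, and the gaps are filled by other species. In a
fully stem-mapped plot this hypothesis has a spatial signature — large trees
should show higher *species mingling* than small trees — and `treemingle`
implements the two complementary statistics that detect it.

**Nearest-neighbour mingling.** For reference tree $i$ with $k$ nearest
neighbours (conventionally $k = 4$),

$$M_i = \frac{1}{k}\sum_{j \in \mathrm{nn}_k(i)} \mathbf{1}(m_j \neq m_i),$$

where $m$ is the species mark. For $k = 4$, $M_i \in \{0, 0.25, 0.5, 0.75,
1\}$. Because trees with *no* heterospecific neighbour are typically a small
minority, the two lowest levels are pooled into $\{0, 0.25\}$ before any
level-wise comparison. The association between size and mingling is tested
by two-sided Wilcoxon rank-sum tests on dbh between every pair of grouped
levels, Holm-adjusted, and summarised by compact letters
(`dbh_mingling_test()`); the joint structure is visualised as a set of
Gaussian-kernel dbh densities, one per grouped level, weighted by level
frequency (`mingling_dbh_density()`).

**Cumulative mark mingling functions.** Fixed-$k$ indices ignore scale. The
second-order view uses the mingling indicator as the test function of a
cumulative mark correlation statistic. With translation edge-correction
weights $\omega_{ij} = ab\,/\,\big((a - |\Delta x|)(b - |\Delta y|)\big)$
for an $a \times b$ window, the package computes

$$\hat K_m(r) = \frac{1}{\hat\lambda^2 A} \sum_{i}\sum_{j \neq i}
  \mathbf{1}(m_i \neq m_j)\,\mathbf{1}(\|x_i - x_j\| \le r)\,\omega_{ij},$$

and, removing the unmarked spatial structure, the mark mingling function

$$\hat k_m(r) = \frac{\sum_i \sum_{j\neq i} \mathbf{1}(m_i \neq m_j)\,
  \mathbf{1}(\|x_i-x_j\| \le r)\,\omega_{ij}}
  {\sum_i \sum_{j\neq i} \mathbf{1}(\|x_i-x_j\| \le r)\,\omega_{ij}}
  \in [0, 1],$$

the edge-corrected proportion of heterospecific ordered pairs within
distance $r$ of the reference trees. Reference trees $i$ may be restricted
to a dbh size class $d$; partner trees $j$ always range over the whole
pattern, because the question is "what surrounds a class-$d$ tree", not
"what surrounds it within its own class". The class-conditional curve can be
normalized by the expected mingling of the class under random species
arrangement,

$$EM_d = \sum_{s} \frac{n_{ds}\,(n - n_s)}{n_d\,(n - 1)},$$

with $n_s$ the abundance of species $s$, $n_d$ the class size and $n_{ds}$
the species count inside the class, so that independent marking gives values
fluctuating around 1. Finally, size-class contrasts use the difference of
**non-normalized** curves, $\Delta \hat k_v(r) = \hat k_{v,\mathrm{hi}}(r) -
\hat k_{v,\mathrm{lo}}(r)$: positive values mean the larger class has the
more heterospecific neighbourhood within $r$.

## Size classes

The default scheme is small $[5, 10)$ cm, medium $[10, 25]$ cm, large
$(25, \infty)$ cm. The boundary convention is deliberate: interior
breakpoints other than the last are attained by the class above
(`dbh >= 10` is medium), while the top breakpoint is strict (`dbh > 25` is
large), so "large" always means strictly above the top break. Two-class
schemes (e.g. split at 25 cm for the simulated stand) follow the same rule.
Classification is a partition: every dbh at or above the census threshold
receives exactly one class, which the test suite verifies on a dense dbh
grid.

## Null models and envelopes

Mingling statistics conflate two things: genuine mark–location dependence
and plain abundance/size-distribution structure. Both null models therefore
*retain every (species, dbh) pair* and randomize only locations:

* **Homogeneous Poisson** (`randomize_homogeneous()`): uniform independent
  relocation, conditioned on the observed tree count. Destroys all spatial
  structure; appropriate for simulated stands built on homogeneous Poisson
  locations.
* **Heterogeneous Poisson** (`randomize_heterogeneous()`): each species is
  relocated according to its own smoothed intensity surface
  $\hat\lambda(x, y)$, conditioned on the observed per-species counts. This
  removes tree-to-tree interaction structure while preserving habitat-scale
  aggregation, and is the default for real multi-species plots.

The intensity surface is a moving-window estimate: a uniform disc of radius
20 m (the scale below which tree–tree interactions are typically confined),
evaluated on a 1 m grid, with the disc clipped to the window near borders
(local edge correction) and the surface rescaled so its integral equals the
species count exactly. The disc kernel is the literal reading of a "moving
window with radius r"; smoother kernels would change little at this
bandwidth. Border-cell clipped areas use a 400-panel trapezoid quadrature of
the chord length, which is accurate to well below the estimator's
Monte-Carlo noise. Relocation samples a grid cell proportionally to
$\hat\lambda \cdot \text{cell area}$ and then places the tree uniformly
within the cell.

`mingling_envelope()` runs `nsim` replicates (default 1000) and returns the
pointwise 2.5%/97.5% empirical quantiles, the pointwise mean (the dotted
"expected under independent marking" line), and its standard error.
Replicates are seeded from per-replicate substreams derived from one master
seed, so results are reproducible and increasing `nsim` never changes
earlier replicates. Grid points where a replicate's statistic is undefined
(no admissible pair) are dropped from that point's quantile pool, and the
count of defining replicates is reported.

**Limitation:** the envelopes are pointwise. At one pre-chosen distance the
band is an approximate 95% interval — the suite calibrates this on CSR
patterns with independent marks — but scanning the whole curve for *any*
excursion inflates the global type-I error. No global rank envelope is
implemented.

## The dependent-marking generator

`simulate_dependent_marking()` builds the fully specified two-species test
stand: homogeneous Poisson locations at $\lambda = 0.1$ trees/m² in a
100 × 100 m window; species 1 where the second-nearest-neighbour distance
is below $r_0 = 2.5$ m, species 2 otherwise (aggregating conspecific
"common small" trees; for Poisson patterns the species-2 fraction has the
closed form $e^{-\lambda\pi r_0^2}(1 + \lambda\pi r_0^2) \approx 0.416$,
which the suite checks); dbh normal with means 20 and 30 cm per species,
truncated below at the 5 cm census floor; and finally every tree with dbh
above 25 cm forces its nearest neighbour to the other species, planting
heterospecific neighbourhoods around large trees.

Choices the construction leaves open were fixed once:

* **dbh standard deviation 5 cm** for both species. The construction needs
  species 1 mostly at or below 25 cm and species 2 mostly above; 5 cm
  achieves that while keeping realistic overlap.
* **Step-4 order**: trees are processed in ascending id order and later
  reassignments override earlier ones; the reference tree's *current*
  species is used, so the rule stays well-defined when a reference was
  itself flipped. Any fixed order yields the same qualitative structure;
  this one is deterministic and seed-reproducible.
* **Poisson count**: the number of trees is drawn as Poisson($\lambda A$)
  — a literal homogeneous Poisson process — with `fixed_n` available to
  condition on an exact count.

`simulate_community()` emulates multi-species plots: per species a
Thomas-type cluster process (Poisson parents at 15/ha by default, Gaussian
offspring displacements with 5 m sd, torus-wrapped, conditioned on the
requested abundance) with species-specific truncated-normal dbh. It
reproduces the two features that drive community-level mingling behaviour —
conspecific clustering and species-specific size distributions — but not
others found in real plots (habitat gradients, size-dependent thinning
within species, canopy gaps). Passing tests on these generators therefore
validate the *machinery*, not any ecological claim about a particular
forest.

## Numerical choices

* Distance grids exclude zero (no self-pairs; coincident stems contribute
  at the first positive grid point). The default grid is 0.25–30 m in
  0.25 m steps — covering the scales where interactions are reported while
  staying well below the window's shorter side, which also guarantees every
  admissible pair has a defined translation weight.
* The distance condition is a closed ball, $\|x_i - x_j\| \le r$.
* Neighbour ties in $k$-NN queries are broken by ascending tree id —
  deterministic and input-order independent.
* Curve values with an empty denominator are `NA` (undefined), never zero.
* Pair sums run in a small C++ kernel (ordered pairs binned by distance,
  then cumulated); the test suite holds it to 1e-12 agreement with a plain
  double-loop enumeration over dozens of random patterns.
* Rank-sum tests use the exact null distribution for small untied samples
  and the tie-corrected normal approximation otherwise; Holm's method
  adjusts the (at most six) pairwise comparisons — it is assumption-free,
  which suits the unplanned nature of level-wise contrasts. The compact
  letters are maximal sets of mutually non-distinguishable levels.
* The "bivariate" dbh × mingling density treats mingling as a discrete
  factor (a 2-D kernel over a five-valued axis is ill-posed); the shared
  dbh bandwidth defaults to Silverman's rule.
* Every tree serves as an $M_i$ reference, including border trees whose
  true neighbours may lie outside the plot — a known, documented bias of
  fixed-$k$ indices; the second-order statistics are edge-corrected and do
  not share it.

## Problem sizes used by the checks

The packaged checks run the generator at its native conditions
(about 1000 trees/ha) with 199-replicate envelopes for stability runs and
one 1000-replicate envelope for the headline reproduction; envelope
calibration uses 200 trials of 300-tree patterns with 199 replicates each;
oracle comparisons sweep 50 random patterns of up to 200 trees. These sizes
give Monte-Carlo error comfortably inside the stated tolerances.

## A worked example

```{r example, eval = FALSE}
set.seed(1)
stand <- simulate_dependent_marking(seed = 1)
scheme <- size_scheme(c(5, 25), c("small", "large"))
grid <- r_grid(15, 0.5)

env_small <- mingling_envelope(
  stand, function(p) mingling_function(p, grid, scheme, "small"),
  null = "homogeneous", nsim = 199, seed = 2)
plot(env_small, ylab = "k_m(r), small trees")

env_delta <- mingling_envelope(
  stand, function(p) mingling_difference(p, grid, scheme, "large", "small"),
  null = "homogeneous", nsim = 199, seed = 2)
plot(env_delta, ylab = "delta k_v(r), large - small")
```

The small-tree curve falls below the lower envelope at short range
(conspecific aggregation) and the large-minus-small difference rises above
the upper envelope (large trees carry the more heterospecific
neighbourhoods) — the designed behaviour of the generator, recovered by the
estimators.

## Known limitations

* Rectangular windows only; no polygonal plots or geographic coordinates.
* Pointwise envelopes (no global test, no MAD/DCLF summaries).
* No bivariate (size × species) mark correlation functions.
* The fixed-$k$ mingling index has an uncorrected border bias.
* The heterogeneous null treats the estimated intensity as fixed; its
  estimation uncertainty is not propagated.
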