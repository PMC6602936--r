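---
title: "Landscape resistance modelling with resistkit: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landscape resistance modelling with resistkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resistkit)
```

## The inference problem

Individual-based landscape genetics asks which landscape features shape
gene flow. The data are multilocus genotypes of georeferenced individuals;
the hypotheses are *resistance surfaces* — rasters assigning every cell a
cost to movement — and the currency connecting the two is the pairwise
distance matrix. resistkit implements the full chain:

1. **Genetic distance.** The proportion of shared alleles across loci,
   `Dps = 1 - shared / (2 L)`, turned into an individual-by-individual
   distance matrix with pairwise deletion of missing loci.
2. **Effective resistance.** Each candidate surface becomes a conductance
   graph (cells are nodes, 8-neighbour edges, edge resistance the mean of
   the two cell resistances, `sqrt(2)`-scaled on diagonals). Pairwise
   effective resistance between individuals is computed by sparse
   Laplacian solves; it integrates over all paths, unlike least-cost
   distance.
3. **Inference on distance matrices.** Mantel and partial Mantel tests
   with permutation inference, multiple regression on distance matrices
   (MRM) with AICc ranking and variance inflation factors, and sequential
   Bonferroni (Holm) correction.
4. **Causal modelling.** A candidate is accepted only if it explains
   genetic distance *after* removing the isolation-by-resistance (IBR)
   null — a uniform surface of ones, carrying only study-area geometry —
   *and* the null explains nothing after removing the candidate.
   Competing candidates are compared by relative support,
   `RS = r(GD ~ M1 | M2) - r(GD ~ M2 | M1)`.
5. **Corridors.** For the selected model, per-cell cumulative current over
   all focal pairs marks likely movement corridors.

## Resistance transformations

Two families cover the variables handled here. Classified features
(rivers, roads, a land-cover class) map feature cells to `R_max` and
everything else to 1. Continuous variables use a deviation-power form

\[ R(v) = 1 + (R_\mathrm{max} - 1)\,\Delta(v)^x, \]

where `Δ` is the deviation from an optimum value normalized to `[0, 1]` —
circular for aspect (angular distance / 180), absolute deviation scaled by
the raster's maximum deviation otherwise. `R_max` sets the magnitude of
the effect and `x` its contrast; `R_max = 1` collapses to the IBR surface
for any `x`. The printed optimum (e.g. aspect 90°, slope 15°, elevation
500 m) is interpreted as the minimum-resistance value. The default search
grid is `R_max ∈ {2, 10, 100, 1000}` and, for the continuous family,
`x ∈ {0.5, 1, 2, 5, 10}` with the optimum fixed — spanning the
magnitudes that landscape studies of large mammals typically report.
Whether a printed slope value is an optimum or an inflection is ambiguous
in general; resistkit models it as an optimum, and the `max_dev` and
`circular` fields of `transform_spec()` expose the alternative readings.

## Permutation schemes and numerical choices

* **Mantel**: Pearson correlation of lower triangles; rows and columns of
  the first matrix permuted jointly; one-tailed upper P by default, since
  resistance hypotheses predict positive association. `exact = TRUE`
  enumerates all `n!` permutations for `n ≤ 7`.
* **Partial Mantel**: both matrices are residualized on the conditioning
  matrix; the residuals of the first are folded back into a symmetric
  matrix and its rows/columns permuted (residual-permutation method).
  Schemes differ in type-I behaviour, so the method is fixed and recorded
  rather than configurable-by-accident.
* **MRM**: OLS on lower-triangle vectors; the response matrix is permuted
  for coefficient and overall P; standardized betas from z-scored vectors;
  `VIF_j = 1/(1-R²_j)`. AICc uses the `n(n-1)/2` pairs as its effective
  sample size with `k = p + 2`. Distance pairs are not independent, so
  this AICc is a ranking heuristic (the common MRM practice), not a
  calibrated likelihood criterion; it is only ever used to compare models
  of the same response.
* **HWE screen**: permutation test with observed heterozygosity as the
  statistic and a two-sided (doubled-tail) P, so both homozygote excess
  (null alleles) and heterozygote excess (negative F_IS) register. The
  null-allele frequency uses the homozygote-excess estimator
  `(He - Ho)/(1 + He)`; a locus is excluded when the estimate exceeds
  0.05 *and* its Holm-adjusted HWE P is significant.
* **Circuit solver**: one node grounded, sparse Cholesky factorization of
  the reduced Laplacian shared across all focal injections. Cells hosting
  several individuals are solved once; coincident individuals get zero
  effective resistance rather than being merged, keeping the matrix
  aligned with the genotype table. The dense pseudoinverse appears only in
  test oracles.

## Model selection procedure

Univariate optimization evaluates every parameterization of a variable by
the partial Mantel r of genetic distance against its resistance distances,
partialling out IBR; the best significant parameterization wins and the
full ranking is retained. The two-step causal test then decides support.

The multivariate stage composes surfaces by cell-wise summation and
proceeds in rank order. Two design points deserve a note, because the
obvious alternatives fail in predictable ways:

* **The first pair is optimized over the joint parameter grid.** The
  objective surface often has a ridge along which both variables must
  strengthen together; coordinate-wise alternation started at the
  univariate optima can stall at weak parameterizations of both variables
  (each single-variable move makes the composite worse). The joint grid is
  small — the product of two univariate grids — so the exhaustive scan is
  cheap and removes the stall.
* **Later variables are judged at their univariate-best parameters.**
  Re-optimizing a candidate's parameters on the same objective *before*
  the reduced-model test inflates the test's acceptance rate (the test
  statistic is then a maximum over the grid), which lets uninformative
  variables into the model. Tuning happens only after a variable has
  passed tests (3) and (4): full-model-given-reduced significant,
  reduced-given-full not.

α is 0.05 throughout. A candidate identical to the IBR matrix is rejected
as degenerate before testing. When predictors are collinear (the
rivers-versus-roads situation on real landscapes), `mrm_model_select()`
refits dropping each member of the worst pair and ranks the model set by
AICc with Akaike weights.

## The simulator: what it emulates and what it does not

`make_landscape()` builds smooth correlated elevation (moving-average
filtered Gaussian noise), derives slope and aspect by central finite
differences, and rasterizes vertical river and horizontal road lines one
cell wide. `deme_model()` places a Wright–Fisher deme of `n_e = 50`
diploids on every cell; migration on each 8-neighbour edge is
`m_max · c_e / max(c)`, exactly proportional to the edge conductance of a
chosen *true* resistance surface, so the spatial genetic structure that
accumulates is, in expectation, the structure the circuit model assumes.
Mutation is stepwise (±1 repeat, `μ = 5·10⁻⁴`) on 13 microsatellite loci
with founders drawn uniformly from 8–20 repeats — the marker count and
diversity scale of a typical large-mammal microsatellite panel.

The reference study condition is a 15 × 15 grid (1 km cells), 100
generations, `m_max = 0.1`, 150 sampled individuals. These values were
fixed by a design requirement of the method itself: causal modelling
assumes genetic distance responds approximately linearly to effective
resistance. Longer drift histories (or dense sampling that piles many
individuals onto few cells) push `Dps` into saturation, where even the
*true* generating model fails the second causal test — the residual
curvature masquerades as unexplained IBR signal. The chosen regime keeps
differentiation mild, which is also the biologically relevant situation:
the populations this analysis chain targets are weakly structured,
quasi-panmictic ones. `sample_from = "habitat"` draws individuals only
from cells below the geometric midpoint of the resistance range,
mirroring the fact that animals are not sampled on the barrier features
themselves.

The `"strong"` preset generates migration from rivers plus roads (both
classified, `R_max = 100`) — two geometrically independent barrier
systems — and keeps aspect available as a decoy; aspect is a
finite-difference derivative field whose fine-grained patches leave too
weak a circuit imprint at this grid size to serve as a reliable generator.
The `"weak"` preset (rivers, `R_max = 2`) and the `"ibd"` preset (uniform
surface) bracket the no-signal end.

What the simulator does **not** emulate: overlapping generations,
sex-biased dispersal (the sexes are assigned at random, so female
philopatry can only be *imitated* by sampling design, not generated),
coalescent-scale deep history, genotyping error, and spatially continuous
(non-deme) populations. Passing recovery tests on these presets therefore
shows that the inference chain is self-consistent on data meeting its own
assumptions — it does not certify performance on real landscapes, where
the migration–resistance link is looser and partial Mantel inference is
known to be fragile.

## Problem sizes used by the test suites

The packaged tests run the chain at deliberately small scales chosen as
the smallest sizes at which each property is statistically decidable:
circuit oracles on 5×5–6×6 rasters against a dense pseudoinverse; Mantel
calibration with 500 null replicates at n = 20; drift decay over 50
single-deme replicates (`N_e = 50`, G = 100); and parameter recovery over
10 strong-preset and 10 pure-IBD replicates at the reference condition
with 99-permutation tests (P resolution 0.01 at α = 0.05).

## Known limitations

* Partial Mantel tests have documented type-I inflation under spatial
  autocorrelation; the causal-modelling protocol inherits this. The
  package reports raw permutation P-values and leaves α to the user.
* The AICc for MRM is heuristic (non-independent pairs).
* Effective resistance is computed on the raster as given; no resampling,
  reprojection or multi-resolution support.
* The bootstrap CI of the correlogram resamples pairs within a distance
  class, which under-represents the dependence induced by shared
  individuals; it matches common practice but is approximate.
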