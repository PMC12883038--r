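---
title: "Spot-level co-localization inference: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spot-level co-localization inference: models, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spotcoloc)
```

## Scope and model

`spotcoloc` asks whether a *response* cell type is enriched in the spatial
neighbourhoods of a *target* cell type, given a spot table (2-D physical
coordinates) and a spot-by-cell-type composition matrix from upstream
deconvolution. The package does not deconvolve; it consumes proportions.

The observed statistic is the neighbourhood mean
$$M = \frac{1}{|T|}\sum_{t \in T} \frac{1}{k}\sum_{j \in N_k(t)} r_j,$$
where $N_k(t)$ are the $k$ nearest spots to target spot $t$ (Euclidean,
self excluded, exact distance ties broken by ascending spot index so every
run is deterministic) and $r$ is the response proportion field. The null of
spatial independence is simulated by permuting $r$ uniformly over spots
while coordinates, the target set and the graph stay fixed: the marginal
distribution of proportions is preserved, spatial arrangement is destroyed.
The enrichment ratio is $E = M/\overline{M}_{\text{perm}}$ with
$\overline{M}_{\text{perm}}$ the mean of the permuted statistics (not a
single permutation — the mean of the full null sample), and the one-sided
p-value uses the add-one rule $p = (1+m)/(1+n_{\text{perm}})$ with $m$ the
number of null means at or above $M$, which can never return an exact zero.

Permuting the *response vector* (targets fixed) rather than jointly
permuting all cell labels is an explicit choice: it matches the operational
definition of the statistic, keeps the target set — which on real data
comes from the same deconvolution — conditioned on, and makes the null
exactly exchangeable when the response field itself carries no spatial
structure. A joint label permutation would answer a different question
(arrangement of all identities at once) and is not implemented.

## Tunable parameters

| parameter | default | units / range | why |
|---|---|---|---|
| `k_grid` | 5, 10, …, 50 | neighbours | the conventional scan range for spot neighbourhood analysis; small k undersamples, large k dilutes |
| `delta_threshold` | 0.05 | ratio units | stability cutoff on consecutive \|ΔE\|; the point where the curve stops moving more than noise |
| `n_perm` | 1000 | permutations | resolves p down to ~1/1001 at tolerable cost |
| `alpha` (ssGSEA) | 0.25 | exponent on ranks | the canonical single-sample rank weight; configurable |
| `tau` / `tau_quantile` | — / 0.9 | proportion / quantile | spot-identity threshold and the top-decile target selector |
| `k_weights` (Moran) | k* | neighbours | reuse of the selected neighbourhood scale; never a fallback k* (the pipeline drops to the smallest grid k and flags it) |

**Stable-k selection.** $\Delta E_i = |E(k_i) - E(k_{i-1})|$ is attached to
the right endpoint $k_i$. The stable interval starts at the first $k_i$
with $\Delta E_i$ strictly below the threshold and ends at the last k
before $\Delta E$ next strictly exceeds it (or at the final grid point).
Within the interval, k* is the peak-E point, ties broken toward smaller k
(cheaper graphs, less dilution). If no $\Delta E$ falls below the
threshold, k* falls back to the global argmax of E and the curve carries an
explicit `fallback` flag — a fallback k* is reported prominently and never
silently reused as the Moran default.

**Spot identity.** The argmax rule labels every spot by its most abundant
cell type; the threshold rule labels a spot only when some proportion
reaches τ, leaving ambiguous spots unassigned. Ties break to the
lexicographically smallest cell-type name in both rules, which makes
labelling deterministic under permutation of columns. For co-localization
runs the pipeline also offers `target_selection: top_quantile` — targets
are the spots in the top decile of the target proportion. On synthetic
compositions built from bounded logistic weights against Gamma-distributed
filler types, no spot has the target as its argmax, so quantile selection
is the realistic analogue of "spots called iTRM by deconvolution".

## The synthetic generator: what it emulates and what it does not

`generate_spots()` produces a unit-spaced square lattice (Visium-like
packing, without the hexagonal offset) or uniform random positions on the
same extent. `generate_composition()` plants co-localization as follows:

- `z1`, `z2` i.i.d. standard normal per spot;
- latent **target** field `v`: `z1` smoothed by a Gaussian kernel of
  bandwidth `spatial_scale` (truncated at 4 bandwidths), standardized;
- latent **response** field `u = rho·v + sqrt(1 − rho²)·z2`;
- abundance weights `plogis(v)`, `plogis(u)` for target/response; filler
  cell types draw Gamma(2, 1) weights plus `noise_sd`-scaled Gaussian
  noise; rows normalize to proportions.

`cor(v, u) = rho` by construction, and the generator returns the latent
fields for parameter-recovery tests.

The key design choice is that the **idiosyncratic response component `z2`
is not smoothed**. If it were, the response field would be spatially
autocorrelated even at rho = 0, and the coordinate-preserving permutation
test — like every naive spatial shuffle — is anti-conservative against an
autocorrelated field: its null sample destroys smoothness that the observed
statistic retains. Under such a generator no parameter setting yields a
calibrated rho = 0 null. With `z2` unsmoothed, rho = 0 makes the response
exchangeable and the test exact; response smoothness then enters only
through the shared component, i.e. exactly through the co-localization
being tested. The test suite verifies this: rejection at α = .05 over 200
null replicates sits inside the binomial band [0.022, 0.086] and mean E is
within 1 ± 0.05.

Two calibration caveats are therefore explicit rather than hidden. First,
on real tissue the response field *does* have intrinsic autocorrelation,
so the permutation p-value is an optimistic lower bound there — Moran's I
is reported alongside precisely to expose that structure. Second, when
targets are themselves selected from the composition (top decile of the
target proportion), target selection and the response are weakly
negatively coupled through the shared row-normalization denominator; the
measured effect at rho = 0 is E ≈ 0.96 and a conservative rejection rate
(~0.01). The calibration study therefore draws targets independently of
the composition (a uniform 10% of spots), the regime where the null
hypothesis is true; power and monotonicity studies use the
deconvolution-style top-decile targets the pipeline uses.

Generator defaults are fixed once: `spatial_scale = 2` spot spacings
(niche-scale structure spanning a few spots, as deconvolved Visium fields
show), `n_celltypes = 5`, `noise_sd = 0.1`, square lattice. The generator
does not emulate hexagonal packing, platform-specific noise, segmentation
or deconvolution error structure, or multi-sample batch effects — so
passing tests demonstrate the statistics are correct and calibrated under
exchangeability, not that any particular deconvolution output is reliable.

## Signature scoring

`ssgsea_score()` implements the rank-weighted running sum: per sample,
genes are ranked by expression (average ranks at ties; positional order at
ties is by gene index, making scores reproducible), and the score is
$\sum_j (P^{in}_j - P^{out}_j)$ where $P^{in}$ steps by normalized
$\text{rank}^{\alpha}$ at in-set genes and $P^{out}$ uniformly at out-set
genes. Raw sums are returned; a cross-sample range normalization is
available but off by default since downstream use here is rank-based.
Signature genes missing from the matrix are dropped with a warning when at
least half remain, otherwise scoring errors out. `mean_score()` (plain mean
of signature-gene expression) is the default for spot-level maps: spots are
sparse and rank statistics on thousands of near-tied zeros are noisier than
the mean; ssGSEA is the default for bulk samples. Whether a survival-style
"signature score" should be ssGSEA or a mean score is left as a flag, both
being defensible readings.

`derive_signature()` applies strict thresholds (log2FC > 1, p < .05 by
default) preserving input order, and errors on an empty result rather than
returning a silent empty set.

## Composition statistics

Odds ratios use the pooled 2×2 construction per (cluster, group):
OR = ad/bc with the Haldane–Anscombe +0.5 on all cells when any is zero
(keeps OR finite and log-OR defined), Fisher's exact two-sided p on the
uncorrected table, and a depletion flag at OR < 0.5. Raw p-values are
reported without multiplicity correction — the flag is a conventional
effect-size cutoff, not an inference. Shannon equitability is
$H/\ln S$ with $S$ the size of the *declared* label universe, so a group
missing subpopulations scores lower even when its observed classes are
balanced; $S = 1$ is defined as 0.

## Numerical and degenerate-input policy

- All stochastic paths derive their streams from a master seed through a
  stage-label hash, so results are bit-reproducible and extending a k grid
  never perturbs earlier grid points.
- Constant response fields give E = 1, p = 1 exactly (ties count as ≥);
  constant fields are rejected before Moran's I or correlations with a
  `zero_variance` error rather than returning NaN.
- A permutation mean of zero with a nonzero observed mean signals a
  degenerate response field and errors.
- n = 2 Moran's I returns the closed form −1 with no permutation p.
- Composition rows must sum to 1 within 1e-6; duplicate coordinates are
  legal (distance-0 neighbours participate normally).
- Multi-sample spot tables are rejected by the pipeline; analyses run per
  tissue section, which is equivalent to within-sample stratification and
  simpler to reason about.

## Problem sizes in the test-suite studies

Oracle agreement uses exhaustive enumeration on instances of up to 7 spots
(all n! response permutations) against Monte-Carlo runs of 20 000
permutations; null calibration uses 200 replicate datasets of 400 spots
(k = 10, 200 permutations); power uses 100 datasets of 900 spots at
rho = 0.9 (k = 15) and a 50-seed sweep over rho ∈ {0, .3, .6, .9}. These
sizes give binomial confidence bands narrow enough for the stated
acceptance windows while keeping the full suite in the minutes range.

## Known limitations

- The permutation null ignores intrinsic spatial autocorrelation of the
  response; on real tissue treat p as anti-conservative and read it with
  the Moran diagnostics.
- Proportions are compositional; target selection by proportion induces
  mild negative dependence with every other proportion. E is therefore a
  ratio against the *permutation* expectation, not an absolute abundance
  effect.
- k-NN neighbourhoods are isotropic; anisotropic tissue architecture
  (layers, vessels) is summarized only through the k scan.
- No hexagonal-lattice adjacency, no local (LISA-type) Moran statistics,
  no multiple-testing correction across cell-type pairs.
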