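# spotcoloc

Spot-level spatial co-localization inference for deconvolved spatial
transcriptomics.

## The problem

Spatial transcriptomics platforms (Visium and similar spot-based assays)
measure mixed-cell expression at capture spots with known 2-D coordinates.
After deconvolution, each spot carries an estimated composition vector of
cell-type proportions. A recurring question in tumour-microenvironment work
is whether two cell populations — say an inflammatory tissue-resident
macrophage state and neutrophils — occupy the same spatial niches. Visual
co-occurrence is not evidence: spot proportions are compositional, noisy,
and spatially autocorrelated. `spotcoloc` provides the statistical machinery
to answer this question at the spot level, for analysts working downstream
of any deconvolution tool.

## The method

For a designated **target** cell type T and **response** cell type R:

1. **Neighbourhoods.** Each target spot's neighbourhood is its k nearest
   neighbours in physical space (Euclidean, focal spot excluded, distance
   ties broken by spot index). The observed statistic is the mean response
   proportion over target neighbourhoods:

   `M = (1/|T|) Σ_{t∈T} (1/k) Σ_{j∈N_k(t)} r_j`

2. **Adaptive k.** The enrichment ratio `E(k) = M(k) / perm_mean(k)` is
   scanned over k = 5, 10, …, 50. With `ΔE_i = |E(k_i) − E(k_{i−1})|`, the
   *stable interval* starts at the first k with ΔE < 0.05 and ends where ΔE
   next exceeds 0.05; within it, the k with peak E is selected as k*. Small
   k undersamples neighbourhoods; large k dilutes signal — the dual
   criterion avoids both. If no stable interval exists, the global peak is
   returned with an explicit fallback flag.

3. **Permutation test.** The null of spatial independence is built by
   permuting the response proportion vector across all spots (coordinates,
   targets and graph fixed), n_perm = 1000 by default. `E = M / perm_mean`
   and the one-sided p-value uses the add-one rule
   `p = (1 + #{null ≥ M}) / (1 + n_perm)`.

4. **Spatial structure.** Global Moran's I with row-standardized k-NN
   weights (`E[I] = −1/(n−1)`, permutation significance) quantifies
   autocorrelation of a field; Spearman correlation between the two
   proportion fields summarizes pointwise association.

Supporting modules: ssGSEA-style single-sample signature scoring (Barbie
running-sum with rank weight `rank^0.25`) and mean-expression scoring;
signature derivation from DE tables (log2FC > 1, p < .05); odds-ratio
tissue-distribution enrichment with Haldane–Anscombe correction and Fisher
exact p (OR < 0.5 flagged as depletion); Shannon equitability `H / ln S`;
and a synthetic Visium-like generator with a controllable co-localization
strength `rho` used for calibration and power analysis.

## Worked example

```r
library(spotcoloc)

cfg    <- synthetic_config(n_spots = 400, rho = 0.8, spatial_scale = 2, seed = 42)
spots  <- generate_spots(cfg)
comp   <- generate_composition(spots, cfg)$composition
targets <- top_target_spots(comp, "target", 0.9)   # top decile of target proportion

curve <- scan_k(comp, spots, targets, "response",
                k_grid = seq(5, 50, 5), n_perm = 1000, seed = 42)
curve
#> Enrichment curve E(k):
#>   k      E  delta
#>   5 1.2994     NA
#>  10 1.2464 0.0529
#>  15 1.2214 0.0250
#>  20 1.1855 0.0360
#>  25 1.1810 0.0044
#>  30 1.1688 0.0122
#>  35 1.1605 0.0084
#>  40 1.1564 0.0041
#>  45 1.1435 0.0128
#>  50 1.1301 0.0134
#> Stable interval [15, 50]; k* = 15

permutation_test(comp, build_knn(spots, curve$k_star), targets, "response",
                 n_perm = 1000, seed = 42)
#> Spatial permutation test (n_perm = 1000)
#>   observed neighbourhood mean: 0.0969186
#>   permutation mean:            0.0796829
#>   enrichment ratio E:          1.2163
#>   one-sided p (add-one):       0.000999

morans_i(spots, comp[, "response"], k_weights = curve$k_star, seed = 42)
#> Global Moran's I = 0.2446 (expected -0.0025 under exchangeability)
#>   two-sided permutation p = 0.001 (n_perm = 999, knn_row_standardized weights, k = 15)
```

Reading: response proportions in target neighbourhoods are 22% above the
spatial-independence expectation (E = 1.22) at the stable neighbourhood
size k* = 15, with p ≈ 0.001 — the planted co-localization (rho = 0.8) is
recovered. Moran's I confirms genuine spatial structure in the response
field. The same calls work on real data via `read_spot_table()` /
`read_composition()`, or end-to-end through `run_pipeline()` with a YAML
config (see `inst/scripts/coloc.R` for the shell entry point).

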