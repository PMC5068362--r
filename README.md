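# commdecomp

Disentangling the environmental and spatial drivers of **taxonomic,
functional, and phylogenetic community structure**.

Community ecologists routinely ask whether the composition of local
communities along a disturbance gradient (say, bat assemblages across a
fragmented Neotropical landscape) is shaped by *environmental filtering*,
by *niche availability*, or merely by *spatial processes* such as dispersal
limitation. Answering that requires more than comparing species lists:
communities can keep the same average trait profile while the *breadth* of
traits they support expands or contracts. `commdecomp` implements the full
inference chain for that question, aimed at ecologists with site-by-species
count matrices, species trait tables, a phylogeny, and site coordinates.

## What it computes

**Responses.** For a site-by-species abundance matrix `Y`:

- *Taxonomic structure* `X̄_T`: the Hellinger transform,
  `x̄_ij = sqrt(y_ij / y_i·)`.
- *Functional / phylogenetic structure*: an eigenvector `u` of species
  scores is extracted from a distance matrix — axis-weighted Gower
  distances on mixed binary/mensural traits (each niche axis receives equal
  total weight), or cophenetic distances on the phylogeny. The
  abundance-by-score (Hadamard) weighting, with cell weights
  `w_ij = y_ij · o_j` (`o_j` = number of occupied sites, down-weighting
  rare species), is redistributed into per-site means and variances:

  - composition `m_i = Σ_j w_ij u_j / Σ_j w_ij` (`X̄_F`, `X̄_P`)
  - dispersion `s_i = sqrt( Σ_j w_ij (u_j − m_i)² / Σ_j w_ij )`
    (`s_F`, `s_P`)

  so that with normalized weights `Σ_j w̃_ij u_j² = m_i² + s_i²` exactly.

**Predictors.** Environmental tables (e.g., nine landscape indices per
focal scale) and a Moran's-eigenvector-map (MEM) spatial predictor: the
site distance matrix is thresholded at the longest minimum-spanning-tree
edge, and the eigenvector of the doubly centered connectivity matrix with
the largest positive eigenvalue — the broad-scale pattern maximizing
Moran's I — serves as the spatial variable `S`.

**Partition.** Full and partial redundancy analysis splits each response's
variation into `[a]` (environment | space), `[b]` (spatially structured
environment), `[c]` (space | environment) and `[d]` (residual), on the
Ezekiel-adjusted R² scale (`R²_adj = 1 − (1 − R²)(n−1)/(n−p−1)`):

    [a] = [abc] − [bc],  [c] = [abc] − [ab],
    [b] = [ab] + [bc] − [abc],  [d] = 1 − [abc]

Negative adjusted fractions are kept in the raw output and clamped to zero
for display. Unique fractions are tested by permutation (partial pseudo-F):
response-row permutation for the taxonomic response, and a conservative
double permutation for trait-based responses (site vectors of the tested
predictor block, and species entries of the score vector with the
decomposition recomputed; the reported p is the max of the two).
Significance codes follow `**` (p ≤ 0.01), `*` (0.01 < p ≤ 0.05), `@`
(0.05 < p ≤ 0.10).

A synthetic metacommunity generator (`simulate_metacommunity()`) produces
communities with a *known* assembly mechanism — environmental filtering,
a niche-availability (dispersion) gradient, pure spatial structure, or
exchangeable null — on a simulated phylogeny with phylogenetically
structured traits and spatially autocorrelated environmental gradients, so
every stage has a parameter-recovery test.

## Worked example

Simulate a 15-site, 34-species metacommunity whose *functional dispersion*
(not composition) tracks an environmental gradient, then recover that
signal:

```r
library(commdecomp)

cfg <- scenario_config("dispersion_gradient", effect_size = 2, seed = 42)
sim <- simulate_metacommunity(cfg)

scores <- species_scores(gower_dist(sim$traits, sim$meta))
decomp <- decompose_structure(sim$abundance, scores)
head(decomp, 3)
#> # A tibble: 3 × 5
#>   site    composition dispersion dispersion_var total_weight
#>   <chr>         <dbl>      <dbl>          <dbl>        <dbl>
#> 1 site_01     -0.0314      0.142         0.0202          831
#> 2 site_02      0.0101      0.147         0.0216          885
#> 3 site_03      0.0111      0.109         0.0120          946

W <- build_connectivity(sim$sites)
S <- mem_predictor(mem_basis(W))
E <- sim$sites[c("site", paste0("env_", 1:9))]

part <- partition_variation(
  tibble::tibble(site = decomp$site, value = decomp$dispersion),
  E, S, weights = decomp$total_weight)
tests <- test_unique_trait(sim$abundance, scores, E, S,
                           nperm = 999, seed = 42)
add_partition_tests(part, tests)
#> Variation partition (adjusted R2 scale)
#>   [a] environment | space                  0.6914  (P = 0.169 )
#>   [b] spatially structured environment     0.0636
#>   [c] space | environment                 -0.0612  (P = 0.982 )
#>   [d] residual                             0.3062

structure_variance_shares(decomp)
#> # A tibble: 1 × 4
#>   var_composition var_dispersion composition_share dispersion_share
#>             <dbl>          <dbl>             <dbl>            <dbl>
#> 1        0.000589        0.00206             0.222            0.778
```

Reading the output: per-site `composition` is essentially flat while
`dispersion` varies (78% of the between-site variance sits in dispersion) —
the communities differ in trait *breadth*, not average trait value — and
the environment-bearing fractions `[a] + [b] ≈ 0.75` dwarf the unique
spatial fraction. That is exactly the generating mechanism. `tidy()`,
`glance()`, `autoplot()` and `plot_partition_report()` expose the same
results as tibbles and stacked-bar figures, and `run_partition_analysis()`
drives the whole loop over seasons × focal scales × responses (including
per-niche-axis dispersion) with Moran's I autocorrelation tables and a
provenance log.

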