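# plumevol

Tools for studying how plumage coloration evolves across a phylogeny, built
for comparative analyses of reflectance spectra measured on museum
specimens (the motivating system is a species-rich clade of colorful birds
scored at 22 body patches, in triplicate, for both sexes of ~72 species).

The package covers the full pipeline:

1. **Avian visual model.** Reflectance spectra *R*(λ) on the bird-visible
   300–700 nm grid are converted to quantum catches
   *Q*ᵢ = Σ_λ *R*(λ)·*I*(λ)·*S*ᵢ(λ)·Δλ for the four single cones
   (u, s, m, l) and the double cone. Chromatic differences follow the
   receptor-noise-limited model: the log-catch contrast Δ*f*ᵢ = ln(*Q*ᵃᵢ/*Q*ᵇᵢ)
   is projected onto the chromatic subspace (the complement of the
   achromatic direction under the noise metric diag(*e*ᵢ²)⁻¹, with
   *e*ᵢ = ω/√ηᵢ), and its norm is the distance in just-noticeable
   differences (JND). `to_xyz()` maps catches to 3-D coordinates in which
   Euclidean distance *equals* that JND distance, so ordinary multivariate
   machinery applies. Luminance is scaled as (ln *Q*_dbl − ln 0.01)/ω with
   ω = 0.1, so differences are achromatic JNDs.
2. **Plumage complexity.** Three intraspecific metrics from the patch ×
   patch JND matrix: c1 = mean interpatch distance; c2 = convex-hull volume
   of the patch cloud in colorspace (chromatic) or luminance range
   (achromatic); c3 = number of contiguous plumage regions, i.e. connected
   components of the graph whose edges join patches that are both adjacent
   on the body (M_adj) and perceptually indistinguishable (JND < 1).
3. **Tempo and mode.** Pagel's λ fitted to the multivariate color block;
   phylogenetic PCA; multivariate phylogenetic signal (K-mult);
   multivariate Brownian rates σ²_mult with group rate-ratio permutation
   tests (island vs continent, complex vs plain plumage); branch-specific
   rates by phylogenetic ridge regression.
4. **Ecological predictors.** Univariate PGLS with ML λ, bidirectional
   stepwise AIC, VIF diagnostics; multivariate distance-based PGLS with
   residual-randomization permutation (RRPP); two-block phylogenetic
   integration (r-PLS) for male vs female plumage.
5. **Variance partitioning.** REML components for patch, sex, species, and
   residual, summed over the three chromatic coordinates.
6. **Synthetic data.** A generator with known ground truth (pure-birth
   tree, island-colonization Markov regimes, regime-dependent Brownian
   rates, patch/sex/replicate structure) so every stage is verifiable
   without the original specimen data.

## Worked example

Simulate a study-scale dataset (72 species, 22 patches, island regimes with
a 1.8× rate multiplier), score complexity, fit λ, and test for an island
effect on evolutionary rates:

```r
library(plumevol)

cfg <- sim_config(seed = 42)
sim <- simulate_plumage_dataset(cfg)
lay <- default_patch_layout()
map <- setNames(lay$patch_names, sort(unique(sim$profile$patch)))
sim$profile$patch <- unname(map[sim$profile$patch])

head(plumage_complexity(sim$profile, lay, variant = "chromatic"), 3)
#>   species   variant   wing       c1       c2 c3
#> 1    sp01 chromatic folded 6.248747 311.5788 22
#> 2    sp02 chromatic folded 6.172623 290.8993 22
#> 3    sp03 chromatic folded 6.129204 289.1436 22

sc <- sim$species_colors
Y <- do.call(rbind, lapply(split(sc, sc$species),
                           function(d) as.numeric(t(as.matrix(d[c("x", "y", "z")])))))
Y <- Y[sim$tree$tip.label, ]

(fl <- fit_lambda(Y, sim$tree))
#> Pagel's lambda fit: lambda = 0.9954, logLik = 516.07, AIC = -766.14 (BM AIC = -606.44); best: lambda

g <- setNames(ifelse(sim$regimes$tip_state == 1, "island", "continent"),
              sim$tree$tip.label)
set.seed(1)
rate_ratio_test(Y, lambda_tree(sim$tree, fl$lambda), g, nperm = 999)
#> rate ratio test (66 traits): ratio = 1.751, p = 0.0080 (999 permutations)
#> continent    island
#>    0.1563    0.2737
```

Reading the output: each species' plumage is ~6.2 JND of average interpatch
contrast with all 22 patches perceptibly distinct (c3 = 22); the color
block carries strong phylogenetic signal (λ̂ ≈ 1); and island lineages
evolve color about 1.75× faster than continental ones (σ²_island = 0.27 vs
σ²_cont = 0.16 JND² per unit tree depth, permutation p = 0.008) — the
generator's island multiplier (1.8) is recovered.

## Acceptance script

`scripts/acceptance.R` exercises the whole pipeline end-to-end on a
freshly simulated dataset — spectra round trip through the visual model,
complexity metrics, variance partition, λ and K-mult, rate-ratio tests for
insularity and binary complexity, species-specific ridge rates with
stepwise PGLS and VIFs, d-PGLS, and male/female r-PLS — and writes its JSON
report to `--out`:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
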