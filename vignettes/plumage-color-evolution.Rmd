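---
title: "Models and methods for plumage color evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for plumage color evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plumevol)
```

This vignette documents the models behind `plumevol`, their assumptions,
the tunable parameters, and the numerical and design choices made where
the methodology left genuine freedom. It states no empirical result that
the package's tests do not themselves compute.

## 1. The visual model

Plumage color is quantified from the viewpoint of a bird, not a human.
Reflectance spectra are collapsed into photoreceptor **quantum catches**

$$Q_i = \sum_{\lambda=300}^{700} R(\lambda)\, I(\lambda)\, S_i(\lambda)\,\Delta\lambda,$$

for the four single cones $i \in \{u, s, m, l\}$ (chromatic channels) and
the double cone (achromatic channel). Discriminability follows the
receptor-noise-limited model: the log-catch contrast between two stimuli,
$\Delta f_i = \ln(Q^a_i/Q^b_i)$, is compared against channel noise
$e_i = \omega/\sqrt{\eta_i}$, where $\eta_i$ is the relative density of
cone class $i$ and $\omega$ the chromatic Weber fraction. Overall
intensity carries no chromatic information, so the distance is the norm of
$\Delta f$ *after projecting out the achromatic direction* $(1,1,1,1)$
under the metric $\mathrm{diag}(e_i^2)^{-1}$:

$$\Delta S \;=\; \min_t \Big\|\,\Delta f - t\,\mathbf{1}\,\Big\|_{\mathrm{diag}(e^2)^{-1}}.$$

One unit of $\Delta S$ is one just-noticeable difference (JND): stimuli
closer than 1 JND are indistinguishable to the modeled viewer. This
projection form is algebraically identical to the classical
pairwise/triple-ratio formula for a tetrachromat; the test suite checks
the identity on random stimuli.

`to_xyz()` maps catches to three coordinates such that Euclidean distance
equals $\Delta S$ exactly (tolerance $10^{-9}$ in the acceptance suite).
Such coordinates are defined only up to a rigid rotation/reflection of the
chromatic subspace, so a fixed convention makes outputs reproducible
bit-for-bit: Gram–Schmidt under the noise metric on the channel-difference
directions $l - m$, then $s$ against the $l/m$ average, then $u$ against
the rest, with signs chosen so that increasing $l$, $s$, $u$ catches
increase the first, second, and third coordinate respectively. Any other
valid basis differs from this one by a rigid motion and leaves every
downstream distance unchanged.

Luminance uses the double-cone catch on the scale
$(\ln Q_{dbl} - \ln 0.01)/\omega_a$, so *differences* are achromatic JNDs
and the floor catch 0.01 maps to 0.

**Assumptions and defaults.** Exact cone sensitivity tables for the
species of interest are rarely available, so the default `visual_system()`
uses Gaussian templates for a UV-type retina (peaks 372, 456, 544, 609 nm;
widths 30–45 nm; a broadband double cone at 560/90 nm), each normalized to
unit area. Relative cone densities default to $\eta = (1, 2, 2, 4)$ and
$\omega_c = \omega_a = 0.1$ — conventional values for passerine-style
visual systems — and the illuminant defaults to flat white. All of these
are configurable, and every *difference*-based quantity is invariant to
the illuminant's overall scale, so analyses of color variation are robust
to the illuminant choice. Quadrature is a plain rectangle rule on the 1-nm
grid (Δλ = 1): the grid is dense enough that anything fancier changes
results below measurement noise, and the simple rule is exactly
reproducible. Inputs on coarser grids are linearly interpolated; replicate
spectra are averaged per patch per specimen *on reflectance, before* the
visual model is applied.

## 2. Complexity metrics

All three metrics start from the patch × patch JND matrix (chromatic:
Euclidean distance of `xyz`; achromatic: |Δ luminance JND|). Per-specimen
matrices are averaged within species before anything else, so the species
matrix represents a typical individual rather than a pooled cloud.

- **c1 — mean interpatch distance** (JND): the mean of the strictly lower
  triangle.
- **c2 — colorspace volume** (JND³): the volume of the 3-D convex hull of
  the patch coordinates; for the 1-D achromatic variant, the luminance
  range. No hull library is available in this stack, so the hull is an
  in-package randomized incremental construction; it is validated against
  the determinant formula for the unit tetrahedron (1/6 exactly) and a
  Monte-Carlo membership oracle. Collinear/coplanar point clouds return 0
  (degeneracy tolerance $10^{-7}$ relative to the cloud's extent, chosen
  above the $\sqrt{\varepsilon}$-scale cancellation noise of squared
  distances).
- **c3 — contiguous plumage regions**: patches are merged when they are
  **both** adjacent on the body (`M_adj[i,j] = 1`) **and**
  indistinguishable (JND strictly < 1); c3 is the number of connected
  components of the resulting graph (isolated patches count). The
  elementwise product of the indistinguishability and adjacency matrices
  implements the published "matrix multiplication" description, whose
  stated result (1 iff adjacent *and* indistinguishable) is elementwise. A
  tie at exactly 1 JND counts as *distinguishable*: the discrimination
  convention marks "> 1" as distinct and the model's JND unit makes
  equality a measure-zero event anyway.
- Note on naming: one part of the source methodology's text labels the
  volume metric "c3"; everywhere else (including its own workflow figure)
  volume is c2 and the region count c3. This package follows the
  figure: **c2 = volume, c3 = regions**.

Binary complexity groups (for rate comparisons) come from exhaustive 1-D
2-means: every ordered split of the sorted scores is scored by
within-cluster sum of squares. This is deterministic — no random restarts —
and optimal, because an optimal 1-D 2-means partition is always an
interval split.

The default 22-patch body layout ships with folded-wing adjacency (the
wing overlaps the flanks and breast side, and the primaries reach the tail
base) and a spread-wing variant that removes the wing–body contacts. The
folded graph is connected, so `c3 = 1` is attainable.

## 3. Phylogenetic machinery

Tip covariance under Brownian motion is $C_{ij}$ = shared root-to-MRCA
path length. **Pagel's λ** multiplies the off-diagonal of $C$ (equivalently:
scales all edges by λ and stretches terminal edges to preserve tip depths —
`lambda_tree()` implements the edge-wise version used before rate
analyses).

`fit_lambda()` maximizes the Gaussian phylogenetic likelihood over
$\lambda \in [10^{-10}, 1]$ with **traits independent given the tree** and
per-trait rates profiled out. With p = 66 traits and n = 72 species a full
trait covariance is unidentifiable; the penalized-likelihood route used in
the motivating study is approximated here by this diagonal restriction,
plus optional ridge shrinkage $R + \delta\,\mathrm{tr}(R)/p\,I$ (default
$\delta = 10^{-8}$) in the phylogenetic PCA. Model comparison against BM
(λ = 1) uses AIC on the same restricted likelihood; the original study's
generalized information criterion is not printed anywhere, so AIC is the
documented approximation. The optimizer is Brent search (`optimize`) with
tolerance $10^{-8}$; the profile likelihood is unimodal in practice, and
an explicit endpoint check admits λ̂ = 1 (the optimizer never evaluates
the boundary exactly).

**Phylogenetic PCA** uses the evolutionary covariance
$R = (Y - \mathbf{1}a)^\top C^{-1}(Y - \mathbf{1}a)/(n-1)$ with the GLS
(phylogenetic) mean $a$; scores are centered data on the eigenvectors. On
a star tree this reduces exactly to ordinary covariance PCA, which is the
test oracle; an `ordinary` mode ($C = I$) is provided because component
selection bias makes pPCA controversial for downstream use.

**K-mult** generalizes Blomberg's K: the ratio of raw to
phylogenetically-corrected mean squared deviation from the phylogenetic
mean, scaled by its BM expectation and summed across traits; its
expectation is ~1 under BM. Significance permutes species across tips.

## 4. Rates

$$\hat\sigma^2_{mult} = \frac{\sum_j (y_j - a_j\mathbf{1})^\top C^{-1}(y_j - a_j\mathbf{1})}{N\,p}$$

is the net rate across the p traits — exactly the mean of per-trait GLS
rate estimates (tested to $10^{-10}$). The divisor is $N$, matching the
established multivariate-rate estimator this mirrors (not $N - 1$).

For **group comparisons**, deviations from the *common* phylogenetic mean
are whitened by the symmetric inverse square root $C^{-1/2}$
(eigendecomposition: basis-stable and exact for SPD matrices); each
group's rate is its share of the whitened squared deviations over
$N_g\,p$, the statistic is the max/min ratio, and the null permutes
**group labels across tips** — not phenotypes — because label permutation
preserves the trait covariance structure and labels are exchangeable under
the equal-rate null. p-values follow the $(1 + \#\{\geq\})/(n_{perm}+1)$
convention throughout the package. The λ-transformed tree (from
`fit_lambda`) is applied before rate computations.

**Species-specific rates** use phylogenetic ridge regression: with the
tips × branches path matrix $L$ (entries = branch lengths along each
root-to-tip path), solve per trait
$\hat\beta = \arg\min \|y - a - L\beta\|^2 + \kappa\|\beta\|^2$. The
root state is not separately estimated; centering at the phylogenetic mean
$a$ plays that role, which keeps the penalized system free of an
unpenalized intercept column. A branch's scalar rate is the L2 norm of its
coefficients across traits, and the **species rate is the terminal-branch
rate** — the branch-specific quantity that belongs to one species alone,
which is what gets regressed on ecological predictors. The penalty is
chosen by generalized cross-validation on a 60-point log grid scaled by
the mean squared singular value of $L$ (one SVD, shared across the grid
and traits).

## 5. Regressions

`pgls_fit()` is GLS with $V = \sigma^2 C_\lambda$ and λ estimated by ML
jointly with the coefficients (bounds $[10^{-10}, 1]$, matching the
conventional lower bound). Variables are expected to be z-scored
(`zscore()`) when coefficients are to be read as standardized effect
sizes. $R^2 = 1 - \exp\{(2/n)(\ell_0 - \ell)\}$ is the likelihood R²
against the intercept-only PGLS with its own λ̂; the original study's
exact R² flavor is not stated, so this standard likelihood form is the
documented choice. VIFs regress each predictor on the rest under the same
PGLS machinery and report $1/(1 - R^2_j)$ — the printed formula
"1/(1·R²)" in the source text is an obvious typesetting casualty of the
standard definition. Perfect collinearity reports `Inf` with a warning
rather than an error, since the diagnostic's job is to reveal it.

Stepwise selection is bidirectional: from the full candidate model, the
single addition or deletion with the largest AIC decrease is applied until
no move improves, with a rank guard so duplicated or confounded columns
can never co-enter. Given data, the procedure is deterministic.

**d-PGLS** whitens the trait block and design by $C_\lambda^{-1/2}$ and
uses sequential (type-I) sums of squares in formula order — the
morphometric convention, with the predictor order of interest specified by
the user — summed across traits;
$F = (SS_{term}/df)/(SS_{res}/df_{res})$ with the full-model residual.
Significance randomizes **reduced-model residuals** (RRPP): residual rows
of the whitened reduced fit are exchangeable under the null, permuted and
added back to the reduced fitted values, and F recomputed. With a single
trait this equals the univariate sequential PGLS F to $10^{-8}$ (tested).

**r-PLS** (two-block integration) whitens and phylo-centers both blocks,
takes the SVD of the cross-block covariance, and reports the absolute
correlation of the first score pair. The permutation shuffles rows of the
*whitened* second block: whitened rows are exchangeable under
independence, whereas raw tip rows are phylogenetically correlated and
permuting them makes the test anticonservative (the null-calibration test
in the suite demonstrates the calibrated behavior).

## 6. Variance partitioning

Per chromatic coordinate, a crossed random-effects model
`value ~ 1 + (1|patch) + (1|sex) + (1|species)` is fitted by REML
(`lme4`), components are summed across the three coordinates, and
proportions of the total are reported. The Bayesian MCMC machinery used in
the motivating study (priors, chain length, convergence diagnostics) is
deliberately out of scope: the reported quantity — variance proportions —
is estimator-agnostic at simulation tolerance, and REML is deterministic
and testable. The suite cross-checks REML against method-of-moments ANOVA
on balanced designs instead of against a Gibbs sampler. Caveat: sex has
only two levels, so its variance component rests on a single degree of
freedom and is fragile; it is reported, but boundary (zero) estimates and
occasional marginal-convergence warnings are expected, and a factor with
one level in a clade is fixed at 0 with a warning.

## 7. The synthetic world

`sim_config()` defaults encode the study design the package emulates:
72 species, 22 patches, 1–3 specimens per species, two sexes, a pure-birth
tree rescaled to depth 1, symmetric island/continental Markov transitions
(q = 0.5) from a continental root, Brownian rate σ² = 0.2 JND²/depth per
trait, an island rate multiplier of 1.8 (the scale of the empirically
reported chromatic island/continent rate contrast), λ = 1, and sympatric
species counts of 1–9 (islands) and 6–38 (mainland). Patch identity is a
**shared mean offset** drawn once for the clade (scale 3 JND): the same
patch tends toward the same color family in every species, which is what
makes the patch factor dominate the variance partition while leaving
phylogenetic signal in the species-level block intact. Sex dimorphism is a
per-patch ±offset (sd 0.5 JND); replicate noise is 0.3 JND.

The island effect is a branch-wise **rate multiplier**, not a mean shift —
matching the finding the generator emulates (faster island evolution, no
convergence); a mean-shift scenario can be built by adding offsets to
island tips directly (as the power tests do for terminal branches). For
complexity–rate coupling, a config mode draws each species' offset scale
and sets its terminal-branch multiplier as a linear function of realized
c1, giving regressions a known truth.

What the generator does **not** emulate: realistic spectral shapes
(reflectance fixtures are smooth basis-function curves found by bounded
optimization, `colors_to_spectra()`), within-feather patterning (invisible
to patch-level metrics by construction), biogeographically structured
island assignment, and trait–trait covariance beyond what shared
processes and offsets induce. A green test therefore establishes that the
estimators recover the stated statistical structure at the stated scale —
not that any particular empirical dataset satisfies those assumptions.

## 8. Numerical notes and limitations

- Permutation p-values can never be 0: the observed statistic is included,
  so $p \geq 1/(n_{perm}+1)$. All permutation tests are seed-reproducible.
- Cholesky solves are used for $C^{-1}$ products; the symmetric
  eigendecomposition square root for $C^{-1/2}$; singular covariances
  raise errors rather than being silently regularized (except the
  documented pPCA ridge).
- `read_tree()` admits non-ultrametric trees with a warning flag
  (relative tolerance $10^{-6}$) rather than refusing them.
- `match_data()` requires a non-empty species intersection and messages
  when fewer than 3 species survive; individual analyses impose their own
  stricter minima.
- The λ likelihood's diagonal-trait restriction means λ̂ can differ from a
  penalized full-covariance fit on the same data; no result in this
  package depends on matching any particular λ̂ exactly.
- Spectra are accepted in long or wide CSV; inputs must cover the full
  300–700 nm range (no extrapolation), and out-of-range wavelengths are
  dropped.
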