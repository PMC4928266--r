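# paridmorph

Tits (Paridae) look outwardly uniform, yet one member — the Ground Tit
*Pseudopodoces humilis* of the Tibetan steppes — is so aberrant it was long
misclassified as a ground jay. Quantifying how body morphology and beak shape
vary across such a radiation, and how much of that variation traces to shared
ancestry, altitude, and interactions between overlapping species, takes a
pipeline that spans geometric morphometrics, multivariate statistics and
phylogenetic comparative methods. `paridmorph` packages that pipeline for R,
tidyverse-style: data frames in, tibbles out, `tidy()`/`glance()` on every
fitted object, `autoplot()` on every result worth looking at.

It is aimed at evolutionary biologists and morphometricians who want the full
chain — landmark input to partial Mantel table — as composable, tested
functions rather than a sequence of GUI tools (tpsDig/tpsRelw, MorphoJ, PAST)
with files passed between them.

## What it computes

**Geometric morphometrics.** Beak outlines are 21-point configurations: three
fixed landmarks (LM1/LM2 where the nares line crosses the upper-mandible
outline, LM3 at the tip) and 18 semilandmarks, nine per profile. Generalized
Procrustes analysis (`gpa()`) removes position, scale and orientation:
configurations are centred, scaled to unit centroid size
(CS = √Σᵢ‖xᵢ − x̄‖²), and rotated to minimise Σ‖Xᵢ − consensus‖².
`slide_semilandmarks()` then lets each semilandmark slide along its local
tangent to minimise Procrustes distance to the consensus (bending energy
optional), since points along a curve carry no point-wise homology.
`tangent_project()` yields tangent-space coordinates where ordinary
multivariate statistics apply.

**Morphospace statistics.** Log-transformed linear traits (body weight, body
length, wing, tail, tarsus, culmen) and shape coordinates go through one-way
ANOVA (`one_way_anova()`), PCA with a reproducible sign convention
(`morpho_pca()`), canonical variate analysis with pairwise Mahalanobis
distances D²ᵢⱼ = (mᵢ−mⱼ)ᵀW⁻¹(mᵢ−mⱼ) on a rank-reduced subspace
(`morpho_cva()`), and Goodall's Procrustes ANOVA, whose F uses degrees of
freedom multiplied by the shape dimension 2k − 4 (`procrustes_anova()`).

**Phylogenetic comparative methods.** With a rooted, branch-length tree
(`read_newick()`): Blomberg's K with a permutation test (`blomberg_k()`),
Pagel's λ by maximum likelihood with a likelihood-ratio test
(`pagel_lambda()`), PGLS regression under Brownian-motion covariance
(`pgls()`), squared-change parsimony ancestral states
(`squared_change_parsimony()`), and phylomorphospace projections
(`phylomorphospace()`).

**Range overlap and character divergence.** The Jaccard-type index
D_O = O_AB / (S_A + S_B − O_AB) and its complement D_AB = 1 − D_O turn range
areas and altitudinal intervals into distance matrices
(`overlap_distance_matrix()`, `altitudinal_overlap_distance()`);
`partial_mantel()` tests morphological against distributional distance while
controlling for patristic distance, by permutation.

**Synthetic studies.** `generate_study()` simulates the whole data layout —
pure-birth tree, species mean traits and beak outlines evolving by Brownian
motion, allometric scaling on a latent size, altitudinal clines,
within-species noise, partially overlapping ranges — with every generating
value recorded, so the pipeline is testable end to end without any external
data. `run_pipeline()` executes all stages in order and emits labelled CSVs
plus a JSON provenance file.

## Worked example

```r
library(paridmorph)

study <- generate_study(simulation_config(n_species = 8, n_per_species = 10, seed = 42))
study
#> Synthetic study: 8 species x 10 individuals (seed 42)
#>   80 measurement records, 80 landmark configurations

aligned <- study$landmarks |> gpa() |> slide_semilandmarks()
aligned
#> Generalized Procrustes analysis: 80 configurations, 21 landmarks (18 sliding)
#>   iterations: 3, total Procrustes SS: 0.108113

shape_pca <- aligned |> tangent_project() |>
  dplyr::select(-specimen_id, -centroid_size) |> species_means() |> morpho_pca()
glance(shape_pca)
#> # A tibble: 8 × 4
#>   component std_dev variance_fraction cumulative
#>   <chr>       <dbl>             <dbl>      <dbl>
#> 1 PC1       0.0341            0.987        0.987
#> 2 PC2       0.00241           0.00492      0.992
#> 3 PC3       0.00175           0.00259      0.995
#> 4 PC4       0.00151           0.00193      0.997

report <- run_pipeline(pipeline_config(study = study, seed = 1,
                                       n_perm_mantel = 999, n_perm_signal = 199))
describe_report(report)
#> Trait ANOVAs: F range 35.6 - 1.58e+03 (all df_between = 7)
#> Body PCA: PC1 90.33%, PC2 6.74% of variance
#> Shape PCA: first 3 PCs carry 99.48% of variance
#> Procrustes ANOVA: shape F(266, 2736) = 33.15, p = 0
#>                   size  F(7, 72) = 30.98, p = 2.5e-19
#> Phylogenetic signal: 12 of 32 tests significant at 0.05
#> Altitude regressions: 22 fits (4 with p < 0.05)
#> Partial Mantel body x geographic: r = -0.045, p = 0.65
#> Partial Mantel body x altitudinal: r = -0.152, p = 0.766
#> Partial Mantel beak x geographic: r = 0.323, p = 0.023
#> Partial Mantel beak x altitudinal: r = 0.375, p = 0.029
```

Reading the output: the simulated radiation separates species strongly in
every linear trait (ANOVA F ≥ 35.6 on 7 between-species df); most body-trait
variance loads on a single size axis (PC1 90.3%), as expected when all six
traits scale allometrically with one latent size; beak shape variation is
effectively three-dimensional (99.5% in three PCs); and with the default
half-overlapping ranges the beak-shape Mahalanobis distances correlate
positively with both distributional distances after controlling for
phylogeny (r ≈ 0.32–0.38), while body distances do not — the kind of table
the study design is meant to interrogate.

Species-level inference on 8–14 taxa is low-powered; expect wide spread in
K, λ and Mantel r across seeds.

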