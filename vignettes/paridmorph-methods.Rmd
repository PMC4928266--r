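---
title: "Methods: morphometrics and phylogenetic comparative analysis in paridmorph"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometrics and phylogenetic comparative analysis in paridmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of the models and procedures it
implements, the defaults it chose where choices were open, and what its tests
do and do not establish.

## The analysis chain

The package reconstructs a complete morphometric-comparative workflow for a
bird radiation:

1. ingest linear measurements (CSV), beak landmark configurations (TPS or
   plain coordinate matrices), a rooted phylogeny (Newick) and range tables;
2. superimpose the landmark configurations (GPA with sliding semilandmarks)
   and project them into tangent space;
3. characterise variation: per-trait one-way ANOVAs, PCA of standardized
   species means, CVA with Mahalanobis distance matrices, Goodall's
   Procrustes ANOVA for shape and a classical ANOVA for log centroid size;
4. quantify phylogenetic structure: Blomberg's K, Pagel's lambda,
   squared-change parsimony ancestral states, phylomorphospace projections;
5. relate morphology to altitude: PGLS across species on altitudinal
   midpoints, OLS across individuals within the widest-ranging species;
6. relate character divergence to range overlap: Jaccard-type overlap
   distances and partial Mantel tests controlling for patristic distance.

`run_pipeline()` executes 2-6 in that order on either real files or a
synthetic study and writes one labelled CSV per table plus a JSON provenance
record of seeds and versions.

## Superimposition

GPA centres every configuration, scales it to unit centroid size (full
Procrustes scaling), rotates it onto the running consensus, and re-estimates
the consensus as the unit-scaled mean until the consensus root-mean-square
change falls below `tol` (default 1e-8, capped at 200 iterations — failure to
converge is an error, not a silent truncation). Rotations are constrained to
determinant +1: all outlines are digitized in one orientation, so a
reflection would be an artefact, never a fit. The initial consensus is the
unit-scaled mean preshape, which makes the procedure equivariant under
permutation of the inputs (the orientation of the result does not depend on
which specimen happens to come first).

Procrustes distance is the full Procrustes distance (optimal translation,
scaling and rotation); it is computed from the aligned residual directly
rather than via `sqrt(1 - s^2)`, which loses half the significant digits near
identical shapes.

**Sliding semilandmarks.** Each semilandmark may move along its tangent
direction, the chord between its neighbours along the outline curve.
The default criterion minimizes Procrustes distance to the consensus, which
decouples point-wise into a projection of the consensus deviation onto the
tangent; thin-plate-spline bending energy is available as
`method = "bending"` (a joint generalized least-squares solve in the bending
energy metric of the consensus). The implementation was chosen so the
Procrustes criterion needs no thin-plate-spline machinery. Two details
matter numerically:

- slid points are re-projected onto the specimen's outline polyline, so
  sliding cannot carry a point off the observed curve;
- under the Procrustes criterion each specimen's update is accepted only if
  it does not increase that specimen's distance to the consensus (with step
  halving otherwise). Together with the fact that the unit-scaled mean is the
  optimal unit consensus, this makes the total Procrustes sum of squares
  provably non-increasing across sliding iterations — a property the tests
  assert on random inputs.

By default sliding alternates with full re-superimposition; this moves the
coordinates of fixed landmarks slightly (re-centering and re-rotation act on
the whole configuration). `resuperimpose = FALSE` performs a single sliding
pass against the current consensus, leaving fixed landmarks bit-for-bit
untouched, at the cost of only approximate centering.

Sliding against the consensus (rather than a designated reference specimen)
is assumed throughout; it is the common default of the field's sliding
implementations.

## Morphospace statistics

Linear traits are natural-log transformed; species means are taken over
complete rows only, in first-appearance order (stable, deterministic output
ordering everywhere). The body-morphology PCA standardizes species means to
zero mean and unit variance first — the traits carry different units — while
the shape PCA works on the covariance matrix of tangent coordinates, which
share a unit. PCA signs follow one convention: the largest-magnitude loading
of each component is positive.

CVA inverts the pooled within-group covariance, which is singular for
superimposed shape coordinates (superimposition removes four degrees of
freedom and sliding more). The data are therefore first reduced to principal
components with eigenvalues above 1e-10 of the largest, and to at most
`n - g` dimensions; canonical axes and Mahalanobis distances are computed in
that subspace. Mahalanobis distances are invariant to invertible linear
transforms of the data, so the reduction does not change them when the data
are full rank (a tested invariant).

Goodall's F decomposes summed squared tangent-space deviations between and
within groups with both degrees of freedom multiplied by the shape dimension,
`2k - 4` for `k` two-dimensional landmarks. The F ratio itself is
algebraically independent of that multiplier — embedding univariate data as a
one-coordinate "shape" reproduces the classical ANOVA F exactly, which the
tests use as an oracle. The parametric p-value from the F reference
distribution is the default; `n_perm > 0` adds a permutation p, which guards
against non-normality of shape deviations. With zero within-group variation
the F is reported as infinite with a warning rather than an error: the
decomposition is still well-defined, only the reference distribution is not.

One published detail is knowingly not reproduced: the residual degrees of
freedom printed in the original shape analysis (12096) are inconsistent with
the stated specimen and landmark counts, which give (306 - 14) x 38 = 11096.
The package always reports degrees of freedom computed from its own inputs.

## Phylogenetic comparative stage

The Brownian covariance `C` (shared root-to-tip path lengths) is built by one
tree traversal and cross-checked against an independent implementation in the
tests. Blomberg's K follows the original estimator: the ratio of the observed
`MSE0/MSE` (mean squared deviation from the GLS mean over the GLS mean
squared error) to its expectation under Brownian motion; its p-value permutes
trait values across tips, with the +1 exactness correction, 999 permutations
by default (the permutation count is a free choice; 999 balances resolution
against runtime). Pagel's lambda scales the off-diagonal of `C`; the ML
estimate is found by bounded one-dimensional optimization on
`[0, lambda_max]`, where `lambda_max` is the largest value keeping the
transformed matrix positive definite (found by bisection, always at least 1).
Near that bound the likelihood can spike as the matrix approaches
singularity; the optimizer's candidate is therefore compared against the
boundary values 0, 1 and `lambda_max` and the best kept. The p-value is a
likelihood-ratio test against lambda = 0 on one chi-squared degree of
freedom.

PGLS fixes the Brownian correlation (lambda = 1) rather than estimating
lambda jointly — plain PGLS is what the workflow calls for, and the signal
tests are reported separately; the slope test uses `n - 2` degrees of
freedom. Branch-length scale cancels, a tested invariant. Squared-change
parsimony solves the weighted-average linear system exactly (internal nodes
are branch-length-weighted averages of their neighbours), merging endpoints
of zero-length internal edges; its root value coincides with the GLS mean,
and the whole solution matches a generic numerical minimizer in tests.
Multivariate traits (PC score pairs for the phylomorphospace) are solved
per axis; no multivariate K is attempted.

One procedural sentence in the source workflow — running each regression
twice and averaging — is a no-op for deterministic least-squares fits and is
not implemented.

## Range overlap and partial Mantel tests

`D_O = O_AB / (S_A + S_B - O_AB)` and `D_AB = 1 - D_O` apply unchanged to
areas and to altitudinal intervals. Species pairs missing from the overlap
table are treated as disjoint with a message (an absent polygon intersection
means the ranges do not meet). When both intervals of a pair are degenerate
points, the distance is 0 if they coincide and 1 otherwise — a documented
convention for an otherwise 0/0 case.

The partial Mantel test residualizes both target matrices on the control by
OLS over the unfolded lower triangles and permutes the residualized first
matrix jointly over rows and columns (the residual-permutation scheme, chosen
for its type-I error control over raw-matrix permutation). The default is
one-tailed for positive association — the directional hypothesis of the
character-divergence analysis — with a two-tailed option. With a constant
control, partial and simple Mantel statistics coincide identically. The
pipeline default of 10,000 permutations matches the scale of the original
analysis; tests use fewer.

## The synthetic-data generator

`generate_study()` is the package's study-conditions definition, not a
tuning knob. Defaults:

- 14 species, 20 individuals per species — the dimensions of the study the
  pipeline re-implements;
- a unit-depth pure-birth tree (`simulate_tree()` rescales to depth 1 so
  Brownian rates read as variance per total tree depth);
- ancestral trait means typical of parids (weight 15 g; body 130 mm, wing
  65, tail 55, tarsus 17, culmen 10 mm), evolving on the log scale as
  `allometry_slope x latent log size + independent per-trait deviation`,
  with size rate 0.03 and per-trait rate 0.01 per unit depth — giving
  interspecific spreads of roughly 15-30% in linear traits and up to
  ~50-70% in weight (slope 3 on the latent size), the right order for a
  family whose extremes differ severalfold in mass;
- within-species log-SD 0.05 (about 5% coefficient of variation): the source
  study reports no within-species variances, so this is the package's own
  choice of a plausible museum-series spread, and it is deliberately
  prominent here and in `simulation_config()`'s documentation;
- altitudinal clines per metre on the log scale: culmen 5e-5, tarsus 3e-5,
  weight 2e-5, others 0 — i.e. ~20% culmen increase over 4000 m, matching
  the size of cline the study design is meant to detect; individual
  altitudes are uniform within each species' interval (simplest defensible
  choice, recorded in the truth record);
- beak outlines from three parameters (length, depth, curvature of quadratic
  Bezier profiles), with nine semilandmarks per profile placed at equal arc
  length on a 512-sample polyline; landmark noise 0.5% of beak length plus a
  random placement transform that superimposition must remove;
- ranges as discs with exact lens-intersection overlap areas, blended from
  disjoint (`overlap_level = 0`) to identical (`overlap_level = 1`), default
  0.5.

Every stage draws from a sub-seed derived deterministically from the master
seed, so a fixed seed gives byte-identical studies while stages stay
statistically independent.

**What the generator does not emulate:** measurement error correlated across
traits, sexual dimorphism or age classes, non-Brownian evolution (no
Ornstein-Uhlenbeck or early-burst regimes), realistic biogeography, or
digitization artefacts such as the outline-abrasion effects that make one
shape axis unreliable in real museum material. Passing tests therefore
establish that the estimators recover what they claim under their own model
assumptions — not that those assumptions hold for any particular real
dataset.

## Test design and problem sizes

The suite runs everything at desk scale, chosen so the whole suite finishes
in a few minutes on one core: oracle equivalence on 5-20-row random
instances against hand-rolled linear algebra; geometric invariance harnesses
(50 random similarity-transform trials, 100 sliding sets, 1000
triangle-inequality triples); calibration experiments of 500 replicates (K
centring on 1 under Brownian motion on a 16-tip tree; lambda medians under
Brownian motion and under tip shuffling; PGLS slope recovery; partial-Mantel
type-I error at 499 permutations) and 1000 replicates for the
Procrustes-ANOVA permutation null; and one full 14 x 20 end-to-end run. The
Brownian-signal integration check summarizes each replicate study by the
median lambda across its six Brownian-evolved log traits — single-trait
lambda estimates on 14 tips are too variable to characterize a study run,
and the median of the trait table is the natural per-run summary. The
altitude-cline recovery experiment sets the Brownian rates to zero so that
pooled ordinary-least-squares confidence intervals (which assume independent
errors) are exact for the generating model; with species-level Brownian
deviations present the same intervals undercover, which is a property of
pooled OLS, not of the generator.

The deposited-data checks (specimen counts, published variance fractions and
the published Goodall F) require the original study's supplementary files,
which are not redistributable with the package; `read_deposited_study()`
documents the expected layout and the corresponding acceptance test reports
the files as missing until they are supplied.

## Known limitations

- Two-dimensional landmarks only; no partial (non-scaling) Procrustes, no
  outline methods without landmarks.
- CVA is used for ordination and distances, not for classifying new
  specimens.
- Signal tests are univariate (per trait or per PC axis).
- The Mantel family's statistical limitations (conservativeness of the
  residual permutation under strong autocorrelation) are inherited, not
  solved.
- Size correction applies to linear traits only; shape is analysed size-free
  via superimposition, with centroid size tested separately.
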