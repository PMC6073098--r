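---
title: "Models and methods behind leafevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind leafevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(leafevo)
```

`leafevo` analyses the evolution of leaf physiognomy — the quantitative
size, shape and margin-tooth characters that palaeobotanists use as climate
proxies — on a time-calibrated phylogeny. This vignette explains the models
the package fits, the choices made where the design was genuinely open, the
synthetic data the test suite calibrates against, and the limits of what
those calibrations show.

## From leaf images to species traits

The measurement layer assumes upstream image processing has already
produced, per leaf: blade area `A`, perimeter `P`, the perimeter `Pi` and
area after teeth are digitally removed, the major and minor axis lengths,
and manual counts of primary and secondary teeth. From these,
`derive_traits()` computes the twenty standard variables: the perimeter
ratio `P/Pi`, compactness `P²/A`, shape factor `4πA/P²`, Feret diameter
`2√(A/π)` (the diameter of the circle with the leaf's area) and its ratio
to the major axis, tooth area `TA = A − area-after-tooth-removal`, its
normalizations by blade area and both perimeters, and the tooth counts and
densities.

Three conventions matter:

* **Untoothed leaves** carry a tooth area of zero, so the average tooth
  area `TA/primary-teeth` is defined as 0 when there are no primary teeth —
  this keeps every trait finite without dropping records.
* **Measurement slop**: digital tooth removal occasionally leaves the
  teeth-removed area a hair above the blade area; the resulting slightly
  negative `TA` is clamped to zero with a warning rather than rejected,
  mirroring how manual image editing behaves. Hard violations (internal
  perimeter exceeding the perimeter, shape factor above 1 beyond tolerance)
  are errors, reported with row and field by `validate_measurements()`.
* **Aggregation precedes the log transform.** Species values are the mean
  (or, for robustness runs, the minimum or maximum) over all pooled leaves,
  and the `Ln(x+1)` transform is applied to the aggregated table. Because
  `Ln(x+1)` is not scale-invariant, the schema fixes units to cm/cm² in the
  column names. Leaves are pooled per species rather than averaged per
  herbarium sheet first; sheet-level structure is retained in `sample_id`
  so users can pre-average if their sampling design demands it.

The trait identities `ShapFact × Comp = 4π`, `ShapFact ≤ 1`
(isoperimetric inequality) and `FerDiam ≤ MajLen` (isodiametric) hold for
every geometrically valid record and are enforced as tests.

## The likelihood engine

All four evolutionary models are multivariate normal with a constant mean
vector; they differ only in the covariance structure among species:

| model | covariance | parameters (k) |
|---|---|---|
| Brownian motion | σ²·C, C_ij = shared time | σ², z₀ (2) |
| Pagel's λ | σ²·C(λ), off-diagonals scaled by λ | σ², z₀, λ |
| Ornstein–Uhlenbeck | σ²/2α · e^(−α·d_ij)·(1 − e^(−2α·s_ij)) | σ², z₀, α (3) |
| white noise | σ²·I | σ², μ (2) |

For any fixed structure matrix the mean and rate have closed-form GLS
profiles, so only λ (bounded in [0, 1]) and the OU pull strength α need a
1-D numeric search. Numerical contract: all solves go through a Cholesky
factorization — no explicit inverse — with log-determinants accumulated
from the factor diagonal; every fit's reported log-likelihood reproduces
through the generic Gaussian kernel at its reported parameters to 1e-10,
which the test suite asserts on random instances.

Choices made where the convention was open:

* **λ search**: an 11-point grid on [0, 1] brackets the optimum, refined by
  bounded golden-section search (tolerance 1e-8), with explicit boundary
  snapping; λ is hard-bounded at 1, matching the usual reporting convention
  for this statistic.
* **Significance of signal**: likelihood-ratio test of λ̂ against λ = 0 on
  χ² with 1 df. The boundary-mixture refinement (½χ²₀ + ½χ²₁) would halve
  small p-values; the plain χ²₁ convention is the one comparative packages
  report and is conservative, so it is used here.
* **OU parameterization**: Hansen's single-optimum form with the root state
  equal to the optimum and k = 3. α is optimized on a log scale over
  [1e-9/T, 1e3/T] (T = tree depth), seeded from a 30-point grid: the lower
  bound makes the BM limit reachable to 1e-4 in log-likelihood, the upper
  bound is effectively the white-noise limit for any realistically resolved
  tree. The OU fit requires an ultrametric tree (relative tolerance 1e-6 of
  depth); non-ultrametric trees only draw a warning elsewhere.
* **AIC, not AICc**, and Akaike weights computed over exactly the trio
  {BM, OU, WN} — weights are shift-invariant and sum to one, which the
  tests assert directly.
* Degenerate (constant) traits are skipped with a warning, never fitted.

## PSR curves and the choice of centering

The phylogenetic signal representation curve regresses a trait by OLS on
successively more eigenvectors of the double-centered patristic distance
matrix, plotting R² against the cumulative eigenvalue fraction ξ. Two
details deserve explanation.

**The patristic matrix is centered unsquared.** Classical principal
coordinate analysis double-centers element-wise *squared* distances. But a
patristic distance matrix already *is* a matrix of squared Euclidean
distances — on any tree, D_ij = C_ii + C_jj − 2·C_ij with C the Brownian
covariance, which is exactly the squared-distance identity of the Brownian
embedding of the tips. Centering D itself therefore gives B = −½·J·D·J =
J·C·J, whose eigenvectors diagonalize the (centered) Brownian covariance.
That is the property that makes the method interpretable: for a Brownian
trait the expected explained sum of squares after k eigenvectors is
proportional to the k-th partial eigenvalue sum, so the curve tracks the
45° diagonal, which is the reference line the whole analysis reads against.
Squaring the patristic distances first destroys this correspondence (on the
reference fixture it pushes the mean Brownian curve area from about −0.05
to −0.12). A consequence worth knowing: *squared* Euclidean distances in
the scaled eigenvector space reproduce the patristic matrix, and that is
the reconstruction identity the tests check.

**The diagonal is exact only as a ratio of expectations.** R²_k is the
ratio Σ_{j≤k} e_j z_j² / Σ_j e_j z_j² with z_j standard normal under BM, so
E[numerator]/E[denominator] equals ξ_k exactly, but E[R²_k] itself carries
a Jensen-type negative bias at early k whenever eigenvalues are unequal —
the clade structure of any realistic chronogram guarantees they are. On the
reference 27-species fixture the mean signed area of Brownian curves is
about −0.05 (200 replicates), not 0. The package therefore treats the
diagonal as the idealized reference it is and reports Monte-Carlo envelopes
instead: the white-noise mean R²_k = k/(n−1) is *exact* regardless of
eigenvalues (projections of an isotropic vector on any orthonormal basis
are exchangeable) and is asserted tightly, while Brownian placement is
asserted as "far closer to the diagonal than white noise", which is the
comparison the curves are used for in practice. Envelopes default to 999
simulations with pointwise 2.5/97.5% bands and a recorded seed; the
eigenvalue axis uses the retained positive spectrum (cutoff 1e-10 of the
leading eigenvalue; materially negative eigenvalues are treated as input
corruption, since a true tree metric has none).

The signed curve area is positive above the diagonal (faster-than-Brownian,
early-diversification patterns) and negative below (slower, OU-like
evolution), integrating R²(ξ) − ξ trapezoidally from the origin.

## Ancestral states and traitgrams

Traitgrams need point states at internal nodes, so the package computes the
joint ML reconstruction under BM: the states minimizing the branch-weighted
sum of squared changes, i.e. the solution of a weighted-Laplacian linear
system in which every internal state is the 1/branch-length-weighted
average of its neighbours. Its root solution equals the GLS root state of
the BM fit (asserted to 1e-8), all reconstructed states obey the
weighted-averaging maximum principle (they lie within the observed trait
range), and the whole map is equivariant under adding a constant.
Zero-length branches would make weights infinite and are rejected with
guidance to collapse them first. No uncertainty bands are produced — the
reconstruction feeds figures, not inference.

## Synthetic data: what it emulates and what it does not

The generators define the package's reference study conditions:

* `fixture_tree()` builds a 27-species, depth-80 chronogram with four
  monophyletic clades of sizes 7, 6, 5 and 9 — echoing a four-subgenus
  family whose radiation began around 80 My ago. The backbone splits fall
  within the first quarter of the depth (an early radiation) and clade
  crowns sit at 55% of the depth, giving the long subtending stems typical
  of such families; within-clade topologies are coalescent draws, rescaled,
  deterministic per seed.
* `simulate_traits()` draws replicates from the exact model covariances via
  a single pivoted-Cholesky factorization — one code path for all four
  models, so λ = 1 is *identical* (not just equal in distribution) to the
  BM draw under the same seed, a property the tests exploit as a
  cross-check. Default rate σ² = 1.
* `simulate_leaf_measurements()` parameterizes each species directly in
  (blade area, shape factor, aspect ratio, tooth density, relative tooth
  area) and inverts to raw measurements — perimeter from the shape factor,
  axes from an elliptical aspect ratio — so every record satisfies the
  geometric invariants by construction rather than by rejection. Leaf-level
  noise: lognormal area (sd 0.25 on the log scale), logit-normal shape
  factor, Poisson tooth counts; 5–6 leaves per simulated herbarium sheet.
  `example_species_params()` leaves the last quarter of the species list
  untoothed, mimicking an entire-margined tropical clade nested in a
  toothed family.

Calibration results under these conditions (asserted in the test suite and
recomputed by `scripts/acceptance.R`): Brownian data recover median λ̂ = 1
and white-noise data median λ̂ = 0 (200 replicates each); the generating
model or its nested OU neighbour takes the top Akaike weight in a large
majority of replicates, and BM data essentially never prefer WN; OU pull
strength α = 2/T is recovered within a factor of two in the median.

What passing these calibrations does *not* show about real data: the
generator draws traits from the exact model likelihoods being fitted, so
recovery demonstrates estimator correctness, not robustness. Real
herbarium measurements add intraspecific variation driven by light
environment and life stage, uneven sampling across species, measurement
error correlated within sheets, and chronogram uncertainty — none of which
the generator emulates. Simulation sizes in the tests (50–300 replicates
per property) were chosen to hold Monte-Carlo error comfortably below the
asserted margins while keeping the default suite quick.

## Known limitations

* Single-trait analyses only: no multivariate (correlated-trait) fitting,
  no measurement-error variance term, no multi-optimum OU or other
  transform families (early-burst, δ, κ).
* The λ likelihood is profiled, not integrated; p-values use the plain
  χ²₁ convention described above and can differ in the second decimal from
  implementations using the boundary mixture.
* PSR eigenvector selection strategies (broken-stick, autocorrelation
  criteria) are out of scope; the curve always uses the full retained
  spectrum.
* Discrete characters (margin type as a state) and climate-niche
  reconstruction are not modelled; ancestral reconstruction accepts any
  user-supplied continuous tip values instead.
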