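---
title: "Morphometric mapping of tooth crowns: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric mapping of tooth crowns: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crownmap)
```

## Why landmark-free

Mammalian molar crowns differ in cusp number, cusp arrangement, crest
(loph) development and outline shape. Across a panel that spans wild-type
mice, severely simplified mutants and wild murine species, there is no set
of landmarks present on every tooth, so classical geometric morphometrics
cannot be applied uniformly. `crownmap` instead parameterizes the whole
crown surface on a polar grid and treats model choice — which surface
variables, and how much spatial detail — as an explicit, criterion-driven
selection problem rather than a convention.

## The representation

### Standard pose

Every analysis starts from a triangle mesh plus two annotations that
cannot be derived from geometry alone: the cervical outline (the digitized
neckline where crown meets root) and a buccal anchor point. The
least-squares (total least squares, via SVD) plane of the outline becomes
*z* = 0 with the crown on the positive side; the outline centroid is moved
to the *z* axis; the buccal anchor is rotated to the +*x* half-plane. The
pose is therefore fully determined, which is what makes the pipeline
invariant to arbitrary rigid motions of the input — a property the test
suite checks directly. Anatomical labels are inputs by design: a mirrored
or arbitrarily rotated mesh carries no buccal information.

The model is then shifted down so that exactly the upper 80% of crown
height (highest cusp tip to cervical plane) lies above *z* = 0 and cropped
there with an exact plane clip (triangles crossing the plane are split, new
vertices receive *z* = 0 exactly). The clip, rather than vertex filtering,
guarantees every section curve terminates on the cut plane, which the
sampler relies on. Re-posing an already-posed crown is the identity; a
posed crown legitimately floats 0.2 × height above its own cervical plane,
so the sanity check for a detached outline only fires when the gap exceeds
30% of crown height.

### Sampling and maps

The surface is sectioned by `grid_L` equiangular vertical half-planes
through the *z* axis, starting at the buccal azimuth, and each section
curve is sampled at `grid_K` equal arc-length intervals from its innermost
point (*d* = 0, the crown centre) to its endpoint on the cut plane
(*d* = 1). Defaults are K = L = 300, the density used for the full-scale
analyses this package targets; the test suite and examples run at 16–48 to
keep runtimes in seconds, and all structural properties are
resolution-independent. When a half-plane meets the surface in several
curve components (overhanging flanks), the component ending on *z* = 0 with
the largest mean radius is kept — the outermost wall, matching the idea of
sampling from the axis to the outer intersection with the base plane.

Six K × L maps are recorded: height *h* (the sample's *z*), radius *r*
(distance from the *z* axis), the interpolated unit vertex normal
(*Nx*, *Ny*, *Nz*), and surface curvature *c*. The original description
leaves "surface curvature" unspecified; we use the cotangent-Laplacian
discrete mean curvature (magnitude of the mean-curvature normal over twice
the barycentric vertex area), signed positive for convexity against the
outward normal, because it is the standard estimator in dental topography
and is exactly testable: a unit sphere must give *c* = 1, which the
acceptance suite verifies at 10k faces (within 5% on at least 95% of
samples; the residual tail sits on the clipped boundary ring, where
one-ring estimators are undefined and values are filled from interior
neighbours). Curvature at sample points is interpolated along the crossed
mesh edges, like the normals.

### Normalization and weighting

Centroid size is CS = √Σ(*h*² + *r*²) over all K × L samples; *h* and *r*
are divided by CS and *c* is multiplied by it (curvature scales as
1/length), making the maps exactly scale invariant — a ×5 mesh reproduces
the normalized maps to 1e-10 in practice. The normal maps are already
dimensionless. CS uses the unweighted sum: weighting is a property of the
metric, not of the size variable, and keeping the two independent makes
each testable on its own.

Polar sampling over-represents the crown centre, so cell (k, l) carries
the area of its annular sector of the unit disk,
a_kl = π[(k/K)² − ((k−1)/K)²]/L (the weights sum to π exactly). Maps are
multiplied by √(a_kl/π): with square-root weights, the plain Euclidean
distance between weighted maps *is* the area-weighted L2 map distance, and
by Parseval the full-coefficient Fourier distance equals K·L times that
distance — an identity the acceptance tests check to 1e-6 on random maps.
Weighting with a_kl directly would square the areas inside every distance;
the √a convention is the one under which "weighted by area" describes the
realized metric.

## Fourier features and alignment

Both axes are treated as periodic and transformed with the standard
unnormalized 2D DFT. The angular axis is naturally periodic; the radial
axis is not, but low-pass selection only needs a fixed orthonormal basis,
and periodicity in *d* costs nothing once the maps are smooth at the scale
retained. "Filter size" *f* keeps coefficients whose radial and angular
frequency indices both lie in {0, ±1, …, ±f}: a (2f+1)² block. The
admissible range is 0 ≤ f ≤ ⌊min(K, L)/2⌋, with the retained index set
taken modulo the grid so that at the top of the range the whole transform
(including the Nyquist row/column of even grids) is kept and filtering is
exactly lossless; capping one step lower would silently discard the
Nyquist terms and break both reconstruction and the Parseval identity on
generic input.

Specimens are pre-oriented anatomically, so residual orientation error is
a small rotation about *z*. Alignment is restricted to integer grid
rotations (1.2° at L = 300, below any plausible signal at the filter sizes
in use), applied as phase factors e^{2πi·v·s/L} on angular frequency *v*,
and iterated generalized-Procrustes style against the running mean until
the total distance decreases by less than 1e-9 (cap 100 iterations, with a
warning and best-so-far result on non-convergence). The first specimen
seeds the reference, as in standard Procrustes superimposition. Alignment
runs once per (combination, filter size) on the concatenated retained
blocks, so all maps of a specimen rotate together; a duplicate specimen
rotated by a known number of columns is recovered exactly, matching a
brute-force search over all L shifts. Feature vectors concatenate real
then imaginary parts per map in combination order; the Hermitian-redundant
half of the block is kept, which doubles coordinates uniformly and leaves
all relative distances intact while keeping indexing trivial.

## Model selection

### Classification accuracy

`cv_accuracy_grid()` scores every (combination, filter size, learner) cell
by stratified k-fold cross-validation (default 10-fold, reduced with a
warning to the smallest class size; partitions are seeded and bit
reproducible). The learner families are a decision tree, multinomial
logistic regression, regularized linear discriminant analysis, a linear
SVM (cost 1), and k-nearest neighbours with k ∈ {1, 3, 5} on Euclidean
distance. The binary-only learners (SVM, LDA) are wrapped one-vs-one with
hinge-loss decoding — the error-correcting-output-codes construction for
which the original MATLAB defaults are not fully documented; one-vs-one
with loss-based decoding is that toolbox's default for these learners.
Features are z-scored on the training folds only before the
distance-based learners. The LDA ridge (1e-3 of the mean pooled variance)
and the rpart small-sample controls (minsplit 5, minbucket 2) exist
because the grid must stay well-defined when cells have few specimens per
class and more features than observations; cells that still fail
numerically are recorded as missing, never as zero accuracy.

Classification operates on individual specimens, not strain means:
cross-validation needs within-class replicates, and the strain label is
the class. `select_parsimonious_model()` breaks ties among cells within a
tolerance of the best accuracy by smallest filter size, then fewest map
variables, then learner order — smallest model first, matching the idea of
using the most parsimonious of the comparably accurate models.

### Phylogenetic signal

`phylo_signal_grid()` screens the same grid (no learner axis) by the
multivariate K statistic: with C the Brownian-motion covariance of shared
root-to-ancestor path lengths and a the GLS phylogenetic mean,
K = (D₀/D) / [(tr C − N/(1ᵀC⁻¹1))/(N−1)], D₀ = tr[(X−1a)ᵀ(X−1a)],
D = tr[(X−1a)ᵀC⁻¹(X−1a)]. K = 1 is the Brownian expectation; on a star
phylogeny K is algebraically 1 for any data, which the tests assert to
1e-8, and with p = 1 the implementation agrees with an independent
univariate Blomberg's K to 1e-10. Tips with several specimens are averaged
on the aligned feature vectors (means are only well-defined after
rotational alignment). Significance, when wanted, comes from tip-label
permutation: p = (1 + #{K* ≥ K}) / (n_perm + 1).

## Comparative analyses

Between-group PCA eigendecomposes the covariance of group means (via SVD,
rank ≤ groups − 1) and projects individuals and ancestors onto those axes;
this keeps group separation from being diluted by within-group variance
and keeps the axes interpretable as between-strain contrasts. Ancestral
states minimize the branch-length-weighted sum of squared changes (the
maximum-likelihood internal states under Brownian motion), solved as one
linear system in the graph Laplacian of the tree — verified against direct
numerical minimization and against an independent ML implementation.
Because the solution is a weighted average, reconstructed ancestors always
lie within the tips' per-axis range.

The pseudo-genetic code per gene is loss = 0, hetero = 0.5, normal = 1,
gain = 2; distance from wild type is Σ|code − 1| (one homozygous-null plus
one heterozygous-null locus gives 1.5), and the pairwise strain distance
is the L1 distance on code vectors — the only extension of
"sum of individual mutations" that reproduces the distance-from-WT
definition when one strain is wild type. Genes absent from a strain's
record count as normal. Two phenotype–genotype comparisons are exposed
separately because they answer different questions: the Pearson
correlation of per-strain disparities from wild type, and the Mantel
correlation of the full distance matrices (with simultaneous row/column
permutation, delegated to vegan).

PGLS with a categorical predictor whitens responses and dummy design by P
with PᵀP = C⁻¹ and evaluates trace-based sums of squares; significance
uses residual randomization under the intercept-only model (RRPP, 999
permutations by default), the convention of the geometric-morphometrics
PGLS literature. With C = I it reduces exactly to ordinary permutation
MANOVA. Type-I error of both permutation tests is calibrated to
0.05 ± 0.02 in the acceptance suite (500 null simulations each, 199
permutations per test — the permutation count enters only the p-value
resolution, not its validity). Phenetic distances default to the first
two PC axes, the plane in which the morphospaces are compared and hulls
are drawn; hull coverage classifies points as inside/on/outside with
exact orientation tests.

## The synthetic generator

`tooth_spec()` describes a crown as a superellipse cervical outline
(semi-axes a, b, exponent e) carrying a low basal dome plus one Gaussian
bump per cusp, tapered smoothly to meet *z* = 0 exactly at the outline.
Defaults emulate a generalized murine lower first molar in millimetres:
a = 1.5, b = 1.0, e = 2.5 (slightly boxy outline), basal dome 0.3 mm, and
two longitudinal rows of three cusps (height 0.7 mm, width 0.35 mm), the
six-cusp bauplan of the wild-type tooth. `make_strain_sample()` jitters
cusp positions additively and heights/widths log-normally with SD `noise`
(default 0.02 — a few percent, the order of within-strain variation);
generation is bit-reproducible per seed. `simulate_bm_traits()` draws
Brownian tip data with covariance σ²C for the phylogenetic components.

What the generator does *not* emulate is as important for reading the
tests: height-field crowns have no overhangs (the multi-component section
logic is exercised separately), no enamel/dentine distinction, no scan
noise or segmentation artefacts, and cusp bumps are isotropic Gaussians
rather than real cusp shapes. Passing tests therefore demonstrate that the
machinery — pose, sampling, spectra, selection, statistics — is correct and
calibrated, not that any particular biological effect size will be
recovered from real micro-CT material.

## Numerical choices and limitations

* Vertices exactly on a section plane are nudged by 1e-12 of the mesh
  scale; section segments are chained by endpoint proximity at 1e-7 of the
  mesh scale, and sub-tolerance segments are dropped.
* The section sampler places row K exactly on the cut plane, so the last
  height row is exactly zero by construction.
* `area_weight_matrix()` is exact (no quadrature); weights sum to π to
  machine precision for any grid.
* Degenerate inputs error early and by name: collinear outlines, buccal
  anchors on the rotation axis, sections that miss the axis (reported with
  the section index), zero centroid size, double weighting, singular
  phylogenetic covariances, unknown dosage classes.
* The full-scale grids (seven combinations × filter sizes 1–50 for
  classification, 1–100 for signal, at K = L = 300) are expensive by
  design; the package computes any sub-grid, and the vignette-scale
  examples restrict combinations and filter sizes rather than changing the
  method.
* Alignment is rotation-about-*z* only; teeth whose pose error is not a
  pure crown rotation (e.g. badly fitted cervical planes) need better
  annotations, not a larger search space.
* Between-group PCA with many more features than groups spans at most
  groups − 1 axes; variance fractions refer to that between-group
  subspace.
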