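---
title: "Auditing distributional bias in generated molecule sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing distributional bias in generated molecule sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(molaudit)
```

## The problem

Generative models for 3D molecules are trained on a reference database
and sample new molecules from the learned distribution. Even when most
samples are individually valid, the *distribution* of the generated set
can drift away from the training distribution: heteroatoms and
unsaturated carbon over-expressed, aliphatic motifs suppressed, sizes
and molecular weights shifted. `molaudit` quantifies and localizes that
drift. It compares a reference ("train") set and a candidate
("generated") set along four complementary views:

1. **Composition and geometry** — elemental fractions, atom-count and
   molecular-weight histograms, bonded-distance distributions, with
   Welch's unequal-variance *t* test and the two-sample
   Kolmogorov-Smirnov (KS) test deciding whether a shift is
   significant.
2. **Substructure** — SMARTS-based functional-group prevalence and a
   three-way ring classification (aromatic / unsaturated aliphatic /
   saturated) over the smallest set of smallest rings (SSSR).
3. **Latent chemical space** — a 2D plane spanned by the first
   principal component of a geometric descriptor and the first
   principal component of a bonding descriptor, fit jointly on the
   concatenation of both sets, with kernel-density maps and a two-stage
   clustering.
4. **A discriminator** — a balanced-class decision tree trained to tell
   the two sets apart from circular fingerprints; test balanced
   accuracy near 0.5 means the sets are statistically alike, and the
   tree's most important features name the chemistry that gives the
   generated set away.

Two corrective resamplers are included: atom-count-matched
downsampling of a generated set, and latent-grid "flattening" of a
training set (one molecule per occupied cell of a regular grid over the
latent plane) with a data-driven grid resolution.

## Molecule model and perception

Molecules are explicit-atom objects (hydrogens are atoms, coordinates
in Angstrom, bonds stored once per pair with a kekule order and an
aromatic flag). Three input routes converge to the same state:

* **SDF** carries coordinates and bond blocks; aromatic flags are added
  by Open Babel's aromaticity perception over the connection table.
* **XYZ** carries only coordinates. Bonds are perceived by the
  covalent-radius rule — atoms are bonded when their distance is at
  most `factor * (r_i + r_j)` with the shipped consensus radii and
  `factor = 1.3`, a value suited to chemically diverse organic sets —
  and orders/aromaticity are then assigned by Open Babel from the 3D
  geometry.
* **SMILES** gives a connection table with explicit hydrogens and no
  geometry; geometry-dependent stages require an explicit
  [embed_3d()] call.

Perception failures are *flags, not errors*: a molecule whose bonded
atoms physically overlap (closer than 0.6 of the covalent-radius sum),
whose atoms exceed their standard valence, or whose canonical SMILES
cannot be produced is marked invalid and excluded from substructure and
fingerprint analysis, mirroring how unparseable molecules are dropped
from real-world audits. `filter_set()` then removes invalid molecules,
disconnected structures and canonical-SMILES duplicates (first
occurrence kept) and reports per-reason counts.

## The two descriptors and the latent plane

The **structural descriptor** is an averaged SOAP-style power spectrum:
each atom's neighbour density (a sum of Gaussians of width `sigma`,
central atom included) is expanded in `n_radial` orthonormalized
polynomial radial functions inside a `cutoff` and real spherical
harmonics up to `l_max`; the rotation-invariant power spectrum per
species pair is averaged over atoms. Defaults: cutoff 5.0 A, 8 radial
functions, `l_max` 6, width 0.3 A. These were chosen once as standard
values for molecular environments of this size; the descriptor length
then depends only on the species list. The implementation evaluates
radial integrals by Gauss-Legendre quadrature and modified spherical
Bessel functions (series below `x = 1.5`, upward recurrence above),
accurate to about `1e-9` relative against a direct Bessel evaluation;
rotational invariance is exact by construction, and a dimer separated
beyond twice the cutoff equals the average of its monomers.

The **bonding descriptor** is an ordered, versioned schema of ~200
counts and scalars: per-element atom counts, bond-kind x element-pair
counts, ring-class x ring-size counts, functional-group match counts
from the shipped SMARTS catalog, and four scalars (molecular weight,
heavy atoms, hydrogen fraction, rotatable bonds). The schema object is
the source of truth for feature order; audits of the same pair always
see identical registries. Published audits of this kind use bespoke
feature lists of similar families but different lengths; the exact list
is configuration, not a constant of the method.

The **latent plane** takes PC1 of each descriptor, fit by two
independent PCAs (centering only) on the concatenated population, so
that both datasets live in the same coordinates; new sets can be
projected through the stored means and loadings without refitting. Only
PC1 per descriptor is plotted because one component captures the bulk
of each descriptor's variance for homogeneous organic populations
(the audit reports the exact fraction). The KDE over the plane uses a
Gaussian kernel with Scott's-rule bandwidth by default, on a grid
padded by 3.5 bandwidths so the density integrates to ~1.

**Clustering** is two-stage so clusters of very different sizes
survive: an incremental clustering-feature (leader) pass builds
fine-grained subclusters — each point joins the nearest subcluster
centroid within a threshold, auto-tuned so at least `4 * n_clusters`
subclusters exist — and Ward agglomeration merges the subcluster
centroids to the requested count. Because the input is the
concatenation of both sets, co-located molecules from different sets
share a cluster, which is what makes per-cluster train/generated
occupancy tables meaningful.

## Resamplers

`downsample_to_histogram()` matches the generated set's atom-count
histogram to the training set's: with reference bin probabilities
`p_b` and source availability `a_b`, the feasible scale is
`s = min over covered bins of a_b / p_b` and each bin contributes
`floor(s * p_b)` molecules, sampled uniformly without replacement. This
reproduces the reference shape at the largest feasible size with
per-bin rounding error at most 1; reference bins with no source
molecules stay empty and trigger a coverage warning. When the two size
distributions overlap poorly the feasible sample is small — that is a
property of the data, not a failure of the sampler, and real audits
therefore generate several times more candidates than they keep.

`grid_flatten()` divides the latent bounding box into `n_grid x n_grid`
equal rectangles (each axis over its own range) and keeps exactly one
uniformly chosen molecule per occupied cell. `select_n_grid()` picks
the resolution by flattening at each candidate, fitting a KDE to the
survivors, and scoring residual localization as the coefficient of
variation of the survivors' self-density; the minimizing candidate wins
and ties go to the smallest. CV of self-density was chosen as the
simplest testable operationalization of "lack of spatial localization";
a perfectly de-localized sample scores 0.

Both samplers are deterministic given a seed and serialize to JSON
plans that replay bit-exactly.

## The discriminator

Features are hashed circular (ECFP-family) fingerprints from Open
Babel, folded to a power-of-two width, optionally augmented with the
heavy-atom total and per-element counts — augmentation helps exactly
when composition is part of the signal. The data are split per class
into 20% test and the remainder 90:10 train:validation. Trees use class
weights inversely proportional to class frequency. The depth sweep
(3-17 by default) is implemented as depth-truncations of one deeply
grown tree: rpart's own `maxdepth` control provably changes greedy
split choices at shallow nodes, so truncation is the only way to get a
clean nested one-tree-per-depth family; validation balanced accuracy
selects the depth (ties to the shallowest, for interpretability), and
the held-out test balanced accuracy is reported together with
impurity-based importances (primary-split improvements of the selected
tree, summed per feature, normalized to 1). Balanced accuracy — the
mean of per-class recalls — is used throughout since class sizes often
differ after filtering and downsampling.

## The synthetic generator

Every stage is testable without downloads because the package ships a
seeded generator of valence-legal, connected organic molecules.
Molecules grow as random trees over a carbon skeleton (optionally from
an aromatic six-ring template), are closed into rings, promoted to
double/triple bonds (at most one promoted bond per atom, so no
cumulated systems), substituted with heteroatoms under organic valence
rules (divalent sulfur; aromatic template atoms are not substituted),
and completed with explicit hydrogens. Defaults define the reference
population: 5-22 heavy atoms (shifted Poisson, mean ~12), heteroatom
probability 0.25 over N/O/F/S/Cl with weights 0.34/0.34/0.10/0.13/0.09,
unsaturation probability 0.15, ring propensity 0.4, aromatic seeding
0.25 — a mid-sized, drug-like organic population.

`bias_config(cfg, shift)` defines the bias axis the audit is calibrated
against: heteroatom and unsaturation probabilities move linearly from
their base values to their ceilings (1.0 and 0.9), and ring propensity
shrinks by a factor `1 - 0.9 * shift`. Shift 0 is the identity —
paired sets are exchangeable; shift 1 is an extreme in which every
substitutable position carries a heteroatom, making the populations
nearly separable by composition alone. The power curve of the
discriminator over shifts 0, 0.25, 0.5, 0.75, 1 under these defaults
rises from chance (0.5) to above 0.95.

`embed_3d()` provides idealized geometry: breadth-first placement at
covalent-radius-sum bond lengths (scaled 0.87/0.78/0.92 for
double/triple/aromatic bonds) followed by spring relaxation with a soft
repulsion keeping non-bonded pairs outside the perception threshold.
The result is plausible, not DFT-quality: bond lengths are within a few
percent of tabulated values and `perceive_bonds()` recovers the
intended graph for >95% of molecules, which is what the geometry stages
need. Conformational realism (torsional preferences, ring pucker,
crystal-like packing) is *not* emulated, so passing geometry tests says
nothing about an audit's sensitivity to subtle conformer-level bias in
real data.

## What the simulations do and do not show

The generator reproduces the statistical *structure* the audit assumes
— paired sets with controllable shifts in composition, unsaturation,
ring content and size — but real training databases have correlated
chemistry (functional-group co-occurrence, synthetic accessibility,
conformer quality) that independent random growth does not capture.
Green tests therefore certify that the audit's statistics are
calibrated (false-positive rate ~5% at `alpha = 0.05` on exchangeable
sets), that its power rises monotonically along the modelled bias axis,
and that every statistic equals its brute-force definition; they do not
certify sensitivity to kinds of bias the generator cannot produce.

## Numerical choices and degenerate inputs

* Histograms: atom counts at bin width 1, molecular weight at
  10 g/mol, bonded distances at 0.02 A over [0.8, 2.2] A (resolving
  single/double/triple C-C peaks). Atom counts include hydrogens;
  heavy-atom counts are reported separately.
* Tests are two-sided; no multiple-testing correction is applied (the
  audit reports a small number of headline comparisons).
* KS uses the asymptotic Kolmogorov p-value with effective size
  `n_x n_y / (n_x + n_y)`. Molecular weights are discrete-ish (ties
  from repeated formulas); with the default population the measured
  null rejection rate stays within 5% +/- 2% at `alpha = 0.05`.
* PCA is centering-only; a descriptor whose columns are all constant is
  a degenerate-fit error. Constant columns are dropped before the fit
  and recorded in the stored feature registry.
* Ring classification: aromatic iff all ring bonds are aromatic,
  saturated iff no multiple/aromatic bond, else unsaturated aliphatic.
  The SSSR basis is not unique for fused systems, so per-class counts
  can depend on atom order there; totals and aromatic counts are
  stable, and only basis-independent quantities are asserted in tests.
* Clustering ties (equidistant centroids) resolve to the first
  centroid, making duplicate points land together deterministically.
* Problem sizes used by the shipped checks: paired sets of 1000/side
  for null calibration (1000 KS repeats, 20 discriminator seeds),
  500/side over five shift levels for the power curve, 150/side with
  idealized geometry for the latent-space audit. These sizes give
  standard errors well inside the asserted bands.

## Known limitations

* Aromaticity follows Open Babel's model; other toolkits disagree on a
  few percent of molecules, so group prevalences involving aromatic
  patterns carry that toolkit dependence.
* The bonding schema is a fixed default, not a reproduction of any
  particular published feature list; comparisons across software
  require exporting the schema (it is an ordinary data frame).
* The discriminator is a single tree by design — interpretability over
  raw accuracy; its accuracy is a lower bound on separability.
* `embed_3d()` geometries support distance-distribution and
  environment-descriptor analysis, not property prediction.
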