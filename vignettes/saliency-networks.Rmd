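---
title: "Saliency correlation networks from volumetric severity classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Saliency correlation networks from volumetric severity classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salnet)
```

## The analysis

`salnet` implements an end-to-end analysis of a structural-MRI severity
spectrum. A volumetric residual classifier is trained to separate
high-severity from low-severity subjects; per-voxel gradient attribution
("saliency") of its decision is aggregated over a two-hemisphere brain
parcellation; and the resulting subjects-by-regions saliency matrix drives
a set of downstream statistics:

* **cross-region saliency correlation networks** -- tie-corrected Kendall
  tau between every pair of regional saliencies across subjects, filtered
  at a significance level and a tau threshold, summarised by hub degree,
  spring-layout embedding, and lobe/hemisphere composition;
* **functional-network involvement** -- how the top-degree hub regions
  distribute over eight named functional networks (Default Mode, Salience,
  Frontoparietal, Social, Language, Sensorimotor, Dorsal/Ventral Attention,
  Limbic/Emotion), per tau threshold and averaged over the sweep
  0.1--0.6;
* **phenotype correlations** -- Kendall tau between five behavioural
  subscores (cognition, awareness, communication, mannerisms, motivation)
  and each cortical region's saliency across scored subjects;
* **hemisphere asymmetry** -- pooled-variance t statistics comparing
  per-region average saliency (and the high-minus-low saliency range)
  between hemispheres;
* **control congruence** -- how unscored, typically-developing controls
  behave when pushed through a model trained only on the scored groups,
  both as a classification rate and as the cross-region linear association
  between control and low-severity mean saliency.

Because real clinical imaging of this kind is access-restricted, the
package ships a synthetic-cohort generator that plants known structure,
and the test suite treats the whole pipeline as a parameter-recovery
problem against that ground truth.

## The synthetic cohort

`generate_atlas()` builds a deterministic two-hemisphere parcellation on an
isotropic grid (default $48^3$): 75 cortical regions per hemisphere tiling
an ellipsoidal shell, 13 subcortical regions per hemisphere tiling the
core, and two midline structures (brain-stem and fornix analogues), 178
regions in total. Regions are grown by multi-source breadth-first flooding
from farthest-point seeds, so they are connected blobs; the left hemisphere
is an exact mirror image of the right; lobes are anterior-to-posterior
bands; functional networks are assigned to mirror pairs, balanced across
the eight networks.

`generate_cohort()` adds, per subject, a shared anatomical template,
i.i.d. voxel noise (`noise_sd`, default 0.5 against template intensities of
order 10), and within each *affected* region an intensity/texture
perturbation of magnitude `effect_scale * (loadings %*% latents)`, scaled
by `asymmetry_factor` (default 1.5) on the left. Each latent factor loads
on the cortical regions of one functional network, so the planted
cross-region correlation structure has disjoint blocks.

Two design points matter for interpretation:

* **Latent 1 is the severity factor.** Its per-group ranges are disjoint
  (high above low above control), it alone determines the SRS-style total
  score (an exact affine map, so the severity split at 70/59 holds by
  construction), and its block carries the group contrast the classifier
  learns. The remaining latents are group-independent phenotype factors.
  If every latent carried the group shift, all affected regions would
  co-vary through the group contrast and the correlation network could
  never resolve the planted blocks -- the block structure would be
  confounded with severity itself.
* **Subscores are noisy linear functions of the latents** (weights drawn
  once per cohort, with the severity factor weighted most), so score-region
  correlations have a recoverable target.

Controls are drawn from the low tail of the severity factor and carry no
scores. The default cohort is 150 subjects (60 high, 60 low, 30 controls)
with 31 held-out test subjects, matching the reported-accuracy granularity
of the study the package emulates.

What the generator does *not* emulate: real morphometry (effects are
intensity perturbations, not deformations), scanner/site variation,
age/sex structure, registration error, and spatially correlated
physiological noise. Planted correlations follow functional networks,
which are spatially scattered, so lobe-composition fractions on synthetic
runs are small; the composition statistics are exercised for correctness
against hand tallies, not for realism of their values. Passing recovery tests therefore demonstrate that the
pipeline's statistics recover the structure they claim to measure, not
that the classifier would reach any particular accuracy on real data.

## The classifier

`model_config()` describes 2D and 3D residual networks. The `resnet50`
preset follows the classic bottleneck stage plan (3, 4, 6, 3 blocks); the
`linear` preset is a flattened linear scorer used for analytic checks. The
workhorse is the `small` desk-scale preset:

* a **voxelwise energy stem** -- a 1x1x1, stride-1 convolution into
  (by default) 8 channels followed by a squared rectifier, i.e. a set of
  rectified-quadratic intensity basis functions applied per voxel;
* two **residual blocks** (3x3x3 convolutions, strides 3 and 2, with 1x1x1
  projection shortcuts) that aggregate spatially; under the default
  `activation = "energy"` plan their activations are linear;
* global average pooling and a fully connected head: `softmax` (2
  logits), `tanh`/`sigmoid` (single unit), or `feature` (a fully connected
  layer of `feature_dim` units replacing the classification layer, with a
  softmax layer on top for gradient training).

The energy/linear plan was chosen deliberately, after measuring the
alternatives on synthetic cohorts. A plain-ReLU network separates the
groups easily but its input Jacobian is almost spatially flat, so gradient
saliency carries no regional information (affected-versus-unaffected
ranking near chance). Squared rectifiers throughout are unstable in
training. A nonlinear (rectified) trunk on top of an energy stem localises
attribution but couples it to a per-subject, severity-linked gain through
the deep gating, which induces spurious rank correlations between
*unrelated* regions (median tau around 0.37 in unaffected pairs at
n = 150) and collapses the thresholded graph into one component. With the
voxelwise energy stem and a linear trunk the Jacobian factorises exactly
into (local energy response) x (fixed spatial readout): attribution is
voxel-local, has no subject-level gain, and the correlation stage recovers
the planted blocks cleanly. The rectified variants remain available
(`activation = "energy_relu"` or `"relu"`).

Inputs are encoded as deviations from a **reference anatomy**: the
voxel-wise minimum over the training subjects (the floor of the severity
spectrum), divided by the global standard deviation of training
deviations. Anchoring the reference at the least-affected end makes the
encoded signal -- and with it attribution -- grow monotonically with the
planted effect; centering on the cohort mean instead makes saliency
V-shaped in severity and destroys monotone score-region correlations. The
encoding is stored in the fitted model and reapplied at prediction time.

Training is minibatch Adam (default 8 epochs, batch 8, learning rate
1e-3) on the scored subjects only; controls are rejected from both the
training and the test set by a protocol check. All randomness (weights,
shuffling, splits) is seeded, and two runs with the same seeds are
bit-identical.

## Saliency and its aggregation

`compute_saliency()` backpropagates the pre-activation score of the
model's predicted class (by default; a fixed class or the high-minus-low
contrast are options) to the input voxels. The default attribution is
**gradient x input in the model's encoded input space**: the absolute
gradient weighted by the voxel's encoded deviation from the reference
anatomy. The plain absolute gradient (`method = "gradient"`) is also
available; on synthetic cohorts it recovers the same region ranking but
dilutes the hemispheric contrast (the planted left-right asymmetry no
longer clears the alpha = 0.01 pooled t at desk scale), which is why the
deviation-weighted form is the default. Saliency magnitudes depend on the
per-cohort encoding scale and are never compared across cohorts in
absolute terms.

One measured caveat: attributing each subject's *predicted* class means
the readout row differs between predicted-high and predicted-low
subjects, which leaves a group-level factor in the saliency of weakly
affected regions. On synthetic cohorts this shows up as a mesh of weak
(but sometimes threshold-crossing) correlations among unaffected regions;
it does not disturb the planted-block components, which separate cleanly
from that mesh, but analyses that care about it can pass
`target = "contrast"` (the fixed high-minus-low score direction), which
removes the class dependence entirely.

`region_mean_saliency()` averages each map over the atlas regions,
yielding the subjects-by-regions matrix every downstream statistic
consumes. `hemisphere_summary()` applies the pooled-variance two-sample t
over the 75 + 75 per-region cortical averages (df = 148 under the default
parcellation), for both the mean saliency and the "saliency range",
defined as the absolute difference between the high-group and low-group
mean of each region. `sagittal_projection()` averages each hemisphere's
sagittal slices for overlay rendering.

## Correlation networks

`kendall_tau()` implements the tie-corrected tau-b statistic. The
two-sided p-value is an exact permutation enumeration for n <= 9 (all n!
relabelings, feasible and preferable at tiny n where the normal
approximation is poor) and the tie-corrected normal approximation
otherwise; the matrix fast path used by `pairwise_region_correlations()`
computes all pairwise concordance counts as one cross-product of
vectorised sign matrices and is tested to agree with the scalar
implementation exactly. Constant columns have no defined rank correlation
and are excluded with a warning.

Edges are filtered at raw p < 0.01 and tau > threshold (positive
correlations, matching the analysis convention; an absolute-value mode and
a Benjamini-Hochberg mode exist but are off by default, since the emulated
analysis applies no multiplicity correction). The threshold sweep is
{0.1, ..., 0.6}; thresholded summaries divide by 6. Tie-breaking is
deterministic everywhere: top edges by (tau descending, p ascending,
region-id pair), hub tables by (degree, mean incident tau, region id).

`spring_layout()` uses a seeded Fruchterman-Reingold embedding. The
convention that edge length reflects 1 - tau is implemented by giving each
edge attraction weight 1 / (1 - tau) (capped), so highly correlated
regions land closer and high-degree regions are pulled centrally while
isolated regions drift to the periphery.

`composition_stats()` reports within-lobe fractions (same lobe *and* same
hemisphere), per-hemisphere-lobe shares, hemisphere pairing fractions, and
-- on the subcortical-involving scope -- the attachment of
subcortical-involving correlations to left cortex, right cortex, or within
the subcortical set. An empty graph yields `NA` fractions: an undefined
proportion is not zero.

## Phenotype statistics

`score_region_correlations()` tests each of the five subscores against
each of the 150 cortical regions (2 x 75) across scored subjects, keeping
rows with p < 0.05 and tabulating per-hemisphere and per-lobe counts;
`alpha = 1` disables the filter and returns all rows.
`avg_std_grid()` builds the eight per-region vectors {LH, RH} x {Avg, STD}
x {High, Low}, reporting Pearson r and OLS slope off the diagonal and a
Shapiro-Wilk statistic on it (reported, never thresholded -- the grid is
descriptive). `control_congruence()` regresses the controls' per-region
mean saliency on the low-severity group's and reports r, slope and
intercept; "linear relationship" is quantified this way because the
emulated analysis names no statistic.

## The pipeline

`run_pipeline()` chains simulate, train (feature model plus kNN/SVM
hybrids and optionally the softmax/tanh/sigmoid head comparison),
saliency, correlation networks in both scopes with the full threshold
sweep, involvement, phenotype statistics and control congruence, writing
TSV/JSON/GraphML artifacts plus a manifest with content digests; reruns
under the same configuration are digest-identical. `pipeline_report()`
regenerates the headline tables from the on-disk artifacts alone. A thin
command-line wrapper lives in `inst/scripts/salnet-pipeline.R`.

```{r, eval = FALSE}
cfg <- list(seed = 1,
            cohort = list(effect_scale = 2.5),
            model = list(feature_dim = 64),
            train = list(epochs = 8, test_n = 31))
run_pipeline(cfg, "run1")
pipeline_report("run1")
```

## Problem sizes and numerical choices

The test suite and the acceptance script run the generator's default
conditions -- 150 subjects at $48^3$, 178 regions, 4 latent blocks, planted
effect 5 x the voxel noise, asymmetry 1.5 -- for recovery checks, and
smaller grids (down to $16^3$) for unit fixtures. Convolutions are im2col
gathers plus BLAS matrix products with exact backward passes
(finite-difference-verified); Adam uses the standard bias-corrected
moments; degenerate inputs (constant columns, empty graphs, single-subject
groups, unlabeled voxels) raise classed errors or `NA`s rather than
silent zeros.

## Known limitations

* The synthetic effects are additive intensity/texture perturbations;
  morphometric effects (volume, thickness, displacement) are out of scope.
* The energy/linear desk preset trades depth-style nonlinearity for exact
  attribution; the rectified variants train equally well but their
  saliency statistics inherit the gain confounds described above.
* Saliency magnitudes are per-cohort; only within-cohort comparisons
  (ranks, contrasts, correlations) are meaningful.
* Exact Kendall p-values are limited to n <= 9; beyond that the
  tie-corrected normal approximation is used, which is slightly
  conservative at small n.
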