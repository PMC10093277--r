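---
title: "Methods: uncertainty-aware PET/CT lesion evaluation and radiomics survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: uncertainty-aware PET/CT lesion evaluation and radiomics survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the parameters
that matter, the synthetic worlds it is tested on, and the numerical and
design choices made where the underlying method descriptions were silent.
It states no empirical result that the test suite or the acceptance script
does not itself compute.

## 1. Posterior checkpoint sampling

Deep segmentation networks fail silently; a practical uncertainty signal
comes from treating checkpoints of late-stage SGD as samples from the
weight posterior. The schedule implemented by `cycle_schedule()` splits a
budget of 1200 epochs into 3 cycles of `T = 400`. Within a cycle, with
`tmod = t mod T`:

* `lr(t) = 0.1` for the single restart epoch `tmod = 0`, kicking the
  optimiser out of its current optimum;
* `lr(t) = 0.01 · (1 − min(tmod, 0.8T)/T)^0.9` otherwise, a polynomial
  decay that freezes once 80% of the cycle has elapsed.

The decay denominator is the full cycle length `T`, not the plateau onset,
so the plateau learning rate is `0.01 · 0.2^0.9 ≈ 0.0023`, strictly
positive — the weights keep moving, which is what makes the plateau
checkpoints diverse. `checkpoint_epochs()` samples 10 epochs per plateau
uniformly without replacement (30 checkpoints over 3 cycles).

`posterior_mean()` averages the member probability maps;
`uncertainty_map()` computes the per-voxel **population** variance (divide
by n) per foreground class. Population rather than sample variance was
chosen so that the two-member {0, 1} disagreement case attains the
Popoviciu bound 0.25 exactly, which in turn makes the 0–0.5 operating-curve
threshold range a true superset of attainable uncertainty densities.
Variance is computed on probabilities, not argmax one-hots: the checkpoint
outputs are probability maps and thresholding before measuring spread would
discard exactly the graded disagreement the method exploits.

## 2. Lesion machinery and false-positive reduction

Lesions are connected components per class (default 26-connectivity in 3D;
configurable — 6-connectivity splits diagonal-touching blobs). The
uncertainty density of lesion `l` with `N` voxels is
`t_uncertain = (1/N) Σ I_uncertain(v) · l(v)`, using the lesion's own class
channel. `N` is the *lesion* voxel count: the global-volume reading would
make the statistic scale with image size and break the fixed 0–0.5
threshold range.

Detection is a coverage criterion, not an assignment problem: a
ground-truth lesion is detected iff some same-class predicted component
overlaps it with `DSC > 0.1` (strictly greater); unmatched predictions are
false positives. No one-to-one matching is enforced. Filtering removes
lesions with `t_uncertain > threshold` (strict), so a threshold of 0.5 is
inert by the variance bound.

**Proposal mask.** The operating-curve sweep consumes a predicted lesion
set derived from the ensemble. The posterior-mean argmax would erase
structures predicted by fewer than half the members — exactly the
false-positive blobs (member fraction 0.3–0.5) the filter is meant to
remove. `ensemble_prediction_mask()` therefore thresholds the posterior
mean at a permissive 0.25 by default: it is the proposal stage; the
uncertainty filter is the disposal stage. Setting `min_fraction = 0.5`
recovers the majority-vote segmentation used for Dice reporting.

## 3. The toy segmentation network

`build_network()` implements a small 3D U-Net with the three architectural
additions whose uncertainty behaviour the package studies: residual conv
blocks, squeeze-and-excitation (SE) channel attention per resolution stage,
and grid attention gates (GA) on each skip connection. All are toggleable;
with everything off the network is a plain two-conv-per-stage U-Net.
Choices the underlying description leaves open, fixed here once:

* SE is applied once per conv block (per resolution stage), reduction ratio
  2 at toy widths.
* GA uses an intermediate width of half the skip channels; the gating
  signal is the coarser decoder/bottleneck feature map, upsampled
  nearest-neighbour.
* Deep supervision weights halve per coarser level and are normalised to
  sum to 1; coarser targets are nearest-neighbour-downsampled labels.
* The Dice term of the loss averages over foreground classes only
  (background excluded), smoothing constant `1e-5`.
* Training is single-patch SGD with momentum 0.9 under the cyclic schedule,
  with the global gradient norm clipped at 12 per update — the convention
  of the pipeline family this network imitates. At toy scale the clip is
  load-bearing: the 0.1 restart epochs otherwise intermittently collapse
  the network (observed as held-out Dice 0), a failure mode full-scale
  training does not share.
* Toy schedule: `cycle_schedule(150, 3)` — cycle length 50 with plateau
  epochs 40–49, the smallest cycle for which "10 checkpoints per plateau"
  is satisfiable without replacement. Chosen once, before any acceptance
  measurement, and not revisited.

The backward pass is hand-written (im2col convolutions in C++, everything
1×1 as matrix algebra in R) and verified against central finite differences
in the test suite at relative error `< 1e-4`.

## 4. Preprocessing

Volumes resample to 1×1×3 mm (trilinear for scalars, nearest for labels;
half-voxel centre convention, edge clamping). CT is clipped to its own
[0.5, 99.5] percentile interval (linear-interpolation order statistics,
computed per volume — cohort-level statistics would need the cohort, which
the tool does not assume) and z-scored with post-clip statistics; PET is
min-max normalised. The crop locator applies Otsu thresholding to PET,
scans axial slices from the top of the stack, takes the four topmost slices
containing any above-threshold voxel, and centres a 260×260×104-voxel crop
on their joint in-plane centroid, extending 104 slices downward;
out-of-bounds voxels are padded and the offset is recorded so coordinates
map back. "First four slices containing the brain" is read as *topmost
four with any above-threshold voxel*; the alternative (first contiguous
run) differs only on pathological phantoms.

## 5. Phantoms: the stated world

`generate_phantom()` emulates the statistical structure downstream stages
assume, not anatomy: random ellipsoids with mild anisotropy for lesions
(volume-controlled; shape realism is irrelevant because only
volume/texture/overlap statistics flow downstream), a bright
high-uptake ellipsoid at the top of the stack as the brain anchor, CT in
Hounsfield-like units (background 40, lesion contrast +60, noise sd 10)
and PET in nonnegative uptake units (background 0.5, tumour 6, node 4,
brain 8, noise sd 0.3). Tumours and nodes differ in PET contrast so the
two classes are learnable. These levels were chosen once as plausible
soft-tissue/FDG figures.

`simulate_ensemble()` plants the two disagreement modes the uncertainty
mechanism exploits: per-member dilation/erosion of true lesions by up to
`boundary_jitter` voxels (membership in **all** members), and
false-positive blobs present in exactly `round(fraction · n)` members
chosen uniformly without replacement. Members are one-hot probability maps.
What a green test on this world does **not** establish: realistic
inter-member correlation structure, calibration of real ensembles, scanner
physics, or anything about the gated clinical dataset the method was
originally evaluated on.

`generate_survival_cohort()` draws event times from an exponential
proportional-hazards model `T ~ Exp(h₀ · exp(βᵀx))` (h₀ = 1/1000 per day)
with independent uniform administrative censoring whose horizon is
calibrated by root-finding so the expected censored fraction matches the
configured rate. Clinical covariates follow head-and-neck cohort
frequencies (82% male, 87% chemotherapy, HPV +/−/NA ≈ 53/12/35, …) and are
independent of outcome.

## 6. Radiomics extraction

No IBSI extractor exists in the supported dependency set, so the package
carries a compact one producing the standard 107-feature default set
(18 first-order, 14 shape, 24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM)
with fixed-bin-width discretisation (`floor(x/w) − floor(min/w) + 1`; 25 HU
for CT, 0.5 uptake units for PET). Known approximations, stated plainly:

* Shape "mesh" quantities are voxel-based: volume is voxel count × voxel
  volume; surface area counts exposed faces (exact for axis-aligned
  cuboids, an overestimate for smooth shapes); axis lengths come from the
  PCA of voxel-centre coordinates; maximum diameters subsample the surface
  at 2000 points for large ROIs.
* Texture matrices use merged-direction aggregation (26-neighbourhood for
  GLCM/GLDM/NGTDM, 13 directions for GLRLM) rather than per-angle
  averaging; GLSZM zones are 26-connected equal-level components.
* Feature values are validated on analytic cases (constant ROIs, cuboids,
  hand-counted two-voxel textures), not against an external extractor's
  numerics — numerical parity with any specific implementation is a
  non-goal.

ROI groups are the ten modality×region combinations; empty regions (e.g.
largest lymph node in a node-free patient) yield an all-NA feature row.

## 7. Survival modelling

`harrell_c()` counts comparable pairs directly (events vs longer-observed
patients, ties credit 1/2) and is cross-checked against a brute-force pair
enumeration. Feature selection is two-step: per-feature Cox fits ranked by
in-sample C (in-sample chosen; the first step is a screen, not an
estimate), ties broken lexicographically for determinism, then forward
aggregation over nested prefixes in rank order scored by cross-validated C
of the learner, keeping the best prefix (smallest on ties). "Best
combination" is read as *best nested prefix*; an exhaustive subset search
over the top 10 is left as a documented option the API shape permits.

The boosted survival learner is gradient boosting of depth-limited
regression trees on the first/second-order gradients of the Cox negative
log partial likelihood (Breslow ties), XGBoost-style leaf values
`−G/(H+λ)` and shrinkage (defaults: 100 rounds, depth 2, η 0.1, λ 1).
A gradient-boosted *classifier* is not compatible with censored time-to-
event evaluation by C-index; the proportional-hazards objective is the only
coherent reading. Risk groups cut the training risk scores at their 33rd
and 66th percentiles (linear-interpolation convention, boundary ties to the
lower group); Kaplan–Meier curves use the product-limit estimator and group
splits are tested with the standard two-group log-rank statistic, both
cross-checked against the survival package.

## 8. Fairness and explainability

Subgroups: age in fixed bins (0–50, 50–60, 60–70, >70), size variables in
cohort quartiles, categorical variables one bin per level with missing
values as their own bin. Metric comparisons use the Mann–Whitney rank-sum
test (tie-corrected normal approximation, two-sided, no continuity
correction) for per-unit metrics, and a two-sided permutation test for
cohort-level metrics (C-index, aggregated Dice): the observed statistic is
subgroup-minus-complement (complement rather than the overlapping "total",
the standard exchangeable construction), the null shuffles subgroup labels
over units, and the p-value carries the +1 correction
`(1 + #{|null| ≥ |obs|})/(1 + B)` so finite permutations never report zero.
Permutations on which the metric is undefined (no comparable pairs) are
resampled and counted. No multiple-testing correction is applied by
default.

Shapley attributions are computed exactly by coalition enumeration with a
background-marginal value function — feasible because selected feature sets
are small (complexity `O(2^m · n_background)` model evaluations per
patient, refused for m > 14). Local additivity (attributions + base value =
prediction) holds identically by the Shapley efficiency axiom, which the
tree-path-dependent approximation this replaces does not guarantee.

## 9. Pipeline, determinism, limitations

`run_pipeline()` executes phantom → preprocess → toy-train → posterior →
fp-reduce → seg-eval → radiomics → survival → fairness, with per-stage
seeds derived from a master seed, a manifest of outputs and MD5 checksums
(wall-clock timings go to a separate file so the manifest is
byte-reproducible), and run-level idempotence (a completed run directory is
not recomputed unless forced). The NIfTI writer produces timestamp-free
gzip output, so artifacts are checksum-stable across runs.

Known limitations: the phantom world is deliberately minimal (no scanner
physics, no anatomy, no DICOM); the network is toy-scale and its
paper-scale configuration (192×192×64 patches, fivefold ensembling) is out
of budget by design; radiomics values are IBSI-*style*, not
pyradiomics-identical; and none of the original study's dataset-level
numbers are reproducible here — the acceptance criteria are property-based
for exactly that reason.
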