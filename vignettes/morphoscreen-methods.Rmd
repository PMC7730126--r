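---
title: "Methods: analysing combinatorial 3D-microenvironment morphogenesis screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analysing combinatorial 3D-microenvironment morphogenesis screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The screen and its analysis problem

High-throughput 3D microenvironment screens culture an epithelial cell line
(typically MCF10A mammary cells) inside synthetic PEG hydrogels whose
properties are varied combinatorially by a liquid-handling robot: matrix
stiffness (set by polymer content), protease (MMP) degradability of the
crosslinker peptide, grafted ECM proteins (laminin, collagen IV, fibronectin
in all subsets, including a blank control), and soluble EGF in the overlay
medium. After fixation and actin staining, each well is imaged as a
z-collapsed single-channel projection, and every colony is scored into one of
four morphogenetic phenotypes:

* **polarized** — round colony with a central actin belt (normal apico-basal
  morphogenesis, acinus-like);
* **non-polarized** — round colony, spatially uniform actin;
* **spread** — elongated colony with diffuse actin fibers;
* **inverted** — actin bundles concentrated at the colony edge (aberrant,
  "inside-out" organisation).

`morphoscreen` implements the full analysis chain: factorial design
enumeration and well assignment, colony segmentation, a 102-measurement
morphometric profile per colony, a random-forest phenotype classifier with
an iterative validation protocol, per-well phenotype frequency profiles, and
three complementary statistical readouts — SVD profiling of the feature
matrix, per-phenotype binomial GLM factor signatures with stepwise-AIC term
selection and Tukey–Kramer contrasts, and top-5 % ranked condition maps.
Because raw screen images are not publicly deposited, the package also ships
a first-class synthetic plate generator with planted condition effects, so
that every stage can be validated against known ground truth.

## The synthetic plate generator

The generator is the package's study definition, not a test fixture.

**Design.** The default `factor_levels()` reproduce the screen's
4 stiffness × 2 degradability × 8 ECM-subset × 2 EGF full factorial
(128 conditions) in triplicate, i.e. 384 wells; wells are assigned by a
seeded permutation over 384-well plate coordinates, so plate position
carries no information (the screen reports no spatial effects, and whether
replicates were spatially randomised is not stated — we randomise).

**Counts.** Per-well colony counts are negative binomial, parameterized by
the reported median (159) and spread (47). The NB mean is calibrated
numerically so the distribution's median hits 159 exactly (`count_params()`);
a zero spread degenerates to a constant count.

**Phenotype mixtures.** Each condition maps to a 4-vector of phenotype
probabilities through a temperature-scaled softmax over additive logit
effects (`phenotype_effect_model()`). The planted defaults encode the
structure the downstream analyses are expected to recover: no EGF or 8 kPa
stiffness drives wells to near-pure inverted colonies; 2–4 kPa with EGF
yields polarized colonies, displaced toward non-polarized whenever the ECM
subset contains fibronectin; 0.5 kPa enriches spread colonies.
Degradability deliberately carries **no** logit effect; instead it sets the
softmax temperature (1.05 for the degradable crosslinker vs 1). This makes
within-well phenotype entropy strictly higher in degradable conditions while
displacing mean frequencies by only ~0.002 in absolute terms. That
calibration is intentional: any entropy-raising mixing must displace means
somewhat, and the temperature is chosen so the displacement stays well below
the detection limit of the global GLM at full plate scale — the generator
would otherwise contradict the degradability-null structure it is supposed
to plant. A consequence worth stating: with so small a gap, the top-5 %
ranked wells are *not* strongly enriched for non-degradable conditions;
that finer-grained contrast of the original screen is outside what this
planted model can reproduce simultaneously with the degradability-null GLM.

**Rendering.** Wells are 1024 × 1024 px projections at 5.2 µm/px (a 5.3 mm
field), with colony radii log-normal around 13 px — 100–200 µm diameters,
matching the screen's scale. At ~1.3 µm/px (the naive reading of typical
microscope resolution) colonies of that physical size cannot be placed
without overlap at 159 per well — the total colony area would exceed the
image — so the coarser pixel size is a deliberate geometry choice.
Each phenotype has a distinct renderable actin architecture: polarized disks
carry a bright annulus between 0.33 and 0.57 of the radius (peak at the ring
containing relative radius 0.45); inverted disks a bright rim beyond 0.85 of
the radius over a dark interior; non-polarized disks are uniform with fine
multiplicative speckle; spread colonies are rotated ellipses (axis ratio 2,
radius scaled 1.4×) with a sinusoidally perturbed boundary and lower mean
intensity. Intensities are 16-bit counts over a constant background (400)
with additive Gaussian read noise (sd 60). Placement is sequential rejection
sampling with a non-overlap margin; if a crowded draw cannot be placed
within 500 attempts, the count is reduced with a warning (this truncates
only the upper tail of the count distribution in spread-heavy wells).

**What the generator does not emulate.** No illumination gradients, PSF
blurring, colony–colony contact or clumping, 3D structure, fluorophore
photophysics, or segmentation-hostile artefacts (debris, edge wells).
Passing tests therefore demonstrate that the analysis chain is correct and
recovers planted effects under the stated noise model — not that the
segmenter or classifier would reach the same accuracy on real micrographs,
where declumping and illumination correction would matter.

## Segmentation

Gaussian smoothing (σ = 2 px) → global Otsu threshold → hole filling →
8-connected labelling → area filter (`min_area` = 100 px, far below the
smallest rendered colony, ~200 px). Numerical choices:

* Otsu is computed on the image normalised to its observed range; on the
  full 16-bit range the histogram of a low-dynamic-range image collapses
  into a few bins and the threshold is meaningless.
* A contrast guard declares a well empty when the Otsu split separates the
  two classes by less than 4 background standard deviations — otherwise a
  background-only well is split through the middle of its noise.
* Labelling is 8-connected; the underlying flood fill is 4-connected, so a
  union–find pass merges labels that touch diagonally.
* Touching colonies are not split (the generator guarantees non-overlap;
  declumping is out of scope). Coordinates are 0-based, pixel-centred,
  (column, row) = (cx, cy); bounding boxes are half-open.

## The 102-measurement morphometric profile

The screen's measurement list is a CellProfiler export that the publication
does not enumerate; the package defines a documented 102-measurement
contract with the same three-family structure — the *count* and the family
split are the conformance contract, the individual names are this package's.

* **Area-shape (20):** area, perimeter, eccentricity, compactness
  (P²/4πA), form factor, solidity, extent, equivalent diameter, major/minor
  axis lengths and their ratio, Hu's seven invariant moments, and the
  mean/sd of centroid-to-boundary radii. Eccentricity and axes come from the
  moment-equivalent ellipse. The perimeter is the corrected chain length of
  the traced boundary polygon (Vossepoel–Smeulders step weights with a
  halved corner correction): the uncorrected polygon overestimates a
  digitized disk's perimeter by ~5 % (compactness 1.11), while the full
  correction pushes convex digital shapes below the isoperimetric bound
  (compactness 0.997); the halved correction keeps a digitized disk at
  compactness ≈ 1.04–1.07 and every tested irregular shape ≥ 1.
* **Intensity (30):** order statistics (mean, median, sd, min, max,
  quartiles, MAD, CV, integrated), mass displacement, edge vs interior
  statistics (edge = pixels with a 4-neighbour outside the mask), and a
  4-ring radial distribution: per ring, the fraction of total intensity
  (FracAtD), that fraction relative to the ring's area share (MeanFrac),
  and the coefficient of variation over 8 angular wedges (RadialCV).
  The normalized radius is computed against a per-direction boundary radius
  (32 angular sectors, circularly filled), so rings follow the colony's
  shape rather than its bounding circle.
* **Texture (52):** 13 classical co-occurrence statistics (angular second
  moment, contrast, correlation, variance, inverse difference moment,
  sum average/variance/entropy, entropy, difference variance/entropy, and
  both information measures of correlation) on 8-level min–max quantized
  intensities, at offset distances 1 and 4 px, summarised as mean and range
  over the four 2D directions. Matrices are restricted to pixel pairs
  inside the mask, symmetrized, and normalised to sum 1. Colonies smaller
  than an offset yield zeros with a warning.

All measurements are translation invariant; intensity scaling by *c* scales
the intensity order statistics by *c* and leaves shape, RadialCV, MeanFrac
and texture unchanged (texture through the per-colony min–max quantization).

## Classification protocol

The screen's interactive protocol — at least 30 training samples per class,
validation on at least 10 held-out examples, iterated until at least 15 are
correctly classified — is implemented with one documented interpretation:
"15 correctly classified" counts *cumulative correct validation examples
across iterations* (the original phrasing does not say which set the 15
refer to); the threshold is configurable in `training_protocol()`. Each
iteration refits the forest with the previously validated batch folded into
the training set, emulating annotate-and-refine. In synthetic mode the
training labels come from generator ground truth on a seeded subset of wells
(the stand-in for the human annotator; `label_fraction`, default 25 % of
wells). Forest hyperparameters (100 trees, √p features per split) are
package defaults — the publication gives none. A confidence floor for an
"unclassified" class exists but defaults to off; the screen's reported class
fractions (67 + 13 + 7.7 + 6.7 ≈ 94.4 %) suggest some colonies were excluded
upstream, but the mechanism is not recoverable, so we do not model it.

## Factor analysis

Features are z-scored per measurement (constants dropped with a record),
decomposed by thin SVD; component signs are fixed so each component's
largest-magnitude loading is positive. Variance explained is σᵢ²/Σσ².
Component selection takes the first components reaching 73 % cumulative
variance, capped at 10. Component–phenotype association is the Pearson
correlation between colony-level scores (unit-norm left singular vectors —
PCC is scale invariant, so not multiplying by the singular values is
inconsequential) and the phenotype frequency of each colony's well of
origin, broadcast to colonies. The well-averaged variant sits behind
`aggregate = "well"`; the colony-level reading is the default because the
screen correlates *individual* left singular vectors with frequencies.
Zero-variance frequencies are flagged undefined rather than reported as 0.
Phenotype co-occurrence clustering uses correlation distance (1 − r) with
average linkage over the four frequency vectors indexed by well; the linkage
and metric are unstated in the original figure, and this is the conventional
choice for frequency profiles.

## GLM factor signatures

Per phenotype, the per-well count of that phenotype against the well total
is modelled as a binomial GLM (logit link) in MP + DG + EC + SF. The screen
reports "proportions" but models counts per well; binomial totals reconcile
the two. A quasi-binomial dispersion (reported with every fit) guards
against overdispersion. Wells with zero colonies are excluded and listed.
Cells with proportions of exactly 0 or 1 produce separation (diverging
coefficients or standard errors); the guard refits with half-count
shrinkage (0.5 pseudo-successes and -failures per well) and flags the model.
Stepwise AIC (both directions, main effects forced, all two-way interactions
as scope) runs on the binomial twin — AIC is undefined under
quasi-likelihood — and the selected formula is refit with the original
family. The full four-way interaction scope is combinatorially fragile at
384 wells and deliberately not offered. LS-means are computed on the link
scale over the factor grid and back-transformed with delta-method errors
(emmeans); an ordinary weighted linear model on frequencies is available
behind `family = "linear"` for comparability with proportion-scale analyses.
All pairwise level contrasts use the Tukey–Kramer studentized-range
adjustment, which honours unequal level sizes; significance codes are
\*\*\* < 0.001, \*\* < 0.01, \* < 0.05.

## Ranked frequency maps

Wells are ranked by a phenotype's frequency; ties break by colony count
(more colonies = more trustworthy frequency) and then well id, making the
order total and reproducible. The top ⌈5 %⌉ wells are selected and, per
factor category, the level composition of the selection is reported as
percentages summing to 100. The original description is ambiguous between
ranking wells and ranking triplicate-averaged conditions; wells are the
default and the condition-averaged variant sits behind `by = "condition"`.
Raising the fraction to 1.0 reproduces each category's design margins
exactly.

## Validation-study sizes

The test suite validates the chain at three scales, chosen as the smallest
studies that exercise the full structure: (i) module tests on single wells
and closed-form shapes; (ii) an end-to-end plate with the complete
128-condition design in duplicate (256 wells, 512 × 512 px, ~40 colonies
per well, ~10,000 colonies) for classifier accuracy, GLM sign recovery,
ranked maps and clustering; (iii) null-model calibration on a 4 × 2 × 2 × 2
design (64 wells) with 200 simulation replicates for per-factor type-I
error and Tukey–Kramer family-wise error. The degradability null is tested
across the four phenotype models at a Bonferroni-corrected threshold
(0.05/4), since it is four simultaneous null hypotheses.

## Known limitations

* The 102-measurement manifest is a documented stand-in with the same
  family structure as the original CellProfiler export, not a
  reconstruction of it.
* Segmentation assumes flat background and non-touching colonies; no
  declumping, no illumination correction.
* The planted effect model is additive on the logit scale (plus the
  degradability temperature); it cannot express arbitrary interactions,
  and the degradability contrast in top-ranked wells is intentionally weak
  (see above).
* Real-data headline numbers (56,892 colonies; 31 PCs for 90 % variance;
  absolute LS-mean values) depend on unreleased raw images and are treated
  as report shapes, not reproduction targets.
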