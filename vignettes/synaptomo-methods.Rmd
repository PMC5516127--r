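---
title: "Quantifying synapses and tau spread in array-tomography volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying synapses and tau spread in array-tomography volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement problem

Array tomography images resin-embedded tissue cut into ribbons of 70 nm
serial sections. Each section is immunostained and imaged separately, and
the sections are computationally reassembled into a volume whose axial
resolution is set by the ultramicrotome, not the optics. Synaptic
compartments appear as small punctate objects ("puncta"): presynaptic
terminals labelled by synaptophysin, postsynaptic densities by PSD95. In a
mouse model in which mutant human tau is expressed by entorhinal-cortex
neurons whose terminals also carry a GFP reporter, three questions are
asked of such volumes:

1. What is the density of presynaptic terminals — all of them, and the
   GFP-positive subset belonging to the tau-expressing circuit?
2. What fraction of postsynaptic densities contain human tau (detected in a
   separate tau channel), i.e. how far has tau spread across synapses?
3. Among putative synaptic pairs — a GFP-positive presynapse apposed to a
   postsynapse within 0.5 um — in what fraction are *both* compartments
   tau-positive?

`synaptomo` implements this entire chain: section registration,
thresholding, 3D object reconstruction, the single-section noise filter,
overlap colocalization, pair matching, per-mouse aggregation, and the
group statistics, plus a ground-truthed synthetic scene generator used to
validate every stage.

## Processing model, stage by stage

### Registration

Sections are aligned by integer-pixel translation only. Adjacent-pair
shifts are estimated on a single reference channel (the total-presynapse
channel by default — it has the densest signal) and composed cumulatively
back to the first section; the same transform is applied to every channel,
because all channels of a section are acquired on the same physical
section. Exposed borders are zero-filled and the transform is returned for
audit.

The shift estimator maximizes a *support-weighted* normalized
cross-correlation over all integer shifts within a search radius (±10 px
by default). Plain correlation is fragile on sparse punctate images: when
two adjacent sections share few puncta, the chance apposition of one
unrelated bright punctum pair can out-correlate the true shift. The score
is therefore NCC multiplied by `log(1 + s)`, where `s` counts overlap
positions at which both images exceed their own upper-decile intensity —
a shift aligning many puncta always beats a shift aligning one brightly.
Ties prefer the smallest shift, so estimation is deterministic. Rotation,
affine and subpixel registration are deliberately out of scope:
translation is sufficient for section-to-section ribbon jitter and is
exactly testable against planted transforms.

Registration needs shared structure. A punctum spanning several 70 nm
sections appears in adjacent images; fields much smaller than the default
10 um crop carry few such shared objects per pair and can be unregistrable
in principle. The package's own tests therefore exercise exact transform
recovery on full-size fields and keep very small fields for logic tests
that bypass alignment.

### Thresholding

Each channel is binarized per section — not per volume, because staining
intensity varies from physical section to section along a ribbon. The
default `"combined"` method takes the union of two classical automatic
thresholds: Otsu (maximizing between-class variance; reliable for the
bright punctum class) and the triangle method (geometric threshold for
unimodal histograms with a faint tail; admits dim puncta). The union
honours the requirement that both high- and low-intensity synapses
segment, without per-image hand tuning. The algorithm pair is
configurable; thresholds actually used are recorded per section.

One guard is applied: synaptic puncta are sparse, occupying a few percent
of any real section. If an algorithm's threshold would mark more than
`max_foreground_frac` (default 25%) of a section as foreground, that
section is treated as signal-free for that algorithm and contributes empty
foreground. Without this, an automatic threshold applied to a channel
with no signal at all — the human-tau channel of a control animal — would
simply split the noise distribution in half and report massive spurious
colocalization. The guard generalizes the degenerate constant-image case
and is recorded as an `NA` threshold.

### 3D object reconstruction and the noise filter

Foreground voxels are grouped into maximal 26-connected components
(8-connectivity in plane plus all inter-section diagonals). The permissive
connectivity is chosen so that a punctum continuing across sections stays
one object despite residual one-pixel misalignment. Centroids are
unweighted voxel means in physical micrometres (anisotropic: 0.1 um
in-plane by default, 0.07 um axially); volume is voxel count times the
voxel volume; `section_span` counts distinct sections touched.

The noise rule is the field's standard one: objects present in only a
single section are removed. Real synaptic structures span multiple 70 nm
sections; single-section objects are staining speckle. The filter keeps
exactly the objects with `section_span >= 2`, is idempotent, and is the
only size filter applied — there is no minimum in-plane area rule. Border
objects are retained by default (`exclude_border` is available).

### Colocalization and synaptic pairs

Tau colocalization is classified per target punctum: the overlap fraction
is the share of the punctum's *own* voxels lying inside the reference
(tau) foreground, and the punctum is positive when that fraction reaches
`min_overlap = 0.5` (inclusive). The fraction is directional — of the
synapse object, not of the tau object — because the scientific question is
which synapses contain tau. The same 50% rule classifies GFP positivity of
presynapses, by symmetry.

Putative synaptic pairs are (GFP-positive presynapse, postsynapse)
candidates whose 3D centroid distance is at most 0.5 um (inclusive),
matched one-to-one greedily by ascending distance with deterministic tie
breaks. Centroid distance is used rather than surface gap because it is
reproducible without a surface model; an all-candidates mode exists for
sensitivity analysis. A pair is tau-positive only when both compartments
are.

### Aggregation and group statistics

Two distinct per-mouse aggregation rules are used, and they are not
interchangeable: density statistics are the *mean* over a mouse's crops,
while percentage statistics are pooled *by sums* — total positives over
total objects across crops — never the mean of per-crop percentages.

Density statistics are compared by a two-way ANOVA (genotype x age),
computed from the classical sum-of-squares decomposition on balanced
designs and from Type-II sums of squares (via nested least-squares
residuals) on unbalanced ones; cohort sizes of 3-6 mice per cell are the
norm, so unbalance is expected and Type II is the conventional choice when
interactions are weak. Colocalization percentages are compared with the
Kruskal-Wallis rank test, implemented from the defining formula with the
standard tie correction and the chi-square approximation on k-1 degrees of
freedom; when all observations are identical the statistic is defined as
H = 0 with p = 1. A Shapiro-Wilk gate at alpha = 0.05 chooses the branch
automatically, and the branch can be forced to mirror a predetermined
analysis plan (densities parametric, colocalization nonparametric — the
convention the package's report follows, including mean ± SEM for
densities and median [IQR] for percentages).

## The synthetic scene generator

Real mouse volumes are not available at desk scale, so validation uses
generated scenes with exact ground truth. The generator plants:

* presynapses and postsynapses as ellipsoids with in-plane radius
  ~N(0.2, 0.04) um, spanning 2-5 consecutive sections (the z semi-axis is
  span x 35 nm about the span midpoint, so each object intersects exactly
  its stated sections);
* a GFP flag on 30% of presynapses, and tau flags on 10% of postsynapses
  and 80% of GFP-positive presynapses (tau travels in the labelled
  axons); control-genotype scenes set both tau fractions to zero while
  keeping the GFP reporter, as in the animal model;
* planted synaptic pairs: 60% of GFP-positive presynapses receive a
  partner postsynapse at an isotropic offset of mean 0.25 um, keeping
  pairs inside the 0.5 um detection radius;
* dim and bright amplitude classes (uniform on 25-40 and 150-220, half
  each) so the combined-threshold claim is exercisable;
* per-section jitter translations up to ±3 px (section 1 is never
  jittered, so planted translations equal the cumulative transforms an
  aligner should recover), Gaussian background (level 10, sd 5), and
  single-section speckles (5 per section per channel) that the
  persistence filter must remove.

Defaults were chosen once for testability and realism: a 10 x 10 um field
over 30 sections (2.1 um depth, 210 um^3), densities 0.6 um^-3
(presynapses) and 0.5 um^-3 (postsynapses) — the source analyses report
relative, not absolute, densities, so these sit in the plausible range for
neuropil while giving ~100 postsynapses per scene, enough that five scenes
pool over 500 objects for binomial checks. A minimum same-channel centroid
separation of 0.5 um keeps touching-object merges rare, so detected counts
can be compared to planted counts within a few percent.

What the generator does *not* emulate — and hence what passing tests do
not certify on real data: point-spread blur and chromatic offsets between
channels, staining-efficiency variation along a ribbon, lost or folded
sections, rotational misalignment, and object shapes beyond ellipsoids.
The generator validates the measurement chain, not the microscope.

## Numerical conventions

* Voxel centres sit at `(i - 0.5) x` spacing; physical coordinates are
  micrometres with x along columns, y along rows, z along sections. Crops
  are half-open `[origin, origin + size)` and record their origin so
  centroids stay reportable in parent coordinates.
* All thresholds and classification rules are inclusive (`>=`) at their
  boundaries: a punctum with exactly 50% overlap is positive, a pair at
  exactly 0.5 um is a candidate.
* Component labels, pair order and report rows have deterministic
  orderings (lexicographic minimum voxel; ascending distance with id tie
  breaks), so identical inputs give byte-identical outputs.
* One master seed drives everything; per-scene and per-channel substreams
  are derived from it, so adding a channel or a mouse does not perturb the
  others.
* TIFF export is 16-bit grayscale, one page per section; intensities are
  integers on [0, 65535] and round-trip exactly.

## Problem sizes used in the test-suite and acceptance runs

The package's own checks run on: full-size single scenes (10 x 10 um, 30
sections) for detection quality and planted-fraction recovery (five seeds
pooled for the binomial criteria); reduced cohorts (two genotypes x three
ages x two mice, one crop) for end-to-end determinism; 2,000-replicate
null simulations at 3-6 mice per cell for the type-I calibration of both
tests; and small pre-aligned fields for pure logic tests. The acceptance
script runs a three-mouse-per-cell cohort at full scene size. These sizes
are the package's own choice of test conditions; all statistical claims
are made at the corresponding n.

## Known limitations

* Translation-only registration; rotational drift along a ribbon is not
  corrected and will degrade long stacks.
* Touching puncta are not split (no watershed); at the default densities
  merges are rare, but crowded tissue will undercount.
* The Kruskal-Wallis p-value uses the chi-square approximation, which is
  conservative below ~4 observations per group; exact permutation
  p-values are not implemented.
* GFP positivity is classified on synaptophysin objects via overlap; a
  direct count of GFP-channel objects is available
  (`label_components` on the GFP mask) but is not the default reading.
* The 10 um field notation in the source protocol is read as a
  10 um x 10 um field; a literal 10 um^2 area is expressible through
  `footprint_um` if preferred.
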