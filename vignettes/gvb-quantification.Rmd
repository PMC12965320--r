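---
title: "Quantifying GVB-positive neurons in high-content screens: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying GVB-positive neurons in high-content screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gvbscreen)
```

## The measurement problem

Granulovacuolar degeneration bodies (GVBs) are neuron-specific lysosomal
structures that form in a subset of neurons carrying pathological tau
assemblies. Their dense cores are strongly immunopositive for markers such
as pPERK, CK1&delta; and GOLGINA4, which appear as bright punctae in the
soma. In a high-content screen of primary neuron cultures, the questions a
plate must answer are: which nuclei belong to neurons, which neurons carry
tau pathology, which tau-positive neurons are GVB-positive, and how do
intensity readouts (puromycin incorporation as a protein-synthesis proxy,
ribosomal proteins, immediate-early genes, and so on) differ between the
tau&#8722;, tau+/GVB&#8722; and tau+/GVB+ populations.

`gvbscreen` implements that whole chain as composable, tested functions,
plus a synthetic-scene generator with planted ground truth so every stage
can be validated quantitatively without access to microscope data.

## Segmentation model

**Nuclei.** The DAPI channel is Gaussian-smoothed (default sigma 1.3 um),
Otsu-thresholded, hole-filled, and split on distance-transform watershed
maxima. Every connected object is retained; an object is *neuronal* only
if it passes three gates:

1. *MAP2 overlap* - its mean MAP2 intensity exceeds the field MAP2 gate
   (default: field median + 2 MAD). A nucleus must sit on a
   MAP2-positive soma to count as neuronal.
2. *Size* - area within 25-300 um^2.
3. *Roundness* - `4 * pi * area / perimeter^2` of at least 0.7.

Non-neuronal objects stay in the table (flagged, with the first failing
gate named) because they are needed in counting denominators. The exact
cutoffs are deliberately configurable: in real screens they are
re-optimised per experiment, and the defaults here are tuned to the
synthetic scenes' geometry.

**Somata.** The soma of a neuron is the smoothed, hole-filled,
thresholded MAP2 signal within 13 um of its nucleus boundary. Pixels
contested between bordering somata are assigned to the nearest nucleus by
a seeded Voronoi propagation on the MAP2 mask; a `discard_contested`
switch drops them instead, for users who prefer that overlap between
bordering somata be excluded outright. Somata of distinct neurons
are disjoint by construction, each soma contains its nucleus, and a
nucleus with no surrounding MAP2 keeps `soma = nucleus` and is flagged.

**Tau status.** A neuron is tau-positive when its somatic mean
tau-channel intensity exceeds `mean + k * sd` (default `k = 3`) of the
same readout in untransduced control wells. The threshold is calibrated
per plate; an absolute threshold can be supplied when no control wells
exist.

## The GVB detection cascade

The marker channel passes five stages, mirroring the structure of
vendor-style HCS "spot" analyses:

1. **Background filter.** A difference-of-Gaussians band-pass (default
   small sigma 0.85 um at the punctum scale, large sigma 3.5 um at the
   soma scale), clipped at zero. The band-pass removes both the flat
   background and the diffuse somatic marker signal while preserving
   blob-scale structure. Per-marker profiles are looked up by name;
   unknown markers require explicit sigmas.
2. **Punctum selection.** Local maxima of the filtered image above
   `mean + k * sd` of the in-soma filtered signal, `k = 4` by default.
   The factor was fixed at design time to keep the per-soma false-punctum
   expectation far below the two-punctum classification rule (a 4-sigma
   one-sided tail across a few hundred soma pixels), because a false
   *punctum* rate that is small is not enough - false *GVB+ neurons*
   require two coincident false punctae surviving all gates. Plateau ties
   break by raster order, so detection is deterministic.
3. **Proximity clustering.** Single linkage at 2 um, never across soma
   boundaries. Cluster identities are assigned in raster order of each
   cluster's first punctum.
4. **Cluster acceptance.** Five independent gates, all of which must
   pass: area 0.5-20 um^2; roundness at least 0.5; mean marker intensity
   at least 2x the parent soma's cytosolic marker level (cytosol
   excluding all clusters); mean MAP2 in the cluster above the field MAP2
   gate; and nuclear exclusion (less than half the cluster's pixels
   inside a nucleus). Each rejection records the first failing gate, so
   gate-level QC is one `table()` away.
5. **Neuron classification.** GVB+ with two or more accepted punctae
   (the confocal definition), GVB&#8722; with none, *indeterminate* with
   exactly one. The single-punctum case is undefined in the confocal
   rule; by default it is excluded from both classes, and
   `indeterminate_to_negative = TRUE` folds it into GVB&#8722; to mirror the
   high-content "GVB+ somas / all somas" counting. Both the per-neuron
   percentage (`pct_gvb_pos`) and the per-cluster convention
   (`pct_gvb_clusters`, accepted clusters per 100 neurons) are reported,
   since the two counting modes answer slightly different questions.

Tau&#8722; neurons are forced GVB&#8722; in the final status (the
false-positive exclusion rule); the raw call is kept in
`gvb_status_raw` for QC.

## Intensity readouts

Somatic means are plain averages over the soma (cytosol plus nucleus);
the marker channel additionally gets a variant excluding accepted GVB
clusters ("somatic level without the GVBs"). Nuclear values are
background-corrected by subtracting the same neuron's cytosolic mean -
negative values are legitimate for cytosolic markers and are never
clipped, because clipping would bias population means. The ARC/c-FOS
convention (`correct = FALSE`) skips the correction.

Each channel also carries a *field-background-corrected* somatic mean
(`somatic_<ch>_corr`): the field background, estimated as the median
intensity outside all somata, is subtracted. Population *contrasts* are
computed on these corrected values. The reason is arithmetic, not
cosmetic: a multiplicative biological effect acts on the cell-derived
signal, while the raw somatic mean is `background + signal`, so ratios of
raw means are compressed toward 1 by the additive background. With the
correction, a planted 31% deficit is recovered as 31%, not as whatever
the background level dilutes it to.

GFP gating uses the 0.99 quantile of somatic GFP in untransduced control
neurons as the threshold. The gating rule is inherently qualitative -
GFP+ means brighter than the negative control - so the quantile, which
fixes the control false-positive rate at 1%, is our concrete choice.

## The synthetic-scene generator

The generator emulates wide-field HCS images of dissociated cortical
cultures at 20x: fields of 25-500 neurons, disk-like nuclei (4 um mean
radius), blob-like somata (8 um) with thin random-walk neurites, bright
Gaussian punctae (sigma 0.85 um, 6x the somatic marker level) planted
only in the somata of GVB+ neurons and only outside the nucleus, at
least two per GVB+ neuron. Pixel values are integer camera counts:
Poisson shot noise on the expected signal plus Gaussian read noise
(sd 3) on a background of 100 counts. The default pixel size is 0.65
um/px, typical of a 20x sCMOS HCS system; every micron-specified rule
converts through it and it is configurable end to end.

**Quota planting.** Population memberships are planted by quota -
`floor(f * n)` plus a Bernoulli draw on the fractional remainder,
stratified by tau and GFP status - rather than per-neuron Bernoulli
draws. Planted fractions are therefore exact up to one neuron per
stratum, which makes recovery experiments measure *pipeline* error
rather than planting noise. Where a scenario needs an exactly realised
fraction, choosing `f * n` integral makes the plant deterministic.

**What the generator does not emulate.** There is no optical PSF model
(spot size is a free, documented parameter; modelling acquisition
optics is outside this package's scope), no uneven illumination by
default (the band-pass and the field-background estimator would absorb
moderate gradients), no neurite-level morphology beyond cosmetic strokes
(neurite tracing is out of scope; presynapse density takes dendrite
length as an external input), no 3D stacks, photobleaching or live-cell
dynamics. Passing recovery tests on these scenes demonstrates the
pipeline's internal correctness and statistical calibration - it does
not certify performance on real images, where segmentation error modes
(clumped somata, debris, staining variability) are richer.

## GVB half-life under a formation block

With a treatment that completely blocks new GVB formation, any GVB+
neuron observed after treatment start must have been GVB+ at start. The
*expected* fraction is therefore the control trajectory at `t0`
(linearly interpolated; the control is observed at discrete days). For a
treated observation at offset `dt`, retention `r = observed / expected`
gives a per-offset half-life `t_half = dt * log(2) / log(1 / r)`, and
the reported estimate is the arithmetic mean over offsets ("an average
half-life"); a joint log-linear fit through the origin is available as
an alternative mode. Offsets with `r >= 1` carry no decay signal and
are excluded with a warning; if all are excluded the estimator stops
rather than fabricate a value.

Whether "expected" should be the control at treatment start or the
contemporaneous control admits two defensible readings; both
conventions are implemented (`expected = "start"` is the default,
as it is the one that follows from the formation-block argument) and
labelled in the fit object. At zero noise the default convention inverts
the generator exactly, which is the identity the tests pin down.

## Nested statistics

The well is the technical replicate (n), the culture preparation the
biological replicate (N). All nested tests first collapse wells to
unweighted biological-replicate means - each preparation counts once
regardless of its well count, matching the superplot convention - and
the degrees of freedom follow N, never n. The default nested t is a
pooled-variance two-sample t on those means; a random-intercept mixed
model (`mode = "lmm"`, via lmerTest) is provided as the
variance-components alternative. The nested one-way ANOVA runs on the
same collapsed means, with Dunnett's test against a reference (via
multcomp) or Sidak-adjusted pairwise comparisons
(`p_adj = 1 - (1 - p)^m`). Paired per-well comparisons (tau+/GVB&#8722;
vs tau+/GVB+ from the same well) use a standard paired t with explicit
degenerate handling: zero-variance differences yield an infinite t
flagged as degenerate instead of an error or a fake p-value.

Outlier flagging is a location-only analogue of robust-regression FDR
outlier removal: robust z scores around the median, scaled by the
68.27th percentile of absolute residuals with an `n/(n-1)` small-sample
correction (a lower-variance robust scale than the MAD), t-distribution
tails, Benjamini-Hochberg cut at `Q`%. The test suite verifies the
calibration (clean symmetric samples flagged in well under 1% of draws
at `Q = 1`) and affine invariance. Exact numerical agreement with the
proprietary original is explicitly not claimed.

## Numerical choices and degenerate inputs

- **Perimeter/roundness.** Perimeter is estimated as the exposed
  4-neighbour edge count times pi/4, which converts the taxicab boundary
  length of a smooth convex shape to its Euclidean length exactly for
  disks. For elongated shapes the estimator (and mask smoothing) biases
  roundness upward - a 3:1 ellipse measures ~0.8 against an analytic
  ~0.66 - which is conservative for gates that ask "is this disk-like",
  but means roundness cutoffs should be read as calibrated to this
  estimator, not as analytic values. Roundness is capped at 1.
- **Determinism.** All thresholds are data-derived but deterministic;
  local-maximum plateau ties and cluster numbering break by raster
  order; identical inputs give identical outputs, which the tests
  assert.
- **Degenerate inputs.** A flat DAPI channel yields an empty nucleus
  list (not an error); a constant marker image filters to all zeros;
  somata without MAP2 collapse to the nucleus and are flagged; empty
  cytosols give `NA` corrected intensities; zero-variance statistics
  are reported as t = 0 / p = 1 (no difference) or flagged degenerate
  (difference with no variance) rather than erroring mid-plate.
- **Seeds.** Every stochastic step is seeded; plate generation derives
  per-field seeds from the configuration seed and well/field indices,
  so a plate is reproducible from its layout alone.

## Problem sizes

The recovery scenarios in the test suite use plates of 6-18 wells with
125-150 neurons per field (one to three fields per well) and two
untransduced calibration wells per plate; the acceptance script scales
the same scenarios up (for example 20 fields for the fraction-recovery
scenario and 27 wells for the nested ribosomal-marker design, matching
the N = 3 x n = 9 replicate structure those readouts use). The
low-count treatment scenario deliberately plants about one GVB+ neuron
per treated field to exercise the regime where positives are rare.
These sizes are the package's own validation design: large enough that
the planted effects dominate counting noise, small enough to run
routinely.

## Known limitations

- The roundness estimator's elongation bias (above).
- The "curvature" background filter of the original vendor software is
  proprietary; the difference-of-Gaussians band-pass is a principled
  stand-in whose parameters are per-marker profiles, not a numerical
  reimplementation.
- Outlier flagging approximates, but is not, the proprietary original.
- Presynapse density requires dendrite length as an input; the package
  does not trace neurites.
- The somatic ubiquitin readout mentioned in passing in the source
  methods is not implementable from its (fragmentary) description and
  is not provided.
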