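---
title: "Methods: quantifying excitatory synapses in multiplexed immunofluorescence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying excitatory synapses in multiplexed immunofluorescence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

synaptiq implements a complete image-quantification and statistics workflow
for excitatory synapses labelled by multiplexed immunofluorescence in
ultrathin (200–400 nm) sections of cortical tissue. This vignette is the
package's account of the method: the operators and their exact semantics,
the tunable parameters, what the synthetic-cohort generator does and does
not emulate, and the design decisions taken where the workflow leaves room.

## The measurement model

Excitatory synapses are identified by punctate PSD-95 immunofluorescence.
All downstream quantities derive from a small set of image operators applied
in a fixed order:

1. **Segmentation.** The PSD-95 channel is smoothed with a Gaussian filter
   (sigma 2 px), thresholded with Otsu's 256-bin histogram criterion, and
   intersected with a *segmented-particles* partition obtained from
   prominence-based maxima detection. The intersection splits merged masks
   of adjacent synapses along watershed boundaries, so that each label
   contains exactly one intensity maximum. A component that contains no
   accepted maximum is discarded: a particle exists only around a maximum,
   which is what keeps a structureless noise field empty.
2. **Background.** Intensity measurements are taken on
   background-subtracted images, with the background estimated by the
   rolling-ball algorithm (radius 7 px), implemented as the grayscale
   opening of the image with a ball (spherical-cap) structuring function.
   Background-subtracted intensities are clipped at zero, since negative
   fluorescence is unphysical.
3. **Morphometry.** Area is pixel count times squared pixel size. The
   aspect ratio (AR) is the axis ratio of the ellipse matched to each
   region's second central moments (axis length $4\sqrt{\lambda}$, plus a
   per-pixel variance of 1/12 so discrete rectangles reproduce their exact
   side ratio). Synapses with AR >= 2.7 are classified *side view* (cut
   edge-on), the rest *en face*; the boundary is a config parameter.
4. **Abundance.** Synapse density is label count over analyzable area, and
   the mean nearest-neighbour distance (NND) between centroids provides a
   density summary robust to excluded regions. The mean NND is
   border-corrected: a point closer to the field border than to its nearest
   neighbour is dropped from the mean, because its true neighbour may lie
   outside the field. Objects touching the border are excluded from area
   and NND statistics entirely (truncated footprints bias both).
5. **Protein content.** A paired protein's mean synaptic fluorescence is
   divided by the population mean of PSD-95 fluorescence within the same
   immunoreaction ("normalized mean intensity"), absorbing
   labelling-efficiency differences between reactions.
6. **Nanoclusters.** On STED-scale images (20 nm/px), Munc13-1 release-site
   nanoclusters are counted as intensity maxima falling inside each synapse
   mask dilated by 3 px (the dilation admits the presynaptic active zone of
   side-view synapses, which sits just outside the postsynaptic mask). One
   shared prominence is used for every subject of an experiment. Where
   dilated masks overlap, a peak goes to the label with the nearest
   non-dilated boundary.
7. **Synapses on PV dendrites.** PSD-95 is weak at synapses on
   parvalbumin-positive dendrites, so masks for that analysis are built
   from the summed PSD-95 + AMPAR + GluN1 fluorescence, filtered to
   synapses with background-subtracted PSD-95 integral above 10 AU.
   Receptor content is the per-synapse receptor/PSD-95 integral ratio; for
   PV-dendrite synapses it is reported relative to the mean ratio of the
   surrounding (non-PV) synapses of the same subject.
8. **Somatic PV.** PV cell bodies are segmented with the triangle threshold
   on the blurred PV channel (components above 50 um^2; an exclusion
   annotation file replays manual mask revisions); somatic means are
   measured on the unfiltered image minus the mean over a neuropil mask
   (pixels at or below the image-mean threshold).
9. **Statistics.** All group inference is at subject level: subject means
   enter classical pooled-variance two-tailed t tests
   (df $n_1 + n_2 - 2$), with step-down Holm–Bonferroni correction within
   each declared comparison family. Spearman's rank correlation (mid-ranks
   on ties, large-sample t approximation for p) is used for
   count-versus-area relationships; Shapiro–Wilk (small n) and a
   Lilliefors-corrected Kolmogorov–Smirnov test (large n) check normality;
   ordinary least squares with t-based coefficient p values checks that
   condition effects are not explained by age, gender, or postmortem
   interval.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| blur radius (sigma) | 2 | px | pre-threshold smoothing of the puncta channel |
| maxima prominence, confocal | 5 | AU | splits touching puncta; > 3x the post-blur noise sd of the default generator |
| maxima prominence, Munc13-1 | 10 | AU | shared across subjects; resolves 60 nm-spaced clusters at the default contrast |
| rolling-ball radius | 7 | px | background length scale; larger than a punctum, smaller than illumination gradients |
| AR threshold | 2.7 | – | side-view/en-face boundary |
| mask dilation | 3 | px | admits presynaptic active zones at 20 nm/px |
| PSD-95 integral filter | 10 | AU | inclusion rule for the summed-channel masks |
| soma minimum area | 50 | um^2 | excludes dendritic fragments from the soma map |
| PV overlap rule | 1 | px | a synapse "is on" a PV dendrite if its mask shares >= 1 pixel with the dendrite mask |

The "radius" of the Gaussian filter is interpreted as the standard
deviation in pixels with the kernel truncated at 4 sigma. All histogram
thresholds use 256 equal-width bins spanning the image's [min, max];
foreground is strictly above the threshold. Borders are handled by
symmetric reflection, which conserves total intensity. No universal
prominence exists — like the empirically chosen noise tolerance of any
particle-counting workflow, it is set once per experiment and shared across
subjects; both values above are the defaults validated against the
generator's ground truth.

## The synthetic-cohort generator

No image archive accompanies the tissue study this workflow addresses, so
the package ships a generator that renders multi-channel cohorts with
exhaustive ground truth. Its defaults *are* the study conditions:

* **Cohort.** 9 control and 6 case subjects (7/6 for the PV-dendrite
  experiment, 8/6 for the somatic PV experiment), with age, gender and
  postmortem-interval covariates drawn in the cohort's documented ranges.
* **Layer-2 confocal fields.** 70 x 210 um at 100 nm/px; PSD-95 puncta as a
  hard-core point process (minimum separation 0.6 um, about one punctum
  diameter) at 0.15 um^-2; en-face fraction 196/264; uniform-intensity
  elliptical templates blurred by a 130 nm-sigma PSF on a 20 AU background
  with Poisson shot noise plus Gaussian read noise (sd 2).
* **STED fields.** 10 x 10 um at 20 nm/px, PSF sigma 17 nm (about 40 nm
  FWHM — the resolution a STED instrument of this class actually delivers;
  a coarser PSF would make the generator's own 60 nm minimum inter-cluster
  spacing unresolvable, since two equal Gaussian peaks merge below a
  separation of twice the PSF sigma). Nanocluster counts are Poisson with
  mean linear in synapse area, calibrated so the population mean is 3.4;
  clusters are placed with a hard 60 nm minimum spacing, laterally offset
  by 40 nm for side-view synapses.
* **Deep-layer PV fields.** 40 x 40 um at 100 nm/px; surrounding synapses
  at 0.23 um^-2; one to two annotated PV dendrites per field whose synapses
  follow a renewal process along the polyline (hard minimum gap 0.45 um
  plus an exponential tail with mean gap 1/0.87 um, so the planted linear
  density equals 0.87 synapses/um exactly); PV-synapse PSD-95 scaled by
  122/192; receptor/PSD-95 subject-mean multipliers 1.72 (AMPAR), 1.60
  (GluN1) and 1.72 (GluN2B) in controls versus 1.54, 1.30 and 1.43 in
  cases, with the documented between-subject SDs. The dendrite tube plus
  0.7 um is excluded volume for surrounding synapses — the 2-D stand-in for
  the fact that in tissue a synapse cannot occupy the same space as the
  dendrite.
* **Somatic PV fields.** 200 x 400 um at 500 nm/px; ~15 um somata with
  subject-level mean intensities of 1,362 (control) versus 955 (case) AU on
  a 300 AU neuropil background.
* **Side-view fixture.** `make_sideview_fixture()` renders one
  deterministic, zero-noise, five-channel side-view synapse at 20 nm/px
  with presynaptic channels offset from the PSD-95 bar by 0 (GluA2), 40
  (Munc13-1), 100 (Bassoon) and 220 nm (VGLUT1) — all integer multiples of
  the pixel grid. It regenerates identically on every call, which is what
  the package's tests check.

Two distributional choices deserve comment. Synapse areas are lognormal.
The STED arm uses sigma_log = 0.5; the confocal Layer-2 arm deliberately
uses a tighter sigma_log = 0.35, because at 100 nm/px with a 130 nm PSF and
the workflow's 2 px smoothing, the broad tail of sub-0.05 um^2 puncta is
optically undetectable, and a generator most of whose smallest objects
cannot be seen at confocal resolution would not emulate data in which the
areal density is a measurable 0.15 um^-2. Second, object brightness in the
PV-dendrite arm (PSD-95 integral mean 4,800 AU on a 6 AU background) is set
high relative to the noise floor: the rolling-ball estimate of a noisy
background sits about two noise-sigma low, and the resulting additive
residual in every integral compresses receptor/PSD-95 ratios toward 1 when
objects are dim — a measurement property worth knowing about when applying
the pipeline to faint channels.

**What passing tests do and do not show.** The generator renders 2-D fields
of well-separated, convex, uniformly-filled objects with stationary
background and Poisson-plus-Gaussian noise. It does not emulate section-
thickness effects, fractures, blood vessels, variable antibody penetration,
non-specific labelling, chromatic misalignment beyond integer translation,
or the irregular and perforated synapse shapes of real tissue. Recovery of
planted densities, counts and ratios therefore validates the operators and
their composition — not the biological accuracy of any particular tissue
measurement.

## Numerical choices and degenerate inputs

* Maxima semantics: a local maximum is reported iff no strictly higher
  pixel is reachable along a path that never descends more than the
  prominence below it. Equal-valued maxima within one tolerance region
  merge to a single point at the plateau centroid, snapped to the nearest
  plateau pixel (row-major tie-break); maxima whose plateau touches the
  border are suppressed, so a constant image yields none. Segmentation
  assigns every pixel to exactly one maximum by highest-frontier-first
  flood descent.
* Connectivity is 8-neighbour throughout (components, flooding).
* A constant (or numerically constant, range below 1e-9 relative) image is
  a degenerate input for histogram thresholds; segmentation then returns an
  empty label map with a warning.
* Pooled t with zero pooled variance returns p = 1 for equal means and a
  flagged degenerate p = 0 otherwise; Spearman on constant input returns NA
  with a warning; fewer than two points yield an empty NND vector with a
  warning.
* Otsu thresholds are computed per image (not per reaction batch); the
  scope is a config decision and per-image is the default because
  acquisition settings are fixed within an experiment while section quality
  varies.
* The surrounding-population normalisation of PV-dendrite ratios uses the
  mean of per-synapse ratios (`mean_of_ratios`), scoped per subject; the
  ratio-of-population-integrals alternative is available
  (`ratio_of_means`). Per-subject scoping absorbs between-subject staining
  differences.
* Holm families are declared per analysis: the three receptor-density
  comparisons of the PV-dendrite experiment form one family; unassigned
  measures are singleton families.
* Float TIFFs store intensities on [0, 1]; cohort images are scaled by a
  power of two recorded in the sidecar metadata, and physical pixel sizes
  live in that metadata too, never in TIFF tags.

## Problem sizes

The test suite validates operators against brute-force oracles on grids up
to 32 x 32 (and 15 x 15 for exhaustive maxima enumeration), and runs
recovery on 20 full-size Layer-2 fields (70 x 210 um), about 200 STED
synapses, and a 7-subject PV-dendrite cohort of two 40 x 40 um fields per
subject. Calibration suites (type-I error at 9 vs 6 subjects over 500
replicates; power of the GluN1 contrast at 7 vs 6 over 200 replicates) run
on subject-level summaries drawn directly from the generator's
subject-effect model, image rendering having been validated separately —
one field's rendering and quantification costs seconds, a subject-level
replicate microseconds.

## Known limitations

* Strictly 2-D: no stereological correction for section thickness or
  orientation bias beyond the AR-based view classes.
* Translation-only registration; rotational or non-rigid misalignment
  between imaging rounds is out of scope.
* The rolling-ball noise-floor bias described above is inherent to
  morphological background estimation on noisy images; ratios of dim
  channels inherit it.
* Manual steps of the original workflow (mask revision, dendrite outlining,
  myelinated-axon exclusion by MBP) are replaced by deterministic defaults
  plus annotation files (exclusion-id CSVs, polyline CSVs with
  `pv_positive` / `is_myelinated_axon` flags) so runs are scriptable and
  human edits replayable.
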