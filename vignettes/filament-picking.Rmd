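---
title: "Picking helical filaments from score maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Picking helical filaments from score maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(filapick)
```

## The problem

Amyloid filaments are helical aggregates with a cross-beta core whose
beta-rungs stack every 4.75 Å along the helical axis.  Cryo-EM
structure determination of such filaments starts from micrographs in
which the filaments appear as long, dark, nearly straight threads.
Helical reconstruction needs, per filament, a *start--end coordinate
pair*: segments for alignment are then extracted along that line at a
fixed arc spacing, each carrying orientational priors (the in-plane
angle from the line direction, and a tilt prior of 90° because the
filament lies in the image plane).

Manual clicking of start--end pairs is the traditional bottleneck.
This package implements an automated alternative that operates on the
*score map* of a sliding-window particle scorer -- an image of
per-pixel figure-of-merit (FOM) values on a down-sampled grid, where
high values mean "filament-like".  Any scorer that produces such a map
can sit upstream; for testing, the package ships a self-contained
surrogate scorer (below).

## The four extraction steps

`extract_traces()` converts a score map into start--end pairs in four
steps:

1. **Binarize** (`binarize()`): foreground is every pixel with FOM
   strictly greater than the user threshold `-t`.  The threshold is
   the one parameter that usually needs tuning per data set; picking
   the weak half-period of strongly width-modulated filaments may need
   a relatively low value.
2. **Skeletonize** (`skeletonize()`): Zhang--Suen iterative thinning
   reduces the foreground to one-pixel-wide, 8-connected medial lines.
   The algorithm runs to a fixed point, so it is idempotent, and it
   only ever deletes foreground pixels, so the skeleton is a subset of
   the mask.
3. **Detect lines** (`detect_lines()`): a probabilistic Hough
   transform visits skeleton pixels in a pseudo-random order fixed by
   `rng_seed`.  Each visited pixel votes into a (rho, theta)
   accumulator with theta sampled at 1° over [-90°, 90°).  When a
   pixel's best bin reaches the accumulator threshold, the transform
   walks along that line in both directions, bridging gaps up to
   `line_gap` pixels, and accepts the segment if it is at least
   `line_length_fl` pixels long.  Accepted segments have their pixels
   removed -- including the 8-neighbourhood of each walked pixel,
   because the walk rounds to the nearest pixel while real skeletons
   wiggle by one pixel; clearing only the exact walked pixels leaves
   one-pixel-offset residue that later resurfaces as short, slightly
   misoriented duplicate segments.
4. **Merge** (`merge_lines()`): two segments merge when the
   undirected angle between them is smaller than `merge_angle_deg`
   (default 10°) and at least two of their four endpoints lie within
   `merge_dist` of the infinite supporting line of the respective
   other segment.  Measuring to the infinite line (not the finite
   segment) is what makes collinear-but-gapped fragments mergeable,
   which is the step's purpose: a filament whose weak sections fell
   below threshold reappears as one long trace.  A merged segment is
   constructed from the *original* constituent segments it absorbs:
   their length-weighted mean direction (averaging doubled angles,
   since segments are undirected), with every constituent endpoint
   projected onto that axis through the endpoint centroid and the two
   extremal projections kept.  Working from original constituents
   rather than intermediate merge results makes the outcome
   independent of merge order whenever the final grouping is; merging
   iterates in index order, restarting after every accepted merge,
   until a full pass accepts none, so the result is a deterministic
   fixed point and the operation is idempotent.

Finally the merged endpoints are rescaled to original-micrograph
pixels.  All coordinates are 0-based pixel-centre; the rescaling is
centre-preserving, `x_mic = (x_ds + 0.5) * f - 0.5` for down-sampling
factor `f`.

### Parameter defaults

The picking radius `-r` (in down-sampled pixels) is half the expected
filament width, converted with `radius_pixels()`.  From it derive, per
the conventions of the upstream picker's filament mode:
`line_length_fl = 2 r`, accumulator threshold
`round(0.1 * line_length_fl)` floored at 1, `line_gap = r`,
`merge_dist = r`, and a 10° merge angle.  Only `-t` and `-r` are
normally set by hand.

Two parameterizations are worth noting as deliberate choices.  The
binarization comparison is strict (`>`), so a pixel exactly at the
threshold is background.  The angle between segments is undirected and
lies in [0°, 90°]; merging decisions never depend on which endpoint of
a segment was labelled "start".  Zero-length segments, should the
transform ever emit one, are dropped before merging.

## Helical bookkeeping

The package groups the small arithmetic that recurs in helical
processing:

- `twist_from_crossover(d, rise)` = −(rise × 180°)/d.  In projection a
  twisted filament completes a half-turn over the crossover distance
  *d*, so for the canonical amyloid rise of 4.75 Å a 720 Å crossover
  gives −1.19° and 750 Å gives −1.14° (two-decimal refinement
  precision).  The sign is negative because amyloid filaments are
  almost always left-handed; the magnitude satisfies
  |twist| × d = 180 × rise exactly.
- `interparticle_distance(rise, n_asu)`: segment extraction spacing;
  three beta-rungs (3 × 4.75 = 14.25 Å, conventionally quoted 14.2 Å)
  works well in most cases.
- `downscaled_pixel_size(p, box, ds_box)`: Fourier down-scaling of
  extraction boxes enlarges the pixel by the box ratio (0.824 Å at
  768 → 128 gives 4.944 Å).
- `corrected_pixel_size(p, observed_rise)`: a refined rise deviating
  from 4.75 Å usually indicates a miscalibrated magnification; the
  correction attributes the whole deviation to the pixel size.
- `sample_particles(trace, spacing, pixel)`: records along the trace
  from its start, never overshooting the end, with
  `psi_prior_deg = -atan2(dy, dx)` (degrees, image y downward, wrapped
  to (−180°, 180°]), tilt prior 90°, and track length in Å from the
  trace start.  One psi convention had to be fixed; this one is
  documented here and in the STAR writer, and anchored by a test
  (a trace along +x has psi 0).

## File formats

Coordinates travel as STAR files: pick files are a single `loop_` of
`_rlnCoordinateX`/`_rlnCoordinateY` where consecutive row pairs are
one filament's start and end; particle files carry the minimal
helical-prior column set (`_rlnMicrographName`, coordinates,
`_rlnHelicalTubeID`, `_rlnAngleTiltPrior`, `_rlnAnglePsiPrior`,
`_rlnHelicalTrackLengthAngst`).  Written coordinates are 0-based
pixel-centre values in original-micrograph pixels, at 6 decimals --
consumers differ in their conventions, so this is stated prominently.
Images are read and written as MRC2014 (modes 0/1/2/6 read, mode 2
written), with the pixel size taken from the header cell dimensions.

## The synthetic-micrograph simulator

`simulate_micrograph()` emulates the features of filament micrographs
that the picker must cope with, and nothing more.  Filaments are
rendered as dark Gaussian-profile ridges along circular-arc
centrelines, on a flat background with additive white Gaussian noise.
Three phenotypes mirror what micrograph inspection distinguishes:

- **good**: a twisting filament with an anisotropic cross-section
  repeats its projected width twice per crossover, so the apparent
  full width oscillates sinusoidally between `width_min_A` and
  `width_max_A` with arc period `crossover_A / 2`.
- **swollen**: damaged, "blobby" filaments; the width follows a
  smooth random profile over the same range (control points every
  150 Å, linearly interpolated, normalised to the width band).
- **ribbon**: non-twisting flat ribbons; constant projected width
  (`width_min_A` forced equal to `width_max_A`).

The ridge depth scales inversely with the local apparent width,
normalised to `contrast` at the band centre: projected mass per unit
length is conserved, so narrow edge-on sections are strong and wide
flat-on sections weak.  This reproduces the alternating strong/weak
signal of twisted filaments -- the reason a relatively low picking
threshold is sometimes needed -- and makes non-twisting ribbons
uniformly faint, which is the regime where automated picking degrades.

Default study conditions, chosen once as representative of recombinant
tau data and used throughout the tests: 1024 × 1024 px at 2 Å/px,
five filaments per field, widths 60--160 Å around a 120 Å mean,
crossover 720 Å, curvature at most 0.005 rad per 100 Å of arc (a 2 µm
curvature radius -- amyloid filaments have persistence lengths of
micrometres and above, so fields of view this size show at most gentle
bending), unit contrast, and noise standard deviation 0.5.  Start
points are uniform over the field with uniform directions, so filament
crossings occur at a realistic rate and the picker must cope with
junctions.

What the simulator deliberately does *not* model: CTF oscillations,
ice-thickness gradients, radiation damage, carbon edges, and true 3-D
helical projection density.  Tests passing on these images therefore
show that the geometry pipeline behaves correctly on images with the
stated phenomenology; they do not certify performance on any
particular real data set, where the upstream scorer quality dominates.

## The surrogate scorer

The neural-network scorer that normally produces score maps is out of
scope, so `surrogate_score_map()` stands in for it during testing (it
is a deliberate component of this package, not a reimplementation of
any trained network).  It block-averages the micrograph by the
down-sampling factor, then applies matched oriented line filters: a
second derivative of a Gaussian across the filament (scales of half
and the full expected width, accommodating the width modulation) times
a Gaussian of three times the width scale along it, over 12
orientations at 15° spacing, keeping the strongest response per pixel.
The sign convention makes dark ridges score high, and the map is
standardised to zero mean and unit variance (an all-zero map is
returned for blank input).  Oriented matched filtering, rather than an
isotropic band-pass, is what keeps the response tight across the
filament, even along width-modulated stretches, and suppresses the
blob responses at filament crossings that an isotropic filter produces
-- isotropic variants tried during development produced wide, blobby
masks whose skeletons sprouted short spurious branches.  On
standardised surrogate maps a binarization threshold of 1.5 is a good
default operating point; thresholds are scorer-specific, so this value
has no meaning for maps from other scorers.

Known limitation: near filament tips the orientation-max response
spreads into a small blob, which can curl the skeleton and emit a
short, slightly misoriented segment, and filaments much shorter than
the along-axis filter support (~230 Å at the defaults) are scored
poorly.  Both are end effects of the surrogate, not of the extraction
steps; with crisp score maps the extraction traces straight bands to
within a pixel and a degree (see the tests).

## Evaluation metrics

`evaluate_picks()` compares traces with ground-truth centrelines.  A
trace is a true positive when both endpoints lie within `dist_tol_px`
of the same centreline and its direction is within `angle_tol_deg` of
the local centreline direction at both endpoints.  Precision is the
true-positive fraction of traces (1 for an empty pick list, by
convention); coverage is the fraction of ground-truth arc length
within `dist_tol_px` of a true-positive trace; `recall_by_length` is
the length-weighted fraction of filaments at least half covered.
Matching is greedy by decreasing trace length with ties broken by
tube id.  Under the default study conditions (noise/contrast = 0.5)
the default pipeline reaches coverage and precision above 0.9 over a
20-field batch, and both degraded phenotypes yield lower coverage than
good filaments at equal noise -- the directional behaviour expected
from data sets where such filaments defeated automated picking.

## Numerical and degenerate-input choices

- The Hough accumulator uses rho bins of one pixel, offset so all
  distances are positive; ties in the best-theta search resolve to the
  first (most negative) theta, as in the de-facto reference
  implementation.
- Walks stop at image borders; a segment's endpoints are the last
  foreground pixels seen, so they always lie on or within one pixel of
  the skeleton.
- `detect_lines()` saves and restores the caller's RNG state; all of
  its randomness derives from `rng_seed` (default 0), making the whole
  pipeline reproducible and batch output byte-identical across runs.
- Empty masks, empty skeletons, empty segment lists, and empty trace
  tables flow through every step and writer without error; a
  threshold above the score maximum produces a header-only but valid
  STAR file plus a warning.
- Scorer scales are clamped so that a filament width below one
  down-sampled pixel warns and is widened to half a pixel, and filter
  kernels are truncated to fit small images.

## Problem sizes in the test suite

The suite simulates its fixtures at run time: twenty 1024² fields for
the recovery property, ten per phenotype for the degradation
comparison, 1000 random small-segment instances for the
merge-oracle equivalence, and smaller fields (256²--512²) for
unit-level checks.  These sizes keep the full suite in the
few-minute range on a single core while leaving each property with
enough replicates to be meaningful.
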