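---
title: "Quantifying chemically induced inflammation in zebrafish larvae: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chemically induced inflammation in zebrafish larvae: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chinassay)
```

## The assay

Copper sulfate dissolved in the water selectively damages the
mechanosensory neuromasts of the zebrafish lateral line. Within minutes,
myeloid leukocytes (neutrophils and macrophages) leave their ventral and
posterior reservoirs and cluster around the damaged organs. Because the
insult is waterborne, no larva has to be handled individually, which makes
this chemically induced inflammation (ChIn) readout scalable to microtiter
plates: one larva per well of a 384-well plate, imaged on an automated
fluorescence microscope in three channels (bright-field; GFP-labelled
neuromasts; DsRED2-labelled leukocytes).

`chinassay` implements the full quantification chain for such screens:

1. **Focus selection** — an autofocus picks the central focal plane;
   following the plate acquisition protocol, the plane found on the first
   well is applied to the rest of the plate.
2. **Extended focus projection** — five optical sections, two on each side
   of the central plane, are combined by a per-pixel maximum.
3. **Neuromast detection** — green blobs are segmented and a square
   analysis region is placed around each detected rosette.
4. **Leukocyte quantification** — the inflammation score of a larva is the
   mean, over its squares, of the background-subtracted mean red intensity
   per square. A *count mode* reproduces the manual protocol instead:
   leukocyte spots are counted within five cell diameters above and below
   the horizontal myoseptum.
5. **Screen statistics** — per-condition mean ± SEM with QC accounting,
   and Welch's unpaired t-tests of every treatment against the control,
   with the conventional star mapping.

A synthetic plate generator with exact ground truth stands in for the
microscope, so that every stage is testable offline against known answers.

## The synthetic scene model

A larva is modelled by its horizontal myoseptum — a line segment carrying
`n_neuromasts` (default 7) regularly spaced rosettes — and a body
silhouette of half-height `body_half_height` around it. Fluorescent
structures are isotropic Gaussian spots:

* a neuromast is a ring of 8 cell-spots of width 3 px at radius 8 px
  (a rosette); its brightness is drawn per rosette from a lognormal
  around 2200 camera counts (sdlog 0.35), reflecting expression
  variability between organs;
* a leukocyte is a single spot of width 3 px, lognormal brightness around
  3000 counts (sdlog 0.3).

Leukocyte placement encodes the biology being assayed. Every larva holds a
Poisson(`baseline_count`, default 10) pool of resident cells in a
ventral/posterior stripe below the myoseptum, kept at least 2.5 rosette
radii away from the axis so that untreated larvae show only occasional
cells near neuromasts. Under treatment each neuromast additionally
attracts Poisson(λ) cells placed uniformly within two rosette radii of its
centre, with λ following the saturating dose–response

λ(dose) = `recruit_rmax` · dose / (dose + `recruit_k50`),

zero at dose 0 and monotone in dose. The published screens report
concentration dependence but no functional form; the two-parameter
saturating curve is the minimal monotone model, with defaults
`recruit_rmax = 8`, `recruit_k50 = 2` placing the standard 10 µM-like dose
near saturation. The absolute baseline and recruitment counts are free
parameters of the simulator — no published number fixes them — and are
chosen to give contrast typical of the real images.

Mounting is Bernoulli: with probability `lateral_orientation_prob`
(default 0.75, consistent with the reported >70% of larvae being usable
without manual re-orientation) the larva lies laterally and its axis is
horizontal; otherwise the body is rotated by 15–40° and foreshortened, and
the larva is flagged as unfavourably positioned. The spacing invariant
(neuromast separation ≥ 4 radii) applies to the lateral anatomy; tilted
bodies may appear crowded in projection, which is exactly the pathology
the orientation QC exists to exclude.

### Camera model and rendering

Images are rendered at 16-bit camera scale with an offset of 100 counts
and additive Gaussian noise (`noise_sd`, default 50 counts). Slice *k*
carries blur of width `psf_sigma + |k − central| · defocus_sigma_per_slice`
(defaults 1 px and 1.5 px/slice). Because the scene is a sum of Gaussians,
the blur is applied analytically — a spot of ideal width *s* blurred by
*b* renders as a Gaussian of width √(s² + b²) with conserved flux — which
is exact rather than discretised. Amplitudes are normalised so the central
slice shows the model's stated peak; consequently a rendered spot's peak
reads back from the central slice, and its integrated intensity equals
peak · 2π · σ₀² in every slice, two properties the test suite verifies.
The bright-field silhouette is the analytic blur of a rectangle (products
of error-function ramps in the body frame). The defaults emulate the
acquisition camera's 1300 × 1024 px frame with 9 optical sections.

Per-pixel noise is drawn from a dedicated xorshift128+/Box–Muller stream
seeded from R's RNG, so a single `set.seed()` reproduces an entire plate
bit for bit while megapixel noise stays cheap. Each well derives its own
seed from the plate seed by a fixed arithmetic schedule, so adding wells
never perturbs earlier wells.

## Numerical choices in the pipeline

**Autofocus.** Slices are scored by the variance of their
Laplacian-of-Gaussian response (pre-smoothing σ = 2 px). The Gaussian step
matters: per-pixel camera noise contributes the same Laplacian variance to
every slice, and without smoothing it can drown the object signal when
structures are sparse. Exact score ties resolve toward the middle slice,
so degenerate (featureless) stacks behave predictably. The plate-wide
*first-well* policy mirrors the acquisition protocol; a per-well policy is
selectable.

**Projection.** "Extended focus" is implemented as the per-pixel maximum
over the five-slice window — the simplest operator that keeps sparse
bright objects sharp wherever they are in z. At stack edges the window is
clipped and re-centred so exactly `min(5, Z)` real slices enter; no
zero-padding.

**Neuromast segmentation.** Background (image median) subtraction,
Gaussian smoothing (σ = 3 px), then Otsu's threshold computed on the
*log*-intensity image. Rosette brightness spans a wide range; on the raw
scale Otsu's cut rides up on the brightest rosette and loses dim ones,
while on the log scale it separates tissue from signal independently of
brightness. Touching blobs are split by an intensity watershed on the log
image (tolerance 0.4 log-units, brightness-scale invariant). Components
pass an area gate (40–4000 px²) and a circularity gate
(4πA/P² ≥ 0.4, rejecting elongated autofluorescence streaks), and each
survivor yields an intensity-weighted centroid with a square analysis
region of side 48 px — about three rosette diameters; the original
system's square is described only as empirically established, so the side
is an exposed tuning parameter, not a published value. Squares overlapping
by more than half of the smaller square merge at the score-weighted
centroid. A larva with at least one surviving region is *data-producing*;
larvae with none are excluded and tallied.

**Intensity score.** "Relative" red fluorescence is defined as the mean
over the square minus the per-larva background, floored at zero, where
background is the median of the red pixels outside all squares. This makes
the zero point the unstained tissue level and the score invariant to the
camera offset. Whether the original software background-corrected is not
documented; the subtraction is this package's explicit choice.

**Count mode.** Difference-of-Gaussians spot detection (σ = 2.2 px, ratio
1.6) with Otsu's threshold on the positive response; local maxima are
resolved through connected components, so two cells closer than the
resolution limit merge into one detection — as they would for a human
counter. Membership in the myoseptum band uses a boundary-inclusive
perpendicular distance test against the segment (half-width default 50 px
= five cell diameters at the simulator's 10 px cell diameter convention);
counting a 2D projection inherently scores one side of the larva, like
the manual protocol. When no band is given, the axis is estimated by
least squares through the detected neuromast centroids.

**Statistics.** Welch's unpaired two-sided t-test (no equal-variance
pooling, Welch–Satterthwaite degrees of freedom) backed by
`stats::t.test`; the test suite checks it against the closed-form
formulas and its type-I error by simulation. Stars follow the
conventional mapping (*** for P < 0.001, ** for 0.001 ≤ P < 0.01, * for
0.01 ≤ P < 0.05), with boundary values resolving to the weaker claim
since the printed inequalities leave boundaries open. No multiple-testing
correction is applied by default, matching the assay's original analysis;
a Bonferroni option exists. Condition summaries report mean ± SEM, the
exclusion tally (orientation failures first, then zero-ROI larvae), and a
minimum-n gate: 30 analyzed larvae for the automated intensity mode, 15
for count mode.

**Orientation QC.** In the original screens plates were checked by eye
and badly mounted larvae re-oriented; there is no image-based orientation
classifier here. The flag travels with the data — from the simulator's
ground truth or an `orientation_ok` manifest column — and gates larvae in
the summaries.

## Conventions

Coordinates are 1-based pixel positions `(x, y)` with the origin at the
top-left, the native R convention. Stacks are stored per channel as
`H × W × Z` arrays; on disk they are multi-page 16-bit TIFFs in
channel-major page order (all bright-field, all green, all red), with an
interleaved-order switch on reading. Missing calibration metadata is kept
as explicit `NA`, never silently defaulted.

## Problem sizes used by the tests and the acceptance script

Simulation-heavy checks run at a 320 × 200 px field of view with 5
optical sections. All rendered structures keep their absolute pixel sizes
(rosette radius 8 px, spot widths 3 px, ROI side 48 px), so the detector
operates in the same regime as at the full 1300 × 1024 × 9 frame; only
the empty margins shrink. The screen-sensitivity check uses 200
simulation repetitions of 30 analyzed larvae per group — generated with
`lateral_orientation_prob = 1`, emulating plates whose mounting was
manually corrected before imaging — and the plate-accounting check
averages triplicates of 24 larvae over repeated seeds.

## What passing tests do and do not show

The generator emulates the *statistical* structure of the screen: spot-like
fluorescent objects on a dark tissue background, defocus across sections,
camera noise, brightness variability, dose-dependent recruitment,
drug-like suppression (a scaled recruitment mean), and the plate's
orientation attrition. It does not emulate pigmentation, autofluorescent
gut/skin texture, neuromast rosette disintegration after damage, cell
motion during exposure, anterior lateral-line organs, or optical
vignetting. Detection rates measured on synthetic plates therefore bound
the method's behaviour under the model's assumptions, not its performance
on any particular microscope; on real data the detector's tuning
parameters (smoothing, gates, ROI side) are the knobs to revisit. The
biology itself — which compounds suppress infiltration, and by how much —
lives in live fish and is out of reach of any desk-scale simulation.

## Known limitations

* The intensity score is reported in camera counts; comparisons across
  conditions are meaningful within a plate set imaged with fixed
  integration times, and enter the analysis only through the t-test.
* Two leukocytes closer than the optical resolution count as one in count
  mode (documented merge behaviour).
* The myoseptum-band estimate needs at least two detected neuromasts; in
  count mode, larvae with fewer are flagged rather than scored.
* The orientation QC is an input, not an inference; fully unattended
  operation would need an image-based mounting classifier.
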