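---
title: "Measuring 3D TIPS stent geometry: models, algorithms and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring 3D TIPS stent geometry: models, algorithms and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tips3d)
```

## The measurement problem

A transjugular intrahepatic portosystemic shunt (TIPS) is a covered stent
graft running from the portal vein, through the liver parenchyma, into a
hepatic vein close to the inferior vena cava (IVC). How the stent sits in
this tract — how sharply it curves, how far its cranial end stops short of
the IVC, how long its covered portion is — is a candidate predictor of
shunt dysfunction. `tips3d` measures that geometry in three dimensions
from a labelled post-procedure CT volume, and provides the downstream
statistics stage (group comparisons and Cox proportional-hazards
modelling) used to relate geometry to time-to-event outcomes.

The measurement substrate is a *venous path*: an ordered 3D curve from the
portal venous confluence, through the stent, to the IVC, with millimetre
arc length. All seven reported parameters are defined on this path and its
orthogonal cross-sections:

| parameter | definition |
|---|---|
| `cranial_end_to_ivc_mm` | along-path length from the cranial stent end to the IVC junction |
| `min_stent_diameter_mm` | smallest equivalent-circle diameter over the stent's cross-sections |
| `covered_length_mm` | along-path length between the two covered stent ends |
| `max_curvature_deg` | maximum sectional curvature (below) |
| `covered_ends_angle_deg` | angle between the tangent axes at the two covered ends |
| `alpha_angle_deg` | angle between the portal-vein course and the stent entry direction |
| `confluence_to_stent_mm` | along-path length from the path origin to the distal stent begin |

Distances are *along-path arc lengths*, not straight-line distances: the
parameters describe lengths measured along drawn vessel courses. Where the
original description of the curvature parameter carries the unit
"degrees/cm", the reported quantity is the angle itself in degrees — the
two printed worked examples (0 for a straight stent, 90 for a 90° bend)
and the reported cohort tables are only consistent with the plain angle,
and that is what this package reports.

## The maximum sectional curvature

The stented segment of the path is segmented into straight sections:
chords of 1 cm, separated by gaps of 5 mm. The parameter is the maximum
change of direction between two consecutive sections anywhere within the
stent:

* at a station $s$, take the chord over $[s, s+c]$ and the chord over
  $[s+c+g, s+2c+g]$ with $c = 10$ mm, $g = 5$ mm;
* the sectional curvature at $s$ is the angle between the two chord
  directions;
* the reported value is the maximum over all admissible $s$ in the stent
  interval (the uncovered distal portion is included — the parameter is
  defined over the entire stent).

A straight path scores 0; a single localized planar bend whose curved part
falls entirely inside the gap scores exactly the bend angle. The
maximisation slides the station on a 0.5 mm grid — at most a tenth of the
gap, which keeps the discrete maximum within half a degree of the
continuous optimum on smooth paths (verified against an exhaustive 0.1 mm
search in the test suite). We deliberately slide rather than evaluate a
fixed 15 mm partition: a fixed-phase partition can miss a bend that
straddles two of its windows, and sliding can only increase the reported
maximum. Whether the historical implementation slid or used a fixed
partition is not documented; the sliding choice is ours and is stated
here rather than guessed as the original intent. Likewise "gap" is read
as chord-end to chord-start separation, not midpoint distance.

```{r worked-examples}
straight <- resample_path(rbind(c(0, 0, 0), c(0, 0, 60)), spacing_mm = 0.5)
max_section_curvature(straight, arc_interval(0, 60))

bend90 <- resample_path(rbind(c(0, 0, 0), c(0, 0, 20), c(20, 0, 20)), 0.5)
max_section_curvature(bend90, arc_interval(0, path_length(bend90)))
```

## Centerline extraction

The path is extracted semiautomatically from an integer label volume
(0 background, 1 lumen, 2 uncovered stent, 3 covered stent; LPS
millimetre frame, NIfTI RAS converted on load) with two user-supplied
seeds (portal confluence and IVC, optional ordered waypoints):

1. **Distance transform.** An exact 3D Euclidean distance-to-background
   transform (Felzenszwalb–Huttenlocher, anisotropic spacings, volume
   border treated as background) gives every interior voxel its clearance.
2. **Medial shortest path.** A 26-connected directed voxel graph over the
   non-background voxels is weighted with
   $w = \text{step length} / (\varepsilon + d(\text{target}))$,
   $\varepsilon = 0.1$ mm, and the minimum-cost path between the seeds is
   found with Dijkstra's algorithm (igraph). The inverse-clearance weight
   keeps the route near the lumen axis. Whether the original software's
   path was medial or user-traced is undocumented; medialness is this
   package's design choice.
3. **Sub-voxel recentering.** Each station is re-positioned in the plane
   orthogonal to its local tangent (4 mm central-difference chord) at the
   clearance-weighted centroid of in-plane samples whose distance value
   exceeds 85% of the local ridge height. The ridge height is capped at
   the path-median maximum — the tube's typical inscribed radius — so a
   neighbouring limb glancing through the plane cannot drag the centroid.
   Two passes at a 0.5 mm in-plane grid bring a straight tube's station
   error well below a tenth of a voxel.
4. **Kink refinement.** At a sharp bend the voxelized tube is a mitered
   corner whose medial surface runs through the straight-extension vertex;
   clearance information alone cannot distinguish that vertex from the
   rounded spine, so every ridge-following path cuts the corner. A tube
   prior resolves the ambiguity: straight lines are fitted to the limbs
   flanking any zone whose local direction change exceeds 40° over 4 mm,
   the corner's rounding radius is estimated from the inner-wall clearance
   at the fitted vertex ($w_{in} = r - r_f(1/\cos(\theta/2) - 1)$ for a
   constant-radius tube), and the zone is rebuilt as the circular fillet
   tangent to both limbs. On phantoms this removes a 1–2 mm corner-cut
   bias at 90–120° bends while leaving gentle arcs untouched.
5. **Resampling.** The result is interpolated at uniform 1 mm stations
   (linear, no spline fitting; optional moving-average smoothing exists
   but defaults to off, because smoothing smears localized bends and must
   be an explicit choice).

## Cross-sections and the minimal diameter

Cross-sections orthogonal to the path (the multiplanar-reconstruction
step, done with the package's own resampler) sample the selected labels on
a 0.25 mm in-plane grid over a 40 mm window, keep the 8-connected
component containing the path point, and report its area and
equivalent-circle diameter $2\sqrt{A/\pi}$. The equivalent-circle
definition is robust to ragged strut boundaries; a Feret-type caliper
would not be, and is deliberately not the default. A station whose plane
contains none of the selected labels yields a flagged zero-area profile,
not an error. The in-plane basis is constructed in the volume's voxel
frame, which makes the measurement exactly invariant when volume and path
are moved rigidly together; nearest-voxel ties at half-voxel positions are
broken upward deterministically for the same reason.

The minimal stent diameter is the minimum over stations 1 mm apart,
after insetting the profiled interval 2 mm from both stent ends: a plane
straddling the stent's end face cuts a partial section whose area says
nothing about calibre.

## Phantoms and what validation shows

Real post-TIPS CT scans are not redistributable, so validation rests on
parametric phantoms with analytic ground truth: exact piecewise line/arc
centerlines (straight; single planar bends; whole-path circular arcs;
multi-bend composites, optionally out of plane) swept with a constant
4 mm radius (8 mm diameter, matching the measured stents) and an optional
waist, rendered into label volumes at 0.5 and 1.0 mm voxels by
nearest-sample stamping. Sharp vertices carry a 2 mm fillet so the tube is
renderable; the fillet arc stays below the 5 mm curvature gap up to 130°
bends, so a localized bend still attains its full angle. Truth values are
computed on the exact curve with the operative chord definitions (the
curvature truth is an exhaustive chord-pair maximisation at 0.05 mm on the
analytic curve; for a circular arc it equals the closed form
$(c+g)/R$ radians). The deterministic battery (`phantom_suite()`) spans
bends of 15–120°, waists of 6–8 mm, cranial offsets of 0–26.5 mm — the
range that brackets the reported cohort medians — and both voxel sizes,
40 phantoms in all; the acceptance suite requires every length within
max(0.5 mm, 1 voxel), every angle within 3°, and the minimal diameter
within 1 voxel of truth.

What passing does *not* show: phantoms have clean labels (dropout
simulates strut artefacts but defaults to 0), perfectly tubular lumina,
no motion artefacts, no neighbouring vessels touching the stent, and
landmarks given exactly. Performance on clinical segmentations depends on
segmentation quality in ways these tests cannot certify.

## The cohort statistics stage

The statistics stage mirrors a standard dysfunction-risk analysis plan:

* **Group comparisons** (`compare_groups()`): Mann–Whitney U for
  continuous variables (medians with interquartile ranges), chi-square for
  categorical counts, pairwise missing-value exclusion, two-sided p.
* **Cox regression** (`cox_univariate()`, `cox_forward_stepwise()`):
  partial likelihood with Efron tie handling (`survival::coxph`), hazard
  ratios per unit with Wald 95% CIs on the log scale, per-analysis
  complete cases. Forward stepwise selection admits the candidate with the
  smallest entry p below 0.1 and removes included terms whose Wald p
  exceeds 0.1, after a univariate screen at p < 0.1
  (`screen_candidates()`). The plan's description of the multivariate step
  as stepwise *logistic* regression in a time-to-event analysis is
  implemented as stepwise *Cox* selection — the endpoint is a censored
  time throughout. The entry statistic is a partial-likelihood-ratio test
  refit on the common complete cases (a score test is first-order
  equivalent; `stats_config(enter_test=)` exposes a Wald alternative, and
  the exact flavour used by the original SPSS analysis is unknown).
* **Imaging-delay sensitivity** (`sensitivity_time_to_ct()`): the same
  stepwise rule over the two retained geometry covariates plus the
  procedure-to-CT delay, with excluded incomplete cases counted.

The simulator (`simulate_cohort()`) draws geometry covariates from
truncated normals matched to the reported cohort medians and interquartile
ranges (IQR/1.349 as spread), and event times from an exponential
proportional-hazards model with the reported multivariate hazard ratios as
default effects: 1.020 per degree of curvature and 1.061 per millimetre of
cranial-end distance. The default baseline hazard, 3.1·10⁻⁴ per day,
anchors the median event time near the cohort's 539 days at median
covariates; the default censoring rate, 5.5·10⁻⁴ per day, yields roughly
30% censoring, the regime the parameter-recovery tests operate in. With
n = 500 and 100 seeded replicates, the 95% CIs cover both true effects in
at least 90% of replicates and the stepwise pipeline selects both true
effects in at least 90% despite five added noise covariates, while under
null effects each candidate enters in about the nominal 10% of replicates.
These checks certify the machinery, not the clinical findings: the actual
patient-level results cannot be reproduced without the patient data, and
reproducing them is explicitly not a claim of this package.

## Numerical choices and degenerate inputs

* Paths need at least two distinct points; an all-coincident polyline is a
  degenerate-path error, and consecutive duplicates are dropped before
  resampling.
* Angles come from a clamped arccos; zero-length chord vectors are
  degenerate-vector errors.
* If several stations tie for the maximum curvature, the angle is the
  scalar result and the first attaining station is exposed as an
  attribute for diagnostics.
* Landmarks may arrive as arc positions or as clicked 3D points snapped to
  the nearest path segment; orderings are validated and the terminus must
  agree with the path length within 1 mm (sub-millimetre bookkeeping is
  clamped, never silently extrapolated).
* Stent intervals shorter than one chord pair (25 mm at the defaults) are
  an insufficient-length error rather than a silent 0.
* All package errors carry `tips3d_*` condition classes so callers can
  dispatch on failure modes.

## Problem sizes

The shipped validation runs at deliberately desk-friendly sizes: phantom
volumes of roughly 100–160³ voxels at 0.5–1 mm spacing, cohort
simulations of n = 300–500 with 100 replicates for the recovery and
calibration suites, and 2000 for the independence checks. All were chosen
to exercise the estimators at realistic scale; none are tuned to any
particular hardware.

## Known limitations

* The centerline is as good as the segmentation; touching vessels merged
  into one label component can divert the medial path.
* The kink refinement assumes a locally constant tube radius; a stenosis
  exactly at a sharp bend would bias its radius estimate.
* Sectional curvature is a window statistic, not differential curvature
  (1/R); two stents with equal maxima can bend very differently elsewhere.
  Torsion and spline models are out of scope by design.
* DICOM series reading, automatic stent segmentation from grey values,
  and spontaneous shunt quantification are out of scope.
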