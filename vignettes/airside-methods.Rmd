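---
title: "Methods: airside telemetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: airside telemetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airside)
```

## The problem

Terrestrial mammals living on airfields pose a strike risk only while they
are inside the manoeuvring areas — runways, taxiways and the connecting
strips between them ("tarmacked areas"). `airside` analyses GPS-collar
telemetry of such animals (its design case is hares resident on a large
Irish airfield) to quantify how often, when and where individuals enter
tarmacked surfaces, how far they travel, and how their home ranges overlap
the airfield's habitat mosaic.

The pipeline is: ingest and quality-control fix tables → build movement
steps → detect step × tarmac intersections → anchor event times to sunrise
and sunset → summarise daily/monthly movement → estimate kernel home ranges
and their habitat composition. A two-state movement simulator generates
synthetic airfields and collar datasets with ground truth so every stage is
testable without restricted field data.

## Coordinate frame

All geometry is planar, in metres, in a local transverse-Mercator frame
(WGS84 ellipsoid, scale 1 on the central meridian) centred on the study
site. For a site spanning under 10 km the planar distance error is far
below GPS accuracy; the projection is validated in the test suite against
geodesic distances to within centimetres over 5 km. GeoJSON maps written by
the package carry the frame descriptor and are re-projected into the
caller's frame on load, so maps and trajectories never mix frames.

## Quality control

Two filters, both exposed as parameters of `filter_fixes()`:

* **Accuracy**: fixes with horizontal accuracy *strictly greater than*
  30 m are removed. The threshold is motivated by surface widths: taxiways
  (~35 m) and runways (~60 m) are not much wider than a bad fix's error
  circle, so poorer fixes manufacture false crossings. Fixes with missing
  accuracy are retained (removal would bias against older collar firmware
  that omits the field) and logged.
* **Burn-in**: the first 5 whole days (24 h blocks from deployment start)
  are dropped to exclude handling-influenced movement.

Filtering is idempotent and order-preserving; an all-removed trajectory is
returned empty with a warning rather than an error so batch runs survive a
failed collar.

## Interaction detection

A *step* is the straight segment joining two consecutive retained fixes; a
trajectory of *n* fixes yields exactly *n − 1* steps. An *interaction* is
one (step, tarmacked polygon) pair whose geometries intersect, with closed
boundaries: grazing an edge or touching a corner counts, because
"intersects" without qualification is the only deterministic reading. One
step crossing two surfaces yields two events (each intersected surface is
an independent strike opportunity), but a step that enters, leaves and
re-enters the same polygon counts once — the counting unit is the pair,
not the crossing component.

The event timestamp is the step's **earlier** fix. Nothing in the data
says where along the step the crossing happened; the earlier fix is the
deterministic "event began by" anchor, and at 10-min sampling the choice
moves an event by at most one sampling interval.

Known limitation: crossings that begin and end between two fixes on the
same side (fast out-and-back in under 10 min) are invisible to any
segment-based detector and are not imputed. Step lengths (mean ≈ 50–60 m at
the 10-min schedule) are shorter than a runway's 60 m width, which bounds
how much such misses can matter.

Detection is verified two ways: against a dense point-sampling oracle
(points every 1 cm along each segment, tested point-in-polygon) over
thousands of random segment/rectangle cases, exactly; and against the
simulator's ground-truth crossing log, where every truth crossing witnessed
by a fix must be recalled.

## Sun-anchored activity offsets

For each event we compute the signed offset to its solar reference:
events between 00:00 and 11:59 local civil time reference **sunrise**,
events from 12:00 on reference **sunset**. The magnitude is the absolute
difference in hours; the sign is positive in daylight (sunrise ≤ t ≤
sunset) and negative in darkness, so offsets are exactly zero at the sun
events and continuous everywhere except the noon reference switch.
Offsets are kept as continuous hours, not rounded to whole hours — the
natural worked example (+3 h 30 min) has sub-hour precision.

Sunrise/sunset come from the standard NOAA solar-position formulation
(zenith 90.833°, i.e. refraction plus solar radius), computed at a single
reference coordinate for the whole site (the airfield spans far less than
one solar minute). A user-supplied lookup table overrides computation when
an authority's published times are preferred. The implementation is checked
against solstice daylight durations at the study latitude (~17 h summer,
~7.5 h winter) and equator-equinox symmetry, all within ±2 minutes'
tolerance of the expected durations.

Seasonal comparison uses the Kruskal–Wallis test on offsets grouped by
meteorological season (winter = Dec–Feb, spring = Mar–May, summer =
Jun–Aug, autumn = Sep–Nov), with Dunn pairwise post-hoc z tests and
Benjamini–Hochberg adjustment. Clock-time histograms use 3 h bins anchored
at local midnight, right-open.

## Rank statistics

`kruskal_wallis()`, `dunn_posthoc()` and `bh_adjust()` are self-contained:
mid-ranks for ties, the usual tie-correction factors, chi-square (KW) and
normal (Dunn) reference distributions, two-sided Dunn p-values. The
chi-square approximation alone is used — group sizes in this pipeline are
dozens to hundreds of observations, where exact small-sample tables are
irrelevant. The implementations are cross-checked in the tests against
`stats::kruskal.test` and `stats::p.adjust(method = "BH")`, and calibrated
under the null (type-I error 0.05 ± 0.02 over 2,000 simulations).

## Movement metrics

Daily distance is the sum of step lengths assigned to the local date of
each step's earlier fix; steps spanning midnight are not split (the
simplest deterministic rule; at 10-min sampling the at-stake length is one
step). Distances are planar Euclidean and therefore conservative: real
paths between fixes are at least as long as the chord. Cumulative monthly
distance keeps, per animal, only months fully covered by the deployment,
with an explicit exemption list for partially covered months one decides
to keep (e.g. a first month where all collars started a few days in).
Step-length summaries default to steps of ≤ 20 min duration, isolating the
10-min active schedule from 6 h resting gaps.

## Kernel home ranges

The utilisation distribution is a bivariate Gaussian kernel density with
the reference bandwidth

h_ref = sqrt((var(x) + var(y)) / 2) · n^(−1/6),

the standard bivariate-normal reference choice built from the coordinate
standard deviations and the number of relocations. All retained fixes enter
equally (both schedules); the 6 h resting fixes are few relative to the
10-min active fixes, and any reweighting scheme would be an unsupported
model choice.

Numerical choices: the grid covers the fixes' bounding box expanded by 4·h
per side (kernel mass beyond that margin is ~3·10⁻⁴), with at least 200
cells per axis and cells never coarser than h/2; the discrete density is
renormalised to sum exactly to one. The 95% home range is the smallest
density superlevel set capturing ≥ 0.95 probability: cells are ranked by
density, the capturing threshold found, and the iso-density contour
polygonised by marching squares (`grDevices::contourLines`), with areas
from the polygon rings (even-odd rule for holes) rather than cell counts.
The estimator is validated against the closed-form 95% region of an
isotropic bivariate normal (area π σ² χ²₀.₉₅,₂ ≈ 18.8 ha at σ = 100 m):
the mean relative error shrinks monotonically across n = 200, 1,000, 5,000
draws and ends within 15%.

Habitat composition ("overlap analysis") is computed on a fine sampling
grid (~400 cells per axis across the home range): each in-range cell centre
is assigned to the first containing map polygon, and the unmapped
remainder — including area outside the airfield boundary — is reported as
its own class. The gridding error is below 0.5% on half-overlap test
geometries.

## Surface-map validation

Habitat classes and activity statuses come from fixed vocabularies;
tarmacked surfaces must carry a real activity status (a closed runway is
still a tarmacked area, and `tarmacked_subset()` keeps every status).
Self-intersecting or zero-area rings are rejected, naming the offending
surface. Tarmacked polygons may share edges (a connecting strip abuts its
runway) but may not overlap with positive area, which would double-count
events; the overlap test requires > 1 mm of perpendicular penetration so
that abutting edges reconstructed through lon/lat round-trips do not
spuriously fail.

## The simulator

`simulate_hares()` generates, per animal, a continuous path on a 1-min
grid driven by a two-state process:

* **Activity**: the probability of starting an active bout is a baseline
  (0.1) plus Gaussian bumps (height 0.85, width 1.5 h) centred on sunrise
  and sunset — the simplest crepuscular model producing the bimodal dawn /
  dusk pattern typical of hares. Bout ends are geometric with mean 60 min
  (active) and 90 min (resting).
* **Movement**: active animals follow a correlated random walk (speed
  7 m/min, turning-angle sd 0.6 rad/min) with a linear attraction
  (0.003/min) to the home centre, giving stationary home ranges of tens of
  hectares and 10-min step lengths around 50–60 m; resting animals are
  stationary.
* **Tarmac excursions**: a Poisson process per animal (rate configurable)
  triggers directed trips toward the nearest tarmacked polygon, either
  *through* it or just *touching* it. This is the explicit
  crossing-propensity dial that creates the near-tarmac vs distant-animal
  contrast.
* **Sampling**: a fix is taken when the time since the last fix reaches
  the state's interval — 10 min active, 6 h resting — exactly emulating an
  accelerometer-informed schedule without simulating the accelerometer
  signal itself (the activity state stands in for the variance threshold).
  Gaussian position noise (sd 5 m) is added, and per-fix accuracy values
  are drawn from a gamma distribution (mean 7.5 m) with a configured 2%
  of fixes worse than 30 m (those get noise matched to their accuracy, so
  the QC filter removes genuinely bad positions).

Ground truth records the full path, per-day true path length, and every
true crossing — a connected path interval inside a tarmacked polygon, plus
within-step pass-throughs. Truth crossings are per-interval-per-polygon
while detection is per-step-per-polygon, so tests map between the units by
time containment rather than asserting equal counts.

`scenario_paper_like()` fixes the study conditions at desk scale: five
collars over 30 days from early December, a three-runway synthetic
airfield (runways 60 m, taxiways 35 m wide), two animals homed ~190 m from
a semi-operational taxiway with 1.5 excursions/day and three in distant
grassland with 0.2 excursions/day. Those rates and placements were chosen
so that, by configuration, near animals interact at well over ten times
the rate of distant ones while interactions remain a minority (< 20%) of
any animal's steps — the qualitative structure of the motivating study,
at sample sizes a laptop processes in seconds.

What the simulator does **not** emulate: real GPS error is
autocorrelated and habitat-dependent, hare speeds are bursty during
breeding chases, activity responds to weather and disturbance, and fences
channel movement. Passing tests therefore demonstrate correctness of the
pipeline's computations under a plausible movement model, not ecological
validity of any particular field inference.

## Problem sizes and determinism

Default verification sizes — 30-day scenarios, 200 × 200 density grids,
12-replicate calibration runs, 2,000-replicate null calibrations, 1,000
random segments against the geometric oracle — were chosen so a full
verification pass completes in minutes on one core while keeping Monte
Carlo error well inside the asserted tolerances. Every stochastic
component is seeded: the same seed reproduces byte-identical fix tables,
GeoJSON maps and reports.

## Known limitations

* Segment-based detection cannot see sub-interval out-and-back crossings;
  counts are lower bounds.
* Planar chord distances under-measure tortuous paths; daily distances are
  conservative.
* The KUD with reference bandwidth oversmooths multimodal ranges
  (h_ref is derived from a unimodal reference); no cross-validated or
  autocorrelation-aware bandwidths are provided.
* `dunn_posthoc` reports z and adjusted p only — no effect sizes.
* Only polygonal (not multi-polygon) GeoJSON features are supported.
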