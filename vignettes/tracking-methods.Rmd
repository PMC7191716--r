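---
title: "Methods: detection, tracking, selection and motility statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detection, tracking, selection and motility statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactrack)
```

bactrack quantifies the swimming behaviour of bacterial populations from 2-D
video microscopy. It is built for the high-throughput regime — hundreds of
cells per frame at a 10x objective, videos of several minutes — where
per-cell appearance models are too expensive. The strategy is deliberately
*moderate fidelity, high selectivity*: detection and linking are cheap and
simple, and a stringent selection stage afterwards discards every track
whose provenance is in doubt. The statistics are then computed only over
tracks that survived selection.

This vignette explains each stage, the parameters that matter, and the
choices made where the design was genuinely open.

## Detection by grey value

Each frame is converted to grey scale (BT.601 luma for colour input) and
smoothed with a small Gaussian blur (`blur_kernel`, default 3) to suppress
single-pixel noise. Bacteria are then segmented by one of three threshold
modes:

* **`marker_gated`** (default). An adaptive Gaussian threshold (kernel
  `adaptive_kernel`, default 11; offset `adaptive_offset` grey levels below
  the local mean for dark cells, above it for bright cells) produces
  *candidate* regions. A second, stricter threshold (`marker_offset`)
  produces *marker* regions. A candidate region is kept only if at least
  one marker pixel lies inside its pixel set — faint fluctuations that
  pass the loose threshold but contain no confidently dark (or bright)
  core are discarded. "Inside" means the region's own pixels, not its
  bounding box: the strictest reading of marker containment.
* **`adaptive_simple`**: the candidate threshold alone.
* **`global_rolling`**: a single global threshold per frame, computed as
  the frame's mean grey value offset by `global_offset` standard
  deviations towards the cells, then averaged over a moving window of
  `rolling_window_s` seconds (default 5) so that slow illumination drift
  moves the threshold gradually rather than per frame.

The adaptive local mean is a separable Gaussian convolution with
replicate-padded borders, with the kernel's standard deviation derived
from its size by the convention `sigma = 0.3 * ((k - 1)/2 - 1) + 0.8`. The
two adaptive offsets are signed grey-level constants; the marker offset
defaults to the candidate offset plus 5 grey levels. Both are
configurable, since the appropriate contrast margin depends on the
illumination and camera.

White regions are labelled with 8-connectivity (a thin diagonal rod stays
one object) and each region becomes one detection: for rod-shaped cells
the minimum-area rotated rectangle of the region (rotating calipers over
the convex hull of the pixel corners), giving width, height and a rotation
angle in [0, 180); for coccoid cells the axis-aligned bounding box with
angle 0. The rectangle centre — the *tracking target* — is the coordinate
used for linking. Coordinates follow image convention: origin at the
top-left pixel centre, x rightward, y downward, 0-based frames, time =
frame / fps.

## Tracking

Linking is nearest-neighbour in space, stabilised by a motion model. For
every live track a constant-velocity finite-impulse-response (FIR) filter
maintains a window of the most recent `filter_window` measurements
(default 5) and fits a linear trend by least squares; the filtered
position is the trend at the current frame, the prediction the trend one
frame ahead, and the velocity its slope. Optionally
(`filter_reweight`, default on) one Gaussian re-weighting pass
down-weights window entries by their residual to the fitted trend, which
softens the influence of single bad measurements (overlap events, partial
detections). On noiseless linear motion the smoother is exact: filtered
positions and predictions reproduce the true line, which is the
property the tests pin down.

Per frame, predictions and detections are joined greedily: repeatedly bind
the pair with the smallest Euclidean distance until nothing remains within
the gate. The gate is the per-frame displacement implied by a configurable
top speed (`gate_speed_um_s`, default 50 µm/s — safely above the ~20-30
µm/s of fast swimmers), scaled up for tracks that have been coasting.
Greedy matching is the literal "join the neighbours with the least
distance", is deterministic (ties break by track id, then detection
order), and scales to a thousand objects; it can differ from the optimal
assignment in crossing configurations, which is one reason the selection
stage treats suspicious tracks harshly rather than trusting the linker.

Unmatched tracks receive a *gap point*: width and height 0, position at
the prediction, angle carried over. A track not re-detected within
`track_expiry_s` (default 1 s) is retired, and its trailing gap points —
pure extrapolation — are removed. Unmatched detections open fresh ids;
ids are never reused. The raw table (id, time, filtered position, width,
height, angle) is written as a CSV sorted by id then time.

## Track selection

Selection runs in two stages with per-criterion exclusion counters.

**Coarse stage, whole tracks.** A track is dropped when its mean bounding
rectangle area — gap points counted at area zero, so a brief detection
burst followed by a second of coasting averages close to zero — falls
below `coarse_area_lower_frac` (default 20%) or above
`coarse_area_upper_mult` (default 5x) of the expected cell area
`avg_bacterial_area_px2`, or when it is shorter than `min_track_time_s`.
The expected area is user-supplied rather than estimated from the data:
estimation would make every other threshold depend on the detection
outcome, and the rule-of-thumb limits are deliberately broad.

**Point scrubbing.** Zero-area gap placeholders are removed (they sit at
predicted, not measured, positions), as are points whose area exceeds
`point_area_outlier_mult` times the track's mean non-gap area — the
signature of two cells overlapping into one rectangle. Removal creates
gaps by timestamp.

**Splitting.** Runs of more than `max_consecutive_gaps` missing frames
cut the track, as do per-step distances above the Tukey outer fence
(Q3 + 3·IQR, quartiles by linear interpolation) of the track's step
distances when `distance_outlier_enabled`. Every resulting segment
re-enters the pipeline at the coarse stage. Because fences degenerate
when most objects are immotile (quartiles collapse to zero and every
twitch becomes an outlier), distance splitting disables itself for the
whole table when the fraction of outlier steps exceeds
`distance_outlier_auto_disable_frac`, and the report flags it.

**Fine stage, per segment, first failure wins:** minimum duration; maximum
consecutive-gap run; gap fraction (missing frames over the segment's span
at the frame cadence, robust to prior scrubbing); mean area within the
[p, 100−p] percentile band of the candidate size distribution
(`size_percentile`; the band is two-sided by default, one-sided by
configuration — the criterion exists to catch area outliers that slipped
past the coarse limits, and those can sit on either side); and mean
position at least `edge_margin_frac` of the frame dimension away from
every edge, because ids near the edges can be reassigned when cells enter
the frame.

If several parts of a split track pass, only the longest survives (ties:
more points, then earlier start). Finally, `max_track_time_s` truncates
accepted tracks at the exact relative time — or the closest earlier point
when a gap sits there — and `drop_short_after_truncation` optionally
rejects tracks that fall short.

**Counter semantics.** Each original track that ends with no accepted
segment is counted exactly once, under the criterion that rejected its
longest surviving candidate. A candidate that was created by a split and
then fails the minimum-time check (or has fewer than 2 points) inherits
the split cause — the split destroyed its viability, and without this
rule the gap-run and distance-outlier counters could never fire, since
splitting always removes the trigger from the pieces. With this
attribution the conservation law `tracks_in = accepted + sum(exclusions)`
holds exactly, and the tests assert it on constructed and random tables.

One caveat the tests respect: "disabling a criterion never decreases the
number of accepted tracks" is guaranteed only for the pure-rejection
criteria (times, gap fraction, size percentile, edge margin). The
split-triggering criteria can rescue a track — splitting a gappy track
may produce halves that pass a gap-fraction check the whole would fail —
so disabling them is not monotone in general.

## Motility statistics

Seven parameters per accepted track, computed on the points as stored
(filtered positions, no additional smoothing): total travelled distance
(µm); mean speed (total distance / duration, µm/s — identical to the mean
instantaneous speed at uniform frame cadence); duration (s); maximum
distance between tracked positions (µm, exact via convex-hull antipodal
pairs); percentage of time motile (fraction of steps whose instantaneous
speed reaches `motile_speed_threshold_um_s`); turn points per second; and
the arc-chord ratio (path length over first-to-last chord; 1 for straight
motion, `NaN` for a closed track with zero chord — never an error).

Steps that span a gap use their actual time difference and count toward
distance and speed, but are excluded from turn detection: heading across
a gap is unreliable.

A *turn point* is an interior point whose adjacent-step heading change
exceeds `turn_angle_threshold_deg` (default 30°), with both steps at
least `turn_min_step_px` (default 0.5 px, a noise floor below which
headings are meaningless). This is a point count, as the parameter's name
says, not an event count: the position filter spreads a sharp
reorientation over a few points, so one large tumble can contribute
several above-threshold points, while reorientations below the angle
threshold contribute none. At the default settings these two effects
nearly cancel — on simulated run-and-tumble populations (below) the
mean turn-point rate tracks the simulated tumble rate to within about
±15% — which is why the point count was kept over an explicit
event-merging rule, whose systematic undercount (~25%) was measurably
worse. The motile-speed default of 4 µm/s sits well below typical
swimming speeds (15-30 µm/s) and above the apparent speed that residual
localisation noise induces on filtered stationary tracks.

## Synthetic ground truth

The simulator generates run-and-tumble motion: straight runs at
`speed_um_s`, tumbles as a per-frame Bernoulli process with probability
`tumble_rate_hz / fps`, each tumble an instantaneous heading rotation
drawn uniformly from ± the dispersion half-width (default 180°, i.e.
isotropic — the simplest null model for a tumble). An immotile fraction
jitters around a fixed anchor (Gaussian, `jitter_px` per frame). Cells
whose centre leaves the frame have their truth truncated there and ids
are never reused. Rendering draws each cell as a filled rotated ellipse
(default 4 x 2 px, the scale of a rod at ~2 px/µm) darker or brighter
than the background per the configured polarity, adds Gaussian pixel
noise, and writes an MJPEG (or uncompressed) AVI with the truth CSV
beside it.

What this emulates: object scale, contrast polarity, frame rate, density,
motion statistics, boundary truncation, overlap events. What it does not:
optics (defocus, shading, point-spread function), Brownian rotational
diffusion during runs, cell division, or the gradual intensity
variations of real illumination. Passing the recovery tests therefore
shows the pipeline is internally consistent and recovers known motion
statistics under its stated assumptions — not that any particular real
recording will segment cleanly; the threshold offsets and expected area
must still be set for the instrument at hand.

## Numerical and procedural choices

* Quartiles use linear interpolation (R type 7) everywhere.
* The CV-FIR re-weighting uses `s = 1.4826 * median(|r|)` (the normal-
  consistent MAD scale) and weights `exp(-0.5 (r/s)^2)`; windows shorter
  than 3 measurements skip re-weighting; exactly linear windows are left
  untouched (residual scale below 1e-9).
* Track CSVs round positions to 4 decimals (far below localisation
  accuracy) so that write → read is exactly identity.
* Matching ties break deterministically by (id, detection order); mask
  extraction orders detections by (centre y, centre x).
* Degenerate inputs: empty frames produce empty detection lists; an empty
  video produces a header-only CSV; a zero-chord track produces a `NaN`
  arc-chord ratio; a single-pixel region is a 1 x 1 rectangle.
* Problem sizes in the validation suite: identity recovery uses 50
  well-separated cells for 30 s at 30 fps (800 x 600 px, noiseless
  MJPEG); parameter recovery uses 150 cells for 15 s (same frame), which
  leaves roughly 80 accepted tracks after selection — enough that the
  sampling error of the stochastic turn-rate estimate is small against
  its tolerance. The detection oracle cross-check runs 200 random 64 x 64
  masks against a flood-fill labeller written independently of the
  implementation.

## Known limitations

* Greedy linking can swap ids when cells cross within the gate; the
  selection stage limits the damage but does not repair lineages, and
  merge/split events are not modelled.
* The Gaussian-sum FIR filter is realised as a least-squares linear-trend
  smoother with one Gaussian re-weighting pass; window length and
  re-weighting are configurable, and the realisation is deliberately
  swappable (`cv_filter_step` is the single entry point).
* Rotation angles of near-circular regions are unstable; coccoid mode
  reports 0 by design.
* Turn-point counts and the arc-chord ratio are sensitive to residual
  localisation noise: noise adds spurious heading changes on short steps
  and inflates the path length of weakly displacing tracks. On noisy
  recordings, raise `turn_min_step_px` towards the observed per-frame
  noise amplitude (or raise the angle threshold); the defaults are set
  for the near-noiseless validation regime.
* The MJPEG/uncompressed AVI reader covers the two containers the
  pipeline itself writes; arbitrary third-party containers and codecs are
  out of scope.

## A worked example

```{r example, eval = FALSE}
cfg <- bt_default_config(frame_width = 640L, frame_height = 480L)
params <- motion_params(n_bacteria = 30, duration_s = 15, seed = 7)
truth <- simulate_tracks(params, cfg)
paths <- render_video(truth, params, cfg, noise_sd = 0,
                      out_path = "demo.avi")
run <- track_video(paths$video, cfg, outdir = "demo_out")
summary(run)
plot_tracks(run$selection, "rose")
plot_violin(run$stats)
```
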