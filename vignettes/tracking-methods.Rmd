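---
title: "Methods: multi-animal tracking and stimulus-aligned analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-animal tracking and stimulus-aligned analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optotrack)
```

## The problem

Optogenetic behaviour experiments on small animals — fly larvae, adult
flies, zebrafish — produce overhead grayscale videos of several
near-identical individuals moving in an arena while a light stimulus is
switched by a separate microcontroller. Extracting per-animal behaviour
requires three things: detecting the animals in each frame, linking
detections into persistent identities (including through collisions, when
two animals touch and merge into one blob), and aligning the trajectories
with the stimulus record, which is timestamped by a different, unsynchronised
clock. `optotrack` implements this pipeline offline, together with a
synthetic video generator that provides exact ground truth so every stage
can be validated quantitatively.

## Segmentation model

Frames are grayscale intensity matrices in [0, 1], whatever the source bit
depth. The static background is estimated as the **per-pixel median** over a
regularly strided sample of frames (at most 101, preferring an odd count):
provided each pixel is covered by a moving animal in fewer than half of the
sampled frames, the median ignores the animals entirely. A dynamic variant
(`update_background()`) blends each new frame in with a small weight for
slowly changing illumination.

Foreground is the **absolute** difference from the background — one code
path serves both recording polarities (dark animals on a light, ambient-lit
background, and bright animals on a dark background under IR darkfield
illumination). A strict threshold (`diff > t`, with `t` a fraction in
[0, 1]; values below 0.1 suit typical arena footage) produces a binary
image, optionally restricted by a user-drawn mask (positive pixels keep,
zero removes). Connected components use **8-connectivity**, so
diagonally-touching thin bodies remain single objects, and are gated by a
pixel-area interval `[min_area, max_area]`.

Each surviving cluster is measured: the centroid is the mean of pixel
centres (coordinates are 0-based, x = column, y = row, sub-pixel); the
orientation is the principal axis of the pixel-coordinate second-moment
matrix; the "length across the primary axis" is the peak-to-peak extent of
pixel centres projected onto that axis, plus one pixel, so a single pixel
has length 1. The projected-extent definition (rather than a fitted-ellipse
major axis) is an explicit, auditable choice: it is exact for bars, robust
to ragged rasterisation, and reproducible by a three-line oracle.

## Identity model

The tracker's identity features are a track's **temporal mean area** and
**temporal mean primary-axis length** — time-independent characteristics of
each animal — combined with location and trajectory. The assignment cost
between track and cluster is

```
cost = w_d * d / max_move
     + w_a * |area - mean_area| / mean_area
     + w_l * |length - mean_length| / mean_length
```

with default weights 1, 1, 1 (the field reports no canonical weighting; equal
weights keep the three normalised terms commensurate). `d` is the distance
from the track's predicted position: last position plus the last *per-frame*
displacement, extrapolated over the gap since the track was last observed —
a one-step constant-velocity model. A pair is infeasible when
`d > max_move * gap`. Per frame, a globally minimum-total-cost one-to-one
matching (Jonker–Volgenant shortest augmenting paths; optimal, not greedy)
is solved over the feasible pairs; among matchings of maximum cardinality
the total cost is minimised, and the solver is deterministic for fixed
input order.

Track lifecycle follows three user parameters: a provisional track must be
matched `min_active` consecutive frames before it is recognised as active
(noise suppression; its provisional prefix is then emitted retroactively,
and provisionals that miss a frame before activating are discarded); an
unmatched track keeps its last position and is archived once its inactivity
exceeds `max_inactive` frames.

### Merges and splits

When two animals collide their blobs fuse into one component. Discarding
that component (it exceeds `max_area`) would orphan both tracks, so the
full pipeline segments with an open upper gate and hands the segmentation
`max_area` to the tracker as its `merge_area`. A cluster larger than
`merge_area` never births a track; instead every feasible unmatched track
attaches to it in a *merged* state. A normal-sized cluster also becomes a
merge when it is the unique feasible target of otherwise-unmatched tracks
so that at least two tracks claim it — including the case where the cluster
won a one-to-one match with one track while another unmatched track has
nowhere else to go. (Requiring the cluster itself to be unmatched, as a
literal reading of the association rules might suggest, can never trigger
with two tracks and one blob, because the optimal matching always pairs the
blob with one of them; the implemented rule follows the intent.)

While merged, a track records the blob centroid in its history (flagged
`merged`) but its mean area and length are **frozen**, so the collision
blob cannot corrupt the identity features. Two numerical details matter at
the split: first, velocity is never estimated across a merged observation —
the blob-centroid jump is not animal motion; second, the distance gate is
widened by the blob's semi-length for merged tracks (and for merge-sized
clusters), because the centroid of a newly separated cluster appears up to
half a blob-length away from the merged centroid in a single frame. With
those two details, the post-split assignment — minimum-cost matching with
the frozen means — restores identities whenever the animals differ in size
or length, and `resolve_split()` exposes that matching directly.

## Stimulus layer and clock drift

Stimulation protocols are step-function event lists (`time_s`, byte value):
`intensity_ramp()` increments one byte per `interval` starting from the
value-0 event at t = 0 (the inclusive starting event is a documented choice;
the firmware loop it mirrors is ambiguous), and `blinking()` holds 0 for
`interval_low`, then alternates `brightness`/0 phases of `interval` seconds.
Event lists, not dense samples, keep epoch boundaries exact.

The acquisition computer and the stimulation controller run independent
clocks; their relation is modelled as a line `device = slope * host +
offset` (a constant-rate drift — about 3.96 s/hour for the hardware pair
this mirrors — is `slope = 1 + 3.96/3600`). `write_state_log()` simulates
the device reporting its state every 100 ms (configurable; the nominal
reporting period is treated as such) with host-clock stamps and optional
Gaussian receive jitter; `estimate_drift()` recovers the line by ordinary
least squares, and `frame_states()` assigns each video frame the value of
the latest record at or before it (0 before the first record).

Sensor-signal smoothing (`moving_average()`) is a causal trailing mean —
output index i averages the last `min(window, i)` samples — and the
illuminance-to-irradiance calibration is an ordinary least-squares
quadratic with `r_squared = 1 - SS_res/SS_tot`, defined as 1 for a
zero-variance target (a perfect constant fit), and evaluation clipped below
at zero since irradiance cannot be negative.

## Epoch statistics

`segment_epochs()` splits a trajectory's time span into maximal
constant-state intervals of the stimulus record; the intervals tile the
span exactly. Per track and epoch, displacement is the **path length** (sum
of Euclidean steps between consecutive raw samples in the window; net
start-to-end distance would hide back-and-forth crawling, and smoothing is
deliberately out of scope), and mean crawl velocity is displacement divided
by epoch duration. Off-vs-on comparisons use a two-sided paired Wilcoxon
signed-rank test implemented in-package: zero differences dropped, ties
mid-ranked, exact p by enumeration of all sign patterns for up to 12
non-zero pairs (reproducibility over approximation at the sample sizes
these experiments use), normal approximation with tie-corrected variance
(`Var W = sum r_i^2 / 4`, no continuity correction) above, and p = 1 by
convention when every difference is zero.

## The synthetic arena and what it does (not) show

`make_arena()` renders animals as rotated ellipses (semi-axes set by
`target_area` and `axis_ratio`, orientation following the heading,
centre-of-pixel rasterisation — so area and length have analytic oracles)
on a uniform background with i.i.d. Gaussian pixel noise clipped to [0, 1],
the simplest model that stresses thresholding. Motion is a persistent
random walk — heading perturbed per frame by Gaussian noise scaled by
`1 - heading_persistence`, reflection at borders — with defaults (speed
2 px/frame, persistence 0.8) chosen as plausible for crawling larvae at
low-resolution scales; real larval or fish kinematics are not calibrated
here, and the motion statistics are stand-ins. Both recording regimes are
emulated: the low-quality regime (1000 x 1200 px, 30 FPS, 8 individuals,
~60 px each) directly, and the high-quality many-animal/~500 px regime as a
scaled-down analogue. Outside scheduled collisions the generator keeps
blobs disjoint (a step that would bring two bounding circles into contact
is rejected and the animals turn around); a `collision_event` steers two
animals onto a pass-through crossing — linear convergence to the shared
midpoint of their entry positions, overlap, continuation to the partner's
entry position — giving a reproducible merge-and-split. One seeded private
RNG stream drives everything; the same seed is bit-reproducible, and frames
are rendered lazily so long high-resolution videos never sit in memory.

What passing tests on this generator do **not** show: robustness to
non-uniform illumination, shadows, reflections at arena walls, body
bending/peristalsis, lens distortion, or compression artefacts of real
camera footage. The generator validates the algorithmic core — median
background recovery, size-gated segmentation, optimal assignment, merge
handling, drift correction — not photometric realism.

The identity-preservation score itself is this package's definition (the
field reports such percentages without defining them): tracks are mapped to
animals once, by minimum-distance matching on the first common frame, and
the score is the share of visible, non-merged ground-truth records whose
nearest track (within `max_move`) is the mapped one. Because the mapping
absorbs any constant relabelling, only identity *changes* after the first
frame lower the score; merge-frame records are excluded since no
centroid-level assignment is well-defined inside a single blob.

## Numerical and design notes

- Coordinates are 0-based with x = column, y = row, origin top-left;
  centroids are sub-pixel floats at pixel centres; frames are indexed from 1.
- Even-count medians are the mean of the two central order statistics.
- The threshold comparison is strict (`>`); threshold auto-estimation in
  `run_pipeline()` is an Otsu split of the difference histogram, clamped to
  at most 0.1 and always logged as "estimated" — an explicit stand-in for
  an unpublished heuristic.
- Component labels are ordered by top-most, then left-most first pixel, so
  cluster tables are deterministic.
- Isotropic pixel sets (where the principal axis is undefined) report
  orientation 0 by convention.
- CSV writers print doubles with 17 significant digits; write-then-read is
  exact, and repeated runs are byte-identical.
- Polarity inversion is exactly mirror-symmetric only for noise-free
  renders: per-draw Gaussian noise is not sign-symmetric, so with noise the
  symmetry holds in distribution, not per pixel.
- Validation problem sizes (the regimes exercised in the test-suite): 101
  sampled frames for background recovery; 30 noise-free frames for
  segmentation recovery; 1000 random instances (up to 5 x 5) for the
  assignment oracle; 300 frames at 1000 x 1200 for the disjoint-identity
  run; 100 seeded collision videos for the split study; one simulated hour
  at 10 Hz for drift recovery.

## Known limitations

Appearance or texture re-identification is out of scope: if two animals of
identical size and shape collide, the post-split assignment can only use
distance and will not recover a crossing reliably. The merge detector
requires either an oversize blob or unambiguous (unique-target) evidence;
two animals whose fused blob stays under `max_area` and who keep other
feasible clusters nearby can evade it. Barrel-distortion correction,
behaviour classification (e.g. rolling), and curvature statistics are
deliberately delegated elsewhere. Video-container input is not read
directly; numbered lossless PNG/TIFF sequences are the supported frame
source, with `frame_seq()` as the extension point for other backends.
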