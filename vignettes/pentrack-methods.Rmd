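---
title: "pentrack: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pentrack: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentrack)
```

`pentrack` turns per-frame pig detections into identities, movement
phenotypes and aggression-event logs. This vignette is the package's own
account of the science: the models it implements, the assumptions they
carry, every tunable that matters, what the synthetic world does and does
not emulate, and the choices made where the design was genuinely open.

## 1. Geometry and I/O conventions

Boxes are continuous corner rectangles `(x1, y1, x2, y2)`, origin
top-left, y downward, area `(x2−x1)(y2−y1)` with no `+1` pixel
correction. IoU is intersection over union; corner-touching boxes score
exactly 0. On disk the package speaks the MOT-Challenge CSV dialects
(`frame, id, bb_left, bb_top, bb_width, bb_height, conf, class,
visibility`, headerless, id `-1` for raw detections); frame indices are
1-based and timestamps are `frame / fps`. The video frame rate is never
guessed: `fps` is a required argument everywhere time is involved,
because detector files carry no rate and a silently assumed one would
corrupt every speed and duration downstream. The class vocabulary is
closed: code 0 is `pig`, code 1 is `pig_fighting` (one box around an
ongoing fight, not an animal).

## 2. The motion model

Each track carries a constant-velocity linear-Gaussian state
`(cx, cy, a, h, v_cx, v_cy, v_a, v_h)` — box center, aspect ratio `w/h`,
height and their per-frame velocities. Process and measurement standard
deviations are proportional to the box height (weights 1/20 for
position-like terms, 1/160 for velocities; small constants on the
dimensionless aspect terms), the convention of the tracker family this
follows: apparent size sets the scale of plausible motion. The
assumptions are the usual ones — locally linear motion between frames and
Gaussian errors — and they are adequate at 25 fps for animals that turn
smoothly; the filter lags briefly at sharp waypoint turns, which the
association step absorbs as a slightly lower IoU.

One numerical guard: when a lost track is extrapolated for many frames,
`h` or `a` can be driven non-positive by their velocity terms; the state
projection clamps the box to a 1 px minimum extent rather than producing
a degenerate rectangle.

## 3. Two-stage association

Per frame, after predicting all live tracks forward:

1. detections are split at `high_thresh` (default 0.6); those below
   `low_thresh` (0.1) are discarded;
2. high-score detections are matched to all live (active *and* lost)
   tracks — Hungarian assignment on cost `1 − IoU`, matches above cost
   `1 − first_match_min_iou` (gate 0.2) dissolved;
3. low-score detections are offered to the still-unmatched *active*
   tracks, gated harder (`second_match_min_iou` 0.5): this is the
   occlusion-rescue stage, where a pig whose confidence collapsed behind
   a penmate keeps its identity;
4. unmatched detections at or above `new_track_thresh` (0.7) found new
   tracks; ids increase strictly and are never reused;
5. unmatched tracks age; past `max_lost_frames` (30 video frames) they
   are removed for good.

The score thresholds are the cited tracker's published defaults — the
source work states none of its own — and all of them are exposed in
`tracker_params()`. Retention is counted in *video* frames (the
alternative, detector-processed frames, is indistinguishable when every
frame is processed, as here). Two open design points and how they were
settled:

- **Lost tracks join the first association only.** Re-matching a
  reappearing animal requires lost tracks to stay candidates, but letting
  week-old ghosts compete for low-confidence boxes manufactures identity
  errors; restricting stage 2 to active tracks is the conservative
  reading.
- **The `tentative` state is unused.** Track birth is already gated by
  `new_track_thresh`; adding a probationary period would silently drop
  legitimate single-frame tracks (one confident detection is, by
  contract, one new track). The status enum retains the value for
  interoperability, but no code path produces it.

Determinism: within a frame, detections are sorted by descending score
then coordinates before association, so output never depends on detector
file row order; the assignment solver itself (shortest-augmenting-path
Hungarian with potentials, written in-package and checked against
exhaustive enumeration) scans columns in index order and is exactly
reproducible.

## 4. Detection evaluation

Matching for evaluation is greedy and confidence-ordered, one-to-one,
within each frame; flags are pooled over frames per class, re-sorted by
score, and cumulative precision `TP_k/(TP_k+FP_k)` and recall
`TP_k/n_gt` are computed after every detection. AP is the exact area
under the all-point-interpolated precision envelope (at each recall, the
maximum precision at any recall at least as large); the 11-point
approximation is deliberately not offered, because the definition being
implemented is an integral over recall. mAP is the unweighted mean of
per-class APs; at the conventional 0.5 IoU threshold this is mAP@0.5.
Whether the reference evaluation pooled over the test set or averaged
per image is not stated anywhere; pooled per-class evaluation is
implemented and documented, which is also what the standard VOC-style
tools do. Zero ground-truth boxes make recall undefined and raise an
error rather than returning a quiet 0.

## 5. Behavior phenotypes

**Movement.** Per identity, centroids of consecutive boxes are joined
and Euclidean segment lengths accumulated; duration is
`(last − first)/fps` seconds and mean speed their ratio. A single-box
track has zero distance and undefined speed, reported as 0 with a
`degenerate` flag rather than `NaN`. With a `px_per_m` scale, metres are
reported alongside pixels; the default example scale of ~190 px/m
corresponds to a 5 m pen edge spanning ~950 px in 1080p overhead video.

**Fight events.** The timing rule is the appear/disappear rule: T1 when
an aggression box appears, T2 when it disappears, both reported in
frames (the precise primitive) and seconds. Two debouncing parameters
with no counterpart in the source — which gives no debouncing rule — are
exposed and defaulted once: runs separated by at most
`merge_gap_frames = 12` empty frames (~0.5 s at 25 fps) are merged, and
merged runs shorter than `min_len_frames = 3` are dropped, suppressing
single-frame detector flicker. Simultaneous spatially distinct fights
are an unspecified corner: here fight detections are first clustered by
spatio-temporal overlap (boxes within the merge window that intersect),
so two concurrent fights that never overlap become separate events,
while any single-fight stream reduces exactly to the plain temporal
rule. Participant attribution — the source records only times and "the
current ID" — is an extension: the two pig tracks with highest positive
mean IoU against the fight box over the event, which matches the
fight-box-as-union geometry.

**RFID binding.** At each ear-tag read, the unique track whose centroid
is inside the feeder zone within ±0.5 s (`tol_s`) is bound to the tag.
Ambiguous reads (two candidates) and conflicting reads are skipped and
logged, never guessed. A tag read for a new track while its previous
holder has ended transfers the tag — the re-identification path after
target loss, which is what makes long-horizon phenotypes per *animal*
(rather than per track fragment) possible. Binding one tag to two
simultaneously live tracks is a data contradiction and raises an error.

## 6. The synthetic pen

The simulator states a world resembling the filmed units: a 1920×1080
pen, 8–20 pigs (default 12) of ~220×110 px (~1.2 m at ~190 px/m),
waypoint-seeking random walks at ~4 px/frame (~0.5 m/s) with heading
noise, 25 fps. Scripted fight episodes steer the pair together until
their boxes overlap and emit a `pig_fighting` detection equal to the
pair's union box each episode frame — mirroring how a fight annotation
encloses both animals. The detection channel then degrades truth:
corner jitter (2 px), Beta-scored confidences with a high mode
(Beta(18, 4), mean ≈ 0.82) for clean views and a low mode (Beta(4, 8),
mean ≈ 0.33, below the 0.6 split) for occluded ones — so the second
association stage is genuinely exercised — and misses at 2% baseline,
~12% under occlusion (inter-pig IoU > 0.1), the profile of a strong
modern detector. One global integer seed drives every draw in a fixed
loop order; identical seeds give identical streams.

The *noiseless* world used by the tracking oracles additionally fixes
jitter and misses to zero, confines each pig to its own grid cell
(`layout = "grid"`, so inter-pig IoU stays below the first-stage gate),
and concentrates scores at Beta(60, 8): a detector with perfect boxes is
also a confident one, and diffuse scores would conflate score noise with
the geometric claim under test. These choices were fixed before the
oracle tests were frozen.

What a green test does and does not establish: the simulator produces
rigid, non-articulated boxes, no camera distortion, no lighting, no
prolonged pile-ups, and its occlusions only dim scores rather than merge
shapes. Perfect recovery here verifies the association logic, not
real-world tracking accuracy; conversely the default noisy world shows
the expected failure mode of IoU-only association (identity switches
under persistent low-score occlusion), which is why the RFID path
exists.

Tracking quality is scored frame-wise by gated Hungarian IoU matching
against truth. *ID switches* count changes of the matched predicted id
between a truth identity's consecutive matched frames. *Fragmentation*
counts, per truth identity, the distinct predicted ids beyond the first:
a definition chosen so that pure detection gaps bridged by the same id
(e.g. every second frame deleted, retention ≥ 2) fragment nothing —
the interruption-counting alternative would count those gaps.
*Frame agreement* is the fraction of frames whose matched-animal count
equals the true count, the statistic used for frame-level generalization
checks against manual annotation.

## 7. Architecture accounting

The `arch` module defines the two-class YOLOv8 n/s/m layer graphs
(CSPDarknet-style backbone, PAN neck, decoupled anchor-free head with
`reg_max = 16`) as exact per-layer accounting tables: parameters are
convolution kernels plus batch-norm affine pairs plus head biases; FLOPs
are `2 ×` convolution multiply-accumulates at 640×640. The arithmetic
was validated bit-exactly against the published 80-class family totals
(3,157,200 / 11,166,560 / 25,902,640 parameters) before the two-class
numbers were read off; there is no randomness anywhere in the
accounting. Depth/width multipliers are the published ones (n:
0.33/0.25/1024; s: 0.33/0.50/1024; m: 0.67/0.75/768), channels rounded
up to multiples of 8.

`num_classes = 2` everywhere: that is what reconciles the n-variant's
3.01 M with the 80-class 3.16 M, and it is the configuration all
reported totals refer to. Exact accounting gives 11.14 M (s) and
25.86 M (m) against printed values of 11.13 M and 25.84 M — a ≤0.1%
gap attributable to the source's own counting or rounding, reported
as computed rather than adjusted; every FLOPs column (8.1 / 28.4 /
78.7 G) and both n-variant parameter totals match exactly.

The EMA (efficient multi-scale attention) block groups channels, pools
along each spatial direction into a shared 1×1 convolution with sigmoid
gates, runs a parallel 3×3 branch, couples the two branches by
softmax-weighted spatial attention and closes with a sigmoid gate — a
reweighting that never reshapes its input. Its parameters (one 1×1 and
one 3×3 kernel plus a group-norm pair over `C/groups` channels) are
independent of spatial size. The published diagram fixes its placement
only pictorially; a single block on the backbone output (after SPPF,
256 channels at n-scale, 8 groups, +10,368 parameters ≈ +0.34%)
reproduces both printed figures for the attention variant (3.02 M,
8.1 G) and is the placement implemented. The block also has a real
numeric forward pass (used by the shape/finiteness/gating tests); the
full detector's forward is analytic shape propagation only, since no
deep-learning runtime is assumed — the module exists for structural
verification, not inference.

## 8. Known limitations

- No appearance model: identity maintenance under long, dense occlusion
  is out of reach of IoU-only association by design; RFID binding is the
  intended correction channel.
- Pooled (not per-image) mAP; no COCO-style mAP@[.5:.95].
- The fight participant rule assumes the fight box tracks the pair; a
  fight box that drifts onto a bystander can misattribute.
- The simulator's occlusion model is confidence-only; it cannot produce
  the merged-blob detections real detectors emit for touching animals.
- Architecture accounting covers the n/s/m family and the EMA variant
  only; other attention modules and detector families are out of scope.
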