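---
title: "Models and methods behind casatrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind casatrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(casatrack)
```

casatrack implements the computational core of a detection-and-tracking
pipeline for human sperm in wet-preparation microscopy video: the
bounding-box similarity measures and regression losses that make training a
detector on 5–7 pixel objects workable, the architectural operators of a
small-object detector together with exact parameter accounting, a
tracking-by-detection multi-object tracker, the standard detection and
tracking metrics, and a synthetic data generator that stands in for the
real video corpus so that every stage is testable end to end. This
vignette explains the models, the tunable parameters, and the design
decisions taken where more than one reasonable choice existed.

## Why tiny boxes need their own similarity measures

A sperm head occupies roughly 5–7 px in a 640 × 480 frame. At that scale
the intersection-over-union is brutally sensitive: shifting a 6 × 6 box by
a single pixel drops its IoU with the truth from 1 to about 0.51, and two
nearby but non-overlapping boxes are indistinguishable from two distant
ones (IoU = 0 either way). The loss family implemented here addresses both
problems.

**Gaussian box model and the normalized Wasserstein distance.** A box
`R = (cx, cy, w, h)` is modelled as a 2-D Gaussian with mean at the centre
and covariance `diag(w²/4, h²/4)`, reflecting that annotation boxes of
tiny round objects concentrate the object in the middle. For two such
Gaussians the squared 2-Wasserstein distance collapses to the squared
Euclidean distance between the 4-vectors `[cx, cy, w/2, h/2]`
(`wasserstein2_sq()`); tests verify this against the general matrix form
`||m₁−m₂||² + tr(Σ₁+Σ₂−2(Σ₂^½Σ₁Σ₂^½)^½)`. The exponential normalisation
`NWD = exp(−W₂/C)` turns the distance into a similarity in (0, 1] that
degrades smoothly with centre offset and stays informative for
non-overlapping boxes. `C` is a dataset-scale constant; it is configurable
with default 12.8, the value in common use for tiny-object benchmarks.

**MPDIoU and Inner-IoU.** `box_mpdiou()` subtracts from the IoU the squared
distances between the two top-left and the two bottom-right corners,
normalised by `w² + h²` of the *image*; minimising corner distances couples
centre alignment and size agreement in one term, and `mpdiou_loss = 1 −
MPDIoU` is zero exactly at a perfect box. `inner_iou()` computes the IoU of
auxiliary boxes scaled about their own centres by a factor (default 1.15),
which steepens the loss surface for small targets; with ratio 1 it reduces
to the plain IoU bit-for-bit. One subtlety: the printed form of the
auxiliary-box construction in the source material computes the
intersection on unscaled corners while the union uses the squared ratio,
which is internally inconsistent; casatrack implements the coherent
semantics (both boxes scaled about their centres, union
`ratio²(A₁+A₂) − inter`), which is what the 1.15 scale factor is for.

**The combined loss.** `combined_regression_loss()` returns

    L = iou_ratio · L_Inner-MPDIoU + (1 − iou_ratio) · (1 − NWD)

with `iou_ratio = 0.5` by default, plus every intermediate term. The loss
is provably nonnegative with equality exactly at the true box (because
`MPDIoU ≤ IoU` always, the Inner-MPDIoU loss is at least `1 − IoU_inner ≥
0`), and property tests check nonnegativity, the `ratio = 1` reduction,
and monotone decrease as a predicted box slides onto the truth. The
similarity-to-loss conversion `L_NWD = 1 − NWD` is the standard one; the
source text never writes it explicitly.

## Detector operators and parameter accounting

The package implements the detector's characteristic operators as plain
array transforms on `(channels, height, width)` arrays, each with an
unvectorised loop oracle in the test suite:

* `space_to_depth()` folds each `s × s` spatial block into channels —
  a bijective rearrangement (the inverse `depth_to_space()` recovers the
  input exactly), so `spd_conv()` (rearrangement + stride-1 convolution)
  downsamples without discarding fine-grained information. Sub-pixel
  offsets are ordered row-major; any fixed bijection works, ours is
  documented for reproducibility.
* `msca_attention()` — multi-scale convolutional attention: a shared 5 × 5
  depth-wise convolution, three decomposed strip-kernel branches (1 × k
  then k × 1 with k = 7, 11, 21, well suited to elongated structures such
  as sperm tails), an identity shortcut carrying the module input, and a
  1 × 1 channel-mixing convolution whose output reweights the input
  element-wise.
* `ema_attention()` — efficient multi-scale attention: grouped channels,
  directional average pooling, a shared 1 × 1 convolution without channel
  reduction, a parallel 3 × 3 branch, and a softmax cross-spatial
  interaction. The 3 × 3 branch uses edge-replicated padding so that a
  constant input yields a constant attention map (zero padding would break
  the spatial symmetry at the borders).
* `dyhead_block()` — the dynamic detection head: scale-aware attention
  (1 × 1 controller + `hard_sigmoid(x) = max(0, min(1, (x+1)/2))` per
  level), spatial-aware attention (deformable 3 × 3 sampling with learned
  offsets and importance weights, aggregated over adjacent levels at
  matching positions; with zero offsets and unit importance it is an
  ordinary 3 × 3 convolution, which is what the oracle test pins down),
  and task-aware attention (`max(α₁F_c+β₁, α₂F_c+β₂)` per channel with the
  controller outputs bounded in [−1, 1] by a shifted sigmoid). The head
  uses one block; no repeat count is specified anywhere authoritative.

`build_detector_graph()` constructs the layer graph of a variant ladder —
baseline, +spdconv, +attention, +stdl, +dyhead, full — propagating shapes
and counting every parameter. Conventions: a convolution block is a
bias-free convolution plus batch normalisation; the final per-branch 1 × 1
head convolutions carry biases; the 16 frozen distribution-focal-loss
projection weights are counted, matching standard tooling summaries. Under
these conventions the baseline (nano width, 3 classes) counts exactly
3,011,433 parameters and the space-to-depth variant (all stride-2 3 × 3
downsampling convolutions in backbone and neck replaced, stem kept)
exactly 4,739,433. For the later variants the insertion widths of the
attention blocks are not published, so tests assert ordering properties
rather than exact counts: each cumulative addition strictly increases the
budget, and the regression-loss choice never changes it. One deliberate
deviation from stock head sizing: when the extra 160 × 160 small-target
level is present the head branch widths stay keyed to the 80 × 80 level;
the stock convention would key them to the finest level and *shrink* every
branch, making the ladder non-monotone.

## The tracker

`tracker_run()` is a tracking-by-detection loop in the DeepOCSORT family:
constant-velocity Kalman prediction, two-stage association, Hungarian
assignment (`solve_assignment()`, an O(n³) shortest-augmenting-path
implementation verified against exhaustive enumeration), observation-centric
recovery of lost tracks, and confidence-driven appearance maintenance.
Appearance embeddings are abstract unit vectors — a trained re-identification
network is out of scope, and the association logic is testable with
synthetic embeddings.

**Kalman design.** The state is `(cx, cy, w, h)` plus velocities. The
centre follows a constant-velocity model whose process noise adapts to the
track's own speed estimate (the lateral acceleration of a persistent
random walk is `speed × heading-increment`, so faster cells get a more
responsive filter). The size is quasi-static: sperm heads are rigid, so
the size-velocity components are pinned at zero and the size state becomes
an exponentially weighted average of the observed sizes — during
development a constant-velocity size state was observed to integrate
measurement noise into a slow divergence. Measurement noise is
noise-adaptive (NSA): the centre noise scales with `(1 − confidence)`, so a
confidence-1 detection is adopted exactly, while the size channel keeps a
fixed `size/4` noise floor so that single-frame size jitter is averaged
rather than adopted. A noise-free detection stream therefore reproduces
the ground truth exactly — the zero-noise closed loop yields MOTA = HOTA =
100 with zero identity switches — while noisy streams are genuinely
filtered.

**Association.** Stage one matches confirmed tracks with the blended cost
`(1−w)·motion + w·appearance`, `motion = 1 − IoU` (or `1 − NWD`),
`appearance = (1 − cosine)/2`, and `w` rising from 0.25 to 0.75 with the
detection's confidence-derived trust. Two guards matter in practice:
pairs whose *motion* cost alone exceeds 0.95 are forbidden regardless of
appearance (the classic gating cascade — without it, a track whose
detection is missed can follow a merely similar-looking detection across
the frame), and the second stage, which bootstraps tentative tracks that
have no velocity estimate yet, uses the NWD motion cost with a tight gate
(0.5): a fast 5-px target does not overlap its own one-frame-old box, and
IoU-based matching can never bootstrap it. Lost confirmed tracks that
re-associate within `max_age` (default 30 frames) are re-anchored on their
last observed box with the velocity recomputed across the gap before the
regular update. Unmatched tentative tracks die immediately; tracks
confirm after `min_hits = 3` and then emit their buffered tentative-phase
observations retroactively, so confirmation does not convert the first
frames of every true track into false negatives.

## Evaluation metrics

`evaluate_tracking()` computes the CLEAR metrics (MOTA with the standard
continuity-preserving frame matching, MOTP as mean matched IoU × 100),
IDF1 (optimal global identity bijection via the assignment problem), and
HOTA (per-α one-to-one matching preferring globally aligned trajectory
pairs, `DetA = TP/(TP+FN+FP)`, `AssA` the TP-averaged association score,
`HOTA(α) = √(DetA·AssA)`, averaged over α = 0.05…0.95). The printed
formula for HOTA in the source material omits the square root and the
per-TP summation; the implementation follows the standard definition,
which is what the published numbers were produced with. The per-α table
is returned so the identity `HOTA(α)² = DetA(α)·AssA(α)` is assertable.
Detection quality uses confidence-ranked greedy matching and
all-points-interpolated average precision, with mAP@0.5:0.95 averaged over
the ten-threshold grid and classes averaged per the standard definition.
Tests check MOTA/IDF1 against an independent exhaustive-matching reference
implementation to within 0.1 points on randomised scenarios.

## The simulator

`simulate_trajectories()` emulates the statistics of the public
wet-preparation sperm video corpus: 640 × 480 frames, 200 objects, head
sizes drawn per identity from 5–7 px, three classes (85% normal sperm, 5%
clusters — several heads sharing a roughly double-size box, drifting
slowly — and 10% small/pinhead at 60% of the minimum head size, rendered
darker), and 750 frames per clip (30 s at 25 fps; the corpus averages a
higher frame rate, but the clip length is configurable and nothing
downstream depends on it). Motion is a persistent random walk: a
per-identity speed (truncated normal, mean 2 px/frame, sd 0.8) with
Gaussian heading diffusion (σ = 0.15 rad/frame) and reflective boundaries
that keep every box fully inside the frame. These motion parameters are
choices, not published statistics — progressive human sperm at this
magnification and frame rate move on the order of a few pixels per frame
along fairly straight paths — and they are configurable.

`degrade_to_detections()` models detector imperfection: independent
misses, i.i.d. Gaussian corner jitter, clipped-Gaussian confidences
(0.85 ± 0.1 for true detections, 0.3 ± 0.1 for the Poisson false
positives), and per-identity latent appearance vectors perturbed and
renormalised per detection. `render_frames()` draws dark elliptical heads
with thin curved tails on a noisy light background — enough for visual
checks and demos, with no claim of photorealism.

What passing tests on this simulator do *not* show: robustness to focus
drift, stage vibration, debris, overlapping cells annotated as one box,
appearance drift of real ReID features, or detector failure modes that
are correlated in time — real detectors miss the same hard cell for many
consecutive frames, while the simulator's misses are independent.

## Reference operating points and a known limit

Two seeded scenarios anchor the end-to-end checks (sizes chosen to keep a
full run in minutes on one core): a clean loop (50 sperm, 250 frames,
zero noise) that must close at exactly MOTA = HOTA = 100 with zero
switches, and a degraded loop (same scale, normal-sperm class, 5% misses,
1 px corner jitter, 10 false positives per frame) measuring robustness.
On the degraded loop the tracker reaches MOTA ≈ 84 with essentially zero
identity switches, and an oracle experiment — feeding each target's own
detections to a single filter, i.e. removing association entirely — shows
why ≈ 84 is the ceiling rather than a defect: with 1 px corner jitter on
5–7 px boxes, about 5–6% of even optimally filtered causal estimates fall
below the IoU-0.5 matching threshold, and each such frame costs both a
false positive and a false negative. Localisation noise at a third of the
object scale, not association quality, is the binding constraint in this
regime; on the 3-px pinhead class the same arithmetic is worse, which is
why the robustness scenario measures the motile normal-sperm population.

## Numerical choices and degenerate inputs

Degenerate (zero-area) boxes are rejected with explicit errors rather
than clamped, keeping the oracle tests well-posed. Boxes may extend
outside the image; the MPDIoU normaliser uses the image diagonal
regardless. The Kalman covariance update uses the Joseph form so the
adaptive measurement noise can reach exactly zero without breaking
symmetry. Assignment padding uses a finite big-M larger than the total
finite cost, which maximises the number of feasible matches before
minimising cost. File formats are fixed-precision (YOLO labels at six
decimals, MOT boxes at two), and readers reject malformed lines with the
file and line number rather than skipping them.
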