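---
title: "Opposite-flow detection of plankton: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Opposite-flow detection of plankton: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(planktonflow)
```

## The problem

Deep-sea survey video is shot from a moving platform under active lighting:
the camera drifts with the submersible, the seafloor background is uneven,
and diffuse sediment clouds float through the scene. Counting plankton in
such footage is a moving-target-detection problem under a dynamic
background, where frame differencing and other background-subtraction
detectors mistake the sediment for organisms. `planktonflow` implements a
detector built on a simple and testable physical observation: a small
organism that moves *further than its own diameter* between frames leaves
an unmistakable signature in two consecutive dense optical-flow fields.

## The opposition property

Write $I_{x,y,t}$ for the gray value at pixel $(x, y)$ in frame $t$.
Three spatiotemporal gradients are estimated for each frame pair from 2x2x2
difference kernels on an edge-replicated padded block:

$$\nabla t = \tfrac12\left[(I_{x,y,t}-I_{x,y,t-1}) +
   (I_{x+1,y,t}-I_{x+1,y,t-1})\right]$$
$$\nabla x = \tfrac12\left[(I_{x+1,y,t}-I_{x,y,t}) +
   (I_{x+1,y,t-1}-I_{x,y,t-1})\right]$$

and $\nabla y$ as the exact $y$-analogue of $\nabla x$. The flow field
$(u, v)$ is obtained by relaxation of the brightness-constancy constraint
$\nabla x\,u + \nabla y\,v + \nabla t = 0$, starting from $u_0 = v_0 = 0$:

$$\Delta = \frac{\nabla x\,u_n + \nabla y\,v_n + \nabla t}
                {\alpha^2 + \nabla x^2 + \nabla y^2},\qquad
  u_{n+1} = u_n - \nabla x\,\Delta,\qquad
  v_{n+1} = v_n - \nabla y\,\Delta.$$

Now take three consecutive frames and the two flow fields they induce. If
the blob's positions in frames $t-1$, $t$, $t+1$ are pairwise disjoint with
its position at $t$, and the background around it is time-invariant
($I_{t-1} = I_{t+1}$ at the relevant pixels), then at the blob's mid-frame
position the second pair's gradients satisfy $\nabla t' = -\nabla t$,
$\nabla x' = \nabla x$, $\nabla y' = \nabla y$. By induction over the
iteration, every iterate satisfies $u_n' = -u_n$ and $v_n' = -v_n$: the two
flow fields are *exact negatives* there. Nothing else in the scene — a
drifting sediment cloud, a slowly evolving background, a slow-moving
organism overlapping its own previous position — produces this signature.

### The dual thresholds

Exact opposition degrades in practice because grayscale constancy is only
approximate. Two thresholds turn the property into a decision rule at each
pixel and axis:

* $|u + u'| < \beta_1$ — the opposition-sum tolerance. The sum of two
  opposite flows is zero; $\beta_1$ (default 0.35, flow units) allows the
  small residual real footage produces.
* $-u\,u' > \beta_2$ — the anti-null floor. When there is no plankton and
  both flows happen to be small, the sum test passes vacuously; requiring
  a substantially negative product (default $\beta_2 = 3$, squared-flow
  units) rejects exactly that case.

The defaults are the best-scoring cell of the cosine-similarity threshold
sweep over $\beta_1 \in \{0.05, \dots, 0.35\}$ (step 0.05) and
$\beta_2 \in \{3, \dots, 9\}$ (step 1); two cells of that sweep tie at the
top and the package uses $(0.35, 3)$, with both grids re-runnable via
`threshold_sweep()`. How the two inequalities combine across axes is not
forced by the rule itself; the package requires sum-and-product to hold on
the *same* axis and then ORs across axes (`combine = "axis_and_then_or"`),
because the product floor only neutralizes the small-flow failure mode of
the sum test when both are evaluated on the same component. The literal
any-axis reading is available as `combine = "joint_or"`. Similarly, the
sum inequality is applied to $|u + u'|$: without the absolute value a
strongly negative sum — co-directed strong flows — would pass a test whose
purpose is a tolerance around zero.

Marked pixels are grouped by connected-component labeling (8-adjacency by
default), components below `min_area = 2` pixels are dropped as flicker,
and the component count per frame is the plankton count.

## The pointwise relaxation, and what flow it produces

The update above uses each pixel's own current $(u, v)$; the classic
Horn–Schunck scheme substitutes a neighborhood average, which couples
pixels and propagates flow into textureless regions. The package's default
is the pointwise form, for two reasons: it is the form for which the
opposition proof holds exactly (the induction argument is pixel-local), and
it is deterministic and cheap. The consequence is worth stating plainly:
pointwise relaxation recovers the *normal flow* $-\nabla t\,
\vec g/|\vec g|^2$ (with $\vec g = (\nabla x, \nabla y)$), which is nonzero
only where spatial gradients exist. For a hard-edged blob the detector
therefore marks a small cluster of pixels on the blob's contrast edges —
not its full interior — and those clusters, not filled silhouettes, are
what get counted. Counting and localization are unaffected; pixel-accurate
segmentation masks are out of scope. Users who want propagated flow can
set `neighborhood_average = "exclude_center"` (or `"include_center"`), but
the opposition guarantee then holds only approximately.

Two further estimator details are configurable rather than asserted. The
temporal kernel averages over the x-neighbor pair only, matching its
printed two-term form; a full four-term 2x2 cube average is available via
`cube_mean = TRUE`. The $\Delta$ denominator uses the per-pixel
$\nabla x^2 + \nabla y^2$.

## Parameters that matter

| Parameter | Units | Default | Role |
|---|---|---|---|
| `alpha2` | dimensionless | 100 | smoothness weight; keeps the denominator positive and damps the step. Convergence to the pointwise solution is geometric with ratio $\alpha^2 / (\alpha^2 + |\vec g|^2)$, so larger values need more iterations near weak gradients. |
| `n_iters` | iterations | 100 | relaxation length; 100 converges to machine precision wherever $|\vec g|^2 \gtrsim \alpha^2$. |
| `beta1` | flow units (px/frame) | 0.35 | opposition-sum tolerance |
| `beta2` | squared flow units | 3 | anti-null product floor |
| `connectivity` | – | 8 | component adjacency |
| `min_area` | px | 2 | flicker filter; set 1 to disable |
| `pixel_stride` / `frame_stride` | – | 1 / 1 | interval sampling for speed; the mask is upsampled by nearest neighbor before labeling |
| `fov_w`, `fov_h` | m | none | physical field-of-view calibration; deployment-specific, so deliberately without default |

No default is published for $\alpha^2$ or $n$; the package's 100/100 are
recorded in every run manifest and chosen so that the relaxation is fully
converged on blob edges (where $|\vec g|$ is tens of gray levels) while
staying insensitive to sensor noise (where $|\vec g| \ll \alpha$, the flow
stays near zero — a desirable side effect of the damping).

## Physical quantification

A component of $N$ pixels covers $S = N\,(W/\text{width})(H/\text{height})$
square meters, where $W \times H$ meters is the calibrated field of view.
The organism's volume is approximated by the sphere whose great-circle area
equals $S$:

$$V = \tfrac43\,\pi^{-1/2}\,S^{3/2}
    = \tfrac43\,\pi\,\left(\sqrt{S/\pi}\right)^{3}.$$

Volumes are computed per component and then summed per frame. The map is
homogeneous of degree $3/2$, so pooling areas before converting would
report the volume of one fictitious large organism rather than the summed
volume of many small ones. No perspective or optical-distortion correction
is applied: organisms far from the focal plane are sized as if at it.

## The synthetic-scene generator

The study footage is not redistributable, so every end-to-end claim is
exercised on synthetic scenes whose properties are controlled and whose
ground truth is exact. The generator emulates the regime the detector is
built for, and nothing more:

* a background that is constant, textured, or a texture drifting at a
  sub-blob velocity (toroidal wrap) — approximating slow camera motion
  while keeping the background near each blob locally time-invariant;
* small bright organisms as hard-edged discrete disks (radius 2–4 px,
  additive intensity offset 60–120 on a level-60 background) making
  per-frame jumps of 9–14 px, with a floor of $2r+1$ px in "fast" mode so
  consecutive positions never overlap — the detector's premise;
* an optional sediment cloud: a large, low-contrast (amplitude 8) Gaussian
  intensity bump drifting about 1 px/frame — the distractor that fools
  frame differencing but produces co-directed, never opposite, flows;
* additive Gaussian sensor noise (default $\sigma = 1$ gray level),
  applied last and clamped to 0–255.

Hard-edged disks are the default so the truth support is unambiguous
(`soft_edge = TRUE` exists for robustness experiments). One global seed
drives everything through R's Mersenne–Twister generator; each blob's
trajectory runs from a sub-seed drawn once from the main stream, so scenes
are bit-reproducible and a blob's path does not depend on how many other
blobs exist. The reference scene is 20 frames of 128×128 with 8 blobs,
noise $\sigma = 1$, seed 7.

What the generator does *not* emulate — defocus, light attenuation,
occlusion in dense aggregations, organism deformation, interlacing — bounds
what passing tests show: they validate the method's mathematics and its
behavior under its stated premises, not performance on arbitrary real
footage. In particular the premise violation the method itself documents
(slow movers that overlap their own position are invisible; dense
overlapping clouds degrade precision) is reproduced, not repaired, by this
implementation: the `slow_blob` fixture is asserted to yield *zero*
detections.

For the unit fixtures, `generate_triple("fast_blob")` uses out-and-back
motion: the blob sits at $p_1$ in frames $t-1$ and $t+1$ and at $p_2$
(more than a diameter away) in frame $t$. The flanking frames are then
*identical*, so the time-invariance premise holds at every pixel and the
opposition $u = -u'$, $v = -v'$ is global — the sharpest testable form of
the property (residuals are at double-precision rounding level, tested
below $10^{-8}$). Under this motion the mid-frame position and the
vacated-then-reoccupied site are both genuine opposition events, and the
detector correctly marks both; tests assert two components. Continuing
motion, as in `generate_scene()`, satisfies the premise only locally around
the mid-frame position, and there the tests assert one component per blob,
confined to a 1-px dilation of the truth support.

## Evaluation conventions

Detections are matched to truth blobs greedily by ascending centroid
distance, one-to-one, accepting pairs within the truth blob's radius + 2 px
(configurable); matched = TP, surplus detections = FP, missed truths = FN.
Matching is by centroid rather than mask IoU because real ground truth for
this task is manual *counts*, not masks. Precision, recall and F1 follow
their standard definitions; an undefined metric (zero denominator) is
reported as `NA`, never silently as 0, except the convention F1 = 0 when
P + R = 0. Count series are summarized by mean and *population* standard
deviation (divide by $n$): the package treats the evaluated frames as the
complete population of interest rather than a sample, and this convention
is pinned by a discriminating test (the sample convention changes the
rounded first-series spread from 1.7 to 1.8).

The threshold sweep scores each $(\beta_1, \beta_2)$ cell by the cosine
similarity between each evaluated frame and its masked detection (original
intensities where the mask is true, zero elsewhere), averaged over frames;
a binary-mask vectorization is available via a flag. Scores are averaged
per frame rather than computed on a single representative frame. Note the
score is a *similarity* (larger = more alike) even where tradition would
say "distance".

## Numerical and degenerate-input choices

* All arithmetic is double precision; the solver is free of randomness, so
  repeated runs are bit-identical.
* $|\Delta| \le (|\nabla x\,u| + |\nabla y\,v| + |\nabla t|)/\alpha^2$,
  so iterates stay finite for any finite gradients and $\alpha^2 > 0$.
* Frames smaller than 2×2, non-finite intensities, non-consecutive triple
  indices, $\alpha^2 \le 0$, non-positive thresholds, and geometry with
  non-positive extents are rejected with named errors, not coerced.
* An empty mask labels to zero components; an all-zero vector scores
  cosine 0 by convention.
* Sweep argmax ties resolve to the first cell in grid order.
* Blob trajectories re-draw a step (up to 200 times) when a sampled jump
  would leave the margin or undercut the $2r+1$ floor, then fall back to a
  deterministic hop toward the frame center; the fallback preserves seeded
  reproducibility.
* PNG export quantizes intensities to 8 bits; in-memory pipelines keep full
  precision, which is why all exactness tests run in memory.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data
sized for exactness rather than scale: 16×16 frames for the gradient
oracle (100 pairs), 48×48 triples for the opposition suite (50 seeds × 2
smoothness weights × 2 iteration counts), the 128×128×20-frame reference
scene for detection recovery and stride agreement, and 1000 random areas
for the volume identities. These sizes exercise every code path; nothing
in the implementation is specific to them, and 1080×1920 frames differ
only in run time (the per-frame cost is linear in pixel count ×
iterations).

## Known limitations

* Slow movers (displacement ≤ diameter) are invisible by design.
* Counting, not segmentation: with the default pointwise solver the masks
  are edge clusters, so `n_pixels`-derived areas systematically understate
  hard-edged organism areas. Area/volume series are comparable across
  frames and scenes but are not calibrated organism sizes.
* Two organisms closer than one pixel merge into one component.
* The physical conversion assumes every organism lies in the calibrated
  focal plane.
* Video containers (MP4/AVI) are not decoded; supply PNG/TIFF image
  sequences (or in-memory frames) extracted with any standard tool.
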