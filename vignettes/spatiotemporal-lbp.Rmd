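---
title: "Spatio-temporal local binary patterns: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatio-temporal local binary patterns: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stlbp)
```

## The problem

Subtle facial micro-movements — involuntary expressions lasting a fraction
of a second — produce only faint intensity changes between consecutive
video frames.  Descriptors for this regime must summarize *dynamic
texture*: statistical regularity in both space and time.  `stlbp`
implements a family of such descriptors built on the local binary pattern
(LBP) operator, together with the preprocessing, synthetic data and
cross-validated SVM evaluation needed to study them end to end.

## The basic LBP operator

For a pixel $c$ with intensity $I_c$ and $P$ circular neighbors at radius
$R$ with intensities $I_p$,

$$\mathrm{LBP}_{P,R}(c) = \sum_{p=0}^{P-1} s(I_p - I_c)\, 2^p,\qquad
s(x) = \begin{cases}1 & x \ge 0\\ 0 & x < 0.\end{cases}$$

A neighbor at least as bright as the centre contributes a 1-bit.  Codes of
all codable pixels are tallied into a $2^P$-bin histogram; with a block
grid, one histogram per block, concatenated row-major, each L1-normalized.

Conventions fixed throughout the package (and restated in the oracle tests
independently of the implementation):

* coordinates are 0-based, `x` = column, `y` = row, `y` increases downward;
  `t` is the last axis of a volume;
* neighbor $p$ sits at angle $2\pi p/P$ counter-clockwise from east, i.e.
  at $(x + R\cos a,\; y - R\sin a)$; for $P=4$ the order is east, north,
  west, south with bit 0 = east;
* off-grid neighbors are sampled bilinearly (at $P=4$, $R=1$ — the
  configuration used by all the headline settings — neighbors fall exactly
  on grid pixels, so no interpolation error enters);
* block boundaries lie at $\lfloor i \cdot \mathrm{extent} / k \rfloor$,
  trailing blocks absorbing remainders;
* border pixels without a full neighborhood are excluded
  (`border = "exclude"`); `border = "replicate"` instead pads with edge
  values so that every pixel is coded, which is also how the comparison
  counters below measure idealized full-volume cost;
* a block that receives no codable pixel raises an error naming the block,
  rather than silently emitting zeros.

The threshold direction ($I_p \ge I_c \Rightarrow 1$) is the standard LBP
convention.  The opposite reading (centre $\ge$ neighbor) merely
complements every bit, permuting histogram bins; classification behaviour
is unaffected, so only one convention is implemented.

A note on invariance: the ideal operator is invariant to any strictly
increasing intensity transform.  With bilinear interpolation that holds
exactly only when neighbors fall on grid points (e.g. $P=4$, $R=1$);
interpolated neighbors commute with affine maps only.  The test suite
asserts exactly these forms.

## Three descriptors on a video volume

A video volume of size $h \times w \times l$ can be viewed as three stacks
of planes: XY (frames), XT (one per row) and YT (one per column).

**LBP-TOP** codes every voxel once per plane with an independent
neighborhood in each plane, and concatenates the three per-plane
histograms per spatial block: $2^P \times 3$ bins per block ($48m$ total
for $P=4$ and $m$ blocks).  With per-axis radii $(R_x, R_y, R_t)$ the
4-neighbor sets are axis-aligned; for general $P$ neighbors lie on the
ellipse with the two plane radii.  Codable voxels are those with full
margins on all three axes, so every codable voxel contributes exactly one
code to each plane's histogram.

**LBP-SIP** observes that the three planes' neighbor sets share points:
their union contains only six unique points, the intersections of the
three lines through the centre — $(x \pm R_x, y, t)$, $(x, y \pm R_y, t)$,
$(x, y, t \pm R_t)$.  These are grouped "XY+2": a 4-bit spatial code over
the in-frame neighbors plus a 2-bit temporal code (bit 0 = past frame
$t - R_t$, bit 1 = future frame $t + R_t$), giving $2^4 + 2^2 = 20$ bins
per block — under half of LBP-TOP's 48.  The spatial histogram is
*identically* the per-frame $P=4$ LBP histogram accumulated over the
temporal interior, an exact identity the tests exploit as an oracle.

**LBP-MOP** collapses each plane stack to its pixel-wise mean image first
and computes a 2-D block LBP histogram on the three mean images only.
Dimensionality matches LBP-TOP; the comparison cost drops by a factor of
roughly $3l$.  Means are kept in floating point — re-quantizing to
integers would discard exactly the subtle differences the method targets.
Mean-plane orientations: `xt_mean` has x as rows and t as columns,
`yt_mean` has y as rows and t as columns; a per-plane grid `c(3, 2)` means
3 blocks along the spatial axis and 2 along the temporal axis (the
temporal extent of a length-normalized clip is the short axis, hence the
coarser split).

Comparison costs, with 4 neighbors per plane, on an idealized full volume:
$12whl$ (TOP), $6whl$ (SIP), $4(wh + wl + hl)$ (MOP).  Each descriptor
carries an instrumented `n_comparisons` attribute; run with
`border = "replicate"` it reproduces these closed forms exactly:

```{r counts}
v <- make_video(synth_spec(), 1, 1)
attr(lbp_top(v, R = c(1, 1, 3), border = "replicate"), "n_comparisons") / prod(dim(v))
attr(lbp_sip(v, R = c(1, 1, 3), border = "replicate"), "n_comparisons") / prod(dim(v))
```

## Parameters that matter

| parameter | meaning | default | notes |
|---|---|---|---|
| `P` | neighbors per plane | 4 | all headline settings use 4 |
| `R = c(R_x, R_y, R_t)` | radii per axis (pixels, frames) | `c(1, 1, 4)` | high-frame-rate corpora use $R_t = 4$; 10-frame length-normalized clips use $R_t = 3$ |
| `grid` | spatial block grid | `c(1, 1)` | 5×5 and 8×8 are the common protocol choices; blocks preserve coarse facial layout |
| `border` | border policy | `"exclude"` | `"replicate"` codes every voxel |
| MOP grids | per-plane grids | 1×1 each | 3×3 / 3×2 / 3×2 suits 10-frame clips |

## Preprocessing

* **Wiener filter** (`wiener_filter`): pixel-wise adaptive estimate
  $m + \frac{\max(0, v - \nu)}{\max(v, \nu)}(I - m)$ from local window
  mean $m$ and variance $v$; the noise variance $\nu$ defaults to the mean
  of the local variances.  Window defaults to 3×3 (the window size is a
  free choice; it is exposed in the API).  Edge handling is by
  replication, so constants are fixed points.  For the mean-plane
  descriptor the filter may be applied either to every frame or to the
  three mean images (`extract_features(..., preprocess = list(wiener =
  TRUE, wiener_on = "means"))`); both orders are defensible and the switch
  makes the choice explicit.
* **Gaussian pyramid** (`gaussian_pyramid`): 5-tap binomial kernel
  $[1,4,6,4,1]/16$, separable, reflective borders, even-index
  downsampling (an $n$-pixel axis becomes $\lceil n/2 \rceil$); every
  level optionally resized bilinearly to a common shape so one descriptor
  configuration fits all levels.  `pyramid_features` extracts per-level
  descriptors and their all-level concatenation.
* **Temporal resampling** (`temporal_resample`): per-voxel linear
  interpolation to a fixed frame count with exact endpoints.  This is a
  deliberately plain stand-in for model-based temporal interpolation; the
  pipeline only needs the fixed frame count.

## Evaluation harness

`make_folds` builds leave-one-video-out (one fold per sample) or
leave-one-subject-out (one fold per subject, subject-disjoint) partitions;
their structural contracts — exhaustive, disjoint, no subject leakage —
are verified by tests on every run.  `cross_validated_accuracy` fits an
SVM per fold (e1071/libsvm: one-vs-one multi-class) and pools test
predictions over all folds.  Kernels: linear, RBF (width
$1/\mathrm{dim}$), and a sixth-order polynomial.  The polynomial kernel
uses `coef0 = 1`: with L1-normalized histogram features, the homogeneous
degree-6 form underflows toward zero, and the inhomogeneous form is the
standard remedy.  Cost defaults to 1.  Since the features are already
normalized histograms, standardization defaults off (a `scale` switch
exists).  Absolute accuracies on any real corpus naturally depend on these
hyperparameters; the harness fixes and reports them for reproducibility.

## The synthetic corpus generator

`make_corpus(synth_spec())` emulates what the descriptors assume about
real micro-movement corpora:

* **subject identity confound** — a per-subject band-limited base texture
  shared by all of that subject's clips, so subject-dependent appearance
  dominates single frames (this is why LOSO is the stringent protocol);
* **subtle class signal in the dynamics** — a Gabor patch (spatial
  frequency 0.18 cycles/px at 30°, Gaussian envelope
  $\sigma = \min(h,w)/3$) whose *spatial* structure is identical for all
  classes and whose carrier phase drifts at a class-specific speed;
* **sensor noise** — i.i.d. Gaussian, sd 2 on the 0–255 scale.

For a drifting sinusoid, the 2-bit temporal code of a pixel with phase
offset $\theta = 2\pi v R_t$ between centre and its temporal neighbors has
distribution $(\theta, \pi - \theta, \pi - \theta, \theta)/2\pi$ over
bins $(0, 1, 2, 3)$ — and is symmetric in $\theta \mapsto -\theta$, i.e.
blind to drift *direction*.  Class speeds are therefore chosen as
$v_k = (2k-1)/(12C)$ cycles/frame, which spaces the offset magnitudes
evenly in $(0, \tfrac12)$ cycle at the reference radius $R_t = 3$ and
avoids any two classes aliasing to the same magnitude.  Defaults (16
subjects × 2 clips × 3 classes, 24×24×10 volumes, amplitude 16 vs noise
sd 2) give a corpus that SIP + LOSO + a linear SVM separates essentially
perfectly, while single-frame (spatial-only) features stay near chance —
the class signal genuinely lives in time.

What the generator does *not* emulate: faces and their articulated
geometry, registration error, illumination flicker, compression artifacts,
head pose, and class-conditional spatial appearance.  Passing tests
therefore demonstrate the correctness and the discriminative mechanics of
the descriptors, not expected accuracy on real facial data.

```{r endtoend}
cor <- make_corpus(synth_spec())
ft <- extract_features(cor, "sip", params = list(R = c(1, 1, 3), grid = c(4, 4)))
cross_validated_accuracy(feature_corpus(ft), "loso", "linear", seed = 7)
```

## Numerical and testing choices

* Histograms are normalized per segment (per block, per plane), not over
  the concatenated vector, so every segment is a probability vector and
  blocks contribute equally regardless of codable-pixel counts.
* Degenerate configurations fail loudly: empty blocks, too-short videos,
  over-deep pyramids and out-of-bounds samples are errors, not warnings.
* Oracle tests compare the vectorized implementation against naive
  per-pixel/per-voxel loops on volumes up to 12×12×9 and images up to
  16×16; end-to-end tests use the default 32-clip corpus.  The whole
  suite runs in a few seconds.
* All randomness flows through explicit seeds; video generation is a pure
  function of `(seed, subject, class, index)` and restores the caller's
  RNG state.

## Known limitations

* Only the plain code histogram is implemented — no uniform-pattern,
  rotation-invariant or center-symmetric compressions.
* The temporal 2-bit code cannot distinguish motion direction (see the
  symmetry argument above); descriptors inherit this.
* Frame decoding covers PNG, PGM and TIFF; container video formats must
  be exploded to frames first.
* The PGM writer quantizes to 8-bit integers; round-trips are exact only
  for integer-valued volumes in [0, 255].
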