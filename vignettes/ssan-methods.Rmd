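---
title: "Interpolating serial-section EM slices with sparse self-attention: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpolating serial-section EM slices with sparse self-attention}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssan)
```

## The problem

Serial-section electron microscopy images a tissue block as an ordered stack
of physical sections. Sections are routinely lost or damaged during cutting
and imaging, which breaks registration, segmentation and 3D reconstruction
downstream. Because biological structure varies smoothly across adjacent
sections, a missing section can be synthesized from its two neighbours —
but EM stacks combine large non-rigid deformation, stage drift, heavy noise
and per-section differences in blur, brightness and contrast, which defeat
optical-flow and local-kernel interpolators designed for natural video.

This package trains a network that synthesizes the middle slice
$\hat{\mathbf I}_t$ of a triplet $(\mathbf I_{t-1},\mathbf I_t,\mathbf I_{t+1})$
from the two outer slices. Its core is an *attention-aware layer* (AAL): each
output pixel is aggregated from **all** positions of the input feature map
through a softmax affinity, so correspondence is established globally rather
than within a fixed kernel support.

## The attention-aware layer

### Dense self-attention

For a feature map $\mathbf X \in \mathbb R^{C\times N}$ over $N = HW$
positions, with learned projections
$\mathbf W_f,\mathbf W_g,\mathbf W_h \in \mathbb R^{\bar C\times C}$ and
$\mathbf W_v \in \mathbb R^{C\times\bar C}$ (realized as bias-free $1\times1$
convolutions, $\bar C = C/k$):

$$\mathbf A = \mathrm{softmax}\!\left(\frac{(\mathbf W_f\mathbf X)^{\top}(\mathbf W_g\mathbf X)}{\sqrt d}\right),
\qquad \mathbf Z = \mathbf W_v\left[(\mathbf W_h\mathbf X)\,\mathbf A\right],$$

with temperature $d = C/2$. The softmax normalizes over the *key* index, so
every column of $\mathbf A$ sums to one and each output position is a convex
aggregation of value vectors — the orientation required for
$\mathbf Z = (\mathbf W_h\mathbf X)\mathbf A$ to be an average per output
position. The layer output is gated residually,
$\mathbf Y = \gamma\mathbf Z + \mathbf X$, with a single learnable scalar
$\gamma$ initialized at 0: the network first relies on local evidence and
gradually learns to trust the non-local branch.

### Interlaced factorization

Dense attention costs $O(4HWC^2/k + 2(HW)^2C/k)$ multiply–accumulates and is
quadratic in the pixel count. The layer therefore factorizes the affinity
into block-diagonal pieces:

* **long-range attention** permutes the grid so that positions at stride
  $(P_h, P_w)$ — spatially distant samples — form $P_hP_w$ contiguous groups
  of $Q_hQ_w$ positions each ($H = P_hQ_h$, $W = P_wQ_w$), and runs dense
  attention inside each group;
* **short-range attention** does the same over the $Q_hQ_w$ contiguous
  $P_h\times P_w$ tiles.

Each pass has an exactly block-diagonal effective affinity (up to the
interlacing permutation); their composition connects every pixel to every
other. The group layouts are the only ones consistent with both the
long-spatial-interval description of the scheme and its printed cost terms
$1/(P_hP_w)$ and $1/(Q_hQ_w)$.

### Two-level decomposition

The long-range groups are themselves factorized once more: within each
level-1 long-range part, a level-2 long-range then a level-2 short-range
pass run on the part's $Q_h\times Q_w$ grid (partitioned by
$P'_h,P'_w$), and finally a level-1 short-range pass runs over the merged
map. Each of the three attention applications carries its own projection
set and its own $\gamma$ — this is what the tripled projection term
$12HWC^2/k$ in the two-level cost expression implies. Depth is fixed at two
levels; the recursion threshold that would motivate deeper decomposition is
never quantified in the source method, so the level count is explicit
configuration here.

### Operation counting

`op_count_complexity()` evaluates the three printed cost expressions
literally; `op_count_measured()` instruments the implementation and counts
one multiply–accumulate per scalar product term in the two $Q\times Q$
matrix products per group (softmax, $1/\sqrt d$ scaling and additions
uncounted). Under this convention the measured affinity cost reproduces the
dense and two-level formulas exactly. The one-level (interlaced) formula is
printed with a coefficient $3/2$ where the counting convention gives $2$;
the evaluator reproduces the formula as printed, and the measured count is
accordingly $4/3$ of its affinity term. We treat this as an inconsistency of
the printed expression rather than harmonizing it silently.

Two further notes on the cost model:

* The affinity term is minimized at $P_hP_w = (HW)^{1/2}$ (one level,
  $O((HW)^{3/2})$) and at $P_hP_w = (HW)^{1/3}$ with the second level split
  at the square root of the remaining group (two levels, $O((HW)^{4/3})$);
  `op_count_minimized_affinity()` exposes these for scaling analysis.
* The claimed strict ordering *two-level < interlaced < dense* in **total**
  cost does **not** hold at small maps: the two-level scheme pays a fixed
  $12HWC^2/k$ projection cost against $4HWC^2/k$, and at $64\times64$,
  $C=64$, $k=2$ that difference (67M MACs) exceeds any possible affinity
  saving (at most ~13M). The ordering is a genuine consequence of the
  formulas only once $HW$ is large; the test suite asserts it at the
  $512\times512$ operating size.

## Network architecture

A weight-shared (siamese) **residual dense network** encodes the ordered,
channel-stacked pair $(\mathbf I_{t-1},\mathbf I_{t+1})$ into
$\mathbf F_{t-1\to t+1}$, and the reversed pair into
$\mathbf F_{t+1\to t-1}$; direction is carried purely by channel order, so
swapping the inputs swaps the outputs exactly. The trunk is deliberately
pooling-free (shallow feature extraction, residual dense blocks with local
fusion, global feature fusion with a global residual), preserving spatial
detail for synthesis. Block/channel sizes are not prescribed by the source
method; the defaults are $D=4$ blocks of 4 convolutions (growth 16,
$G_0=32$, $C=64$) and a `tiny` preset ($D=2$, 2 convolutions, growth 8,
$G_0=8$, $C=16$) for CPU-scale work.

Each direction's features pass through the AAL and a $1\times1$ linear head
whose output is **added to that direction's source frame**: the warp is
predicted as a residual correction, so at initialization (zero-init head,
$\gamma=0$) each warp equals its source frame exactly. An earlier purely
generative head (features $\to$ image with no skip) was evaluated and
discarded: at desk scale it spends the entire training budget learning to
reproduce brightness before any correspondence learning can start, ending
far below even the average-of-inputs baseline, whereas residual prediction
matches the global-residual philosophy of the trunk itself.

A small **hybrid fusion network** (3×3 conv, batch normalization, ReLU,
3×3 conv, sigmoid) maps the concatenated features and warps to a weight
mask $\mathbf M \in (0,1)^{H\times W}$ and blends
$\hat{\mathbf I}_t = \mathbf M \odot \mathrm{warp}_0 + (1-\mathbf M)\odot \mathrm{warp}_1$,
clamped to $[0,1]$ on output. With zero-initialized mask logits the blend
starts as the plain average. Whether the two directions should attend to
each other (cross-attention) is unspecified in the source method;
independent self-attention per direction is implemented.

## Training objectives

With $\phi_j$ the activations of a frozen four-layer feature extractor and
the Gram matrix
$G^{\phi}_j(x)_{c,c'} = \frac1{C_jH_jW_j}\sum_{h,w}\phi_j(x)_{h,w,c}\,\phi_j(x)_{h,w,c'}$:

* **style reconstruction** $\mathcal L_{style}(x,y) = \sum_{j=1}^4 \lVert G_j^\phi(x)-G_j^\phi(y)\rVert_2^2$;
* **adaptive style balance**
  $\mathcal L_{bs} = \sum_{j=0}^{2}\beta_j\,\mathrm{sign}\!\left(\mathcal L_{style}(\hat I,I_j)-\mathcal L_{style}(I^{gt},I_j)\right)\mathcal L_{style}(\hat I,I_j)$
  with $\beta = (0.1, 1, 0.1)$ and frame 1 the ground truth itself. The sign
  gate pulls the synthesized frame's style toward a neighbour while it is
  farther from it than the ground truth is, and pushes it away once it is
  closer — balancing the style transition across the triplet.
  $\mathrm{sign}(0)$ is defined as 0 so the loss vanishes exactly at the
  optimum, and the gate is treated as a constant during backpropagation
  (no gradient through the sign);
* **feature reconstruction** $\mathcal L_f = \sum_j \frac1{C_jH_jW_j}\lVert\phi_j(\hat I)-\phi_j(I^{gt})\rVert_2^2$;
* **Charbonnier pixel loss** $\mathcal L_1 = \sum_x\sqrt{(\hat I(x)-I^{gt}(x))^2+\varepsilon^2}$,
  $\varepsilon = 10^{-6}$ (floor $N\varepsilon$, attained only at equality).

The total is $\mathcal L = \alpha_1\mathcal L_{bs} + \alpha_2\mathcal L_f + \alpha_3\mathcal L_1$
with $\alpha = (10^6, 1, 1)$, and every term (including the three signed
balance components) is logged per step so the loss-term dynamics can be
inspected.

**The feature extractor.** The published weighting presumes a pretrained
16-layer perceptual network, which cannot be bundled here; the package
ships two self-contained variants — `identity` and `convstack`, a frozen
fixed-seed stack of four 3×3 convolution stages with ReLU and 2×2 average
pooling (channels 4/8/12/16). The convstack weights are drawn at 0.2× the
He scale: activation (hence Gram) magnitudes then sit in the regime the
$\alpha_1 = 10^6$ weighting presumes, making the style terms a meaningful
regularizer of comparable size to the pixel term instead of swamping it by
four orders of magnitude, which a unit-scale random stack does. Grayscale
images feed the stub directly (no 3-channel replication); a user-supplied
pretrained extractor would follow its own input convention.

## Synthetic triplets

The generator produces the study data: a shared membrane-like base texture
(thin dark ridges along the boundary set of a random seed-point
tessellation, elliptical dark blobs, a low-frequency intensity field and
band-limited grain), a smooth random displacement field $u$
(Gaussian-filtered white noise scaled to a peak magnitude), a global drift,
and per-frame style (blur, additive noise, contrast jitter). Frames 0 and 2
are warps of the base by $\mp(u + \mathrm{drift})$; frame 1 is the styled
but un-deformed base, hence exactly the temporal middle.

Defaults define the desk-scale study conditions: $64\times64$ px, peak
deformation 3 px, correlation length 12 px, drift 1 px/step, noise
$\sigma = (0.02, 0.01, 0.03)$, blur $\sigma = (0.5, 0, 1.0)$ px, contrast
jitter $\pm5\%$. These place the data in the regime the method targets —
deformation large against the membrane width, visible drift, per-frame
style asymmetry. Texture grain is band-limited (Gaussian $\sigma=1$) and
ridges are ~1.8 px wide so that the generator satisfies its own consistency
contract: inverse-warping frame 0 by the stored field recovers frame 1 to
< 0.02 mean absolute intensity in the clean limit (pixel-scale white grain
would alias under sub-pixel warps and break this bound for any method).
The ground-truth displacement field is stored with each triplet even though
training never consumes it, enabling oracle checks and flow baselines.

What passing tests on this generator do *not* show: robustness to real
section artifacts (folds, knife marks, charging), to non-smooth deformation
at tears, or to the content statistics of real tissue; the data-preparation
module exists precisely to build real-volume datasets.

## Data preparation for real volumes

For each consecutive slice triple of a volume (a directory of PNG or TIFF
slices; HDF5 volumes must be exported to an image sequence first, since no
HDF5 reader is available to this package): integer-translation alignment by
template matching (central template of half the frame, normalized
cross-correlation objective, translation only — serial-section jitter is
predominantly translational and integer shifts fabricate no pixels);
stride-grid cropping with half-open windows; quality filtering; histogram
specification of the outer frames toward the middle frame; a contiguous
3:1:1 train/validation/test split **by slice index** so no slice leaks
across splits.

The deletion rules for damaged samples are qualitative in the source
method; the filter makes them measurable and configurable, always reporting
its scores: saturated/zero-pixel fraction (default max 0.1), minimum
consecutive-frame correlation (default 0.2), and the Laplacian-variance
ratio between sharpest and blurriest frame (default max 3.0) as an explicit
stand-in for "substantial differences in blurring". Histogram specification
maps each 8-bit level to the reference level of nearest CDF value — a
monotone remap that inverts mild monotone intensity distortions to within
~2 gray levels (stronger compression collapses dark levels irreversibly at
8 bits, which no remap can undo).

## Training harness

Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$), batch size 3, initial learning
rate $10^{-3}$ for 30 epochs then $10^{-4}$ for 20 — the full recipe is the
package default and is asserted by a configuration snapshot test. The
`desk` preset keeps the optimizer and learning rate and shortens the
schedule to 10 epochs for CPU runs; presets are recorded in the returned
object. Augmentation applies independent horizontal/vertical flips and the
temporal-order swap (outer frames exchanged, middle fixed). Everything is
seeded: data order, augmentation draws and weight initialization; two runs
with one seed agree to floating-point determinism.

Batch normalization lives in the fusion network only and uses ordinary
single-device statistics (running mean/variance for inference) — the
multi-GPU synchronized variant degenerates to this on one device.
Validation PSNR is computed each epoch and the best-validation parameters
are kept, alongside the final-epoch parameters.

Metrics: PSNR $= -10\log_{10}\mathrm{MSE}$ on the $[0,1]$ scale; SSIM with
the standard 11×11 Gaussian window ($\sigma = 1.5$, $K_1 = 0.01$,
$K_2 = 0.03$, dynamic range 1); interpolation error IE $= 255\cdot\mathrm{RMSE}$,
the gray-level RMS convention of the frame-synthesis literature (neither IE
nor the SSIM settings are defined in the source method; these are the
field-standard choices). Evaluation always reports two input-only
baselines — the per-pixel average of the two inputs and frame 0 copied —
because any learned interpolator must be judged against them.

## Problem sizes used in the checks

The verification suite runs entirely on synthetic data at desk scale:
attention oracles on $8\times8\times8$ maps (50 random draws), support and
complexity checks at $4 \le H = W \le 128$, and one end-to-end run of the
`tiny` preset on 200 synthetic $64\times64$ triplets (120/40/40 split) for
10 epochs at batch 3 — about 400 optimizer steps, minutes on one CPU. At
that budget the trained model's held-out PSNR is compared against the
average-of-inputs baseline; the residual-head design above is what makes
this comparison meaningful at desk scale.

## Numerical choices and degenerate inputs

* Column softmax subtracts the column maximum before exponentiation.
* The dense oracle (`dense_attention_oracle()`) is an independent
  straightforward evaluation with an explicit per-column softmax loop,
  refuses $N > 4096$, and never shares code with the grouped fast path.
* Gradients flow through every component except the style-balance sign
  gates (constants by construction) and the 8-bit output quantization
  (inference only).
* $\gamma = 0$ initialization makes the whole AAL an exact identity; the
  test suite asserts bit-exactness.
* Equal inputs, constant references (histogram specification), empty crops
  (frames smaller than the window) and $n = 0$ dataset requests are
  handled as defined no-op/empty cases, not errors; indivisible partition
  geometry raises a configuration error naming the offending factorization.

## Known limitations

* No HDF5 ingestion (no reader in the environment); volumes arrive as
  image-sequence directories.
* The pretrained perceptual extractor is not bundled; the stub variants
  preserve the loss structure but not the semantics of pretrained features.
* Training is CPU-bound R + compiled kernels; the full 512×512, 50-epoch
  recipe is expressible but intended for much longer runs than the desk
  preset exercises.
* The interlaced one-level cost formula is reproduced as printed, including
  its $3/2$ coefficient that the MAC convention cannot produce.
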