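---
title: "Reference-free EIT reconstruction with electrical impedance maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free EIT reconstruction with electrical impedance maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eimnet)
```

## The problem

Electrical impedance tomography (EIT) drives small currents through
electrodes around a body section and reconstructs the interior conductivity
from the boundary voltages. *Absolute* (reference-free) EIT reconstructs
from a single voltage frame, without subtracting a baseline measurement.
This is substantially harder than difference imaging: the inverse problem
is non-linear and severely ill-posed, and there is no baseline to cancel
modelling error. `eimnet` implements a complete desk-scale pipeline for this
problem on a circular 16-electrode domain: FEM simulation of training data,
the electrical-impedance-map (EIM) representation, data augmentation, a
rotationally weight-shared neural reconstruction network, a Gauss-Newton
(GN) baseline, and figures of merit adapted to absolute images.

## Forward model

The forward solver implements the complete electrode model (CEM) with
first-order triangular finite elements on a disc. Currents are injected
through adjacent electrode pairs (unit current; pair k is electrodes
(k, k+1) mod 16) and voltages are measured over all adjacent pairs that do
not contain an injecting electrode — the standard four-probe
adjacent-adjacent protocol, giving 16 x 13 = 208 measurements per frame.
Contact impedance enters through the CEM boundary terms; its per-electrode
values are perturbed multiplicatively (Normal with mean 1 and std drawn
from {1e-5, 1e-3, 1e-1}) to emulate well and poorly attached electrode
sets.

The mesh is constructed ring by ring (ring i carries 16 i nodes), so a
rotation by one electrode pitch maps nodes, elements and electrodes onto
themselves by an exact permutation. Discrete rotational identities then
hold to solver precision rather than mesh accuracy, which is what the
equivariance tests rely on. The default mesh uses 14 rings (3136 elements,
radius 28 model units); this element count makes a full 16-injection solve
take a few tens of milliseconds on one core while leaving the boundary
discretization fine enough for half-pitch electrodes. The electrode arc is
realized as the nearest even number of boundary edges centred on the
electrode's centre node.

The domain here is two-dimensional: the conductivity phantoms are the
z = 0 slices of the three-dimensional shape masks (the masks themselves
keep full 3-D transforms), and the forward solve and raster are planar.
A 3-D cylindrical solver can be substituted behind `forward_solve()`
without touching anything downstream.

## Training-data generator

Phantoms are a uniform background with 1-4 enclosure shapes painted over
it (later enclosures overwrite earlier ones where they overlap):

* background conductivity log-uniform on [1e-5, 1] S/m — wide enough to
  cover thoracic tissue with a margin on both sides;
* enclosure shapes drawn uniformly from unit sphere, cube and octahedron,
  placed by `v' = (R(v - t)) / s` with translation components uniform on
  ±0.8 radius (resampled until the in-plane centre is within 0.8 radius),
  per-axis scaling uniform on [0.1, 0.8] radius, and three intrinsic Euler
  angles uniform on [0, 2 pi);
* contrast (multiplier on the background) log-uniform on [1e-2, 1e2], so
  conductive and resistive targets are symmetric in log space;
* per-value multiplicative Gaussian inhomogeneity, std log-uniform on
  [1e-8, 1e-2] independently per conductivity value.

Because translations are sampled in 3-D, an enclosure can miss the imaging
plane entirely; this is deliberate (the slice then sees a reduced target
count) and `planar = TRUE` is available when every enclosure must
intersect the plane. The generator emulates randomized geometric phantoms
only — no anatomical priors, no electrode-position errors, no boundary
shape variation. Passing tests therefore show correctness of the pipeline
on its own simulation distribution, not performance on anatomical data.

Measurement-noise augmentation operates on the packed EIM: multiplicative
thermal/jitter noise (Normal(1, 1e-6) per valid entry), additive
quantization noise (Normal(0, 1e-8)), and one multiplicative gain per
injection row (Normal(1, std)). The channel-gain model is printed
ambiguously in the source material as a zero-mean multiplier, which would
null entire rows; the unit-mean form is the default and the zero-mean form
stays available behind `mean_zero = TRUE`.

## The EIM and rotation

One frame packs into a 16 x 16 matrix: rows are injection pairs, columns
measurement pairs, and the 48 cells where the pairs share an electrode are
structural zeros (a circular band around the diagonal). Rotating the
conductivity counter-clockwise by one electrode pitch (22.5 degrees)
relabels the electrodes, which shifts both EIM indices cyclically by one —
a *diagonal* shift. `shift_eim()` is an exact Z/16 group action, and the
package verifies the physical identity
`EIM(F(rotate(sigma, n))) = shift(EIM(F(sigma)), n)` to 1e-3 relative on
the symmetric mesh (it holds to ~1e-11 in practice). Rotation expansion
(`expand_rotations()`) exploits this to produce 15 extra training samples
per simulated phantom at the cost of an image rotation.

Alpha-blending creates further samples: conductivities (and targets)
combine linearly, so under constant injection current voltages combine
harmonically, `U = (a/U1 + (1-a)/U2)^-1`. Adjacent voltages can take
opposite signs, so the harmonic denominator can cancel; entries where it
nearly does fall back to the linear blend (guard threshold
1e-12 scaled by the smaller voltage magnitude). Blending pairs are formed
by pairing each item of a batch with a random item of a second shuffled
batch, with alpha uniform on [0, 1].

## Network

The reconstruction network is:

1. **Convolutional front end** — five 5 x 5, stride-1 convolutions with
   *circular* padding on both EIM axes (the neighbour of pair 15 is pair
   0), layer normalization after each convolution, leaky rectifier
   activations, no pooling anywhere. The stack's receptive field is
   21 x 21, deliberately larger than the 16 x 16 map so boundary cells
   contribute as strongly as central ones. Circular padding plus stride 1
   makes the front end *exactly* equivariant to diagonal shifts.
2. **Row canonicalization** — the 16 x 16 x C feature map is read as 16
   injection rows of 16 column blocks; row k's blocks are cyclically
   unrotated by k. A diagonal shift of the input then simply permutes the
   rows.
3. **Shared dense head** — every row passes through the same two dense
   layers (2048 -> 2048 -> 4096 in the default configuration, dropout 0.1
   between them): 16 passes of one 2048-vector instead of one
   32768-vector, which is what makes the head rotation-aware and small.
4. **Rotation aggregation** — each row's 4096-vector is a 64 x 64
   *canonical* map in log1p-conductivity space; row k's map is rotated by
   k x 22.5 degrees and the 16 maps are averaged. The final image is
   `expm1` of the average.

The 16 rotation operators are composed as (exact 90-degree pixel
permutation)^f ∘ (bilinear rotation by r x 22.5 degrees), n = 4f + r, with
border-clamped sampling. Because the 90-degree factor is a permutation,
composing any operator with a multiple of 90 degrees is exact, and the
full network is exactly equivariant to shifts n in {4, 8, 12}; at other
shifts the bilinear factor makes equivariance approximate (observed, not
asserted).

Two numerical choices deserve a note. First, layer normalization is
per-sample, which would erase the absolute voltage scale — precisely the
quantity that encodes the absolute conductivity level. The input is
therefore fed as two channels: the EIM divided by its root-mean-square,
plus a constant channel carrying log10 of that RMS. Both channels are
shift-equivariant, so no symmetry is lost. Second, the head works in
log1p-conductivity space and the final image is `expm1` of it: the MSLE
loss becomes an ordinary squared error in the head's output space, is
well-conditioned across the five-decade conductivity range, and
predictions can never reach the log1p domain boundary at -1.

## Losses and training

The composite loss is `w2 * Lw2 + l1 * LTV + l2 * LMSLE` with

* `Lw2`: sum of squared weight-matrix entries (biases and normalization
  parameters excluded; the literal sum-of-weights form, which is
  sign-indefinite, is available behind `squared = FALSE`);
* `LTV`: anisotropic total variation of the output image, forward
  neighbour differences without wraparound;
* `LMSLE`: mean over the 4096 pixels of squared log1p differences.

The published weighting (`loss_weights("printed")`: w2 = 1, TV = 0.1,
MSLE = 1e-6) puts almost all mass on the regularizers; taken literally it
drives the weights to zero rather than fitting data. The package therefore
ships a `"sane"` preset (MSLE = 1, TV = 0.1, w2 = 1e-6) that exchanges the
data-term and weight-decay roles; it is the preset used by the training
smoke tests. During training the TV component is averaged over neighbour
pairs rather than summed, so its weight is resolution-independent and the
TV gradient per pixel is commensurate with the MSLE gradient per pixel;
the exported `loss_tv()` keeps the plain-sum definition.

Training uses Adam (initial learning rate 1e-3), per-epoch batch pairing
with alpha-blending, dropout 0.1, and a plateau schedule: when the
validation MSLE has not improved for 10 epochs the learning rate is
multiplied by 0.3 (a 70 percent cut). Runs are bit-reproducible from the
config seed. The smoke-scale study in the test suite trains the reduced
configuration `net_config_small()` (channels 8/16/16/16/16, head
128 -> 4096 — same topology and receptive field as the default) on 500
simulated samples for 50 epochs; this halves the validation MSLE and
localizes a held-out single off-centre target to within 8 pixels on the
64 x 64 grid. Problem sizes were chosen once, as the package's own
smoke-scale study conditions.

## Gauss-Newton baseline

`gn_reconstruct()` minimizes
`0.5 ||F(sigma) - V||^2 + 0.5 lambda ||L (sigma - sigma0)||^2` from the
best-fit homogeneous start `sigma0` (a one-dimensional log-scale fit),
with an adjoint-method Jacobian — for adjacent protocols the measurement
fields are the injection fields, so the 16 stored solves provide the full
208 x n_elem sensitivity at no extra cost. The prior is centred on the
homogeneous start so that the infinite-regularization limit returns the
start image; `lambda` is made dimensionless by scaling with the mean
diagonal of the first normal matrix. A backtracking line search keeps the
accepted objective sequence non-increasing; stalls return the best iterate
with a flag. Since the L-curve is reported unusable for reference-free
data in this setting, hyperparameter selection is by metric-based sweep
(`sweep_lambda()`), argmin of the position error. Tests simulate on the
fine (14-ring) mesh and invert on a coarser (8-ring) one to avoid the
inverse crime.

## Figures of merit

For absolute images the usual difference-image figures of merit need an
anchor: the scalar *median* is subtracted first (an ideal two-valued
reconstruction keeps its background at exactly zero). The evaluation mask
is then all pixels strictly below half the minimum (for resistive targets;
above half the maximum for conductive ones). The three reported metrics
are the amplitude response (sum of centred in-mask pixels), the position
error (Euclidean distance of the unweighted mask centroid to the true
target centre, in pixels of the 64 x 64 grid — magnitudes comparable to
published tables assume this unit), and ringing (population standard
deviation of the out-of-mask pixels). Series over target positions are
summarized as mean ± sample standard deviation in AR, PE, RNG order.
The true position is taken as the enclosure's analytic centre projected to
the imaging plane, converted to pixel coordinates.

## Conventions and degenerate inputs

* Pixels are 0-based, sampled at pixel centres, x rightwards, y
  *downwards*; the domain centre sits at pixel centre (31.5, 31.5) and the
  domain diameter spans the 64 pixels. Pixels outside the disc take the
  background value.
* Positive shifts and rotations are counter-clockwise in world
  coordinates; `shift_eim(e, n)` corresponds to rotating the medium by
  +n pitches.
* An enclosure covering zero mesh elements warns and is kept (it may still
  be a valid sub-element target); an all-flat image yields an empty
  evaluation mask and flagged `NA` metrics, which series summaries exclude
  with a count.
* Structural zeros are preserved exactly by every augmentation; corrupted
  maps (nonzero structural entries) are rejected when unpacking.
* Datasets are plain-text directories (CSV arrays plus a JSON manifest)
  written atomically; phantom specs serialize to YAML.

## Known limitations

* The 2-D slice domain cannot reproduce out-of-plane current spreading;
  absolute amplitudes therefore differ from cylindrical-tank values.
* The published architecture figure fixes neither kernel sizes nor depth;
  the five-layer 5 x 5 stack is the smallest stride-1 stack matching the
  printed receptive field (21) and head width (16 x 2048), and is a
  reconstruction of the design, not a copy.
* Rotation aggregation at non-90-degree multiples uses bilinear
  resampling, so claimed equivariance is exact only at 90-degree
  multiples.
* Training at desk scale (hundreds of samples, minutes of CPU) shows the
  pipeline learns and localizes; it does not reach the reconstruction
  quality of a full-scale training run, and no attempt is made to
  reproduce published benchmark tables, which depend on an unpublished
  trained model and physical hardware.
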