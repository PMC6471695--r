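---
title: "Validating cryo-EM map resolution with volumetric classifiers"
author: "cryores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating cryo-EM map resolution with volumetric classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The resolution claimed for a reconstructed cryo-EM density map is the
subject of long-standing debate: the standard Fourier Shell Correlation
(FSC) measure depends on how the particle data were split and thresholded,
produces a single global number for maps whose quality varies spatially,
and is blind to isotropic filtering. `cryores` implements a complementary,
supervised approach: classifiers trained on density volumes with known
resolution labels, which then judge an unseen map from its voxel content
alone. Three architectures are covered — a dense network and a 3D
convolutional network that assign one of three global classes
(high < 5 Å, medium 5–10 Å, low > 10 Å), and a 3D U-Net that labels every
voxel with one of ten resolution bins (0–2 Å, 2–3 Å, …, 9–10 Å, 10 Å and
above) the way local-resolution estimators such as MonoRes or ResMap
report it.

Everything needed to exercise the approach end to end ships in the
package: a map simulator, a synthetic structure generator, local-resolution
phantoms with exact voxel labels, the full preprocessing protocol, compact
implementations of the three networks, and the evaluation metrics.

## Simulating resolution-labelled maps

An atomic model is rendered as a sum of mass-normalised 3D Gaussians, one
per atom. Resolution R is *defined in Fourier space*: the rotationally
averaged Fourier amplitude of the map falls to one half of its
zero-frequency value at spatial frequency $s = 1/R$, i.e. the Gaussian
spectrum is $\exp(-R^2 \ln 2\, |k|^2)$, equivalently a real-space standard
deviation $\sigma = R \sqrt{\ln 2 / 2} / \pi$.

At the standard sampling of 1 Å/voxel this width is *sub-voxel* for sharp
maps ($\sigma \approx 0.47$ voxel at R = 2.5 Å), and point-sampling the
real-space Gaussian would alias so badly that the half-amplitude property
becomes unattainable on the grid — the sampled spectrum of a box-centred
atom never falls to one half below Nyquist. The simulator therefore works
band-limited: atoms are first rasterized with a wider, well-sampled
auxiliary Gaussian (1.2 voxels, circularly wrapped to match the DFT's
periodic view of the box), and the spectrum is then reshaped to the exact
target Gaussian by Fourier multiplication. The half-amplitude contract
holds on the produced map to well under a percent for every resolution
whose crossing lies inside Nyquist; the package warns when the requested
resolution is at or beyond the sampling limit (below about 2 Å at
1 Å/voxel) and then renders as sharp as the grid allows.

After synthesis, voxels farther than a cutoff from every atom are set to
exactly zero. The cutoff is $\max(5\sigma, 10\,\text{voxels})$: five
standard deviations makes the discarded Gaussian mass negligible, and the
10-voxel floor keeps enough of the band-limited kernel's tail that the
spectral contract survives truncation even for a single isolated atom
(the hardest case; for realistic many-atom structures the tails overlap).
Exact zeros matter downstream: empty-cube removal and structure masks are
defined by them.

```{r}
library(cryores)
model <- makeSyntheticModel(250, extent = 19, seed = 1)
map <- simulateMap(model, resolution = 7.5, box = 32)
halfCrossingFrequency(map)   # ~ 1/7.5
```

`makeSyntheticModel` builds protein-like structures as random walks with
1.5 Å steps (covalent-bond spacing) confined to a cube, so a desk-scale
corpus needs no structure downloads; `readAtomicModel` reads real PDB
files when those are available. Atom weights default to uniform — the
alternative of weighting by atomic number is exposed, but for resolution
classification the spectral envelope, not the element contrast, carries
the signal.

## Local-resolution phantoms

The voxel-wise classifier needs training maps whose per-voxel resolution
is known exactly. `makeLocalResPhantom` renders one shared structure
independently at each region's resolution and composites the renders by
region (axis-aligned slabs or concentric spheres), so every voxel's
density carries precisely its region's spectral signature and its label is
exact *by construction* — no external local-resolution estimator is
involved. In-mask voxels (non-zero density) get the ten-bin class of
their region; everything else a background sentinel (−1) that is excluded
from training losses and accuracy. Phantom labels depend only on the
region resolutions, never on the density scale.

These phantoms emulate the *geometry* of local-resolution supervision:
spatially coherent regions of differing blur inside one particle. They do
not emulate experimental noise, solvent background, CTF effects, or the
estimation noise of real MonoRes/ResMap labels — passing tests on
phantoms demonstrates that the network and pipeline learn spatially
varying spectral content, not that the model transfers to experimental
maps.

## Preprocessing protocol

All rules operate on `(input, label)` pairs in lockstep and preserve shape
equality at every stage:

* `minMaxNormalize` — linear rescale to [0, 1]; a constant map becomes all
  zeros (and then counts as empty downstream).
* `threeClassLabel` / `binResolution10` — global and voxel label rules.
  Bins are half-open $[lo, hi)$ with $[10, \infty)$ last; exactly 5 Å and
  exactly 10 Å are medium. The training resolutions (2.5/7.5/12.5 Å)
  never touch a boundary.
* `centralCropOrPad` — fixed-size standardisation for the global
  classifiers: centre-crop large axes, zero-pad small axes at the
  trailing end. Deliberately distinct from `padToPow2`, which pads
  *symmetrically* with the odd voxel assigned front or back by a seeded
  coin flip — the two protocols serve different model families.
* `applyMask` / `thresholdMask` — binary structure masks; masks may come
  from files or by thresholding (default level 0, exact for simulated
  maps).
* `partitionPatches` / `reassemblePatches` — non-overlapping 16³ tiling
  with removal of all-zero input cubes (exact zero by default; a
  tolerance is exposed for noisy experimental maps) and provenance
  offsets for exact reassembly, removed positions returning as
  background.
* `splitDataset` — seeded uniform splits; validation and test sizes are
  `round(ratio * n)` with the remainder to training, so 10 ids at
  60/20/20 give 6/2/2 and 100 ids at 72/8/20 give 72/8/20.

## The three networks

The architectures follow the published configurations:

* **Dense network** — flatten(64³) → 1000 ReLU → 100 ReLU → 3-way
  softmax; trained with constant-rate gradient descent (0.01), sparse
  softmax cross-entropy, batch 150. At the published 64³ input this is
  262,245,403 trainable parameters.
* **3D CNN** — 32 7³ filters (ELU) → pool → 64 5³ (ELU) → pool → 128 5³
  (ReLU) → pool → dense 1024 (tanh, dropout 0.4) → 3-way softmax, "same"
  zero padding throughout, so a 64³ input reaches the dense layer as
  8³ × 128.
* **3D U-Net** — four encoder levels (two 3³ ReLU convolutions, spatial
  dropout 0.5, 2× max-pool; 64/128/256/512 filters), a 1024-filter root,
  and four decoder levels (nearest-neighbour 2× upsampling, a 2³
  convolution, concatenation with the encoder level's *dropout* output,
  two 3³ convolutions), closed by a 1³ convolution to ten channels with a
  per-voxel softmax; He initialisation, Adam, categorical cross-entropy
  with one-hot voxel labels, background voxels carrying zero loss weight.
  At the 16³ patch input the root works on a 1³ spatial grid.

Because no deep-learning framework is part of this package's dependency
footprint, the layers are implemented directly: C++ (Armadillo) kernels
for im2col/col2im 3D convolution, max-pooling and upsampling, with R
orchestration for activations, losses, dropout and the SGD/Adam updates.
Correctness is pinned by finite-difference gradient tests through both the
convolutional and the U-Net (skip-connection) paths, and
trainable-parameter counts are checked against closed-form arithmetic.

Numerical conventions worth stating once: "same" padding for even kernels
puts the extra voxel at the trailing side (the U-Net decoder's 2³
convolution); argmax class decisions break ties toward the lowest class
index; early stopping keeps the weights of the epoch with the smallest
validation loss and halts once no improvement has been seen for
`patience` epochs; all weight initialisation, shuffling and dropout draw
from one seeded RNG stream, so a config seed reproduces a run exactly.
Updates are guarded by global gradient-norm clipping (`clipNorm`, default
5): cross-entropy training of the convolutional classifier is prone to a
sudden mid-descent explosion (validation loss jumping from ~0.5 to
overflow within one epoch), and rescaling oversized gradient steps lets
the same run continue to convergence; a non-finite validation loss is
treated as "no improvement", so even a diverged run keeps its best
weights and stops via patience.

## Desk-scale study conditions

The published corpora (12,671 structures × three resolutions = 38,013
simulated maps; EMDB experimental sets) and GPU-scale training are out of
reach of a test suite, so the learning properties are demonstrated at
desk scale, chosen once as:

* **Global classifiers**: 50 synthetic 250-atom structures, each rendered
  at the three training resolutions 2.5/7.5/12.5 Å (the published corpus
  construction — every selected structure appears at every resolution) in
  a 32³ box at 1 Å/voxel; 150 maps, 60/20/20 split at the map level. The
  dense classifier trains with desk-scale hidden widths 32/8 (the full
  1000/100 at 90 training maps of 32,768 voxels is massively
  over-parameterised and no more accurate at this corpus size) and the
  CNN with 8/16/32 filters and a 256-unit dense layer — same topology,
  narrower layers.
* **U-Net**: two-bin phantoms (2.5 Å vs 12.5 Å halves, classes {1, 9}),
  24 phantoms in 32³ boxes partitioned into 16³ patches (~190 retained
  cubes), base width 6. Chance level is 10%.

These sizes keep each training run in the minutes range on one CPU, which
is what the desk-scale properties are meant to show: that the
implementations *learn* the intended signal. They make no claim about the
published accuracies, which depend on the full corpora. The convolutional
models carry the clearest margin (the CNN typically reaches the mid-90s
and the U-Net well above 90% voxel accuracy against a 10% chance level);
the dense classifier is the data-hungriest of the three — its first layer
can only form linear projections of the flattened map, so the per-voxel
statistics that separate the classes must be assembled from many such
projections, and with only 90 training maps its held-out accuracy sits
near the 90% line rather than comfortably above it.

## The worked example

The packaged 30-map benchmark (`experimentalBenchmark()`) carries the
published per-map classifications of thirty experimental EMDB maps by the
two global classifiers, with author-claimed resolutions spanning ten maps
per class. Feeding its columns through `confusionMatrix3`,
`combinedAgreement` and `classMetrics` reproduces the published
confusion matrices, the 60.0% / 56.7% agreements and every per-class
sensitivity/specificity/PPV/NPV value. Percentages round half-up to one
decimal — the only convention under which 19/26 prints as 73.1 and 10/18
as 55.6. Ratios with zero denominators are reported as `NA`, never
silently as 0 or 100. `classMetricsSoft` provides the general
partial-class-membership form of the same metrics; with crisp labels the
two agree exactly, which the tests assert.

## Design choices made where the protocol was open

* *Axis convention*: MRC files store column/row/section order; the package
  normalises every volume to logical (x, y, z) indexing at read time and
  states the convention once, avoiding silent transposes.
* *Voxel centres* sit at `origin + (i + 0.5) * voxelSize` (0-based `i`).
* *Mask construction* is unspecified for experimental maps; the default
  derives masks by thresholding the normalised map at 0, and external
  masks are accepted.
* *Normalise-then-crop* is the default order for experimental maps (the
  alternative order is a one-line change at the call site).
* *Experimental voxel spacing is preserved*: maps are not resampled to
  1 Å/voxel; callers who need a common grid must resample upstream.
* *Patch repositories* are stored as RDS runtime artifacts behind the same
  interface a hierarchical container would offer.
* The boundary scan accepts either a trained network or a plain function
  of (map, resolution), so the analytic three-class thresholds can serve
  as a reference "model": on the 0.5 Å grid from 1.5–15 Å they place
  change points at 5.0 and 10.5 Å — the first grid resolutions whose
  class differs from their predecessor's.

## Known limitations

* Simulated maps are noise-free and resolution-homogeneous; classifiers
  trained on them are known to transfer poorly to experimental maps (the
  benchmark's 60.0%/56.7% agreements illustrate exactly this), which is
  the motivation for the voxel-wise, experimentally supervised route.
* The U-Net route is exercised here on synthetic phantoms only; real
  MonoRes/ResMap label volumes can be supplied as MRC files but no
  estimator is bundled.
* The fixed 64³ global input discards the periphery of large maps and
  zero-pads small ones; sizing strategies are an open question in this
  approach generally.
* Anisotropic voxel sizes are carried through I/O faithfully, but the
  network engine assumes cubic grids (all published configurations are
  cubic).
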