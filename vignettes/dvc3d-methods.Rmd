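---
title: "Measuring matrix deformation with dvc3d: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring matrix deformation with dvc3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement problem

Cells embedded in a fibrous extracellular matrix (ECM), such as a collagen
type I gel, pull on the fibers around them; external loads (a magnet
embedded in the gel, a micromanipulator) deform the network too. Volumetric
coherent imaging — optical coherence microscopy (OCM) and its Gabor-domain
variant — records the gel as a 3-D speckle volume in which the fibrous
texture is a trackable fingerprint of the material. Digital volume
correlation (DVC) turns a pair of such volumes into a full-field
displacement map: it finds, for each subvolume (*subset*) of the reference
image, the shift that maximizes the cross-correlation with the deformed
image, and refines that shift to subvoxel precision. Differentiating the
displacement map yields the infinitesimal strain tensor field.

dvc3d implements this whole chain in R, together with a synthetic phantom
generator that plays the role of the microscope: it produces speckle
volumes of known fiber scenes and deforms them by *exactly known* fields,
so every stage can be validated against ground truth.

## The phantom: what it emulates, and what it does not

`generate_phantom()` builds a scene in four steps:

1. **Fiber network.** `fiber_count` straight segments with uniformly random
   positions and orientations are rasterized as point mass on the voxel
   lattice. The default density (300 fibers in a 128-voxel-scale volume)
   gives the dense, overlapping texture of a ~2.5 mg/mL collagen gel as it
   appears at micrometre resolution; fibers are kinematic texture, not a
   mechanical model.
2. **Optics.** The scene is convolved with an anisotropic Gaussian
   point-spread function. The defaults — transverse FWHM 2.0 µm, axial
   FWHM 2.6 µm — correspond to a high-NA OCM objective whose axial
   resolution is set by the source coherence length; the fiber
   cross-section (`fiber_radius`, a Gaussian σ of 0.3 µm) folds into the
   same blur.
3. **Speckle.** Coherent imaging of sub-resolution scatterers produces
   fully developed speckle: the magnitude of a circular complex Gaussian
   field. We synthesize it by low-pass filtering an i.i.d. complex
   Gaussian field to the PSF scale and taking its modulus, so the speckle
   grain size matches the resolution cell, which is what makes speckle
   *trackable* rather than destructive. Pointwise the amplitude stays
   Rayleigh (contrast ≈ 0.52). A uniform `background` reflectivity (0.12)
   keeps texture alive between fibers, as real gels scatter everywhere.
4. **Detector noise.** Additive white Gaussian noise at `noise_snr` dB
   relative to the RMS signal. Real OCM noise figures vary with source
   power and detector; 25 dB is a realistic mid-range default that leaves
   the error floor measurable but far below a voxel.

What the phantom does **not** model: interferometric image formation,
depth-dependent defocus and Gabor-stack fusion, refraction, absorption,
motion artifacts, or any constitutive mechanics (applied deformation
fields are prescriptions, not FEM solutions). Consequently, passing the
validation suite demonstrates the correctness of the *analysis chain* under
realistic texture and noise — not the performance of any particular
instrument on real tissue.

Three exact deformation oracles feed the validation: `apply_integer_shift`
(a circular voxel roll — exact, with a mandated `crop_margin()` so wrapped
content never reaches the correlator), `apply_subvoxel_shift` (a spectral
phase ramp, exact for band-limited content), and `apply_field` (backward
warping by an arbitrary field, trilinear). The sign convention throughout
is `deformed(x) = reference(x − u(x))`: material moves by +u, and all
displacements are in µm with axis order (x, y, z), z axial.

## The correlator

`correlate_subset()` computes zero-mean normalized cross-correlation
spectrally. Two numerical choices matter:

* **Windowing and envelope division.** Each subset is tapered with a
  separable Tukey window (α = 0.5) before the FFT, suppressing the
  spurious correlations that periodic (circular) FFT correlation
  otherwise introduces at the block edges. Tapering, however, makes the
  raw correlation decay with lag magnitude (the window overlap shrinks),
  which drags the three-point subpixel fit toward zero lag — a bias of
  ~0.06 voxel in our convergence experiments. Dividing the correlation by
  the window's autocorrelation envelope removes this decay exactly; the
  envelope is clipped below 0.05 to avoid amplifying far-lag noise, and
  the integer search is restricted to lags within a quarter of the subset
  anyway.
* **Subpixel refinement.** A separable three-point fit per axis around the
  integer peak: log-parabolic when all three samples are positive — exact
  for a Gaussian-shaped peak, and speckle autocorrelation is close to
  Gaussian — otherwise plain parabolic. Ties at the integer search are
  broken toward the smallest lag, making results deterministic. The
  offset is clamped to ±0.5 voxel.

`run_dvc()` iterates: lay a subset grid (default spacing a quarter of the
subset, 75% overlap — the paper-scale protocols use a single pass at a
fixed 128-voxel subset, while iterative runs halve the subset down to 32),
warp the *reference* by the running field, correlate against the deformed
volume, and accumulate the residuals. Warping the reference rather than
the deformed volume is deliberate: the fixed point of that iteration is
exactly `u` at the grid nodes, whereas warping the deformed volume
converges to `u` sampled at the deformed position, which is biased by
∇u·u for non-uniform fields (we measured ~0.25 voxel on a traction
scene before making this choice). Dense warps interpolate the node field
trilinearly and extend it *linearly* beyond the node hull — constant
(clamped) extension leaves affine fields inconsistent near volume borders
and visibly degrades edge nodes.

Interpolation for warping is trilinear. Tricubic warping was considered
and rejected: in pure R it costs ~8× more per pass, and the convergence
experiments met every accuracy target (shift equivariance to 0.1–0.15
voxel, traction-field RMSE < 0.2 voxel, strain components to a few
percent) without it.

Subsets that would leave the volume are simply not evaluated (no
padding — padding corrupts speckle statistics), and nodes with peak
correlation below `correlation_threshold` (0.2) or zero variance are
flagged invalid rather than erroring.

## Drift correction and accumulation over time

Thermal expansion, gel settling and stage backlash superimpose a rigid
apparent displacement on each acquisition depth stack. Following the
mean-subtraction approach, `correct_drift()` removes the mean of each
component over each stack's valid nodes and reports the removed vectors.
The correction operates in the displacement domain (after DVC), not on
the images; with synthetic data the whole volume is one stack by default,
and a stack thickness of ~10 µm mimics stepped-focus acquisition.

Cumulative maps compose increments by evaluating each incremental field at
the node's current deformed position:

    cum_1(x) = inc_1(x)
    cum_n(x) = cum_{n-1}(x) + inc_n(x + cum_{n-1}(x)),  n ≥ 2

with trilinear interpolation of the incremental field at the moved
position. The printed form of this recursion in the source literature
indexes the increment at n−1; taken literally that double-counts the
first increment and never uses the last, so we implement the only
self-consistent reading (increment n at the position deformed by
cum_{n−1}). Nodes whose moved position leaves the measurement grid become
invalid from that timestep on — clamping them instead would silently bias
long accumulations.

`segment_foreground()` masks cell bodies before DVC: mean projections
along the three axes are Otsu-thresholded, back-projected, and
intersected. A projection whose above-threshold fraction exceeds 25% is
treated as homogeneous texture (no segmentable object): a cell is a
bright, localized minority of a projection, whereas Otsu applied to pure
speckle texture just splits the histogram near its middle. The mask is
dilated by 4 voxels (≈ one PSF support at the default sampling) to recover
the blurred object rim.

## Strain

Strain is the symmetrized displacement gradient,
εij = ½(∂ui/∂xj + ∂uj/∂xi). Because node-to-node DVC noise is amplified
by differentiation, the field is first box-mean filtered (default 3³
nodes, matching the differentiation stencil; box filtering preserves
affine fields exactly on the interior). Gradients are estimated by
central differences along each axis averaged over the orthogonal 3×3
plane of neighbors — a 3×3×3 stencil that is exact for affine fields and
attenuates uncorrelated node noise by √9 per gradient; a plain 1-D
central difference is available (`method = "axial"`). Physical node pitch
(grid step × voxel spacing, µm) makes the strains dimensionless. Strains
are reported on the measurement grid: resampling to voxel resolution
would fabricate resolution the measurement does not have. Boundary nodes
and nodes with any invalid stencil neighbor are invalid.

## Validation protocols and the problem sizes used

`sampling_rates()` reproduces the transverse sampling arithmetic: a fixed
320 µm field of view scanned at 400/600/800 pixels gives 0.8/0.53/0.4
µm/px. The axial rate is fixed at 0.73 µm/px.

`error_floor()` measures the sensitivity limit: DVC between two volumes of
the same scene (here: one speckle realization, two independent additive
noise draws at 25 dB — an instrument would add rescan noise we cannot
reproduce physically, so the published floor is treated as an upper
bound). Reported per component: STD, IQR, mean, median over valid nodes,
plus their three-component average.

`virtual_translation_experiment()` runs the accuracy protocol: per
transverse rate, a phantom is generated at that spacing, shifted by the
prescribed whole-voxel transverse amount (4/6/8 voxels — the same 3.20 µm
at every rate) and by 4.42 µm axially. The axial ground truth deserves a
note: the protocol text quotes 4.43 µm (≈ 6.06 voxels × 0.73 µm), but the
published ground-truth value is 4.42 µm, which is not an integer multiple
of 0.73; we apply exactly 4.42 µm via the Fourier oracle and record
4.42 µm as ground truth. Ground-truth columns always come from the shift
prescription, never from DVC output. The emitted table mirrors the
published layout: rows U, V, W, Average; per rate an error-floor column
pair (STD, IQR) and a displacement pair (mean, median); a ground-truth
column.

Desk-scale sizes, chosen once: the acceptance script runs 256×256×160
phantoms (cropped to 236×236×140 before correlation; 16 subset-128 nodes
per case), and the test suite runs 192×192×176 scenes for the same
protocol plus 64³–128³ scenes for unit and property tests. The original
protocol volumes (600×600×220 at 0.53 µm/px) change the node count, not
the method; the recovered means at both scales agree with ground truth
within the stated tolerances.

Grid density is a genuinely open choice — the source protocol states
subset size but not overlap — so Table-style statistics are computed over
whatever grid the configuration produces; the default (spacing =
subset/4) follows common DVC practice, and the single-pass subset-128
configuration is used for protocol replication.

## Known limitations

* Translation-only subsets: no affine subset matching, so very strong
  local rotations/stretches (beyond a few percent across a subset) bias
  individual nodes until the iterative warp compensates.
* The phantom's noise and speckle-grain defaults stand in for unreported
  instrument values; error-floor results are bounds, not reproductions.
* Infinitesimal strain only (no Green–Lagrange tensor, no stress, no
  constitutive model).
* Drift is modeled as per-stack rigid translation; rotational drift or
  within-stack gradients are not corrected.
* Pure-R FFT correlation is single-threaded; a 16-node subset-128 case
  takes tens of seconds, and large grids cost proportionally more.
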