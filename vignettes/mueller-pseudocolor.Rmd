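---
title: "Depolarization observables and pseudo-coloring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depolarization observables and pseudo-coloring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muellerpc)
```

This vignette documents the model behind `muellerpc`, the numerical choices
the implementation makes where the mathematics leaves room, and what the
synthetic-data tests do and do not demonstrate about real polarimetric data.

## The depolarization model

A Mueller matrix `M` acts on Stokes vectors; its block form
`M = m00 [[1, D^T], [P, m]]` exposes the unpolarized intensity `m00`, the
diattenuation vector `D`, the polarizance vector `P` and a 3×3 submatrix `m`
that entangles retardance and depolarization.  All observables are computed
on the `m00`-normalized matrix, so every channel except `m00` is invariant
to the intensity scale.

The per-pixel pipeline is:

1. **Coherency matrix.**  `H(M) = (1/4) Σ_ab m_ab (σ_a ⊗ σ_b*)`, with the
   Pauli basis in the order `σ0 = I`, `σ1 = diag(1, −1)`,
   `σ2 = antidiag(1, 1)`, `σ3 = [[0, −i], [i, 0]]`.  `H` is Hermitian with
   trace `m00`; it is positive semidefinite exactly when `M` is a physically
   realizable Mueller matrix.  This construction pins down both limits: a
   pure element gives a rank-one `H`, and the ideal depolarizer
   `diag(1, 0, 0, 0)` gives `H = I/4`.  (The literature varies in the
   constant in front of the sum; the indices below use *normalized*
   eigenvalues, so they are invariant to that convention.  We use `1/4` so
   that `tr H = m00`.)
2. **Eigen-spectrum.**  The eigenvalues are sorted descending, clamped
   (below) and normalized to sum to 1, giving the Cloude convex-sum weights
   `λ̂0 ≥ λ̂1 ≥ λ̂2 ≥ λ̂3 ≥ 0`.
3. **Indices of polarimetric purity.**  `P1 = λ̂0 − λ̂1`,
   `P2 = λ̂0 + λ̂1 − 2λ̂2`, `P3 = λ̂0 + λ̂1 + λ̂2 − 3λ̂3`.  The ordering
   `0 ≤ P1 ≤ P2 ≤ P3 ≤ 1` is algebraic, not empirical: each difference
   `P2 − P1 = λ̂1 − λ̂2` etc. is non-negative by the sort.
4. **Components of purity.**  `D`, `P` as vector norms of the first
   row/column over `m00`; `P_S = ‖m‖_F/(√3 m00)`.  The "2-norm" of the
   submatrix is interpreted as the Frobenius norm — the only reading under
   which the two forms of the depolarization index coincide, which the test
   suite verifies on random convex mixtures to `1e−9`.
5. **Depolarization index.**  `P_Δ = √(D² + P² + 3P_S²)/√3`, identically
   equal to `√(2P1² + (2/3)P2² + (1/3)P3²)/√3` for any real 4×4 matrix
   (both equal `√((tr(MᵀM)/m00² − 1)/3)`), which is why a disagreement
   between the two forms is diagnostic of eigenvalue clamping or other
   numerical intervention rather than of the input.

### Numerical choices

- **Clamping.**  Experimental matrices are only approximately physical.
  Eigenvalues in `[−ε, 0)` with `ε = eps_rel · tr H` (default
  `eps_rel = 1e−8`) are set to zero silently; more negative eigenvalues are
  also clamped but the pixel is *flagged* and a summary warning emitted.
  With realistic noise a large fraction of pixels flag — the flag marks
  "non-physical beyond numerical noise", not "unusable".  No realizability
  pre-filtering is applied before decomposition; clamp-and-report leaves the
  user in control.
- **Degenerate eigenvalues.**  Ties in the sorted spectrum are broken
  arbitrarily by the solver; every exported quantity depends only on the
  sorted values, so the result is well defined.
- **Invalid pixels.**  `m00 ≤ 0` (no light) and non-positive coherency
  traces are masked, propagate as `NA` through every channel, and render
  black in every output image.

## ROI class statistics

A class model is the per-observable mean and standard deviation of one
triplet — `(P1, P2, P3)` or `(P, D, P_S)`, always `n = 3` observables — over
the union of one or more user-supplied rectangles (0-based, half-open
coordinates, origin top-left), plus an RGB color.  Choices made where the
definition is open:

- **Sample standard deviation** (`n − 1`).  With ROIs of thousands of pixels
  the distinction is immaterial, but the choice is recorded in the run
  metadata so any rendering is exactly reproducible.
- **`σ` floor** (`sigma_floor = 1e−6`, on the dimensionless observable
  scale).  A constant ROI — common in synthetic scenes — has zero sample
  deviation, which the Gaussian model cannot accept; the floor substitutes a
  width far below any physically meaningful observable spread.
- ROIs may be drawn on any reference channel; the statistics only consume
  pixel coordinates.

## The two pseudo-coloring methods

**Euclidean (k = 2).**  The per-observable residual `m_j^i − p_j` is scaled
by the between-class mean difference `m_j^1 − m_j^2`, the scaled residuals
combined into `d_i`, and the color weights `ℜ^i = 1 − d_i/(d_1 + d_2)`
applied to the class colors.  The weights always sum to 1.  Two degenerate
situations need rules the formula does not give:

- If some observable has equal class means (within `1e−9`) its scaling is
  undefined; that observable is dropped with a warning, and if all three are
  degenerate the classes are indistinguishable and the call errors.
- A pixel exactly on both means simultaneously (impossible when the means
  differ, but reachable after dropping observables) gets `ℜ = (1/2, 1/2)`.

**Normal (k ≥ 1).**  `P^i = Π_j exp(−z_j²)` with `z_j` the class z-score.
The exponent deliberately carries no 1/2 factor and no normalizing constant:
the score is a membership weight equal to 1 exactly at the class means, not
a calibrated density.  Because real per-pixel values scatter around the
class means, the score of a pixel that genuinely belongs to a class is
`exp(−Σ z²)` with `Σ z² ~ O(3)`, i.e. typically far below 1 — images
rendered with this method are darker than Euclidean ones, and pixels far
from every class go black with no threshold.

**Clipping.**  Both methods clip each RGB channel to `[0, 1]` after summing
class contributions.  With complementary color pairs (yellow/blue,
pink/lime-green — the built-in presets in `class_colors`) the Euclidean sum
never exceeds 1; overlapping classes with non-complementary colors can, and
clipping keeps the output displayable.

**Classification export.**  Only the Normal method classifies: argmax over
`P^i`, with pixels unassigned when the best score falls below a threshold
(default `1e−3`, configurable).  Note the default intentionally leaves the
far tail of each class's own spread unassigned (about 7 % of in-class
pixels under Gaussian scatter, since `exp(−Σz²) < 1e−3` once `Σz² > 6.9`);
use `threshold = 0` for a pure argmax partition.  The threshold affects only
the label map, never the RGB image.

## The synthetic-scene generator

Real tissue Mueller images are instrument output and not redistributable, so
the generator produces scenes with known ground truth for testing every
pipeline stage:

- **Class matrices** are built from textbook pure elements (identity, linear
  diattenuators, linear retarders, or arbitrary Jones-derived matrices) and
  their Cloude convex mixtures, so every noiseless pixel is physically
  realizable by construction.
- **Layouts**: `halfplane` (two-region split), `stripes` (bands cycling
  through classes, ring-like), `disks` (class disks on background,
  lesion-like).
- **Noise**: additive element-wise Gaussian with standard deviation
  `noise_sd · m00` — the simplest stand-in for detector noise.  The default
  study condition in the tests is `noise_sd = 0.005` (0.5 % of the
  intensity), a level at which two well-separated classes remain cleanly
  recoverable while the realizability clamping path is genuinely exercised
  (noisy pixels are routinely slightly non-physical).
- **Determinism**: one seed controls all randomness; identical parameters
  and seed give bit-identical scenes.

What the generator does **not** emulate: spatial correlation of tissue
texture, scattering and depth effects, instrument calibration errors,
wavelength dependence, or class boundaries that are gradual rather than
sharp.  Passing tests therefore demonstrate the correctness of the
*computations* under controlled conditions, not segmentation performance on
real tissue.

### A caveat on recovering class means under noise

For a class whose coherency spectrum has *distinct* eigenvalues the
observable map is smooth, and ROI means converge to the noiseless values at
the usual `SD/√N` rate — the property suite checks exactly this on a
mixture with weights `(0.55, 0.25, 0.15, 0.05)`.  But for spectra with
*degenerate* eigenvalues (both `diag(1, a, a, a)` classes and any pure
element have a triply degenerate minor eigenvalue), noise splits the
degenerate eigenvalues at first order and the descending sort rectifies the
split, biasing the sorted spectrum — and hence the IPP means — by an amount
proportional to the noise level itself (≈ `noise_sd`), independent of ROI
size.  At `noise_sd = 0.005` the bias reaches ≈ 0.02 on `P3`.  Tests and
users should therefore compare recovered means of such classes at a
noise-calibrated absolute tolerance, not at `3 SE`.  This is a property of
the observables' definition (sorted eigenvalues), not an implementation
artifact; experimental IPP images carry the same bias wherever the true
spectrum is nearly degenerate.

## Problem sizes in the test suite

The suite exercises: 1×1 to 256×256 scenes; 10⁴ random convex mixtures for
the depolarization-index identity; 10³ random matrices against an
independently coded brute-force coherency/eigenvalue oracle (agreement to
`1e−10`); and one 256×256 two-class recovery scene (`diag(1, 0.4, 0.4, 0.4)`
vs. identity, `noise_sd = 0.005`, 50×50 ROIs) on which both rendering
methods reproduce the ground-truth partition on more than 99 % of pixels.
These sizes keep the full suite under a minute while leaving every code path
(including clamping, masking and multi-rectangle ROIs) covered.

## File-format notes

Mueller images travel as 16-page 32-bit-float TIFFs in row-major element
order `m00..m33`, or as RDS array archives holding an `(H, W, 4, 4)` array.
The float TIFFs are written by a minimal built-in writer (uncompressed,
little-endian, IEEE-float sample format) and read back with the `tiff`
package; Mueller elements are signed, so the integer-scaled TIFF path that
`tiff::writeTIFF` offers is not applicable.  PNG output quantizes as
`round(255·c)`, bounding the round-trip error by `1/255` per channel.

## Known limitations

- The Euclidean method is defined for exactly two classes; the CLI refuses
  more and points to the Normal method.
- Class statistics assume per-observable independence (the Gaussian product
  has no covariance terms) and rectangular ROIs.
- No retardance extraction beyond `P_S`, no product (Lu–Chipman style)
  decompositions, no instrument calibration — the input is assumed to be a
  finished Mueller image.
```{r session}
sessionInfo()
```
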