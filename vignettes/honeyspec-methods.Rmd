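---
title: "Detecting honey adulteration from simulated hyperspectral transmittance: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting honey adulteration from simulated hyperspectral transmittance: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Syrup adulteration of monofloral honey can be detected from transmission
hyperspectral microscopy: a spectral sweep over the visible range produces a
hypercube (one image per wavelength band), the cube is calibrated against a
white reference into per-neighborhood transmittance curves, each curve is
compressed to a small sum-of-sines coefficient vector, and a supervised
classifier assigns the adulteration level. Raw acquisitions of this kind are
rarely deposited publicly, so `honeyspec` ships a seeded simulator of the
whole acquisition chain; every stage of the analysis is therefore testable
end to end, at desk scale, from a single master seed.

## The model

**Acquisition.** A white-reference cube is modeled as
\[ W_{\lambda r c} = L(\lambda)\, I(r, c) + \eta, \qquad
   P_{\lambda r c} = L(\lambda)\, I(r, c)\, \tau(\lambda) + \eta', \]
where \(L\) is a smooth lamp emission spectrum, \(I\) a smooth multiplicative
illumination field (a gentle radial vignette), \(\tau\) the sample's
transmittance, and \(\eta, \eta'\) independent additive white readout noise
of standard deviation `sigma_read` per pixel and band. Dividing the
noiseless sample by the noiseless white recovers \(\tau\) exactly; this
identity is a unit test.

**Materials.** Pure-material transmittances are drawn as
\(\tau = e^{-A(\lambda)}\) with absorbance \(A\) a baseline plus 3–6 broad
Gaussian bands (widths 30–120 nm), giving smooth curves in \((0, 1]\).
Libraries are redrawn until every material pair differs by at least the
`separation` parameter (default 0.1) somewhere on the grid. A mixture at
honey mass fraction \(w\) is \(\tau = w\,\tau_h + (1-w)\,\tau_s\) by default
(`linear`), or \(\tau_h^{\,w}\tau_s^{\,1-w}\) (`beer_lambert`, mixing
absorbances). Either way mixtures lie pointwise between the endmembers, so
curve families are ordered by purity.

**Preprocessing.** A region of interest whose extent is a multiple of 4 is
tiled into non-overlapping \(4\times4\) neighborhoods; the 16 pixels of each
tile are averaged at every band, and transmittance is the band-wise ratio
\(\tau_\lambda = P_\lambda / W_\lambda\) of the averaged sample and white
curves — averaging happens *before* division, and a test pins that order.
Values slightly above 1 under noise are flagged, never clipped. The tile
population is then randomly subsampled to a fixed number of curves per class
(default 100).

**Features.** Each curve is compressed to
\[ \hat\tau(\lambda) = \sum_{n=1}^{8} a_n \sin(b_n \lambda + c_n), \]
with \(\lambda\) in nm, i.e. 24 coefficients per curve in place of 311 band
values. Coefficients are stored canonically (\(a_n \ge 0\), \(b_n \ge 0\),
\(c_n \in (-\pi, \pi]\), terms sorted by ascending frequency), collapsing the
sign/phase/order symmetries of the sine so equivalent fits map to one
representation.

**Classification.** Three families, 10-fold stratified cross-validation,
features z-scored with training-fold statistics only: a pooled-covariance
Gaussian discriminant (LDA, diagonal ridge \(10^{-6}\)); a soft-margin SVM
with a degree-2 polynomial kernel whose scale is the median pairwise
training distance (one-vs-one multiclass, via `e1071`/libsvm); and a
one-hidden-layer network of 100 ReLU units with softmax output, trained
full-batch by L-BFGS on the cross-entropy loss with an \(L_2\) penalty.

**Metrics.** Per class, one-vs-rest precision, recall and specificity in
percent, F1 as their harmonic mean; overall accuracy as the rate of correct
predictions; macro averages rounded to one decimal, half away from zero.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `grid` | 420–730 nm, 311 bands | nm | visible sweep, 1 nm steps |
| `dims` | 64 × 64 | pixels | desk-scale cube; 256 tiles ≥ 100 curves/class |
| `sigma_read` | 0.002 | intensity | low-noise acquisition regime |
| `separation` | 0.1 | transmittance | minimum pairwise endmember identity |
| `n_bumps_range` | 3–6 | — | broad-band visible absorbance |
| `total_mass` | 23 | g | mixture design bookkeeping |
| `class_fractions` | 90, 80, 70, 60 | % honey | the four classified levels |
| `n_per_class` | 100 | curves | working set per class |
| `k_neighborhood` | 4 | pixels | averaging tile side |
| `n_terms` | 8 | — | 24 coefficients per curve |
| `k_folds` | 10 | — | cross-validation |
| `early_stop` | 2e-3 | transmittance | fit acceptance floor (below) |

The five adulteration levels (100, 90, 80, 70, 60% honey) are all
simulatable; by default the pure level is used as a reference/design row and
the four adulterated levels form the classification task
(`include_pure = TRUE` adds the fifth class).

## Numerical design of the sum-of-sines fit

A free Levenberg–Marquardt fit of all 24 parameters is *sloppy*: many
frequency/amplitude/phase combinations produce nearly identical curves, so
band noise of a few \(10^{-4}\) moves the optimizer far along flat valleys
of the cost surface. In early versions this turned physically identical
curves into coefficient vectors with ~50% within-class amplitude scatter —
raw curves were perfectly separable while their fingerprints were
near-chance for the SVM. The final design therefore treats conditioning of
the *coefficient map*, not only residual size, as the goal:

1. **Greedy dictionary start.** Frequencies are selected one at a time by
   orthogonal matching pursuit from a fixed dictionary oversampling the FFT
   bins 8×, re-solving all amplitudes and phases linearly at each step
   (they enter the model linearly once frequencies are fixed). The discrete
   dictionary keeps selected frequencies identical across near-identical
   curves. Remaining terms are padded with fixed, well-separated integer-bin
   frequencies.
2. **Early acceptance.** A start whose RMSE is already below `early_stop`
   (2e-3 transmittance units) is accepted outright. The floor sits above
   the band-noise level of averaged low-noise acquisitions (~7e-4) and five
   times below the 1% fit-quality target: refinement past it chases noise
   and destabilizes the coefficients.
3. **Refinement when needed.** Any start above the floor is refined by
   Levenberg–Marquardt (`minpack.lm`, analytic Jacobian) over a
   deterministic multistart list (greedy, FFT-peak initialization, a
   near-DC variant carrying the curve's mean level — the model has no
   intercept — and seeded jitters), so exact-model curves still fit to
   machine precision.
4. **Canonicalization** maps the winner to the unique representative of its
   symmetry class; ties in the frequency sort are broken by amplitude.

Degenerate inputs are handled without errors: constant curves fall back to
padded low-frequency terms with a warning; a fit that never converges
returns the best parameters found with `converged = FALSE`. An optional
`init` argument lets a lower-order fit seed a larger one, which guarantees
(and a test asserts) that more terms never fit worse.

Coefficients are stored interleaved per term — `a1, b1, c1, …, a8, b8, c8`
— matching the canonical sort, and `b` is a per-nm angular frequency so
fingerprints are portable across grids.

## What the simulator does and does not emulate

Emulated: the multiplicative illumination/lamp structure, independent
additive readout noise, mass-fraction mixing ordered by purity, the
4×4-neighborhood averaging and white-reference calibration, per-class
subsampling, and the full feature/classifier/metrics chain. Not emulated:
pixel-to-pixel sensor heterogeneity and spatial texture of real honey
(fields are smooth), wavelength-dependent noise, filter bandwidth
(bands are ideal), scattering/fluorescence, chemical interactions between
honey and syrup beyond the two mixing laws, and acquisition drift between
the sample and white sweeps. Consequently classifier scores on synthetic
data describe the synthetic task; they are structurally, not numerically,
comparable to results on real honey.

## Problem sizes used

Unit and property tests run on cubes from \(4\times4\) to \(16\times16\)
pixels with 4–311 bands, seconds each. The full default pipeline — 6
combinations × 4 levels, \(64\times64\) cubes, 100 curves per class, all
three classifiers — runs in roughly 3 minutes on one CPU; the acceptance
surface runs it with the SVM alone. The reference acquisition geometry
(1200×1920 pixels) is supported by the data structures but not exercised in
tests.

## Known limitations

- The greedy/early-stop design trades a slightly larger (still ≪ 1%)
  residual for coefficient stability; applications needing the absolute
  minimum RMSE per curve can lower `early_stop` at the cost of noisier
  fingerprints.
- The ReLU network is full-batch and deterministic given its seed, but its
  L-BFGS path can differ across BLAS builds in borderline problems.
- TIFF persistence stores intensities as scaled 32-bit floats; round trips
  are exact only to single precision (~1e-7 relative).
- `derive_seed` is a simple multiplicative hash: distinct stage tags give
  distinct, reproducible streams, but no cryptographic independence claims.
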