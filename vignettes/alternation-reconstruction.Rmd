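---
title: "Alternation reconstruction for lens-free holographic microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alternation reconstruction for lens-free holographic microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holocell)
```

## The problem

In lens-free (lensless) in-line holography a bare sensor records the
diffraction pattern of a sample a millimetre or so above it; the image of
the sample — for cells in suspension, two real maps per pixel, the optical
path difference $L$ (µm) and the negative absorption coefficient $A$ — must
be recovered computationally. Two features make this inversion hard:

* **Phase loss.** The sensor records intensity only, so half the field
  information is missing (the origin of twin-image artefacts).
* **Phase wrapping.** The transmission
  $E(L, A) = \exp(2i\pi L/\lambda + A)$ is invariant under
  $L \to L + N\lambda$ for any integer $N$, so any data-driven
  reconstruction of $L$ is determined modulo $\lambda$ only. Suspended
  cells routinely accumulate OPDs of ~1 µm — several waves at
  $\lambda = 0.45$ µm (a phase shift of ~5$\pi$) — so wrapping is the rule,
  not the exception.

`holocell` implements a three-step *alternation* between a physics-based
variational solver and a learned unwrapper:

1. **First reconstruction** — conjugate-gradient minimization of a
   regularized criterion from a null initialization, with the coherent
   forward model and few (20) iterations. Accurate in data terms, wrapped
   in $L$.
2. **Network unwrapping** — a fully-convolutional network, trained purely
   on synthetic phantom pairs, maps the wrapped $(L, A)$ maps to an
   unwrapped prediction.
3. **Final reconstruction** — a longer (70-iteration) minimization
   initialized at the prediction, with the partial-coherence kernel and an
   OPD-domain regularizer. Because it only descends the criterion, network
   hallucinations that contradict the measured hologram are corrected.

## Forward model

The hologram intensity is modelled as

$$I(L, A) = B\,\bigl(\lvert E(L,A) * h_Z \rvert^2 * K\bigr),$$

with $h_Z(r) = \frac{1}{i\lambda Z}\exp(i\pi r^2/\lambda Z)$ the Fresnel
kernel over the sample–sensor distance $Z$, $K$ a convolution kernel
capturing the partial coherence of the LED source, and $B$ the uniform
background in grey levels.

**Propagation is spectral and exactly unitary.** `fresnel_propagate()`
multiplies by the analytic transfer function
$H(f) = \exp(-i\pi\lambda Z\lvert f\rvert^2)$ on the periodic FFT grid.
This makes energy conservation and $\pm Z$ inversion exact to round-off,
and makes back-propagation the exact adjoint of forward propagation — the
property the analytic gradient of the criterion relies on. We deliberately
do *not* zero-pad by default: at the reference geometry the diffracted
field spreads by hundreds of pixels, so any practical pad-and-crop scheme
loses energy many orders of magnitude above round-off and silently breaks
the adjoint identity. Users who prefer wrap-around suppression over exact
unitarity can set `pad_factor > 1`.

**Wrap invariance is engineered to be exact.** `transmission()` reduces
$L/\lambda$ modulo one before exponentiating, so $I(L + N\lambda, A)$ and
$I(L, A)$ agree bit-for-bit whenever $L + N\lambda$ is exactly
representable, and to ~$10^{-13}$ relative otherwise.

**The coherence kernel** can be obtained two ways. The physical route
(`coherence_kernel()`) simulates the hologram of a Dirac object — an opaque
point on the unit background; a bare delta field would propagate to a
structureless uniform intensity — once under coherent monochromatic
point-source illumination and once under the discretized extended source
(≤ 9 off-axis points whose tilts shift the pattern by the geometric
demagnification $Z/\text{source distance}$; the ring of 8 points sits at
$R/\sqrt{2}$, preserving the second moment of the uniform disc; 5 equally
weighted wavelengths span the spectral width). $K$ is the Wiener-floor
deconvolution of the two ring systems, computed on the mean-subtracted
images — the huge DC term would otherwise set the floor and drown the
structure — with unit DC gain restored, negatives and the residual floor
below 1% of the peak clipped, and the result normalized to unit sum. The
simulation dialect (`gaussian_kernel()`, FWHM 1.75 µm) is a cheap
controlled stand-in used by the synthetic pipeline.

## Inverse problem

Both reconstruction stages minimize

$$\epsilon(L, A) = \sum_{\text{pixels}}
  \frac{\bigl(I(L,A) - I_{meas}\bigr)^2}{\max(I_{meas}, 1)}
  + \alpha\,\zeta(L, A).$$

Stage 1 uses total variation on the *field* $E$ — blind to wavelength jumps
of $L$, so wrapping is tolerated rather than propagated — plus an OPD
sparsity term and a one-sided penalty $10A^2\,\mathbb{1}(A>0)$. Stage 2,
run after unwrapping, applies TV to $L$ itself, weights the sparsity term
by $1/5$, smooths $A$ through $\frac15(\Delta A)^2$, and adds
$L^2\,\mathbb{1}(L<0)$ to keep the unwrapped OPD positive. The printed
interior weights ($1/5$, $1/5$, $10$, $1$) are fixed; the global $\alpha$
is not stated anywhere, and is the one genuinely free constant.

**Choosing $\alpha$.** Balancing $\alpha\zeta$ (at the ground truth of a
reference-parameter phantom) against 10% of the initial fidelity gives
$\alpha \approx 37$, but that weight over-regularizes badly: the stage-1
recovery error on an isolated sub-wrapping cell degrades from 18% to 65%.
A 1% balance gives $\alpha \approx 3.7$; the default is `alpha = 4` for
both stages. With it, stage-1 sub-wrapping recovery lands within 20%, and
stage 2 initialized at the truth of a noise-free hologram stays within 5%
(measured: <1%) relative RMS. $\alpha$ is exposed in `solver_config()`.

**Numerical choices.** Non-smooth magnitudes are smoothed as
$\sqrt{x^2 + \varepsilon^2}$ with $\varepsilon = 10^{-3}$; the one-sided
penalties are exact piecewise quadratics ($C^1$, no smoothing needed).
Spatial derivatives are forward differences with replicate boundaries; the
Laplacian is the self-adjoint composite $-(D_x^\top D_x + D_y^\top D_y)$,
so its quadratic term has gradient $\frac{2}{5}\Delta(\Delta A)$ exactly.
The minimizer is Polak–Ribière+ nonlinear conjugate gradient with Armijo
backtracking (factor 0.5, $c_1 = 10^{-4}$, ≤ 20 trials), restarts every
$\min(n_{\text{pixels}}, 50)$ iterations or on a non-descent direction, a
steepest-descent fallback on line-search failure, and a trial-step cap of
0.2 µm per pixel per move. The gradient of the full chain (through $K$,
$\lvert\cdot\rvert^2$, $h_Z$ and $\exp$) is analytic — the adjoint of the
forward model — and the tests hold it to $10^{-4}$ against central
differences (it agrees to ~$10^{-8}$ in practice). Measured pixels below 1
grey level are floored in the $1/I_{meas}$ weight. Iteration 0 of the
logged history records the criterion at the initialization, so the descent
guarantee of step 3 ("final fidelity ≤ fidelity at the prediction") is
directly readable from the log.

The background $B$ is taken from the optics configuration; for measured
holograms where it is unknown, passing `background = NA` uses the median of
the measurement. Note the reference parameter table lists $B$ as
"105 ± 30%" grey levels; whether 105 lost a superscript ($10^5$) in
typesetting cannot be resolved from the text, so 105 is the default and the
value is fully configurable.

## Synthetic world

The generator (`sim_params()`, `sample_scene()`, `render_maps()`,
`simulate_hologram()`) emulates suspended cells as homogeneous spheres in
the projection approximation: a sphere of radius $r$ contributes its chord
$T = 2\sqrt{r^2 - d^2}$, thicknesses of overlapping spheres add, and

$$L = \sum_k T_k\,\Delta n_r^{(k)}, \qquad
  A = -\frac{2\pi}{\lambda}\sum_k T_k\,\Delta n_i^{(k)}.$$

Defaults are the stated reference conditions: 500–5000 cells per
1000×1000 image (179–1792 cells/mm² at 1.67 µm pitch), radii 5–20 µm,
$\Delta n_r \in [0.01, 0.05]$, $\Delta n_i \in [0, 0.005]$,
$Z = 1270\ \mu\text{m} \pm 5\%$ and $B = 105 \pm 30\%$ jittered per image,
$\lambda = 0.450 \pm 0.015$ µm, 50 µm source at 50 mm. Sensor noise is
Poisson with the predicted intensity as mean (grey levels read as counts);
no read-noise, no non-spherical cells, no motion blur. Cell centres are
uniform over the field and may straddle the border; overlaps are permitted
(the 2D projection is additive, so this is consistent by construction).
Surface densities are floored to integers, which reproduces the printed
500 → 179, 1001 → 358, 5000 → 1792 triplet; the same arithmetic gives 913
and 1638 cells/mm² for 2547 and 4569 cells, and the implementation follows
the arithmetic rather than any individually printed figure.

A green test on this world establishes that the pipeline inverts *its own
forward model* under shot noise — not that it reconstructs real
acquisitions, which additionally involve sensor nonidealities, focus/$Z$
uncertainty and non-spherical morphology.

## The unwrapping network

The full-scale architecture is 20 blocks of (5×5 convolution, 32 features →
batch normalization → ReLU) closed by a 5×5 convolution with 2 features,
same-padded throughout, so any image size passes through unchanged. The
training protocol is Adam at learning rate $10^{-4}$, 10 epochs of 12,800
random 121×121 vignette pairs cut from 1000 simulated image pairs — about
10 h of GPU-class compute, shipped as the optional script
`inst/scripts/full_scale_validation.R` and *not* exercised by the tests.
The test suite and the desk-scale demonstration use the reduced variant
(6 blocks, 16 features) trained for a few minutes on CPU.

No deep-learning framework is available to this package, so the network is
self-contained: im2col + GEMM convolutions in compiled code, batch
normalization and Adam in R. Design points the source does not fix, decided
here: the regression loss is mean-squared error equally weighted over the
two channels; channels are normalized per-channel ($L$ by $\lambda$, so a
one-wave jump has unit magnitude; $A$ by 1); padding is zero-padding;
batch size 32 (8 in the reduced protocol); inference uses running
batch-norm statistics frozen at training end. The model stores its training
$Z$: the unwrapper is distance-specific, and `run_alternation()` refuses a
hologram whose $Z$ differs from it by more than 5% (the simulation's own
$Z$-jitter band) rather than silently extrapolating.

The "two sets of vignettes" of the original protocol is read as a
train/validation split; `train_unwrapper()` accepts an optional held-out
set and logs its loss per epoch.

## Evaluation

Per-cell refractive-index contrasts are recovered by integrating the maps
over each cell's known disc (pixel-centre membership, pixel-area
weighting) and dividing by the sphere volume:

$$\Delta n_{r}^{(k)} = \frac{1}{V^{(k)}}\int_{S^{(k)}} L, \qquad
  \Delta n_{i}^{(k)} = -\frac{\lambda}{2\pi V^{(k)}}\int_{S^{(k)}} A,$$

which on ground-truth maps is exact up to pixelization (the chord integral
over the disc *is* the sphere volume); the tests hold the discretization
error under 2% for radii ≥ 5 µm at 1.67 µm pitch. Reconstructed-vs-true
scatter is summarized by ordinary least squares with intercept (slope,
$R^2$). PSNR is reported on the $L$ channel with `data_range = max(truth)`
by default (the source states neither range nor channel; both are
arguments), and an exact match returns a 120 dB sentinel rather than
infinity. No cell detection is performed: evaluation uses the known phantom
geometry by design.

Desk-scale conversions: `surface_density()` (count/area, floored),
`phase_shift_in_pi()` ($2L/\lambda$), and `surface_to_volumetric()`
(cells/mm² divided by chamber thickness in µm is numerically
$10^6$ cells/ml).

## Known limitations

* Scalar, paraxial, single-plane model: no high-NA/vectorial diffraction,
  no multiple scattering, no 3D objects, no autofocus or $Z$ search.
* The fidelity's pixel-count normalization is absorbed into $\alpha$; if
  you change the grid size drastically, revisit `alpha`.
* The physically derived coherence kernel depends on a discretization
  (9 source points, 5 wavelengths) that is stated as a count, not derived;
  widths are accurate to the few-percent level, not spectroscopic.
* Reduced-network results demonstrate the *logic* of the three-step
  alternation (wrapping, unwrapping, data-fidelity repair); the full-scale
  quantitative slopes require the optional full training protocol.
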