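---
title: "Models and methods behind histopam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind histopam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`histopam` is a desk-scale computational counterpart to an image-guided,
robot-positioned histotripsy workflow for venous clot ablation. The physical
system translates a 1.5 MHz elliptic focused source along a treatment path
under B-mode guidance, monitors bubble-cloud activity with passive acoustic
mapping through a coaxial linear array, and grades the outcome with
segmentation-overlap metrics. This package implements the computational
machinery — field prediction, beamforming, planning, and metrics — and a
synthetic-data generator that supplies every input with known ground truth,
so the whole chain can be validated in closed loop.

## Linear focal-field model

The therapy source is modeled as a spherically focused shell of 6 cm radius
of curvature whose outline projects to a 9 cm x 7 cm ellipse, with a central
rectangular cutout holding the imaging array. At low (linear) drive the
focal field is computed by Rayleigh–Sommerfeld summation: the shell is
sampled on a regular grid with pitch at most $\lambda/4$ (about 0.25 mm at
1.5 MHz in 37 °C water, $c = 1524$ m/s, $\rho = 993$ kg/m³), and the
relative pressure magnitude at a field point $\mathbf{r}$ is

$$ |p(\mathbf{r})| \;\propto\; \Bigl|\sum_j \Delta A_j\,
   \frac{e^{i k R_j}}{R_j}\Bigr|, \qquad R_j = \lVert \mathbf{r} -
   \mathbf{r}_j \rVert . $$

Element areas $\Delta A_j$ are true cap areas (planar cell area times the
local slope factor $F/\sqrt{F^2-\rho^2}$); with this convention the on-axis
sum converges to the exact closed-form solution for a focused circular
radiator (O'Neil 1949), which serves as the model's analytic oracle — the
package reproduces it to well under 1% of the focal peak across 0.5–1.5
focal lengths. The eight sector elements of the physical source are driven
in parallel and are therefore modeled as one uniform aperture; nonlinear
propagation is out of scope because the characterization itself is a
linear-drive measurement.

Two geometric details are genuinely open and were fixed once as package
defaults:

* **Central window.** The array housing dimensions are not documented, so
  the cutout defaults to 40 mm x 14 mm. Orientation follows the axis
  convention below: a linear array's long (lateral) axis lies along its
  imaging azimuth, so the 40 mm side runs along the 9 cm aperture axis.
  Numerically the two orientations give nearly identical widths, so this
  choice is geometric, not tuned. The window mainly lengthens the axial
  lobe (4.45 mm without a window, 4.76 mm with it), which is what brings
  the model in line with the instrument characterization.
* **Axis naming.** The −6 dB width triplet is reported as (azimuth,
  elevation, range), with azimuth along the 9 cm axis. The larger aperture
  focuses more tightly, so the azimuth width is the narrower lateral one.

At the default sampling the model yields −6 dB widths of 0.87 x 1.14 x
4.76 mm against the instrument's characterized 0.9 x 1.1 x 4.8 mm, and the
widths move by less than 2% when the sampling density doubles.

The predicted ablation footprint scales the linear field so its maximum is
the calibrated 35 MPa peak negative pressure and thresholds the
azimuth–range plane at 27.4 MPa, the cavitation-cloud threshold for agarose
phantoms. The supra-threshold region is summarized by its extents through
the peak (computed with the same sub-grid crossing interpolation as the
widths); the simulated extents are 2.89 mm along range by 0.54 mm in
azimuth, versus the 3.4 x 0.5 mm ellipse used by the physical planning GUI.
The range extent is the sensitive one: it depends on the exact axial lobe
shape, hence on the undocumented window, and a 15% shortfall is within
what that uncertainty produces.

## Passive acoustic mapping

Receive-only RF channel data are mapped to relative acoustic power with the
robust Capon beamformer. Per pixel $\mathbf{r}$:

1. each channel is advanced by $(d_n - \min_m d_m)/c$ (windowed-sinc
   fractional delay, 32 taps) so a wavefront from $\mathbf{r}$ aligns
   across channels;
2. the time-domain correlation matrix
   $R_{nm} = \int_0^{T_H} s_n(t)\, s_m(t)\, dt$ is formed over the full
   record (broadband emissions are handled in the time domain, matching
   the integral literally, rather than per frequency bin);
3. with eigendecomposition $R = U V U^\top$ and nominal (post-steering)
   steering vector $\bar{a} = \mathbf{1}$, the data-adaptive vector is the
   robust Capon solution
   $\hat{a} = \bar{a} - (I + \lambda R)^{-1}\bar{a}$, where the Lagrange
   multiplier $\lambda > 0$ solves the monotone constraint
   $\sum_i z_i^2/(1+\lambda v_i)^2 = \varepsilon$, $z = U^\top \bar{a}$
   (bisection after bracket expansion);
4. the pixel power is
   $$ P(\mathbf{r}) = \frac{4\pi \bar{d}^{\,2}}{T_H\, \rho c}\,
      \Bigl[\sum_i \frac{\lambda^2 v_i z_i^2}{(1+\lambda v_i)^2}
      \Bigr]^{-1}, $$
   where the bracketed sum is exactly $\hat{a}^\top R^{-1} \hat{a}$.

Notes on choices that the literature leaves open here:

* The spreading prefactor uses the mean pixel–element distance squared
  (energy-conserving spherical spreading); a `range_exponent` switch allows
  the linear alternative. Map *shape* — everything the accuracy metrics
  consume — is unaffected.
* The uncertainty bound defaults to $\varepsilon = 0.1 N$; it is exposed in
  `rcb_params()`. As $\varepsilon \to 0$ the estimator reduces to the
  standard Capon power $1/(\bar{a}^\top R^{-1} \bar{a})$, which the tests
  verify against dense matrix inversion; a brute-force constrained
  optimizer over the uncertainty sphere is the oracle for finite
  $\varepsilon$.
* Diagonal loading of $10^{-6}\,\mathrm{tr}(R)/N$ guarantees a positive
  spectrum before eigendecomposition.
* "Within 1 dB of the peak emission level" is interpreted on the
  acoustic-power scale ($P \ge P_\mathrm{peak}\,10^{-1/10}$), since the
  mapped quantity is a power; an amplitude convention is available and
  yields a smaller region.
* A conventional delay-sum-square beamformer is provided as a cross-check;
  it must (and does, in tests) agree with the robust Capon map on the
  azimuth of a strong source.

Passive maps are diffraction-limited in range: a point emitter reconstructs
as a range-elongated, slightly range-biased blob (about 0.6 mm of centroid
bias at the default demo geometry), while azimuth localization is good to a
fraction of a grid step. This asymmetry mirrors the physical system, where
the emission centroid was likewise the trusted statistic and range spread
was treated with caution.

## Planning

Waypoints are interpolated piecewise-linearly and re-parameterized by arc
length with stops every 0.5 mm; the final waypoint is always a stop so the
treated extent equals the planned extent (a 1 cm vessel path yields 21
stops). Higher-order splines are unconstrained by waypoints placed ~5 mm
apart on a near-straight vessel, so the linear scheme is the default and
only one. Area treatments are covered hexagonally: a triangular lattice at
0.5 mm pitch, anchored at the region centroid with rows parallel to the
azimuth axis, clipped boundary-inclusively to the region. Plans carry pulse
bookkeeping only (500 pulses per stop at 40 Hz with every 10th pulse
imaged for clots; 200 single-cycle pulses for phantoms) — there is no
hardware control in this package.

## Segmentation and accuracy metrics

Lumen, liquefaction and (optionally) clot regions are segmented by Otsu's
threshold over a 256-bin histogram of range-normalized intensities
(invariant to increasing affine rescaling), followed by hole filling,
speck removal (< 5 px) and largest-component selection. The clot, which the
physical workflow segmented manually, is handled by restricting the Otsu
histogram to the lumen interior (`segment_within()`); a manual mask can be
supplied through the PNG + JSON mask container instead.

Metrics operate on pixel-center world coordinates in mm: unweighted region
centroids; targeting error as focus–centroid distance; Dice
$2|A\cap B|/(|A|+|B|)$ on identical geometry; Hausdorff distance with the
directed form $\max_{a\in A}\min_{b\in B} d(a,b)$ as default (exactly the
printed definition) and a symmetric mode because prose descriptions of
"maximum distance between" regions are ambiguous. Distances are computed
exactly (chunked pairwise), not via pixel-unit distance transforms, so
anisotropic spacings are handled correctly. Fiducial co-registration is the
closed-form least-squares rigid (optionally similarity) transform via SVD;
masks are resampled through recovered transforms by nearest neighbour to
stay binary.

## Synthetic data: what it emulates, and what it does not

* `simulate_emissions()` models bubble-cloud acoustic emissions as point
  sources radiating a Gaussian-windowed 3 MHz sinusoid with 100%
  fractional bandwidth (broadband, as cavitation emissions are; the true
  emission spectrum is uncharacterized), received with $1/R$ amplitude
  spreading plus white Gaussian noise at a stated SNR. There is no bubble
  dynamics, no nonlinear propagation, no attenuation.
* `make_vessel_image()` produces an intensity-level B-mode lookalike of the
  latex model vessel (6.35 mm inner diameter, 0.79 mm wall) with an
  optional ~2 mm clot, under multiplicative log-normal speckle. It is not
  an RF-level speckle simulation; downstream operations consume intensity
  only.
* `make_liquefaction_truth()` builds the "actual" ablation mask as the
  union of per-stop footprint ellipses with seeded Gaussian centre jitter
  (0.3 mm default, between the 0.03 mm positioner repeatability and the
  ±0.5 mm registration precision of the physical setup) and one pixel of
  boundary erosion to mimic the under-treatment that slight elevational
  misalignment of a thin target layer produces. Erosion is a morphological
  stand-in, not a physics model.

Because the generators share their geometry with the analysis chain,
passing closed-loop tests demonstrates internal consistency — the pipeline
recovers exactly what was planted (Dice 1, Hausdorff 0, targeting error
below a grid step at zero noise) — and realistic-regime behaviour under
default noise. They do not demonstrate robustness to real tissue clutter,
reverberation, aberration or respiratory motion.

## Desk-scale experiment drivers

`run_clot_assessment()` mirrors the clot-targeting study: a 1 cm path at
0.5 mm steps (21 stops), 50 passive frames per stop averaged pixel-wise,
emission centroid versus clot centre, and Dice of the 1 dB region against
clot and lumen cross-sections, plus a B-mode lumen-tracking stage with a
0.45 mm per-axis operator placement jitter (chosen so the tracking-error
regime matches the physical study's 0.5–0.6 mm). To keep a full run at
around a minute on one core, the demo default decimates the receive
aperture to 32 elements at 1.2 mm pitch, uses a 0.5 x 1 mm map grid over
±4 x 54–66 mm, and records 16 µs windows; the localization tests run the
full 128-element array on the default 0.2 x 0.5 mm grid. With zero noise
and zero jitter, identical frames are computed once and the averaging
bookkeeping retained.

`run_phantom_assessment()` mirrors the ablation-accuracy study: hexagonal
packing of a 2.5 mm-radius region, predicted mask as the union of
footprint ellipses, synthetic liquefaction outcome in a rigidly
misregistered photo frame (2°, (0.8, −0.5) mm by default), fiducial-based
recovery of the registration, then Dice and Hausdorff. The default
footprint block is the instrument characterization (3.4 x 0.5 mm);
`compute_footprint = TRUE` derives it from the field model at the cost of
roughly a minute.

Reports are plain JSON + CSV with a configuration hash, and re-running a
config is byte-identical.

## Numerical choices and degenerate inputs

* Width/extent measurements interpolate threshold crossings linearly
  between grid nodes; a lobe clipped by the grid raises a
  `widths-unresolved` error rather than returning a truncated width.
* A footprint threshold above the drive peak returns an explicitly empty
  footprint; a threshold at the peak collapses to the peak pixel(s).
* Zero-energy correlation matrices yield zero power without division; a
  Lagrange bracket that cannot be expanded raises a numeric-failure error
  carrying the spectrum.
* Steering delays longer than the record raise a truncation error; the
  generators warn when an arrival falls beyond the record.
* Empty masks are errors for centroids, Dice (both empty) and Hausdorff;
  Dice with one empty operand is 0.
* Duplicate consecutive waypoints collapse with a warning; a region
  smaller than one lattice cell packs to its centroid.

## Known limitations

The field model is linear and continuous-wave; shocked waveforms,
cavitation physics and tissue attenuation are out of scope. The passive
maps use time-domain broadband correlation only; narrowband per-bin
processing and advanced PAM beamformers are not implemented. B-mode
content is synthetic at the intensity level, so image-quality effects
(clutter, shadowing) on segmentation are not represented. All accuracy
metrics are two-dimensional, matching the in-plane analysis they
reproduce.
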