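# histopam

Desk-scale computational pipeline for assessing the targeting accuracy of
image-guided, robot-positioned **histotripsy** — focused-ultrasound ablation
that destroys tissue mechanically through cavitation bubble clouds. Treating
an extended target such as a venous clot requires translating the focus
along a planned path; the open questions are whether the planned path tracks
the vessel, whether bubble activity lands where it was aimed, and how close
the ablated region comes to the predicted one. `histopam` implements the
computational machinery behind those questions for scientists working on
cavitation monitoring and treatment planning:

* **Focal-field model** — linear Rayleigh–Sommerfeld simulation of an
  elliptic focused source (9 x 7 cm aperture, 6 cm focal length, 1.5 MHz)
  with a central imaging-array window; −6 dB focal widths and the predicted
  cavitation footprint (field scaled to a 35 MPa focal peak, thresholded at
  the 27.4 MPa agarose cloud threshold).
* **Passive acoustic mapping** — robust Capon beamforming of receive-only RF
  channel data. Per map pixel $\vec r$, with steered-channel correlation
  matrix $R = UVU^\top$ and nominal steering vector $\bar a = \mathbf 1$:

  $$P_{RCB}(\vec r) = \frac{4\pi \bar d^{\,2}}{T_H\,\rho c}
    \left[\hat a^\top R^{-1} \hat a\right]^{-1},\qquad
    \hat a = \bar a - (I+\lambda R)^{-1}\bar a,$$

  where $\lambda$ solves $\lVert\hat a - \bar a\rVert^2 = \varepsilon$.
  Frame averaging, emission centroid and the region within 1 dB of the peak
  emission level; a delay-and-sum baseline for cross-checks.
* **Path planning** — arc-length interpolation of waypoints at 0.5 mm stops;
  hexagonal packing of a drawn region at 0.5 mm pitch.
* **Accuracy metrics** — Otsu segmentation, centroid targeting error, Dice
  coefficient $2|A\cap B|/(|A|+|B|)$, directed/symmetric Hausdorff distance,
  and fiducial-based rigid co-registration.
* **Synthetic data** — seeded generators for emitter channel data, vessel /
  clot phantom images and liquefaction masks with known ground truth, so the
  full chain is testable in closed loop.

## Worked example

The two experiment drivers reproduce the study designs end-to-end on
synthetic inputs:

```r
library(histopam)

run_clot_assessment(clot_config(seed = 17))
#> <assessment_report: clot> seed 17
#>   stops 21, frames/stop 50 (total 1050)
#>   targeting 0.76 +/- 0.24 mm; tracking 0.52 +/- 0.28 mm
#>   Dice vs clot 26.6%, vs lumen 13.6%

run_phantom_assessment(phantom_config(seed = 17))
#> <assessment_report: phantom> seed 17
#>   stops 91; Dice 89.8%; Hausdorff 0.42 mm (sym 0.57)
```

Reading the clot report: a 1 cm path along the model vessel is treated in
0.5 mm increments (21 stops, 50 passive frames each). *Tracking* is the
distance between the planned focus and the Otsu-segmented lumen centroid at
each stop — 0.52 ± 0.28 mm here, i.e. sub-millimetre path following under
the default 0.45 mm operator placement jitter. *Targeting* is the distance
between the frame-averaged emission centroid of the robust-Capon maps and
the clot centre — 0.76 ± 0.24 mm, dominated by the placement jitter plus
the range bias inherent to diffraction-limited passive maps. The Dice rows
quantify how much of the 1-dB emission region overlaps the clot and lumen
cross-sections on the map grid. The phantom report compares the predicted
liquefaction mask (union of per-stop footprint ellipses) with a synthetic
outcome observed in a misregistered photo frame after fiducial
registration: Dice 89.8% and a worst-case (Hausdorff) boundary distance of
0.42 mm. With noise, jitter and misregistration all set to zero both
drivers recover their ground truth exactly (Dice 1, Hausdorff 0).

The field model itself:

```r
fc <- run_field_characterization(points_per_wavelength = 4)
fc$widths
#> <focal_widths> azimuth 0.87, elevation 1.14, range 4.76 mm
fc$footprint$ellipse
#> <footprint_ellipse> 2.89 x 0.54 mm
```

— the simulated −6 dB focal widths sit within a few percent of the
instrument's characterized 1.1 x 0.9 x 4.8 mm (azimuth along the larger,
more tightly focusing 9 cm aperture axis), and the supra-threshold
footprint approximates the 3.4 x 0.5 mm planning ellipse.

A thin CLI wrapping the same functions ships in `inst/exec/histopam`
(`histopam field`, `histopam demo clot|phantom`, `histopam plan`,
`histopam pam`).

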