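---
title: "Methods: single-fibril bowstring mechanics and post-rupture structural analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-fibril bowstring mechanics and post-rupture structural analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrilmech)
```

## Overview

`fibrilmech` implements the complete computational workflow of a
structure–function study at the single collagen fibril level: an AFM tip pulls
a surface-anchored fibril to failure in bowstring geometry while the lateral
force (500 Hz) and a video of the midpoint deflection (20 fps) are recorded;
the broken fibril is then characterized by AFM topography, polarization-
resolved second-harmonic-generation (SHG) microscopy, and fluorescence after
staining with a collagen hybridizing peptide (CHP) that binds denatured
chains. Because raw instrument data of this kind are bulky and
instrument-specific, the package pairs every analysis stage with a seeded
synthetic generator that emulates the same statistical structure with known
ground truth, so each stage is validated by parameter recovery and closed-form
oracles rather than by eye.

## Cantilever lateral calibration

Board-shaped tensile-testing cantilevers are calibrated vertically (thermal
noise for $K_z$, hard-substrate ramp for $S_z$); the lateral quantities follow
from the geometry:

$$K_L = \frac{2 L^2 K_z}{3 (1+\nu) H^2}, \qquad S_L = \frac{3 H S_z}{2 L},$$

with $L$ the lever length, $H$ the tip height measured from the torsion axis,
and $\nu$ the Poisson ratio of the lever material (default 0.27, silicon
\<111\>; exposed as a parameter). Lateral force is $F = K_L S_L V$, reported
in µN. Both formulas are dimensionally homogeneous in $(L, H)$, which the test
suite exercises by unit-rescaling. Since a typical spec sheet does not list
$L$ and $H$ for each lever, the ~3800 N/m stiffness typical of these tests is
treated as a plausibility check, not a reproducible constant.

## Bowstring mechanics

A fibril segment of anchored length $L_0$ pulled laterally at its midpoint by
$d$ forms two straight arms, giving the engineering strain and the
force–tension relation

$$\varepsilon = \frac{2\sqrt{(L_0/2)^2 + d^2} - L_0}{L_0}, \qquad
  T = \frac{F\sqrt{(L_0/2)^2 + d^2}}{2d}.$$

Stress is tension over the *dry* cross-sectional area (µN/µm² = MPa). The
processing chain in `analyze_pull()` is:

1. **Rupture detection** — the largest single-sample drop in the force trace,
   accepted if it exceeds 5× the standard deviation of the post-drop window
   (threshold exposed; the event is qualitatively unmistakable, a sudden fall
   to the friction background).
2. **Background subtraction** — the tip–glass friction appears as a constant
   noisy level; its mean over the post-rupture window is subtracted from the
   whole trace.
3. **Smoothing** — 5-point centered adjacent averaging with shrinking edge
   windows. We subtract first and smooth second, and we smooth only the
   pre-rupture segment: averaging across the rupture step would mix
   post-rupture background into the last pre-rupture samples and bias the
   rupture stress downward.
4. **Synchronization** — the video time axis is shifted so the last frame with
   the fibril present coincides with the last force sample before the drop;
   midpoint deflection is linearly interpolated onto the force timestamps.
   The residual alignment error is below one frame (50 ms, i.e. 0.05 µm at
   the 1 µm/s pull speed), which bounds the rupture-strain error.
5. **Full-tension onset** — before the bowstring is taut the probe force is a
   mix of bending and friction. The onset is located as the breakpoint of a
   two-segment fit (constant, then line) to the force–deflection record,
   minimizing total residual sum of squares; a manual (video-derived) index
   can be passed instead. Points before onset are discarded, which is why
   curves begin at a few percent strain rather than zero.
6. **Summary** — rupture strain/stress from the last retained point;
   toughness as the trapezoidal integral of the curve plus a linear
   extrapolation of the initial data to 0 % strain (slope from the first 2 %
   strain of retained data, least squares; a negative extrapolated intercept
   is clamped at its zero crossing); high-strain modulus and its standard
   error from a least-squares line over the final 10 % strain before rupture.
   With stress in MPa and strain as a fraction, toughness is in MJ/m³.

Two physical side-calculations support interpretation. The bending force
before full tension is bounded with a centrally loaded beam with both ends
fixed (the ends are glued): $F = 192 E I d / L_0^3$, $I = \pi r^4/4$; with a
0.17 GPa bending modulus, 100 nm radius, 50 µm segment and 5 µm deflection
this gives ≈0.1 nN, negligible against µN-scale tensile forces. A simply
supported variant ($48EId/L_0^3$) is provided for comparison. Second, since
fibril radius roughly doubles on hydration, dry-basis stresses can be mapped
to a hydrated-area basis by dividing by the squared swelling factor (≈4).

## AFM morphometry

Height maps (8 nm pixels by default) are levelled by a least-squares plane
fitted to off-fibril pixels (background estimated from the outermost rows,
with the thresholded footprint dilated so low flanks stay out of the fit).
The centerline is traced by ridge following — per-column height-weighted
centroid around the column maximum, smoothed — with pixel-center coordinates
and arc length in nm.

* **Cross-sectional area**: cross-profiles over a straight 500 nm segment
  (≥62 scanlines at 8 nm pixels) are re-centred on the centerline, averaged,
  and integrated trapezoidally. On synthetic half-cylinders the estimate
  converges to $\pi r^2/2$ as pixels shrink. No tip-deconvolution is applied,
  so real areas are slight overestimates by design.
* **D-band period**: the centerline height signal is mean-removed,
  Hann-windowed, zero-padded, and the periodogram peak (searched between 30
  and 150 nm) is refined by parabolic interpolation on log power. The axial
  coordinate is taken from a strongly low-passed copy of the traced path:
  raw tracing wiggle inflates arc length and would bias the period upward by
  1–2 %. A period is only reported when the peak exceeds 10× the median
  in-band power, otherwise "no periodicity detected".
* **Kinks**: the damage sites of a ruptured fibril appear as sharp centerline
  bends. Tangent directions are estimated by least squares over trailing and
  leading 200 nm windows; positions where the direction change exceeds 20°
  are marked, with non-maximum suppression within one window. The study this
  emulates marked kinks by hand and gives no numeric criterion; 20°/200 nm
  are explicit stand-ins chosen to separate the generator's 30° bends from
  tracing noise, and both are parameters. Undamaged segments are the
  intervals between consecutive damage sites longer than one window; we also
  include the two end intervals, since the glued ends bound loadable,
  undamaged material.
* **Height loss**: mean centerline height before rupture, minus after, also
  as a percentage.

## SHG polarimetry

For a fibril lying along angle $\varphi$ in the image plane, with excitation
polarization $\alpha$, cylindrical symmetry and Kleinman symmetry leave two
independent susceptibility components whose ratio
$\rho = \chi^{(2)}_{xxx}/\chi^{(2)}_{xyy}$ controls the polarization response:

$$I_{2\omega} \propto \left[\rho\cos^2(\varphi-\alpha) +
  \sin^2(\varphi-\alpha)\right]^2 + \sin^2\!\big(2(\varphi-\alpha)\big).$$

This expands exactly into three harmonics,
$I \propto a_0 + a_2\cos 2(\varphi-\alpha) + a_4\cos 4(\varphi-\alpha)$, with
(at unit amplitude) $a_0+a_2+a_4 = \rho^2$ and $a_0-a_2+a_4 = 1$. Stacks are
acquired at 25 polarizations, 0–240° in 10° steps; both the maximum-intensity
projection and the harmonic analysis use **exactly the first 18 images**
(0–170°): they span one exact 180° period, so the discrete projections at
harmonics 1 and 2 are leakage-free, and images 19–25 are redundant re-samples
kept only as checks. Per pixel, `fourier_coeffs()` computes
$a_0 = \bar I$, $z_1 = \tfrac2N\sum I_k e^{2i\alpha_k} = a_2 e^{2i\varphi}$,
$z_2 = \tfrac2N\sum I_k e^{4i\alpha_k} = a_4 e^{4i\varphi}$, and the
anisotropy follows as

$$\rho = \sqrt{\frac{a_0 + a_2 + a_4}{a_0 - a_2 + a_4}}.$$

Two numerical choices deserve note. First, the square root: the ratio
$(a_0+a_2+a_4)/(a_0-a_2+a_4)$ equals $\rho^2$, not $\rho$, for any trace
generated by the intensity law, so the root is required for exact inversion;
this is consistent with the FFT-based extraction literature the approach
derives from. Second, the truncated three-term cosine model alone cannot
distinguish $(a_2, \varphi)$ from $(-a_2, \varphi+90^\circ)$ — but the full
law can, because the two candidates imply different $a_4$; the implementation
scores both candidates against the observed $a_4$ and keeps the consistent
one. At $\rho = 1$ the $2\theta$ harmonic vanishes and $\varphi$ is only
defined modulo 90°, which is a property of the physics, not of the estimator.
Pixels where either coefficient combination is non-positive have no physical
solution and are marked undefined rather than clipped. $\rho$ is a ratio, so
no trace normalization is needed and the estimate is invariant to intensity
scaling and to a common rotation of $\varphi$ and the polarization axis.

Cohort statistics mirror the deposition schema: the distribution of defined
$\rho$ values is histogrammed at bin width 0.05 (the source work states no
binning; 0.05 resolves the FWHM of realistic distributions without starving
bins), the modal bin is refined by a three-point parabola, and the FWHM is
read off by linear interpolation of the half-maximum crossings. The
ruptured/control intensity ratio is the mean of the max-intensity map over
the ruptured-fibril mask divided by the control mask mean, with masks from a
background-mean + 3 sd threshold on the border-estimated background.

## Fluorescence call

The CHP positivity call in the source data was visual. The package uses an
explicit stand-in: positive when the fibril-mask mean exceeds the background
mean by more than $k$ background standard deviations ($k = 3$ default), with
the margin reported in background-sd units so the call is scale-invariant.
Laser power is carried as metadata and never used for normalization (the
deposited images are raw). The fibril mask comes from thresholding the
brightfield silhouette and dilating.

## The synthetic generator: what it does and does not emulate

The generator is the package's stand-in for the deposited raw data; its
defaults are the study conditions, chosen once:

| parameter | default | basis |
|---|---|---|
| dry radius | 100 nm | typical fibril radius in this preparation |
| segment length | 50 µm | typical prepared segment |
| D-band period / depth | 67 nm / 4 nm p-p | conserved collagen banding; depth is a minimal-model choice |
| anisotropy $\rho$ | 1.5 | mid-range for fibrillar collagen |
| constitutive law | linear, 500 MPa | matches the few-hundred-MPa dry moduli of these tests |
| rupture strain | 20 % | typical of single-fibril pulls |
| slack deflection | 5 µm | typical bending deflection before full tension |
| rates | 500 Hz / 20 fps / 1 µm/s | acquisition protocol |
| friction | 1 µN mean, 0.05 µN sd | friction appears as a constant noisy level; SNR is unreported, so these are exposed parameters |

Pol-stacks evaluate the intensity law exactly (so noiseless closure is
machine-precision) with optional Poisson shot noise — the natural model for
photon counting; the source states no noise model. Height maps render a
half-cylinder (adsorbed fibril) with multiplicative sinusoidal banding and a
centerline that bends by a fixed angle at each kink; tip convolution is
deliberately not simulated. Pull experiments ramp the tip at constant speed,
engage the fibril once the slack deflection is taken up, and zero the fibril
term between two adjacent force samples at the rupture strain, matching the
frame-to-frame suddenness of real ruptures. Rupture is ideal (no partial
strand failure), the substrate is flat, friction is white about a constant
level (an optional drift is not enabled by default), and video deflection is
noise-free — so passing recovery tests demonstrates correctness of the
estimators under the stated model, not robustness to every instrumental
artifact of real AFM video data. The deflection extraction from video frames
itself is out of scope: the analysis takes a deflection trace as input.

All generators draw from a single explicit seed per call and are
bit-reproducible.

## Problem sizes and tolerances used in validation

The shipped checks use deliberately desk-scale problems: 5 µm banded segments
(≥20 seeds) for the D-band estimator, 2 µm segments for area convergence
(16/8/4 nm pixels), 50 µm noiseless pulls for mechanics closure, 18-angle
stacks on small rasters (closure to 1e−10; shot-noise Monte Carlo at
10²–10⁴ expected counts), and 10⁴-pixel Gaussian fields for the distribution
statistics (peak within 0.02, FWHM within 0.02 of $2\sqrt{2\ln 2}\,\sigma$).
Mechanics recovery is held to one video-frame strain step for rupture strain
and 1 % relative for stress, toughness and modulus; the D-band estimate to
±2 nm at SNR 5. Per-fibril results of the original biological dataset are
not reproducible without its raw data; for those paths the package's
guarantees are the schema-exact round trips plus the recovery properties
above.

## Known limitations

* Strain is underestimated near the anchors (stress localization at glue and
  tip) and no correction is attempted, matching the source method.
* True (hydrated, instantaneous-area) stresses are not computed; only the
  dry-area basis and the ÷4 hydrated approximation.
* The centerline tracer assumes a mostly axial fibril (heading below 45°);
  the generator enforces the same bound.
* `rho_distribution()` requires ≥50 defined pixels; FWHM falls back to the
  bin width for effectively constant distributions.
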