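---
title: "Lamb-wave OCE analysis: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lamb-wave OCE analysis: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(arfoce)
```

## The measurement problem

Acoustic-radiation-force optical coherence elastography (ARF-OCE) launches a
guided elastic wave in a thin tissue layer with a focused-ultrasound push and
tracks the wave interferometrically with phase-sensitive OCT. The optic nerve
head (ONH) is, mechanically, a soft plate a few hundred micrometres thick
bounded by fluid on both faces, so the wave that propagates is the zero-order
antisymmetric (A0) Lamb mode: strongly dispersive at low frequency, with
phase velocity bounded above by the shear speed. Measuring the phase-velocity
dispersion and inverting a plate model yields Young's modulus — the quantity
that changes with intraocular pressure.

`arfoce` implements the full analysis: phase-resolved Doppler displacement
estimation, spatio-temporal mapping, two-dimensional Fourier (k-space)
dispersion estimation, local velocity mapping, and modulus inversion —
together with a synthetic M-B scan simulator with known mechanics, so every
stage can be validated end to end without instrument data.

## Doppler displacement model

The OCT signal at A-line $m$ is a complex field $F_m$. The inter-A-line
Doppler phase is
$$\Delta\varphi_m = \operatorname{atan2}\!\big(\mathrm{Im}(F_m F_{m+1}^*),\,
\mathrm{Re}(F_m F_{m+1}^*)\big) \in (-\pi,\pi],$$
and the axial displacement increment follows the linear map
$$\Delta d = \frac{\lambda_0}{4\pi n}\,\Delta\varphi,$$
with $\lambda_0$ the centre wavelength (default 1300 nm) and $n$ the tissue
refractive index. The instrument never states $n$ for ONH tissue; the package
default is 1.38, a conventional soft-tissue value, and it is overridable
everywhere it enters.

**Sign convention.** The simulator encodes motion so that a positive
$\Delta d$ means motion toward the beam source; the convention is fixed by
computing the Doppler product as $F_m F_{m+1}^*$ and is consistent end to end
between simulator and estimator. One radian of Doppler phase corresponds to
75.0 nm at the defaults.

Temporal phase unwrapping (`unwrap_temporal()`) is available for large
displacements, but at the default push amplitude (150 nm peak) the
*inter-A-line* increments stay far below the $\lambda_0/(8n) \approx 118$ nm
wrap guard — it is the frame-to-frame increment, not the absolute
displacement, that must stay small.

## The A0 dispersion relation and its inversion

For an incompressible elastic plate of half thickness $h$, shear modulus
$\mu$ and density $\rho$, immersed in an incompressible fluid of equal
density, the antisymmetric characteristic equation is
$$4 k_L^3 \beta \cosh(k_L h)\sinh(\beta h)
  - (k_S^2 - 2k_L^2)^2 \sinh(k_L h)\cosh(\beta h)
  = k_S^4 \cosh(k_L h)\cosh(\beta h),$$
with $k_L = \omega/c$, $k_S = \omega/V_S$, $V_S = \sqrt{\mu/\rho}$ and
$\beta = \sqrt{k_L^2 - k_S^2}$. Numerically the residual is evaluated after
dividing both sides by $\cosh(k_L h)\cosh(\beta h)$ (a tanh form), which has
the same roots and cannot overflow at large $f h$. The A0 root is found by
bracketed Brent iteration on $(0.01, 0.99)\,V_S$ with a $10^{-4}$ m/s
tolerance: deterministic, no starting-guess sensitivity, and an explicit
error (never extrapolation) if the bracket holds no sign change.

In the thin-plate (low $f h$) limit the root approaches the closed form
$$V_{L,\mathrm{vac}} = \sqrt{\tfrac{2\pi f H V_S}{\sqrt 3}}, \qquad
  V_L = V_{L,\mathrm{vac}}/\sqrt 2,$$
where $H = 2h$ is the full thickness and the $1/\sqrt 2$ factor accounts for
fluid loading on both faces. Two remarks on this pair of formulas:

* The $1/\sqrt2$ fluid correction is the unique factor consistent with the
  modulus inversion below: substituting it makes the three closed forms an
  exact algebraic round trip. (A literal factor of $1/2$, which sometimes
  appears in print, breaks that identity.) With fluid density equal to plate
  density, $V_{L,\mathrm{vac}}/\sqrt2$ is also exactly the known
  low-frequency asymptote of the submerged-plate equation above.
* The dispersion equation uses the *half* thickness; the closed forms are
  written with the *full* thickness as tabulated for tissue. Both are carried
  as separate fields of `plate_material()` so neither is silently reused.

Young's modulus follows from the measured velocity $V_L$ at frequency $f$:
$$E = \frac{9\rho V_L^4}{(\pi f H)^2}, \qquad E = 3\rho V_S^2 .$$

Numerically (496 µm plate, $V_S = 8$ m/s), the full A0 root and the
corrected closed form agree to within 1.5% for $f \le 2$ kHz and to within
about 4–8% up to 4 kHz — the closed form is an asymptote, not an identity.
Because the modulus scales as $V_L^4$, that velocity-level model gap is
amplified four-fold in $E$; see *Known limitations*.

## k-space velocity estimation

The spatio-temporal displacement map $u(t, x)$ (time × lateral position) at a
chosen depth band is high-pass filtered per column (zero-phase
forward–backward Butterworth, order 4, 200 Hz cutoff by default — zero-phase
so arrival times are unbiased; the cutoff removes push-recovery drift and
bulk motion without touching the kHz wave band) and transformed by 2D FFT.
In the resulting (frequency, wavenumber) magnitude map the wave mode is a
ridge; at each frequency the phase velocity is
$$c(f) = \frac{2\pi f}{k^*(f)},$$
with $k^*$ the wavenumber of maximum magnitude at that frequency — the only
dimensionally meaningful reading of "frequency divided by the peak
wavenumber". Conventions and numerical choices:

* **Axes.** One-sided in frequency, signed in wavenumber, oriented so a wave
  propagating toward increasing lateral position appears at positive $k$;
  only the half-plane matching the excitation geometry is searched, which
  suppresses any counter-propagating energy.
* **Taper and padding.** Hann taper in both dimensions, zero-padding ×4
  (both axes) before the FFT; a 3-point parabolic interpolation refines the
  peak to sub-bin resolution. Ties are broken toward the smaller wavenumber
  (faster velocity) and logged.
* **Row gating.** A frequency row enters the dispersion curve only if its
  peak reaches 10% of the global in-band maximum *and* exceeds 4× the row's
  median magnitude. The second (prominence) gate is an SNR test: for white
  noise the maximum of a few hundred magnitude bins is only ≈3× the median,
  so noise-dominated rows are rejected while a coherent ridge passes easily.
* **Ridge smoothing (windowed estimation only).** Within the small lateral
  analysis windows the magnitude is boxcar-averaged over a 100 Hz frequency
  neighbourhood before peak picking. The ridge is locally linear in
  frequency, so a symmetric average leaves the peak wavenumber unbiased to
  first order while averaging down the noise.

The **2D velocity map** slides a 32-position lateral window in steps of 8
positions; each window is filtered, transformed, and read at its own dominant
frequency (temporal-spectrum argmax with parabolic refinement, DC excluded);
estimates sit at the window centres and are linearly interpolated to every
position — never extrapolated beyond the outermost valid centre, and never
read at a dominant frequency outside the extracted band. Two failure guards
make the mapper robust rather than fragile: any window whose extraction fails
contributes `NA` with a logged warning (never an error), and an *onset guard*
rejects windows whose transient is already under way at the first analysed
sample. The onset guard matters near the push: the analysis window starts
after the excitation A-lines, so positions close to the focus see a truncated
pulse whose spectrum is badly conditioned — the same reason practical
shear-wave elastography excludes the push zone.

The modulus summary converts the mask-mean velocity of each repeat at the
recorded dominant frequency (`f_mode = "per_sample"`, the default, matching
the single-frequency form of the inversion; `"per_position"` converts per
position first) and reports mean ± sample SD across repeats.

## The synthetic M-B scan

The simulator replaces the instrument:

* **Acquisition timing** mirrors the hardware protocol: 50 kHz A-line rate,
  1000 A-lines per position, the push between A-lines 101 and 125, 1300 nm
  centre wavelength.
* **Wavefield.** A coherent transient with a Gaussian amplitude spectrum
  (centre 2 kHz, FWHM 1.5 kHz by default) is synthesised as
  $u(x,t) = \sum_j A(f_j)\cos(\phi_j(x) - 2\pi f_j (t - t_c))$ from 96
  spectral components, with $\phi_j$ accumulating the local A0 wavenumber
  from the dispersion solver segment by segment (so lateral stiffness
  contrast is exact), scaled to a 150 nm peak. The component spacing keeps
  the discrete-spectrum revival time beyond the record length. The field is
  exactly zero before the push, zero behind the focus (single-sided
  propagation, matching the half-plane k-space search), uniform over the
  tissue depth band. The transient is centred one push duration (at least 3
  envelope sigma) after the gate so the onset is continuous.
* **Complex encoding.** Each (depth, lateral) pixel gets a time-frozen
  log-normal speckle amplitude around the geometry's structural intensity
  and a static uniform random phase; displacement modulates the optical
  phase, and i.i.d. Gaussian phase noise of SD 167.3 mrad (the phase
  stability of a realistic swept-source system) is added per sample. The
  Doppler difference of two such phases carries noise SD
  $0.1673\sqrt2$ rad — the variance-addition property the tests verify.
* **What it does not model:** reflections at stiffness boundaries, geometric
  spreading and attenuation (the estimator uses phase, not amplitude),
  viscoelastic dispersion, speckle decorrelation, bulk motion, the MHz
  ultrasound carrier, and pressure-to-stiffness mechanics (a pressure sweep
  imposes stiffness levels directly). Passing closure tests therefore shows
  the *estimator chain* is correct and noise-robust; it does not certify
  performance against motion artifacts or reverberant fields in vivo.

Because the wavefield is uniform over the tissue depth band, a thin depth
stack measures exactly the same velocities as a full-size cube; the test
suite therefore runs with ~12 depth pixels (with the axial pitch chosen so
band × pitch equals the physical plate thickness) and the full 1000 × 256
time–lateral grid, keeping the suite fast without changing any estimate.

**Scan geometry.** The default lateral sampling is 256 positions at 50 µm
(12.8 mm aperture). At the 2 kHz excitation the A0 wavelengths for 50–400
kPa plates are 1–2 mm, so the 32-position (1.6 mm) analysis window spans
roughly one wavelength — the minimum for a stable windowed wavenumber peak.
This aperture is wider than an anatomical ONH scan; it is a phantom-geometry
choice driven by wavelength coverage, not anatomy. Equivalently, the true
instrument operates at a higher dominant frequency (shorter wavelengths)
over a smaller field of view: reproducing published ONH velocities of
8–10 m/s on a 496 µm plate would require a push spectrum centred near
8–9 kHz, whereas the simulator's default 2 kHz transient produces 2.6–4.9
m/s over the same stiffness range.

## Known limitations

* **Thin-plate inversion bias.** The estimator measures the *true* (full
  model) A0 velocity essentially without bias (<1% noiseless), but the
  closed-form inversion $E \propto V_L^4/f^2$ assumes the thin-plate
  asymptote. The recovered modulus therefore carries a factor
  $(c_{\mathrm{A0}}/c_{\mathrm{thin}})^4$ evaluated at the dominant
  frequency. At a ~2.2 kHz dominant frequency on a 496 µm plate this factor
  is ≈0.97 at 200 kPa and ≈1.04 at 400 kPa (recoveries within ±5%), but
  ≈0.71 at 50 kPa: a plate that soft is outside the thin-plate regime
  ($k_S h \approx 0.8$) at that frequency, and the closed-form inversion
  systematically underestimates its modulus by ~30%. This is a property of
  the inversion formula, not of the estimator; recovering soft plates
  accurately requires either a lower excitation band or a full
  dispersion-curve fit, both out of scope here.
* **Elastic only.** Shear viscosity is stored on `plate_material` but the
  solver requires it to be zero; viscoelastic inversion from the dispersion
  slope is deliberately not implemented.
* **Thickness estimator.** `thickness_from_structure()` (median
  above-threshold depth run × pixel pitch) is a declared stand-in for an
  unspecified instrument procedure; it defaults to geometric thickness
  (refractive divisor 1), with an optical-path correction available.
* **Percent-increase convention.** Percent changes are reported to two
  decimals from the supplied means. Note that the bundled pressure-sweep
  example table yields a modulus increase of 129.45% from its printed means;
  summary tables computed from unrounded data can differ in the last digit.
* **Direction sweeps** are represented as independent equal-stiffness
  phantoms (the measurement question is constancy, and anisotropy is not
  modelled); the sweep report quantifies constancy as the maximum absolute
  deviation from the across-direction mean.

## Reproducing the analysis

`scripts/acceptance.R --seed <int> --out <path>` regenerates the headline
quantities from scratch: the pressure-sweep percent increases and quadratic
trend fit from the bundled summary table, the directional-constancy
deviation, the plane-wave k-space read-out, the reference A0 root, and
end-to-end modulus recovery on simulated noisy phantoms. All simulation
randomness derives from `--seed`; the closed-form and table-derived
quantities are deterministic.
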