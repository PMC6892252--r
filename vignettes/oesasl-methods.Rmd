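---
title: "Designing off-resonance-corrected PCASL and VEPCASL encodings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing off-resonance-corrected PCASL and VEPCASL encodings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 5)
library(oesasl)
```

## The model

PCASL drives a flow-mediated pseudo-adiabatic inversion of arterial blood as
it crosses a labeling plane. The state the blood ends up in is controlled by
the *net phase per RF interval*: 0 leaves the spins on the inversion branch
(label), π on the non-inverting branch (control). Everything this package
does reduces to controlling that one phase, per vessel, per cycle.

Two mechanisms disturb it. Off-resonance at the vessel location adds a phase
ψ(r) every interval. Vessel-encoding *deliberately* adds a spatially varying
phase 2π**k**·r + φ₀ via transverse gradient blips and an RF phase increment.
The design problem is therefore: given desired per-vessel phases

$$\theta_j = \{0 \text{ or } \pi\} - \psi(r_j),$$

find (**k**, φ₀) such that 2π**k**·r_j + φ₀ ≈ θ_j (mod 2π) at every vessel.
The package solves this in Fourier space: the vessels are rendered as
$e^{i\theta_j}$ point sources in a complex image, and the magnitude of the
zero-padded discrete Fourier transform at frequency **k** is exactly
$|\sum_j e^{i\theta_j} e^{-2\pi i \mathbf{k}\cdot r_j}|$ — maximal when the
plane wave interferes constructively with every desired phase. The peak bin
of the masked, weighted spectrum gives the design; its complex phase gives
φ₀.

Two hardware conventions matter. The blips are *unipolar* (same polarity
every interval): only then does a static per-pulse RF phase schedule add a
constant per-interval phase that can cancel a static ψ. And φ₀ is realized
purely through RF phase (transmit phase advanced by −φ₀ per pulse), with the
blip areas per axis satisfying γ̄·A = k, so the round trip
`predicted_phase()` = 2π**k**·r + φ₀ is exact to machine precision — this is
asserted to 1e-9 in the tests.

## Inversion response

`inversion_response()` tabulates the final Mz/M0 of a spin transiting the
plane as a function of the net extra phase per interval, by hard-pulse Bloch
simulation: the Gaussian RF envelope is discretized into ≤ 10 µs substeps
(symmetric z–x–z splitting of precession and nutation), the inter-pulse
rephasing gradient is lumped into a single z-rotation per interval (exact
for constant velocity, since the gradient-moment integral equals the lobe
area times the mid-gap position), and the encoding/off-resonance phase is one
additional z-rotation per interval. Halving the substep moves the result by
less than 1e-3, and with relaxation disabled the transit conserves |M| to
1e-6 (both tested).

Numerical conventions worth stating:

* **Envelope.** The 600 µs "duration" is taken as the total pulse window,
  with the Gaussian truncated at the window edges = ±3σ (σ = 100 µs). An
  FWHM-600 µs Gaussian truncated at ±3σ would span 1.5 ms and overlap the
  next pulse, so that reading is not physical.
* **Transit.** Spins start 2 cm below and end 2 cm above the plane; at
  6 mT/m they are several kHz off-resonant at those offsets, so the RF has
  negligible effect at entry and exit.
* **Velocity model.** The through-plane velocity average is the one genuinely
  open modelling choice: published zero-offset efficiencies pin only the
  *effective average* of the response. The default is a uniform average over
  0.05–0.6 m/s in 0.05 m/s steps — a flat sampling of physiological speeds
  in the neck (vertebral means near 0.1–0.2 m/s, carotid systolic peaks near
  0.6 m/s, laminar profiles extending toward zero at the wall). This yields a
  zero-offset PCASL efficiency of 0.886. The value is sensitive to the set:
  restricting it to 0.1–0.4 m/s (no slow spins) raises it to ≈ 0.94, and
  extending to 0.8 m/s lowers it to ≈ 0.84. Relaxation during the ≲ 1 s
  transit is off by default (T1 of blood ≈ 1.65 s at 3 T) but blood T1/T2
  can be supplied.

```{r response}
resp <- inversion_response(n_phases = 64, velocities = seq(0.1, 0.5, 0.1))
plot(resp$phases, resp$mz, type = "l", xlab = "net phase per interval (rad)",
     ylab = "Mz/M0")
abline(v = c(0, pi), h = 0, lty = 3)
```

## The optimizer

`optimize_encoding()` evaluates the spectrum of the 1 mm-resolution vessel
image zero-padded to 1024² (frequency step ≈ 0.001 cycles/mm). Two search
parameters shape the solution:

* **Mask.** Frequencies with |**k**| > 1/(4·max_motion) are excluded: an
  encoding function's minimum wavelength is four times the predicted subject
  motion (default 4 mm → |**k**| ≤ 1/16 cycles/mm), so a bulk shift of the
  head cannot swap label and control regions. The mask is a full circle —
  the vessel image is complex, its spectrum is not conjugate-symmetric.
* **Weight.** Remaining magnitudes are multiplied by
  w(|k|) = 1 − 0.1·|k|/k_cut. The taper's only job is to bias the choice
  among near-equivalent peaks (families of aliased solutions reaching the
  same phases mod 2π) toward the lowest spatial frequency; motion robustness
  is already enforced by the mask. A much steeper taper (0.5) was evaluated
  and rejected: at large offsets it overrides phase-match quality, selecting
  low-|k| bins with ~1 rad residuals at the vessels even though near-perfect
  matches (peak magnitude 3.99/4) exist inside the mask, and the corrected
  designs then no longer restore the no-offset efficiency. The slope is
  configurable (`oes_config(weight_slope = )`).

Degenerate inputs are legitimate: if every vessel wants the same phase
(conventional PCASL), the peak is the DC bin, **k** = 0, and φ₀ is that
phase. Ties are broken deterministically — lowest |**k**|, then
lexicographic (k_x, k_y) — so runs are reproducible. Off-grid vessels snap
to the nearest voxel; at 1 mm resolution and |**k**| ≤ 1/16 cycles/mm the
snapping error in phase is below 0.2 rad and usually far less.

The default evaluation path computes the spectrum only on the ~12 900 bins
inside the mask, directly from the vessel positions; this is algebraically
identical, bin for bin, to masking the full 1024² FFT (the image is zero
outside the vessels) and is what makes the full simulation study cheap. The
FFT path is retained (`method = "fft"`) and the two are tested to agree
exactly on the selected bin over hundreds of random instances, alongside an
independently coded brute-force loop over every masked bin.

## SNR-efficiency

For PCASL, efficiency is the achieved label–control difference over the
ideal difference: (m_c − m_l)/2 per vessel. For an N-cycle vessel-encoded
design the package uses the least-squares decoding precision with a
static-tissue column, G = [m | **1**]:

$$\eta_j = \frac{1}{\sqrt{N}\,\sqrt{[(G^\top G)^{-1}]_{jj}}}.$$

This form was chosen because it yields exactly 1 for the ideal ±1 Hadamard
design — vessel-encoding costs no SNR relative to conventional PCASL — and
collapses exactly to (m_c − m_l)/2 for a 2-cycle single-vessel design (2×2
inverse; both identities are tested). Whether the static column belongs in
the efficiency definition is not settled by those two constraints; the
variant without it is available (`static_column = FALSE`). Values above 1
cannot occur and are flagged as formula regressions; singular designs (two
vessels with identical magnetization patterns) report 0 with a warning.

## The simulation study

`run_scenarios()` reproduces the efficiency study at its full size: 20
arrangements × 20 fieldmap scales × 3 scenarios × 2 schemes. What the
generator emulates, and its defaults:

* **Vessels.** A symmetric neck-like layout (carotids ±25 mm lateral, 10 mm
  anterior; vertebrals ±10 mm lateral, 10 mm posterior), each coordinate
  perturbed by Normal(0, 2 mm) per arrangement.
* **Fieldmap.** A linear term (along x, the left–right shim axis) plus a
  quadratic bowl centred at the isocenter, each contributing half of the
  maximum vessel offset, globally normalized so the largest |ψ| over the
  *base* vessels is 1.2 rad at scale 1, then swept over scales 1–20.
  Normalizing against the base geometry (not each perturbed arrangement)
  keeps the map a property of the "subject", with arrangements seeing
  offsets *up to approximately* the nominal ceiling.
* **Scenarios.** `no_offsets` (ψ = 0 in design and evaluation — independent
  of scale, recorded once per arrangement), `uncorrected` (designed at
  ψ = 0, evaluated at the true ψ) and `corrected` (true ψ in both). The
  no-offset PCASL efficiency does not depend on vessel positions at all, so
  its spread across arrangements is exactly zero — a useful self-check.

```{r study}
st <- run_scenarios(study_config(n_arrangements = 4,
                                 scale_levels = c(1, 5, 10, 20), seed = 2))
summary(st)
plot(st)
```

At full size the study completes in well under a minute on one core (the
response curve is pre-computed once; each design is one masked-spectrum
evaluation). The headline behaviour: uncorrected efficiency collapses as the
offsets grow (non-monotonically once vessel phases wrap past 2π), while the
corrected designs stay within 0.01 of the no-offset level for both schemes.

What passing this study does *not* show about real data: the generator has
smooth, static fields (no B₀ drift, no motion between fieldmap and scan),
point-like vessels with a single constant through-plane velocity
distribution, and no noise in ψ. Published in-vivo recoveries with acquired
fieldmaps are correspondingly slightly weaker than the synthetic-map
results. The uncorrected-scenario pooled mean is particularly sensitive to
where the vessels sit relative to the field's zero set — an aspect of the
unpublished coefficient choices that cannot be pinned from the stated 1.2 rad
ceiling alone — so that figure should be read as order-of-magnitude, unlike
the no-offset and corrected levels, which are robust.

## Fieldmap ingestion

`psi_from_echoes()` implements the two-echo shortcut: when the echo-time
difference equals the RF interval (e.g. TE 5.19/6.19 ms against 1 ms
spacing), the wrapped phase difference between echoes *is* the per-interval
offset, with no unwrapping. For general echo spacings the wrapped difference
is unwrapped in 2-D by quality-guided region growing (highest-quality voxel
first, each voxel unwrapped against its best already-done neighbour; quality
is the magnitude image when available, otherwise inverse local phase
roughness), then rescaled by rf_interval/ΔTE. The result is exact up to a
global 2π multiple, which is irrelevant downstream (only phases mod 2π enter
the design) but is anchored at the seed voxel's wrapped value. Offsets are
sampled at single vessel-centre voxels by default — fieldmaps are smooth —
with an opt-in 3×3 average for low-SNR acquisitions (variance ≈ 9× lower,
tested by Monte Carlo).

## Known limitations

* 2-D point-vessel geometry: tilted labeling planes, tortuous vessels above
  the circle of Willis, and finite vessel cross-sections are out of scope.
* Static ψ: B₀ drift or post-fieldmap motion violates the design assumption.
* Laminar/pulsatile flow, B1 inhomogeneity and magnetization-transfer
  effects are not modelled in the inversion response.
* Hadamard schemes require a power-of-two order ≥ n_vessels + 1.
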