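---
title: "Simulating comb-illuminated spectral-domain OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating comb-illuminated spectral-domain OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(comboct)
```

## Scope

`comboct` simulates spectral-domain optical coherence tomography (SD-OCT)
with discrete frequency-comb illumination — dissipative Kerr soliton (DKS)
microcombs in particular — alongside conventional superluminescent-diode
(SLD) sources, and implements the analyses that distinguish the two: RIN
estimation with shot-noise and excess-photon-noise floors, per-line
noise-correlation analysis, and tomogram reconstruction by either the full
interferogram or the comb-tone-subsampled (optical-domain subsampling /
circular ranging) pipeline.

The package deliberately models the *measurement chain*, not the
nonlinear cavity: soliton formation, laser tuning dynamics, dispersion
engineering and hardware control are out of scope. A comb enters as a set
of spectral lines on the dispersion grid
$\nu_\mu = \nu_0 + f_{\mathrm{rep}}\mu + \tfrac12 d_2 \mu^2$ with a
parametric envelope; a chaotic modulation-instability (MI) comb is modelled
phenomenologically as a flat, rippled envelope whose intensity noise is
per-line-independent and strongly elevated (about 20 dB) rather than via
nonlinear dynamics.

## Source models

**Soliton comb.** `make_dks_spectrum()` builds sech²-envelope line powers
$P_\mu \propto \operatorname{sech}^2\!\big((\nu_\mu-\nu_0)/\Delta\nu_S\big)$,
normalized so the pre-suppression line powers sum to the requested total.
The 3-dB bandwidth parameter fixes $\Delta\nu_S$ through the sech² half-power
points at $\pm\operatorname{acosh}(\sqrt2)\,\Delta\nu_S$. The
`pump_suppression_db` argument models a notch filter acting on the pumped
line. In the bundled scenarios it is 0: physically, the pump fibre Bragg
grating removes the pump's strong CW *excess*, leaving the line
approximately on the soliton envelope. Setting a deep suppression instead
carves a one-line notch into the envelope; because any sharp spectral
feature couples envelope (common-mode) noise into *all* depth bins of the
tomogram, such a notch visibly degrades the correlated-noise immunity
discussed below — worth knowing when configuring filters in a real system.

Comb lines are treated as spectral delta functions: their optical linewidth
(∼100 kHz) is many orders of magnitude below any spectrometer resolution,
so it is retained only as metadata. A corollary used throughout is that a
comb line's interference fringe does not dephase within a spectrometer
pixel, which is why the subsampled reconstruction shows no
depth-dependent roll-off.

**Transform-limited duration.** `transform_limited_duration()` assumes
flat spectral phase, places the field amplitude $\sqrt{P}$ on a frequency
grid that oversamples the envelope at least 16-fold (for combs, a grid
whose step divides the FSR, so equidistant lines sit exactly on bins),
zero-pads to at least $2^{16}$ samples, inverse-FFTs and measures the
intensity FWHM with linear interpolation. The sech² and Gaussian
time-bandwidth products (0.315, 0.441) are reproduced to better than 1 %.
One practical caveat the tests encode: the sech wings carry weight, and a
comb truncated at ±2.4 envelope bandwidths (41 lines at 1 THz for an
8.3 THz envelope) measures ≈ 6 % broad; ±5 bandwidths (81 lines) converges.

**SLD.** `make_sld_spectrum()` is Gaussian in *wavelength* with the stated
FWHM and integrated power; the spectral density is stored per unit
wavelength and converted internally (factor $\lambda^2/c$) where a
per-frequency density is needed.

## Intensity noise model

The classical intensity noise of a multi-line source is decomposed into
two white multiplicative terms with one-sided PSDs
(`noise_model()`): a common-mode fluctuation $x_c(t)$ shared by every
line — the soliton regime, where all comb teeth breathe with the pump —
and per-line-independent fluctuations $x_\mu(t)$ — the chaotic/incoherent
regime. Detected line power is
$P_\mu(t) = \bar P_\mu (1 + x_c + x_\mu) + n_{\mathrm{shot}}$, with shot
noise entering at the detector with one-sided PSD $2h\nu\bar P$.
Published noise measurements do not pin down a unique composition model;
this is the minimal construction that reproduces the observed dichotomy: the
zero-lag Pearson correlation between two lines equals the common-mode
fraction of the classical variance within the sampled Nyquist band, and
integrating the estimated RIN recovers the injected variance.

Two closed-form floors anchor the RIN scale. A coherent source detected at
power $P$ is bounded by shot noise, $\mathrm{RIN} = 2h\nu/P$
(−145.1 dBc/Hz at 100 µW, 1300 nm), improving 3 dB per power doubling.
(The formula evaluated at 20 µW gives −138.2 dBc/Hz; a printed −145
figure at that power corresponds to ≈100 µW, and the implementation
reports the formula.) An incoherent source of rectangular optical
bandwidth $B_0$ is instead limited by spontaneous-emission beat noise at
$\mathrm{RIN} = 1/B_0$ (−136.5 dBc/Hz for 45 THz), independent of power —
the reason reference-arm power cannot buy unlimited dynamic range with an
SLD. `simulate_thermal_intensity()` provides the independent Monte-Carlo
oracle: band-limited circular complex Gaussian fields, two polarization
modes for unpolarized light (one mode doubles the plateau), whose
intensity RIN plateau matches $1/B_0$ within estimator scatter. RIN is
defined as the one-sided PSD of power fluctuations over the *squared mean*
power (the conventional normalization; for the small fluctuations
considered, the distinction from the mean-squared power is negligible).

PSD estimation everywhere uses Hann-windowed averaged modified
periodograms (Welch) with per-segment mean removal; the resolution
bandwidth is $f_s/L$ for segment length $L$. `rin_spectrum_stitched()`
mimics instrument RBW sweeps by combining estimates from several segment
lengths, each contributing the decade it resolves best.

## Forward model

`spectrometer()` describes a grating spectrometer: 2048 pixels uniform in
wavelength over 1235–1385 nm by default, a Gaussian per-pixel spectral
response of FWHM $\delta k_{\mathrm{CCD}}$ in spectroscopic wavenumber
$\tilde\nu = 1/\lambda$, full-well capacity, integration time (default
1/46 kHz), quantum efficiency and read noise. Sampling theory gives the
single-sided imaging window $z_{\max} = 1/(4\delta k_{\mathrm{CCD}})$;
the default $\delta k_{\mathrm{CCD}} = 125\,\mathrm{m^{-1}}$ is chosen to
give the 2 mm range of a representative system (the physical spectrometer's
response width is not published, so it is reverse-engineered from the
range). The interferometric phase convention is $4\pi\tilde\nu z$ with $z$
the one-way optical path depth ($n\cdot$geometric; the tissue index is
carried as metadata only), which makes $z_{\max}$ exact at Nyquist.

`simulate_interferogram()` decomposes the source into narrow spectral
components (comb lines, or a fine uniform-$\tilde\nu$ sampling of a
continuous density), applies the interferometric modulation
$R_r + \sum_s R_s + 2\sum_s\sqrt{R_r R_s}\cos(4\pi\tilde\nu z_s + \phi_s)$
at each component's exact wavenumber, spreads each component over pixels
with the Gaussian response (truncated at ±4 FWHM, energy-normalized on the
grid), converts to photoelectrons and clips at full well (saturation is
flagged, not raised). The reference power is auto-scaled so the brightest
reference-only pixel sits at 50 % of full well — a camera operating point,
configurable via `exposure_gain()`. Source noise enters as one common-mode
draw per acquisition plus per-line draws over the acquisition bandwidth
$1/(2\tau)$; detector noise as Gaussian-approximated shot noise plus read
noise. With no noise model the acquisition is exactly deterministic, which
the folding tests exploit.

Because a continuous source's fringe varies *within* a pixel's response,
its reconstructed amplitude rolls off with depth as the Fourier transform
of the response evaluated at the fringe frequency $2z$:
$a(z) = \exp(-\pi^2\delta k^2 z^2/\ln 2)$. This form is what the forward
simulation actually produces (the mirror-sweep oracle matches it within
2 %); a variant with $4\ln 2$ in the denominator that circulates in some
write-ups corresponds to conflating the transform variable $2z$ with $z$.
Comb lines, being unresolved, evade the roll-off entirely.

## Reconstruction

Both pipelines of the two-way processing comparison are implemented.

* `background_subtract()` removes the per-B-scan mean spectrum — the
  reference DC and all static autocorrelation structure — acting as a
  temporal high-pass of characteristic frequency
  $f_{\mathrm{line}}/N_{\mathrm{B\,scan}}$ (≈ 90 Hz at 46 kHz and 512
  lines). It is applied per B-scan, never pooled.
* `resample_to_k()` cubic-splines the wavelength-uniform pixels onto a
  uniform wavenumber grid of equal length. Spline interpolation costs a
  few percent of amplitude at fringe frequencies near Nyquist; the
  roll-off oracle therefore uses a uniform-$k$ spectrometer
  (`spectrometer_uniform_k()`) to isolate the response physics.
* `ascan_full()` takes the unitary-DFT magnitude of the full
  interferogram (non-illuminated pixels included), depth axis
  $z_j = j/(2N\Delta k)$. With comb input the A-scan shows the
  characteristic replica train with period equal to the ambiguity range.
* `detect_comb_pixels()` finds one pixel per tone by marching from the
  brightest pixel in steps of the locally updated tone spacing, taking
  the local maximum in a ±half-spacing window (lowest index on ties —
  a deterministic tie-break) and requiring each candidate to stand at
  least 6× proud of the window median, which also rejects smooth
  (comb-free) spectra. Marching with a locally updated spacing is needed
  because uniform-wavelength pixels render the comb chirped in pixel
  index (≈ ±11 % spacing variation across a 150 nm band).
* `ascan_subsampled()` discards all non-tone pixels and DFTs the short
  tone vector: A-scan length equals the line count, no zero-padding
  (a documented choice — padding would interpolate but not add
  information), and the depth axis spans exactly one ambiguity range
  $z_{\mathrm{amb}} = c/(2 n f_{\mathrm{rep}})$. Reflectors beyond
  $z_{\mathrm{amb}}$ fold back modulo the range; a magnitude
  reconstruction additionally cannot distinguish $z$ from
  $z_{\mathrm{amb}} - z$ (complex-conjugate mirror), so the unambiguous
  window is half the range. Both conventions are exposed via
  `ambiguity_range(..., halve_for_conjugate=)`: at a nominal 1 THz FSR
  the full period is ≈150 µm, while the conjugate-limited window at the
  device repetition rate (1.05 THz) is ≈71 µm. Complex-conjugate-resolved
  demodulation (frequency shifters) is out of scope.
* `log_clip_filter()` produces display volumes: $10\log_{10}$ of power, a
  fixed 3×3 median filter per plane, then clipping at the 0.01 % / 99.9 %
  percentiles of the filtered plane — identical for every source.
* `axial_resolution()` measures the mirror-peak FWHM on the linear
  (non-log) amplitude scale with parabolic peak refinement; for a
  Gaussian source this matches the coherence-length formula
  $\delta z = (2\ln 2/\pi)\,\lambda_0^2/\delta\lambda$ (5.05 µm at
  1310/150 nm) within 5 % through the whole pipeline.
  `dynamic_range()` is $10\log_{10}$ of peak power over the median power
  of a user-designated empty region — a defined, reproducible proxy; the
  empty-region choice behind any particular published figure is not
  reconstructable. No apodization window is applied by default (windowing
  changes the measured FWHM and is flagged when enabled).

## Noise correlation analysis

`decimate_trace()` (zero-phase FIR low-pass at the new Nyquist, integer
factors only, realized in the frequency domain on a reflection-padded
trace so edge transients stay out of the data), `cross_correlate()`
(Pearson-normalized, exactly symmetric under trace swap with lag
negation), `correlation_vs_rate()` (a logarithmic rate sweep of the
maximum near-zero-lag correlation, window fixed at ±5 lags) and
`cross_psd()` (Welch cross-PSD with magnitude-squared coherence, bias
≈ 1/segments) reproduce the per-line analysis chain. The quantitative
content is parameter *recovery*: injected common-mode variance fractions
{0, 0.25, 0.5, 0.8, 0.95, 1} are recovered as $r(0)$ within ±0.03 at
$10^6$ samples. Measured device values (0.95 for a soliton comb at
500 kSa/s, 0.01 for an MI comb) characterize physical hardware and serve
only as regime anchors for the scenarios, not as reproduction targets.
Trace lengths behind published correlation figures are not stated
anywhere; the default $10^6$ samples is chosen for statistical adequacy.

## Why correlated noise is harmless — and when it is not

A Fourier-domain tomogram maps spectral structure to depth. Common-mode
noise multiplies the whole spectral envelope, so its energy lands on the
DFT support of the *static* spectrum — the DC/autocorrelation ridge (a few
bins wide, set by the envelope bandwidth) and the existing signal peaks —
leaving the background floor untouched. Per-line-independent noise is
spectrally white across pixels and raises the floor at *every* depth. The
bundled `dks_correlated_noise` / `dks_uncorrelated_noise` scenarios encode
this: a 100-A-scan B-scan of a weak reflector with 1 % noise per
acquisition either common-mode (floor shift below 0.5 dB against a
shot-noise-limited baseline) or per-line (floor raised by more than 6 dB).

Two modelling conditions matter and are deliberate scenario choices.
First, the reflector is weak ($R = 10^{-4}$, tissue-like): multiplicative
common-mode noise also rides on the sample fringe itself, and with a
strong reflector that signal-dependent term leaks past the peak's
neighbourhood and lifts the floor — the immunity statement concerns
reference-dominated acquisitions. Second, the envelope must be smooth:
a deep pump-suppression notch (or any sharp spectral feature) gives the
envelope broadband DFT content that common-mode noise re-excites at all
depths. Both effects are reproducible with the package by flipping the
corresponding scenario parameters.

## Synthetic data and scenarios

Phantoms are discrete partial reflectors (`make_mirror()`,
`make_layered()`); `make_speckle_tissue()` draws Poisson-positioned
scatterers per A-line with exponentially distributed reflectivities and
random phases folded into signed amplitudes — adequate for testability
(known ground truth, reproducible under a seed), *not* for tissue-optics
realism: there is no absorption/scattering physics, no confocal gating,
no multiple scattering, and speckle statistics are only qualitatively
Rayleigh-like. Passing tests on these phantoms validate the measurement
and reconstruction chain, not biological image fidelity.

`make_scenario()` pins named study conditions (a 1 THz comb at 229 THz —
an exact FSR multiple, so equidistant-comb folding is exact to rounding —
with an 8.3 THz sech² envelope; a 1310/150 nm, 9.15 mW SLD; 46 kHz line
rate; 512-line tissue B-scans; noise regimes as above), derives per-stage
seeds from one master seed by a Lehmer step (all below $2^{31}$), and
records every parameter in a ground-truth sidecar; `run_pipeline()` chains
generate → reconstruct → report with a JSON manifest (config MD5, seeds,
package version, outputs) so reruns are bit-identical. Serialization is
plain text throughout: commented-header CSV for spectra, phantoms, traces
and tomograms; YAML configs; JSON sidecars.

## Numerical choices and problem sizes

Defaults keep every analysis interactive: 2048-pixel interferograms,
26 in-band comb lines, 100-repeat noise studies, $2^{18}$-sample thermal
Monte Carlo, $10^6$-sample correlation recovery, an 8192-pixel fine
spectrometer for PSF work. Degenerate inputs fail loudly with the
offending argument named (non-positive powers, non-monotone axes,
zero-mean RIN traces, comb-free spectra, single-A-scan background
subtraction). Floating-point ties are broken deterministically (lowest
pixel index). The folding-equivalence property holds to machine precision
only when comb lines are exactly equidistant and the centre frequency is
an integer multiple of the FSR; the scenario defaults satisfy both, and
the tests state the property in that regime.

## Known limitations

Beyond the non-goals above: no polarization, no dispersion mismatch
between arms, no lateral/confocal PSF, no acousto-optic demodulation for
conjugate-resolved ranging, no fibre-link transport effects, and the MI
comb's chaotic dynamics are represented only through their noise
statistics. Printed device measurements that depend on the physical
instrument (measured axial resolutions of ~6/~10 µm, measured dynamic
ranges, the specific 0.95/0.24/0.01 correlation values, measured RIN
curves) are reproduced here only at the level of their mechanisms and
scalings, which is the package's purpose.
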