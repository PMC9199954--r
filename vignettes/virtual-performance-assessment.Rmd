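---
title: "Virtual performance assessment of time-domain diffuse-optics instruments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual performance assessment of time-domain diffuse-optics instruments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsperf)
```

`nirsperf` implements the three protocol families used to benchmark
time-domain near-infrared spectroscopy (TD-NIRS) instruments — basic
instrument performance, optical-property retrieval quality, and
inhomogeneity detection — together with a virtual instrument and virtual
phantom kits, so that every figure of merit (FOM) can be computed, tested
and calibrated without physical hardware. This vignette records the model,
the tunable parameters, and the design decisions that were genuinely open.

## 1. Forward model

Photon migration in a homogeneous turbid medium is described by the
time-dependent diffusion approximation. We use one canonical variant
throughout (laboratories in real comparisons each use their own; a single
documented choice is what makes the virtual pipeline self-consistent):

* diffusion coefficient $D = 1/(3\mu_s')$, deliberately independent of
  $\mu_a$. This makes the time-domain Beer–Lambert factorization
  $R(t;\mu_a) = R(t;0)\,e^{-\mu_a v t}$ exact (to machine precision), a
  property the test suite asserts at $10^{-12}$;
* speed of light in the medium $v = c/n$ with $c = 0.0299792458$ cm/ps;
* extrapolated-boundary condition: isotropic point source at
  $z_0 = 1/\mu_s'$, negative image at $-(z_0 + 2z_b)$, $z_b = 2AD$, with
  the internal-reflection parameter $A$ from the standard polynomial
  approximation of the effective Fresnel coefficient for the
  $n_{\mathrm{in}}/n_{\mathrm{out}}$ mismatch;
* slab transmittance as the image-source series, truncated when an added
  image pair's peak contribution falls below $10^{-9}$ of the running sum.
  The truncation criterion is evaluated on the absorption-free weight so
  the retained order — and hence the Beer–Lambert identity — does not
  depend on $\mu_a$;
* internal units cm and ps; public interfaces use mm for geometry and
  cm$^{-1}$ for optical properties.

Defaults: medium refractive index 1.55 (epoxy-resin solid phantoms),
external index 1.0, source–detector separation 30 mm in reflectance. All
are configurable.

### Absorbing inclusion

The switchable solid phantom realizes a localized perturbation equivalent
to $\Delta\mu_a = 0.17$ cm$^{-1}$ over 1 cm$^3$ in a
$(\mu_a, \mu_s') = (0.1, 10)$ cm$^{-1}$ background. We treat the inclusion
as a *point* absorber of strength $\Delta\mu_a V$ in first-order Born
approximation: the change in detected reflectance is the time convolution
of the fluence Green's function (source → inclusion) with the escape
Green's function (inclusion → detector), both with their boundary images,
integrated by trapezoid quadrature on a uniform grid of step
$\min(\text{channel width}, 25\,\mathrm{ps})/4$. The cylinder geometry of
the physical rod is not resolved; the equivalent-$\Delta\mu_a$ reduction
already collapses it to a point strength. Consequences worth knowing:

* the perturbation is *exactly* linear in $\Delta\mu_a V$ (first-order by
  construction), which the tests exploit;
* at shallow depths and early times the linearized deficit can exceed the
  unperturbed signal; the result is then clipped at zero and flagged
  (`born_clipped` attribute plus a warning). Early-window contrasts at
  depths of a few mm therefore saturate, while the late-window/20-mm FOM
  region is safely within the Born regime.

## 2. The virtual instrument

`instrument_model()` bundles everything the synthetic-data generator needs:

| parameter | meaning | default |
|---|---|---|
| `irf` | Gaussian core FWHM (ps), exponential-tail fraction and decay (ps), peak position | 230 ps, no tail, 1000 ps |
| `channel_width_ps`, `n_channels` | TCSPC grid | 10 ps × 1024 |
| `dark_rate_cps` | uniform dark counts | 1000 s⁻¹ |
| `dnl_pattern` | static multiplicative channel-width modulation, mean 1 | flat |
| `drift_amp_per_min`, `drift_t0_ps_per_min` | slow linear drift of amplitude and timing | 0 |
| `session_jitter` | day-to-day fractional perturbation | 0 |

The IRF family (Gaussian ⊕ exponential tail) captures the qualitative
split between hybrid-PMT-like detectors (narrow, tail-free) and
silicon-based detectors (pronounced diffusion tail); real IRFs are only
qualitatively described in the protocol literature, so a two-parameter
shape family is an explicit modelling choice. The 230-ps default width is
a typical mid-range single-photon timing response; defect terms default to
zero so that defects are always *injected deliberately* by the test that
probes them. A sub-channel-width, tail-free IRF collapses to a single
channel — the exact delta response used by oracle tests.

A synthesized measurement has channel expectations

$$\mu_k = \big[ s\,(R \circledast \mathrm{IRF})_k + \tfrac{r_d\,t_{acq}}{N_{ch}} \big] \cdot \mathrm{DNL}_k,$$

scaled so the in-grid signal sums to the requested counts, then
Poisson-sampled. Expectation curves are carried alongside sampled counts
(`$expectation`) so tests can check the sampling against the bookkeeping.
Standard acquisition conditions are the generator defaults: 1-s
acquisitions, 20 repetitions, $5\times10^5$ counts. All stochastic
operations are reproducible from an integer seed; repetitions draw
sequentially from the one seeded stream, which keeps them independent and
bit-reproducible.

Session-to-session jitter perturbs amplitude, IRF width and IRF timing
(timing as a fraction of the FWHM). Analysis deliberately uses the
*nominal* IRF — as in practice, where the IRF is calibrated once — which
is what converts instrument jitter into day-to-day reproducibility error.
Pure amplitude jitter alone would be invisible to a shape-only fit.

The virtual phantom kit is the full 32-point grid ($\mu_a$ 0…0.35 by
0.05; $\mu_s'$ 5…20 by 5, at 800 nm). Labels follow letter = scattering
series (A–D ↔ 5–20 cm$^{-1}$), digit = absorption step (1–8 ↔ 0–0.35
cm$^{-1}$), anchored at B2 = (0.05, 10) and B3 = (0.1, 10) cm$^{-1}$; the
lettering convention beyond those anchors is documented here rather than
claimed of any physical kit.

## 3. Retrieval

`fit_optical_properties()` minimizes the Poisson deviance
$2\sum_k [m_k - y_k + y_k \ln(y_k/m_k)]$ between measured counts and
$A\,(R \circledast \mathrm{IRF})$ — valid at low counts where Gaussian
least squares is not. Choices that were open:

* **fit range**: from 80% of peak on the rising edge to 1% of peak on the
  tail, a common TD-NIRS convention; configurable and recorded in the
  result;
* **amplitude** is profiled analytically ($A = \sum y / \sum s$ over the
  fit range), so the optimizer works in 2–3 dimensions;
* **optimizer**: bounded L-BFGS-B, multi-start from
  $\mu_a \in \{0.05, 0.2\}$, $\mu_s' = 10$ cm$^{-1}$; bounds
  $\mu_a \in [0,2]$, $\mu_s' \in [0.5, 100]$ cm$^{-1}$; an estimate on a
  property bound clears `converged`;
* **timing offset** $t_0$ is fitted by default. For stability analyses it
  must be *pinned* (`fit_t0 = FALSE`): a drifting TCSPC timebase is
  exactly what the stability test should see, and a free $t_0$ would
  absorb it;
* background is subtracted from the pre-peak region (or a paired dark
  measurement) before fitting, negatives clipped at zero.

On noise-free self-generated data the fit returns the generating
parameters to well under 1%; on Poisson replicates at $10^6$ counts the
median absolute error is ≲1% and the coefficient of variation follows the
$N^{-1/2}$ counting-noise law over $10^4$–$10^7$ counts (log–log slope
$-0.5 \pm 0.05$) — the mechanism behind the noise FOM.

## 4. Figures of merit — conventions

* **IRF FWHM**: background (median of the lowest decile of channel
  values) subtracted, half-maximum crossings located by linear
  interpolation between adjacent channels. Whether published widths were
  background-subtracted per laboratory is unknown; this package's
  convention is fixed and documented.
* **DNL**: $(\max-\min)/\text{mean}$ over the active range, excluding 2%
  of channels at each edge (edge artifacts); the estimator converges to
  the injected pattern's peak-to-peak as counts per channel grow. Because
  the extremes are order statistics over ~10³ channels, Poisson sampling
  biases the estimate upward by $\mathcal{O}(\sqrt{1/N_{ch,counts}})$;
  calibration checks therefore use $10^6$ counts/channel, where that bias
  is a few permille against a 0.2 pattern.
* **Accuracy**: deviation around the *population median* across
  instruments, never against "conventionally true" phantom values (the
  kit's true properties are not knowable to the protocol).
* **Linearity/crosstalk**: ordinary least squares of retrieved vs
  *nominal* grid values within each series (the kit's design variable);
  the crosstalk FOM re-expresses the median absolute slope at the
  reference point $(\mu_{a0}, \mu_{s0}') = (0.1, 10)$ cm$^{-1}$.
  Coefficients are named **cause → effect**
  ($F_{\mu_a\to\mu_s'} = S_{\mu_s'|\mu_a}\,\mu_{a0}/\mu_{s0}'$ and
  symmetrically), because the protocol literature's subscript usage is
  internally inconsistent; the interpretation "$F = 0.13$ means a 10%
  cause change yields a 1.3% effect" is preserved exactly.
* **Stability**: range $(\max-\min)/\text{mean}$ and drift = |OLS slope|
  normalized by the mean, per minute, both in percent — relative measures,
  matching how stability bands are quoted in practice.
* **Noise**: CV per count level (sample sd over mean), straight-line fit
  in log–log space, solved at CV = 1%.
* **Reproducibility**: CV of per-session means over ≥ 2 (typically 3)
  sessions.
* **Contrast/CNR**: computed signed, per 400-ps window; the reported FOMs
  are magnitudes at the late window and 20 mm. The time origin for
  windows is the IRF peak channel (configurable); published protocols do
  not state the zero reference. Edge channels partially covered by a
  window contribute proportionally. Window counts $M_i$ average the 20
  repetitions (whether published values did is unstated; the mean is this
  package's documented choice). The CW variant uses a single full-span
  window.
* **Summary statistics**: sample (n−1) sd; 25/50/75% percentiles by
  linear interpolation between closest ranks (R type 7). Percentile
  conventions differ between software; numeric comparisons across
  toolchains should be convention-aware.

## 5. What the simulations show — and what they do not

The generator reproduces the *statistical structure* each test assumes:
Poisson counting noise at the target rate, uniform dark counts, static
multiplicative DNL, linear drift, Gaussian session jitter, and
diffusion-theory DTOF shapes. Passing tests therefore demonstrate that the
estimators are correct and calibrated *under those assumptions*. Real
instruments add physics the virtual bench deliberately omits: afterpulsing
and pile-up, count-rate-dependent timing shifts, structured ambient
background, IRF shapes outside the Gaussian⊕tail family, cylindrical
phantom boundaries, and each laboratory's proprietary analysis settings —
the last being why the inter-instrument spread of a real campaign cannot
be reproduced, only *represented* by drawing virtual instruments from
parameter ranges.

A null campaign (identical ideal instruments) yields linearity ≲1%,
coupling coefficients ≲0.02, reproducibility CV ≲0.3% and depth-scan FOMs
statistically at zero, so a nonzero FOM in any other configuration is
attributable to the injected defect; each defect moves primarily its own
FOM.

## 6. Problem sizes

Desk-scale defaults keep the full test battery tractable: kit sweeps use
1–3 repetitions per phantom at $10^6$ counts (the per-point CV of ~1% is
small against the 2% linearity null band); noise calibration uses 4 count
levels × 20–30 repetitions; depth scans use 15 positions × 20 repetitions
at $5\times10^5$ counts; the campaign driver's sizes are all
`campaign_config()` entries. The synthetic generators themselves keep the
protocol's standard conditions (1 s, 20 repetitions, $5\times10^5$ s$^{-1}$)
as defaults.

## 7. Known limitations

* One diffusion-theory variant; no Monte-Carlo, method-of-moments,
  multidistance or frequency-domain retrieval.
* First-order point-inclusion perturbation; saturating (clipped) contrast
  at shallow depth/early windows.
* The depth scan parameterizes inclusion depth directly; the physical
  side-surface optode arrangement of the switchable phantom is not
  modelled geometrically.
* Single-wavelength fixtures; spectral slopes are out of scope.
* SNIRF/HDF5 export is not provided; the interchange format is CSV + JSON
  sidecar (`write_dtof()` / `read_dtof()`), round-tripping bit-exactly.
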