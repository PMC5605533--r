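---
title: "Models and methods for bound-water dynamics in hydrated cellulose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for bound-water dynamics in hydrated cellulose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cellwater)
```

# The scientific problem

Water bound to crystalline cellulose occupies two distinct environments:
a *non-freezing* population adsorbed on microfibril surfaces that becomes
gradually mobile on warming, and a *freezing bound* (confined) population in
the narrow interfibrillar spaces that melts abruptly near 260 K. `cellwater`
implements the quantitative analysis chain by which these populations are
characterised:

* **QENS** (quasi-elastic neutron scattering): per-Q spectral fits of a
  resolution-convolved elastic + Lorentzian model; the Q-dependence of the
  narrow Lorentzian half-width yields the translational diffusion
  coefficient through the jump-diffusion model.
* **Elastic temperature scans**: segmented fits locating the dynamical
  onset temperatures (~220 K and ~260 K), and mean square displacements via
  the Gaussian approximation.
* **SANS**: power-law + Lorentzian correlation-peak fits; the peak position
  converts to the centre-to-centre microfibril repeat distance.
* **XRD**: pseudo-Voigt peak fits, Bragg spacings and Scherrer crystallite
  sizes; SANS repeat minus crystallite width gives the interfibrillar gap.
* **MD-style water trajectories**: per-molecule diffusion coefficients and
  their decomposition into slow/fast populations with a two-Gaussian
  mixture.

Because the underlying neutron and X-ray data are not publicly deposited,
every stage is exercised against synthetic data with known ground truth,
generated under the instrument and sample conditions reported for the
original experiments.

# Spectral model and convolution

Each QENS spectrum at momentum transfer $Q$ is modelled as

$$I(Q,E) = A\,\bigl[x\,\delta(E) + (1-x)\,S(Q,E)\bigr] \otimes R(Q,E)
          + C_1 E + C_2,$$

with $S = p\,L(\Gamma_1) + (1-p)\,L(\Gamma_2)$ a one- or two-Lorentzian
scattering function, $x$ the elastic fraction, $p$ the narrow component's
weight, and $R$ the instrument resolution. The resolution defaults to an
analytic Gaussian of FWHM 3.5 µeV (the near-backscattering Si(111) value);
a measured low-temperature curve can be supplied instead and is
renormalised to unit area.

Numerical choices:

* Convolution is discrete (FFT) on a uniform energy grid; the kernel is
  renormalised so a unit-area input gives a unit-area output to $10^{-6}$.
  Against an adaptive-quadrature Voigt oracle the convolution is accurate to
  better than $10^{-4}$ relative.
* The elastic term uses the resolution line shape directly
  ($\delta \otimes R = R$), avoiding discrete-delta artefacts.
* The quasielastic term is evaluated on a grid padded by 60 µeV before
  convolution so Lorentzian tails are not clipped at the ±100 µeV window.
* The spectrum is treated as symmetric in $E$ (classical approximation);
  no detailed-balance asymmetry correction is applied.

Fitting is weighted Levenberg–Marquardt with box bounds
($x, p \in [0,1]$, $\Gamma > 0$). Initialisation: $x$ from the ratio of the
observed peak to a resolution line of equal area, $\Gamma_1 = 1$ µeV,
$\Gamma_2 = 20$ µeV, $p = 0.5$ — robust starting points for
backscattering-spectrometer widths. After every fit the components are
relabelled so $\Gamma_1 \le \Gamma_2$ and $p$ always reports the narrow
component. One- versus two-component model choice is reported through a
small-sample-corrected information criterion (AICc); the original analysis
chose the two-Lorentzian form by inspecting the dynamic susceptibility,
which is not algorithmic, so the criterion here is a decision of this
implementation with a user override.

The susceptibility representation is
$\chi''(Q,E) = S(Q,E)\,\bigl(e^{E/k_BT}-1\bigr)$ on $0 < E \le 100$ µeV
with $k_B = 86.173$ µeV/K; the proportionality constant is fixed at 1 and
all $\chi''$ values are arbitrary units.

# Jump diffusion

The narrow half-width disperses as

$$\Gamma_{1/2}(Q) = \frac{\hbar}{\tau_0}
  \left[1 - \frac{1}{1 + D Q^2 \tau_0}\right],
  \qquad l = \sqrt{6 D \tau_0},$$

with $\hbar = 658.212$ µeV·ps. Internal units are Å²/ps for $D$ and ps for
$\tau_0$, which makes $DQ^2\tau_0$ dimensionless with no hidden constants;
reported values use the conventional $10^{-10}$ m²/s (= Å²/ps ÷ 100). Fits
are restricted to $Q \le 0.9$ Å⁻¹ by default because coherent scattering
from crystalline cellulose suppresses the apparent widths at higher $Q$;
the cutoff is configurable. Uncertainty on the jump length is first-order
propagation from the $(D, \tau_0)$ covariance. A deterministic 200×200
grid search over $(D, \tau_0)$ is the fallback for non-convergent fits and
the independent oracle in the test suite.

# Elastic scans, transitions and MSD

Synthetic elastic scans are piecewise linear in temperature with slope
changes at the two transition temperatures (the upper one steeper),
multiplied by a mild per-Q attenuation. `detect_transitions()` fits
continuous segmented linear models with 0–2 breakpoints on the temperature
grid and selects the number by BIC. The original figures mark inflection
points without stating a method, so segmented regression is this package's
choice, not an inference of theirs; quoted breakpoint uncertainties are the
half grid spacing of the on-grid search.

MSD extraction fits $\ln S_{el}$ versus $Q^2$ (free intercept) over
$Q = 0.5$–$0.9$ Å⁻¹ and returns $-3 \times$ slope; the free intercept makes
the result invariant to the arbitrary intensity scale. This is the exact
inverse of the Gaussian approximation
$S_{el} = \exp(-Q^2 \langle \Delta r^2 \rangle / 3)$ implemented in the
water-dynamics module, and the round trip is the identity to $10^{-6}$.

# SANS and XRD

SANS profiles follow $I(Q) = (PQ)^{-\alpha} + B$ plus, for hydrated
samples, a Lorentzian correlation peak
$A\,(1/\pi)\,(w/2)/\bigl[(w/2)^2 + (Q-\sigma)^2\bigr]$ whose centre maps to
the real-space repeat $d = 2\pi/\sigma$ (distinct from the Bragg
$\lambda/2\sin\theta$ convention used for XRD; both are implemented and
documented). The hydrated-sample power law is fitted on $Q < 0.08$ Å⁻¹,
where the measured profile is peak-free. Two background conventions are
provided — simultaneous fit of $B$ and pre-subtraction of a flat
high-Q estimate — because the original description is ambiguous about the
order. On the low-Q window the flat term is weakly identifiable, so the
peak fit co-fits a constant offset that absorbs the resulting baseline
mismatch in the subtracted residual; the peak itself is located by
significance (residual/σ ≥ 4, then amplitude ≥ 3σ after fitting), and a
profile without a significant peak returns a flagged no-peak result rather
than an error.

XRD peaks are pseudo-Voigt, $\eta L + (1-\eta)G$ with a shared FWHM and
unit peak height (so the amplitude parameter is the peak height for any
mixing). The four-reflection cellulose Iα default places (100), (010),
(11̄2) and (110) at 14.8°, 16.9°, 20.7° and 22.9°; the (110) width default
of 1.622° corresponds to a 50 Å crystallite at Cu Kα through the Scherrer
relation $L = 0.9\lambda/(\beta_{1/2}\cos\theta)$ with $\beta_{1/2}$ in
radians (the degree→radian conversion is unit-tested explicitly — a classic
failure mode). No instrument broadening is deconvolved, since the original
analysis reports none; Scherrer sizes are therefore slight underestimates.
Since no peak widths are printed in the source tables, the 50 Å crystallite
is reproducible only as a round-trip fixture, not from published widths.
The interfibrillar gap is repeat distance minus crystallite width with
quadrature-combined uncertainties.

# Water dynamics and the two-population mixture

The trajectory generator produces Brownian surrogates — 3-D random walks
with per-axis step variance $2D\,\Delta t$, one $D$ per molecule drawn from
a two-Gaussian mixture — not molecular dynamics: there is no caging,
sub-diffusive regime, hydrogen-bond exchange or cellulose surface. Passing
tests therefore validate the *estimators* (MSD, per-molecule $D$, mixture
decomposition), not any claim about real interfacial water. Defaults mirror
the reported simulation protocol: 2 ps frames, 5 ns analysed span, 1000
molecules.

MSD uses time-origin averaging (all valid origins) by default; a
single-origin variant is available since the angular-bracket average is
ambiguous in the source. Per-molecule $D$ comes from the least-squares
slope of MSD versus lag over 10–400 ps — the lower cutoff excludes the
short-time non-diffusive regime, the upper keeps enough independent
segments per molecule; 20 evenly spaced lags are used, a resolution/cost
compromise. Negative slopes are clipped to zero and flagged; systematic
curvature (e.g. ballistic motion) raises a per-molecule `nonlinear` flag.

The mixture decomposition runs expectation-maximisation with ≥10 restarts
from a fixed internal seed stream, then polishes the estimate by direct
maximum likelihood under the *left-truncated-at-zero* two-Gaussian model.
The truncation-aware step matters: the fast component at 263 K
($m_2 = 2.21$, $\sigma_2 = 1.76$ in $10^{-10}$ m²/s) has ~10% of its mass
below zero, and because sampled diffusion coefficients are physically
non-negative (the generator redraws negative values within their
component), a plain Gaussian EM on such samples overestimates $m_2$ by
about 0.3. The truncated-mixture MLE is the statistically consistent
estimator for this sampling scheme and recovers the parent parameters.
A BIC comparison against a single Gaussian flags samples with no evidence
for two components, and a histogram-curve least-squares mode (bin width
0.1 × 10⁻¹⁰ m²/s) mirrors the way such distributions are usually displayed.
Recovery tolerances on the component SDs are looser than on weights and
means, because per-molecule estimator noise inflates the apparent widths —
whether the published SDs include that noise is not decidable from the
source text.

# Synthetic study conditions

Values the source states are used as-is: Q range 0.2–2.0 Å⁻¹ (analysis set
0.3–0.9 Å⁻¹, step 0.1), energy window ±100 µeV, resolution FWHM 3.5 µeV,
transitions at 220/260 K, SANS exponents 3.20 (dry) and 3.55 (hydrated),
peak (A = 1, w = 0.04, centre 0.094 Å⁻¹), diffraction peaks as above, and
the three mixture rows at 213/243/263 K. Where the source is silent, one
realistic choice was made and frozen:

* relative Gaussian noise, 1% with σ = level × max(I, floor) — a simple,
  invertible stand-in for counting statistics;
* elastic fraction x = 0.6 and narrow weight p = 0.5, constant in Q;
  broad widths 20 µeV (250 K) and 30 µeV (265 K);
* energy grid step 0.4 µeV (501 points across the window);
* SANS power-law scale P = 2.4 and background B = 0.5, chosen so the
  correlation peak is a few-percent excess over the power law near its
  centre — as in the measured hydrated profile, where the peak emerges only
  after subtraction — while staying well above the 1% noise floor;
* an optional elastic-only "coherent contamination" term for
  Q > 1.1 Å⁻¹, off by default;
* hydration level is carried as a label only (the experiment used
  0.22 g/g, the simulations 0.20 g/g; neither constrains the generators).

Under these conditions a single synthetic temperature point determines the
diffusion coefficient to about 5% — comparable to the published ±0.04 on
0.86 — so the end-to-end demonstration pools the narrow widths of five
replicate spectra per temperature (the synthetic analogue of longer
counting) before the jump-diffusion fit, giving ~2% reproducibility.

The problem sizes used by the bundled tests and the acceptance script —
501-point spectra at 7 Q values, 250-point SANS curves, 1751-point
diffraction patterns, 1000–100 000 mixture samples, 1000 molecules ×
2500 frames for the trajectory demonstration — were chosen to match the
reported experiment scales while keeping a full run in the order of a
minute.

# Degenerate inputs, tie-breaks and error handling

* Lorentzian components are sorted by width after every fit; `p` always
  reports the narrow one.
* Non-convergence at one Q flags that row (`NA` parameters) and leaves
  other Q values untouched; the jump-diffusion stage drops unusable rows.
* Negative fitted backgrounds are permitted with a warning.
* A fitted mixture with one weight ≥ 0.99, coincident means, or a
  collapsing component is flagged degenerate and falls back to the
  single-component answer.
* Zero breakpoints is an admissible outcome of transition detection (flat
  or single-slope scans), selected by BIC with an RSS floor so noiseless
  data do not produce spurious breaks.
* Inconsistent structural inputs (crystallite wider than the repeat
  distance) raise an error rather than a negative gap.

# Known limitations

* The Brownian surrogate omits every mechanistic feature of interfacial
  water; only estimator correctness is demonstrated on it.
* The analytic Gaussian stands in for the true per-Q resolution of a
  backscattering spectrometer, which is not publicly tabulated.
* The abstract of the source reports D(250 K) = 0.85 while its parameter
  table prints 0.86 ± 0.04; the table is treated as canonical. Its last
  row (268 K, 9.41) is a literature NMR value, not a fit output, and is
  excluded from fitting surfaces.
* The MSD evaluation time is quoted both as 800 ps and as ~400 ps
  (resolution-equivalent) in the source; the default here is 800 ps,
  exposed as a parameter.
* No stretched-exponential fitting, multiple-scattering correction,
  Rietveld refinement, crystallinity index or instrument-geometry handling
  is included.
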