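# cellwater

Analysis of the dynamics and nanoscale structure of water bound to
crystalline cellulose, as probed by quasi-elastic neutron scattering
(QENS), small-angle neutron scattering (SANS), X-ray diffraction (XRD) and
molecular-dynamics-style water trajectories.

Hydrated cellulose carries two populations of bound water: non-freezing
surface water that becomes mobile gradually above ~220 K, and confined
water in the ~2 nm interfibrillar spaces that melts abruptly near 260 K.
`cellwater` implements the quantitative chain that separates and
characterises them, plus synthetic-data generators with known ground truth
for every stage, so the whole pipeline is testable without any instrument
data.

## The models

**QENS spectra** at each momentum transfer Q are fitted with a
resolution-convolved elastic + Lorentzian model,

I(Q,E) = A [ x δ(E) + (1 − x) (p L(Γ₁) + (1 − p) L(Γ₂)) ] ⊗ R(E) + C₁E + C₂,

with R a Gaussian resolution of FWHM 3.5 µeV by default. The Q-dependence
of the narrow half-width follows the jump-diffusion dispersion

Γ½(Q) = (ħ/τ₀) [ 1 − 1/(1 + DQ²τ₀) ],  l = √(6Dτ₀),

giving the translational diffusion coefficient D, residence time τ₀ and
jump length l. Spectra convert to the dynamic susceptibility
χ″ = S·(exp(E/k_BT) − 1); elastic temperature scans yield transition
temperatures (segmented fits) and mean square displacements
(S_el ∝ exp(−Q²⟨Δr²⟩/3)).

**SANS** profiles follow I(Q) = (PQ)^(−α) + B plus a Lorentzian
correlation peak whose centre Q* maps to the microfibril repeat distance
d = 2π/Q*. **XRD** peaks are pseudo-Voigt; widths give Scherrer
crystallite sizes L = 0.9λ/(β½ cosθ), and d − L is the interfibrillar gap.

**Water trajectories** (Brownian surrogates of MD water) yield per-molecule
diffusion coefficients from MSD slopes (⟨Δr²⟩ = 6Dt); their bimodal
distribution is decomposed into slow/fast populations by a two-Gaussian
mixture fitted by EM with a truncation-aware maximum-likelihood polish.

## Worked example

Structure pipeline on a synthetic hydrated-cellulose SANS profile
(exponent 3.55, correlation peak at 0.094 Å⁻¹) plus a four-peak cellulose
Iα diffraction pattern:

```r
library(cellwater)
cfg <- pipeline_config(
  seed = 5,
  simulate_sans = list(P = 2.4, alpha = 3.55, B = 0.5,
                       peak = list(A = 1, w = 0.04, center = 0.094),
                       noise = 0.01),
  simulate_xrd = list(noise = 0.01)
)
run_structure_pipeline(cfg)
#> <run_report> structure pipeline
#> status:
#>   sans               ok
#>   xrd                ok
#>   gap                ok
#> SANS power-law exponent: 3.551 +/- 0.001
#> repeat distance: 66.6 +/- 0.7 A
#> crystallite width (110): 50.0 A
#> interfibrillar gap: 16.6 +/- 0.7 A
```

The repeat distance is 2π/Q* for the fitted peak centre (~67 Å
centre-to-centre microfibril spacing); subtracting the 50 Å crystallite
width from the (110) reflection leaves the ~17 Å water-filled gap between
microfibrils.

Jump-diffusion analysis of narrow Lorentzian half-widths
(here generated at the 265 K parameters, D = 0.0177 Å²/ps, τ₀ = 110 ps):

```r
q <- seq(0.3, 0.9, 0.1)
pts <- data.frame(Q = q, gamma = gamma_jump(q, D = 0.0177, tau0 = 110),
                  sigma = 0.02)
fit_jump_diffusion(pts, q_max = 0.9)
#> <jump_diffusion_fit>
#>   D    = 1.77 +/- 4.7e-16 x 1e-10 m^2/s
#>   tau0 = 110 +/- 2.9e-14 ps
#>   l    = 0.34 nm (jump length)
#>   fitted 7 points up to Q = 0.9 1/A
```

D is reported in 10⁻¹⁰ m²/s (1 Å²/ps = 100 × 10⁻¹⁰ m²/s); the ~0.34 nm
jump length is about the diameter of a water molecule, consistent with
surface water hopping between adjacent binding sites.

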