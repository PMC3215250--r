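# cpmgdisp

Analysis of CPMG relaxation dispersion NMR data in R: for protein NMR
spectroscopists who record Carr-Purcell-Meiboom-Gill (CPMG) dispersion
experiments to characterise microsecond-to-millisecond conformational
exchange, and who need the whole chain from peak intensities to exchange
parameters — rates, minor-state populations, chemical shift differences
— with honest error bars and statistical model selection.

## What it computes

Peak intensities become effective transverse relaxation rates,

R₂ᵉᶠᶠ(ν_CPMG) = (1/T_CPMG) · ln[I(0)/I(ν_CPMG)],

with per-residue errors pooled over replicate spectra.  Each residue's
dispersion profile is fitted by bounded, multi-start Levenberg-Marquardt
minimisation of χ² = Σₙ (R₂ᶜᵃˡᶜ − R₂ᵉᶠᶠ)²/σ² to three models:

1. **no exchange** — R₂ᵉᶠᶠ = R₂⁰;
2. **fast-limit exchange** — R₂ᵉᶠᶠ = R₂⁰ + (Φ/kₑₓ)[1 − (4ν/kₑₓ)
   tanh(kₑₓ/4ν)], Φ = pₐ·p_b·δω²;
3. **slow-limit exchange** — the Carver-Richards equation in
   (R₂⁰, kₑₓ, p_b, δω).

Models are ranked by AICc (default), AIC or F-test; parameter errors
come from parametric Monte Carlo (500 simulations by default).  Data
from several static fields can be fitted globally (shared kₑₓ, p_b and
a field-scaled δω), and residues sharing one exchange process can be
fitted as a cluster (shared kₑₓ, p_b; per-residue R₂⁰ and δω).  The
package also carries the downstream thermodynamics — ΔG between states,
populations from known δω, van't Hoff (linear and heat-capacity) fits,
Eyring activation barriers — plus readers for peak lists (generic TSV,
assignment-string and NMRView-style), Bruker vd lists, FASTA/PDB
sequences, CSV writers and a PyMOL macro writer for colour-coded
structures.  A synthetic-data generator reproduces dispersion curves
with controlled noise for validation.

## Worked example

```r
library(cpmgdisp)

# slow-exchange residue: kex = 306.2 1/s, pb = 0.072, dw = 1875.5 rad/s
pars <- list(r20 = 15.23, kex = 306.2, pb = 0.072, dw = 1875.5)
prof <- simulate_profile(3, pars, noise_percent = 2, seed = 1)

sel <- fit_models(prof, criterion = "AICc")
sel
#> Model selection (AICc), residue 1
#>  model      chi2     score
#>      1 4105.3800 4107.7200
#>      2  102.0490  110.4490
#>      3   10.8356   23.2801
#> Selected: model 3  (Rex = 20.72 1/s, kex = 462.3 1/s)

fit <- monte_carlo_errors(sel$fit, n_sims = 200, seed = 2)
summary(fit)
#> CPMG dispersion fit, model 3
#>
#> Coefficients:
#>            Estimate    MC error
#> r20_800 1.51159e+01   0.2885060
#> kex     4.62261e+02 174.5040000
#> pb      5.00855e-02   0.0522967
#> dw      1.86803e+03  66.6660000
#>
#> chi2 = 10.8356 on 14 points (4 parameters)
#> AIC = 18.8356, AICc = 23.2801, Rex = 20.72 1/s
#> Monte Carlo: 200 simulations, 0 failed
```

The slow-limit model wins by ~87 AICc units over the fast-limit fit.
The fitted kₑₓ of 462 ± 175 1/s brackets the generating 306.2 — with 2%
noise on a single field the kₑₓ/p_b correlation keeps individual errors
large, which is exactly what the Monte Carlo errors report; the
composite observables (R_ex ≈ 20.7 1/s, δω = 1868 ± 67 rad/s vs the
generating 1875.5) are far better determined.  A two-field global fit
(`simulate_multifield()` + `cpmg_fit()`) tightens the exchange
parameters substantially; `plot(fit)` draws the profile with error bars
and the fitted curve.

A thin command-line wrapper is installed at
`system.file("cli", "cpmgdisp", package = "cpmgdisp")` with
`simulate`, `fit` and `thermo` subcommands.

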