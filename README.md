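# lipadsorb

Quantitative analysis of small-molecule adsorption and transport at
phospholipid liposome surfaces, as measured by surface-sensitive second
harmonic generation (SHG) spectroscopy and modeled by umbrella-sampling
molecular dynamics.

Liposomes — large unilamellar vesicles of lipids such as DOPG — are standard
model membranes. When a drug-like organic cation (e.g. malachite green) is
added, it adsorbs to the outer leaflet, producing a coherent SHG signal, and
then crosses the bilayer; dye on the inner leaflet cancels the outer-leaflet
field, so the SHG decay tracks transport in real time. This package
implements the full analysis chain for such experiments, plus the
trajectory-side observables used to interpret them, and a synthetic-data
module that generates every input class with known ground truth so that each
stage is testable end to end.

## The models

**Transport kinetics.** The SHG field (the square root of the
background-subtracted intensity) decays as

E(t) = a₀ + a₁ e^(−t/τ)

where τ is the transport time. Rate constants k = 1/τ are linear in added
dye concentration at each temperature, and those slopes are linear in
temperature.

**Depletion-corrected Langmuir isotherm.** The colloid's cumulative surface
area is large enough that adsorption depletes the bulk pool, so the mass
balance M = C − N is solved jointly with the Langmuir equilibrium. With the
dimensionless equilibrium constant K (water-reference convention, 55.5 M),

N = ½ [ (C + N_max + c_w/K) − √((C + N_max + c_w/K)² − 4 C N_max) ]

and the time-zero intensity is I₀ = B + α M + A (N/N_max)², combining a
coherent adsorbed-layer term, an incoherent free-dye term, and a baseline.

**Thermodynamics.** ΔG = −RT ln K per temperature, and the van't Hoff line
ΔG(T) = ΔH − T ΔS separates enthalpy from entropy.

**Potential of mean force.** Umbrella-sampling windows (harmonic biases on
the membrane–dye center-of-mass separation z) are combined by the standard
self-consistent WHAM equations into W(z) = −k_B T ln p(z), with per-bin
standard errors from contiguous-block averaging and barrier/well extraction
relative to the bulk plateau.

**Trajectory observables.** Membrane surface position from per-lipid
outermost oxygens, dye dipole orientation relative to the membrane normal,
interfacial water counts within a 3.5 Å slab, and waters displaced upon
adsorption.

## Worked example

```r
library(lipadsorb)

# adsorption free energies from the four measured equilibrium constants
dg <- adsorption_free_energy(K = c(9.1e7, 8.1e7, 7.2e7, 6.2e7),
                             temp = c(298.15, 303.15, 308.15, 313.15))
round(dg$dG, 3)
#> [1] -10.858 -10.970 -11.079 -11.166

vh <- vant_hoff(dg)
vh
#> Van't Hoff decomposition: dG(T) = dH - T dS
#>   dH = -4.714 +/- 0.257 kcal/mol
#>   dS = 0.02063 +/- 0.000842 kcal/(mol K)
#>   4 temperatures, R^2 = 0.9967

spontaneity_report(vh)$message
#> [1] "dH < 0 and dS >= 0: adsorption is spontaneous (dG < 0) at all positive temperatures."
```

ΔH < 0: adsorption is exothermic. ΔS > 0: although the adsorbed dye itself
is more ordered, each adsorbing molecule displaces many interfacial waters
and counterions, so total entropy rises; with both signs favorable the
process is spontaneous at every aqueous temperature.

A transport-kinetics fit on synthetic data with known truth:

```r
tr <- simulate_shg_trace(a0 = 0.2, a1 = 0.8, tau = 300, noise_sd = 0.01, seed = 7)
fit <- fit_transport_time(tr)
glance(fit)[, 1:3]
#> # A tibble: 1 × 3
#>     tau tau_se r.squared
#>   <dbl>  <dbl>     <dbl>
#> 1  297.   1.64     0.989
autoplot(fit)
```

The whole chain — simulate traces, isotherms, umbrella windows and frames;
fit; decompose; reconstruct — runs with one call:

```r
report <- run_pipeline(seed = 1, output_dir = "out")
```

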