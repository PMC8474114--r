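---
title: "Models and methods: adsorption and transport at liposome surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: adsorption and transport at liposome surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lipadsorb)
```

This vignette explains the models implemented in **lipadsorb**, the
assumptions behind them, the tunable parameters that matter, what the
synthetic-data generators emulate (and what they do not), and the numerical
and design choices made where the design was genuinely open.

## The experimental picture

A second harmonic generation (SHG) signal arises only where inversion
symmetry is broken, which makes it a surface-selective probe of colloidal
interfaces. When a cationic dye is added to a suspension of anionic
liposomes, adsorption to the outer leaflet produces a coherent SHG field
proportional to the number of aligned adsorbates; as dye crosses to the
inner leaflet, inner- and outer-surface contributions cancel (the bilayer is
far thinner than the SHG coherence length), so the signal decays on the
transport timescale. Two experiment classes feed the pipeline: time traces
of SHG intensity after dye addition at fixed concentration and temperature,
and adsorption isotherms of time-zero intensity versus added concentration
at each temperature.

## Transport kinetics

The SHG field is modeled as $E(t) = a_0 + a_1 e^{-t/\tau}$. The package
fits on the field scale, $E = \sqrt{I}$, with delta-method uncertainties
$\sigma_E = \sigma_I / (2E)$.

Choices that were open and how they were pinned:

* **Negative intensities** can occur after background subtraction; they are
  clipped to zero before the square root (the field magnitude is
  non-negative) and the count of clipped points is recorded on the result.
* **Initialization** is derivative-free: $a_0$ from the mean of the last
  10% of the field, $a_1 = E(0) - a_0$, and $\tau$ from the first grid time
  at which $E - a_0$ falls to $a_1/e$. This is robust to noise and needs no
  gradient of the data.
* **Weighting.** Whether the original fits were error-weighted is not
  something the data format dictates, so both modes exist. The weighted
  mode is two-pass: a first unweighted fit supplies a smooth curve on which
  $\sigma_E$ is evaluated, and the weighted fit uses those. Weights built
  from the *observed* field correlate with the noise (a point that
  fluctuates up gets a larger weight) and bias $\tau$ by about 1% at
  typical noise levels; the two-pass scheme removes this while keeping the
  efficiency gain. Replicate studies show calibrated 95% intervals
  (coverage ≈ 91% at 200 replicates) and mean $\tau$ within 0.5% of truth.
* **Bounds.** $\tau \in [1, 10^6]$ s — outside any plausible observation
  window — with a warning when an estimate lands on a bound.

Rate analysis is two nested ordinary least squares: $k = 1/\tau$ on
concentration within each temperature (requiring at least three
concentrations; sparser temperatures are excluded with a warning), then the
per-temperature slopes on temperature. The mechanism behind the
concentration dependence of $\tau$ is an open question experimentally; the
package only quantifies the observed linear structure.

## Depletion-corrected Langmuir isotherm

Classical Langmuir fits assume the bulk concentration is unchanged by
adsorption. Colloidal liposome samples violate this: the total adsorption
site concentration (micromolar) is comparable to the added dye, so the mass
balance $M = C - N$ must be solved together with the equilibrium condition.
With the dimensionless equilibrium constant $K$ defined against the water
reference concentration $c_w = 55.5$ M,

$$K = \frac{N/N_{max}}{(1 - N/N_{max})\,(C - N)/c_w},$$

which is quadratic in $N$; the physical root is

$$N = \tfrac12\Big[s - \sqrt{s^2 - 4 C N_{max}}\Big],
  \qquad s = C + N_{max} + c_w/K.$$

Numerical and design choices:

* **Stable root.** At $K \sim 10^7$–$10^8$ the naive root subtracts nearly
  equal numbers; the implementation uses the multiply-conjugate form
  $N = 2 C N_{max} / (s + \sqrt{s^2 - 4CN_{max}})$, verified against a
  bisection solution of the un-solved equilibrium condition to $10^{-10}$ µM.
* **Water reference.** $c_w$ enters only through the non-dimensionalization
  of $K$; it is a named, configurable constant. This convention is what
  makes $\Delta G = -RT\ln K$ come out near $-10.8$ kcal/mol for
  $K \approx 9\times 10^7$, consistent with the measured scale.
* **Coverage exponent.** The coherent term defaults to squared coverage,
  $I_0 = B + \alpha M + A\,(N/N_{max})^2$: the SHG field is proportional to
  the number of coherently added adsorbates and the intensity to the field
  squared. A linear-coverage variant is available via `coverage_exponent`.
* **Parameter transforms.** $K$ and $N_{max}$ are optimized on the log
  scale (positivity, scale); standard errors return to the natural scale by
  the delta method, and the confidence interval for $K$ is a t-interval on
  $\log K$ mapped through `exp`.
* **Starting values** come from a coarse profile search: on a grid of
  $(K, N_{max})$ candidates the remaining parameters enter the model
  linearly and are solved exactly; the best candidate seeds the
  Levenberg–Marquardt polish.
* **The free-dye slope α** can be fixed from a calibration series of dye
  without liposomes — the experimental procedure — or co-fitted. This
  matters: a Fisher-information analysis at realistic parameters shows the
  relative uncertainty of $K$ roughly quadruples when α is co-fitted, and
  replicate studies confirm that co-fitting α leaves $K$ essentially
  unidentified at percent-level noise. Analyses that care about $K$ should
  fix α.

### What the recovery studies can and cannot show

With a 12-point concentration grid and 2% *proportional* intensity noise
(the regime of spectra averaged to fixed relative precision), the
information bound on the relative standard deviation of $K$ is 11–13%
across the measured parameter range, and the fit achieves a 6–8% median
error with 93–98% interval coverage. Under 2% *absolute* noise the bound
itself rises to 29–69%: no estimator can do better on such data, which is
worth knowing before designing an isotherm. The package's replicate studies
therefore use the proportional model; both noise models are available in
the generator (`noise_model`).

## Thermodynamics

$\Delta G = -RT \ln K$ with $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹
(energies are kcal/mol throughout; conversions to kJ/mol belong in the
reporting layer). The van't Hoff line $\Delta G(T) = \Delta H - T\Delta S$
is fitted by least squares; the intercept is $\Delta H$, minus the slope is
$\Delta S$. Temperatures convert as $T(\mathrm{K}) = T(°\mathrm{C}) +
273.15$.

Two error conventions are provided. The default scales parameter standard
errors by the residual variance (ordinary regression). With only four
temperatures the residual variance is itself poorly estimated, so the
weighted fit can instead propagate the supplied $\Delta G$ uncertainties
directly (`scale_errors = FALSE`, known-variance mode); the demo pipeline
uses this. Published per-temperature free energies are typically quoted
after rounding; reproducing an enthalpy/entropy decomposition from a table
should recompute unrounded $\Delta G$ from the $K$ values rather than
fitting the rounded row, which visibly changes the slope.

## WHAM reconstruction of the potential of mean force

Umbrella windows bias the collective variable $z$ (membrane–dye
center-of-mass separation along the interface normal) with harmonic
restraints on a ladder of centers. The standard self-consistent equations

$$p(z_b) = \frac{\sum_i n_{ib}}{\sum_i N_i e^{[f_i - U_i(z_b)]/k_BT}},
\qquad f_i = -k_BT \ln \sum_b p(z_b)\, e^{-U_i(z_b)/k_BT}$$

are iterated until the window shifts move by less than `tol`, and
$W(z) = -k_BT \ln p(z)$.

Open choices and their resolutions:

* **Grid.** Bin width 0.25 Å over the window centers ± 3 Å — about a sixth
  of a typical 1.5 Å window spacing, fine enough that binning bias is far
  below statistical error at realistic sample sizes.
* **Empty bins** are reported as missing, not as infinite energy; assigning
  them $+\infty$ fabricates barriers in unsampled regions.
* **Convergence.** `tol` = 1e-8 kcal/mol on $\max_i |\Delta f_i|$,
  `max_iter` = 1e5; the residual at return is asserted, not assumed, and
  the iteration count is part of the result.
* **Referencing.** $W \equiv 0$ at the mean over a user-declared bulk
  region (the far-from-interface plateau), falling back to the minimum when
  no bulk region is declared. Barrier height and well depth are measured
  relative to that plateau; a profile whose approach-path maximum does not
  rise above the plateau is classified barrierless, and a barrier smaller
  than its own block-averaged error is flagged as within error.
* **Errors** come from contiguous-block averaging: each window's series is
  split in order into $n$ blocks (default 4, mirroring 14 ns of retained
  data in 3.5 ns blocks), WHAM is solved per block, block profiles are
  re-referenced, and the per-bin SE is the between-block standard deviation
  over $\sqrt{n}$. For correlated samples the between-block variance
  correctly exceeds the naive i.i.d. estimate, which is the point of
  blocking.
* **Equilibration.** `equilibration_trim()` drops a leading fraction of
  each window (default 4/18, the discard-4-of-18 convention).
* **Spring constants** are never published reliably; the sampler and the
  manifest format require them explicitly.

The synthetic umbrella sampler draws i.i.d. samples from the *exact* biased
density by inverse-CDF on a fine grid — clean statistics for validating the
estimator — with an optional Gaussian-copula AR(1) correlation that
preserves the exact marginal for block-averaging tests. Real MD samples are
correlated in more structured ways (slow orthogonal degrees of freedom,
drift during equilibration); passing these tests shows the estimator is
correct, not that any given simulation is converged.

## Trajectory observables

* **Surface position**: per lipid, the extremal-$z$ oxygen on the
  dye-facing leaflet; averaged across lipids per frame. This is the most
  literal reading of "outermost oxygen", and it is what the water-count
  slab is anchored to.
* **Dipole orientation**: $\mu = \sum_a q_a (r_a - r_{ref})$. For a
  net-charged cation the dipole depends on the reference point, so the
  convention is pinned — the dye center of mass (equal-mass centroid when
  masses are absent) — and configurable. The spread statistic is the
  standard deviation of $\cos\theta$: zero for a point mass, larger for
  broader distributions, directly comparable across temperature groups.
* **Interfacial waters**: water oxygens within 3.5 Å of the surface along
  $z$, one-sided on the water side by default (the side a dye approaches
  from); a two-sided mode exists because published 3.5 Å definitions rarely
  say which is meant. Displaced waters are a difference of means with combined standard
  error.
* **Periodic boundaries**: synthetic frames are generated pre-wrapped and
  no unwrapping beyond minimum-image in $z$ is attempted.

The frame generator plants exact truths (a known surface, an exact
interfacial water count, a prescribed orientation law) rather than
simulating physics; it validates the geometry and statistics of the
analysis code, not force fields.

## Problem sizes

The replicate studies in the test suite and acceptance script use 100
isotherm replicates per parameter set (12 concentrations each), 200 trace
replicates (601 points each), 32 umbrella windows with 1800 samples each
(trimmed to 1400, 4 blocks), and tens of frames with hundreds of atoms —
sizes chosen so the statistical assertions (medians, coverages, 3-sigma
bounds) are sharp while a full run stays in the minutes range on one core.

## Known limitations

* The Gaussian intensity-noise models (constant or proportional) are
  idealizations; real background-subtracted CCD data mix shot, read and
  subtraction noise, and a proportional model understates the noise floor
  of near-zero-intensity points.
* The isotherm model excludes Frumkin/Hill cooperativity and
  electrostatic double-layer corrections; counterion effects enter only
  through the fitted parameters' temperature trends.
* The van't Hoff fit is a straight line (no heat-capacity term).
* WHAM here is strictly one-dimensional, and no autocorrelation-time
  estimation is attempted beyond block averaging.
* Transport fitting is single-exponential; multi-exponential or stretched
  decays, and deconvolution of the ~1 s dye-addition transient, are out of
  scope.
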