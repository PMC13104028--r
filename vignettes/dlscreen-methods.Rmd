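---
title: "Models and methods behind dlscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dlscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dlscreen)
```

`dlscreen` implements the quantitative analysis behind a dynamic-ligation
(acylhydrazone-exchange) fragment screen against a PDZ domain, read out by
fluorescence anisotropy (FA). This vignette is the package's own account of
the models it fits, the conventions and tolerances it adopts, the choices
made where the underlying protocol left the design open, and what the
synthetic-data generators do and do not establish.

## 1. Anisotropy from polarized channels

A plate reader measures two polarized emission intensities per well:
parallel (`S`) and perpendicular (`P`), linked by an instrument gain factor
`G`. The package computes

$$ I = 2PG + S, \qquad r = \frac{S - PG}{I}. $$

`G` defaults to 1 (a G-calibrated instrument) and is a per-plate scalar in
the run configuration. Physically meaningful anisotropies lie in
$(-0.5, 1)$: outside that range one channel intensity would be negative,
so the generator-side inversion (`channels_from_anisotropy()`) enforces it.
Wells with $I \le 0$ carry no information and raise a degenerate-well
error rather than propagating NaN.

## 2. Direct titration: the ligand-depletion isotherm

With tracer at concentration $[FL]$ comparable to its dissociation
constant, the free-ligand approximation is invalid, so the bound-tracer
concentration at total protein $x$ is the exact mass-balance root

$$ y = \frac{(K_D + x + [FL]) - \sqrt{(K_D + x + [FL])^2 - 4x[FL]}}{2}, $$

implemented in the rationalized form $2x[FL]/(s + \sqrt{s^2 - 4x[FL]})$,
which is immune to the catastrophic cancellation the textbook form suffers
when $x \gg [FL]$ (verified against a mass-balance fixed-point oracle to
1e-10 over six decades of concentration).

Anisotropy maps to bound fraction through

$$ L_b = \frac{r - r_{min}}{\lambda\,(r_{max} - r) + (r - r_{min})}, $$

with $\lambda = I_{bound}/I_{unbound}$ fixed to 1 by default (the tracer's
intensity does not change on binding; the parameter is exposed for tracers
where it does).

**Fitting.** `fit_direct_kd()` follows the staged protocol: a sigmoidal
logistic pre-fit estimates the plateaus $r_{min}, r_{max}$; anisotropies
convert to $L_b$; the depletion quadratic is fitted for $K_D$. Two
numerical choices matter:

* *Plateau clamping tolerance.* Noise (and the logistic's own model error —
  it is only an approximation to the depletion curve) pushes points past
  the fitted plateaus. Points within $3\sigma$ of a plateau (replicate SD
  or the pre-fit's residual scale, whichever is larger) are clamped with a
  warning; points further out are a hard error.
* *Joint refinement.* Freezing the logistic plateau estimates biases
  $K_D$ by a few parts in $10^4$ even on noiseless data. The final stage
  therefore re-fits $(K_D, r_{min}, r_{max})$ jointly against the exact
  model, seeded by the staged estimates. On noiseless synthetic data the
  planted $K_D$ is recovered to better than $10^{-6}$ relative.

All nonlinear fits use `nls(algorithm = "port")` (nl2sol) with analytic
initialization — plateaus from the series extremes, midpoint from the
concentration nearest the half-range crossing, slope $\pm 1$ — bounds,
at most 500 iterations and relative tolerance $10^{-10}$. Port handles
zero-residual (noiseless round-trip) data, which the default Gauss-Newton
criterion cannot. Flat series fail fast with a classed fit error instead of
returning garbage.

## 3. Competition: exact ternary equilibrium and logistic IC50

Competition wells contain protein P, tracer L and competitor C sharing one
site. The generative model solves the coupled equilibria exactly by damped
fixed-point iteration on the three free concentrations (damping 0.5,
relative tolerance $10^{-12}$, at most $10^4$ iterations):

$$ P_f = \frac{P_{tot}}{1 + L_f/K_L + C_f/K_C}, \quad
   L_f = \frac{L_{tot}}{1 + P_f/K_L}, \quad
   C_f = \frac{C_{tot}}{1 + P_f/K_C}. $$

Convergence is declared on the *mass-balance residuals*, not the damped
step size — the step size understates the true error when the contraction
is slow (strongly competed systems), which a step-size criterion let slip
to ~$10^{-7}$. The test suite cross-checks the solver against the
closed-form competitive-binding cubic (trigonometric solution, Newton
polished) to $10^{-8}$ on randomized systems.

Empirical potency uses the four-parameter logistic

$$ y = r_{max} + \frac{r_{min} - r_{max}}{1 + (x/x_0)^p}, $$

whose midpoint $x_0$ is reported as the IC50. Plateaus are deliberately
unordered and the slope's sign is free: the parameterization is exactly
symmetric under $(r_{min} \leftrightarrow r_{max},\ p \to -p)$, so
ascending and descending curves fit identically. IC50 is *not* converted
to $K_i$ — the assay reports midpoints, and the package keeps that
convention.

**Why unweighted fits by default.** The staged protocol suggests weighting
points by replicate SDs. With triplicates, each per-point SD has 2 degrees
of freedom (relative error ~52%); inverse-variance weights built from them
correlate with the residuals and bias the fitted midpoint. Measured on the
weak-competitor recovery setup (true midpoint 246.1 uM, 200 replicates),
weighted fits were biased +10.8 uM (3.6 SE) versus +3.2 uM (2.1 SE)
unweighted. `fit_ic50()` and `fit_direct_kd()` therefore default to
unweighted least squares; `weighted = TRUE` restores SD weighting for
deeper replication where it is sound.

## 4. Protocol constants and the mixing model

Concentrations are microMolar everywhere inside the package; unit
conversions happen only at I/O boundaries (a `units` column in an input
file is rejected outright rather than silently reinterpreted).

Each well receives three sequential 20 uL additions (buffer/competitor,
protein, tracer), so every stock is diluted 3x into the final 60 uL —
encoded as `mix_dilution = 3`. The tracer's "50 nM" is read as the stock
concentration, giving 16.7 nM final; the 2-fold serial dilution runs
*before* mixing, so the top final concentration is stock/3. Under this
convention the direct titration spans 66.7 uM to 8e-6 uM protein over 24
points (stock 200 uM) and the competition ladder spans 1666.7 uM to 0.05 uM
competitor over 16 points (stock 5000 uM) — both bracket the relevant
transitions comfortably, which is what matters; an alternative reading
(dilution after the first buffer addition) would shift every concentration
by a constant factor without changing any fitted-parameter conclusions,
since the package fits concentrations as given.

## 5. Screen model: relative anisotropy and mean-minus-3-sigma thresholds

Screen wells are normalized as a *ratio* to the buffer-well mean
(`r_rel = r / mean(r_buffer)`), making thresholds dimensionless and
plate-comparable and rendering hit calls exactly invariant to any common
positive rescaling of the raw anisotropies; a difference mode is available.
Two thresholds are computed per plate from that plate's own control
replicates (no cross-plate pooling):

* `t_neg` — buffer mean minus $k$ SD (negative control);
* `t_pos` — anchor-peptide mean minus $k$ SD (positive control),

with $k = 3$ by default. A fragment is a **hit** when its duplicate-well
mean falls strictly below `t_neg`, and **improved** when it additionally
falls strictly below `t_pos` (it outperforms the anchor peptide itself);
ties are non-hits, and the improved tier is nested inside the hit tier.
Duplicate wells are accepted because the screen is designed in duplicate;
`min_replicates` can require more.

**Control-well count.** The protocol does not state how many control wells
a plate carries. This matters: a 3·SD threshold built from an SD estimated
with few degrees of freedom fluctuates low often enough to inflate the
false-hit rate beyond the nominal 3-sigma tail (with 8 buffer wells the
simulated null rate was 1.4–3.5 per mille against the 1.35 per mille
bound). A 384-well plate running 165 fragments in duplicate uses 330
sample wells, leaving 54; the generator therefore defaults to 24 buffer +
24 anchor control wells, under which the simulated null false-hit rate sits
well below the one-sided 3-sigma tail (duplicate-well averaging alone puts
the idealized rate near $\Phi(-3\sqrt{2}) \approx 10^{-5}$).

## 6. Fragment-library curation

The relaxed rule-of-three filter retains a fragment iff
$80 < M_W < 400$ (strict, Da — widened above the classical rule of three
to leave room for the formyl group every aldehyde fragment carries),
$HBA \le 3$, $HBD \le 3$ and $c\log P \le 5$ (non-strict, following the
printed inequalities). Descriptors in the input table are authoritative —
different cheminformatics engines disagree on clogP/LogS, so computed
values never silently overwrite tabulated ones; `fill_descriptors()` only
fills gaps.

Structural operations (path-based 2048-bit hashed fingerprints for greedy
Tanimoto diversity pruning at a default 0.7 cutoff, and SMARTS substructure
matching for functional-group exclusion) delegate to a bundled RDKit
helper run through the system `python` — no R cheminformatics stack is
assumed. The pruning is greedy in input order and therefore deterministic
for a fixed table; the original library-design tool's similarity metric is
unspecified, so both the fingerprint type and the cutoff are configurable.
The default exclusion-pattern list ships empty: the undesired functional
groups are assay-specific and were never enumerated.

## 7. Exchange kinetics and resin loading

Hydrazone-exchange conversions come from extracted-ion-chromatogram peak
areas, `conversion = area_product / sum(areas)`; extra species columns
widen the normalization, and the quantity is exactly invariant under any
common rescaling of the areas. With aldehyde in 5-fold excess the exchange
is pseudo-first-order, so time courses are fitted with the
single-exponential approach to equilibrium
$c(t) = c_{eq}\,(1 - e^{-kt})$; bi-exponential schemes are out of scope.
The practical-equilibration judgment is formalized as
`equilibration_time(fit, f)` $= -\ln(1-f)/k$ — e.g. 95% of plateau at
$k = 0.125\,h^{-1}$ is ~24 h, matching the workflow's 24 h incubation
choice. Resin loading implements the fulvene-absorbance formula
$L = 101 \cdot A_{301} / (7.8 \cdot m)$ (mmol/g, $m$ in mg), averaged over
the triplicate assay.

The reported 24/48 h conversion ranges cannot be reproduced exactly
because the per-fragment rate constants behind them are not available;
only the model machinery is testable, and the generator's defaults
($c_{eq} = 0.9$, $k = 0.125\,h^{-1}$, the 1–48 h sampling grid) put the
24/48 h conversions at 85.5% and 89.8%, the order of magnitude the
workflow reports.

## 8. ITC: single-site isotherm with displacement bookkeeping

`simulate_itc()` models a single-site titration: after each injection the
cell concentrations update under proportional displacement (an injection
of $dv$ into cell volume $V_0$ displaces the fraction $dv/V_0$ of the
instantaneously mixed contents — the instrument's exact perfusion
correction is proprietary, and this standard approximation agrees with a
brute-force injection-by-injection equilibrium integrator to $10^{-6}$),
the complex concentration is the depletion-quadratic root for totals
$(N \cdot P, X)$, and the injection heat is the enthalpy of the *change*
in cell complex content, correcting for complex expelled by the injection
itself. Heats are reported in uJ and carry the sign of $\Delta H$.

`fit_itc()` recovers $(K_D, \Delta H, N)$ by bounded least squares on a
log-$K_D$ scale; the customary small first injection is dropped by default;
dilution heats are assumed pre-subtracted (a constant-offset nuisance
parameter is available). When the endpoint fills fewer than 90% of sites
the fit warns that $K_D$ is poorly constrained — the regime one of the
measured hybrids actually ends up in under the stated protocol (25 uM cell
at a ~34 uM $K_D$ gives $c < 1$). Thermodynamic bookkeeping uses
$\Delta G = RT \ln K_D$ with $R = 8.314$ J mol$^{-1}$ K$^{-1}$ and
$T = 298.15$ K by default, and the identity
$\Delta G = \Delta H + (-T\Delta S)$ is enforced on records to 0.15 kJ/mol
— the tolerance implied by values printed to one decimal place.

## 9. The synthetic-data generators: what a green test establishes

Every generator is a deterministic function of `(seed, parameters)` and
emits a ground-truth sidecar sufficient to score any downstream stage.
Noise enters either on the raw channels (additive Gaussian on P and S —
the physical noise source; the default SD 0.124 at intensity scale 100
induces $\sigma_r \approx 0.002$ near $r = 0.2$, chosen so triplicate
error bars resemble a realistic plate reader) or directly on anisotropy,
never both in one run. The anisotropy plateaus default to
$r_{min} = 0.05$ (free tracer) and $r_{max} = 0.20$ (bound) — typical FA
values for a FAM-labeled short peptide on a small domain. The anchor
control's true relative anisotropy defaults to 0.8, between buffer and
full displacement, reflecting the anchor peptide's intermediate potency.

The generators emulate the *statistical* structure the analysis assumes:
serial dilution, sequential-addition mixing, replicate structure, Gaussian
channel noise, duplicate screens with planted effect sizes. They do not
emulate scattering or inner-filter artifacts, plate-position (edge)
effects, pipetting bias, aldehyde cross-reactivity, or raw chromatogram
shapes. A green recovery test therefore establishes that the estimators
are correct and well-calibrated *under the assay's own model*, not that
the model captures every systematic error of a real plate.

Planted-potency calibration (`calibrate_competitor_kd()`) chooses the
competitor $K_D$ whose *noiseless* exact-equilibrium curve, fitted with
the logistic, has its midpoint at a requested IC50 — so recovery tests
compare noisy estimates against a target that is exactly attainable by
construction, separating estimator bias from model mismatch.

## 10. Known limitations

* IC50s are assay-conditional (they depend on protein and tracer
  concentrations); no Cheng-Prusoff-style conversion is attempted.
* The logistic's midpoint on a partially displaced curve (weak
  competitors near the top of the dilution ladder) carries a small
  positive finite-range bias (~1% at the weakest potency tested); it is
  within the acceptance tolerances but would grow if the ladder stopped
  further from the midpoint.
* The hit-calling false-positive guarantee assumes enough control wells
  to estimate the threshold SD (Section 5); plates with very few controls
  will exceed the nominal tail rate.
* Multi-site and cooperative binding, competitive ITC, Z'-factor plate
  quality metrics and vendor binary formats are out of scope.
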