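---
title: "Modelling electrochemical HOCl generation and transport in an electrified catheter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling electrochemical HOCl generation and transport in an electrified catheter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, eval = FALSE}
library(ecathsim)
```

## The system

An electrified catheter generates hypochlorous acid (HOCl) in place by
electrolyzing the 0.9% NaCl solution that fills its lumen. Two wire
electrodes run axially through the hub (and optionally further down the
device): chloride is oxidized to HOCl at the working electrode (anode),

Cl⁻ + H₂O ⇌ HOCl + H⁺ + 2e⁻,

and hydrogen evolves at the counter electrode (cathode),

2H⁺ + 2e⁻ ⇌ H₂.

The solution is stagnant and unbuffered, so the H⁺ released by chloride
oxidation and by HOCl degradation directly sets the local pH. `ecathsim`
simulates the coupled electrode kinetics, homogeneous chemistry and
diffusive transport of ten species (HOCl, ClO⁻, ClO₂⁻, ClO₃⁻, O₂, H⁺, H₂,
OH⁻, Cl⁻, Na⁺) over polarization/relaxation schedules of days.

## Homogeneous chemistry

Two acid–base equilibria are treated *kinetically*: HOCl ⇌ ClO⁻ + H⁺ at
rate k_a (c_HOCl − c_ClO c_H / K_a,HOCl) and water autoionization at rate
k_a* (1 − c_OH c_H / K_a,H₂O). The rate constants (k_a = 1000 s⁻¹,
k_a* = 1000 mol m⁻³ s⁻¹) are deliberately large so the solution tracks the
mass-action equilibria everywhere; the test suite verifies relaxation to
within 0.1% of both equilibrium constants in well under a second of
simulated time. Treating the equilibria kinetically (rather than
eliminating them algebraically) keeps the state vector plain concentrations
at the price of stiffness, which the implicit integrator absorbs.

HOCl degrades through four reactions:

| reaction | rate law | constant (tabulated) | reference T | E_a |
|---|---|---|---|---|
| HOCl → H⁺ + Cl⁻ + ½O₂ | K₀ c | 4.65×10⁻⁴ min⁻¹ | 30 °C | 19 kcal/mol |
| 2 HOCl → 2H⁺ + Cl⁻ + ClO₂⁻ | K₁ c² | 0.45 L mol⁻¹ min⁻¹ | 30 °C | 15 kcal/mol |
| HOCl + ClO₂⁻ → H⁺ + Cl⁻ + ClO₃⁻ | K₂ c c' | 3×10⁻³ L mol⁻¹ min⁻¹ | 30 °C | 15 kcal/mol |
| HOCl + ClO⁻ → H⁺ + Cl⁻ + ClO₂⁻ | K₃ c c' | 7.5×10⁻⁶ L mol⁻¹ min⁻¹ | 60 °C | 15 kcal/mol |

All constants are converted to SI once at load time (a table-driven test
pins the conversions) and moved from their reference temperatures to the
local cell temperature with the standard Arrhenius correction
k(T) = k(T_ref) exp(−(E_a/R)(1/T − 1/T_ref)), R = 1.9872×10⁻³
kcal mol⁻¹ K⁻¹. The stoichiometries conserve chlorine atoms and charge
exactly, which the suite asserts at the rate level for random states. The
chlorite and chlorate acids are strong and enter directly in ionic form;
chlorate carries charge −1. Two additional speciation rate constants
(k_HOCl = 3.4 and k_ClO = 44000 m³ mol⁻¹ s⁻¹ with their activation
energies) are tabulated with the network and accepted by `chem_params()`
but are not attached to any reaction in the default model; they are stored
for configurability and left inert.

The initial composition is computed in closed form from the initial pH
(5.5) and NaCl content (154.04 mol/m³): c_H from the pH, c_OH from the
water equilibrium, c_Na = C_NaCl, and c_Cl from electroneutrality (the pH
adjustment is attributed to HCl). All other species start at zero.

## Electrode kinetics

Each electrode is described by its standard reduction potential vs
Ag/AgCl (WE 1.297 V for HOCl + H⁺ + 2e⁻ ⇌ Cl⁻ + H₂O; CE −0.197 V for the
hydrogen couple), exchange current density (0.032 / 0.003 A m⁻²), transfer
coefficient (0.95 / 0.05) and applied potential (1.5 / −0.6 V by default).
The electrolyte potential is taken as zero everywhere (highly conductive
saline), so the overpotential is η = φ_applied − E with E the Nernst
potential computed from the *local* concentrations against a 1 M
(1000 mol m⁻³) standard state. Current density follows the Butler–Volmer
expression with anodic exponent (1−α)Fη/RT; Faraday's law r_e = −i/(2F)
converts it to a reaction rate per wire area, distributed over the species
by the reaction stoichiometry. Exponent arguments are capped at ±50 purely
as an overflow guard; the cap never binds at operating potentials.

Two numerical choices matter here:

* **Trace floor.** At t = 0 the products (HOCl, H₂) are exactly zero and
  the Nernst logarithms diverge. Concentrations are floored at
  ε = 1×10⁻¹² mol m⁻³ *inside logarithms only* (the state itself is never
  modified), which turns the initial singularity into a large-but-finite
  driving force. Because the floored term leaves the logarithm within the
  first moments of polarization (products accumulate past ε almost
  immediately) the 48 h results are insensitive to the exact ε; the system
  is kinetically, not thermodynamically, limited after the first instants.
* **Concentration feedback.** As HOCl and H⁺ accumulate at the anode the
  Nernst potential rises, the overpotential shrinks, and the current
  falls — the simulated anode current is strictly decreasing during
  constant-potential runs (a property the suite enforces). Absolute
  production over long runs is therefore sensitive to how this feedback is
  treated: formulations that hold the redox potential at its initial
  (regularized) value sustain the initial current indefinitely and yield
  roughly twice the accumulated product of the full local-feedback
  treatment used here. `ecathsim` always applies the feedback with local
  concentrations, consistent with the Nernst expressions above.

## Geometry and dimensional reduction

The catheter is a stack of four straight cylindrical segments — hub
(32.6 mm × 5.4 mm), Luer top (6.4 mm × 4.0 mm), Luer bottom
(12.2 mm × 1.6 mm) and tube (300 mm × 1.6 mm), 0.3512 m in total — at
25 °C except the tube at body temperature (37 °C), with D ∝ (T/298 K)^{3/2}.
The dominant concentration gradient is axial: the radial diffusion time
over the hub radius (~1.8 h for HOCl) is short compared with 48 h runs, so
cross-sections are treated as well mixed and the model is reduced to one
axial dimension with variable cross-section. Each cell carries its fluid
area (lumen minus wire cross-sections), the wire lateral area π d Δx of any
electrode passing through it, and its temperature. Electrode surface fluxes
become volumetric sources via the wire-area/fluid-volume density a/V.

Two consequences of the reduction should be kept in mind when comparing
with fully three-dimensional solutions:

* "maximum near the electrode surface" becomes "axial maximum over
  wire-bearing cells" — the radial boundary layer around a 0.245 mm wire is
  not resolved (it contributes of order 0.1 mM at typical operating
  currents, estimated from flux × r_wire ln(R/r)/D);
* the radial offset between working and counter electrodes in the hub is
  meaningless in 1D and is dropped; both wires occupy the same cells.

**Discretization.** Finite volumes with species-fastest state ordering
(Jacobian half-bandwidth = 10). Interior face fluxes use the exact series
diffusion resistance of the two adjoining half-cells,
G = 1/(h₁/(A₁D₁) + h₂/(A₂D₂)), which reduces to the usual harmonic-mean
conductance within uniform segments and remains second-order accurate
across the abrupt area changes at segment junctions. (The simpler
convention of assigning the smaller adjoining cross-section to the junction
face was tried first and rejected: its first-order junction error kept the
smaller compartments from meeting the 1% self-convergence requirement at
practical resolutions.) Both domain ends are no-flux. The default
resolution is 30/5/10/200 cells per segment (245 cells); halving Δx changes
48 h compartment-average HOCl by < 0.2% (tested).

## Time integration

The semi-discrete system (2450 unknowns at default resolution) is stiff —
the kinetic equilibria relax on microseconds, the schedule spans days — and
is integrated with backward-differentiation formulas
(`deSolve::lsode`) using an internally generated banded Jacobian.
Default tolerances: rtol 10⁻⁶, atol 10⁻⁹ mol m⁻³ (overridable). Phase
boundaries in the polarization schedule are hard integration restarts;
switching off is modelled as source removal (open circuit), not a potential
ramp. The solver may produce transient negative concentrations of order
atol; rates and logarithms use the ε floor, and a run fails if negatives
beyond 10·atol persist at a phase end. Electrode currents and conservation
totals are recorded at every snapshot; `conservation_audit()` checks
chlorine and sodium drift (< 10⁻⁴ required) and reconciles the change in
total ionic charge against ∫(I_we + I_ce) dt / F.

## Scenario presets

| preset | layout | schedule |
|---|---|---|
| S1 | WE + CE in hub, d = 0.245 mm | 48 h at 1.5 / −0.6 V |
| S1-relax | as S1 | + 120 h open circuit |
| S2-1.7, S2-1.9 | as S1 | WE at 1.7 / 1.9 V |
| S3 | WE through connectors and tube (d = 0.245 mm), CE in hub | 48 h at 1.5 V |
| S4 | hub WE d = 0.615 mm, connector/tube WE d = 0.054 mm | 48 h at 1.5 V |

S4's diameters equalize the wire-area/fluid-volume ratio of hub and tube to
within 2% (asserted in the tests), the design intent being uniform
generation per unit volume. In S3 the working electrode passes through the
Luer segments as well as the tube; the Luer-bottom segment has the highest
wire-area/volume ratio and is where HOCl peaks.

## What the tests do and do not show

The suite verifies the implementation against independent references:
closed-form Arrhenius/Nernst/Butler–Volmer values, the semi-infinite erfc
diffusion solution (≤ 1%), a deliberately naive fixed-step explicit
chemistry integrator (≤ 0.1% on shared-validity instances), exact
chlorine/sodium/charge bookkeeping, equilibrium fixed points, grid
self-convergence, monotone anode-current decay, and the ordering of 48 h
maxima with applied potential. Scenario regression values in the acceptance
tests are compared against a reference three-dimensional finite-element
study of the same device at a ±20% band; the concentration-magnitude
comparisons are sensitive to the electrode-feedback treatment discussed
above, and several sit below that band under the full local-feedback model.
None of this validates the chemistry against laboratory measurements of an
actual device; parameters are literature values, and phenomena outside the
model (convection during flushes, buffering by biological fluids, chlorine
outgassing, electrode fouling) are out of scope by design.

Problem sizes were chosen so the whole suite runs in about half a minute:
scenario runs integrate the default 245-cell grid once each (cached across
test files), the convergence check doubles it, and oracle instances use
two-cell or single-segment grids.

## Known limitations

* 1D axial reduction: no radial boundary layer, no 3D wire placement.
* Diffusion only — no ionic migration (justified by the high, nearly
  uniform conductivity of saline) and no convection.
* No gas escape: O₂ and H₂ accumulate as dissolved species.
* Unbuffered chemistry only; no chloramines, no reactions with biological
  substrates.
* The O₂ diffusion coefficient is not part of the tabulated parameter set;
  the standard literature value 2.1×10⁻⁹ m² s⁻¹ is used. O₂ is a terminal
  product, so this affects only its own profile.
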