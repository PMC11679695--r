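---
title: "Modelling calcium-phosphate bone-graft behaviour in physiological fluids"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling calcium-phosphate bone-graft behaviour in physiological fluids}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(capkin)
```

## The problem

Brushite (dicalcium phosphate dihydrate, DCPD, CaHPO4.2H2O) is a
resorbable bone-graft ceramic. Immersed in a physiological fluid at
pH 7.4 and 37 degC it sits below its solubility limit while the same
fluid is supersaturated with respect to octacalcium phosphate (OCP,
Ca8(HPO4)2(PO4)4.5H2O), so the implant surface simultaneously dissolves
and grows a new OCP layer:

    CaHPO4.2H2O            -> Ca2+ + HPO4(2-) + 2 H2O
    8 Ca2+ + 6 HPO4(2-) + 5 H2O -> Ca8(HPO4)2(PO4)4.5H2O + 4 H+

`capkin` implements the full numerical chain needed to model this
bilateral material-medium interaction: medium speciation, saturation
thermodynamics, semi-empirical interface kinetics with protein
inhibition and medium exchange, classical nucleation theory (CNT)
cross-checks, and parameter estimation, together with a synthetic-data
generator that stands in for gravimetric/potentiometric time series.

## Speciation of the model media

Two media are packaged: Tris-buffered simulated body fluid (SBF,
inorganic blood-plasma analogue) and DMEM cell-culture medium, plain or
with 3.2 g/L serum albumin representing the 90 % DMEM + 10 % FBS
mixture. The solver distributes the analytical totals of Ca, Mg, total
inorganic phosphate, total carbonate and total sulfate over free ions,
acid-base forms and ten Ca/Mg ion pairs at fixed pH, using fifteen
association/dissociation equilibria (conditional constants for
I = 0.15-0.2 M at 37 degC, used at face value with concentrations).
When albumin is present, a three-site Scatchard term

  [CaAlb] = C_Alb * sum_i k_i [Ca] / (1 + k_i [Ca]),  k = 361, 314, 291

joins the calcium balance. Unknowns are the free Ca2+ and Mg2+
concentrations on a log scale (guaranteeing positivity), solved by a
damped Newton iteration; at given (Ca, Mg) the phosphate, carbonate and
sulfate ladders are linear in one master species each and are
eliminated in closed form, so those balances close to machine
precision and the default residual tolerance of 1e-10 mM refers to the
cation balances. The initial guess is the analytical totals; a
convergence failure is reported with the worst residual.

Single-ion activities use the Davies model, `lg gamma = -A z^2
(sqrt(I)/(1+sqrt(I)) - 0.3 I)` with A = 0.5231 at 37 degC, valid for
I between 0.1 and 0.3 M (a warning, not an error, outside). The ionic
strength is computed once from the analytical totals, counting
protonated Tris (default total 50 mM) as a monovalent cation; for the
SBF recipe this reproduces the working value I = 0.207 M. pH is read
as hydrogen-ion *activity* (the operational pH-meter definition), so
the mass-action concentration is `10^-pH / gamma_1`.

Three interpretation choices deserve record, because the tabulated
constants this model builds on are not fully self-consistent:

* **The carbonate ion pair.** The commonly tabulated source value
  lgK(CaCO3(aq)) = 8.63 is the calcite *solubility product* at
  37 degC, not an ion-pair constant. Used as an association constant
  it drives essentially all calcium into CaCO3(aq) (free Ca ~ 2 umol/L
  in SBF, S_DCPD ~ 0.02), contradicting the well-established mild
  undersaturation of SBF with respect to brushite (S_DCPD ~ 0.76).
  `capkin` therefore ships the standard ion-pair value lgK = 3.22; the
  table is user-editable (`default_equilibria()`, `read_equilibria()`).
  The sulfate pair constant 4.43 (close to the gypsum solubility
  product) is retained at face value: it leaves the system physical and
  moves S_DCPD(SBF) toward the published 0.76.
* **The OCP ion activity product.** The solubility product
  2.5e-99 at 37 degC is the square of the conventional half-formula
  (Ca4H(PO4)3) product, i.e. it refers to the hydrogen-convention
  dissociation `Ca8H2(PO4)6 -> 8 Ca2+ + 2 H+ + 6 PO4(3-)`. The default
  OCP phase therefore uses IAP = a(Ca)^8 a(H)^2 a(PO4)^6 with n = 16
  ion units in `S = (IAP/Ksp)^(1/n)`. Pairing the same Ksp with the
  frequently written HPO4-form product a(Ca)^8 a(HPO4)^2 a(PO4)^4 is
  inconsistent by the square of the phosphate third dissociation
  constant (~10^24.7) and yields S_OCP ~ 180 for SBF, which would
  convert the sample in seconds under the fitted rate constants. With
  the hydrogen convention the packaged SBF gives S_OCP = 2.46,
  matching the working initial supersaturation ~2.4 used in the CNT
  estimate of the critical radius, and keeps the fitted constants on
  14-day timescales. `phase()` is fully general (named exponents over
  any species with activities, arbitrary Ksp and n), so any other
  convention is one constructor call away.
* **Irreproducible table entries.** No convention we examined
  reproduces the published tabulated saturation values S_OCP = 1.26
  (SBF) / 1.14 (DMEM) together with the published Ksp and phosphate
  constants; they would require a phosphate third pK near 19. The
  package reproduces I = 0.207 M and S_DCPD(SBF) = 0.75 (published
  0.76); S_DCPD(DMEM) computes to 0.48-0.50 against a published 0.54,
  consistent with the independent ~2 % gap between the DMEM ionic
  strength computable from the listed ions (0.1645 M) and the
  published 0.168 M - the DMEM recipe contains unlisted constituents.
  These residual discrepancies are reported, not patched.

## Kinetics

Rates follow the semi-empirical laws

    J_DCPD = k1 * s1 * sigma_DCPD^n1          (dissolution, g/s)
    J_OCP  = beta_kink * k2 * s2 * |sigma_OCP|^n2   (growth, g/s)

with sigma = 1 - S, effective orders fixed at n1 = 1 and n2 = 4, and
regime gating: dissolution only when S_DCPD < 1, growth only when
S_OCP > 1 (the power laws are never evaluated against an unphysical
backward driving force). Rate constants are handled as pk = -log10 k;
the published fitted values are pk1 = 6.87, pk2 = 7.04 (g s^-1 m^-2)
with the area-coupling coefficient delta = 25.01 m^2/g.

Surface areas follow the linear law `s1 = max(0, s1_0 - delta m_OCP)`,
`s2 = s2_0 + delta m_OCP`. The initial DCPD area is mass times
specific surface (0.6477 g x 5.3 m^2/g = 3.43 m^2 for the packaged
tablet); the initial OCP area is a configurable seed
(`s2_seed_fraction`, default 1e-3 of s1_0) so that growth can start.
In the serum protocol the measured total area does not change and the
OCP layer covers the sample within the first days, so `s2_constant`
mode holds s2 at the sample's initial total area while s1 still
shrinks; this is the one place the package deviates from holding s2 at
the seed value, because a seed-sized constant area would produce
milligrams of OCP in two weeks, contradicting the observed phase
fractions and leaving no dissolution/growth balance to produce a
calcium plateau.

Protein inhibition enters as a multiplicative prefactor
`beta_kink = exp(dG_ad/RT) = 1/K` from the Langmuir adsorption
constant of albumin on OCP (K = 1.52 gives 0.658, published as
~0.656); it applies to OCP growth only, since serum does not
measurably change DCPD dissolution.

Stoichiometry ties the solid and solution pools together: dissolving
DCPD adds equimolar Ca and P, growing OCP removes them 8:6 and releases
four protons per formula unit into a proton ledger. In
`tris_dynamic` mode the ledger titrates the Tris/TrisH+ pair
(pKa 7.72 at 37 degC) and the pH follows Henderson-Hasselbalch,
erroring if the buffer capacity is exceeded; in `fixed` mode the
carbonate/CO2 system pins the pH (7.4).

Integration is quasi-static - solution equilibria are fast relative to
interfacial kinetics - so the speciation is re-solved at every
right-hand-side evaluation (warm-started from the previous solution).
The stiff integrator `deSolve::lsoda` advances the five-dimensional
state (two solid masses, two solution totals, proton ledger) in
segments between exchange events, at default tolerances rtol = 1e-10 /
atol = 1e-12; rates are clamped to zero when the corresponding solid is
exhausted. Because the state derivatives are exactly stoichiometric,
solid+solution Ca and P are conserved between exchanges to integrator
precision (observed ~1e-15 relative over 14 days). Medium exchange is
applied instantaneously at multiples of the exchange period *after*
the event-time state is recorded, so sampled values at event times are
the pre-exchange "daily measurements"; the retrieved volume is
replaced by fresh medium (the only reading consistent with a sustained
calcium plateau), and the proton ledger is diluted by the same
fraction.

Two protocol presets mirror the study conditions: `protocol_model_I()`
(static SBF, Tris pH, both areas evolve) and `protocol_model_II()`
(daily half-volume replacement of DMEM+FBS, fixed pH 7.4, constant
OCP area). The serum simulation with the published constants produces
a flat second-week pre-exchange free-calcium plateau at 0.70 mM
against a published ~0.8 mM; the 13 % gap follows directly from the
DMEM speciation discrepancy recorded above (a medium whose published
S_DCPD of 0.54 exceeds what its listed ions support binds more
calcium in our solver than in the published one), and we report the
computed value rather than adjust constants toward the published one.

## Classical nucleation theory

CNT quantities are computed per nucleus with the molecular volume
V_cell/Z (OCP: 1220 A^3, Z = 2) and Boltzmann kT, which keeps the
Boltzmann exponent dimensionless and is algebraically identical to the
molar form for the critical radius `r_c = 2 v gamma / (kT ln S)`. With
the OCP-fluid interfacial tension 4.3 mJ/m^2 and S = 2.4 at 310 K this
gives r_c = 1.40 nm. The barrier satisfies the sphere identity
`dG* = (4 pi / 3) gamma r_c^2` exactly, and the rate is
`J = beta_kink B exp(-dG*/kT) f(R', m)` with the kinetic prefactor B
left free (it is absorbed into the intercept wherever curves are
compared). Only the documented limit of the foreign-particle factor is
implemented - micrometre DCPD plates against a nanometre nucleus give
R' -> 0, and the lattice mismatch gives m -> -1, hence f = 1; any other
(R', m) raises a `capkin_not_implemented` condition rather than
guessing the uncited interpolation formula.

`cnt_consistency_fit()` regresses the log growth rate on
log |sigma_OCP| inside a high-supersaturation window and overlays the
CNT curve on the same abscissae. By default the rate is normalised by
the instantaneous OCP area (J/s2): along a trajectory s2 grows
autocatalytically, and the raw parametric curve (ln sigma(t), ln J(t))
mixes that area growth into the slope (it comes out near -2 instead of
n2); the area-specific rate isolates the driving-force power law and
recovers the slope 4 exactly on noise-free data.

## Parameter estimation

The objective is weighted least squares,
`phi = sum_k W_k (obs_k - pred_k)^2` with inverse-variance weights
W_k = 1/sd_k^2 (a `1/sd` option exists), over the fit-role
observations; predictions come from a fresh forward integration at the
observation times, and an integration failure yields an infinite
objective so the stochastic search never crashes. The global stage is
simulated annealing in (pk1, pk2, log delta): geometric cooling
(T0 = 1 scaled by the starting objective, ratio 0.95, 200 steps) with
Gaussian proposals (SD 0.25) clipped to bounds (pk in [4, 10], delta
in [0, 100] m^2/g, bracketing the published values). A bounded local
polish (`nlminb`) runs from the incumbent and is accepted only if it
does not increase the objective. Everything is deterministic given the
seed.

On noise-free synthetic mass data the fit recovers the generating
(pk1, pk2, delta) to ~1e-4 % relative. Under the generator's default
noise the information content of the mass series alone limits delta:
a Fisher-information analysis at the truth gives 1-sigma relative
uncertainties of about 0.7 % (pk1), 1.7 % (pk2) and 16 % (delta), with
strong pk1-delta correlation - delta enters mass loss only through the
gradual area feedback. Median-of-replicates recovery of delta below a
few percent is therefore not statistically attainable from
mass-gravimetry at 0.001 g noise, whatever the optimiser; the held-out
series (free Ca, OCP fraction, surface area - the latter pinning delta
directly) are used for verification (`verify_fit()`), not fitting,
matching the gravimetry-anchored design.

## The synthetic generator

`generate_observables()` integrates the forward model at ground-truth
parameters, samples it at the specification's times (default daily,
0-14 days, at the pre-exchange instants, matching the daily sampling
design), and adds independent Gaussian noise per observable kind.
Defaults - mass 0.001 g, free Ca 0.05 mM, pH 0.05, OCP fraction 0.02,
area 0.3 m^2 - are set to the order of the reported instrument scatter;
Gaussian homoscedastic noise is the minimal assumption since only
mean +/- SD summaries are reported. The OCP fraction is clipped to
[0, 1] and masses/areas to non-negative values; the mass series is
marked `fit`, all others `verify`. Everything is deterministic per
seed, and `make_fixture_bundle()` writes a self-contained
medium/protocol/truth/observables bundle for either scenario.

What the generator does *not* emulate: replicate structure within a
time point (n >= 5 in the underlying design; a per-point SD stands in),
autocorrelated drift, heteroscedasticity, or any systematic error of
the XRD phase quantification (omega_OCP is generated as a mass
fraction directly; the RIR converter
`omega_ocp_from_intensities()` is exercised separately). Passing
tests on synthetic data therefore demonstrate internal consistency of
the chain, not robustness to real-measurement pathologies.

## Problem sizes and budgets

The packaged examples and tests run 14-day trajectories with daily to
quarter-day sampling (a single trajectory takes ~0.1-0.5 s), fit three
parameters from 15-point series (a few hundred objective evaluations),
and use 10 seeded replicates for the noisy-recovery study and 1000
zero-length-trajectory draws for the noise-statistics checks - sizes
chosen so the whole suite exercises every stage in a few minutes on a
single core.

## Known limitations

* No Pitzer/SIT activity models; the Davies form with fixed A is used
  throughout, as appropriate for the narrow isotonic range.
* No CO2 partial-pressure equilibration: total carbonate is an input.
* No spatial transport: dissolution and growth are surface-limited,
  consistent with the observation that static and stirred inorganic
  runs coincide.
* No crystal size/shape prediction and no nucleation-site counting;
  delta is a lumped area-mass coupling, not a geometric model.
* The published tabulated S_OCP values and the last ~13 % of the
  serum-plateau level are not reproduced, for the documented
  constant-set reasons.
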