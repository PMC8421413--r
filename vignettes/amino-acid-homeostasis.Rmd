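---
title: "Modeling cellular amino acid homeostasis from transporter kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling cellular amino acid homeostasis from transporter kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aaflux)
```

## The model

Mammalian cells maintain cytosolic amino acid concentrations far above those
of blood plasma or culture media, and they do so almost entirely through
plasma-membrane transport: uptake and efflux are much faster than metabolism
or protein synthesis for most amino acids. `aaflux` simulates this process
from the kinetic and thermodynamic properties of the individual transporters.

Each transporter is described by a small set of established principles:

1. **Substrate saturation.** Binding of each amino acid follows simple
   Michaelis–Menten saturation, `[AA] / (Km + [AA])`.
2. **Competition.** Substrates sharing a carrier compete; the apparent Km of
   substrate *i* is inflated to `Km_i (1 + sum_a [AA_a]/Km_a)` over the other
   substrates *a* of the same membrane face. The fractional saturations of
   all substrates on a face therefore sum to the carrier's total occupancy,
   always below 1.
3. **Ion coupling.** Saturation by each coupled ion (Na+, K+, H+) follows a
   Hill equation; cotransported ions bind on the same face as the substrate,
   antiported ions on the opposite face. The couplings multiply.
4. **Membrane potential.** Translocation of a complex with net charge z is
   scaled by `beta = exp(-z F 0.5 dPsi / (R T))` — a symmetric barrier at
   the midpoint of the field — applied as a multiplier in the favored
   direction and a divisor against it.

A cell model is a roster of transporters plus cell volume, a protein-to-cell
correlate, ion conditions, and optional first-order metabolic conversions
(glutamine to glutamate; cystine to two cysteines) and depletions. The
engine holds the extracellular pool fixed, computes every transporter's
per-substrate influx and efflux at the current cytosolic concentrations,
converts the summed net fluxes into concentration increments through the
cell volume, and steps forward explicitly until the pool stops moving. The
resulting equilibrium is a property of the transporter endowment and the ion
gradients, not of the starting concentrations — except for rosters made
exclusively of 1:1 exchangers, where the conserved cytosolic total is set by
the initial pool and only the proportions equilibrate.

## Thermodynamic consistency

A kinetic scheme of this kind can easily violate the second law if its
parameters are unconstrained, so three rules are enforced or audited by
`validate_model()`:

* One Vmax governs forward and backward flux of a carrier.
* Uniporters and symporters must carry identical Km on both faces;
  otherwise they would accumulate substrate with no driving gradient.
  Antiporters are exempt and typically carry cytosolic Km values 100–1000
  fold above the extracellular ones.
* An electrogenic symporter must not accumulate beyond the closed-form
  limit set by its ion gradients and the membrane potential
  (`thermodynamic_limit()`); the full potential exponent
  `exp(-z F dPsi / RT)` governs this equilibrium ratio, while the kinetic
  factor uses the half-barrier form.

The third rule drove the central design decision of the rate laws. The
carriers that can respond to the membrane potential are those that return
empty — the *net-transport fraction*, one minus the trans-face occupancy.
Carriers that return loaded cycle in electroneutral exchange mode. We
implement the unidirectional symporter rate as

```
rate = Vmax * frac_cis * isat_cis * (ntf_trans * beta_dir + effocc_trans)
```

where `effocc_trans` is the ion-weighted substrate occupancy of the trans
face. The first term is net transport (potential-sensitive), the second an
exchange component identical in the two directions, so it cancels from the
single-substrate net flux. Two properties follow by construction and are
verified by the test suite:

* at saturating ion concentrations the factor reduces to the linear blend
  `ntf * beta + (1 - ntf)`, so the potential dependence fades exactly as
  exchange takes over;
* detailed balance: the single-substrate equilibrium ratio is
  `(isat_in / isat_out) * beta^2`, which can never exceed the closed-form
  thermodynamic limit, at *every* substrate occupancy. A simpler
  formulation that multiplies the whole rate by the blended factor fails
  this bound once the trans face saturates, because the cis/trans asymmetry
  of the ion saturation is then no longer attenuated — that failure mode is
  what the `validate_model()` equilibrium audit is designed to catch in
  user-supplied parameterizations.

Antiporters are implemented as a shared exchange cycle: the cycle rate is
bounded by Vmax times the (ion-weighted) occupancies of both faces, and the
inward and outward legs are allocated across each face's substrates by
fractional saturation. Total influx equals total efflux exactly — a pure
exchanger conserves the cytosolic amino acid total to floating-point
precision — which is the minimal mechanism consistent with an obligatory
1:1 exchanger that "cannot mediate net uptake". Mixed Na+-symport/H+-antiport
carriers (SNAT3/5-type) are electroneutral: beta is pinned at 1 and the
accumulation limit is the pure gradient product, about 15-fold under
physiological gradients versus about 95-fold for a SNAT1-type symporter.

Uniporters keep the bare `beta` / `1/beta` factors with no net-transport
correction, mirroring the rule set, which names the correction for
symporters only. The known consequence is that a *charged* uniporter whose
trans face saturates can locally exceed its Nernst ratio; in realistic
rosters this is buffered by the paired cationic efflux route (CAT1 works
against y+LAT2-mediated efflux), but it is a genuine limitation of the
carrier description, not of the integrator.

## Numerical choices

* **Integrator.** Explicit forward Euler with fixed `dt` (default 0.05 min),
  matching the loop structure the method is defined by. A guard warns when
  any species moves more than 5% of its value in one step; a second guard
  aborts when a concentration passes 1 M, which with validated rosters only
  happens for deliberately unbounded stoichiometries (an active EAAT-type
  transporter can in theory accumulate >100 M glutamate — such rosters are
  simulated only to demonstrate the diagnostic).
* **Equilibrium detection.** The run stops when every species above a 1 µM
  floor changes by less than `tol` (default 1e-4) per minute in relative
  terms. The floor keeps trace species from stalling detection; the
  stopping residual scales as `tol` times the slowest relaxation time, so
  stiff-but-slow rosters use a smaller `tol`.
* **Metabolism.** Conversions and depletions are first-order in the source
  pool per minute — the simplest reading of a "fractional rate" — with a
  stoichiometric multiplier (2 for cystine to cysteine).
* **Convergence checks** (divergence, overshoot, equilibrium) run every few
  steps rather than every step; they cost as much as a rate evaluation and
  a stop a few steps late is harmless.

## Parameterization

`vmax_from_flux()` inverts an initial-rate measurement
(`Vmax = v (Km + [S]) / [S]`, rates normalized to one minute);
`vmax_from_expression()` distributes a total transport capacity across a
roster in proportion to relative mRNA expression, for systems (such as
primary myotubes) where direct flux measurements are unavailable. Models are
stored as YAML configs with units declared in the schema and an `estimated`
flag on every Km that is an educated guess rather than a measurement.

The shipped `builtin_model()` rosters ("A549-like", "U87MG-like",
"myotube-like") follow the functional classification of amino acid
transporters — loaders that mediate net uptake (SNAT1, CAT1, B0AT2),
harmonizers that equalize amino acid ratios by fast exchange (LAT1, ASCT2,
ASCT1, y+LAT2, xCT) and controllers that cap accumulation (SNAT3/5, LAT4).
Every constant in them is an order-of-magnitude estimate flagged `est`;
they reproduce the qualitative physiology (glutamine in the tens of mM,
essential amino acids a few fold above the medium, cationic amino acids
barely accumulated, glutamate maintained by glutaminolysis against xCT
efflux) and are intended as starting points, not as replicas of any
measured cell line.

## What the toy generators emulate — and what they do not

`make_toy_model()` builds minimal rosters whose equilibria are known in
closed form: a neutral uniporter (equilibrium equals the medium), a
single-substrate Na+ symporter in a regime where the carrier senses the full
Na+ gradient (equilibrium at the accumulation limit), a symmetric 1:1
exchanger (conserved total, split in proportion to the medium), and
loader/harmonizer(/controller) combinations displaying tertiary active
transport: the loader concentrates its own substrate and the exchanger uses
it to lift a second amino acid it does not itself import above the medium
concentration. Parameters are jittered deterministically per seed;
generators restore the caller's RNG state.

`make_pseudo_observations()` adds multiplicative log-normal noise to a
simulated equilibrium to exercise the agreement statistics
(`pearson_agreement()`, `signed_log2_quadrant()` — the latter clamps
changes below 1 µM to zero before the log, a floor the statistic needs and
which is documented rather than hidden).

Passing tests on these fixtures demonstrates internal consistency — the
engine solves the stated equations, respects conservation and
thermodynamic bounds, and matches a naive fine-step integrator — on
problem sizes of one to three transporters and up to twenty species,
equilibrated over a few simulated hours. They do not demonstrate that any
particular real cell line is parameterized correctly: that requires
measured Km/Vmax tables and measured cytosolic concentrations, which are
exactly what the config format is designed to hold.

## Knockout sensitivity

`knockout_sensitivity()` re-simulates the model with one or several
transporters removed and reports per-species equilibrium fold changes
against the full model (normalized to 1). The expected signatures follow
from the classification: removing a loader shifts shared substrates down,
removing a controller shifts them up, removing a harmonizer produces small
or mixed changes because the pool it equalizes is already harmonized.

## Known limitations

* Carriers are single-state: no alternating-access or multi-substrate
  ordered binding; the exchange-mode decomposition is a mean-field stand-in.
* Charged uniporters can exceed their Nernst ratio at trans saturation (see
  above).
* No organellar compartments, volume regulation, or pH dynamics; ion
  gradients are boundary conditions, not state.
* Hill coefficients above the ion stoichiometry can break the second law;
  `validate_model()` warns rather than forbids, since sub-stoichiometric
  cooperativity is legitimate.
* The equilibrium is found by integration, not root finding; rosters whose
  slowest relaxation is hours long need correspondingly long horizons.
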