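---
title: "Methods: a Dynamic Energy Budget model for plant carbon-nitrogen allocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Dynamic Energy Budget model for plant carbon-nitrogen allocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantdeb)
```

## The modelling problem

Terrestrial vascular plants acquire their resources with different organs
operating in different environments: shoots fix carbon, fine roots take up
nitrogen (standing in here for everything roots collect). Neither organ can
grow from its own harvest alone, so whole-plant growth is an emergent
outcome of inter-organ exchange. `plantdeb` implements a Dynamic Energy
Budget (DEB) model of this exchange with deliberately few state variables
and *no* central optimizing controller: each organ keeps what its own
synthesizing units can use and exports only the surplus.

Two models share one kinetic core:

* the **root-shoot model** (`simulate_plant()`): two organs, each with
  structural biomass, a reduced-carbon reserve and a nitrogen-rich reserve;
* the **root-stem-leaf model** (`simulate_rsl()`): three structural masses
  in series, used to compare Liebig minimum-rule growth with parallel
  complementary SU (PCSU) growth when a stem is interposed between the
  acquiring organs.

## Synthesizing-unit kinetics

A synthesizing unit (SU) turns substrate arrival fluxes into a product
flux. After scaling each arrival by its stoichiometric yield
(`scaled_arrivals()`), the two rules are

* minimum rule: \(j = \min(\rho_1, \rho_2)\) — a perfectly efficient
  idealization of Liebig's law;
* PCSU: \(j = (1/\rho_1 + 1/\rho_2 - 1/(\rho_1+\rho_2))^{-1}\) — parallel
  binding of complementary substrates with stochastic waiting times.

At equal balanced arrivals the PCSU runs at exactly 2/3 of the minimum
rule; the test suite checks this closed form against an independent
stochastic binding-site simulation (one site per substrate, exponential
arrivals, product release when both sites fill). For more than two
substrates the inclusion-exclusion generalization
\(1/j = \sum_{A \neq \emptyset} (-1)^{|A|+1} / \sum_{i \in A} \rho_i\) is
available; the shipped models use only one- and two-substrate SUs.
Acquisition SUs saturate hyperbolically with the environmental
concentration (`saturating_uptake()`); internal SUs are demand-unconstrained
and process whatever arrives.

## The root-shoot flux cascade

State: structural masses \(M_{V,S}, M_{V,R}\) (C-mol), four reserve
densities \(m_{EC,i}, m_{EN,i}\) (C-mol reserve per C-mol structure), plus
cumulative audit pools (products, litter C and N, metabolic CO2, excreted
N, assimilated C and N). Both organs are V1-morphs: surface scales with
volume, so specific rates are size-independent and growth in a constant
environment is exponential and indeterminate.

Each right-hand-side evaluation runs the cascade:

1. **Acquisition.** \(J_{AC} = M_{V,S}\, j_{CAm} f(\mathrm{CO_2})
   f(\mathrm{light})\, A(T)\) and \(J_{AN} = M_{V,R}\, j_{NAm}
   f(\mathrm{soil~N})\, A(T)\), with \(A(T) = \exp(T_A/T_{ref} - T_A/T)\)
   the Arrhenius factor applied uniformly to every rate. By default light
   is a multiplicative saturating factor; `light_mode = "pcsu"` instead
   couples CO2 and light as complementary substrates of one SU. The
   environment is prescribed, never depleted.
2. **Mobilization.** First-order reserve turnover \(\nu\, m\, M_V\), one
   \(\nu\) per reserve class shared by both organs.
3. **Maintenance, then growth.** Maintenance \(p_M M_V\) is paid from the
   mobilized C reserve first, then from the carbon of the N-rich reserve
   (whose nitrogen is then excreted); any shortfall is a recorded deficit.
   What remains feeds the organ's growth PCSU with yields
   \(y_{EC,V}, y_{EN,V}\); a fraction \(\kappa_P\) of its output becomes
   products (wood/dead xylem: no maintenance, no turnover), the rest new
   structure. The growth SU's rejected fluxes are the organ's surplus.
4. **Translocation.** Surpluses cross to the partner organ with efficiency
   \(\eta_T\); the carbon of the losses is respired, the nitrogen becomes
   litter. The shoot's CH2O surplus is the phloem stream that feeds the
   root's assembly SU; the other three surpluses top up the partner's
   corresponding reserves directly.
5. **Reserve assembly with N priority.** In each organ the SU forming the
   N-rich reserve (a PCSU over CH2O and inorganic N, yields
   \(y_{C,EN}, n_{NE}\)) has priority; the C reserve receives only the CH2O
   it rejects. The root SU runs first on the phloem stream and its local
   share \((1-\lambda_N) J_{AN}\); the N it rejects rides the xylem to the
   shoot SU together with \(\lambda_N J_{AN}\). N rejected by the shoot SU
   is excreted and tracked, rather than recirculated, which avoids an
   algebraic loop while conserving nitrogen exactly.
6. **Senescence and resorption.** Structure turns over at \(h_V\); a
   fraction \(\sigma\) of the lost biomass is resorbed. The resorbed
   nitrogen is repackaged into the N-rich reserve (as \(n_{NV}/n_{NE}\)
   C-mol of reserve per senesced C-mol, carrying that carbon with it) and
   the remaining resorbed carbon refills the C reserve; the rest is litter.
   This partition is chosen so resorption creates and destroys nothing.

Reserve densities evolve as
\(\dot m = (\text{inflows} - \text{mobilized})/M_V - m\,\dot M_V/M_V\),
with the dilution term using the *net* structural rate (growth minus
senescence): senescing structure does not carry reserve away here (that is
what resorption represents), and only the net form keeps reserve mass
\(m M_V\) exactly conservative — which the audit below demands.

### Death by carbon starvation

A plant dies when an organ runs a maintenance deficit while both of its
reserve densities sit below `eps_death`. The default threshold is 0.02
(reserves below 2% of structural mass). It cannot be made arbitrarily
small: with resorption active, a starving plant sustains a residual reserve
density of roughly \(\sigma h_V (1 - n_{NV}/n_{NE})/(\nu - h_V) \approx
0.016\) under the default rates, so the threshold marks reserves that are
functionally exhausted, slightly above that floor. Death is located by
sign-change root finding on the indicator and terminates the integration;
there is no structure shrinkage rescue in the default configuration.

### Mass-balance auditing

`mass_balance_audit()` performs two independent checks at every record:
the signed sum of all carbon (and nitrogen) ledger entries must vanish,
and the change in stored element plus cumulative exports must equal
cumulative assimilation. The integrated check closes to the integrator
tolerance (about 1e-9 relative at the default tolerances, asserted at
1e-6); the instantaneous check closes to floating-point roundoff. Injecting
an error into a saved ledger makes the audit report it, which the tests
exercise.

## The root-stem-leaf comparison

Three masses \(m_L, m_S, m_R\); the leaf acquires \(A_C = a_C m_L\), the
root \(A_N = a_N m_R\); growth is \(\dot m_i = g_i - \mu_i m_i\). The stem
sits in series: carbon bound for the root and nitrogen bound for the leaf
must pass the stem's growth SU, which keeps what it uses and shares both
surpluses onward. The three SU fluxes are mutually dependent, and are
resolved at each evaluation by damped fixed-point iteration on the two stem
pass-through fluxes (damping 0.5, relative tolerance 1e-10, initialized
from zero transfer so the resolution is a pure function of the state; the
iteration cap is generous because the map contracts slowly near a
limitation switch). A brute-force nested-grid search over the transfer
fluxes serves as the independent oracle in the tests.

**Stem stoichiometry matters.** The default yields make the stem
carbon-rich and nitrogen-poor (`y_C = (1, 1.5, 1)`, `y_N = (1, 0.5, 1)`),
as wood is. This is not cosmetic: if the stem's C:N requirement is exactly
proportional to the terminal organs', the minimum-rule allocation between
stem and organs becomes indeterminate at balanced streams (the fixed-point
map acquires a neutral direction) and the dynamics are ill-posed there.
With a distinct stem stoichiometry the resolution is unique everywhere and
the two rules separate cleanly:

* **minimum rule** (perfectly efficient SUs): the stem never has to share
  both a carbon and a nitrogen surplus at once, so from a leaf-deficient
  start the leaf grows transiently but root and leaf are eventually cut
  off and decay while the stem absorbs the streams — the plant collapses
  to stems (`classify_outcome()` returns `COLLAPSE_TO_STEM`);
* **PCSU**: the stem's inefficiency makes it reject part of *both*
  streams, the terminal organs always receive something, and all three
  organs settle into balanced exponential growth — with a stem share
  that is large out of all proportion to any physiological service,
  because its central position gives it first access to both streams.

`run_alpha_sweep()` varies the availability ratio \(\alpha = a_C/a_N\) by
scaling \(a_C\) at fixed \(a_N\) (one degree of freedom, matching the
ratio's definition). Because acquisition is linear in mass the dynamics are
homogeneous of degree one, so the sweep renormalizes the state to unit
total mass after every 100 d window — fractions and specific rates are
unaffected, overflow on long runs is impossible — and integrates until the
fraction drift per window falls below 1e-6 (3000 d cap; undrained rows are
flagged, not silently reported). Quasi-steady fractions shift monotonically
from leaves (cheap nitrogen, small \(\alpha\)) to roots (cheap carbon,
large \(\alpha\)), with a positive stem share throughout. Uniform \(\mu\)
leaves the quasi-steady fractions unchanged (it shifts every organ's net
rate equally), so the fractions reflect the SU network alone.

## Numerical choices

* Integration uses `deSolve::lsoda` (stiff-capable; reserve turnover is
  fast relative to structural growth) at `rel_tol = 1e-8`,
  `abs_tol = 1e-10`. These defaults are tight so the elemental audit can be
  asserted at 1e-6.
* States are projected onto the nonnegative orthant at records;
  undershoots beyond 1e-9 raise an error rather than being hidden.
* The temperature-consistency check integrates the second run exactly at
  the Arrhenius-rescaled record times of the first, so states are compared
  index by index with no interpolation error.
* Zero substrate short-circuits every SU rate to zero before any
  reciprocal is formed.
* Tie-breaks: maintenance draws on the C reserve before the N-rich
  reserve; the root assembly SU runs before the shoot's (Fig-5 priority
  wiring); the sweep records the state reached from the shared
  leaf-deficient start.

## Default parameters

Defaults are normalized fixture values (half-saturations 1, maximum
specific assimilation 1, order-one yields, `p_M = 0.05 d^-1`,
`nu = 0.2 d^-1`, `h_V = 0.01 d^-1`, `j_NAm = 0.08`), chosen once so that
the default constant environment supports viable balanced growth; they are
not species measurements. Time is in days, carbon in C-mol (nitrogen in
N-mol). The shipped problem sizes — 500 d fixture runs, a 1000 d
homeostasis run, 41 sweep points — are the package's standard example
sizes; all scale linearly if longer runs are wanted.

## What the synthetic scenarios do and do not show

The scenario generator produces constant, step, seasonal and lognormal-noise
forcings of CO2, light, soil N and temperature. These emulate the *shape*
of environmental variation, not real microclimates: there is no water, no
humidity, no feedback of plant uptake on the soil pool, no self-shading,
and temperature acts through a single shared Arrhenius factor. Passing
tests therefore demonstrate internal consistency (conservation, emergent
homeostasis, the SU-rule contrast) under idealized forcing — not predictive
skill for any real species. Reproduction, defence, maturity partitioning
and mechanistic death beyond the starvation flag are deliberately out of
scope.

## Known limitations

* The minimum-rule three-organ model with *exactly* proportional stem
  stoichiometry is structurally indeterminate (see above); the package
  resolves it only through the default non-proportional yields.
* Shoot-rejected nitrogen is excreted, not stored; in strongly N-pulsed
  environments a vacuolar holding pool would behave differently.
* The starvation threshold is a density cutoff, not a mechanistic damage
  model; death times should be read as order-of-magnitude.
* The damped fixed point slows near SU limitation switches; pathological
  hand-built parameter sets can still exhaust the iteration cap, which is
  reported as an error with diagnostics, never silently.
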