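# plantdeb

Dynamic Energy Budget (DEB) simulation of carbon–nitrogen allocation in
terrestrial vascular plants.

## What this package is for

A plant's organs harvest different resources in different places — shoots
fix CO₂, fine roots take up nitrogen — yet neither can grow without the
other's harvest. `plantdeb` implements a generic whole-plant DEB model in
which coordination between organs is *not* imposed by an optimizing
controller: each organ runs its own synthesizing units (SUs), keeps what
they can use, and translocates only the surplus. Whole-plant homeostasis —
a common exponential growth rate and steady reserve densities — emerges
from the dynamics of the coupled organs.

The package provides, for modellers of plant resource allocation:

* **SU kinetics** (`production_rate()`, `su_process()`): Liebig
  minimum-rule and parallel complementary SU (PCSU) rates. For two
  complementary substrates arriving at scaled rates ρ₁, ρ₂:

  - minimum rule: *j* = min(ρ₁, ρ₂)
  - PCSU: *j* = (1/ρ₁ + 1/ρ₂ − 1/(ρ₁+ρ₂))⁻¹

  At balanced arrivals the PCSU runs at exactly 2/3 of the minimum rule.

* **The root–shoot model** (`simulate_plant()`): two V1-morph organs ×
  (structure + C reserve + N-rich reserve), with saturating acquisition,
  priority formation of the N-rich reserve, maintenance paid before
  growth, product (wood) formation, senescence with resorption,
  surplus-sharing translocation, Arrhenius temperature scaling, and death
  by carbon starvation (inability to pay maintenance) as a terminal event.

* **The root–stem–leaf comparison** (`simulate_rsl()`,
  `run_alpha_sweep()`): three structures in series, with the stem's SU
  interposed on both transport paths. Under the minimum rule the stem
  never shares both surpluses at once and the plant collapses to stems;
  under the PCSU all three organs persist, and the quasi-steady mass
  fractions shift monotonically from leaves to roots as the
  carbon:nitrogen availability ratio α rises.

* **Auditing** (`mass_balance_audit()`): every simulated trajectory
  carries a complete flux ledger; carbon and nitrogen closure is checked
  both instantaneously and in integrated form.

* **Scenario and config tooling** (`make_scenario()`, `load_config()`,
  `fixture_config()`, `plant_deb_cli()`): constant, step, seasonal and
  seeded-noise forcings; YAML/JSON configs with aggregated validation; CSV
  trajectories with reproducibility metadata; JSON summaries; a thin CLI
  (`inst/cli/plantdeb.R`).

## A worked example

Simulate the default plant in a constant, balanced environment and ask
whether whole-plant homeostasis emerges:

```r
library(plantdeb)

p  <- plant_params()                      # normalized fixture parameters
sc <- make_scenario("constant", list(co2 = 1, light = 1, soil_n = 1,
                                     temperature = 293.15))
traj <- simulate_plant(p, sc, settings = solver_settings(t_span = c(0, 1000),
                                                         record_every = 2))
traj
#> <deb_trajectory> model=root_shoot, 501 records over t=[0, 1000] d
#>   final state:  M_V_S=1.197e+19, M_V_R=2.995e+18, m_EC_S=9.297e-01,
#>   m_EN_S=1.530e-01, m_EC_R=6.391e-01, m_EN_R=4.024e-01, M_P=2.040e+18, ...

growth_rate(traj, "M_V_S")$rate   # shoot specific growth rate (d^-1)
#> [1] 0.04410841
growth_rate(traj, "M_V_R")$rate   # root agrees to ~1e-13
#> [1] 0.04410841

mass_balance_audit(traj)
#> <mass_balance_audit> integrated closure: C 1.37e-09, N 5.34e-09 (relative);
#>   ledger closure: C 4.38e-16, N 1.74e-17 (relative)
```

Shoot and root converge to one exponential rate (0.0441 d⁻¹ here) with
constant reserve densities — homeostasis as an outcome, not an input —
and the audit confirms that carbon and nitrogen are conserved to solver
tolerance. A plant in a resource-free environment instead runs down its
reserves and dies of carbon starvation:

```r
starved <- run_config(fixture_config("starvation"))
starved$events[[1]][c("type", "time", "organ")]
#> $type
#> [1] "starvation"
#> $time
#> [1] 22.99444
#> $organ
#> [1] "S"
```

The three-organ contrast of Liebig vs parallel-complementary SUs:

```r
classify_outcome(run_config(fixture_config("fig3a")))  # minimum rule
#> [1] "COLLAPSE_TO_STEM"
classify_outcome(run_config(fixture_config("fig3b")))  # PCSU
#> [1] "BALANCED_GROWTH"
```

The command-line interface wraps the same functions:

```sh
Rscript inst/cli/plantdeb.R make-config --out-dir runs
Rscript inst/cli/plantdeb.R simulate --config runs/config.yaml --out-dir runs
Rscript inst/cli/plantdeb.R audit --config runs/trajectory.csv
```

See `vignettes/plantdeb-methods.Rmd` for the model equations, parameter
meanings, numerical choices and limitations.

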