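# osmosys

Unified van 't Hoff calculations for osmosis systems: forward computation of
osmotic concentration and pressure under real solutes and real membranes, and
inverse estimation of the coefficients that quantify non-ideality.

## The problem

Osmotic pressure in physiology, nephrology and membrane science is taught and
computed through a zoo of van 't Hoff variants — `π = CRT`, `π = gC·RT`,
`π = σC·RT`, `π = (Σ gⱼΦⱼCⱼ)RT`, ... — each valid for one combination of
solute composition, solution non-ideality and membrane selectivity. All of
them are the same law applied to the right concentration, the **initial
osmotic concentration** of a simple osmosis system (solution | membrane |
water):

```
π = RT · OC₀ ,   OC₀ = Σⱼ gⱼ σⱼ Φⱼ Cⱼ
```

with `g` the dissociation number, `Φ` the per-molecule osmotic coefficient,
`σ` the reflection coefficient, and `C` the molar concentration. OC₀ is a
property of the *system* (solution + membrane), distinct from the solution's
intrinsic total-solute-particle concentration `C_TSP = Σ gⱼCⱼ`. Where per-
solute coefficients cannot capture a fluid's collective behaviour, the
extended empirical form applies:

```
π = θ · C_TSP · RT
```

with `θ`, the osmosis-system coefficient, fitted from a measured pressure or
an osmometer reading (`θ = corrected osmolar activity / C_TSP`). For body
fluids θ ≈ 0.93–0.94: ideal predictions overshoot activity-corrected
pressures by ~6 %, and θ absorbs the whole error.

The package is for anyone who computes tonicity, osmolar gaps, or membrane
pressure gradients and wants the membrane-dependence handled explicitly:
simple, composite (S₁-m-S₂) and complex systems (with non-negligibly
permeant solutes, split into osmosis + diffusion subsystems) are all
first-class.

## Worked example

```r
library(osmosys)

nacl <- solute("NaCl", g = 2, phi = 0.93,
               stoichiometry = list(species("Na+", 1), species("Cl-", -1)))
sol <- solution(list(nacl, solute("glucose")), c(0.140, 0.005))

ctsp_ideal(sol)       # 0.285   osmol/L: 2*0.140 + 0.005
ctsp_nonideal(sol)    # 0.2654  osmol/L: Φ = 0.93 applied to NaCl

ctx <- thermo_context(310.15, "mmHg")
osmotic_pressure(oc0_molecule_based(sol, membrane()), ctx)
#> <osmo_pressure> 5133.39 mmHg  (OC = 0.2654 osmol/L, T = 310.15 K)

fit_theta_from_activity(282.0, 299.8)       # plasma osmometry
#> <osmo_theta> theta = 0.940627 (fitted_from_activity)

comp <- composite_system(sol, solution(list(solute("glucose")), 0.25),
                         membrane(), ctx)
composite_gradient(comp)
#> <osmo_gradient> delta_pi = 297.868 mmHg (water flows toward solution_1)
#>   OC_1 = 0.2654, OC_2 = 0.25 osmol/L
```

The first pressure is the fluid's total osmotic pressure at 37 °C against an
ideal membrane; the gradient says the mixed compartment out-pulls a 250 mM
glucose bath by ~298 mmHg, so water moves toward it.

Built-in validation against published sucrose osmometry and body-fluid
osmolarity tables:

```r
validate_sucrose_table()
#> <osmo_validation> sucrose: PASS (22/24 cells matched, 2 flagged)
validate_body_fluids()
#> <osmo_validation> body_fluids: PASS (11/15 cells matched, 4 flagged)
```

Flagged cells are documented printed-rounding discrepancies in the source
tables (see the vignette), excluded from the pass criterion rather than
silently matched.

## Command line

A thin wrapper is installed at `inst/cli/osmo`:

```sh
Rscript inst/cli/osmo compute --system system.json --method molecule
Rscript inst/cli/osmo validate --table sucrose --report cells.csv
Rscript inst/cli/osmo fit-theta --ctsp 299.8 --activity 282.0
Rscript inst/cli/osmo fit-phi --conc 0.2 --pressure 4.77 \
    --pressure-unit bar --temperature-K 295.15
Rscript inst/cli/osmo deconstruct --system system.json --sigma-cutoff 0.95
```

Exit codes: 0 success/pass, 1 validation failure, 2 input error. See
`?osmo_main` for the JSON system-spec and CSV solute-table formats.

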