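---
title: "Osmotic concentration, membranes, and the unified van 't Hoff framework"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Osmotic concentration, membranes, and the unified van 't Hoff framework}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osmosys)
```

## The model

Van 't Hoff's original law, $\pi = C\,RT$, holds for a single non-dissociable
solute in an ideal, very dilute solution against a membrane permeable only to
water. Real solutions dissociate, interact, and face leaky membranes, and
over a century a family of adapted forms has accumulated
($\pi = gC\,RT$, $\pi = \sigma C\,RT$, $\pi = (\sum g_j \Phi_j C_j)RT$, ...).
This package implements the unifying observation that every one of these is
the same law applied to the right concentration:

$$\pi = RT \cdot \mathrm{OC}_0,
\qquad \mathrm{OC}_0 = \sum_j g_j\,\sigma_j\,\Phi_j\,C_j,$$

where, per solute molecule $j$: $C_j$ is the molar concentration (mol/L),
$g_j$ the dissociation number (particles per molecule under the assumed
complete dissociation: glucose 1, NaCl 2, CaCl$_2$ 3), $\Phi_j$ the osmotic
coefficient correcting for solution non-ideality, and $\sigma_j$ the
membrane's reflection coefficient (1 impermeant, 0 freely permeant).

Two quantities are deliberately kept distinct:

* **C_TSP**, the total-solute-particle concentration
  $\sum_j g_j C_j$ (ideal) or $\sum_j g_j \Phi_j C_j$ (non-ideal) — an
  intrinsic property of the solution (`ctsp_ideal()`, `ctsp_nonideal()`);
* **OC$_0$**, the initial osmotic concentration — the membrane-dependent,
  osmotically effective fraction of C_TSP in a *simple osmosis system*
  (solution | membrane | water). It is a property of the system, not of the
  solution; under an ideal membrane the two coincide.

Reflection coefficients can be applied two ways, and both are exposed:

* **molecule-based** (`oc0_molecule_based()`, the default):
  $\sum_j g_j \sigma_j \Phi_j C_j$. This is the only form in which $\Phi$
  participates, because osmotic coefficients are defined per molecule type,
  not per dissociated ion.
* **particle-based** (`oc0_particle_based()`):
  $\sum_i \sigma_i C_i$ over the expanded particle view, allowing different
  $\sigma$ for, say, Na$^+$ and Cl$^-$. No $\Phi$ factor is attached here:
  combining a per-molecule coefficient with per-ion reflection would be an
  invention with no defined semantics, so the particle route assumes an
  ideal solution. The two methods agree exactly whenever all $\Phi = 1$ and
  each molecule's constituent ions share the molecule's $\sigma$ (this is
  property-tested).

Per-species forms only apply when the membrane is exclusively impermeable to
all cations or to all anions; otherwise permeant counter-ions diffuse and
membrane potentials develop. `electroneutrality_check()` surfaces this as a
PASS/WARN verdict — a warning, not an error, because it is an applicability
criterion, not a computational rule, and the package does not model membrane
potentials.

### Composite and complex systems

A composite system S$_1$–m–S$_2$ deconstructs into two mirrored simple
systems (S$_1$–m–H$_2$O and H$_2$O–m–S$_2$); the gradient is the signed sum

$$\Delta\pi = RT\,(\mathrm{OC}_0(S_1) - \mathrm{OC}_0(S_2)).$$

The sign convention is fixed and stated in every output: $\Delta\pi > 0$
means net water movement toward compartment 1. It is computed at $t = 0$
from OC$_0$ as defined; for membranes with permeant solutes the literature
does not fully settle whether the gradient should instead be read after
equilibration, and no kinetics are modelled here.

A *complex* system — one whose membrane passes some solute non-negligibly —
splits into an osmosis subsystem of the impermeant molecules plus a
diffusion subsystem of the permeant ones (`split_complex()`). Classification
is per molecule (so dissociated ion pairs stay together, matching the
canonical inulin-vs-urea example), with a configurable threshold
`sigma_cutoff` defaulting to 0.95: no published number defines "negligible"
permeability, and 0.95 places only near-impermeant solutes in the osmosis
subsystem. The diffusion subsystem is represented, not simulated — no flux
model is attached, and the possibility that the permeant fraction exerts an
anti-osmotic effect during osmosis is noted but not modelled.

### The extended law and $\theta$

When OC$_0$ cannot be assembled reliably from per-solute $\sigma$ and $\Phi$
(heterogeneous mixtures, solute–solute and solute–membrane interactions),
the extended empirical form applies:

$$\pi = \theta \cdot C_\mathrm{TSP} \cdot RT,$$

where $\theta$, the osmosis-system coefficient, is a system-level emergent
property fitted from a measured pressure (`fit_theta_from_pressure()`) or
from an osmometer reading (`fit_theta_from_activity()`,
$\theta = \text{corrected osmolar activity} / C_\mathrm{TSP}$). $\theta = 1$
recovers the ideal law, and $\theta\,C_\mathrm{TSP}$ generalises OC$_0$. In
the extended gradient (`extended_gradient()`) the package pairs $\theta$
with the *ideal* C_TSP, since $\theta$ is defined to absorb the
non-ideality that per-molecule $\Phi$ would otherwise carry; a single
$\theta$ is applied to both compartments, which the caller must judge
appropriate. Fitting $\theta$ as a function of C_TSP (a possible nonlinear
dependence in protein-containing fluids) is out of scope.

## Parameters and units

| quantity | unit | default | notes |
|---|---|---|---|
| $C_j$ | mol/L | — | mM/mOsm accepted at I/O boundaries, converted by 1000 |
| $g_j$ | count | 1 | complete dissociation assumed; partial equilibria not modelled |
| $\Phi_j$ | — | 1 | constant, or a (conc, $\Phi$) table interpolated linearly |
| $\sigma$ | — | 1 (ideal membrane) | per molecule and/or per species, in $[0,1]$ |
| $T$ | K | 298.15 | |
| $R$ | L·unit/mol/K | matches pressure unit | 0.0831446 (bar), 62.3637 (mmHg), 0.0820574 (atm); overridable |
| `sigma_cutoff` | — | 0.95 | complex-system split threshold |

Numerical choices: no rounding is ever applied inside the computational
layer; table-matching rounding lives only in the validation suites. A
$\Phi$ table is never extrapolated — a concentration outside its range is an
error. The empty solution is legal everywhere and yields zero concentrations
and pressures. Ties at $\Delta\pi = 0$ report direction `"none"`; a molecule
exactly at `sigma_cutoff` joins the osmosis subsystem ($\geq$).

Where $\Phi$ depends on concentration in a mixture, the package resolves
each molecule's coefficient at that molecule's own concentration. Whether it
should instead be resolved at total ionic strength is genuinely open in the
underlying theory; the per-molecule convention is exposed and this
limitation documented. Activity-coefficient theory (Debye–Hückel, Pitzer)
and oncotic models for proteins (Landis–Pappenheimer, virial, Donnan) are
non-goals.

Molecules declared without explicit ion stoichiometry are represented in the
particle view by a single neutral placeholder species carrying the
molecule's name with multiplicity $g$: particle totals are conserved and the
electroneutrality check passes trivially. Supply explicit `species()`
entries when per-ion $\sigma$ or charge matters.

## Validation suites

Two embedded reference tables validate the framework end to end.

**Sucrose osmometry** (`validate_sucrose_table()`): constant-volume osmotic
pressures of sucrose solutions at 22 °C, six concentrations from 0.050 to
0.300 mol/L. The suite recomputes the ideal prediction $RT\,C$ (with the
source's rounded RT = 24.54 L·bar/mol), the measurement error, the fitted
$\Phi = \pi_\mathrm{exp}/(RT\,C)$, and OC$_0 = \sigma\Phi C$ with
$\sigma = 1$. The published cells reproduce exactly under one specific
convention, recovered by recomputation: $\Phi$ is rounded to 3 decimal
places *before* forming OC$_0$ (4 dp). Two cells of the 0.050 row carry
precision not derivable from the printed inputs (1.10/1.227 rounds to 0.896,
the table shows 0.897, presumably from an unrounded measurement); they are
flagged as known discrepancies and excluded from the pass criterion rather
than silently matched.

```{r}
validate_sucrose_table()
```

**Body fluids** (`validate_body_fluids()`): total osmolarity (C_TSP) and
corrected osmolar activity of plasma, interstitial and intracellular fluid
at 37 °C. The suite recomputes $\theta$ (4 dp), predicted and corrected
pressures (nearest mmHg, with RT/1000 = 19.3421 mmHg/mOsm), and absolute and
relative errors formed from the rounded integers. Plasma and interstitial
columns reproduce exactly; four intracellular cells differ from
recomputation by one rounding unit (301.2 × 19.3421 rounds to 5826 mmHg, the
source shows 5824, and $\theta$, absolute and relative error inherit the
difference) and are flagged.

```{r}
validate_body_fluids()
```

The headline result — ideal predictions overshoot activity-corrected
pressures by ~6 %, fully absorbed by $\theta \approx 0.93\text{–}0.94$ — is
what the acceptance checks assert.

## What the random-system tests do and do not show

Property tests run on randomly generated compositions (up to four molecules,
$g \in \{1,2,3\}$, concentrations up to 0.5 mol/L, $\Phi \in [0.7, 1]$,
$\sigma \in [0,1]$, temperatures 260–340 K) under fixed seeds. They verify
the structural identities of the framework: particle conservation,
homogeneity, the $\Phi = 1$ reduction, method-1/method-2 equivalence in the
aligned-$\sigma$ limit, $\Delta\pi$ antisymmetry, deconstruction
consistency, split-partition completeness, OC$_0 \leq$ C_TSP, and exact
$\theta$ round-trips (1000 systems, recovered to floating precision; with
1 % multiplicative pressure noise the mean recovered $\theta$ stays within
0.5 % of truth). These ensembles emulate dilute aqueous mixtures; they do
not emulate concentrated solutions, ionic-strength-dependent coefficients,
membrane-potential feedback, or protein oncotic behaviour, so passing them
says nothing about those regimes — the law itself is a dilute-solution law.

Suite sizes (50-repetition unit loops, 1000-system round-trip, 400-system
noise study) keep the full test run around ten seconds while exercising each
invariant across its parameter space.

## Known limitations

* Complete dissociation is assumed; partial dissociation equilibria are not
  modelled.
* $\Phi$ and $\sigma$ must be supplied; nothing is predicted from molecular
  structure or ionic strength.
* No osmosis kinetics: water permeability, flux rates and equilibration
  times are out of scope, as are membrane-potential dynamics for
  single-permeant-ion membranes (the WARN verdict is the boundary of what is
  computed).
* $\theta$ is a constant per system; its possible dependence on C_TSP is
  not fitted.
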