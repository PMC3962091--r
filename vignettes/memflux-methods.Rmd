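---
title: "Modelling uremic-toxin transport across hemodialysis membranes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling uremic-toxin transport across hemodialysis membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(memflux)
```

## The problem

Middle-molecule uremic toxins — solutes of roughly 0.5–60 kDa such as
endothelin (~2.5 kDa), cystatin C (~13 kDa) and interleukin-6 (~21 kDa) —
are cleared poorly by conventional hemodialysis. The hollow-fiber walls of a
high-flux dialyzer are thick (~50 µm), tortuous, and present only a small
open-pore fraction (~5.45%) to the blood, so diffusion of these molecules
through the wall is hindered by three orders of magnitude relative to free
solution. A nanofabricated membrane — a thin sheet (~1 µm) perforated by
straight cylindrical nanopores (radius ~10 nm) — removes most of that
hindrance and additionally admits new driving forces, notably an applied
electric potential.

`memflux` models this design space in the irreversible-thermodynamics
(non-equilibrium) framework: the membrane is treated as a black box, and the
solute flux is written as a sum of independent terms, each a transport
coefficient multiplied by a driving force. No kinetic model of the pore
interior is attempted.

## The flux decomposition

For one solute crossing one membrane, the transmembrane molar flow
$J$ (mol/s) is decomposed into five terms:

$$
J \;=\;
\underbrace{-D_\mathrm{eff} A K_\mathrm{diff} \frac{\Delta c}{x}}_{\text{diffusion}}
\;\underbrace{-\,\frac{D_\mathrm{eff} A C_m z F}{R T}\,\frac{\Delta V}{x}}_{\text{electromigration}}
\;\underbrace{-\,\frac{D_\mathrm{eff} A C_m}{x}\bigl(-4.606\,\mathrm{pH}_1 - 2.303\log_{10}\mathrm{pH}_2^2\bigr)}_{\text{pH (proton-motive)}}
\;+\;\underbrace{K_\mathrm{conv} A C_m J_v}_{\text{convection}}
\;+\;\underbrace{\Omega L_p A (\Delta P + \Delta\pi)}_{\text{ultrafiltration}}
$$

with $D_\mathrm{eff}$ the effective diffusivity in the membrane, $A$ the
membrane area, $C_m$ the solute concentration at the membrane, $z$ the
valence, $F = 96485$ C/mol, $R = 8.314$ J/(mol K), $x$ the membrane
thickness, $J_v$ the volumetric flux, $L_p$ the hydraulic permeability and
$\Omega$ the solute-coupling coefficient. Gradients are taken as uniform:
$\mathrm{d}V/\mathrm{d}x = \Delta V / x$ and
$\mathrm{d}c/\mathrm{d}x = \Delta c / x$; the model evaluates at fixed
thicknesses and performs no spatial discretisation.

Three interpretive choices in this equation are genuinely open, and the
package makes each one explicit rather than silent:

* **Double hindrance.** The diffusion term multiplies $D_\mathrm{eff}$ by
  $K_\mathrm{diff}$ even though $D_\mathrm{eff} = K_\mathrm{diff} D_0$
  already contains the hindrance. `memflux` implements this literal form as
  the default and offers `double_hindrance = FALSE` to drop the extra
  factor; every result object records which was used.
* **The pH bracket.** The proton-motive term's algebra
  $(-4.606\,\mathrm{pH}_1 - 2.303 \log_{10} \mathrm{pH}_2^2)$ is implemented
  literally, and which physical side (blood or dialysate) fills each slot is
  a configurable, logged choice (`ph_order`). Note that the bracket does not
  vanish when $\mathrm{pH}_1 = \mathrm{pH}_2$, so this term should be read
  as an empirical proton-motive contribution, not a gradient law; treat its
  absolute magnitude with caution and its *differences* across conditions
  as the meaningful quantity.
* **Valence.** The toxins' net valences are not established; by default
  $z$ is unset and the electromigration term is reported as a per-unit-
  valence magnitude ($J_\mathrm{electromigr}/z$), flagged `per_z` in the
  result.

Sign convention: positive flux is blood→dialysate. The leading minus signs
are kept, so `delta_c` and `delta_V` are downstream-minus-upstream
differences; every report header restates this.

## From structure to effective diffusivity

**Maximal dimension.** The solute size parameter is the molecule's maximal
linear dimension: the diameter of its atomic point set, i.e. the largest
pairwise inter-atomic distance, which equals the largest extent seen when
the molecule is rotated through all orientations. `max_dimension()` computes
this exactly by blocked all-pairs evaluation. A convex-hull prefilter would
reduce the asymptotic cost, but the structures in scope are a few thousand
atoms, where the exact quadratic evaluation runs in well under a second, so
the package keeps the single exact code path (tested against an independent
`stats::dist()` oracle).

The atom selection behind a reported dimension is a convention, and
`read_structure()` records it: by default the first model only, all chains
of the deposited asymmetric unit, no waters, no hydrogens, no heteroatoms,
alternate locations resolved to the highest-occupancy conformer. Published
dimension measurements of this kind rarely state their selection; ours is a
documented default, adjustable per call (`chains`, `include_hydrogens`,
`include_hetero`, `model`).

**Free diffusivity.** $D_0$ comes from the molar-volume correlation

$$D_0 = \frac{13.26 \times 10^{-5}}{\eta^{p}\, V_M^{0.589}} \quad
[\mathrm{cm^2/s};\ \eta\ \mathrm{in\ cP},\ V_M\ \mathrm{in\ cm^3/mol}]$$

The viscosity exponent is typeset ambiguously in the source literature of
this correlation family: the printed value reads 1.4, while the classical
dilute-aqueous (Hayduk–Laudie) form uses 1.14. Both are selectable
(`eta_exponent`, default the printed 1.4); at 37 °C they differ by ~10%,
which is within the uncertainty of $V_M$ itself. $V_M$ is estimated as
molar mass × partial specific volume (default 0.73 cm³/g, the conventional
value for globular proteins), since the "crystallographic" molar volumes
behind published $D_0$ values are not stated. Water viscosity uses the
Vogel-type fit $\eta(T) = 2.414\times10^{-2}\,10^{247.8/(T-140)}$ cP
(0.691 cP at 310.15 K, 1.002 cP at 293.15 K, within 0.5% of tabulated
values over the liquid range).

Because of the $V_M$ and exponent uncertainty, forward $D_0$ predictions are
soft; the tightly checkable route is *cross-membrane*: infer $D_0$ from a
measured $D_\mathrm{eff}$ in one membrane, predict $D_\mathrm{eff}$ in
another (next section).

**Hindrance.** Two geometries:

* Cylindrical nanopore: the Renkin polynomial
  $K_\mathrm{diff} = 1 - 2.3\lambda + 1.154\lambda^2 + 0.224\lambda^3$ with
  $\lambda = a/b$, solute radius over pore radius, valid to
  $\lambda \approx 0.6$ (warned beyond).
* Open-area wall: $K_\mathrm{diff} = (\varepsilon/(2-\varepsilon))^2$ with
  $\varepsilon$ the open-area fraction of the wall face.

**The λ convention.** The governing text of the hindrance correlation in
the source domain describes $r$ as the molecule's *maximum dimension*, read
literally a diameter, not a radius. `memflux` uses the solute **radius**
($\lambda = (d_\mathrm{max}/2)/b$) by default, for a quantitative reason:
only the radius reading makes the two hindrance formulas mutually
consistent with the published effective-diffusivity table. Inferring $D_0$
from each toxin's measured high-flux wall $D_\mathrm{eff}$ through the
open-area formula ($\varepsilon = 5.45\%$) and re-applying the Renkin
polynomial at $b = 10$ nm reproduces the published nanofabricated values to
0.7% (endothelin), 0.6% (cystatin C) and 3.2% (interleukin-6); the literal
diameter reading misses them by far (and excludes any solute wider than the
pore radius). The literal mode remains available (`lambda_mode =
"literal"`) and every result logs which was used. This cross-membrane
consistency is asserted in the test suite and recomputed by
`scripts/acceptance.R`.

## Parameters that matter

| parameter | meaning | unit | default | why |
|---|---|---|---|---|
| `b_nm` | nanopore radius | nm | 10 | reference nanofabricated design |
| `epsilon` | wall open-area fraction | — | 0.0545 | measured for the high-flux fiber's blood-side face |
| `x_m` | membrane thickness | m | 1e-6 (nanofab), 50e-6 (fiber wall) | the two design points compared |
| `A_m2` | membrane area | m² | 1 | reference scale |
| `S` | sieving coefficient | — | 1 | assumed unhindered sieving for the nanofab design |
| `K_conv` | convective hindrance | — | 1 | no convective hindrance model in scope |
| `T_K` | temperature | K | 310.15 | body temperature |
| `eta_exponent` | exponent on viscosity in $D_0$ | — | 1.4 | printed value; 1.14 selectable |
| `partial_specific_volume` | protein $\bar v$ | cm³/g | 0.73 | globular-protein convention |
| `z` | valence | — | unset | not established; per-valence reporting |

$L_p$ and $\Omega$ default to unset: the ultrafiltration term evaluates
only when both are configured, and setting a pressure difference without
them is an explicit configuration error — matching the model's focus on the
diffusion, electromigration and pH terms.

Concentrations are entered as mass concentrations with explicit units
(ng/L … g/L) and converted exactly to mol/m³ via the molar mass. The
bundled panel uses *normal* plasma concentrations as the reference $C_m$;
uremic concentrations vary between patients and are out of scope. Molar
masses are not part of the published tables; the bundled values
(endothelin-1 2492 g/mol, cystatin C 13343 g/mol, interleukin-6
20900 g/mol) are referenced in the catalog TSV and overridable.

## Non-normative published coefficients

The source results include one linear coefficient per toxin for the
electromigration term (e.g. $3.49\times10^{-9}$ for endothelin, per unit
valence) and one for the pH term (e.g. $492.30\times10^{-12}$). We
attempted to reconstruct these under every plausible convention —
$C_m$ in mol/m³ vs mol/L, potential in V vs mV, $D_\mathrm{eff}$ in cm²/s
vs m²/s, molar masses spanning the literature range — and found no single
convention that reproduces all six (the three electromigration coefficients
alone span four orders of magnitude while the underlying $D_\mathrm{eff}
C_m$ products span two). They evidently depend on unstated valences and
unit choices. `memflux` therefore ships them verbatim in
`reference_flux_coefficients()`, flagged `non_normative`, and never uses
them in computation; the package exposes the formulas and logs its own SI
convention instead. A test asserts both the table's fidelity and that the
package's documented convention does not reproduce it.

## Synthetic data: what it does and does not emulate

Tests must run without structure downloads, so the package generates its
own ground truth:

* `synthetic_structure()` emits fixed-column PDB text whose point-set
  diameter is *exactly* the requested value by construction: two anchor
  atoms sit the target distance apart and all other atoms are
  rejection-sampled strictly inside the open ball spanned by the anchors,
  with a 0.01 Å margin absorbing the PDB format's 3-decimal rounding. The
  guarantee is analytic, not searched-for, and is property-tested across
  100 random specifications. These fixtures exercise the parser and the
  diameter algorithm but do not resemble proteins: no bonding, no secondary
  structure, no realistic density.
* `synthetic_scenario()` pairs a known free diffusivity with a membrane,
  toxin and set of driving forces, and computes the expected flux breakdown
  with a straight-line arithmetic oracle — a plain transcription of the
  five formulas sharing no code with `total_flux()`. Pipeline and oracle
  agree to 1e-12 relative; `infer_d0()` recovers the generated $D_0$
  exactly.

Passing these tests shows the arithmetic and the conventions are
implemented as documented. It does not validate the physics against real
membranes: adsorption, fouling, charge interactions and patient-specific
concentrations are all outside the model.

## Numerical choices

* Diameter: exact blocked all-pairs (block 512 atoms, peak memory
  ~512 × n doubles); ties between equally distant pairs resolve to the
  first pair in block order. Rotation/translation invariance holds to
  1e-9 relative (verified by property test).
* All internal computation is SI (m, s, mol, V, K, Pa); diffusivities are
  carried in cm²/s in result objects because every published value is
  printed in cm²/s, and converted at the flux boundary.
* Degenerate inputs fail loudly: < 2 atoms, empty atom selections,
  molecules wider than the pore, out-of-range λ or ε, pressure terms
  without $L_p/\Omega$, unknown units.
* Report numbers are rendered with explicit fixed significant digits
  (`%.5e`) so golden-file comparisons are byte-stable across platforms.
* Test problem sizes: the diameter oracle comparison runs on 100 random
  point sets up to 400 atoms plus spot checks at 2000; the full suite
  completes in a few seconds on one CPU.

## Known limitations

* Adsorption of proteins to the membrane — a real elimination pathway and
  fouling mechanism — is not modelled.
* The flux terms are uncoupled: no electroneutrality constraint, no
  space-charge, no Poisson–Nernst–Planck solving.
* The pH term is an empirical literal form (see above), and the printed
  per-toxin coefficients are non-normative.
* Normal, not uremic, plasma concentrations parameterise $C_m$.
* Dimension measurements on deposited structures depend on the documented
  atom-selection convention; deposited asymmetric units do not always match
  the biological assembly.
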