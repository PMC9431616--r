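---
title: "Growth-coupled metabolism-and-expression modeling with palme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Growth-coupled metabolism-and-expression modeling with palme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The modeling framework

`palme` implements a metabolism-and-expression (ME) modeling framework
for anaerobic-photoheterotrophic bacteria — purple nonsulfur organisms
such as *Rhodopseudomonas palustris* that grow on organic carbon with
light-driven cyclic photophosphorylation while fixing N2, and that
balance their internal redox state through carbon fixation, nitrogen
fixation and auxiliary NADH sinks.

A plain metabolic (M) model is a stoichiometric matrix $S$ with flux
bounds, solved by flux balance analysis: $S v = 0$, $l \le v \le u$. An
ME model adds the gene-expression machinery as explicit reactions:

* a **transcription reaction** per gene consumes NTP equivalents
  according to the coding sequence, produces one unit of that gene's
  mRNA species, and produces a bookkeeping species `biomass_mrna` with
  stoichiometric coefficient equal to the transcript molecular weight
  in kDa;
* a **translation reaction** per gene consumes amino acids and ATP per
  residue and produces the protein plus `biomass_protein` at the
  protein molecular weight;
* **complex assembly** reactions combine subunit proteins (and rRNAs
  for the ribosome) into catalytic machines;
* a single **biomass dilution reaction**, whose flux is pinned to the
  growth rate $\mu$, consumes the biomass components including
  `biomass_protein` and `biomass_mrna` — so total macromolecule
  synthesis must match growth.

The metabolic and expression layers are tied together by **coupling
constraints** of the form $\mu/k_{cat}$: a reaction carrying flux $v$
consumes its catalyzing complex at rate $(\mu/k_{cat})\,v$ — the enzyme
built for catalysis is diluted by growth, so faster growth demands more
machinery per unit flux. Likewise, translation consumes ribosome
capacity at $\mu L / k_{ribosome}$ and mRNA at $\mu / k_{mRNA}$, and
transcription consumes RNA polymerase at $\mu L / k_{RNAP}$. With
$\mu$ as a variable these terms are bilinear; **fixing $\mu$ makes the
whole system a linear program**. The maximal growth rate is the largest
$\mu$ at which that LP is feasible, found by bisection
(`max_growth()`), mirroring the scan-to-infeasibility protocol of ME
modeling. Flux distributions are reported under a parsimonious outer
objective — minimize $\sum_j |v_j|$ at the pinned $\mu$
(`pfba_fluxes()`) — which collapses alternate optima and selects the
most efficient isozymes; `flux_range()` quantifies any residual
degeneracy instead of claiming uniqueness.

### Turnover numbers

Measured $k_{cat}$ values are rare, so the package assigns them by
solvent-accessible surface area (SASA) scaling: $SASA = MW^{3/4}$ and

$$k_{cat,e} = k_{cat,\mathrm{mean}} \cdot \frac{SASA_e}{SASA_\mathrm{mean}},$$

anchored at a mean turnover of 234{,}000 day$^{-1}$ for a generic
31.09 kDa bacterial enzyme of 283 residues (`assign_kcat()`). The
identity is exact at the anchor, and a 16-fold mass increase yields an
8-fold turnover increase. Rubisco is the exception with measured
per-active-site rates: 3.7 s$^{-1}$ per site for the L8S8 form I (eight
active sites) and 6.6 s$^{-1}$ per site for the L2 form II (two sites);
`convert_per_site_kcat()` raises these to the complex level, since the
coupling consumes whole complexes. Whether published models multiply by
site count is not stated anywhere we know of; multiplying is this
package's documented default and can be switched off by passing
per-site values directly. Temperature enters through the Arrhenius
relation (`temperature_scale_kcat()`); the activation energy default of
50 kJ/mol is a typical enzymatic value used only for qualitative
scans — the temperature analysis proper works with direct $k_{cat}$
multipliers.

### Photoheterotroph-specific constraints

Two constraints specific to this physiology are implemented in
`constraints.R`:

**Rubisco coexpression.** Left to cost minimization alone, the model
expresses only the cheaper form II. Experimentally both isoforms are
expressed, tracking cellular CO2. The constraint ties form I flux to
total CO2 production:

$$v_{\mathrm{rubisco I}} = \left[-\sum v_{CO_2} +
\frac{\mu}{\mu_{max}}\sum v_{CO_2,max}\right]
\cdot \frac{k_{cat,I}}{k_{cat,II}}.$$

$\mu_{max}$ and $\sum v_{CO_2,max}$ are obtained by a **two-pass
protocol** (`calibrate_rubisco_coexpression()`): solve once without the
constraint, record the optimum, then re-solve with it. This is the only
self-consistent reading of the calibration. The bracket can be negative
at operating points that produce more CO2 than the scaled calibration
value; the published formulation is silent on this case. The default
`"nonneg"` mode implements $v_I \ge$ bracket together with $v_I \ge 0$
(the parsimonious objective keeps $v_I$ at that floor, i.e.
$v_I = \max(0, \mathrm{bracket})$); a `"strict"` equality mode is
provided and surfaces infeasibility rather than clamping silently.
The CO2-production sum covers every non-exchange reaction producing
cytosolic CO2 (`co2_producing_reactions()` emits the weighted list).

**Photosynthetic ATP caps.** ATP production is capped per substrate by
its photosynthetic yield, $v_S = v_{ace}\,\phi_S/\phi_{ace}$, with
tabulated caps (mmol gDW$^{-1}$ day$^{-1}$): acetate 54.0, succinate
45.7, butyrate 56.7, p-coumarate 85.4. The cap is applied as an upper
bound on the pmf-driven ATP synthase — the single photophosphorylation
ATP-production step of the model; the "photosystem" here is the single
photosystem of an anoxygenic bacterium. These caps are what ultimately
limit growth at high uptake in the toy network, and their ordering
drives the substrate ordering of maximal growth rates.

**Nitrogenases.** Three independent N2-fixation reactions (Mo, V, Fe)
consume reduced ferredoxin and ATP and release NH3 plus obligatory H2.
Stoichiometries are not published for this organism; the package
defaults follow the standard literature ordering:
Mo: $N_2 + 8\,fd_{red} + 16\,ATP \to 2\,NH_3 + H_2$;
V: $12\,fd_{red}, 24\,ATP, 3\,H_2$;
Fe: $20\,fd_{red}, 40\,ATP, 7\,H_2$. Only the cost ordering
Mo < V < Fe is constrained by observation; it is enforced at
construction (ties are admitted only via `strict = FALSE`, and then the
isozyme choice is degenerate and should be reported through
`flux_range()`).

## The synthetic toy network

The full genome-scale reconstruction (about 1400 reactions) is out of
scope; instead `build_toy_me_model()` generates a seeded ~170-reaction
network that embodies the same structural logic, so that every analysis
stage is testable end to end. What it contains:

* **Substrates** acetate (C2H4O2), succinate (C4H6O4), butyrate
  (C4H8O2) and p-coumarate (C9H8O3) as neutral acids, spanning mean
  carbon oxidation states +0.5 (succinate) to −1 (butyrate). Each has
  an exchange and an active-transport uptake costing 1 ATP per
  molecule.
* **Catabolism**: a lumped TCA-like full oxidation per substrate,
  producing CO2 and NADH according to the electron content
  ($4x + y - 2z$ electrons for $C_xH_yO_z$).
* **Anabolism**: assimilation into generic carbon units (CH2O) runs
  through the TCA route and is obligatorily decarboxylating — 1 CO2 is
  lost per acetate or butyrate, 2 per succinate or p-coumarate, with
  the matching NADH released. This is the crucial design choice: the
  released CO2 + NADH create an internal refixation pressure, so the
  Calvin-Benson-Bassham module is *required* for maximal yield and
  carbon fixation is active at intermediate uptake for every substrate,
  as observed. Without it, CO2 refixation exactly ties with direct
  assimilation and parsimony silently drops rubisco flux.
* **Cyclic photophosphorylation**: photosystem -> quinone pool -> bc1
  (pumping a massless proton-motive quantum, 3 per quinol) -> ATP
  synthase (2 pmf per ATP, the Eq-cap target), plus a proton leak so
  electron transport is not hard-locked to ATP synthesis. Electrons
  enter the chain from NADH (NDH) and leave through the
  ferredoxin-reduction branch — the explicit **ETFD** reaction
  (photon + 2 cyt$c_{red}$ + 2 fd$_{ox}$ -> 2 cyt$c_{ox}$ +
  2 fd$_{red}$). Light makes ATP but no net reducing power: all
  ferredoxin electrons trace back to substrate NADH.
* **CBB module** with real chemistry: phosphoribulokinase,
  rubisco carboxylation duplicated for form I and form II (distinct
  enzymes, distinct $k_{cat}$), phosphoglycerate reduction by NADH or
  by reduced ferredoxin (the fd-coupled variant is what lets elevated
  ETFD flux compete with nitrogen fixation), and the
  ribulose-5P -> ribose-5P drain into nucleotide precursors.
* **Nitrogen**: the three nitrogenases (sole NH3 source; sole H2
  source besides a capacity-limited ferredoxin hydrogenase), ammonium
  assimilation into the amino-acid pool.
* **NADH sinks**: malate dehydrogenase sits on an ATP-free
  amino-acid synthesis route (oxidative oxaloacetate synthesis ->
  MDH -> malate amination); the cell switches from the direct
  ATP-dependent route to this detour when the photosynthetic ATP cap
  binds, which is why MDH flux rises toward maximal growth.
  Glycerol-3-phosphate dehydrogenase supplies the biomass lipid
  precursor and can overflow to secreted glycerol, disposing of excess
  NADH and carbon.
* **Expression layer**: ~20 genes with seeded random coding sequences
  (GC fraction 0.65, lengths 150–900 nt, standard genetic code, no
  internal stops — cosmetic beyond their lengths and compositions);
  RNA polymerase (2 alpha, beta, beta', omega), the 70S ribosome
  (5S 120 nt, 23S 2900 nt, 16S 1542 nt; 31 + 21 proteins, lumped into
  two representative proteins at the stated copy numbers); rubisco I/II,
  the three nitrogenases, MDH and G3PDH carry dedicated gene products;
  every other catalyzed reaction carries the generic 31.09 kDa enzyme.
  mRNAs are diluted through a usage coupling
  ($\mu/k_{mRNA}$, $k_{mRNA} = 10^4$ translations/day) rather than
  consumed stoichiometrically, and have first-order turnover sinks;
  there is no separate degradation pathway.
* **Biomass** (per gDW): 0.55 g protein, 0.03 g mRNA-bookkeeping RNA,
  1.8 mmol amino acids, 0.35 mmol ribose-5P, 0.45 mmol glycerol-3P,
  15 mmol ATP of growth-associated maintenance.

Filler conversions (default 10) carry the generic enzyme and give the
network inert degrees of freedom; one filler carries an isozyme pair
for knockout-redundancy tests.

Determinism: a fixed config seed reproduces the model byte for byte
(`serialize_me_model()`), and building never perturbs the caller's RNG
stream. Elemental balance (C, H, O, N, P, S, Fe) is validated for every
metabolic reaction from the species formulas; redox carriers are
written as explicit hydrogen-carrying pairs (NADH = NAD + 2H,
QH2 = Q + 2H, fd$_{red}$ = fd$_{ox}$ + H) precisely so that this check
is closed. Expression reactions involve macromolecule pseudo-species
and balance only by construction; they are exempt from the element
check, as is the massless photon/pmf pair.

### Free parameters and what they were chosen for

The lumped stoichiometries have no literature values; they are free
parameters with defaults chosen once so that the network exhibits the
physiology the analyses probe — all four substrates support growth,
carbon fixation is active at intermediate uptake and diminishes at
maximal growth, and the electron-distribution experiment has slack to
respond. They are exposed through `toy_network_config(params =)`:

| parameter | default | role |
|---|---|---|
| `pmf_per_qh2` / `pmf_per_atp` | 3 / 2 | chain H+/ATP economy (1.5 ATP per quinol) |
| `gam_atp` | 15 | growth-associated maintenance, mmol ATP/gDW |
| `transport_atp` | 1 | ATP per imported substrate molecule; makes forced surplus uptake compete with the CBB module for capped ATP |
| `hyd_cap` | 2 | ferredoxin-hydrogenase capacity, mmol/gDW/day; bounds cheap H2 venting so that surplus ferredoxin electrons must engage nitrogenase in the sweep, while leaving enough disposal for forced-uptake solves |
| `nitrogenase_fd` | 8/12/20 | reduced ferredoxin per N2 |
| `photon_uptake_cap` | 150 | photon supply; far above use, so the ATP caps bind first |
| `biomass` | see above | composition per gDW |

With these defaults the succinate growth curve saturates at about
0.32 day$^{-1}$; butyrate and p-coumarate support markedly faster
growth than succinate and acetate (as their larger ATP caps dictate),
while the close succinate/acetate pair can order either way. Absolute
values are not comparable to the full reconstruction and are never
asserted.

The toy biomass has a mean carbon oxidation state near 0 rather than
the −0.13 reported for real biomass; the generator makes no assertion
about it (the CH2O carbon-unit abstraction fixes it implicitly).

## Analyses

**Growth profile** (`growth_profile()`): for each uptake value, the
maximal growth rate is found with uptake as an upper bound, then
parsimonious fluxes are computed with uptake pinned to the grid value,
so surplus substrate must actually be accommodated — this is what makes
carbon fixation decline past its peak while the sinks rise. Where
forced full consumption exceeds the network's disposal capacity, the
bounded solve is reported and flagged in the `pinned` column.
`classify_regions()` labels the curve SNL / Janusian / SPL from
central-difference slopes with thresholds $\alpha = 0.9$ and
$\beta = 0.05$ of the maximal slope, made contiguous; labels are
invariant to uniform grid rescaling.

**Electron-distribution sweep** (`etfd_sweep()`): growth and uptake are
pinned, ETFD is pinned at its parsimonious value and at elevated
multiples, and the total rubisco flux is pinned across a grid while
nitrogenase flux is recorded. The operating point defaults to half the
maximal growth rate at the given uptake: at the optimum itself every
flux is forced by the binding constraints and nothing can vary; at half
$\mu_{max}$ with the full uptake still pinned there is genuine slack.
At the parsimonious ETFD level, nitrogenase is the only remaining
ferredoxin sink, so its flux is locked by the electron balance and is
invariant to the carbon-fixation pin. At elevated ETFD the fd-coupled
phosphoglycerate reduction gives carbon fixation a claim on ferredoxin
electrons, so pinning carbon fixation higher strips electrons from
nitrogenase — the negative correlation. Infeasible combinations are
recorded as missing, never fabricated.

**Fold-change validation** (`fold_change_validation()`): per-gene fold
changes A/B against a baseline condition B; greater than one is "up",
less than one "down"; accuracy is the nearest-integer percentage of
direction matches. Exact ties are classified "unchanged" and excluded
from the denominator with a logged count, and baselines below
$\varepsilon = 10^{-9}$ use a pseudo-flux and are flagged — the
published procedure is silent on both cases. `make_expression_fixture()`
builds seeded fixtures whose ground-truth mismatch count is exact, so
23/25 correct gives 92% and 25/37 gives 68% by construction of the
procedure, not by assertion.

**Nitrogenase temperature scan**
(`nitrogenase_temperature_scan()`): cooling is emulated by scaling the
Mo-nitrogenase $k_{cat}$ down (the Arrhenius direction), and the
maximal growth of wild type and single-isozyme mutants
(`nitrogenase_mutant()`, built by knocking out the other gene sets) is
tracked. At multiplier 1 the ordering is WT ≈ Mo-only > V-only >
Fe-only, set by the ATP costs under the binding ATP cap. As the
multiplier falls, the enzyme-usage coupling $\mu/(\gamma k_{cat})$
inflates the Mo-nitrogenase machinery demand until the V-only strain
overtakes — in the default network near $\gamma^* \sim 10^{-4}$. The
scan reports the crossover multiplier.

## Numerical design

The $\mu$-pinned LPs mix coupling coefficients of order $10^{-7}$ with
macromolecule masses of order $10^3$ — ill-scaled and heavily
degenerate. The backend (no LP solver package is available in this
R installation) is:

* a **presolve** that removes fixed variables, dead-end fluxes
  (no-producer/no-consumer propagation — e.g. the subsystems of
  substrates that are not being fed) and singleton rows, which
  eliminates most structural degeneracy;
* a dense **bounded-variable two-phase simplex** with geometric-mean
  equilibration, a Harris-style two-pass ratio test (largest pivot
  among near-minimal ratios), periodic refactorization with iterative
  refinement, and Bland's rule as anti-cycling fallback;
* an escalation ladder: a fast Dantzig configuration first; any
  "infeasible" or breakdown verdict escalates to a near-exact
  configuration (refactorization every 2 pivots, Bland pricing) whose
  verdict is authoritative — a stalled degenerate phase 1 can
  masquerade as infeasibility;
* a **crossover polish**: near-bound variables are clamped and the
  remaining square system re-solved exactly, rescuing drifted but
  basically-correct solves.

Tolerances: bisection 1e-4 day$^{-1}$ by default (the published
protocol used an unspecified incremental scan); steady-state residual
of every returned flux vector at most 1e-6; constraint residuals of the
coexpression row within solver precision (~1e-8). `is_feasible()`
raises on solver breakdown rather than conflating it with
infeasibility; the bisection uses an opt-in conservative mode in which
an unresolvable boundary probe counts as infeasible and can shift the
result by at most one tolerance step. Monotone feasibility in $\mu$ is
an assumption (true for this coupling structure); `max_growth()`
validates it with a 10-point guard scan per solve and falls back to a
fine linear scan on violation. The test suite cross-checks feasibility
verdicts against `quadprog` (an independent quadratic-programming
oracle) on random problems, and bisection against exhaustive grid scans
on five seeded models.

Problem sizes used by the tests and the acceptance script — toy models
of ~170 reactions, uptake grids of 5–6 points, 5 bisection seeds,
two-level ETFD sweeps, two-point temperature scans at tolerance
1e-3 — are the package's choices for a thorough-but-quick default
experience; all stages accept finer grids and tolerances.

## Known limitations

* The toy network is a structural emulator: absolute growth rates,
  uptakes and fluxes are not comparable to the genome-scale
  reconstruction, and nothing kinetic (Michaelis-Menten saturation,
  metabolite concentrations) is represented — the formalism is
  capacity-based.
* Acetate's electron economy is the least redox-stressed of the four
  substrates, and its electron-distribution response is correspondingly
  weak — consistent with observation, but it means sweep tests are run
  on succinate-like conditions.
* tRNA charging, protein translocation, posttranslational modification
  and DNA replication are deliberately excluded, matching the stated
  scope of the formalism for this organism.
* The parsimonious objective reports one vertex of the optimal face;
  statements about individual fluxes should go through `flux_range()`.
* SBML export covers the metabolic subset only (the expression layer
  has no standard SBML representation) and is flagged lossy; no SBML
  validator is bundled, so conformance testing is structural.
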