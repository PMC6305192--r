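---
title: "Cell-type-resolved flux prediction for conifer needle metabolism"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-type-resolved flux prediction for conifer needle metabolism}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resinflux)
```

## The scientific problem

Conifer needles contain resin ducts lined by secretory epithelial cells that
synthesize and excrete oleoresin — a mixture dominated by monoterpenes (C10)
and diterpene resin acids (C20) — while the surrounding mesophyll carries
out photosynthesis. The two cell types share a genome but run strikingly
different metabolic programs: the epithelial cell is heterotrophic (it
imports sucrose, and its plastids are non-photosynthetic leucoplasts),
whereas the mesophyll cell fixes CO2 through the Calvin–Benson cycle.

`resinflux` implements the computational side of comparing these programs:

1. estimating cross-contamination between laser-capture-microdissected
   (LCM) cell-type transcriptomes from marker genes,
2. reconstructing cell-type-specific constraint-based models from a
   reference reaction set plus transcript evidence,
3. building biomass objective functions from measured end-product
   compositions, reference-protein amino-acid profiles, and needle/duct
   geometry, and
4. predicting flux distributions by expression-weighted flux minimization
   (E-Fmin) under varying photosynthetic activity.

A miniature plant-cell network and a transcriptome simulator make every
stage testable without external data.

## Constraint-based model and solver

A model is a set of compartmentalized metabolites (cytosol, plastid,
mitochondrion, peroxisome, plus extracellular space for exchange plumbing)
and bounded stoichiometric reactions, with one designated biomass
pseudo-reaction. Steady-state flux analysis solves linear programs over
$S v = 0$, $l \le v \le u$: flux balance analysis (FBA) maximizes the
biomass flux; flux variability analysis (FVA) reports per-reaction flux
ranges.

Default bounds are $[0, 1000]$ for irreversible and $[-1000, 1000]$ for
reversible reactions, in mmol gDW$^{-1}$ h$^{-1}$; the published fluxes this
work builds on are relative, so the unit convention matters only for
consistency. All LPs are solved by a bounded-variable two-phase primal
simplex implemented in compiled code (`src/simplex.cpp`): phase 1 drives
artificial variables out of the basis, phase 2 optimizes the true
objective; ties in the ratio test are broken by the largest pivot for
stability, switching to Bland's smallest-index rule after $4(n+m)$
iterations to preclude cycling. Tolerances: $10^{-9}$ on reduced costs,
$10^{-10}$ on pivots, $10^{-7}$ on phase-1 feasibility. Fixed variables
(equal bounds) are never priced — they cannot move, and pricing them is a
classic source of stalling. Because all flux bounds are finite, the flux
LPs cannot be unbounded; the status is still propagated for completeness.
The test suite cross-checks the solver against two independent dense LP
implementations on randomized problems, and the E-Fmin objective against an
independently assembled split-variable LP on every toy network.

## The miniature plant-cell network

`make_mini_plant_model()` builds a 65-reaction, 59-metabolite network
containing photon capture and lumped light reactions, a lumped
Calvin–Benson cycle, sucrose import and degradation, glycolysis, the
oxidative pentose phosphate pathway, the citric acid cycle, oxidative
phosphorylation, ethanolic fermentation, both ferredoxin-NADP$^+$ reductase
(FNR) directions, lumped MEP and MVA isoprenoid pathways, terpenoid
synthases, and sinks plus biomass drains for eight end-product classes.
Notable modeling choices, each made once at design time:

* **Lumped stoichiometries** use textbook net equations. The MEP lump is
  GAP + pyruvate + ATP + NADPH + 2 Fd$_{red}$ $\rightarrow$ IPP + CO2
  (the HDS/HDR steps are ferredoxin-dependent); the MVA lump consumes
  3 acetyl-CoA, 3 ATP and 2 NADPH per IPP.
* **Light reactions** are condensed to
  photon + 2 ADP + Fd$_{ox}$ $\rightarrow$ 2 ATP + Fd$_{red}$ + 1/4 O2 — a
  generous lumped quantum yield chosen so that light competes with
  respiration as an energy source at realistic expression weights.
* **The two FNR isoforms** are separate irreversible reactions. The
  non-photosynthetic (reverse) isoform is ATP-coupled
  (NADPH + 2 Fd$_{ox}$ + ATP $\rightarrow$ NADP$^+$ + 2 Fd$_{red}$ + ADP).
  This is a thermodynamic surrogate: without the coupling, the isoform pair
  would itself form a closed futile cycle, and the base network must be
  loop-free so that planted loops can be detected exactly.
* **Non-photosynthetic plastid redox** enters via a lumped
  glucose-6-phosphate/triose shuttle (cytosolic NADPH equivalent
  exchanged for plastidial), the route leucoplasts actually use; without
  it heterotrophic MEP flux would be structurally infeasible.
* **Unit biomass demand.** The biomass reaction's upper bound is 1, so
  "satisfying the objective" means draining the measured composition at
  unit rate; carbon uptake is otherwise unconstrained. FBA optima are
  therefore 1 whenever the demand is satisfiable, and flux predictions
  reflect routing rather than maximal yield. This also keeps the
  photosynthesis titration well-posed: the demand is a measurement and
  must not shrink with the photon supply.
* **Cell-type variants.** The epithelial model imports sucrose and drains
  mono-/sesqui-/diterpenoids plus protein (amino-acid profile of a
  glutathione-S-transferase analog, the most abundant non-photosynthetic
  protein of that cell type); the mesophyll model has sucrose import
  closed, a photon allowance of 200 instead of 40 (its demand includes
  NADPH-hungry end products), and drains chlorophyll, starch, lignin,
  flavonoids and protein (Rubisco-analog profile) plus trace terpenoids.

## Composition tables and the biomass objective

The epithelial composition centers on the needle oleoresin measurements:
monoterpenes 5.76 mg/gDW, sesquiterpenes 0.35 (total volatiles 6.11), resin
acids 3.81 plus other diterpenoids 0.11 (total diterpenoids 3.92). Protein
content is not measured at cell-type resolution; 50 mg/gDW (epithelial) and
150 mg/gDW (mesophyll) are field-plausible estimates, and the mesophyll
table allocates mass to chlorophyll (10), starch (80), lignin (120) and
flavonoids (15), with every terpenoid class held at or below 5% of the
epithelial value.

`build_biomass_reaction()` converts concentrations to drain coefficients
$-c_i / M_i$ (mmol gDW$^{-1}$), so mass balance
$\sum_i |\nu_i| M_i = \sum_i c_i$ holds exactly over non-protein
components. Oleoresin classes are represented by one proxy metabolite per
class with a class-representative molecular weight (α-pinene 136.23 for
monoterpenes, β-caryophyllene 204.35 for sesquiterpenes, abietic acid
302.45 for resin acids). The protein component is expanded into
per-residue drains by mole fraction, using average residue masses (free
amino acid minus one water); in the mini model all residues map to a single
lumped amino-acid pool, so the expansion collapses to one coefficient with
the composition-weighted mean residue mass. A growth-associated ATP
maintenance drain of 30 mmol gDW$^{-1}$ (hydrolyzed to ADP) is included by
default — a mid-range literature value for plant cells; it is configurable
because nothing in the underlying measurements pins it down.

Needle geometry converts bulk-tissue measurements to cell-level outputs.
The proximal two thirds of a needle is treated as a cylinder and the
tapering distal third as an elliptical solid, giving volume
$(8/9) A L$; ducts are cylinders running the full length, so their volume
fraction is $(9/8) \sum a_j / A$, independent of needle length. Passing
this fraction as `scale` divides the oleoresin class concentrations,
turning bulk mg/gDW into epithelial-cell output demands (other classes are
not duct-localized and are left unscaled). Only the geometric part of the
bulk-to-cell conversion is modeled; the time base of the secretion rate is
a unit convention.

## Contamination estimation

The estimator is the single-marker ratio: for a marker assumed absent from
the pure target cell type and abundant in the source type, the contamination
fraction is TPM(target)/TPM(source). With the printed marker abundances
(Rubisco small subunit 13470 vs 33020 TPM) this gives 40.8%; the reciprocal
pair (diterpene synthase, 165 vs 596 TPM) gives 27.7% at one decimal — the
implementation reports the arithmetic of its inputs. Ratios above 1 are
flagged rather than clamped: the estimate is an upper bound, attributing
the entire marker signal to contamination. An optional multi-marker median
is available but off by default, matching the single-marker reasoning the
ratio mimics. The estimator neither corrects nor deconvolves the profiles.

## Reconstruction

* **Transcript association** keeps hits at or above 40% global identity
  (the threshold is configurable; the underlying procedure states the
  criterion but not the number), then, per transcript, only the
  highest-priority database with a surviving hit (Arabidopsis core model >
  AraCyc > MetaCyc), and within it every target within 1 percentage point
  of the best hit — a transcript may support several reactions of a
  multifunctional enzyme, for which no published rule exists, so the
  co-best window is explicit and adjustable. Gene sets are flat: no
  AND/OR gene-protein-reaction logic, matching the flat
  transcript-association procedure, and reaction-level (not
  enzyme-complex-level) mapping is assumed.
* **Expression pruning** removes reactions with no associated transcripts.
  Exchanges, the biomass reaction, and transport reactions are protected by
  default: boundary reactions are modeling constructs, and transporters are
  chronically under-annotated, so pruning them on expression evidence
  mostly creates artifactual gaps. The protection is switchable.
* **Nonfunctional removal** iterates dead-end elimination and an FVA sweep
  (biomass relaxed to $\ge 0$; reactions with min = max = 0 within
  $10^{-9}$ removed) to a fixed point. FVA rather than mere connectivity
  defines "cannot carry flux": connectivity misses stoichiometrically
  blocked reactions.
* **Loop handling.** Thermodynamically infeasible loops are internal
  reactions that can carry flux with every exchange closed. Resolution
  under the default `tighten_reversibility` policy repeatedly extracts a
  maximal closed-system cycle, walks its members in sorted-id order, and
  closes — on the first originally-reversible member where this preserves
  the FBA optimum — the bound direction the cycle flows through. A member
  may be tightened in both directions across successive cycles, which fixes
  it to zero; cycles through exclusively irreversible reactions are
  irreducible under this policy and raise an error listing the loop
  (the `remove` policy deletes loop reactions not needed for feasibility
  instead). Full loopless-FBA inside the LP is deliberately out of scope;
  loop hygiene is a reconstruction step, and the loop set is a
  thermodynamic artifact, not a yield source — resolution must leave the
  FBA optimum unchanged, which the tests assert.
* **Localization** assigns each reaction the majority compartment of its
  transcripts' predictions, breaking ties by mean score and then by fixed
  compartment order, rewriting metabolites into the winning compartment.

## E-Fmin

E-Fmin predicts fluxes by minimizing expression-weighted total flux while
holding the biomass at its optimum:

$$\min \sum_i w_i |v_i| \quad \text{s.t.}\; S v = 0,\; l \le v \le u,\;
v_{biomass} = \beta \cdot v^{FBA}_{biomass}$$

with $e_i$ the sum (configurable: max, mean) of TPM over the transcripts
mapped to reaction $i$, $\hat e_i = \min(e_i / \text{ceiling}, 1)$ where the
ceiling is the `normalization_cap` percentile (default 100 = max) of the
positive $e_i$, and $w_i = \max(1 - \hat e_i, 10^{-4})$. The published
algorithm name fixes the shape $w = 1 - \hat e$; the normalization details
are not restated in the source this package follows, so they are explicit
options. The weight floor prevents zero-cost flux through maximally
expressed reactions. Reactions with no mapped transcripts carry full
weight 1; with all-zero expression the solver falls back to uniform weights
(plain parsimonious minimization) with a warning. Absolute values are
realized by splitting fluxes into nonnegative forward/reverse parts, and
$\beta = 1$ by default (the objective function is fully satisfied).
Flux-minimization LPs are often degenerate; `check_uniqueness = TRUE`
re-solves with the active reactions' weights raised by $10^{-6}$ and flags
the result when the flux vector moves, so downstream analyses can avoid
over-interpreting individual fluxes of a non-unique optimum.

## Photosynthesis titration

`titrate_photosynthesis()` scales the photon-uptake bound to fractions
1, 0.75, 0.5, 0.25, 0.10, 0 of its reference magnitude and re-runs E-Fmin,
holding the biomass demand fixed at the optimum of the most constrained
(lowest-fraction) condition — the demand is a measured composition, not a
function of light. On the epithelial mini model this reproduces the
expected qualitative transitions, which the acceptance tests assert: light
reaction flux is non-increasing and respiratory (citric acid cycle +
oxidative phosphorylation) flux non-decreasing as photons are withdrawn,
photosynthetic FNR carries the ferredoxin/NADPH load when photons are
ample, and at 0% the non-photosynthetic FNR takes over (it must: the MEP
drains in the biomass need reduced ferredoxin) while the photosynthetic
isoform and the light reactions fall silent.

## The transcriptome simulator

`simulate_expression()` draws one log-normal baseline per transcript
(meanlog 2, sdlog 1.2 on the TPM scale — RNA-Seq abundances are
heavy-tailed; no distribution is prescribed by the source data, so this is
a realism/testability choice), shared between the two cell types for a
given seed, multiplies subsystem members by cell-type fold-changes, zeroes
the opposite type's marker (a Rubisco-small-subunit analog exists only in
the mesophyll baseline, a diterpene-synthase analog only in the
epithelial), mixes with the opposite pure profile as
$(1-\rho)\,\text{own} + \rho\,\text{other}$, and rescales to $10^6$ TPM.
Mixing is exactly linear before renormalization, and because both pure
profiles are already normalized, the single-marker estimator recovers the
planted $\rho$ exactly when target and source share a seed. The default
fold-changes encode the observed biology: oleoresin pathways, sucrose
catabolism, fermentation and oxidative phosphorylation enriched in the
epithelial type; light reactions and the Calvin–Benson cycle enriched in
the mesophyll, yet still present in the epithelial baseline, as observed
in the real secretory-cell transcriptome.

What the simulator does **not** emulate: replicate structure and
between-sample dispersion (each profile is one draw; the demo pipeline's
two samples use different seeds, so its marker-ratio estimate recovers the
planted mixing only up to replicate variation), read-level count noise and
transcript-length bias (TPM tables are generated directly), isoform
ambiguity, and partial contamination of markers in their "absent" cell
type. Passing tests on synthetic data therefore validate the estimators
and the LP machinery, not the upstream RNA-Seq processing.

## Problem sizes and runtimes

The packaged analyses run on the 65-reaction mini models (LPs of ~130
split variables, milliseconds per solve); FVA and loop detection are a few
hundred solves. The full test suite runs in well under a minute, the
end-to-end demo pipeline in a few seconds; the same code paths scale to
genome-scale models (hundreds of reactions) at dense-LP cost, which is the
intended scope.

## Known limitations

* Loop resolution is greedy and order-dependent (deterministic by sorted
  id); it preserves the biomass optimum but does not guarantee the
  minimal set of bound changes.
* The SBML layer covers the constraint-based subset (compartments, species,
  stoichiometry, flux bounds, the active objective, notes-encoded
  subsystem/EC/gene annotations), not kinetic or rule-based SBML; it is
  cross-checked against the COBRApy reader.
* E-Fmin fluxes inherit LP degeneracy; only objective values are
  comparable when the uniqueness probe flags alternative optima.
* The mini network is a caricature: lumped cofactor stoichiometries are
  configurable but not elementally balanced, and absolute flux values on
  it are in model units, not measurements.
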