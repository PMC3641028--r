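---
title: "Methods: stoichiometric and statistical machinery behind mucaflux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stoichiometric and statistical machinery behind mucaflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucaflux)
```

This vignette documents the models, conventions and numerical choices
behind the package: what is assumed, which knobs exist, and what the tests
do and do not demonstrate.

## The core metabolic model

`build_core_model()` returns a curated, carbon-balanced core model of
*P. fluorescens* SBW25 central carbon and alginate metabolism: 70
metabolites and 77 reactions covering fructose PTS entry,
1-phosphofructokinase and fructose bisphosphatase (there is deliberately no
6-phosphofructokinase — the organism cannot phosphorylate
fructose-6-phosphate), the Entner–Doudoroff and pentose-phosphate pathways
(with both NAD- and NADP-linked glucose-6-phosphate dehydrogenase
isozymes), EMP lower glycolysis, PEP synthase, the pyruvate shunt
(malate → pyruvate → oxaloacetate), a full TCA cycle without a glyoxylate
shunt, glycerol uptake through a facilitator, kinase and quinone-linked
dehydrogenase, acetate overflow, the complete alginate route
(mannose-6-phosphate isomerase, phosphomannomutase, GTP-consuming
GDP-mannose pyrophosphorylase with pyrophosphatase, GDP-mannose
dehydrogenase producing 2 NADH, polymerization/export with optional
acetylation from acetyl-CoA), nucleoside diphosphate kinase, and the
four-reaction NADPH-oxidizing cycle (aspartate aminotransferase, catalase,
NADP-glutamate dehydrogenase, L-aspartate oxidase).

### Proton economy and the P/O ratio

Respiration is proton-explicit with a single pooled periplasmic proton
species (no membrane-potential term). The conventions are:

* NADH dehydrogenase I: 4 H⁺ pumped per NADH;
* cytochrome-c oxidase branch: 6 H⁺ translocated per electron pair;
* *bd* and *bo* ubiquinol oxidases: 2 H⁺ per electron pair;
* ATP synthase: 4 H⁺ per ATP.

`set_po_mode()` opens exactly one oxidase class (recognized by the
subsystem tags `respiration:cytochrome-c` / `respiration:ubiquinol`), so
the theoretical P/O ratio is (4+6)/4 = 2.5 in `"high"` mode and
(4+2)/4 = 1.5 in `"low"` mode. `measure_po_ratio()` verifies this
operationally by FBA on a unit NADH source. Chemistry protons are tracked
only where they matter for the reported stoichiometries (the
glutamate-dehydrogenase step of the NADPH cycle); a free cytosolic proton
exchange absorbs the remainder, which cannot short-circuit the gradient
because the periplasmic pool connects to the cytosol only through the
pumps and the synthase.

### Biomass calibration

The biomass drain lumps precursor demand (6 pyruvate, 2 oxaloacetate, 1.45
2-oxoglutarate, 0.5 fructose-6-phosphate, 0.5 glyceraldehyde-3-phosphate,
9 NH₄⁺, 12 NADPH per gDW) into 37.75 mmol of a 1-carbon biomass unit, i.e.
a cellular carbon content of 0.4534 gC/gDW, chosen so that growth at
D = 0.04 h⁻¹ exports 1.51 mmolC/gDW/h of biomass carbon — the constant
"carbon in biomass" column of the steady-state table. Growth-associated
maintenance (GAM) of 43 mmol ATP/gDW is charged inside the biomass
equation; non-growth-associated maintenance (NGAM, default 0, typical
bacterial scenario 1.5 mmol ATP/gDW/h) is the lower bound of the explicit
ATP-hydrolysis reaction. Because the monomer unit carries exactly one
carbon, the biomass reaction is itself carbon-balanced, and exchange-level
carbon conservation holds for growing solutions.

### Alginate pathway cost accounting

`alginate_pathway_cost()` walks the canonical linear route at unit flux
and sums the change in high-energy phosphate bond equivalents (ATP/GTP 2,
ADP/GDP/GDP-sugars/PEP/PPi 1, AMP 0). From extracellular fructose the
route hydrolyzes 3 bonds — the PTS PEP, the 1-phosphofructokinase ATP and
the GDP-mannose pyrophosphorylase GTP (whose pyrophosphate the
pyrophosphatase commits) — and reduces 2 NAD⁺ at GDP-mannose
dehydrogenase. This is a path-accounting quantity, distinct from the
FBA optimum, which additionally decides how the PTS-released pyruvate is
recycled or burned.

## Linear programming

No dedicated LP package is part of the package's dependency footprint, so
`solve_fba()` rests on a self-contained bounded-variable two-phase revised
simplex (`R/lp.R`): variables keep their box bounds natively, phase 1
minimizes artificial residuals, phase 2 optimizes the user objective,
Dantzig pricing falls back to Bland's rule after prolonged degeneracy, and
the basis is refactorized by dense solve at every pivot. For the model
sizes targeted here (≤ a few hundred reactions) refactorization costs
microseconds and buys reproducible, drift-free solutions; the engine is
validated in the test suite against brute-force vertex enumeration on
polytopes with ≤ 2 degrees of freedom at 10⁻⁹ tolerance. Feasibility and
optimality tolerances are 10⁻⁹; yields are reported to 4 decimals (the
source data carry 2). Infeasibility and unboundedness are reported as
statuses, never as numbers.

Two conventions matter for reproducing the yield calculators:

* uptake is normalized to 1 mmol/gDW/h (LP homogeneity makes the scale
  irrelevant) with the uptake-negative sign convention on exchanges;
* with degenerate alternate optima only the objective value is
  contract-stable; individual fluxes are reported but not asserted.

The theoretical-yield functions fix the substrate exchange at −1, close
the other carbon source, pick the oxidase branch, and maximize biomass (or
the monomer exchange with biomass pinned to zero — the non-growing
cell-factory scenario). The printed genome-scale reference values for
these yields depend on stoichiometric detail that a core model cannot
carry, so the package documents its own optima and asserts the structural
facts instead: the glycerol alginate yield is P/O-independent, the
fructose yield is strictly larger on the efficient branch, both respect
their carbon ceilings (1 and 0.5 mmol/mmol), and biomass yield is
non-increasing in NGAM.

## Chemostat arithmetic

All physiology functions take specific rates in mmolC/gDW/h and use
μ = D at steady state. Defaults: OD₆₆₀ → gDW/L conversion 0.36, fructose
180.16 g/mol (6 C), glycerol 92.09 g/mol (3 C). Rounding follows the
precision of the source data: yields 2 decimals, carbon fractions
integers, ratios 2 decimals. The alginate efficiency subtracts from the
producer's uptake the uptake of the non-producing strain with the highest
biomass yield on the same carbon source, then divides monomer production
(6-C skeleton; acetyl carbon excluded) by the remaining substrate;
`alginate_carbon_fraction()` by contrast includes acetyl carbon, since it
is part of the secreted polymer. Recomputing balances from a table rounded
to one decimal cannot reproduce a balance column computed from raw
instrument data exactly; the packaged table's recomputed balances agree
with the printed column within ±1.5 percentage points, and that tolerance
is part of the acceptance contract.

## Expression analysis

* Log base 2 throughout.
* Quantile normalization maps every sample onto the row-wise mean of the
  sorted columns, with ties averaged over tied positions; it is idempotent
  and distribution-equalizing by construction.
* The significance screen is per-gene one-way fixed-effects ANOVA on log2
  intensities. A gene with zero within-group variance gets p = 1 when the
  group means agree (no evidence) and p = 0 otherwise — degenerate inputs
  are decided, not NaN. The selection rule is |log2 FC| ≥ 1 AND p < 0.005
  at the defaults; because the rule is a conjunction, the order of the two
  filters is immaterial.
* PCA operates on gene-centered log2 data; explained-variance fractions
  are non-increasing and components with numerically zero variance are
  dropped (a constant matrix yields an empty decomposition).
* GPR projection: complexes (AND) adopt the subunit with the smallest
  absolute change — the limiting-subunit assumption; isozyme sets (OR)
  adopt the most extreme signed change rather than a sum, which keeps the
  rule independent of how many minor isozymes are annotated, and flag the
  reaction when member signs disagree. Significance travels with the
  adopted gene. Input is gene-level; probe summarization is out of scope.

## Flux sampling and evidence scores

`sample_flux_space()` parameterizes the polytope on the SVD null space of
S and runs coordinate hit-and-run: 10·dim warm-up steps, thinning 10, the
start point an average of LP vertices along the null-space coordinates.
Seeds are mandatory arguments and the caller's RNG state is restored, so
the sampler is a pure function of (model, constraints, n, seed).
Measured exchange windows default to ±5 % relative tolerance, with
mmolC→mmol conversion through the carbon count of the exchanged species.

For two conditions sampled with independent chains, the flux-change
probability is P⁺ = (1/N) Σ 1{v_B > v_A} over index-paired samples, ties
counting ½ (index pairing is a neutral choice; nothing couples the two
chains). The evidence score is the probability that the flux change is
concordant with a significant expression change: P⁺ for up-regulation,
1 − P⁺ for down, 0 without significant expression; a significant flag with
a zero change is demoted with a warning. Classification thresholds
(`score_hi`, `flux_hi`, both 0.9) must exceed 0.5 so the calls are
mutually exclusive. Ranking is by descending score with deterministic
tie-breaks (|Δe|, then reaction id).

Two caveats are documented rather than hidden. First, internal loop fluxes
(e.g. futile PEP-synthase/pyruvate-kinase cycling) are only weakly
constrained by exchange windows; their marginals are wide, mix slowly, and
their P⁺ values should not be over-interpreted — the ground-truth set of
the synthetic study therefore contains only reactions whose flux change
the constraint windows actually force. Second, convergence is checked in
the tests by the doubling criterion (P⁺ shifts under sample doubling stay
within 3 binomial standard errors) on well-mixing fixtures.

## Synthetic data: what it emulates, what it does not

The generators mirror the study layout end-to-end: five strains × two
carbon sources × triplicate chemostats, a 6,519-gene array, an alginate
operon (12 genes plus the separately transcribed phosphomannomutase gene)
up 1 log2 unit in mucA-background strains, and the four NADPH-cycle genes
down 1 log2 unit in mucA backgrounds on fructose — effect sizes chosen to
straddle the 2-fold significance cut. Intensities are log-normal with
gene baselines drawn once per seed from N(8, 2) log2 units and replicate
noise of 0.5 log2 units, a realistic magnitude for biological triplicates
on expression arrays. Chemostat tables are generated from a noiseless
truth whose carbon balance is exactly 100 %, with unbiased multiplicative
noise (default 3 %) per measured channel and acetylation degrees of 0.19
(fructose) and 0.32 (glycerol).

What passing tests on these data do **not** show about real data: no
probe-level artifacts, dye bias, or array spatial effects; no correlated
noise between genes (co-regulation beyond the planted effects); no
growth-rate dynamics or gas-transfer corrections; and the two-condition
study plants expression effects directly at reaction level, bypassing
real GPR ambiguity. The generators validate the machinery, not the
biology.

## Problem sizes used in the packaged checks

The test suite and the acceptance script run the full pipeline at sizes
chosen to exercise every code path at interactive speed: the 77-reaction
core model for all FBA and sampling scenarios, 5,000 flux samples per
condition for the regulation-score recovery and its identical-condition
null, 1,000-gene null simulations for the type-I-error check, and 300–500
samples for the distributional sampler tests. All are the package's own
defaults or documented arguments and scale up unchanged.

## Known limitations

* The core model is a calibrated stand-in for a genome-scale
  reconstruction; absolute FBA yields depend on biomass composition and
  energetic detail that a core network cannot fully represent, so
  genome-scale reference yields are treated as annotations, not oracles.
* The fructose alginate efficiency computed from the rounded steady-state
  table (0.97) differs from a value computable only from unrounded
  instrument data; the package reports what its inputs support.
* The evidence-score formula is a declared definition (concordance
  probability), since the score's functional form is not uniquely
  determined by its 0–1 range and intended interpretation.
* `overlap_counts()` mechanizes reaction matching through canonical keys
  and an explicit synonym table; manual curation decisions that identify
  differently-written reactions as equivalent cannot be recovered
  automatically — such reactions surface as flagged-unmapped rather than
  being silently merged.
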