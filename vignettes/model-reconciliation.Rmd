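---
title: "Predicting knockout viability and reconciling a metabolic model against phenotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting knockout viability and reconciling a metabolic model against phenotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluxrec)
```

## The problem

Genome-scale metabolic models predict whether a mutant strain can grow on
a given medium. When a laboratory deletes large contiguous chromosome
intervals — tens of genes at a time — and plates the mutants on several
media, the result is a matrix of observed growth calls that the model can
be tested against. Two things can then happen: the model predicts growth
for a strain that died (a *false positive*, FP), or predicts death for a
strain that grew (a *false negative*, FN). Each disagreement is evidence
of a concrete defect somewhere in the model or in the in-silico medium
formulation, and fixing those defects systematically turns a phenotype
screen into a model-refinement instrument. `fluxrec` implements that
workflow end to end: viability prediction by flux balance analysis (FBA),
a twelve-class taxonomy of correction hypotheses with greedy
net-beneficial acceptance, and rescue-metabolite prediction for strains
the refined model still calls unviable.

## Flux balance analysis

The model is a stoichiometric matrix $S$ (metabolites $\times$
reactions), flux bounds $lb \le v \le ub$, and one designated biomass
reaction whose flux is the growth proxy. FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \;\; lb \le v \le ub,$$

where $c$ selects the biomass reaction. Media enter through exchange
reactions, written `compound_e ->` so that positive flux is secretion and
negative flux uptake: a medium sets each listed compound's exchange lower
bound to $-\text{max\_uptake}$ and closes uptake for everything else.
Bounds are kept finite throughout, with $\pm 1000$ flux units standing in
for "unconstrained" as in published genome-scale models; growth recipes
give concentrations rather than fluxes, and a yes/no growth call is
invariant to a common rescaling of all uptake bounds, so limited
compounds share one default uptake of 10 flux units.

Gene deletions act through gene–protein–reaction (GPR) rules: boolean
expressions in which `and` encodes complexes and `or` isozymes. A
knockout disables every reaction whose rule evaluates false without the
deleted genes; disabled reactions are constrained to zero flux in both
directions (the model structure is untouched), and the strain is called
viable iff the re-optimized biomass flux exceeds a threshold
$\varepsilon$. Background lesions of a master strain are instead mirrored
structurally, by removing every reaction *associated* with the inactivated
genes (`remove_gene_reactions()`), which is deliberately stronger than
rule evaluation.

The LP itself is solved by a dense two-phase bounded-variable primal
simplex implemented in C++. Problems at the package's working scale are a
few hundred columns, where a dense tableau with an explicit basis inverse
is faster than any sparse machinery; the solver short-circuits phase one
whenever the zero flux vector is feasible, which is the common case
($b = 0$). It is validated in the test suite against two independent
references: exhaustive vertex enumeration of the flux polytope for
networks of up to ten reactions, and a second simplex implementation on
generic dense LPs.

### Numerical choices

- viability threshold $\varepsilon = 10^{-6}$ biomass-flux units
  (configurable): growth means "nonzero biomass flux", and the tolerance
  guards against LP round-off;
- solver pivot/optimality tolerances $10^{-9}$; mass-balance residuals of
  returned optima are asserted $\le 10^{-6}$ in the tests;
- degenerate optima: only the objective value is contract-bearing.
  Individual fluxes are reported but FBA solutions are generally
  non-unique, so no code path depends on them;
- an unbounded biomass objective is reported as an error (it would imply
  a thermodynamically impossible free-energy loop feeding biomass); with
  finite bounds it cannot occur.

## Scoring against observations

Observed calls use the closed vocabulary `viable` / `slow` / `unviable` /
`not_attempted`. Scoring bins strains by their *observed* phenotype per
medium — a `+` row and a `-` row per medium plus overall rows — because
prediction accuracy differs sharply between viable and unviable strains
and a single pooled number hides that. `slow` counts as viable under the
default policy (slow colonies are still colonies); the alternative policy
is one argument away. Rows carrying a revision note (for example growth
later attributed to cross-feeding from neighbouring colonies) are scored
against the revised call stored in the `call` column; the note preserves
provenance.

## The twelve error classes and greedy reconciliation

Every misprediction is prompted by either an FP or an FN, and each
direction admits six typed corrections:

| FP (predicted viable, observed unviable) | FN (predicted unviable, observed viable) |
|---|---|
| add a missing biomass component | remove a spurious biomass component |
| restrict a reaction's GPR (add a required gene) | relax a GPR (drop a wrongly required gene) |
| remove a spurious isozyme (`or` branch) | add a missing isozyme from homology candidates |
| remove a spurious reaction | add missing reactions (gapfilling from a candidate db) |
| make a reaction irreversible | make a reaction reversible |
| remove an extra media compound | add a missing media compound |

`reconcile_greedy()` runs the four-step refinement loop:

1. **propose** — for every current misprediction, enumerate single edits
   from the classes above (reaction additions may be minimal sets of up
   to `max_gapfill = 3` database reactions, found by exhaustive subset
   search with superset pruning). Only edits that flip the prompting
   prediction in isolation are kept;
2. **evaluate** — apply each hypothesis to a copy, re-simulate all
   phenotypes, and record which observed calls it corrects and which it
   breaks;
3. **accept** — take the best hypothesis by (max net = corrected −
   broken, then fewest broken, then smallest edit, then lexicographic
   id), provided net > 0, and repeat;
4. **confirm** — the wet-lab step; exported as a proposed-experiments
   table (`propose_validation_experiments()`), since it is not
   computable.

Strict positivity of the acceptance rule means overall accuracy strictly
increases at each step, which both guarantees termination and forbids
churn. Failures that no net-beneficial edit can explain stay in the
ledger's residual list — on real data these are the fingerprints of
regulatory effects a purely metabolic steady-state model cannot capture,
so an honest residual list is a feature, not a failure mode.

Design choices worth recording:

- *Gapfilling* is an exhaustive search over small subsets of a
  user-supplied candidate database rather than a MILP: the candidate dbs
  this package targets are tens of reactions, where exhaustive search up
  to size 3 is exact, transparent and fast. Minimality is verified by
  construction (supersets of working sets are pruned).
- *Isozyme additions* come from a user-supplied homolog table
  (gene → candidate reactions). No sequence search is performed;
  homology evidence belongs upstream of this package.
- *Biomass edits* add or remove a component at a small fixed coefficient
  (default $10^{-4}$ mmol/gDW): the dependency matters for a yes/no
  growth call, the magnitude would only distort yields.
- *Reversibility edits* only open or close one side of a bound; they
  never flip a reaction's primary direction.
- *Tie-breaking is deterministic*, so identical inputs produce
  byte-identical ledgers; this is asserted in the tests.
- Several distinct edits can be *phenotype-equivalent* — indistinguishable
  on every tested strain × medium cell (e.g. gating a spurious bypass by
  the affected strain's own genes vs. deleting the bypass). The greedy
  loop is evaluated on prediction matrices, so any member of the
  equivalence class is an acceptable fix; only experiments (step 4) can
  separate them.

Two pure optimizations keep the loop fast and are verified equivalent:
media-only edits re-solve only the touched medium's column, and a
tightening (FP) edit never re-solves cells already predicted unviable,
nor a relaxing (FN) edit cells already viable, since the objective moves
monotonically with the feasible region.

## Rescue metabolites

A knockout predicted unviable carries an implicit hypothesis about the
pathway it lost. `find_rescues()` makes it testable: scan supplement sets
of size 1, 2, 3 over the compounds that an existing exchange-plus-transport
route can actually import, prune supersets of working sets, and return
every minimal compound set whose addition flips the prediction. Compounds
importable only through candidate-database transporters are reported only
under an explicit flag, because using them implies a model edit.
Supplements receive the media default uptake bound. Soundness and
minimality of returned sets are brute-force checked in the tests.

## The synthetic ground truth

The generator (`make_truth_bundle()`) emulates the study design the
pipeline targets, at desk scale:

- a gene-ordered toy genome (default 60 genes) in which preserved genes —
  nutrient transporters plus random fill to `preserved_fraction = 0.3` —
  define contiguous deletion intervals, exactly as preserved loci bound
  deletable regions on a real chromosome;
- six linear biosynthetic pathways (nutrient uptake, two enzymatic
  steps, one biomass precursor each); the first half of the pathways
  also have a reversible product transporter, so their knockouts are
  medium-dependent — the analog of auxotrophs rescued by rich media;
- two alternative nitrogen-assimilation routes feeding one biomass
  component, so two minimal media differing only in nitrogen source
  dissociate;
- GPR structure with isozymes (rate 0.2) and two-gene complexes; one
  isozyme step and one complex step are always present, their probe
  genes placed in intervals of their own so that every error class has a
  plantable site;
- an irreversible side reaction draining one product to an excretable
  waste compound present only in the rich medium: the planted
  "wrongly-reversible" corruption opens exactly the kind of
  thermodynamically implausible bypass that reversibility errors cause
  in real models;
- four media: rich superset, defined rich, and two minimal media
  differing in nitrogen source.

Phenotypes are the FBA verdicts of the truth network (noise-free mode),
so the truth model scores 100% on its own bundle by construction — the
self-consistency check. `plant_errors()` corrupts the bundle by applying
the *inverse* of each class's correction (delete a pathway reaction to
create a missing-pathway FN, add a spurious compound to a medium to
create an extra-nutrient FP, ...), scanning candidate sites in seeded
random order and keeping only sites that provably change at least one
phenotype prediction in the class's direction. The planted inverse fix,
the deleted reactions (as the candidate db, padded with dead-end decoys)
and removed isozymes (as the homolog table) are returned so recovery can
be judged against ground truth.

What the generator does *not* emulate — and therefore what passing tests
do not show about real data: operon structure and polar effects of
interval end points, regulatory control of pathway expression,
growth-rate (continuous) phenotypes, measurement noise beyond optional
independent call flips, and the sheer combinatorial depth of a real
genome-scale network, where several errors interact within one
misprediction. The default problem size (60 genes, ~40 reactions, ~13
intervals, 4 media, ≈ 50 phenotypes) was chosen so that a full
reconciliation run takes well under a second and large seeded sweeps
(the 12 × 50 recovery study in the test suite) complete in a few
minutes on one CPU.

## A worked run

```{r example, eval = FALSE}
b <- make_truth_bundle(seed = 42)
pl <- plant_errors(b, plant_spec(FN_reaction_add = 1), seed = 7)
res <- reconcile_greedy(pl$model, pl$media_set, pl$db, b$strain_defs,
                        b$phenotypes, homologs = pl$homologs)
res$ledger
#> <edit_ledger> 1 accepted edits; accuracy 92.3% -> 100.0%; 0 residual errors
#>   FN_reaction_add:S3_1 (net +4)
```

The planted corruption deleted pathway reaction `S3_1`; reconciliation
proposed, evaluated and accepted exactly its re-addition, repairing all
four broken phenotype predictions and nothing else.

## Known limitations

- The greedy loop optimizes one edit at a time; a pair of edits that
  only helps jointly will not be found (the residual list will say so).
- Hypothesis enumeration is restricted to edits that flip their
  prompting prediction *in isolation*; this mirrors the per-error
  workflow but can miss fixes that act only in combination.
- Reaction additions are searched over an explicit candidate database;
  the package does not mine reaction databases itself.
- FBA is steady-state and unregulated: conflicts between observed
  phenotypes that only regulation can explain are reported, not
  resolved.
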