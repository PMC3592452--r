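# fluxrec

Flux-balance viability prediction for multi-gene deletion strains, and
systematic reconciliation of a genome-scale metabolic model against the
observed growth phenotypes.

## Who this is for

Groups that delete large chromosome intervals (or any multi-gene sets)
and plate the mutants on several media end up with a strain × medium
matrix of growth calls. A constraint-based metabolic model predicts that
same matrix in silico. `fluxrec` is for the step after the comparison:
every disagreement between prediction and observation points at a
concrete defect in the model or in the in-silico medium, and this package
finds, types, evaluates and applies the corrections — then proposes
rescue metabolites to test the remaining unviable predictions at the
bench.

## What it computes

**Prediction.** Flux balance analysis: maximize biomass flux $c^\top v$
subject to mass balance $Sv = 0$ and bounds $lb \le v \le ub$, with media
setting exchange uptake bounds. A knockout disables every reaction whose
gene–protein–reaction (GPR) boolean rule fails without the deleted genes
(`and` = complex, `or` = isozymes); the strain is viable iff the optimal
biomass flux exceeds a threshold (default `1e-6`). The LP core is a dense
two-phase bounded-variable simplex in C++, validated against exhaustive
vertex enumeration in the test suite.

**Reconciliation.** Mispredictions are false positives (predicted
viable, observed unviable) or false negatives (the reverse). Each
direction admits six typed corrections — biomass composition, GPR
structure, isozymes, reaction content (gapfilling from a candidate
database), reversibility, and media composition — twelve error classes in
all. `reconcile_greedy()` proposes every single edit that flips its
prompting misprediction, re-simulates all phenotypes under each, and
greedily accepts edits that correct strictly more predictions than they
break, until none remains. Accuracy increases monotonically; what cannot
be fixed stays in an explicit residual list.

**Rescue.** For a knockout predicted unviable on a medium,
`find_rescues()` returns every minimal set (size ≤ 3) of importable
compounds whose addition flips the prediction to viable — the testable
hypothesis about which pathway the deletion severed.

**Synthetic ground truth.** `make_truth_bundle()` generates a seeded toy
genome, metabolic network, four media (rich / defined rich / two minimal),
deletion intervals defined by preserved genes, and noise-free phenotype
tables; `plant_errors()` corrupts it with any of the twelve error classes
(as the inverse of the correction) and hands back the ground-truth fix.
Every pipeline stage is testable offline against known answers.

## A worked example

```r
library(fluxrec)

b  <- make_truth_bundle(seed = 42)        # ground-truth bundle
pl <- plant_errors(b, plant_spec(FN_reaction_add = 1), seed = 7)

# the corrupted model now mispredicts:
pred <- batch_predict(pl$model, b$strain_defs, pl$media_set)
score_predictions(pred, b$phenotypes)[9:11, ]
#>      media phenotype  n correct percent
#> 9  Overall         + 20      16      80
#> 10 Overall         - 32      32     100
#> 11 Overall       all 52      48      92

res <- reconcile_greedy(pl$model, pl$media_set, pl$db, b$strain_defs,
                        b$phenotypes, homologs = pl$homologs)
res$ledger
#> <edit_ledger> 1 accepted edits; accuracy 92.3% -> 100.0%; 0 residual errors
#>   FN_reaction_add:S3_1 (net +4)
```

The planted corruption deleted pathway reaction `S3_1`, breaking four
phenotype predictions (all false negatives: strains observed viable were
predicted dead). Reconciliation proposed candidate edits for each
failure, found that re-adding `S3_1` from the candidate database corrects
all four while breaking none, accepted it, and restored 100% accuracy
with an empty residual list.

File-level entry points mirror the same pipeline (`cmd_simulate`,
`cmd_predict`, `cmd_reconcile`, `cmd_rescue`), and
`inst/cli/fluxrec.R` exposes them as shell subcommands.

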