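# molforge

Composable molecular design workflows in R: generate candidate molecules
from leads, filter them against a target compound profile, rank by
multi-parameter desirability or Pareto dominance, design sparse
combinatorial arrays, fit Free-Wilson models, and iterate with
explore/exploit active learning.

## Who this is for

Computational and medicinal chemists running lead-optimisation iterations
who want the machinery of an automated design platform — molecule
generators, profile filters, experimental design, QSAR fit/predict and
batch selection — as plain, scriptable R functions over CSV/SMILES/SDF
files, with no services or databases required. Every stochastic step is
seeded and every workflow run is reproducible byte for byte.

## The methods at the core

- **Generation.** (a) *Matched-molecular-pair transforms*: the lead is cut
  at every acyclic single bond; when a detached fragment equals a rule's
  left-hand side the right-hand side is swapped in. (b) *BRICS fragment
  replacement*: the lead is fragmented at the published BRICS bond types
  (sixteen chemical environments L1–L16 with a compatibility table); any
  fragment can be exchanged for a pool fragment carrying the same
  attachment labels, optionally relaxing the aromatic/aliphatic ring label
  distinction (phenyl ↔ cyclohexyl), inserted into a cut bond, or deleted.
  An unmodified fragmentation always reassembles to the input molecule.
  (c) *Similarity search/filtering* with two open fingerprints (a 1024-bit
  path fingerprint of length ≤ 7 and a radius-2 circular fingerprint) and
  Tanimoto similarity.
- **Profile filter and ranking.** Hard property windows (oral/inhaled
  presets or user XML/JSON), SMARTS liability alerts, and a linear
  desirability score: 1 inside the `[min, max]` window, decreasing at
  `gradient` per unit outside, clamped at 0; compounds ranked by score sum
  or by Pareto front (whole fronts returned, never split).
- **Sparse array design.** Equally sampled incomplete balanced block
  designs over 2–3 monomer positions: `M` cells with each level of factor
  `i` appearing exactly `r_i = M / N_i` times; reagents are then assigned
  to levels by steepest-descent maximisation of summed product
  desirability.
- **Free-Wilson analysis.** `y = μ + Σ positions effect(monomer)` by least
  squares with reference-level coding; predictions for every combination
  of observed monomers; top-N selection of unsynthesised compounds.
- **Active learning.** A seeded bagged-tree ensemble predicts a candidate
  pool; the batch splits into Exploit (top predictions) and Explore (top
  per-tree dispersion among the remainder).
- **Workflow engine.** Tasks with JSON parameter objects and column
  contracts compose into validated linear chains (a generator must be
  followed by a filter); branching by artifact reuse; structured JSON run
  logs.

## Worked example

```r
library(molforge)

# the 24 x 32 two-position array sampled at a 1/8 fraction
spec <- plan_replicates(c(24, 32), fraction = 1/8)
spec
#> Sparse array design spec: 24 x 32 levels, M = 96
#>   replicates per level: 4, 3
cells <- generate_balanced_design(spec, seed = 7)
nrow(cells)                      # 96 compounds to synthesise
#> [1] 96
all(tabulate(cells$f1 + 1, 24) == 4)  # every RG1 monomer used 4 times
#> [1] TRUE

# simulate the campaign on a 50 x 50 virtual library with known truth
lspec <- library_spec(n_levels = c(50, 50))   # mu 5, effects 0.5, noise 0.2,
lib   <- make_library(lspec)                  # 36% synthesis attrition
nrow(lib$library)
#> [1] 2500
design <- generate_balanced_design(plan_replicates(c(50, 50), M = 100),
                                   seed = 1)
obs <- observe_library(lib, design, lspec)
nrow(obs)        # ~64 records survive attrition
#> [1] 60

fw <- fit_freewilson(obs)
fw
#> Free-Wilson model: 60 records, 43 x 43 monomers
#>   intercept 5.225 | R^2 1.000 | residual SD 0.000 | ridge fallback
top <- top_predictions(predict_freewilson(fw), 10, exclude_observed = TRUE)
head(top[, c("m1", "m2", "pred")], 3)
#>      m1  m2     pred
#> 162 A40 B05 8.180389
#> 143 A15 B05 7.612024
#> 144 A17 B05 7.610076
```

The design numbers mean: 96 of the 768 possible products are made, each
monomer equally leveraged, so the downstream additive model sees every
monomer; the top predictions are unsynthesised combinations the model
ranks above everything measured.

Exact output of `fw` and `top` depends on the seeds shown; all values
above are what the code prints with those seeds.

## Command line

A thin CLI over the same functions ships in `inst/cli/molforge.R`:

```sh
Rscript inst/cli/molforge.R design --levels=24,32 --fraction=0.125 --seed=7
Rscript inst/cli/molforge.R validate workflow.json
Rscript inst/cli/molforge.R run workflow.json --force
Rscript inst/cli/molforge.R list-tasks
```
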