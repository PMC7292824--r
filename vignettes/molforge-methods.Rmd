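---
title: "Models and methods behind molforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind molforge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

molforge is a local, scriptable engine for iterative small-molecule
design: generate candidates from leads, enforce a target compound
profile, rank, design a sparse combinatorial array, fit a Free-Wilson
model, and select the next batch by active learning. This vignette
explains the models, their assumptions, the tunable parameters, and the
design choices made where the design was genuinely open.

## Molecular structure handling

All structure chemistry (SMILES parsing, canonical SMILES, MW, clogP,
TPSA, H-bond donors/acceptors, SMARTS matching, fingerprints) is
delegated to OpenBabel via ChemmineR/ChemmineOB. On top of it the package
maintains a light connection-table graph (kekulized bond orders, formal
charges, isotope-numbered attachment dummies) so that fragmentation and
recombination can edit bonds directly and re-emit canonical SMILES.

Aromaticity is perceived from ring enumeration with an added Hückel
sanity check: a ring counts as aromatic only if every ring carbon carries
a double bond in the kekulized table. Without this check, saturated
five-membered heterocycles (pyrrolidine, tetrahydrofuran) are
misclassified by the ring enumerator, which would corrupt fragmentation
environments downstream.

Two identity conventions hold everywhere: molecules are compared by
canonical-SMILES string equality (deduplication, merge, pool membership),
and malformed input rows are *rejected and logged*, never fatal — an
empty surviving set is an error at the workflow-task level.

Descriptor conventions worth noting:

* `HBA`/`HBD` are OpenBabel's acceptor/donor counts; `clogP` is the
  Wildman–Crippen-style computed logP.
* `RotB` counts acyclic single bonds between two non-terminal heavy atoms
  with no triple-bond participation (amide C–N bonds are counted; the
  stricter pharma convention that excludes them would shift counts by
  one per amide).
* `PFI_proxy = clogP + aromatic_rings`. The Property Forecast Index
  proper uses measured chromatographic logD7.4; computed clogP is the
  only desk-computable stand-in, and the proxy is named accordingly.
* `aromatic_rings` counts aromatic rings of size ≤ 7, so naphthalene
  counts 2 (the 10-membered envelope is not counted).

Fingerprints are OpenBabel's FP2 (`path7`: linear paths of length 1–7
hashed into 1024 bits) and ECFP4 (`circular2`: radius-2 circular,
4096 bits). These are the open equivalents of the proprietary path/
circular pair the similarity machinery was designed around; only the
path length and radius are load-bearing, the exact bit widths are those
of the open implementations. Tanimoto similarity is defined as 1.0 when
both bit sets are empty (two structureless inputs are not evidence of
dissimilarity).

## BRICS fragmentation and single-edit generation

Cleavable bonds are located with the published BRICS rule set: sixteen
atom environments (acyl, amine, ether oxygen, lactam nitrogen, aromatic
carbon between aromatic carbons, and so on) and a compatibility table of
bond types between them, implemented as predicates over the molecular
graph. Every matching acyclic bond is cut exactly once and replaced by a
pair of numbered attachment dummies carrying the environment codes. The
implementation agrees fragment-for-fragment with an independent
widely-used implementation of the same published rules on the test
corpus, and reassembly of an unmodified fragmentation is the identity by
construction — a property the test suite asserts for every corpus
molecule.

The generator makes **one edit per output molecule**:

* *Replacement*: a fragment is exchanged for a pool fragment with the
  same attachment-label multiset. With `relax_ring_labels = TRUE` the
  aromatic-ring labels (14, 16) and aliphatic-ring labels (13, 15)
  collapse into one class, e.g. phenyl may be replaced by cyclohexyl.
* *Insertion*: a two-attachment fragment whose labels equal a cut bond's
  label pair is spliced into that bond (growth).
* *Deletion*: a terminal fragment is removed and the open valence capped
  with hydrogen (shrinkage). Interior fragments are not deletable — that
  would require re-joining two incompatible ends and has no unambiguous
  chemistry.

Deeper exploration is achieved by feeding outputs back as seeds, which
keeps provenance exact (each record carries its seed id and a change
note naming position and fragment).

One subtlety: the "single edit" property is checked in the tests by
comparing BRICS fragment multisets of seed and analogue. For
replacements the symmetric difference is at most 2. For deletions it can
reach 3, because capping the neighbour's open valence changes that
fragment's own label set — the edit is still single, but the fragment
fingerprint of the neighbour shifts.

Matched-molecular-pair transforms use exact-fragment matching: the seed
is cut at every acyclic single bond, and a rule fires when its
(canonicalised) left-hand fragment equals the detached piece exactly.
This mirrors fragment-index MMP practice and avoids SMARTS-environment
guessing; the cost is that a rule written for a methyl matches only a
terminal methyl, not "any carbon that looks methyl-like".

## Profile filtering, desirability and Pareto ranking

A target compound profile is a set of per-property criteria
`(min, max, gradient, hard)`. Hard criteria are pass/fail windows; a
molecule fails if *any* hard criterion is violated and the failure lists
all violated criteria. Scored criteria contribute a desirability of 1
inside the window, decreasing linearly at `gradient` per unit outside,
**clamped at 0**. The clamp is deliberate: the raw linear form is
unbounded below, and a single catastrophic property would otherwise veto
the sum invisibly. A missing property value scores 0 and flags the row.
Only `hard = FALSE` criteria enter the score; windows used for hard
filtering express constraints, not preferences, and summing them would
double-count.

The shipped oral preset (MW ≤ 500, clogP ≤ 5, HBD ≤ 5, HBA ≤ 10,
TPSA ≤ 140, RotB ≤ 10, PFI_proxy ≤ 7) and inhaled preset (clogP ≤ 3,
PFI_proxy ≤ 5, others as oral) are package conventions in line with
common druglikeness practice, fully overridable via the XML/JSON profile
file. Externally computed predictions (e.g. ADMET model outputs) are
treated as ordinary numeric columns and may be scored by extending the
profile's known-property list.

Pareto mode ranks by iterative non-dominated peeling (A dominates B iff
A ≥ B on every criterion and > on at least one; equal vectors share a
front). Top-N in Pareto mode returns whole fronts until N is reached —
fronts are never split, so more than N rows may come back; within-front
order uses the sum score, then id, so output order is deterministic. The
test suite checks the ranking against an independently coded
longest-dominance-chain oracle on a thousand random instances.

Sphere-exclusion clustering is the classic greedy leader pass in input
order with a Tanimoto threshold (default 0.65 on the circular
fingerprint): deterministic, order-dependent, cheap — appropriate for
annotating result sets, not for publication-grade cluster analysis.

## Sparse array design

An equally sampled incomplete balanced block design selects `M` distinct
cells of an `N1 × N2 (× N3)` virtual array such that level `i` of factor
`k` appears exactly `r_k = M / N_k` times. `M` must therefore be
divisible by every `N_k`; infeasible sizes are rejected with the nearest
feasible alternatives (multiples of the lcm of the level counts).

Construction: factor 1 is the sorted vector of each level repeated `r_1`
times; the other columns are independent shuffles of their balanced
level vectors (for two factors this is a random biregular bipartite
matching). Duplicate cells are then removed by swap-repair: a duplicated
cell exchanges one non-fixed column entry with a random partner cell,
accepted only when both resulting cells are previously unoccupied — a
move that strictly reduces duplicates and touches no margin. Repair runs
in sweeps with an occupancy hash, restarting from a fresh shuffle if a
sweep budget is ever exhausted (vanishingly rare for sparse fractions;
surfaced as an error, never silently violated). The full-factorial limit
`M = ΠN_k` short-circuits to the complete grid. Only first-order
(per-level) balance is guaranteed; pairwise co-occurrence balance is
explicitly not claimed.

A statistical caveat the package surfaces rather than hides: with
`r = 2` (e.g. 100 cells from a 50 × 50 array) the design's bipartite
graph is a union of cycles and is usually *disconnected*. Monomer
effects are then only identified within a connected component, and the
Free-Wilson fit falls back to a tiny ridge penalty (flagged in the fit
stats). This is inherent to equally-sampled designs at minimal
replication, not an implementation artefact; it caps how well per-
monomer effects can be recovered at `r = 2` (see below).

Reagent assignment: the design is agnostic to reagent identity, so a
separate step maps levels to physical reagents maximising the summed
product desirability over the selected cells. The optimiser is
best-improvement hill climbing over within-factor reagent swaps, ties
broken by lowest (factor, i, j) for determinism, from a seeded random
start; the objective trace is recorded and non-decreasing. On small
instances the tests verify it reaches the exhaustive optimum over all
`N1! · N2!` assignments; in general only local optimality under the swap
neighbourhood is claimed.

## Free-Wilson analysis

The classical additive model `y = μ + Σ_positions effect(monomer)` is
fitted by least squares with reference-level coding (lexicographically
first monomer per position pinned to 0, so effects read as contributions
versus that reference — standard Free-Wilson practice and directly
interpretable). Monomers that lose all records (synthesis attrition) are
dropped from the vocabulary with a warning and excluded from
predictions. If the normal equations are singular — disconnected design,
`n ≤ p` — a fixed ridge penalty of 1e-6 on the effect terms engages and
is flagged; the penalty is small enough to leave well-identified effects
numerically untouched while making aliased ones finite.

`predict_freewilson` enumerates the full vocabulary product (2500 rows
for a 50 × 50 array) with prediction standard errors from the
coefficient covariance; observed (training) combinations are flagged and
their predictions equal the fitted values. No interaction terms are
offered: the analysis exists to assess additivity, and non-additivity
surfaces through residual diagnostics, not extra parameters.

## Active learning

The surrogate is a seeded random forest (bagged trees, default 100).
Uncertainty is the standard deviation of the per-tree predictions — the
dispersion of the ensemble's votes; a single-tree ensemble has
uncertainty identically 0. Featurisation is either a hashed circular
fingerprint folded to 256 numeric columns (structure pools) or a
one-hot R-group encoding matching the Free-Wilson representation
(array-derived pools). Model quality is reported as k-fold
cross-validated R² and RMSE (default 5 folds) and the fit refuses a
constant response, where uncertainty-driven selection would be
meaningless. A gradient-boosted backend was deliberately not wrapped:
boosted trees are not independent voters, so per-tree dispersion would
not mean what it means for a bagged ensemble.

Batch selection with size `k` and explore fraction `f`: the top
`k − round(f·k)` molecules by prediction are Exploit picks; the top
`round(f·k)` by uncertainty *among the remainder* are Explore picks, so
a molecule leading both lists is selected once, as Exploit. Ties break
by id. The defaults (batch 50, 20% explore, 100 trees) mirror a typical
array-follow-up configuration where the initial model is already decent
and exploitation dominates.

## Synthetic libraries and what the tests do (and do not) show

The simulator generates combinatorial libraries with additive ground
truth: per-monomer effects from N(0, `effect_sd`), optional cell-level
interaction terms from N(0, `interaction_sd`) on a configured fraction
of cells, Gaussian assay noise, and independent Bernoulli synthesis
attrition. The default condition — a 50 × 50 library (2500 products),
baseline pIC50 5, effect SD 0.5, noise SD 0.2, 36% attrition — emulates
a sparse-array campaign in which 100 designed compounds return roughly
64 measured records. Effects are drawn from centred normals because no
empirical effect distribution is available; real attrition is likely
monomer-correlated rather than independent (a failing reagent fails
everywhere), which the independent-Bernoulli model does not capture — a
per-monomer failure hook is the natural extension. Monomer structures
are simple alkyl/aryl/heteroaryl R-groups on a phenyl-sulphonamide
template; they make the chemistry real (products parse, round-trip and
compute properties) but do not emulate the diversity of a corporate
reagent store.

Frozen empirical properties (each computed once at a pilot run, then
fixed as regression levels; problem sizes chosen to keep the default
suite in minutes):

* End-to-end pipeline (design → attrition/noise → Free-Wilson → top-10
  unsynthesised): the top-10's mean true activity beats the library mean
  by ≥ 2 effect SDs in ≥ 90 of 100 seeded replicates.
* Effect recovery at `r = 2` under attrition: mean centred correlation
  between fitted and true effects > 0.6 over 10 replicates. The
  disconnected-design aliasing discussed above is what bounds this —
  with ~64 records against ~99 parameters, near-perfect per-monomer
  recovery is not achievable at this replication, and the pipeline's
  value shows up in the *ranking* enrichment, not in parameter fidelity.
* The true best combination appears in the unsynthesised top-10 in at
  least 3 of 20 replicates (observed 7/20 at pilot) — a regression
  floor, not a performance claim.
* Active learning (3 rounds of 20, 20% explore) finds a better true-best
  compound than an equal random budget in ≥ 70% of replicates.
* Surrogate validation: CV R² > 0.85 on a deterministic linear response;
  ≤ 0.1 on pure noise.

Because the generator's world is additive by construction, passing these
tests shows the machinery is correct and well-calibrated under its own
assumptions; it does not show that real SAR is additive, that real
attrition is independent, or that the thresholds transfer to any
particular assay.

## Workflow engine

Tasks are registered with a name, a single JSON-representable parameter
object validated against a schema, declared input/output columns, and a
role. Workflows are linear chains over file artifacts; validation checks
task existence, parameter schemas, column-contract compatibility
step-to-step, and a data-driven best-practice rule set shipping with one
rule: a molecule generator must be immediately followed by a profile or
liability filter (raw generator output is never ranked, merged or
selected from). Each step writes `step_NN_<task>/output.csv` (plus
`rejects.csv`) and appends a JSON log line with input/output/reject
counts, so every run is auditable from the log alone; failures stop the
chain naming the step, and `resume` restarts mid-chain from stored
artifacts. Branching is artifact reuse: any step's output can seed new
workflows. A distributed deployment (services, queues) is out of scope;
the single-object parameter convention and column contracts are the
stable interface a service wrapper would sit on.

## Numerical and degenerate-input conventions

* All randomness flows through per-call seeds (`with_seed` scoping), so
  no global RNG state leaks between operations; fixed seeds make whole
  workflow runs byte-identical.
* Ties are always broken deterministically (ids for compounds, lowest
  index for optimiser swaps, pool order for similarity hits).
* Empty inputs produce empty outputs plus a warning, not errors, in
  filter tasks; empty references or pools are errors (the operation is
  meaningless without them).
* Single-atom molecules are supported throughout descriptors and
  fingerprints; they are rejected by the SDF *reader* (the underlying
  parser requires a bond block), which the reject report surfaces.
* Stereochemistry present in input SMILES is preserved through
  canonicalisation but generation makes no stereo-aware edits; tautomer
  enumeration and 3D are out of scope.

## Known limitations

* Include-mode similarity filtering uses the two fingerprints only; a
  reduced-graph equality measure (sometimes used as a third include
  channel) depends on a reduced-graph scheme with no open counterpart
  and is omitted rather than guessed.
* MMP matching is exact-fragment, not environment-generalised.
* The design generator guarantees first-order balance only.
* PFI_proxy substitutes computed clogP for measured logD7.4.
* The BRICS environment predicates implement the published rule set over
  kekulized graphs with perceived aromaticity; exotic aromatic systems
  (mesoionics, large-ring aromatics) may be classified differently than
  by other toolkits.
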