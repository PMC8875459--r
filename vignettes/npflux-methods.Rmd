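---
title: "Methods: the npflux prioritisation workflow"
author: "npflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the npflux prioritisation workflow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npflux)
```

# The problem

Natural products act on many targets at once, and their target annotation
in public databases is sparse: a knockout screen driven only by known
targets misses most of what such compounds do to a cell. `npflux`
implements a workflow that sidesteps this by reading the compound's effect
off the *metabolic state* of treated cells: context-specific metabolic
models are built from the expression profiles of treated and control
(vehicle) cultures, and compounds are prioritised by combining four
evidence streams computed on those models:

1. **Target deletion** — knock out each compound's annotated target genes
   in the control model and record the growth ratio
   `grRatio = mu_ko / mu_wt` from flux balance analysis (FBA). A ratio of
   0 predicts growth arrest.
2. **Content dissimilarity** — compare each treated model's reaction set
   `A` with the control set `B` through the Jaccard index
   `J = |A ∩ B| / |A ∪ B|`, reporting `D = 1 − J`. Large `D` means the
   treatment remodels the metabolic network.
3. **Flux similarity to reference drugs** — run flux variability analysis
   (FVA) and compare per-reaction flux ranges with those of the control
   model constrained by the targets of approved drugs. The per-reaction
   overlap score is
   `max(0, min(v1max, v2max) − max(v1min, v2min) + ε) /
   (max(v1max, v2max) − min(v1min, v2min) + ε)`,
   and `si` is its mean over the union of reactions, a reaction absent
   from one model contributing the range `[0, 0]`. Treated models similar
   (high `si`) to growth-arresting reference drugs are promising.
4. **Pathway alteration** — per pathway (subsystem), the presence rate is
   the fraction of the reference pathway's reactions present in a context
   model; the step reports the difference of presence rates against the
   control.

A compound flagged by at least two steps is selected, with explicit
include/exclude lists standing in for external evidence (toxicity,
literature, databases) — that judgment is configuration, never inferred.

# Constraint-based machinery

All analyses operate on a `MetabolicModel`: stoichiometric matrix `S`,
flux bounds (mmol/gDW/h), gene–protein–reaction (GPR) boolean rules
(`and` = complex, `or` = isozymes), subsystem labels and a biomass
objective. FBA maximises biomass flux subject to `S v = 0` and bounds;
FVA minimises and maximises each reaction's flux with the objective held
at a fraction of its optimum (default 1.0 — the usual toolbox default;
the fraction is exposed because published workflows rarely state it).
When the optimum is negative a fraction is meaningless and the objective
is pinned at its optimum instead.

No linear-programming backend is assumed: the package carries its own
dense bounded-variable two-phase primal simplex (`solveLP`), using
Bland's rule throughout, which guarantees termination on the small,
frequently degenerate flux LPs this package generates. Infinite bounds
are clamped to ±1e6. An exponential basic-solution enumeration oracle
(`enumerateLP`) ships alongside and the test suite requires agreement to
1e-6 on hundreds of random problems; the oracle enumerates over a maximal
independent subset of constraint rows so that rank-deficient systems
(orphan metabolites) are handled exactly.

Knockouts go through the GPR layer: a reaction is disabled (both bounds
zero) iff its rule evaluates false with the knocked genes false. Growth
ratios below 1e-6 are reported as exactly 0 — observed knockout screens
cluster at 0 and 1, and a hard zero keeps the classification
reproducible. Combination knockouts flag synergy when the pair ratio
drops more than `synergy_delta = 0.01` (configurable; the literature
typically reports "no significant reduction" without a numeric bar)
below the better single ratio.

# Context-specific model extraction

Building a context model from expression data proceeds in four moves:

* **Medium constraining.** Exchange reactions are those with exactly one
  nonzero stoichiometric entry; negative flux is uptake. Every uptake
  whose metabolite is not in the medium is closed (bounded at 0);
  secretion is untouched. Identifier matching is exact — cross-namespace
  metabolite name normalisation is out of scope.
* **Consistency.** `fastcc()` removes blocked reactions — those unable to
  carry `|v| ≥ ε` in any steady state — using the classic scheme: one LP
  per round pushes flux through as many unchecked reactions as possible
  (auxiliary variables `z ≤ ε`, `v ≥ z`), with direction flips for
  reversible candidates, plus a per-reaction fallback. The brute-force
  two-LPs-per-reaction test is exported as
  `consistentReactionsOracle()` and the suite requires set equality on
  random networks.
* **Activity calls.** Full microarray discretisation pipelines are
  deliberately out of scope; `callActivity()` applies two explicit
  thresholds (defaults 1 and 0): score ≥ high ⇒ active, ≤ low ⇒
  inactive, otherwise unknown. `genesToCoreReactions()` then evaluates
  each GPR rule three-valuedly: a reaction is *core* when active genes
  alone satisfy the rule; a reaction that could be satisfied only if
  unknown genes were active is *undecided*; a reaction whose rule fails
  even then is *inactive*. Reactions with no rule carry no evidence.
* **Extraction.** `extractContextModel()` grows a flux-consistent
  sub-model containing every core reaction by alternating an
  activation LP over the uncovered core with an L1-minimisation over
  penalised non-core reactions. Undecided and rule-free reactions get
  zero weight in that penalty: they may be recruited freely but are not
  sought. Minimality is heuristic, not guaranteed — determinism (by
  declaration-order tie-breaking) was preferred over minimality. The
  biomass reaction is always forced into the core, and a core reaction
  blocked under the medium raises an explicit infeasible-core error
  naming the reactions. A final per-reaction consistency check prunes
  numerically marginal non-core stragglers, so the returned model always
  passes the flux oracle at `ε`.

`flux_epsilon` defaults to 1e-4, the same magnitude as the ε in the flux
overlap score; direction handling in the consistency LPs never leaks into
the returned model.

# Scores and ranking

`jaccardDissimilarity` is the standard ratio; some published prose
describes it garbled, and the standard definition is used here. The flux
overlap ε (default 1e-4) keeps zero-width ranges well defined: two
absent reactions compare as identical (`ε/ε = 1`), so averaging over the
union of reaction ids — rather than some global reaction universe — is
the natural reading of "absent reactions get zero bounds"; the
alternative universe is available via the scoring functions' inputs since
callers control the FVA tables they pass. Rankings
(`rankProducts`) sort descending with alphabetical tie-break, making
every top-k list deterministic.

Reference drugs are those whose constrained-control model shows flux
dissimilarity to the unconstrained control above a floor (default 1e-4,
matching the score's ε); the step-3 flag is membership in the union of
per-reference top-k lists (default k = 10), mirroring how combined
top-ten lists are used in screening practice. The step-4 flag requires
both a known target gene in the pathway of interest and a nonzero
presence-rate difference there; any nonzero difference counts, as no
published cutoff exists, and the 0.1 threshold is reserved for the
report's `display` flag.

Pathway reports exclude pathways with ≤ 3 reactions (tiny denominators
make presence-rate differences jumpy) and rank pathways by the
interquartile range of differences across treatments, computed with R's
default type-7 linear-interpolation quantiles (the choice of quantile
method is not standardised in the sources this mirrors; type 7 is R's
default and is stated here for reproducibility).

# The synthetic scenario generator

`makeToyNetwork()` builds a network with one essential *backbone* pathway
producing a biomass precursor and `n_pathways − 1` redundant pathways
producing a common currency metabolite; biomass consumes both. Chains
default to 4 reactions (one above the pathway-size exclusion cutoff),
with GPRs mixing single genes, an AND complex at chain position 2 and an
OR isozyme pair at position 3. Each pathway starts from its own nutrient
exchange (uptake bound −10), so wild-type growth is 10 by construction:
the backbone saturates its uptake and the redundant pathways jointly
oversupply the currency.

This layout gives the planted signals clean mechanisms: a product
targeting the backbone's single-gene step is growth-essential
(`grRatio = 0`), while silencing a redundant pathway's genes removes that
pathway from the extracted context model without touching viability —
the presence-rate difference for that pathway is −1 against the control.
With exactly two pathways the single redundant pathway is itself
essential, so planted shutdowns are restricted to scenarios with at
least three.

Expression scores are N(2, 0.5²) for intended-active and N(−2, 0.5²) for
intended-inactive genes — cleanly separated from the default thresholds
(1, 0) at zero noise. Noise is modelled as measurement contamination:
with probability `noise_rate` a score is drawn from an ambiguous
mid-distribution N(0.5, 0.5²) straddling the threshold band. Most
contaminated measurements therefore become *unknown* calls (which the
extractor treats as unpenalised, so structurally required reactions are
unaffected), and a minority become outright miscalls. A harsher model
that flips the full activity state with probability `noise_rate` was
considered and rejected: flipping any of a silenced pathway's genes back
to *active* forcibly re-activates the whole pathway through the core,
which makes recovery collapse at contamination levels that real
ambiguous measurements would tolerate.

What the generator does *not* emulate: probe-level microarray structure,
normalisation artefacts, correlated gene noise, reversible reactions in
the toy chains, and any realistic pathway topology beyond
linear-with-redundancy. Passing recovery tests on these scenarios shows
the workflow's logic is implemented correctly, not that it will rank
compounds correctly on real expression data.

# Problem sizes and numerical choices

The shipped tests and the acceptance script run, by design, on desk-scale
problems: toy networks of ~20–40 reactions, random LP/consistency checks
on networks of ≤ 8 reactions (where the enumeration oracle is exact), 500
randomised score comparisons, and a 100-replicate seeded recovery study
at 5% contamination. LP tolerances: optimality/feasibility 1e-9,
phase-1 infeasibility 1e-7, consistency support threshold 0.99 ε.
All randomness flows through explicit seeds; reruns are byte-identical
(run manifests except their timing fields).

# Known limitations

* The simplex recomputes a dense factorisation per iteration — fine at
  toy scale, not intended for genome-scale models; a genome-scale run
  would want a sparse LP backend behind the same `solveLP` contract.
* Extraction guarantees consistency and core coverage but not minimality,
  and can include unpenalised reactions that a weighted variant would
  drop.
* Expression handling starts at gene-level scores; anything upstream
  (normalisation, probe mapping, replicate averaging) is the caller's
  responsibility. Whether to pool replicates before calling activity is
  left to the caller; the generator emits one column per condition.
* The selection rule encodes external evidence purely as include/exclude
  lists; it performs no literature or database mining.
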