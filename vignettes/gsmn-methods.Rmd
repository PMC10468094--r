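---
title: "Curating and simulating genome-scale metabolic networks with gsmn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating and simulating genome-scale metabolic networks with gsmn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsmn)
```

# Scope of the package

`gsmn` covers the road from a multi-source metabolic *reconstruction* (a
knowledge base of metabolites, reactions, genes and their provenance) to
a constraint-based *model* that simulates growth and metabolite
production. The pipeline is the one used for modern fungal
reconstructions: merge subnetworks obtained from genome annotation,
orthology against template models and earlier reconstructions; admit
external reactions only under identifier-compatibility and gene-support
rules; monitor the topological producibility of known target metabolites
and gap-fill the network until they are reachable; tighten the
reconstruction into a flux model by fixing reaction directionality,
resolving duplicates, checking mass/charge balance and screening for
structural artefacts; and finally run FBA/FVA under defined media.

# Data model and conventions

A reconstruction holds two compartments, intracellular `c` and
extracellular `e`; organelles are deliberately not modelled. The system
boundary is *implicit*: exchange reactions have an empty side, so an
uptake is written `∅ -> m[e]` and a production `m[e] -> ∅`. Four
artificial reaction families model the environment interface, each
carrying its own artificial gene series so their origin is legible in
the GPRs:

| category    | direction              | gene series | id pattern       |
|-------------|------------------------|-------------|------------------|
| uptake      | boundary → e           | `u###`      | `Uptake_###`     |
| production  | e → boundary           | `p###`      | `Production_###` |
| demand      | e → c, irreversible    | `d###`      | `Demand_###`     |
| sink        | species ↔ boundary     | `sk###`     | `Sink_###`       |
| transport   | e ↔ c (enzymatic)      | `t###`      | —                |

The demand convention — an irreversible transfer from the external to
the intracellular environment — is kept as stated even though much of
the community uses "demand" for intracellular drains; the package
reproduces the curation convention of its reference pipeline, and the
SBO annotation (SBO:0000628) is retained.

Two further conventions run through everything. First, *curation never
deletes*: wrong or unsupported reactions are blocked by setting both
flux bounds to zero, so the reconstruction keeps all knowledge while
the model cannot use it. Second, *determinism*: entities are stored
sorted by id, artificial numbering is dense and ordered, gap-filling
tie-breaks are lexicographic, and the SBML writer is byte-stable, so
every derived artefact is diffable.

Formulas use a strict Hill-notation dialect: element symbols from the
periodic table with optional positive counts. Generic groups (`R`,
`X`), polymer notation and charges-in-formula are reported as
`unparseable` rather than guessed at; charge is a separate integer
field (the FBC convention) and is never inferred from the formula.

# Topological producibility

`compute_scope()` implements network expansion: starting from the seed
set, a reaction direction fires when all its substrates are producible
and contributes its products; iterate to the least fixed point.
Three semantic choices matter:

* **Seeds** are the metabolites fed by an uptake reaction — the
  nutrients the environment can supply. Uptakes blocked during curation
  feed nothing and are excluded.
* **Coefficients are ignored** (pure hypergraph reachability), the
  standard semantics of topological producibility tools. This is why a
  stoichiometric defect can never change the scope, which the test
  suite exploits.
* **Reversible reactions fire in each direction independently**, a
  known over-approximation of topological approaches; the flux layer is
  the corrective.

`compute_scope()` uses an unmet-substrate counter and a frontier queue
(each substrate edge visited once). `compute_scope_naive()` is a
deliberately plain quadratic re-implementation — full passes with set
operations — kept as an in-package reference; the two share no
bookkeeping, and their exact agreement on randomized networks is part
of the validation suite. The synthetic generator computes its ground
truth with a third, local closure for the same reason.

# Gap-filling

`minimal_completion(mode = "exact")` searches for a minimum-cardinality
set of repair reactions making the targets producible: depth-first
branch-and-bound over the lexicographically ordered repair set, pruning
a branch when it cannot beat the incumbent or when even taking every
remaining candidate fails to reach the targets (scope is monotone in
the reaction set, so this prune is exact). Ties among equal-cardinality
optima resolve to the lexicographically smallest sorted id tuple —
topological gap-filling generally has many optima, and determinism is
worth more than any particular choice. `brute_force_completion()` is
the exhaustive reference (subsets in increasing cardinality, refusing
more than 20 repair reactions). Greedy mode returns a subset-minimal
completion by reverse-order elimination. Targets unreachable even with
the whole repair database are reported `unsatisfiable`, never silently
dropped.

`iterative_gapfill()` runs the tiered protocol: target tiers from
highest to lowest confidence; within a tier, repair databases from most
to least trusted, then their union; the first query that unlocks any
new target wins, so a high-confidence route is preferred over a
shorter low-confidence one. Accepted reactions get provenance
`gapfill:<label>` and — when the database supplies no gene — an
artificial `s###` gene, the series also used by
`admit_spontaneous()`, which admits no-enzyme reactions exactly when
they share a metabolite with the draft.

# Reconciliation rules

`merge_networks()` takes the permissive stance appropriate to the
knowledge-base stage: shared reactions union their provenance, OR-join
their GPRs (verbose GPRs are information, not noise) and widen their
bounds to the union interval; restriction happens later in model
derivation. The same id with different stoichiometry is a hard error
that prints both equations.

`admit_external_reaction()` encodes the external-source rule: admit
under the mapped id when the reaction id itself resolves to the
reference namespace, admit under the original id when every reactant
and product resolves, reject otherwise; both routes require at least
one gene association. The reference namespace is defined by the
supplied identifier dictionary (its target column).

Duplicate reactions — identical or exactly swapped stoichiometric
multisets — are resolved by blocking the weaker member, but only when
the gene associations are identical or nested; otherwise the pair is
flagged for manual review. Preference order: the mass-balanced member,
then the member with a reference-namespace id, then the
lexicographically smaller id. "Reference-namespace" is a caller-supplied
predicate whose default recognises MetaCyc-style reaction ids
(`…-RXN`, `RXN-…`, `TRANS-RXN…`); reconciliation-era "homemade" ids
fail it.

InChIKey matching is tiered on the hyphenated 14–10–1 layout: exact
(tier 3), first two blocks (tier 2, stereochemistry/isotopes ignored),
first block only (tier 1, planar connectivity). Model comparison under
the tier-1 key collapses same-skeleton metabolites inside one model to
a single comparison unit and reports unkeyed metabolites as
incomparable rather than exclusive.

# From reconstruction to flux model

`derive_model()` binds an objective (the biomass reaction by default)
and an uptake policy: `closed` shuts every uptake, `open` allows all at
10 mmol·gDW⁻¹·h⁻¹, `default` opens exactly the uptakes of a
`medium_spec()` at their stated rates. "Unlimited" uptakes (oxygen)
get a large finite bound (10⁶ by default) for solver robustness.

## Linear programming

All quantitative analyses reduce to one LP shape: maximise `c'v`
subject to `S v = 0` and finite box bounds. The solver is the simplex
routine from the recommended `boot` package, but driven through a
reduction that keeps it on its numerically reliable single-phase path:

1. fixed variables (`lb == ub`, mostly blocked reactions) are pinned
   and dropped — their zero-width box rows would otherwise make the
   tableau maximally degenerate;
2. the steady-state equalities over the free variables are eliminated
   exactly through an orthonormal null-space basis (full SVD) around a
   feasible anchor flux `v0`; every feasible flux is `v0 + N y`;
3. splitting `y` into positive and negative parts yields a
   nonnegative-variable LP with only `≤` rows and non-negative
   right-hand sides, solvable from the slack basis without artificial
   variables.

The anchor is `v0 = 0` for plain FBA (always feasible because no lower
bound is positive) and the FBA optimum for FVA subproblems. Because the
objective is always a single reaction, the FVA constraint
`c'v ≥ f·opt` is a raised lower bound on that reaction, never an extra
constraint row. Rank decisions in the SVD use a relative tolerance of
1e-9; feasibility slack is 1e-7; fluxes below 1e-9 count as zero, and
QC detectors flag offenders above 1e-6. These are deliberate two-sided
margins around double-precision SVD accuracy on networks of this
scale (10²–10³ reactions).

## Balance, leaks, energy cycles

`check_balance()` reports per-element residuals (products minus
reactants, coefficient-weighted); a reaction with any participant
lacking a usable formula is `undetermined`, not guessed. Boundary and
pseudo-reactions are evaluated but tagged `exempt` — an exchange
reaction is "imbalanced" by construction. Protons and water are not
auto-excluded; imbalance is reported raw because the downstream policy
is blocking, not rebalancing.

`detect_leaks_siphons()` works on the closed model and asks, per
metabolite, whether a steady-state flux exists with strictly positive
net production (leak) or consumption (siphon) of that metabolite while
every other metabolite stays balanced — one small LP each, obtained by
dropping the metabolite's row from `S` and optimising its net balance.
Production, sink, biomass and dissipation pseudo-reactions are zeroed
first (uptakes already are, in closed mode): they create or destroy
mass by design and would otherwise flag every exportable species.
Demand reactions stay open — they conserve mass between compartments.

`energy_cycle_check()` appends, per energy carrier, a temporary
dissipation reaction and maximises its flux on the closed model; any
positive optimum means the network charges that carrier from nothing.
The built-in table covers the 13 standard carriers (ATP, CTP, GTP,
UTP, ITP, NADH, NADPH, FADH2, FMNH2, ubiquinol-8, acetyl-CoA,
glutamate, proton). Hydrolysis probes use the neutral-species form
(`ATP + H2O -> ADP + Pi`), which is exactly mass-balanced under the
package's neutral-formula convention and — more importantly — emits no
free proton that a closed network would have to reabsorb; a probe
whose by-products cannot be consumed is structurally forced to zero
flux and would mask real cycles. Redox probes discharge to the
oxidised form plus protons; the proton carrier is probed as a
gradient-dissipating `H[e] -> H[c]` transfer. Carriers whose species
ids do not resolve in the model are skipped with a warning.

# The synthetic-data generator

`generate_toy()` emulates, at miniature scale, the features of a real
multi-source fungal reconstruction that the pipeline must handle:
parallel linear biosynthetic pathways fed by extracellular seeds
through uptake and transport reactions; optional branch byproducts
(water, drained by the model's single sink); an ATP
synthesis/maintenance couple with imported ADP/phosphate (playing the
micronutrient role that vitamins and iron play in real media); a
biomass reaction consuming all pathway terminals 1:1; export routes
and production exchanges for the terminals; and provenance tags drawn
from several pseudo-sources. Formulas are assigned compositionally —
a product's formula is its precursor's minus any split-off water — so
every designed reaction is mass- and charge-balanced by construction,
and the open-model FBA optimum has the closed form
`min_i(rate_i / demand_i)` (equal to the uptake bound for the default
1:1 toys).

Defaults are five pathways of length four, 30% branching, 25%
reversible steps and three provenance sources — small enough that
exhaustive oracles stay cheap, rich enough that branching, cycles,
reversibility and multi-source provenance all actually occur. Defect
injection is opt-in and recorded in a registry: stoichiometric
imbalance (a product coefficient bumped to 2 — topologically invisible
by the coefficient-free scope semantics, so defective fixtures remain
valid scope fixtures), erased formulas, duplicate reactions under
"homemade" ids, and mass-leak cycles (`B -> 2A` against an existing
`A -> B`, placed on single-substrate chain steps so the injected leak
is a clean single-metabolite certificate).

`degrade()` removes pathway steps, one per chosen pathway; since each
chain is a line, every removal provably disconnects that pathway's
terminal, making the removed set a known minimal completion.
`decoy_reactions()` supplies repair candidates over fresh off-pathway
metabolites that can never restore reachability, so ground-truth
minimality survives arbitrary padding of the repair database.

What the toys deliberately do **not** emulate: hub metabolites and
realistic degree distributions, intracellular compartmentation, GPR
complexity beyond single genes, thermodynamics, and genome-scale size.
Passing the validation suite therefore demonstrates algorithmic
correctness against enumerable ground truth, not predictive accuracy
on any real organism — on real networks the same algorithms face far
denser connectivity, and runtimes (not results) will differ.

# Validation protocol and problem sizes

The acceptance layer (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) recomputes six families of checks from scratch;
the sizes are chosen so each oracle remains exhaustive:

* scope vs. naive closure: 100 random networks of up to 30 reactions,
  exact set equality of producible metabolites and active reactions;
* gap-filling minimality: 100 random degrade/decoy instances with up
  to 12 repair reactions, exact cardinality agreement between
  branch-and-bound and exhaustive enumeration;
* FBA vs. closed form: 60 random substrate/demand models, agreement to
  1e-6 (observed errors are at machine precision);
* defect recovery: five heavily-defective toys; 100% of injected
  imbalances, duplicate pairs and leaks must be flagged;
* closed-model soundness: ten defect-free toys; zero growth and zero
  flagged energy carriers on the closed model;
* FVA invariants: range nesting across biomass fractions 0.5 and 0.9,
  and `(0,0)` ranges for blocked reactions.

# Known limitations

* The dense-simplex LP stack targets curation-scale models (up to a
  few thousand reactions); genome-scale FVA over every reaction is
  feasible but slow compared to sparse interior-point solvers.
* Scope semantics over-approximate through reversible reactions and
  under-approximate cyclic self-sustaining machinery (a cycle's
  members are unreachable until one member is seeded) — the classic
  gap between topological and steady-state producibility; the package
  exposes both views precisely so they can be compared.
* Duplicate detection is exact-multiset only; near-duplicates through
  alternative protonation states or compound-class identifiers are out
  of scope and belong to identifier curation.
* Unique-metabolite counting strips the compartment suffix from ids;
  both the raw and the stripped counts are reported because published
  model statistics are ambiguous between the two.
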