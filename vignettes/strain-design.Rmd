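---
title: "Constraint-based design of growth-coupled producer strains"
author: "budstrain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint-based design of growth-coupled producer strains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(budstrain)
```

## The problem

2,3-butanediol (BDO) is a fermentative product that *Saccharomyces
cerevisiae* makes only in traces: pyruvate and acetaldehyde, its
precursors, are drained by the highly active alcoholic fermentation
pathway, and the NADH that butanediol dehydrogenase needs is consumed
by the same ethanol branch and by glycerol formation. Computational
strain design asks which reaction (and hence gene) deletions force a
production organism to secrete the product *while it grows* — a
growth-coupled design — rather than relying on the organism to
volunteer flux it has no reason to give.

This package implements the full in-silico side of that workflow for
constraint-based (stoichiometric) models: flux balance analysis and its
lexicographic refinement, flux variability analysis, production
envelopes, gene–protein–reaction (GPR) boolean logic with minimal gene
knockout mapping, and the bilevel knockout-design program (OptKnock)
solved as a single-level mixed-integer linear program through LP strong
duality. A hand-solvable fermentation fixture makes every stage
testable against exact rational arithmetic; an opt-in reproduction mode
accepts the published iMM904 yeast genome-scale model as a
user-supplied SBML file.

## Flux balance analysis and its refinements

A model has stoichiometric matrix $S$ (metabolites × reactions,
negative coefficients for consumption) and flux bounds $l \le v \le u$
in mmol·gDCW⁻¹·h⁻¹. FBA solves

$$\max_v \; c^\top v \quad \text{s.t.} \quad S v = 0, \; l \le v \le u,$$

usually with $c$ selecting the biomass reaction. The environment enters
as bound overrides (`environmentSpec()`): uptake bounds on exchange
reactions with the standard sign convention (uptake negative, so
glucose uptake of 10 is a lower bound of −10), and a lower bound on the
ATP maintenance pseudo-reaction. The defaults — glucose 10, oxygen 2,
maintenance 1 — are the constraint set used throughout the package.
Maintenance is a lower bound, not an equality, so surplus ATP can be
dissipated.

FBA optima are almost always degenerate: many flux vectors achieve the
same growth. Every "production at maximal growth" number this package
reports therefore comes from `fixAndOptimize()`, which optimizes
growth, fixes it within `1e-9·max(1, |μ*|)`, and then maximizes (and
separately minimizes) the product flux over the optimal face. Reporting
both the maximum and the minimum makes weak coupling visible: a design
is growth-coupled only when the *minimum* product flux at maximal
growth is positive.

`solveFVA()` computes per-reaction flux ranges with growth constrained
to at least a fraction of its maximum; `productionEnvelope()` fixes
growth at each point of an equispaced grid (equality within tolerance,
so the envelope of the objective against itself collapses onto the
grid) and records the attainable product range. A collapsed envelope
(min = max > 0) at the right-hand end is the growth-coupling signature.

## Gene–protein–reaction logic

Reactions carry boolean GPR rules: OR over isozymes, AND over complex
subunits. `applyKnockouts()` disables any reaction whose rule
evaluates FALSE under a gene deletion set, in addition to explicit
reaction-level deletions. `minimalGeneKnockouts()` inverts the map: to
disable a set of reactions, every DNF conjunct of every target rule
must lose at least one gene, so the answer is the family of minimal
hitting sets over the pooled conjuncts. Below 12 involved genes the
package enumerates subsets exhaustively and returns *all*
inclusion-minimal sets; above that, an implicit enumeration finds the
minimum-cardinality sets. Each returned set carries a side-effect
report listing every other reaction it silences — important in
practice, where an enzyme such as pyruvate decarboxylase sits behind
two different reactions, and where a multimeric complex can be
switched off through any single subunit even though the design table
lists all of them.

## OptKnock: bilevel design as a single-level MILP

OptKnock chooses up to $K$ reaction knockouts maximizing product flux
while the cell inside the optimization maximizes growth:

$$\max_{y} \; v_{\text{product}} \quad \text{s.t.} \quad v \in
\arg\max \{ v_{\text{biomass}} : Sv = 0,\; l_j y_j \le v_j \le u_j
y_j \},$$

with binary activity indicators $y_j$ on a candidate set and a budget
$\sum (1 - y_j) \le K$. The inner problem is replaced by its KKT
certificate: dual feasibility rows
$S^\top \lambda + \mu^{ub} - \mu^{lb} = c_{\text{inner}}$ and one
strong-duality row equating the inner objective with the dual
objective, in which the bilinear products $y_j \mu_j$ are linearized
with big-M constraints ($z \le My$, $z \le \mu$, $z \ge \mu - M(1-y)$,
$z \ge 0$). A viability row keeps growth above `f_min` (default 5% of
the wild-type optimum). Because strong duality pins $v$ to the
inner-optimal face, the outer maximization automatically returns the
lexicographic product maximum at optimal growth.

Design choices worth knowing:

* **Big-M = 1000**, the conventional bound magnitude; dual variables
  are boxed by the same constant. Big-M reformulations can silently
  lie when M binds, so every returned strategy is re-verified by
  independent LPs (`verifyStrategy()`) and a discrepancy beyond 1e-6
  relative raises a warning — the verified numbers always win.
* **Determinism.** Among equal-objective designs the package returns
  the one with fewest knockouts, then lexicographically smallest
  reaction ids, pinned by a refinement pass (maximize the number of
  active reactions at the optimum, then fix candidates one by one in
  lexicographic order with feasibility queries). The refinement works
  at the tolerance edge; if its pinned set ever fails independent
  verification the incumbent's own deletion set is kept instead.
* **Candidate construction** (`buildCandidateSet()`) excludes exchange
  and transport reactions by kind, the biomass and maintenance
  pseudo-reactions, reactions essential at `f_min`, and blocked
  reactions; every exclusion is recorded with its reason. This
  pre-screening shrinks the binary space but is plumbing, not part of
  the formulation.
* **Alternative solutions** (`enumerateAlternatives()`) come from
  integer cuts $\sum_{j \in D} y_j \ge 1$ over each previously
  returned deletion set $D$; the empty deletion set cannot be cut this
  way, so enumeration stops when it becomes optimal.
  `iterativeRefine()` re-runs the design with candidates removed — the
  step that, on the genome-scale model, turns non-intuitive deletion
  sets into the interpretable all-ADH strategy.

## The solver layer

No linear-programming backend is assumed: the package carries a dense
bounded-variable two-phase primal simplex (C++ via RcppArmadillo)
sized for desk-scale models, and a depth-first branch-and-bound over
the knockout binaries. Numerical choices: feasibility and optimality
tolerances 1e-9; Dantzig pricing with a Bland's-rule fallback after a
stall so degenerate problems terminate; basis inverse maintained by
eta updates with refactorization every 30 pivots. At claimed optimality
the basis is refactorized and primal feasibility re-verified — the
big-M rows make some MILP node bases ill-conditioned enough for
eta-update drift to push a basic variable past its bound, which would
otherwise let a "fractional" binary at 1 + 1e-5 send branch-and-bound
into a loop. A drifted solve is repeated with conservative settings
(Bland from the first pivot, refactorization every 10); residual
artificial variables at that point are classified as infeasibility.
Branch-and-bound additionally clamps relaxation values into the node
box before integrality testing, so branching always makes progress.
The strong-duality identity (primal = dual objective reconstructed
from $\lambda$ and reduced costs) is asserted across the test suite,
and the simplex is property-tested against an independent
vertex-enumeration oracle on seeded random LPs.

## PYRCORE: the hand-solvable fixture

`makePyrcore()` builds a 21-metabolite, 23-reaction, two-compartment
fermentation network around the pyruvate branch point: lumped
glycolysis in two steps (net 2 ATP, 1 NADH per pyruvate), branches to
ethanol (ADH, behind the isozyme rule `ADH1 or ADH3 or ADH5`),
glycerol (GPD, `GPD1 or GPD2`), and acetoin → 2,3-butanediol (the
acetoin condensation and the decarboxylation share `PDC1`; BDH is
`BDH1`), oxygen-limited respiration with P/O ratio 2, ATP maintenance,
and a biomass sink costing 1 pyruvate + 3 ATP. All coefficients are
small integers, so under the default environment every optimum is an
exact small rational, derivable by hand from the NADH and ATP balances:

| condition | growth | BDO at max growth | other |
|---|---|---|---|
| wild type | 11 | 0 | ethanol 2, glycerol 7 |
| ΔADH | 117/11 | 10/11 (min = max) | glycerol 83/11 |
| ΔADH, zero growth | 0 | max 8 | |
| ΔADH + ΔRESP | 7 | 2 | |

The fixture reproduces, qualitatively, the biology that motivates the
design: deleting the ethanol branch strictly increases growth-coupled
butanediol *and* glycerol secretion (the cell's remaining redox
valve), and removing respiration on top — the in-silico analogue of
anaerobiosis — pushes butanediol further at the cost of growth.
Acetoin deliberately has no transport or exchange, so the
acetoin-to-butanediol flux equality is forced and the hand solutions
are airtight; real fermentations secrete acetoin, a wet-lab matter
outside this package's scope.

## The random-model generator

`makeRandomModel()` draws growth-feasible models from balanced
templates rather than random matrices, so no repair step is needed: a
substrate uptake chain (randomized split coefficient and length)
producing a hub metabolite with redox and optionally energy cofactor
coupling, one to several fermentation branches off the hub (randomized
redox coupling, GPR rules drawn from a small gene pool with occasional
shared genes and two-step pathways), an oxygen-limited cofactor
recycler, maintenance, and a biomass sink. The first branch is always
a pure redox valve, which—together with a nonzero oxygen
bound—guarantees positive growth for every draw. All randomness sits
behind one seed; identical specs serialize byte-identically, and the
global RNG stream is left untouched.

What the generator emulates is the cofactor-balance structure that
drives knockout design; what it does not emulate is everything else
about real metabolism — compartmentalized cofactor pools, reversible
reactions, alternative substrates, regulation, enzyme kinetics. Tests
passing on these models therefore certify the *algorithms* (the MILP
agrees with exhaustive enumeration; round trips are lossless), not
quantitative behaviour of any real organism.

## Problem sizes and runtime

The shipped tests and the acceptance script run the fixture (23
reactions), 30–50 seeded random models (roughly 20–30 reactions, 3–9
knockout candidates), and knockout budgets K ≤ 3 — sizes chosen so
exhaustive enumeration remains an airtight oracle for the MILP and the
whole suite completes in well under a minute. The genome-scale
reproduction (`reproduce-table1`) is an explicit opt-in that takes a
user-supplied iMM904 SBML file; it is never downloaded automatically,
and the comparison table reports relative deviations rather than
asserting equality because the exact model encoding the original
study used is not documented.

## Known limitations

* The simplex is dense; genome-scale models (≈1500 reactions) solve,
  but slowly. The design aim was correctness and auditability at desk
  scale, not speed at genome scale.
* Gene-level binaries are not part of the MILP; gene realization is
  post-hoc via minimal hitting sets, as in the published design
  tables.
* No MOMA, no regulatory constraints, no thermodynamics, and no
  kinetic simulation; reversibility is representational (bounds
  crossing zero) with no reaction splitting.
* The JSON schema (`budstrain-model/1`) and both SBML dialects round
  trip everything the package models; annotations beyond bounds, GPRs,
  kinds and the objective are not preserved.
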