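---
title: "Multi-output Boolean minimization for configurational causal inference"
author: "mopir"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-output Boolean minimization for configurational causal inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mopir)
```

## The problem

Configurational comparative methods (CCMs) infer Boolean cause--effect
models from case-level binary data: each case is a complete assignment
of k binary inputs (risk factors, policies, socio-demographic markers)
and one or more binary outcomes.  A causally interpretable model is a
minimally necessary disjunction of minimally sufficient conjunctions --
in switching-circuit terms, an irredundant sum of prime implicants.

Classic tools optimize one outcome at a time.  That is inadequate
whenever outcomes co-occur systematically, as in multi-morbidity data
where, say, every diabetic patient group also shows depression: a
conjunction that explains the *joint* presence of two conditions may be
no prime implicant of either condition alone, so single-outcome
optimization can never find it.  `mopir` therefore optimizes the whole
system of output functions jointly.

## The model

Write the data as a system of incompletely specified Boolean functions
$F = \{f_1(\mathbf{x}), \ldots, f_m(\mathbf{x})\}$ over inputs
$\mathbf{x} = \{x_1, \ldots, x_k\}$.  Each output has an on-set,
off-set and dc-set (don't-care set) of minterms, where the first
declared input is the most significant bit of the minterm index.

A **multi-output prime implicant (MOPI)** is a product of literals that
is a prime implicant of some $f_j$ or of some product
$f_{j_1} f_{j_2} \cdots$ of the output functions.  Operationally we
store each cube with its maximal **output tag** -- the set of outputs
whose off-sets it avoids -- and characterize MOPIs as: non-empty tag,
no one-literal expansion with a tag superset, and at least one covered
on-minterm of a tagged output (a cube covering only don't-cares can
never help a model).  The equivalence of this characterization with
the product-function definition rests on the fact that expanding a cube
can only shrink its tag, so primality for the largest product implies
primality for every sub-product that needs it; the argument is spelled
out in the source of `generate_mopis()`.

An **irredundant system** selects MOPIs such that (i) every on-minterm
of every output is covered by a selected MOPI tagged with that output,
(ii) no selected MOPI can be removed, and (iii) no literal of a
selected MOPI can be cancelled -- the expanded product replacing the
original in every model where it is written -- without breaking
F-equivalence (correct values on every on- and off-minterm).  The
**solution** is the set of *all* irredundant systems; multiple systems
are reported as systems ambiguity, never silently ranked.

The **writing rule** puts a selected MOPI into the model of every
tagged output whose on-set it touches.  A shared MOPI may then be
absorbable inside a single output's sum (e.g. `roca + mys·roca`); it
is retained there deliberately, because cancellation operates on the
system as a whole and removing it from one model only would hide the
shared cause the method exists to reveal.

## Pipeline and algorithms

`mopir_solve()` runs: aggregate cases into a truth table → assign
output values under thresholds → derive on/off/dc sets → generate
MOPIs → build the covering chart → enumerate all irredundant systems.
Everything is exact and deterministic; there is no randomness anywhere
in the pipeline and hence no seed parameter.

* **Truth table.** One row per observed input configuration with case
  count n and per-output inclusion score
  Inc = (cases showing the output)/n.  A single cut assigns the row
  value 1 iff Inc ≥ `inc_threshold`; rows with n < `n_threshold` and
  all unobserved configurations become don't-cares.  Contradictory
  rows (0 < Inc < 1) fall under the same cut -- there is no separate
  "contradiction" state, which keeps the assignment monotone in the
  threshold.
* **MOPI generation.** Two equivalent routes.  The default `"on-dc"`
  route is a tagged Quine–McCluskey pass: minterms outside at least one
  off-set are seeded with the tag of those outputs, adjacent cubes
  merge with intersected tags, and a cube is checked off only by a
  merge preserving its full tag.  The `"on-off"` route grows cubes from
  on-minterms by literal cancellation and tests candidates directly
  against the off-sets; it is the better choice when off-sets are small
  relative to the dc-sets.  Both finish with an explicit primality and
  usefulness filter and are property-tested to agree bit-exactly, and
  both agree with `brute_force_mopis()`, which enumerates all $3^k$
  cubes and applies the definition literally.
* **Enumeration.** Petrick's method: the chart's product-of-sums is
  expanded to a sum-of-products with absorption (X + XY = X) after
  every distribution step, which provably yields exactly the
  inclusion-minimal covers.  No row- or column-dominance pruning is
  applied -- dominance can delete rows that participate in non-minimum
  irredundant covers, and the solution is defined as all of them.  Only
  duplicate columns are collapsed.
* **Literal-irredundancy filter.** Inclusion-minimal covers do not by
  themselves guarantee condition (iii) above when don't-cares are
  present: a shared-tag MOPI used only where one of its expansions also
  suffices would admit a literal cancellation.  Each cover is therefore
  checked by attempting every one-literal cancellation within the
  written models; covers admitting one are discarded.  On dc-free data
  the filter never triggers.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `inc_threshold` | 0.6 | inclusion score at or above which a truth-table row is assigned 1; in (0, 1] |
| `n_threshold` | 1 | minimum cases per row; rows below it become don't-cares |
| `algorithm` | `"on-dc"` | MOPI generation route (`"on-off"` equivalent) |
| `term_cap` | 10^6 | capacity guard on the Petrick expansion |
| `max_width` | 20 | capacity guard on the number of inputs |
| `cov_threshold` | — | mining only: minimum per-output model coverage; no default on purpose |

The default `inc_threshold` of 0.6 is a conventional consistency cut
for crisp-set configurational work; it is deliberately the smallest
value at which the bundled injury-rate truth table assigns the
contradictory five-case row to its suicide outcome.  Any cut in
(0, 0.6] gives the same table there; the choice is this package's
default, not a claim about other software.  Mining
(`mine_tuples()`) requires both thresholds explicitly because the
"researcher's criteria" are substantive choices that should not be
defaulted silently.

Fit statistics follow the field's definitions: consistency = share of
model-satisfying cases exhibiting the outcome, coverage = share of
outcome-positive cases the model captures; 0/0 is reported as `NA`,
never as 0 or 1.

## Data mining

`mine_tuples()` searches input subsets in ascending size and rebuilds
the whole pipeline per tuple.  A tuple passes when at least one of its
irredundant systems reaches the coverage criterion **for every
output** -- the per-output (conjunctive) reading of the criteria; an
alternative joint reading was rejected because a tuple that explains
one outcome well and another badly is not a usable explanation of the
system.  All passing tuples of the stopping size are reported, since
parsimony concerns tuple size, not identity.  The search relies on the
superset principle: a system using only inputs Y found on a larger
input set X ⊇ Y is found again when solving on exactly Y; this is
property-tested on planted noise-free data, where it holds exactly.

## Logic diagrams

`build_netlist()` converts a system into a two-level netlist: one AND
gate per distinct multi-literal product (shared products fan out to
every OR gate using them when `shared = TRUE`; `shared = FALSE`
instantiates per-output gates for comparison), one OR gate per output
with at least two terms, single literals wired directly, negation drawn
as a dot on the source end of the wire, and inverters deduplicated per
rail.  A universal-cube term is rendered as a constant-1 node.  The
netlist evaluates exactly like the models it was built from (checked
exhaustively in the tests), and exports deterministically to Graphviz
DOT and to a simplified SVG; faithful MIL-STD-806B glyphs are a
cosmetic non-goal.

## The synthetic generator

`simulate_cases()` draws input configurations uniformly with
replacement and sets outputs by evaluating a planted system of
sum-of-products models, flipping each output with probability `noise`.
Defaults (30 cases, 4 inputs, 2 outputs, noise 0) mirror the
small-to-medium case counts typical of configurational studies.  The
generator emulates the data structure the method is defined on --
complete binary observations whose outcomes follow a Boolean mechanism
-- and deliberately not the measurement problems of real data
(calibration of continuous variables, missingness, case weighting,
selection effects).  Passing tests therefore show algorithmic
correctness on the method's own terms, not robustness to measurement
error.

## Numerical and degenerate-input choices

* Cube encoding: two machine integers per cube (care mask + value),
  first input = most significant bit; merge, containment and coverage
  are O(1) bit operations.
* Canonical orders everywhere: MOPIs by (literal count, positional
  string); systems by (size, lexicographic row indices); disjuncts in
  canonical cube order.  Reports are byte-reproducible; chart row
  labels p1, p2, … follow the canonical order and are presentational.
* An output whose on-set is empty gets the empty disjunction as its
  model, with a warning at specification time.
* An output with an empty off-set has the universal cube among its
  implicants; a constant-1 model is legal and renders as `1 <=> f`.
* Missing values and non-binary codes are rejected at the door; the
  method is defined on complete binary data only.
* Capacity guards (`term_cap`, `max_width`, the 10^5 mining tuple cap)
  raise explicit errors that point to mining or threshold changes
  rather than degrading silently.

## Problem sizes used in the test suite

Property tests run the dual-route MOPI generation against the
brute-force oracle on 200 random incompletely specified systems with
up to 8 inputs and 3 outputs, and verify the system enumeration against
exhaustive subset search on every generated chart with at most 15 rows
(about half of them).  These sizes were chosen because exhaustive
oracles remain exact there while covering the regime -- a handful of
inputs -- in which configurational studies operate.

## Known limitations

* One known divergence risk of the writing rule: a shared MOPI tagged
  with an output whose on-set it does not touch is not written into
  that output's model.  No analyzed dataset exercises the case, but it
  is the place where reasonable conventions could differ.
* Worked examples in the literature print the shared patient-group
  conjunction with a positive marital-status literal; the bundled data
  imply the negated one (`i'm'`), and this package always follows the
  data.  Tests assert model shape and the data-implied polarity.
* Exact enumeration is exponential in the worst case; the capacity
  guards make the limits explicit.  Heuristic minimization for very
  large k is out of scope, as are multi-valued (non-binary) inputs,
  fuzzy-set memberships, cost-weighted objective functions and
  probabilistic or sequential circuits.
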