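# mopir

Exact multi-output Boolean minimization for configurational causal
inference in R.

Configurational comparative methods (QCA, CNA and relatives) infer
cause–effect models from case-level binary data, but optimize one
outcome at a time.  When outcomes co-occur — the multi-morbidity
setting, where chronic conditions cluster in the same patients — a
conjunction explaining the *joint* effect may be a prime implicant of
no single outcome, so single-outcome methods cannot find it.  `mopir`
optimizes the whole system of outcome functions jointly, the way
electrical engineers optimize multi-output switching circuits.

Given a system $F = \{f_1(\mathbf{x}), \ldots, f_m(\mathbf{x})\}$ of
incompletely specified Boolean functions (on-set / off-set / dc-set per
outcome), the package computes

* the complete set of **multi-output prime implicants** (MOPIs): products
  of literals that are prime implicants of some $f_j$ or of a product
  $f_{j_1} f_{j_2}\cdots$ of outcome functions, each stored with its
  maximal output tag, via a tagged Quine–McCluskey pass (an equivalent
  on-off route and a brute-force oracle are included);
* **all irredundant systems** — selections of MOPIs from which no MOPI
  and no literal can be cancelled without breaking F-equivalence — by
  Petrick's method with absorption over the MOPI chart;
* truth tables with inclusion (consistency) scores, model consistency
  and coverage, minimal-input-tuple **mining**, and **logic diagrams**
  (two-level gate netlists with shared-gate fan-out, exported to
  Graphviz DOT or SVG).

For a single outcome the result reduces exactly to the classic
irredundant sums over Quine–McCluskey prime implicants.  Everything is
exact and deterministic.

## Worked example

Twelve West European countries, five binary inputs (`gnp` income,
`mys` schooling, `apac` alcohol consumption, `unem` unemployment,
`roca` Roman-Catholic share) and two binary outcomes (`mvta` traffic
mortality, `ssii` suicide mortality); the data ship with the package.

```r
library(mopir)
inj <- read_cases_csv(system.file("extdata", "injury_rates.csv", package = "mopir"),
                      input_names  = c("gnp", "mys", "apac", "unem", "roca"),
                      output_names = c("mvta", "ssii"))
print(aggregate_cases(inj))
#> Truth table: 7 configuration(s) over 5 input(s), 12 case(s)
#>  gnpmysapacunemroca minterm n Inc(mvta) Inc(ssii)
#>               00011       3 1         1       0.0
#>               00101       5 1         1       0.0
#>               00111       7 1         1       0.0
#>               10111      23 1         1       0.0
#>               11000      24 5         0       0.6
#>               11110      30 1         0       1.0
#>               11111      31 2         1       1.0
```

Seven distinct configurations; the five-case row `11000` shows the
suicide outcome in 60 % of its cases (Inc = 0.6) and the traffic
outcome never.  Solving with the default inclusion cut of 0.6:

```r
sol <- mopir_solve(inj, inc_threshold = 0.6)
print(sol)
#> Solution: 4 irredundant system(s), 11 MOPI(s)
#> S*1:
#>   roca <=> mvta
#>   mys <=> ssii
#> S*2:
#>   roca + mys·roca <=> mvta
#>   roca' + mys·roca <=> ssii
#> S*3:
#>   mys' + mys·roca <=> mvta
#>   roca' + mys·roca <=> ssii
#> S*4:
#>   mys' + mys·roca <=> mvta
#>   mys + mys·roca <=> ssii
```

Four irredundant systems explain the data equally well (systems
ambiguity).  S\*1 reproduces what separate single-outcome optimization
finds — independent causes `roca` and `mys`.  The other three reveal
what separate optimization cannot: the shared conjunction `mys·roca`
explaining the *joint* occurrence of both mortality outcomes (it is a
prime implicant of the product `mvta·ssii`, not of either outcome
alone).  Note S\*2 keeps `mys·roca` inside the `mvta` model although
`roca` absorbs it there: it is retained because it is shared.
Per-system fit statistics are attached (`sol$systems[[1]]$fit`); over
the 12 cases, S\*1's `mvta` model has consistency 1.00 and its `ssii`
model 0.75, both with coverage 1.00.

Mining asks for the smallest input sets that support a full-coverage
solution:

```r
mine_tuples(inj, inc_threshold = 0.6, cov_threshold = 1.0)
#> Tuple mining: 15 tuple(s) tested, 7 passing
#> ... no singleton passes; (mys, roca) is among the passing pairs
```

A logic diagram of any system:

```r
n <- build_netlist(sol$systems[[2]], shared = TRUE)
count_gates(n)
#> and  or inv
#>   1   2   1
writeLines(netlist_to_dot(n), "system2.dot")
```

A thin command-line front end with subcommands `truthtable`, `solve`,
`mine` and `draw` is installed under `exec/` (see
`system.file("exec", "mopir", package = "mopir")`).

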