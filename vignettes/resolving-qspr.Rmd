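---
title: "Resolving topological indices and QSPR models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving topological indices and QSPR models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(resolvti)
```

## The model

A hydrogen-suppressed molecular graph represents a molecule's heavy atoms as
vertices and its bonds as edges, with bond multiplicity collapsed: a double or
aromatic bond contributes a single edge. On such a simple connected graph,
a vertex subset $S = \{v_1, \dots, v_k\}$ *resolves* the graph when every
vertex $x$ has a distinct vector of shortest-path distances
$r(x \mid S) = (d(x, v_1), \dots, d(x, v_k))$. A minimum-cardinality
resolving set is a *metric basis*, and its size is the *metric dimension*
$\beta(G)$.

The *resolving degree* $d_\beta(v)$ of a vertex is the minimum size of a
resolving set containing $v$. It is two-valued: $d_\beta(v) = \beta(G)$ when
$v$ lies in some metric basis, and $\beta(G) + 1$ otherwise, because
appending $v$ to any basis still resolves the graph. Five degree-based
indices summarise this structure:

* $\mathrm{FRZI}_1 = \sum_v d_\beta(v)^2$ and
  $\mathrm{FRZI}_2 = \sum_{uv \in E} (d_\beta(u) + d_\beta(v))$ — the first
  resolving Zagreb indices,
* $\mathrm{SRZI} = \sum_{uv \in E} d_\beta(u)\, d_\beta(v)$ — the second
  resolving Zagreb index,
* $\mathrm{RHM} = \sum_{uv \in E} (d_\beta(u) + d_\beta(v))^2$ — the
  resolving hyper-Zagreb index,
* $\mathrm{RF} = \sum_{uv \in E} (d_\beta(u)^2 + d_\beta(v)^2)$ — the
  resolving forgotten index.

Because the degrees take only the two values $\beta$ and $\beta + 1$, all
five indices are determined by the invariant tuple
$(\beta, \eta, \xi_1, \xi_2, |V|, |E|)$, where $\eta$ counts vertices at
degree $\beta$, $\xi_1$ counts edges with mixed endpoint degrees and $\xi_2$
counts edges with both endpoints at $\beta + 1$. The package implements both
routes — direct summation (`indices_direct()`) and the closed forms
(`indices_closed()`) — and `index_table()` refuses to emit a row unless the
two agree. The expansion $(a+b)^2 = a^2 + b^2 + 2ab$ summed over edges gives
the identity $\mathrm{RHM} = \mathrm{RF} + 2\,\mathrm{SRZI}$, which is
asserted on every index record the package constructs.

## Exact search

`minimum_resolving_sets()` enumerates vertex subsets in increasing size
$k = 1, 2, \dots$, lexicographically within each size, and stops at the
first size containing a resolving subset; it then keeps *all* resolving
subsets of that size, because the resolving degrees (hence $\eta$) depend on
basis membership across the whole collection. Representation vectors are
compared through exact integer encodings (each vector is folded into a
single integer in base $n + 1$; distances are below $n$, so the encoding is
injective and exact in double precision for every graph size the solver
accepts). No floating point enters the combinatorial layer.

Two vertices that are equidistant from every other vertex (*twins* — e.g.
the two carbons of an aziridine ring) can never be separated by a subset
omitting both, so every basis must hit every twin pair. The solver uses this
as an optional pruning filter (`prune_twins = TRUE`, the default); the test
suite verifies that pruned and unpruned searches return identical results.
The largest packaged searches — $\binom{22}{5} \approx 2.6 \times 10^4$
subsets for anastrozole and $\binom{32}{4} \approx 3.6 \times 10^4$ for
ribociclib — complete in about a second together with the other eight drugs.

Single-vertex graphs are rejected rather than assigned $\beta = 0$: the
definitions above are only meaningful with at least two vertices, and the
edge-list constructor already requires at least one edge.

## The packaged study

`load_all_drugs()` ships ten breast-cancer drugs (toremifene, tucatinib,
ribociclib, olaparib, abemaciclib, anastrozole, letrozole, thiotepa,
tamoxifen, megestrol acetate) as plain-text edge lists, together with their
published invariant and index tables and a table of five physicochemical
properties: molar volume (MV, cm³), polarizability (P, cm³), molar
refractivity (MR, cm³), polar surface area (PSA, Å²) and surface tension
(ST, dyne/cm).

The source publication shows the molecular graphs only as drawings, so the
edge lists here are transcriptions of the drugs' standard hydrogen-suppressed
structures. Every fixture matches the published vertex and edge counts
exactly. For nine of the ten drugs the exhaustive solver also reproduces the
published $(\beta, \eta, \xi_1, \xi_2)$ exactly. The exception is olaparib:
the standard structure (32 heavy atoms, 36 bonds, matching the published
counts) yields $(4, 13, 14, 16)$ where the published table prints
$(3, 8, 10, 23)$. Since no machine-readable structure accompanies the
publication, the disagreement cannot be arbitrated from the available data;
it is recorded in the packaged `known_discrepancies.csv`, surfaced by
`reproduce_report()` as a documented discrepancy, and deliberately not
patched. The closed-form algebra from the published invariant row to the
published index row is checked for all ten drugs regardless, because it is
independent of any transcription.

## Regression layer

`fit_polynomial()` fits a property on the raw powers $x, x^2, x^3$ of one
index by ordinary least squares through `stats::lm`, which solves via a QR
decomposition — relevant because cubic powers of indices near 600 reach
$2 \times 10^8$ and normal equations would be needlessly ill-conditioned.
Coefficients are reported on the raw scale so they are directly comparable
to published model equations. Conventions:

* $R$ is the non-negative $\sqrt{R^2}$ for every model. An inverse
  relationship shows in the coefficient sign, not in $R$.
* The residual standard error uses denominator $n - p$ with $p$ the number
  of fitted parameters (so $n - 2$ for the linear model on $n = 10$ drugs).
* The overall test is the $F$ statistic with $(\text{degree},
  n - \text{degree} - 1)$ degrees of freedom; per-coefficient tests in the
  MLR are two-sided $t$ tests with $n - 3$ degrees of freedom.
* With two predictors both variance inflation factors coincide:
  $\mathrm{VIF} = 1 / (1 - r_{12}^2)$ with $r_{12}$ the predictor
  correlation (`vif_pair()`).

`best_fit_report()` reports, per property, the single best index at each
polynomial degree plus one fixed two-index MLR model per property
(MV, MR, ST on FRZI1 + FRZI2; P on FRZI2 + RHM; PSA on FRZI2 + SRZI). The
predictor pairs are fixed rather than selected: the reproduction targets a
specific published model set whose selection procedure was not described,
and a generic `fit_mlr()` is exported for any other pair. Equation strings
are rounded to a configurable precision (default 3 decimals, the dominant
precision of the published tables); all statistics are kept at full double
precision in the returned objects.

With ten observations these fits characterise association, not predictive
performance; no cross-validation or variable selection is attempted, and the
PSA models in particular are statistically insignificant and are reported
as-is.

## Synthetic data

`random_connected_graph()` generates molecular-like test graphs: a uniformly
random labelled spanning tree (Prüfer sequence, rejection-sampled to respect
the degree cap), then uniformly random admissible non-edges until the
requested edge count. The default degree cap of 4 mimics organic skeletons
(carbon valence). The generator emulates size, sparsity and degree structure
only — it makes no attempt at chemically valid rings, heteroatom placement or
realistic ring statistics, so tests passing on generated graphs demonstrate
combinatorial correctness, not chemical realism. `synthesize_property()`
draws property vectors as a polynomial in an index plus Gaussian noise,
mirroring the statistical model the regression layer assumes. Both are
deterministic given a single integer seed and restore the caller's RNG
state.

The test suite uses these generators at sizes $n \le 12$ with exhaustive
solving (200 graphs for the structural properties; 200 replicates at
$n = 30$ observations for unbiased slope recovery) — small enough to run the
whole suite in well under a minute while still exercising every invariant:
two-valued degrees, direct-versus-closed index agreement, the RHM identity,
twin-pair coverage of every basis, and agreement of the subset test with a
naive pairwise oracle.

## Numerical and degenerate-input choices

* Distance matrices are integer hop counts from breadth-first search
  (`igraph::distances`); a Floyd–Warshall oracle double-checks them in the
  tests.
* Disconnected input is a hard error naming the components; metric
  dimension as used here is defined only for connected graphs.
* Duplicate edges and self-loops are format errors, not silently collapsed:
  the edge-list files are declarations of the collapsed simple graph.
* A constant predictor, a perfectly collinear MLR pair and a zero-variance
  property are all rejected or flagged explicitly rather than producing
  `NaN` statistics.
* Ties in "best index per degree" resolve to the first index in the fixed
  column order (FRZI1, FRZI2, SRZI, RHM, RF); with the packaged data no tie
  occurs.

## Known limitations

* Edge lists are the only input format; there is deliberately no
  SMILES/InChI/SDF parser, stereochemistry, charge or 3D information.
* The exhaustive solver is exponential in $\beta$; it is intended for the
  drug-sized graphs packaged here (up to ~40 vertices with small $\beta$),
  not for large networks.
* The regression layer reproduces a ten-observation study; its statistics
  carry the corresponding caveats, and the package makes no claims beyond
  association on this dataset.
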