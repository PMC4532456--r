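---
title: "Exact dynamics of graph dynamical systems: models, conventions and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact dynamics of graph dynamical systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(graphdyn)
```

# The model

A graph dynamical system couples four ingredients:

* a **dependency graph** `X` on vertices `1..n`, where a directed edge
  `(u, v)` means the state of `u` is an input to `v`'s function; an
  undirected edge is shorthand for both directions. A self-loop makes
  `v`'s 1-neighborhood *closed*: `v` reads its own state through its
  inputs. Nothing is ever implicit — the closed-neighborhood convention
  used by threshold-type functions is realized by actually adding
  self-loops (templates take `self_loops = TRUE`).
* a **state set** `K = {0, ..., r-1}`, uniform across vertices
  (`r = 2` for Boolean systems).
* one **vertex function** per vertex, consuming the *restricted state*
  `x[v]`: the states of `v`'s in-neighbors listed in ascending vertex
  order. Bithreshold and multi-threshold functions additionally branch
  on `v`'s own state, which is passed explicitly so that the families
  remain well defined on open neighborhoods.
* an **update scheme**, normalized internally to a *block word*: an
  ordered sequence of non-empty vertex blocks. Within a block, all
  functions read the same pre-block state and fire simultaneously;
  blocks compose left to right. Synchronous update is the single
  all-vertex block; a sequential permutation is a word of singletons;
  block-sequential is the general fair case; unfair words may repeat or
  omit vertices.

**One time step is one full pass of the block word**, for unfair words
too. Periods, transients and basins are always defined with respect to
this composite map. This is a genuine choice for unfair words — one
could instead count each block firing as a step — but the composite-map
convention keeps the phase space a functional digraph on `r^n` states
for every scheme, and it is the convention under which the classical
reductions hold exactly (singleton blocks ≡ sequential; one block ≡
synchronous), which the test suite verifies pointwise.

# Vertex function families

All thresholds are integers (counts or sums of states); edge weights are
unitless reals.

* **nor**: next state 1 iff every input is 0. On closed neighborhoods a
  nor system can have no fixed point: a vertex at 1 sees itself and must
  fall, a stable all-zero neighborhood must rise. The suite checks this
  on random closed-nor systems.
* **threshold** `k`: 1 iff `sigma_v >= k`, where `sigma_v` counts the 1s
  among the inputs. `k = 0` pins the vertex at 1; `k = d_in + 1` pins it
  at 0.
* **bithreshold** `(k01, k10)`: from state 0, rise iff
  `sigma_v >= k01`; from state 1, fall iff `sigma_v < k10`. With
  `k01 = k10` this is exactly the threshold function (verified
  exhaustively over all inputs for small arities). The effective ranges
  are `k01` in `[0, d_in + 1]` and `k10` in `[1, d_in + 2]`, but any
  natural `k01` is accepted: a value like `n` pins a whole class of
  vertices at 0 without inspecting degrees. `k10 = 1` means "never
  fall", because in a closed neighborhood a vertex at 1 always counts
  itself.
* **multi-threshold** (`r`-state): each ordered pair `(i, j)` of states
  carries a threshold `k_ij` on the sum `s` of neighborhood states.
  From state `i`, an up-move to `j > i` is enabled iff `s >= k_ij`, a
  down-move to `j < i` iff `s < k_ij`. Two conventions had to be fixed
  where the family is otherwise underdetermined:
  1. the sum `s` runs over the in-neighborhood as given, so it includes
     the vertex itself exactly when a self-loop is present — the same
     rule the Boolean families use;
  2. when several targets are enabled, the **farthest enabled target
     wins**, with up-moves examined before down-moves. For monotone
     threshold vectors up- and down-enablement cannot overlap, so the
     precedence only matters for pathological parameter choices; fixing
     it keeps every transition deterministic.
  Both conventions are validated computationally: with them, the
  three-state circle systems below reproduce the known
  fixed-point/bifurcation dichotomy exactly, and with `r = 2` the family
  collapses onto the bithreshold function input-for-input.
* **linear threshold** `k_v` with edge weights `w_uv`: next state 1 iff
  `sum_u w_uv x_u - k_v > 0`. The inequality is strict — a weighted sum
  exactly at threshold yields 0 — and negative weights inhibit. This is
  the standard threshold-automaton model for gene regulatory networks.
* **truth table**: an explicit output vector indexed by the mixed-radix
  code of the restricted state; the escape hatch for functions outside
  the named families.

# State encoding and canonical order

States `(x_1, ..., x_n)` are numbered by the mixed-radix code
`sum_v x_v * r^(n - v)` with `x_1` most significant, so tuples sort
lexicographically by code and printed output is stable. Codes live in
`[0, r^n)` and are exact doubles well past the enumeration cap
(`2^24 < 2^53`). Vertices are 1-based everywhere, matching both the
`(x_1, ..., x_n)` notation and R's indexing; only state codes are
0-based.

Attractors are canonicalized by rotating each cycle to start at its
minimum state code and ordering attractors by that code — diffable
output regardless of traversal order.

# Phase-space derivation

`enumerate_phase_space()` computes all `r^n` successors in one
vectorized pass (per block, per vertex, a column operation over the
whole state matrix), then derives structure in `O(r^n)`:

1. cycle detection by walk-marking: follow successors from each unseen
   state, stamping walk positions; re-entering the current walk closes a
   new cycle, hitting settled territory ends it;
2. transients and basins by a reverse breadth-first search from the
   periodic states over predecessor lists, so `transient(x)` is the
   exact distance to the first periodic state and every state inherits
   its basin label from its successor.

The enumeration cap defaults to `2^24` states; above it the package
refuses and points to `forward_trajectory()`, which iterates a single
orbit with a hash of visited states and splits it into transient prefix
and cycle. The suite cross-checks the two paths state by state on small
systems, and additionally checks the whole vectorized engine against an
independent scalar evaluator built only from the public single-vertex
functions.

Fixed points satisfy a purely local condition (`x_v = f_v(x[v])` for
all `v`), so they are identical for every fair scheme on the same graph
and functions — a property the suite exercises across random
permutations. The same locality justifies
`count_fixed_points_factorized()`: when the underlying undirected
influence graph is disconnected, the fixed-point count is the product of
per-component counts, letting systems far beyond the cap be counted
exactly (e.g. nine disjoint closed 6-cliques under bithreshold `(5,5)`:
`2^9 = 512`, each clique contributing exactly its all-0 and all-1
states).

# Equivalence and stability

*Functional equivalence* is equality of maps, decided by comparing the
two image matrices over all states. *Cycle equivalence* is implemented
as equality of cycle-length multisets: for functional digraphs,
isomorphism of periodic structure reduces to matching cycle lengths, so
nothing finer is needed. Functional equivalence implies cycle
equivalence; the converse fails (the tests never assert it).

The **attractor graph** has one node per attractor and an edge
`(A_i, A_j)` when some cycle state of `A_i`, with one coordinate changed
to any other symbol, lands in `A_j`'s basin. For `r > 2` every
alternative symbol is tried, the natural generalization of the Boolean
flip. Each edge retains one witness perturbation, and self-edges are
recorded but cannot affect the component structure. **Ergodic sets** are
the strongly connected components of this graph (computed with igraph);
because usage varies on whether only *recurrent* classes deserve the
name, every component is reported together with a `closed` flag (no
out-edges to other components), and callers can filter to closed
components if they adopt the stricter reading.

# Three-state fixed-point conditions and the bifurcation

For sequential multi-threshold systems with `r = 3`, four inequalities
on the six thresholds guarantee that all limit sets are fixed points
(`check_fixed_point_conditions()`; see its help page for the
inequalities). The free constants default to `C1 = -2`, `C2 = -6`,
the values that maximize the right-hand sides of the first two
conditions — both then read `Delta <= 1` — giving the widest threshold
ranges per condition. Callers may supply other constants; tightening one
side loosens another.

The conditions are sharp in a computationally visible way.
`sweep_max_cycle()` over circles with thresholds
`(k01, k10, k12, k21, k02, k20) = (2, 3, 6, 6, 4, 5)` (which satisfy all
four conditions) finds only fixed points at every size, while dropping
`k01` to 1 — violating condition (i) minimally, `Delta01 = 2` — makes
the maximum cycle length jump to `n - 1` at every size: a bifurcation
from the smallest possible limit sets to ones growing without bound.
The suite and the acceptance script verify this at `n = 4..9`
(up to `3^9 = 19683` states), the sizes at which exhaustive enumeration
stays comfortably inside a test-suite budget; the `n - 1` law itself is
size-independent, so small `n` exercise it fully.

# The random-instance generator

Property tests run over seeded random systems
(`random_gds_instance()`). The generator emulates the regime the
worked examples live in: small dense undirected influence graphs
(Erdős–Rényi pairs at `p = 0.5` plus a path spine so instances are
connected), closed neighborhoods by default, per-vertex parameters drawn
uniformly from each family's valid range (`k01` in `[0, d_in + 1]`,
`k10` in `[1, d_in + 2]`, optionally constrained to
`k10 - k01 <= delta_max`; unit ± weights for linear threshold), and a
fair scheme drawn among synchronous, random permutation and random block
partition. Identical seeds give identical instances, and the caller's
RNG stream is left untouched.

What it deliberately does *not* emulate: heavy-tailed degree
distributions, sparse modular topology, correlated or multi-level
weights, unfair words. Passing property tests therefore demonstrate the
structural laws (functional-digraph invariants, scheme reductions,
fixed-point invariance, bithreshold cycle bounds) on small dense
instances — they are evidence about the engine's correctness, not about
how any particular biological network behaves.

Default problem sizes in the tests: Boolean sweeps at `n = 4..6`
(16–64 states, dozens of seeds), three-state systems to `3^9` states,
factorized counts cross-checked against brute force at `<= 2^12`
states. These sizes were chosen so each law is exercised exhaustively
rather than by sampling.

# Degenerate inputs and edge cases

* Empty blocks, non-permutation sequential orders, and fair schemes that
  miss or repeat a vertex are constructor errors; unfair words are legal
  only through `scheme_word()`.
* A vertex with no in-edges has an empty restricted state: `nor`
  returns 1 (empty product), `threshold` compares `0 >= k`, a truth
  table needs exactly one entry.
* Ties cannot arise in multi-threshold transitions (targets are
  examined farthest-first and the first enabled one is taken).
* `r = 1` is rejected everywhere: a one-symbol system has no dynamics.
* Enumeration refuses politely above the cap rather than exhausting
  memory; the cap is a parameter, not a constant.

# Known limitations

* Everything rests on exhaustive enumeration, so `r^n` is the hard
  currency; beyond the cap only trajectory mode and factorized
  fixed-point counting apply. No symbolic or BDD-based attractor
  detection is attempted.
* Update schemes are deterministic words; stochastic function selection
  (probabilistic Boolean networks) and single-random-vertex asynchronous
  update are out of scope.
* The 12-vertex weighted network shipped under `inst/extdata/` is
  **synthetic** — constructed to exercise the linear-threshold code path
  end to end — and is not a published biological network; conclusions
  about real regulatory systems require transcribing the real weighted
  network into the edge-list format.
* Cycle equivalence compares systems with equal `n` and `r` only; the
  broader notion across different state spaces is not implemented.
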