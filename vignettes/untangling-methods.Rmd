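---
title: "Untangling tanglegrams: model, metrics and search heuristics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untangling tanglegrams: model, metrics and search heuristics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(untangler)
```

## The problem

A tanglegram draws two dendrograms over the same $n$ labelled leaves face to
face and joins matching leaves by straight inter-tree edges. The two trees
typically come from two hierarchical clusterings (or two phylogenetic
reconstructions) of the same objects, and the reader compares them by
following the inter-tree edges. Every internal vertex of a dendrogram can be
rotated — its two children exchanged — without changing what the clustering
says, so each tree admits $2^{n-1}$ drawable leaf orders. Choosing the
rotation pattern that minimizes the number of edge crossings is the
tanglegram layout problem (two-tree crossing minimization), which is
NP-complete; this package implements a greedy baseline and three stronger
local-search heuristics for it, plus an exhaustive oracle to audit them on
small instances.

## Data model

A dendrogram is stored as its *linkage matrix* $Z$: an $(n-1)\times 4$ table
whose row $t$ merges the two nodes in columns 1–2 into internal node $n+t$,
with the merge height in column 3 and the merged leaf count in column 4.
Leaves are `1..n`, the root is $2n-1$. Heights are carried through I/O
untouched but ignored by every algorithm — only topology and child order
matter. A tanglegram is an ordered pair $L = [Z_l, Z_r]$ over the same leaf
set.

The drawn leaf order $V$ is obtained by depth-first traversal from the root,
visiting each row's column-1 child before its column-2 child. The
convention (which child is drawn first) is not forced by the model; any
fixed choice gives the same algorithms up to a global mirror image, and
`untangler` fixes this one so that results are reproducible. The elementary
move is $\Omega_i(Z)$: exchange the two children of internal vertex $i$
(`swap_omega()`); it is an involution and exchanges the two child blocks of
that vertex inside the leaf order, leaving everything else in place.

## Displacement, entanglement, crossings

Identify the leaf at position $k$ of the left order with its position
$\pi(k)$ in the right order. The displacement of the layout is the $p$-norm
$\left(\sum_k |k - \pi(k)|^p\right)^{1/p}$, and its entanglement is the
displacement relative to the worst layout possible at that size — the one
whose right order is the exact reverse of the left:

$$
\varepsilon(L) \;=\; \frac{\sum_k |k-\pi(k)|^p}
                          {\sum_k |k-(n+1-k)|^p} \in [0,1],
$$

with $\varepsilon = 0$ exactly for crossing-free drawings and
$\varepsilon = 1$ for the reversed order. All shipped defaults use $p = 2$.
Two normalizations are offered: the default `power-ratio` divides the sums
of $p$-th powers (compatible with the entanglement of the dendextend R
package, from which the measure is inherited), while `norm-ratio` takes the
$1/p$-th root of both sums first. They are linked by a strictly monotone
transform, so they agree at the endpoints and rank layouts identically —
the choice changes reported values, never algorithm behaviour.

The crossing count equals the number of inversions of $\pi$ and is computed
by merge counting in $O(n\log n)$; the test suite checks it against a
quadratic pair count on randomized batches. Entanglement is the cheaper
quantity and is what all searches minimize.

## The search heuristics

All four methods use the selector $\xi$, the argmin of $\varepsilon$ over a
candidate list with ties broken by earliest position — so every run is
deterministic given its input.

**step2side** (baseline). Scan $i = 1..n-1$ on the right tree, accepting any
$\Omega_i$ that strictly lowers $\varepsilon$; do the same on the left tree;
repeat until a full pass accepts nothing. We read the per-vertex
conditional replacement as *first improvement* within a fixed ascending
scan (not best improvement), and complete each pass before rescanning;
other implementations may differ on tie-adjacent choices. The result is
locally optimal under single one-sided rotations, but the method never
rotates both trees at once and therefore stalls on instances — including
three-leaf ones, see `tanglegram_fixtures()$step2side_trap` — where only a
coordinated pair of rotations helps.

**stepBothSides.** Run step2side to convergence, then scan all pairs
$(i, j) \in [1, n-1]^2$ and replace the incumbent by
$[\Omega_i(Z_l), \Omega_j(Z_r)]$ whenever that strictly improves it (first
improvement, scan continuing against the updated incumbent; the outer
repeat-until-no-reduction loop restores completeness). The pair scan costs
$O(n^2)$ evaluations per round but escapes the one-sided local optima.
Rotating four or more branches simultaneously would generalize this
further at $O(n^4)$ cost and is deliberately not implemented.

**shufS2S.** A shuffled-restart scheme. With
$\mathcal{L}_{ini}(0) = \{L_0\}$, generation $m$ applies the four-layout
shuffle $\mu_{n-m}$ (rotate vertex $n-m$ on the left, on the right, both,
or neither — `shuffle_quad()`) to every member of the *unoptimized*
previous generation, giving up to $4^m$ layouts: the root first, then
step-wise toward the leaves. Each layout is optimized by step2side; the
generation's best is compared with the best seen so far, and the search
stops at zero entanglement, when a deeper shuffle brings no improvement,
or at the optional depth cutoff $\bar m$.

**ShUnTan.** The same shuffle schedule, with the per-layout optimizer
replaced by a two-stage untangler: a *symmetric sweep* applying
$L \leftarrow \xi(\mu_i(L))$ for $i = 1..n-m-1$ (same vertex on both
sides, leaves toward the root, iterated to a fixed point) followed by an
*asymmetric pass* that, for every leaf $k$, applies $\xi$ over the quad at
the generally different rows $\tau(k, Z_l), \tau(k, Z_r)$ holding $k$ on
the two sides, iterated until a full scan changes nothing. The asymmetric
move reaches layouts the symmetric sweep cannot;
`tanglegram_fixtures()$asym_gain` is a searched instance where it strictly
improves a symmetric fixed point.

## Parameters that matter

* `p` (norm order, default 2): the exponent of the displacement norm.
  Dimensionless; all reference results use 2.
* `mode` (default `power-ratio`): reporting scale only, see above.
* `tol` (default `1e-12`, entanglement units on the power-ratio scale):
  "strictly lower" means lower by more than `tol`. This guarantees
  termination — each accepted move decreases a bounded quantity by a fixed
  amount — and prevents oscillation caused by floating-point rounding. It
  is applied on the power-ratio scale in both modes, which leaves the
  accepted-move sequence identical across modes.
* `m_cutoff` ($\bar m$, default $n-1$, i.e. no cutoff): caps the shuffle
  depth and thereby the $4^m$ growth of the candidate sets. In practice
  the no-improvement rule stops the search much earlier — on the clustered
  instances used in the checks below, converged depths are typically 2–3
  even at $n = 100$ — so the cutoff is a cost guard, not a tuning knob.
  "Target layout" termination means $\varepsilon = 0$, at which point no
  deeper shuffle can help.

Duplicate layouts inside a candidate set are pruned by ordered-matrix
equality before optimization. This is purely a speed-up: the selector is
an argmin, so removing copies cannot change the generation's best.

## The synthetic generator and the oracle

`generate_tanglegram()` emulates the comparison protocol used to study
these methods: draw $n$ points from a standard normal in `n_features`
dimensions (default 5 — the protocol's source data has a handful of
informative dimensions, and the choice is documented as arbitrary) and pair
the single-linkage dendrogram with the complete-linkage dendrogram of the
same points, via `stats::hclust()`. The two trees then share large-scale
structure but disagree in detail, which is what makes untangling
non-trivial. A `random-topology` mode builds two independent uniformly
random merge sequences instead; since the methods only ever see topology,
this is an equally valid and faster source of test instances. What the
generator does *not* emulate: real data with cluster structure, ties in
distances, or correlated features — so passing tests demonstrate correct
search behaviour on typical random topologies, not performance claims
about any particular empirical dataset.

`brute_force_optimum()` enumerates all $2^{n-1} \times 2^{n-1}$ layouts
(refused above 10 leaves by default) and returns the global minimum
entanglement and minimum crossing count, with ties resolved by the first
configuration in lexicographic mask order. The test suite verifies it
against a second, independent enumeration (recursively generated leaf
orders, metrics recomputed in plain R) on $n \le 5$, then uses it as the
lower bound every heuristic must respect.

## Numerical and degenerate-input choices

* Zero-entanglement inputs return immediately and unchanged: no move can
  improve 0, and the shuffled searches short-circuit before building sets.
* Endpoints are exact in floating point: the reversed layout's numerator
  and denominator are the same sum term-for-term, so
  $\varepsilon_{\mathrm{rev}} = 1$ identically, and identical orders give
  exactly 0.
* $n = 2$ is the smallest supported size (one merge row); multifurcating
  trees are outside the model and rejected at the Newick boundary.
* Heights may be non-monotone (as in the four-leaf toy example shipped in
  `tanglegram_fixtures()$eq1`); Newick export then falls back to unit
  branch lengths with a warning, since branch lengths are the only place
  heights surface at all.
* On-disk linkage tables default to the one-based numbering above; the
  zero-based dialect of scientific-Python linkage output (leaves `0..n-1`,
  internals `n..2n-2`) is converted on read/write by a uniform $\pm 1$ on
  the child columns.

## Scale of the shipped checks

The package's acceptance checks run the drawability boundary exhaustively
($n = 2..5$; every tree pair, every layout), oracle dominance on 100
clustered instances at $n = 6$, the method ordering on 40 clustered
instances at $n = 20$, and the converged-depth report on 20 instances at
$n = 100$ — sizes chosen so the whole suite completes on a laptop in well
under a minute while still exercising every code path at the sizes where
exhaustive ground truth (for the first two) is available.

## Known limitations

* All methods are local searches: none guarantees the global optimum, and
  the oracle-dominance tests measure attainment rates rather than assert
  optimality.
* Strictly binary trees only; generalized (multi-edge, weighted)
  tanglegrams are out of scope.
* The shuffled searches grow candidate sets as $4^m$; adversarial
  instances that keep improving at large $m$ will be slow unless capped
  with `m_cutoff`.
* Automatic, data-driven selection of the shuffle depth is not attempted.
* No graphical rendering of tanglegrams is provided; the package's outputs
  are layouts, metrics and benchmark tables.
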