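# untangler

Crossing minimization for tanglegrams of paired dendrograms.

A *tanglegram* draws two dendrograms over the same `n` labelled leaves face
to face, joining matching leaves by straight inter-tree edges — the standard
way to compare two hierarchical clusterings (or two phylogenies) of the same
objects. Every internal vertex of either tree can be rotated (its children
exchanged) without changing the clustering, so each tree admits `2^(n-1)`
drawable leaf orders; choosing rotations that minimize edge crossings is the
two-tree crossing minimization problem, which is NP-complete. This package
is for anyone who needs readable tanglegrams or a testbed for layout
heuristics: it provides the linkage-matrix data model, the metrics, four
untangling algorithms, an exhaustive oracle, a seeded generator, file I/O
and a CLI.

## The quantity being minimized

Writing `pi(k)` for the right-side position of the leaf drawn at left-side
position `k`, the **entanglement** of a layout `L = [Z_l, Z_r]` with norm
order `p` (default 2) is its displacement relative to the worst layout of
that size (the exactly reversed order):

    eps(L) = sum_k |k - pi(k)|^p  /  sum_k |k - (n+1-k)|^p   in [0, 1]

`eps = 0` iff the drawing has no crossings; `eps = 1` for the reversed
order. The crossing count itself is the number of inversions of `pi`,
computed in `O(n log n)`.

Four minimizers are provided, all deterministic:

| method | move set | cost/round |
|---|---|---|
| `step2side()` | single rotations, one tree at a time (greedy baseline) | `O(n)` |
| `step_both_sides()` | adds all simultaneous rotation pairs `(i, j)` | `O(n^2)` |
| `shuf_s2s()` | shuffled restarts (root-down, `4^m` layouts), each optimized by step2side | adaptive in `m` |
| `shuntan()` | same restarts, optimized by a symmetric leaf-to-root sweep plus a per-leaf asymmetric pass | adaptive in `m` |

The baseline stalls in one-sided local optima — there are three-leaf
instances it cannot untangle although a zero-crossing layout exists
(`tanglegram_fixtures()$step2side_trap`); the other three escape them by
rotating both trees at once. See `vignette("untangling-methods")` for the
full account.

## Worked example

```r
library(untangler)
L <- generate_tanglegram(20, mode = "clustered", seed = 7)
print(L)
#> Tanglegram: 20 leaves
#>   left order : 11 20 4 9 12 13 15 1 10 17 14 18 6 2 3 5 7 8 16 19
#>   right order: 20 4 9 17 6 2 3 5 1 10 12 13 15 11 18 16 19 14 7 8
#>   entanglement (p = 2): 0.247368   crossings: 59

for (m in c("step2side", "stepbothsides", "shufs2s", "shuntan"))
  print(untangle(L, m))
#> step2side: entanglement 0.0315789, crossings 11 (114 evaluations, 3 passes)
#> stepBothSides: entanglement 0.0157895, crossings 8 (874 evaluations, 4 passes)
#> shufS2S: entanglement 0.0157895, crossings 8 (2280 evaluations, m reached 2)
#> ShUnTan: entanglement 0.0157895, crossings 8 (5346 evaluations, m reached 2)
```

The generated pair (single- vs complete-linkage trees of the same 20
random points) starts at entanglement 0.247 with 59 crossings. The greedy
baseline gets to 0.032, and all three coordinated methods reach 0.016 —
here the best layout any of them finds — at increasing evaluation cost;
the two shuffled searches converged at depth `m = 2`. Averaged over many
instances the ordering is the same (`benchmark_untanglers(20, reps = 40)`
gives mean entanglements 0.052 / 0.035 / 0.026 / 0.019 for step2side /
stepBothSides / shufS2S / ShUnTan).

On small instances the result can be audited exactly:

```r
opt <- brute_force_optimum(generate_tanglegram(8, seed = 1))
opt$min_crossings      # global optimum over all 2^7 x 2^7 layouts
```

## Command line

```sh
inst/cli/untangler simulate  --n 20 --seed 7 --out-left l.linkage --out-right r.linkage
inst/cli/untangler entangle  --left l.linkage --right r.linkage
inst/cli/untangler untangle  --left l.linkage --right r.linkage --method shuntan --trace trace.json
inst/cli/untangler oracle    --left l.linkage --right r.linkage
inst/cli/untangler benchmark --n 20,40 --reps 10 --out-csv bench.csv
```

Linkage files are 4-column tables (child, child, height, size), whitespace-
or comma-separated, in one-based or (`--dialect zero-based`) the
scientific-Python zero-based numbering; Newick import/export preserving
child order is available via `to_newick()` / `from_newick()`.

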