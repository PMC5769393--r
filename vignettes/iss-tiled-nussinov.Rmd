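---
title: "Iteration-space-sliced tiling of the Nussinov fill: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iteration-space-sliced tiling of the Nussinov fill: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nusstile)
```

## The model

Nussinov's dynamic program scores an RNA strand \(x_1 \dots x_N\) by the
maximum number of complementary base pairs, a classical proxy for free
energy. With \(\sigma(i,j) = 1\) when \((x_i, x_j)\) is an allowed pair and
\(i < j - 1\) (at least one unpaired base between the partners), the upper
triangle of the \(N \times N\) matrix \(S\) is filled by

\[
S(i,j) = \max\Big( S(i+1,j-1) + \sigma(i,j),\;
\max_{i \le k < j} S(i,k) + S(k+1,j) \Big),
\]

and \(S(0, N-1)\) is the optimal pair count. The triple loop realizing
this recurrence has two statements: `s1`, one split evaluation per `k`,
and `s2`, the diagonal update that closes cell `(i, j)`. The interesting
part of the package is not the recurrence — it is *how* the loop nest is
scheduled: the same fill is executed serially (`fill_reference()`),
diagonal-by-diagonal with a barrier (`chang_fill()`), diagonal-by-diagonal
with a transposed lower triangle so both split operands are read along
rows (`li_fill()`), and tile-by-tile under an iteration-space-sliced (ISS)
wavefront schedule (`tiled_fill()`). All four must agree bit-exactly; the
test suite holds them to that.

What "allowed pair" means is deliberately configurable. The default
`pairing_rule()` is Watson–Crick (A-U, G-C) plus the G-U wobble, the usual
choice for maximum-matching folding; `wobble = FALSE` gives strict
Watson–Crick. The minimum separation is fixed at \(j - i \ge 2\), which is
what \(i < j - 1\) encodes; we validate rather than parameterize it,
because the dependence analysis below is derived for exactly this domain.

Indices are 0-based internally, matching the loop nest; everything
user-facing (structure reports, pair lists) is 1-based.

## Instances, dependences, and an exact closure

`enumerate_instances(N)` lists every statement execution in serial order:
`i` descending, `j` ascending, `s1` with `k` ascending, then `s2`. Each
instance's position in the list is its timestamp. Dependences are derived
from the access pattern per memory cell: an instance of cell `(i, j)`
reads and rewrites its own cell; `s1(i,j,k)` also reads the prefix cell
`(i, i+k)` and the suffix cell `(i+k+1, j)`; `s2(i,j)` reads
`(i+1, j-1)`. Consecutive conflicting accesses (at least one a write)
yield the direct edges: the read-modify-write chain along a cell's own
instances, then an edge from the cell's final write to each external read.
Diagonal cells are never written, so reads of them carry no dependence.

The transitive closure of this graph has a closed form. Writing `cell(x)`
for the cell an instance updates, `p` reaches `q` exactly when

* they share a cell and `p` runs earlier, or
* `cell(p)` is strictly nested inside `cell(q)`
  (\(i_q \le i_p \le j_p \le j_q\)), and the chain can enter `q`'s cell no
  later than `q` itself: always when \(i_p > i_q\) (the suffix operand is
  read from `k = 0` on), and when \(i_p = i_q\) only from split
  \(k = j_p - i_q\) on.

This is the package's one piece of real derivation, so it is never
trusted on its own: `transitive_closure(graph, "brute")` recomputes
reachability by breadth-first search over the direct edges (via igraph),
and the suite checks the two agree — exhaustively for \(N \le 12\), on
sampled instance pairs up to \(N = 25\). The closed form is what makes
tile correction affordable at production sizes.

## Tile correction by iteration space slicing

Original tiles are rectangular blocks of the *execution order*:
`ii = floor((N-1-i)/b1)` (descending `i`), `jj = floor((j-i-1)/b2)`
(diagonal offset), `kk = floor(k/b3)`. The diagonal update `s2` closes its
cell, so its original k-block is the last one of its cell,
`floor((j-i-1)/b3)` — the placement that mirrors the serial code, where
`s2` follows the final split. Placing `s2` in k-block zero instead would
make it a dependence target of its own cell's later splits and force the
correction to move every such `s2`; with the closing placement the `s2`
correction set is empty, which the suite verifies for every tested
configuration rather than assumes.

Correction applies the closure to the tiles in lexicographic order of
`(ii, jj, kk)`. A tile's retained part removes every instance reached
from a lexicographically later tile (`TILE_ITR = TILE − R⁺(TILE_GT)`);
its absorbed part collects instances of earlier tiles that are reached
from the retained part and not from anything later
(`TVLD_LT = (R⁺(TILE_ITR) ∩ TILE_LT) − R⁺(TILE_GT)`); the valid tile is
their union. Equivalently — and this is how `build_valid_tiles()`
computes it — every instance lands in the lexicographic maximum of its
own original tile and the original tiles of all instances that reach it.
Note the direction: a moved instance is a dependence *target* of a later
tile, so correction can only *delay* work into lexicographically greater
tiles, never advance it.

Two consequences fall out of the closed form and are relied on by the
executor (and, again, verified rather than assumed):

* correction never changes `(ii, jj)`, only `kk`: the lexicographically
  greatest source reaching cell `(i, j)` is the deepest split of the
  neighbour cell `(i+1, j)`, whose tile can exceed the target's only in
  the `kk` coordinate;
* grouping tiles by the skew `w = ii + jj`, with a member's k-blocks kept
  serial, gives a wavefront schedule in which distinct members of one
  wave are mutually independent (a dependence shrinks the cell interval,
  so it cannot increase `ii` or `jj` while preserving their sum).

`validate_schedule()` checks an arbitrary tile order against the direct
edges and returns a violation report (empty = valid); `wavefronts()`
verifies the skew contract when handed the graph and refuses the
configuration otherwise. `tiled_fill()` executes the corrected tiles wave
by wave, members optionally in shuffled order — the shuffle is the test
surrogate for true thread-level parallelism, which a pure-R executor does
not attempt; `workers` is a declared contract, checked by order
independence.

Under this normalized tiling, sizes with `b1 = 1` (outermost loop
untiled) turn out to need no correction at all — the lexicographic order
of the original tiles is already valid — which is why they form the
pre-verified family that production runs may use without desk-scale
validation. Arbitrary `b1 > 1` sizes are first validated against the full
oracle at a proxy size (default 16; large enough to exercise several
blocks per dimension for the tile sizes in range, small enough that the
instance-level oracle is instant).

## The parametric factor model

Lifting two fixed-tile-size codes into one parametric code rests on an
observation about the generated code text: the two codes share their
structure and differ only in integer factors at matching positions, and
every factor obeys

\[ y = a_0\, b_1 b_2 + a_1\, b_1 + a_2\, b_2 + a_3\, b_3 + a_4 \]

with at most two nonzero integer coefficients. `fit_factor_model()`
solves the two-equation
system for a factor pair exactly over integer supports of size ≤ 2,
searched in a fixed priority order — constant; single linear terms; linear
term + constant; linear pairs; supports involving the bilinear term. The
search is data-driven with deterministic tie-breaking: two exact
solutions at the same rank raise an ambiguity error listing both
candidates, and a pair no support fits raises an "unmodellable" error.
Arithmetic is integer-only (2×2 determinant plus divisibility tests), so
fits are exact by construction, and `predict_factor()` must reproduce the
observed pair — the defining round trip, asserted everywhere. The default
tile sizes are the prime vectors `[23,47,113]` and `[37,79,167]`; primes
keep factors from coinciding accidentally, which is what makes the ten
canonical formula classes uniquely recoverable (the suite checks
uniqueness by exhausting the support lattice).

## Tile-size selection

`tss_search()` mirrors the standard empirical protocol: enumerate a
candidate grid (default: 20 values per dimension,
{1, 2, 4, 6, 8, 12, 16, 24, 32, 40, 48, 64, 96, 128, 150, 200, 256, 300,
400, 512}, hence 8000 candidates), check each candidate's validity
(family membership or the desk-scale oracle), time the tiled fill — one
warm-up, then the median of `repeats` runs (default 3) — and rank valid
candidates by ascending runtime with lexicographic tie-breaking, so the
ranking is stable under record permutation; the warm-up/repeat protocol
is the package's own choice. The timer is injectable precisely because absolute runtimes
are machine facts, not package facts: tests drive the search with
deterministic fake timers and assert only ranking logic, never wall-clock
values, and no published speed-up figure is treated as reproducible.

## Synthetic data

`synth_rna()` emulates the randomly generated strands used to benchmark
folding codes: i.i.d. residues, uniform base composition by default,
configurable length, fully determined by an explicit seed (the caller's
RNG state is left untouched). Real transcripts are not i.i.d. — they have
local composition bias, repeats, and genuine secondary structure — so
passing equivalence tests on synthetic strands certifies the *schedules*
(which are sequence-oblivious: the iteration domain depends only on `N`),
not biological realism of the fold. That is the right trade: schedule
correctness is exactly sequence-independent, while score correctness is
separately pinned to the exhaustive enumeration oracle for `N ≤ 14`.

## Problem sizes and numerical choices

The suite's scales are chosen so the whole run stays in minutes on one
core: exhaustive closure checks to `N = 12`, sampled to 25; the
construction grid `N = 4..20` against six tile sizes including the
degenerate `(1,1,1)` and non-divisible shapes like `(2,3,5)`; schedule
equivalence over 200 seeded strands of lengths 2–64 plus 128 and 300,
with the tiled executor run at the published best parallel size
`(1, 96, 8)` at `N = 300`. All arithmetic is integer; there are no
tolerances anywhere — every equality in the package is exact, including
the executor-versus-reference matrix comparisons.

Degenerate inputs are pinned by tests: `N = 1` folds to a 1×1 zero
matrix and an empty iteration domain; an empty pairing rule zeroes every
score; tiles larger than the domain collapse to a single tile and a
single wavefront; adjacent residues never pair.

## Known limitations

* The executor is serial R; parallelism is a verified contract (shuffled
  member order), not an implementation. The schedules are faithful, the
  wall-clock behaviour of a threaded C implementation is out of scope.
* Tile validity for `b1 > 1` at production `N` is established at a proxy
  size, matching the per-size check of the empirical search protocol; it
  is not a symbolic proof over all `N`.
* Scoring is maximum base pairs only — no thermodynamic energy model, no
  suboptimal structures, no pseudoknots (non-crossing structures only).
* Published wall-clock tables and speed-ups are hardware-bound and are
  neither reproduced nor asserted.
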