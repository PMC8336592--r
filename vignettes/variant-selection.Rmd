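---
title: "Selecting variants for variation graphs with mappability guarantees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting variants for variation graphs with mappability guarantees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vgsieve)
```

## The problem

A complete variation graph encodes a linear reference plus every catalogued
variant: SNPs as parallel labeled edges, deletions as label-free skip edges,
insertions as labeled chains that leave and re-enter their host vertex.
Including every variant inflates the graph with recombinant paths, makes the
pangenome more repetitive, and eventually hurts read-to-graph mapping rather
than helping it. vgsieve selects a reduced variant subset with an explicit
guarantee: every string of length $\alpha$ spelled by a path of the complete
graph still maps to the reduced graph, from the corresponding start vertex,
within $\delta$ differences. $\alpha$ should track read length and $\delta$
the error tolerance of the intended mapper — the two presets are
$(\alpha = 150, \delta = 8)$ for short reads and
$(\alpha = 10\,000, \delta = 1\,000)$ for long reads.

Differences are counted in Hamming distance when only SNPs are present (path
ends then stay pinned to the coordinate axis) and in edit distance once
indels are involved. Two reduction objectives are supported: minimizing the
number of variant-containing loci, and minimizing the total number of
variants. Selection is always all-or-nothing per locus: an optimal solution
never keeps a strict subset of the alleles at a coordinate, because once one
allele is dropped the locus already charges its error to every overlapping
window, so dropping the rest is free.

## The model

The backbone of a reference of length $L$ has $L + 1$ ordered coordinate
vertices $v_0, \dots, v_L$. All coordinates in the package are 0-based: a
variant's coordinate is the backbone vertex its first deviating edge leaves
from. VCF's 1-based anchored records are converted at the I/O boundary only
(`read_variants()` splits multi-allelic records and de-anchors indels).
Several variant types may share a coordinate; they live in one locus and are
kept or dropped as a unit. `N` bases are ordinary characters that mismatch
everything but `N`.

A path may visit a vertex at most twice, and may traverse each insertion
chain at most once. The first rule is the standard one and forbids
combining two insertions at the same coordinate. The second makes the
rule's purpose explicit: vertex counting alone still admits a walk that
starts in the middle of an insertion chain, exits to the host vertex, and
then runs the full loop again, spelling up to $2\Delta_{ins} - 1$ inserted
characters; such walks would break the per-locus penalty bound below, so
the oracle excludes them. A path that starts inside a chain has thereby
spent that chain's single traversal.

## Algorithms

### SNP-only graphs

**Sweep greedy (`greedy_snp`).** Feasibility only needs checking on the
$\alpha$-windows $(p_i - \alpha,\, p_i]$ that end at the $n$ variant
coordinates: no window may contain more than $\delta$ removed loci. Each
locus spawns a start event at $\max(0, p_i - \alpha + 1)$ and an end event
at $p_i$; sweeping the events (starts before ends at ties) and removing a
locus whenever the running count of removed loci in the active segment is
below $\delta$ maximizes the number of removed loci in $O(n)$ after
sorting. The exchange argument is the usual one: the leftmost point of
disagreement with any optimum can be swapped toward the greedy choice
without losing feasibility.

**Interval programme (`lp_snp`).** To minimize retained *variants*, locus
$i$ carries gain $c_i$ = its allele count, and the programme maximizes
$\sum c_i x_i$ subject to $\sum_{j \in (p_i-\alpha,\, p_i]} x_j \le \delta$
for every $i$, $x \in [0,1]^n$. The constraint matrix has consecutive ones
per row (an interval matrix), so it is totally unimodular and the relaxed
optimum is integral. vgsieve solves it exactly through the equivalent
minimum-cost-flow problem: differencing consecutive rows of the
equality-form system turns each variable into a unit-capacity arc spanning
the contiguous block of rows that cover it (cost $-c_j$), slack variables
into zero-cost arcs along the chain of row nodes, and the programme into
shipping $\delta$ units across the chain. Successive shortest paths on
integer capacities return an integral flow, which is then re-checked
against the window constraints and for integrality (tolerance $10^{-6}$,
which only guards against arithmetic surprises — the flow is integral by
construction). Ties among equally optimal solutions depend on the
augmenting order, so tests compare objective values, never the identity of
the removed set.

### Graphs with indels

**Windows (`compute_windows`).** With deletions, an $\alpha$-path can span
more than $\alpha$ of the coordinate axis. The window start of locus $i$ is
the leftmost backbone vertex from which $v_{p_i}$ is reachable using fewer
than $\alpha$ labeled edges — paths starting left of it cannot traverse the
locus's variants within their $\alpha$ labels. Only deletion edges matter
(SNPs and insertions never extend reach), giving the recursion
$f(v_i, x) = \min\big(i,\ f(v_{i-1}, x-1),\ f(v_s, x)\ \text{for deletions } s \to i\big)$,
evaluated left-to-right with an $\alpha$-length rolling vector in
$O(\alpha (L + y))$ time for $y$ deletion edges. Runs of vertices beyond
the reach of any deletion shortcut are skipped, since there
$f(v_i, \alpha) = \max(0, i - \alpha + 1)$; a deletion's influence decays
within $\alpha$ vertices of its target unless another deletion renews it.
Note that window starts are *not* monotone across loci: a locus at a
deletion's target vertex reaches far left through the skip edge while its
immediate neighbours do not, so all code that maps loci to the windows
covering them enumerates memberships directly instead of bisecting.

**Penalties (`locus_penalty`).** Dropping all variants at a locus costs any
overlapping $\alpha$-path at most $\Delta_{ins} + \Delta_{del}$ edits,
where $\Delta_{ins}$/$\Delta_{del}$ are the longest insertion and deletion
at the locus. With no deletion present, a co-located SNP costs one
substitution, so an SNP-only locus has penalty 1 and an insertion+SNP locus
$\Delta_{ins} + 1$ (a path may take the insertion and then the SNP edge —
the conservative reading of "adjusted easily"). The bound never drops
below 1.

**Conservative greedy (`greedy_indel`).** Scan loci left to right; remove a
locus iff in *every* window containing it — including windows of later loci
stretched back over it by deletions — the penalties of already-removed loci
plus its own stay within $\delta$. Feasibility of the output is guaranteed
because penalties are upper bounds; optimality is not (the problems with
indels have no known polynomial exact algorithm).

**Branch and bound (`ilp_indel`).** The same window constraints with
weights (penalties) and binary variables, maximizing either total variants
(`ilp_iv`) or locus count (`ilp_ip`). Weighted constraints are no longer
totally unimodular — a single window is a knapsack — so vgsieve runs an
exact depth-first branch and bound: presolve fixes every locus with
penalty $> \delta$ to retained and drops windows whose coverage is
contained in another's; the search is warm-started from the greedy
solution and prunes with the suffix-sum-of-gains bound. Because the
incumbent starts at the greedy solution, the reported objective is never
below greedy's, including when the soft time limit (default 60 s) stops
the proof of optimality — the result is then flagged `"timeout"` but
remains feasible.

## The oracle

`verify_compatibility()` is the ground truth the selection algorithms are
tested against: it enumerates every $\alpha$-path of the complete graph
(exhaustively, with an explicit path cap that errors rather than
truncates) and maps each spelled string against the reduced graph from its
start vertex. Start vertices inside dropped insertion chains are remapped
to the closest vertex on the coordinate axis, i.e. the chain's host.
Hamming distance is the minimum positionwise mismatch count over
equal-length paths from the same start — computed by a level DP over
(vertex, offset) states with deletion edges relaxed within levels. Edit
distance is semi-global: the whole string must be consumed but the path
end is free, computed as a 0/1-weight shortest path over (vertex, offset)
states; freeing the end is the more permissive and alignment-realistic
reading of mapping "with edit distance $\le \delta$", and the mapping side
deliberately does not enforce the path-traversal rules — a mapper may use
any walk of the reduced graph, which can only lower distances and never
falsifies a guarantee. On SNP-only graphs, window feasibility and Hamming
compatibility coincide (asserted exhaustively on small instances); with
indels the implication runs one way only, since penalties are upper
bounds.

`brute_force_select()` closes the loop for optimality tests: all $2^n$
locus subsets, feasibility by the window system (fast mode) or by full
path verification, for either objective.

## Synthetic catalogues

`simulate_variation()` emulates the three catalogue regimes the tool is
aimed at, on a uniform random reference:

* **SNPs** — per-base rate `1/39` (the mean inter-SNP gap of dense human
  chromosome-scale call sets), alternative alleles uniform over the three
  non-reference bases, a second allele with probability `0.003` (roughly
  the observed multi-allelic fraction: variants exceed
  variant-containing loci by ~0.3%).
* **Short indels** — per-base rate `0.001` (short indels are roughly 4% of
  SNP counts in such call sets), half insertions half deletions, geometric
  lengths (`p = 0.35`, mean ≈ 2.9 bp) truncated to `[1, 50]`.
* **Indel SVs** — a fixed count of ≥50 bp insertions/deletions with
  log-uniform lengths, default range `[50, 5000]` bp, placed without
  mutual overlap so that window and penalty semantics stay unambiguous
  (overlap can be allowed with a flag).

Everything is deterministic given the seed. What the generator does *not*
emulate: haplotype structure and linkage (irrelevant to the recombinant-path
guarantee), locus clustering and SV hot-spots, sequence context of indels,
and genotype columns. Passing tests therefore certify the combinatorial
guarantees on realistic densities — not calling accuracy on real data.

## Numerical and design choices

* Windows use the half-open convention $(p_i - \alpha,\, p_i]$ literally;
  window membership for constraint $k$ is the closed coordinate interval
  $[\mathrm{ws}_k, p_k]$ including $p_k$ itself.
* $\alpha$ greater than the backbone length is clamped to it in SNP-only
  graphs (no path can be longer).
* When a locus is removed, its outgoing label falls back to the reference
  base; any fixed character would preserve the budget semantics, but the
  reference base is the choice emitted in outputs.
* Two deletions with identical (coordinate, span) are one edge:
  `build_variation_graph()` deduplicates identical tuples, which affects
  allele counts.
* The sweep processes start events before end events at equal positions;
  the branch and bound explores "remove" before "keep" so good incumbents
  appear early.
* Degenerate inputs: SNP alleles equal to the reference base are an error
  (or skipped with a warning under `lenient = TRUE`); deletions may not
  run off the reference; an empty variant set yields the bare backbone and
  every algorithm returns an empty selection.

## Problem sizes used by the test suite

The suite verifies optimality on 500 random SNP instances (up to 14 loci,
$\alpha \le 10$, $\delta \le 3$) against exhaustive search, the weighted
programme on 200 instances with gains up to 5, oracle-certified safety of
all five algorithms on 100 instances (references of 22–24 bp, $\alpha \le
6$), window correctness against an independent backward shortest-path
oracle on 100 deletion-bearing instances (references up to 200 bp,
$\alpha \le 20$), branch-and-bound dominance on 100 instances, and the SV
retention floor on a 100 kbp reference with 40 SVs. The acceptance script
scales the SV experiment to a 1 Mbp reference with 500 SVs. These sizes
keep exhaustive enumeration exact while covering the combinatorics;
chromosome-scale runs use the same code paths with the oracle replaced by
the algorithms' proofs.

## Known limitations

* Only SNPs, insertions and deletions are modeled; duplications,
  inversions and complex rearrangements are out of scope, as are
  haplotype-restricted path sets (whose selection problems are NP-hard
  even for $\delta = 1$) and allele-frequency weighting.
* The indel heuristics guarantee feasibility, not optimality; the penalty
  bound is conservative, so the reduction understates what an exact
  (unknown) algorithm could remove.
* The oracle is exponential in local branching and is meant for small
  instances; `max_paths` makes the refusal explicit.
* A symbolic `<INS>` without a resolved sequence is stood in by `N`s of
  the declared length, which preserves lengths but not labels.
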