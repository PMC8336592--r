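# vgsieve

Variant selection for variation graphs, with an explicit mappability
guarantee.

Pangenome variation graphs encode a linear reference plus catalogued
variants — SNPs as parallel labeled edges, deletions as ε-labeled skip
edges, insertions as labeled loops. Putting *every* known variant in the
graph is counterproductive: recombinant paths explode combinatorially, the
reference becomes more repetitive, and read-to-graph mapping accuracy
eventually degrades. The question vgsieve answers is which variants can be
left out *safely*: it computes a reduced variant set such that every
α-long string spelled by a path of the complete graph still maps to the
reduced graph, from the corresponding start vertex, within δ differences —
Hamming distance for SNP-only graphs, edit distance once indels are
involved. Choose α to match read length and δ to match the error tolerance
of your mapper (presets: α = 150, δ = 8 for short reads; α = 10 000,
δ = 1000 for long reads).

It is aimed at people building graph references from FASTA + VCF who want
a principled, parameter-driven reduction instead of frequency thresholds.

## Algorithms

With loci (variant-containing coordinates) `p_1 < … < p_n`, feasibility
only needs checking on the windows `(p_i − α, p_i]`:

* **`greedy_snp`** (SNP-only) — sweep-line greedy over start/end events;
  removes the maximum possible number of loci subject to ≤ δ removed loci
  per window. Optimal for the locus-count objective, O(n) after sorting.
* **`lp_snp`** (SNP-only) — maximizes the number of removed *variants*
  `Σ c_i x_i` under the same window constraints. The constraint matrix is
  an interval matrix, hence totally unimodular; the relaxation is solved
  exactly via its min-cost-flow equivalent and the optimum is integral.
* **`compute_windows` / `locus_penalty`** — with indels, a window's reach
  is computed by a rolling recursion over deletion edges (fewer than α
  labeled edges), and dropping a locus is charged the conservative edit
  bound Δins + Δdel.
* **`greedy_indel`** — removes a locus iff every window containing it
  keeps its accumulated penalty ≤ δ; output guaranteed (α, δ)-compatible
  under edit distance.
* **`ilp_indel`** — exact branch and bound over the same weighted window
  constraints, maximizing removed variants (`ilp_iv`) or removed loci
  (`ilp_ip`); warm-started from the greedy so it never does worse.
* **`verify_compatibility`** — an independent oracle that enumerates all
  α-paths and re-maps each string against the reduced graph; used
  throughout the tests to certify outputs.

## Worked example

```r
library(vgsieve)

# a 100 kbp reference with human-like SNP density (one locus per ~39 bp)
sim <- simulate_variation(sim_spec(100000, snp_rate = 1/39, indel_rate = 0, seed = 7))
g   <- build_variation_graph(sim$reference, sim$variants)
g
#> <variation_graph> reference length 100000, 2580 variant(s) at 2573 locus/loci

sel <- greedy_snp(g, alpha = 150, delta = 8)
sel
#> <variant_selection> greedy_s (alpha = 150, delta = 8)
#>   loci:     2508 removed / 2573 total (97.47%)
#>   variants: 2515 removed / 2580 total (97.48%)
```

At short-read settings, 97.5% of the SNP loci can be dropped while every
150 bp path of the complete graph still maps within 8 mismatches: the 65
retained loci are exactly the ones needed so that no 150 bp window ever
accumulates more than 8 removed loci. The mean gap between retained loci
grows from ~39 bp to ~1.4 kbp, leaving long variant-free stretches. At
long-read settings the whole catalogue goes:

```r
greedy_snp(g, alpha = 10000, delta = 1000)
#> <variant_selection> greedy_s (alpha = 10000, delta = 1000)
#>   loci:     2573 removed / 2573 total (100.00%)
#>   variants: 2580 removed / 2580 total (100.00%)
```

Results are tibble-friendly (`tidy()`, `glance()`, `autoplot()`), and
`write_selection()` emits the retained subset as VCF plus a per-locus TSV
report. Structural variants behave oppositely: at α = 150, δ = 8 every
≥50 bp indel has penalty ≥ 50 > δ, so nothing may be removed — see the
acceptance script below.

## Command line

```sh
vf simulate --ref-length 100000 --snp-rate 0.0256 --seed 7 --out-ref ref.fa --out-vcf cat.vcf
vf select   --ref ref.fa --vcf cat.vcf --algorithm greedy_s --preset short-read \
            --out-vcf kept.vcf --out-report report.tsv
vf verify   --ref ref.fa --vcf cat.vcf --reduced-vcf kept.vcf \
            --alpha 20 --delta 2 --metric hamming
vf stats    --ref ref.fa --vcf cat.vcf
```

`vf` is installed to the package's `exec/` directory
(`system.file("exec", "vf", package = "vgsieve")` — or call
`vgsieve::run_cli()` directly). Flags can be supplied via a YAML
`--config`; `--delta-frac` expresses δ as a fraction of α.

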