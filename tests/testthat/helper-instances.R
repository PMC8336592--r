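# Seeded random instances and independent oracles used across the suite.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

alt_base <- function(ref_base) sample(setdiff(c("A", "C", "G", "T"), ref_base), 1)

# SNP-only instance: n loci at distinct coordinates, 1..max_gain alleles each
make_snp_instance <- function(seed, L = 40, n = 8, max_gain = 1) {
  withr::with_seed(seed, {
    ref <- rand_dna(L)
    coords <- sort(sample(0:(L - 1), n))
    rows <- lapply(coords, function(c0) {
      refb <- substr(ref, c0 + 1, c0 + 1)
      k <- sample.int(max_gain, 1)
      alts <- sample(setdiff(c("A", "C", "G", "T"), refb), min(k, 3))
      variants(rep(c0, length(alts)), rep("SNP", length(alts)), alts)
    })
    build_variation_graph(ref, do.call(rbind, rows))
  })
}

# mixed instance with SNPs, short insertions and deletions
make_mixed_instance <- function(seed, L = 30, n_snp = 2, n_ins = 1, n_del = 1,
                                max_ins = 3, max_del = 4) {
  withr::with_seed(seed, {
    ref <- rand_dna(L)
    coords <- sample(1:(L - max_del - 1), n_snp + n_ins + n_del)
    snp_c <- coords[seq_len(n_snp)]
    ins_c <- coords[n_snp + seq_len(n_ins)]
    del_c <- coords[n_snp + n_ins + seq_len(n_del)]
    v <- rbind(
      if (n_snp > 0) {
        variants(snp_c, rep("SNP", n_snp),
          vapply(snp_c, function(c0) alt_base(substr(ref, c0 + 1, c0 + 1)), character(1))
        )
      },
      if (n_ins > 0) {
        variants(ins_c, rep("INS", n_ins),
          vapply(sample.int(max_ins, n_ins, replace = TRUE), rand_dna, character(1))
        )
      },
      if (n_del > 0) {
        variants(del_c, rep("DEL", n_del), rep("", n_del),
          sample.int(max_del, n_del, replace = TRUE)
        )
      }
    )
    build_variation_graph(ref, v)
  })
}

# deletion-only instance for window testing
make_deletion_instance <- function(seed, L = 120, n_del = 4, n_snp = 4, max_span = 25) {
  withr::with_seed(seed, {
    ref <- rand_dna(L)
    del_c <- sort(sample(0:(L - max_span - 1), n_del))
    spans <- sample.int(max_span, n_del, replace = TRUE)
    snp_c <- sample(setdiff(0:(L - 1), del_c), n_snp)
    v <- rbind(
      variants(del_c, rep("DEL", n_del), rep("", n_del), spans),
      variants(snp_c, rep("SNP", n_snp),
        vapply(snp_c, function(c0) alt_base(substr(ref, c0 + 1, c0 + 1)), character(1))
      )
    )
    build_variation_graph(ref, v)
  })
}

# Independent window oracle: explicit backward shortest path over the
# deletion-only graph, counting labeled (backbone) edges; the window start of
# `coord` is the leftmost vertex from which `coord` is reachable with fewer
# than alpha labeled edges. Differs from the package's rolling recursion: it
# walks the explicit edge set once per query, in decreasing vertex order.
bfs_window_start <- function(graph, coord, alpha) {
  L <- graph$length
  dels <- unique(graph$variants[graph$variants$vtype == "DEL", c("coordinate", "span")])
  dist <- rep(Inf, L + 1) # labeled edges needed to reach `coord` from vertex v
  dist[coord + 1] <- 0
  for (v in seq(coord, 0)) {
    i <- v + 1
    if (v < L && dist[v + 2] + 1 < dist[i]) dist[i] <- dist[v + 2] + 1
    hits <- which(dels$coordinate == v)
    for (h in hits) {
      tgt <- dels$coordinate[h] + dels$span[h]
      if (dist[tgt + 1] < dist[i]) dist[i] <- dist[tgt + 1]
    }
  }
  min(which(dist <= alpha - 1)) - 1L
}

# objective value of a selection
sel_objective <- function(sel, objective = c("positions", "variants")) {
  objective <- match.arg(objective)
  if (objective == "positions") sel$removed_locus_count else sel$removed_variant_count
}
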