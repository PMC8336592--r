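test_that("windows reduce to p - alpha + 1 without deletions", {
  g <- build_variation_graph(strrep("A", 20), variants(12, "SNP", "C"))
  expect_equal(compute_windows(g, 4)$window_start, 9)
  g2 <- build_variation_graph(strrep("A", 20), variants(2, "SNP", "C"))
  expect_equal(compute_windows(g2, 10)$window_start, 0) # clamped at the origin
})

test_that("a deletion stretches downstream windows leftward", {
  g <- build_variation_graph(
    strrep("A", 20),
    variants(c(5, 12), c("DEL", "SNP"), c("", "C"), c(5, 1))
  )
  w <- compute_windows(g, 4)
  # v4 -1 label-> v5 -eps-> v10 -2 labels-> v12: 3 < 4 labeled edges
  expect_equal(w$window_start[w$coordinate == 12], 4)
})

test_that("chained deletions compose through the recursion", {
  g <- build_variation_graph(
    strrep("A", 20),
    variants(c(2, 6, 10), c("DEL", "DEL", "SNP"), c("", "", "C"), c(4, 3, 1))
  )
  w <- compute_windows(g, 2)
  # v2 -eps-> v6 -eps-> v9 -1 label-> v10 needs one labeled entry edge into v2
  expect_equal(w$window_start[w$coordinate == 10], 2)
  expect_equal(w$window_start, c(1, 1, 2))
})

test_that("windows agree with an explicit backward shortest-path oracle", {
  for (seed in 1:40) {
    alpha <- withr::with_seed(seed, sample(2:20, 1))
    g <- make_deletion_instance(seed, L = 150, n_del = 4, n_snp = 4, max_span = 30)
    w <- compute_windows(g, alpha)
    oracle <- vapply(
      w$coordinate, function(c0) bfs_window_start(g, c0, alpha), integer(1)
    )
    expect_equal(w$window_start, oracle, info = sprintf("seed %d alpha %d", seed, alpha))
    expect_true(all(w$window_start <= w$coordinate))
  }
})

test_that("penalties follow the longest-insertion-plus-longest-deletion bound", {
  L <- strrep("A", 80)
  pen1 <- locus_penalty(build_variation_graph(L, variants(3, "SNP", "C")))
  expect_equal(pen1, 1)
  both <- build_variation_graph(L, variants(c(9, 9), c("INS", "DEL"), c("CCCCCCC", ""), c(0, 50)))
  expect_equal(locus_penalty(both), 57)
  del_only <- build_variation_graph(L, variants(4, "DEL", "", 50))
  expect_equal(locus_penalty(del_only), 50)
  ins_snp <- build_variation_graph(L, variants(c(6, 6), c("INS", "SNP"), c("CCC", "C")))
  expect_equal(locus_penalty(ins_snp), 4) # insertion then a substituted base
  ins_only <- build_variation_graph(L, variants(6, "INS", "CC"))
  expect_equal(locus_penalty(ins_only), 2)
})

test_that("with unit penalties and no deletions the greedy reduces to the sweep", {
  for (seed in 1:20) {
    g <- make_snp_instance(seed + 40, L = 60, n = 10)
    alpha <- withr::with_seed(seed, sample(3:12, 1))
    delta <- withr::with_seed(seed + 9, sample(0:3, 1))
    expect_equal(
      greedy_indel(g, alpha, delta)$removed_coordinates,
      greedy_snp(g, alpha, delta)$removed_coordinates
    )
  }
})

test_that("a structural variant survives a short-read budget", {
  g <- build_variation_graph(strrep("A", 400), variants(100, "DEL", "", 50))
  for (alg in c("greedy_i", "ilp_iv", "ilp_ip")) {
    sel <- select_variants(g, 150, 8, algorithm = alg)
    expect_equal(sel$retained_coordinates, 100)
  }
})

test_that("penalty mass accumulates within shared windows", {
  # three deletion loci of span 3 inside one alpha window: 3 + 3 <= 7 < 9
  g <- build_variation_graph(
    strrep("A", 60),
    variants(c(10, 14, 18), rep("DEL", 3), rep("", 3), c(3, 3, 3))
  )
  sel <- greedy_indel(g, alpha = 30, delta = 7)
  expect_equal(sel$removed_coordinates, c(10, 14))
  expect_equal(sel$retained_coordinates, 18)
})

test_that("branch and bound beats a left-first greedy when gains differ", {
  # penalties {6,4,3} share one window; gains favour the right-hand pair
  g <- build_variation_graph(
    strrep("A", 80),
    rbind(
      variants(10, "DEL", "", 6),
      variants(15, "DEL", "", 4),
      variants(c(20, 20, 20, 20, 20), c("DEL", "SNP", "SNP", "SNP", "INS"),
        c("", "C", "G", "T", "AA"), c(3, 1, 1, 1, 0)
      )
    )
  )
  pen <- locus_penalty(g)
  expect_equal(pen, c(6, 4, 5)) # locus 20: del 3 + ins 2
  gre <- greedy_indel(g, alpha = 40, delta = 9)
  ilp <- ilp_indel(g, alpha = 40, delta = 9, objective = "variants")
  expect_equal(gre$removed_coordinates, 10) # takes 6 first, blocks the rest
  expect_equal(sort(ilp$removed_coordinates), c(15, 20))
  expect_gt(ilp$removed_variant_count, gre$removed_variant_count)
})

test_that("zero budget keeps every locus (penalties are at least one)", {
  g <- make_mixed_instance(3, L = 40)
  expect_length(greedy_indel(g, 10, 0)$removed_coordinates, 0)
  expect_length(ilp_indel(g, 10, 0)$removed_coordinates, 0)
})

test_that("branch-and-bound objectives dominate the greedy on random instances", {
  for (seed in 1:30) {
    g <- make_mixed_instance(seed + 60, L = 60, n_snp = 3, n_ins = 2, n_del = 2)
    alpha <- withr::with_seed(seed, sample(4:15, 1))
    delta <- withr::with_seed(seed + 5, sample(1:6, 1))
    gre <- greedy_indel(g, alpha, delta)
    for (obj in c("variants", "positions")) {
      ilp <- ilp_indel(g, alpha, delta, objective = obj)
      expect_gte(sel_objective(ilp, obj), sel_objective(gre, obj))
    }
  }
})

test_that("the branch and bound is exact on exhaustively solvable instances", {
  for (seed in 1:25) {
    g <- make_mixed_instance(seed + 900, L = 50, n_snp = 3, n_ins = 2, n_del = 2)
    alpha <- withr::with_seed(seed, sample(4:12, 1))
    delta <- withr::with_seed(seed + 7, sample(1:6, 1))
    for (obj in c("variants", "positions")) {
      ilp <- ilp_indel(g, alpha, delta, objective = obj)
      opt <- brute_force_select(g, alpha, delta,
        metric = "edit", objective = obj, check = "window"
      )
      expect_equal(sel_objective(ilp, obj), sel_objective(opt, obj),
        info = sprintf("seed %d obj %s", seed, obj)
      )
    }
  }
})

test_that("greedy removal decisions respect windows of later loci", {
  # deletion at 30 stretches locus 34's window back over early loci
  g <- build_variation_graph(
    strrep("A", 60),
    rbind(
      variants(c(2, 4), c("SNP", "SNP"), c("C", "G")),
      variants(30, "DEL", "", 20),
      variants(52, "SNP", "T")
    )
  )
  w <- compute_windows(g, alpha = 8)
  sel <- greedy_indel(g, alpha = 8, delta = 2)
  p <- g$loci$coordinate
  pen <- locus_penalty(g)
  x <- p %in% sel$removed_coordinates
  for (k in seq_along(p)) {
    inside <- p >= w$window_start[k] & p <= p[k]
    expect_lte(sum(pen[x & inside]), 2)
  }
})
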