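check_snp_only <- function(graph) {
  if (any(graph$variants$vtype != "SNP")) {
    abort(paste0(
      "graph contains insertion/deletion variants; ",
      "use greedy_indel() or ilp_indel() for graphs with indels"
    ))
  }
}

clamp_alpha <- function(graph, alpha) {
  alpha <- as.integer(alpha)
  if (alpha < 1) abort("`alpha` must be >= 1")
  min(alpha, max(1L, graph$length))
}

check_delta <- function(delta) {
  delta <- as.integer(delta)
  if (delta < 0) abort("`delta` must be >= 0")
  delta
}

#' Sweep-line greedy selection for SNP-only graphs
#'
#' Removes variants at as many loci as possible while keeping every
#' alpha-long window with at most `delta` removed loci, which preserves
#' mappability of all alpha-long paths within Hamming distance `delta`.
#' Each locus coordinate `p` spawns a *start* event at `max(0, p - alpha + 1)`
#' and an *end* event at `p`; sweeping the sorted events (starts before ends
#' at equal positions) and removing whenever the running count of removed
#' loci inside the current segment is below `delta` yields a maximum-size
#' removed set in O(n) after sorting.
#'
#' @param graph A SNP-only `variation_graph`.
#' @param alpha Path length in bp (clamped to the reference length).
#' @param delta Error budget (Hamming distance), a non-negative integer.
#' @return A `variant_selection` object.
#' @export
#' @examples
#' g <- build_variation_graph("ACGTACGTAC", variants(0:3, rep("SNP", 4), c("C", "A", "T", "A")))
#' greedy_snp(g, alpha = 4, delta = 2)$removed_coordinates
greedy_snp <- function(graph, alpha, delta) {
  stopifnot(inherits(graph, "variation_graph"))
  check_snp_only(graph)
  alpha <- clamp_alpha(graph, alpha)
  delta <- check_delta(delta)

  p <- variant_coordinates(graph)
  n <- length(p)
  if (n == 0 || delta == 0) {
    return(new_selection_result(graph, integer(), "greedy_s", alpha, delta))
  }
  pos <- c(pmax(0L, p - alpha + 1L), p)
  typ <- rep(c(0L, 1L), each = n) # 0 = start (first at ties), 1 = end
  idx <- rep(seq_len(n), 2)
  ord <- order(pos, typ)

  removed <- logical(n)
  count <- 0L
  for (e in ord) {
    i <- idx[e]
    if (typ[e] == 0L) {
      if (count < delta) {
        removed[i] <- TRUE
        count <- count + 1L
      }
    } else if (removed[i]) {
      count <- count - 1L
    }
  }
  new_selection_result(graph, p[removed], "greedy_s", alpha, delta)
}

#' Interval constraint system of a SNP-only graph
#'
#' One constraint row per locus `i`: the loci whose coordinates fall in the
#' half-open window `(p_i - alpha, p_i]` form the contiguous index range
#' `[lo[i], i]`, and at most `delta` of them may be removed. The matrix of
#' these rows has consecutive ones (an interval matrix), so the associated
#' relaxed programme has integral optimal vertices.
#'
#' @inheritParams greedy_snp
#' @return A list of class `interval_constraints` with elements `n`,
#'   `coordinates`, `lo` (first covered index per row), `gains` (variants per
#'   locus), `alpha`, `delta`.
#' @export
build_interval_constraints <- function(graph, alpha, delta) {
  stopifnot(inherits(graph, "variation_graph"))
  alpha <- clamp_alpha(graph, alpha)
  delta <- check_delta(delta)
  p <- variant_coordinates(graph)
  lo <- findInterval(p - alpha, p) + 1L # first j with p[j] > p[i] - alpha
  structure(
    list(
      n = length(p), coordinates = p, lo = lo,
      gains = graph$loci$n_variants, alpha = alpha, delta = delta
    ),
    class = "interval_constraints"
  )
}

# counts of removed loci per window row; x is a 0/1 vector over loci
window_counts <- function(cons, x, weights = NULL) {
  w <- if (is.null(weights)) x else x * weights
  cs <- c(0, cumsum(w))
  cs[seq_len(cons$n) + 1L] - cs[cons$lo]
}

#' Optimal variant-count selection for SNP-only graphs
#'
#' Maximizes the total number of removed variants subject to at most `delta`
#' removed loci in every alpha-long window. The constraint matrix is an
#' interval matrix, hence totally unimodular, so the linear relaxation has an
#' integral optimum; it is computed exactly through the equivalent
#' minimum-cost-flow problem obtained by row-differencing the consecutive-ones
#' system (locus `j` becomes a unit-capacity arc spanning the rows that cover
#' it, with cost equal to its negated gain). The returned solution is verified
#' to be integral and window-feasible.
#'
#' @inheritParams greedy_snp
#' @return A `variant_selection`; `removed_variant_count` is globally maximal.
#' @export
#' @examples
#' g <- build_variation_graph(
#'   "ACGTACGTAC",
#'   variants(c(0, 2, 2, 2), rep("SNP", 4), c("C", "A", "C", "T"))
#' )
#' lp_snp(g, alpha = 4, delta = 1)$removed_coordinates # the 3-variant locus
lp_snp <- function(graph, alpha, delta) {
  stopifnot(inherits(graph, "variation_graph"))
  check_snp_only(graph)
  cons <- build_interval_constraints(graph, alpha, delta)
  alpha <- cons$alpha
  delta <- cons$delta
  p <- cons$coordinates
  n <- cons$n
  if (n == 0 || delta == 0) {
    return(new_selection_result(graph, integer(), "lp_s", alpha, delta))
  }

  # rows covering locus j are [j, hi[j]]; arcs j -> hi[j] + 1 over nodes 1..n+1
  hi <- findInterval(p + alpha - 1L, p) # last i with p[i] < p[j] + alpha
  from <- c(seq_len(n), seq_len(n))
  to <- c(hi + 1L, seq_len(n) + 1L)
  cap <- c(rep(1, n), rep(delta, n))
  cost <- c(-cons$gains, rep(0, n))
  sol <- min_cost_flow(n + 1L, from, to, cap, cost,
    source = 1L, sink = n + 1L, value = delta
  )
  x <- sol$flow[seq_len(n)]
  if (max(abs(x - round(x))) > 1e-6) {
    abort("internal error: non-integral flow solution") # cannot occur: integral caps
  }
  x <- as.integer(round(x))
  if (any(window_counts(cons, x) > delta)) {
    abort("internal error: flow solution violates window constraints")
  }
  new_selection_result(graph, p[x == 1L], "lp_s", alpha, delta)
}
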