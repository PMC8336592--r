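#' Run a variant-selection algorithm by name
#'
#' Single dispatcher over the five selection algorithms: `greedy_s` and
#' `lp_s` for SNP-only graphs (Hamming semantics), `greedy_i`, `ilp_iv`
#' (minimize variants) and `ilp_ip` (minimize variant-containing loci) for
#' graphs that may contain indels (edit semantics).
#'
#' @param graph A `variation_graph`.
#' @param alpha Path length in bp.
#' @param delta Error budget.
#' @param algorithm One of `"greedy_s"`, `"lp_s"`, `"greedy_i"`, `"ilp_iv"`,
#'   `"ilp_ip"`.
#' @param time_limit Solver time limit in seconds (branch-and-bound
#'   algorithms only).
#' @return A `variant_selection`.
#' @export
#' @examples
#' sim <- simulate_variation(sim_spec(500, snp_rate = 0.05, seed = 3))
#' g <- build_variation_graph(sim$reference, sim$variants)
#' glance(select_variants(g, alpha = 20, delta = 2, algorithm = "greedy_s"))
select_variants <- function(graph, alpha, delta,
                            algorithm = c("greedy_s", "lp_s", "greedy_i", "ilp_iv", "ilp_ip"),
                            time_limit = 60) {
  algorithm <- match.arg(algorithm)
  switch(algorithm,
    greedy_s = greedy_snp(graph, alpha, delta),
    lp_s = lp_snp(graph, alpha, delta),
    greedy_i = greedy_indel(graph, alpha, delta),
    ilp_iv = ilp_indel(graph, alpha, delta, objective = "variants", time_limit = time_limit),
    ilp_ip = ilp_indel(graph, alpha, delta, objective = "positions", time_limit = time_limit)
  )
}
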