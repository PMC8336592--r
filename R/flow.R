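# Minimum-cost flow by successive shortest paths (SPFA label-correcting
# search, integer capacities). Small instances only; used to solve the
# totally unimodular interval-constraint programme of lp_snp() exactly.
#
# Arcs are stored forward/backward interleaved: arc 2k-1 is the k-th input
# arc, arc 2k its residual reverse.
min_cost_flow <- function(n_nodes, from, to, cap, cost, source, sink, value) {
  m <- length(from)
  stopifnot(length(to) == m, length(cap) == m, length(cost) == m)
  if (value == 0 || m == 0) {
    return(list(flow = numeric(m), cost = 0))
  }
  head_ <- integer(2 * m)
  caps <- numeric(2 * m)
  costs <- numeric(2 * m)
  head_[seq(1, 2 * m, 2)] <- to
  head_[seq(2, 2 * m, 2)] <- from
  caps[seq(1, 2 * m, 2)] <- cap
  costs[seq(1, 2 * m, 2)] <- cost
  costs[seq(2, 2 * m, 2)] <- -cost
  adj <- vector("list", n_nodes)
  for (k in seq_len(m)) {
    adj[[from[k]]] <- c(adj[[from[k]]], 2L * k - 1L)
    adj[[to[k]]] <- c(adj[[to[k]]], 2L * k)
  }

  remaining <- value
  total_cost <- 0
  while (remaining > 0) {
    dist <- rep(Inf, n_nodes)
    prev_arc <- integer(n_nodes)
    in_queue <- rep(FALSE, n_nodes)
    dist[source] <- 0
    queue <- c(source)
    in_queue[source] <- TRUE
    while (length(queue) > 0) {
      u <- queue[1]
      queue <- queue[-1]
      in_queue[u] <- FALSE
      du <- dist[u]
      for (a in adj[[u]]) {
        if (caps[a] <= 0) next
        v <- head_[a]
        nd <- du + costs[a]
        if (nd < dist[v] - 1e-12) {
          dist[v] <- nd
          prev_arc[v] <- a
          if (!in_queue[v]) {
            queue <- c(queue, v)
            in_queue[v] <- TRUE
          }
        }
      }
    }
    if (!is.finite(dist[sink])) {
      abort("min_cost_flow: requested flow value is infeasible")
    }
    # bottleneck along the shortest path
    push <- remaining
    v <- sink
    while (v != source) {
      a <- prev_arc[v]
      push <- min(push, caps[a])
      v <- head_[if (a %% 2 == 1) a + 1L else a - 1L]
    }
    v <- sink
    while (v != source) {
      a <- prev_arc[v]
      caps[a] <- caps[a] - push
      rev <- if (a %% 2 == 1) a + 1L else a - 1L
      caps[rev] <- caps[rev] + push
      v <- head_[rev]
    }
    total_cost <- total_cost + push * dist[sink]
    remaining <- remaining - push
  }
  flow <- caps[seq(2, 2 * m, 2)] # residual on reverse arc == flow sent
  list(flow = flow, cost = total_cost)
}
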