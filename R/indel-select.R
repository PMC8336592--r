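penalty_from_components <- function(delta_ins, delta_del, has_snp, has_ins, has_del) {
  pen <- ifelse(has_ins, delta_ins, 0L) +
    ifelse(has_del, delta_del, ifelse(has_snp, 1L, 0L))
  pmax(as.integer(pen), 1L)
}

#' Edit-distance penalty of dropping a locus
#'
#' Upper bound on the edit distance any alpha-long path can incur if all
#' variants at a locus are removed: `delta_ins + delta_del` where `delta_ins`
#' and `delta_del` are the longest insertion and deletion at the locus. With
#' no deletion present a co-located SNP contributes one substitution, so an
#' SNP-only locus costs 1 and an insertion+SNP locus costs `delta_ins + 1`;
#' the bound never drops below 1.
#'
#' @param graph A `variation_graph`.
#' @return Integer vector of penalties aligned with `graph$loci`.
#' @export
#' @examples
#' g <- build_variation_graph("ACGTACGTAC", variants(2, "DEL", "", 3))
#' locus_penalty(g) # 3
locus_penalty <- function(graph) {
  stopifnot(inherits(graph, "variation_graph"))
  graph$loci$penalty
}

#' Leftmost window start of every locus
#'
#' For each variant locus at coordinate `p_i`, computes the coordinate of the
#' leftmost backbone vertex from which `v_{p_i}` can be reached by a path
#' using fewer than `alpha` labeled edges. Deletion edges consume no label and
#' therefore stretch windows leftward; SNPs and insertions never do, so only
#' deletion edges are considered. The recursion
#' `f(v_i, x) = min(i, f(v_{i-1}, x - 1), f(v_src, x) for deletions src -> i)`
#' is evaluated left-to-right with an alpha-length rolling vector per vertex;
#' runs of vertices out of reach of any deletion shortcut are skipped since
#' there `f(v_i, alpha) = max(0, i - alpha + 1)`.
#'
#' @param graph A `variation_graph`.
#' @param alpha Path length in bp.
#' @return A tibble (`window_table`) with columns `coordinate` and
#'   `window_start`, one row per locus in ascending coordinate order.
#' @export
#' @examples
#' g <- build_variation_graph(strrep("A", 20), variants(c(5, 12), c("DEL", "SNP"), c("", "C"), c(5, 1)))
#' compute_windows(g, alpha = 4) # locus 12 reaches back to vertex 4 via the deletion
compute_windows <- function(graph, alpha) {
  stopifnot(inherits(graph, "variation_graph"))
  alpha <- as.integer(alpha)
  if (alpha < 1) abort("`alpha` must be >= 1")
  need <- variant_coordinates(graph)
  dels <- distinct(
    graph$variants[graph$variants$vtype == "DEL", c("coordinate", "span")]
  )
  ws <- windows_core(
    graph$length,
    del_src = dels$coordinate, del_tgt = dels$coordinate + dels$span,
    need = need, alpha = alpha
  )
  structure(
    tibble(coordinate = need, window_start = ws),
    class = c("window_table", "tbl_df", "tbl", "data.frame")
  )
}

windows_core <- function(L, del_src, del_tgt, need, alpha) {
  xs <- seq_len(alpha)
  baseline <- function(i) pmax(0L, i - xs + 1L)
  if (length(need) == 0) {
    return(integer())
  }
  out <- pmax(0L, need - alpha + 1L) # overwritten where a deletion interferes
  names(out) <- NULL
  if (length(del_src) == 0) {
    return(out)
  }

  src_by_tgt <- split(del_src, del_tgt)
  tgt_pos <- as.integer(names(src_by_tgt))
  src_set <- unique(del_src)
  stored <- new.env(parent = emptyenv()) # f vectors at deletion sources
  need_at <- split(seq_along(need), need)

  events <- sort(unique(c(tgt_pos, src_set, need)))
  ei <- 1L
  i <- -1L
  dirty <- FALSE
  f_prev <- NULL
  while (TRUE) {
    if (dirty) {
      i <- i + 1L
    } else {
      while (ei <= length(events) && events[ei] <= i) ei <- ei + 1L
      if (ei > length(events)) break
      i <- events[ei]
    }
    if (i > L) break

    is_tgt <- !is.null(src_by_tgt[[as.character(i)]])
    if (!dirty && !is_tgt) {
      # f equals the deletion-free baseline here
      if (i %in% src_set) stored[[as.character(i)]] <- NULL
      next
    }
    fp <- if (dirty) f_prev else baseline(i - 1L)
    f <- c(i, fp[-alpha])
    if (is_tgt) {
      for (s in src_by_tgt[[as.character(i)]]) {
        fs <- stored[[as.character(s)]]
        if (is.null(fs)) fs <- baseline(s)
        f <- pmin(f, fs)
      }
    }
    dirty <- any(f < baseline(i))
    f_prev <- f
    if (i %in% src_set) {
      stored[[as.character(i)]] <- if (dirty) f else NULL
    }
    ni <- need_at[[as.character(i)]]
    if (!is.null(ni)) out[ni] <- f[alpha]
  }
  out
}

resolve_tables <- function(graph, alpha, windows, penalties) {
  if (is.null(windows)) windows <- compute_windows(graph, alpha)
  if (is.null(penalties)) penalties <- locus_penalty(graph)
  p <- variant_coordinates(graph)
  if (!identical(as.integer(windows$coordinate), as.integer(p))) {
    abort("window table does not match the graph's loci")
  }
  if (length(penalties) != length(p)) {
    abort("penalty vector does not match the graph's loci")
  }
  list(ws = as.integer(windows$window_start), pen = as.integer(penalties), p = p)
}

# Constraint k covers the contiguous locus index range q[k]..k (the loci
# whose coordinates fall in the window [ws_k, p_k]). Window starts need not
# be monotone across loci -- a locus sitting at a deletion's target vertex
# reaches far left while its neighbours do not -- so the set of windows
# covering a given locus is computed directly, not by bisection.
window_index_ranges <- function(p, ws) {
  list(q = findInterval(ws - 1L, p) + 1L) # first j with p[j] >= ws[k]
}

# indices k of windows containing locus i: k >= i and ws_k <= p_i
windows_covering <- function(p, ws, i) {
  which(seq_along(ws) >= i & ws <= p[i])
}

#' Conservative greedy selection for graphs with indels
#'
#' Scans loci in ascending coordinate order and removes a locus if and only
#' if, in every window that contains it (including windows of later loci,
#' which deletion edges may stretch back over it), the accumulated penalties
#' of already-removed loci plus its own penalty stay within `delta`. The
#' result is guaranteed `(alpha, delta)`-compatible under edit distance
#' because penalties upper-bound the per-locus cost of dropping variants.
#'
#' @param graph A `variation_graph`.
#' @param alpha Path length in bp.
#' @param delta Edit-distance budget.
#' @param windows Optional precomputed [compute_windows()] table.
#' @param penalties Optional precomputed [locus_penalty()] vector.
#' @return A `variant_selection` object.
#' @export
greedy_indel <- function(graph, alpha, delta, windows = NULL, penalties = NULL) {
  stopifnot(inherits(graph, "variation_graph"))
  alpha <- clamp_alpha_indel(graph, alpha)
  delta <- check_delta(delta)
  tb <- resolve_tables(graph, alpha, windows, penalties)
  n <- length(tb$p)
  if (n == 0) {
    return(new_selection_result(graph, integer(), "greedy_i", alpha, delta))
  }
  load <- numeric(n) # removed penalty mass per window k
  removed <- logical(n)
  for (i in seq_len(n)) {
    ks <- windows_covering(tb$p, tb$ws, i)
    if (max(load[ks]) + tb$pen[i] <= delta) {
      removed[i] <- TRUE
      load[ks] <- load[ks] + tb$pen[i]
    }
  }
  new_selection_result(graph, tb$p[removed], "greedy_i", alpha, delta)
}

clamp_alpha_indel <- function(graph, alpha) {
  alpha <- as.integer(alpha)
  if (alpha < 1) abort("`alpha` must be >= 1")
  alpha
}

#' Window-constrained branch-and-bound selection for graphs with indels
#'
#' Maximizes the removal objective subject to, for every locus `k`, the
#' penalties of removed loci inside `k`'s window summing to at most `delta`.
#' `objective = "variants"` weights each locus by its variant count
#' (minimizing retained variants); `objective = "positions"` weights each
#' locus 1 (minimizing retained variant-containing loci). The programme is
#' solved by depth-first branch and bound after a presolve that fixes loci
#' with `penalty > delta` to retained and drops dominated (non-maximal)
#' windows; the search is warm-started from [greedy_indel()]'s solution, so
#' the reported objective is never below the greedy one, including when the
#' time limit cuts the search short (flagged `"timeout"`).
#'
#' @inheritParams greedy_indel
#' @param objective `"variants"` or `"positions"`.
#' @param time_limit Soft wall-clock limit for the search, seconds.
#' @return A `variant_selection`; flag `"timeout"` marks an incumbent that is
#'   feasible but not proven optimal.
#' @export
ilp_indel <- function(graph, alpha, delta, objective = c("variants", "positions"),
                      windows = NULL, penalties = NULL, time_limit = 60) {
  stopifnot(inherits(graph, "variation_graph"))
  objective <- match.arg(objective)
  alpha <- clamp_alpha_indel(graph, alpha)
  delta <- check_delta(delta)
  tb <- resolve_tables(graph, alpha, windows, penalties)
  n <- length(tb$p)
  label <- if (objective == "variants") "ilp_iv" else "ilp_ip"
  if (n == 0) {
    return(new_selection_result(graph, integer(), label, alpha, delta))
  }
  gains <- if (objective == "variants") graph$loci$n_variants else rep(1L, n)

  warm <- greedy_indel(graph, alpha, delta,
    windows = tibble(coordinate = tb$p, window_start = tb$ws),
    penalties = tb$pen
  )
  warm_x <- tb$p %in% warm$removed_coordinates

  free <- which(tb$pen <= delta)
  if (length(free) == 0) {
    return(new_selection_result(graph, integer(), label, alpha, delta))
  }

  q <- window_index_ranges(tb$p, tb$ws)$q
  # keep only maximal windows: k is dominated when a later window starts
  # at or before q[k] (its coverage is then a superset)
  suff_min <- rev(cummin(rev(q)))
  keep_k <- q < c(suff_min[-1], Inf)
  kept <- which(keep_k)
  if (length(kept) == 0) kept <- n # degenerate: all identical, keep last
  # per free variable, the kept constraints covering it
  cov <- lapply(free, function(j) which(kept >= j & q[kept] <= j))

  sol <- bb_window_ilp(
    w = tb$pen[free], g = as.numeric(gains[free]),
    cov = cov, n_cons = length(kept),
    delta = delta, warm = warm_x[free], time_limit = time_limit
  )
  flags <- if (sol$timed_out) "timeout" else character()
  new_selection_result(graph, tb$p[free[sol$x]], label, alpha, delta, flags = flags)
}

# Exact DFS branch and bound for: max sum(g[j] x[j]) s.t. for every
# constraint k, sum of w[j] x[j] over j covered by k is <= delta, x binary.
# cov[[j]] lists the constraints covering variable j. Bound: gain so far +
# suffix sum of undecided gains.
bb_window_ilp <- function(w, g, cov, n_cons, delta, warm, time_limit) {
  m <- length(w)
  warm_gain <- sum(g[warm])
  best_gain <- warm_gain
  best_x <- warm
  suffix <- rev(cumsum(rev(g)))
  load <- numeric(n_cons)
  x <- logical(m)
  timed_out <- FALSE
  t0 <- proc.time()[["elapsed"]]
  nodes <- 0L

  # stack entries: variable index j and phase (1 = try remove, 2 = try keep)
  sp <- 1L
  stack_j <- integer(2L * m + 2L)
  stack_ph <- integer(2L * m + 2L)
  stack_j[1] <- 1L
  stack_ph[1] <- 1L
  while (sp > 0L) {
    nodes <- nodes + 1L
    if (nodes %% 4096L == 0L &&
      proc.time()[["elapsed"]] - t0 > time_limit) {
      timed_out <- TRUE
      break
    }
    j <- stack_j[sp]
    ph <- stack_ph[sp]
    if (j > m) {
      gain <- sum(g[x])
      if (gain > best_gain) {
        best_gain <- gain
        best_x <- x
      }
      sp <- sp - 1L
      next
    }
    gain_now <- if (j == 1L) 0 else sum(g[which(x[seq_len(j - 1L)])])
    if (ph == 1L) {
      stack_ph[sp] <- 2L
      ks <- cov[[j]]
      if (length(ks) > 0 && max(load[ks]) + w[j] <= delta) {
        x[j] <- TRUE
        load[ks] <- load[ks] + w[j]
        sp <- sp + 1L
        stack_j[sp] <- j + 1L
        stack_ph[sp] <- 1L
      }
    } else if (ph == 2L) {
      if (x[j]) { # undo the removal branch
        ks <- cov[[j]]
        load[ks] <- load[ks] - w[j]
        x[j] <- FALSE
      }
      stack_ph[sp] <- 3L
      if (gain_now + (if (j < m) suffix[j + 1L] else 0) > best_gain) {
        sp <- sp + 1L
        stack_j[sp] <- j + 1L
        stack_ph[sp] <- 1L
      }
    } else {
      sp <- sp - 1L
    }
  }
  list(x = which(best_x), objective = best_gain, timed_out = timed_out)
}
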