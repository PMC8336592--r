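# Ground-truth machinery: explicit edge lists, exhaustive alpha-path
# enumeration under the visit-a-vertex-at-most-twice rule, minimum
# Hamming/edit distance of a string against paths from a fixed start vertex,
# and exhaustive selection on tiny instances.

# Explicit edge-level view of a variation graph. Vertices are named:
# coordinate vertices "v<i>" and insertion-chain vertices
# "i<coord>:<allele>:<k>" for the k-th intermediate vertex of that chain.
graph_edges <- function(graph) {
  L <- graph$length
  ref_bases <- strsplit(graph$reference, "", fixed = TRUE)[[1]]
  from <- paste0("v", 0:(L - 1))
  to <- paste0("v", 1:L)
  label <- ref_bases
  chain <- integer(L) # 0 = not part of an insertion chain
  v <- graph$variants
  next_chain <- 0L
  for (r in seq_len(nrow(v))) {
    c0 <- v$coordinate[r]
    if (v$vtype[r] == "SNP") {
      from <- c(from, paste0("v", c0))
      to <- c(to, paste0("v", c0 + 1L))
      label <- c(label, v$allele[r])
      chain <- c(chain, 0L)
    } else if (v$vtype[r] == "DEL") {
      from <- c(from, paste0("v", c0))
      to <- c(to, paste0("v", c0 + v$span[r]))
      label <- c(label, "")
      chain <- c(chain, 0L)
    } else {
      bases <- strsplit(v$allele[r], "", fixed = TRUE)[[1]]
      len <- length(bases)
      host <- paste0("v", c0)
      mid <- if (len > 1) {
        paste0("i", c0, ":", v$allele[r], ":", seq_len(len - 1))
      } else {
        character()
      }
      nodes <- c(host, mid, host)
      next_chain <- next_chain + 1L
      from <- c(from, nodes[seq_len(len)])
      to <- c(to, nodes[seq_len(len) + 1L])
      label <- c(label, bases)
      chain <- c(chain, rep(next_chain, len))
    }
  }
  tibble(from = from, to = to, label = label, chain = chain)
}

indexed_graph <- function(graph) {
  e <- graph_edges(graph)
  vnames <- unique(c(e$from, e$to))
  vid <- seq_along(vnames)
  names(vid) <- vnames
  from <- unname(vid[e$from])
  to <- unname(vid[e$to])
  out <- split(seq_len(nrow(e)), factor(from, levels = vid))
  list(
    vnames = vnames, vid = vid, from = from, to = to,
    label = e$label, chain = e$chain, n_chains = max(0L, e$chain),
    out = out, n_edges = nrow(e)
  )
}

# the insertion chain a vertex lies inside, 0 for coordinate vertices
vertex_chain <- function(ig, vtx_id) {
  if (startsWith(ig$vnames[vtx_id], "v")) {
    return(0L)
  }
  # mid-chain vertices are the target of exactly one edge, a chain edge
  ig$chain[which(ig$to == vtx_id)[1]]
}

#' Enumerate every alpha-long path of a small variation graph
#'
#' Exhaustively lists all paths with exactly `alpha` non-epsilon (labeled)
#' edges, starting from every coordinate vertex and every insertion-chain
#' vertex, under two rules: a path may visit a vertex at most twice, and it
#' may traverse each insertion chain at most once (a path that starts inside
#' a chain has thereby consumed that traversal). Together these ensure a path
#' spells at most one insertion allele per coordinate, which is what the
#' per-locus penalty bound of the selection heuristics presumes. Intended for
#' ground-truth verification on small graphs; cost is exponential in local
#' branching.
#'
#' @param graph A `variation_graph`.
#' @param alpha Number of labeled edges per path.
#' @param max_paths Hard cap; exceeding it raises an "instance too large"
#'   error rather than silently truncating.
#' @return A tibble with columns `start` (vertex name), `string` (the alpha
#'   spelled characters) and `edges` (list column of edge index vectors).
#' @export
enumerate_alpha_paths <- function(graph, alpha, max_paths = 1e6) {
  stopifnot(inherits(graph, "variation_graph"))
  alpha <- as.integer(alpha)
  ig <- indexed_graph(graph)
  n_v <- length(ig$vnames)
  acc_start <- character()
  acc_string <- character()
  acc_edges <- list()
  count <- 0L

  visits <- integer(n_v)
  edge_buf <- integer(alpha * 4L + 8L)
  char_buf <- character(alpha)

  dfs <- function(vtx, labels_used, depth) {
    if (labels_used == alpha) {
      count <<- count + 1L
      if (count > max_paths) {
        abort(sprintf("instance too large: more than %g alpha-paths", max_paths))
      }
      acc_start[count] <<- start_name
      acc_string[count] <<- paste(char_buf, collapse = "")
      acc_edges[[count]] <<- edge_buf[seq_len(depth)]
      return(invisible())
    }
    for (eidx in ig$out[[vtx]]) {
      w <- ig$to[eidx]
      if (visits[w] >= 2L) next
      ch <- ig$chain[eidx]
      if (ch > 0L) {
        # an insertion chain is traversed at most once per path; leaving the
        # chain (arriving back at the host vertex) exhausts the traversal
        if (chain_state[ch] == 2L) next
        old_state <- chain_state[ch]
        chain_state[ch] <<- if (startsWith(ig$vnames[w], "v")) 2L else 1L
      }
      lab <- ig$label[eidx]
      visits[w] <<- visits[w] + 1L
      edge_buf[depth + 1L] <<- eidx
      if (nzchar(lab)) {
        char_buf[labels_used + 1L] <<- lab
        dfs(w, labels_used + 1L, depth + 1L)
      } else {
        dfs(w, labels_used, depth + 1L)
      }
      visits[w] <<- visits[w] - 1L
      if (ch > 0L) chain_state[ch] <<- old_state
    }
    invisible()
  }

  start_name <- ""
  chain_state <- integer(max(1L, ig$n_chains)) # 0 unused, 1 inside, 2 used
  for (s in seq_len(n_v)) {
    start_name <- ig$vnames[s]
    visits[] <- 0L
    visits[s] <- 1L
    chain_state[] <- 0L
    sc <- vertex_chain(ig, s)
    if (sc > 0L) chain_state[sc] <- 1L # a mid-chain start is that traversal
    dfs(s, 0L, 0L)
  }
  tibble(
    start = acc_start, string = acc_string,
    edges = if (count > 0) acc_edges else list()
  )
}

#' Minimum distance of a string against graph paths from a fixed start
#'
#' `metric = "hamming"`: minimum, over all paths with exactly `nchar(string)`
#' labeled edges leaving `start_vertex`, of the positionwise mismatch count.
#' `metric = "edit"`: minimum semi-global unit-cost edit distance, i.e. the
#' whole string must be consumed but the path end is free; computed as a
#' shortest path over (vertex, string offset) states with 0/1 weights
#' (deque-based Dijkstra), since insertion chains create cycles.
#'
#' @param string Query string (length alpha).
#' @param graph A `variation_graph` (typically the reduced graph).
#' @param start_vertex Vertex name (`"v<coord>"` or an insertion-chain vertex
#'   id) or an integer coordinate. The vertex must exist in `graph`: callers
#'   must first remap starts inside dropped insertions to the host coordinate
#'   vertex.
#' @param metric `"hamming"` or `"edit"`.
#' @param context Optional prebuilt [indexed_graph()] (internal use).
#' @return Integer distance; `Inf` under Hamming if no alpha-labeled path
#'   leaves the start vertex.
#' @export
min_distance_from_vertex <- function(string, graph, start_vertex,
                                     metric = c("hamming", "edit"),
                                     context = NULL) {
  metric <- match.arg(metric)
  ig <- if (is.null(context)) indexed_graph(graph) else context
  if (is.numeric(start_vertex)) start_vertex <- paste0("v", start_vertex)
  if (!start_vertex %in% ig$vnames) {
    abort(sprintf(
      "start vertex '%s' absent from graph; remap dropped-insertion starts to their host coordinate vertex",
      start_vertex
    ))
  }
  s_id <- unname(ig$vid[start_vertex])
  chars <- strsplit(string, "", fixed = TRUE)[[1]]
  m <- length(chars)
  if (m < 1) abort("string must have length >= 1")
  if (metric == "hamming") {
    hamming_level_dp(ig, s_id, chars)
  } else {
    edit_01bfs(ig, s_id, chars)
  }
}

# Level DP over consumed characters; epsilon (deletion) edges relaxed within
# each level in ascending source order (they always jump forward along the
# coordinate axis, so one ordered pass reaches the fixpoint).
hamming_level_dp <- function(ig, s_id, chars) {
  n_v <- length(ig$vnames)
  m <- length(chars)
  eps <- which(!nzchar(ig$label))
  if (length(eps) > 0) eps <- eps[order(ig$from[eps])]
  lab <- which(nzchar(ig$label))
  dist <- rep(Inf, n_v)
  dist[s_id] <- 0
  relax_eps <- function(d) {
    for (e in eps) {
      nd <- d[ig$from[e]]
      if (nd < d[ig$to[e]]) d[ig$to[e]] <- nd
    }
    d
  }
  dist <- relax_eps(dist)
  for (t in seq_len(m)) {
    nxt <- rep(Inf, n_v)
    for (e in lab) {
      nd <- dist[ig$from[e]] + (ig$label[e] != chars[t])
      if (nd < nxt[ig$to[e]]) nxt[ig$to[e]] <- nd
    }
    dist <- relax_eps(nxt)
  }
  min(dist)
}

# 0-1 BFS over states (vertex, offset 0..m); offset m states are goals.
edit_01bfs <- function(ig, s_id, chars) {
  n_v <- length(ig$vnames)
  m <- length(chars)
  n_states <- n_v * (m + 1L)
  sid <- function(v, t) v + n_v * t
  dist <- rep.int(NA_integer_, n_states)
  start <- sid(s_id, 0L)
  dist[start] <- 0L
  # deque as two stacks of state ids
  front <- c(start)
  back <- integer()
  best <- Inf
  while (length(front) > 0 || length(back) > 0) {
    if (length(front) == 0) {
      front <- rev(back)
      back <- integer()
    }
    st <- front[length(front)]
    front <- front[-length(front)]
    d <- dist[st]
    v <- ((st - 1L) %% n_v) + 1L
    t <- (st - 1L) %/% n_v
    if (d >= best) next
    if (t == m) {
      best <- min(best, d)
      next
    }
    push <- function(nst, nd) {
      if (is.na(dist[nst]) || nd < dist[nst]) {
        dist[nst] <<- nd
        if (nd == d) front[length(front) + 1L] <<- nst else back[length(back) + 1L] <<- nst
      }
    }
    # insertion into the string: consume chars[t+1], stay put
    push(sid(v, t + 1L), d + 1L)
    for (e in ig$out[[v]]) {
      w <- ig$to[e]
      lab <- ig$label[e]
      if (!nzchar(lab)) {
        push(sid(w, t), d) # epsilon edge, free
      } else {
        push(sid(w, t + 1L), d + (lab != chars[t + 1L])) # match/substitute
        push(sid(w, t), d + 1L) # deletion from the string
      }
    }
  }
  # goal states may remain queued with recorded distances
  goal <- dist[sid(seq_len(n_v), m)]
  min(best, suppressWarnings(min(goal, na.rm = TRUE)))
}

#' Verify (alpha, delta)-compatibility of a reduced graph
#'
#' Enumerates every alpha-long path of the complete graph and checks that its
#' string maps to the reduced graph from the corresponding start vertex within
#' `delta` differences. Start vertices inside dropped insertion chains are
#' remapped to the closest vertex along the coordinate axis (the insertion's
#' host vertex).
#'
#' @param graph The complete `variation_graph`.
#' @param reduced The reduced graph, typically from [apply_selection()].
#' @param alpha Path length.
#' @param delta Error budget.
#' @param metric `"hamming"` (SNP-only semantics) or `"edit"`.
#' @param max_paths Enumeration cap, see [enumerate_alpha_paths()].
#' @return A `compatibility_report`: list with `compatible`,
#'   `n_paths_checked`, `worst` (start, string, distance), `metric`, `alpha`,
#'   `delta`.
#' @export
verify_compatibility <- function(graph, reduced, alpha, delta,
                                 metric = c("hamming", "edit"),
                                 max_paths = 1e6) {
  metric <- match.arg(metric)
  delta <- check_delta(delta)
  paths <- enumerate_alpha_paths(graph, alpha, max_paths = max_paths)
  ig_red <- indexed_graph(reduced)
  # remap starts of dropped insertion chains to the host coordinate vertex
  start <- paths$start
  missing <- !(start %in% ig_red$vnames)
  if (any(missing)) {
    host <- sub("^i([0-9]+):.*$", "v\\1", start[missing])
    start[missing] <- host
  }
  key <- paste(start, paths$string)
  uniq <- !duplicated(key)
  start <- start[uniq]
  strings <- paths$string[uniq]

  worst <- list(start = NA_character_, string = NA_character_, distance = -Inf)
  for (k in seq_along(strings)) {
    d <- min_distance_from_vertex(strings[k], reduced, start[k],
      metric = metric, context = ig_red
    )
    if (d > worst$distance) {
      worst <- list(start = start[k], string = strings[k], distance = d)
    }
    if (d > delta) break # first violation suffices
  }
  if (length(strings) == 0) worst$distance <- 0
  structure(
    list(
      compatible = worst$distance <= delta,
      n_paths_checked = length(strings),
      worst = worst, metric = metric,
      alpha = as.integer(alpha), delta = delta
    ),
    class = "compatibility_report"
  )
}

#' @export
#' @method print compatibility_report
print.compatibility_report <- function(x, ...) {
  cat(sprintf(
    "<compatibility_report> metric = %s, alpha = %d, delta = %d\n",
    x$metric, x$alpha, x$delta
  ))
  cat(sprintf("  compatible: %s (%d path strings checked)\n", x$compatible, x$n_paths_checked))
  if (is.finite(x$worst$distance) && !is.na(x$worst$start)) {
    cat(sprintf(
      "  worst: start %s, distance %s\n", x$worst$start,
      format(x$worst$distance)
    ))
  }
  invisible(x)
}

#' @export
glance.compatibility_report <- function(x, ...) {
  tibble(
    compatible = x$compatible, n_paths_checked = x$n_paths_checked,
    worst_distance = x$worst$distance, metric = x$metric,
    alpha = x$alpha, delta = x$delta
  )
}

#' Exhaustive optimal selection on tiny instances
#'
#' Tries all `2^n` locus subsets and keeps a feasible subset maximizing the
#' removal objective. Feasibility is judged either by the window-constraint
#' system (`check = "window"`: the fast mode used for optimality testing) or
#' by full path verification (`check = "oracle"`).
#'
#' @inheritParams verify_compatibility
#' @param objective `"positions"` (count of removed loci) or `"variants"`
#'   (total removed variants).
#' @param check `"window"` or `"oracle"`.
#' @param max_loci Refuse instances with more loci than this.
#' @return A `variant_selection` with the optimal removed set found.
#' @export
brute_force_select <- function(graph, alpha, delta,
                               metric = c("hamming", "edit"),
                               objective = c("positions", "variants"),
                               check = c("window", "oracle"),
                               max_loci = 20L) {
  metric <- match.arg(metric)
  objective <- match.arg(objective)
  check <- match.arg(check)
  stopifnot(inherits(graph, "variation_graph"))
  delta <- check_delta(delta)
  n <- n_loci(graph)
  if (n > max_loci) {
    abort(sprintf("brute force refused: %d loci exceeds max_loci = %d", n, max_loci))
  }
  p <- variant_coordinates(graph)
  gains <- if (objective == "variants") graph$loci$n_variants else rep(1L, n)
  if (n == 0) {
    return(new_selection_result(graph, integer(), "brute_force", alpha, delta))
  }

  n_sub <- 2L^n
  xmat <- vapply(
    seq_len(n),
    function(b) bitwAnd(0:(n_sub - 1L), bitwShiftL(1L, b - 1L)) > 0L,
    logical(n_sub)
  ) # n_sub x n
  if (check == "window") {
    snp_only <- all(graph$variants$vtype == "SNP")
    if (snp_only && metric == "hamming") {
      cons <- build_interval_constraints(graph, alpha, delta)
      amat <- vapply(
        seq_len(n),
        function(i) as.numeric(seq_len(n) >= cons$lo[i] & seq_len(n) <= i),
        numeric(n)
      ) # n x n, row i = window i (as columns after vapply -> transpose use
      loads <- xmat %*% amat # subsets x windows
      feasible <- rowSums(loads > delta) == 0L
      alpha_used <- cons$alpha
    } else {
      wt <- compute_windows(graph, alpha)
      pen <- locus_penalty(graph)
      rg <- window_index_ranges(p, as.integer(wt$window_start))
      amat <- vapply(
        seq_len(n),
        function(k) ifelse(seq_len(n) >= rg$q[k] & seq_len(n) <= k, pen, 0),
        numeric(n)
      )
      loads <- xmat %*% amat
      feasible <- rowSums(loads > delta) == 0L
      alpha_used <- as.integer(alpha)
    }
  } else {
    alpha_used <- as.integer(alpha)
    feasible <- vapply(seq_len(n_sub), function(s) {
      red <- apply_selection(graph, p[xmat[s, ]])
      verify_compatibility(graph, red, alpha_used, delta, metric = metric)$compatible
    }, logical(1))
  }
  obj <- as.numeric(xmat %*% gains)
  obj[!feasible] <- -Inf
  best <- which.max(obj)
  new_selection_result(graph, p[xmat[best, ]], "brute_force", alpha_used, delta)
}
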