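# Breadth-first machinery over the directed arc view. Distances count edges:
# a path of k molecules has length k - 1. Unreachable is Inf, which orders
# above every finite length and sends the decay score to exactly zero.

#' Breadth-first shortest distances from a source node
#'
#' Exact unweighted shortest-path distances following arc direction. If a
#' `stop_set` is given the search finishes the level on which the first stop
#' node is reached and then halts: the minimum distance to the stop set is
#' final, and every reported distance is exact.
#'
#' @param net A `molnet` object.
#' @param source Node identifier.
#' @param stop_set Optional character vector of node identifiers.
#' @return Named numeric vector of distances to every reached node (always
#'   includes `source` at 0). Nodes absent from the result are unreachable
#'   (within the explored horizon when `stop_set` is used).
#' @export
bfs_distances <- function(net, source, stop_set = NULL) {
  s <- node_index(net, source)
  if (is.na(s)) stop("unknown source node: ", source)
  stop_idx <- if (is.null(stop_set)) integer(0) else
    node_index(net, stop_set)
  stop_idx <- stop_idx[!is.na(stop_idx)]
  n <- nrow(net$nodes)
  dist <- rep(NA_real_, n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  hit <- s %in% stop_idx
  while (length(frontier) > 0 && !hit) {
    nxt <- unique(unlist(net$adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    d <- d + 1
    dist[nxt] <- d
    if (length(stop_idx) > 0 && any(nxt %in% stop_idx)) hit <- TRUE
    frontier <- nxt
  }
  reached <- which(!is.na(dist))
  stats::setNames(dist[reached], net$nodes$id[reached])
}

# Full BFS (no stopping), internal, returns numeric vector indexed by node.
bfs_all <- function(net, s, reverse = FALSE) {
  adj <- if (reverse) net$radj else net$adj
  n <- nrow(net$nodes)
  dist <- rep(NA_real_, n)
  dist[s] <- 0
  frontier <- s
  d <- 0
  while (length(frontier) > 0) {
    nxt <- unique(unlist(adj[frontier], use.names = FALSE))
    nxt <- nxt[is.na(dist[nxt])]
    d <- d + 1
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Enumerate shortest paths between two nodes
#'
#' Lists shortest paths from `source` to `sink` in lexicographic node-id
#' order, up to `cap` paths. The exact number of distinct shortest paths is
#' computed by dynamic programming on the breadth-first predecessor structure,
#' never by enumeration, so the cap affects only the listing. The result also
#' carries the set of all nodes lying on any shortest path, which is how
#' downstream code assembles DEP molecule sets independently of the cap.
#'
#' @param net A `molnet` object.
#' @param source,sink Node identifiers.
#' @param cap Maximum number of paths to list (default 100).
#' @return A `pathset` object with fields `source`, `sink`, `length` (Inf if
#'   unreachable), `paths` (list of node-id vectors), `truncated`,
#'   `total_count`, `nodes`.
#' @export
enumerate_shortest_paths <- function(net, source, sink, cap = 100) {
  stopifnot(cap >= 1)
  s <- node_index(net, source)
  t <- node_index(net, sink)
  if (is.na(s)) stop("unknown source node: ", source)
  if (is.na(t)) stop("unknown sink node: ", sink)

  distF <- bfs_all(net, s)
  if (is.na(distF[t])) {
    return(new_pathset(source, sink, Inf, list(), FALSE, 0, character(0)))
  }
  L <- distF[t]
  if (s == t) {
    return(new_pathset(source, sink, 0, list(source), FALSE, 1, source))
  }
  distB <- bfs_all(net, t, reverse = TRUE)
  on_path <- which(!is.na(distF) & !is.na(distB) & distF + distB == L)

  # Count paths from each on-path node to the sink, processed by decreasing
  # forward distance so successors are already counted.
  cnt <- rep(0, nrow(net$nodes))
  cnt[t] <- 1
  ord <- on_path[order(distF[on_path], decreasing = TRUE)]
  for (v in ord) {
    if (v == t) next
    succ <- net$adj[[v]]
    succ <- succ[!is.na(distF[succ]) & distF[succ] == distF[v] + 1 & cnt[succ] > 0]
    cnt[v] <- sum(cnt[succ])
  }
  total <- cnt[s]

  # Capped listing by depth-first traversal of the shortest-path DAG with
  # successors taken in node-id order -> lexicographic path order.
  ids <- net$nodes$id
  paths <- vector("list", min(cap, total))
  np <- 0L
  walk <- function(v, prefix) {
    if (np >= cap) return()
    if (v == t) {
      np <<- np + 1L
      paths[[np]] <<- ids[c(prefix, v)]
      return()
    }
    succ <- net$adj[[v]]
    succ <- succ[!is.na(distF[succ]) & distF[succ] == distF[v] + 1 & cnt[succ] > 0]
    for (w in succ[order(ids[succ])]) {
      if (np >= cap) break
      walk(w, c(prefix, v))
    }
  }
  walk(s, integer(0))

  new_pathset(source, sink, L, paths[seq_len(np)], total > cap, total,
              sort(ids[on_path]))
}

new_pathset <- function(source, sink, length, paths, truncated, total_count,
                        nodes) {
  structure(list(source = source, sink = sink, length = length,
                 paths = paths, truncated = truncated,
                 total_count = total_count, nodes = nodes),
            class = "pathset")
}

#' @export
print.pathset <- function(x, ...) {
  if (is.infinite(x$length)) {
    cat(sprintf("Path set %s -> %s: unreachable\n", x$source, x$sink))
  } else {
    cat(sprintf("Path set %s -> %s: length %d, %s shortest path(s)%s\n",
                x$source, x$sink, as.integer(x$length),
                format(x$total_count), if (x$truncated) " (listing capped)" else ""))
    for (p in x$paths) cat("  ", paste(p, collapse = " -> "), "\n", sep = "")
  }
  invisible(x)
}
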