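# Independent oracles and fixture builders. The oracles never call the
# package's BFS/enumeration/AUROC code paths they are used to check.

# Random directed graph as interaction records + adjacency matrix.
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(stats::runif(n * n) < p, n, n)
  diag(A) <- FALSE
  ids <- sprintf("N%02d", seq_len(n))
  idx <- which(A, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    # guarantee at least one arc so build_network registers nodes
    A[1, 2] <- TRUE
    idx <- which(A, arr.ind = TRUE)
  }
  recs <- data.frame(
    src = ids[idx[, 1]], src_kind = "gene",
    dst = ids[idx[, 2]], dst_kind = "gene",
    relation = "activation", directed = 1L, provenance = "test",
    stringsAsFactors = FALSE)
  # isolated nodes: anchor them with arcs into a sink-only role is not needed;
  # instead register every node by a self-describing record pair via an
  # auxiliary node would distort the graph, so drop isolated nodes from A too.
  present <- sort(unique(c(idx[, 1], idx[, 2])))
  list(records = recs, A = A[present, present, drop = FALSE],
       ids = ids[present])
}

# All-pairs shortest distances by dynamic programming on boolean matrix
# powers (Floyd-Warshall-equivalent oracle, no BFS).
brute_distances <- function(A) {
  n <- nrow(A)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  reach <- A
  for (k in seq_len(n - 1)) {
    newly <- reach & !is.finite(d)
    d[newly] <- k
    reach <- (reach %*% A) > 0
  }
  d
}

# Exhaustive enumeration of all shortest s -> t paths by depth-first search,
# pruned only with oracle distances (never the package's).
brute_shortest_paths <- function(A, s, t) {
  d <- brute_distances(A)
  L <- d[s, t]
  if (!is.finite(L)) return(list(length = Inf, paths = list()))
  paths <- list()
  walk <- function(v, path) {
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    used <- length(path) - 1
    for (w in which(A[v, ])) {
      if (used + 1 + d[w, t] == L) walk(w, c(path, w))
    }
  }
  walk(s, s)
  list(length = L, paths = paths)
}

# Trapezoidal area under the ROC curve computed directly from scores.
trapezoid_auroc <- function(pos, neg) {
  s <- c(pos, neg)
  y <- rep(c(1, 0), c(length(pos), length(neg)))
  th <- sort(unique(s), decreasing = TRUE)
  tpr <- vapply(th, function(t) mean(pos >= t), 0)
  fpr <- vapply(th, function(t) mean(neg >= t), 0)
  tpr <- c(0, tpr); fpr <- c(0, fpr)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Write a minimal edge-table TSV; rows is a data frame in the edge dialect.
write_edge_tsv <- function(rows, path = tempfile(fileext = ".tsv")) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

edge_row <- function(src, dst, relation = "activation", directed = 1L,
                     src_kind = "gene", dst_kind = "gene") {
  data.frame(src = src, src_kind = src_kind, dst = dst, dst_kind = dst_kind,
             relation = relation, directed = directed, provenance = "test",
             stringsAsFactors = FALSE)
}

write_map_tsv <- function(entity, associated, relation = NULL,
                          path = tempfile(fileext = ".tsv")) {
  df <- data.frame(entity_id = entity, associated_id = associated,
                   stringsAsFactors = FALSE)
  if (!is.null(relation)) df$relation <- relation
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# Diamond lattice of given depth: 2^depth shortest source -> sink paths.
diamond_records <- function(depth) {
  rows <- list()
  prev <- "v0"
  for (i in seq_len(depth)) {
    a <- sprintf("a%d", i); b <- sprintf("b%d", i)
    for (p in prev) {
      rows[[length(rows) + 1L]] <- edge_row(p, a)
      rows[[length(rows) + 1L]] <- edge_row(p, b)
    }
    prev <- c(a, b)
  }
  for (p in prev) rows[[length(rows) + 1L]] <- edge_row(p, "sink")
  do.call(rbind, rows)
}
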