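# Drug effect paths (DEPs): for each drug target, all shortest paths to the
# nearest disease gene(s). Hormone effect paths (HEPs): among all shortest
# paths from any receptor of the hormone to any DEP molecule, those achieving
# the globally minimal length.

#' Infer drug effect paths for a drug-disease pair
#'
#' For each drug target independently, finds the minimal breadth-first
#' distance to any disease gene and collects all shortest paths to every
#' disease gene at that minimal distance (ties are all kept). A target that is
#' itself a disease gene yields a zero-length single-node path. The DEP
#' molecule set `molecules` is the union of all nodes on all shortest paths —
#' targets, intermediates and disease genes — computed from the full
#' shortest-path structure, so the listing cap cannot change it.
#'
#' @param net A `molnet` object.
#' @param targets Character vector of drug target identifiers (non-empty).
#' @param disease_genes Character vector of disease gene identifiers
#'   (non-empty).
#' @param cap Per target-gene pair listing cap (see
#'   [enumerate_shortest_paths()]).
#' @return A `depset` object with `entries` (one per in-network target),
#'   `molecules`, `n_paths` (exact total DEP count) and `unscorable` flag.
#' @export
infer_deps <- function(net, targets, disease_genes, cap = 100) {
  stopifnot(length(targets) >= 1, length(disease_genes) >= 1)
  targets <- sort(unique(targets))
  disease_genes <- sort(unique(disease_genes))
  miss_t <- targets[!has_node(net, targets)]
  miss_g <- disease_genes[!has_node(net, disease_genes)]
  if (length(miss_t) > 0) {
    warning("drug target(s) not in network, skipped: ",
            paste(miss_t, collapse = ", "))
  }
  if (length(miss_g) > 0) {
    warning("disease gene(s) not in network, skipped: ",
            paste(miss_g, collapse = ", "))
  }
  targets <- setdiff(targets, miss_t)
  genes <- setdiff(disease_genes, miss_g)
  if (length(targets) == 0 || length(genes) == 0) {
    return(new_depset(list(), character(0), 0, unscorable = TRUE))
  }

  entries <- vector("list", length(targets))
  molecules <- character(0)
  n_paths <- 0
  for (i in seq_along(targets)) {
    tg <- targets[i]
    d <- bfs_distances(net, tg, stop_set = genes)
    reached <- intersect(names(d), genes)
    if (length(reached) == 0) {
      entries[[i]] <- list(target = tg, nearest_distance = Inf,
                           nearest_disease_genes = character(0),
                           paths = list())
      next
    }
    dmin <- min(d[reached])
    nearest <- sort(reached[d[reached] == dmin])
    ps <- lapply(nearest, function(g) enumerate_shortest_paths(net, tg, g, cap))
    entries[[i]] <- list(target = tg, nearest_distance = dmin,
                         nearest_disease_genes = nearest, paths = ps)
    molecules <- union(molecules, unlist(lapply(ps, `[[`, "nodes")))
    n_paths <- n_paths + sum(vapply(ps, `[[`, 0, "total_count"))
  }
  new_depset(entries, sort(molecules), n_paths, unscorable = FALSE)
}

new_depset <- function(entries, molecules, n_paths, unscorable) {
  structure(list(entries = entries, molecules = molecules,
                 n_paths = n_paths, unscorable = unscorable),
            class = "depset")
}

#' @export
print.depset <- function(x, ...) {
  if (x$unscorable) {
    cat("Drug effect paths: unscorable (no target in network)\n")
    return(invisible(x))
  }
  cat(sprintf("Drug effect paths: %s path(s) from %d target(s), %d molecule(s)\n",
              format(x$n_paths), length(x$entries), length(x$molecules)))
  for (e in x$entries) {
    if (is.infinite(e$nearest_distance)) {
      cat(sprintf("  %s: no reachable disease gene\n", e$target))
    } else {
      cat(sprintf("  %s -> {%s} at distance %d\n", e$target,
                  paste(e$nearest_disease_genes, collapse = ", "),
                  as.integer(e$nearest_distance)))
    }
  }
  invisible(x)
}

#' Infer hormone effect paths against a drug's effect paths
#'
#' One breadth-first search per receptor, stopping once the nearest DEP
#' molecule is final; the global minimum over all (receptor, molecule) pairs
#' is the HEP length. `start_nodes` holds exactly the receptors achieving the
#' minimum and `end_nodes` the DEP molecules achieving it. A receptor that is
#' itself a DEP molecule gives length 0 with that node in both sets.
#'
#' @param net A `molnet` object.
#' @param receptors Character vector of receptor identifiers for the hormone.
#' @param dep A `depset` (see [infer_deps()]).
#' @param cap Per receptor-molecule pair listing cap.
#' @return A `hepset` object with `min_length` (Inf if no route),
#'   `start_nodes`, `end_nodes` and capped `paths`.
#' @export
infer_heps <- function(net, receptors, dep, cap = 100) {
  stopifnot(inherits(dep, "depset"))
  receptors <- sort(unique(receptors))
  receptors <- receptors[has_node(net, receptors)]
  M <- dep$molecules
  if (length(receptors) == 0 || length(M) == 0) {
    return(new_hepset(Inf, character(0), character(0), list()))
  }
  per_rec <- lapply(receptors, function(r) {
    d <- bfs_distances(net, r, stop_set = M)
    hit <- intersect(names(d), M)
    if (length(hit) == 0) return(NULL)
    dmin <- min(d[hit])
    list(receptor = r, dmin = dmin, ends = sort(hit[d[hit] == dmin]))
  })
  per_rec <- per_rec[!vapply(per_rec, is.null, TRUE)]
  if (length(per_rec) == 0) {
    return(new_hepset(Inf, character(0), character(0), list()))
  }
  dmins <- vapply(per_rec, `[[`, 0, "dmin")
  L <- min(dmins)
  winners <- per_rec[dmins == L]
  S <- sort(vapply(winners, `[[`, "", "receptor"))
  E <- sort(unique(unlist(lapply(winners, `[[`, "ends"))))
  paths <- list()
  for (w in winners) {
    for (m in w$ends) {
      paths[[length(paths) + 1L]] <-
        enumerate_shortest_paths(net, w$receptor, m, cap)
    }
  }
  new_hepset(L, S, E, paths)
}

new_hepset <- function(min_length, start_nodes, end_nodes, paths) {
  structure(list(min_length = min_length, start_nodes = start_nodes,
                 end_nodes = end_nodes, paths = paths),
            class = "hepset")
}

#' @export
print.hepset <- function(x, ...) {
  if (is.infinite(x$min_length)) {
    cat("Hormone effect paths: none (no receptor-to-DEP route)\n")
  } else {
    cat(sprintf("Hormone effect paths: length %d, n(S) = %d, n(E) = %d\n",
                as.integer(x$min_length), length(x$start_nodes),
                length(x$end_nodes)))
    cat("  S = {", paste(x$start_nodes, collapse = ", "), "}\n", sep = "")
    cat("  E = {", paste(x$end_nodes, collapse = ", "), "}\n", sep = "")
  }
  invisible(x)
}

#' Mechanism report: the crosstalk subgraph of a hormone-drug-disease triple
#'
#' Combines the listed DEPs and HEPs into a node-typed subgraph suitable for
#' rendering the crosstalk mechanism: each node is labeled with every role it
#' plays (drug target, disease gene, hormone receptor, intermediate), and
#' edges are tagged by the path family they appear in. Ordering is
#' deterministic.
#'
#' @param dep A `depset`.
#' @param hep A `hepset`.
#' @return A `mechanism_report` object: list with `nodes` (id, roles),
#'   `edges` (from, to, family), `n_dep_paths`, `n_hep_paths` and a
#'   `crosstalk_found` flag (FALSE when there are no HEPs).
#' @export
mechanism_report <- function(dep, hep) {
  targets <- vapply(dep$entries, `[[`, "", "target")
  genes <- unique(unlist(lapply(dep$entries, `[[`, "nearest_disease_genes")))
  receptors <- hep$start_nodes

  collect_edges <- function(pathsets, family) {
    rows <- list()
    for (ps in pathsets) {
      for (p in ps$paths) {
        if (length(p) < 2) next
        rows[[length(rows) + 1L]] <- data.frame(
          from = p[-length(p)], to = p[-1], family = family,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) {
      return(data.frame(from = character(0), to = character(0),
                        family = character(0)))
    }
    do.call(rbind, rows)
  }
  dep_edges <- collect_edges(unlist(lapply(dep$entries, `[[`, "paths"),
                                   recursive = FALSE), "dep")
  hep_edges <- collect_edges(hep$paths, "hep")
  edges <- unique(rbind(dep_edges, hep_edges))
  edges <- edges[order(edges$family, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL

  all_nodes <- sort(unique(c(dep$molecules,
                             unlist(lapply(hep$paths, `[[`, "nodes")),
                             targets, genes, receptors)))
  roles <- vapply(all_nodes, function(id) {
    r <- c(if (id %in% targets) "drug_target",
           if (id %in% genes) "disease_gene",
           if (id %in% receptors) "hormone_receptor")
    if (length(r) == 0) r <- "intermediate"
    paste(r, collapse = ";")
  }, "")
  nodes <- data.frame(id = all_nodes, roles = unname(roles),
                      stringsAsFactors = FALSE)

  structure(list(
    nodes = nodes, edges = edges,
    n_dep_paths = dep$n_paths,
    n_hep_paths = sum(vapply(hep$paths, `[[`, 0, "total_count")),
    crosstalk_found = is.finite(hep$min_length)
  ), class = "mechanism_report")
}

#' @export
print.mechanism_report <- function(x, ...) {
  cat(sprintf("Mechanism report: %s DEP(s), %s HEP(s)%s\n",
              format(x$n_dep_paths), format(x$n_hep_paths),
              if (!x$crosstalk_found) " [no crosstalk found]" else ""))
  cat("  nodes:\n")
  for (i in seq_len(nrow(x$nodes))) {
    cat(sprintf("    %s (%s)\n", x$nodes$id[i], x$nodes$roles[i]))
  }
  invisible(x)
}
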