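#' @keywords internal
"_PACKAGE"

# Relation vocabulary. Signaling/regulatory edges are directed; physical
# binding is symmetric, so binding/association and dissociation travel with
# physical_ppi as bidirectional.
.relation_vocab <- c(
  "activation", "inhibition", "expression", "repression",
  "phosphorylation", "dephosphorylation", "binding/association",
  "dissociation", "physical_ppi"
)

#' Relation labels treated as bidirectional
#'
#' Physical protein-protein interactions and binding-type edges are symmetric;
#' signaling and gene-regulatory edges keep their direction.
#'
#' @return Character vector of relation labels.
#' @export
bidirectional_relations <- function() {
  c("physical_ppi", "binding/association", "dissociation")
}

#' Read a molecular interaction edge table
#'
#' Reads a tab-separated edge table with header columns
#' `src, src_kind, dst, dst_kind, relation, directed, provenance`
#' (`#` comment lines ignored). Self-interactions are dropped. Relation labels
#' outside the controlled vocabulary are retained with an `other:` prefix
#' unless a `relation_filter` is given, in which case only rows whose raw
#' relation label is in the filter survive.
#'
#' @param path Path to the TSV file.
#' @param relation_filter Optional character vector of relation labels to keep.
#' @return A data frame of interaction records with attributes `n_self_loops`
#'   and `n_filtered` recording dropped row counts.
#' @export
read_interactions <- function(path, relation_filter = NULL) {
  if (!file.exists(path)) stop("interaction file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  required <- c("src", "src_kind", "dst", "dst_kind", "relation", "directed")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("edge table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  if (!"provenance" %in% names(df)) df$provenance <- ""
  if (nrow(df) == 0) {
    df$directed <- logical(0)
    return(structure(df[required_record_cols()],
                     n_self_loops = 0L, n_filtered = 0L))
  }
  df$directed <- as.integer(df$directed) != 0L

  self <- df$src == df$dst
  n_self <- sum(self)
  if (n_self > 0) {
    warning(n_self, " self-interaction row(s) dropped")
    df <- df[!self, , drop = FALSE]
  }

  n_filtered <- 0L
  if (!is.null(relation_filter)) {
    keep <- df$relation %in% relation_filter
    n_filtered <- sum(!keep)
    df <- df[keep, , drop = FALSE]
  } else {
    unknown <- !(df$relation %in% .relation_vocab) &
      !startsWith(df$relation, "other:")
    df$relation[unknown] <- paste0("other:", df$relation[unknown])
  }
  rownames(df) <- NULL
  structure(df[required_record_cols()],
            n_self_loops = as.integer(n_self),
            n_filtered = as.integer(n_filtered))
}

required_record_cols <- function() {
  c("src", "src_kind", "dst", "dst_kind", "relation", "directed", "provenance")
}

#' Assemble a molecular network from interaction records
#'
#' Builds a directed arc set over genes and compounds. Records whose relation
#' is bidirectional (or whose `directed` flag is 0) contribute reciprocal
#' arcs; duplicate arcs are merged and carry the union of their relation
#' labels. An identifier seen as both gene and compound is a fatal
#' inconsistency.
#'
#' @param records Data frame of interaction records
#'   (see [read_interactions()]).
#' @param bidirectional Character vector of relation labels realized as
#'   reciprocal arcs. Defaults to [bidirectional_relations()].
#' @return A `molnet` object.
#' @export
build_network <- function(records, bidirectional = bidirectional_relations()) {
  ids <- c(records$src, records$dst)
  kinds <- c(records$src_kind, records$dst_kind)
  ord <- order(ids, kinds)
  ids <- ids[ord]; kinds <- kinds[ord]
  dup <- duplicated(paste(ids, kinds, sep = "\r"))
  ids <- ids[!dup]; kinds <- kinds[!dup]
  if (anyDuplicated(ids)) {
    bad <- unique(ids[duplicated(ids)])
    stop("identifier(s) registered with conflicting kinds: ",
         paste(bad, collapse = ", "))
  }

  is_bidir <- (records$relation %in% bidirectional) | !records$directed
  src <- c(records$src, records$dst[is_bidir])
  dst <- c(records$dst, records$src[is_bidir])
  rel <- c(records$relation, records$relation[is_bidir])

  key <- paste(src, dst, sep = "\r")
  uk <- !duplicated(key)
  labels <- split(rel, factor(key, levels = key[uk]))
  labels <- lapply(labels, function(x) sort(unique(x)))
  arcs <- data.frame(src = src[uk], dst = dst[uk], stringsAsFactors = FALSE)
  ord <- order(arcs$src, arcs$dst)
  arcs <- arcs[ord, , drop = FALSE]
  labels <- labels[ord]
  rownames(arcs) <- NULL

  new_molnet(data.frame(id = ids, kind = kinds, stringsAsFactors = FALSE),
             arcs, unname(labels))
}

new_molnet <- function(nodes, arcs, labels) {
  n <- nrow(nodes)
  idx_src <- match(arcs$src, nodes$id)
  idx_dst <- match(arcs$dst, nodes$id)
  if (anyNA(idx_src) || anyNA(idx_dst)) {
    stop("arc endpoint not registered as a node")
  }
  adj <- split(idx_dst, factor(idx_src, levels = seq_len(n)))
  radj <- split(idx_src, factor(idx_dst, levels = seq_len(n)))
  structure(list(
    nodes = nodes,
    arcs = arcs,
    labels = labels,
    adj = lapply(adj, function(v) sort(unname(v))),
    radj = lapply(radj, function(v) sort(unname(v)))
  ), class = "molnet")
}

#' @export
print.molnet <- function(x, ...) {
  cat("Molecular interaction network\n")
  cat("  nodes:", nrow(x$nodes),
      sprintf("(%d gene, %d compound)\n",
              sum(x$nodes$kind == "gene"), sum(x$nodes$kind == "compound")))
  cat("  arcs: ", nrow(x$arcs), "\n", sep = "")
  invisible(x)
}

node_index <- function(net, ids) match(ids, net$nodes$id)

#' Test whether identifiers are nodes of a network
#'
#' @param net A `molnet` object.
#' @param ids Character vector of identifiers.
#' @return Logical vector.
#' @export
has_node <- function(net, ids) ids %in% net$nodes$id

#' Remove nodes (and incident arcs) from a network
#'
#' Used for the receptor-removal robustness experiment: rebuilding the network
#' without selected receptors and rescoring shows how much the score relies on
#' them. Absent identifiers are ignored with a warning. The input network is
#' unchanged.
#'
#' @param net A `molnet` object.
#' @param nodes Character vector of node identifiers to remove.
#' @return A new `molnet` object.
#' @export
ablate_nodes <- function(net, nodes) {
  nodes <- unique(nodes)
  absent <- nodes[!has_node(net, nodes)]
  if (length(absent) > 0) {
    warning("ignoring identifiers not in the network: ",
            paste(absent, collapse = ", "))
  }
  if (length(nodes) == length(absent)) return(net)
  keep_nodes <- !(net$nodes$id %in% nodes)
  keep_arcs <- !(net$arcs$src %in% nodes) & !(net$arcs$dst %in% nodes)
  new_molnet(net$nodes[keep_nodes, , drop = FALSE],
             net$arcs[keep_arcs, , drop = FALSE],
             net$labels[keep_arcs])
}

#' Write a network back to the edge-table dialect
#'
#' Reciprocal arc pairs whose label sets match and consist only of
#' bidirectional relations are collapsed to a single row with `directed = 0`;
#' every other arc is written as a directed row. A network written and re-read
#' is identical (node set, arc set, labels).
#'
#' @param net A `molnet` object.
#' @param path Output TSV path.
#' @param bidirectional Labels eligible for collapsing.
#' @return Invisibly, the number of rows written.
#' @export
write_network <- function(net, path, bidirectional = bidirectional_relations()) {
  arcs <- net$arcs
  labels <- net$labels
  kind <- stats::setNames(net$nodes$kind, net$nodes$id)
  n <- nrow(arcs)
  lab_str <- vapply(labels, paste, "", collapse = ";")
  key <- paste(arcs$src, arcs$dst, sep = "\r")
  rkey <- paste(arcs$dst, arcs$src, sep = "\r")
  rev_idx <- match(rkey, key)
  all_bidir <- vapply(labels, function(l) all(l %in% bidirectional), TRUE)

  rows <- vector("list", n)
  emitted <- logical(n)
  for (i in seq_len(n)) {
    if (emitted[i]) next
    j <- rev_idx[i]
    collapse <- !is.na(j) && !emitted[j] && i != j &&
      all_bidir[i] && lab_str[i] == lab_str[j]
    if (collapse) emitted[j] <- TRUE
    emitted[i] <- TRUE
    rows[[i]] <- data.frame(
      src = arcs$src[i], src_kind = kind[[arcs$src[i]]],
      dst = arcs$dst[i], dst_kind = kind[[arcs$dst[i]]],
      relation = labels[[i]],
      directed = if (collapse) 0L else 1L,
      provenance = "pathcross",
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(out)) {
    out <- data.frame(src = character(), src_kind = character(),
                      dst = character(), dst_kind = character(),
                      relation = character(), directed = integer(),
                      provenance = character())
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(nrow(out))
}

read_two_col <- function(path, relation_filter = NULL) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                          colClasses = "character", quote = "",
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("annotation table needs at least two columns: ", path)
  names(df)[1:2] <- c("entity_id", "associated_id")
  has_rel <- ncol(df) >= 3
  if (has_rel) names(df)[3] <- "relation"
  dropped <- character(0)
  if (!is.null(relation_filter)) {
    if (!has_rel) stop("relation filter given but table has no relation column: ", path)
    before <- unique(df$entity_id)
    df <- df[df$relation %in% relation_filter, , drop = FALSE]
    dropped <- c(dropped, setdiff(before, unique(df$entity_id)))
  }
  empty <- is.na(df$associated_id) | df$associated_id == ""
  if (any(empty)) {
    before <- unique(df$entity_id)
    df <- df[!empty, , drop = FALSE]
    dropped <- c(dropped, setdiff(before, unique(df$entity_id)))
  }
  m <- split(df$associated_id, df$entity_id)
  m <- lapply(m, function(x) sort(unique(x)))
  m <- m[order(names(m))]
  list(map = m, dropped = sort(unique(dropped)))
}

#' Read hormone/drug/disease annotation maps
#'
#' Loads the four two-column association tables: hormone -> receptor genes,
#' drug -> target genes, disease -> disease genes, disease -> treating drugs.
#' Every hormone must keep at least one receptor, every drug at least one
#' target and every disease at least one gene; entities violating this (all
#' association rows empty, or removed by the relation filter) are dropped with
#' a warning and listed in the `audit` attribute.
#'
#' @param receptor_path,target_path,disease_gene_path,disease_drug_path TSV
#'   paths (`entity_id<TAB>associated_id[<TAB>relation]`).
#' @param disease_gene_filter Optional relation labels to keep in the
#'   disease-gene table (e.g. `"marker/mechanism"` to keep etiology
#'   associations and drop therapeutic-target rows).
#' @return An `annot_maps` object: a list with elements `receptors`,
#'   `targets`, `disease_genes`, `disease_drugs`, each a named list of
#'   character vectors.
#' @export
read_annotations <- function(receptor_path, target_path, disease_gene_path,
                             disease_drug_path, disease_gene_filter = NULL) {
  rec <- read_two_col(receptor_path)
  tgt <- read_two_col(target_path)
  dg <- read_two_col(disease_gene_path, relation_filter = disease_gene_filter)
  dd <- read_two_col(disease_drug_path)

  entity <- c(rec$dropped, tgt$dropped, dg$dropped)
  audit <- data.frame(
    map = rep(c("receptors", "targets", "disease_genes"),
              c(length(rec$dropped), length(tgt$dropped), length(dg$dropped))),
    entity = entity,
    reason = rep("no association after filtering", length(entity)),
    stringsAsFactors = FALSE
  )
  if (nrow(audit) > 0) {
    warning("dropped ", nrow(audit),
            " annotation entit(ies) with no remaining association: ",
            paste(audit$entity, collapse = ", "))
  }
  for (nm in c("receptors", "targets", "disease_genes")) {
    m <- switch(nm, receptors = rec$map, targets = tgt$map,
                disease_genes = dg$map)
    if (length(m) == 0) stop("annotation map '", nm, "' is empty after filtering")
  }
  structure(list(receptors = rec$map, targets = tgt$map,
                 disease_genes = dg$map, disease_drugs = dd$map),
            audit = audit, class = "annot_maps")
}

#' @export
print.annot_maps <- function(x, ...) {
  cat("Annotation maps:",
      length(x$receptors), "hormones,",
      length(x$targets), "drugs,",
      length(x$disease_genes), "diseases (genes),",
      length(x$disease_drugs), "diseases (drugs)\n")
  invisible(x)
}
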