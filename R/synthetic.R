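# Synthetic worlds: a deterministic toy network reproducing the worked
# example (one drug, one hormone, one disease) and seeded random worlds with
# planted short-HEP gold pairs against long-or-disconnected background pairs.
# The generator emits the same TSV dialects as the readers so that tests can
# exercise the real I/O path.

interaction_record <- function(src, dst, relation = "activation",
                               src_kind = "gene", dst_kind = "gene",
                               directed = 1L, provenance = "synthetic") {
  data.frame(src = src, src_kind = src_kind, dst = dst, dst_kind = dst_kind,
             relation = relation, directed = directed,
             provenance = provenance, stringsAsFactors = FALSE)
}

new_world <- function(network, maps, gold, ddi, params) {
  structure(list(network = network, maps = maps, gold = gold, ddi = ddi,
                 params = params), class = "synthetic_world")
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat("Synthetic crosstalk world\n")
  print(x$network)
  print(x$maps)
  cat("  gold pairs:", nrow(x$gold), "\n")
  invisible(x)
}

#' The worked-example toy world
#'
#' A deterministic 14-node directed network holding one drug (targets T1,
#' T2), one disease (genes S1, S2) and one hormone (receptors R1, R2):
#' T1 reaches S1 through a1, a2 (length 3, one path); T2 reaches S2 through
#' b1 or b2 (length 2, two paths); R1 reaches T2 through M1 or M2 (length 2);
#' R2 reaches S1 through c1, c2 (length 3). The drug therefore has three
#' effect paths, and the hormone's effect paths have length 2 with start set
#' {R1} and end set {T2}, so the pair scores `alpha^-2` at unit start/end
#' counts. The gold table contains the single pair H1 -> D1.
#'
#' @return A `synthetic_world` object; identical on every call.
#' @export
toy_world <- function() {
  arcs <- rbind(
    interaction_record("T1", "a1"), interaction_record("a1", "a2"),
    interaction_record("a2", "S1"),
    interaction_record("T2", "b1"), interaction_record("b1", "S2"),
    interaction_record("T2", "b2"), interaction_record("b2", "S2"),
    interaction_record("R1", "M1"), interaction_record("M1", "T2"),
    interaction_record("R1", "M2"), interaction_record("M2", "T2"),
    interaction_record("R2", "c1"), interaction_record("c1", "c2"),
    interaction_record("c2", "S1")
  )
  net <- build_network(arcs)
  maps <- structure(list(
    receptors = list(H1 = c("R1", "R2")),
    targets = list(D1 = c("T1", "T2")),
    disease_genes = list(Z1 = c("S1", "S2")),
    disease_drugs = list(Z1 = "D1")
  ), class = "annot_maps")
  gold <- data.frame(hormone = "H1", drug = "D1",
                     relation_class = "enhances", stringsAsFactors = FALSE)
  ddi <- data.frame(actor = "H1", recipient = "D1",
                    relation_class = "enhances", provenance = "synthetic",
                    stringsAsFactors = FALSE)
  new_world(net, maps, gold, ddi, list(kind = "toy"))
}

#' Default parameters of the random world generator
#'
#' @return Named list of generator parameters; see [generate_world()].
#' @export
world_params <- function() {
  list(
    n_genes = 160,        # filler gene nodes forming the random background
    n_compounds = 12,     # filler compound nodes
    arc_density = 0.03,   # arc probability within the filler subgraph
    ppi_fraction = 0.3,   # fraction of filler arcs that are bidirectional PPI
    n_hormones = 14,
    n_drugs = 8,
    n_diseases = 1,
    n_gold = 10,          # planted gold hormone-drug pairs (one per hormone)
    genes_per_disease = 10,
    targets_per_drug = 2,
    receptors_per_hormone = 2,
    planted_hep_length = 1,
    background_min_length = 4,
    label_noise = 0
  )
}

#' Generate a seeded random world with planted crosstalk signal
#'
#' Builds a random background digraph plus a planted scaffold: each drug's
#' targets are wired to its disease's genes through fresh chains of length
#' `background_min_length - planted_hep_length`, so effect paths exist by
#' construction; each gold hormone's first receptor is wired to its gold
#' drug's first target through a fresh chain of length `planted_hep_length`;
#' every remaining hormone is wired to one drug target through a chain of
#' exactly `background_min_length`. Because receptors have no other outgoing
#' arcs and chain intermediates are fresh nodes, gold pairs have HEP length
#' exactly `planted_hep_length` and every background pair has HEP length at
#' least `background_min_length` or no route at all. `label_noise` flips a
#' fraction of gold labels (swapping planted pairs out of the gold table and
#' background pairs in) without rewiring, producing imperfect-AUROC regimes.
#' A drug-drug interaction table is emitted so that
#' [extract_gold_standard()] recovers exactly the (possibly noised) gold set.
#'
#' @param params Parameter list, see [world_params()]; entries you pass
#'   override the defaults.
#' @param seed Integer seed; everything is reproducible from it.
#' @return A `synthetic_world` object.
#' @export
generate_world <- function(params = list(), seed = 1) {
  p <- utils::modifyList(world_params(), params)
  stopifnot(p$planted_hep_length < p$background_min_length,
            p$arc_density > 0, p$arc_density <= 1,
            p$n_gold <= p$n_hormones, p$n_diseases >= 1, p$n_drugs >= 1)
  set.seed(seed)

  hormones <- sprintf("H%02d", seq_len(p$n_hormones))
  drugs <- sprintf("D%02d", seq_len(p$n_drugs))
  diseases <- sprintf("Z%02d", seq_len(p$n_diseases))
  dep_len <- max(1L, p$background_min_length - p$planted_hep_length)

  recs <- list()
  fresh_counter <- 0L
  fresh <- function(prefix, k) {
    fresh_counter <<- fresh_counter + 1L
    sprintf("%s%04d_%02d", prefix, fresh_counter, seq_len(k))
  }
  chain <- function(from, to, len, prefix = "I") {
    # directed chain from -> ... -> to with len arcs (len - 1 fresh nodes)
    nodes <- c(from, if (len > 1) fresh(prefix, len - 1L), to)
    do.call(rbind, lapply(seq_len(len), function(i) {
      interaction_record(nodes[i], nodes[i + 1])
    }))
  }

  # Disease genes, drug targets, receptors: distinct fresh nodes throughout,
  # so no accidental shortcut can undercut the planted lengths.
  disease_genes <- lapply(diseases, function(z)
    sprintf("S_%s_%02d", z, seq_len(p$genes_per_disease)))
  names(disease_genes) <- diseases
  targets <- lapply(drugs, function(d)
    sprintf("T_%s_%02d", d, seq_len(p$targets_per_drug)))
  names(targets) <- drugs
  receptors <- lapply(hormones, function(h)
    sprintf("R_%s_%02d", h, seq_len(p$receptors_per_hormone)))
  names(receptors) <- hormones

  # Assign drugs to diseases round-robin; wire each target to a random gene
  # of its disease through a fresh chain of length dep_len.
  drug_disease <- stats::setNames(rep(diseases, length.out = p$n_drugs), drugs)
  for (d in drugs) {
    z <- drug_disease[[d]]
    for (tg in targets[[d]]) {
      g <- sample(disease_genes[[z]], 1)
      recs[[length(recs) + 1L]] <- chain(tg, g, dep_len)
    }
  }

  # Planted gold pairs: first n_gold hormones, one drug each (round-robin);
  # receptor 1 -> first target of the drug, chain of planted_hep_length.
  gold_h <- hormones[seq_len(p$n_gold)]
  gold_d <- drugs[rep_len(seq_len(p$n_drugs), p$n_gold)]
  for (i in seq_len(p$n_gold)) {
    recs[[length(recs) + 1L]] <-
      chain(receptors[[gold_h[i]]][1], targets[[gold_d[i]]][1],
            p$planted_hep_length, prefix = "P")
  }

  # Background hormones: receptor 1 -> a random drug target, chain of exactly
  # background_min_length, so background pairs are long but mostly finite.
  bg_h <- setdiff(hormones, gold_h)
  for (h in bg_h) {
    d <- sample(drugs, 1)
    recs[[length(recs) + 1L]] <-
      chain(receptors[[h]][1], targets[[d]][1],
            p$background_min_length, prefix = "B")
  }

  # Random filler subgraph (genes + compounds), self-contained so it cannot
  # shorten any receptor-to-effect-path route.
  filler <- c(sprintf("G%03d", seq_len(p$n_genes)),
              sprintf("C%03d", seq_len(p$n_compounds)))
  filler_kind <- rep(c("gene", "compound"), c(p$n_genes, p$n_compounds))
  n_f <- length(filler)
  n_arcs <- max(1L, round(p$arc_density * n_f * (n_f - 1) / 2))
  src_i <- sample.int(n_f, n_arcs, replace = TRUE)
  dst_i <- sample.int(n_f, n_arcs, replace = TRUE)
  ok <- src_i != dst_i
  src_i <- src_i[ok]; dst_i <- dst_i[ok]
  is_ppi <- stats::runif(length(src_i)) < p$ppi_fraction
  rel <- ifelse(is_ppi, "physical_ppi",
                sample(c("activation", "inhibition", "expression"),
                       length(src_i), replace = TRUE))
  rel[filler_kind[src_i] == "compound" | filler_kind[dst_i] == "compound"] <-
    "binding/association"
  if (length(src_i) > 0) {
    recs[[length(recs) + 1L]] <- interaction_record(
      filler[src_i], filler[dst_i], relation = rel,
      src_kind = filler_kind[src_i], dst_kind = filler_kind[dst_i],
      directed = as.integer(!(rel %in% bidirectional_relations())))
  }

  records <- do.call(rbind, recs)
  records <- records[records$src != records$dst, , drop = FALSE]
  net <- build_network(records)

  true_gold <- data.frame(hormone = gold_h, drug = gold_d,
                          stringsAsFactors = FALSE)
  gold <- unique(true_gold)

  # Label noise: swap a fraction of planted pairs out of the gold table and
  # an equal number of background pairs in. Wiring is untouched.
  n_flip <- floor(p$label_noise * nrow(gold) + 0.5)
  if (n_flip > 0) {
    universe <- expand.grid(hormone = hormones, drug = drugs,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    bg_pairs <- universe[!(paste(universe$hormone, universe$drug, sep = "|") %in%
                           paste(gold$hormone, gold$drug, sep = "|")), ]
    drop_i <- sample.int(nrow(gold), n_flip)
    add_i <- sample.int(nrow(bg_pairs), n_flip)
    gold <- rbind(gold[-drop_i, , drop = FALSE],
                  bg_pairs[add_i, , drop = FALSE])
  }
  gold <- gold[order(gold$hormone, gold$drug), , drop = FALSE]
  gold$relation_class <- sample(c("enhances", "disturbs", "adverse"),
                                nrow(gold), replace = TRUE)
  rownames(gold) <- NULL

  # DDI table: the gold rows plus distractors that extraction must reject
  # (unknown class; drug acting on a hormone).
  ddi <- rbind(
    data.frame(actor = gold$hormone, recipient = gold$drug,
               relation_class = gold$relation_class,
               provenance = "synthetic", stringsAsFactors = FALSE),
    data.frame(actor = hormones[1], recipient = drugs[1],
               relation_class = "unknown", provenance = "synthetic"),
    data.frame(actor = drugs[1], recipient = hormones[1],
               relation_class = "enhances", provenance = "synthetic")
  )
  ddi <- unique(ddi)

  maps <- structure(list(
    receptors = receptors,
    targets = targets,
    disease_genes = disease_genes,
    disease_drugs = split(drugs, stats::setNames(drug_disease[drugs], drugs))
  ), class = "annot_maps")
  maps$disease_drugs <- lapply(maps$disease_drugs, unname)

  new_world(net, maps, gold, ddi,
            c(p, list(seed = seed, drug_disease = drug_disease)))
}

#' Verify the planted/background length contract of a generated world
#'
#' Recomputes every hormone-drug HEP length with the pathfinding machinery
#' and checks that planted gold pairs are short (<= `planted_hep_length`) and
#' non-gold pairs are long (>= `background_min_length`) or unreachable.
#' Label-noise flips are exempt: the check runs against the wiring (the
#' originally planted pairs), not the noised labels.
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @return TRUE invisibly; stops with a message on violation.
#' @export
verify_world <- function(world) {
  p <- world$params
  planted_keys <- character(0)
  for (z in names(world$maps$disease_drugs)) {
    fit <- crosstalk(world$network, world$maps, z)
    gold_h <- sprintf("H%02d", seq_len(p$n_gold))
    gold_d <- sprintf("D%02d", rep_len(seq_len(p$n_drugs), p$n_gold))
    planted_keys <- paste(gold_h, gold_d, sep = "|")
    keys <- paste(fit$scores$hormone, fit$scores$drug, sep = "|")
    is_planted <- keys %in% planted_keys
    len <- fit$scores$hep_length
    bad_gold <- is_planted & !(len <= p$planted_hep_length)
    bad_bg <- !is_planted &
      !(len >= p$background_min_length | !is.finite(len))
    if (any(bad_gold)) {
      stop("planted pair(s) with HEP length above the planted bound: ",
           paste(keys[bad_gold], collapse = ", "))
    }
    if (any(bad_bg)) {
      stop("background pair(s) with HEP length below the background bound: ",
           paste(keys[bad_bg], collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Write a world to TSV files
#'
#' Emits `interactions.tsv`, `receptors.tsv`, `targets.tsv`,
#' `disease_genes.tsv`, `disease_drugs.tsv` and `ddi.tsv` in the dialects the
#' package readers consume, so a written world can be re-read with
#' [read_world()].
#'
#' @param world A `synthetic_world`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_network(world$network, file.path(dir, "interactions.tsv"))
  wmap <- function(m, path) {
    df <- data.frame(
      entity_id = rep(names(m), lengths(m)),
      associated_id = unlist(m, use.names = FALSE), stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wmap(world$maps$receptors, file.path(dir, "receptors.tsv"))
  wmap(world$maps$targets, file.path(dir, "targets.tsv"))
  wmap(world$maps$disease_genes, file.path(dir, "disease_genes.tsv"))
  wmap(world$maps$disease_drugs, file.path(dir, "disease_drugs.tsv"))
  utils::write.table(world$ddi, file.path(dir, "ddi.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(world$params) && length(world$params) > 0) {
    keep <- vapply(world$params, function(x)
      is.atomic(x) && length(x) >= 1, TRUE)
    jsonlite::write_json(world$params[keep],
                         file.path(dir, "params.json"), auto_unbox = TRUE)
  }
  invisible(dir)
}

#' Read a world back from TSV files
#'
#' @param dir Directory written by [write_world()].
#' @return A `synthetic_world` (params restored from `params.json` when
#'   present; gold pairs re-derived from the DDI table).
#' @export
read_world <- function(dir) {
  recs <- read_interactions(file.path(dir, "interactions.tsv"))
  net <- build_network(recs)
  maps <- read_annotations(file.path(dir, "receptors.tsv"),
                           file.path(dir, "targets.tsv"),
                           file.path(dir, "disease_genes.tsv"),
                           file.path(dir, "disease_drugs.tsv"))
  ddi <- utils::read.delim(file.path(dir, "ddi.tsv"), header = TRUE,
                           sep = "\t", colClasses = "character",
                           quote = "", stringsAsFactors = FALSE)
  gold <- extract_gold_standard(ddi, names(maps$receptors),
                                unique(unlist(maps$disease_drugs)))
  pfile <- file.path(dir, "params.json")
  params <- if (file.exists(pfile)) jsonlite::read_json(pfile, simplifyVector = TRUE)
            else list()
  new_world(net, maps, gold, ddi, params)
}
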