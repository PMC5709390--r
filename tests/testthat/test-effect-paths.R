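test_that("the worked-example drug has exactly three effect paths", {
  w <- toy_world()
  dep <- infer_deps(w$network, c("T1", "T2"), c("S1", "S2"))
  expect_false(dep$unscorable)
  expect_equal(dep$n_paths, 3)
  byt <- setNames(dep$entries, vapply(dep$entries, `[[`, "", "target"))
  expect_equal(byt$T1$nearest_distance, 3)
  expect_equal(byt$T1$nearest_disease_genes, "S1")
  expect_equal(byt$T2$nearest_distance, 2)
  expect_equal(byt$T2$nearest_disease_genes, "S2")
  expect_setequal(dep$molecules, c("T1", "a1", "a2", "S1", "T2", "b1", "b2", "S2"))
})

test_that("the worked-example hormone effect paths have length two from R1 to T2", {
  w <- toy_world()
  dep <- infer_deps(w$network, c("T1", "T2"), c("S1", "S2"))
  hep <- infer_heps(w$network, c("R1", "R2"), dep)
  expect_equal(hep$min_length, 2)
  expect_equal(hep$start_nodes, "R1")      # R2's length-3 route to S1 excluded
  expect_equal(hep$end_nodes, "T2")
  expect_equal(sum(vapply(hep$paths, `[[`, 0, "total_count")), 2)
})

test_that("a target that is a disease gene yields a zero-length single-node path", {
  net <- build_network(rbind(edge_row("T", "X"), edge_row("X", "G")))
  dep <- infer_deps(net, "T", c("T", "G"))
  expect_equal(dep$entries[[1]]$nearest_distance, 0)
  expect_equal(dep$entries[[1]]$nearest_disease_genes, "T")
  expect_equal(dep$entries[[1]]$paths[[1]]$paths, list("T"))
  expect_true("T" %in% dep$molecules)
  expect_equal(dep$n_paths, 1)
})

test_that("unreachable targets contribute an empty entry and nothing to M(d)", {
  net <- build_network(rbind(edge_row("T1", "G"), edge_row("T2", "X")))
  dep <- infer_deps(net, c("T1", "T2"), "G")
  byt <- setNames(dep$entries, vapply(dep$entries, `[[`, "", "target"))
  expect_equal(byt$T2$nearest_distance, Inf)
  expect_length(byt$T2$paths, 0)
  expect_setequal(dep$molecules, c("T1", "G"))
})

test_that("no target in the network flags the pair unscorable", {
  net <- build_network(edge_row("A", "B"))
  dep <- suppressWarnings(infer_deps(net, "T99", "B"))
  expect_true(dep$unscorable)
  expect_length(dep$molecules, 0)
})

test_that("disease-gene ties at the minimal distance are all kept", {
  net <- build_network(rbind(edge_row("T", "G1"), edge_row("T", "G2"),
                             edge_row("T", "X"), edge_row("X", "G3")))
  dep <- infer_deps(net, "T", c("G1", "G2", "G3"))
  expect_equal(dep$entries[[1]]$nearest_distance, 1)
  expect_equal(dep$entries[[1]]$nearest_disease_genes, c("G1", "G2"))
  expect_false("G3" %in% dep$molecules)   # strictly farther gene excluded
})

test_that("per-target minimality holds against the distance oracle", {
  for (seed in 1:10) {
    g <- random_digraph(12, 0.2, seed)
    net <- build_network(g$records)
    ids <- net$nodes$id
    set.seed(seed)
    targets <- sample(ids, 2)
    genes <- sample(setdiff(ids, targets), 3)
    dep <- infer_deps(net, targets, genes)
    for (e in dep$entries) {
      d <- bfs_distances(net, e$target)
      reach <- intersect(names(d), genes)
      want <- if (length(reach) > 0) min(d[reach]) else Inf
      expect_equal(e$nearest_distance, want)
    }
  }
})

test_that("HEP minimality, start/end sets and zero-length consistency hold", {
  for (seed in 11:20) {
    g <- random_digraph(12, 0.2, seed)
    net <- build_network(g$records)
    ids <- net$nodes$id
    set.seed(seed)
    targets <- sample(ids, 2)
    genes <- sample(setdiff(ids, targets), 2)
    receptors <- sample(ids, 3)
    dep <- infer_deps(net, targets, genes)
    hep <- infer_heps(net, receptors, dep)
    # oracle: all (receptor, molecule) distances
    pair_d <- expand.grid(r = receptors, m = dep$molecules,
                          stringsAsFactors = FALSE)
    if (nrow(pair_d) == 0) {
      expect_equal(hep$min_length, Inf)
      next
    }
    pair_d$d <- mapply(function(r, m) {
      dd <- bfs_distances(net, r)
      if (m %in% names(dd)) unname(dd[m]) else Inf
    }, pair_d$r, pair_d$m)
    L <- min(pair_d$d)
    expect_equal(hep$min_length, L)
    if (is.finite(L)) {
      expect_setequal(hep$start_nodes, unique(pair_d$r[pair_d$d == L]))
      expect_setequal(hep$end_nodes, unique(pair_d$m[pair_d$d == L]))
      expect_equal(L == 0, length(intersect(receptors, dep$molecules)) > 0)
    } else {
      expect_length(hep$start_nodes, 0)
      expect_length(hep$end_nodes, 0)
    }
  }
})

test_that("a receptor inside M(d) gives HEP length zero with itself in S and E", {
  net <- build_network(rbind(edge_row("T", "R"), edge_row("R", "G")))
  dep <- infer_deps(net, "T", "G")
  expect_true("R" %in% dep$molecules)
  hep <- infer_heps(net, "R", dep)
  expect_equal(hep$min_length, 0)
  expect_equal(hep$start_nodes, "R")
  expect_equal(hep$end_nodes, "R")
})

test_that("disconnected receptors give an unreachable HEP set", {
  net <- build_network(rbind(edge_row("T", "G"), edge_row("R", "Q")))
  dep <- infer_deps(net, "T", "G")
  hep <- infer_heps(net, "R", dep)
  expect_equal(hep$min_length, Inf)
  expect_length(hep$start_nodes, 0)
  expect_length(hep$end_nodes, 0)
})

test_that("adding arcs never increases the HEP length", {
  g <- random_digraph(10, 0.15, 33)
  net <- build_network(g$records)
  ids <- net$nodes$id
  set.seed(33)
  targets <- sample(ids, 2); genes <- sample(ids, 2); receptors <- sample(ids, 2)
  L1 <- infer_heps(net, receptors, infer_deps(net, targets, genes))$min_length
  extra <- edge_row(sample(ids, 6, replace = TRUE), sample(ids, 6, replace = TRUE))
  extra <- extra[extra$src != extra$dst, ]
  net2 <- build_network(rbind(g$records, extra))
  L2 <- infer_heps(net2, receptors, infer_deps(net2, targets, genes))$min_length
  expect_lte(L2, L1)
})

test_that("mechanism report counts paths and labels node roles", {
  w <- toy_world()
  dep <- infer_deps(w$network, c("T1", "T2"), c("S1", "S2"))
  hep <- infer_heps(w$network, c("R1", "R2"), dep)
  rep <- mechanism_report(dep, hep)
  expect_equal(rep$n_dep_paths, 3)
  expect_equal(rep$n_hep_paths, 2)
  expect_true(rep$crosstalk_found)
  roles <- setNames(rep$nodes$roles, rep$nodes$id)
  expect_equal(unname(roles["T1"]), "drug_target")
  expect_equal(unname(roles["S2"]), "disease_gene")
  expect_equal(unname(roles["R1"]), "hormone_receptor")
  expect_equal(unname(roles["b1"]), "intermediate")

  rep2 <- mechanism_report(dep, infer_heps(w$network, character(0), dep))
  expect_false(rep2$crosstalk_found)
  expect_equal(rep2$n_hep_paths, 0)

  # a node that is both target and disease gene carries both roles
  net <- build_network(rbind(edge_row("T", "X"), edge_row("X", "G")))
  dep2 <- infer_deps(net, "T", c("T", "G"))
  hep2 <- infer_heps(net, "T", dep2)
  rep3 <- mechanism_report(dep2, hep2)
  r <- setNames(rep3$nodes$roles, rep3$nodes$id)
  expect_match(unname(r["T"]), "drug_target;disease_gene;hormone_receptor")
})
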