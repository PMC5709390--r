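test_that("gold extraction keeps directed hormone-to-drug rows with known class", {
  ddi <- data.frame(
    actor = c("H1", "D2", "H1"),
    recipient = c("D1", "H1", "D3"),
    relation_class = c("enhances", "disturbs", "unknown"),
    stringsAsFactors = FALSE)
  gold <- extract_gold_standard(ddi, hormones = "H1",
                                disease_drugs = c("D1", "D3"))
  expect_equal(nrow(gold), 1)
  expect_equal(gold$hormone, "H1")
  expect_equal(gold$drug, "D1")

  # hormone acting on a drug that does not treat the disease is excluded
  expect_warning(
    gold2 <- extract_gold_standard(ddi, hormones = "H1", disease_drugs = "D9"),
    "empty")
  expect_warning(
    gold3 <- extract_gold_standard(ddi, hormones = "H9", disease_drugs = "D1"),
    "empty")
  expect_equal(nrow(gold2) + nrow(gold3), 0)

  expect_error(extract_gold_standard(ddi[, 1:2], "H1", "D1"),
               "missing required column")
})

test_that("unlabeled sampling is sized, gold-disjoint and seed-reproducible", {
  hormones <- sprintf("H%02d", 1:10)
  drugs <- sprintf("D%02d", 1:5)
  gold <- data.frame(hormone = c("H01", "H02", "H03"),
                     drug = c("D01", "D02", "D03"), stringsAsFactors = FALSE)
  ds <- sample_unlabeled(hormones, drugs, gold, multiplier = 10, seed = 4)
  expect_length(ds$replicates, 5)
  expect_false(ds$truncated)
  gk <- paste(gold$hormone, gold$drug, sep = "|")
  for (r in ds$replicates) {
    expect_equal(nrow(r), 30)
    expect_false(any(paste(r$hormone, r$drug, sep = "|") %in% gk))
    expect_false(anyDuplicated(paste(r$hormone, r$drug)) > 0)
  }
  keys <- vapply(ds$replicates, function(r)
    paste(r$hormone, r$drug, collapse = ";"), "")
  expect_gt(length(unique(keys)), 1)     # replicates differ

  ds2 <- sample_unlabeled(hormones, drugs, gold, multiplier = 10, seed = 4)
  expect_identical(ds$replicates, ds2$replicates)

  # universe exactly |gold| non-gold pairs: forced identical, not truncated
  h2 <- c("H1", "H2"); d2 <- "D1"
  g2 <- data.frame(hormone = "H1", drug = "D1")
  ds3 <- sample_unlabeled(h2, d2, g2, multiplier = 1, seed = 1)
  expect_false(ds3$truncated)
  expect_true(all(vapply(ds3$replicates, function(r)
    identical(r, ds3$replicates[[1]]), TRUE)))

  # requested size above the universe: take all, flag truncation
  ds4 <- sample_unlabeled(h2, d2, g2, multiplier = 5, seed = 1)
  expect_true(ds4$truncated)
  expect_equal(nrow(ds4$replicates[[1]]), 1)
})

test_that("AUROC handles separation, full ties, and matches the exhaustive pair oracle", {
  expect_equal(compute_auroc(c(3, 4, 5), c(0, 1, 2))$auroc, 1.0)
  expect_equal(compute_auroc(rep(1, 4), rep(1, 6))$auroc, 0.5)

  pos <- c(0.9, 0.8, 0.8, 0.5, 0.3, 0.1)
  neg <- c(0.8, 0.7, 0.5, 0.5, 0.4, 0.2, 0.2, 0.1, 0.0)
  wins <- 0
  for (p in pos) for (n in neg) wins <- wins + (p > n) + 0.5 * (p == n)
  expect_equal(compute_auroc(pos, neg)$auroc, wins / (6 * 9))
  expect_error(compute_auroc(numeric(0), 1), "at least one")
})

test_that("rank-statistic AUROC equals the trapezoidal ROC area", {
  set.seed(10)
  for (rep in 1:200) {
    np <- sample(2:12, 1); nn <- sample(2:12, 1)
    # discretized scores produce plenty of ties
    pos <- round(stats::rnorm(np, mean = 0.5), 1)
    neg <- round(stats::rnorm(nn), 1)
    m <- compute_auroc(pos, neg)
    expect_equal(m$auroc, trapezoid_auroc(pos, neg), tolerance = 1e-12)
  }
})

test_that("label shuffling centers AUROC at one half", {
  set.seed(11)
  scores <- stats::rnorm(40)
  aucs <- replicate(100, {
    lab <- sample(rep(c(TRUE, FALSE), 20))
    compute_auroc(scores[lab], scores[!lab])$auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("AUPR is the non-interpolated step area and is one under separation", {
  m <- compute_auroc(c(5, 6), c(1, 2, 3))
  expect_equal(m$aupr, 1.0)
  # hand case: scores pos {3, 1}, neg {2}; thresholds 3,2,1 ->
  # (rec .5, prec 1), (rec .5, prec .5), (rec 1, prec 2/3)
  m2 <- compute_auroc(c(3, 1), 2)
  expect_equal(m2$aupr, 0.5 * 1 + 0.5 * (2 / 3))
})

test_that("HEP-length comparison matches a hand-computed Welch statistic", {
  out <- compare_hep_lengths(c(0, 0, 1), c(2, 3, 2, 3))
  expect_equal(out$mean_gold, 1 / 3, tolerance = 1e-12)
  expect_equal(out$mean_unlabeled, 2.5)
  expect_equal(out$pct_le1_gold, 100)
  expect_equal(out$pct_le1_unlabeled, 0)
  expect_equal(out$t_stat, -13 / sqrt(7), tolerance = 1e-10)
  expect_lt(out$t_stat, 0)

  # unreachable lengths: excluded from means, counted as "not <= 1"
  out2 <- compare_hep_lengths(c(0, 1, Inf), c(2, Inf))
  expect_equal(out2$mean_gold, 0.5)
  expect_equal(out2$n_unreachable_gold, 1)
  expect_equal(out2$pct_le1_gold, 100 * 2 / 3)

  # degenerate group: test skipped, descriptives still returned
  out3 <- compare_hep_lengths(c(0, Inf), c(2, 3))
  expect_true(is.na(out3$t_stat))
  expect_equal(out3$mean_gold, 0)
})

test_that("identical distributions give a non-significant HEP-length test", {
  set.seed(12)
  x <- sample(0:4, 30, replace = TRUE)
  y <- sample(0:4, 30, replace = TRUE)
  out <- compare_hep_lengths(x, y)
  expect_gt(out$p_value, 0.01)
})

test_that("gold pairs have shorter HEPs than unlabeled pairs in a planted world", {
  world <- generate_world(seed = 21)
  fit <- crosstalk(world$network, world$maps, "Z01")
  keys <- paste(fit$scores$hormone, fit$scores$drug, sep = "|")
  gk <- paste(world$gold$hormone, world$gold$drug, sep = "|")
  out <- compare_hep_lengths(fit$scores$hep_length[keys %in% gk],
                             fit$scores$hep_length[!(keys %in% gk)])
  expect_lt(out$mean_gold, out$mean_unlabeled)
  expect_lt(out$t_stat, 0)
})

test_that("the alpha sweep reuses cached effect paths and matches the default pipeline", {
  world <- generate_world(list(label_noise = 0.2), seed = 31)
  fit <- crosstalk(world$network, world$maps, "Z01")
  sw <- sweep_alpha(fit, world$gold, alphas = c(2, 4, 8), seed = 5)
  expect_equal(nrow(sw), 3)
  ev <- evaluate_scores(fit$scores, world$gold,
                        unique(fit$scores$hormone), unique(fit$scores$drug),
                        multipliers = 10, seed = 5)
  expect_equal(sw$mean_auroc[sw$alpha == 8], mean(ev$auroc))
  sw1 <- sweep_alpha(fit, world$gold, alphas = 8, seed = 5)
  expect_equal(nrow(sw1), 1)
  expect_equal(sw1$mean_auroc, sw$mean_auroc[sw$alpha == 8])
})

test_that("mean AUROC is non-decreasing to a plateau across the alpha sweep", {
  # separation is length-dominated by construction, so heavier decay can
  # only help until the ranking saturates
  world <- generate_world(list(label_noise = 0.1), seed = 41)
  fit <- crosstalk(world$network, world$maps, "Z01")
  sw <- sweep_alpha(fit, world$gold, alphas = 2:10, seed = 7)
  expect_true(all(diff(sw$mean_auroc) >= -1e-9))
  expect_equal(sw$mean_auroc[sw$alpha == 9], sw$mean_auroc[sw$alpha == 10])
})

test_that("receptor ablation only changes scores of hormones using those receptors", {
  world <- generate_world(seed = 51)
  fit <- crosstalk(world$network, world$maps, "Z01")
  victim <- world$gold$hormone[1]
  rec <- world$maps$receptors[[victim]]
  # only the wired receptor is a network node; absent ids warn and are ignored
  net2 <- suppressWarnings(ablate_nodes(world$network, rec))
  fit2 <- crosstalk(net2, world$maps, "Z01")
  changed <- fit$scores$score != fit2$scores$score
  expect_true(all(fit$scores$hormone[changed] == victim))
  v2 <- fit2$scores[fit2$scores$hormone == victim, ]
  expect_true(all(v2$score == 0))
})

test_that("cross-validation folds are stratified and reproducible", {
  gold <- data.frame(hormone = sprintf("H%02d", 1:10), drug = "D1")
  unl <- data.frame(hormone = sprintf("H%02d", 11:40), drug = "D1")
  f1 <- cv_folds(gold, unl, k = 10, times = 3, seed = 9)
  f2 <- cv_folds(gold, unl, k = 10, times = 3, seed = 9)
  expect_identical(f1, f2)
  per <- table(f1$repeat_id, f1$fold, f1$label)
  expect_true(all(per[, , "1"] == 1))   # one gold pair per fold
  expect_true(all(per[, , "0"] == 3))   # identical unlabeled ratio per fold
})
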