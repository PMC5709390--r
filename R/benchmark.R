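# Evaluation harness: gold-standard extraction from classified directional
# drug-drug interactions, unlabeled sampling at several multiplier sizes,
# rank-based AUROC / step-function AUPR, decay-constant sweep and the
# HEP-length comparison between gold and unlabeled pairs.

#' Extract the gold standard from a classified drug-drug interaction table
#'
#' Keeps rows whose actor is a known hormone, whose recipient is a drug
#' treating the disease under study and whose directional relation class is
#' not `unknown`. Direction is preserved: only actor-to-recipient influence
#' counts, so a drug influencing a hormone is never a gold pair.
#'
#' @param ddi A data frame with columns `actor`, `recipient`,
#'   `relation_class` (one of `enhances`, `disturbs`, `adverse`, `unknown`),
#'   or a path to a TSV with those columns.
#' @param hormones Character vector of hormone identifiers.
#' @param disease_drugs Character vector of drugs treating the disease.
#' @return Data frame of gold pairs (`hormone`, `drug`, `relation_class`),
#'   sorted; zero rows (with a warning) when the intersection is empty.
#' @export
extract_gold_standard <- function(ddi, hormones, disease_drugs) {
  if (is.character(ddi) && length(ddi) == 1) {
    ddi <- utils::read.delim(ddi, header = TRUE, sep = "\t",
                             comment.char = "#", colClasses = "character",
                             quote = "", stringsAsFactors = FALSE)
  }
  need <- c("actor", "recipient", "relation_class")
  missing_cols <- setdiff(need, names(ddi))
  if (length(missing_cols) > 0) {
    stop("DDI table is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  keep <- ddi$actor %in% hormones & ddi$recipient %in% disease_drugs &
    ddi$relation_class != "unknown"
  out <- data.frame(hormone = ddi$actor[keep], drug = ddi$recipient[keep],
                    relation_class = ddi$relation_class[keep],
                    stringsAsFactors = FALSE)
  out <- unique(out)
  out <- out[order(out$hormone, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0) warning("gold standard is empty for this disease")
  out
}

#' Sample unlabeled hormone-drug pairs
#'
#' Draws `n_replicates` unlabeled sets, each of size
#' `multiplier * nrow(gold)` (or the whole non-gold pair universe if smaller,
#' with a truncation flag), uniformly without replacement from
#' hormones x disease drugs minus the gold pairs. Replicate `i` uses seed
#' `seed + i - 1`, so the whole dataset is reproducible from `seed`.
#'
#' @param hormones,disease_drugs Character vectors defining the pair universe.
#' @param gold Gold-pair data frame (`hormone`, `drug`).
#' @param multiplier Unlabeled-to-gold size ratio (the study uses
#'   1, 3, 5, 7, 10).
#' @param n_replicates Number of independent unlabeled sets (default 5).
#' @param seed Integer seed.
#' @return An `eval_dataset` object: list with `gold`, `replicates` (list of
#'   pair data frames), `multiplier`, `seeds`, `truncated`.
#' @export
sample_unlabeled <- function(hormones, disease_drugs, gold, multiplier,
                             n_replicates = 5, seed = 1) {
  universe <- expand.grid(hormone = sort(unique(hormones)),
                          drug = sort(unique(disease_drugs)),
                          KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  gold_keys <- paste(gold$hormone, gold$drug, sep = "|")
  universe <- universe[!(paste(universe$hormone, universe$drug, sep = "|")
                         %in% gold_keys), , drop = FALSE]
  rownames(universe) <- NULL
  if (nrow(universe) < 1) stop("no non-gold pairs available to sample")
  want <- multiplier * nrow(gold)
  size <- min(want, nrow(universe))
  seeds <- seed + seq_len(n_replicates) - 1L
  replicates <- lapply(seeds, function(s) {
    set.seed(s)
    idx <- sample.int(nrow(universe), size)
    out <- universe[sort(idx), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
  structure(list(gold = gold, replicates = replicates,
                 multiplier = multiplier, seeds = seeds,
                 truncated = size < want),
            class = "eval_dataset")
}

#' AUROC and AUPR for positive vs negative score vectors
#'
#' AUROC is the Mann-Whitney rank statistic with midrank tie correction,
#' identical to the area under the ROC curve traced by sweeping a score
#' threshold. AUPR is the non-interpolated step-function area under the
#' precision-recall curve. Curve points are emitted at every distinct
#' threshold.
#'
#' @param pos Numeric scores of the positive (gold) pairs.
#' @param neg Numeric scores of the negative (unlabeled) pairs.
#' @return An `eval_metrics` object: `auroc`, `aupr`, `roc_points`,
#'   `pr_points`, `n_pos`, `n_neg`.
#' @export
compute_auroc <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np < 1 || nn < 1) stop("need at least one positive and one negative score")
  r <- rank(c(pos, neg))
  auroc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)

  s <- c(pos, neg)
  y <- rep(c(1L, 0L), c(np, nn))
  ord <- order(s, decreasing = TRUE)
  s <- s[ord]; y <- y[ord]
  # group ties: cumulative TP/FP at the end of each distinct-threshold block
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[last]
  fp <- cumsum(1L - y)[last]
  tpr <- tp / np
  fpr <- fp / nn
  prec <- tp / (tp + fp)
  rec <- tpr
  roc_points <- data.frame(fpr = c(0, fpr), tpr = c(0, tpr))
  pr_points <- data.frame(recall = rec, precision = prec)
  aupr <- sum(diff(c(0, rec)) * prec)

  structure(list(auroc = auroc, aupr = aupr, roc_points = roc_points,
                 pr_points = pr_points, n_pos = np, n_neg = nn),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf("AUROC %.4f, AUPR %.4f (%d positives, %d negatives)\n",
              x$auroc, x$aupr, x$n_pos, x$n_neg))
  invisible(x)
}

score_lookup <- function(scores) {
  stats::setNames(scores$score,
                  paste(scores$hormone, scores$drug, sep = "|"))
}

pair_scores_for <- function(lookup, pairs) {
  keys <- paste(pairs$hormone, pairs$drug, sep = "|")
  miss <- keys[!(keys %in% names(lookup))]
  if (length(miss) > 0) {
    stop("pair(s) missing from score table: ", paste(miss, collapse = ", "))
  }
  unname(lookup[keys])
}

#' Evaluate a score table against gold and unlabeled datasets
#'
#' For every multiplier and replicate, computes AUROC/AUPR of gold pairs
#' against the sampled unlabeled pairs using the supplied score table.
#'
#' @param scores Score data frame covering every evaluated pair (e.g. from a
#'   [crosstalk()] fit, which retains unscorable drugs at score 0 precisely
#'   so dataset sizes stay constant).
#' @param gold Gold-pair data frame.
#' @param hormones,disease_drugs Pair universe for unlabeled sampling.
#' @param multipliers Integer vector of unlabeled-set size multipliers.
#' @param n_replicates Replicates per multiplier (default 5).
#' @param seed Integer seed; replicate seeds are derived per multiplier.
#' @return Data frame with one row per (multiplier, replicate):
#'   `multiplier`, `replicate`, `auroc`, `aupr`, `n_pos`, `n_neg`, `seed`.
#' @export
evaluate_scores <- function(scores, gold, hormones, disease_drugs,
                            multipliers = c(1, 3, 5, 7, 10),
                            n_replicates = 5, seed = 1) {
  if (nrow(gold) < 1) stop("empty gold standard")
  lookup <- score_lookup(scores)
  pos <- pair_scores_for(lookup, gold)
  rows <- list()
  for (mi in seq_along(multipliers)) {
    m <- multipliers[mi]
    ds <- sample_unlabeled(hormones, disease_drugs, gold, m,
                           n_replicates = n_replicates,
                           seed = seed + (mi - 1L) * n_replicates)
    for (ri in seq_along(ds$replicates)) {
      neg <- pair_scores_for(lookup, ds$replicates[[ri]])
      met <- compute_auroc(pos, neg)
      rows[[length(rows) + 1L]] <- data.frame(
        multiplier = m, replicate = ri, auroc = met$auroc, aupr = met$aupr,
        n_pos = met$n_pos, n_neg = met$n_neg, seed = ds$seeds[ri])
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Sweep the decay constant and track mean AUROC
#'
#' Effect paths are computed once in the fit; only the closed-form score is
#' re-evaluated per decay constant, and the same unlabeled datasets are
#' reused across the sweep so the comparison is paired.
#'
#' @param fit A `crosstalk` fit.
#' @param gold Gold-pair data frame.
#' @param alphas Decay constants to evaluate (default 2:10).
#' @param multipliers,n_replicates,seed As in [evaluate_scores()].
#' @return Data frame with columns `alpha` and `mean_auroc`.
#' @export
sweep_alpha <- function(fit, gold, alphas = 2:10,
                        multipliers = 10, n_replicates = 5, seed = 1) {
  stopifnot(inherits(fit, "crosstalk"))
  hormones <- unique(fit$scores$hormone)
  drugs <- unique(fit$scores$drug)
  out <- data.frame(alpha = as.numeric(alphas), mean_auroc = NA_real_)
  for (i in seq_along(alphas)) {
    sc <- predict(fit, alpha = alphas[i])
    ev <- evaluate_scores(sc, gold, hormones, drugs,
                          multipliers = multipliers,
                          n_replicates = n_replicates, seed = seed)
    out$mean_auroc[i] <- mean(ev$auroc)
  }
  out
}

hep_lengths <- function(x) {
  if (is.numeric(x)) return(x)
  vapply(x, function(h) {
    if (inherits(h, "hepset")) h$min_length else as.numeric(h)
  }, 0)
}

#' Compare HEP lengths of gold vs unlabeled pairs
#'
#' Gold pairs are expected to sit closer to the drugs' effect paths than
#' random pairs. Means are taken over finite lengths only (unreachable pairs
#' are counted separately); the percentage of pairs with HEP length zero or
#' one is taken over all pairs, with unreachable counted as "not <= 1". The
#' difference in mean length is tested with a Welch two-sample t-test when
#' both groups have at least two finite lengths.
#'
#' @param gold_heps,unlabeled_heps Numeric HEP-length vectors (may contain
#'   `Inf`) or lists of `hepset` objects.
#' @return List with `mean_gold`, `mean_unlabeled`, `pct_le1_gold`,
#'   `pct_le1_unlabeled` (percent), `n_unreachable_gold`,
#'   `n_unreachable_unlabeled`, `t_stat`, `p_value` (NA when the test is
#'   skipped).
#' @export
compare_hep_lengths <- function(gold_heps, unlabeled_heps) {
  g <- hep_lengths(gold_heps)
  u <- hep_lengths(unlabeled_heps)
  gf <- g[is.finite(g)]
  uf <- u[is.finite(u)]
  t_stat <- NA_real_; p_value <- NA_real_
  if (length(gf) >= 2 && length(uf) >= 2 &&
      (stats::var(gf) > 0 || stats::var(uf) > 0)) {
    tt <- stats::t.test(gf, uf)
    t_stat <- unname(tt$statistic)
    p_value <- tt$p.value
  }
  list(
    mean_gold = if (length(gf) > 0) mean(gf) else NA_real_,
    mean_unlabeled = if (length(uf) > 0) mean(uf) else NA_real_,
    pct_le1_gold = 100 * mean(g <= 1),
    pct_le1_unlabeled = 100 * mean(u <= 1),
    n_unreachable_gold = sum(!is.finite(g)),
    n_unreachable_unlabeled = sum(!is.finite(u)),
    t_stat = t_stat, p_value = p_value
  )
}

#' Stratified cross-validation folds over an evaluation dataset
#'
#' Splits gold and one unlabeled replicate into `k` folds, each preserving
#' the positive:unlabeled ratio, repeated `times` times with fresh seeded
#' shuffles. Fold membership is returned; model scoring itself needs no
#' training, so folds are consumed by scoring the test fold only.
#'
#' @param gold Gold-pair data frame.
#' @param unlabeled Unlabeled-pair data frame.
#' @param k Number of folds (default 10).
#' @param times Number of repeats (default 30).
#' @param seed Integer seed.
#' @return Data frame with columns `repeat_id`, `fold`, `hormone`, `drug`,
#'   `label` (1 gold / 0 unlabeled).
#' @export
cv_folds <- function(gold, unlabeled, k = 10, times = 30, seed = 1) {
  mk <- function(df, label, s) {
    set.seed(s)
    idx <- sample.int(nrow(df))
    data.frame(hormone = df$hormone[idx], drug = df$drug[idx],
               label = label,
               fold = rep_len(seq_len(k), nrow(df)),
               stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(times), function(r) {
    g <- mk(gold, 1L, seed + 2L * (r - 1L))
    u <- mk(unlabeled, 0L, seed + 2L * (r - 1L) + 1L)
    cbind(repeat_id = r, rbind(g, u))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
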