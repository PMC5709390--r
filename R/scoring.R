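# The decay score of a hormone-drug pair:
#   i(h, d) = alpha^(-L) * n(S) * n(E)
# with L the HEP length, n(S)/n(E) the distinct HEP start/end node counts and
# alpha > 1 a decay constant. An unreachable HEP (L = Inf) scores exactly 0.

#' Score a hormone-drug pair from its hormone effect paths
#'
#' @param hep A `hepset` (see [infer_heps()]).
#' @param alpha Decay constant, must exceed 1 (default 8, the saturation
#'   point of the decay sweep).
#' @return One-row data frame with columns `hep_length`, `n_start`, `n_end`,
#'   `alpha`, `score`.
#' @export
score_from_hep <- function(hep, alpha = 8) {
  stopifnot(inherits(hep, "hepset"))
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 1) {
    stop("alpha must be a single number > 1")
  }
  L <- hep$min_length
  score <- if (is.finite(L)) {
    alpha^(-L) * length(hep$start_nodes) * length(hep$end_nodes)
  } else 0
  data.frame(hep_length = L, n_start = length(hep$start_nodes),
             n_end = length(hep$end_nodes), alpha = alpha, score = score)
}

#' Score all hormone-drug pairs of a disease
#'
#' The central fitting function. For every drug treating `disease`, drug
#' effect paths are inferred once; every hormone is then scored against each
#' drug via its hormone effect paths and the decay score. Drugs whose targets
#' are all absent from the network are retained with score 0 and an
#' `unscorable` flag so that evaluation dataset sizes stay constant.
#'
#' @param network A `molnet` object.
#' @param annotations An `annot_maps` object (see [read_annotations()]).
#' @param disease Disease identifier (must appear in
#'   `annotations$disease_drugs` and `annotations$disease_genes`).
#' @param hormones Hormones to score; defaults to every hormone with
#'   receptors.
#' @param alpha Decay constant (> 1).
#' @param cap Shortest-path listing cap (never affects scores).
#' @return A `crosstalk` object: list with `scores` (one row per
#'   hormone-drug pair), `deps` (per drug), `heps` (per hormone|drug),
#'   `disease`, `alpha`, `call`.
#' @export
crosstalk <- function(network, annotations, disease,
                      hormones = names(annotations$receptors),
                      alpha = 8, cap = 100) {
  stopifnot(inherits(network, "molnet"), inherits(annotations, "annot_maps"))
  if (!disease %in% names(annotations$disease_genes)) {
    stop("disease has no disease genes: ", disease)
  }
  drugs <- annotations$disease_drugs[[disease]]
  if (is.null(drugs) || length(drugs) == 0) {
    stop("disease has no treating drugs: ", disease)
  }
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 1) {
    stop("alpha must be a single number > 1")
  }
  hormones <- sort(hormones)
  drugs <- sort(drugs)
  genes <- annotations$disease_genes[[disease]]

  deps <- lapply(drugs, function(d) {
    tg <- annotations$targets[[d]]
    if (is.null(tg) || length(tg) == 0 || !any(has_node(network, tg)) ||
        !any(has_node(network, genes))) {
      return(new_depset(list(), character(0), 0, unscorable = TRUE))
    }
    suppressWarnings(infer_deps(network, tg, genes, cap = cap))
  })
  names(deps) <- drugs

  heps <- list()
  rows <- vector("list", length(hormones) * length(drugs))
  k <- 0L
  for (h in hormones) {
    rec <- annotations$receptors[[h]]
    for (d in drugs) {
      hep <- if (is.null(rec) || deps[[d]]$unscorable) {
        new_hepset(Inf, character(0), character(0), list())
      } else {
        infer_heps(network, rec, deps[[d]], cap = cap)
      }
      heps[[paste(h, d, sep = "|")]] <- hep
      k <- k + 1L
      rows[[k]] <- cbind(
        data.frame(hormone = h, drug = d, disease = disease,
                   stringsAsFactors = FALSE),
        score_from_hep(hep, alpha),
        data.frame(unscorable = deps[[d]]$unscorable)
      )
    }
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  structure(list(scores = scores, deps = deps, heps = heps,
                 disease = disease, alpha = alpha, call = match.call()),
            class = "crosstalk")
}

#' @export
print.crosstalk <- function(x, ...) {
  cat("Hormone-drug crosstalk scores for disease ", x$disease,
      " (alpha = ", x$alpha, ")\n", sep = "")
  cat("  ", length(unique(x$scores$hormone)), " hormone(s) x ",
      length(unique(x$scores$drug)), " drug(s) = ",
      nrow(x$scores), " pair(s); ",
      sum(x$scores$score > 0), " with finite effect paths\n", sep = "")
  invisible(x)
}

#' @export
summary.crosstalk <- function(object, top = 10, ...) {
  sc <- rank_scores(object$scores)
  finite <- is.finite(sc$hep_length)
  structure(list(
    disease = object$disease, alpha = object$alpha,
    n_pairs = nrow(sc), n_finite = sum(finite),
    length_table = table(sc$hep_length[finite]),
    top = utils::head(sc, top)
  ), class = "summary.crosstalk")
}

#' @export
print.summary.crosstalk <- function(x, ...) {
  cat("Crosstalk summary for disease ", x$disease,
      " (alpha = ", x$alpha, ")\n", sep = "")
  cat("  pairs scored:", x$n_pairs, "of which", x$n_finite,
      "have a finite HEP length\n")
  if (length(x$length_table) > 0) {
    cat("  HEP length distribution:\n")
    print(x$length_table)
  }
  cat("  top pairs:\n")
  print(x$top, row.names = FALSE)
  invisible(x)
}

#' @export
coef.crosstalk <- function(object, ...) {
  stats::setNames(object$scores$score,
                  paste(object$scores$hormone, object$scores$drug, sep = "|"))
}

#' Re-evaluate scores at a different decay constant
#'
#' HEP statistics are cached in the fit, so changing `alpha` is a closed-form
#' re-evaluation with no path search.
#'
#' @param object A `crosstalk` fit.
#' @param alpha New decay constant (> 1); default keeps the fitted one.
#' @param ... Unused.
#' @return The scores data frame with the `alpha` and `score` columns
#'   recomputed.
#' @export
predict.crosstalk <- function(object, alpha = object$alpha, ...) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 1) {
    stop("alpha must be a single number > 1")
  }
  sc <- object$scores
  sc$alpha <- alpha
  sc$score <- ifelse(is.finite(sc$hep_length),
                     alpha^(-sc$hep_length) * sc$n_start * sc$n_end, 0)
  sc
}

#' @export
plot.crosstalk <- function(x, top = 15, ...) {
  sc <- rank_scores(x$scores)
  sc <- utils::head(sc[sc$score > 0, , drop = FALSE], top)
  if (nrow(sc) == 0) {
    warning("no positive scores to plot")
    return(invisible(x))
  }
  graphics::barplot(rev(sc$score),
                    names.arg = rev(paste(sc$hormone, sc$drug, sep = " | ")),
                    horiz = TRUE, las = 1,
                    xlab = "crosstalk score",
                    main = paste("Top hormone-drug pairs,", x$disease), ...)
  invisible(x)
}

# Deterministic ranking: score descending, ties by (hormone, drug).
rank_scores <- function(scores) {
  ord <- order(-scores$score, scores$hormone, scores$drug)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Select novel candidate pairs from a score table
#'
#' Candidate criteria: rank within the top `top_k` by score (ties broken
#' lexicographically by hormone then drug id), score strictly above
#' `min_score`, and not already in the gold standard (i.e. unlabeled).
#'
#' @param scores Score data frame (from a `crosstalk` fit or
#'   [predict.crosstalk()]).
#' @param gold Data frame with `hormone` and `drug` columns, or a character
#'   vector of `"hormone|drug"` keys.
#' @param top_k Rank cutoff (default 10).
#' @param min_score Score threshold (default 1.0, strict).
#' @return The filtered, ranked score rows.
#' @export
select_candidates <- function(scores, gold, top_k = 10, min_score = 1.0) {
  keys <- if (is.data.frame(gold)) {
    paste(gold$hormone, gold$drug, sep = "|")
  } else as.character(gold)
  ranked <- rank_scores(scores)
  keep <- ranked$rank <= top_k & ranked$score > min_score &
    !(paste(ranked$hormone, ranked$drug, sep = "|") %in% keys)
  out <- ranked[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
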