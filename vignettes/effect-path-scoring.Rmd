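---
title: "Scoring hormone-drug crosstalk with network effect paths"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring hormone-drug crosstalk with network effect paths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathcross)
```

## The problem and the model

Endogenous hormones can change the efficacy of drugs: their receptors sit on
signaling routes that intersect the molecular mechanism through which a drug
reaches its disease. `pathcross` quantifies that potential interference on a
heterogeneous molecular interaction network whose nodes are genes (proteins
are represented by their encoding genes) and chemical compounds, and whose
arcs are signaling, gene-regulatory and physical interactions. Physical
protein-protein and binding interactions are symmetric and are realized as
reciprocal arcs; signaling and regulatory interactions keep their direction.

Two path constructs carry the model:

* **Drug effect paths (DEPs).** For a drug $d$ treating a disease, each drug
  target is paired with its *nearest* disease gene(s) by breadth-first
  search, and all shortest paths from the target to those genes are
  collected. Distances count edges, so a path of three molecules has length
  two, and a target that is itself a disease gene contributes a path of
  length zero. The union of all nodes on all DEPs — targets, intermediates
  and disease genes — is the molecule set $M(d)$, the proxy for the drug's
  mechanism of action. Disease genes cluster in network neighborhoods, which
  is why a per-target nearest-gene search (rather than paths to every
  disease gene) is a defensible mechanism proxy.

* **Hormone effect paths (HEPs).** Hormones are not network nodes; their
  influence enters through their receptors $R(h)$. Among all shortest paths
  from any receptor to any molecule of $M(d)$, the HEPs are those achieving
  the *globally* minimal length
  $L = \min_{r \in R(h),\, m \in M(d)} d(r, m)$. The start set $S$ holds the
  receptors achieving $L$ and the end set $E$ the $M(d)$ molecules achieving
  it; receptors or molecules with longer routes are excluded, because only
  the very shortest paths are taken to carry crosstalk.

The pair score is an exponential decay in the HEP length weighted by how
broad the crosstalk front is:

$$ i(h, d) = \alpha^{-L} \cdot n(S) \cdot n(E), \qquad \alpha > 1. $$

When no receptor reaches $M(d)$, $L = \infty$ and the score is exactly 0
(`Inf` is the package's unreachability sentinel; `alpha^-Inf` evaluates to 0
in floating point, so no special-casing is needed downstream).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha` | 8 | Decay base, dimensionless, sensible over roughly 2–10. Larger values punish each extra path step harder. AUROC on the evaluation harness saturates well before 8 on planted worlds, and 8 is the conventional saturation choice, so it is the default. `predict(fit, alpha = ...)` re-evaluates the closed form from cached HEP statistics without re-running any path search. |
| `cap` | 100 | Maximum number of shortest paths *listed* per (source, sink) pair. Path counts are computed exactly on the breadth-first predecessor DAG and $M(d)$ is assembled from the full shortest-path node set, so the cap affects reporting only — never a distance, count or score. Shortest-path counts can grow exponentially (a depth-$k$ diamond lattice has $2^k$ of them), hence the cap. |
| `multipliers` | 1, 3, 5, 7, 10 | Unlabeled-to-gold size ratios for evaluation. |
| `n_replicates` | 5 | Independently sampled unlabeled sets per multiplier; replicate $i$ uses seed `seed + i - 1`. |

## Evaluation protocol

Gold-standard pairs are extracted from a *directional* classified drug-drug
interaction table: a row is kept when the acting drug is a known hormone,
the recipient treats the disease under study, and the relation class
(enhances / disturbs / adverse) is not `unknown`. Unlabeled pairs are drawn
uniformly without replacement from hormones × disease drugs minus the gold
pairs — they are presumed negatives, not verified ones, which is why
multiple replicates and multiple sizes are evaluated. Gold pairs of *other*
diseases are not excluded from the unlabeled universe; whether they should
be is genuinely open, and excluding only the current disease's gold set is
the more conservative choice (it can only deflate measured AUROC).

AUROC is computed as the Mann–Whitney rank statistic with midrank tie
correction — ties get credit 1/2, which equals the trapezoidal area under
the threshold-swept ROC curve (the test suite asserts this equivalence to
1e-12 against an independently coded trapezoid). AUPR is the
non-interpolated step-function area. Unreachable pairs enter the ranking at
score 0; a fully tied comparison gives AUROC 0.5 by construction.

The HEP-length comparison between gold and unlabeled pairs uses a Welch
two-sample t-test on *finite* lengths (a mean over lengths including
infinity is undefined; unreachable pairs are counted separately and count
as "not ≤ 1" in the short-path percentage). The compared quantity is a
scalar mean length per group, so a univariate two-sample test is the
appropriate instrument; the test is skipped (descriptives still returned)
when either group has fewer than two finite lengths or both are constant.

## The synthetic worlds

`toy_world()` is a fixed 14-node network with one drug (targets T1, T2),
one disease (genes S1, S2) and one hormone (receptors R1, R2), wired so
that every definitional quantity is hand-checkable: T1 reaches S1 in 3
steps by one path, T2 reaches S2 in 2 steps by two paths (three DEPs in
total), and R1 reaches T2 in 2 steps by two routes while R2 needs 3 to
reach S1 — so the HEPs have length 2 with $S = \{R1\}$, $E = \{T2\}$ and
the pair scores $8^{-2} = 0.015625$ at the default decay.

`generate_world()` builds seeded random worlds with *planted* signal. Its
defaults are fixed study conditions, not tuning knobs: 14 hormones (10 of
them forming planted gold pairs with 8 drugs of one disease, round-robin),
2 receptors per hormone, 2 targets per drug, 10 disease genes, a filler
background of 160 genes and 12 compounds at arc density 0.03 with a 30%
bidirectional PPI fraction, planted HEP length 1 and background minimum
length 4. These sizes are in the range of a small disease module study and
keep the full 5 × 5 evaluation grid plus the decay sweep comfortably inside
interactive runtimes. Construction, not hope, guarantees the length
contract: receptors are fresh nodes whose only outgoing arc starts a fresh
chain (length 1 for gold hormones, length 4 for background hormones) ending
at a drug target; target-to-disease-gene chains have length
`background_min_length - planted_hep_length` (3 by default), so even a gold
hormone's route to a *different* drug of the same disease is at least
1 + 3 = 4; and the random filler subgraph is self-contained, so it cannot
shortcut any receptor-to-mechanism route. `verify_world()` re-derives every
HEP length with the path machinery and checks the contract post hoc.

Label noise (`label_noise`) swaps a fraction of planted pairs out of the
gold table and an equal number of background pairs in, without rewiring.
This models annotation error — the main imperfection of a curated gold
standard — and produces realistic sub-1 AUROC regimes. What the synthetic
worlds deliberately do *not* emulate: hub-dominated degree distributions,
correlated false edges, literature bias in which interactions are known,
and incomplete receptor annotations. Perfect recovery on planted worlds
therefore validates the machinery (distances, counting, set assembly,
scoring, ranking), not real-data performance, which depends on the quality
of the interaction and annotation databases supplied.

## Numerical and design choices

* **Ties at the nearest disease gene.** When several disease genes are
  equally nearest to a target, all of them are kept as DEP endpoints. The
  tie case is not otherwise specified by the construct's definition, and
  keeping all is the only order-independent deterministic choice.
* **Nearest is per target, not global**: each target pairs with its own
  nearest gene(s), so a drug's DEPs can mix lengths.
* **$S$ and $E$ are restricted to pairs achieving the global minimum**, not
  to every receptor with a finite route — HEPs are the very shortest paths
  only, and $n(S)$, $n(E)$ count nodes involved in them.
* **Receptors may coincide with drug targets or disease genes**; roles are
  unioned, never exclusive, and a receptor inside $M(d)$ gives $L = 0$ with
  itself in both $S$ and $E$.
* **Deterministic ordering everywhere**: path listings are lexicographic by
  node-id sequence, score tables break ties by (hormone, drug), and all
  set-valued outputs are sorted, so reports are byte-reproducible.
* **Conflicting edge directions** (`A→B` directed plus `A–B` bidirectional)
  union to both reciprocal arcs with the directed label only on `A→B` —
  the most permissive reachability consistent with the records.
* **Unscorable drugs** (no target in the network) stay in the score table
  at score 0 with a flag, keeping evaluation dataset sizes constant across
  replicates.
* **Identifier namespaces are opaque strings.** Conventionally genes are
  Entrez-style and compounds KEGG-style ids, but nothing is validated
  against a registry; the method is id-agnostic and synthetic ids are
  first-class. Which curated relation type defines the disease-to-treating-
  drug map is left to the data supplier: the loader accepts any pre-filtered
  two-column table.

## Known limitations

* The network is unweighted; all arcs count equally regardless of evidence
  strength or interaction sign (activation and inhibition both conduct
  "influence").
* Gold standards derived from drug-drug interaction descriptions are small
  and noisy; unlabeled sampling treats unknown pairs as negatives, so all
  reported AUROC/AUPR values are positive-unlabeled estimates, biased
  downward when true interactions hide among the unlabeled pairs.
* Hormone concentration, tissue specificity and direction of effect
  (enhancing vs disturbing) are outside the score; the relation class is
  carried through extraction but not modeled.
* Path enumeration is exponential in the worst case; only counts and
  distances are exact at scale, listings are capped.
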