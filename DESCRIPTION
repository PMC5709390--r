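Package: pathcross
Title: Network Effect-Path Scoring of Hormone-Drug Crosstalk
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores the potential of an endogenous hormone to interfere with a
    drug's efficacy for a disease by tracing effect paths on a heterogeneous
    molecular interaction network. Drug effect paths (DEPs) are all shortest
    paths from each drug target to its nearest disease gene; hormone effect
    paths (HEPs) are the very shortest paths from the hormone's receptors to
    any DEP molecule. Each hormone-drug pair is scored by an exponential decay
    of the HEP length weighted by the numbers of distinct HEP start and end
    nodes. Includes TSV readers/writers for edge and annotation tables,
    breadth-first shortest-path machinery with exact path counting, a
    gold-standard/unlabeled-sampling evaluation harness (AUROC/AUPR, decay
    sweep, HEP-length comparison, receptor ablation), and a seeded synthetic
    world generator with planted crosstalk signal.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
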