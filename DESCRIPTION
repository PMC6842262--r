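Package: randsig
Title: Gene Prioritization from Significant Random Survival Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines random gene signatures that are significantly associated
    with survival outcome under both a nominal Cox/log-rank p-value and a
    permutation-based empirical p-value, scores genes by their occurrence in
    the selected signatures, diffuses the scores over a weighted
    protein-protein interaction network with the heat (diffusion) kernel of
    the graph Laplacian, and calls significant genes by a permutation
    procedure. Includes per-patient weighted pathway scores with a
    phenotype-separation test, exact Wilcoxon rank-sum inference with a
    bootstrap variant, readers for expression/survival/GMT/STRING-style
    formats, and a synthetic-data generator (survival cohort with a planted
    driver module, scale-free weighted network, size-matched signature
    templates) so the full pipeline runs end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    survival,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
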