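Package: strainopt
Title: Computational Strain Optimization over Constraint-Based Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A workbench for computational strain optimization. Loads
    constraint-based metabolic models (SBML Level 3 FBC or a plain JSON
    dialect), simulates phenotypes with flux balance analysis and its
    mutant-prediction variants (pFBA, FVA, lMOMA, ROOM, MOMA), integrates
    Boolean transcriptional regulation (rFBA, srFBA) and protein-pool
    enzymatic constraints, and searches for sets of genetic modifications
    (deletions, over- and under-expression of reactions, genes, enzymes or
    regulatory variables) that maximize production objectives such as the
    biomass-product coupled yield (BPCY) and the weighted product yield
    (WYIELD) using single- and multi-objective evolutionary algorithms
    (GA, SA, NSGA-II).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    quadprog,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse
Config/testthat/edition: 3
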