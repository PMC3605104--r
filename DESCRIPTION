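Package: gemkit
Title: Reconstruction, Quality Control and Simulation of Genome-Scale Metabolic Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolbox for semi-automated reconstruction and analysis of
    genome-scale metabolic models (GEMs). Builds draft models from template
    GEMs via bidirectional-best-hit orthology or from orthology-group reaction
    databases; reads and writes SBML and a tabular workbook dialect; runs the
    quality-control suite of mixed-integer gap diagnostics (free-lunch
    detection, producibility, dead-end classification, minimal gap filling);
    assigns enzymes to subcellular compartments by simulated annealing against
    localization-predictor scores; simulates phenotypes with flux balance
    analysis, MoMA, deletion screens and maintenance/P-O parameter fitting;
    and integrates transcriptome data through flux-space sampling and
    Reporter Metabolite scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    quadprog,
    xml2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    readxl,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
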