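Package: pepscope
Title: Peptide Interaction Analysis for Coarse-Grained and Atomistic Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale analysis of peptide-membrane and peptide-receptor
    molecular trajectories, sequence conservation and assay dose-response
    data. Provides trajectory containers with periodic-boundary geometry,
    single-linkage aggregation clustering, per-residue lipid contact
    profiles, Shrake-Rupley solvent-accessible surface area, divalent-ion
    displacement series, Kabsch superposition and RMSD, geometric detectors
    for cation-pi, pi-stacking and hydrogen-bond interactions with
    occupancy statistics, multiple-sequence-alignment conservation and
    consensus analysis with reference-position mapping, Nei-Gojobori
    dN/dS selection metrics, four-parameter logistic and 1:1 binding
    fits, and a therapeutic-index calculator. Synthetic-data generators
    with planted ground truth make every analysis stage testable without
    external simulation or assay data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    withr,
    ggplot2,
    igraph,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
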