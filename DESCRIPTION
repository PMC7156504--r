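Package: tpbla
Title: Directed-Evolution Analytics for Tripartite Beta-Lactamase Aggregation Screens
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of in vivo tripartite beta-lactamase
    (TPBLA) aggregation screens. Scores antibiotic survival curves by
    trapezoidal area (in vivo growth score), aggregates replicates, ranks
    variants and picks representatives spaced by replicate error; profiles
    error-prone PCR libraries into per-residue mutational frequencies with
    two-sigma hotspot calling, substitution spectra and bias-weighted
    expected substitution frequencies; enumerates single-base codon
    neighbourhoods and hydropathy-ordered reachable amino-acid sets; computes
    Shrake-Rupley solvent accessibility normalised to residue-type maxima;
    and ships a seeded error-prone PCR / phenotype / plate-selection
    simulator so the whole screen can be exercised end to end without
    laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Sequencing, MutationDetection, Software
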