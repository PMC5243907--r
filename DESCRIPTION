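Package: pxdscout
Title: Homozygosity Filtering and Candidate-Variant Discovery for Recessive Canine Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for Mendelian recessive disease-gene discovery
    from whole-genome variant calls, modelled on the strategy used to map
    canine paroxysmal dyskinesia to a hypomorphic PIGN missense allele.
    It annotates variants with coding consequences and HGVS c./p.
    nomenclature against simple gene models, filters case variants with the
    three-criteria rule (amino-acid-altering, homozygous in the case, absent
    from a control-genome variant store), intersects candidate sets across
    cases, calls biallelic genotypes from two-channel endpoint-fluorescence
    data and evaluates recessive segregation and case/control association,
    and summarises residue conservation in ortholog alignment columns. A
    seeded synthetic-data generator produces every input the pipeline
    consumes, with a planted causal variant and a truth manifest, so the
    whole analysis is exercisable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
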