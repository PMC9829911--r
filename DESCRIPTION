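Package: codonopt
Title: Codon Optimality from Measured tRNA Pools and Ribosome Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes tRNA adaptability of codons (TAc) from sequencing-based
    tRNA abundance measurements with wobble base-pairing penalties, for
    organisms such as Mycobacterium tuberculosis that carry single-copy tRNA
    genes and where gene copy number is uninformative. Combines TAc with
    demand-normalized codon usage (nCU) into codon (cOpt) and mRNA (mOpt)
    optimality scores with interquartile-range outlier calling, and provides
    ribosome-profiling utilities (gene filtering, metagene P-site offset
    estimation, A-site codon pause scores) plus seeded synthetic-data
    generators for the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
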