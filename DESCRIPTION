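Package: codonscope
Title: Codon Usage Statistics for Coding Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: BLAST-guided extraction of in-frame coding regions from
    assembled transcriptomes and the classical codon-usage statistics
    computed on them: codon counts, relative synonymous codon usage
    (RSCU), GC content by codon position, synonymous third-position GC
    (GC3s), Wright's effective number of codons (Nc), the codon bias
    index (CBI) and frequency of optimal codons (Fop), correspondence
    analysis of per-gene codon usage, dinucleotide observed/expected
    ratios, a within-sequence codon-bias flagging statistic, and a
    simulated expected-Nc null curve.  A seeded synthetic transcriptome
    generator with matching BLAST-tabular fixtures makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    seqinr,
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
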