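Package: transeval
Title: Consistency Evaluation of De Novo Transcriptome Assembly Metrics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates EST/cDNA sequencing of a transcript set under a rank
    power-law expression model with length-proportional sampling, builds
    "perfect" assemblies from read provenance (contigs from reads overlapping
    by at least one base, with error-free consensus and error-corrected
    singletons), and computes a suite of assembly quality metrics over contigs
    and unigenes: counts, read usage, N50, coverage, read-count dispersion,
    annotation rarefaction, ortholog hit ratio and its error decomposition,
    reciprocal best hits, collapse factors and reverse rarefaction. A ladder
    runner varies sequencing depth and read length and classifies each
    metric's behaviour as consistent or fully consistent. Includes a synthetic
    transcriptome generator (isoforms, paralog families, UTRs, diverged
    reference sets) so every metric can be exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
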