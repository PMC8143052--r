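Package: mapbyseq
Title: Mapping-by-Sequencing of EMS-Induced Point Mutations and Large
    Insertions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for mapping-by-sequencing experiments in forward
    genetics. Implements bulked-segregant linkage mapping of point
    mutations induced by ethyl methanesulfonate (EMS) from pooled
    test/control short-read samples (four backcross/outcross experimental
    designs, two variant-filtering stringency levels), tagged-sequence
    mapping of large insertions of known sequence (T-DNA, transposons)
    from junction and discordant-mate evidence, a desk-scale seeded read
    aligner and polymorphic-site caller, functional-effect annotation of
    candidate mutations with genotyping-primer design, and a seeded
    experiment simulator (EMS mutagenesis, F2 pool construction under
    recombination with phenotypic selection, paired/single-end read
    generation, insertion lines) that provides ground truth for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    grDevices,
    graphics,
    methods,
    rtracklayer,
    stats,
    utils,
    vcfR,
    withr
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
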