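Package: mtxsim
Title: Simulation and Annotation-Accuracy Evaluation of Metatranscriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates 454- and Illumina-style metatranscriptome read sets from
    microbial community profiles with known per-read provenance, and scores
    protein-domain annotations obtained after data reduction (sequence
    clustering, assembly) against the known domain content of the sample.
    Community coverage profiles are scaled to discrete organism abundances,
    per-gene expression follows a bounded discrete power law, and reads are
    drawn from the resulting weighted transcript pool with pluggable
    platform-style error models. Downstream utilities translate sequences into
    their longest open reading frames, run a reference greedy clusterer and a
    clustering parameter sweep, ingest CD-HIT cluster files and SAM
    read-to-contig mappings, transfer annotations from cluster representatives
    to members, and report true/false positive, true negative and potential
    domain counts, weighted domain-content correlations, and contig
    read-provenance entropy. A fully synthetic fixture generator with planted
    amino-acid motif domains makes every stage testable without external
    genome or domain databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    graphics,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    Rsamtools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    seqinr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
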