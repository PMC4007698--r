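Package: gcmosaic
Title: Compositional Compartmentalization of Genomes into GC Segments and Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the compositional organization of genome assemblies by
    partitioning chromosomes into fixed non-overlapping GC windows, merging
    windows into compositionally homogeneous segments, pooling segments into
    0.5%-GC bins to obtain distributions of DNA by weight, and detecting
    compositional families classified against the vertebrate isochore scheme
    (L1, L2, H1, H2, H3). Also computes codon-position GC (GC1, GC2, GC3)
    for coding-sequence sets and fits orthogonal (major-axis) regressions
    between codon positions and between orthologous gene sets of two species.
    Includes a synthetic-data module that generates compartmentalized genomes
    and ortholog CDS sets with known ground truth, so every stage of the
    pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    MASS,
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
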