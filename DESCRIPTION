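Package: circweld
Title: Circularization of Long-Read Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly detection and resolution of circular replicons
    (bacterial chromosomes, plasmids, organelle genomes) in draft long-read
    assemblies. Corrected reads near contig ends are reassembled locally with a
    greedy exact-overlap assembler; the resulting units drive coordinate-rule
    contig merging, two-path circularization (replacement by a circular unit, or
    end-joining through a unit spanning the junction), containment-based
    refinement, and rotation of circular contigs to start at an anchor gene
    (dnaA by default). Includes two optimized overlap-based baseline methods for
    comparison, a built-in seed-chain-extend aligner compatible with
    show-coords style hit tables, and a ground-truthed simulator of the
    characteristic pathologies of linear representations of circular molecules
    (duplicated ends, missing junction sequence, tandem multi-copies,
    fragmentation, repeat-induced false overlaps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
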