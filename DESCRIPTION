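Package: vpseq
Title: Virtual Primer-Based Elongation of De Novo Transcriptome Contigs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-assembly elongation of incomplete de novo transcriptome
    contigs toward full-length open reading frames by an overlap-consensus,
    "in silico RACE" procedure: 20-bp terminal virtual primers recruit reads
    from a k-mer hash store (exact, one-mismatch, or IUPAC-ambiguous search),
    and extension bases are called one position at a time from
    pseudo-count-regularized posterior nucleotide probabilities, with
    heterozygous sites emitted as two-base ambiguity codes. Includes the
    accompanying read cleaning (PCR-duplicate removal, quality-driven
    trimming), ORF-completeness classification, contig-redundancy and
    asymmetric-fragment detection, FPKM quantification with GO-term
    enrichment scoring, UPGMA tree construction with tree cutting and
    species-sharing tallies, and a synthetic-data generator with
    gold-standard evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
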