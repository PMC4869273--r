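Package: mhctyper
Title: Coverage-Based MHC Class I Allele Typing and Novel Allele Discovery
    from RNA-Seq Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls MHC class I alleles of an individual directly from short
    paired-end RNA-seq reads by exact, end-to-end alignment of reads to a
    catalogue of known allele cDNA sequences, declaring an allele present only
    when its entire sequence is covered by zero-mismatch reads.  A relaxed
    bounded-mismatch pass proposes "parent" alleles for novel variants, which
    are reconstructed from consistent pileup variants phased with read and
    mate-pair evidence, or assembled de novo by greedy overlap extension, and
    then validated by complete zero-mismatch re-coverage and protein-level
    checks.  Also provides allele-level expression quantification as
    within-class read proportions, Mendelian validation of multi-allele
    genotypes in families including SNP-based haplotype tracking, and a
    seeded simulator of copy-number-variable MHC haplotypes, pedigrees and
    paired-end reads used as a hermetic test bed.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
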