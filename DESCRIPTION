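Package: ldprune
Title: Whole-Genome Linkage Disequilibrium Pruning by Minor Allele Count Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prunes bi-allelic SNP panels for complete and high pairwise
    linkage disequilibrium (squared correlation r2 above a threshold) across
    the whole genome, without computing almost all pairwise r2 values.  Loci
    are sorted on minor allele count (MAC); complete LD (r2 = 1) is detected
    by direct comparison of minor-oriented alleles within equal-MAC groups,
    and high LD by an analytic per-MAC candidate bound plus a partial-sum
    screen over nested subsets of individuals, so that exact r2 is evaluated
    only for the few pairs that survive.  Works on phased haplotypes or
    allele counts (0/1/2), reads PLINK BED/BIM/FAM, phased VCF and plain
    integer matrices, writes PLINK-style prune lists, and ships a synthetic
    panel generator with planted LD structure plus a brute-force all-pairs
    oracle for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    parallel,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
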