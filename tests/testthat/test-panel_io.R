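test_that("PLINK BED round-trips against an independent byte-level encoder", {
  # 3 individuals x 2 loci, known counts -> known codes (0->0, 1->2, 2->3)
  counts <- cbind(c(0L, 1L, 2L), c(2L, 2L, 0L))
  codes <- counts; codes[counts == 1L] <- 2L; codes[counts == 2L] <- 3L
  prefix <- encode_bed_fixture(codes, file.path(tempdir(), "bedfix"))
  panel <- read_plink_bed(prefix)
  expect_identical(panel$counts, counts)
  expect_identical(panel$loci$locus_id, c("snp1", "snp2"))

  # package encoder -> package decoder, wider-than-4 individuals case
  set.seed(42)
  big <- genotype_panel(matrix(sample(0:2, 11 * 7, TRUE), 11, 7),
                        chromosome = rep("2", 7), position = 1:7 * 10L)
  prefix2 <- file.path(tempdir(), "bedfix2")
  write_plink_bed(big, prefix2)
  back <- read_plink_bed(prefix2)
  expect_identical(back$counts, big$counts)
  expect_identical(back$loci$locus_id, big$loci$locus_id)
  expect_identical(back$loci$position, big$loci$position)
})

test_that("BED reader rejects bad magic and missing genotypes", {
  prefix <- file.path(tempdir(), "badmagic")
  writeBin(as.raw(c(0x00, 0x1b, 0x01, 0xff)), paste0(prefix, ".bed"))
  writeLines("1\tsnp1\t0\t1\tA\tB", paste0(prefix, ".bim"))
  writeLines("1\t1\t0\t0\t0\t-9", paste0(prefix, ".fam"))
  expect_error(read_plink_bed(prefix), "magic")

  # missing code (01) for one genotype -> error citing missing genotypes
  codes <- cbind(c(0L, 3L, 2L), c(3L, 1L, 0L))
  prefix <- encode_bed_fixture(codes, file.path(tempdir(), "missfix"),
                               ids = c("ok1", "miss1"))
  expect_error(read_plink_bed(prefix), "missing genotypes.*miss1")
  expect_message(panel <- read_plink_bed(prefix, drop_missing_loci = TRUE),
                 "dropping 1")
  expect_identical(panel$loci$locus_id, "ok1")
  expect_identical(ncol(panel$counts), 1L)
})

test_that("phased VCF GT fields map to haplotypes; contract violations error", {
  hap <- haplotype_panel(cbind(c(0L, 1L, 1L, 1L), c(1L, 0L, 0L, 0L)),
                         locus_ids = c("v1", "v2"),
                         chromosome = c("1", "1"), position = c(100L, 1100L))
  path <- file.path(tempdir(), "phased.vcf")
  write_vcf_phased(hap, path)
  back <- read_vcf_phased(path)
  expect_identical(back$alleles, hap$alleles)
  expect_identical(back$loci$locus_id, c("v1", "v2"))
  expect_identical(back$loci$position, c(100L, 1100L))

  # GT 0|1, 1|1 for two individuals -> haplotype slice (0,1),(1,1)
  expect_identical(back$alleles[, 1L], c(0L, 1L, 1L, 1L))

  vcf_lines <- function(gt_rows, alt = rep("C", length(gt_rows))) {
    c("##fileformat=VCFv4.2",
      '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tA\tB",
      sprintf("1\t%d\trec%d\tA\t%s\t.\tPASS\t.\tGT\t%s", seq_along(gt_rows),
              seq_along(gt_rows), alt, gt_rows))
  }
  unphased <- file.path(tempdir(), "unphased.vcf")
  writeLines(vcf_lines("0/1\t1|1"), unphased)
  expect_error(read_vcf_phased(unphased), "phas")

  missing <- file.path(tempdir(), "missing.vcf")
  writeLines(vcf_lines(".|1\t1|1"), missing)
  expect_error(read_vcf_phased(missing))

  tri <- file.path(tempdir(), "tri.vcf")
  writeLines(vcf_lines(c("0|1\t1|1", "0|2\t1|0", "0|0\t0|1"),
                       alt = c("C", "C,G", "T")), tri)
  expect_warning(panel <- read_vcf_phased(tri), "multi-allelic")
  expect_identical(n_loci(panel), 2L)
  expect_identical(attr(panel, "skipped_multiallelic"), 1L)
})

test_that("text matrix IO honours orientation, ids and the {0,1,2} contract", {
  path <- file.path(tempdir(), "zeros.txt")
  writeLines(c("0 0 0", "0 0 0"), path)
  p <- read_matrix_txt(path, orientation = "individuals")
  expect_identical(dim(p$counts), c(2L, 3L))
  expect_true(all(p$counts == 0L))
  pt <- read_matrix_txt(path, orientation = "loci")
  expect_identical(pt$counts, t(p$counts))

  writeLines(c("0 1 2", "0 0.7 1"), path)
  expect_error(read_matrix_txt(path, orientation = "individuals"),
               "line 2, column 2")
  writeLines(c("0 1 3"), path)
  expect_error(read_matrix_txt(path, orientation = "individuals"), "0,1,2")

  # round trip with locus ids, both orientations
  wp <- worked_panel()
  for (or in c("loci", "individuals")) {
    f <- file.path(tempdir(), paste0("rt_", or, ".txt"))
    write_matrix_txt(wp, f, orientation = or)
    back <- read_matrix_txt(f, orientation = or)
    expect_identical(back$counts, wp$counts)
    expect_identical(back$loci$locus_id, wp$loci$locus_id)
  }
})

test_that("dosage rounding follows the fixed 0.5/1.5 rule", {
  expect_identical(round_dosages(c(0.5, 1.5, 0.51, 1.49)), c(0L, 2L, 1L, 1L))
  expect_identical(round_dosages(c(0, 1, 2)), c(0L, 1L, 2L))
  m <- matrix(c(0.2, 1.0, 1.7, 0.9), 2, 2)
  expect_identical(round_dosages(m), matrix(c(0L, 1L, 2L, 1L), 2, 2))
  expect_error(round_dosages(2.01), "\\[0, 2\\]")
  expect_error(round_dosages(-0.1), "\\[0, 2\\]")
})

test_that("prune lists partition the analyzed loci and report pair distances", {
  counts <- cbind(c(0, 0, 1, 2), c(0, 0, 1, 2), c(0, 1, 1, 2), c(0, 0, 0, 0))
  panel <- genotype_panel(counts, locus_ids = c("L1", "L2", "L3", "M1"),
                          chromosome = rep("1", 4),
                          position = c(100L, 1100L, 2000L, 3000L))
  res <- ld_prune(panel, 0.99)
  prefix <- file.path(tempdir(), "lists")
  write_prune_lists(res, prefix)
  kept <- readLines(paste0(prefix, ".prune.in"))
  removed <- readLines(paste0(prefix, ".prune.out"))
  expect_identical(removed, "L1")
  expect_identical(kept, c("L2", "L3"))      # M1 monomorphic: in neither list
  expect_length(intersect(kept, removed), 0L)
  expect_setequal(c(kept, removed), c("L1", "L2", "L3"))
  pairs <- read.delim(paste0(prefix, ".pairs.tsv"))
  expect_identical(pairs$reason, "complete")
  expect_equal(pairs$r2, 1)
  expect_identical(pairs$distance, 1000L)    # positions 100 and 1100

  # empty removal set -> empty prune.out, header-only pairs.tsv
  lone <- genotype_panel(cbind(c(0, 1, 1, 2), c(1, 0, 2, 0)))
  res2 <- ld_prune(lone, 0.99)
  prefix2 <- file.path(tempdir(), "lists2")
  write_prune_lists(res2, prefix2)
  expect_identical(readLines(paste0(prefix2, ".prune.out")), character(0))
  expect_identical(nrow(read.delim(paste0(prefix2, ".pairs.tsv"))), 0L)
})

test_that("collapsing haplotypes preserves MACs and text round trip is exact", {
  set.seed(11)
  hap <- generate_base_panel(20, 30, seed = 11)
  gen <- collapse_haplotypes(hap)
  sh <- summarize_loci(hap)
  sg <- summarize_loci(gen)
  expect_identical(sh$mac, sg$mac)
  expect_identical(sh$allele_sum, sg$allele_sum)
  f <- file.path(tempdir(), "collapse_rt.txt")
  write_matrix_txt(gen, f)
  expect_identical(read_matrix_txt(f)$counts, gen$counts)
})
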