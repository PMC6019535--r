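# Shared fixtures, all built in code at test time.

# The 5-locus worked panel: L1/L2 are mirrored (complete LD), L3/L4 share a
# MAC but have r2 = 0.25, L5 is a low-MAC singleton.
worked_panel <- function() {
  counts <- cbind(c(0, 0, 1, 2), c(2, 2, 1, 0), c(0, 1, 1, 2),
                  c(0, 1, 2, 1), c(0, 0, 0, 1))
  genotype_panel(counts, locus_ids = paste0("L", 1:5))
}

# Independent, byte-level PLINK .bed encoder used to validate the reader:
# packs 2-bit codes (0 = hom A1/0 copies, 2 = het, 3 = hom A2/2 copies,
# 1 = missing) four genotypes per byte, least-significant pair first.
encode_bed_fixture <- function(codes, prefix,
                               ids = paste0("snp", seq_len(ncol(codes)))) {
  n <- nrow(codes); m <- ncol(codes)
  bpr <- ceiling(n / 4)
  bytes <- raw(0)
  for (j in seq_len(m)) {
    col <- c(codes[, j], rep(0L, bpr * 4 - n))
    for (b in seq_len(bpr)) {
      q <- col[(4 * b - 3):(4 * b)]
      bytes <- c(bytes, as.raw(q[1] + q[2] * 4 + q[3] * 16 + q[4] * 64))
    }
  }
  writeBin(c(as.raw(c(0x6c, 0x1b, 0x01)), bytes), paste0(prefix, ".bed"))
  writeLines(paste("1", ids, "0", seq_len(m) * 100, "A", "B", sep = "\t"),
             paste0(prefix, ".bim"))
  writeLines(paste(seq_len(n), seq_len(n), 0, 0, 0, -9, sep = "\t"),
             paste0(prefix, ".fam"))
  prefix
}

# Exact pairwise r2 matrix from integer sums (NA where variance is zero);
# shared oracle helper for property tests.
r2_matrix <- function(x) {
  Nfac <- nrow(x)
  s <- colSums(x)
  den <- as.numeric(Nfac) * colSums(x * x) - as.numeric(s)^2
  num <- (as.numeric(Nfac) * crossprod(x) - outer(as.numeric(s), as.numeric(s)))^2
  out <- num / outer(den, den)
  out[outer(den, den) == 0] <- NA_real_
  out
}

removed_key <- function(result) {
  paste(result$removed$locus_id, result$removed$reason)
}
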