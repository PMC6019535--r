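#' Read a PLINK 1 binary fileset (.bed/.bim/.fam)
#'
#' Decodes a SNP-major PLINK 1 fileset into a [genotype_panel()].  The
#' returned value at each genotype is the count of the `.bim` A2 allele
#' (2-bit code `00`, homozygous A1, decodes to 0; `10` to 1; `11` to 2),
#' the PLINK 1.9 convention.  Pairwise r2 and all pruning decisions are
#' invariant to this orientation choice; it only affects how kept/removed
#' alleles are reported.
#'
#' Missing genotypes (code `01`) are a hard error naming the first offending
#' locus, because the pruning algorithm requires complete data; with
#' `drop_missing_loci = TRUE` loci containing missing codes are dropped with
#' a message instead.
#'
#' @param path_prefix path prefix; `<prefix>.bed`, `<prefix>.bim` and
#'   `<prefix>.fam` must exist.
#' @param drop_missing_loci drop loci with missing genotypes instead of
#'   erroring (default `FALSE`).
#' @return a [genotype_panel()] with loci in `.bim` order.
#' @seealso [write_plink_bed()]
#' @export
read_plink_bed <- function(path_prefix, drop_missing_loci = FALSE) {
  bed <- paste0(path_prefix, ".bed")
  bim <- paste0(path_prefix, ".bim")
  fam <- paste0(path_prefix, ".fam")
  for (f in c(bed, bim, fam))
    if (!file.exists(f)) stop("file not found: ", f)
  bim_df <- utils::read.table(bim, header = FALSE, stringsAsFactors = FALSE,
                              col.names = c("chromosome", "locus_id", "cm",
                                            "position", "a1", "a2"))
  fam_df <- utils::read.table(fam, header = FALSE, stringsAsFactors = FALSE)
  n <- nrow(fam_df)
  m <- nrow(bim_df)
  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3L || raw[1L] != as.raw(0x6c) || raw[2L] != as.raw(0x1b))
    stop("not a PLINK .bed file: bad magic bytes (format error)")
  if (raw[3L] != as.raw(0x01))
    stop("only SNP-major .bed files (mode byte 0x01) are supported (format error)")
  bpr <- (n + 3L) %/% 4L                       # bytes per locus row
  if (length(raw) - 3L != bpr * m)
    stop(".bed payload size does not match .bim/.fam dimensions")
  codes <- bed_codes_from_bytes(raw[-(1:3)], n, m)   # n x m 2-bit codes
  # 0 = hom A1 -> 0 copies of A2; 2 = het -> 1; 3 = hom A2 -> 2; 1 = missing
  missing_loci <- which(apply(codes == 1L, 2L, any))
  if (length(missing_loci)) {
    if (!drop_missing_loci)
      stop(sprintf("missing genotypes are not supported (first offending locus: %s)",
                   bim_df$locus_id[missing_loci[1L]]))
    message(sprintf("dropping %d locus/loci with missing genotypes", length(missing_loci)))
    codes <- codes[, -missing_loci, drop = FALSE]
    bim_df <- bim_df[-missing_loci, , drop = FALSE]
  }
  counts <- codes
  counts[codes == 2L] <- 1L
  counts[codes == 3L] <- 2L
  genotype_panel(counts,
                 locus_ids = bim_df$locus_id,
                 individual_ids = as.character(fam_df[[2L]]),
                 chromosome = bim_df$chromosome,
                 position = bim_df$position)
}

# Unpack SNP-major 2-bit codes into an n x m integer matrix of codes 0..3.
# Genotype i of a locus sits in bits (2(i-1), 2(i-1)+1) of byte ceiling(i/4),
# least-significant pair first.
bed_codes_from_bytes <- function(bytes, n, m) {
  bpr <- (n + 3L) %/% 4L
  ints <- as.integer(bytes)
  dim(ints) <- c(bpr, m)
  out <- matrix(0L, n, m)
  for (k in 0:3) {                       # genotype slot within byte
    rows <- seq_len(bpr) * 4L - 3L + k   # individual index for slot k of each byte
    keep <- rows <= n
    out[rows[keep], ] <- (ints[keep, , drop = FALSE] %/% (4L^k)) %% 4L
  }
  out
}

#' Write a genotype panel as a PLINK 1 binary fileset
#'
#' Inverse of [read_plink_bed()]: counts are interpreted as copies of the A2
#' allele.  Used for round-trip tests and to export synthetic panels.
#'
#' @param panel a [genotype_panel()] (haplotype panels are collapsed first).
#' @param path_prefix output path prefix.
#' @return invisibly, the three file paths written.
#' @export
write_plink_bed <- function(panel, path_prefix) {
  if (inherits(panel, "haplotype_panel")) panel <- collapse_haplotypes(panel)
  counts <- panel$counts
  n <- nrow(counts); m <- ncol(counts)
  codes <- counts
  codes[counts == 1L] <- 2L
  codes[counts == 2L] <- 3L
  bpr <- (n + 3L) %/% 4L
  padded <- matrix(0L, bpr * 4L, m)
  padded[seq_len(n), ] <- codes
  bytes <- padded[seq(1L, bpr * 4L, by = 4L), , drop = FALSE] +
           padded[seq(2L, bpr * 4L, by = 4L), , drop = FALSE] * 4L +
           padded[seq(3L, bpr * 4L, by = 4L), , drop = FALSE] * 16L +
           padded[seq(4L, bpr * 4L, by = 4L), , drop = FALSE] * 64L
  bed <- paste0(path_prefix, ".bed")
  con <- file(bed, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  loci <- panel$loci
  chr <- ifelse(is.na(loci$chromosome), "0", loci$chromosome)
  pos <- ifelse(is.na(loci$position), 0L, loci$position)
  utils::write.table(data.frame(chr, loci$locus_id, 0L, pos, "A", "B"),
                     paste0(path_prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  ids <- panel$individual_ids
  utils::write.table(data.frame(ids, ids, 0L, 0L, 0L, -9L),
                     paste0(path_prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  invisible(paste0(path_prefix, c(".bed", ".bim", ".fam")))
}

#' Read phased haplotypes from a VCF
#'
#' Extracts phased GT fields from a VCF into a [haplotype_panel()].  All
#' kept records must be bi-allelic and fully phased: an unphased separator
#' (`/`) or a missing allele (`.`) is an error.  Multi-allelic records are
#' skipped with a warning; the number skipped is available as
#' `attr(panel, "skipped_multiallelic")`.
#'
#' @param path path to a VCF (plain or bgzipped) with GT fields.
#' @return a [haplotype_panel()] in record order.
#' @export
read_vcf_phased <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  n_skip <- sum(multi)
  if (n_skip > 0L)
    warning(sprintf("skipped %d multi-allelic record(s); only bi-allelic loci are used", n_skip))
  gt <- vcfR::extract.gt(vcf, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  m <- nrow(gt)
  if (any(is.na(gt)) || any(grepl(".", gt, fixed = TRUE)))
    stop("missing allele ('.') in GT field; complete data required")
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("unphased genotype separator '/' found; phasing is required (use '|')")
  if (!all(grepl("^[01]\\|[01]$", gt)))
    stop("GT fields must be phased bi-allelic calls like 0|1")
  n <- ncol(gt)
  alleles <- matrix(0L, 2L * n, m)
  a1 <- matrix(as.integer(substr(gt, 1L, 1L)), m, n)
  a2 <- matrix(as.integer(substr(gt, 3L, 3L)), m, n)
  alleles[seq(1L, 2L * n, by = 2L), ] <- t(a1)
  alleles[seq(2L, 2L * n, by = 2L), ] <- t(a2)
  ids <- fix[, "ID"]
  if (any(is.na(ids) | ids == ".")) {
    fallback <- paste0(fix[, "CHROM"], ":", fix[, "POS"])
    ids <- ifelse(is.na(ids) | ids == ".", fallback, ids)
  }
  panel <- haplotype_panel(alleles, locus_ids = ids,
                           individual_ids = colnames(gt),
                           chromosome = fix[, "CHROM"],
                           position = as.integer(fix[, "POS"]))
  attr(panel, "skipped_multiallelic") <- n_skip
  panel
}

#' Write a haplotype panel as a minimal phased VCF
#'
#' @param panel a [haplotype_panel()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_vcf_phased <- function(panel, path) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  n <- n_individuals(panel); m <- n_loci(panel)
  h1 <- a[seq(1L, 2L * n, by = 2L), , drop = FALSE]
  h2 <- a[seq(2L, 2L * n, by = 2L), , drop = FALSE]
  gt <- matrix(paste0(t(h1), "|", t(h2)), m, n)
  loci <- panel$loci
  chr <- ifelse(is.na(loci$chromosome), "1", loci$chromosome)
  pos <- ifelse(is.na(loci$position), loci$input_index, loci$position)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", panel$individual_ids), collapse = "\t"))
  body <- apply(cbind(chr, pos, loci$locus_id, "A", "C", ".", "PASS", ".", "GT", gt),
                1L, paste, collapse = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype panel from a whitespace-delimited integer matrix
#'
#' Accepts only the integer tokens 0, 1 and 2 (plus optional identifiers, see
#' below); anything else is an error reporting the offending line and column.
#' The default orientation is `"loci"` (one row per locus), the natural
#' layout for sequence-scale panels where loci far outnumber individuals.
#'
#' Identifiers are optional: with `orientation = "loci"` a non-numeric first
#' column is taken as locus ids; with `orientation = "individuals"` a
#' non-numeric first line is taken as a header of locus ids.  Otherwise loci
#' are named `snp1..snpm`.
#'
#' @param path path to the text file.
#' @param orientation `"loci"` (rows are loci, default) or `"individuals"`.
#' @return a [genotype_panel()].
#' @seealso [write_matrix_txt()]
#' @export
read_matrix_txt <- function(path, orientation = c("loci", "individuals")) {
  orientation <- match.arg(orientation)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty matrix file: ", path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  locus_ids <- NULL
  # a leading identifier row/column is recognized by non-numeric tokens only;
  # numeric-looking tokens are always treated (and validated) as data
  numericish <- function(x) grepl("^[0-9.eE+-]+$", x)
  if (orientation == "individuals" && !all(numericish(toks[[1L]]))) {
    locus_ids <- toks[[1L]]
    toks <- toks[-1L]
  } else if (orientation == "loci" && !numericish(toks[[1L]][1L])) {
    locus_ids <- vapply(toks, `[`, "", 1L)
    toks <- lapply(toks, `[`, -1L)
  }
  if (!length(toks)) stop("matrix file contains no data rows: ", path)
  nc <- lengths(toks)
  if (length(unique(nc)) != 1L)
    stop("matrix is not rectangular (line ", which(nc != nc[1L])[1L], ")")
  for (i in seq_along(toks)) {
    bad <- which(!toks[[i]] %in% c("0", "1", "2"))
    if (length(bad))
      stop(sprintf("invalid token '%s' at line %d, column %d: allele counts must be integers in {0,1,2}",
                   toks[[i]][bad[1L]], i, bad[1L]))
  }
  mat <- do.call(rbind, lapply(toks, as.integer))
  if (orientation == "loci") mat <- t(mat)
  genotype_panel(mat, locus_ids = locus_ids)
}

#' Write a genotype panel as a whitespace-delimited integer matrix
#'
#' @param panel a [genotype_panel()] (haplotype panels are collapsed first).
#' @param path output path.
#' @param orientation `"loci"` (one row per locus, prefixed by the locus id)
#'   or `"individuals"` (header line of locus ids).
#' @return invisibly, `path`.
#' @export
write_matrix_txt <- function(panel, path, orientation = c("loci", "individuals")) {
  orientation <- match.arg(orientation)
  if (inherits(panel, "haplotype_panel")) panel <- collapse_haplotypes(panel)
  ids <- panel$loci$locus_id
  if (orientation == "loci") {
    rows <- apply(t(panel$counts), 1L, paste, collapse = " ")
    writeLines(paste(ids, rows), path)
  } else {
    writeLines(c(paste(ids, collapse = " "),
                 apply(panel$counts, 1L, paste, collapse = " ")), path)
  }
  invisible(path)
}

#' Round real-valued dosages to allele counts
#'
#' Applies the fixed rounding rule for partially imputed genotypes on the
#' 0--2 scale: values at or below 0.5 become 0, values at or above 1.5
#' become 2, everything in between becomes 1.
#'
#' @param values numeric vector or matrix with all values in `[0, 2]`.
#' @return integer object of the same shape with values in `{0, 1, 2}`.
#' @export
round_dosages <- function(values) {
  if (anyNA(values) || any(values < 0 | values > 2))
    stop("dosages must lie in [0, 2]")
  out <- ifelse(values <= 0.5, 0L, ifelse(values >= 1.5, 2L, 1L))
  storage.mode(out) <- "integer"
  if (is.matrix(values)) dim(out) <- dim(values)
  out
}

#' Write PLINK-style prune lists and a pair report
#'
#' Writes `<prefix>.prune.in` (kept locus ids, one per line, input order),
#' `<prefix>.prune.out` (removed ids, input order) and `<prefix>.pairs.tsv`
#' with one row per removal: `locus_removed`, `partner`, `reason`
#' (`complete` or `high`), `r2`, `same_chromosome` and `distance` (base
#' pairs, only when both positions are known and chromosomes match).
#' Monomorphic loci excluded from the analysis appear in neither prune list.
#'
#' @param result a `prune_result` from [ld_prune()] or [brute_force_prune()].
#' @param out_prefix output path prefix.
#' @return invisibly, the paths written.
#' @export
write_prune_lists <- function(result, out_prefix) {
  stopifnot(inherits(result, "prune_result"))
  writeLines(result$kept, paste0(out_prefix, ".prune.in"))
  writeLines(result$removed$locus_id, paste0(out_prefix, ".prune.out"))
  rem <- result$removed
  pairs <- data.frame(locus_removed = rem$locus_id,
                      partner = rem$partner_id,
                      reason = rem$reason,
                      r2 = rem$r2,
                      same_chromosome = rem$same_chromosome,
                      distance = rem$distance,
                      stringsAsFactors = FALSE)
  utils::write.table(pairs, paste0(out_prefix, ".pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paste0(out_prefix, c(".prune.in", ".prune.out", ".pairs.tsv")))
}
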