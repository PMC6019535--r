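#' Genotype panel (allele counts 0/1/2)
#'
#' Container for a bi-allelic genotype panel with no missing data: an
#' `n_individuals x n_loci` integer matrix of allele counts (number of copies
#' of the counted allele, 0, 1 or 2) plus locus metadata.  Locus order always
#' equals input order; this order is the tie-break used by the pruning rules.
#'
#' @param counts integer matrix, individuals in rows, loci in columns; every
#'   entry must be 0, 1 or 2 (missing values are not supported).
#' @param locus_ids character vector of unique locus identifiers; defaults to
#'   `snp1..snpm`.
#' @param individual_ids character vector of individual identifiers; defaults
#'   to `ind1..indn`.
#' @param chromosome optional character vector of chromosome labels per locus.
#' @param position optional integer vector of base-pair positions per locus.
#'   `chromosome` and `position` must be given together or not at all.
#' @return an object of class `genotype_panel` with elements `counts`
#'   (integer matrix), `loci` (data.frame: `locus_id`, `chromosome`,
#'   `position`, `input_index`) and `individual_ids`.
#' @seealso [haplotype_panel()], [collapse_haplotypes()]
#' @export
genotype_panel <- function(counts, locus_ids = NULL, individual_ids = NULL,
                           chromosome = NULL, position = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (nrow(counts) < 2L)
    stop("a genotype panel needs at least 2 individuals")
  if (anyNA(counts) || (length(counts) && !all(counts %in% 0:2)))
    stop("allele counts must all be 0, 1 or 2 (missing genotypes unsupported)")
  m <- ncol(counts)
  loci <- make_locus_meta(m, locus_ids, chromosome, position)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(nrow(counts)))
  dimnames(counts) <- NULL
  structure(list(counts = counts, loci = loci,
                 individual_ids = as.character(individual_ids)),
            class = "genotype_panel")
}

#' Haplotype panel (phased alleles 0/1)
#'
#' Container for phased bi-allelic data: a `2*n_individuals x n_loci` integer
#' matrix of allele codes (0/1), where rows `2i - 1` and `2i` are the two
#' haplotypes of individual `i`.  Collapsing the two haplotypes by summation
#' yields the corresponding [genotype_panel()].
#'
#' @param alleles integer matrix of 0/1 allele codes, `2n` haplotype rows by
#'   `m` locus columns.
#' @inheritParams genotype_panel
#' @return an object of class `haplotype_panel` with elements `alleles`,
#'   `loci` and `individual_ids`.
#' @export
haplotype_panel <- function(alleles, locus_ids = NULL, individual_ids = NULL,
                            chromosome = NULL, position = NULL) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  if (nrow(alleles) %% 2L != 0L)
    stop("allele matrix must have an even number of rows (2 haplotypes per individual)")
  n <- nrow(alleles) %/% 2L
  if (n < 2L) stop("a haplotype panel needs at least 2 individuals")
  if (anyNA(alleles) || (length(alleles) && !all(alleles %in% 0:1)))
    stop("phased alleles must all be 0 or 1 (missing alleles unsupported)")
  loci <- make_locus_meta(ncol(alleles), locus_ids, chromosome, position)
  if (is.null(individual_ids)) individual_ids <- paste0("ind", seq_len(n))
  dimnames(alleles) <- NULL
  structure(list(alleles = alleles, loci = loci,
                 individual_ids = as.character(individual_ids)),
            class = "haplotype_panel")
}

make_locus_meta <- function(m, locus_ids, chromosome, position) {
  if (is.null(locus_ids))
    locus_ids <- if (m > 0L) paste0("snp", seq_len(m)) else character(0)
  locus_ids <- as.character(locus_ids)
  if (length(locus_ids) != m) stop("locus_ids length does not match locus count")
  if (anyDuplicated(locus_ids)) stop("locus identifiers must be unique")
  if (xor(is.null(chromosome), is.null(position)))
    stop("chromosome and position must be given together or not at all")
  data.frame(locus_id = locus_ids,
             chromosome = if (is.null(chromosome)) NA_character_ else as.character(chromosome),
             position = if (is.null(position)) NA_integer_ else as.integer(position),
             input_index = seq_len(m),
             stringsAsFactors = FALSE)
}

#' Number of individuals / loci in a panel
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @return integer count.
#' @export
n_individuals <- function(panel) {
  if (inherits(panel, "haplotype_panel")) nrow(panel$alleles) %/% 2L
  else nrow(panel$counts)
}

#' @rdname n_individuals
#' @export
n_loci <- function(panel) nrow(panel$loci)

#' Collapse a haplotype panel to allele counts
#'
#' Sums the two phased alleles of each individual at each locus, producing a
#' genotype panel with identical locus metadata.  Minor allele counts are
#' unchanged by this operation.
#'
#' @param panel a [haplotype_panel()].
#' @return a [genotype_panel()].
#' @export
collapse_haplotypes <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  counts <- a[seq(1L, nrow(a), by = 2L), , drop = FALSE] +
            a[seq(2L, nrow(a), by = 2L), , drop = FALSE]
  out <- list(counts = counts, loci = panel$loci, individual_ids = panel$individual_ids)
  storage.mode(out$counts) <- "integer"
  class(out) <- "genotype_panel"
  out
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d individuals x %d loci (allele counts 0/1/2)\n",
              n_individuals(x), n_loci(x)))
  invisible(x)
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("<haplotype_panel> %d individuals x %d loci (phased alleles 0/1)\n",
              n_individuals(x), n_loci(x)))
  invisible(x)
}

# Matrix of the panel in the active mode: counts (n x m) or alleles (2n x m).
panel_matrix <- function(panel, mode) {
  if (mode == "phased") {
    if (!inherits(panel, "haplotype_panel"))
      stop("phased mode requires a haplotype panel")
    panel$alleles
  } else {
    if (inherits(panel, "haplotype_panel")) collapse_haplotypes(panel)$counts
    else panel$counts
  }
}
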