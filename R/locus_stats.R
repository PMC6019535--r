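#' Minor allele count from an allele sum
#'
#' Translates the sum of 0/1-coded alleles over all `2n` haplotypes (or,
#' equivalently, the sum of allele counts over `n` individuals) into the
#' count of the minor allele: sums below `n + 1` are already minor counts,
#' otherwise the complement `2n - sum` is taken.  At a minor allele
#' frequency of exactly 0.5 (`sum == n`) the first branch applies and the
#' allele coded 1 is reported as minor; downstream code treats such loci as
#' orientation-ambiguous wherever that matters.
#'
#' @param allele_sum integer sum of coded alleles, in `[0, 2n]`.
#' @param n number of individuals.
#' @return a list with `mac` (integer) and `minor_is_one` (logical: is the
#'   allele coded 1 the minor allele).
#' @export
minor_allele_count <- function(allele_sum, n) {
  if (any(allele_sum < 0L) || any(allele_sum > 2L * n))
    stop("allele_sum must lie in [0, 2n]")
  minor_is_one <- allele_sum < n + 1L
  list(mac = as.integer(ifelse(minor_is_one, allele_sum, 2L * n - allele_sum)),
       minor_is_one = minor_is_one)
}

#' Per-locus summaries for LD pruning
#'
#' Computes, for every locus of a panel, the quantities the pruning stages
#' need so that the only per-pair work left is a single cross-product: the
#' allele sum, minor allele count (MAC) and orientation flag, the raw and
#' minor-oriented second moments, the integer variance term of the r2
#' denominator, the phased-equivalent variance term used by the candidate
#' bound, and the cumulative minor-oriented partial sums over nested subsets
#' of individuals.
#'
#' Subset `p` (of `subset_count`) covers the first `ceiling(p * n /
#' subset_count)` individuals in input order; using deterministic prefixes
#' rather than random subsets makes results machine-independent and lets
#' all partial sums be computed in one pass.  Orientation is recorded as a
#' flag; the stored allele codes are never rewritten.
#'
#' In count mode the partial sums and the phased-equivalent variance term
#' treat the minor-oriented counts as if the two minor alleles of a
#' homozygote sat on known haplotypes (pseudo-phasing), which is what makes
#' the phased candidate bound applicable to genotype data; the exact r2
#' denominators use the true genotype moments.
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param mode `"phased"` or `"counts"`; defaults to the panel's natural
#'   mode.
#' @param subset_count number of nested partial-sum subsets (default 10).
#' @return an object of class `locus_summaries`: a data.frame with one row
#'   per locus (`locus_index`, `locus_id`, `allele_sum`, `mac`,
#'   `minor_is_one`, `sum_x`, `sum_x2`, `den`, `variance_term`) plus
#'   attributes `partial` (a `subset_count x m` integer matrix of
#'   minor-oriented prefix sums), `n`, `mode` and `subset_count`.
#' @export
summarize_loci <- function(panel, mode = NULL, subset_count = 10L) {
  if (is.null(mode)) mode <- if (inherits(panel, "haplotype_panel")) "phased" else "counts"
  mode <- match.arg(mode, c("phased", "counts"))
  subset_count <- as.integer(subset_count)
  if (subset_count < 1L) stop("subset_count must be at least 1")
  x <- panel_matrix(panel, mode)
  n <- n_individuals(panel)
  m <- ncol(x)
  s <- as.integer(colSums(x))
  mm <- minor_allele_count(s, n)
  mac <- mm$mac
  minor_is_one <- mm$minor_is_one
  if (mode == "phased") {
    sum_x2_raw <- s                      # a^2 = a for 0/1 codes
    sum_x2_min <- mac
    den <- as.numeric(2 * n) * s - as.numeric(s)^2
  } else {
    sum_x2_raw <- as.integer(colSums(x * x))
    # sum (2 - x)^2 = 4n - 4 sum x + sum x^2
    sum_x2_min <- ifelse(minor_is_one, sum_x2_raw, 4L * n - 4L * s + sum_x2_raw)
    den <- as.numeric(n) * sum_x2_raw - as.numeric(s)^2
  }
  variance_term <- mac - mac^2 / (2 * n)
  # minor-oriented cumulative prefix sums over individuals; subset p covers
  # the first bounds[p] individuals (= 2*bounds[p] haplotype rows when phased)
  bounds <- as.integer(ceiling(seq_len(subset_count) * n / subset_count))
  rows <- if (mode == "phased") 2L * bounds else bounds
  if (m > 0L) {
    cs <- matrix(apply(x, 2L, cumsum)[rows, , drop = FALSE], nrow = subset_count)
  } else {
    cs <- matrix(integer(), subset_count, 0L)
  }
  cap <- if (mode == "phased") 1L else 2L
  # oriented prefix sum for major-coded loci: count of (cap - x) among the prefix
  flip <- !minor_is_one
  if (any(flip)) {
    sizes <- if (mode == "phased") 2L * bounds else bounds
    cs[, flip] <- cap * matrix(sizes, subset_count, sum(flip)) - cs[, flip, drop = FALSE]
  }
  out <- data.frame(locus_index = seq_len(m),
                    locus_id = panel$loci$locus_id,
                    allele_sum = s,
                    mac = mac,
                    minor_is_one = minor_is_one,
                    sum_x = mac,
                    sum_x2 = as.integer(sum_x2_min),
                    sum_x2_raw = sum_x2_raw,
                    den = den,
                    variance_term = variance_term,
                    stringsAsFactors = FALSE)
  attr(out, "partial") <- cs
  attr(out, "n") <- n
  attr(out, "mode") <- mode
  attr(out, "subset_count") <- subset_count
  class(out) <- c("locus_summaries", "data.frame")
  out
}

#' Stable minor-allele-count ordering of loci
#'
#' Sorts loci ascending by `(mac, input_index)`; the sort is stable so that
#' within an equal-MAC group input order is preserved.  Equal-MAC group
#' start offsets are recorded for the complete-LD stage.
#'
#' @param summaries a `locus_summaries` object, or any data.frame with
#'   `mac` and `locus_index` columns (e.g. a subset of analyzable loci).
#' @return an object of class `mac_order`: list with `permutation` (locus
#'   input indices in sorted order), `mac` (their MACs, ascending) and
#'   `group_starts` (first sorted position of each equal-MAC run).
#' @export
sort_loci_by_mac <- function(summaries) {
  if (nrow(summaries) == 0L) stop("no loci to sort")
  ord <- order(summaries$mac, summaries$locus_index)
  macs <- summaries$mac[ord]
  starts <- which(c(TRUE, macs[-1L] != macs[-length(macs)]))
  structure(list(permutation = summaries$locus_index[ord],
                 mac = macs,
                 group_starts = starts),
            class = "mac_order")
}

#' Exclude loci on which r2 is undefined
#'
#' Splits loci into an analyzable set and an excluded set.  Monomorphic loci
#' (MAC 0) are always excluded; in count mode, constant columns with zero
#' genotype variance (every individual heterozygous) are excluded as well,
#' since the allele-count correlation is undefined there.  Excluded loci
#' take no part in any pairing: they are never pruned and never serve as
#' partners.
#'
#' @param summaries a `locus_summaries` object.
#' @return list with `analyzable` and `excluded`, both `locus_summaries`
#'   subsets (attributes preserved).
#' @export
filter_monomorphic <- function(summaries) {
  bad <- summaries$mac == 0L | summaries$den == 0
  split_summaries(summaries, !bad)
}

split_summaries <- function(summaries, keep) {
  part <- attr(summaries, "partial")
  mk <- function(rows) {
    out <- summaries[rows, , drop = FALSE]
    attr(out, "partial") <- part[, rows, drop = FALSE]
    attr(out, "n") <- attr(summaries, "n")
    attr(out, "mode") <- attr(summaries, "mode")
    attr(out, "subset_count") <- attr(summaries, "subset_count")
    class(out) <- class(summaries)
    out
  }
  list(analyzable = mk(which(keep)), excluded = mk(which(!keep)))
}
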