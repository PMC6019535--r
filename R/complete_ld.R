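#' Test whether two equal-MAC loci are identical up to orientation
#'
#' The complete-LD criterion: two phased loci have r2 = 1 exactly when their
#' allele vectors are identical (same orientation) or complementary
#' (opposite orientation); in count mode the genotype vectors must satisfy
#' `x_j == x_k` or `x_j == 2 - x_k` respectively.  Comparison is exact; no
#' mismatch tolerance is applied.
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param j,k locus input indices with equal minor allele counts.
#' @param orientation `"same"` or `"opposite"`.
#' @param mode `"phased"` or `"counts"`; defaults to the panel's natural mode.
#' @return logical flag.
#' @export
vectors_identical <- function(panel, j, k, orientation = c("same", "opposite"),
                              mode = NULL) {
  orientation <- match.arg(orientation)
  if (is.null(mode)) mode <- if (inherits(panel, "haplotype_panel")) "phased" else "counts"
  x <- panel_matrix(panel, mode)
  sj <- sum(x[, j]); sk <- sum(x[, k])
  n2 <- if (mode == "phased") nrow(x) else 2L * nrow(x)
  if (min(sj, n2 - sj) != min(sk, n2 - sk))
    stop("vectors_identical requires equal minor allele counts")
  cap <- if (mode == "phased") 1L else 2L
  if (orientation == "same") all(x[, j] == x[, k])
  else all(x[, j] == cap - x[, k])
}

#' Detect and remove loci in complete LD
#'
#' Works through each equal-MAC group in MAC order, maintaining a survivor
#' set.  Each incoming locus is compared against the current survivors; on a
#' match (identical minor-oriented vectors) the earlier-appearing locus --
#' the survivor -- is removed and the incoming locus recorded as its
#' partner, so within a group of mutually identical loci the last-appearing
#' one survives.  Orientation of the comparison follows the minor-allele
#' flags: equal flags call for the same-orientation test, unequal flags for
#' the opposite test; at MAC = n (minor allele frequency exactly 0.5) the
#' coding is ambiguous and both orientations are tried.
#'
#' Removed loci take no further part in this or later stages.
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param summaries `locus_summaries` of the analyzable loci (monomorphic
#'   loci already excluded), as from [filter_monomorphic()].
#' @param order a `mac_order` built on the same loci; computed when `NULL`.
#' @return data.frame with one row per removal: `removed_index`,
#'   `partner_index` (input indices) and `orientation` (`"same"`/`"opposite"`).
#' @export
find_complete_ld <- function(panel, summaries, order = NULL) {
  if (is.null(order)) order <- sort_loci_by_mac(summaries)
  mode <- attr(summaries, "mode")
  x <- panel_matrix(panel, mode)
  n <- attr(summaries, "n")
  cap <- if (mode == "phased") 1L else 2L
  flag <- summaries$minor_is_one[match(order$permutation, summaries$locus_index)]
  removed <- integer(0); partner <- integer(0); orient <- character(0)
  g_end <- c(order$group_starts[-1L] - 1L, length(order$permutation))
  for (g in seq_along(order$group_starts)) {
    pos <- order$group_starts[g]:g_end[g]
    if (length(pos) < 2L) next
    idx <- order$permutation[pos]
    fl <- flag[pos]
    ambiguous <- order$mac[order$group_starts[g]] == n
    survivors <- 1L            # positions within idx
    for (p in 2L:length(idx)) {
      cur <- idx[p]
      hit <- 0L; hit_or <- ""
      for (s in survivors) {
        cand <- idx[s]
        if (ambiguous) {
          if (all(x[, cand] == x[, cur])) { hit <- s; hit_or <- "same"; break }
          if (all(x[, cand] == cap - x[, cur])) { hit <- s; hit_or <- "opposite"; break }
        } else if (fl[s] == fl[p]) {
          if (all(x[, cand] == x[, cur])) { hit <- s; hit_or <- "same"; break }
        } else {
          if (all(x[, cand] == cap - x[, cur])) { hit <- s; hit_or <- "opposite"; break }
        }
      }
      if (hit > 0L) {
        removed <- c(removed, idx[hit])
        partner <- c(partner, cur)
        orient <- c(orient, hit_or)
        survivors <- survivors[survivors != hit]
      }
      survivors <- c(survivors, p)
    }
  }
  data.frame(removed_index = removed, partner_index = partner,
             orientation = orient, stringsAsFactors = FALSE)
}
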