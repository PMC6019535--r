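#' Maximum achievable r2 for a MAC pair
#'
#' Given minor allele counts `c_j <= c_k` at two loci of `n` individuals,
#' the phased cross-product is maximized when every minor allele at the
#' rarer locus co-occurs with one at the commoner locus, i.e. the
#' cross-product equals `c_j`.  The resulting closed-form ceiling is
#' `c_j (2n - c_k) / (c_k (2n - c_j))`, which equals 1 exactly when
#' `c_j == c_k`.  This is the quantity the candidate bound table scans.
#'
#' @param c_j,c_k minor allele counts with `1 <= c_j <= c_k <= n`.
#' @param n number of individuals.
#' @return numeric maximum achievable r2 in `(0, 1]`.
#' @export
max_r2_same_overlap <- function(c_j, c_k, n) {
  if (any(c_j < 1L) || any(c_k > n) || any(c_j > c_k))
    stop("require 1 <= c_j <= c_k <= n")
  (c_j * (2 * n - c_k)) / (c_k * (2 * n - c_j))
}

#' Build the per-MAC candidate bound table
#'
#' For each possible minor allele count `c` from 1 to `n`, finds the largest
#' partner MAC that can still yield r2 above the threshold `t`, by starting
#' the partner sum at `c` and increasing it while the inequality
#' `c > sqrt(t * v(c) * v(partner)) + c * partner / (2n)` still holds,
#' where `v(c) = c - c^2 / (2n)` is the phased-equivalent variance term
#' (for minor-oriented 0/1 codes the sum of squared alleles equals the sum).
#' The last passing value is stored.  Since the inequality always holds at
#' `partner == c` (equal-MAC pairs can reach r2 = 1), `max_mac(c) >= c`,
#' and the bound is non-decreasing in `c`.
#'
#' Pairs with r2 exactly 1 belong to the complete-LD stage, so `t` must lie
#' strictly inside (0, 1).
#'
#' @param n number of individuals.
#' @param t r2 threshold in (0, 1).
#' @return an object of class `bound_table`: list with `threshold`, `n` and
#'   `max_mac`, an integer vector indexed by MAC value 1..n.
#' @export
build_bound_table <- function(n, t) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1)
    stop("threshold t must lie strictly in (0, 1)")
  if (n < 2L) stop("n must be at least 2")
  v <- function(c) c - c^2 / (2 * n)
  max_mac <- integer(n)
  ck <- 1L
  for (cj in seq_len(n)) {
    if (ck < cj) ck <- cj
    while (ck < n && cj > sqrt(t * v(cj) * v(ck + 1L)) + cj * (ck + 1L) / (2 * n))
      ck <- ck + 1L
    max_mac[cj] <- ck
  }
  structure(list(threshold = t, n = as.integer(n), max_mac = max_mac),
            class = "bound_table")
}

#' Enumerate candidate pairs under the MAC interval
#'
#' Emits each unordered pair of analyzable loci once, as positions in the
#' MAC-sorted order: for every sorted position `j` not in the excluded set,
#' all later positions `k` whose MAC does not exceed `max_mac(mac_j)` (and
#' which are not excluded).  The stream is deterministic: `j` ascending,
#' `k` ascending.  Because loci are sorted, the admissible `k` for each `j`
#' form a contiguous run.
#'
#' @param order a `mac_order` over the analyzable loci.
#' @param bounds a `bound_table` for the same `n` and the target threshold.
#' @param excluded integer vector of locus *input indices* to skip on either
#'   side (e.g. complete-LD removals).
#' @return a 2-column integer matrix of sorted positions (`j`, `k`); the
#'   corresponding input indices are `order$permutation[j]` etc.
#' @export
candidate_pairs <- function(order, bounds, excluded = integer(0)) {
  macs <- order$mac
  keep <- !(order$permutation %in% excluded)
  upper <- findInterval(bounds$max_mac[macs], macs)   # last position with mac <= bound
  js <- integer(0); ks <- integer(0)
  for (j in seq_along(macs)) {
    if (!keep[j] || upper[j] <= j) next
    kk <- (j + 1L):upper[j]
    kk <- kk[keep[kk]]
    if (length(kk)) {
      js <- c(js, rep.int(j, length(kk)))
      ks <- c(ks, kk)
    }
  }
  cbind(j = js, k = ks)
}

#' Partial-sum screen for a candidate pair
#'
#' Rejects a candidate pair when any nested subset of individuals already
#' shows more minor alleles at the commoner locus than the bound-table
#' slack allows: with `slack = max_mac(mac_j) - mac_j`, the pair cannot
#' exceed the threshold if `partial_k[p] - partial_j[p] > slack` for any
#' subset `p`.  When either locus has a minor allele frequency of exactly
#' 0.5 (`mac == n`) the minor orientation is ambiguous and the screen is
#' skipped (unconditional pass).
#'
#' @param summaries a `locus_summaries` object.
#' @param j,k locus input indices with `mac_j <= mac_k <= max_mac(mac_j)`.
#' @param bounds a `bound_table`.
#' @return `TRUE` (pass: exact r2 must be computed) or `FALSE` (reject).
#' @export
partial_sum_screen <- function(summaries, j, k, bounds) {
  rj <- match(j, summaries$locus_index)
  rk <- match(k, summaries$locus_index)
  if (summaries$mac[rj] > summaries$mac[rk]) { tmp <- rj; rj <- rk; rk <- tmp }
  n <- attr(summaries, "n")
  if (summaries$mac[rj] == n || summaries$mac[rk] == n) return(TRUE)
  slack <- bounds$max_mac[summaries$mac[rj]] - summaries$mac[rj]
  part <- attr(summaries, "partial")
  !any(part[, rk] - part[, rj] > slack)
}

#' Exact r2 between phased alleles
#'
#' The squared correlation between the 0/1 allele codes of two loci over
#' all `2n` haplotypes (the Hill-Robertson r2), evaluated as a ratio of
#' integer-valued quantities: `(2n * cross - s_j * s_k)^2 / (den_j * den_k)`
#' with `den = 2n * s - s^2`.  Only the cross-product is computed here; the
#' marginal terms come from the stored summaries.  The value is invariant
#' to the allele orientation at either locus.
#'
#' @param panel a [haplotype_panel()].
#' @param j,k locus input indices; both loci must be polymorphic.
#' @param summaries optional `locus_summaries` in phased mode.
#' @return r2 in `[0, 1]`.
#' @export
r2_phased <- function(panel, j, k, summaries = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  N <- nrow(a)
  if (is.null(summaries)) {
    sj <- sum(a[, j]); sk <- sum(a[, k])
    dj <- as.numeric(N) * sj - as.numeric(sj)^2
    dk <- as.numeric(N) * sk - as.numeric(sk)^2
  } else {
    rj <- match(j, summaries$locus_index); rk <- match(k, summaries$locus_index)
    sj <- summaries$allele_sum[rj]; sk <- summaries$allele_sum[rk]
    dj <- summaries$den[rj]; dk <- summaries$den[rk]
  }
  if (dj == 0 || dk == 0) stop("r2 undefined for a monomorphic locus")
  cross <- sum(a[, j] * a[, k])
  (as.numeric(N) * cross - as.numeric(sj) * sk)^2 / (dj * dk)
}

#' Exact r2 between allele counts
#'
#' The squared correlation between per-individual allele counts (genotypes
#' 0/1/2) of two loci, evaluated as
#' `(n * cross - s_j * s_k)^2 / (den_j * den_k)` with
#' `den = n * sum(x^2) - s^2`.  Its expectation equals the phased r2.
#' Orientation-invariant.
#'
#' @param panel a [genotype_panel()] (haplotype panels are collapsed).
#' @param j,k locus input indices; both loci must have nonzero genotype
#'   variance.
#' @param summaries optional `locus_summaries` in count mode.
#' @return r2 in `[0, 1]`.
#' @export
r2_allele_counts <- function(panel, j, k, summaries = NULL) {
  x <- panel_matrix(panel, "counts")
  n <- nrow(x)
  if (is.null(summaries)) {
    sj <- sum(x[, j]); sk <- sum(x[, k])
    dj <- as.numeric(n) * sum(x[, j]^2) - as.numeric(sj)^2
    dk <- as.numeric(n) * sum(x[, k]^2) - as.numeric(sk)^2
  } else {
    rj <- match(j, summaries$locus_index); rk <- match(k, summaries$locus_index)
    sj <- summaries$allele_sum[rj]; sk <- summaries$allele_sum[rk]
    dj <- summaries$den[rj]; dk <- summaries$den[rk]
  }
  if (dj == 0 || dk == 0) stop("r2 undefined for a zero-variance locus")
  cross <- sum(x[, j] * x[, k])
  (as.numeric(n) * cross - as.numeric(sj) * sk)^2 / (dj * dk)
}

#' Detect and remove loci in high LD
#'
#' The second pruning stage.  For each MAC-sorted position `j` (skipping
#' loci removed in the complete-LD stage), later positions `k` inside the
#' candidate MAC interval are scanned in ascending order; pairs passing the
#' partial-sum screen get an exact r2 (phased or allele-count, by mode).
#' At the first pair with `r2 > t` -- a strict comparison, evaluated as
#' `numerator > t * denominator` on integer-valued sums with no epsilon --
#' locus `j` (the leftmost: lower MAC, or earlier input position on ties)
#' is removed with `k` as its recorded partner, and scanning for this `j`
#' stops.  Each `j`'s decision depends only on the complete-LD-surviving
#' data, so partitioning the `j` positions over workers cannot change the
#' result.
#'
#' Counters tally the pairs actually examined: every emitted candidate is
#' either screened out or receives an exact r2, so
#' `candidate_pairs == screened_out + r2_computed` always holds.
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param t r2 threshold, strictly inside (0, 1).
#' @param mode `"phased"` or `"counts"`; defaults to the panel's natural mode.
#' @param workers number of parallel workers over sorted positions
#'   (forked via \pkg{parallel}; any value yields identical results).
#' @param excluded integer vector of input indices removed by the
#'   complete-LD stage.
#' @param summaries,order,bounds optional precomputed inputs (analyzable
#'   loci only); computed when `NULL`.
#' @return list with `removals` (data.frame: `removed_index`,
#'   `partner_index`, `r2`) and `counters` (list: `candidate_pairs`,
#'   `screened_out`, `r2_computed`).
#' @export
prune_high_ld <- function(panel, t, mode = NULL, workers = 1L,
                          excluded = integer(0), summaries = NULL,
                          order = NULL, bounds = NULL) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1)
    stop("threshold t must lie strictly in (0, 1)")
  if (is.null(mode)) mode <- if (inherits(panel, "haplotype_panel")) "phased" else "counts"
  mode <- match.arg(mode, c("phased", "counts"))
  if (is.null(summaries)) {
    summaries <- filter_monomorphic(summarize_loci(panel, mode = mode))$analyzable
  }
  if (is.null(order)) order <- sort_loci_by_mac(summaries)
  n <- attr(summaries, "n")
  if (is.null(bounds)) bounds <- build_bound_table(n, t)
  x <- panel_matrix(panel, mode)
  Nfac <- if (mode == "phased") 2 * n else n
  perm <- order$permutation
  macs <- order$mac
  mpos <- length(perm)
  row <- match(perm, summaries$locus_index)
  s_sorted <- summaries$allele_sum[row]
  den_sorted <- summaries$den[row]
  part_sorted <- attr(summaries, "partial")[, row, drop = FALSE]
  xs <- x[, perm, drop = FALSE]
  keep <- !(perm %in% excluded)
  upper <- findInterval(bounds$max_mac[macs], macs)
  exempt <- macs == n

  scan_j <- function(jset) {
    rem_j <- integer(0); rem_k <- integer(0); rem_r2 <- numeric(0)
    cand <- 0; scr <- 0; comp <- 0
    for (j in jset) {
      if (!keep[j] || upper[j] <= j) next
      kk <- (j + 1L):upper[j]
      kk <- kk[keep[kk]]
      if (!length(kk)) next
      slack <- bounds$max_mac[macs[j]] - macs[j]
      diffs <- part_sorted[, kk, drop = FALSE] - part_sorted[, j]
      rejected <- colSums(diffs > slack) > 0L
      rejected[exempt[kk] | exempt[j]] <- FALSE
      xj <- xs[, j]
      tden_j <- t * den_sorted[j]
      for (q in seq_along(kk)) {
        cand <- cand + 1
        if (rejected[q]) { scr <- scr + 1; next }
        k <- kk[q]
        comp <- comp + 1
        num <- (Nfac * sum(xj * xs[, k]) - as.numeric(s_sorted[j]) * s_sorted[k])^2
        if (num > tden_j * den_sorted[k]) {
          rem_j <- c(rem_j, j); rem_k <- c(rem_k, k)
          rem_r2 <- c(rem_r2, num / (den_sorted[j] * den_sorted[k]))
          break
        }
      }
    }
    list(j = rem_j, k = rem_k, r2 = rem_r2, cand = cand, scr = scr, comp = comp)
  }

  workers <- max(1L, as.integer(workers))
  if (workers > 1L && mpos > 1L && .Platform$OS.type == "unix") {
    chunks <- split(seq_len(mpos), cut(seq_len(mpos), workers, labels = FALSE))
    parts <- parallel::mclapply(chunks, scan_j, mc.cores = workers)
  } else {
    parts <- list(scan_j(seq_len(mpos)))
  }
  removals <- data.frame(
    removed_index = perm[unlist(lapply(parts, `[[`, "j"))],
    partner_index = perm[unlist(lapply(parts, `[[`, "k"))],
    r2 = unlist(lapply(parts, `[[`, "r2")))
  ord <- order(match(removals$removed_index, perm))
  removals <- removals[ord, , drop = FALSE]
  rownames(removals) <- NULL
  counters <- list(candidate_pairs = sum(vapply(parts, `[[`, 0, "cand")),
                   screened_out = sum(vapply(parts, `[[`, 0, "scr")),
                   r2_computed = sum(vapply(parts, `[[`, 0, "comp")))
  list(removals = removals, counters = counters)
}
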