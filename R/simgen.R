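#' Generate a random phased base panel
#'
#' Draws each locus independently: a minor allele frequency uniform in
#' `[maf_low, maf_high]`, then `2n` independent alleles at that frequency.
#' There is no recombination or demographic model -- the pruning algorithm
#' is position-agnostic, so LD structure is planted explicitly with
#' [plant_duplicate()] instead of simulated.  Loci that come out
#' monomorphic are redrawn up to `retry` times and then kept, so the
#' zero-variance filter is occasionally exercised.  Chromosome labels are
#' assigned round-robin over `n_chromosomes` with positions spaced 1 kb
#' apart, so pair-distance reporting is exercised.
#'
#' @param n number of individuals (>= 2).
#' @param m number of loci (0 allowed).
#' @param maf_low,maf_high minor allele frequency range, with
#'   `0 < maf_low <= maf_high <= 0.5`.
#' @param seed integer seed; identical seeds give identical panels.
#' @param n_chromosomes chromosomes for round-robin metadata (default 5).
#' @param retry redraw attempts for monomorphic loci (default 10).
#' @return a [haplotype_panel()].
#' @export
generate_base_panel <- function(n, m, maf_low = 0.05, maf_high = 0.5,
                                seed = NULL, n_chromosomes = 5L, retry = 10L) {
  if (maf_low <= 0 || maf_low > maf_high || maf_high > 0.5)
    stop("require 0 < maf_low <= maf_high <= 0.5")
  if (n < 2L) stop("n must be at least 2")
  if (!is.null(seed)) set.seed(seed)
  N <- 2L * n
  p <- stats::runif(m, maf_low, maf_high)
  alleles <- matrix(stats::rbinom(N * m, 1L, rep(p, each = N)), N, m)
  if (m > 0L) {
    for (r in seq_len(retry)) {
      s <- colSums(alleles)
      mono <- which(s == 0L | s == N)
      if (!length(mono)) break
      alleles[, mono] <- stats::rbinom(N * length(mono), 1L, rep(p[mono], each = N))
    }
  }
  chrom <- as.character(rep_len(seq_len(n_chromosomes), m))
  pos <- 1000L * (((seq_len(m) - 1L) %/% n_chromosomes) + 1L)
  haplotype_panel(alleles, chromosome = chrom, position = pos)
}

#' Plant a duplicate (or near-duplicate) locus
#'
#' Appends a copy of an existing locus column, optionally complemented
#' (`flip`) and optionally perturbed by flipping a given number of randomly
#' chosen haplotype entries.  The true r2 between source and copy is
#' recomputed from the resulting panel, so planted truth is always
#' oracle-derived: exact copies and complemented copies carry r2 = 1,
#' perturbed copies carry whatever the perturbation produced.
#'
#' @param panel a [haplotype_panel()].
#' @param source input index of a polymorphic source locus.
#' @param flip complement the copied alleles (r2 is invariant to this).
#' @param perturb_haplotypes number of haplotype entries to flip, `< 2n`.
#' @param seed optional integer seed for the perturbation draw.
#' @return list with `panel` (the panel with one appended locus) and
#'   `planted` (one-row data.frame: `source_index`, `copy_index`,
#'   `planted_relation`, `true_r2`; r2 is `NA` if the copy came out
#'   monomorphic).
#' @export
plant_duplicate <- function(panel, source, flip = FALSE,
                            perturb_haplotypes = 0L, seed = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  a <- panel$alleles
  N <- nrow(a)
  s <- sum(a[, source])
  if (s == 0L || s == N) stop("source locus is monomorphic")
  if (perturb_haplotypes >= N) stop("perturb_haplotypes must be < 2n")
  if (!is.null(seed)) set.seed(seed)
  col <- a[, source]
  if (flip) col <- 1L - col
  if (perturb_haplotypes > 0L) {
    idx <- sample.int(N, perturb_haplotypes)
    col[idx] <- 1L - col[idx]
  }
  m <- ncol(a)
  loci <- panel$loci
  n_chr <- length(unique(loci$chromosome[!is.na(loci$chromosome)]))
  new_id <- sprintf("dup%d_of_%s", m + 1L, loci$locus_id[source])
  new_chr <- if (n_chr > 0L) as.character((m %% n_chr) + 1L) else NA_character_
  new_pos <- if (n_chr > 0L) 1000L * ((m %/% n_chr) + 1L) else NA_integer_
  out <- panel
  out$alleles <- cbind(a, col)
  dimnames(out$alleles) <- NULL
  out$loci <- rbind(loci, data.frame(locus_id = new_id, chromosome = new_chr,
                                     position = new_pos, input_index = m + 1L))
  sc <- sum(col)
  r2 <- if (sc == 0L || sc == N) NA_real_ else r2_phased(out, source, m + 1L)
  relation <- if (perturb_haplotypes > 0L) "perturbed"
              else if (flip) "flipped-duplicate" else "duplicate"
  list(panel = out,
       planted = data.frame(source_index = source, copy_index = m + 1L,
                            planted_relation = relation, true_r2 = r2,
                            stringsAsFactors = FALSE))
}

#' Generate a panel with planted LD structure
#'
#' Convenience wrapper: draws a base panel and plants exact duplicates,
#' complemented duplicates and perturbed copies of randomly chosen
#' polymorphic source loci.  The defaults are the standard validation
#' conditions used throughout the test suite: 100 individuals, 1000 base
#' loci, 20 planted pairs of each kind, perturbation of 5 haplotype
#' entries.
#'
#' @param n,m,maf_low,maf_high,seed passed to [generate_base_panel()].
#' @param n_duplicates,n_flipped,n_perturbed number of planted copies of
#'   each kind.
#' @param perturb_haplotypes haplotype entries flipped in each perturbed
#'   copy.
#' @return list with `panel` (a [haplotype_panel()]) and `planted`
#'   (data.frame of all planted pairs with oracle-computed `true_r2`).
#' @export
generate_ld_panel <- function(n = 100L, m = 1000L, n_duplicates = 20L,
                              n_flipped = 20L, n_perturbed = 20L,
                              perturb_haplotypes = 5L,
                              maf_low = 0.05, maf_high = 0.5, seed = 1L) {
  panel <- generate_base_panel(n, m, maf_low, maf_high, seed = seed)
  s <- colSums(panel$alleles)
  poly <- which(s > 0L & s < 2L * n)
  n_plant <- n_duplicates + n_flipped + n_perturbed
  sources <- sample(poly, n_plant, replace = n_plant > length(poly))
  kinds <- rep(c("dup", "flip", "pert"),
               c(n_duplicates, n_flipped, n_perturbed))
  planted <- vector("list", n_plant)
  for (i in seq_len(n_plant)) {
    res <- plant_duplicate(panel, sources[i],
                           flip = kinds[i] == "flip",
                           perturb_haplotypes = if (kinds[i] == "pert") perturb_haplotypes else 0L)
    panel <- res$panel
    planted[[i]] <- res$planted
  }
  list(panel = panel, planted = do.call(rbind, planted))
}

#' Brute-force all-pairs pruning oracle
#'
#' Reference implementation used as testing ground truth: computes every
#' pairwise r2 directly (all `(m^2 - m)/2` pairs, feasible only at test
#' scale) and applies the identical leftmost-removal rule with the
#' identical stage sequencing as [ld_prune()] -- exact r2 = 1 removals
#' first (within the MAC-sorted survivor scan), then `r2 > t` removals in a
#' single pass over sorted positions -- so results are comparable
#' bit-for-bit with the screened fast path.  All r2 comparisons use the
#' same integer-sum arithmetic as the fast path, so r2 = 1 detection is
#' exact.
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param t r2 threshold in (0, 1).
#' @param mode `"phased"` or `"counts"`.
#' @param max_loci guard on the number of loci (default 5000).
#' @return a `prune_result` (without screen counters).
#' @export
brute_force_prune <- function(panel, t = 0.99, mode = NULL, max_loci = 5000L) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1)
    stop("threshold t must lie strictly in (0, 1)")
  if (is.null(mode)) mode <- if (inherits(panel, "haplotype_panel")) "phased" else "counts"
  mode <- match.arg(mode, c("phased", "counts"))
  if (mode == "phased" && !inherits(panel, "haplotype_panel"))
    stop("phased mode requires phased input (a haplotype panel)")
  m_in <- n_loci(panel)
  if (m_in > max_loci) stop("too many loci for brute-force enumeration")
  x <- panel_matrix(panel, mode)
  Nfac <- nrow(x)                  # 2n in phased mode, n in count mode
  n <- n_individuals(panel)
  s <- colSums(x)
  sx2 <- colSums(x * x)
  den <- as.numeric(Nfac) * sx2 - as.numeric(s)^2
  macs <- minor_allele_count(s, n)$mac
  num <- (as.numeric(Nfac) * crossprod(x) - outer(as.numeric(s), as.numeric(s)))^2
  denm <- outer(den, den)
  analyzable <- which(den > 0)
  ord <- analyzable[order(macs[analyzable], analyzable)]
  removed_reason <- character(m_in)
  partner <- integer(m_in)
  r2_rec <- rep(NA_real_, m_in)
  # stage 1: exact r2 = 1, survivor scan in MAC order
  survivors <- integer(0)
  for (cur in ord) {
    if (length(survivors)) {
      hit <- survivors[num[survivors, cur] == denm[survivors, cur]]
      if (length(hit)) {
        h <- hit[1L]
        removed_reason[h] <- "complete"
        partner[h] <- cur
        r2_rec[h] <- 1
        survivors <- survivors[survivors != h]
      }
    }
    survivors <- c(survivors, cur)
  }
  # stage 2: r2 > t over complete-LD survivors, first hit per sorted position
  surv_sorted <- ord[removed_reason[ord] == ""]
  for (pos in seq_along(surv_sorted)) {
    j <- surv_sorted[pos]
    if (pos == length(surv_sorted)) break
    later <- surv_sorted[(pos + 1L):length(surv_sorted)]
    hits <- which(num[j, later] > (t * den[j]) * den[later])
    if (length(hits)) {
      k <- later[hits[1L]]
      removed_reason[j] <- "high"
      partner[j] <- k
      r2_rec[j] <- num[j, k] / denm[j, k]
    }
  }
  loci <- panel$loci
  rem_idx <- which(removed_reason != "")
  removed <- data.frame(locus_id = loci$locus_id[rem_idx],
                        locus_index = rem_idx,
                        partner_id = loci$locus_id[partner[rem_idx]],
                        partner_index = partner[rem_idx],
                        reason = removed_reason[rem_idx],
                        r2 = r2_rec[rem_idx],
                        stringsAsFactors = FALSE)
  same_chr <- !is.na(loci$chromosome[removed$locus_index]) &
              !is.na(loci$chromosome[removed$partner_index]) &
              loci$chromosome[removed$locus_index] == loci$chromosome[removed$partner_index]
  removed$same_chromosome <- same_chr
  removed$distance <- ifelse(same_chr,
                             abs(loci$position[removed$locus_index] -
                                 loci$position[removed$partner_index]),
                             NA_integer_)
  excluded_ids <- loci$locus_id[den == 0]
  kept <- setdiff(loci$locus_id[den > 0], removed$locus_id)
  counters <- list(candidate_pairs = NA_real_, screened_out = NA_real_,
                   r2_computed = NA_real_)
  structure(list(kept = kept, removed = removed, excluded = excluded_ids,
                 counters = counters, report = NULL,
                 threshold = t, mode = mode),
            class = "prune_result")
}
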