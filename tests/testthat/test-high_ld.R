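# Build the nested haplotype configuration that attains the r2 ceiling for a
# MAC pair (every minor allele of the rarer locus co-occurs with one of the
# commoner locus) and evaluate r2 directly -- the independent oracle for the
# closed form.
nested_pair_r2 <- function(c_j, c_k, n) {
  N <- 2L * n
  a_k <- c(rep(1L, c_k), rep(0L, N - c_k))
  a_j <- c(rep(1L, c_j), rep(0L, N - c_j))
  r2_phased(haplotype_panel(cbind(a_j, a_k)), 1L, 2L)
}

test_that("the closed-form r2 ceiling matches direct evaluation of nested pairs", {
  expect_equal(max_r2_same_overlap(5, 5, 10), 1)
  expect_equal(max_r2_same_overlap(5, 6, 10), 5 * 14 / (6 * 15))
  expect_equal(max_r2_same_overlap(5, 6, 10), nested_pair_r2(5L, 6L, 10L))
  expect_equal(max_r2_same_overlap(1, 10, 10), 1 * 10 / (10 * 19))
  expect_equal(max_r2_same_overlap(1, 10, 10), nested_pair_r2(1L, 10L, 10L))
  for (cfg in list(c(2, 7, 12), c(3, 3, 8), c(1, 2, 4)))
    expect_equal(max_r2_same_overlap(cfg[1], cfg[2], cfg[3]),
                 nested_pair_r2(cfg[1], cfg[2], cfg[3]))
  expect_error(max_r2_same_overlap(6, 5, 10), "c_j <= c_k")
})

test_that("bound table stores the last partner MAC that can pass the threshold", {
  bt <- build_bound_table(10L, 0.99)
  expect_identical(bt$max_mac[5L], 5L)   # partner sum 6 already fails Eq-style check
  bt2 <- build_bound_table(2L, 0.5)
  expect_identical(bt2$max_mac[1L], 1L)
  bt3 <- build_bound_table(12L, 1e-6)
  expect_identical(bt3$max_mac[1L], 12L) # vanishing threshold admits everything
  expect_error(build_bound_table(10L, 1), "strictly in \\(0, 1\\)")
  expect_error(build_bound_table(10L, 0), "strictly in \\(0, 1\\)")
})

test_that("bound table is sound, tight and monotone against the closed form", {
  for (t in c(0.8, 0.95)) {
    for (n in c(5L, 17L, 30L)) {
      bt <- build_bound_table(n, t)
      expect_true(all(diff(bt$max_mac) >= 0L))
      expect_true(all(bt$max_mac >= seq_len(n)))
      for (cj in seq_len(n)) {
        M <- bt$max_mac[cj]
        expect_gt(max_r2_same_overlap(cj, M, n), t)          # tightness
        if (M < n)
          expect_lte(max_r2_same_overlap(cj, M + 1L, n), t)  # soundness
      }
    }
  }
})

test_that("candidate pairs are the contiguous equal-or-near-MAC runs", {
  # sorted macs [1,1,3,4] with max_mac(c) = c: only the two mac-1 loci pair up
  summ <- data.frame(mac = c(1L, 1L, 3L, 4L), locus_index = 1:4)
  ord <- sort_loci_by_mac(summ)
  bt <- build_bound_table(4L, 0.99)
  expect_identical(bt$max_mac, 1:4)
  cp <- candidate_pairs(ord, bt)
  expect_identical(unname(cp), cbind(1L, 2L))

  # a permissive bound emits every pair involving the first locus
  bt$max_mac <- rep(4L, 4L)
  cp2 <- candidate_pairs(ord, bt)
  expect_identical(sum(cp2[, "j"] == 1L), 3L)

  # an excluded locus appears on neither side
  cp3 <- candidate_pairs(ord, bt, excluded = 1L)  # input index 1 = sorted pos 1
  expect_false(any(cp3 == 1L))
})

test_that("the partial-sum screen rejects on slack violation and exempts MAF 0.5", {
  # identical loci: all partial differences zero -> pass
  p <- genotype_panel(cbind(c(0, 1, 1, 2, 0), c(0, 1, 1, 2, 0)))
  s <- summarize_loci(p)
  bt <- build_bound_table(5L, 0.99)
  expect_true(partial_sum_screen(s, 1L, 2L, bt))

  # same MAC, slack 0, commoner-minor subset excess -> rejected
  q <- genotype_panel(cbind(c(0, 1, 1, 0, 0), c(1, 1, 0, 0, 0)))
  sq <- summarize_loci(q)
  expect_identical(sq$mac, c(2L, 2L))
  expect_false(partial_sum_screen(sq, 1L, 2L, bt))
  # the early subsets decide: partial difference [1,1,1,1,0,...] > slack 0

  # MAF exactly 0.5 at one locus -> unconditional pass
  r <- genotype_panel(cbind(c(2, 2, 1, 0, 0), c(1, 1, 2, 0, 1)))
  sr <- summarize_loci(r)
  expect_identical(sr$mac, c(5L, 5L))
  expect_true(partial_sum_screen(sr, 1L, 2L, bt))
})

test_that("exact r2 agrees with hand-derived values and generic correlation", {
  # phased, n = 2: haplotypes j = (1,0),(0,0), k = (0,1),(0,0)
  hap <- haplotype_panel(cbind(c(1L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L)))
  expect_equal(r2_phased(hap, 1L, 2L), 1 / 9)
  expect_equal(r2_phased(hap, 1L, 1L), 1)
  comp <- haplotype_panel(cbind(hap$alleles[, 1L], 1L - hap$alleles[, 1L]))
  expect_equal(r2_phased(comp, 1L, 2L), 1)

  p <- genotype_panel(cbind(c(0, 1, 1, 2), c(0, 1, 2, 1), c(0, 0, 1, 2),
                            c(2, 2, 1, 0)))
  expect_equal(r2_allele_counts(p, 1L, 2L), 0.25)
  expect_equal(r2_allele_counts(p, 1L, 1L), 1)
  expect_equal(r2_allele_counts(p, 3L, 4L), 1)

  # agreement with cor()^2 on random columns
  set.seed(21)
  hap2 <- generate_base_panel(30, 15, seed = 21)
  gen2 <- collapse_haplotypes(hap2)
  for (i in 1:10) {
    jk <- sample(15L, 2L)
    expect_equal(r2_phased(hap2, jk[1], jk[2]),
                 cor(hap2$alleles[, jk[1]], hap2$alleles[, jk[2]])^2,
                 tolerance = 1e-12)
    expect_equal(r2_allele_counts(gen2, jk[1], jk[2]),
                 cor(gen2$counts[, jk[1]], gen2$counts[, jk[2]])^2,
                 tolerance = 1e-12)
  }
  mono <- genotype_panel(cbind(c(0, 0, 0, 0), c(0, 1, 1, 2)))
  expect_error(r2_allele_counts(mono, 1L, 2L), "undefined")
})

test_that("high-LD stage on the worked panel computes nothing above threshold", {
  p <- worked_panel()
  s <- filter_monomorphic(summarize_loci(p))$analyzable
  comp <- find_complete_ld(p, s)
  res <- prune_high_ld(p, 0.99, excluded = comp$removed_index, summaries = s)
  expect_identical(nrow(res$removals), 0L)
  ct <- res$counters
  expect_equal(ct$candidate_pairs, ct$screened_out + ct$r2_computed)
  expect_equal(ct$r2_computed, 1)   # only the L3-L4 pair reaches exact r2
  expect_error(prune_high_ld(p, 1.5), "strictly in \\(0, 1\\)")
})

test_that("a single-haplotype perturbation at large n is pruned as high LD", {
  base <- generate_base_panel(300, 120, seed = 31)
  # force a common source so one flip keeps r2 above 0.99
  src <- which.max(summarize_loci(base)$mac)[1]
  pl <- plant_duplicate(base, src, perturb_haplotypes = 1L, seed = 32)
  expect_gt(pl$planted$true_r2, 0.99)
  expect_lt(pl$planted$true_r2, 1)
  for (mode in c("phased", "counts")) {
    res <- ld_prune(pl$panel, 0.99, mode = mode)
    high <- res$removed[res$removed$reason == "high", ]
    expect_identical(nrow(high), 1L)
    expect_true(high$locus_index %in% c(src, pl$planted$copy_index))
    bf <- brute_force_prune(pl$panel, 0.99, mode = mode)
    expect_identical(removed_key(res), removed_key(bf))
  }
})

test_that("screen and interval never drop a phased pair the final stage would prune", {
  # exhaustive: all binary columns over 10 haplotypes (n = 5 individuals)
  n <- 5L; N <- 10L
  cols <- as.matrix(expand.grid(rep(list(0:1), N)))
  A <- t(cols)
  hap <- suppressWarnings(haplotype_panel(A))
  s <- summarize_loci(hap)
  part <- attr(s, "partial")
  r2m <- r2_matrix(A)
  for (t in c(0.8, 0.99)) {
    bt <- build_bound_table(n, t)
    hot <- which(upper.tri(r2m) & !is.na(r2m) & r2m > t, arr.ind = TRUE)
    swap <- s$mac[hot[, 1L]] > s$mac[hot[, 2L]]
    j <- ifelse(swap, hot[, 2L], hot[, 1L])
    k <- ifelse(swap, hot[, 1L], hot[, 2L])
    interval_reject <- s$mac[k] > bt$max_mac[s$mac[j]]
    slack <- bt$max_mac[s$mac[j]] - s$mac[j]
    diffs <- part[, k, drop = FALSE] - part[, j, drop = FALSE]
    screen_reject <- colSums(diffs > rep(slack, each = nrow(part))) > 0L
    screen_reject[s$mac[j] == n | s$mac[k] == n] <- FALSE
    expect_gt(length(j), 400L)    # the enumeration is non-trivial
    expect_identical(sum(interval_reject), 0L)
    expect_identical(sum(screen_reject & !interval_reject), 0L)
  }
})

test_that("lower thresholds activate the high-LD stage and still match the oracle", {
  g <- generate_ld_panel(n = 100, m = 300, n_duplicates = 5, n_flipped = 5,
                         n_perturbed = 15, perturb_haplotypes = 1, seed = 41)
  for (mode in c("phased", "counts")) {
    fast <- ld_prune(g$panel, 0.9, mode = mode)
    slow <- brute_force_prune(g$panel, 0.9, mode = mode)
    expect_identical(removed_key(fast), removed_key(slow))
    expect_identical(fast$kept, slow$kept)
    expect_gt(sum(fast$removed$reason == "high"), 0L)
  }
})
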