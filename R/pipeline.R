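#' Prune a panel for complete and high LD
#'
#' Runs the two pruning stages sequentially: first the complete-LD stage
#' (exact comparison of minor-oriented alleles within equal-MAC groups),
#' then the high-LD stage (candidate MAC interval, partial-sum screen,
#' exact r2 for the survivors).  One locus of each pair exceeding the
#' threshold is removed; the removal rule is uniform across stages: the
#' leftmost locus -- lower MAC, or earlier input position on ties -- goes.
#' Loci with undefined r2 (monomorphic, or constant genotypes in count
#' mode) are excluded from all pairing and reported separately.
#'
#' @param panel a [genotype_panel()] or [haplotype_panel()].
#' @param t r2 threshold, strictly inside (0, 1); default 0.99.
#' @param mode `"phased"` or `"counts"`.  Defaults to the panel's natural
#'   mode; `"counts"` on a haplotype panel collapses it first, `"phased"`
#'   on a genotype panel is an error.
#' @param workers parallel workers for the high-LD stage (identical results
#'   for any value).
#' @param subset_count number of partial-sum subsets (default 10).
#' @return an object of class `prune_result`: list with
#'   \describe{
#'     \item{kept}{kept locus ids, input order (excluded loci not included)}
#'     \item{removed}{data.frame: `locus_id`, `locus_index`, `partner_id`,
#'       `partner_index`, `reason` (`"complete"`/`"high"`), `r2`,
#'       `same_chromosome`, `distance`}
#'     \item{excluded}{ids of loci excluded as zero-variance}
#'     \item{counters}{high-LD stage screen counters}
#'     \item{report}{a `run_report`, see [ld_report()]}
#'   }
#' @seealso [brute_force_prune()] for the all-pairs reference
#'   implementation, [write_prune_lists()] for PLINK-style output.
#' @export
ld_prune <- function(panel, t = 0.99, mode = NULL, workers = 1L,
                     subset_count = 10L) {
  if (!is.numeric(t) || length(t) != 1L || t <= 0 || t >= 1)
    stop("threshold t must lie strictly in (0, 1)")
  if (is.null(mode)) mode <- if (inherits(panel, "haplotype_panel")) "phased" else "counts"
  mode <- match.arg(mode, c("phased", "counts"))
  if (mode == "phased" && !inherits(panel, "haplotype_panel"))
    stop("phased mode requires phased input (a haplotype panel)")
  m_in <- n_loci(panel)
  summaries <- summarize_loci(panel, mode = mode, subset_count = subset_count)
  flt <- filter_monomorphic(summaries)
  ana <- flt$analyzable
  res_complete <- if (nrow(ana)) {
    ord <- sort_loci_by_mac(ana)
    find_complete_ld(panel, ana, ord)
  } else {
    ord <- NULL
    data.frame(removed_index = integer(0), partner_index = integer(0),
               orientation = character(0))
  }
  if (nrow(ana)) {
    high <- prune_high_ld(panel, t, mode = mode, workers = workers,
                          excluded = res_complete$removed_index,
                          summaries = ana, order = ord)
  } else {
    high <- list(removals = data.frame(removed_index = integer(0),
                                       partner_index = integer(0), r2 = numeric(0)),
                 counters = list(candidate_pairs = 0, screened_out = 0, r2_computed = 0))
  }
  removed <- rbind(
    data.frame(locus_index = res_complete$removed_index,
               partner_index = res_complete$partner_index,
               reason = rep("complete", nrow(res_complete)),
               r2 = rep(1, nrow(res_complete))),
    data.frame(locus_index = high$removals$removed_index,
               partner_index = high$removals$partner_index,
               reason = rep("high", nrow(high$removals)),
               r2 = high$removals$r2))
  removed <- removed[order(removed$locus_index), , drop = FALSE]
  loci <- panel$loci
  removed$locus_id <- loci$locus_id[removed$locus_index]
  removed$partner_id <- loci$locus_id[removed$partner_index]
  same_chr <- !is.na(loci$chromosome[removed$locus_index]) &
              !is.na(loci$chromosome[removed$partner_index]) &
              loci$chromosome[removed$locus_index] == loci$chromosome[removed$partner_index]
  removed$same_chromosome <- same_chr
  removed$distance <- ifelse(same_chr,
                             abs(loci$position[removed$locus_index] -
                                 loci$position[removed$partner_index]),
                             NA_integer_)
  removed <- removed[, c("locus_id", "locus_index", "partner_id", "partner_index",
                         "reason", "r2", "same_chromosome", "distance")]
  rownames(removed) <- NULL
  excluded_ids <- flt$excluded$locus_id
  kept <- setdiff(loci$locus_id[!loci$locus_id %in% excluded_ids], removed$locus_id)
  report <- ld_report(n_individuals = n_individuals(panel),
                      n_loci_input = m_in,
                      n_monomorphic_excluded = length(excluded_ids),
                      n_removed_complete = sum(removed$reason == "complete"),
                      n_removed_high = sum(removed$reason == "high"),
                      n_kept = length(kept),
                      counters = high$counters,
                      threshold = t, mode = mode)
  structure(list(kept = kept, removed = removed, excluded = excluded_ids,
                 counters = high$counters, report = report,
                 threshold = t, mode = mode),
            class = "prune_result")
}

#' @export
print.prune_result <- function(x, ...) {
  cat(sprintf("<prune_result> t = %g, mode = %s\n", x$threshold, x$mode))
  print(x$report)
  invisible(x)
}

#' Assemble a pruning run report
#'
#' Collects the per-stage counts and the screen counters, and derives the
#' two standard efficiency percentages: the number of exact r2 evaluations
#' as a percentage of all possible pairs among the input loci, and as a
#' percentage of all possible pairs among loci surviving the complete-LD
#' stage.
#'
#' @param n_individuals,n_loci_input,n_monomorphic_excluded
#'   panel and exclusion counts.
#' @param n_removed_complete,n_removed_high,n_kept stage outcomes.
#' @param counters high-LD screen counters.
#' @param threshold,mode run settings.
#' @return an object of class `run_report` (a list of the above plus
#'   `percentage_all_pairs` and `percentage_after_complete`).
#' @export
ld_report <- function(n_individuals, n_loci_input, n_monomorphic_excluded,
                      n_removed_complete, n_removed_high, n_kept,
                      counters, threshold, mode) {
  stopifnot(n_loci_input == n_monomorphic_excluded + n_removed_complete +
              n_removed_high + n_kept)
  all_pairs <- n_loci_input * (n_loci_input - 1) / 2
  m_after <- n_loci_input - n_monomorphic_excluded - n_removed_complete
  after_pairs <- m_after * (m_after - 1) / 2
  structure(list(n_individuals = n_individuals,
                 n_loci_input = n_loci_input,
                 n_monomorphic_excluded = n_monomorphic_excluded,
                 n_removed_complete = n_removed_complete,
                 n_removed_high = n_removed_high,
                 n_kept = n_kept,
                 counters = counters,
                 threshold = threshold,
                 mode = mode,
                 percentage_all_pairs =
                   if (all_pairs > 0) 100 * counters$r2_computed / all_pairs else 0,
                 percentage_after_complete =
                   if (after_pairs > 0) 100 * counters$r2_computed / after_pairs else 0),
            class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("  individuals:              %d\n", x$n_individuals))
  cat(sprintf("  loci in:                  %d\n", x$n_loci_input))
  cat(sprintf("  excluded (zero variance): %d\n", x$n_monomorphic_excluded))
  cat(sprintf("  removed, complete LD:     %d\n", x$n_removed_complete))
  cat(sprintf("  removed, high LD:         %d\n", x$n_removed_high))
  cat(sprintf("  kept:                     %d\n", x$n_kept))
  cat(sprintf("  candidate pairs:          %.0f\n", x$counters$candidate_pairs))
  cat(sprintf("  screened out:             %.0f\n", x$counters$screened_out))
  cat(sprintf("  r2 values computed:       %.0f\n", x$counters$r2_computed))
  cat(sprintf("  %% of all pairs:           %.2f\n", x$percentage_all_pairs))
  cat(sprintf("  %% after complete LD:      %.2f\n", x$percentage_after_complete))
  invisible(x)
}

#' Read, prune and write in one call
#'
#' End-to-end driver: reads a panel (PLINK BED prefix, phased VCF, or text
#' matrix), runs [ld_prune()], writes the prune lists and pair report via
#' [write_prune_lists()] plus a `<prefix>.report.tsv`, and logs the run
#' report to standard error.
#'
#' @param input input path; for `format = "bed"` the path prefix of the
#'   `.bed/.bim/.fam` trio.
#' @param format `"auto"` (by extension), `"bed"`, `"vcf"` or `"matrix"`.
#' @param mode `"phased"` or `"counts"`; default: phased for VCF input,
#'   counts otherwise.
#' @param threshold r2 threshold in (0, 1); validated before any I/O.
#' @param workers parallel workers.
#' @param out_prefix output path prefix; no files are written when `NULL`.
#' @param drop_missing_loci for BED input, drop loci with missing genotypes
#'   instead of erroring.
#' @param subset_count number of partial-sum subsets.
#' @param matrix_orientation orientation for `format = "matrix"`.
#' @return invisibly, a list with `result` (the `prune_result`), `report`
#'   and `files` (paths written).
#' @export
run_prune <- function(input, format = c("auto", "bed", "vcf", "matrix"),
                      mode = NULL, threshold = 0.99, workers = 1L,
                      out_prefix = NULL, drop_missing_loci = FALSE,
                      subset_count = 10L,
                      matrix_orientation = c("loci", "individuals")) {
  format <- match.arg(format)
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1)
    stop("configuration error: threshold must lie strictly in (0, 1)")
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", input)) "vcf"
      else if (file.exists(paste0(input, ".bed"))) "bed"
      else "matrix"
  }
  panel <- switch(format,
    bed = read_plink_bed(input, drop_missing_loci = drop_missing_loci),
    vcf = read_vcf_phased(input),
    matrix = read_matrix_txt(input, orientation = matrix_orientation))
  result <- ld_prune(panel, t = threshold, mode = mode, workers = workers,
                     subset_count = subset_count)
  files <- character(0)
  if (!is.null(out_prefix)) {
    files <- write_prune_lists(result, out_prefix)
    rep_file <- paste0(out_prefix, ".report.tsv")
    rp <- result$report
    utils::write.table(
      data.frame(field = c("n_individuals", "n_loci_input",
                           "n_monomorphic_excluded", "n_removed_complete",
                           "n_removed_high", "n_kept", "candidate_pairs",
                           "screened_out", "r2_computed",
                           "percentage_all_pairs", "percentage_after_complete"),
                 value = c(rp$n_individuals, rp$n_loci_input,
                           rp$n_monomorphic_excluded, rp$n_removed_complete,
                           rp$n_removed_high, rp$n_kept,
                           rp$counters$candidate_pairs, rp$counters$screened_out,
                           rp$counters$r2_computed,
                           round(rp$percentage_all_pairs, 2),
                           round(rp$percentage_after_complete, 2))),
      rep_file, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, rep_file)
  }
  message(paste(utils::capture.output(print(result$report)), collapse = "\n"))
  invisible(list(result = result, report = result$report, files = files))
}

#' Pairwise-evaluation count of sliding-window pruning
#'
#' The number of pairwise r2 evaluations a sliding-window pruner performs
#' on `m` loci with window size `ws` shifted in steps of `ss`:
#' `(m / ss) * (ws^2 - ws) / 2`, evaluated in real arithmetic (the window
#' count `m / ss` is not rounded).  Useful to compare the whole-genome
#' approach against window-based tools.
#'
#' @param m total number of loci.
#' @param window window size `ws` (>= 1).
#' @param step step size `ss` (>= 1).
#' @return numeric evaluation count.
#' @export
window_cost <- function(m, window, step) {
  if (any(c(m, window, step) < 1)) stop("m, window and step must be positive")
  (m / step) * (window^2 - window) / 2
}
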