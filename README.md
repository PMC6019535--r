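# ldprune

Whole-genome linkage disequilibrium (LD) pruning for bi-allelic SNP panels:
removes one locus from every pair whose squared correlation r² is 1
(complete LD) or exceeds a threshold (high LD), across the **whole genome**
rather than within a sliding window, while computing exact r² for only a
tiny fraction of all pairs.  It is aimed at quantitative and population
geneticists preparing dense array or sequence genotypes for genomic
prediction, where redundant, co-linear SNPs -- including distant and
cross-chromosome pairs that window-based pruners never compare -- inflate
model cost without adding information.

## Method in brief

For phased alleles *a<sub>i,j,l</sub>* ∈ {0,1} (individual *i*, locus *j*,
haplotype *l*; *n* individuals), LD is the Hill–Robertson squared
correlation

r²(j,k) = (Σ a<sub>·j</sub>a<sub>·k</sub> − S<sub>j</sub>S<sub>k</sub>/2n)² / [(S<sub>j</sub> − S<sub>j</sub>²/2n)(S<sub>k</sub> − S<sub>k</sub>²/2n)],  S<sub>j</sub> = Σ a<sub>·j</sub>,

with the analogous formula over allele counts 0/1/2 when phase is unknown.
Computing all (m² − m)/2 pairs is unfeasible for sequence-scale m.  Instead:

1. **MAC sort** — r² = 1 requires equal minor allele counts (MAC), so
   complete-LD detection only compares minor-oriented vectors inside
   equal-MAC groups, with early exit at the first mismatch.  The
   earlier-in-data locus of each identical pair is removed.
2. **Candidate bound** — for MACs c<sub>j</sub> ≤ c<sub>k</sub> the maximum
   achievable r² is c<sub>j</sub>(2n − c<sub>k</sub>) / (c<sub>k</sub>(2n −
   c<sub>j</sub>)); a precomputed table maps each MAC to the largest
   partner MAC that can still beat the threshold, so each locus faces only
   a contiguous run of MAC-sorted candidates.
3. **Partial-sum screen** — per-locus minor-allele sums over 10 nested
   prefixes of individuals discard most remaining candidates by a counting
   argument, before any cross-product is touched.  Exact r² is computed
   only for the survivors.

Inputs: PLINK BED/BIM/FAM (allele counts), phased VCF (haplotypes), plain
0/1/2 matrices, or real dosages on [0,2] via the fixed rounding rule
(≤ 0.5 → 0, ≥ 1.5 → 2, else 1).  No missing data.  See the vignette
`vignettes/ld-pruning-methods.Rmd` for the full account, including the
pseudo-phasing assumption behind count mode and its limits.

## Worked example

```r
library(ldprune)
counts <- cbind(c(0,0,1,2), c(2,2,1,0), c(0,1,1,2), c(0,1,2,1), c(0,0,0,1))
panel  <- genotype_panel(counts, locus_ids = paste0("L", 1:5))
res    <- ld_prune(panel, t = 0.99)
res
#> <prune_result> t = 0.99, mode = counts
#>   individuals:              4
#>   loci in:                  5
#>   excluded (zero variance): 0
#>   removed, complete LD:     1
#>   removed, high LD:         0
#>   kept:                     4
#>   candidate pairs:          1
#>   screened out:             0
#>   r2 values computed:       1
#>   % of all pairs:           10.00
#>   % after complete LD:      16.67
res$removed[, c("locus_id", "partner_id", "reason", "r2")]
#>   locus_id partner_id   reason r2
#> 1       L1         L2 complete  1
res$kept
#> [1] "L2" "L3" "L4" "L5"
```

L1 and L2 are mirror images (x and 2 − x), so they are in complete LD and
the first-appearing one, L1, is removed.  L3 and L4 share a MAC — the only
candidate pair the bound admits — but their exact r² is 0.25, far below the
threshold, so both are kept; out of 10 possible pairs only 1 r² value was
ever computed.  On a larger synthetic panel with planted duplicates
(`generate_ld_panel(seed = 1)`: 100 individuals, 1060 loci) the same run
removes the 40 planted exact/complemented duplicates and computes 868 of
561,270 possible r² values (0.15%).

File-to-file operation, PLINK-style:

```sh
Rscript inst/cli/ldprune.R --matrix data.txt --r2 0.99 --out pruned
# writes pruned.prune.in, pruned.prune.out, pruned.pairs.tsv, pruned.report.tsv
Rscript inst/cli/ldprune.R window-cost --m 10812225 --window 50 --step 5
#> 2,648,995,125
```

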