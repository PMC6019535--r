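---
title: "Whole-genome LD pruning by minor allele count screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-genome LD pruning by minor allele count screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldprune)
```

## The problem

Dense SNP arrays and whole-genome sequence panels are highly redundant: in
populations with small effective size -- livestock especially -- many pairs
of loci are in complete or near-complete linkage disequilibrium (LD).  For
genomic prediction and related models this redundancy adds co-linearity and
computation without adding information, so one locus of every pair with
squared correlation $r^2$ above a threshold (typically 0.99) is removed
before modelling.  Window-based pruners only compare loci that sit close
together on the genome; in structured populations high LD also occurs
between distant loci and across chromosomes, which a window never sees.
Comparing all pairs directly, however, costs $(m^2 - m)/2$ correlations --
hopeless for millions of loci.

`ldprune` implements a whole-genome pruner that avoids computing almost all
pairwise $r^2$ values, using three exact devices: minor allele count (MAC)
sorting, an analytic candidate bound per MAC value, and a partial-sum screen
over nested subsets of individuals.

## The statistic

For phased data, with $a_{i,j,l} \in \{0,1\}$ the allele of haplotype $l$ of
individual $i$ at locus $j$ and $n$ individuals,

$$r^2_{LD}(j,k) =
\frac{\left(\sum_{l}\sum_i a_{i,j,l} a_{i,k,l} -
\frac{\sum_{l}\sum_i a_{i,j,l} \sum_{l}\sum_i a_{i,k,l}}{2n}\right)^2}
{\left(\sum_{l}\sum_i a^2_{i,j,l} - \frac{(\sum_{l}\sum_i a_{i,j,l})^2}{2n}\right)
 \left(\sum_{l}\sum_i a^2_{i,k,l} - \frac{(\sum_{l}\sum_i a_{i,k,l})^2}{2n}\right)},$$

the familiar haplotype-frequency $r^2$.  When phase is unknown the same
formula over per-individual allele counts $x_{i,j} \in \{0,1,2\}$ gives
$r^2_{ac}$, whose expectation equals $r^2_{LD}$.  Every marginal term is
computed once per locus and stored; only the cross-product is per-pair work.

## The algorithm

**Complete LD.**  $r^2 = 1$ forces both loci to have the same minor allele
count, and (for 0/1 alleles) the vectors to be identical or complementary.
So: compute each locus's MAC (allele sums below $n+1$ are already minor
counts, otherwise take $2n - \text{sum}$), sort loci by MAC, and compare
vectors only within equal-MAC groups, stopping at the first mismatching
entry.  Orientation flags decide whether the identity or the complement
test applies; at minor allele frequency exactly 0.5 the coding is ambiguous
and both are tried.  Within a group the scan keeps a survivor set: a locus
matching a survivor displaces it (the earlier-in-data locus is removed), so
of a run of identical columns the last one survives.

**High LD.**  For a MAC pair $c_j \le c_k$ the cross-product is at most
$c_j$, giving a closed-form ceiling
$$\max r^2 = \frac{c_j\,(2n - c_k)}{c_k\,(2n - c_j)},$$
equal to 1 only at $c_j = c_k$.  For each $c$ the bound table stores
`max_mac(c)`: the largest partner MAC whose ceiling still exceeds the
threshold $t$, found by increasing the partner sum from $c$ while the
inequality holds.  We store the last *passing* value, so the candidate
interval $[c, \text{max\_mac}(c)]$ contains no partner that is provably
unreachable; the table is non-decreasing and `max_mac(c) >= c` by
construction.  After MAC sorting each locus's candidates are one contiguous
run of later positions.

**Partial-sum screen.**  The same counting argument applies to any subset
of individuals: if over some subset the commoner locus already shows more
minor alleles than the slack `max_mac(c_j) - c_j` allows, the pair cannot
exceed $t$.  We store, per locus, minor-oriented cumulative sums over 10
nested prefixes of the individuals (the first $\lceil pn/10 \rceil$
individuals for $p = 1..10$); a pair is discarded at the first prefix whose
difference exceeds the slack.  Prefixes rather than random subsets make the
screen deterministic and one-pass.  Loci at minor allele frequency exactly
0.5 skip the screen (their orientation is ambiguous), and survive to the
exact-$r^2$ step.

**Decision rule.**  Both stages remove the *leftmost* locus of an offending
pair: lower MAC, or earlier input position on ties.  In the high-LD pass
each sorted position $j$ scans its candidates in order and is removed at
its first partner with $r^2 > t$; the decision for $j$ depends only on the
complete-LD survivors, never on other high-LD removals, which makes the
pass order-independent and safe to partition over workers.

## Modes, and what count mode cannot see

Count mode treats allele counts as pseudo-phased: for the bound and the
screen a homozygote contributes two minor alleles "on the same haplotype",
which is exactly the configuration that maximizes $r^2$, so the phased
machinery applies; only the final exact $r^2$ uses the true genotype
moments.  This inherits a real limitation: the bound and screen assume that
after minor orientation the correlation is non-negative and the only
perfect relations are $x_k = x_j$ and $x_k = 2 - x_j$.  Genotype columns
admit other affine relations -- $x_k = x_j + 1$, $x_k = 2x_j$, $x_k = 1 -
x_j$ -- with $r^2_{ac} = 1$ that no phased configuration can produce.  Such
pairs can be discarded by the candidate interval or the screen even though
their exact $r^2$ exceeds the threshold.  An exhaustive enumeration of all
$3^6$ genotype columns of six individuals (in the test suite) shows exactly
this: every such falsely-discarded pair is one of these affine cases, with
negative minor-oriented covariance or a MAC-incompatible slope, while the
same enumeration over all $2^{10}$ phased columns finds no false discard at
any threshold tested.  On genotype data that arises from real (or
simulated) haplotypes these relations require extreme allele-frequency
coincidences and were never observed in the randomized validation panels;
phased input avoids the issue entirely.  This is why the two input modes
are reported to agree to better than 99% yet are not guaranteed identical.

## Numerical choices

- $r^2$ is evaluated as a ratio of integer-valued quantities,
  $(N\,\mathrm{cross} - s_j s_k)^2 / ((N\,q_j - s_j^2)(N\,q_k - s_k^2))$
  with $N = 2n$ (phased) or $n$ (counts) and $q$ the sum of squares.  At
  validation scale all intermediates are exact in double precision.
- The threshold comparison is strict ($r^2 > t$) with no epsilon, evaluated
  as `numerator > (t * den_j) * den_k`; the reference oracle uses the same
  association so borderline pairs reproduce bit-for-bit.
- Zero-variance loci are excluded up front and reported: MAC-0 loci in
  either mode, plus all-heterozygote columns in count mode (MAC $= n$ but
  zero genotype variance, so $r^2_{ac}$ is undefined).
- Stored allele codes are never rewritten for orientation; a flag plus
  oriented prefix sums carry all orientation-dependent state.
- Ties everywhere break on input order, which is preserved from the input
  file; of identical loci the *last* in the data survives (a direct
  consequence of removing the earlier locus of each detected pair).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `t` | 0.99 | $r^2$ threshold, strictly in (0, 1).  Below ~0.8 the candidate interval widens sharply and the screen loses its advantage. |
| `mode` | by input | `"phased"` uses haplotypes (requires phased input); `"counts"` uses genotypes. |
| `subset_count` | 10 | partial-sum prefixes; more subsets reject earlier but cost more memory per locus. |
| `workers` | 1 | forked parallelism over sorted positions; results are identical for any value. |

## The synthetic generator

`generate_base_panel()` draws each locus independently (frequency uniform
in `[maf_low, maf_high]`, default 0.05--0.5, then $2n$ Bernoulli alleles),
with round-robin chromosome/position metadata; `plant_duplicate()` appends
exact copies, complemented copies, or copies perturbed by flipping a chosen
number of haplotype entries, with the pair's true $r^2$ recomputed from the
data.  There is deliberately no recombination or demographic model: the
pruner is position-agnostic, so the LD structure that matters is planted
explicitly and verified by a brute-force all-pairs oracle
(`brute_force_prune()`), which applies the identical removal rule to
directly-computed $r^2$ values.

What this does and does not show: passing the oracle-equivalence suite
demonstrates the screening machinery loses nothing and the decision rule is
applied exactly, on panels whose LD is pairwise and planted.  It does not
demonstrate behaviour under realistic LD decay, linked backgrounds, or the
allele-frequency spectra of real populations, and the count-mode caveat
above is exercised only by the exhaustive small-column enumeration.

A scale note: with $n = 100$ individuals, two distinct columns differing in
at least one haplotype cannot have $r^2$ between $\approx 0.98$ and 1, so
at $t = 0.99$ the standard validation panels exercise an empty high-LD
stage by design; high-LD removals are validated separately at $n = 300$
(where one flipped haplotype on a common locus gives $r^2 \approx 0.993$)
and at lower thresholds.

## Validation problem sizes

The test suite runs entirely on generated data: 50 seeded panels of
$n = 100$, $m = 1000$ base loci plus 60 planted pairs for oracle
equivalence in both modes; exhaustive enumerations of all genotype columns
of length 6 and all phased columns of 10 haplotypes for screen soundness;
all $n \le 50$ for bound-table correctness; and $n = 300$ panels for active
high-LD pruning.  The whole suite and the acceptance script each complete
in well under a minute on one core.

## Known limitations

- Missing genotypes are rejected outright (optionally, affected loci can be
  dropped).  Extending the counting arguments to tolerate missingness is
  possible but not implemented.
- No mismatch tolerance in the complete-LD stage: a single genotyping error
  hides a duplicate from stage one (it may still be caught by stage two if
  $r^2$ stays above the threshold).
- Count mode can, in principle, keep both members of an affine-related
  genotype pair (see above).
- No sliding-window mode; `window_cost()` only quantifies what a window
  pruner would compute, for comparison.
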