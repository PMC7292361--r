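---
title: "Reliability of MEC-based haplotype assembly: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reliability of MEC-based haplotype assembly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hapmec)
```

## The model

A diploid genome carries two haplotypes; at each heterozygous bi-allelic
SNP one chromosome has the reference allele, the other the alternative.
Sequencing reads that span two or more SNPs constrain the relative phase
of those sites. hapmec encodes the data as a fragment matrix `R`
(`N` reads × `l` SNPs) over `{−1, 0, +1}`: `+1` reference, `−1`
alternative, 0 unobserved. Reads covering fewer than two SNPs carry no
phase information and are removed at construction.

The error process is reduced to *bi-substitutions*. A sequencing
substitution replaces a base by one of the other three; only the one
substitution that turns the reference allele into the alternative (or
vice versa) changes a matrix entry, so an entry flips sign with
probability `p_e = p_s / 3` for a device with substitution probability
`p_s`. Substitutions to the two non-allelic bases leave the site
unreadable at that read: in the `base_aware` error mode such entries are
erased (set to 0) with probability `2 p_s / 3`, while the `flip_only`
mode applies the pure sign-flip process with a user-given `p_e`. Both
modes treat entries as independent — the iid assumption under which the
reliability theory below is exact. Real long-read error processes are
not iid (indel-induced alignment artefacts cluster errors at specific
sites); the simulator therefore *understates* failure rates relative to a
full read-simulator-plus-alignment pipeline, and results here should be
read as best-case bounds for a given `(coverage, p_e)`.

The MEC objective charges each read the mismatch count against the better
of `h` and `−h` (a read's haplotype of origin is unknown), using the
extended Hamming distance `D`, which ignores positions where either
vector is 0. `D` is deliberately not a metric — distinct vectors with
disjoint support are at distance zero, and the triangle inequality can
fail (both properties are asserted in the test suite by exhaustive
search over `{−1,0,1}^3`).

## When MEC must fail, and when the inequality needs care

If the bi-substitution errors in column `k` form a *strict* majority of
its coverage, flipping the exact haplotype at `k` removes one mismatch
for each erroneous read covering `k` and adds at most one for each
correct read — a net strict improvement, so the exact haplotype cannot
minimise MEC. `failure_witness()` constructs this column-flip witness.

One subtlety discovered while validating the witness on randomly
perturbed instances: the per-read bookkeeping above assumes each
erroneous read is still (weakly) closer to its origin orientation than to
the complement. A read whose *other* errors make it closer to the
opposite haplotype contributes with reversed sign, and a small instance
can then satisfy the majority antecedent while the column flip only ties
the truth's MEC (a 3-read, 3-SNP example with one read 2/3 erroneous
does exactly this). With iid `p_e < 1/2` and reads spanning several
SNPs, orientation-flipped reads are rare, so the regime in which the
guarantee holds is the practically relevant one; the property-based
tests generate their instances in that regime (per-read background
errors below half the span) and verify the strict inequality in 100% of
200 instances against a brute-force minimiser.

A second boundary case: at even coverage, "errors exactly half of
coverage" is not a strict majority. The tail sum defining the per-column
success probability runs to `⌊c/2⌋`, counting the tie as a success, and
the package follows that summation convention throughout; the census of
"high bi-substitution" sites (`high_bisub_census()`) instead uses
`rate ≥ 0.5`, a deliberately distinct threshold matching how such sites
are flagged in practice. Both conventions are documented at their
definitions and tested separately.

## Reliability theory

With iid entry errors the per-column error count is `Binomial(c, p_e)`,
so the probability that no column defeats MEC factorises over columns:
`p_cmec()` accumulates `pbinom(floor(c/2), c, p_e, log.p = TRUE)` and
exponentiates the sum — numerically safe for `l` up to 10⁶ and depths up
to 10⁴ (the naive term-by-term product underflows long before that).

Coverage models: constant `c`; quasi-uniform (integer-uniform on
`[a, b]`, the discrete analogue of a uniform depth profile); and Poisson
with mean λ. The Poisson model is **zero-truncated** everywhere in the
package: a site with no reads is unobservable and cannot be phased, so
depth 0 is excluded from the support, mirroring the quasi-uniform ranges
starting at 1. Users comparing against untruncated Poisson expectations
should note the mean of the truncated law is `λ / (1 − e^{−λ})`.

`p_cmec_under_model()` offers two modes. `marginal` (default,
deterministic) returns `(E_c[per-column success])^l`, the exact
expectation under independent per-column depths; `sampled` draws one
depth per column and evaluates the product for that realisation. The
Monte-Carlo estimator `mc_cmec()` draws per-column error counts directly
from the binomial law — identical in distribution to flipping individual
entries and counting per column — and provides the independent
stochastic check used in the tests (agreement within three standard
errors at 20,000 trials across five coverage/error settings).

## Device evaluation

`device_profiles()` ships per-run characteristics (substitution
probability, reads per run, read length) for six machines spanning three
sequencing generations. `runs_needed()` inverts the averaged-coverage
(Lander-Waterman) relation `c_a = l_r N_t n / G` with a ceiling; the
genome length defaults to 3 × 10⁹ (human scale) and is configurable.
Two long-read devices land very close to an integer multiple of the
target coverage, where any difference in rounding convention changes the
run count; the tests therefore assert only the four rounding-robust
rows.

`evaluate_device()` derives `p_e = p_s/3` and computes P{c-MEC} under a
default of constant coverage 10 and `l = 1000`, with an applicability
verdict at a configurable threshold (default 0.5). The haplotype length
and coverage distribution behind any published per-device reliability
figure are rarely stated, and P{c-MEC} depends strongly on both — the
defaults here are the package's own, chosen so that short-read devices
sit near 1 and error-prone long-read devices fall clearly below the
threshold at coverage 10; the *ordering* of devices is invariant to
these choices (monotonicity in `p_e` is tested).

## The simulator

`generate_diplotype()` draws the SNP count as
`Binomial(genome_length, snp_rate)` with positions uniform without
replacement; the default rate of 1 SNP per 1,000 bases matches typical
human heterozygosity. Haplotype signs are iid uniform — sites are
treated as unlinked in the truth, which is conservative for switch-error
evaluation (no LD structure to exploit).

`sample_fragments()` assigns each read a haplotype of origin by a fair
coin (shotgun sequencing of a diploid mixes both chromosomes equally;
exact balance is deliberately not enforced) and copies the origin
haplotype's alleles at every covered SNP. Read placement is chosen per
coverage model so that the *realised per-column depth law is exactly the
analytic one*:

* Poisson λ: `N ~ Poisson(λ·(G + l_r − 1)/l_r)` reads with uniform
  starts on the widened window, giving exactly Poisson(λ) depth at every
  site (verified by a chi-square goodness-of-fit on columns spaced at
  least one read length apart — nearby columns share reads and are
  correlated, so they cannot serve as independent draws).
* constant `c`: the genome is tiled with `c` complete layers of abutting
  reads — depth exactly `c` everywhere.
* quasi-uniform `[a, b]`: read-length tiles receive
  `K ~ DiscreteUniform[a, b]` spanning reads each, giving the exact
  marginal at every site. Depths within a tile are shared; this
  correlation is the price of keeping reads contiguous and is
  documented rather than hidden.

Reads are single contiguous spans. Mate-pair gap structure is not
modelled: at SNP resolution a paired-end fragment is approximated by its
insert span (the Illumina-like profile uses 300 b for this reason).
There is no base-level FASTQ output, no indels and no alignment step —
replacing those stages with direct SNP-level sampling is the point of
the design, since it gives exact ground truth (origins and the full
error record) at negligible cost.

`inject_errors()` returns the corrupted matrix *and* the exact error
record; `column_stats()` recounts errors independently from the truth
and origins, and the two bookkeeping paths are required to agree exactly
in the tests. When base-aware erasure drops a read below two covered
SNPs the read is removed (with a message), and the error record is
renumbered to match the surviving matrix.

## Assemblers

`exact_mec_minimizer()` enumerates all `2^(l−1)` sign vectors with the
first coordinate fixed (haplotype and complement are one solution) and is
refused above `l = 22`; ties return the lexicographically smallest
minimiser (`+1` ordered before `−1`), so results are deterministic. It
exists to be an oracle, not a production solver.

`heuristic_assemble()` is an explicit stand-in for graph-cut style MEC
heuristics, and all simulation results produced by the package are
labelled as its output, not that of any external tool. Per phase-connected
block (connected components, via igraph, of the column graph induced by
read co-coverage) it chains majority votes of relative orientation along
a BFS tree for the initial haplotype, then alternates (a) assigning each
read to its closer orientation (ties stay aligned) and (b) resetting each
column to the majority vote of its assigned reads, stopping when the MEC
value stops improving (cap 100 iterations). The first start is the
deterministic chained initialisation; further restarts are random, and
the best MEC over restarts is kept, so doubling restarts can never hurt.
The suite checks the heuristic never beats the exact minimum, attains it
on error-free input, and reaches it in at least 90% of noisy 10-SNP
instances (a regression floor calibrated once against the exact solver).

Zero-coverage columns are reported as `NA` ("unknown"), never imputed.
`cluster_rows()` implements the final read bipartition: group 1 strictly
closer to `h`, group 2 strictly closer to `−h`, ties unassigned.

## Evaluation metrics

*Switch errors* count changes of relative orientation between
consecutive phased SNPs within a block, with each block's global
orientation free and the count resetting across block boundaries (the
standard convention for block-wise phasing evaluation; an isolated
interior flip costs two switches, a flip at a block edge one). The rate
divides by the full haplotype length `l`. *Block length* is measured in
phased SNPs per block — not genomic bases — because SNPs are the unit
the fragment model sees; unphased singletons are not blocks.

Coverage throughout the experiment drivers means the **total** per-site
depth pooled over both haplotypes; the per-haploid depth is half of it.
Both spellings appear explicitly in the documentation to avoid the
factor-of-two ambiguity common in phasing papers.

## Problem sizes and numerical choices

The experiment drivers default to scales chosen to make every
distributional claim testable in minutes on one core while keeping the
per-column depth laws exact: the census experiments use ~2×10⁴ SNPs
(20 Mb at 1 SNP/kb) for the high-coverage zero-failure check and 20
replicates of ~6×10³ SNPs for the low-coverage counterpart; the
assembly sweep uses 20 replicates per coverage in {10, 20, 30, 45} at
~5×10³ SNPs with 2 restarts. Replicate seeds are derived from one
master seed (`derive_seeds()`), so every driver is reproducible
bit-for-bit. Monte-Carlo comparisons use 20,000 trials and a
three-standard-error band. Binomial tails always go through `pbinom`;
products of per-column probabilities always go through log-space.

## Known limitations

* The iid error model cannot reproduce the clustered, alignment-induced
  failures of real long-read pipelines at intermediate coverages; an
  optional per-site error-rate heterogeneity hook was considered and left
  out of scope — users wanting it can pass site-specific rates by
  splitting the matrix and injecting errors per stratum.
* The exact solver is exponential by design; beyond 22 SNPs only the
  heuristic is available, and it carries no optimality guarantee.
* Only diploids are supported; the polyploid generalisation of MEC is a
  different objective and is out of scope.
* Quality strings are parsed and ignored: the objective is unweighted.
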