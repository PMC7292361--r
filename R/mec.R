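#' Mismatch indicator between two allele codes
#'
#' The elementary penalty underlying the extended Hamming distance: `1` when
#' both codes are observed (non-zero) and disagree, else `0`. Vectorised.
#'
#' @param a,b allele codes in `{-1, 0, +1}` (0 = unobserved).
#' @return integer 0/1 vector.
#' @examples
#' mismatch_indicator(1, -1)   # 1
#' mismatch_indicator(0, 1)    # 0
#' @export
mismatch_indicator <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (!all(a %in% c(-1L, 0L, 1L)) || !all(b %in% c(-1L, 0L, 1L)))
    stop("allele codes must be in {-1, 0, +1}")
  as.integer(a != 0L & b != 0L & a != b)
}

#' Extended Hamming distance between two allele vectors
#'
#' Counts positions where both vectors are non-zero and disagree. Despite the
#' name this is not a metric: two different vectors can be at distance zero
#' (whenever they never overlap in observed positions), and the triangle
#' inequality can fail. Those properties are what make partial reads
#' comparable to a full-length haplotype.
#'
#' @param a,b equal-length vectors over `{-1, 0, +1}`.
#' @return non-negative integer.
#' @export
extended_hamming <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  sum(mismatch_indicator(a, b))
}

#' Minimum error correction (MEC) objective
#'
#' For each read the better of the candidate haplotype `h` and its complement
#' `-h` is charged the mismatch count; the MEC value is the total over reads:
#' `sum_i min{ D(r_i, h), D(r_i, -h) }` with `D` the extended Hamming
#' distance. Invariant under `h -> -h`, so a haplotype and its complement are
#' one solution, as they should be for an unphased diploid.
#'
#' `h` may contain `NA` (or 0) at unphased columns; entries there are charged
#' to neither orientation, which is the convention needed to score per-block
#' assemblies that leave uncovered sites unphased.
#'
#' @param x a [fragment_matrix()].
#' @param h candidate haplotype: length-`n_snps` vector over `{-1, +1}`,
#'   optionally with `NA`/0 for unphased columns.
#' @return non-negative integer MEC value.
#' @examples
#' R <- fragment_matrix(read = c(1, 1), col = c(1, 2), allele = c(1, 1))
#' mec(R, c(1, -1))  # 1: either orientation leaves one mismatch
#' @export
mec <- function(x, h) {
  h <- as.integer(h)
  if (length(h) != x$n_snps)
    stop("haplotype length (", length(h), ") != n_snps (", x$n_snps, ")")
  h[is.na(h)] <- 0L
  if (!all(h %in% c(-1L, 0L, 1L))) stop("haplotype entries must be +1, -1 or NA")
  hv <- h[x$col]
  obs <- hv != 0L
  mism <- rowsum_int(as.integer(obs & x$allele != hv), x$read, x$n_reads)
  tot  <- rowsum_int(as.integer(obs),                  x$read, x$n_reads)
  sum(pmin(mism, tot - mism))
}

# fast grouped integer sums over read index (dense groups 1..n)
rowsum_int <- function(v, g, n) {
  out <- numeric(n)
  if (length(v)) {
    s <- rowsum(v, g)
    out[as.integer(rownames(s))] <- s[, 1L]
  }
  as.integer(out)
}

#' Per-column coverage, error counts and bi-substitution rates
#'
#' Against a known simulated truth, counts for every SNP column its coverage,
#' the number of entries that differ from the allele of the read's haplotype
#' of origin (bi-substitution errors), and their ratio, the bi-substitution
#' rate. A column whose rate strictly exceeds 1/2 makes the MEC objective
#' provably prefer a wrong haplotype (see [failure_witness()]).
#'
#' @param x a [fragment_matrix()].
#' @param truth the true haplotype `h_ex` (length `n_snps`, over `{-1, +1}`)
#'   or a [generate_diplotype()] truth object.
#' @param origin per-read haplotype-of-origin labels (1 = carries `+truth`,
#'   2 = carries `-truth`); defaults to the labels stored in `x`.
#' @return a tibble with columns `col`, `coverage`, `error_count`,
#'   `bisub_rate` (`NaN` where coverage is 0).
#' @export
column_stats <- function(x, truth, origin = x$origin) {
  h <- validate_haplotype(haplotype_of(truth), x$n_snps)
  if (is.null(origin)) stop("per-read origin labels are required")
  origin <- as.integer(origin)
  if (length(origin) != x$n_reads)
    stop("need one origin label per read with observed entries")
  if (!all(origin %in% c(1L, 2L))) stop("origin labels must be 1 or 2")
  sign_o <- c(1L, -1L)[origin[x$read]]
  err <- x$allele != sign_o * h[x$col]
  coverage <- tabulate(x$col, x$n_snps)
  error_count <- tabulate(x$col[err], x$n_snps)
  tibble::tibble(col = seq_len(x$n_snps), coverage = coverage,
                 error_count = error_count,
                 bisub_rate = error_count / coverage)
}

# accept a bare +/-1 vector or a sim_truth object wherever truth is expected
haplotype_of <- function(truth) {
  if (inherits(truth, "sim_truth")) truth$h_ex else truth
}

#' Majority-error failure witness for the MEC objective
#'
#' If some column's bi-substitution errors form a strict majority of its
#' coverage (`error_count / coverage > 1/2`), the haplotype equal to the
#' truth except sign-flipped at that column attains a strictly lower MEC
#' value than the truth itself — so no MEC minimiser can return the exact
#' haplotype. This function finds such a column and constructs the witness.
#'
#' A column at exactly rate 1/2 is not a witness (the antecedent is strict);
#' the census of "high" bi-substitution sites used in device evaluation
#' ([high_bisub_census()]) separately uses a `>= 0.5` threshold — the two
#' cutoffs are deliberately distinct.
#'
#' @param x a [fragment_matrix()].
#' @param h_ex the exact haplotype the instance was generated from.
#' @param stats per-column statistics from [column_stats()] computed against
#'   `h_ex`; computed here if omitted (requires origin labels in `x`).
#' @return `NULL` when no column qualifies; otherwise a list with elements
#'   `col` (the offending column, smallest index when several qualify),
#'   `h_d` (the witness haplotype), `mec_ex` and `mec_d` (MEC values of truth
#'   and witness; `mec_d < mec_ex` always holds).
#' @export
failure_witness <- function(x, h_ex, stats = NULL) {
  h_ex <- validate_haplotype(haplotype_of(h_ex), x$n_snps)
  if (is.null(stats)) stats <- column_stats(x, h_ex)
  bad <- which(stats$coverage > 0L &
                 stats$error_count * 2L > stats$coverage)
  if (!length(bad)) return(NULL)
  k <- bad[1L]
  h_d <- h_ex
  h_d[k] <- -h_d[k]
  list(col = k, h_d = h_d, mec_ex = mec(x, h_ex), mec_d = mec(x, h_d))
}
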