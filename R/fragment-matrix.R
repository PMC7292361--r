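#' Fragment matrix of sequencing reads over bi-allelic SNP sites
#'
#' A fragment matrix is the standard input object of haplotype assembly: an
#' `N x l` matrix whose rows are reads and whose columns are heterozygous
#' bi-allelic SNP sites. Each observed entry is `+1` (the read carries the
#' reference allele) or `-1` (the alternative allele); sites a read does not
#' cover are implicit zeros. The object stores only the observed entries in
#' triplet form, so matrices with millions of implicit zeros stay cheap.
#'
#' Reads covering fewer than two SNP sites carry no phase information and are
#' dropped at construction (a message reports how many); surviving rows are
#' renumbered `1..N` in their original order.
#'
#' @param read integer vector of read (row) indices, 1-based.
#' @param col integer vector of SNP (column) indices, 1-based.
#' @param allele integer vector of allele codes, each `+1` or `-1`.
#' @param n_snps number of SNP columns `l`. Defaults to `max(col)`.
#' @param origin optional integer vector (one per *input* read index) giving
#'   the simulated haplotype of origin, `1` (maternal, alleles `+h`) or `2`
#'   (paternal, alleles `-h`). Kept in step with any row filtering.
#' @param quiet suppress the dropped-read message.
#'
#' @return A `fragment_matrix` object: a list with integer vectors `read`,
#'   `col`, `allele`, counts `n_reads` and `n_snps`, and optional `origin`.
#' @examples
#' R <- fragment_matrix(read = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
#'                      allele = c(1, -1, -1, 1))
#' column_coverage(R)
#' @export
fragment_matrix <- function(read, col, allele, n_snps = NULL, origin = NULL,
                            quiet = FALSE) {
  read <- as.integer(read); col <- as.integer(col); allele <- as.integer(allele)
  stopifnot(length(read) == length(col), length(col) == length(allele))
  if (length(allele) && !all(allele == 1L | allele == -1L))
    stop("allele codes must be +1 or -1 (0 is encoded by absence)")
  if (length(col) && min(col) < 1L) stop("column indices must be >= 1")
  if (length(read) && min(read) < 1L) stop("read indices must be >= 1")
  if (is.null(n_snps)) n_snps <- if (length(col)) max(col) else 0L
  n_snps <- as.integer(n_snps)
  if (length(col) && max(col) > n_snps) stop("column index exceeds n_snps")
  if (anyDuplicated(cbind(read, col)))
    stop("duplicate (read, col) entry in fragment matrix")

  # drop reads with < 2 observed sites: uninformative for phasing
  n_in <- if (length(read)) max(read) else 0L
  per_read <- tabulate(read, n_in)
  keep_read <- which(per_read >= 2L)
  n_dropped <- sum(per_read >= 1L) - length(keep_read)
  if (n_dropped > 0L && !quiet)
    message(n_dropped, " read(s) covering < 2 SNP sites dropped")
  new_id <- integer(n_in)
  new_id[keep_read] <- seq_along(keep_read)
  keep <- per_read[read] >= 2L
  out <- structure(
    list(read = new_id[read[keep]], col = col[keep], allele = allele[keep],
         n_reads = length(keep_read), n_snps = n_snps,
         origin = if (!is.null(origin)) as.integer(origin)[keep_read]),
    class = "fragment_matrix")
  if (!is.null(out$origin) && length(out$origin) != out$n_reads)
    stop("origin must have one label per input read")
  out
}

#' @export
print.fragment_matrix <- function(x, ...) {
  cat("<fragment_matrix> ", x$n_reads, " reads x ", x$n_snps, " SNPs, ",
      length(x$allele), " observed entries\n", sep = "")
  cov <- column_coverage(x)
  cat("  column coverage: min ", if (x$n_snps) min(cov) else NA,
      ", mean ", if (x$n_snps) round(mean(cov), 2) else NA,
      ", max ", if (x$n_snps) max(cov) else NA, "\n", sep = "")
  if (!is.null(x$origin)) cat("  read origins recorded (simulated truth)\n")
  invisible(x)
}

#' @importFrom tibble as_tibble
#' @method as_tibble fragment_matrix
#' @export
as_tibble.fragment_matrix <- function(x, ...) {
  tibble::tibble(read = x$read, col = x$col, allele = x$allele)
}

#' @export
as.matrix.fragment_matrix <- function(x, ...) {
  m <- matrix(0L, x$n_reads, x$n_snps)
  m[cbind(x$read, x$col)] <- x$allele
  m
}

#' @rdname fragment_matrix
#' @param x a `fragment_matrix`.
#' @export
n_reads <- function(x) x$n_reads

#' @rdname fragment_matrix
#' @export
n_snps <- function(x) x$n_snps

#' Per-column read coverage
#'
#' Coverage of SNP column `k` is the number of reads with an observed allele
#' there, i.e. the number of stored entries in that column.
#'
#' @param x a [fragment_matrix()].
#' @return integer vector of length `n_snps`.
#' @export
column_coverage <- function(x) tabulate(x$col, x$n_snps)

#' Flip the sign of selected fragment-matrix entries
#'
#' Deterministically inverts the allele code at the given (read, column)
#' positions — the building block for constructing instances with a
#' prescribed error pattern, e.g. a column whose errors form a strict
#' majority. Positions must refer to observed entries.
#'
#' @param x a [fragment_matrix()].
#' @param read,col equal-length vectors of entry positions to flip.
#' @return the modified `fragment_matrix`.
#' @export
flip_entries <- function(x, read, col) {
  stopifnot(length(read) == length(col))
  idx <- match(paste(read, col), paste(x$read, x$col))
  if (anyNA(idx)) stop("cannot flip an unobserved entry")
  x$allele[idx] <- -x$allele[idx]
  x
}

validate_haplotype <- function(h, l, allow_na = FALSE) {
  h <- as.integer(h)
  if (length(h) != l)
    stop("haplotype length (", length(h), ") != number of SNP columns (", l, ")")
  ok <- h == 1L | h == -1L
  if (allow_na) ok <- ok | is.na(h)
  if (!all(ok)) stop("haplotype entries must be +1 or -1")
  h
}
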