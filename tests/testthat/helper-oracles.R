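# Independent oracles and fixture builders used across the suite.
# Everything here is deliberately naive (double loops, dense matrices,
# exhaustive enumeration) so it shares no code path with the package.

# naive extended Hamming distance on dense +/-1/0 vectors
oracle_ehd <- function(a, b) {
  s <- 0L
  for (k in seq_along(a))
    if (a[k] != 0 && b[k] != 0 && a[k] != b[k]) s <- s + 1L
  s
}

# naive MEC: per-row min over the two orientations, rows as dense vectors
oracle_mec <- function(dense, h) {
  tot <- 0L
  for (i in seq_len(nrow(dense)))
    tot <- tot + min(oracle_ehd(dense[i, ], h), oracle_ehd(dense[i, ], -h))
  tot
}

# exhaustive global MEC minimum over all 2^l sign vectors
oracle_mec_min <- function(dense) {
  l <- ncol(dense)
  best <- Inf
  for (code in 0:(2^l - 1)) {
    h <- 1L - 2L * ((code %/% 2^(seq_len(l) - 1L)) %% 2L)
    best <- min(best, oracle_mec(dense, h))
  }
  best
}

# plain union-find over columns co-covered by a read
oracle_components <- function(dense) {
  l <- ncol(dense)
  parent <- seq_len(l)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(nrow(dense))) {
    cols <- which(dense[i, ] != 0)
    if (length(cols) > 1L)
      for (k in cols[-1L]) {
        a <- find(cols[1L]); b <- find(k)
        if (a != b) parent[b] <- a
      }
  }
  vapply(seq_len(l), find, integer(1))
}

# random sparse fragment instance built directly (no genome machinery):
# truth signs, Bernoulli(1/2) origins, each read covers a random window of
# >= 2 columns, entries flipped iid with rate p_err
rand_instance <- function(n_reads, l, p_err = 0, min_span = 2L,
                          max_span = NULL) {
  if (is.null(max_span)) max_span <- l
  h <- sample(c(-1L, 1L), l, replace = TRUE)
  origin <- sample(c(1L, 2L), n_reads, replace = TRUE)
  rows <- integer(0); cols <- integer(0); alleles <- integer(0)
  for (i in seq_len(n_reads)) {
    span <- sample(min_span:max_span, 1L)
    start <- sample(seq_len(l - span + 1L), 1L)
    cc <- start:(start + span - 1L)
    a <- h[cc] * c(1L, -1L)[origin[i]]
    flip <- stats::runif(length(a)) < p_err
    rows <- c(rows, rep.int(i, length(cc)))
    cols <- c(cols, cc)
    alleles <- c(alleles, ifelse(flip, -a, a))
  }
  list(R = fragment_matrix(rows, cols, alleles, n_snps = l, origin = origin,
                           quiet = TRUE),
       h = h, origin = origin)
}

# instance whose column k carries a strict majority of errors: constant
# coverage c (every read spans all columns), n_bad = floor(c/2) + 1 flips.
# Background errors are kept below half of each erroneous read's span so
# every such read stays (weakly) closer to its origin orientation — the
# regime in which a flipped column provably lowers the MEC; a read whose
# background errors flip its preferred orientation can neutralise the
# majority argument (see the methods discussion of the failure condition).
majority_instance <- function(l, c, extra_rate = 0.05) {
  h <- sample(c(-1L, 1L), l, replace = TRUE)
  origin <- sample(c(1L, 2L), c, replace = TRUE)
  k <- sample.int(l, 1L)
  n_bad <- floor(c / 2) + 1L
  bad_reads <- sample.int(c, n_bad)
  rows <- integer(0); cols <- integer(0); flips <- logical(0)
  for (i in seq_len(c)) {
    forced <- i %in% bad_reads
    extra <- which(stats::runif(l) < extra_rate & seq_len(l) != k)
    cap <- max(0L, floor(l / 2) - as.integer(forced))
    if (length(extra) > cap) extra <- extra[seq_len(cap)]
    fl <- logical(l)
    fl[extra] <- TRUE
    fl[k] <- forced
    rows <- c(rows, rep.int(i, l)); cols <- c(cols, seq_len(l))
    flips <- c(flips, fl)
  }
  alleles <- h[cols] * c(1L, -1L)[origin[rows]]
  R <- fragment_matrix(rows, cols, ifelse(flips, -alleles, alleles),
                       n_snps = l, origin = origin, quiet = TRUE)
  list(R = R, h = h, origin = origin, k = k)
}

# worked five-SNP example: C/T, C/G, G/T, A/C, A/G with haplotype 1
# carrying C G T A G (signs + - - + -)
example_truth <- function() {
  diplotype_from_sites(pos = c(14L, 19L, 25L, 33L, 38L),
                       ref = c("C", "C", "G", "A", "A"),
                       alt = c("T", "G", "T", "C", "G"),
                       h_ex = c(1L, -1L, -1L, 1L, -1L),
                       genome_length = 40L)
}
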