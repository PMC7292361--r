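#' Exact MEC minimiser by exhaustive enumeration
#'
#' Enumerates every sign vector with the first phased coordinate fixed to
#' `+1` (the `h ~ -h` equivalence halves the space) and returns a global
#' minimiser of the MEC objective together with its value. Intended as the
#' small-instance oracle: the search is `2^(l-1)` and is refused for
#' `l > 22` — use [heuristic_assemble()] beyond that.
#'
#' Ties are broken deterministically: the lexicographically smallest
#' minimiser is returned, with `+1` ordered before `-1`.
#'
#' @param x a [fragment_matrix()].
#' @return list with `h_opt` (sign vector of length `n_snps`) and `mec`
#'   (the global minimum).
#' @export
exact_mec_minimizer <- function(x) {
  l <- x$n_snps
  if (l > 22L)
    stop("exhaustive search refused for l = ", l,
         " (> 22 SNPs); use heuristic_assemble() instead")
  if (l < 1L) stop("empty fragment matrix")
  k <- l - 1L
  n_cand <- bitwShiftL(1L, k)
  # lexicographic enumeration, +1 < -1: candidate i has sign pattern given
  # by the big-endian bits of i over columns 2..l (bit 1 -> -1)
  H <- matrix(1L, n_cand, l)
  if (k > 0L) {
    for (j in seq_len(k)) {
      bit <- bitwShiftR(seq_len(n_cand) - 1L, k - j) %% 2L
      H[, j + 1L] <- 1L - 2L * bit
    }
  }
  if (as.numeric(n_cand) * length(x$allele) > 2e8)
    stop("instance too large for dense enumeration (", n_cand, " x ",
         length(x$allele), " comparisons)")
  # mismatches of every candidate against every entry, summed per read
  Hsub <- H[, x$col, drop = FALSE]
  M <- Hsub != matrix(x$allele, n_cand, length(x$allele), byrow = TRUE)
  mode(M) <- "integer"
  per_read <- t(rowsum(t(M), group = x$read))          # n_cand x reads
  cov_read <- tabulate(x$read, x$n_reads)
  vals <- rowSums(pmin(per_read,
                       matrix(cov_read, n_cand, x$n_reads, byrow = TRUE)
                       - per_read))
  best <- which.min(vals)                              # first = lexic. smallest
  list(h_opt = H[best, ], mec = as.integer(vals[best]))
}

#' Partition SNP columns into phase-connected blocks
#'
#' Two columns can be phased relative to one another only if some chain of
#' reads connects them; blocks are the connected components of the graph on
#' columns whose edges join columns co-covered by a read. Zero-coverage
#' columns form singleton unphased blocks. Components are computed with
#' igraph; block ids are assigned in order of each block's smallest column.
#'
#' @param x a [fragment_matrix()].
#' @return tibble with one row per column: `col`, `block`, `phased`
#'   (logical, FALSE for zero-coverage singletons).
#' @export
define_blocks <- function(x) {
  l <- x$n_snps
  cov <- column_coverage(x)
  edges <- read_adjacency(x)
  g <- igraph::make_empty_graph(n = l, directed = FALSE)
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$from, edges$to))
  comp <- igraph::components(g)$membership
  # renumber blocks by smallest member column
  first_col <- stats::ave(seq_len(l), comp, FUN = min)
  block <- match(first_col, sort(unique(first_col)))
  tibble::tibble(col = seq_len(l), block = as.integer(block),
                 phased = cov > 0L)
}

# consecutive co-covered column pairs per read; sufficient for connectivity
read_adjacency <- function(x) {
  o <- order(x$read, x$col)
  r <- x$read[o]; cc <- x$col[o]
  same <- which(r[-1L] == r[-length(r)])
  if (!length(same)) return(tibble::tibble(from = integer(), to = integer()))
  tibble::tibble(from = cc[same], to = cc[same + 1L])
}

#' Heuristic MEC assembly by alternating reassignment
#'
#' A local-search stand-in for graph-cut MEC heuristics. Each block is
#' initialised by chaining majority votes of relative orientation along a
#' spanning tree of co-covered columns, then the solver alternates (a)
#' assigning each read to its nearer haplotype orientation and (b) resetting
#' every column sign to the majority vote of its assigned reads, until the
#' MEC value stops improving. The best result over `restarts` seeded
#' starts (the first deterministic, the rest random) is kept, so the
#' achieved MEC is non-increasing in `restarts`.
#'
#' @param x a [fragment_matrix()].
#' @param restarts number of starts (default 3).
#' @param seed optional integer seed for the random restarts.
#' @param max_iter iteration cap per start.
#' @return a `hap_assembly` object: list with `haplotype` (length-`n_snps`
#'   sign vector, `NA` at unphased columns), `blocks` (the [define_blocks()]
#'   tibble), `mec`, `restarts`, `iterations` (total across starts).
#' @export
heuristic_assemble <- function(x, restarts = 3L, seed = NULL,
                               max_iter = 100L) {
  blocks <- define_blocks(x)
  phased <- column_coverage(x) > 0L
  with_seed_if(seed, {
    best_h <- NULL; best_mec <- Inf; iter_total <- 0L
    for (r in seq_len(max(1L, restarts))) {
      h0 <- if (r == 1L) chained_init(x, blocks, phased)
            else ifelse(phased, sample(c(-1L, 1L), x$n_snps, TRUE),
                        NA_integer_)
      res <- refine_haplotype(x, h0, max_iter)
      iter_total <- iter_total + res$iterations
      if (res$mec < best_mec) { best_mec <- res$mec; best_h <- res$h }
    }
    structure(list(haplotype = best_h, blocks = blocks,
                   mec = as.integer(best_mec),
                   restarts = as.integer(max(1L, restarts)),
                   iterations = iter_total),
              class = "hap_assembly")
  })
}

# majority-vote chaining along a BFS tree of the column adjacency graph
chained_init <- function(x, blocks, phased) {
  l <- x$n_snps
  h <- rep(NA_integer_, l)
  edges <- read_adjacency(x)
  if (nrow(edges)) {
    # aggregate relative-orientation votes per column pair
    o <- order(x$read, x$col)
    r <- x$read[o]; cc <- x$col[o]; aa <- x$allele[o]
    same <- which(r[-1L] == r[-length(r)])
    key <- paste(cc[same], cc[same + 1L])
    vote <- rowsum(aa[same] * aa[same + 1L], key)
    pair <- do.call(rbind, strsplit(rownames(vote), " ", fixed = TRUE))
    from <- as.integer(pair[, 1L]); to <- as.integer(pair[, 2L])
    adj <- split(seq_along(from), from)
    adj_rev <- split(seq_along(to), to)
    w <- vote[, 1L]
    for (b in unique(blocks$block[phased])) {
      cols <- blocks$col[blocks$block == b & phased]
      root <- cols[1L]
      h[root] <- 1L
      queue <- root
      while (length(queue)) {
        u <- queue[1L]; queue <- queue[-1L]
        ei <- c(adj[[as.character(u)]], adj_rev[[as.character(u)]])
        for (e in ei) {
          v <- if (from[e] == u) to[e] else from[e]
          if (!is.na(h[v])) next
          s <- sign(w[e])
          h[v] <- h[u] * if (s == 0) 1L else as.integer(s)
          queue <- c(queue, v)
        }
      }
    }
  }
  h[is.na(h) & phased] <- 1L   # isolated phased columns (no pair votes)
  h
}

# alternate read-orientation / column-majority updates until MEC stalls
refine_haplotype <- function(x, h, max_iter) {
  best <- mec(x, h)
  it <- 0L
  repeat {
    it <- it + 1L
    hv <- h[x$col]; hv[is.na(hv)] <- 0L
    agree <- rowsum_int(as.integer(hv != 0L & x$allele == hv), x$read,
                        x$n_reads)
    tot <- rowsum_int(as.integer(hv != 0L), x$read, x$n_reads)
    orient <- ifelse(agree * 2L >= tot, 1L, -1L)   # tie -> aligned
    votes <- rowsum_int(orient[x$read] * x$allele, x$col, x$n_snps)
    h_new <- h
    upd <- !is.na(h) & votes != 0L
    h_new[upd] <- as.integer(sign(votes[upd]))
    val <- mec(x, h_new)
    if (val < best) { best <- val; h <- h_new } else break
    if (it >= max_iter) break
  }
  list(h = h, mec = best, iterations = it)
}

#' @export
print.hap_assembly <- function(x, ...) {
  nb <- length(unique(x$blocks$block[x$blocks$phased]))
  cat("<hap_assembly> MEC ", x$mec, ", ", nb, " phased block(s), ",
      sum(x$blocks$phased), "/", nrow(x$blocks), " SNPs phased\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-SNP view of an assembly
#'
#' @param x a `hap_assembly`.
#' @param ... unused.
#' @return tibble with `col`, `block`, `phased`, `sign` (`NA` unphased).
#' @method tidy hap_assembly
#' @export
tidy.hap_assembly <- function(x, ...) {
  dplyr::mutate(x$blocks, sign = x$haplotype)
}

#' One-row summary of an assembly
#'
#' @param x a `hap_assembly`.
#' @param ... unused.
#' @return tibble with `mec`, `n_blocks`, `avg_block_length`, `n_phased`,
#'   `restarts`, `iterations`.
#' @method glance hap_assembly
#' @export
glance.hap_assembly <- function(x, ...) {
  ph <- x$blocks[x$blocks$phased, ]
  nb <- length(unique(ph$block))
  tibble::tibble(mec = x$mec, n_blocks = nb,
                 avg_block_length = if (nb) nrow(ph) / nb else NA_real_,
                 n_phased = nrow(ph), restarts = x$restarts,
                 iterations = x$iterations)
}

#' Cluster reads by haplotype orientation
#'
#' Step two of the MEC procedure: once a haplotype is fixed, each read goes
#' to group 1 if it is strictly closer (extended Hamming) to `h` than to
#' `-h`, group 2 if strictly closer to `-h`, and stays unassigned (`NA`) on
#' a tie.
#'
#' @param x a [fragment_matrix()].
#' @param h haplotype (may contain `NA` at unphased columns).
#' @return tibble with `read`, `group` (1, 2 or `NA`).
#' @export
cluster_rows <- function(x, h) {
  h <- as.integer(h); h[is.na(h)] <- 0L
  if (length(h) != x$n_snps) stop("haplotype length mismatch")
  hv <- h[x$col]
  obs <- hv != 0L
  mism <- rowsum_int(as.integer(obs & x$allele != hv), x$read, x$n_reads)
  tot <- rowsum_int(as.integer(obs), x$read, x$n_reads)
  agree <- tot - mism
  group <- ifelse(mism < agree, 1L, ifelse(mism > agree, 2L, NA_integer_))
  tibble::tibble(read = seq_len(x$n_reads), group = group)
}
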