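#' Simulate a diploid ground truth: SNP sites and the exact haplotype
#'
#' Places bi-allelic heterozygous SNPs along a genome of the given length at
#' the given per-base rate (site count `~ Binomial(genome_length, snp_rate)`,
#' positions uniform without replacement), draws a reference and a distinct
#' alternative base per site, and assigns the exact haplotype `h_ex` as iid
#' uniform signs: `+1` means haplotype 1 carries the reference allele at
#' that site, `-1` the alternative. The default rate of one SNP per
#' thousand bases matches typical human heterozygosity.
#'
#' @param genome_length genome size in bases.
#' @param snp_rate per-base probability of a heterozygous SNP, in `(0, 1)`.
#' @param seed optional integer seed; identical `(parameters, seed)` give
#'   bit-identical output. `NULL` uses the current RNG stream.
#' @return a `sim_truth` object: list with `sites` (tibble `pos`, `ref`,
#'   `alt`), `h_ex` (sign vector), `genome_length`, `snp_rate`, `seed`.
#' @examples
#' truth <- generate_diplotype(1e5, 1e-3, seed = 1)
#' truth$sites
#' @export
generate_diplotype <- function(genome_length, snp_rate = 1e-3, seed = NULL) {
  stopifnot(snp_rate > 0, snp_rate < 1, genome_length >= 1 / snp_rate)
  with_seed_if(seed, {
    n <- stats::rbinom(1L, as.integer(min(genome_length, .Machine$integer.max)),
                       snp_rate)
    if (n < 1L) stop("no SNP sites drawn; increase genome_length or snp_rate")
    pos <- sort(sample.int(as.integer(genome_length), n))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1),
                  USE.NAMES = FALSE)
    h_ex <- sample(c(-1L, 1L), n, replace = TRUE)
    new_sim_truth(pos, ref, alt, h_ex, genome_length, snp_rate, seed)
  })
}

#' Build a diplotype truth from explicitly given SNP sites
#'
#' Escape hatch for worked examples and regression fixtures: supply the
#' positions, alleles and haplotype signs directly instead of sampling them.
#'
#' @param pos strictly increasing 1-based genomic positions.
#' @param ref,alt single-character reference/alternative alleles per site,
#'   pairwise distinct.
#' @param h_ex haplotype sign vector (`+1` = haplotype 1 has `ref`).
#' @param genome_length genome size; defaults to `max(pos)`.
#' @return a `sim_truth` object.
#' @export
diplotype_from_sites <- function(pos, ref, alt, h_ex,
                                 genome_length = max(pos)) {
  stopifnot(length(pos) == length(ref), length(ref) == length(alt),
            length(alt) == length(h_ex))
  if (is.unsorted(pos, strictly = TRUE)) stop("positions must strictly increase")
  if (any(ref == alt)) stop("ref and alt alleles must differ at every site")
  new_sim_truth(as.integer(pos), ref, alt,
                validate_haplotype(h_ex, length(pos)),
                genome_length, length(pos) / genome_length, NULL)
}

new_sim_truth <- function(pos, ref, alt, h_ex, genome_length, snp_rate, seed) {
  structure(list(
    sites = tibble::tibble(pos = as.integer(pos), ref = ref, alt = alt),
    h_ex = as.integer(h_ex),
    genome_length = genome_length, snp_rate = snp_rate, seed = seed),
    class = "sim_truth")
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth> ", nrow(x$sites), " bi-allelic SNPs on ",
      format(x$genome_length, big.mark = ","), " bases\n", sep = "")
  invisible(x)
}

#' Allele strings of the two haplotypes
#'
#' Renders the sign vector of a truth object as the actual allele sequences
#' of haplotype 1 and haplotype 2.
#'
#' @param truth a `sim_truth`.
#' @return list with character vectors `hap1`, `hap2`.
#' @export
haplotype_alleles <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  s <- truth$sites
  list(hap1 = ifelse(truth$h_ex == 1L, s$ref, s$alt),
       hap2 = ifelse(truth$h_ex == 1L, s$alt, s$ref))
}

#' Read geometry and depth for the fragment simulator
#'
#' @param read_length read span in bases (for paired-end data, treat as the
#'   insert spanned by the pair; only SNP sites matter at this resolution).
#' @param coverage a `coverage_model` giving the per-site total depth over
#'   both haplotypes (see Details of [sample_fragments()]).
#' @return a `read_model` object.
#' @export
read_model <- function(read_length, coverage) {
  stopifnot(read_length >= 1, inherits(coverage, "coverage_model"))
  structure(list(read_length = as.integer(read_length), coverage = coverage),
            class = "read_model")
}

#' Sample error-free reads from a diplotype into a fragment matrix
#'
#' Generates reads on the genome, assigns each a haplotype of origin with
#' probability 1/2 each (as in shotgun sequencing of a diploid), and records
#' the origin haplotype's allele at every SNP the read spans. Reads covering
#' fewer than two SNPs are discarded. The result is an error-free fragment
#' matrix whose MEC against the exact haplotype is zero.
#'
#' Read placement depends on the coverage model:
#' \describe{
#'   \item{poisson}{`N ~ Poisson(lambda * G / l_r)` reads with uniform
#'     starts, so per-site depth is exactly Poisson(`lambda`) marginally
#'     (depth-0 sites simply receive no entries).}
#'   \item{constant}{the genome is tiled with `c` complete layers of
#'     abutting reads: every site has depth exactly `c`.}
#'   \item{quasi_uniform}{the genome is cut into read-length tiles and each
#'     tile receives `K ~ DiscreteUniform[a, b]` spanning reads, so each
#'     site's depth has exactly the quasi-uniform marginal (sites within a
#'     tile share their depth, the unavoidable correlation of contiguous
#'     reads).}
#' }
#' Depth here counts reads from both haplotypes together (total depth);
#' per-haploid depth is on average half of it.
#'
#' @param truth a `sim_truth`.
#' @param model a [read_model()].
#' @param seed optional integer seed.
#' @return a [fragment_matrix()] with per-read `origin` labels stored.
#' @export
sample_fragments <- function(truth, model, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(model, "read_model"))
  with_seed_if(seed, {
    G <- truth$genome_length
    lr <- model$read_length
    cm <- model$coverage
    if (cm$kind == "poisson") {
      # uniform starts on a window widened by lr-1 so every genomic site is
      # coverable by exactly lr start positions: per-site depth is then
      # exactly Poisson(lambda) marginally
      window <- as.numeric(G) + lr - 1
      n_reads <- stats::rpois(1L, cm$lambda * window / lr)
      start <- sample.int(as.integer(window), n_reads, replace = TRUE) -
        lr + 1L
    } else {
      n_tiles <- ceiling(G / lr)
      layers <- if (cm$kind == "constant") rep(cm$c, n_tiles)
                else sample.int(cm$b - cm$a + 1L, n_tiles, replace = TRUE) +
                     cm$a - 1L
      start <- rep.int((seq_len(n_tiles) - 1L) * lr + 1L, layers)
      n_reads <- length(start)
    }
    if (n_reads < 1L) stop("no reads generated; increase coverage or genome")
    end <- start + lr - 1L
    pos <- truth$sites$pos
    if (lr < max(1L, min(diff(pos), Inf)))
      warning("read length below minimum SNP spacing: most reads cover < 2 ",
              "SNPs and will be discarded")
    lo <- findInterval(start - 1L, pos) + 1L   # first SNP index >= start
    hi <- findInterval(end, pos)               # last  SNP index <= end
    cnt <- pmax(0L, hi - lo + 1L)
    origin <- sample(c(1L, 2L), n_reads, replace = TRUE)
    rr <- rep.int(seq_len(n_reads), cnt)
    cols <- sequence(cnt, from = lo)
    allele <- truth$h_ex[cols] * c(1L, -1L)[origin[rr]]
    fragment_matrix(read = rr, col = cols, allele = allele,
                    n_snps = length(pos), origin = origin, quiet = TRUE)
  })
}

#' Inject bi-substitution errors into a fragment matrix
#'
#' Two error modes mirror how sequencing substitutions reach the fragment
#' matrix. In `flip_only`, every observed entry independently flips sign
#' with probability `p` — the pure additive bi-substitution model. In
#' `base_aware`, `p` is the device's substitution probability `p_s`: an
#' entry flips with `p_s/3` (the one substitution that lands on the other
#' allele) and is erased with `2*p_s/3` (substitutions to the two
#' non-allelic bases cannot be encoded, so the site drops out of the read).
#' Reads left with fewer than two entries after erasure are removed.
#'
#' @param x a [fragment_matrix()].
#' @param p flip probability `p_e` (`flip_only`) or substitution
#'   probability `p_s` (`base_aware`), in `[0, 1]`.
#' @param mode `"flip_only"` or `"base_aware"`.
#' @param seed optional integer seed.
#' @return list with `fragments` (the corrupted matrix), `flips` (tibble
#'   `read`, `col` of flipped entries, read indices matching the returned
#'   matrix), `deletions` (tibble of erased entries, base_aware only),
#'   `n_entries_dropped` (entries lost because their read fell below two
#'   sites), `p`, `mode`.
#' @export
inject_errors <- function(x, p, mode = c("flip_only", "base_aware"),
                          seed = NULL) {
  mode <- match.arg(mode)
  if (p < 0 || p > 1) stop("error probability must be in [0, 1]")
  with_seed_if(seed, {
    n <- length(x$allele)
    u <- stats::runif(n)
    if (mode == "flip_only") {
      flip <- u < p
      keep <- rep(TRUE, n)
    } else {
      flip <- u < p / 3
      keep <- flip | u >= p         # erase when p/3 <= u < p
    }
    allele <- ifelse(flip, -x$allele, x$allele)
    deletions <- tibble::tibble(read = x$read[!keep], col = x$col[!keep])
    # rebuild (constructor renumbers rows dropped below 2 entries)
    out <- fragment_matrix(read = x$read[keep], col = x$col[keep],
                           allele = allele[keep], n_snps = x$n_snps,
                           origin = x$origin, quiet = TRUE)
    n_dropped <- x$n_reads - out$n_reads
    if (n_dropped > 0L)
      message(n_dropped, " read(s) fell below 2 covered SNPs after ",
              "base-aware erasure and were removed")
    # flips surviving in the returned matrix, with its read numbering
    surv <- flip & keep
    per_read_after <- tabulate(x$read[keep], x$n_reads)
    kept_read <- per_read_after >= 2L
    new_id <- integer(x$n_reads)
    new_id[kept_read] <- seq_len(sum(kept_read))
    surv <- surv & kept_read[x$read]
    flips <- tibble::tibble(read = new_id[x$read[surv]], col = x$col[surv])
    list(fragments = out, flips = flips, deletions = deletions,
         n_entries_dropped = sum(keep) - length(out$allele),
         p = p, mode = mode)
  })
}

#' Simulate a full device dataset: truth, reads and errors
#'
#' Composes [generate_diplotype()], [sample_fragments()] (Poisson total
#' depth with mean `mean_coverage`, device read length) and
#' [inject_errors()] with the device's substitution probability
#' (`base_aware` by default; `flip_only` applies `p_s/3` directly as a pure
#' bi-substitution rate).
#'
#' @param device a device name matched against [device_profiles()], or a
#'   one-row tibble with columns `p_s` and `read_length`.
#' @param genome_length genome size in bases.
#' @param snp_rate per-base heterozygous SNP rate (default 1e-3).
#' @param mean_coverage mean per-site total depth (both haplotypes; the
#'   per-haploid mean is half of this).
#' @param seed optional integer seed for the whole composition.
#' @param error_mode `"base_aware"` (default) or `"flip_only"`.
#' @return list with `fragments` (a [fragment_matrix()]), `truth`
#'   (`sim_truth`), `flips`, `deletions`, `device` (the profile row used).
#' @export
simulate_device_dataset <- function(device, genome_length, snp_rate = 1e-3,
                                    mean_coverage = 10, seed = NULL,
                                    error_mode = c("base_aware",
                                                   "flip_only")) {
  error_mode <- match.arg(error_mode)
  dev <- resolve_device(device)
  with_seed_if(seed, {
    truth <- generate_diplotype(genome_length, snp_rate)
    rm_ <- read_model(dev$read_length, poisson_coverage(mean_coverage))
    clean <- sample_fragments(truth, rm_)
    p <- if (error_mode == "base_aware") dev$p_s else dev$p_s / 3
    inj <- inject_errors(clean, p, mode = error_mode)
    list(fragments = inj$fragments, truth = truth,
         flips = inj$flips, deletions = inj$deletions, device = dev)
  })
}

resolve_device <- function(device) {
  if (is.character(device)) {
    tab <- device_profiles()
    hit <- grep(device, tab$device, ignore.case = TRUE, fixed = FALSE)
    if (length(hit) != 1L)
      stop("device '", device, "' matches ", length(hit),
           " built-in profiles; supply a one-row tibble instead")
    tab[hit, ]
  } else {
    stopifnot(is.data.frame(device), nrow(device) == 1L,
              all(c("p_s", "read_length") %in% names(device)))
    device
  }
}

#' Deterministic replicate seeds from a master seed
#'
#' Derives `n` distinct sub-seeds (all below 2^31) so that multi-replicate
#' experiments are reproducible bit-for-bit from one master seed.
#'
#' @param seed master integer seed.
#' @param n number of replicate seeds.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(seed, n) {
  # headroom below 2^31 so callers can offset a derived seed by a few units
  with_seed_if(as.integer(seed), sample.int(.Machine$integer.max - 64L, n))
}
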