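#' Switch errors of an assembled haplotype against the truth
#'
#' Within each phased block, compare the estimated signs to the truth and
#' count the transitions in their relative orientation along consecutive
#' phased SNPs; the block orientation is free (a globally flipped block is
#' perfect), and orientation resets at block boundaries, so transitions are
#' never counted across blocks. The rate divides the total switch count by
#' the haplotype length `l` (all SNP columns, not just phased ones).
#'
#' @param truth the exact haplotype: a sign vector or `sim_truth`.
#' @param result a `hap_assembly` from [heuristic_assemble()], or any object
#'   with `haplotype` and `blocks` in the same shape.
#' @return one-row tibble: `switch_count`, `switch_error_rate`.
#' @examples
#' # an isolated flipped SNP inside a block creates two switches
#' @export
switch_error <- function(truth, result) {
  h_ex <- haplotype_of(truth)
  est <- result$haplotype
  blocks <- result$blocks
  if (is.null(est) || !length(est)) stop("empty assembly result")
  l <- length(h_ex)
  stopifnot(length(est) == l)
  ok <- blocks$phased & !is.na(est)
  switches <- 0L
  for (b in unique(blocks$block[ok])) {
    cols <- blocks$col[ok & blocks$block == b]
    if (length(cols) < 2L) next
    rel <- est[cols] * h_ex[cols]
    switches <- switches + sum(rel[-1L] != rel[-length(rel)])
  }
  tibble::tibble(switch_count = as.integer(switches),
                 switch_error_rate = switches / l)
}

#' Mean phased SNPs per haplotype block
#'
#' Block length is measured in phased SNPs (the unit the fragment model
#' sees), not genomic bases. Unphased zero-coverage singletons are not
#' blocks and are excluded.
#'
#' @param result a `hap_assembly` (or its `blocks` tibble).
#' @return mean block length (numeric).
#' @export
average_block_length <- function(result) {
  blocks <- if (is.data.frame(result)) result else result$blocks
  ph <- blocks[blocks$phased, ]
  if (!nrow(ph)) stop("no phased blocks")
  nrow(ph) / length(unique(ph$block))
}

#' Census of high bi-substitution SNP sites
#'
#' Counts columns whose bi-substitution rate reaches the threshold
#' (`>= threshold`; default 0.5, the boundary at which a site can defeat
#' the MEC objective). Zero-coverage columns are not counted.
#'
#' @param stats a [column_stats()] tibble.
#' @param threshold rate cutoff in `(0, 1]`.
#' @return integer count.
#' @export
high_bisub_census <- function(stats, threshold = 0.5) {
  stopifnot(threshold > 0, threshold <= 1)
  sum(stats$coverage > 0L & stats$bisub_rate >= threshold)
}

#' Combined evaluation metrics for one simulated assembly
#'
#' @param truth `sim_truth` (or sign vector).
#' @param result `hap_assembly`.
#' @param stats optional [column_stats()] tibble for the census column.
#' @param bisub_threshold census threshold (default 0.5).
#' @return one-row tibble: `mec`, `switch_count`, `switch_error_rate`,
#'   `avg_block_length`, `n_blocks`, and `high_bisub_count` when `stats`
#'   is supplied.
#' @export
eval_metrics <- function(truth, result, stats = NULL, bisub_threshold = 0.5) {
  g <- glance(result)
  sw <- switch_error(truth, result)
  out <- tibble::tibble(mec = g$mec, switch_count = sw$switch_count,
                        switch_error_rate = sw$switch_error_rate,
                        avg_block_length = g$avg_block_length,
                        n_blocks = g$n_blocks)
  if (!is.null(stats))
    out$high_bisub_count <- high_bisub_census(stats, bisub_threshold)
  out
}

default_pe_grid <- function() 10^seq(log10(1e-4), log10(0.5), length.out = 25)

default_theory_models <- function() {
  list(constant_coverage(2), constant_coverage(10), constant_coverage(100),
       quasi_uniform_coverage(1, 2), quasi_uniform_coverage(1, 10),
       quasi_uniform_coverage(1, 100),
       poisson_coverage(2), poisson_coverage(10), poisson_coverage(100))
}

#' Analytic performance-curve experiment
#'
#' Tabulates P{c-MEC} curves for a battery of coverage models at one
#' haplotype length (the nine canonical models: constant depth 2/10/100,
#' quasi-uniform over \[1,2\]/\[1,10\]/\[1,100\], Poisson mean 2/10/100),
#' and, separately, a length sweep (`l` = 100, 10k, 1M) for constant depths
#' 2/10/30. Both tables are deterministic (marginal mode).
#'
#' @param l haplotype length for the model battery (default 1000).
#' @param p_e_grid bi-substitution probability grid.
#' @param models list of `coverage_model`s (default: the nine above).
#' @param lengths,length_coverages the length-sweep settings.
#' @return list of two `performance_curve` tibbles: `by_model`, `by_length`.
#' @export
run_theory_experiment <- function(l = 1000, p_e_grid = default_pe_grid(),
                                  models = default_theory_models(),
                                  lengths = c(100, 1e4, 1e6),
                                  length_coverages = c(2, 10, 30)) {
  by_model <- dplyr::bind_rows(
    lapply(models, performance_curve, l = l, p_e_grid = p_e_grid))
  by_length <- dplyr::bind_rows(lapply(length_coverages, function(cc)
    dplyr::bind_rows(lapply(lengths, function(ll)
      performance_curve(constant_coverage(cc), ll, p_e_grid)))))
  class(by_model) <- c("performance_curve", class(tibble::tibble()))
  class(by_length) <- c("performance_curve", class(tibble::tibble()))
  list(by_model = by_model, by_length = by_length)
}

#' Default simulation error profiles
#'
#' Two stylised device profiles for SNP-level read simulation: an
#' Illumina-like short accurate profile (substitution probability 0.001,
#' 300 b span) and a PacBio-like long noisy profile (0.06, 20 kb). The
#' bi-substitution probability seen by the fragment matrix is `p_s / 3`.
#'
#' @return tibble with columns `profile`, `p_s`, `read_length`.
#' @export
default_sim_profiles <- function() {
  tibble::tribble(
    ~profile,        ~p_s,  ~read_length,
    "illumina-like", 0.001, 300,
    "pacbio-like",   0.06,  20e3)
}

#' High bi-substitution census across coverage levels
#'
#' For each (profile, coverage): simulate a device dataset, compute the
#' per-column bi-substitution statistics against the known truth, and count
#' sites at or above the census threshold. Also returns the per-rate
#' histogram of bi-substitution rates for each setting.
#'
#' @param coverages mean total depths to sweep (default 10, 15, 20, 25,
#'   30, 45).
#' @param profiles tibble with `profile`, `p_s`, `read_length` rows
#'   (default: an Illumina-like short-read and a PacBio-like long-read
#'   profile).
#' @param genome_length genome size per simulation (default 2e6, ~2000 SNPs
#'   at the default rate).
#' @param snp_rate per-base SNP rate.
#' @param threshold census cutoff (default 0.5).
#' @param error_mode passed to [simulate_device_dataset()]; `"flip_only"`
#'   applies the pure bi-substitution probability `p_s/3`.
#' @param seed master seed; per-setting seeds derived deterministically.
#' @return list with `census` (tibble: profile, coverage, n_snps_observed,
#'   high_bisub_count, seed) and `histogram` (tibble: profile, coverage,
#'   rate_bin, n).
#' @export
run_bisub_experiment <- function(coverages = c(10, 15, 20, 25, 30, 45),
                                 profiles = default_sim_profiles(),
                                 genome_length = 2e6, snp_rate = 1e-3,
                                 threshold = 0.5,
                                 error_mode = "base_aware", seed = 1) {
  grid <- tidyr::expand_grid(profiles, coverage = coverages)
  seeds <- derive_seeds(seed, nrow(grid))
  res <- purrr::pmap(list(grid$p_s, grid$read_length, grid$coverage, seeds),
    function(p_s, read_length, coverage, s) {
      dev <- tibble::tibble(p_s = p_s, read_length = read_length)
      sim <- simulate_device_dataset(dev, genome_length, snp_rate,
                                     mean_coverage = coverage, seed = s,
                                     error_mode = error_mode)
      st <- column_stats(sim$fragments, sim$truth)
      obs <- st[st$coverage > 0L, ]
      hist_tb <- dplyr::count(
        dplyr::mutate(obs, rate_bin = cut(obs$bisub_rate,
                                          breaks = seq(0, 1, 0.1),
                                          include.lowest = TRUE)),
        .data$rate_bin)
      list(census = tibble::tibble(n_snps_observed = nrow(obs),
                                   high_bisub_count =
                                     high_bisub_census(st, threshold),
                                   seed = s),
           histogram = hist_tb)
    })
  census <- dplyr::bind_cols(
    grid[c("profile", "coverage")],
    dplyr::bind_rows(purrr::map(res, "census")))
  histogram <- dplyr::bind_rows(
    purrr::map2(seq_len(nrow(grid)), res, function(i, r)
      dplyr::bind_cols(grid[i, c("profile", "coverage")], r$histogram)))
  list(census = census, histogram = histogram)
}

#' Coverage sweep of assembly accuracy and continuity
#'
#' For each coverage level, simulates `n_replicates` independent datasets,
#' assembles each with [heuristic_assemble()], and reports switch error
#' rate, average block length and MEC, both per replicate and aggregated
#' (mean and sd over replicates).
#'
#' @param coverages mean total depths to sweep.
#' @param n_replicates independent datasets per coverage (default 20).
#' @param profile one-row tibble with `p_s`, `read_length` (default: the
#'   PacBio-like profile).
#' @param genome_length genome size per replicate (default 5e6, ~5000 SNPs).
#' @param snp_rate per-base SNP rate.
#' @param restarts assembler restarts.
#' @param error_mode passed to [simulate_device_dataset()].
#' @param seed master seed; replicate seeds derived deterministically.
#' @return list with `replicates` (per-run metrics) and `summary`
#'   (per-coverage mean/sd of each metric).
#' @export
run_assembly_experiment <- function(coverages = c(10, 20, 30, 45),
                                    n_replicates = 20,
                                    profile = default_sim_profiles()[2, ],
                                    genome_length = 5e6, snp_rate = 1e-3,
                                    restarts = 2, error_mode = "base_aware",
                                    seed = 1) {
  grid <- tidyr::expand_grid(coverage = coverages,
                             replicate = seq_len(n_replicates))
  seeds <- derive_seeds(seed, nrow(grid))
  dev <- tibble::tibble(p_s = profile$p_s, read_length = profile$read_length)
  reps <- purrr::pmap(list(grid$coverage, grid$replicate, seeds),
    function(coverage, replicate, s) {
      sim <- simulate_device_dataset(dev, genome_length, snp_rate,
                                     mean_coverage = coverage, seed = s,
                                     error_mode = error_mode)
      asm <- heuristic_assemble(sim$fragments, restarts = restarts, seed = s)
      st <- column_stats(sim$fragments, sim$truth)
      dplyr::bind_cols(
        tibble::tibble(coverage = coverage, replicate = replicate, seed = s),
        eval_metrics(sim$truth, asm, stats = st))
    })
  replicates <- dplyr::bind_rows(reps)
  summary <- dplyr::summarise(
    dplyr::group_by(replicates, .data$coverage),
    dplyr::across(c("switch_error_rate", "avg_block_length", "mec",
                    "high_bisub_count"),
                  list(mean = mean, sd = stats::sd)),
    .groups = "drop")
  list(replicates = replicates, summary = summary)
}
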