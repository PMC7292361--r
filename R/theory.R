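#' Coverage models for SNP columns
#'
#' Three families of per-column read-depth distributions are supported:
#' a constant depth `c`, a quasi-uniform depth (the discrete analogue of the
#' uniform distribution, on the integers `a..b`), and a Poisson depth with
#' mean `lambda`. The Poisson model is zero-truncated throughout this
#' package: a site covered by no read is unobservable and cannot be phased,
#' so depth 0 is excluded from the support (and the quasi-uniform ranges
#' start at 1 for the same reason).
#'
#' @param c constant depth, integer `>= 1`.
#' @param a,b integer bounds `1 <= a <= b` of the quasi-uniform range.
#' @param lambda Poisson mean, `> 0`.
#' @return a `coverage_model` object.
#' @examples
#' poisson_coverage(10)
#' quasi_uniform_coverage(1, 10)
#' @export
constant_coverage <- function(c) {
  c <- as.integer(c)
  stopifnot(length(c) == 1L, c >= 1L)
  structure(list(kind = "constant", c = c), class = "coverage_model")
}

#' @rdname constant_coverage
#' @export
quasi_uniform_coverage <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  stopifnot(length(a) == 1L, length(b) == 1L, a >= 1L, a <= b)
  structure(list(kind = "quasi_uniform", a = a, b = b),
            class = "coverage_model")
}

#' @rdname constant_coverage
#' @export
poisson_coverage <- function(lambda) {
  stopifnot(length(lambda) == 1L, lambda > 0)
  structure(list(kind = "poisson", lambda = lambda), class = "coverage_model")
}

#' @export
print.coverage_model <- function(x, ...) {
  cat("<coverage_model>", format(x), "\n")
  invisible(x)
}

#' @export
format.coverage_model <- function(x, ...) {
  switch(x$kind,
         constant      = paste0("constant c=", x$c),
         quasi_uniform = paste0("quasi-uniform [", x$a, ",", x$b, "]"),
         poisson       = paste0("poisson lambda=", x$lambda))
}

#' Draw per-column coverages from a coverage model
#'
#' Sampling matches the analytic treatment: the Poisson model is
#' zero-truncated (inverse-cdf draw conditioned on depth `>= 1`).
#'
#' @param model a `coverage_model`.
#' @param n number of columns.
#' @return integer vector of depths, all `>= 1`.
#' @export
sample_coverage <- function(model, n) {
  stopifnot(inherits(model, "coverage_model"))
  switch(model$kind,
         constant      = rep(model$c, n),
         quasi_uniform = sample.int(model$b - model$a + 1L, n,
                                    replace = TRUE) + model$a - 1L,
         poisson       = stats::qpois(stats::runif(
           n, stats::ppois(0, model$lambda), 1), model$lambda))
}

# pmf of the (possibly truncated) coverage distribution on 1..cmax
coverage_pmf <- function(model) {
  switch(model$kind,
    constant = list(c = model$c, p = 1),
    quasi_uniform = list(c = model$a:model$b,
                         p = rep(1 / (model$b - model$a + 1L),
                                 model$b - model$a + 1L)),
    poisson = {
      cmax <- max(2L, stats::qpois(1 - 1e-13, model$lambda))
      cc <- seq_len(cmax)
      p <- stats::dpois(cc, model$lambda) / (1 - stats::dpois(0, model$lambda))
      list(c = cc, p = p / sum(p))
    })
}

#' Probability that one SNP column does not defeat MEC
#'
#' With depth `c` and independent per-entry bi-substitution probability
#' `p_e`, the number of erroneous entries in a column is
#' `Binomial(c, p_e)`; the column is safe when errors do not reach a
#' majority, i.e. the error count is at most `floor(c/2)`. This is the
#' binomial lower tail `P{X <= floor(c/2)}`, evaluated with the stable
#' cumulative distribution (safe up to depths of 1e4 and beyond and error
#' probabilities down to 1e-4 and below).
#'
#' At even depth the boundary case "errors exactly c/2" is counted as a
#' success, following the floor in the tail's upper limit; the strict-
#' majority condition of the failure theorem leaves this tie ambiguous and
#' the summation bound is the convention adopted here.
#'
#' @param c integer depth(s), `>= 1`; vectorised.
#' @param p_e bi-substitution probability in `[0, 1]`.
#' @param log.p return the log-probability.
#' @return probability (or log-probability) per depth.
#' @examples
#' per_column_success(1, 0.1)  # 0.9
#' per_column_success(2, 0.1)  # 0.99: only the both-flipped pattern fails
#' @export
per_column_success <- function(c, p_e, log.p = FALSE) {
  if (any(c < 1) || any(c != floor(c))) stop("coverage must be integer >= 1")
  if (p_e < 0 || p_e > 1) stop("p_e must be in [0, 1]")
  stats::pbinom(floor(c / 2), c, p_e, log.p = log.p)
}

#' Reliability of MEC for a whole haplotype: P{c-MEC}
#'
#' The probability that the exact haplotype attains the minimum MEC value,
#' given per-column depths and an iid bi-substitution probability: the
#' product over columns of [per_column_success()]. Accumulated in log space
#' so haplotype lengths up to 1e6 do not underflow.
#'
#' @param coverages integer vector of per-column depths, all `>= 1`.
#' @param p_e bi-substitution probability.
#' @return probability in `[0, 1]`.
#' @examples
#' p_cmec(rep(1, 100), 0.01)   # (1 - 0.01)^100
#' @export
p_cmec <- function(coverages, p_e) {
  if (!length(coverages)) stop("empty coverage vector")
  exp(sum(per_column_success(coverages, p_e, log.p = TRUE)))
}

#' P{c-MEC} under a coverage model
#'
#' Either draws one depth per column from the model and applies [p_cmec()]
#' (`mode = "sampled"`), or returns the length-`l` power of the marginal
#' expected per-column success (`mode = "marginal"`), the exact value of
#' `E[P{c-MEC}]` per column under independent depths.
#'
#' @param model a `coverage_model`.
#' @param p_e bi-substitution probability.
#' @param l haplotype length (number of SNP columns), `>= 1`.
#' @param mode `"marginal"` (default, deterministic) or `"sampled"`.
#' @param seed optional seed for `mode = "sampled"`; when `NULL` the current
#'   RNG stream is used.
#' @return probability in `[0, 1]`.
#' @export
p_cmec_under_model <- function(model, p_e, l, mode = c("marginal", "sampled"),
                               seed = NULL) {
  stopifnot(inherits(model, "coverage_model"), l >= 1)
  mode <- match.arg(mode)
  if (mode == "sampled") {
    cov <- with_seed_if(seed, sample_coverage(model, l))
    return(p_cmec(cov, p_e))
  }
  pmf <- coverage_pmf(model)
  marg <- sum(pmf$p * per_column_success(pmf$c, p_e))
  # guard the l -> 1e6 regime against log(1) rounding
  exp(l * log(marg))
}

#' Tabulate a MEC performance curve
#'
#' Evaluates P{c-MEC} over a grid of bi-substitution probabilities for one
#' coverage model and haplotype length, the analytic analogue of a
#' performance curve of reliability against error rate.
#'
#' @param model a `coverage_model`.
#' @param l haplotype length.
#' @param p_e_grid numeric vector of bi-substitution probabilities in `[0, 1]`.
#' @inheritParams p_cmec_under_model
#' @return a `performance_curve` tibble with columns `p_e`, `p_cmec`,
#'   `model` (label), `l`. Plot with [ggplot2::autoplot()].
#' @export
performance_curve <- function(model, l, p_e_grid,
                              mode = c("marginal", "sampled"), seed = NULL) {
  stopifnot(all(p_e_grid >= 0), all(p_e_grid <= 1))
  mode <- match.arg(mode)
  vals <- vapply(p_e_grid, function(pe)
    p_cmec_under_model(model, pe, l, mode = mode, seed = seed), numeric(1))
  out <- tibble::tibble(p_e = as.numeric(p_e_grid), p_cmec = vals,
                        model = format(model), l = as.numeric(l))
  class(out) <- c("performance_curve", class(out))
  out
}

#' Monte-Carlo estimate of P{c-MEC}
#'
#' Empirical frequency, over seeded trials, of the event "no column's
#' bi-substitution error count exceeds half its depth". Each trial draws the
#' per-column error counts `Binomial(c_j, p_e)` — identical in law to
#' drawing a full error matrix with iid entry flips and counting per column.
#' Serves as the independent stochastic cross-check of the analytic
#' [p_cmec()].
#'
#' @param coverages integer depth vector, or a `coverage_model` (depths then
#'   redrawn each trial).
#' @param p_e bi-substitution probability.
#' @param l haplotype length, required when `coverages` is a model.
#' @param trials number of Monte-Carlo trials.
#' @param seed optional integer seed.
#' @return a one-row tibble: `estimate`, `se` (binomial standard error),
#'   `trials`.
#' @export
mc_cmec <- function(coverages, p_e, l = NULL, trials = 20000, seed = NULL) {
  with_seed_if(seed, {
    is_model <- inherits(coverages, "coverage_model")
    if (!is_model) {
      cov <- as.integer(coverages)
      l <- length(cov)
    }
    succ <- 0L
    chunk <- max(1L, floor(2e6 / l))
    done <- 0L
    while (done < trials) {
      nb <- min(chunk, trials - done)
      cv <- if (is_model) sample_coverage(coverages, l * nb) else rep(cov, nb)
      e <- stats::rbinom(l * nb, cv, p_e)
      ok <- e <= floor(cv / 2)
      dim(ok) <- c(l, nb)
      succ <- succ + sum(colSums(ok) == l)
      done <- done + nb
    }
    p <- succ / trials
    tibble::tibble(estimate = p, se = sqrt(p * (1 - p) / trials),
                   trials = as.integer(trials))
  })
}

#' Built-in sequencing device profiles
#'
#' Typical per-run characteristics of six short- and long-read sequencing
#' devices: substitution error probability `p_s`, reads per run `n_reads_m`
#' (millions), and read length `read_length` (bases; paired-end total for
#' the Illumina machines). The bi-substitution probability relevant to
#' fragment-matrix errors is `p_e = p_s / 3`, since only one of the three
#' possible substitutions converts the reference allele into the
#' alternative (or vice versa).
#'
#' @return a tibble with columns `device`, `p_s`, `n_reads_m`, `read_length`.
#' @export
device_profiles <- function() {
  tibble::tribble(
    ~device,                      ~p_s,  ~n_reads_m, ~read_length,
    "Illumina MiSeq V3",          0.001, 50,         300,
    "Illumina HiSeq 4000",        0.001, 2500,       150,
    "Illumina HiSeq X",           0.001, 2600,       150,
    "Pacific BioSciences RS II",  0.06,  0.055,      20e3,
    "Pacific BioSciences Sequel", 0.06,  0.35,       12e3,
    "Oxford Nanopore MinION",     0.02,  0.1,        200e3)
}

#' Sequencing runs needed to reach a target coverage
#'
#' Inverts the Lander-Waterman averaged-coverage relation
#' `c_a = l_r * N_t * n / G`: the number of runs is the ceiling of
#' `target_coverage * G / (l_r * N_t)`, and the averaged coverage actually
#' delivered by that many runs is reported alongside.
#'
#' @param devices a device table as from [device_profiles()] (columns
#'   `device`, `p_s`, `n_reads_m`, `read_length`), or a subset of it.
#' @param target_coverage desired averaged coverage (default 10).
#' @param genome_length genome size `G` in bases (default 3e9, a human-scale
#'   genome).
#' @return the input tibble with columns `n_runs` (integer) and
#'   `averaged_coverage` appended.
#' @examples
#' runs_needed(device_profiles())
#' @export
runs_needed <- function(devices, target_coverage = 10, genome_length = 3e9) {
  stopifnot(all(c("n_reads_m", "read_length") %in% names(devices)),
            target_coverage > 0, genome_length > 0)
  n_t <- devices$n_reads_m * 1e6
  if (any(n_t <= 0) || any(devices$read_length <= 0))
    stop("reads per run and read length must be positive")
  yield <- devices$read_length * n_t
  n <- as.integer(ceiling(target_coverage * genome_length / yield))
  dplyr::mutate(tibble::as_tibble(devices),
                n_runs = n,
                averaged_coverage = yield * n / genome_length)
}

#' Evaluate MEC applicability for sequencing devices
#'
#' For each device: derives `p_e = p_s / 3`, computes P{c-MEC} for the given
#' coverage model and haplotype length, plans the runs needed for the target
#' coverage, and issues an applicability verdict (`P{c-MEC} >= threshold`).
#'
#' @inheritParams runs_needed
#' @param model coverage model used for the reliability computation
#'   (default: constant at `target_coverage`).
#' @param l haplotype length for the reliability computation (default 1000).
#' @param threshold verdict cutoff on P{c-MEC} (default 0.5).
#' @return tibble with `p_e`, `p_cmec`, `n_runs`, `averaged_coverage`,
#'   `applicable` columns appended.
#' @export
evaluate_device <- function(devices, model = NULL, l = 1000,
                            target_coverage = 10, genome_length = 3e9,
                            threshold = 0.5) {
  if (is.null(model)) model <- constant_coverage(target_coverage)
  out <- runs_needed(devices, target_coverage, genome_length)
  out$p_e <- out$p_s / 3
  out$p_cmec <- vapply(out$p_e, function(pe)
    p_cmec_under_model(model, pe, l), numeric(1))
  out$applicable <- out$p_cmec >= threshold
  out
}

# run expr under a temporary seed when one is given, else in the current
# RNG stream (so composite generators can share one outer seed)
with_seed_if <- function(seed, expr) {
  if (is.null(seed)) expr
  else withr::with_seed(as.integer(seed), expr)
}
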