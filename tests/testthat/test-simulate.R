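test_that("diplotype generation is reproducible and respects the SNP rate", {
  t1 <- generate_diplotype(1e5, 1e-3, seed = 5)
  t2 <- generate_diplotype(1e5, 1e-3, seed = 5)
  expect_identical(t1$sites, t2$sites)
  expect_identical(t1$h_ex, t2$h_ex)
  expect_true(is.unsorted(t1$sites$pos) == FALSE)
  expect_true(all(t1$sites$ref != t1$sites$alt))
  expect_true(all(t1$h_ex %in% c(-1L, 1L)))

  # site counts concentrate around genome_length * snp_rate
  counts <- vapply(1:8, function(s)
    nrow(generate_diplotype(1e6, 1e-3, seed = s)$sites), numeric(1))
  expect_true(all(abs(counts - 1000) <= 4 * sqrt(1e6 * 1e-3 * (1 - 1e-3))))
  expect_error(generate_diplotype(100, 1e-3), "genome_length")
})

test_that("the worked five-SNP diplotype yields the two allele sequences", {
  truth <- example_truth()
  al <- haplotype_alleles(truth)
  expect_equal(paste(al$hap1, collapse = ""), "CGTAG")
  expect_equal(paste(al$hap2, collapse = ""), "TCGCA")
  expect_error(diplotype_from_sites(c(5, 3), c("A", "C"), c("C", "G"),
                                    c(1, 1)), "strictly increase")
  expect_error(diplotype_from_sites(c(3, 5), c("A", "C"), c("A", "G"),
                                    c(1, 1)), "must differ")
})

test_that("fragment sampling with constant coverage tiles every column exactly", {
  truth <- generate_diplotype(5e4, 1e-3, seed = 6)
  R <- sample_fragments(truth, read_model(6e4, constant_coverage(5)),
                        seed = 2)
  expect_equal(column_coverage(R), rep(5L, nrow(truth$sites)))
  expect_equal(mec(R, truth$h_ex), 0L)
  # reads carry the origin haplotype's alleles exactly
  st <- column_stats(R, truth)
  expect_equal(sum(st$error_count), 0L)
})

test_that("fragment sampling is deterministic given a seed", {
  truth <- generate_diplotype(2e5, 1e-3, seed = 7)
  rm_ <- read_model(2e4, poisson_coverage(8))
  a <- sample_fragments(truth, rm_, seed = 3)
  b <- sample_fragments(truth, rm_, seed = 3)
  expect_identical(a[c("read", "col", "allele", "origin")],
                   b[c("read", "col", "allele", "origin")])
})

test_that("mean SNPs per read tracks read_length * snp_rate", {
  truth <- generate_diplotype(2e6, 1e-3, seed = 8)
  R <- sample_fragments(truth, read_model(2e4, poisson_coverage(10)),
                        seed = 4)
  snps_per_read <- tabulate(R$read, n_reads(R))
  expect_gt(n_reads(R), 500)
  expect_lt(abs(mean(snps_per_read) - 20), 2)  # within 10 %
})

test_that("a read length below the SNP spacing warns about discards", {
  truth <- diplotype_from_sites(c(100L, 300L, 500L), c("A", "C", "G"),
                                c("T", "G", "A"), c(1L, -1L, 1L),
                                genome_length = 600)
  expect_warning(
    try(sample_fragments(truth, read_model(50, poisson_coverage(20)),
                         seed = 1), silent = TRUE),
    "minimum SNP spacing")
})

test_that("flip-only error injection flips the recorded entries and nothing else", {
  set.seed(131)
  inst <- rand_instance(50, 20)
  clean <- as.matrix(inst$R)

  inj0 <- inject_errors(inst$R, 0, seed = 1)
  expect_equal(nrow(inj0$flips), 0L)
  expect_equal(as.matrix(inj0$fragments), clean)

  inj1 <- inject_errors(inst$R, 1, seed = 1)
  expect_equal(as.matrix(inj1$fragments), -clean)
  expect_equal(nrow(inj1$flips), length(inst$R$allele))
  expect_equal(mec(inj1$fragments, inst$h), mec(inst$R, inst$h))

  inj <- inject_errors(inst$R, 0.3, seed = 2)
  diff <- as.matrix(inj$fragments) != clean
  expect_equal(sum(diff), nrow(inj$flips))
  expect_true(all(diff[cbind(inj$flips$read, inj$flips$col)]))
  # conservation: flipped + unchanged = observed
  expect_equal(nrow(inj$flips) + sum(!diff[clean != 0]),
               length(inst$R$allele))
})

test_that("empirical flip fraction concentrates at the requested rate", {
  set.seed(141)
  inst <- rand_instance(2000, 100, min_span = 40, max_span = 80)
  n <- length(inst$R$allele)
  expect_gt(n, 1e5)
  inj <- inject_errors(inst$R, 0.02, seed = 3)
  se <- sqrt(0.02 * 0.98 / n)
  expect_lt(abs(nrow(inj$flips) / n - 0.02), 3 * se)
})

test_that("base-aware injection erases non-allelic substitutions and drops thin reads", {
  set.seed(151)
  inst <- rand_instance(400, 30, min_span = 2L, max_span = 4L)
  n <- length(inst$R$allele)
  suppressMessages(inj <- inject_errors(inst$R, 0.3, "base_aware", seed = 4))
  # flips ~ n*p/3, deletions ~ n*2p/3
  expect_lt(abs(nrow(inj$deletions) / n - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_equal(length(inj$fragments$allele) + nrow(inj$deletions) +
                 inj$n_entries_dropped, n)
  expect_true(all(tabulate(inj$fragments$read,
                           n_reads(inj$fragments)) >= 2L))
  # surviving flip records match the rebuilt matrix against the truth
  st <- column_stats(inj$fragments, inst$h)
  expect_equal(st$error_count,
               tabulate(inj$flips$col, n_snps(inj$fragments)))
})

test_that("realized Poisson coverage matches the zero-truncated pmf", {
  truth <- generate_diplotype(1e8, 1e-3, seed = 9)
  R <- sample_fragments(truth, read_model(2e4, poisson_coverage(10)),
                        seed = 10)
  cov_all <- column_coverage(R)
  # depths of columns closer than a read length are correlated (they share
  # reads); keep columns spaced >= read_length apart so the chi-square
  # sampling assumptions hold
  pos <- truth$sites$pos
  pick <- logical(length(pos))
  last <- -Inf
  for (i in seq_along(pos))
    if (pos[i] - last >= 2e4) { pick[i] <- TRUE; last <- pos[i] }
  cov <- cov_all[pick]
  cov <- cov[cov > 0]
  expect_gt(length(cov), 3000)
  kmax <- max(cov)
  obs <- tabulate(cov, kmax)
  p <- dpois(seq_len(kmax), 10) / (1 - dpois(0, 10))
  # pool bins with small expectation into the tail
  keep <- which(length(cov) * p >= 5)
  o <- c(obs[keep], sum(obs[-keep]))
  e <- c(p[keep], 1 - sum(p[keep]))
  chi <- sum((o - length(cov) * e)^2 / (length(cov) * e))
  pval <- pchisq(chi, df = length(o) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("device dataset composition is reproducible and glues the stages", {
  sim1 <- simulate_device_dataset("MinION", 2e5, mean_coverage = 12,
                                  seed = 11)
  sim2 <- simulate_device_dataset("MinION", 2e5, mean_coverage = 12,
                                  seed = 11)
  expect_identical(as.matrix(sim1$fragments), as.matrix(sim2$fragments))
  expect_identical(sim1$truth$h_ex, sim2$truth$h_ex)
  expect_equal(n_snps(sim1$fragments), nrow(sim1$truth$sites))
  # flips against the truth equal the recorded error bookkeeping
  st <- column_stats(sim1$fragments, sim1$truth)
  expect_equal(st$error_count,
               tabulate(sim1$flips$col, n_snps(sim1$fragments)))
  expect_error(simulate_device_dataset("nope", 1e5), "matches 0")
})

test_that("derived replicate seeds are deterministic and distinct", {
  expect_identical(derive_seeds(42, 10), derive_seeds(42, 10))
  expect_equal(anyDuplicated(derive_seeds(1, 1000)), 0L)
  expect_true(all(derive_seeds(7, 100) < 2^31))
})
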