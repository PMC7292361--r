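make_result <- function(h, block = NULL) {
  l <- length(h)
  if (is.null(block)) block <- rep(1L, l)
  list(haplotype = as.integer(h),
       blocks = tibble::tibble(col = seq_len(l), block = as.integer(block),
                               phased = !is.na(h)))
}

test_that("switch errors count orientation changes within blocks", {
  h <- c(1L, -1L, 1L, 1L, -1L, 1L, -1L, -1L, 1L, 1L)
  # perfect result and globally flipped result: zero switches
  expect_equal(switch_error(h, make_result(h))$switch_count, 0L)
  expect_equal(switch_error(h, make_result(-h))$switch_count, 0L)
  # one isolated flipped SNP strictly inside a single block: two switches
  est <- h; est[5] <- -est[5]
  sw <- switch_error(h, make_result(est))
  expect_equal(sw$switch_count, 2L)
  expect_equal(sw$switch_error_rate, 0.2)
  # flipping the truth globally changes nothing either
  expect_equal(switch_error(-h, make_result(est))$switch_count, 2L)
})

test_that("switch errors reset across block boundaries", {
  h <- rep(1L, 6)
  est <- c(1L, 1L, 1L, -1L, -1L, -1L)
  # one block: a single switch at the junction
  expect_equal(switch_error(h, make_result(est))$switch_count, 1L)
  # two blocks split at the junction: each is internally consistent
  two <- make_result(est, block = c(1, 1, 1, 2, 2, 2))
  expect_equal(switch_error(h, two)$switch_count, 0L)
})

test_that("a flipped SNP at a block edge causes one switch, not two", {
  h <- rep(1L, 5)
  est <- c(-1L, 1L, 1L, 1L, 1L)
  expect_equal(switch_error(h, make_result(est))$switch_count, 1L)
})

test_that("average block length is phased SNPs per block", {
  one <- make_result(rep(1L, 7))
  expect_equal(average_block_length(one), 7)
  sizes <- make_result(rep(1L, 6), block = c(1, 1, 2, 2, 2, 2))
  expect_equal(average_block_length(sizes), 3)
  # unphased singletons are not blocks
  h <- c(1L, 1L, NA, 1L, 1L)
  mixed <- make_result(h, block = c(1, 1, 2, 3, 3))
  expect_equal(average_block_length(mixed), 2)
  # independent recount on random partitions
  set.seed(251)
  for (i in 1:10) {
    l <- sample(5:30, 1)
    blk <- sort(sample(1:4, l, replace = TRUE))
    res <- make_result(rep(1L, l), block = blk)
    expect_equal(average_block_length(res),
                 l / length(unique(blk)))
  }
})

test_that("high bi-substitution census uses >= threshold and ignores empty columns", {
  st <- tibble::tibble(col = 1:4, coverage = c(3L, 4L, 0L, 2L),
                       error_count = c(2L, 2L, 0L, 0L),
                       bisub_rate = c(2 / 3, 0.5, NaN, 0))
  expect_equal(high_bisub_census(st), 2L)          # 2/3 and exactly 0.5
  expect_equal(high_bisub_census(st, 0.6), 1L)
  # census is non-increasing in the threshold
  th <- seq(0.1, 1, by = 0.1)
  counts <- vapply(th, function(t) high_bisub_census(st, t), integer(1))
  expect_true(all(diff(counts) <= 0L))
  expect_equal(high_bisub_census(st[st$error_count == 0L, ]), 0L)
})

test_that("theory experiment reproduces the canonical curve battery", {
  grid <- c(1e-4, 1e-3, 0.01, 0.05, 0.1, 0.3, 0.5)
  th <- run_theory_experiment(l = 1000, p_e_grid = grid)
  expect_equal(length(unique(th$by_model$model)), 9L)
  # every curve is monotone non-increasing in p_e
  for (m in unique(th$by_model$model)) {
    v <- th$by_model$p_cmec[th$by_model$model == m]
    expect_true(all(diff(v) <= 1e-12), info = m)
  }
  # leftmost grid point dominates the rightmost on every curve
  left <- th$by_model[th$by_model$p_e == grid[1], ]
  right <- th$by_model[th$by_model$p_e == 0.5, ]
  expect_true(all(left$p_cmec >= right$p_cmec))
  # the length sweep never rewards longer haplotypes
  bl <- th$by_length
  for (m in unique(bl$model)) {
    sub <- bl[bl$model == m & bl$p_e == 0.05, ]
    sub <- sub[order(sub$l), ]
    expect_true(all(diff(sub$p_cmec) <= 1e-12), info = m)
  }
})

test_that("bisub experiment flags more sites at low coverage for noisy long reads", {
  res <- run_bisub_experiment(coverages = c(6, 30),
                              genome_length = 5e5,
                              error_mode = "flip_only", seed = 5)
  expect_named(res, c("census", "histogram"))
  pac <- res$census[res$census$profile == "pacbio-like", ]
  expect_equal(nrow(pac), 2L)
  expect_gte(pac$high_bisub_count[pac$coverage == 6],
             pac$high_bisub_count[pac$coverage == 30])
  # short accurate reads never flag at these scales
  ill <- res$census[res$census$profile == "illumina-like", ]
  expect_equal(sum(ill$high_bisub_count), 0L)
  # reruns with the same master seed reproduce the table
  res2 <- run_bisub_experiment(coverages = c(6, 30),
                               genome_length = 5e5,
                               error_mode = "flip_only", seed = 5)
  expect_identical(res$census, res2$census)
})

test_that("assembly experiment aggregates replicate metrics per coverage", {
  res <- run_assembly_experiment(coverages = c(3, 25), n_replicates = 3,
                                 genome_length = 2e5, restarts = 1,
                                 error_mode = "flip_only", seed = 9)
  expect_equal(nrow(res$replicates), 6L)
  expect_equal(nrow(res$summary), 2L)
  expect_true(all(res$replicates$switch_error_rate >= 0 &
                    res$replicates$switch_error_rate <= 1))
  expect_true(all(res$replicates$avg_block_length >= 1))
  lo <- res$summary[res$summary$coverage == 3, ]
  hi <- res$summary[res$summary$coverage == 25, ]
  # depth 3 leaves uncovered sites, fragmenting the haplotype; depth 25
  # phases essentially everything in one block
  expect_gt(mean(res$replicates$n_blocks[res$replicates$coverage == 3]),
            mean(res$replicates$n_blocks[res$replicates$coverage == 25]))
  expect_gt(hi$avg_block_length_mean, lo$avg_block_length_mean)
  expect_lte(hi$switch_error_rate_mean,
             lo$switch_error_rate_mean + lo$switch_error_rate_sd)
  # bit-for-bit reproducibility from the master seed
  res2 <- run_assembly_experiment(coverages = c(3, 25), n_replicates = 3,
                                  genome_length = 2e5, restarts = 1,
                                  error_mode = "flip_only", seed = 9)
  expect_identical(res$replicates, res2$replicates)
})

test_that("error-free assembly has zero switch error at any coverage", {
  truth <- generate_diplotype(1e5, 1e-3, seed = 13)
  R <- sample_fragments(truth, read_model(5e4, constant_coverage(8)),
                        seed = 14)
  asm <- heuristic_assemble(R, restarts = 1, seed = 15)
  m <- eval_metrics(truth, asm, stats = column_stats(R, truth))
  expect_equal(m$switch_error_rate, 0)
  expect_equal(m$mec, 0L)
  expect_equal(m$high_bisub_count, 0L)
})
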