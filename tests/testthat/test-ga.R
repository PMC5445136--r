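test_that("chromosome decoding matches the worked examples", {
  expect_equal(decode_chromosome("10100010"), c(1L, 3L, 7L))
  expect_equal(decode_chromosome(strrep("1", 36)), 1:36)
  expect_error(decode_chromosome("10102"), "non-binary")
  # decode / encode identity on arbitrary index sets
  set.seed(5)
  for (i in 1:25) {
    idx <- sort(sample(36, sample(0:36, 1)))
    expect_equal(decode_chromosome(encode_chromosome(idx, 36)), idx)
  }
  # channel-wise 12+12+12 formatting round-trips
  bits <- encode_chromosome(c(1, 13, 25, 36), 36)
  fm <- format_chromosome(bits)
  expect_equal(unname(nchar(fm)), c(12L, 12L, 12L))
  expect_equal(decode_chromosome(paste(fm, collapse = "")), c(1L, 13L, 25L, 36L))
})

test_that("two-point crossover swaps segments and invents no alleles", {
  p1 <- rep(1L, 10)
  p2 <- rep(0L, 10)
  expect_equal(two_point_crossover(p1, p1, rate = 1), p1)
  expect_equal(two_point_crossover(p1, p2, rate = 1, cuts = c(0, 10)), p2)
  expect_equal(two_point_crossover(p1, p2, rate = 1, cuts = c(3, 7)),
               c(1, 1, 1, 0, 0, 0, 0, 1, 1, 1))
  expect_error(two_point_crossover(p1, p2[1:5]), "length")
  set.seed(2)
  pa <- rbinom(36, 1, 0.5); pb <- rbinom(36, 1, 0.5)
  for (i in 1:20) {
    off <- two_point_crossover(pa, pb, rate = 1)
    expect_true(all(off == pa | off == pb))
  }
  # rate 0 always returns the first parent
  set.seed(3)
  expect_true(all(replicate(20, identical(two_point_crossover(pa, pb, 0), pa))))
})

test_that("bit-flip mutation has the configured expected Hamming distance", {
  bits <- rep(0L, 36)
  expect_equal(mutate_chromosome(bits, 0), bits)
  expect_equal(mutate_chromosome(bits, 1), rep(1L, 36))
  set.seed(11)
  flips <- replicate(10000, sum(mutate_chromosome(bits, 0.01)))
  expect_equal(mean(flips), 0.36, tolerance = 0.06 / 0.36)
})

test_that("roulette selection is fitness-proportional", {
  set.seed(1)
  expect_true(all(replicate(50, roulette_select(c(0, 0, 1))) == 3))
  # all-equal fitness: uniform draw (chi-square over 10,000 draws)
  draws <- replicate(10000, roulette_select(rep(0.4, 4)))
  expect_gt(stats::chisq.test(table(factor(draws, levels = 1:4)))$p.value,
            0.001)
  # zero-total wheel falls back to uniform
  draws0 <- replicate(10000, roulette_select(rep(0, 4)))
  expect_gt(stats::chisq.test(table(factor(draws0, levels = 1:4)))$p.value,
            0.001)
})

test_that("fitness: empty subset is 0, separable data scores 1, memoisation works", {
  d <- make_blobs(20, centers = 2, d = 2, spacing = 10, sd = 0.5)
  colnames(d$x) <- c("a", "b")
  cfg <- ga_config(cv_folds = 4)
  cache <- new.env(parent = emptyenv())
  expect_equal(chromosome_fitness(rep(0L, 2), d$x, d$y, cfg, cache), 0)
  set.seed(6)
  f1 <- chromosome_fitness(c(1L, 1L), d$x, d$y, cfg, cache)
  expect_equal(f1, 1.0)
  evals_before <- cache$evals
  f2 <- chromosome_fitness(c(1L, 1L), d$x, d$y, cfg, cache)
  expect_identical(cache$evals, evals_before)  # no second CV run
  expect_identical(f1, f2)
  # class smaller than the fold count is refused
  y_bad <- c(rep("a", 3), rep("b", 37))
  expect_error(chromosome_fitness(c(1L, 1L), d$x, y_bad, ga_config(cv_folds = 5)),
               "fewer samples")
})

test_that("steady-state GA: monotone best fitness, fixed sizes, determinism", {
  d <- planted_dataset(99, n_per = 30)
  cfg <- ga_config(population_size = 12, max_generations = 4, cv_folds = 3,
                   seed = 7)
  res <- run_ga(d$x, d$y, cfg)
  expect_s3_class(res, "ga_result")
  expect_true(all(diff(res$history) >= 0))
  expect_length(res$history, cfg$max_generations + 1)
  expect_length(res$best_chromosome, 36)
  expect_lte(res$best_generation, cfg$max_generations)
  expect_equal(res$best_fitness, max(res$history))
  res2 <- run_ga(d$x, d$y, cfg)
  expect_identical(res$best_chromosome, res2$best_chromosome)
  expect_identical(res$history, res2$history)
  # tidy/glance accessors
  td <- tidy(res)
  expect_equal(td$best_fitness, res$history)
  expect_equal(glance(res)$n_features, length(res$selected))
})
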