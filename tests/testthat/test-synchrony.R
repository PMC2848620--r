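test_that("pearson_r matches the product-moment definition", {
  expect_equal(pearson_r(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(pearson_r(c(1, 2, 3, 4), c(4, 3, 2, 1)), -1)
  # direct covariance / (sd * sd) oracle, computed independently
  x <- c(1, 2, 3, 4); y <- c(2, 4, 6, 9)
  oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), oracle, tolerance = 1e-12)
  expect_equal(oracle, 11.5 / sqrt(5 * 26.75)) # hand computation
  # degenerate input is flagged, not an error
  expect_true(is.na(pearson_r(c(2, 2, 2), c(1, 2, 3))))
  expect_error(pearson_r(1:2, 1:2), "3 paired")
  expect_error(pearson_r(1:4, 1:3), "equal length")
})

test_that("pearson_r is affine invariant and antisymmetric under negation", {
  set.seed(31)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8)
    r <- pearson_r(x, y)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_r(a * x + b, y), r, tolerance = 1e-12)
    expect_equal(pearson_r(x, -y), -r, tolerance = 1e-12)
  }
})

test_that("genewise_synchrony agrees with a per-gene loop oracle", {
  d <- random_paired(50, 10, seed = 32)
  r <- genewise_synchrony(d)
  oracle <- vapply(seq_len(50), function(g)
    cor(unclass(d$region_a)[g, ], unclass(d$region_b)[g, ]), numeric(1))
  expect_lt(max(abs(r - oracle)), 1e-12)
  expect_identical(names(r), rownames(d$region_a))
})

test_that("genewise_synchrony respects pairing, not subject order", {
  d <- random_paired(30, 8, seed = 33)
  r <- genewise_synchrony(d)
  shuffled <- subset_subjects(d, sample(colnames(d$region_a)))
  expect_equal(unname(genewise_synchrony(shuffled)), unname(r))
  # identical regions give r = 1 everywhere
  d2 <- paired_dataset(d$region_a,
                       make_expr(unclass(d$region_a),
                                 genes = rownames(d$region_a),
                                 subjects = colnames(d$region_a),
                                 region = "b"),
                       d$subjects)
  expect_equal(unname(genewise_synchrony(d2)), rep(1, 30))
  expect_error(genewise_synchrony(d, subjects = c("s1", "s2")), "3 subjects")
})

test_that("bootstrap_synchrony is seeded-deterministic and degenerate-safe", {
  d <- random_paired(40, 12, seed = 34)
  cfg <- analysis_config(n_bootstrap = 200, rng_seed = 9)
  s1 <- bootstrap_synchrony(d, cfg)
  s2 <- bootstrap_synchrony(d, cfg)
  expect_identical(s1, s2)
  expect_true(all(s1$ci_low <= s1$r_boot_median + 1e-12))
  expect_true(all(s1$r_boot_median <= s1$ci_high + 1e-12))
  expect_true(all(s1$ci_low >= -1 & s1$ci_high <= 1))
  # identical regions: every bootstrap r is 1, CI collapses to [1, 1]
  d2 <- paired_dataset(d$region_a,
                       make_expr(unclass(d$region_a),
                                 genes = rownames(d$region_a),
                                 subjects = colnames(d$region_a),
                                 region = "b"),
                       d$subjects)
  s3 <- bootstrap_synchrony(d2, cfg)
  expect_equal(s3$r_boot_median, rep(1, 40))
  expect_equal(s3$ci_low, rep(1, 40))
  expect_equal(s3$ci_high, rep(1, 40))
})

test_that("bootstrap CI width shrinks with the number of subjects", {
  width <- function(n) {
    cfg <- sim_config(n_genes = 150, n_subjects_per_group = n, groups = "g",
                      rho_distribution = rho_dist("constant", value = 0.5),
                      rng_seed = 35)
    ds <- generate_paired_cohort(cfg)$datasets$g
    s <- bootstrap_synchrony(ds, analysis_config(n_bootstrap = 300,
                                                 rng_seed = 36))
    mean(s$ci_high - s$ci_low)
  }
  expect_gt(width(10), width(100))
})

test_that("scrambling the subject linkage destroys synchrony", {
  # region_b identical to region_a (true r = 1 for every gene): after
  # derangement the mean null r is near 0 (mild -1/(n-1) finite-sample bias)
  set.seed(37)
  vals <- matrix(rnorm(1000 * 100), 1000, 100)
  a <- make_expr(vals, region = "a")
  b <- make_expr(vals, region = "b")
  meta <- subject_table(colnames(a), rep("control", 100), runif(100, 30, 70))
  d <- paired_dataset(a, b, meta)
  cfg <- analysis_config(n_permutations = 50, rng_seed = 38)
  null <- permutation_null(d, cfg)
  expect_identical(dim(null$values), c(1000L, 50L))
  expect_lt(abs(mean(null$values)), 0.03)
  expect_true(all(null$values < 1)) # derangements never keep the true pairing
  # seeded determinism
  expect_identical(permutation_null(d, cfg)$values, null$values)
})

test_that("null r values have the Fisher-z sampling scale on rho-free data", {
  cfg <- sim_config(n_genes = 500, n_subjects_per_group = 30, groups = "g",
                    rho_distribution = rho_dist("constant", value = 0),
                    rng_seed = 39)
  ds <- generate_paired_cohort(cfg)$datasets$g
  null <- permutation_null(ds, analysis_config(n_permutations = 100,
                                               rng_seed = 40))
  expect_lt(abs(mean(null$values)), 0.02)
  expect_lt(abs(sd(null$values) / (1 / sqrt(30 - 3)) - 1), 0.2)
})

test_that("derangements have no fixed points", {
  set.seed(41)
  for (n in c(2, 3, 5, 9)) {
    for (i in 1:100) {
      p <- regsync:::rderangement(n)
      expect_true(all(p != seq_len(n)))
      expect_identical(sort(p), seq_len(n))
    }
  }
})

test_that("global_shift_test is calibrated and detects separation", {
  set.seed(42)
  hits <- 0L
  for (i in 1:200) {
    p <- global_shift_test(rnorm(50), rnorm(200))
    hits <- hits + (p < 0.05)
  }
  expect_lt(abs(hits / 200 - 0.05), 0.03)
  expect_lt(global_shift_test(rep(0.9, 1000), rep(0, 1000)), 1e-6)
  expect_error(global_shift_test(numeric(0), rnorm(10)), "nonempty")
})

test_that("the subject-level permutation p-value is floored at 1/(P+1)", {
  cfg <- sim_config(n_genes = 400, n_subjects_per_group = 14, groups = "g",
                    rho_distribution = rho_dist("constant", value = 0.6),
                    rng_seed = 43)
  ds <- generate_paired_cohort(cfg)$datasets$g
  out <- permutation_median_p(ds, analysis_config(n_permutations = 99,
                                                  rng_seed = 44))
  expect_equal(out$p_value, 1 / 100)
  expect_gt(out$observed_median, 0.4)
  expect_length(out$null_medians, 99)
})
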