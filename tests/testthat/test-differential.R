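test_that("high-synchrony selection uses the absolute value in either group", {
  r_ctrl <- c(0.8, 0.5, -0.75, 0.1, 0.69)
  r_case <- c(0.1, 0.6, 0.0, 0.8, 0.69)
  sel <- select_high_synchrony_genes(r_ctrl, r_case, cutoff = 0.7)
  expect_identical(sel, c(1L, 3L, 4L))
})

test_that("bh_fdr reproduces the step-up definition", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  out <- bh_fdr(p, q = 0.05)
  expect_identical(out$significant, 1:5) # p_(i) <= i * 0.05 / 5 for all i
  expect_equal(out$q_values, bh_brute_force(p))
  out1 <- bh_fdr(0.04, q = 0.05)
  expect_equal(out1$q_values, 0.04)
  expect_identical(out1$significant, 1L)
  empty <- bh_fdr(numeric(0))
  expect_length(empty$q_values, 0)
  expect_length(empty$significant, 0)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # random vectors, including ties, against the brute-force oracle
  set.seed(60)
  for (i in 1:50) {
    pv <- round(runif(sample(1:40, 1)), sample(c(1, 2, 6), 1))
    expect_equal(bh_fdr(pv, q = 0.1)$q_values, bh_brute_force(pv))
  }
})

test_that("gain/loss classification follows the magnitude thresholds", {
  r_ctrl <- c(0.85, 0.10, 0.75, -0.80, 0.15, 0.85)
  r_case <- c(0.05, 0.80, 0.50, -0.10, -0.90, 0.05)
  sig <- c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  lab <- classify_gain_loss(r_ctrl, r_case, sig)
  expect_identical(lab, c("loss", "gain", "not_classified", "loss", "gain", NA))
  # a classified gain always increases the synchrony magnitude
  g <- which(lab == "gain")
  expect_true(all(abs(r_case[g]) - abs(r_ctrl[g]) > 0))
  l <- which(lab == "loss")
  expect_true(all(abs(r_ctrl[l]) - abs(r_case[l]) > 0))
})

test_that("bootstrap shift p-values are deterministic and order-invariant", {
  cfg <- sim_config(n_genes = 30, n_subjects_per_group = 10, n_gain = 10,
                    gain_rho = c(0, 0.9), rng_seed = 61)
  out <- generate_paired_cohort(cfg)
  ctrl <- out$datasets$control; case <- out$datasets$mdd
  ac <- analysis_config(n_bootstrap = 400, rng_seed = 62)
  p1 <- bootstrap_diff_pvalues(ctrl, case, config = ac)
  p2 <- bootstrap_diff_pvalues(ctrl, case, config = ac)
  expect_identical(p1, p2)
  expect_true(all(p1 >= 1 / 401 & p1 <= 1))
  # permuting subject columns changes nothing
  ctrl_shuf <- subset_subjects(ctrl, sample(colnames(ctrl$region_a)))
  case_shuf <- subset_subjects(case, sample(colnames(case$region_a)))
  p3 <- bootstrap_diff_pvalues(ctrl_shuf, case_shuf, config = ac)
  expect_equal(unname(p3), unname(p1))
  # gene subsets return the same per-gene values in the requested order
  p4 <- bootstrap_diff_pvalues(ctrl, case, genes = c(5L, 2L, 17L), config = ac)
  expect_equal(as.vector(p4), as.vector(p1[c(5, 2, 17)]))
})

test_that("swapping group labels negates deltas and swaps gain/loss", {
  cfg <- sim_config(n_genes = 40, n_subjects_per_group = 12, n_gain = 10,
                    n_loss = 10, gain_rho = c(0, 0.9), loss_rho = c(0.9, 0),
                    rng_seed = 63)
  out <- generate_paired_cohort(cfg)
  ctrl <- out$datasets$control; case <- out$datasets$mdd
  ac <- analysis_config(n_bootstrap = 300, rng_seed = 64)
  p_fwd <- bootstrap_diff_pvalues(ctrl, case, config = ac)
  p_rev <- bootstrap_diff_pvalues(case, ctrl, config = ac)
  expect_equal(as.vector(p_rev), as.vector(p_fwd)) # exact: shared index streams
  expect_equal(attr(p_rev, "delta_obs"), -attr(p_fwd, "delta_obs"))
  r_ctrl <- genewise_synchrony(ctrl); r_case <- genewise_synchrony(case)
  sig <- p_fwd < 0.05
  lab_fwd <- classify_gain_loss(r_ctrl, r_case, sig)
  lab_rev <- classify_gain_loss(r_case, r_ctrl, sig)
  expect_identical(lab_fwd == "gain", lab_rev == "loss")
  expect_identical(lab_fwd == "loss", lab_rev == "gain")
})

test_that("comparing a dataset against itself finds nothing", {
  cfg <- sim_config(n_genes = 300, n_subjects_per_group = 14, groups = "g",
                    rho_distribution = rho_dist_with_median(0.32),
                    rng_seed = 65)
  ds <- generate_paired_cohort(cfg)$datasets$g
  ac <- analysis_config(n_bootstrap = 200, rng_seed = 66, fdr_q = 0.05)
  res <- run_differential_pipeline(ds, ds, ac)
  expect_identical(sum(res$q_bh <= 0.05, na.rm = TRUE), 0L)
  expect_true(all(res$delta == 0))
})

test_that("the pipeline recovers designed gains and losses", {
  cfg <- sim_config(n_genes = 800, n_subjects_per_group = 14, n_gain = 60,
                    n_loss = 30, gain_rho = c(0, 0.9), loss_rho = c(0.9, 0),
                    rho_distribution = rho_dist("constant", value = 0.4),
                    rng_seed = 67)
  out <- generate_paired_cohort(cfg)
  ac <- analysis_config(n_bootstrap = 1000, rng_seed = 68, fdr_q = 0.2)
  res <- run_differential_pipeline(out$datasets$control, out$datasets$mdd, ac)
  truth <- out$truth
  true_gain <- truth$gene[truth$class == "gain"]
  true_loss <- truth$gene[truth$class == "loss"]
  called_gain <- res$gene[!is.na(res$label) & res$label == "gain"]
  called_loss <- res$gene[!is.na(res$label) & res$label == "loss"]
  # nearly all designed rewired genes reach significance at 20% FDR ...
  expect_gt(mean(true_gain %in% res$gene[res$q_bh <= 0.2]), 0.9)
  expect_gt(mean(true_loss %in% res$gene[res$q_bh <= 0.2]), 0.85)
  # ... while the strict gain/loss label additionally needs |r| <= 0.2 in the
  # low group, which at n = 14 holds for about half the rewired genes
  expect_gt(mean(true_gain %in% called_gain), 0.4)
  expect_gt(mean(true_loss %in% called_loss), 0.4)
  # classified calls are mostly true rewirings; the excess over the nominal
  # FDR reflects the high-|r| pre-selection (winner's curse on stable genes)
  fdp <- function(called, truthset)
    if (length(called)) mean(!(called %in% truthset)) else 0
  expect_lte(fdp(called_gain, true_gain), 0.35)
  expect_lte(fdp(called_loss, true_loss), 0.5)
  # stable genes scatter symmetrically about the diagonal
  r_ctrl_all <- genewise_synchrony(out$datasets$control)
  r_case_all <- genewise_synchrony(out$datasets$mdd)
  stable_all <- truth$class == "stable"
  expect_lt(abs(mean(r_case_all[stable_all] - r_ctrl_all[stable_all])), 0.05)
  # summary grid is monotone in the FDR level
  s <- attr(res, "summary")
  expect_true(all(diff(s$n_significant) >= 0))
})

test_that("an empty selection yields an empty, well-formed result", {
  cfg <- sim_config(n_genes = 50, n_subjects_per_group = 10,
                    rho_distribution = rho_dist("constant", value = 0),
                    rng_seed = 69)
  out <- generate_paired_cohort(cfg)
  ac <- analysis_config(n_bootstrap = 150, rng_seed = 70,
                        selection_cutoff = 0.999)
  res <- run_differential_pipeline(out$datasets$control, out$datasets$mdd, ac)
  expect_identical(nrow(res), 0L)
  expect_identical(attr(res, "n_selected"), 0L)
  expect_true(all(attr(res, "summary")$n_significant == 0))
})
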