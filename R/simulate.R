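#' Describe a per-gene true-correlation distribution
#'
#' The generator draws each gene's true cross-region correlation rho from a
#' named family. Two families cover the use cases: a point mass (`"constant"`)
#' and a shifted/scaled Beta on an interval inside (-1, 1) (`"beta"`), whose
#' right-shifted shape mimics the observed control-cohort synchrony
#' distribution while retaining a negative tail.
#'
#' @param family `"constant"` or `"beta"`.
#' @param value point mass location for `"constant"`.
#' @param shape1,shape2 Beta shape parameters for `"beta"`.
#' @param lo,hi support interval for `"beta"`; must lie inside (-1, 1).
#' @return a `rho_dist` list usable in [sim_config()].
#' @export
rho_dist <- function(family = c("constant", "beta"), value = 0,
                     shape1 = 2, shape2 = 2, lo = -0.4, hi = 0.9) {
  family <- match.arg(family)
  if (family == "constant") {
    if (abs(value) >= 1) stop("|rho| must be < 1")
    out <- list(family = "constant", value = value)
  } else {
    if (lo <= -1 || hi >= 1 || lo >= hi) stop("need -1 < lo < hi < 1")
    if (shape1 <= 0 || shape2 <= 0) stop("Beta shapes must be positive")
    out <- list(family = "beta", shape1 = shape1, shape2 = shape2,
                lo = lo, hi = hi)
  }
  structure(out, class = "rho_dist")
}

#' Beta-family rho distribution with a prescribed median
#'
#' Solves for the second Beta shape so that the median of the scaled Beta on
#' `(lo, hi)` equals `median`; used by [emulate_control_cohort()] to place
#' the median true correlation at 0.32.
#'
#' @param median target median of rho.
#' @param lo,hi support interval inside (-1, 1).
#' @param shape1 first Beta shape (controls dispersion).
#' @return a `rho_dist` of family `"beta"`.
#' @export
rho_dist_with_median <- function(median = 0.32, lo = -0.4, hi = 0.9,
                                 shape1 = 2.8) {
  if (median <= lo || median >= hi) stop("median must lie inside (lo, hi)")
  target <- (median - lo) / (hi - lo)
  f <- function(b) stats::qbeta(0.5, shape1, b) - target
  shape2 <- stats::uniroot(f, c(0.1, 100), tol = 1e-12)$root
  rho_dist("beta", shape1 = shape1, shape2 = shape2, lo = lo, hi = hi)
}

draw_rho <- function(dist, n) {
  stopifnot(inherits(dist, "rho_dist"))
  switch(dist$family,
         constant = rep(dist$value, n),
         beta = dist$lo + (dist$hi - dist$lo) *
           stats::rbeta(n, dist$shape1, dist$shape2))
}

#' Configuration for the paired-cohort generator
#'
#' Defines a two-group (e.g. control vs. case), two-region cohort with known
#' per-gene cross-region correlation, optional age confounding, and
#' group-specific synchrony rewiring. Gene classes:
#' \describe{
#'   \item{stable}{rho drawn from `rho_distribution`, identical in both
#'     groups (labelled `null` when it is exactly 0 with no age slope).}
#'   \item{gain}{rho jumps from `gain_rho[1]` (first group) to
#'     `gain_rho[2]` (second group).}
#'   \item{loss}{rho drops from `loss_rho[1]` to `loss_rho[2]`.}
#'   \item{age_driven}{true rho = 0 in both groups, but both regions carry a
#'     shared-sign age slope of magnitude `age_slope_magnitude`, so the raw
#'     cross-region correlation is induced solely by age.}
#' }
#'
#' @param n_subjects_per_group subjects per group (default 14, the reference
#'   cohort size).
#' @param n_genes total genes; class counts must fit inside it.
#' @param groups character vector of exactly two group labels; presets with a
#'   single group are produced by passing one label.
#' @param rho_distribution a [rho_dist()] for stable genes.
#' @param n_gain,n_loss numbers of rewired genes.
#' @param gain_rho,loss_rho length-2 numeric, (rho in first group, rho in
#'   second group).
#' @param n_age_driven number of age-driven genes.
#' @param age_slope_magnitude |beta| (expression units per year) for
#'   age-driven genes; sign is drawn per gene and shared across regions.
#' @param age_slope_sd standard deviation of the N(0, sd) age slopes given to
#'   all non-age-driven genes (0 = no age trend).
#' @param age_range ages are drawn uniformly over `[min, max]` years.
#' @param baseline_mean,baseline_sd per-gene baseline level mu_g ~ N(mean, sd)
#'   (log2-intensity scale).
#' @param noise_sd residual scale sigma (> 0) of the latent-factor model.
#' @param rng_seed integer seed; generation is fully deterministic given it.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_subjects_per_group = 14L, n_genes = 1000L,
                       groups = c("control", "mdd"),
                       rho_distribution = rho_dist("constant", value = 0),
                       n_gain = 0L, n_loss = 0L,
                       gain_rho = c(0, 0.9), loss_rho = c(0.9, 0),
                       n_age_driven = 0L, age_slope_magnitude = 0.1,
                       age_slope_sd = 0, age_range = c(30, 70),
                       baseline_mean = 7, baseline_sd = 1, noise_sd = 1,
                       rng_seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_gain <- as.integer(n_gain); n_loss <- as.integer(n_loss)
  n_age_driven <- as.integer(n_age_driven)
  if (n_gain + n_loss + n_age_driven > n_genes)
    stop("gene class counts exceed n_genes")
  if (length(groups) < 1L || length(groups) > 2L)
    stop("one or two group labels are required")
  if (anyDuplicated(groups)) stop("group labels must be distinct")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  if (any(abs(c(gain_rho, loss_rho)) >= 1)) stop("|rho| must be < 1")
  if (age_range[1L] < 0 || age_range[2L] < age_range[1L])
    stop("age_range must be non-negative and increasing")
  if (n_subjects_per_group < 3L) stop("need >= 3 subjects per group")
  structure(list(n_subjects_per_group = as.integer(n_subjects_per_group),
                 n_genes = n_genes, groups = as.character(groups),
                 rho_distribution = rho_distribution,
                 n_gain = n_gain, n_loss = n_loss,
                 gain_rho = gain_rho, loss_rho = loss_rho,
                 n_age_driven = n_age_driven,
                 age_slope_magnitude = age_slope_magnitude,
                 age_slope_sd = age_slope_sd, age_range = age_range,
                 baseline_mean = baseline_mean, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' Generate a paired two-region cohort with known ground truth
#'
#' Latent-factor generative model: for gene g and subject s with age a_s
#' drawn uniformly over the configured range, with shared latent
#' z ~ N(0,1) and independent residuals eA, eB ~ N(0,1),
#' \deqn{A_{gs} = \mu_g + \beta^A_g a_s + \sigma(\sqrt{|\rho_g|} z + \sqrt{1-|\rho_g|}\, e^A)}
#' \deqn{B_{gs} = \mu_g + \beta^B_g a_s + \sigma(\mathrm{sign}(\rho_g)\sqrt{|\rho_g|} z + \sqrt{1-|\rho_g|}\, e^B)}
#' so the age-free cross-region correlation equals rho_g exactly; negative
#' rho is obtained by sign-flipping the shared component in region B.
#' Age-driven genes use rho = 0 with a shared-sign slope in both regions, so
#' their raw correlation is entirely age-induced and their partial
#' correlation given age is 0 by construction.
#'
#' @param config a [sim_config()].
#' @return a list with
#'   \item{datasets}{named list of [paired_dataset()] objects, one per group;}
#'   \item{truth}{a `sim_truth` data frame: per gene, class label, true rho
#'     in each group, and per-region age slopes.}
#' @export
generate_paired_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$rng_seed, {
    G <- config$n_genes
    classes <- rep("stable", G)
    idx <- seq_len(G)
    gain_idx <- utils::head(idx, config$n_gain)
    loss_idx <- utils::head(setdiff(idx, gain_idx), config$n_loss)
    age_idx <- utils::head(setdiff(idx, c(gain_idx, loss_idx)),
                           config$n_age_driven)
    classes[gain_idx] <- "gain"
    classes[loss_idx] <- "loss"
    classes[age_idx] <- "age_driven"

    rho_stable <- draw_rho(config$rho_distribution, G)
    two_groups <- length(config$groups) == 2L
    rho1 <- rho_stable
    rho2 <- rho_stable
    rho1[gain_idx] <- config$gain_rho[1L]; rho2[gain_idx] <- config$gain_rho[2L]
    rho1[loss_idx] <- config$loss_rho[1L]; rho2[loss_idx] <- config$loss_rho[2L]
    rho1[age_idx] <- 0; rho2[age_idx] <- 0

    mu <- stats::rnorm(G, config$baseline_mean, config$baseline_sd)
    beta_a <- stats::rnorm(G, 0, max(config$age_slope_sd, 0))
    if (config$age_slope_sd == 0) beta_a <- numeric(G)
    beta_b <- if (config$age_slope_sd > 0)
      stats::rnorm(G, 0, config$age_slope_sd) else numeric(G)
    sgn <- sample(c(-1, 1), length(age_idx), replace = TRUE)
    beta_a[age_idx] <- sgn * config$age_slope_magnitude
    beta_b[age_idx] <- sgn * config$age_slope_magnitude

    classes[classes == "stable" & rho1 == 0 & rho2 == 0 &
              beta_a == 0 & beta_b == 0] <- "null"

    gene_ids <- sprintf("g%05d", idx)
    rho_by_group <- if (two_groups) list(rho1, rho2) else list(rho1)

    datasets <- list()
    for (k in seq_along(config$groups)) {
      grp <- config$groups[k]
      n <- config$n_subjects_per_group
      subj <- sprintf("%s_%02d", grp, seq_len(n))
      ages <- stats::runif(n, config$age_range[1L], config$age_range[2L])
      rho <- rho_by_group[[k]]
      z <- matrix(stats::rnorm(G * n), G, n)
      ea <- matrix(stats::rnorm(G * n), G, n)
      eb <- matrix(stats::rnorm(G * n), G, n)
      wr <- sqrt(abs(rho)); we <- sqrt(1 - abs(rho)); sg <- sign(rho)
      agetrend_a <- outer(beta_a, ages)
      agetrend_b <- outer(beta_b, ages)
      vals_a <- mu + agetrend_a + config$noise_sd * (wr * z + we * ea)
      vals_b <- mu + agetrend_b + config$noise_sd * (sg * wr * z + we * eb)
      a <- expression_matrix(vals_a, gene_ids, subj, region = "region_a")
      b <- expression_matrix(vals_b, gene_ids, subj, region = "region_b")
      meta <- subject_table(subj, rep(grp, n), ages)
      datasets[[grp]] <- paired_dataset(a, b, meta)
    }

    truth <- data.frame(gene = gene_ids, class = classes,
                        stringsAsFactors = FALSE)
    truth[[paste0("rho_", config$groups[1L])]] <- rho1
    if (two_groups) truth[[paste0("rho_", config$groups[2L])]] <- rho2
    truth$beta_a <- beta_a
    truth$beta_b <- beta_b
    class(truth) <- c("sim_truth", "data.frame")
    list(datasets = datasets, truth = truth)
  })
}

#' Preset: control-like cohort with median true correlation 0.32
#'
#' Convenience preset emulating the control cohort's synchrony structure:
#' 14 subjects, 10,000 genes, per-gene true cross-region correlations drawn
#' from a right-shifted Beta on (-0.4, 0.9) whose median is 0.32, and no age
#' trends (age confounding is studied separately with explicit
#' `age_driven` genes).
#'
#' @param seed integer seed.
#' @param n_genes number of genes (default 10,000).
#' @param n_subjects number of subjects (default 14).
#' @param group group label attached to the subjects.
#' @return a list with elements `dataset` (a [paired_dataset()]) and `truth`
#'   (the `sim_truth` table).
#' @export
emulate_control_cohort <- function(seed = 1L, n_genes = 10000L,
                                   n_subjects = 14L, group = "control") {
  cfg <- sim_config(n_subjects_per_group = n_subjects, n_genes = n_genes,
                    groups = group,
                    rho_distribution = rho_dist_with_median(0.32),
                    rng_seed = seed)
  out <- generate_paired_cohort(cfg)
  list(dataset = out$datasets[[group]], truth = out$truth)
}
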