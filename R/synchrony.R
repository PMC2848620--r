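#' Pearson product-moment correlation with degenerate-input flagging
#'
#' Standard Pearson r, except that zero-variance input yields `NA` rather
#' than an error: constant probesets occur in resampled data and must not
#' abort vectorized pipelines.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in \[-1, 1\], or `NA` if either vector is constant.
#' @examples
#' pearson_r(1:4, c(2, 4, 6, 9))
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("at least 3 paired observations are required")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("inputs must be finite")
  row_cor(matrix(x, nrow = 1L), matrix(y, nrow = 1L))[1L]
}

#' Genewise cross-region synchrony
#'
#' For each gene, the Pearson correlation of its region-A and region-B
#' transcript levels across subjects — the package's core statistic. A gene
#' is "synchronised" when its levels co-vary across regions within subjects.
#'
#' @param data a [paired_dataset()].
#' @param subjects optional subject ids (or indices) restricting the
#'   computation; at least 3 must remain.
#' @return named numeric vector of per-gene r values (NA for degenerate,
#'   i.e. zero-variance, genes).
#' @export
genewise_synchrony <- function(data, subjects = NULL) {
  stopifnot(inherits(data, "paired_dataset"))
  if (!is.null(subjects)) data <- subset_subjects(data, subjects)
  if (n_subjects(data) < 3L) stop("at least 3 subjects are required")
  r <- row_cor(unclass(data$region_a), unclass(data$region_b))
  names(r) <- rownames(data$region_a)
  r
}

# Canonical form used by every resampling routine: columns sorted by subject
# id, so results are invariant to the input's subject order, and the
# per-dataset RNG substream is a function of the data, not of argument order.
canonical_order <- function(data) {
  ord <- order(data$subjects$subject_id)
  if (is.unsorted(data$subjects$subject_id)) subset_subjects(data, ord) else data
}

dataset_stream_seed <- function(config_seed, data, stage) {
  mix_seed(config_seed, paste0(stage, ":",
                               paste(sort(data$subjects$subject_id),
                                     collapse = ",")))
}

# G x B matrix of genewise r over bootstrap resamples of subjects (pairs
# kept intact). Optionally age-detrends both regions within each resample,
# refitting the per-gene regression on the resampled ages.
boot_r_matrix <- function(data, n_bootstrap, detrend = FALSE, seed = NULL) {
  a <- unclass(data$region_a)
  b <- unclass(data$region_b)
  ages <- data$subjects$age
  n <- ncol(a)
  with_seed(seed, {
    out <- matrix(NA_real_, nrow(a), n_bootstrap)
    for (k in seq_len(n_bootstrap)) {
      idx <- sample.int(n, n, replace = TRUE)
      ak <- a[, idx, drop = FALSE]
      bk <- b[, idx, drop = FALSE]
      if (detrend) {
        ag <- ages[idx]
        ak <- detrend_matrix(ak, ag)
        bk <- detrend_matrix(bk, ag)
      }
      out[, k] <- row_cor(ak, bk)
    }
    out
  })
}

#' Bootstrapped genewise synchrony with percentile confidence intervals
#'
#' Resamples subjects with replacement (keeping each subject's region-A /
#' region-B pair intact), recomputes genewise r per resample, and summarises
#' each gene's bootstrap distribution by its median and a percentile
#' confidence interval. With `config$detrend_age = TRUE` (or
#' [bootstrap_synchrony_detrended()]), both regions are detrended on age
#' within each resample before correlating, so the age fit is itself
#' re-estimated under resampling.
#'
#' Resamples in which a gene is degenerate (zero variance) are recorded as
#' missing for that gene and excluded from its percentiles; the total count
#' is available as `attr(result, "n_degenerate")`.
#'
#' @param data a [paired_dataset()].
#' @param config an [analysis_config()]; uses `n_bootstrap`, `ci_level`,
#'   `rng_seed` and `detrend_age`.
#' @param detrend logical, overrides `config$detrend_age`.
#' @return a `synchrony_result` data frame with columns `gene`, `r_obs`,
#'   `r_boot_median`, `ci_low`, `ci_high`, `n_subjects`.
#' @export
bootstrap_synchrony <- function(data, config = analysis_config(),
                                detrend = config$detrend_age) {
  stopifnot(inherits(data, "paired_dataset"), inherits(config, "analysis_config"))
  data <- canonical_order(data)
  seed <- dataset_stream_seed(config$rng_seed, data, "bootstrap")
  rmat <- boot_r_matrix(data, config$n_bootstrap, detrend = detrend,
                        seed = seed)
  alpha <- (1 - config$ci_level) / 2
  qs <- rowQuantiles(rmat, c(alpha, 1 - alpha))
  r_obs <- if (detrend) {
    row_cor(detrend_matrix(unclass(data$region_a), data$subjects$age),
            detrend_matrix(unclass(data$region_b), data$subjects$age))
  } else {
    unname(genewise_synchrony(data))
  }
  res <- data.frame(gene = rownames(data$region_a),
                    r_obs = r_obs,
                    r_boot_median = rowMedians(rmat),
                    ci_low = qs[, 1L], ci_high = qs[, 2L],
                    n_subjects = n_subjects(data),
                    stringsAsFactors = FALSE)
  structure(res, class = c("synchrony_result", "data.frame"),
            n_bootstrap = config$n_bootstrap, ci_level = config$ci_level,
            detrended = detrend, n_degenerate = sum(is.na(rmat)))
}

#' Permutation null: synchrony after scrambling the subject linkage
#'
#' The null model for "no within-subject coordination": region-B subject
#' columns are permuted so every subject's A profile is paired with a
#' different subject's B profile, destroying within-subject linkage while
#' preserving each region's marginal distribution. Permutations are
#' derangements (no subject keeps its own pair), so no residue of the true
#' linkage leaks into the null at small n. Genewise r values are pooled over
#' permutations.
#'
#' @param data a [paired_dataset()] with >= 4 subjects.
#' @param config an [analysis_config()]; uses `n_permutations`, `rng_seed`.
#' @return a `synchrony_null` object: list with `values` (genes x
#'   permutations matrix of r), `n_permutations`, `n_genes`.
#' @export
permutation_null <- function(data, config = analysis_config()) {
  stopifnot(inherits(data, "paired_dataset"), inherits(config, "analysis_config"))
  if (n_subjects(data) < 4L) stop("at least 4 subjects are required")
  data <- canonical_order(data)
  a <- unclass(data$region_a)
  b <- unclass(data$region_b)
  seed <- dataset_stream_seed(config$rng_seed, data, "permutation")
  vals <- with_seed(seed, {
    out <- matrix(NA_real_, nrow(a), config$n_permutations)
    for (k in seq_len(config$n_permutations)) {
      p <- rderangement(ncol(a))
      out[, k] <- row_cor(a, b[, p, drop = FALSE])
    }
    out
  })
  rownames(vals) <- rownames(a)
  structure(list(values = vals, n_permutations = config$n_permutations,
                 n_genes = nrow(a)),
            class = "synchrony_null")
}

#' @export
print.synchrony_null <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<synchrony_null> %d genes x %d permutations; mean r = %.4f, median r = %.4f\n",
              x$n_genes, x$n_permutations, mean(v), stats::median(v)))
  invisible(x)
}

#' Global shift test: observed synchrony vs. the permutation null
#'
#' One-sided Wilcoxon rank-sum test of whether the observed genewise r
#' values are stochastically larger than the pooled scrambled-linkage null
#' values. Genes are correlated, so the p-value is anti-conservative in
#' principle; [permutation_median_p()] provides the conservative
#' subject-level companion based on the median-r statistic.
#'
#' @param observed numeric vector of observed genewise r (NAs dropped), as
#'   returned by [genewise_synchrony()].
#' @param null a `synchrony_null` or a numeric vector of pooled null r.
#' @return the one-sided p-value (numeric scalar).
#' @export
global_shift_test <- function(observed, null) {
  if (inherits(null, "synchrony_null")) null <- as.numeric(null$values)
  observed <- observed[is.finite(observed)]
  null <- null[is.finite(null)]
  if (!length(observed) || !length(null)) stop("observed and null must be nonempty")
  stats::wilcox.test(observed, null, alternative = "greater",
                     exact = FALSE)$p.value
}

#' Subject-level permutation p-value for the median synchrony shift
#'
#' Empirical p-value of the observed median genewise r against the medians
#' of the scrambled-linkage permutations, floored at 1/(P + 1). Conservative
#' companion to [global_shift_test()]: its resolution is limited by the
#' number of permutations, but it treats the subject linkage (not the gene)
#' as the sampling unit.
#'
#' @param data a [paired_dataset()].
#' @param config an [analysis_config()].
#' @return list with `p_value`, `observed_median`, `null_medians`.
#' @export
permutation_median_p <- function(data, config = analysis_config()) {
  obs <- stats::median(genewise_synchrony(data), na.rm = TRUE)
  null <- permutation_null(data, config)
  meds <- apply(null$values, 2L, stats::median, na.rm = TRUE)
  p <- (1 + sum(meds >= obs)) / (length(meds) + 1)
  list(p_value = p, observed_median = obs, null_medians = meds)
}
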