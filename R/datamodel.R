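#' Construct an expression matrix for one brain region
#'
#' A thin, validated container for already-normalised, log2-scale transcript
#' intensities: a genes x subjects numeric matrix with unique row (gene /
#' probeset) and column (subject) identifiers and a region label. Missing or
#' non-finite values are rejected outright: every downstream statistic
#' assumes complete within-subject pairs, and silent imputation would change
#' the correlations being studied.
#'
#' @param values numeric matrix, genes in rows and subjects in columns.
#'   Row names are gene identifiers and column names subject identifiers
#'   unless given explicitly.
#' @param gene_ids,subject_ids optional character vectors overriding the
#'   dimnames of `values`.
#' @param region character scalar naming the region (e.g. `"amygdala"`).
#' @return an object of class `expr_matrix` (a numeric matrix with a
#'   `region` attribute).
#' @examples
#' m <- matrix(rnorm(12), 4, 3,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
#' expression_matrix(m, region = "amygdala")
#' @export
expression_matrix <- function(values, gene_ids = rownames(values),
                              subject_ids = colnames(values), region = "") {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix (genes x subjects)")
  if (is.null(gene_ids) || is.null(subject_ids))
    stop("gene and subject identifiers are required (dimnames or arguments)")
  gene_ids <- as.character(gene_ids)
  subject_ids <- as.character(subject_ids)
  if (length(gene_ids) != nrow(values) || length(subject_ids) != ncol(values))
    stop("identifier lengths do not match matrix dimensions")
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g))
    stop("duplicate gene id(s): ", paste(utils::head(dup_g, 5L), collapse = ", "))
  dup_s <- unique(subject_ids[duplicated(subject_ids)])
  if (length(dup_s))
    stop("duplicate subject id(s): ", paste(utils::head(dup_s, 5L), collapse = ", "))
  if (ncol(values) < 3L) stop("at least 3 subjects are required")
  if (nrow(values) < 1L) stop("at least 1 gene is required")
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at gene '%s', subject '%s'; missing data are not allowed",
                 gene_ids[bad[1L]], subject_ids[bad[2L]]))
  }
  dimnames(values) <- list(gene_ids, subject_ids)
  structure(values, region = as.character(region)[1L],
            class = c("expr_matrix", class(values)))
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> region '%s': %d genes x %d subjects\n",
              attr(x, "region"), nrow(x), ncol(x)))
  invisible(x)
}

#' Construct a subject metadata table
#'
#' @param subject_id character vector of unique subject identifiers, or a
#'   data frame holding columns `subject_id`, `group`, `age`.
#' @param group group labels (e.g. `"control"`, `"mdd"`), kept verbatim.
#' @param age ages in years; must be finite and non-negative.
#' @return a `subject_table` data frame.
#' @export
subject_table <- function(subject_id, group = NULL, age = NULL) {
  if (is.data.frame(subject_id)) {
    df <- subject_id
    need <- c("subject_id", "group", "age")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
    subject_id <- df$subject_id; group <- df$group; age <- df$age
  }
  subject_id <- as.character(subject_id)
  group <- as.character(group)
  age <- as.numeric(age)
  if (anyDuplicated(subject_id))
    stop("duplicate subject id(s): ",
         paste(unique(subject_id[duplicated(subject_id)]), collapse = ", "))
  if (length(group) != length(subject_id) || length(age) != length(subject_id))
    stop("subject_id, group and age must have equal length")
  if (any(!is.finite(age)) || any(age < 0))
    stop("ages must be finite and non-negative")
  structure(data.frame(subject_id = subject_id, group = group, age = age,
                       stringsAsFactors = FALSE),
            class = c("subject_table", "data.frame"))
}

#' Pair two regional expression matrices over the same subjects
#'
#' The paired dataset is the unit of all inference in this package: each
#' subject contributes one expression profile per region, and genewise
#' synchrony is the correlation of the two profiles across subjects. The
#' constructor requires the two matrices to be already aligned (identical
#' gene order and subject order); use [align_paired_dataset()] to intersect
#' and reorder unaligned inputs.
#'
#' @param region_a,region_b `expr_matrix` objects with identical gene and
#'   subject identifier order.
#' @param subjects a `subject_table` covering every subject in the matrices.
#' @return a `paired_dataset` (list with elements `region_a`, `region_b`,
#'   `subjects`), with the metadata rows reordered to the column order.
#' @export
paired_dataset <- function(region_a, region_b, subjects) {
  if (!inherits(region_a, "expr_matrix") || !inherits(region_b, "expr_matrix"))
    stop("region_a and region_b must be expression_matrix objects")
  if (!identical(rownames(region_a), rownames(region_b)))
    stop("gene identifier order differs between regions; use align_paired_dataset()")
  if (!identical(colnames(region_a), colnames(region_b)))
    stop("subject identifier order differs between regions; use align_paired_dataset()")
  if (!inherits(subjects, "subject_table")) subjects <- subject_table(subjects)
  missing_subj <- setdiff(colnames(region_a), subjects$subject_id)
  if (length(missing_subj))
    stop("subject(s) absent from metadata: ",
         paste(utils::head(missing_subj, 5L), collapse = ", "))
  subjects <- subjects[match(colnames(region_a), subjects$subject_id), , drop = FALSE]
  rownames(subjects) <- NULL
  class(subjects) <- c("subject_table", "data.frame")
  structure(list(region_a = region_a, region_b = region_b, subjects = subjects),
            class = "paired_dataset")
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("<paired_dataset> %d genes x %d subjects; regions '%s' / '%s'\n",
              nrow(x$region_a), ncol(x$region_a),
              attr(x$region_a, "region"), attr(x$region_b, "region")))
  grp <- table(x$subjects$group)
  cat("  groups:", paste(sprintf("%s (n=%d)", names(grp), grp), collapse = ", "), "\n")
  invisible(x)
}

#' Number of genes / subjects in a paired dataset
#' @param data a `paired_dataset`.
#' @return integer scalar.
#' @export
n_genes <- function(data) nrow(data$region_a)

#' @rdname n_genes
#' @export
n_subjects <- function(data) ncol(data$region_a)

#' Align two regional matrices and metadata into a paired dataset
#'
#' Restricts both matrices to the intersection of their gene and subject
#' identifiers, reorders them identically (following the order of
#' `region_a`), and reports how many genes/subjects were dropped. Aligning
#' an already-aligned dataset is a no-op.
#'
#' @param region_a,region_b `expr_matrix` objects sharing at least 3 subject
#'   ids and 1 gene id.
#' @param subjects a `subject_table` covering the shared subjects.
#' @return a `paired_dataset` over the shared genes and subjects.
#' @export
align_paired_dataset <- function(region_a, region_b, subjects) {
  shared_subj <- intersect(colnames(region_a), colnames(region_b))
  shared_gene <- intersect(rownames(region_a), rownames(region_b))
  if (length(shared_subj) < 3L)
    stop(sprintf("alignment failed: only %d shared subject(s) (need >= 3)",
                 length(shared_subj)))
  if (length(shared_gene) < 1L)
    stop("alignment failed: no shared gene identifiers")
  dropped_subj <- (ncol(region_a) - length(shared_subj)) +
    (ncol(region_b) - length(shared_subj))
  dropped_gene <- (nrow(region_a) - length(shared_gene)) +
    (nrow(region_b) - length(shared_gene))
  if (dropped_subj > 0L || dropped_gene > 0L)
    message(sprintf("align_paired_dataset: kept %d genes x %d subjects (dropped %d gene and %d subject entries)",
                    length(shared_gene), length(shared_subj),
                    dropped_gene, dropped_subj))
  # preserve region_a's ordering for the shared ids
  shared_gene <- rownames(region_a)[rownames(region_a) %in% shared_gene]
  shared_subj <- colnames(region_a)[colnames(region_a) %in% shared_subj]
  a <- expression_matrix(unclass(region_a)[shared_gene, shared_subj, drop = FALSE],
                         region = attr(region_a, "region"))
  b <- expression_matrix(unclass(region_b)[shared_gene, shared_subj, drop = FALSE],
                         region = attr(region_b, "region"))
  if (!inherits(subjects, "subject_table")) subjects <- subject_table(subjects)
  keep <- subjects$subject_id %in% shared_subj
  paired_dataset(a, b, subjects[keep, , drop = FALSE])
}

#' Restrict a paired dataset to a subset of subjects
#'
#' @param data a `paired_dataset`.
#' @param subject_ids character vector of subject ids (or integer indices).
#' @return a `paired_dataset` over the selected subjects, in the given order.
#' @export
subset_subjects <- function(data, subject_ids) {
  if (is.numeric(subject_ids)) subject_ids <- colnames(data$region_a)[subject_ids]
  stopifnot(all(subject_ids %in% colnames(data$region_a)))
  if (length(subject_ids) < 3L) stop("at least 3 subjects are required")
  a <- expression_matrix(unclass(data$region_a)[, subject_ids, drop = FALSE],
                         region = attr(data$region_a, "region"))
  b <- expression_matrix(unclass(data$region_b)[, subject_ids, drop = FALSE],
                         region = attr(data$region_b, "region"))
  keep <- match(subject_ids, data$subjects$subject_id)
  paired_dataset(a, b, data$subjects[keep, , drop = FALSE])
}

#' Analysis configuration
#'
#' Bundles the tuning parameters of the inferential stages. Defaults follow
#' the reference analysis: 20,000 bootstrap resamples, a 0.7 absolute-r
#' selection cutoff with a 0.2 low threshold for gain/loss classification,
#' and percentile confidence intervals at the 95% level.
#'
#' @param n_bootstrap positive integer, bootstrap resamples (>= 100 for any
#'   reported p-value).
#' @param n_permutations positive integer, subject-linkage permutations for
#'   the null distribution.
#' @param selection_cutoff absolute-r cutoff in (0, 1] for selecting
#'   high-synchrony genes.
#' @param low_threshold absolute-r threshold below which a gene counts as
#'   unsynchronised; must be smaller than `selection_cutoff`.
#' @param fdr_q target Benjamini-Hochberg false discovery rate in (0, 1).
#' @param ci_level percentile-bootstrap confidence level in (0, 1).
#' @param rng_seed integer seed making every resampling stage reproducible,
#'   or `NULL` to use the session's random stream.
#' @param detrend_age logical; if `TRUE`, expression is detrended on age
#'   within every bootstrap resample.
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(n_bootstrap = 20000L, n_permutations = 100L,
                            selection_cutoff = 0.7, low_threshold = 0.2,
                            fdr_q = 0.2, ci_level = 0.95,
                            rng_seed = NULL, detrend_age = FALSE) {
  n_bootstrap <- as.integer(n_bootstrap)
  n_permutations <- as.integer(n_permutations)
  if (n_bootstrap < 100L) stop("n_bootstrap must be >= 100 for stable p-values")
  if (n_permutations < 1L) stop("n_permutations must be positive")
  if (!(selection_cutoff > 0 && selection_cutoff <= 1))
    stop("selection_cutoff must be in (0, 1]")
  if (low_threshold >= selection_cutoff)
    stop("low_threshold must be smaller than selection_cutoff")
  if (!(fdr_q > 0 && fdr_q < 1)) stop("fdr_q must be in (0, 1)")
  if (!(ci_level > 0 && ci_level < 1)) stop("ci_level must be in (0, 1)")
  if (!is.null(rng_seed)) rng_seed <- as.integer(rng_seed)
  structure(list(n_bootstrap = n_bootstrap, n_permutations = n_permutations,
                 selection_cutoff = selection_cutoff,
                 low_threshold = low_threshold, fdr_q = fdr_q,
                 ci_level = ci_level, rng_seed = rng_seed,
                 detrend_age = isTRUE(detrend_age)),
            class = "analysis_config")
}
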