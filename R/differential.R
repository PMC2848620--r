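#' Select genes with high synchrony in at least one group
#'
#' Power-increasing pre-selection: only genes whose absolute correlation
#' reaches `cutoff` in at least one group are carried into the shift test.
#' The absolute value matters because negatively synchronised genes are real
#' (anti-coordinated regulation) and their rewiring is equally of interest.
#'
#' @param r_ctrl,r_case numeric vectors of genewise r, aligned to the same
#'   gene list.
#' @param cutoff absolute-r threshold (default 0.7).
#' @return integer indices of selected genes.
#' @export
select_high_synchrony_genes <- function(r_ctrl, r_case, cutoff = 0.7) {
  stopifnot(length(r_ctrl) == length(r_case))
  which(pmax(abs(r_ctrl), abs(r_case)) >= cutoff)
}

#' Percentile-bootstrap p-values for group shifts in synchrony
#'
#' For each selected gene, subjects are resampled with replacement
#' independently within each group (no pairing exists across groups); the
#' correlation difference delta = r_case - r_ctrl is recorded per resample,
#' and the two-sided percentile-bootstrap p-value is
#' `2 * min(P(delta <= 0), P(delta >= 0))`, floored at `1/(n_bootstrap + 1)`
#' and capped at 1. With `config$detrend_age = TRUE`, each group's resample
#' is age-detrended before correlating. Degenerate resamples are dropped
#' from a gene's tally (count attached as an attribute).
#'
#' Each group's resample-index stream is seeded from the configuration seed
#' and that group's subject identifiers, so p-values are invariant to gene
#' and subject order and exactly antisymmetric under swapping the group
#' arguments.
#'
#' @param ctrl,case [paired_dataset()] objects over the same gene universe,
#'   each with >= 4 subjects.
#' @param genes integer indices (or gene ids) of genes to test; `NULL` tests
#'   all genes.
#' @param config an [analysis_config()].
#' @return named numeric vector of p-values (one per tested gene), with
#'   attributes `delta_obs` (observed r_case - r_ctrl) and `n_degenerate`.
#' @export
bootstrap_diff_pvalues <- function(ctrl, case, genes = NULL,
                                   config = analysis_config()) {
  stopifnot(inherits(ctrl, "paired_dataset"), inherits(case, "paired_dataset"))
  if (!identical(rownames(ctrl$region_a), rownames(case$region_a)))
    stop("ctrl and case must share an identical gene universe")
  if (n_subjects(ctrl) < 4L || n_subjects(case) < 4L)
    stop("each group needs >= 4 subjects")
  gene_ids <- rownames(ctrl$region_a)
  if (is.null(genes)) genes <- seq_along(gene_ids)
  if (is.character(genes)) genes <- match(genes, gene_ids)
  stopifnot(!anyNA(genes))

  ctrl <- canonical_order(subset_genes(ctrl, genes))
  case <- canonical_order(subset_genes(case, genes))
  B <- config$n_bootstrap
  seed_c <- dataset_stream_seed(config$rng_seed, ctrl, "diff")
  seed_k <- dataset_stream_seed(config$rng_seed, case, "diff")
  r_ctrl_b <- boot_r_matrix(ctrl, B, detrend = config$detrend_age, seed = seed_c)
  r_case_b <- boot_r_matrix(case, B, detrend = config$detrend_age, seed = seed_k)
  delta <- r_case_b - r_ctrl_b

  n_ok <- rowSums(!is.na(delta))
  n_le <- rowSums(delta <= 0, na.rm = TRUE)
  n_ge <- rowSums(delta >= 0, na.rm = TRUE)
  p <- 2 * pmin(n_le, n_ge) / pmax(n_ok, 1L)
  p <- pmin(1, pmax(p, 1 / (B + 1)))
  p[n_ok == 0L] <- NA_real_
  names(p) <- gene_ids[genes]

  d_obs <- genewise_synchrony(case) - genewise_synchrony(ctrl)
  structure(p, delta_obs = unname(d_obs),
            n_degenerate = sum(is.na(delta)))
}

# genes: integer indices into the row order
subset_genes <- function(data, genes) {
  a <- expression_matrix(unclass(data$region_a)[genes, , drop = FALSE],
                         region = attr(data$region_a, "region"))
  b <- expression_matrix(unclass(data$region_b)[genes, , drop = FALSE],
                         region = attr(data$region_b, "region"))
  paired_dataset(a, b, data$subjects)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) plus the significant set
#' at level `q`.
#'
#' @param pvalues numeric vector of p-values in \[0, 1\] (NA allowed,
#'   propagated).
#' @param q FDR level in (0, 1).
#' @return list with `q_values` (adjusted values, same order/names as input)
#'   and `significant` (integer indices with q_value <= q).
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  if (length(pvalues) == 0L)
    return(list(q_values = numeric(0), significant = integer(0)))
  ok <- !is.na(pvalues)
  if (any(pvalues[ok] < 0 | pvalues[ok] > 1))
    stop("p-values must lie in [0, 1]")
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  qv <- stats::p.adjust(pvalues, method = "BH")
  list(q_values = qv, significant = which(!is.na(qv) & qv <= q))
}

#' Classify significant genes as gains or losses of synchrony
#'
#' Among significant genes, a *loss* has high absolute synchrony in the
#' control group (`|r_ctrl| >= high`) collapsing to low in the case group
#' (`|r_case| <= low`); a *gain* is the mirror image. Significant genes
#' meeting neither pattern are `not_classified` (still reported). Absolute
#' values are used so negatively synchronised genes classify by magnitude.
#'
#' @param r_ctrl,r_case genewise r per group.
#' @param significant logical vector or integer indices of significant genes.
#' @param high,low magnitude thresholds with `low < high` (defaults 0.7, 0.2).
#' @return character vector of labels (`"gain"`, `"loss"`,
#'   `"not_classified"`), `NA` for non-significant genes.
#' @export
classify_gain_loss <- function(r_ctrl, r_case, significant,
                               high = 0.7, low = 0.2) {
  stopifnot(length(r_ctrl) == length(r_case), low < high)
  sig <- logical(length(r_ctrl))
  if (is.logical(significant)) sig <- significant else sig[significant] <- TRUE
  lab <- rep(NA_character_, length(r_ctrl))
  lab[sig] <- "not_classified"
  loss <- sig & abs(r_ctrl) >= high & abs(r_case) <= low
  gain <- sig & abs(r_case) >= high & abs(r_ctrl) <= low
  lab[loss] <- "loss"
  lab[gain] <- "gain"
  lab
}

#' End-to-end differential synchrony analysis
#'
#' Runs the full case/control comparison: genewise synchrony per group,
#' selection of high-synchrony genes (`|r| >= selection_cutoff` in at least
#' one group, or all genes with `select = FALSE` for sensitivity analysis),
#' percentile-bootstrap shift p-values, Benjamini-Hochberg adjustment over
#' the selected genes, and gain/loss classification at
#' `config$fdr_q`. A summary of gain/loss counts over `fdr_grid` is attached
#' as `attr(result, "summary")`.
#'
#' @param ctrl,case [paired_dataset()] objects sharing the gene universe.
#' @param config an [analysis_config()].
#' @param fdr_grid FDR levels for the summary table.
#' @param select if `FALSE`, skip the high-synchrony pre-selection.
#' @return a `differential_result` data frame over the selected genes:
#'   `gene`, `r_ctrl`, `r_case`, `delta`, `p_boot`, `q_bh`, `label`.
#' @export
run_differential_pipeline <- function(ctrl, case, config = analysis_config(),
                                      fdr_grid = c(0.1, 0.2, 0.3),
                                      select = TRUE) {
  r_ctrl <- genewise_synchrony(ctrl)
  r_case <- genewise_synchrony(case)
  sel <- if (select)
    select_high_synchrony_genes(r_ctrl, r_case, config$selection_cutoff)
  else seq_along(r_ctrl)
  if (!length(sel))
    return(structure(data.frame(gene = character(0), r_ctrl = numeric(0),
                                r_case = numeric(0), delta = numeric(0),
                                p_boot = numeric(0), q_bh = numeric(0),
                                label = character(0)),
                     class = c("differential_result", "data.frame"),
                     summary = data.frame(fdr = fdr_grid, n_significant = 0L,
                                          n_gain = 0L, n_loss = 0L),
                     n_genes_total = length(r_ctrl), n_selected = 0L,
                     config = config))
  p <- bootstrap_diff_pvalues(ctrl, case, genes = sel, config = config)
  adj <- bh_fdr(p, q = config$fdr_q)
  sig <- adj$q_values <= config$fdr_q & !is.na(adj$q_values)
  lab <- classify_gain_loss(r_ctrl[sel], r_case[sel], sig,
                            high = config$selection_cutoff,
                            low = config$low_threshold)
  res <- data.frame(gene = names(r_ctrl)[sel],
                    r_ctrl = unname(r_ctrl[sel]),
                    r_case = unname(r_case[sel]),
                    delta = unname(r_case[sel] - r_ctrl[sel]),
                    p_boot = unname(p), q_bh = unname(adj$q_values),
                    label = lab, stringsAsFactors = FALSE)
  summ <- do.call(rbind, lapply(fdr_grid, function(qq) {
    s <- !is.na(res$q_bh) & res$q_bh <= qq
    l <- classify_gain_loss(res$r_ctrl, res$r_case, s,
                            high = config$selection_cutoff,
                            low = config$low_threshold)
    data.frame(fdr = qq, n_significant = sum(s),
               n_gain = sum(l == "gain", na.rm = TRUE),
               n_loss = sum(l == "loss", na.rm = TRUE))
  }))
  structure(res, class = c("differential_result", "data.frame"),
            summary = summ, n_genes_total = length(r_ctrl),
            n_selected = length(sel), config = config)
}

#' @export
print.differential_result <- function(x, ...) {
  cat(sprintf("<differential_result> %d of %d genes selected (|r| >= cutoff in >= 1 group)\n",
              attr(x, "n_selected"), attr(x, "n_genes_total")))
  s <- attr(x, "summary")
  if (!is.null(s)) {
    cat("  gain/loss counts by FDR level:\n")
    print(s, row.names = FALSE)
  }
  invisible(x)
}
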