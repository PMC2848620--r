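# Shared fixture builders. Everything is generated in code at test time.

make_expr <- function(vals, genes = sprintf("g%d", seq_len(nrow(vals))),
                      subjects = sprintf("s%d", seq_len(ncol(vals))),
                      region = "r") {
  dimnames(vals) <- list(genes, subjects)
  expression_matrix(vals, region = region)
}

# Hand-rolled paired data independent of the package's generator, for
# oracle-style tests of the correlation machinery.
random_paired <- function(n_genes = 20, n_subj = 10, seed = 1,
                          groups = "control") {
  set.seed(seed)
  a <- make_expr(matrix(rnorm(n_genes * n_subj), n_genes, n_subj),
                 region = "amygdala")
  b <- make_expr(matrix(rnorm(n_genes * n_subj), n_genes, n_subj),
                 region = "cingulate")
  meta <- subject_table(colnames(a), rep(groups, length.out = n_subj),
                        runif(n_subj, 30, 70))
  paired_dataset(a, b, meta)
}

# Literal step-up definition of the BH adjustment: for sorted p_(1..m),
# adjusted_(i) = min(1, min_{j >= i} m p_(j) / j). Deliberately brute force.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) adj[i] <- min(1, m * sorted[i:m] / (i:m))
  out <- numeric(m)
  out[o] <- adj
  out
}
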