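# Shared fixtures and independent oracles used across the test files.

# Pearson correlation from first principles (covariance over the product of
# standard deviations), independent of stats::cor.
oracle_pearson <- function(x, y) {
  mx <- sum(x) / length(x)
  my <- sum(y) / length(y)
  sxy <- sum((x - mx) * (y - my))
  sxx <- sum((x - mx)^2)
  syy <- sum((y - my)^2)
  sxy / sqrt(sxx * syy)
}

# Root-mean-square neighbor-correlation difference via an explicit loop.
oracle_dc <- function(x, y) {
  s <- 0
  for (j in seq_along(x)) s <- s + (x[j] - y[j])^2
  sqrt(s / length(x))
}

# Upper-tail binomial probability by exhaustive term-wise summation.
oracle_binom_tail <- function(n, k, p) {
  tot <- 0
  for (x in k:n) tot <- tot + choose(n, x) * p^x * (1 - p)^(n - x)
  if (k > n) 0 else tot
}

# Assemble a coexpression_network_pair directly from an explicit link list.
toy_net <- function(gene_a, gene_b, r1, r2,
                    conditions = c("disease", "control"),
                    cutoff = link_cutoff()) {
  swap <- gene_a > gene_b
  tmp <- gene_a[swap]
  gene_a[swap] <- gene_b[swap]
  gene_b[swap] <- tmp
  links <- data.frame(gene_a = gene_a, gene_b = gene_b, r1 = r1, r2 = r2,
                      stringsAsFactors = FALSE)
  links <- links[order(links$gene_a, links$gene_b), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links,
                 genes = sort(unique(c(gene_a, gene_b))),
                 conditions = conditions, cutoff = cutoff,
                 method = "pearson"),
            class = "coexpression_network_pair")
}

# A dcl_table from explicit columns (for dce/dra unit tests).
toy_dcls <- function(gene_a, gene_b, r1, r2, is_dcl) {
  out <- data.frame(gene_a = gene_a, gene_b = gene_b, r1 = r1, r2 = r2,
                    type = reversal_type(r1, r2), is_dcl = is_dcl,
                    bin = 0L, score = abs(r1 - r2),
                    stringsAsFactors = FALSE)
  class(out) <- c("dcl_table", "data.frame")
  out
}

# Two-condition expression matrix of iid noise with optional exact rows.
toy_expr <- function(n_genes = 20, n1 = 8, n2 = 8, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (n1 + n2), 8), nrow = n_genes,
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              c(sprintf("d%02d", seq_len(n1)),
                                sprintf("c%02d", seq_len(n2)))))
  expression_matrix(m, stats::setNames(rep(c("disease", "control"),
                                           c(n1, n2)), colnames(m)))
}

# fresh scratch directory per use
tmp_dir <- function() {
  d <- tempfile("coexdiff-test-")
  dir.create(d)
  d
}
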