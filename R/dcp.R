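#' Per-gene differential co-expression statistic dC
#'
#' The root-mean-square difference between a gene's two neighbor
#' correlation vectors:
#' \deqn{dC = \sqrt{\frac{\sum_{j=1}^{n} (x_j - y_j)^2}{n}}}
#' where `x` and `y` hold the correlations of the gene with its n network
#' neighbors under condition 1 and condition 2, aligned pairwise. Since
#' correlations lie in \[-1, 1\], dC lies in \[0, 2\]; 0 means an unchanged
#' neighborhood, 2 means every neighbor correlation flipped between the
#' extremes.
#'
#' @param x,y Equal-length numeric vectors of neighbor correlations
#'   (condition 1 and condition 2).
#' @return The dC value; `NA` for empty vectors (a gene with no neighbors
#'   has no defined dC).
#' @examples
#' dc_statistic(c(1, 0), c(0, 1)) # 1
#' dc_statistic(0.9, 0.1)         # 0.8
#' @export
dc_statistic <- function(x, y) {
  if (length(x) != length(y))
    stop("neighbor vectors must have equal length")
  if (length(x) == 0L) return(NA_real_)
  sqrt(mean((x - y)^2))
}

#' Permutation test for per-gene differential co-expression (DCp)
#'
#' Computes the observed dC of every gene over its incident links, then
#' builds a per-gene null by shuffling the sample condition labels
#' `n_permutations` times. Within each permutation the whole pipeline is
#' re-run: both correlation maps are recomputed and, by default
#' (`scheme = "reselect"`), the link cutoff is re-applied to the permuted
#' data, so the permuted statistic is computed exactly as the observed one
#' and the test is exchangeable. A gene with no links in a given
#' permutation contributes a pseudo dC of 0 for that round.
#' `scheme = "fixed"` instead freezes the observed link set and only
#' recomputes the coefficients on it; this is cheaper but strongly
#' anti-conservative when the cutoff has selected links from the data, and
#' is provided for comparison only.
#'
#' The p-value uses the add-one estimator
#' `p = (1 + #\{pseudo dC >= observed dC\}) / (1 + n_permutations)`, so
#' p is never 0 and lies in `[1/(B+1), 1]`. FDR is Benjamini-Hochberg
#' across all tested genes.
#'
#' @param expr The [expression_matrix()] the network was built from.
#' @param net A [build_network_pair()] result.
#' @param n_permutations Number of label shuffles (default 500).
#' @param seed Optional integer; set for reproducible permutations.
#' @param scheme `"reselect"` (default) or `"fixed"`, see Details.
#' @return A data frame of class `gene_dc_result` with columns `gene`,
#'   `dC`, `n_neighbors`, `p_value`, `fdr`, ordered by gene. Genes in the
#'   universe with no incident links are listed in the `skipped` attribute.
#'   Attributes `seed`, `n_permutations` and `scheme` record the plan.
#' @export
dcp_test <- function(expr, net, n_permutations = 500L, seed = NULL,
                     scheme = c("reselect", "fixed")) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(expr, "expression_matrix"),
            inherits(net, "coexpression_network_pair"),
            n_permutations >= 1L)
  if (!is.null(seed)) set.seed(seed)

  genes <- net$genes
  G <- length(genes)
  s1 <- condition_samples(expr, net$conditions[1])
  s2 <- condition_samples(expr, net$conditions[2])
  X <- expr$values[genes, c(s1, s2), drop = FALSE]
  n1 <- length(s1)
  ns <- n1 + length(s2)
  if (ns < 6L)
    stop("need at least 3 samples per condition to permute into two groups")

  ut <- which(upper.tri(diag(G)))
  ia <- ((ut - 1L) %% G) + 1L          # row index of upper-tri entry
  ib <- ((ut - 1L) %/% G) + 1L         # col index

  per_gene_dc <- function(sel, d2) {
    idx <- c(ia[sel], ib[sel])
    cnt <- tabulate(idx, G)
    s <- numeric(G)
    if (length(idx)) {
      rs <- rowsum(c(d2, d2), idx)
      s[as.integer(rownames(rs))] <- rs[, 1L]
    }
    out <- numeric(G)
    nz <- cnt > 0L
    out[nz] <- sqrt(s[nz] / cnt[nz])
    list(dc = out, deg = cnt)
  }

  # observed statistic straight from the retained link set
  li_a <- match(net$links$gene_a, genes)
  li_b <- match(net$links$gene_b, genes)
  obs_idx <- c(li_a, li_b)
  obs_deg <- tabulate(obs_idx, G)
  d2_obs <- (net$links$r1 - net$links$r2)^2
  s_obs <- numeric(G)
  rs <- rowsum(c(d2_obs, d2_obs), obs_idx)
  s_obs[as.integer(rownames(rs))] <- rs[, 1L]
  tested <- obs_deg > 0L
  obs <- numeric(G)
  obs[tested] <- sqrt(s_obs[tested] / obs_deg[tested])

  fixed_sel <- NULL
  if (scheme == "fixed") {
    key <- (match(net$links$gene_b, genes) - 1L) * G +
      match(net$links$gene_a, genes)
    fixed_sel <- match(key, ut)
  }

  n_ge <- integer(G)
  for (b in seq_len(n_permutations)) {
    pp <- sample.int(ns)
    r1p <- suppressWarnings(stats::cor(t(X[, pp[seq_len(n1)], drop = FALSE]),
                                       method = net$method))[ut]
    r2p <- suppressWarnings(stats::cor(t(X[, pp[(n1 + 1L):ns], drop = FALSE]),
                                       method = net$method))[ut]
    sel <- if (scheme == "fixed") fixed_sel else
      select_links(pmax(abs(r1p), abs(r2p)), net$cutoff)
    d2 <- (r1p[sel] - r2p[sel])^2
    ok <- !is.na(d2)
    pseudo <- per_gene_dc(sel[ok], d2[ok])$dc
    n_ge <- n_ge + (pseudo >= obs)
  }

  p <- (1 + n_ge) / (1 + n_permutations)
  res <- data.frame(gene = genes[tested],
                    dC = obs[tested],
                    n_neighbors = obs_deg[tested],
                    p_value = p[tested],
                    fdr = stats::p.adjust(p[tested], method = "BH"),
                    stringsAsFactors = FALSE)
  res <- res[order(res$gene), , drop = FALSE]
  rownames(res) <- NULL
  structure(res,
            class = c("gene_dc_result", "data.frame"),
            skipped = genes[!tested],
            seed = seed, n_permutations = n_permutations, scheme = scheme)
}

#' Call differentially co-expressed genes from DCp results
#'
#' @param results A [dcp_test()] result.
#' @param p_threshold Keep genes with permutation `p_value <= p_threshold`
#'   (default 0.05).
#' @param fdr_threshold Optional; when given, additionally require
#'   `fdr <= fdr_threshold`.
#' @return Sorted character vector of DCG gene ids.
#' @export
call_dcp_dcgs <- function(results, p_threshold = 0.05, fdr_threshold = NULL) {
  stopifnot(is.data.frame(results),
            p_threshold > 0, p_threshold <= 1)
  keep <- results$p_value <= p_threshold
  if (!is.null(fdr_threshold)) {
    stopifnot(fdr_threshold > 0, fdr_threshold <= 1)
    keep <- keep & results$fdr <= fdr_threshold
  }
  sort(results$gene[keep])
}
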