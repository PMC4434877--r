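#' Pairwise gene-gene correlations within one condition
#'
#' Computes the correlation coefficient of every unordered gene pair using
#' the samples of a single condition. Genes with zero variance in that
#' condition cannot be correlated; their pairs are marked `NA` with a
#' warning and are excluded downstream when the network pair is built.
#'
#' @param expr An [expression_matrix()].
#' @param condition Condition label with at least 3 samples.
#' @param method Correlation type, `"pearson"` (default) or `"spearman"`.
#' @return A symmetric genes-by-genes correlation matrix of class
#'   `cor_map`, with attributes `condition` and `method`. The diagonal is
#'   `NA` (self-pairs are never links).
#' @export
pairwise_correlations <- function(expr, condition,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(inherits(expr, "expression_matrix"))
  ids <- condition_samples(expr, condition)
  x <- expr$values[, ids, drop = FALSE]
  sds <- apply(x, 1L, stats::sd)
  flat <- sds == 0
  if (any(flat))
    warning(sprintf(
      "condition '%s': %d zero-variance gene(s) excluded from the pair universe: %s",
      condition, sum(flat),
      paste(utils::head(rownames(x)[flat], 5L), collapse = ", ")))
  r <- suppressWarnings(stats::cor(t(x), method = method))
  r[flat, ] <- NA_real_
  r[, flat] <- NA_real_
  diag(r) <- NA_real_
  structure(r, condition = condition, method = method, class = "cor_map")
}

#' Link retention rule for co-expression networks
#'
#' @param mode `"absolute"` keeps a pair when `max(|r1|, |r2|) >= value`
#'   (default value 0.8). `"quantile"` keeps the top `value` fraction of
#'   pairs ranked by `max(|r1|, |r2|)` (default value 0.01); ties at the
#'   boundary are all kept.
#' @param value Threshold (absolute mode) or retained fraction (quantile
#'   mode).
#' @return A `link_cutoff` object.
#' @export
link_cutoff <- function(mode = c("absolute", "quantile"), value = NULL) {
  mode <- match.arg(mode)
  if (is.null(value)) value <- if (mode == "absolute") 0.8 else 0.01
  if (!is.numeric(value) || length(value) != 1L || is.na(value))
    stop("`value` must be a single number")
  if (mode == "absolute" && (value < 0 || value > 1))
    stop("absolute cutoff must lie in [0, 1]")
  if (mode == "quantile" && (value <= 0 || value > 1))
    stop("quantile fraction must lie in (0, 1]")
  structure(list(mode = mode, value = value), class = "link_cutoff")
}

# Indices (into the pair score vector) retained under a cutoff rule.
# `score` is max(|r1|, |r2|) per unordered pair; NA scores are never kept.
select_links <- function(score, cutoff) {
  if (cutoff$mode == "absolute") {
    which(!is.na(score) & score >= cutoff$value)
  } else {
    ok <- which(!is.na(score))
    if (!length(ok)) return(integer(0))
    k <- min(length(ok), max(1L, ceiling(cutoff$value * length(ok))))
    thr <- sort(score[ok], decreasing = TRUE)[k]
    ok[score[ok] >= thr]
  }
}

#' Build a two-condition co-expression network pair
#'
#' Applies a link cutoff to two correlation maps over the same gene
#' universe and returns the shared link set with both coefficients attached.
#' Both condition-specific networks have, by construction, identical
#' topology: a pair is retained when `max(|r1|, |r2|)` passes the cutoff,
#' so a link strongly co-expressed in either condition is kept and its
#' (possibly weak) coefficient in the other condition is preserved.
#'
#' @param corr1,corr2 `cor_map` matrices from [pairwise_correlations()],
#'   computed on the same expression matrix for two different conditions.
#' @param cutoff A [link_cutoff()].
#' @return A `coexpression_network_pair`: list with `links` (data frame
#'   `gene_a`, `gene_b`, `r1`, `r2`, pairs canonical with
#'   `gene_a < gene_b`), `genes` (the pair universe after zero-variance
#'   exclusion), `conditions` (labels of conditions 1 and 2), `cutoff`,
#'   and `method`.
#' @export
build_network_pair <- function(corr1, corr2, cutoff = link_cutoff()) {
  stopifnot(inherits(corr1, "cor_map"), inherits(corr2, "cor_map"),
            inherits(cutoff, "link_cutoff"))
  g <- rownames(corr1)
  if (!identical(g, rownames(corr2)))
    stop("correlation maps must cover the same gene universe")
  ut <- upper.tri(corr1)
  r1 <- corr1[ut]
  r2 <- corr2[ut]
  ia <- row(corr1)[ut]
  ib <- col(corr1)[ut]
  usable <- !(is.na(r1) | is.na(r2))
  keep <- select_links(ifelse(usable, pmax(abs(r1), abs(r2)), NA_real_),
                       cutoff)
  if (!length(keep))
    stop("no links retained under the cutoff; consider a looser threshold")
  links <- data.frame(gene_a = g[ia[keep]], gene_b = g[ib[keep]],
                      r1 = r1[keep], r2 = r2[keep],
                      stringsAsFactors = FALSE)
  # canonicalize: gene_a < gene_b lexicographically
  swap <- links$gene_a > links$gene_b
  tmp <- links$gene_a[swap]
  links$gene_a[swap] <- links$gene_b[swap]
  links$gene_b[swap] <- tmp
  links <- links[order(links$gene_a, links$gene_b), , drop = FALSE]
  rownames(links) <- NULL
  structure(list(links = links,
                 genes = gene_universe(corr1, corr2),
                 conditions = c(attr(corr1, "condition"),
                                attr(corr2, "condition")),
                 cutoff = cutoff,
                 method = attr(corr1, "method")),
            class = "coexpression_network_pair")
}

# genes usable in both conditions (not flagged zero-variance in either)
gene_universe <- function(corr1, corr2) {
  g <- rownames(corr1)
  flat1 <- apply(is.na(unclass(corr1)), 1L, all)
  flat2 <- apply(is.na(unclass(corr2)), 1L, all)
  sort(g[!(flat1 | flat2)])
}

#' @export
print.coexpression_network_pair <- function(x, ...) {
  cat(sprintf(
    "coexpression_network_pair: %d links over %d genes (%s vs %s, %s, %s cutoff %g)\n",
    nrow(x$links), length(x$genes), x$conditions[1], x$conditions[2],
    x$method, x$cutoff$mode, x$cutoff$value))
  invisible(x)
}

#' Neighbor correlation vectors of one gene
#'
#' For a gene with n incident links, returns the two length-n vectors of
#' correlation coefficients between the gene and its neighbors, one per
#' condition, aligned in canonical (alphabetical) neighbor order. These are
#' the paired vectors the per-gene dC statistic compares.
#'
#' @param net A [build_network_pair()] result.
#' @param gene Gene id.
#' @return List with `neighbors`, `x` (condition-1 coefficients) and `y`
#'   (condition-2 coefficients). All three are empty for a gene with no
#'   incident links (its dC is undefined and the gene is skipped by the
#'   permutation test).
#' @export
neighbor_vectors <- function(net, gene) {
  stopifnot(inherits(net, "coexpression_network_pair"), length(gene) == 1L)
  l <- net$links
  hit_a <- l$gene_a == gene
  hit_b <- l$gene_b == gene
  nb <- c(l$gene_b[hit_a], l$gene_a[hit_b])
  x <- c(l$r1[hit_a], l$r1[hit_b])
  y <- c(l$r2[hit_a], l$r2[hit_b])
  o <- order(nb)
  list(neighbors = nb[o], x = x[o], y = y[o])
}

#' Swap the two conditions of a network pair
#'
#' Exchanges the roles of condition 1 and condition 2 (and so `r1`/`r2` on
#' every link); topology is unchanged.
#'
#' @param net A [build_network_pair()] result.
#' @return A `coexpression_network_pair` with conditions swapped.
#' @export
swap_conditions <- function(net) {
  stopifnot(inherits(net, "coexpression_network_pair"))
  net$links[, c("r1", "r2")] <- net$links[, c("r2", "r1")]
  net$conditions <- rev(net$conditions)
  net
}
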