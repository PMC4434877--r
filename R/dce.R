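#' Co-expression reversal type of a link
#'
#' Type 1 marks a sign reversal: the pair is positively correlated in one
#' condition and negatively correlated in the other (`r1 * r2 < 0`).
#' Type 0 marks no reversal, including the boundary case where either
#' coefficient is exactly zero (no sign change is demonstrable from a zero
#' product).
#'
#' @param r1,r2 Numeric vectors of correlations in condition 1 and 2
#'   (recycled pairwise), each in `[-1, 1]`.
#' @return Integer vector of 0/1 reversal flags.
#' @examples
#' reversal_type(0.94, 0.14)  # 0
#' reversal_type(-0.60, 0.97) # 1
#' @export
reversal_type <- function(r1, r2) {
  if (any(abs(r1) > 1, na.rm = TRUE) || any(abs(r2) > 1, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  as.integer(r1 * r2 < 0)
}

#' Select differentially co-expressed links by the limit-fold-change model
#'
#' Flags the links whose correlation changes most between the two
#' conditions, with a selection threshold that adapts to the magnitude of
#' the stronger coefficient (the limit-fold-change idea: at high signal a
#' smaller relative change is already meaningful, so ranking is done within
#' magnitude bins rather than globally).
#'
#' Links are split into a same-sign group (`r1 * r2 >= 0`) and an
#' opposite-sign (reversal) group. A reversal between two substantial
#' correlations -- opposite signs with `min(|r1|, |r2|) >= switch_min` --
#' is a qualitative change of regulation mode rather than a magnitude
#' change, and is flagged as a DCL outright (the *switch* class; its `bin`
#' is 0). All remaining links compete within their sign group: links are
#' binned into `n_bins` equal-count bins by `max(|r1|, |r2|)`, and within
#' each bin the top `delta` fraction by change score is flagged. The
#' change score is the fold change
#' `max(|r1|, |r2|) / (min(|r1|, |r2|) + epsilon)` for same-sign links and
#' the absolute difference `|r1 - r2|` for opposite-sign links. The
#' per-bin selection count is `delta` times the bin size, rounded half up,
#' and only links with a non-trivial change (fold change > 1, or
#' difference > 0) are eligible, so a network with identical coefficients
#' in both conditions yields no DCLs.
#'
#' @param net A [build_network_pair()] result.
#' @param delta Fraction of links flagged per bin (default 0.25).
#' @param n_bins Number of equal-count magnitude bins per group
#'   (default 20; reduced automatically when a group has fewer links).
#' @param epsilon Small constant guarding the fold-change denominator
#'   (default 1e-8).
#' @param switch_min Minimum correlation magnitude, in both conditions,
#'   for an opposite-sign link to qualify as a switch-class DCL without
#'   ranking. The default 0.8 matches the default link cutoff: a reversal
#'   bypasses the ranking only when the pair would qualify as a
#'   co-expression link in each condition separately.
#' @return A data frame of class `dcl_table` with one row per link:
#'   `gene_a`, `gene_b`, `r1`, `r2`, `type` (reversal flag), `is_dcl`,
#'   `bin` (magnitude bin index within the link's sign group), `score`
#'   (the ranking score used).
#' @export
lfc_select_dcls <- function(net, delta = 0.25, n_bins = 20L,
                            epsilon = 1e-8, switch_min = 0.8) {
  stopifnot(inherits(net, "coexpression_network_pair"),
            delta > 0, delta < 1, n_bins >= 1L, epsilon >= 0,
            switch_min >= 0, switch_min <= 1)
  l <- net$links
  if (nrow(l) == 0L) stop("network pair has no links")
  type <- reversal_type(l$r1, l$r2)
  hi <- pmax(abs(l$r1), abs(l$r2))
  lo <- pmin(abs(l$r1), abs(l$r2))
  score <- ifelse(type == 1L, abs(l$r1 - l$r2), hi / (lo + epsilon))
  eligible <- ifelse(type == 1L, score > 0, score > 1)
  switched <- type == 1L & lo >= switch_min

  is_dcl <- logical(nrow(l))
  is_dcl[switched] <- TRUE
  bin <- integer(nrow(l))
  for (grp in c(0L, 1L)) {
    rows <- which(type == grp & !switched)
    m <- length(rows)
    if (m == 0L) next
    nb <- min(n_bins, m)
    rk <- rank(hi[rows], ties.method = "first")
    b <- as.integer(floor((rk - 1L) * nb / m)) + 1L
    bin[rows] <- b
    for (bi in seq_len(nb)) {
      in_bin <- rows[b == bi]
      n_sel <- floor(delta * length(in_bin) + 0.5)  # round half up
      cand <- in_bin[eligible[in_bin]]
      if (n_sel == 0L || length(cand) == 0L) next
      o <- cand[order(-score[cand], l$gene_a[cand], l$gene_b[cand])]
      is_dcl[utils::head(o, n_sel)] <- TRUE
    }
  }
  if (!any(is_dcl))
    warning("no links flagged as DCLs at delta = ", delta)
  out <- data.frame(gene_a = l$gene_a, gene_b = l$gene_b,
                    r1 = l$r1, r2 = l$r2, type = type,
                    is_dcl = is_dcl, bin = bin, score = score,
                    stringsAsFactors = FALSE)
  class(out) <- c("dcl_table", "data.frame")
  out
}

#' Upper-tail binomial probability of DCL enrichment
#'
#' The probability that a gene with `n_i` links would carry `k_i` or more
#' DCLs if DCLs fell on links uniformly at random:
#' \deqn{P(g_i) = \sum_{x = k_i}^{n_i} \binom{n_i}{x} (K/N)^x (1 - K/N)^{n_i - x}}
#' with `K` DCLs among `N` network links. Computed through the binomial
#' survival function, which is evaluated in a numerically stable way.
#'
#' @param n_i Gene degree(s).
#' @param k_i Incident DCL count(s), `0 <= k_i <= n_i`.
#' @param K Total number of DCLs in the network.
#' @param N Total number of links in the network.
#' @return Probability vector in `(0, 1]`; exactly 1 when `k_i = 0`.
#' @examples
#' binomial_enrichment(2, 1, 1, 2) # 0.75
#' @export
binomial_enrichment <- function(n_i, k_i, K, N) {
  if (any(N < 1) || any(K < 0) || any(K > N))
    stop("require 0 <= K <= N and N >= 1")
  if (any(k_i < 0) || any(k_i > n_i))
    stop("require 0 <= k_i <= n_i")
  stats::pbinom(k_i - 1, size = n_i, prob = K / N, lower.tail = FALSE)
}

#' Per-gene DCL enrichment bookkeeping (DCe)
#'
#' Counts, for every gene incident to at least one link, its degree `n_i`
#' and incident-DCL count `k_i`, together with the network totals `N`
#' (links) and `K` (DCLs), and the resulting enrichment p-value.
#'
#' @param dcls A [lfc_select_dcls()] result.
#' @return A list of class `dce_counts` with elements `N`, `K` and `genes`
#'   (data frame `gene`, `n_i`, `k_i`, `p_value`, sorted by gene). The
#'   invariant `sum(k_i) == 2 * K` holds: every DCL is counted once at each
#'   endpoint.
#' @export
dce_counts <- function(dcls) {
  stopifnot(inherits(dcls, "dcl_table"))
  genes <- sort(unique(c(dcls$gene_a, dcls$gene_b)))
  n_i <- tabulate(match(c(dcls$gene_a, dcls$gene_b), genes),
                  length(genes))
  hit <- dcls$is_dcl
  k_i <- tabulate(match(c(dcls$gene_a[hit], dcls$gene_b[hit]), genes),
                  length(genes))
  N <- nrow(dcls)
  K <- sum(hit)
  structure(list(N = N, K = K,
                 genes = data.frame(gene = genes, n_i = n_i, k_i = k_i,
                                    p_value = binomial_enrichment(n_i, k_i,
                                                                  K, N),
                                    stringsAsFactors = FALSE)),
            class = "dce_counts")
}

#' Call differentially co-expressed genes by DCL enrichment
#'
#' @param counts A [dce_counts()] result.
#' @param p_threshold Keep genes with enrichment `p_value <= p_threshold`
#'   (default 0.05).
#' @return Sorted character vector of DCG gene ids.
#' @export
call_dce_dcgs <- function(counts, p_threshold = 0.05) {
  stopifnot(inherits(counts, "dce_counts"),
            p_threshold > 0, p_threshold <= 1)
  sort(counts$genes$gene[counts$genes$p_value <= p_threshold])
}
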