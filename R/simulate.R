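#' Configuration for the synthetic differential co-expression generator
#'
#' Describes a multi-group expression dataset with planted differential
#' co-expression structure: a set of regulator hubs, each correlated with
#' its targets at `base_correlation` under the baseline structure, with a
#' chosen fraction of hub links flipping sign (reversal) or dropping to the
#' background level (shift) in the altered group(s). Group sizes default to
#' the small case-control design typical of clinical microarray studies
#' (8 patients measured pre- and post-treatment, 8 controls).
#'
#' @param n_genes Total genes (hubs + targets + background).
#' @param samples_per_group Named integer vector, group label -> sample
#'   count (each at least 3). Default `c(pre = 8, post = 8, control = 8)`.
#' @param altered_groups Groups carrying the altered correlation structure
#'   (default `"pre"`: the untreated disease state); all other groups share
#'   the baseline structure.
#' @param n_tf_hubs Number of regulator hubs (default 5).
#' @param targets_per_hub Targets per hub (default 10).
#' @param reversal_fraction Fraction of each hub's links whose correlation
#'   flips sign in the altered groups (default 0.5).
#' @param shift_fraction Fraction whose correlation drops to the
#'   background level in the altered groups (default 0.25); the remaining
#'   links are unchanged. Fractions must sum to at most 1.
#' @param base_correlation Hub-target correlation magnitude (default 0.9).
#' @param background_correlation Correlation among background genes
#'   (default 0).
#' @param noise_sd Standard deviation of expression values on the
#'   log2-like scale (default 1).
#' @param baseline_mean Mean expression level (default 8, a typical
#'   log2 microarray intensity).
#' @param n_decoy_relations Extra TF-to-target relations among background
#'   genes added to the generated library (default 20), so the library is
#'   not trivially equal to the planted truth.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 200L,
                              samples_per_group = c(pre = 8L, post = 8L,
                                                    control = 8L),
                              altered_groups = "pre",
                              n_tf_hubs = 5L, targets_per_hub = 10L,
                              reversal_fraction = 0.5,
                              shift_fraction = 0.25,
                              base_correlation = 0.9,
                              background_correlation = 0,
                              noise_sd = 1, baseline_mean = 8,
                              n_decoy_relations = 20L, seed = 1L) {
  if (is.null(names(samples_per_group)) ||
      any(!nzchar(names(samples_per_group))))
    stop("`samples_per_group` must be a named vector")
  if (any(samples_per_group < 3L))
    stop("every group needs at least 3 samples")
  if (!all(altered_groups %in% names(samples_per_group)))
    stop("`altered_groups` must be a subset of the group names")
  if (reversal_fraction < 0 || shift_fraction < 0 ||
      reversal_fraction + shift_fraction > 1)
    stop("link-class fractions must be non-negative and sum to at most 1")
  if (abs(base_correlation) >= 1 || background_correlation < 0 ||
      background_correlation >= 1)
    stop("correlations must lie strictly inside (-1, 1)")
  if (n_tf_hubs * (1L + targets_per_hub) > n_genes)
    stop("planted structure does not fit in `n_genes`")
  if (noise_sd <= 0) stop("`noise_sd` must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 samples_per_group = samples_per_group,
                 altered_groups = altered_groups,
                 n_tf_hubs = as.integer(n_tf_hubs),
                 targets_per_hub = as.integer(targets_per_hub),
                 reversal_fraction = reversal_fraction,
                 shift_fraction = shift_fraction,
                 base_correlation = base_correlation,
                 background_correlation = background_correlation,
                 noise_sd = noise_sd, baseline_mean = baseline_mean,
                 n_decoy_relations = as.integer(n_decoy_relations),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Simulate a multi-group expression dataset with planted structure
#'
#' Draws each group from a multivariate normal defined by a single-factor
#' model per hub: the hub is a standard normal latent, and each of its
#' targets loads on it with loading `base_correlation` (baseline) whose
#' sign flips for reversal links, or drops to the background for shift
#' links, in the altered groups. Target-target correlations within a hub
#' block equal the product of their loadings; background genes optionally
#' share a weak global factor. Because the covariance is built from factor
#' loadings it is positive semi-definite by construction and needs no
#' repair. Values are scaled to a log2-like intensity scale
#' (`baseline_mean` + `noise_sd` x latent).
#'
#' @param config A [simulation_config()].
#' @return List with `expr` (an [expression_matrix()]) and `truth`, a
#'   `ground_truth` list: `dcg_genes` (the hub regulators whose
#'   neighborhood changes), `dcl_links` (data frame `gene_a`, `gene_b`,
#'   `class` in `reversal`/`shift`, canonical order) and `library`
#'   (a [tf2target_library()] holding every planted hub-to-target relation
#'   plus decoy relations among background genes).
#' @export
simulate_dc_data <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n_hub_genes <- config$n_tf_hubs * (1L + config$targets_per_hub)
  n_bg <- config$n_genes - n_hub_genes

  hubs <- sprintf("TF%02d", seq_len(config$n_tf_hubs))
  targets <- if (config$n_tf_hubs > 0L)
    lapply(seq_len(config$n_tf_hubs), function(h)
      sprintf("TG%02d_%02d", h, seq_len(config$targets_per_hub)))
  else list()
  bg <- if (n_bg > 0L) sprintf("BG%03d", seq_len(n_bg)) else character(0)
  genes <- c(hubs, unlist(targets), bg)

  # per-hub link classes, fixed across groups
  n_rev <- round(config$reversal_fraction * config$targets_per_hub)
  n_shift <- min(round(config$shift_fraction * config$targets_per_hub),
                 config$targets_per_hub - n_rev)
  link_class <- lapply(seq_len(config$n_tf_hubs), function(h) {
    cls <- rep("unchanged", config$targets_per_hub)
    pick <- sample.int(config$targets_per_hub, n_rev + n_shift)
    cls[pick[seq_len(n_rev)]] <- "reversal"
    if (n_shift > 0L) cls[pick[n_rev + seq_len(n_shift)]] <- "shift"
    cls
  })

  draw_group <- function(n, altered) {
    z <- matrix(0, nrow = length(genes), ncol = n,
                dimnames = list(genes, NULL))
    r <- config$base_correlation
    for (h in seq_len(config$n_tf_hubs)) {
      hub_lat <- stats::rnorm(n)
      z[hubs[h], ] <- hub_lat
      lam <- rep(r, config$targets_per_hub)
      if (altered) {
        lam[link_class[[h]] == "reversal"] <- -r
        lam[link_class[[h]] == "shift"] <- 0
      }
      for (j in seq_len(config$targets_per_hub)) {
        z[targets[[h]][j], ] <- lam[j] * hub_lat +
          sqrt(1 - lam[j]^2) * stats::rnorm(n)
      }
    }
    if (n_bg > 0L) {
      bgc <- config$background_correlation
      glob <- if (bgc > 0) stats::rnorm(n) else numeric(n)
      z[bg, ] <- sqrt(bgc) * matrix(glob, n_bg, n, byrow = TRUE) +
        sqrt(1 - bgc) * matrix(stats::rnorm(n_bg * n), n_bg, n)
    }
    config$baseline_mean + config$noise_sd * z
  }

  groups <- names(config$samples_per_group)
  mats <- vector("list", length(groups))
  conds <- character(0)
  for (gi in seq_along(groups)) {
    n <- config$samples_per_group[[gi]]
    m <- draw_group(n, altered = groups[gi] %in% config$altered_groups)
    colnames(m) <- sprintf("%s_%02d", groups[gi], seq_len(n))
    mats[[gi]] <- m
    conds <- c(conds, stats::setNames(rep(groups[gi], n), colnames(m)))
  }
  expr <- expression_matrix(do.call(cbind, mats), conds)

  planted <- do.call(rbind, lapply(seq_len(config$n_tf_hubs), function(h) {
    cls <- link_class[[h]]
    keep <- cls != "unchanged"
    if (!any(keep)) return(NULL)
    data.frame(tf = hubs[h], target = targets[[h]][keep],
               class = cls[keep], stringsAsFactors = FALSE)
  }))
  if (is.null(planted))
    planted <- data.frame(tf = character(0), target = character(0),
                          class = character(0), stringsAsFactors = FALSE)
  dcl_links <- data.frame(
    gene_a = pmin(planted$tf, planted$target),
    gene_b = pmax(planted$tf, planted$target),
    class = planted$class, stringsAsFactors = FALSE)

  # library: every hub-to-target relation (planted and unchanged) plus
  # decoy relations among background genes
  lib_tf <- rep(hubs, each = config$targets_per_hub)
  lib_tg <- unlist(targets)
  if (config$n_decoy_relations > 0L && n_bg >= 2L) {
    d_tf <- bg[sample.int(n_bg, config$n_decoy_relations, replace = TRUE)]
    d_tg <- bg[sample.int(n_bg, config$n_decoy_relations, replace = TRUE)]
    ok <- d_tf != d_tg
    lib_tf <- c(lib_tf, d_tf[ok])
    lib_tg <- c(lib_tg, d_tg[ok])
  }
  truth <- structure(
    list(dcg_genes = if (nrow(dcl_links)) sort(unique(planted$tf))
                     else character(0),
         dcl_links = dcl_links[order(dcl_links$gene_a, dcl_links$gene_b), ,
                               drop = FALSE],
         library = tf2target_library(lib_tf, lib_tg)),
    class = "ground_truth")
  rownames(truth$dcl_links) <- NULL
  list(expr = expr, truth = truth)
}

#' Score a report against the planted ground truth
#'
#' Sensitivity is the fraction of planted elements recovered; the
#' false-discovery fraction is the fraction of reported elements that were
#' not planted. Both are computed separately for genes (report
#' `true_dcgs` vs planted regulator hubs) and links (report `true_dcls`
#' vs planted differential links).
#'
#' @param report A [differential_regulation_report()].
#' @param truth A `ground_truth` from [simulate_dc_data()].
#' @return List with elements `dcg` and `dcl`, each
#'   `c(sensitivity =, fdr_fraction =)`. Values are `NA` when the truth
#'   (for sensitivity) or the report (for the false-discovery fraction)
#'   is empty.
#' @export
recovery_score <- function(report, truth) {
  stopifnot(inherits(report, "differential_regulation_report"),
            inherits(truth, "ground_truth"))
  score <- function(found, planted) {
    c(sensitivity = if (length(planted)) mean(planted %in% found)
                    else NA_real_,
      fdr_fraction = if (length(found)) mean(!found %in% planted)
                     else NA_real_)
  }
  link_key <- function(d) if (nrow(d)) paste(d$gene_a, d$gene_b, sep = "\r")
                          else character(0)
  list(dcg = score(report$true_dcgs, truth$dcg_genes),
       dcl = score(link_key(report$true_dcls), link_key(truth$dcl_links)))
}
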