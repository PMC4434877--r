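#' Remove elements shared with a confounding comparison
#'
#' Implements the individual-effect exclusion of the three-comparison
#' design: results of the disease-vs-control comparison that also appear in
#' the post-treatment-vs-control comparison are attributed to stable
#' between-individual differences and removed, i.e.
#' `primary - (primary intersect confound)`.
#'
#' Gene sets are matched by id. DRL tables are matched by their ordered
#' `(tf, target)` identity -- not by correlation values, which necessarily
#' differ between comparisons.
#'
#' @param primary Character vector of gene ids, or a `drl_table` /
#'   data frame with `tf` and `target` columns.
#' @param confound Object of the same kind.
#' @return Object of the same kind as `primary`, with shared elements
#'   removed. The operation is idempotent in `confound`.
#' @examples
#' exclude_shared(c("A", "B", "C"), c("B", "D")) # "A" "C"
#' @export
exclude_shared <- function(primary, confound) {
  if (is.data.frame(primary)) {
    stopifnot(all(c("tf", "target") %in% names(primary)))
    key <- function(d) paste(d$tf, d$target, sep = "\r")
    ck <- if (is.data.frame(confound)) key(confound) else character(0)
    out <- primary[!key(primary) %in% ck, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    sort(setdiff(primary, confound))
  }
}

#' Overlap DRGs with DRLs to extract the key regulators and key links
#'
#' A DRL is *key* when its transcription factor is itself a
#' disease-associated DRG; the key DRGs are exactly the TFs of the key
#' DRLs. This is the final overlap step of the study design: it keeps the
#' regulatory links that are differential at both ends of the regulation
#' hierarchy (the regulator is a differential hub and the link coincides
#' with a known TF-to-target relation).
#'
#' @param drgs Character vector of DRG ids (after exclusion).
#' @param drls A `drl_table` (after exclusion).
#' @return List with `key_drgs` (sorted character vector) and `key_drls`
#'   (the retained DRL rows).
#' @export
key_overlap <- function(drgs, drls) {
  stopifnot(is.data.frame(drls))
  key_drls <- drls[drls$tf %in% drgs, , drop = FALSE]
  rownames(key_drls) <- NULL
  list(key_drgs = sort(unique(key_drls$tf)), key_drls = key_drls)
}

#' Analysis configuration for one comparison or study arm
#'
#' @param cutoff A [link_cutoff()] (default absolute, 0.8).
#' @param n_permutations Permutations for the DCp null (default 500).
#' @param seed Integer seed; every run derives its randomness from it.
#' @param dcp_p,dcp_fdr DCp DCG thresholds (p 0.05; FDR unused unless set).
#' @param dce_p DCe enrichment DCG threshold (default 0.05).
#' @param lfc_delta,lfc_bins,lfc_epsilon Limit-fold-change selection knobs
#'   (defaults 0.25, 20, 1e-8).
#' @param method Correlation type (default `"pearson"`).
#' @param scheme Permutation scheme for [dcp_test()].
#' @return A `dc_config` list.
#' @export
dc_config <- function(cutoff = link_cutoff(), n_permutations = 500L,
                      seed = 1L, dcp_p = 0.05, dcp_fdr = NULL,
                      dce_p = 0.05, lfc_delta = 0.25, lfc_bins = 20L,
                      lfc_epsilon = 1e-8,
                      method = c("pearson", "spearman"),
                      scheme = c("reselect", "fixed")) {
  structure(list(cutoff = cutoff, n_permutations = as.integer(n_permutations),
                 seed = as.integer(seed), dcp_p = dcp_p, dcp_fdr = dcp_fdr,
                 dce_p = dce_p, lfc_delta = lfc_delta,
                 lfc_bins = as.integer(lfc_bins), lfc_epsilon = lfc_epsilon,
                 method = match.arg(method), scheme = match.arg(scheme)),
            class = "dc_config")
}

#' Run one full differential co-expression + regulation comparison
#'
#' Executes, for a pair of conditions: pairwise correlations, shared-link
#' network construction, the DCp permutation test, limit-fold-change DCL
#' selection with binomial enrichment (DCe), the true-DCG/true-DCL fusion,
#' and TF2target annotation.
#'
#' @param expr An [expression_matrix()].
#' @param cond1,cond2 Condition labels to compare.
#' @param lib A [tf2target_library()].
#' @param config A [dc_config()].
#' @param label Report label (default `"cond1_vs_cond2"`).
#' @return A [differential_regulation_report()] with extra elements
#'   `dcp_results`, `dce_counts`, `dcls`, `net` and `config` attached as
#'   attributes-free list members for inspection.
#' @export
run_comparison <- function(expr, cond1, cond2, lib, config = dc_config(),
                           label = paste0(cond1, "_vs_", cond2)) {
  stopifnot(inherits(config, "dc_config"))
  c1 <- pairwise_correlations(expr, cond1, method = config$method)
  c2 <- pairwise_correlations(expr, cond2, method = config$method)
  net <- build_network_pair(c1, c2, cutoff = config$cutoff)
  dcp <- dcp_test(expr, net, n_permutations = config$n_permutations,
                  seed = config$seed, scheme = config$scheme)
  dcp_set <- call_dcp_dcgs(dcp, config$dcp_p, config$dcp_fdr)
  dcls <- suppressWarnings(
    lfc_select_dcls(net, delta = config$lfc_delta,
                    n_bins = config$lfc_bins,
                    epsilon = config$lfc_epsilon))
  counts <- dce_counts(dcls)
  dce_set <- call_dce_dcgs(counts, config$dce_p)
  tg <- true_dcgs(dcp_set, dce_set)
  tl <- true_dcls(dcls, tg)
  rep <- differential_regulation_report(
    true_dcgs = tg, true_dcls = tl,
    drgs = annotate_drgs(tg, lib),
    drls = annotate_drls(tl, lib, dcp),
    comparison_label = label)
  rep$dcp_results <- dcp
  rep$dce_counts <- counts
  rep$dcls <- dcls
  rep$net <- net
  rep$config <- config
  rep
}

#' Run a full three-comparison study arm
#'
#' The study design for one phenotype arm: compare pre-treatment patients
#' against controls, post-treatment patients against controls, and
#' pre- against post-treatment. Disease-associated DRGs and DRLs are the
#' pre-vs-control results with the elements shared with post-vs-control
#' excluded (stable individual effects); the key regulators are obtained
#' by [key_overlap()]. The pre-vs-post comparison reports the treatment
#' effect; an empty treatment report is a valid outcome meaning no
#' detected effect, never an error.
#'
#' @param expr An [expression_matrix()] containing all three groups.
#' @param conditions Named character vector with entries `pre`, `post`
#'   and `control` giving the condition labels in `expr`.
#' @param lib A [tf2target_library()].
#' @param config A [dc_config()]; each comparison derives its permutation
#'   seed from `config$seed` deterministically.
#' @param label Arm label (e.g. the phenotype name).
#' @return A `study_arm` list: `label`, `reports` (named
#'   `pre_vs_control`, `post_vs_control`, `pre_vs_post`), and `summary`,
#'   a `key_regulation_summary` with `disease_drgs`, `disease_drls`,
#'   `key_drgs`, `key_drls`, `treatment_drgs`, `treatment_drls`.
#' @export
run_study_arm <- function(expr, conditions, lib, config = dc_config(),
                          label = "arm") {
  need <- c("pre", "post", "control")
  if (!all(need %in% names(conditions)))
    stop("`conditions` must name pre, post and control labels; missing: ",
         paste(setdiff(need, names(conditions)), collapse = ", "))
  for (nm in need)
    if (!conditions[[nm]] %in% expr$conditions)
      stop(sprintf("condition '%s' (%s) not present in the expression matrix",
                   conditions[[nm]], nm))
  sub_config <- function(offset) {
    cfg <- config
    cfg$seed <- config$seed + offset
    cfg
  }
  reports <- list(
    pre_vs_control = run_comparison(expr, conditions[["pre"]],
                                    conditions[["control"]], lib,
                                    sub_config(0L), "pre_vs_control"),
    post_vs_control = run_comparison(expr, conditions[["post"]],
                                     conditions[["control"]], lib,
                                     sub_config(1L), "post_vs_control"),
    pre_vs_post = run_comparison(expr, conditions[["pre"]],
                                 conditions[["post"]], lib,
                                 sub_config(2L), "pre_vs_post"))
  disease_drgs <- exclude_shared(reports$pre_vs_control$drgs,
                                 reports$post_vs_control$drgs)
  disease_drls <- exclude_shared(reports$pre_vs_control$drls,
                                 reports$post_vs_control$drls)
  keys <- key_overlap(disease_drgs, disease_drls)
  summary <- structure(
    list(disease_drgs = disease_drgs, disease_drls = disease_drls,
         key_drgs = keys$key_drgs, key_drls = keys$key_drls,
         treatment_drgs = reports$pre_vs_post$drgs,
         treatment_drls = reports$pre_vs_post$drls),
    class = "key_regulation_summary")
  structure(list(label = label, reports = reports, summary = summary),
            class = "study_arm")
}

#' @export
print.study_arm <- function(x, ...) {
  cat(sprintf("study_arm '%s'\n", x$label))
  for (r in x$reports) print(r)
  s <- x$summary
  cat(sprintf("  disease DRGs: %d, disease DRLs: %d, key DRGs: %d, key DRLs: %d\n",
              length(s$disease_drgs), nrow(s$disease_drls),
              length(s$key_drgs), nrow(s$key_drls)))
  cat(sprintf("  treatment effect: %s\n",
              if (length(s$treatment_drgs) == 0L && nrow(s$treatment_drls) == 0L)
                "none detected" else
                  sprintf("%d DRGs, %d DRLs", length(s$treatment_drgs),
                          nrow(s$treatment_drls))))
  invisible(x)
}
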