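#' Transcription-factor-to-target library
#'
#' A set of ordered (TF, target) regulatory relations used to project
#' differential co-expression calls onto known regulation. Duplicated
#' relations are collapsed; a gene may appear both as a regulator and as a
#' target.
#'
#' @param tf,target Character vectors of equal length, one relation per
#'   entry.
#' @return A `tf2target_library`: list with `relations` (data frame `tf`,
#'   `target`, deduplicated, sorted by TF then target), `tfs` and
#'   `targets` (derived sets).
#' @export
tf2target_library <- function(tf, target) {
  stopifnot(length(tf) == length(target))
  tf <- as.character(tf)
  target <- as.character(target)
  if (any(!nzchar(tf)) || any(!nzchar(target)) || anyNA(tf) || anyNA(target))
    stop("empty or missing gene ids in the library")
  rel <- unique(data.frame(tf = tf, target = target,
                           stringsAsFactors = FALSE))
  rel <- rel[order(rel$tf, rel$target), , drop = FALSE]
  rownames(rel) <- NULL
  structure(list(relations = rel,
                 tfs = sort(unique(rel$tf)),
                 targets = sort(unique(rel$target))),
            class = "tf2target_library")
}

#' @export
print.tf2target_library <- function(x, ...) {
  cat(sprintf("tf2target_library: %d relations, %d TFs, %d targets\n",
              nrow(x$relations), length(x$tfs), length(x$targets)))
  invisible(x)
}

#' True DCGs: intersection of the DCp and DCe gene calls
#'
#' A gene is a true differentially co-expressed gene when both methods --
#' the per-gene permutation statistic and the link-enrichment test --
#' agree on it.
#'
#' @param dcp_set,dce_set Character vectors of gene ids from
#'   [call_dcp_dcgs()] and [call_dce_dcgs()].
#' @return Sorted character vector.
#' @export
true_dcgs <- function(dcp_set, dce_set) {
  sort(intersect(dcp_set, dce_set))
}

#' True DCLs: DCLs anchored on at least one true DCG
#'
#' @param dcls A [lfc_select_dcls()] result (only rows with `is_dcl` are
#'   considered).
#' @param true_dcg_set Character vector of true DCG ids.
#' @return Data frame of retained DCL rows with logical columns `star_a`
#'   and `star_b` marking which endpoint(s) are true DCGs.
#' @export
true_dcls <- function(dcls, true_dcg_set) {
  stopifnot(is.data.frame(dcls))
  d <- dcls[dcls$is_dcl, , drop = FALSE]
  star_a <- d$gene_a %in% true_dcg_set
  star_b <- d$gene_b %in% true_dcg_set
  keep <- star_a | star_b
  out <- d[keep, , drop = FALSE]
  out$star_a <- star_a[keep]
  out$star_b <- star_b[keep]
  rownames(out) <- NULL
  out
}

#' Differentially regulated genes: true DCGs that are known TFs
#'
#' @param true_dcg_set Character vector of true DCG ids.
#' @param lib A [tf2target_library()].
#' @return Sorted character vector of DRG ids.
#' @export
annotate_drgs <- function(true_dcg_set, lib) {
  stopifnot(inherits(lib, "tf2target_library"))
  sort(intersect(true_dcg_set, lib$tfs))
}

#' TF2target DCLs (DRLs): true DCLs that coincide with a library relation
#'
#' Each true DCL `(a, b)` is matched against the library in both
#' orientations; every orientation present yields one DRL record (a link
#' regulated both ways produces two records). The `p_dcg` column carries
#' the DCp p-value of the link's starred (true-DCG) endpoint; when both
#' endpoints are true DCGs the smaller p-value is reported.
#'
#' @param links A [true_dcls()] result (DCL rows with `star_a`/`star_b`).
#' @param lib A [tf2target_library()].
#' @param dcp_results A [dcp_test()] result supplying per-gene p-values.
#' @return Data frame of class `drl_table` with columns `tf`, `target`,
#'   `p_dcg`, `r1`, `r2`, `type`, sorted by TF then target.
#' @export
annotate_drls <- function(links, lib, dcp_results) {
  stopifnot(is.data.frame(links), inherits(lib, "tf2target_library"),
            is.data.frame(dcp_results))
  if (nrow(links) && (anyNA(links$r1) || anyNA(links$r2)))
    stop("links are missing correlation coefficients")
  p_of <- stats::setNames(dcp_results$p_value, dcp_results$gene)
  rel_key <- paste(lib$relations$tf, lib$relations$target, sep = "\r")
  one_way <- function(tf, target, star_tf, star_target, r1, r2, type) {
    hit <- paste(tf, target, sep = "\r") %in% rel_key
    p_tf <- ifelse(star_tf, p_of[tf], NA_real_)
    p_tg <- ifelse(star_target, p_of[target], NA_real_)
    data.frame(tf = tf[hit], target = target[hit],
               p_dcg = unname(pmin(p_tf, p_tg, na.rm = TRUE)[hit]),
               r1 = r1[hit], r2 = r2[hit], type = type[hit],
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    one_way(links$gene_a, links$gene_b, links$star_a, links$star_b,
            links$r1, links$r2, links$type),
    one_way(links$gene_b, links$gene_a, links$star_b, links$star_a,
            links$r1, links$r2, links$type))
  out <- out[order(out$tf, out$target), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("drl_table", "data.frame")
  out
}

#' Assemble a differential regulation report for one comparison
#'
#' @param true_dcgs,true_dcls,drgs,drls Components from the corresponding
#'   functions.
#' @param comparison_label Text label, e.g. `"pre_vs_control"`.
#' @return A `differential_regulation_report` list.
#' @export
differential_regulation_report <- function(true_dcgs, true_dcls, drgs,
                                           drls, comparison_label) {
  structure(list(true_dcgs = true_dcgs, true_dcls = true_dcls,
                 drgs = drgs, drls = drls,
                 comparison_label = comparison_label),
            class = "differential_regulation_report")
}

#' @export
print.differential_regulation_report <- function(x, ...) {
  cat(sprintf(
    "differential_regulation_report '%s': %d true DCGs, %d true DCLs, %d DRGs, %d DRLs\n",
    x$comparison_label, length(x$true_dcgs), nrow(x$true_dcls),
    length(x$drgs), nrow(x$drls)))
  invisible(x)
}
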