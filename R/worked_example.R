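#' Bundled worked example: published DRG/DRL tables from a two-subtype
#' depression study
#'
#' The package ships the reported differential-regulation output of a
#' peripheral-blood microarray study that compared two depressive
#' subtypes (major depressive disorder, MDD, and subsyndromal symptomatic
#' depression, SSD) against healthy controls before and after
#' venlafaxine treatment: the TF2target DCL tables of the
#' pre-treatment-vs-control comparisons and the DRG lists of all four
#' patient-vs-control comparisons. These tables exercise the downstream
#' set logic (individual-effect exclusion and key-regulator overlap)
#' exactly as published, without access to the original expression data.
#'
#' Each DRL table has columns `no`, `tf`, `target`, `p_dcg` (DCp p-value
#' of the starred DCG endpoint), `r1`, `r2` (the two condition-specific
#' correlations), `type` (sign-reversal flag), `star` (which endpoint is
#' the DCG: `tf`, `target` or `both`) and `retained` (`FALSE` for the
#' rows the source discarded as stable individual effects).
#'
#' @return A list with elements `mdd` and `ssd`, each a list holding
#'   `drls` (the full DRL table, class `drl_table`), `drg_pre` and
#'   `drg_post` (the pre-/post-treatment-vs-control DRG sets).
#' @examples
#' ex <- worked_example()
#' drg <- exclude_shared(ex$mdd$drg_pre, ex$mdd$drg_post)   # 12 genes
#' keys <- key_overlap(drg, ex$mdd$drls[ex$mdd$drls$retained, ])
#' length(keys$key_drgs)   # 6
#' nrow(keys$key_drls)     # 16
#' @export
worked_example <- function() {
  path <- function(f) system.file("extdata", f, package = "coexdiff",
                                  mustWork = TRUE)
  read_drls <- function(f) {
    d <- utils::read.delim(path(f), stringsAsFactors = FALSE)
    names(d)[names(d) == "cor1"] <- "r1"
    names(d)[names(d) == "cor2"] <- "r2"
    class(d) <- c("drl_table", "data.frame")
    d
  }
  drg <- utils::read.delim(path("drg_sets.tsv"), stringsAsFactors = FALSE)
  set_of <- function(cmp) sort(drg$gene[drg$comparison == cmp])
  list(mdd = list(drls = read_drls("mdd_pre_vs_control_drls.tsv"),
                  drg_pre = set_of("mdd_pre_vs_control"),
                  drg_post = set_of("mdd_post_vs_control")),
       ssd = list(drls = read_drls("ssd_pre_vs_control_drls.tsv"),
                  drg_pre = set_of("ssd_pre_vs_control"),
                  drg_post = set_of("ssd_post_vs_control")))
}
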