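#' Read an expression matrix and sample sheet from tab-separated text
#'
#' The expression file has a header row of sample ids and one row per
#' gene, first column the gene id. The sample sheet has two columns,
#' sample id and condition label, with a header.
#'
#' @param path Expression TSV path.
#' @param sample_sheet Sample-sheet TSV path.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, sample_sheet) {
  fields <- utils::count.fields(path, sep = "\t", quote = "",
                                comment.char = "")
  if (length(unique(fields)) != 1L)
    stop(sprintf("ragged rows in '%s' (lines %s)", path,
                 paste(utils::head(which(fields != fields[1L]), 5L),
                       collapse = ", ")))
  tab <- utils::read.delim(path, check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  ids <- tab[[1L]]
  dup <- duplicated(ids)
  if (any(dup))
    stop(sprintf("duplicate gene id(s) in '%s': %s (line %s)", path,
                 paste(unique(ids[dup]), collapse = ", "),
                 paste(which(dup) + 1L, collapse = ", ")))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric value in '%s' at line %d, sample '%s'",
                 path, bad[["row"]] + 1L, colnames(vals)[bad[["col"]]]))
  }
  rownames(vals) <- ids
  sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE,
                             colClasses = "character")
  if (ncol(sheet) < 2L)
    stop("sample sheet needs two columns: sample id, condition")
  expression_matrix(vals, stats::setNames(sheet[[2L]], sheet[[1L]]))
}

#' Write an expression matrix and sample sheet as tab-separated text
#'
#' @param expr An [expression_matrix()].
#' @param path Expression TSV path.
#' @param sample_sheet Sample-sheet TSV path.
#' @return Invisibly, `expr`. Round-trips exactly through
#'   [read_expression()] up to numeric formatting (15 significant digits).
#' @export
write_expression <- function(expr, path, sample_sheet) {
  stopifnot(inherits(expr, "expression_matrix"))
  tab <- data.frame(gene = rownames(expr$values),
                    format(expr$values, digits = 15, trim = TRUE,
                           scientific = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample = names(expr$conditions),
               condition = unname(expr$conditions)),
    sample_sheet, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(expr)
}

#' Read a TF-to-target library from two-column tab-separated text
#'
#' One relation per line (TF, target), optional header (detected by the
#' literal first line `tf<TAB>target`), `#` comment lines ignored.
#'
#' @param path Library TSV path.
#' @return A [tf2target_library()].
#' @export
read_tf2target <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L)
    stop("library file needs two tab-separated columns: TF, target")
  if (nrow(tab) && tolower(tab[1L, 1L]) %in% c("tf", "regulator"))
    tab <- tab[-1L, , drop = FALSE]
  tf2target_library(tab[[1L]], tab[[2L]])
}

#' Write a TF-to-target library
#'
#' @param lib A [tf2target_library()].
#' @param path Output TSV path.
#' @export
write_tf2target <- function(lib, path) {
  stopifnot(inherits(lib, "tf2target_library"))
  utils::write.table(lib$relations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(lib)
}

#' Write the output tables and manifest of a study arm or single report
#'
#' Writes, per comparison: the per-gene DCp table, the DCL table (layout
#' `NO., gene A, gene B, Cor.1, Cor.2, Type, is_dcl, bin`) and the DRL
#' table (layout `NO., TF, Target, p.DCG, Cor.1, Cor.2, Type`), plus --
#' for a full arm -- the exclusion summary and key tables, and a
#' machine-readable JSON manifest recording configuration, seed and
#' counts.
#'
#' @param x A `study_arm` or `differential_regulation_report`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
write_report <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  drl_out <- function(d) {
    if (nrow(d) == 0L)
      return(data.frame(NO. = integer(0), TF = character(0),
                        Target = character(0), p.DCG = numeric(0),
                        Cor.1 = numeric(0), Cor.2 = numeric(0),
                        Type = integer(0), check.names = FALSE))
    data.frame(NO. = seq_len(nrow(d)), TF = d$tf, Target = d$target,
               p.DCG = d$p_dcg, Cor.1 = d$r1, Cor.2 = d$r2, Type = d$type,
               check.names = FALSE)
  }
  dcl_out <- function(d) data.frame(
    NO. = seq_len(nrow(d)), `gene A` = d$gene_a,
    `gene B` = d$gene_b, Cor.1 = d$r1, Cor.2 = d$r2, Type = d$type,
    is_dcl = d$is_dcl, bin = d$bin, check.names = FALSE)

  write_one <- function(rep, prefix) {
    tsv(as.data.frame(rep$dcp_results), paste0(prefix, "_dcp.tsv"))
    tsv(dcl_out(rep$dcls), paste0(prefix, "_dcls.tsv"))
    tsv(drl_out(rep$drls), paste0(prefix, "_drls.tsv"))
    list(comparison = rep$comparison_label,
         n_links = nrow(rep$net$links),
         n_true_dcgs = length(rep$true_dcgs),
         n_true_dcls = nrow(rep$true_dcls),
         n_drgs = length(rep$drgs), n_drls = nrow(rep$drls))
  }

  if (inherits(x, "study_arm")) {
    counts <- lapply(x$reports, function(r)
      write_one(r, r$comparison_label))
    s <- x$summary
    tsv(data.frame(gene = s$disease_drgs), "disease_drgs.tsv")
    tsv(drl_out(s$disease_drls), "disease_drls.tsv")
    tsv(data.frame(gene = s$key_drgs), "key_drgs.tsv")
    tsv(drl_out(s$key_drls), "key_drls.tsv")
    cfg <- x$reports$pre_vs_control$config
    manifest <- list(label = x$label, comparisons = counts,
                     summary = list(n_disease_drgs = length(s$disease_drgs),
                                    n_disease_drls = nrow(s$disease_drls),
                                    n_key_drgs = length(s$key_drgs),
                                    n_key_drls = nrow(s$key_drls),
                                    n_treatment_drgs = length(s$treatment_drgs),
                                    n_treatment_drls = nrow(s$treatment_drls)),
                     config = config_manifest(cfg))
  } else if (inherits(x, "differential_regulation_report")) {
    manifest <- list(comparisons = list(write_one(x, x$comparison_label)),
                     config = config_manifest(x$config))
  } else stop("`x` must be a study_arm or differential_regulation_report")
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

config_manifest <- function(cfg) {
  if (is.null(cfg)) return(NULL)
  list(cutoff_mode = cfg$cutoff$mode, cutoff_value = cfg$cutoff$value,
       n_permutations = cfg$n_permutations, seed = cfg$seed,
       dcp_p = cfg$dcp_p, dcp_fdr = cfg$dcp_fdr, dce_p = cfg$dce_p,
       lfc_delta = cfg$lfc_delta, lfc_bins = cfg$lfc_bins,
       lfc_epsilon = cfg$lfc_epsilon, method = cfg$method,
       scheme = cfg$scheme,
       package_version = as.character(utils::packageVersion("coexdiff")))
}

#' Write a simulated dataset to disk in the analysis input formats
#'
#' Emits the expression TSV, sample sheet and library TSV the analysis
#' consumes, plus the planted ground truth as tab-separated text.
#'
#' @param sim A [simulate_dc_data()] result.
#' @param dir Output directory (created if needed).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(sim$expr, file.path(dir, "expression.tsv"),
                   file.path(dir, "samples.tsv"))
  write_tf2target(sim$truth$library, file.path(dir, "library.tsv"))
  utils::write.table(sim$truth$dcl_links, file.path(dir, "truth_links.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene = sim$truth$dcg_genes),
                     file.path(dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(sim)
}
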