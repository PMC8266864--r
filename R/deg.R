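#' Call differentially expressed genes
#'
#' Applies the DEG thresholds to a differential-expression table: fold change
#' of at least `fold_change_min` (inclusive: |log2fc| >= log2(fold_change_min)),
#' BH-adjusted p strictly below `padj_max`, and — when a `perm_p` column is
#' present — permutation p strictly below `perm_p_max`.  When `perm_p` is
#' absent that criterion is skipped and the provenance records it.
#'
#' @param de A `de_result` (or data.frame with `gene_id`, `log2fc`, `padj`,
#'   optionally `perm_p`).
#' @param fold_change_min Minimum fold change (default 1.5; must be >= 1).
#' @param padj_max,perm_p_max Strict upper bounds on adjusted and permutation
#'   p (defaults 0.05).
#' @return A \code{deg_list}: data.frame of called genes (`gene_id`,
#'   `log2fc`, `padj`, `perm_p` if present, `direction`) with a `provenance`
#'   attribute recording thresholds and filters applied.
#' @export
call_degs <- function(de, fold_change_min = 1.5, padj_max = 0.05,
                      perm_p_max = 0.05) {
  if (fold_change_min < 1 || padj_max <= 0 || perm_p_max <= 0) {
    stop("thresholds must be positive and fold_change_min >= 1")
  }
  lfc_min <- log2(fold_change_min)
  has_perm <- !is.null(de$perm_p)
  pass <- abs(de$log2fc) >= lfc_min & de$padj < padj_max
  if (has_perm) pass <- pass & de$perm_p < perm_p_max
  cols <- c("gene_id", "log2fc", "padj", if (has_perm) "perm_p")
  out <- as.data.frame(de)[pass, cols, drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  structure(out, class = c("deg_list", "data.frame"),
            contrast = attr(de, "contrast"),
            provenance = list(fold_change_min = fold_change_min,
                              padj_max = padj_max,
                              perm_p_max = if (has_perm) perm_p_max else NA_real_,
                              perm_criterion = has_perm,
                              sex_filter = NULL))
}

#' @export
print.deg_list <- function(x, ...) {
  ct <- attr(x, "contrast")
  pv <- attr(x, "provenance")
  cat(sprintf("DEG list%s: %d genes (%d up, %d down)\n",
              if (!is.null(ct)) sprintf(" [%s vs %s]", ct[1L], ct[2L]) else "",
              nrow(x), sum(x$direction == "up"), sum(x$direction == "down")))
  cat(sprintf("  thresholds: FC >= %g, padj < %g%s\n", pv$fold_change_min,
              pv$padj_max,
              if (isTRUE(pv$perm_criterion)) sprintf(", perm_p < %g", pv$perm_p_max)
              else " (no permutation criterion)"))
  if (!is.null(pv$sex_filter)) {
    cat(sprintf("  sex-bias filter removed %d gene(s)\n", pv$sex_filter$n_removed))
  }
  invisible(x)
}

#' Screen for sex-biased genes among NAT samples
#'
#' Runs the NB Wald engine with contrast male vs female restricted to NAT
#' samples (covariates age and LT; sex is the contrast) and returns the genes
#' with raw p below `sex_p_max` — a deliberately permissive raw-p screen used
#' to exclude sex artifacts from DEG lists.
#'
#' @param counts Filtered count matrix.
#' @param meta Metadata; its NAT samples must contain both sexes.
#' @param sex_p_max Raw-p threshold (default 0.05).
#' @param size_factors Optional size factors (default median-of-ratios on the
#'   full supplied matrix).
#' @return Data.frame of screened genes (`gene_id`, `log2fc` male-over-female,
#'   `pvalue`), with the full `de_result` in attribute `"de"`.
#' @export
find_sex_biased_genes <- function(counts, meta, sex_p_max = 0.05,
                                  size_factors = NULL) {
  nat <- meta[meta$tissue_group == "NAT", , drop = FALSE]
  if (length(unique(nat$sex)) < 2L) {
    stop("NAT samples must contain both sexes for the sex screen")
  }
  de <- run_de(counts[, nat$sample_id, drop = FALSE], nat,
               contrast = c("M", "F"), variable = "sex",
               covariates = c("age", "lt"), size_factors = size_factors)
  hit <- de$pvalue < sex_p_max & de$flag != "all_zero"
  out <- data.frame(gene_id = de$gene_id[hit], log2fc = de$log2fc[hit],
                    pvalue = de$pvalue[hit], stringsAsFactors = FALSE)
  attr(out, "de") <- de
  attr(out, "sex_p_max") <- sex_p_max
  out
}

#' Remove sex-biased genes from a DEG list
#'
#' Returns the DEG list minus its intersection with `sex_genes`; removed IDs
#' and their count are recorded in the provenance.
#'
#' @param degs A `deg_list`.
#' @param sex_genes Character vector of gene IDs (or the data.frame from
#'   [find_sex_biased_genes()]).
#' @return Filtered `deg_list`.
#' @export
apply_sex_filter <- function(degs, sex_genes) {
  if (is.data.frame(sex_genes)) sex_genes <- sex_genes$gene_id
  removed <- intersect(degs$gene_id, sex_genes)
  out <- degs[!(degs$gene_id %in% sex_genes), , drop = FALSE]
  rownames(out) <- NULL
  pv <- attr(degs, "provenance")
  pv$sex_filter <- list(n_removed = length(removed), removed = removed)
  structure(out, class = c("deg_list", "data.frame"),
            contrast = attr(degs, "contrast"), provenance = pv)
}

#' Write a DEG list (with provenance header) to TSV
#' @param degs A `deg_list`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_deg_list <- function(degs, path) {
  pv <- attr(degs, "provenance")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s=%s",
                     c("fold_change_min", "padj_max", "perm_p_max", "sex_filter_removed"),
                     c(pv$fold_change_min, pv$padj_max, pv$perm_p_max,
                       if (is.null(pv$sex_filter)) "none" else pv$sex_filter$n_removed)),
             con)
  utils::write.table(as.data.frame(degs), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
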