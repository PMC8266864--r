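#' Classify a single contrast arm as up / down / stable
#'
#' `up` iff p < 0.05 and log2fc >= `lfc_threshold` (inclusive); `down` iff
#' p < 0.05 and log2fc < -`lfc_threshold` (strict); otherwise `stable`.  The
#' default threshold is 0.584 exactly; set `lfc_threshold = log2(1.5)`
#' (0.58496...) for the exact 1.5-fold bound.
#'
#' @param log2fc Numeric log2 fold change(s).
#' @param p P-value(s) in (0, 1].
#' @param p_max Significance bound (default 0.05, strict).
#' @param lfc_threshold Fold-change bound on the log2 scale (default 0.584).
#' @return Character vector in `{"up", "down", "stable"}`.
#' @export
classify_arm <- function(log2fc, p, p_max = 0.05, lfc_threshold = 0.584) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) stop("p must lie in (0, 1]")
  out <- rep("stable", length(log2fc))
  out[p < p_max & log2fc >= lfc_threshold] <- "up"
  out[p < p_max & log2fc < -lfc_threshold] <- "down"
  out
}

#' Classify DEGs into the six N->NAT->T trajectory patterns
#'
#' Arm 1 (NAT vs N) is classified from each DEG's own statistics — so it is
#' up or down by construction — and arm 2 (T vs NAT) from the supplied second
#' contrast.  Each classified gene receives exactly one of the six patterns
#' (up-up, up-stable, up-down, down-down, down-stable, down-up).  DEGs absent
#' from the arm-2 results are excluded and reported, not called stable.
#'
#' @param degs A `deg_list` for the NAT-vs-N contrast (needs `gene_id`,
#'   `log2fc`, and the p column selected by `p_col`).
#' @param de_arm2 `de_result` (or data.frame) for T vs NAT.
#' @param p_col Which p-value classifies an arm: `"padj"` (default,
#'   consistent with DEG calling on adjusted p) or `"pvalue"` (`degs` must
#'   then carry raw p too).
#' @param p_max,lfc_threshold Passed to [classify_arm()].
#' @return A \code{trajectory_calls} data.frame (`gene_id`, `log2fc_arm1`,
#'   `p_arm1`, `log2fc_arm2`, `p_arm2`, `arm1`, `arm2`, `pattern`) with
#'   attributes `pattern_counts` (named vector over the six patterns) and
#'   `missing_genes`.
#' @export
classify_trajectories <- function(degs, de_arm2, p_col = c("padj", "pvalue"),
                                  p_max = 0.05, lfc_threshold = 0.584) {
  p_col <- match.arg(p_col)
  if (is.null(degs[[p_col]])) stop("degs lacks column '", p_col, "'")
  m <- match(degs$gene_id, de_arm2$gene_id)
  missing_genes <- degs$gene_id[is.na(m)]
  keep <- !is.na(m)
  g <- degs[keep, , drop = FALSE]
  a2 <- de_arm2[m[keep], , drop = FALSE]
  arm1 <- classify_arm(g$log2fc, g[[p_col]], p_max, lfc_threshold)
  arm2 <- classify_arm(a2$log2fc, a2[[p_col]], p_max, lfc_threshold)
  pattern <- paste(arm1, arm2, sep = "-")
  out <- data.frame(gene_id = g$gene_id,
                    log2fc_arm1 = g$log2fc, p_arm1 = g[[p_col]],
                    log2fc_arm2 = a2$log2fc, p_arm2 = a2[[p_col]],
                    arm1 = arm1, arm2 = arm2, pattern = pattern,
                    stringsAsFactors = FALSE, row.names = NULL)
  counts <- table(factor(pattern, levels = PATTERNS))
  structure(out, class = c("trajectory_calls", "data.frame"),
            pattern_counts = stats::setNames(as.integer(counts), PATTERNS),
            missing_genes = missing_genes,
            p_col = p_col, p_max = p_max, lfc_threshold = lfc_threshold)
}

#' @export
print.trajectory_calls <- function(x, ...) {
  pc <- attr(x, "pattern_counts")
  cat(sprintf("trajectory classification of %d genes (threshold |log2FC| %s %g, p < %g on %s)\n",
              nrow(x), "≥", attr(x, "lfc_threshold"), attr(x, "p_max"),
              attr(x, "p_col")))
  for (p in names(pc)) cat(sprintf("  %-12s %d\n", p, pc[[p]]))
  if (length(attr(x, "missing_genes"))) {
    cat(sprintf("  (%d gene(s) absent from the second arm were excluded)\n",
                length(attr(x, "missing_genes"))))
  }
  invisible(x)
}

#' Overlap (Venn) report for two or three DEG lists
#'
#' Exact region counts by set algebra on gene IDs.  For two lists, shared
#' genes are additionally split by whether their log2 fold changes agree or
#' oppose in sign (when both lists carry `log2fc`).
#'
#' @param lists Named list of two or three `deg_list`s / data.frames with a
#'   `gene_id` column (bare character vectors also accepted).
#' @return An \code{overlap_report} list: `labels`, `region_counts` (named by
#'   membership pattern, e.g. `"A&B"`), `union_size`, and for pairs
#'   `direction` (`n_shared`, `n_same`, `n_opposite`).
#' @export
overlap_report <- function(lists) {
  if (!length(names(lists)) || any(!nzchar(names(lists)))) {
    names(lists) <- LETTERS[seq_along(lists)]
  }
  if (length(lists) < 2L || length(lists) > 3L) stop("provide two or three lists")
  ids <- lapply(lists, function(x) if (is.data.frame(x)) x$gene_id else as.character(x))
  for (i in seq_along(ids)) {
    if (anyDuplicated(ids[[i]])) stop("duplicate gene IDs within list '", names(lists)[i], "'")
  }
  universe <- unique(unlist(ids))
  member <- vapply(ids, function(s) universe %in% s, logical(length(universe)))
  if (is.null(dim(member))) member <- matrix(member, nrow = 1L)
  key <- apply(member, 1L, function(r) paste(names(lists)[r], collapse = "&"))
  region_counts <- table(key)
  out <- list(labels = names(lists),
              region_counts = stats::setNames(as.integer(region_counts),
                                              names(region_counts)),
              union_size = length(universe))
  if (length(lists) == 2L) {
    a <- lists[[1L]]; b <- lists[[2L]]
    shared <- intersect(ids[[1L]], ids[[2L]])
    if (is.data.frame(a) && is.data.frame(b) &&
        !is.null(a$log2fc) && !is.null(b$log2fc)) {
      sa <- sign(a$log2fc[match(shared, a$gene_id)])
      sb <- sign(b$log2fc[match(shared, b$gene_id)])
      out$direction <- list(n_shared = length(shared),
                            n_same = sum(sa == sb), n_opposite = sum(sa != sb))
    } else {
      out$direction <- list(n_shared = length(shared), n_same = NA_integer_,
                            n_opposite = NA_integer_)
    }
  }
  class(out) <- "overlap_report"
  out
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("overlap of %s (union %d genes)\n",
              paste(x$labels, collapse = ", "), x$union_size))
  for (k in names(x$region_counts)) cat(sprintf("  %-10s %d\n", k, x$region_counts[[k]]))
  if (!is.null(x$direction) && !is.na(x$direction$n_same)) {
    cat(sprintf("  shared %d: %d same direction, %d opposite\n",
                x$direction$n_shared, x$direction$n_same, x$direction$n_opposite))
  }
  invisible(x)
}

#' Biotype composition of a DEG list
#'
#' Joins the list on the gene annotation and tabulates biotypes; genes absent
#' from the annotation are counted under `"unknown"`.  Percentages are
#' reported to one decimal with the list size as denominator; the
#' protein-coding subtotal is additionally split up/down (denominator: coding
#' subtotal).
#'
#' @param degs A `deg_list` (or data.frame with `gene_id` and, for the
#'   up/down split, `direction` or `log2fc`).
#' @param ann Annotation data.frame ([read_annotation()]).
#' @return A \code{biotype_report} list: `table` (biotype, n, pct sorted by
#'   n), `n_total`, `coding` (n, pct, n_up, n_down, pct_up, pct_down) and
#'   `n_noncoding`.
#' @export
biotype_composition <- function(degs, ann) {
  bt <- ann$biotype[match(degs$gene_id, ann$gene_id)]
  bt[is.na(bt)] <- "unknown"
  n_total <- nrow(degs)
  tab <- sort(table(bt), decreasing = TRUE)
  table_df <- data.frame(biotype = names(tab), n = as.integer(tab),
                         pct = round(100 * as.integer(tab) / n_total, 1L),
                         stringsAsFactors = FALSE, row.names = NULL)
  coding <- bt == "protein_coding"
  dir <- if (!is.null(degs$direction)) degs$direction else
    ifelse(degs$log2fc > 0, "up", "down")
  n_cod <- sum(coding)
  n_up <- sum(coding & dir == "up")
  out <- list(table = table_df, n_total = n_total,
              coding = list(n = n_cod,
                            pct = round(100 * n_cod / max(n_total, 1L), 1L),
                            n_up = n_up, n_down = n_cod - n_up,
                            pct_up = if (n_cod) round(100 * n_up / n_cod, 1L) else NA_real_,
                            pct_down = if (n_cod) round(100 * (n_cod - n_up) / n_cod, 1L) else NA_real_),
              n_noncoding = n_total - n_cod)
  class(out) <- "biotype_report"
  out
}

#' @export
print.biotype_report <- function(x, ...) {
  cat(sprintf("biotype composition of %d genes\n", x$n_total))
  cat(sprintf("  protein coding: %d (%.1f%%), %d up (%.1f%%) / %d down (%.1f%%)\n",
              x$coding$n, x$coding$pct, x$coding$n_up, x$coding$pct_up,
              x$coding$n_down, x$coding$pct_down))
  cat(sprintf("  noncoding/other: %d\n", x$n_noncoding))
  print.data.frame(x$table, row.names = FALSE)
  invisible(x)
}

#' Chromosome composition of a gene set
#'
#' Tabulates chromosomes with percentages to one decimal (denominator: set
#' size); genes without annotation fall under `"unknown"`.  Used e.g. to
#' summarize where sex-biased genes live (Y / X / autosomes).
#'
#' @param gene_ids Character vector of gene IDs (or data.frame with
#'   `gene_id`).
#' @param ann Annotation data.frame.
#' @return Data.frame (`chromosome`, `n`, `pct`) sorted by n.
#' @export
chromosome_composition <- function(gene_ids, ann) {
  if (is.data.frame(gene_ids)) gene_ids <- gene_ids$gene_id
  chr <- ann$chromosome[match(gene_ids, ann$gene_id)]
  chr[is.na(chr)] <- "unknown"
  tab <- sort(table(chr), decreasing = TRUE)
  data.frame(chromosome = names(tab), n = as.integer(tab),
             pct = round(100 * as.integer(tab) / length(gene_ids), 1L),
             stringsAsFactors = FALSE, row.names = NULL)
}
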