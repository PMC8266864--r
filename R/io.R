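#' @useDynLib natrajectory, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

TISSUE_GROUPS <- c("N", "NAT", "T")
SEX_LEVELS <- c("F", "M")
LT_LEVELS <- c("LT+", "LT-", NA_character_)

#' Read a gene x sample count matrix
#'
#' Reads a tab-delimited count file (first column gene IDs, header row of
#' sample IDs, integer cells) into a validated integer matrix with gene IDs as
#' row names and sample IDs as column names.  Row and column order is
#' preserved.  Ensembl gene IDs are treated as opaque strings; version
#' suffixes (e.g. \code{".18"}) are never stripped.
#'
#' @param path Path to a tab-delimited counts file.
#' @return Integer matrix (genes x samples) with dimnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("counts file needs a gene-id column plus >= 1 sample column")
  gene_ids <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-integer or negative count at gene '%s', sample '%s'",
                 gene_ids[bad[1L, 1L]], colnames(m)[bad[1L, 2L]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- gene_ids
  validate_count_matrix(m)
  m
}

#' Write a count matrix to TSV
#'
#' @param counts Integer matrix with gene row names and sample column names.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_count_matrix <- function(m) {
  if (anyDuplicated(rownames(m))) {
    stop("duplicate gene IDs: ", paste(unique(rownames(m)[duplicated(rownames(m))]),
                                       collapse = ", "))
  }
  if (anyDuplicated(colnames(m))) {
    stop("duplicate sample IDs: ", paste(unique(colnames(m)[duplicated(colnames(m))]),
                                         collapse = ", "))
  }
  if (any(m < 0)) stop("negative counts")
  invisible(m)
}

#' Read per-sample metadata
#'
#' Required columns: \code{sample_id}, \code{tissue_group} (N/NAT/T),
#' \code{sex} (F/M), \code{age} (years, may be missing), \code{lt_status}
#' (\code{LT+}/\code{LT-}/missing) and \code{patient_id} (pairing key, may be
#' missing for unpaired samples).
#'
#' @param path Path to a tab-delimited metadata file.
#' @return A data.frame with one row per sample.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("NA", ""), colClasses = "character")
  required <- c("sample_id", "tissue_group", "sex", "age", "lt_status", "patient_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("metadata is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  df$sample_id <- as.character(df$sample_id)
  df$patient_id <- as.character(df$patient_id)
  df$age <- as.numeric(df$age)
  validate_metadata(df)
  df
}

validate_metadata <- function(meta) {
  bad_grp <- setdiff(unique(meta$tissue_group), TISSUE_GROUPS)
  if (length(bad_grp)) {
    stop("unknown tissue_group '", bad_grp[1L], "'; allowed: ",
         paste(TISSUE_GROUPS, collapse = ", "))
  }
  bad_sex <- setdiff(stats::na.omit(unique(meta$sex)), SEX_LEVELS)
  if (length(bad_sex)) {
    stop("unknown sex '", bad_sex[1L], "'; allowed: ", paste(SEX_LEVELS, collapse = ", "))
  }
  bad_lt <- setdiff(stats::na.omit(unique(meta$lt_status)), c("LT+", "LT-"))
  if (length(bad_lt)) {
    stop("unknown lt_status '", bad_lt[1L], "'; allowed: LT+, LT-, NA")
  }
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (any(!is.na(meta$age) & meta$age < 0)) stop("negative age")
  # a tumor sample's patient may pair with at most one NAT sample
  nat_pat <- meta$patient_id[meta$tissue_group == "NAT" & !is.na(meta$patient_id)]
  if (anyDuplicated(nat_pat)) stop("patient_id maps to more than one NAT sample")
  invisible(meta)
}

#' Write sample metadata to TSV
#' @param meta Metadata data.frame as returned by [read_metadata()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a gene annotation table
#'
#' Columns: \code{gene_id}, \code{symbol}, \code{biotype}, \code{chromosome}.
#' Genes absent from the annotation are later reported under biotype
#' \code{"unknown"} by [biotype_composition()].
#'
#' @param path Path to a tab-delimited annotation file.
#' @return A data.frame keyed by unique \code{gene_id}.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("gene_id", "symbol", "biotype", "chromosome")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("annotation is missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  }
  if (nrow(df) && any(!nzchar(df$biotype))) stop("empty biotype in annotation")
  df
}

#' Write a gene annotation table to TSV
#' @param ann Annotation data.frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Cross-check counts, metadata and annotation
#'
#' Report-only consistency check: samples present in the counts but absent
#' from the metadata (and vice versa), genes without annotation, and pairing
#' integrity for tumor samples (every T sample's \code{patient_id} should
#' match exactly one NAT sample).  Never modifies its inputs.
#'
#' @param counts Count matrix.
#' @param meta Metadata data.frame.
#' @param ann Optional annotation data.frame.
#' @return An object of class \code{"validation_report"}: a data.frame of
#'   issues (\code{severity}, \code{issue}, \code{id}) with attribute
#'   \code{"pass"} (TRUE iff no blocking issue).
#' @export
validate_dataset <- function(counts, meta, ann = NULL) {
  issues <- data.frame(severity = character(), issue = character(),
                       id = character(), stringsAsFactors = FALSE)
  add <- function(severity, issue, ids) {
    if (length(ids)) {
      issues <<- rbind(issues, data.frame(severity = severity, issue = issue,
                                          id = as.character(ids),
                                          stringsAsFactors = FALSE))
    }
  }
  add("error", "sample without metadata", setdiff(colnames(counts), meta$sample_id))
  add("warning", "metadata sample absent from counts",
      setdiff(meta$sample_id, colnames(counts)))
  if (!is.null(ann)) {
    add("warning", "gene without annotation", setdiff(rownames(counts), ann$gene_id))
  }
  t_rows <- meta[meta$tissue_group == "T", , drop = FALSE]
  nat_pat <- meta$patient_id[meta$tissue_group == "NAT" & !is.na(meta$patient_id)]
  unpaired <- t_rows$sample_id[is.na(t_rows$patient_id) |
                                 !(t_rows$patient_id %in% nat_pat)]
  add("warning", "T sample without a matching NAT sample (pairing)", unpaired)
  structure(issues, class = c("validation_report", "data.frame"),
            pass = !any(issues$severity == "error"))
}

#' @export
print.validation_report <- function(x, ...) {
  if (nrow(x) == 0L) {
    cat("dataset validation: OK (no issues)\n")
  } else {
    cat("dataset validation:", if (attr(x, "pass")) "PASS with warnings" else "FAIL",
        sprintf("(%d issue%s)\n", nrow(x), if (nrow(x) == 1L) "" else "s"))
    print.data.frame(x, row.names = FALSE)
  }
  invisible(x)
}

#' Subset a count or normalized-expression matrix
#'
#' Slices genes and/or samples keeping the requested order; all parallel
#' fields of a normalized-expression object (size factors, normalized and log
#' matrices) are sliced consistently.
#'
#' @param x A count matrix or a \code{norm_expr} object.
#' @param genes,samples Character vectors of IDs to keep (NULL = keep all).
#'   Unknown IDs raise an error naming the first offender.
#' @return Same type as `x`.
#' @export
subset_expr <- function(x, genes = NULL, samples = NULL) {
  UseMethod("subset_expr")
}

check_ids <- function(requested, available, what) {
  missing <- setdiff(requested, available)
  if (length(missing)) stop("unknown ", what, ": '", missing[1L], "'")
  requested
}

#' @export
subset_expr.default <- function(x, genes = NULL, samples = NULL) {
  if (!is.null(genes)) {
    x <- x[check_ids(genes, rownames(x), "gene ID"), , drop = FALSE]
  }
  if (!is.null(samples)) {
    x <- x[, check_ids(samples, colnames(x), "sample ID"), drop = FALSE]
  }
  x
}

#' @export
subset_expr.norm_expr <- function(x, genes = NULL, samples = NULL) {
  g <- if (is.null(genes)) rownames(x$normalized) else
    check_ids(genes, rownames(x$normalized), "gene ID")
  s <- if (is.null(samples)) colnames(x$normalized) else
    check_ids(samples, colnames(x$normalized), "sample ID")
  x$counts <- x$counts[g, s, drop = FALSE]
  x$normalized <- x$normalized[g, s, drop = FALSE]
  x$log2 <- x$log2[g, s, drop = FALSE]
  x$size_factors <- x$size_factors[s]
  x
}
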