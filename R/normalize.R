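#' Remove low-expression genes
#'
#' A gene is removed iff (a) the fraction of samples with a zero count exceeds
#' `zero_fraction_threshold` in every tissue group present (`zero_rule =
#' "all"`; with `"any"`, in at least one group), OR (b) its mean raw count
#' across all samples is strictly below `min_mean`.  Surviving genes keep
#' their original order.
#'
#' @param counts Count matrix (genes x samples).
#' @param meta Metadata data.frame with `sample_id` and `tissue_group` for
#'   every sample in `counts`.
#' @param zero_fraction_threshold Zero-fraction cut-off per group (default 0.25).
#' @param min_mean Minimum mean raw count over all samples (default 10;
#'   strict: a mean of exactly 10 is kept).
#' @param zero_rule `"all"` (every group exceeds the threshold) or `"any"`.
#' @return List with `counts` (filtered matrix) and `removed` (data.frame of
#'   `gene_id` and triggering `rule`).
#' @export
filter_low_expression <- function(counts, meta, zero_fraction_threshold = 0.25,
                                  min_mean = 10, zero_rule = c("all", "any")) {
  zero_rule <- match.arg(zero_rule)
  grp <- meta$tissue_group[match(colnames(counts), meta$sample_id)]
  if (anyNA(grp)) stop("every sample in counts needs a tissue_group in meta")
  groups <- unique(grp)
  if (any(tabulate(factor(grp, groups)) == 0L)) stop("empty tissue group")
  zfrac <- sapply(groups, function(g) {
    rowMeans(counts[, grp == g, drop = FALSE] == 0)
  })
  if (is.null(dim(zfrac))) zfrac <- matrix(zfrac, ncol = length(groups))
  exceeded <- zfrac > zero_fraction_threshold
  zero_hit <- if (zero_rule == "all") apply(exceeded, 1L, all) else apply(exceeded, 1L, any)
  mean_hit <- rowMeans(counts) < min_mean
  removed <- zero_hit | mean_hit
  rule <- ifelse(zero_hit & mean_hit, "zero_fraction+low_mean",
                 ifelse(zero_hit, "zero_fraction", "low_mean"))
  list(counts = counts[!removed, , drop = FALSE],
       removed = data.frame(gene_id = rownames(counts)[removed],
                            rule = rule[removed], stringsAsFactors = FALSE))
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over reference genes of the
#' ratio of the gene's count in that sample to the gene's geometric mean
#' across samples.  Reference genes are those with a strictly positive count
#' in every sample (geometric mean > 0).
#'
#' @param counts Count matrix (genes x samples).
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
compute_size_factors <- function(counts) {
  logc <- log(counts)
  log_geomean <- rowMeans(logc)
  ref <- is.finite(log_geomean)
  if (!any(ref)) {
    stop("no reference genes (every gene has a zero count in some sample); ",
         "relax filtering before normalizing")
  }
  sf <- apply(logc[ref, , drop = FALSE], 2L, function(x) {
    exp(stats::median(x - log_geomean[ref]))
  })
  stats::setNames(sf, colnames(counts))
}

#' Normalize counts by size factors
#'
#' Divides each sample's counts by its size factor and forms
#' \code{log2(normalized + 1)}.
#'
#' @param counts Count matrix.
#' @param size_factors Positive numeric vector, one per sample (defaults to
#'   [compute_size_factors()] on `counts`).
#' @return An object of class \code{"norm_expr"}: list with `counts`,
#'   `size_factors`, `normalized` and `log2` matrices.
#' @export
normalize_counts <- function(counts, size_factors = compute_size_factors(counts)) {
  if (length(size_factors) != ncol(counts)) {
    stop("size_factors length must match the number of samples")
  }
  if (any(!is.finite(size_factors) | size_factors <= 0)) {
    stop("size factors must be positive")
  }
  if (!is.null(names(size_factors)) && !is.null(colnames(counts))) {
    size_factors <- size_factors[colnames(counts)]
  }
  normalized <- sweep(counts, 2L, size_factors, "/")
  structure(list(counts = counts, size_factors = size_factors,
                 normalized = normalized, log2 = log2(normalized + 1)),
            class = "norm_expr")
}

#' @export
print.norm_expr <- function(x, ...) {
  cat(sprintf("normalized expression: %d genes x %d samples\n",
              nrow(x$normalized), ncol(x$normalized)))
  cat(sprintf("size factors: %.3f .. %.3f (median %.3f)\n",
              min(x$size_factors), max(x$size_factors),
              stats::median(x$size_factors)))
  invisible(x)
}
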