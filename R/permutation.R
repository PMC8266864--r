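#' Permute contrast labels
#'
#' Randomly permutes the contrast-variable labels among the contrast samples;
#' covariates stay attached to their samples.  For paired designs the two
#' labels within each pair are independently swapped with probability 1/2, so
#' group sizes and the one-of-each-per-pair structure are preserved.
#'
#' @param meta Metadata data.frame.
#' @param contrast Character pair `c(test, reference)`.
#' @param variable Metadata column carrying the labels.
#' @param paired Use the within-pair swap scheme.
#' @param seed Integer seed; the same seed gives the identical permutation.
#' @return `meta` with permuted labels.
#' @export
permute_labels <- function(meta, contrast, variable = "tissue_group",
                           paired = FALSE, seed = 1L) {
  set.seed(seed)
  idx <- which(meta[[variable]] %in% contrast)
  if (paired) {
    pats <- unique(meta$patient_id[idx])
    swap <- stats::runif(length(pats)) < 0.5
    names(swap) <- pats
    lab <- meta[[variable]][idx]
    other <- stats::setNames(rev(contrast), contrast)
    do_swap <- swap[meta$patient_id[idx]]
    lab[do_swap] <- other[lab[do_swap]]
    meta[[variable]][idx] <- lab
  } else {
    meta[[variable]][idx] <- sample(meta[[variable]][idx])
  }
  meta
}

#' Permutation p-values for a Wald contrast
#'
#' Re-runs the Wald pipeline under `n_permutations` random relabelings of the
#' contrast samples (dispersions and size factors frozen at their
#' observed-data estimates unless `refit_dispersions = TRUE`) and attaches an
#' empirical p-value per gene with the add-one convention
#' \eqn{p = (1 + \#\{b: |T_b| \ge |T_{obs}|\}) / (B + 1)}, so p is never 0.
#' With `scope = "pooled"` the null set is all genes x all permutations.
#' Permutation b is generated from seed `seed + b`, so any single permutation
#' is reproducible in isolation.
#'
#' @param counts Count matrix used for the observed fit.
#' @param meta Metadata data.frame.
#' @param de A `de_result` from [run_de()] on the same counts/meta.
#' @param n_permutations Number of permutations B (default 1000).
#' @param scope `"per_gene"` (default) or `"pooled"`.
#' @param seed Root integer seed.
#' @param refit_dispersions Re-estimate dispersions within each permutation.
#' @return `de` with a `perm_p` column appended (and permutation settings
#'   recorded in attributes).
#' @export
permutation_pvalues <- function(counts, meta, de, n_permutations = 1000L,
                                scope = c("per_gene", "pooled"), seed = 1L,
                                refit_dispersions = FALSE) {
  scope <- match.arg(scope)
  if (n_permutations < 1L) stop("n_permutations must be >= 1")
  contrast <- attr(de, "contrast")
  variable <- attr(de, "variable")
  paired <- attr(de, "paired")
  covariates <- attr(de, "covariates")
  sub_meta <- meta[match(names(attr(de, "size_factors")), meta$sample_id), ,
                   drop = FALSE]
  sf <- attr(de, "size_factors")
  disp <- attr(de, "dispersions")
  Y <- counts[de$gene_id, sub_meta$sample_id, drop = FALSE]
  t_obs <- abs(de$wald_stat)
  tol <- 1e-8  # |T_b| >= |T_obs| up to numerical noise in the IRLS solutions

  exceed <- numeric(nrow(de))
  pooled <- if (scope == "pooled") vector("list", n_permutations) else NULL
  for (b in seq_len(n_permutations)) {
    pm <- permute_labels(sub_meta, contrast, variable, paired, seed = seed + b)
    d <- suppressWarnings(build_design(pm, contrast, variable, covariates, paired))
    ord <- match(d$meta$sample_id, colnames(Y))
    db <- if (refit_dispersions) {
      estimate_dispersions(Y[, ord, drop = FALSE], sf[ord])
    } else disp
    tb <- nb_glm_wald_cpp(Y[, ord, drop = FALSE], d$X, log(sf[ord]), db,
                          d$contrast_col - 1L)
    tb[!is.finite(tb)] <- 0
    if (scope == "per_gene") {
      exceed <- exceed + (abs(tb) >= t_obs - tol)
    } else {
      pooled[[b]] <- abs(tb)
    }
  }
  perm_p <- if (scope == "per_gene") {
    (1 + exceed) / (n_permutations + 1)
  } else {
    null_set <- sort(unlist(pooled))
    m <- length(null_set)
    # count of null values >= each observed |T|
    (1 + (m - findInterval(t_obs - tol, null_set, left.open = TRUE))) / (m + 1)
  }
  de$perm_p <- perm_p
  attr(de, "permutation") <- list(n_permutations = n_permutations, scope = scope,
                                  seed = seed, refit_dispersions = refit_dispersions)
  de
}
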