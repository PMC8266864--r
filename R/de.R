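#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment: p-values sorted ascending are
#' multiplied by m/rank, monotonicity is enforced from the largest rank down,
#' values are capped at 1 and returned in the input order.
#'
#' @param pvalues Numeric vector with all values in (0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues <= 0 | pvalues > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Method-of-moments NB dispersion estimates with trend shrinkage
#'
#' Per-gene raw dispersion \eqn{\hat\alpha = (s^2 - \bar\xi \bar\mu)/\bar\mu^2}
#' from normalized counts (with \eqn{\bar\xi} the mean reciprocal size factor
#' correcting the Poisson term), floored at `floor`; a mean-dispersion trend
#' is fitted by robust log-log regression of the raw estimates on the mean,
#' and each gene's estimate is shrunk toward the trend on the log scale with
#' weight `shrink`.
#'
#' @param counts Count matrix (genes x samples).
#' @param size_factors Per-sample size factors (default: median-of-ratios on
#'   `counts`).
#' @param shrink Shrinkage weight toward the trend in `[0, 1]` (0 = raw
#'   method-of-moments, 1 = pure trend; default 0.5).
#' @param floor Lower bound for dispersions (default 1e-8, the Poisson limit).
#' @return Named numeric vector of per-gene dispersions (>= floor).
#' @export
estimate_dispersions <- function(counts, size_factors = compute_size_factors(counts),
                                 shrink = 0.5, floor = 1e-8) {
  if (shrink < 0 || shrink > 1) stop("shrink must be in [0, 1]")
  norm <- sweep(counts, 2L, size_factors, "/")
  n <- ncol(norm)
  if (n < 2L) stop("need >= 2 samples to estimate dispersions")
  mu <- rowMeans(norm)
  v <- rowSums((norm - mu)^2) / (n - 1L)
  xi <- mean(1 / size_factors)
  raw <- (v - xi * mu) / mu^2
  out <- shrink_to_trend(raw, mu, shrink, floor)
  stats::setNames(out, rownames(counts))
}

# shrink raw per-gene dispersions toward a robust log-log mean-dispersion
# trend; genes at the floor (Poisson limit) stay there
shrink_to_trend <- function(raw, mu, shrink, floor = 1e-8) {
  raw[!is.finite(raw) | raw < floor] <- floor
  use <- raw > floor & mu > 1
  trend <- rep(stats::median(raw), length(raw))
  if (sum(use) >= 20L) {
    fit <- tryCatch(
      suppressWarnings(MASS::rlm(log(raw[use]) ~ log(mu[use]), maxit = 50)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      co <- stats::coef(fit)
      trend <- exp(co[1L] + co[2L] * log(pmax(mu, 1e-8)))
      # recenter: log-scale robust fits of noisy dispersion estimates sit
      # below the mean (Jensen), so rescale until the winsorized mean ratio
      # of raw to trend is 1 (mean-unbiased, robust to outliers)
      ratio <- pmin(pmax((raw / trend)[use], 0.1), 10)
      adj <- mean(ratio)
      if (is.finite(adj) && adj > 0) trend <- trend * adj
    }
  }
  trend <- pmin(pmax(trend, floor), 10)
  out <- exp((1 - shrink) * log(raw) + shrink * log(trend))
  out[raw <= floor] <- floor
  pmax(out, floor)
}

#' Fit a negative-binomial GLM for one gene
#'
#' Maximizes the NB log-likelihood (log link, known dispersion, log
#' size-factor offset) by iteratively reweighted least squares; convergence
#' when the largest coefficient change is below `tol` (default 1e-8) within
#' `maxit` iterations.  Coefficients are on the natural-log scale.
#'
#' @param y Integer count vector for one gene.
#' @param design Design matrix (samples x p), full rank.
#' @param size_factors Per-sample size factors.
#' @param dispersion NB dispersion alpha (variance = mu + alpha mu^2).
#' @param maxit,tol IRLS controls.
#' @return List with `coefficients`, `se` (asymptotic, natural-log scale) and
#'   `status` (0 converged, 1 iteration cap, 2 degenerate all-zero gene).
#' @export
fit_nb_glm <- function(y, design, size_factors, dispersion, maxit = 100, tol = 1e-8) {
  design <- as.matrix(design)
  if (qr(design)$rank < ncol(design)) {
    stop("design matrix is rank deficient; drop aliased columns first")
  }
  fit <- nb_glm_fit_cpp(matrix(as.numeric(y), nrow = 1L), design,
                        log(size_factors), dispersion, maxit, tol)
  list(coefficients = stats::setNames(drop(fit$beta), colnames(design)),
       se = stats::setNames(drop(fit$se), colnames(design)),
       status = fit$status[1L])
}

# Build the design matrix for a two-level contrast on `variable`, with
# optional covariate adjustment and patient blocking.  Returns the design,
# the index of the contrast column, the metadata rows used (contrast samples,
# test level last in orientation), and names of dropped (aliased) columns.
build_design <- function(meta, contrast, variable = "tissue_group",
                         covariates = c("age", "sex", "lt"), paired = FALSE) {
  if (length(contrast) != 2L) stop("contrast must name two groups: c(test, reference)")
  vals <- meta[[variable]]
  if (is.null(vals)) stop("unknown contrast variable '", variable, "'")
  keep <- vals %in% contrast
  sub <- meta[keep, , drop = FALSE]
  n_per <- table(factor(sub[[variable]], levels = contrast))
  if (any(n_per == 0L)) stop("empty contrast group: ", contrast[which(n_per == 0L)[1L]])
  if (any(n_per < 2L)) stop("need >= 2 samples per contrast group")

  cols <- list("(Intercept)" = rep(1, nrow(sub)))
  if (paired) {
    if (all(is.na(sub$patient_id))) stop("paired design requires patient_id")
    # restrict to patients contributing exactly one sample to each arm
    arm <- sub[[variable]] == contrast[1L]
    complete <- intersect(sub$patient_id[arm], sub$patient_id[!arm])
    complete <- complete[!is.na(complete)]
    one_each <- vapply(complete, function(p) {
      sum(sub$patient_id == p & arm, na.rm = TRUE) == 1L &&
        sum(sub$patient_id == p & !arm, na.rm = TRUE) == 1L
    }, logical(1L))
    complete <- complete[one_each]
    if (length(complete) < 2L) stop("paired design needs >= 2 complete pairs")
    dropped_n <- sum(!(sub$patient_id %in% complete))
    if (dropped_n > 0L) {
      message(dropped_n, " unpaired sample(s) excluded from the paired contrast")
    }
    sub <- sub[sub$patient_id %in% complete, , drop = FALSE]
    cols[["(Intercept)"]] <- rep(1, nrow(sub))
    pat <- factor(sub$patient_id)
    for (lv in levels(pat)[-1L]) cols[[paste0("patient_", lv)]] <- as.numeric(pat == lv)
  }
  if ("age" %in% covariates && "age" != variable) {
    age <- sub$age
    if (anyNA(age)) {
      warning(sum(is.na(age)), " missing age value(s) mean-imputed")
      age[is.na(age)] <- mean(age, na.rm = TRUE)
    }
    s <- stats::sd(age)
    cols[["age"]] <- if (is.na(s) || s == 0) NULL else (age - mean(age)) / s
  }
  if ("sex" %in% covariates && variable != "sex") {
    cols[["sexM"]] <- as.numeric(sub$sex == "M")
  }
  if (any(c("lt", "lt_status") %in% covariates) && variable != "lt_status") {
    lt <- sub$lt_status
    lt[is.na(lt)] <- "LT-"  # unknown LT treated as LT-negative
    cols[["ltPos"]] <- as.numeric(lt == "LT+")
  }
  cols[[paste0(variable, "_", contrast[1L])]] <- as.numeric(sub[[variable]] == contrast[1L])
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)[!vapply(cols, is.null, logical(1L))]

  contrast_col <- ncol(X)
  qx <- qr(X)
  dropped <- character(0)
  if (qx$rank < ncol(X)) {
    keep_cols <- sort(qx$pivot[seq_len(qx$rank)])
    if (!(contrast_col %in% keep_cols)) {
      stop("contrast column is aliased with other design columns")
    }
    dropped <- colnames(X)[setdiff(seq_len(ncol(X)), keep_cols)]
    warning("dropping aliased design column(s): ", paste(dropped, collapse = ", "))
    X <- X[, keep_cols, drop = FALSE]
    contrast_col <- ncol(X)
  }
  list(X = X, contrast_col = contrast_col, meta = sub, dropped = dropped)
}

#' Per-gene differential expression by NB Wald test
#'
#' The central fitting function.  For each gene a negative-binomial
#' log-linear model with log size-factor offset is fitted over the samples of
#' a two-group contrast, adjusting for the requested covariates (age centered
#' and scaled, sex and LT status as 0/1 indicators; missing age is
#' mean-imputed with a warning) or, for paired designs, blocking on patient
#' via fixed per-patient indicators.  The Wald statistic is the contrast
#' coefficient over its asymptotic standard error (natural-log scale),
#' referred to the standard normal; p-values are BH-adjusted across all
#' tested genes.  Genes with all-zero counts are flagged and assigned
#' log2fc = 0, p = 1; non-converged fits are flagged \code{"unreliable"}.
#'
#' When `dispersions` is not supplied, per-gene dispersions are estimated
#' under the full design by maximizing the Cox-Reid adjusted profile
#' likelihood (so variance explained by covariates or patient blocks is not
#' counted as biological dispersion) and then shrunk toward a robust
#' mean-dispersion trend with weight `shrink`.
#'
#' @param counts Filtered count matrix covering at least the contrast samples.
#' @param meta Metadata data.frame (see [read_metadata()]).
#' @param contrast Character pair `c(test, reference)`; log2fc is
#'   test-over-reference.
#' @param variable Metadata column the contrast is on (default
#'   `"tissue_group"`; use `"sex"` for the sex screen).
#' @param covariates Any of `"age"`, `"sex"`, `"lt"`; the contrast variable
#'   itself is ignored if listed.
#' @param paired If TRUE, add per-patient indicator columns (both arms
#'   required for every patient).
#' @param size_factors Per-sample size factors; default computes
#'   median-of-ratios once on the full supplied matrix before subsetting to
#'   the contrast samples.
#' @param dispersions Per-gene dispersions; default [estimate_dispersions()]
#'   on the contrast samples.
#' @param shrink Dispersion shrinkage weight passed to
#'   [estimate_dispersions()].
#' @return A \code{de_result}: data.frame with columns \code{gene_id},
#'   \code{base_mean}, \code{log2fc}, \code{se} (natural-log scale),
#'   \code{wald_stat}, \code{pvalue}, \code{padj}, \code{flag}; contrast and
#'   design details in attributes.
#' @seealso [permutation_pvalues()], [call_degs()], [summary.de_result()]
#' @export
run_de <- function(counts, meta, contrast = c("NAT", "N"),
                   variable = "tissue_group",
                   covariates = c("age", "sex", "lt"), paired = FALSE,
                   size_factors = NULL, dispersions = NULL, shrink = 0.5) {
  meta <- meta[match(intersect(colnames(counts), meta$sample_id), meta$sample_id), ,
               drop = FALSE]
  if (is.null(size_factors)) size_factors <- compute_size_factors(counts)
  d <- build_design(meta, contrast, variable, covariates, paired)
  sub_counts <- counts[, d$meta$sample_id, drop = FALSE]
  sf <- size_factors[d$meta$sample_id]
  if (is.null(dispersions)) {
    # design-aware dispersion: per-gene Cox-Reid adjusted profile likelihood
    # (so variance explained by covariates or patient blocks is not mistaken
    # for biological dispersion), then shrinkage toward the mean-dispersion
    # trend
    grid <- exp(seq(log(1e-6), log(10), length.out = 19L))
    raw <- nb_cr_dispersion_cpp(sub_counts, d$X, log(sf), grid)
    dispersions <- stats::setNames(
      shrink_to_trend(raw, rowMeans(sweep(sub_counts, 2L, sf, "/")), shrink),
      rownames(sub_counts))
  } else {
    dispersions <- dispersions[rownames(sub_counts)]
  }
  fit <- nb_glm_fit_cpp(sub_counts, d$X, log(sf), dispersions)
  cc <- d$contrast_col
  beta <- fit$beta[, cc]
  se <- fit$se[, cc]
  status <- fit$status
  wald <- ifelse(status == 2L | !is.finite(se) | se <= 0, 0, beta / se)
  log2fc <- ifelse(status == 2L, 0, beta / log(2))
  pvalue <- 2 * stats::pnorm(-abs(wald))
  pvalue[status == 2L | !is.finite(se) | se <= 0] <- 1
  pvalue <- pmin(pmax(pvalue, .Machine$double.xmin), 1)
  flag <- c("ok", "unreliable", "all_zero")[status + 1L]
  flag[status != 2L & (!is.finite(se) | se <= 0)] <- "unreliable"
  res <- data.frame(gene_id = rownames(sub_counts),
                    base_mean = rowMeans(sweep(sub_counts, 2L, sf, "/")),
                    log2fc = log2fc, se = se, wald_stat = wald,
                    pvalue = pvalue, padj = bh_adjust(pvalue), flag = flag,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(res, class = c("de_result", "data.frame"),
            contrast = contrast, variable = variable,
            covariates = setdiff(covariates, variable), paired = paired,
            dropped = d$dropped,
            dispersions = dispersions, size_factors = sf, design = d$X,
            contrast_col = cc)
}

#' @export
print.de_result <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat(sprintf("NB Wald differential expression: %s vs %s%s\n", ct[1L], ct[2L],
              if (isTRUE(attr(x, "paired"))) " (paired)" else ""))
  cat(sprintf("  %d genes, %d samples; covariates: %s\n", nrow(x),
              nrow(attr(x, "design")),
              if (length(attr(x, "covariates"))) paste(attr(x, "covariates"), collapse = ", ")
              else "none"))
  cat(sprintf("  padj < 0.05: %d genes%s\n", sum(x$padj < 0.05),
              if (!is.null(x$perm_p)) sprintf("; perm_p < 0.05: %d", sum(x$perm_p < 0.05))
              else ""))
  invisible(x)
}

#' Summarize a differential-expression result
#' @param object A `de_result`.
#' @param fc Fold-change threshold used for the up/down tally (default 1.5).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param ... Unused.
#' @export
summary.de_result <- function(object, fc = 1.5, alpha = 0.05, ...) {
  lfc <- log2(fc)
  up <- sum(object$padj < alpha & object$log2fc >= lfc)
  down <- sum(object$padj < alpha & object$log2fc <= -lfc)
  out <- list(contrast = attr(object, "contrast"), n_genes = nrow(object),
              n_sig = sum(object$padj < alpha), n_up = up, n_down = down,
              n_flagged = sum(object$flag != "ok"), fc = fc, alpha = alpha)
  class(out) <- "summary.de_result"
  out
}

#' @export
print.summary.de_result <- function(x, ...) {
  cat(sprintf("%s vs %s: %d genes tested\n", x$contrast[1L], x$contrast[2L], x$n_genes))
  cat(sprintf("  padj < %g: %d;  with |FC| >= %g: %d up, %d down\n",
              x$alpha, x$n_sig, x$fc, x$n_up, x$n_down))
  cat(sprintf("  flagged fits: %d\n", x$n_flagged))
  invisible(x)
}

#' @export
coef.de_result <- function(object, ...) {
  stats::setNames(object$log2fc, object$gene_id)
}

#' MA plot of a differential-expression result
#' @param x A `de_result`.
#' @param alpha Adjusted-p threshold for highlighting (default 0.05).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.de_result <- function(x, alpha = 0.05, ...) {
  sig <- x$padj < alpha
  graphics::plot(log10(x$base_mean + 1), x$log2fc,
                 col = ifelse(sig, "red3", "grey50"), pch = 20, cex = 0.5,
                 xlab = "log10 mean normalized count", ylab = "log2 fold change",
                 ...)
  graphics::abline(h = 0, col = "grey30")
  invisible(x)
}
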