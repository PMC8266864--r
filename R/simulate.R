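PATTERNS <- c("up-up", "up-stable", "up-down", "down-down", "down-stable", "down-up")

# per-arm signs implied by each trajectory pattern (arm1 = NAT vs N, arm2 = T vs NAT)
PATTERN_SIGNS <- list(
  "up-up"       = c(1, 1),
  "up-stable"   = c(1, 0),
  "up-down"     = c(1, -1),
  "down-down"   = c(-1, -1),
  "down-stable" = c(-1, 0),
  "down-up"     = c(-1, 1)
)

#' Simulation configuration for three-group NB count data
#'
#' Builds a validated configuration for [simulate_dataset()].  Defaults
#' emulate the motivating study design: 12 normal (N), 46 tumor-adjacent (NAT,
#' 37 female / 9 male, 21 of 46 with lymphocytic thyroiditis) and 16 tumor (T)
#' samples paired to a NAT subset.  Baseline means are log-normal and
#' dispersions gamma-distributed, chosen so roughly a quarter of genes fall
#' under the default low-expression filter.
#'
#' @param n_genes Number of genes.
#' @param n_N,n_NAT,n_T Sample counts per tissue group; T samples are paired
#'   with the first `n_T` NAT samples (same patient).
#' @param frac_LT_pos Fraction of NAT samples labeled LT+.
#' @param frac_female_NAT,frac_female_N Female fraction in NAT and N.
#' @param pattern_counts Named integer vector over the six trajectory patterns
#'   (`up-up`, `up-stable`, `up-down`, `down-down`, `down-stable`, `down-up`)
#'   giving the number of genes planted with each pattern (default: 1.25% of
#'   `n_genes` per pattern, i.e. 25 each at the 2000-gene default).
#' @param effect_log2fc Magnitude of the planted |log2 fold change| per
#'   affected arm.
#' @param n_sex_genes Number of planted sex-biased genes (default 1.5% of
#'   `n_genes`), split as evenly as possible across Y-like (near-zero in
#'   females), X-like and autosomal.
#' @param sex_log2fc Magnitude of the male-vs-female |log2FC| for X-like and
#'   autosomal sex genes (Y-like genes are depleted ~50-fold in females).
#' @param lt_effect_genes,lt_log2fc Number (default 2.5% of `n_genes`) and
#'   |log2FC| of genes responding to LT+ status.
#' @param dispersion_shape,dispersion_scale Gamma parameters of the per-gene
#'   NB dispersion (variance = mu + alpha * mu^2).
#' @param mean_log_mu,sd_log_mu Log-normal parameters of baseline gene means.
#' @param size_factor_sd Log-scale SD of per-sample sequencing depth.
#' @param patient_sd Log-scale SD of the gene-level patient expression
#'   profile shared by both members of a T/NAT pair (rescaled per patient to
#'   leave expected library size unchanged).
#' @param age_mean,age_sd Age distribution (years).
#' @param seed Integer seed; one root generator governs all draws.
#' @return A list of class \code{"sim_config"}.
#' @export
sim_config <- function(n_genes = 2000L,
                       n_N = 12L, n_NAT = 46L, n_T = 16L,
                       frac_LT_pos = 21 / 46,
                       frac_female_NAT = 37 / 46,
                       frac_female_N = 0.75,
                       pattern_counts = NULL,
                       effect_log2fc = 2,
                       n_sex_genes = NULL,
                       sex_log2fc = 1.5,
                       lt_effect_genes = NULL,
                       lt_log2fc = 1.5,
                       dispersion_shape = 2,
                       dispersion_scale = 0.05,
                       mean_log_mu = log(22),
                       sd_log_mu = 1.2,
                       size_factor_sd = 0.3,
                       patient_sd = 0.4,
                       age_mean = 48,
                       age_sd = 12,
                       seed = 1L) {
  # planted-gene defaults scale with n_genes (1.25% per pattern, 1.5% sex,
  # 2.5% LT): 25 / 30 / 50 genes at the 2000-gene default
  if (is.null(pattern_counts)) {
    pattern_counts <- stats::setNames(rep(round(0.0125 * n_genes), 6L), PATTERNS)
  }
  if (is.null(n_sex_genes)) n_sex_genes <- round(0.015 * n_genes)
  if (is.null(lt_effect_genes)) lt_effect_genes <- round(0.025 * n_genes)
  pc <- stats::setNames(rep(0L, length(PATTERNS)), PATTERNS)
  if (length(pattern_counts)) {
    bad <- setdiff(names(pattern_counts), PATTERNS)
    if (length(bad)) stop("unknown pattern name(s): ", paste(bad, collapse = ", "))
    pc[names(pattern_counts)] <- as.integer(pattern_counts)
  }
  cfg <- list(n_genes = as.integer(n_genes), n_N = as.integer(n_N),
              n_NAT = as.integer(n_NAT), n_T = as.integer(n_T),
              frac_LT_pos = frac_LT_pos, frac_female_NAT = frac_female_NAT,
              frac_female_N = frac_female_N, pattern_counts = pc,
              effect_log2fc = effect_log2fc, n_sex_genes = as.integer(n_sex_genes),
              sex_log2fc = sex_log2fc, lt_effect_genes = as.integer(lt_effect_genes),
              lt_log2fc = lt_log2fc, dispersion_shape = dispersion_shape,
              dispersion_scale = dispersion_scale, mean_log_mu = mean_log_mu,
              sd_log_mu = sd_log_mu, size_factor_sd = size_factor_sd,
              patient_sd = patient_sd, age_mean = age_mean, age_sd = age_sd,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_genes < 1L) stop("n_genes must be >= 1")
  if (any(cfg$pattern_counts < 0L) || cfg$n_sex_genes < 0L || cfg$lt_effect_genes < 0L) {
    stop("gene counts must be >= 0")
  }
  if (sum(cfg$pattern_counts) + cfg$n_sex_genes + cfg$lt_effect_genes > cfg$n_genes) {
    stop("planted gene counts exceed n_genes")
  }
  if (cfg$frac_LT_pos < 0 || cfg$frac_LT_pos > 1) stop("frac_LT_pos must be in [0,1]")
  if (cfg$effect_log2fc < 0 || cfg$sex_log2fc < 0 || cfg$lt_log2fc < 0) {
    stop("effect magnitudes must be >= 0")
  }
  if (cfg$n_T > cfg$n_NAT) stop("n_T cannot exceed n_NAT (T samples pair with NAT)")
  if (cfg$n_N < 0L || cfg$n_NAT < 0L || cfg$n_T < 0L) stop("sample counts must be >= 0")
  invisible(cfg)
}

#' Simulate a three-group NB count dataset with planted effects
#'
#' Counts are drawn from a negative binomial with
#' \code{mean = size_factor * patient_effect * baseline * 2^(design effects)}
#' and per-gene dispersion alpha (variance = mu + alpha * mu^2).  Trajectory
#' effects act on NAT/T group membership (a gene with pattern signs (a1, a2)
#' has log2 mean shifted by \code{a1*effect} in NAT and \code{(a1+a2)*effect}
#' in T); sex effects act only through the sex covariate (Y-like genes are
#' ~50-fold depleted in females); LT effects act only in LT+ samples.  Paired
#' T samples share their NAT partner's patient intercept.  The same seed
#' yields bit-identical output.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements \code{counts} (integer matrix),
#'   \code{metadata} (data.frame), \code{annotation} (data.frame) and
#'   \code{truth} (class \code{"ground_truth"}: \code{$genes} data.frame and
#'   \code{$size_factors} named numeric).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  validate_sim_config(config)
  set.seed(config$seed)
  G <- config$n_genes
  gene_ids <- sprintf("GSIM%05d", seq_len(G))

  ## ---- samples ----------------------------------------------------------
  meta <- local({
    n_N <- config$n_N; n_NAT <- config$n_NAT; n_T <- config$n_T
    nat_ids <- sprintf("NAT%02d", seq_len(n_NAT))
    n_f_nat <- round(config$frac_female_NAT * n_NAT)
    nat_sex <- sample(c(rep("F", n_f_nat), rep("M", n_NAT - n_f_nat)))
    n_lt <- round(config$frac_LT_pos * n_NAT)
    nat_lt <- sample(c(rep("LT+", n_lt), rep("LT-", n_NAT - n_lt)))
    nat <- data.frame(sample_id = nat_ids, tissue_group = "NAT", sex = nat_sex,
                      age = round(stats::rnorm(n_NAT, config$age_mean, config$age_sd)),
                      lt_status = nat_lt,
                      patient_id = sprintf("P%02d", seq_len(n_NAT)),
                      stringsAsFactors = FALSE)
    n_f_n <- round(config$frac_female_N * n_N)
    nrm <- data.frame(sample_id = sprintf("N%02d", seq_len(n_N)),
                      tissue_group = "N",
                      sex = sample(c(rep("F", n_f_n), rep("M", n_N - n_f_n))),
                      age = round(stats::rnorm(n_N, config$age_mean, config$age_sd)),
                      lt_status = "LT-",
                      patient_id = sprintf("C%02d", seq_len(n_N)),
                      stringsAsFactors = FALSE)
    tum <- if (n_T > 0L) {
      idx <- seq_len(n_T)  # pair with the first n_T NAT samples
      data.frame(sample_id = sprintf("T%02d", idx), tissue_group = "T",
                 sex = nat$sex[idx], age = nat$age[idx],
                 lt_status = nat$lt_status[idx], patient_id = nat$patient_id[idx],
                 stringsAsFactors = FALSE)
    } else NULL
    rbind(nrm, nat, tum)
  })
  meta$age <- pmin(pmax(meta$age, 20), 85)
  S <- nrow(meta)

  ## ---- per-gene truth ---------------------------------------------------
  disp <- pmax(stats::rgamma(G, shape = config$dispersion_shape,
                             scale = config$dispersion_scale), 1e-8)
  base_mu <- stats::rlnorm(G, meanlog = config$mean_log_mu, sdlog = config$sd_log_mu)
  pattern <- rep("null", G)
  lfc1 <- numeric(G); lfc2 <- numeric(G)
  pos <- 0L
  for (p in PATTERNS) {
    k <- config$pattern_counts[[p]]
    if (k > 0L) {
      idx <- pos + seq_len(k)
      pattern[idx] <- p
      s <- PATTERN_SIGNS[[p]]
      lfc1[idx] <- s[1] * config$effect_log2fc
      lfc2[idx] <- s[2] * config$effect_log2fc
      pos <- pos + k
    }
  }
  # sex genes: Y-like / X-like / autosomal split
  n_sex <- config$n_sex_genes
  n_y <- ceiling(n_sex / 3); n_x <- ceiling((n_sex - n_y) / 2)
  n_a <- n_sex - n_y - n_x
  sex_idx <- if (n_sex > 0L) pos + seq_len(n_sex) else integer(0)
  y_idx <- utils::head(sex_idx, n_y)
  x_idx <- utils::head(setdiff(sex_idx, y_idx), n_x)
  a_idx <- setdiff(sex_idx, c(y_idx, x_idx))
  pos <- pos + n_sex
  lt_idx <- if (config$lt_effect_genes > 0L) pos + seq_len(config$lt_effect_genes) else integer(0)
  sex_lfc <- numeric(G)                      # log2FC male vs female
  sex_lfc[y_idx] <- log2(50)                 # near-zero in females
  if (length(x_idx)) sex_lfc[x_idx] <- config$sex_log2fc * rep_len(c(-1, 1), length(x_idx))
  if (length(a_idx)) sex_lfc[a_idx] <- config$sex_log2fc * rep_len(c(1, -1), length(a_idx))
  lt_lfc <- numeric(G)
  if (length(lt_idx)) lt_lfc[lt_idx] <- config$lt_log2fc * rep_len(c(1, -1), length(lt_idx))
  # planted genes draw their baselines from the expressed part of the
  # distribution: a planted effect is meant to be detectable, not buried in
  # counts the low-expression filter would discard
  planted <- c(which(pattern != "null"), sex_idx, lt_idx)
  if (length(planted)) {
    base_mu[planted] <- pmax(stats::rlnorm(length(planted), log(150), 1), 50)
  }

  ## ---- per-sample structure --------------------------------------------
  sf <- exp(stats::rnorm(S, 0, config$size_factor_sd))
  names(sf) <- meta$sample_id
  # gene-level patient effects (a patient-specific expression profile) shared
  # by both members of a T/NAT pair -- this is what the paired design absorbs;
  # unpaired samples stay purely NB.  Each profile is rescaled to be
  # library-size neutral so sequencing depth stays governed by sf alone.
  patients <- unique(meta$patient_id)
  pat_prof <- matrix(1, nrow = G, ncol = length(patients),
                     dimnames = list(NULL, patients))
  paired_pat <- unique(meta$patient_id[meta$tissue_group == "T"])
  if (length(paired_pat) && config$patient_sd > 0) {
    prof <- matrix(exp(stats::rnorm(G * length(paired_pat), 0, config$patient_sd)),
                   nrow = G)
    prof <- sweep(prof, 2L, colSums(base_mu * prof) / sum(base_mu), "/")
    pat_prof[, paired_pat] <- prof
  }

  in_nat_or_t <- as.numeric(meta$tissue_group %in% c("NAT", "T"))
  in_t <- as.numeric(meta$tissue_group == "T")
  is_m <- as.numeric(meta$sex == "M")
  is_lt <- as.numeric(!is.na(meta$lt_status) & meta$lt_status == "LT+")

  # log2-scale design effect per gene x sample
  log2eff <- outer(lfc1, in_nat_or_t) + outer(lfc2, in_t) +
    outer(sex_lfc, is_m) + outer(lt_lfc, is_lt)
  # Y-like genes: shift the reference so base_mu is the male mean and females
  # sit at base_mu / 50 (net term sex_lfc * (is_m - 1))
  if (length(y_idx)) {
    log2eff[y_idx, ] <- log2eff[y_idx, ] - outer(sex_lfc[y_idx], rep(1, S))
  }
  mu <- base_mu * 2^log2eff * pat_prof[, meta$patient_id, drop = FALSE]
  mu <- sweep(mu, 2, sf, "*")
  counts <- matrix(stats::rnbinom(G * S, mu = as.vector(mu),
                                  size = rep(1 / disp, times = S)),
                   nrow = G, ncol = S, dimnames = list(gene_ids, meta$sample_id))
  storage.mode(counts) <- "integer"

  ## ---- annotation -------------------------------------------------------
  biotypes <- c("protein_coding", "processed_pseudogene", "lincRNA", "antisense",
                "snRNA", "snoRNA", "misc_RNA", "scaRNA", "sense_intronic", "TEC")
  bt_prob <- c(0.45, 0.24, 0.08, 0.07, 0.04, 0.03, 0.03, 0.02, 0.02, 0.02)
  ann <- data.frame(gene_id = gene_ids,
                    symbol = sprintf("SYM%05d", seq_len(G)),
                    biotype = sample(biotypes, G, replace = TRUE, prob = bt_prob),
                    chromosome = as.character(sample(1:22, G, replace = TRUE)),
                    stringsAsFactors = FALSE)
  ann$chromosome[y_idx] <- "Y"
  ann$chromosome[x_idx] <- "X"

  truth_genes <- data.frame(gene_id = gene_ids,
                            true_log2fc_NATvsN = lfc1,
                            true_log2fc_TvsNAT = lfc2,
                            true_pattern = pattern,
                            sex_biased = seq_len(G) %in% sex_idx,
                            lt_responsive = seq_len(G) %in% lt_idx,
                            true_dispersion = disp,
                            true_base_mean = base_mu,
                            stringsAsFactors = FALSE)
  truth <- structure(list(genes = truth_genes, size_factors = sf),
                     class = "ground_truth")
  list(counts = counts, metadata = meta, annotation = ann, truth = truth)
}

#' Simulate a dataset with no group effect (pure null for the N/NAT/T contrast)
#'
#' Convenience wrapper around [simulate_dataset()] that zeroes all planted
#' trajectory effects while keeping the covariate structure (sex-biased and
#' LT-responsive genes, which the model adjusts for) and the depth and
#' patient heterogeneity.  Every gene's true arm log2FCs are exactly 0.
#'
#' @inheritParams simulate_dataset
#' @return As [simulate_dataset()].
#' @export
simulate_null_dataset <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must come from sim_config()")
  config$pattern_counts[] <- 0L
  config$effect_log2fc <- 0
  validate_sim_config(config)
  simulate_dataset(config)
}

#' Write simulation ground truth to TSV
#'
#' One row per gene plus a per-sample size-factor block, distinguished by a
#' \code{record_type} column; [read_truth()] round-trips the file losslessly.
#'
#' @param truth A \code{ground_truth} object from [simulate_dataset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_truth <- function(truth, path) {
  g <- truth$genes
  gene_block <- data.frame(record_type = "gene", id = g$gene_id,
                           g[, setdiff(names(g), "gene_id")],
                           true_size_factor = NA_real_,
                           stringsAsFactors = FALSE)
  samp_block <- data.frame(record_type = "sample", id = names(truth$size_factors),
                           true_log2fc_NATvsN = NA_real_, true_log2fc_TvsNAT = NA_real_,
                           true_pattern = NA_character_, sex_biased = NA,
                           lt_responsive = NA, true_dispersion = NA_real_,
                           true_base_mean = NA_real_,
                           true_size_factor = unname(truth$size_factors),
                           stringsAsFactors = FALSE)
  utils::write.table(rbind(gene_block, samp_block), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read ground truth written by [write_truth()]
#' @param path Path to a truth TSV.
#' @return A \code{ground_truth} object.
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  g <- df[df$record_type == "gene", , drop = FALSE]
  s <- df[df$record_type == "sample", , drop = FALSE]
  genes <- data.frame(gene_id = g$id,
                      g[, setdiff(names(g), c("record_type", "id", "true_size_factor"))],
                      stringsAsFactors = FALSE)
  rownames(genes) <- NULL
  structure(list(genes = genes,
                 size_factors = stats::setNames(s$true_size_factor, s$id)),
            class = "ground_truth")
}
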