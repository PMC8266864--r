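test_that("BH adjustment matches the step-up definition and a brute-force oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")

  set.seed(20)
  for (i in 1:200) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("dispersion estimates hit the Poisson floor and recover a known alpha", {
  # var == mean (Poisson-like constructed fixture) and a constant gene
  m <- rbind(g1 = c(4, 6, 4, 6, 4, 6), g2 = rep(7, 6))
  colnames(m) <- paste0("s", 1:6)
  d <- estimate_dispersions(m, rep(1, 6), shrink = 0)
  expect_equal(unname(d["g2"]), 1e-8)
  expect_lt(d["g1"], 0.05)

  set.seed(21)
  mu <- rlnorm(500, log(200), 0.8)
  mm <- matrix(rnbinom(500 * 200, mu = rep(mu, 200), size = 1 / 0.2),
               nrow = 500, dimnames = list(paste0("g", 1:500), paste0("s", 1:200)))
  dd <- estimate_dispersions(mm, rep(1, 200), shrink = 0)
  expect_gt(mean(dd), 0.15)
  expect_lt(mean(dd), 0.25)
})

test_that("the NB GLM reduces to the Poisson closed form and recovers planted log2FCs", {
  set.seed(22)
  y <- c(rpois(10, 40), rpois(10, 90))
  X <- cbind(1, rep(c(0, 1), each = 10))
  fit <- fit_nb_glm(y, X, rep(1, 20), 1e-8)
  expect_equal(fit$status, 0L)
  expect_equal(unname(fit$coefficients[2L]),
               log(mean(y[11:20]) / mean(y[1:10])), tolerance = 1e-6)

  expect_error(fit_nb_glm(y, cbind(X, X[, 2]), rep(1, 20), 0.1), "rank deficient")

  # planted log2FC = 1.5 at n = 40/group, alpha = 0.1: estimates within 0.25
  set.seed(23)
  n <- 40
  reps <- 200
  mu0 <- 100
  est <- replicate(reps, {
    y <- c(rnbinom(n, mu = mu0, size = 10), rnbinom(n, mu = mu0 * 2^1.5, size = 10))
    f <- fit_nb_glm(y, cbind(1, rep(c(0, 1), each = n)), rep(1, 2 * n), 0.1)
    f$coefficients[2L] / log(2)
  })
  expect_lt(mean(abs(est - 1.5)), 0.25)
  expect_lt(abs(mean(est) - 1.5), 0.1)
})

test_that("run_de handles degenerate genes, orientation flips and covariates", {
  sim <- simulate_dataset(sim_config(n_genes = 300, seed = 24))
  counts <- sim$counts
  counts["GSIM00299", ] <- 0L  # force an all-zero gene
  fl <- filter_low_expression(counts, sim$metadata)
  keep <- union(rownames(fl$counts), "GSIM00299")
  de <- run_de(counts[keep, ], sim$metadata, contrast = c("NAT", "N"))
  z <- de[de$gene_id == "GSIM00299", ]
  expect_identical(z$flag, "all_zero")
  expect_equal(z$log2fc, 0)
  expect_equal(z$pvalue, 1)

  # antisymmetry under contrast flip
  flip <- run_de(counts[keep, ], sim$metadata, contrast = c("N", "NAT"))
  expect_equal(flip$log2fc, -de$log2fc, tolerance = 1e-6)
  expect_equal(flip$pvalue, de$pvalue, tolerance = 1e-6)

  # padj respects BH monotonicity relative to raw p
  expect_true(all(de$padj >= de$pvalue - 1e-12))
  ord <- order(de$pvalue)
  expect_true(all(diff(de$padj[ord]) >= -1e-12))

  # Wald statistic is the natural-log coefficient over its SE
  ok <- de$flag == "ok"
  expect_equal(de$wald_stat[ok], de$log2fc[ok] * log(2) / de$se[ok],
               tolerance = 1e-8)
})

test_that("null p-values are calibrated and near-uniform", {
  cfg <- sim_config(n_genes = 2000, n_N = 30, n_NAT = 30, n_T = 0, seed = 25)
  sim <- simulate_null_dataset(cfg)
  fl <- filter_low_expression(sim$counts, sim$metadata)
  de <- run_de(fl$counts, sim$metadata, contrast = c("NAT", "N"))
  rate <- mean(de$pvalue < 0.05)
  expect_gt(rate, 0.035)
  expect_lt(rate, 0.065)
  ks <- suppressWarnings(ks.test(de$pvalue, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})

test_that("pairing on patient increases power when patient effects dominate", {
  cfg <- sim_config(n_genes = 600, effect_log2fc = 0.7, patient_sd = 1.2,
                    n_sex_genes = 0, lt_effect_genes = 0, seed = 26)
  sim <- simulate_dataset(cfg)
  fl <- filter_low_expression(sim$counts, sim$metadata)
  truth <- sim$truth$genes
  arm2_genes <- truth$gene_id[truth$true_log2fc_TvsNAT != 0]
  arm2_genes <- intersect(arm2_genes, rownames(fl$counts))

  paired <- suppressMessages(
    run_de(fl$counts, sim$metadata, contrast = c("T", "NAT"),
           covariates = character(0), paired = TRUE))
  pair_ids <- sim$metadata$patient_id[sim$metadata$tissue_group == "T"]
  sub <- sim$metadata[sim$metadata$patient_id %in% pair_ids &
                        sim$metadata$tissue_group %in% c("T", "NAT"), ]
  unpaired <- run_de(fl$counts[, sub$sample_id], sub, contrast = c("T", "NAT"),
                     covariates = character(0))
  pow_p <- mean(arm2_genes %in% paired$gene_id[paired$padj < 0.05])
  pow_u <- mean(arm2_genes %in% unpaired$gene_id[unpaired$padj < 0.05])
  expect_gt(pow_p, pow_u)
})

test_that("Wald rejections agree with a direct-likelihood LRT oracle", {
  set.seed(27)
  n <- 15
  X <- cbind(1, rep(c(0, 1), each = n))
  offset <- rep(0, 2 * n)
  agree <- logical(300)
  for (i in seq_len(300)) {
    lfc <- sample(c(0, 0, 1), 1)           # mix of null and alternative genes
    alpha <- 0.1
    y <- c(rnbinom(n, mu = 80, size = 1 / alpha),
           rnbinom(n, mu = 80 * 2^lfc, size = 1 / alpha))
    f <- fit_nb_glm(y, X, exp(offset), alpha)
    wald_p <- 2 * pnorm(-abs(f$coefficients[2L] / f$se[2L]))
    lrt_p <- lrt_pvalue(y, X, offset, alpha)
    agree[i] <- (wald_p < 0.05) == (lrt_p < 0.05)
  }
  expect_gte(mean(agree), 0.95)
})
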