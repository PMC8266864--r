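test_that("arm classification respects the documented boundary conventions", {
  expect_identical(classify_arm(0.584, 0.049), "up")      # inclusive >= 0.584
  expect_identical(classify_arm(2.0, 0.10), "stable")      # big FC, weak p
  expect_identical(classify_arm(-0.584, 0.01), "stable")   # down is strict <
  expect_identical(classify_arm(-0.5841, 0.01), "down")
  expect_identical(classify_arm(0.584, 0.05), "stable")    # p bound is strict
  expect_error(classify_arm(1, 0), "\\(0, 1\\]")

  # total partition over a grid including the exact boundary values
  grid <- expand.grid(lfc = c(-2, -0.5841, -0.584, -0.58, 0, 0.58, 0.584, 0.585, 2),
                      p = c(0.001, 0.049, 0.05, 0.051, 1))
  cls <- classify_arm(grid$lfc, grid$p)
  expect_true(all(cls %in% c("up", "down", "stable")))
  manual <- ifelse(grid$p < 0.05 & grid$lfc >= 0.584, "up",
                   ifelse(grid$p < 0.05 & grid$lfc < -0.584, "down", "stable"))
  expect_identical(cls, manual)
})

test_that("trajectory classification partitions DEGs into six patterns", {
  degs <- data.frame(gene_id = c("a", "b", "c"),
                     log2fc = c(1.0, -1.0, 2.0),
                     padj = c(0.001, 0.001, 0.01), stringsAsFactors = FALSE)
  arm2 <- data.frame(gene_id = c("a", "b", "d"),
                     log2fc = c(0.0, 0.7, 1.0),
                     padj = c(0.9, 0.01, 0.01), stringsAsFactors = FALSE)
  tr <- classify_trajectories(degs, arm2)
  expect_identical(tr$pattern[tr$gene_id == "a"], "up-stable")
  expect_identical(tr$pattern[tr$gene_id == "b"], "down-up")
  expect_identical(attr(tr, "missing_genes"), "c")
  expect_equal(sum(attr(tr, "pattern_counts")), nrow(tr))

  # partition property on random inputs: counts always sum to classified genes
  set.seed(51)
  for (i in 1:10) {
    n <- 50
    degs_r <- data.frame(gene_id = paste0("g", 1:n),
                         log2fc = sample(c(-1, 1), n, TRUE) * runif(n, 0.584, 3),
                         padj = runif(n, 1e-6, 0.049), stringsAsFactors = FALSE)
    arm2_r <- data.frame(gene_id = paste0("g", 1:n), log2fc = rnorm(n),
                         padj = runif(n), stringsAsFactors = FALSE)
    tr_r <- classify_trajectories(degs_r, arm2_r)
    expect_equal(sum(attr(tr_r, "pattern_counts")), n)
    expect_true(all(tr_r$pattern %in% c("up-up", "up-stable", "up-down",
                                        "down-down", "down-stable", "down-up")))
    first <- sub("-.*", "", tr_r$pattern)
    expect_identical(first, tr_r$arm1)
  }
})

test_that("overlap reports match brute-force set enumeration", {
  ov <- overlap_report(list(L1 = c("a", "b", "c"), L2 = c("b", "c", "d")))
  expect_equal(ov$region_counts[["L1&L2"]], 2L)
  expect_equal(ov$region_counts[["L1"]], 1L)
  expect_equal(ov$region_counts[["L2"]], 1L)
  expect_equal(ov$union_size, 4L)

  same <- overlap_report(list(A = c("x", "y"), B = c("x", "y")))
  expect_equal(same$region_counts[["A&B"]], 2L)

  expect_error(overlap_report(list(A = c("a", "a"), B = "b")), "duplicate")

  set.seed(52)
  for (i in 1:15) {
    ids <- list(A = sample(letters, sample(5:20, 1)),
                B = sample(letters, sample(5:20, 1)),
                C = sample(letters, sample(5:20, 1)))
    ov3 <- overlap_report(ids)
    oracle <- overlap_brute(ids)
    expect_equal(sum(ov3$region_counts), ov3$union_size)
    for (k in names(oracle)) {
      expect_equal(ov3$region_counts[[k]], unname(oracle[k]), ignore_attr = TRUE)
    }
  }
})

test_that("pairwise overlaps count direction concordance", {
  a <- data.frame(gene_id = c("g1", "g2", "g3"), log2fc = c(1, -1, 2))
  b <- data.frame(gene_id = c("g2", "g3", "g4"), log2fc = c(1, 1.5, -1))
  ov <- overlap_report(list(A = a, B = b))
  expect_equal(ov$direction$n_shared, 2L)
  expect_equal(ov$direction$n_same, 1L)      # g3 agrees
  expect_equal(ov$direction$n_opposite, 1L)  # g2 flips
})

test_that("biotype and chromosome composition report one-decimal shares", {
  degs <- data.frame(gene_id = paste0("g", 1:646),
                     log2fc = c(rep(1, 131), rep(-1, 142), rep(1, 373)),
                     direction = c(rep("up", 131), rep("down", 142), rep("up", 373)),
                     stringsAsFactors = FALSE)
  ann <- data.frame(gene_id = paste0("g", 1:646),
                    symbol = paste0("s", 1:646),
                    biotype = c(rep("protein_coding", 273), rep("processed_pseudogene", 373)),
                    chromosome = "1", stringsAsFactors = FALSE)
  bc <- biotype_composition(degs, ann)
  expect_equal(bc$coding$n, 273L)
  expect_equal(bc$coding$pct, 42.3)
  expect_equal(bc$coding$n_up, 131L)
  expect_equal(bc$coding$pct_up, 48.0)
  expect_equal(bc$n_noncoding, 373L)

  # unannotated genes fall under "unknown"; empty lists stay empty
  bc2 <- biotype_composition(degs[1:3, ], ann[-(1:3), ])
  expect_equal(bc2$table$biotype, "unknown")
  bc3 <- biotype_composition(degs[0, ], ann)
  expect_equal(bc3$n_total, 0L)

  sexg <- paste0("g", 1:52)
  ann2 <- data.frame(gene_id = sexg, symbol = sexg,
                     biotype = "protein_coding",
                     chromosome = c(rep("Y", 22), rep("X", 7), rep("3", 23)),
                     stringsAsFactors = FALSE)
  cc <- chromosome_composition(sexg, ann2)
  expect_equal(cc$pct[cc$chromosome == "Y"], 42.3)
  expect_equal(cc$pct[cc$chromosome == "X"], 13.5)
})
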