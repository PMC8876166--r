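test_that("low-expression filter keeps features at the floor, drops those below", {
  m <- toy_matrix(rbind(c(0.5, 0.5, 0.5, 0.5),
                        c(1.0, 1.0, 1.0, 1.0),
                        c(2.0, 2.0, 2.0, 2.0)))
  f <- filter_low_expression(m, floor = 1)
  expect_identical(f$feature_ids, c("f2", "f3"))
  expect_identical(f$sample_ids, m$sample_ids)
  expect_error(filter_low_expression(m, floor = 0), "> 0")
})

test_that("filter matches a brute-force row-mean oracle on a seeded matrix", {
  m <- null_matrix(2000, 4, seed = 101)
  f <- filter_low_expression(m, floor = 1)
  keep <- apply(m$values, 1, mean) >= 1   # independent recomputation
  expect_identical(f$feature_ids, m$feature_ids[keep])
})

test_that("excluded samples are ignored by the filter mean but kept as columns", {
  m <- toy_matrix(rbind(c(100, 0.1, 0.1, 0.1)))  # mean 25.1 with s1, 0.1 without
  sh <- sample_sheet(c("s1", "s2", "s3", "s4"),
                     c("iWAT", "iWAT", "PANC", "PANC"))
  expect_identical(filter_low_expression(m, 1, sh)$feature_ids, "f1")
  sh5 <- sample_sheet(c("s1", "s2", "s3", "s4", "s5"),
                      c("iWAT", "iWAT", "iWAT", "PANC", "PANC"),
                      excluded = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  m5 <- toy_matrix(rbind(c(100, 0.1, 0.1, 0.1, 0.1)))
  f5 <- suppressWarnings(filter_low_expression(m5, 1, sh5))
  expect_length(f5$feature_ids, 0L)
  expect_equal(ncol(f5$values), 5L)
})

test_that("Welch statistic, Satterthwaite df and p match the hand-computed case", {
  # ref (1,2,3) vs test (4,5,6): t = 3/sqrt(2/3) = 3.674, df = 4, p = 0.0213
  m <- toy_matrix(rbind(c(1, 2, 3, 4, 5, 6)),
                  samples = c("W1", "W2", "W3", "P1", "P2", "P3"))
  sh <- toy_sheet(3)
  res <- welch_de(m, sh)
  expect_equal(res$t_stat, 3 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(res$df, 4, tolerance = 1e-12)
  expect_equal(res$p_value, 0.021312, tolerance = 1e-4)
  expect_true(res$significant)
  expect_identical(res$direction, "up")
})

test_that("vectorized Welch agrees with stats::t.test per feature", {
  m <- null_matrix(200, 5, seed = 21)
  sh <- toy_sheet(5)
  res <- welch_de(m, sh)
  ref_cols <- paste0("W", 1:5); test_cols <- paste0("P", 1:5)
  for (i in c(1, 17, 50, 121, 200)) {
    tt <- stats::t.test(m$values[i, test_cols], m$values[i, ref_cols],
                        var.equal = FALSE)
    expect_equal(res$t_stat[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(res$df[i], unname(tt$parameter), tolerance = 1e-10)
    expect_equal(res$p_value[i], tt$p.value, tolerance = 1e-10)
  }
})

test_that("degenerate features are handled, not errors", {
  # identical values in both groups: t = 0, p = 1, direction none
  m <- toy_matrix(rbind(rep(5, 8), c(1, 1, 1, 1, 3, 3, 3, 3)),
                  samples = c(paste0("W", 1:4), paste0("P", 1:4)))
  res <- welch_de(m, toy_sheet(4))
  expect_equal(res$p_value[1], 1)
  expect_equal(res$t_stat[1], 0)
  expect_identical(res$direction[1], "none")
  expect_true(res$degenerate[1])
  # zero variance in both groups but different means: flagged, p near zero
  expect_true(res$degenerate[2])
  expect_lt(res$p_value[2], 1e-6)
  expect_identical(res$direction[2], "up")
})

test_that("log2 fold change uses group means with the pseudocount", {
  m <- toy_matrix(rbind(c(1, 1, 1, 4, 4, 4)),
                  samples = c(paste0("W", 1:3), paste0("P", 1:3)))
  res <- welch_de(m, toy_sheet(3), thresholds(pseudocount = 1e-9))
  expect_equal(res$log2fc, 2, tolerance = 1e-6)
})

test_that("group-label swap flips log2fc sign and preserves p-values", {
  m <- null_matrix(300, 4, seed = 33)
  sh <- toy_sheet(4)
  swapped <- sample_sheet(sh$sample_id,
                          ifelse(sh$group == "iWAT", "PANC", "iWAT"))
  a <- welch_de(m, sh, thresholds(pseudocount = 0.01))
  b <- welch_de(m, swapped, thresholds(pseudocount = 0.01))
  expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
  expect_equal(a$log2fc, -b$log2fc, tolerance = 1e-12)
})

test_that("classification partitions significant features exactly", {
  m <- null_matrix(500, 4, seed = 55)
  res <- welch_de(m, toy_sheet(4))
  cls <- classify_de(res)
  expect_equal(length(cls$up) + length(cls$down), sum(res$significant))
  # brute-force predicate filter oracle
  expect_setequal(cls$up, res$feature_id[res$p_value < 0.05 & res$log2fc > 0])
  expect_setequal(cls$down, res$feature_id[res$p_value < 0.05 & res$log2fc <= 0])
})

test_that("transcript results collapse to genes with direction logic", {
  res <- toy_mirna_results(c("t1", "t2", "t3", "t4", "t5"),
                           lfc = c(2, 1, -1.5, 3, -2),
                           p = c(0.01, 0.2, 0.03, 0.02, 0.04))
  ann <- data.frame(transcript_id = c("t1", "t2", "t3", "t4", "t5"),
                    gene_symbol = c("G1", "G1", "G2", "G3", "G3"),
                    stringsAsFactors = FALSE)
  degs <- collapse_to_genes(res, ann)
  expect_identical(degs$direction[degs$gene_symbol == "G1"], "up")       # t2 not sig
  expect_identical(degs$direction[degs$gene_symbol == "G2"], "down")
  expect_identical(degs$direction[degs$gene_symbol == "G3"], "discordant")
  expect_equal(degs$best_p[degs$gene_symbol == "G3"], 0.02)
  expect_equal(degs$max_abs_log2fc[degs$gene_symbol == "G3"], 3)

  expect_error(collapse_to_genes(res, ann[-1, ]), "t1")
})

test_that("gene count after collapsing equals a group-by oracle", {
  set.seed(77)
  n <- 400
  res <- toy_mirna_results(sprintf("t%03d", 1:n),
                           lfc = rnorm(n), p = runif(n))
  ann <- data.frame(transcript_id = res$feature_id,
                    gene_symbol = sprintf("G%03d", sample(1:200, n, TRUE)),
                    stringsAsFactors = FALSE)
  degs <- collapse_to_genes(res, ann)
  oracle <- unique(ann$gene_symbol[match(res$feature_id[res$significant],
                                         ann$transcript_id)])
  expect_setequal(degs$gene_symbol, oracle)
})

test_that("outlier flagging finds a noise sample among correlated ones", {
  set.seed(9)
  base <- rexp(500, 0.1)
  m <- sapply(1:8, function(i) base * exp(rnorm(500, 0, 0.1)))
  m[, 8] <- rexp(500, 0.1)    # independent noise sample
  dimnames(m) <- list(sprintf("f%03d", 1:500), sprintf("s%d", 1:8))
  em <- expression_matrix(m, "FPKM")
  flags <- flag_outlier_samples(em, min_median_corr = 0.8)
  expect_identical(flags, "s8")
  # direct median-correlation confirmation
  cc <- cor(m, method = "spearman")
  med <- sapply(1:8, function(i) median(cc[-i, i]))
  expect_identical(em$sample_ids[med < 0.8], flags)
  # degenerate threshold flags everyone on noisy data
  expect_length(flag_outlier_samples(em, min_median_corr = 1.0), 8L)
})
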