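test_that("exclusive miRNA selection applies the p and |log2FC| >= 2 rule", {
  res <- toy_mirna_results(c("m1", "m2", "m3", "m4", "m5"),
                           lfc = c(-3, 1.5, 2.4, -2.0, -4),
                           p = c(0.01, 0.01, 0.02, 0.03, 0.2))
  ex <- select_exclusive_mirnas(res, thresholds())
  expect_setequal(ex$iwat_exclusive, c("m1", "m4"))   # boundary -2.0 included
  expect_setequal(ex$panc_exclusive, "m3")            # m2 below cut, m5 not sig

  # brute-force predicate oracle on a random layer
  set.seed(13)
  r2 <- toy_mirna_results(sprintf("mm%03d", 1:300),
                          lfc = rnorm(300, 0, 2), p = runif(300))
  ex2 <- select_exclusive_mirnas(r2, thresholds())
  expect_setequal(ex2$iwat_exclusive,
                  r2$feature_id[r2$p_value < 0.05 & r2$log2fc <= -2])
  expect_setequal(ex2$panc_exclusive,
                  r2$feature_id[r2$p_value < 0.05 & r2$log2fc >= 2])
})

test_that("direction-consistency filter keeps exactly the anti-correlated sign pairs", {
  degs <- toy_degs()   # A up (+2.5), B down (-1.8), C up (+0.7), D discordant, E down (-2.2)
  mir <- toy_mirna_results(c("up1", "dn1"), lfc = c(2.5, -1.2), p = c(0.01, 0.02))
  edges <- interaction_df(
    c("up1", "up1", "dn1", "dn1", "up1", "dn1"),
    c("B",   "A",   "A",   "B",   "D",   "D"))
  pairs <- map_and_filter_targets(mir, degs, edges, thresholds())
  # miRNA up & gene down and miRNA down & gene up survive; discordant D never
  expect_equal(nrow(pairs), 2L)
  expect_identical(pairs$gene_symbol[pairs$mirna_id == "up1"], "B")
  expect_identical(pairs$gene_symbol[pairs$mirna_id == "dn1"], "A")
  expect_true(all(sign(pairs$mirna_log2fc) * sign(pairs$gene_log2fc) == -1))
  # strong flag: |gene lfc| > 1.5
  expect_true(pairs$strong[pairs$gene_symbol == "B"])   # -1.8
  expect_true(pairs$strong[pairs$gene_symbol == "A"])   # +2.5
})

test_that("strong flag respects the 1.5 highlight cut", {
  degs <- toy_degs()
  mir <- toy_mirna_results("up1", lfc = 2, p = 0.01)
  pairs <- map_and_filter_targets(
    mir, degs, interaction_df(c("up1", "up1"), c("B", "E")), thresholds())
  expect_identical(pairs$strong[order(pairs$gene_symbol)], c(TRUE, TRUE))
  # gene at |lfc| = 0.7 (C) paired with a down miRNA: retained but not strong
  mir2 <- toy_mirna_results("dn1", lfc = -2, p = 0.01)
  p2 <- map_and_filter_targets(mir2, degs, interaction_df("dn1", "C"), thresholds())
  expect_false(p2$strong)
})

test_that("non-significant miRNAs and non-DEG genes never yield pairs", {
  degs <- toy_degs()
  mir <- toy_mirna_results(c("ns", "sig"), lfc = c(3, 3), p = c(0.5, 0.01))
  edges <- interaction_df(c("ns", "sig"), c("B", "Zz"))  # Zz not a DEG
  pairs <- map_and_filter_targets(mir, degs, edges, thresholds())
  expect_equal(nrow(pairs), 0L)
  expect_warning(map_and_filter_targets(mir, degs, interaction_df(character(0),
                                                                  character(0)),
                                        thresholds()),
                 "empty interaction table")
})

test_that("output is monotone in the interaction table", {
  set.seed(41)
  degs <- toy_degs()
  mir <- toy_mirna_results(sprintf("m%d", 1:6),
                           lfc = rnorm(6, 0, 2), p = runif(6, 0, 0.04))
  e1 <- interaction_df(sample(mir$feature_id, 8, TRUE),
                       sample(degs$gene_symbol, 8, TRUE))
  e1 <- e1[!duplicated(e1[c("mirna_id", "gene_symbol")]), ]
  extra <- interaction_df("m1", "E")
  p_small <- map_and_filter_targets(mir, degs, e1, thresholds())
  p_big <- map_and_filter_targets(mir, degs, unique(rbind(e1, extra)), thresholds())
  key <- function(p) paste(p$mirna_id, p$gene_symbol)
  expect_true(all(key(p_small) %in% key(p_big)))
})

test_that("integration summary counts distinct entities and the DEG fraction", {
  degs <- toy_degs()[rep(1, 10), ]; degs$gene_symbol <- sprintf("g%d", 1:10)
  pairs <- data.frame(mirna_id = c("m1", "m1", "m2"),
                      gene_symbol = c("g1", "g2", "g1"),
                      stringsAsFactors = FALSE)
  s <- summarize_integration(pairs, degs)
  expect_equal(s$n_regulated_genes, 2L)
  expect_equal(s$n_de_mirnas_with_targets, 2L)
  expect_equal(s$fraction_degs_explained, 0.2)
  s0 <- summarize_integration(pairs[0, ], degs)
  expect_equal(s0$fraction_degs_explained, 0)
  expect_error(summarize_integration(pairs, degs[0, ]), "undefined")
})

test_that("true repressive edges are recovered on strongly coupled synthetic data", {
  cfg <- simulation_config(seed = 5, n_transcripts = 1200, n_mirnas = 200,
                           effect_size_log2_min = 3, repression_slope = 0.75)
  sim <- simulate_dataset(cfg)
  th <- thresholds()
  tx <- filter_low_expression(sim$transcripts, th$expr_floor, sim$sheet)
  mi <- filter_low_expression(sim$mirnas, th$expr_floor, sim$sheet)
  de_tx <- welch_de(tx, sim$sheet, th)
  de_mi <- welch_de(mi, sim$sheet, th)
  degs <- collapse_to_genes(de_tx, sim$annotation)
  pairs <- map_and_filter_targets(de_mi, degs, sim$interactions, th)
  # every retained pair is sign anti-correlated (full-output assertion)
  expect_true(all(sign(pairs$mirna_log2fc) * sign(pairs$gene_log2fc) == -1))
  # recall of true edges among those whose features survived the floor
  truth <- sim$truth$true_edges
  testable <- truth$mirna_id %in% mi$feature_ids &
    truth$gene_symbol %in% sim$annotation$gene_symbol[
      sim$annotation$transcript_id %in% tx$feature_ids]
  key <- function(m, g) paste(m, g)
  recall <- mean(key(truth$mirna_id, truth$gene_symbol)[testable] %in%
                   key(pairs$mirna_id, pairs$gene_symbol))
  expect_gte(recall, 0.9)
})
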