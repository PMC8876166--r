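make_collection <- function(...) {
  sets <- list(...)
  structure(sets, class = "GeneSetCollection")
}

test_that("fold enrichment and gating follow the (k/n)/(K/N) definition", {
  universe <- sprintf("g%04d", 1:1000)
  term <- make_collection(T1 = universe[1:50])
  query <- c(universe[1:6], universe[100:153])   # n = 60, k = 6, K = 50
  rows <- hypergeom_enrich(query, term, universe, min_count = 3)
  expect_equal(rows$fold_enrichment, (6 / 60) / (50 / 1000))
  expect_equal(rows$fold_enrichment, 2.0)
  expect_equal(rows$k, 6L)
  # passes requires all three gates; fe > 2 fails here (fe == 2 exactly)
  expect_false(rows$passes)
})

test_that("extreme containment gives fold enrichment N/n and a minimal p", {
  universe <- sprintf("g%d", 1:200)
  q <- universe[1:10]
  rows <- hypergeom_enrich(q, make_collection(T1 = q), universe, min_count = 3)
  expect_equal(rows$fold_enrichment, 200 / 10)
  expect_equal(rows$p_value, 1 / choose(200, 10), tolerance = 1e-9)
})

test_that("hypergeometric p matches exhaustive PMF summation (small universes)", {
  for (N in c(5L, 9L, 16L, 20L)) {
    universe <- sprintf("u%02d", seq_len(N))
    for (K in 1:N) {
      term <- make_collection(T = universe[seq_len(K)])
      for (n in 1:N) {
        query <- universe[(N - n + 1):N]   # overlap k = max(0, n + K - N) ... varies
        k <- length(intersect(query, universe[seq_len(K)]))
        if (k == 0) next
        rows <- hypergeom_enrich(query, term, universe, min_count = 1)
        expect_equal(rows$p_value, hyper_upper_oracle(k, K, n, N),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("the EASE variant computes the tail at k - 1", {
  universe <- sprintf("g%d", 1:100)
  term <- make_collection(T1 = universe[1:20])
  query <- universe[c(1:5, 50:64)]   # n = 20, k = 5
  plain <- hypergeom_enrich(query, term, universe, min_count = 1)
  ease <- hypergeom_enrich(query, term, universe, min_count = 1, ease = TRUE)
  expect_equal(ease$p_value, hyper_upper_oracle(4, 20, 20, 100), tolerance = 1e-12)
  expect_gt(ease$p_value, plain$p_value)
})

test_that("query and universe preconditions are enforced", {
  universe <- c("a", "b", "c")
  expect_error(hypergeom_enrich(c("a", "zz"), make_collection(T1 = c("a", "b")),
                                universe), "zz")
  expect_error(hypergeom_enrich("a", make_collection(T1 = "a"), character(0)),
               "empty universe")
})

test_that("GO-circle z-score arithmetic is exact", {
  dirs <- c(setNames(rep("up", 9), sprintf("u%d", 1:9)),
            setNames(rep("down", 16), sprintf("d%d", 1:16)))
  expect_equal(go_circle_zscore(names(dirs), dirs), (9 - 16) / 5)
  expect_equal(go_circle_zscore(names(dirs), dirs), -1.4)
  up4 <- setNames(rep("up", 4), sprintf("u%d", 1:4))
  expect_equal(go_circle_zscore(names(up4), up4), 2.0)
  expect_equal(go_circle_zscore(character(0), up4), 0)
})

test_that("the z-score is standardized under random direction assignment", {
  set.seed(97)
  k <- 25
  genes <- sprintf("g%d", 1:k)
  z <- replicate(10000, {
    dirs <- setNames(sample(c("up", "down"), k, TRUE), genes)
    go_circle_zscore(genes, dirs)
  })
  expect_equal(mean(z), 0, tolerance = 0.05)
  expect_equal(var(z), 1, tolerance = 0.05)
})

test_that("fold enrichment is invariant under universe scaling", {
  fe <- function(k, n, K, N) (k / n) / (K / N)
  base <- fe(6, 60, 50, 1000)
  for (c_ in c(2, 5, 10))
    expect_equal(fe(6 * c_, 60 * c_, 50 * c_, 1000 * c_), base)
})

test_that("null enrichment keeps the false-positive fraction near alpha", {
  set.seed(303)
  universe <- sprintf("g%04d", 1:800)
  sets <- setNames(lapply(1:200, function(i) sample(universe, 40)),
                   sprintf("T%03d", 1:200))
  class(sets) <- "GeneSetCollection"
  query <- sample(universe, 80)
  rows <- hypergeom_enrich(query, sets, universe, min_count = 1)
  # discrete one-sided test: false-positive rate is at most alpha up to MC noise
  expect_lte(mean(rows$p_value < 0.05), 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("marker overlap builds the 2x2 table and the sample odds ratio", {
  # 75 genes: means arranged so the top-10 set is g01..g10
  genes <- sprintf("g%02d", 1:75)
  m <- matrix(rep(75:1, 2), ncol = 2, dimnames = list(genes, c("s1", "s2")))
  em <- expression_matrix(m, "FPKM")
  markers <- c(genes[1:4], genes[20:25])   # a = 4, b = 6
  res <- marker_overlap_fisher(em, markers, top_n = 10)
  expect_equal(c(res$a, res$b, res$c, res$d), c(4, 6, 6, 59))
  expect_equal(res$odds_ratio, (4 * 59) / (6 * 6))
  # one-sided Fisher p against the exhaustive enumeration oracle
  expect_equal(res$p_value, fisher_greater_oracle(4, 6, 6, 59), tolerance = 1e-12)
})

test_that("odds-ratio arithmetic and edge cases behave as documented", {
  genes <- sprintf("g%02d", 1:40)
  m <- matrix(rep(40:1, 2), ncol = 2, dimnames = list(genes, c("s1", "s2")))
  em <- expression_matrix(m, "FPKM")
  # markers disjoint from the top set: anti-enrichment, p well above 0.5
  res <- marker_overlap_fisher(em, genes[30:39], top_n = 10)
  expect_equal(res$a, 0)
  expect_gte(res$p_value, 0.5)
  # all markers inside the top set: infinite sample OR unless Haldane-corrected
  res2 <- marker_overlap_fisher(em, genes[1:5], top_n = 10)
  expect_true(is.infinite(res2$odds_ratio))
  expect_true(res2$infinite_or)
  res3 <- marker_overlap_fisher(em, genes[1:5], top_n = 10, haldane = TRUE)
  expect_true(is.finite(res3$odds_ratio))
  expect_error(marker_overlap_fisher(em, genes[1:5], top_n = 40), "smaller")
})

test_that("abundance ties are broken lexicographically, making ranking deterministic", {
  genes <- c("bb", "aa", "cc", "dd")
  m <- matrix(c(5, 5, 5, 1), ncol = 1, dimnames = list(genes, "s1"))
  m <- cbind(m, m); colnames(m) <- c("s1", "s2")
  em <- expression_matrix(m, "FPKM")
  res <- marker_overlap_fisher(em, c("aa", "bb"), top_n = 2)
  # top 2 of the tie {aa, bb, cc} must be aa, bb
  expect_equal(res$a, 2)
})

test_that("random marker sets give a median odds ratio near 1 across seeds", {
  genes <- sprintf("g%03d", 1:400)
  set.seed(71)
  m <- matrix(rexp(800, 0.1), ncol = 2, dimnames = list(genes, c("s1", "s2")))
  em <- expression_matrix(m, "FPKM")
  ors <- sapply(1:41, function(s) {
    set.seed(1000 + s)
    marker_overlap_fisher(em, sample(genes, 60), top_n = 100)$odds_ratio
  })
  expect_lt(abs(log(median(ors))), log(1.6))
})
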