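#' Gated hypergeometric gene-set over-representation
#'
#' One-sided over-representation test per term: with a universe of `N` genes
#' of which `K` belong to the term, and a query of `n` genes overlapping the
#' term in `k`, the p-value is the hypergeometric upper tail `P[X >= k]` and
#' the fold enrichment is `(k/n) / (K/N)`. A term "passes" when all three
#' gates hold: overlap count `k >= min_count`, fold enrichment strictly above
#' `min_fold_enrichment`, and unadjusted `p < alpha` — the DAVID-style gating
#' used for DEG sets (count >= 10) and miRNA-target sets (count >= 3).
#'
#' Term membership is intersected with the universe before counting, so the
#' universe (by default the expressed set, the detected background) fully
#' determines the contingency table. Optionally the EASE variant (the
#' conservative `k - 1` convention) can be used for the p-value.
#'
#' @param query character vector of gene symbols; must be a subset of
#'   `universe`.
#' @param collection a `GeneSetCollection` from [read_gmt()].
#' @param universe character vector, the expressed background.
#' @param directions optional named character vector mapping overlap genes to
#'   `"up"`/`"down"` for the GO-circle z-score; genes without a direction are
#'   ignored by the z-score.
#' @param th a [thresholds()] object (`alpha`, `min_fold_enrichment`).
#' @param min_count overlap-count gate (10 for DEGs, 3 for miRNA targets).
#' @param ease use the EASE score (p computed at k - 1) instead of the plain
#'   hypergeometric tail.
#' @param adjust add a BH-adjusted `p_adj` column (never drives `passes`).
#' @return data.frame of class `enrichment` sorted by p-value: `term_id,
#'   term_name, k, n, K, N, fold_enrichment, p_value, z_score, passes`. Terms
#'   with no overlap (`k = 0`) are omitted.
#' @export
hypergeom_enrich <- function(query, collection, universe, directions = NULL,
                             th = thresholds(), min_count = th$min_count_deg,
                             ease = FALSE, adjust = FALSE) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  bad <- setdiff(query, universe)
  if (length(bad))
    stop("query genes outside the universe: ", paste(bad, collapse = ", "),
         call. = FALSE)
  N <- length(universe)
  n <- length(query)
  ids <- names(collection)
  members <- lapply(collection, function(s) intersect(s, universe))
  overlaps <- lapply(members, function(m) m[m %in% query])
  K <- lengths(members)
  k <- lengths(overlaps)
  hit <- k >= 1L
  ids <- ids[hit]; K <- K[hit]; k <- k[hit]; overlaps <- overlaps[hit]
  kp <- if (ease) pmax(k - 1L, 0L) else k
  p <- stats::phyper(kp - 1L, K, N - K, n, lower.tail = FALSE)
  z <- if (is.null(directions)) rep(NA_real_, length(ids)) else
    vapply(overlaps, go_circle_zscore, numeric(1), directions = directions)
  nms <- vapply(ids, function(id) {
    nm <- attr(collection[[id]], "term_name")
    if (is.null(nm)) id else nm
  }, character(1))
  out <- if (length(ids))
    data.frame(term_id = ids, term_name = nms,
               k = unname(k), n = n, K = unname(K), N = N,
               fold_enrichment = unname((k / n) / (K / N)),
               p_value = unname(p), z_score = unname(z),
               stringsAsFactors = FALSE)
  else
    data.frame(term_id = character(), term_name = character(),
               k = integer(), n = integer(), K = integer(), N = integer(),
               fold_enrichment = numeric(), p_value = numeric(),
               z_score = numeric(), stringsAsFactors = FALSE)
  out$passes <- out$k >= min_count &
    out$fold_enrichment > th$min_fold_enrichment &
    out$p_value < th$alpha
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("enrichment", "data.frame")
  out
}

#' GO-circle direction z-score
#'
#' Signs a term by the regulation balance of its overlapping genes:
#' `z = (#up - #down) / sqrt(#up + #down)`, the convention of circular GO
#' plots where positive terms are "increased" in the test tissue. Returns 0
#' for an empty overlap.
#'
#' @param overlap_genes character vector of genes in query-AND-term.
#' @param directions named character vector mapping genes to `"up"`/`"down"`.
#' @return single signed score.
#' @export
go_circle_zscore <- function(overlap_genes, directions) {
  d <- directions[intersect(overlap_genes, names(directions))]
  n_up <- sum(d == "up"); n_down <- sum(d == "down")
  if (n_up + n_down == 0L) return(0)
  (n_up - n_down) / sqrt(n_up + n_down)
}

#' Marker-gene overlap with the top-N expressed genes (Fisher test)
#'
#' Ranks genes by mean abundance over all samples (ties broken
#' lexicographically by identifier, so the ranking is deterministic), takes
#' the top `top_n`, and tests whether a marker set — e.g. pancreatic stellate
#' cell markers — is over-represented among them with a one-sided Fisher
#' exact test on the 2x2 table. The odds ratio reported is the sample odds
#' ratio `(a*d)/(b*c)`, not the conditional MLE.
#'
#' @param mat an [expression_matrix()] (gene-level abundances).
#' @param markers character vector of marker gene symbols; intersected with
#'   the matrix's features before testing.
#' @param top_n size of the top-expressed set; must be < number of features.
#' @param haldane apply the Haldane +0.5 correction to the odds ratio when a
#'   zero cell would make it infinite.
#' @return list of class `marker_overlap`: cells `a` (marker in top-N), `b`
#'   (marker outside), `c` (non-marker in top-N), `d` (rest), `odds_ratio`,
#'   `p_value`, and `infinite_or` flag.
#' @export
marker_overlap_fisher <- function(mat, markers, top_n = 1000, haldane = FALSE) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  genes <- mat$feature_ids
  if (top_n >= length(genes))
    stop("'top_n' must be smaller than the number of expressed genes", call. = FALSE)
  means <- rowMeans(mat$values)
  ord <- order(-means, genes)          # abundance desc, then lexicographic
  top <- genes[ord[seq_len(top_n)]]
  markers <- intersect(unique(markers), genes)
  a <- sum(markers %in% top)
  b <- length(markers) - a
  c_ <- top_n - a
  d <- length(genes) - length(markers) - c_
  tab <- matrix(c(a, b, c_, d), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "greater")$p.value
  infinite_or <- (b * c_ == 0)
  or <- if (infinite_or && haldane)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5))
  else if (infinite_or) Inf
  else (a * d) / (b * c_)
  structure(list(a = a, b = b, c = c_, d = d, odds_ratio = or,
                 p_value = p, infinite_or = infinite_or && !haldane),
            class = "marker_overlap")
}

#' @export
print.marker_overlap <- function(x, ...) {
  cat(sprintf("Marker overlap: %d/%d markers in top set; odds ratio %.3g, Fisher p = %.3g\n",
              x$a, x$a + x$b, x$odds_ratio, x$p_value))
  invisible(x)
}
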