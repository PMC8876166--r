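#' Analysis thresholds
#'
#' Bundles every tunable cut-off of the pipeline with the study's defaults:
#' mean-abundance floor 1 (FPKM/TPM), unadjusted alpha 0.05, |log2FC| >= 2 for
#' "exclusively expressed" miRNAs, |log2FC| > 1.5 to highlight strongly
#' repressed targets, enrichment count gates of 10 (DEGs) and 3 (miRNA
#' targets) with fold enrichment > 2, top-1000 expressed genes for the marker
#' overlap, and a 0.01 pseudocount stabilising fold changes of group means.
#'
#' @param expr_floor minimum mean abundance; features below it are removed.
#' @param alpha significance level for unadjusted p-values.
#' @param exclusive_lfc |log2FC| cut defining tissue-exclusive miRNAs.
#' @param highlight_lfc |log2FC| cut flagging strong target repression.
#' @param min_count_deg overlap-count gate for DEG enrichment.
#' @param min_count_target overlap-count gate for miRNA-target enrichment.
#' @param min_fold_enrichment fold-enrichment gate (strictly greater than).
#' @param top_n_expressed size of the top-expressed set for marker overlap.
#' @param pseudocount added to both group means before the log2 ratio.
#' @return list of class `Thresholds`.
#' @export
thresholds <- function(expr_floor = 1, alpha = 0.05, exclusive_lfc = 2,
                       highlight_lfc = 1.5, min_count_deg = 10,
                       min_count_target = 3, min_fold_enrichment = 2,
                       top_n_expressed = 1000, pseudocount = 0.01) {
  th <- list(expr_floor = expr_floor, alpha = alpha, exclusive_lfc = exclusive_lfc,
             highlight_lfc = highlight_lfc, min_count_deg = min_count_deg,
             min_count_target = min_count_target,
             min_fold_enrichment = min_fold_enrichment,
             top_n_expressed = top_n_expressed, pseudocount = pseudocount)
  bad <- names(th)[!vapply(th, function(v) is.numeric(v) && length(v) == 1L && v > 0,
                           logical(1))]
  if (length(bad))
    stop("thresholds must be single positive numbers: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (th$alpha >= 1) stop("'alpha' must be in (0, 1)", call. = FALSE)
  class(th) <- "Thresholds"
  th
}

#' Remove low-expression features
#'
#' Drops every feature whose mean abundance over all non-excluded samples is
#' strictly below `floor` (features at exactly the floor are retained, since
#' only means *below* it are filtered). The sample set is unchanged.
#'
#' @param mat an [expression_matrix()].
#' @param floor minimum mean abundance (> 0); default 1 FPKM/TPM.
#' @param sheet optional `SampleSheet`; excluded samples are ignored when
#'   computing the mean but kept in the returned matrix.
#' @return filtered `ExpressionMatrix`. If no feature survives, an empty
#'   matrix is returned with a warning; downstream statistics refuse it.
#' @export
filter_low_expression <- function(mat, floor = 1, sheet = NULL) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (!is.numeric(floor) || length(floor) != 1L || floor <= 0)
    stop("'floor' must be a single value > 0", call. = FALSE)
  if (nrow(mat$values) == 0L) stop("matrix has no features", call. = FALSE)
  use <- mat$sample_ids
  if (!is.null(sheet)) {
    check_sheet_matrix(sheet, mat)
    excl <- sheet$sample_id[sheet$excluded]
    use <- setdiff(use, excl)
  }
  means <- rowMeans(mat$values[, use, drop = FALSE])
  keep <- means >= floor
  if (!any(keep))
    warning("no feature passes the expression floor; returning empty matrix")
  vals <- mat$values[keep, , drop = FALSE]
  dimnames(vals) <- list(mat$feature_ids[keep], mat$sample_ids)
  expression_matrix(vals, unit = mat$unit)
}

# Group means/variances over non-excluded samples; internal work-horse.
group_stats <- function(mat, sheet) {
  check_sheet_matrix(sheet, mat)
  ref <- attr(sheet, "ref_group"); test <- attr(sheet, "test_group")
  kept <- sheet[!sheet$excluded & sheet$sample_id %in% mat$sample_ids, ]
  ref_ids <- kept$sample_id[kept$group == ref]
  test_ids <- kept$sample_id[kept$group == test]
  if (length(ref_ids) < 2L || length(test_ids) < 2L)
    stop("each group needs >= 2 non-excluded samples present in the matrix",
         call. = FALSE)
  vr <- mat$values[, ref_ids, drop = FALSE]
  vt <- mat$values[, test_ids, drop = FALSE]
  rowVar <- function(v) {
    mu <- rowMeans(v)
    rowSums((v - mu)^2) / (ncol(v) - 1L)
  }
  list(mean_ref = rowMeans(vr), mean_test = rowMeans(vt),
       var_ref = rowVar(vr), var_test = rowVar(vt),
       n_ref = length(ref_ids), n_test = length(test_ids))
}

#' Per-feature Welch differential expression
#'
#' Two-sided Welch unequal-variance t-test on raw abundances per feature, with
#' Welch--Satterthwaite degrees of freedom, exactly the test applied to FPKM /
#' TPM tables in the source study design. Fold change is computed on group
#' means with a small pseudocount: `log2fc = log2((mean_test + pc) /
#' (mean_ref + pc))`, test group over reference. Significance is unadjusted
#' `p < alpha`; Benjamini-Hochberg values can be added in an extra column but
#' never drive the `significant` flag.
#'
#' Degenerate features where both group variances are zero are not errors:
#' equal means give t = 0, p = 1; unequal means have both variances floored at
#' machine epsilon and the feature is flagged in the `degenerate` column.
#'
#' @param mat expression-filtered [expression_matrix()].
#' @param sheet a `SampleSheet`; each group needs >= 2 non-excluded samples.
#' @param th a [thresholds()] object.
#' @param log_transform test on `log2(x + pseudocount)` instead of raw
#'   abundances (off by default, matching the direct test on FPKM/TPM).
#' @param adjust add a BH-adjusted `p_adj` column.
#' @return data.frame of class `welch_de` with one row per feature: columns
#'   `feature_id, mean_ref, mean_test, log2fc, t_stat, df, p_value,
#'   significant, direction, degenerate` (plus `p_adj` when requested).
#'   `direction` is `"up"` (higher in the test group), `"down"`, or `"none"`
#'   for non-significant features.
#' @export
welch_de <- function(mat, sheet, th = thresholds(), log_transform = FALSE,
                     adjust = FALSE) {
  stopifnot(inherits(mat, "ExpressionMatrix"), inherits(th, "Thresholds"))
  if (nrow(mat$values) == 0L)
    stop("matrix has no features (did the expression filter remove everything?)",
         call. = FALSE)
  test_mat <- mat
  if (log_transform)
    test_mat <- expression_matrix(log2(mat$values + th$pseudocount), unit = mat$unit)
  gs <- group_stats(test_mat, sheet)
  raw <- group_stats(mat, sheet)   # means for the fold change: always raw scale

  eps <- .Machine$double.eps
  degenerate <- gs$var_ref == 0 & gs$var_test == 0
  v1 <- gs$var_ref; v2 <- gs$var_test
  flo <- degenerate & (gs$mean_ref != gs$mean_test)
  v1[flo] <- eps; v2[flo] <- eps

  se2 <- v1 / gs$n_ref + v2 / gs$n_test
  t_stat <- (gs$mean_test - gs$mean_ref) / sqrt(se2)
  df <- se2^2 / ((v1 / gs$n_ref)^2 / (gs$n_ref - 1L) +
                 (v2 / gs$n_test)^2 / (gs$n_test - 1L))
  # both variances zero, equal means: define t = 0, p = 1
  null_feat <- degenerate & !flo
  t_stat[null_feat] <- 0
  df[null_feat] <- gs$n_ref + gs$n_test - 2L
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  p[null_feat] <- 1

  lfc <- log2((raw$mean_test + th$pseudocount) / (raw$mean_ref + th$pseudocount))
  significant <- p < th$alpha
  direction <- ifelse(!significant, "none", ifelse(lfc > 0, "up", "down"))

  out <- data.frame(feature_id = mat$feature_ids,
                    mean_ref = raw$mean_ref, mean_test = raw$mean_test,
                    log2fc = lfc, t_stat = t_stat, df = df, p_value = p,
                    significant = significant, direction = direction,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (adjust) out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  class(out) <- c("welch_de", "data.frame")
  out
}

#' @export
print.welch_de <- function(x, ...) {
  cat(sprintf("Welch differential expression: %d features, %d significant (%d up, %d down)\n",
              nrow(x), sum(x$significant),
              sum(x$direction == "up"), sum(x$direction == "down")))
  NextMethod()
}

#' Partition significant features by direction
#'
#' @param results a [welch_de()] result.
#' @return list with character vectors `up` and `down`; their lengths always
#'   sum to the number of significant features.
#' @export
classify_de <- function(results) {
  list(up = results$feature_id[results$significant & results$log2fc > 0],
       down = results$feature_id[results$significant & results$log2fc <= 0])
}

#' Collapse transcript-level results to genes
#'
#' One row per gene with at least one significant transcript. A gene's
#' direction is `"up"`/`"down"` when all its significant transcripts agree in
#' sign and `"discordant"` otherwise; `best_p` is the minimum transcript p and
#' `max_abs_log2fc` the signed log2FC of largest magnitude, both over the
#' significant transcripts only.
#'
#' @param results transcript-level [welch_de()] result.
#' @param annotation data.frame with columns `transcript_id`, `gene_symbol`
#'   (see [read_annotation()]); every significant transcript must be
#'   annotated.
#' @return data.frame of class `deg_sets` with columns `gene_symbol`,
#'   `direction`, `best_p`, `max_abs_log2fc`, `n_transcripts`.
#' @export
collapse_to_genes <- function(results, annotation) {
  sig <- results[results$significant, , drop = FALSE]
  idx <- match(sig$feature_id, annotation$transcript_id)
  if (anyNA(idx))
    stop("significant transcripts without annotation: ",
         paste(sig$feature_id[is.na(idx)], collapse = ", "), call. = FALSE)
  sig$gene_symbol <- annotation$gene_symbol[idx]
  if (nrow(sig) == 0L) {
    out <- data.frame(gene_symbol = character(), direction = character(),
                      best_p = numeric(), max_abs_log2fc = numeric(),
                      n_transcripts = integer(), stringsAsFactors = FALSE)
    class(out) <- c("deg_sets", "data.frame")
    return(out)
  }
  rows <- lapply(split(sig, sig$gene_symbol), function(g) {
    signs <- unique(sign(g$log2fc))
    dir <- if (length(signs) > 1L) "discordant" else if (signs > 0) "up" else "down"
    i <- which.max(abs(g$log2fc))
    data.frame(gene_symbol = g$gene_symbol[1], direction = dir,
               best_p = min(g$p_value), max_abs_log2fc = g$log2fc[i],
               n_transcripts = nrow(g), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out <- out[order(out$gene_symbol), , drop = FALSE]
  class(out) <- c("deg_sets", "data.frame")
  out
}

#' Flag candidate outlier samples by median inter-sample correlation
#'
#' Computes the Spearman correlation between all sample pairs and flags every
#' sample whose median correlation to the others falls below the threshold.
#' Flags are advisory: exclusion happens only through the sample sheet, which
#' keeps the analysis record explicit and reproducible.
#'
#' @param mat an [expression_matrix()] with >= 3 samples.
#' @param min_median_corr flag threshold (default 0.8).
#' @return character vector of flagged sample ids (possibly empty).
#' @export
flag_outlier_samples <- function(mat, min_median_corr = 0.8) {
  stopifnot(inherits(mat, "ExpressionMatrix"))
  if (ncol(mat$values) < 3L) stop("need >= 3 samples", call. = FALSE)
  cc <- stats::cor(mat$values, method = "spearman")
  med <- vapply(seq_len(ncol(cc)),
                function(i) stats::median(cc[-i, i]), numeric(1))
  mat$sample_ids[med < min_median_corr]
}
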