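#' Select tissue-exclusive miRNAs
#'
#' A miRNA counts as "exclusively expressed" in one tissue when it is
#' significant and its |log2FC| reaches the exclusivity cut (default 2, i.e.
#' a 4-fold difference): iWAT-exclusive means log2fc <= -cut (higher in the
#' reference tissue), pancreas-exclusive means log2fc >= +cut. Exclusivity is
#' a reporting overlay; the direction-consistency filter itself uses all
#' significant miRNAs.
#'
#' @param results miRNA-level [welch_de()] result.
#' @param th a [thresholds()] object (`exclusive_lfc` is used).
#' @return list with character vectors `iwat_exclusive` and `panc_exclusive`.
#' @export
select_exclusive_mirnas <- function(results, th = thresholds()) {
  sig <- results$significant
  list(iwat_exclusive = results$feature_id[sig & results$log2fc <= -th$exclusive_lfc],
       panc_exclusive = results$feature_id[sig & results$log2fc >= th$exclusive_lfc])
}

#' Map significant miRNAs to targets and apply the direction-consistency filter
#'
#' Joins every significant miRNA to its experimentally validated target genes
#' and keeps a pair only when the fold changes are anti-correlated — miRNA up
#' with target gene down, or miRNA down with target gene up — reflecting the
#' repressive mode of miRNA action. Genes whose gene-level direction is
#' discordant (significant transcripts of both signs) are never matched, since
#' the direction rule is undefined for them. Pairs whose gene |log2FC| exceeds
#' the highlight cut (default 1.5) are flagged `strong`.
#'
#' @param mirna_results miRNA-level [welch_de()] result.
#' @param deg_sets gene-level [collapse_to_genes()] result.
#' @param interactions interaction table from [read_interaction_table()].
#' @param th a [thresholds()] object (`highlight_lfc` is used).
#' @return data.frame of class `consistent_pairs`: `mirna_id, mirna_log2fc,
#'   gene_symbol, gene_log2fc, strong, sources`.
#' @export
map_and_filter_targets <- function(mirna_results, deg_sets, interactions,
                                   th = thresholds()) {
  empty <- data.frame(mirna_id = character(), mirna_log2fc = numeric(),
                      gene_symbol = character(), gene_log2fc = numeric(),
                      strong = logical(), sources = character(),
                      stringsAsFactors = FALSE)
  class(empty) <- c("consistent_pairs", "data.frame")
  if (nrow(interactions) == 0L) {
    warning("empty interaction table; no pairs can be formed")
    return(empty)
  }
  sig_mir <- mirna_results[mirna_results$significant, , drop = FALSE]
  genes <- deg_sets[deg_sets$direction %in% c("up", "down"), , drop = FALSE]
  j <- interactions[interactions$mirna_id %in% sig_mir$feature_id &
                    interactions$gene_symbol %in% genes$gene_symbol, , drop = FALSE]
  if (nrow(j) == 0L) return(empty)
  m_lfc <- sig_mir$log2fc[match(j$mirna_id, sig_mir$feature_id)]
  g_lfc <- genes$max_abs_log2fc[match(j$gene_symbol, genes$gene_symbol)]
  keep <- sign(m_lfc) * sign(g_lfc) == -1
  out <- data.frame(mirna_id = j$mirna_id[keep], mirna_log2fc = m_lfc[keep],
                    gene_symbol = j$gene_symbol[keep], gene_log2fc = g_lfc[keep],
                    strong = abs(g_lfc[keep]) > th$highlight_lfc,
                    sources = j$sources[keep], stringsAsFactors = FALSE)
  out <- out[order(out$mirna_id, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("consistent_pairs", "data.frame")
  out
}

#' Summarize the miRNA-explained share of the transcriptome differences
#'
#' @param pairs a [map_and_filter_targets()] result.
#' @param deg_sets gene-level [collapse_to_genes()] result; must be non-empty.
#' @return list of class `integration_summary`: `n_de_mirnas_with_targets`,
#'   `n_regulated_genes` (distinct genes across consistent pairs), and
#'   `fraction_degs_explained` = regulated genes / total DEGs.
#' @export
summarize_integration <- function(pairs, deg_sets) {
  if (nrow(deg_sets) == 0L)
    stop("no DEGs: fraction of explained DEGs is undefined", call. = FALSE)
  out <- list(n_de_mirnas_with_targets = length(unique(pairs$mirna_id)),
              n_regulated_genes = length(unique(pairs$gene_symbol)),
              fraction_degs_explained =
                length(unique(pairs$gene_symbol)) / nrow(deg_sets))
  class(out) <- "integration_summary"
  out
}

#' @export
print.integration_summary <- function(x, ...) {
  cat(sprintf("%d DE miRNAs putatively regulating %d genes (%.1f%% of DEGs)\n",
              x$n_de_mirnas_with_targets, x$n_regulated_genes,
              100 * x$fraction_degs_explained))
  invisible(x)
}
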