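#' Partition DEGs by predicted-secreted status and direction
#'
#' Intersects the DEG list with a predicted-secretome gene list (an HPA-style
#' export supplied by the user) and splits the overlap by direction: genes
#' higher in the test tissue (pancreas), genes higher in the reference tissue
#' (iWAT), and direction-discordant genes counted separately. The three parts
#' always sum to |DEGs intersect secreted|.
#'
#' @param deg_sets gene-level [collapse_to_genes()] result.
#' @param secreted character vector of secreted-protein gene symbols.
#' @return list of class `secretome_partition`: `secreted_up_test`,
#'   `secreted_up_ref`, `secreted_discordant` (character vectors) and
#'   `n_secreted_total`.
#' @export
annotate_secretome <- function(deg_sets, secreted) {
  secreted <- unique(as.character(secreted))
  if (length(secreted) == 0L)
    warning("empty secreted gene list; partition is empty")
  hit <- deg_sets[deg_sets$gene_symbol %in% secreted, , drop = FALSE]
  out <- list(
    secreted_up_test = sort(hit$gene_symbol[hit$direction == "up"]),
    secreted_up_ref = sort(hit$gene_symbol[hit$direction == "down"]),
    secreted_discordant = sort(hit$gene_symbol[hit$direction == "discordant"])
  )
  out$n_secreted_total <- length(out$secreted_up_test) +
    length(out$secreted_up_ref) + length(out$secreted_discordant)
  class(out) <- "secretome_partition"
  out
}

#' @export
print.secretome_partition <- function(x, ...) {
  cat(sprintf("Secreted DEGs: %d total (%d higher in test, %d higher in reference, %d discordant)\n",
              x$n_secreted_total, length(x$secreted_up_test),
              length(x$secreted_up_ref), length(x$secreted_discordant)))
  invisible(x)
}

#' Top secreted candidates per tissue
#'
#' Ranks each side of a secretome partition by the magnitude of the gene's
#' strongest transcript log2 fold change (descending); equal fold changes are
#' broken lexicographically by gene symbol so the ranking is deterministic.
#' The ranking key is |log2FC| — a documented interpretation, as effect size
#' is the natural prominence measure for candidate secreted signals.
#'
#' @param partition an [annotate_secretome()] result.
#' @param deg_sets gene-level [collapse_to_genes()] result.
#' @param k list length per side (default 10); a shorter side is returned
#'   whole.
#' @return list with data.frames `top_test` and `top_ref`, each with columns
#'   `rank, gene_symbol, log2fc, best_p`.
#' @export
top_secreted <- function(partition, deg_sets, k = 10) {
  rank_side <- function(genes) {
    d <- deg_sets[match(genes, deg_sets$gene_symbol), , drop = FALSE]
    ord <- order(-abs(d$max_abs_log2fc), d$gene_symbol)
    d <- d[ord[seq_len(min(k, nrow(d)))], , drop = FALSE]
    data.frame(rank = seq_len(nrow(d)), gene_symbol = d$gene_symbol,
               log2fc = d$max_abs_log2fc, best_p = d$best_p,
               stringsAsFactors = FALSE, row.names = NULL)
  }
  list(top_test = rank_side(partition$secreted_up_test),
       top_ref = rank_side(partition$secreted_up_ref))
}
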