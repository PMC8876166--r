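#' Relative qPCR expression by the 2^(-DeltaCt) method
#'
#' `2^-(ct_gene - ct_ref)`: expression of a gene relative to a reference gene
#' (internal control, e.g. Eef2) measured in the same sample. Exact
#' identities: equal cycle thresholds give 1; each cycle the gene crosses the
#' threshold earlier doubles the value.
#'
#' @param ct_gene cycle threshold(s) of the gene of interest.
#' @param ct_ref cycle threshold(s) of the reference gene.
#' @return relative expression (dimensionless), vectorized.
#' @export
relative_expression <- function(ct_gene, ct_ref) {
  if (anyNA(ct_gene) || anyNA(ct_ref))
    stop("missing Ct values", call. = FALSE)
  2^(-(ct_gene - ct_ref))
}

#' Relative expression table from per-sample Ct records
#'
#' Pairs every (sample, gene) Ct with the same sample's reference-gene Ct and
#' computes 2^(-DeltaCt). Group summaries (when a sample sheet is given) are
#' reported both ways: the geometric mean (arithmetic mean of DeltaCt, then
#' transformed — the natural summary on the method's log scale) and the
#' arithmetic mean of the relative expressions.
#'
#' @param ct data.frame with columns `sample_id`, `gene`, `ct`.
#' @param reference_gene internal-control gene (default `"Eef2"`); every
#'   sample must carry a Ct for it.
#' @param sheet optional `SampleSheet` for group summaries.
#' @return list with `per_sample` (sample_id, gene, delta_ct, rel_expr) and,
#'   when a sheet is supplied, `summary` (gene, group, geo_mean, arith_mean,
#'   n).
#' @export
relative_expression_table <- function(ct, reference_gene = "Eef2", sheet = NULL) {
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("Ct table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (any(!is.finite(ct$ct)) || any(ct$ct <= 0))
    stop("Ct values must be finite and positive", call. = FALSE)
  ref <- ct[ct$gene == reference_gene, , drop = FALSE]
  tgt <- ct[ct$gene != reference_gene, , drop = FALSE]
  ref_ct <- ref$ct[match(tgt$sample_id, ref$sample_id)]
  if (anyNA(ref_ct))
    stop("missing reference gene '", reference_gene, "' Ct for sample(s): ",
         paste(unique(tgt$sample_id[is.na(ref_ct)]), collapse = ", "), call. = FALSE)
  per <- data.frame(sample_id = tgt$sample_id, gene = tgt$gene,
                    delta_ct = tgt$ct - ref_ct,
                    rel_expr = relative_expression(tgt$ct, ref_ct),
                    stringsAsFactors = FALSE)
  out <- list(per_sample = per)
  if (!is.null(sheet)) {
    per$group <- sheet$group[match(per$sample_id, sheet$sample_id)]
    if (anyNA(per$group))
      stop("samples in Ct table absent from sample sheet", call. = FALSE)
    agg <- lapply(split(per, list(per$gene, per$group), drop = TRUE), function(g)
      data.frame(gene = g$gene[1], group = g$group[1],
                 geo_mean = 2^(-mean(g$delta_ct)),
                 arith_mean = mean(g$rel_expr), n = nrow(g),
                 stringsAsFactors = FALSE))
    smry <- do.call(rbind, agg)
    rownames(smry) <- NULL
    out$summary <- smry[order(smry$gene, smry$group), , drop = FALSE]
  }
  out
}
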