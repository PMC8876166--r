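#' Pipeline run configuration
#'
#' One document that fully determines a pipeline run: either a simulation
#' config (synthetic mode) or paths to the input tables (ingest mode), plus
#' thresholds, group labels, sample exclusions and the output directory.
#' Stage outputs are pure functions of this configuration, so reruns are
#' byte-identical.
#'
#' @param out_dir output directory.
#' @param simulate a [simulation_config()] for synthetic mode, or `NULL`.
#' @param transcripts,mirnas,sample_sheet,annotation,interactions,gene_sets
#'   input file paths (ingest mode; `interactions` may be several paths).
#' @param secreted,markers,ct_table optional input file paths.
#' @param th a [thresholds()] object.
#' @param ref_group,test_group group labels (reference / test).
#' @param excluded_samples sample ids to exclude on top of the sheet's
#'   `excluded` column.
#' @param reference_gene qPCR internal control.
#' @return list of class `RunConfig`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, transcripts = NULL,
                            mirnas = NULL, sample_sheet = NULL,
                            annotation = NULL, interactions = NULL,
                            gene_sets = NULL, secreted = NULL, markers = NULL,
                            ct_table = NULL, th = thresholds(),
                            ref_group = "iWAT", test_group = "PANC",
                            excluded_samples = character(),
                            reference_gene = "Eef2") {
  cfg <- as.list(environment())
  if (is.null(simulate)) {
    need <- c("transcripts", "mirnas", "sample_sheet", "annotation",
              "interactions", "gene_sets")
    for (f in need) {
      if (is.null(cfg[[f]]))
        stop("ingest mode needs input '", f, "' (or set 'simulate')", call. = FALSE)
      missing <- cfg[[f]][!file.exists(cfg[[f]])]
      if (length(missing))
        stop("input file(s) not found for '", f, "': ",
             paste(missing, collapse = ", "), call. = FALSE)
    }
    for (f in c("secreted", "markers", "ct_table"))
      if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
        stop("input file not found for '", f, "': ", cfg[[f]], call. = FALSE)
  } else stopifnot(inherits(simulate, "SimulationConfig"))
  stopifnot(inherits(th, "Thresholds"))
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; `thresholds:`
#' and `simulate:` sub-maps override the defaults of [thresholds()] and
#' [simulation_config()] field-wise.
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a `RunConfig`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  th <- do.call(thresholds, if (is.null(y$thresholds)) list() else y$thresholds)
  sim <- if (is.null(y$simulate)) NULL else do.call(simulation_config, y$simulate)
  args <- y[setdiff(names(y), c("thresholds", "simulate"))]
  args$th <- th
  args$simulate <- sim
  if (!is.null(out_dir)) args$out_dir <- out_dir
  do.call(pipeline_config, args)
}

# Aggregate a transcript-level matrix to genes (sum of transcript abundances).
gene_level_matrix <- function(mat, annotation) {
  idx <- match(mat$feature_ids, annotation$transcript_id)
  if (anyNA(idx))
    stop("transcripts without annotation: ",
         paste(mat$feature_ids[is.na(idx)][1:min(5, sum(is.na(idx)))],
               collapse = ", "), call. = FALSE)
  g <- rowsum(mat$values, annotation$gene_symbol[idx])
  expression_matrix(g[order(rownames(g)), , drop = FALSE], unit = mat$unit)
}

#' Run the full integrative pipeline
#'
#' Executes every stage in order — simulate/ingest, expression filtering,
#' outlier flagging (advisory), Welch differential expression on both layers,
#' transcript-to-gene collapsing, exclusive-miRNA selection, direction-
#' consistent target mapping, gated enrichment of DEGs and of per-side miRNA
#' targets, secretome partitioning, marker-overlap Fisher testing and (when a
#' Ct table is present) qPCR relative expression — writing every intermediate
#' TSV, a headline summary and a machine-readable JSON manifest with input
#' checksums into `config$out_dir`.
#'
#' @param config a [pipeline_config()] or path to a YAML run configuration.
#' @return object of class `msc_pipeline` holding all stage results, the
#'   summary counts and the manifest. Any stage error aborts with the stage
#'   name.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "RunConfig"))
  th <- config$th
  out_dir <- config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  # -- stage: inputs ----------------------------------------------------------
  input_files <- character(0)
  if (!is.null(config$simulate)) {
    dat <- stage("simulate", {
      sim <- simulate_dataset(config$simulate)
      in_dir <- file.path(out_dir, "inputs")
      write_dataset(sim, in_dir)
      input_files <- list.files(in_dir, full.names = TRUE)
      list(transcripts = sim$transcripts, mirnas = sim$mirnas,
           annotation = sim$annotation, interactions = sim$interactions,
           gene_sets = sim$gene_sets, secreted = sim$secreted,
           markers = sim$markers, sheet = sim$sheet, ct = NULL,
           files = input_files, truth = sim$truth)
    })
  } else {
    dat <- stage("ingest", {
      files <- unlist(config[c("transcripts", "mirnas", "sample_sheet",
                               "annotation", "interactions", "gene_sets",
                               "secreted", "markers", "ct_table")])
      list(transcripts = read_expression_table(config$transcripts, "FPKM"),
           mirnas = read_expression_table(config$mirnas, "TPM"),
           annotation = read_annotation(config$annotation),
           interactions = read_interaction_table(config$interactions),
           gene_sets = read_gmt(config$gene_sets),
           secreted = if (is.null(config$secreted)) NULL
                      else read_gene_list(config$secreted),
           markers = if (is.null(config$markers)) NULL
                     else read_gene_list(config$markers),
           sheet = read_sample_sheet(config$sample_sheet,
                                     ref_group = config$ref_group,
                                     test_group = config$test_group),
           ct = if (is.null(config$ct_table))
             NULL else utils::read.table(config$ct_table, header = TRUE,
                                         sep = "\t", stringsAsFactors = FALSE),
           files = files, truth = NULL)
    })
  }
  sheet <- dat$sheet
  if (length(config$excluded_samples))
    sheet$excluded <- sheet$excluded | sheet$sample_id %in% config$excluded_samples

  # -- stage: filter ----------------------------------------------------------
  tx_f <- stage("filter", filter_low_expression(dat$transcripts, th$expr_floor, sheet))
  mi_f <- stage("filter", filter_low_expression(dat$mirnas, th$expr_floor, sheet))
  outliers <- stage("outlier_flags", list(
    transcripts = flag_outlier_samples(tx_f),
    mirnas = flag_outlier_samples(mi_f)))

  # -- stage: differential expression -----------------------------------------
  de_tx <- stage("de_transcripts", welch_de(tx_f, sheet, th))
  de_mi <- stage("de_mirnas", welch_de(mi_f, sheet, th))
  tx_classes <- classify_de(de_tx)
  mi_classes <- classify_de(de_mi)
  degs <- stage("collapse", collapse_to_genes(de_tx, dat$annotation))

  # -- stage: integration ------------------------------------------------------
  exclusive <- select_exclusive_mirnas(de_mi, th)
  pairs <- stage("integrate",
                 map_and_filter_targets(de_mi, degs, dat$interactions, th))
  integration <- if (nrow(degs)) summarize_integration(pairs, degs) else NULL

  # -- stage: enrichment -------------------------------------------------------
  expressed_genes <- sort(unique(dat$annotation$gene_symbol[
    dat$annotation$transcript_id %in% tx_f$feature_ids]))
  dirs <- stats::setNames(degs$direction, degs$gene_symbol)
  dirs <- dirs[dirs %in% c("up", "down")]
  deg_query <- intersect(degs$gene_symbol, expressed_genes)
  enr_deg <- stage("enrich_degs",
                   hypergeom_enrich(deg_query, dat$gene_sets, expressed_genes,
                                    directions = dirs, th = th,
                                    min_count = th$min_count_deg))
  enrich_side <- function(m_sign) {
    g <- unique(pairs$gene_symbol[sign(pairs$mirna_log2fc) == m_sign])
    hypergeom_enrich(intersect(g, expressed_genes), dat$gene_sets,
                     expressed_genes, directions = dirs, th = th,
                     min_count = th$min_count_target)
  }
  enr_targets <- stage("enrich_targets",
                       list(panc_mirnas = enrich_side(+1),
                            iwat_mirnas = enrich_side(-1)))

  # -- stage: secretome --------------------------------------------------------
  secretome <- top10 <- NULL
  if (!is.null(dat$secreted)) {
    secretome <- stage("secretome", annotate_secretome(degs, dat$secreted))
    top10 <- stage("secretome", top_secreted(secretome, degs, k = 10))
  }

  # -- stage: marker overlap ---------------------------------------------------
  marker_res <- NULL
  if (!is.null(dat$markers)) {
    gmat <- stage("marker_overlap", gene_level_matrix(tx_f, dat$annotation))
    topn <- min(th$top_n_expressed, nrow(gmat$values) - 1L)
    marker_res <- stage("marker_overlap",
                        marker_overlap_fisher(gmat, dat$markers, top_n = topn))
  }

  # -- stage: qPCR -------------------------------------------------------------
  qpcr_res <- if (!is.null(dat$ct))
    stage("qpcr", relative_expression_table(dat$ct, config$reference_gene, sheet))
  else NULL

  # -- stage: report -----------------------------------------------------------
  summary_counts <- list(
    transcripts_tested = nrow(de_tx),
    de_transcripts = sum(de_tx$significant),
    de_transcripts_up = length(tx_classes$up),
    de_transcripts_down = length(tx_classes$down),
    degs = nrow(degs),
    degs_up = sum(degs$direction == "up"),
    degs_down = sum(degs$direction == "down"),
    degs_discordant = sum(degs$direction == "discordant"),
    mirnas_tested = nrow(de_mi),
    de_mirnas = sum(de_mi$significant),
    de_mirnas_up = length(mi_classes$up),
    de_mirnas_down = length(mi_classes$down),
    exclusive_iwat = length(exclusive$iwat_exclusive),
    exclusive_panc = length(exclusive$panc_exclusive),
    consistent_pairs = nrow(pairs),
    mirnas_with_targets = if (is.null(integration)) 0L
                          else integration$n_de_mirnas_with_targets,
    regulated_genes = if (is.null(integration)) 0L
                      else integration$n_regulated_genes,
    fraction_degs_explained = if (is.null(integration)) NA_real_
                              else integration$fraction_degs_explained,
    enrichment_passing_deg = sum(enr_deg$passes),
    enrichment_passing_targets = sum(enr_targets$panc_mirnas$passes) +
      sum(enr_targets$iwat_mirnas$passes),
    secreted_total = if (is.null(secretome)) NA_integer_ else secretome$n_secreted_total,
    secreted_up_test = if (is.null(secretome)) NA_integer_
                       else length(secretome$secreted_up_test),
    secreted_up_ref = if (is.null(secretome)) NA_integer_
                      else length(secretome$secreted_up_ref),
    marker_odds_ratio = if (is.null(marker_res)) NA_real_ else marker_res$odds_ratio,
    marker_p = if (is.null(marker_res)) NA_real_ else marker_res$p_value)

  stage("report", {
    pv <- c(alpha = th$alpha, expr_floor = th$expr_floor,
            pseudocount = th$pseudocount)
    write_result_tsv(as.data.frame(de_tx), file.path(out_dir, "de_transcripts.tsv"), pv)
    write_result_tsv(as.data.frame(de_mi), file.path(out_dir, "de_mirnas.tsv"), pv)
    write_result_tsv(as.data.frame(degs), file.path(out_dir, "degs.tsv"), pv)
    write_result_tsv(as.data.frame(pairs), file.path(out_dir, "consistent_pairs.tsv"),
                     c(highlight_lfc = th$highlight_lfc))
    write_result_tsv(as.data.frame(enr_deg), file.path(out_dir, "enrichment_degs.tsv"),
                     c(min_count = th$min_count_deg, min_fe = th$min_fold_enrichment))
    write_result_tsv(as.data.frame(enr_targets$panc_mirnas),
                     file.path(out_dir, "enrichment_targets_panc.tsv"),
                     c(min_count = th$min_count_target))
    write_result_tsv(as.data.frame(enr_targets$iwat_mirnas),
                     file.path(out_dir, "enrichment_targets_iwat.tsv"),
                     c(min_count = th$min_count_target))
    if (!is.null(secretome)) {
      part <- data.frame(
        gene_symbol = c(secretome$secreted_up_test, secretome$secreted_up_ref,
                        secretome$secreted_discordant),
        side = rep(c("up_test", "up_ref", "discordant"),
                   c(length(secretome$secreted_up_test),
                     length(secretome$secreted_up_ref),
                     length(secretome$secreted_discordant))))
      write_result_tsv(part, file.path(out_dir, "secretome_partition.tsv"))
      write_result_tsv(top10$top_test, file.path(out_dir, "top_secreted_test.tsv"))
      write_result_tsv(top10$top_ref, file.path(out_dir, "top_secreted_ref.tsv"))
    }
    if (!is.null(marker_res))
      write_result_tsv(data.frame(a = marker_res$a, b = marker_res$b,
                                  c = marker_res$c, d = marker_res$d,
                                  odds_ratio = marker_res$odds_ratio,
                                  p_value = marker_res$p_value),
                       file.path(out_dir, "marker_overlap.tsv"))
    if (!is.null(qpcr_res)) {
      write_result_tsv(qpcr_res$per_sample, file.path(out_dir, "qpcr_relative.tsv"))
      if (!is.null(qpcr_res$summary))
        write_result_tsv(qpcr_res$summary, file.path(out_dir, "qpcr_summary.tsv"))
    }
    smry <- data.frame(metric = names(summary_counts),
                       value = vapply(summary_counts, function(v)
                         format(v, digits = 15), character(1)))
    write_result_tsv(smry, file.path(out_dir, "summary.tsv"))
  })

  outputs <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                          c("manifest.json")))
  manifest <- list(
    package = "mscmir", version = pkg_version(),
    mode = if (is.null(config$simulate)) "ingest" else "simulate",
    seed = if (is.null(config$simulate)) NA_integer_ else config$simulate$seed,
    thresholds = unclass(th),
    excluded_samples = config$excluded_samples,
    outlier_flags = outliers,
    input_checksums = {
      f <- sort(unname(dat$files))
      cs <- as.list(unname(tools::md5sum(f)))
      # keys relative to the run directory so reruns compare byte-identical
      stats::setNames(cs, basename(f))
    },
    outputs = outputs,
    summary = summary_counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")

  structure(list(config = config, sheet = sheet, de_transcripts = de_tx,
                 de_mirnas = de_mi, degs = degs, exclusive = exclusive,
                 pairs = pairs, integration = integration,
                 enrichment_degs = enr_deg, enrichment_targets = enr_targets,
                 secretome = secretome, top_secreted = top10,
                 marker_overlap = marker_res, qpcr = qpcr_res,
                 outlier_flags = outliers, truth = dat$truth,
                 summary = summary_counts, manifest = manifest),
            class = "msc_pipeline")
}

#' @export
print.msc_pipeline <- function(x, ...) {
  s <- x$summary
  cat("Integrative transcriptome/miRNome pipeline run\n")
  cat(sprintf("  transcripts: %d tested, %d DE (%d up / %d down) -> %d DEGs (%d up / %d down / %d discordant)\n",
              s$transcripts_tested, s$de_transcripts, s$de_transcripts_up,
              s$de_transcripts_down, s$degs, s$degs_up, s$degs_down,
              s$degs_discordant))
  cat(sprintf("  miRNAs: %d tested, %d DE (%d up / %d down); exclusive iWAT %d / PANC %d\n",
              s$mirnas_tested, s$de_mirnas, s$de_mirnas_up, s$de_mirnas_down,
              s$exclusive_iwat, s$exclusive_panc))
  cat(sprintf("  integration: %d consistent pairs, %d miRNAs regulating %d genes (%.1f%% of DEGs)\n",
              s$consistent_pairs, s$mirnas_with_targets, s$regulated_genes,
              100 * s$fraction_degs_explained))
  cat(sprintf("  enrichment: %d DEG terms / %d target terms pass gates\n",
              s$enrichment_passing_deg, s$enrichment_passing_targets))
  if (!is.na(s$secreted_total))
    cat(sprintf("  secretome: %d secreted DEGs (%d test / %d ref)\n",
                s$secreted_total, s$secreted_up_test, s$secreted_up_ref))
  if (!is.na(s$marker_odds_ratio))
    cat(sprintf("  marker overlap: OR %.3g, p = %.3g\n",
                s$marker_odds_ratio, s$marker_p))
  invisible(x)
}

#' @export
summary.msc_pipeline <- function(object, ...) object$summary
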