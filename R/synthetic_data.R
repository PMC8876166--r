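#' Simulation configuration
#'
#' Parameters of the coupled transcriptome/miRNome simulator. Defaults emulate
#' the study conditions: 8 samples per group, log-normal baseline abundances
#' (log2 baseline ~ N(3, 2)) with 30% multiplicative noise, 20% of genes and
#' 10% of miRNAs truly differentially expressed with effect magnitudes
#' |delta| ~ 1 + Exp(1) on the log2 scale, and 40% of the DE genes driven by a
#' DE miRNA through a repressive edge (gene effect opposite in sign,
#' magnitude ~ 0.75x the miRNA's). Each miRNA also receives decoy edges to
#' non-DE genes so the direction-consistency filter has something to reject.
#'
#' @param n_per_group samples per group (>= 2).
#' @param n_transcripts total transcript count.
#' @param n_mirnas total miRNA count.
#' @param max_transcripts_per_gene transcripts per gene drawn uniformly from
#'   1..this (default 2).
#' @param frac_de_genes fraction of genes truly DE.
#' @param frac_de_mirnas fraction of miRNAs truly DE.
#' @param effect_size_log2_min minimum |log2 effect|; magnitudes are this plus
#'   an Exponential(mean `effect_size_log2_mean_excess`) draw.
#' @param effect_size_log2_mean_excess mean of the exponential excess.
#' @param coupling_fraction fraction of DE genes driven by a DE miRNA.
#' @param repression_slope gene |effect| = slope * miRNA |effect| + noise.
#' @param coupling_noise_sd sd of the magnitude noise on coupled effects.
#' @param decoy_edges_per_mirna decoy targets (non-DE genes) per miRNA.
#' @param max_targets_per_mirna capacity bound per DE miRNA for true edges.
#' @param noise_cv per-sample multiplicative log-normal noise CV.
#' @param baseline_log2_mean,baseline_log2_sd log2-baseline distribution.
#' @param frac_secreted fraction of genes labelled secreted.
#' @param frac_markers fraction of genes put on the marker list (sampling
#'   biased toward high-baseline genes so marker overlap is informative).
#' @param n_terms number of gene-set terms; the first `n_enriched_terms`
#'   over-sample true DE genes, the rest are null terms.
#' @param n_enriched_terms number of truly enriched terms.
#' @param term_size_range min/max members per term.
#' @param discordant_fraction fraction of multi-transcript DE genes given one
#'   sign-flipped transcript, to exercise the discordant path (default 0).
#' @param seed integer seed; a fixed seed makes every output byte-identical.
#' @return list of class `SimulationConfig`.
#' @export
simulation_config <- function(n_per_group = 8, n_transcripts = 3000,
                              n_mirnas = 600, max_transcripts_per_gene = 2,
                              frac_de_genes = 0.2, frac_de_mirnas = 0.1,
                              effect_size_log2_min = 1,
                              effect_size_log2_mean_excess = 1,
                              coupling_fraction = 0.4, repression_slope = 0.75,
                              coupling_noise_sd = 0.1,
                              decoy_edges_per_mirna = 5,
                              max_targets_per_mirna = 20,
                              noise_cv = 0.3, baseline_log2_mean = 3,
                              baseline_log2_sd = 2, frac_secreted = 0.12,
                              frac_markers = 0.05,
                              n_terms = 50, n_enriched_terms = 5,
                              term_size_range = c(10, 50),
                              discordant_fraction = 0, seed = 1L) {
  cfg <- as.list(environment())
  for (f in c("frac_de_genes", "frac_de_mirnas", "coupling_fraction",
              "frac_secreted", "frac_markers", "discordant_fraction"))
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop("'", f, "' must be in [0, 1]", call. = FALSE)
  if (n_per_group < 2) stop("'n_per_group' must be >= 2", call. = FALSE)
  if (repression_slope <= 0) stop("'repression_slope' must be > 0", call. = FALSE)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "SimulationConfig"
  cfg
}

# Multiplicative log-normal noise with mean 1 and coefficient of variation cv.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -sigma2 / 2, sqrt(sigma2)))
}

# Signed effect magnitudes: |delta| = min + Exp(mean), random sign.
draw_effects <- function(n, cfg) {
  if (n == 0L) return(numeric(0))
  mag <- cfg$effect_size_log2_min +
    stats::rexp(n, rate = 1 / cfg$effect_size_log2_mean_excess)
  mag * sample(c(-1, 1), n, replace = TRUE)
}

#' Simulate a coupled transcriptome/miRNome dataset with ground truth
#'
#' Draws per-feature log-normal baselines, applies group effects
#' multiplicatively (`2^delta`) to the test-group (pancreas) samples of DE
#' features, couples a fraction of DE genes to DE miRNAs through repressive
#' edges (the gene's sign is always opposite its driver's), adds per-sample
#' multiplicative noise, and emits every companion table the pipeline needs:
#' transcript-to-gene annotation, an interaction table of true plus decoy
#' edges, a gene-set collection in which designated terms over-sample true DE
#' genes, a secreted-gene list, a baseline-biased marker list, a sample sheet,
#' and the ground-truth record used as the acceptance surface.
#'
#' All randomness flows from `config$seed` through one stream in a fixed draw
#' order, so a fixed seed reproduces every output byte-for-byte.
#'
#' @param config a [simulation_config()].
#' @return list of class `SimulatedDataset` with elements `transcripts`
#'   (FPKM `ExpressionMatrix`), `mirnas` (TPM), `annotation`, `interactions`,
#'   `gene_sets`, `secreted`, `markers`, `sheet`, `truth`. `truth` carries
#'   `true_de_genes` / `true_de_mirnas` (named signed log2 effects),
#'   `true_edges` / `decoy_edges` (data.frames `mirna_id, gene_symbol`),
#'   `enriched_terms`, and `secreted_genes`.
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "SimulationConfig"))
  cfg <- config
  set.seed(cfg$seed)

  # --- gene / transcript scaffold ------------------------------------------
  tpg_pool <- sample(seq_len(cfg$max_transcripts_per_gene),
                     cfg$n_transcripts, replace = TRUE)
  n_genes <- which(cumsum(tpg_pool) >= cfg$n_transcripts)[1]
  tpg <- tpg_pool[seq_len(n_genes)]
  tpg[n_genes] <- tpg[n_genes] - (sum(tpg) - cfg$n_transcripts)
  if (tpg[n_genes] == 0L) { tpg <- tpg[-n_genes]; n_genes <- n_genes - 1L }
  genes <- sprintf("G%04d", seq_len(n_genes))
  annotation <- data.frame(
    transcript_id = unlist(lapply(seq_len(n_genes), function(i)
      sprintf("%s.T%d", genes[i], seq_len(tpg[i])))),
    gene_symbol = rep(genes, tpg), stringsAsFactors = FALSE)
  mirnas <- sprintf("miR-%04d", seq_len(cfg$n_mirnas))

  # --- true effects ---------------------------------------------------------
  n_de_genes <- floor(cfg$frac_de_genes * n_genes)
  n_de_mirnas <- floor(cfg$frac_de_mirnas * cfg$n_mirnas)
  de_genes <- sort(sample(genes, n_de_genes))
  de_mirnas <- sort(sample(mirnas, n_de_mirnas))
  mirna_eff <- stats::setNames(draw_effects(n_de_mirnas, cfg), de_mirnas)

  n_coupled <- round(cfg$coupling_fraction * n_de_genes)
  if (n_coupled > 0 && n_de_mirnas == 0)
    stop("infeasible config: coupled genes requested but no DE miRNAs", call. = FALSE)
  if (n_coupled > n_de_mirnas * cfg$max_targets_per_mirna)
    stop(sprintf(paste("infeasible config: %d coupled genes exceed miRNA capacity",
                       "%d DE miRNAs x %d targets"), n_coupled, n_de_mirnas,
                 cfg$max_targets_per_mirna), call. = FALSE)
  coupled_genes <- if (n_coupled > 0) sample(de_genes, n_coupled) else character(0)
  drivers <- if (n_coupled > 0) {
    base <- rep_len(de_mirnas, n_coupled)   # spread load, capacity respected
    sample(base)
  } else character(0)

  gene_eff <- stats::setNames(draw_effects(n_de_genes, cfg), de_genes)
  if (n_coupled > 0) {
    # repressive coupling: sign forced opposite the driver; magnitude
    # slope*|driver| + noise, floored so the sign never flips
    mag <- pmax(cfg$repression_slope * abs(mirna_eff[drivers]) +
                  stats::rnorm(n_coupled, 0, cfg$coupling_noise_sd), 0.25)
    gene_eff[coupled_genes] <- -sign(mirna_eff[drivers]) * mag
  }

  # --- interaction table: true edges + decoys to non-DE genes ---------------
  true_edges <- data.frame(mirna_id = drivers, gene_symbol = coupled_genes,
                           stringsAsFactors = FALSE)
  true_edges <- true_edges[order(true_edges$mirna_id, true_edges$gene_symbol), ,
                           drop = FALSE]
  rownames(true_edges) <- NULL
  non_de <- setdiff(genes, de_genes)
  decoy_list <- lapply(mirnas, function(m) {
    tg <- sample(non_de, min(cfg$decoy_edges_per_mirna, length(non_de)))
    data.frame(mirna_id = m, gene_symbol = tg, stringsAsFactors = FALSE)
  })
  decoy_edges <- do.call(rbind, decoy_list)
  decoy_edges <- decoy_edges[order(decoy_edges$mirna_id, decoy_edges$gene_symbol), ,
                             drop = FALSE]
  rownames(decoy_edges) <- NULL
  interactions <- rbind(
    data.frame(mirna_id = true_edges$mirna_id,
               gene_symbol = true_edges$gene_symbol,
               sources = rep("sim_true", nrow(true_edges)),
               evidence_type = rep("simulated", nrow(true_edges)),
               stringsAsFactors = FALSE),
    data.frame(mirna_id = decoy_edges$mirna_id,
               gene_symbol = decoy_edges$gene_symbol,
               sources = rep("sim_decoy", nrow(decoy_edges)),
               evidence_type = rep("simulated", nrow(decoy_edges)),
               stringsAsFactors = FALSE))
  interactions <- interactions[order(interactions$mirna_id,
                                     interactions$gene_symbol), , drop = FALSE]
  rownames(interactions) <- NULL

  # --- expression matrices --------------------------------------------------
  n <- cfg$n_per_group
  samples <- c(sprintf("iWAT_%02d", seq_len(n)), sprintf("PANC_%02d", seq_len(n)))
  grp <- rep(c("iWAT", "PANC"), each = n)
  sheet <- sample_sheet(samples, grp)

  tx_eff <- gene_eff[match(annotation$gene_symbol, names(gene_eff))]
  tx_eff[is.na(tx_eff)] <- 0
  # optional discordant transcripts: flip one transcript of multi-transcript
  # DE genes to exercise gene-level discordance
  if (cfg$discordant_fraction > 0) {
    multi <- intersect(de_genes, annotation$gene_symbol[duplicated(annotation$gene_symbol)])
    n_flip <- floor(cfg$discordant_fraction * length(multi))
    if (n_flip > 0) {
      flip_genes <- sample(multi, n_flip)
      for (g in flip_genes) {
        i <- which(annotation$gene_symbol == g)[1]
        tx_eff[i] <- -tx_eff[i]
      }
    }
  }

  make_matrix <- function(ids, eff, unit) {
    p <- length(ids)
    base <- 2^stats::rnorm(p, cfg$baseline_log2_mean, cfg$baseline_log2_sd)
    noise <- matrix(lognormal_noise(p * 2L * n, cfg$noise_cv), nrow = p)
    m <- base * noise
    m[, grp == "PANC"] <- m[, grp == "PANC"] * 2^eff
    dimnames(m) <- list(ids, samples)
    list(mat = expression_matrix(m, unit = unit), baseline = stats::setNames(base, ids))
  }
  tx <- make_matrix(annotation$transcript_id, tx_eff, "FPKM")
  mir_eff_full <- mirna_eff[match(mirnas, names(mirna_eff))]
  mir_eff_full[is.na(mir_eff_full)] <- 0
  mi <- make_matrix(mirnas, mir_eff_full, "TPM")

  # --- gene sets: enriched terms over-sample true DE genes ------------------
  sizes <- sample(seq(cfg$term_size_range[1], cfg$term_size_range[2]),
                  cfg$n_terms, replace = TRUE)
  n_enr <- min(cfg$n_enriched_terms, cfg$n_terms)
  gene_sets <- stats::setNames(vector("list", cfg$n_terms),
                               sprintf("TERM%03d", seq_len(cfg$n_terms)))
  for (i in seq_len(cfg$n_terms)) {
    if (i <= n_enr && n_de_genes > 0) {
      n_de_mem <- min(ceiling(0.6 * sizes[i]), n_de_genes)
      members <- c(sample(de_genes, n_de_mem),
                   sample(non_de, sizes[i] - n_de_mem))
    } else members <- sample(genes, sizes[i])
    gene_sets[[i]] <- structure(sort(unique(members)),
                                term_name = sprintf("synthetic process %03d", i))
  }
  class(gene_sets) <- "GeneSetCollection"

  # --- secreted genes and markers ------------------------------------------
  secreted <- sort(sample(genes, floor(cfg$frac_secreted * n_genes)))
  gene_base <- vapply(split(tx$baseline, annotation$gene_symbol), max, numeric(1))
  n_mark <- max(1L, floor(cfg$frac_markers * n_genes))
  markers <- sort(sample(genes, n_mark, prob = rank(gene_base[genes])^4))

  truth <- list(true_de_genes = gene_eff, true_de_mirnas = mirna_eff,
                true_edges = true_edges, decoy_edges = decoy_edges,
                enriched_terms = names(gene_sets)[seq_len(n_enr)],
                secreted_genes = secreted)

  structure(list(transcripts = tx$mat, mirnas = mi$mat, annotation = annotation,
                 interactions = interactions, gene_sets = gene_sets,
                 secreted = secreted, markers = markers, sheet = sheet,
                 truth = truth, config = cfg),
            class = "SimulatedDataset")
}

#' @export
print.SimulatedDataset <- function(x, ...) {
  cat(sprintf(paste0("Simulated dataset (seed %d): %d transcripts / %d genes, ",
                     "%d miRNAs, %d + %d samples\n"),
              x$config$seed, nrow(x$transcripts$values), nrow(x$annotation) -
                sum(duplicated(x$annotation$gene_symbol)),
              nrow(x$mirnas$values), x$config$n_per_group, x$config$n_per_group))
  cat(sprintf("  true DE genes: %d (%d miRNA-coupled), true DE miRNAs: %d\n",
              length(x$truth$true_de_genes), nrow(x$truth$true_edges),
              length(x$truth$true_de_mirnas)))
  invisible(x)
}

#' Write a simulated dataset to a directory in the canonical formats
#'
#' Emits `transcripts.tsv`, `mirnas.tsv`, `sample_sheet.tsv`,
#' `annotation.tsv`, `interactions.tsv`, `gene_sets.gmt`, `secreted.tsv`,
#' `markers.tsv` and ground-truth TSVs, all readable back by the
#' expression-I/O functions.
#'
#' @param sim a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "SimulatedDataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_expression_table(sim$transcripts, fp("transcripts.tsv"))
  write_expression_table(sim$mirnas, fp("mirnas.tsv"))
  utils::write.table(as.data.frame(sim$sheet), fp("sample_sheet.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$annotation, fp("annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  inter <- data.frame(mirna_id = sim$interactions$mirna_id,
                      gene_symbol = sim$interactions$gene_symbol,
                      source_db = sim$interactions$sources,
                      evidence_type = sim$interactions$evidence_type,
                      stringsAsFactors = FALSE)
  utils::write.table(inter, fp("interactions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_gmt(sim$gene_sets, fp("gene_sets.gmt"))
  utils::write.table(data.frame(gene_symbol = sim$secreted), fp("secreted.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(gene_symbol = sim$markers), fp("markers.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_symbol = names(sim$truth$true_de_genes),
               log2_effect = unname(sim$truth$true_de_genes)),
    fp("ground_truth_genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(mirna_id = names(sim$truth$true_de_mirnas),
               log2_effect = unname(sim$truth$true_de_mirnas)),
    fp("ground_truth_mirnas.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$true_edges, fp("ground_truth_edges.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Simulate a qPCR Ct table with known fold changes
#'
#' Generates cycle thresholds from the linear model
#' `ct = a - b * log2(expression) + noise` for a handful of target genes plus
#' a non-DE reference gene, using the same two-group design as the expression
#' simulator. With zero noise and b = 1, [relative_expression()] recovers
#' the simulated fold changes exactly.
#'
#' @param config a [simulation_config()] (uses `n_per_group`, `noise_cv` as
#'   Ct noise scale in cycles/10, and `seed`, offset so the stream is
#'   independent of [simulate_dataset()]).
#' @param n_genes number of target genes (default 4).
#' @param a,b calibration intercept (default 35) and slope (default 1).
#' @param ct_noise_sd additive Ct noise, cycles (default 0).
#' @param reference_gene name of the internal control.
#' @return list with `ct` (data.frame `sample_id, gene, ct`), `sheet`,
#'   `params` (a, b), and `truth` (named log2 fold changes, test over
#'   reference).
#' @export
simulate_ct_table <- function(config = simulation_config(), n_genes = 4,
                              a = 35, b = 1, ct_noise_sd = 0,
                              reference_gene = "Eef2") {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed + 104729L)   # offset stream; keep below 2^31
  n <- config$n_per_group
  samples <- c(sprintf("iWAT_%02d", seq_len(n)), sprintf("PANC_%02d", seq_len(n)))
  grp <- rep(c("iWAT", "PANC"), each = n)
  sheet <- sample_sheet(samples, grp)
  genes <- sprintf("Tgt%d", seq_len(n_genes))
  eff <- stats::setNames(draw_effects(n_genes, config), genes)
  base <- stats::setNames(2^stats::runif(n_genes + 1L, 2, 6),
                          c(genes, reference_gene))
  rows <- lapply(c(genes, reference_gene), function(g) {
    delta <- if (g == reference_gene) 0 else eff[[g]]
    expr <- base[[g]] * 2^(delta * (grp == "PANC"))
    data.frame(sample_id = samples, gene = g,
               ct = a - b * log2(expr) + stats::rnorm(2L * n, 0, ct_noise_sd),
               stringsAsFactors = FALSE)
  })
  list(ct = do.call(rbind, rows), sheet = sheet, params = list(a = a, b = b),
       truth = eff)
}
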