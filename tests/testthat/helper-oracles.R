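# Shared fixtures and independent oracles used across the test files.

# Small expression matrix with explicit values.
toy_matrix <- function(values, unit = "FPKM",
                       features = sprintf("f%d", seq_len(nrow(values))),
                       samples = sprintf("s%d", seq_len(ncol(values)))) {
  m <- as.matrix(values)
  dimnames(m) <- list(features, samples)
  expression_matrix(m, unit = unit)
}

# Two-group sheet over the columns of a matrix (first half iWAT, second PANC).
toy_sheet <- function(n_per_group, prefix_ref = "W", prefix_test = "P") {
  sample_sheet(c(sprintf("%s%d", prefix_ref, seq_len(n_per_group)),
                 sprintf("%s%d", prefix_test, seq_len(n_per_group))),
               rep(c("iWAT", "PANC"), each = n_per_group))
}

# Seeded random log-normal matrix under the global null, samples named to
# match toy_sheet(n_per_group).
null_matrix <- function(n_features, n_per_group, seed, unit = "FPKM",
                        log2_mean = 3, log2_sd = 2, cv = 0.3) {
  set.seed(seed)
  base <- 2^rnorm(n_features, log2_mean, log2_sd)
  sigma <- sqrt(log(1 + cv^2))
  noise <- matrix(exp(rnorm(n_features * 2 * n_per_group, -sigma^2 / 2, sigma)),
                  nrow = n_features)
  m <- base * noise
  dimnames(m) <- list(sprintf("f%04d", seq_len(n_features)),
                      c(sprintf("W%d", seq_len(n_per_group)),
                        sprintf("P%d", seq_len(n_per_group))))
  expression_matrix(m, unit = unit)
}

# Independent hypergeometric upper-tail oracle: P[X >= k] by direct summation
# of the probability mass written with lchoose (no calls to phyper/dhyper).
hyper_upper_oracle <- function(k, K, n, N) {
  lo <- max(0L, n + K - N)
  hi <- min(n, K)
  if (k > hi) return(0)
  i <- max(k, lo):hi
  sum(exp(lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)))
}

# Independent one-sided Fisher oracle: enumerate all tables with the observed
# margins and sum the probabilities of tables at least as enriched in cell a.
fisher_greater_oracle <- function(a, b, c, d) {
  m <- a + b          # marker total
  n_top <- a + c      # top-set total
  N <- a + b + c + d
  hyper_upper_oracle(a, m, n_top, N)
}

# A tiny deterministic DEG table for integration/secretome tests.
toy_degs <- function() {
  d <- data.frame(
    gene_symbol = c("A", "B", "C", "D", "E"),
    direction = c("up", "down", "up", "discordant", "down"),
    best_p = c(0.01, 0.02, 0.03, 0.001, 0.04),
    max_abs_log2fc = c(2.5, -1.8, 0.7, 3.0, -2.2),
    n_transcripts = 1L, stringsAsFactors = FALSE)
  class(d) <- c("deg_sets", "data.frame")
  d
}

# A miRNA welch_de-like table from explicit fold changes and p-values.
toy_mirna_results <- function(ids, lfc, p, alpha = 0.05) {
  data.frame(feature_id = ids, mean_ref = 10, mean_test = 10 * 2^lfc,
             log2fc = lfc, t_stat = 0, df = 14, p_value = p,
             significant = p < alpha,
             direction = ifelse(p >= alpha, "none", ifelse(lfc > 0, "up", "down")),
             degenerate = FALSE, stringsAsFactors = FALSE)
}

interaction_df <- function(mirna, gene, sources = "db1") {
  data.frame(mirna_id = mirna, gene_symbol = gene,
             sources = rep_len(sources, length(mirna)),
             evidence_type = rep_len("sim", length(mirna)),
             stringsAsFactors = FALSE)
}
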