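#' Construct an expression matrix
#'
#' The shared abundance container of the pipeline: a feature x sample table of
#' non-negative, finite values carrying a unit tag (`"FPKM"` for transcripts,
#' `"TPM"` for miRNAs). Feature and sample identifiers must be unique; missing
#' values are rejected rather than imputed.
#'
#' @param values numeric matrix with feature ids as rownames and sample ids as
#'   colnames.
#' @param unit `"FPKM"` or `"TPM"`.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values`, `unit`, `feature_ids`, `sample_ids`.
#' @export
expression_matrix <- function(values, unit = c("FPKM", "TPM")) {
  unit <- match.arg(unit)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix", call. = FALSE)
  if ((nrow(values) > 0L && is.null(rownames(values))) ||
      (ncol(values) > 0L && is.null(colnames(values))))
    stop("'values' must have feature rownames and sample colnames", call. = FALSE)
  if (anyDuplicated(rownames(values)))
    stop("duplicate feature identifiers: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "),
         call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite and non-missing", call. = FALSE)
  if (any(values < 0))
    stop("expression values must be non-negative", call. = FALSE)
  fid <- rownames(values); sid <- colnames(values)
  structure(
    list(values = values, unit = unit,
         feature_ids = if (is.null(fid)) character(0) else fid,
         sample_ids = if (is.null(sid)) character(0) else sid),
    class = "ExpressionMatrix"
  )
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d features x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$unit))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Read an expression table
#'
#' Expects a delimited text file with a header row of sample identifiers and
#' feature identifiers in the first column. Tab-separated, UTF-8, "." decimal
#' is the canonical dialect; CSV is accepted via `sep = ","`. Lines starting
#' with `#` are treated as comments.
#'
#' @param path file path.
#' @param unit unit tag recorded on the matrix (`"FPKM"` or `"TPM"`).
#' @param sep field separator, tab by default.
#' @return An [expression_matrix()].
#' @export
read_expression_table <- function(path, unit = c("FPKM", "TPM"), sep = "\t") {
  unit <- match.arg(unit)
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                          comment.char = "#", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expression table needs a feature-id column plus >= 1 sample column", call. = FALSE)
  ids <- as.character(df[[1]])
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    col <- vals[[j]]
    if (!is.numeric(col)) {
      bad <- which(is.na(suppressWarnings(as.numeric(col))) & !is.na(col))
      stop(sprintf("non-numeric value in column '%s'%s", names(vals)[j],
                   if (length(bad)) sprintf(", row %d (feature '%s')", bad[1], ids[bad[1]]) else ""),
           call. = FALSE)
    }
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  expression_matrix(m, unit = unit)
}

#' Write an expression table
#'
#' Writes the canonical TSV layout read back by [read_expression_table()]:
#' a `#` comment line recording package version and unit, then a header row of
#' sample ids with the feature-id column named `feature_id`.
#'
#' @param x an `ExpressionMatrix`.
#' @param path output file path.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "ExpressionMatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mscmir %s unit=%s", pkg_version(), x$unit), con)
  df <- data.frame(feature_id = x$feature_ids, x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

pkg_version <- function() {
  as.character(utils::packageVersion("mscmir"))
}

#' Construct a sample sheet
#'
#' Assigns each sample to one of exactly two groups and records advisory
#' exclusions. The default labels match the study design: reference `"iWAT"`
#' (inguinal white adipose tissue MSCs), test `"PANC"` (pancreas MSCs); fold
#' changes are always test over reference.
#'
#' @param sample_id character vector of sample identifiers.
#' @param group group label per sample (exactly two distinct labels).
#' @param excluded logical per sample; excluded samples take no part in any
#'   computation.
#' @param ref_group,test_group which label is the reference / test group.
#' @return data.frame of class `SampleSheet` with attributes `ref_group` and
#'   `test_group`.
#' @export
sample_sheet <- function(sample_id, group, excluded = FALSE,
                         ref_group = "iWAT", test_group = "PANC") {
  sheet <- data.frame(sample_id = as.character(sample_id),
                      group = as.character(group),
                      excluded = rep_len(as.logical(excluded), length(sample_id)),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicate sample ids in sample sheet", call. = FALSE)
  labs <- unique(sheet$group)
  if (length(labs) != 2L)
    stop("sample sheet must contain exactly two group labels, got: ",
         paste(labs, collapse = ", "), call. = FALSE)
  if (!all(c(ref_group, test_group) %in% labs))
    stop(sprintf("group labels must include ref '%s' and test '%s'", ref_group, test_group),
         call. = FALSE)
  kept <- sheet[!sheet$excluded, ]
  n_by <- table(kept$group)
  if (any(n_by < 2L))
    stop("each group needs >= 2 non-excluded samples", call. = FALSE)
  attr(sheet, "ref_group") <- ref_group
  attr(sheet, "test_group") <- test_group
  class(sheet) <- c("SampleSheet", "data.frame")
  sheet
}

#' Read a sample sheet TSV (columns sample_id, group[, excluded])
#' @inheritParams sample_sheet
#' @param path file path.
#' @export
read_sample_sheet <- function(path, ref_group = "iWAT", test_group = "PANC") {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "group")
  if (!all(need %in% names(df)))
    stop("sample sheet must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  excl <- if ("excluded" %in% names(df)) as.logical(df$excluded) else FALSE
  sample_sheet(df$sample_id, df$group, excl,
               ref_group = ref_group, test_group = test_group)
}

# Check a sheet against a matrix: every matrix sample appears exactly once.
check_sheet_matrix <- function(sheet, mat) {
  missing <- setdiff(mat$sample_ids, sheet$sample_id)
  if (length(missing))
    stop("samples absent from sheet: ", paste(missing, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

#' Read a transcript-to-gene annotation TSV (columns transcript_id, gene_symbol)
#' @param path file path.
#' @return data.frame with unique `transcript_id` and non-empty `gene_symbol`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  need <- c("transcript_id", "gene_symbol")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$transcript_id))
    stop("duplicate transcript_id in annotation", call. = FALSE)
  if (any(!nzchar(df$gene_symbol)))
    stop("empty gene_symbol in annotation", call. = FALSE)
  df[need]
}

#' Read a GMT gene-set collection
#'
#' Standard GMT dialect: one term per line, tab-separated as
#' `term_id<TAB>description<TAB>member1<TAB>member2...`. Members are
#' deduplicated; empty files yield an empty collection.
#'
#' @param path file path.
#' @return A named list of class `GeneSetCollection`; each element is a
#'   character vector of member gene symbols with attribute `term_name`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("GMT line %d has %d field(s); need >= 3", i, length(f)), call. = FALSE)
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (!length(members))
      stop(sprintf("GMT line %d: term '%s' has no members", i, f[1]), call. = FALSE)
    if (f[1] %in% names(sets))
      stop(sprintf("duplicate term id '%s' in GMT", f[1]), call. = FALSE)
    sets[[f[1]]] <- structure(members, term_name = f[2])
  }
  structure(sets, class = "GeneSetCollection")
}

#' Write a GMT gene-set collection
#' @param sets a `GeneSetCollection` (or named list of character vectors).
#' @param path output file path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(id) {
    nm <- attr(sets[[id]], "term_name")
    if (is.null(nm)) nm <- id
    paste(c(id, nm, sets[[id]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read validated miRNA-target interaction table(s)
#'
#' TSV columns `mirna_id, gene_symbol, source_db, evidence_type`. Multiple
#' files (e.g. separate TarBase/miRecords/miRTarBase exports) are merged by
#' union; records are deduplicated on (mirna_id, gene_symbol) with source
#' databases accumulated into a single `;`-separated provenance field.
#'
#' @param paths one or more file paths.
#' @return data.frame with columns `mirna_id`, `gene_symbol`, `sources`
#'   (`;`-joined, sorted, unique), `evidence_type` (first seen per pair).
#' @export
read_interaction_table <- function(paths) {
  need <- c("mirna_id", "gene_symbol", "source_db", "evidence_type")
  tabs <- lapply(paths, function(p) {
    df <- utils::read.table(p, header = TRUE, sep = "\t", quote = "",
                            comment.char = "#", stringsAsFactors = FALSE,
                            colClasses = "character")
    miss <- setdiff(need, names(df))
    if (length(miss))
      stop(sprintf("interaction table '%s' missing column(s): %s",
                   p, paste(miss, collapse = ", ")), call. = FALSE)
    df[need]
  })
  df <- do.call(rbind, tabs)
  if (is.null(df) || nrow(df) == 0L)
    return(data.frame(mirna_id = character(), gene_symbol = character(),
                      sources = character(), evidence_type = character(),
                      stringsAsFactors = FALSE))
  key <- paste(df$mirna_id, df$gene_symbol, sep = "\r")
  merged <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    data.frame(mirna_id = df$mirna_id[idx[1]],
               gene_symbol = df$gene_symbol[idx[1]],
               sources = paste(sort(unique(df$source_db[idx])), collapse = ";"),
               evidence_type = df$evidence_type[idx[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  out[order(out$mirna_id, out$gene_symbol), , drop = FALSE]
}

#' Read a one-column gene list (secretome or marker genes)
#'
#' TSV with header; first column must be `gene_symbol`. An optional second
#' column (e.g. an HPA-style `secretome_class`) is carried as a names
#' attribute but not used in any logic.
#'
#' @param path file path.
#' @return character vector of unique gene symbols.
#' @export
read_gene_list <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                          comment.char = "#", stringsAsFactors = FALSE)
  if (!"gene_symbol" %in% names(df))
    stop("gene list must have a 'gene_symbol' column", call. = FALSE)
  genes <- unique(as.character(df$gene_symbol))
  if ("secretome_class" %in% names(df)) {
    cls <- df$secretome_class[match(genes, df$gene_symbol)]
    names(genes) <- cls
  }
  genes
}

# Canonical TSV writer for result tables: one '#' comment line with version
# and parameters, then the header + rows. Deterministic (no timestamps).
write_result_tsv <- function(df, path, params = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  pstr <- if (length(params)) paste(names(params), params, sep = "=", collapse = " ") else ""
  writeLines(trimws(sprintf("# mscmir %s %s", pkg_version(), pstr)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
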