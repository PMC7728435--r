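# Containers and plain-text I/O: expression TSV (long format), eQTL TSV,
# GWAS TSV, dosage TSV panel, GMT gene sets, truth JSON.

#' Construct a replicate-level expression matrix
#'
#' @param values gene x sample matrix of log2 intensities, with rownames
#'   (gene ids) and colnames matching `samples$sample_id`.
#' @param samples data frame with columns `sample_id`, `individual`,
#'   `replicate`, `condition` (SG/HG) and `group` (nDM/nDR/PDR).
#' @param detection_p optional gene x sample matrix of detection p-values.
#' @return object of class `expression_matrix`.
#' @export
expression_matrix <- function(values, samples, detection_p = NULL) {
  stopifnot(is.matrix(values))
  if (nrow(values) > 0 && is.null(rownames(values))) {
    stopf("glucoMR_data_error", "values must carry gene ids as rownames")
  }
  req <- c("sample_id", "individual", "replicate", "condition", "group")
  if (!all(req %in% names(samples))) {
    stopf("glucoMR_data_error", "samples must have columns: %s",
          paste(req, collapse = ", "))
  }
  if (!all(samples$condition %in% c("SG", "HG"))) {
    stopf("glucoMR_data_error", "condition must be SG or HG")
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id)) {
    stopf("glucoMR_data_error", "every column of values needs a samples row")
  }
  if (any(!is.finite(values))) {
    stopf("glucoMR_data_error", "expression values must be finite")
  }
  if (!is.null(detection_p)) {
    stopifnot(identical(dim(detection_p), dim(values)))
  }
  structure(list(values = values, samples = samples, detection_p = detection_p),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d samples (%d individuals)\n",
              nrow(x$values), ncol(x$values), length(unique(x$samples$individual))))
  invisible(x)
}

#' Write / read a replicate-level expression table
#'
#' Long-format TSV with columns gene_id, individual_id, replicate,
#' condition, group, log2_expr.
#' @param expr an `expression_matrix`.
#' @param path file path.
#' @return `write_expression_tsv` returns `path` invisibly;
#'   `read_expression_tsv` returns an `expression_matrix`.
#' @export
write_expression_tsv <- function(expr, path) {
  s <- expr$samples
  long <- data.frame(
    gene_id = rep(rownames(expr$values), times = ncol(expr$values)),
    individual_id = rep(s$individual, each = nrow(expr$values)),
    replicate = rep(s$replicate, each = nrow(expr$values)),
    condition = rep(s$condition, each = nrow(expr$values)),
    group = rep(s$group, each = nrow(expr$values)),
    log2_expr = as.vector(expr$values),
    stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE)
  long$sample_id <- paste(long$individual_id, long$condition, long$replicate,
                          sep = "_")
  samples <- unique(long[, c("sample_id", "individual_id", "replicate",
                             "condition", "group")])
  names(samples)[2] <- "individual"
  genes <- unique(long$gene_id)
  vals <- matrix(NA_real_, length(genes), nrow(samples),
                 dimnames = list(genes, samples$sample_id))
  vals[cbind(match(long$gene_id, genes), match(long$sample_id, samples$sample_id))] <-
    long$log2_expr
  expression_matrix(vals, samples)
}

#' Write / read simple summary-statistic and panel tables
#'
#' Thin TSV wrappers so each pipeline stage can run standalone.
#' @param x data frame (eQTL table, GWAS table) or `genotype_panel`.
#' @param path file path.
#' @name sumstat_io
#' @return writers return `path` invisibly; readers the parsed object.
NULL

#' @rdname sumstat_io
#' @export
write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sumstat_io
#' @export
read_eqtl_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("gene_id", "snp_id", "beta", "se", "pvalue", "fdr")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stopf("glucoMR_data_error", "eQTL table missing columns: %s",
          paste(miss, collapse = ", "))
  }
  if (!"tissue" %in% names(x)) x$tissue <- "unknown"
  x
}

#' @rdname sumstat_io
#' @export
read_gwas_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("snp_id", "beta", "se", "pvalue")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    stopf("glucoMR_data_error", "GWAS table missing columns: %s",
          paste(miss, collapse = ", "))
  }
  x
}

#' @rdname sumstat_io
#' @export
write_panel_tsv <- function(x, path) {
  stopifnot(inherits(x, "genotype_panel"))
  df <- data.frame(individual_id = rownames(x$dosages), x$dosages,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname sumstat_io
#' @export
read_panel_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  dos <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(dos) <- "double"
  rownames(dos) <- df[[1]]
  if (!all(dos %in% c(0, 1, 2))) {
    stopf("glucoMR_data_error", "dosage panel must contain only 0/1/2")
  }
  structure(list(dosages = dos, snp_ids = colnames(dos),
                 allele_freqs = colMeans(dos) / 2, ld_rho = NA_real_),
            class = "genotype_panel")
}

#' Read a GMT gene-set file
#'
#' Each line: set name, description, then member gene ids, tab-separated.
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      stopf("glucoMR_data_error", "malformed GMT line: %s", substr(l, 1, 40))
    }
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write / read the simulation ground truth as JSON
#'
#' @param truth a `truth_table`.
#' @param path file path.
#' @return the reader returns a `truth_table` equal to the one written.
#' @export
write_truth_json <- function(truth, path) {
  stopifnot(inherits(truth, "truth_table"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$eqtl_map <- as.data.frame(x$eqtl_map, stringsAsFactors = FALSE)
  x$response_genes <- as.character(x$response_genes)
  x$diff_response_genes <- as.character(x$diff_response_genes)
  x$pleiotropic_snps <- as.character(x$pleiotropic_snps)
  structure(x[c("response_genes", "diff_response_genes", "eqtl_map",
                "true_b_xy", "pleiotropic_snps")], class = "truth_table")
}
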