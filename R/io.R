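#' Read and write the pipeline's tab-separated tables
#'
#' The on-disk formats are plain TSV: the count matrix has gene ids in the
#' first column (`gene`) and one column per sample; the sample table has
#' columns `sample_id`, `group`, `batch`, `replicate`; the allele count table
#' has `gene`, `sample_id`, `reads_P`, `reads_L`, `reads_unassigned`; the
#' housekeeping list is one gene id per line.
#'
#' @param path file path.
#' @return `read_counts`: an integer matrix with gene rownames;
#'   `read_samples` / `read_allele_counts`: data.frames;
#'   `read_housekeeping`: a character vector.
#' @name eggcross-io
NULL

#' @rdname eggcross-io
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene") stop("first column of a count matrix must be 'gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  m
}

#' @rdname eggcross-io
#' @param counts gene x sample integer matrix.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname eggcross-io
#' @export
read_samples <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "batch")
  if (!all(need %in% names(df))) {
    stop("sample table must have columns ", paste(need, collapse = ", "))
  }
  bad <- setdiff(unique(df$group), EGG_GROUPS)
  if (length(bad)) stop("unknown groups in sample table: ", paste(bad, collapse = ", "))
  df
}

#' @rdname eggcross-io
#' @export
read_allele_counts <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "sample_id", "reads_P", "reads_L", "reads_unassigned")
  if (!all(need %in% names(df))) {
    stop("allele count table must have columns ", paste(need, collapse = ", "))
  }
  df
}

#' @rdname eggcross-io
#' @export
read_housekeeping <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' Write all tables of a simulated experiment to a directory
#'
#' Writes `counts.tsv`, `samples.tsv`, `allele_counts.tsv`, `truth.tsv` and
#' `housekeeping.txt` under `dir`.
#'
#' @param sim an `eggcross_sim` from [simulate_experiment()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "eggcross_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts(sim$counts, file.path(dir, "counts.tsv"))
  write.table(sim$samples, file.path(dir, "samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(sim$allele)) {
    write.table(sim$allele, file.path(dir, "allele_counts.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write.table(sim$truth, file.path(dir, "truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(sim$housekeeping, file.path(dir, "housekeeping.txt"))
  invisible(dir)
}
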