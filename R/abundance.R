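#' Genus-level abundance table
#'
#' The central container of the microbiome stages: a samples x genera matrix
#' of non-negative integer counts together with its row-normalized relative
#' abundances. Samples with a zero library size are allowed but their
#' relative-abundance row is all `NA`.
#'
#' @param counts numeric matrix, samples in rows, genera in columns.
#'   Row names are sample identifiers, column names genus identifiers;
#'   defaults (`S1..`, `g1..`) are supplied when absent.
#' @return An object of class `abundance_table`: a list with elements
#'   `counts`, `rel_abundance`, `sample_ids`, `genus_ids`.
#' @export
abundance_table <- function(counts) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (any(counts < 0, na.rm = TRUE)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("S", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("g", seq_len(ncol(counts)))
  tot <- rowSums(counts)
  rel <- counts / ifelse(tot > 0, tot, NA_real_)
  structure(
    list(counts = counts, rel_abundance = rel,
         sample_ids = rownames(counts), genus_ids = colnames(counts)),
    class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: %d samples x %d genera\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  library sizes: %s - %s (median %s)\n",
              format(min(rowSums(x$counts))), format(max(rowSums(x$counts))),
              format(stats::median(rowSums(x$counts)))))
  invisible(x)
}

#' @export
dim.abundance_table <- function(x) dim(x$counts)

#' Relative abundances of an abundance table
#'
#' @param tab `abundance_table` or a plain matrix already on the relative
#'   scale (returned unchanged).
#' @return samples x genera matrix of row proportions.
#' @export
rel_abundance <- function(tab) {
  if (inherits(tab, "abundance_table")) return(tab$rel_abundance)
  as.matrix(tab)
}

#' Read / write a genus abundance table as TSV
#'
#' Plain tab-separated text: first column the sample identifier, remaining
#' columns one genus each (header row holds genus identifiers).
#'
#' @param path file path.
#' @return `read_abundance_tsv`: an [abundance_table()].
#' @export
read_abundance_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "numeric"
  abundance_table(m)
}

#' @param tab an [abundance_table()] (counts are written).
#' @rdname read_abundance_tsv
#' @export
write_abundance_tsv <- function(tab, path) {
  df <- data.frame(sample_id = tab$sample_ids, tab$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
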