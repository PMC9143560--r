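#' Abundance matrix container
#'
#' Raw (or normalized) sample-by-metabolite intensities with per-sample batch
#' labels and optional metabolite annotation. Missing values (`NA`) are
#' allowed; all observed intensities must be nonnegative and sample and
#' metabolite identifiers must be unique.
#'
#' @param values numeric matrix, samples in rows (rownames = sample ids),
#'   metabolites in columns (colnames = metabolite ids).
#' @param batch character or factor vector of batch labels, one per sample
#'   (named or in row order).
#' @param metabolite_meta optional data.frame keyed by `metabolite` with
#'   annotation columns (e.g. `super_pathway`, `sub_pathway`, `kegg_id`).
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(values, batch, metabolite_meta = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have sample rownames and metabolite colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample ids")
  if (anyDuplicated(colnames(values)))
    stop("duplicate metabolite ids")
  if (any(values < 0, na.rm = TRUE))
    stop("intensities must be nonnegative")
  batch <- as.character(batch)
  if (length(batch) != nrow(values))
    stop("need one batch label per sample")
  names(batch) <- rownames(values)
  structure(
    list(values = values, batch = batch, metabolite_meta = metabolite_meta),
    class = "abundance_matrix"
  )
}

#' @export
print.abundance_matrix <- function(x, ...) {
  v <- x$values
  cat(sprintf(
    "abundance_matrix: %d samples x %d metabolites, %d batches, %.1f%% missing\n",
    nrow(v), ncol(v), length(unique(x$batch)), 100 * mean(is.na(v))
  ))
  invisible(x)
}

#' @export
dim.abundance_matrix <- function(x) dim(x$values)

#' Subset an abundance matrix by sample id
#'
#' @param mat an [abundance_matrix()].
#' @param sample_ids sample ids to keep, in the order requested.
#' @return An [abundance_matrix()] with batch labels kept aligned.
#' @export
subset_samples <- function(mat, sample_ids) {
  abundance_matrix(mat$values[sample_ids, , drop = FALSE],
                   mat$batch[sample_ids], mat$metabolite_meta)
}

#' Read / write abundance tables
#'
#' Tab-separated layout: samples as rows; first column `sample_id`, second
#' column `batch`, remaining columns one per metabolite; missing cells are
#' `NA`.
#'
#' @param path file path.
#' @return `read_abundance_tsv()` returns an [abundance_matrix()].
#' @export
read_abundance_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("sample_id", "batch") %in% names(df)[1:2]))
    stop("expected first two columns 'sample_id' and 'batch' in ", path)
  vals <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(vals) <- df$sample_id
  abundance_matrix(vals, df$batch)
}

#' @param mat an [abundance_matrix()].
#' @rdname read_abundance_tsv
#' @export
write_abundance_tsv <- function(mat, path) {
  df <- data.frame(sample_id = rownames(mat$values), batch = mat$batch,
                   mat$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
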