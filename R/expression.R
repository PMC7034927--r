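# Count normalization (CPM / FPKM) and the empirical noise filter that
# defines the "expressed" transcript set.

#' Count matrix over fractionated samples
#'
#' Raw transcript-level read counts with a per-sample annotation sheet.
#'
#' @param counts integer matrix, transcripts x samples, with transcript ids as
#'   rownames and sample ids as colnames; no negative entries.
#' @param samples data.frame with columns `id`, `fraction` (`"CPE"` or
#'   `"SNE"`), `cell_type`, `replicate`; `id` must match `colnames(counts)`.
#' @return an object of class `CountMatrix` with `$counts` and `$samples`.
#' @export
count_matrix <- function(counts, samples) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(rownames(counts))) stop("counts must have transcript rownames")
  if (anyDuplicated(samples$id)) stop("sample ids must be unique")
  if (!all(c("id", "fraction") %in% names(samples)))
    stop("sample sheet needs at least 'id' and 'fraction' columns")
  if (!all(samples$fraction %in% c("CPE", "SNE")))
    stop("fraction must be 'CPE' or 'SNE'")
  if (!identical(as.character(samples$id), colnames(counts)))
    stop("sample sheet ids must match count matrix columns, in order")
  if (is.null(samples$cell_type)) samples$cell_type <- "unknown"
  if (is.null(samples$replicate)) samples$replicate <- seq_len(nrow(samples))
  structure(list(counts = counts, samples = samples), class = "CountMatrix")
}

#' @export
print.CountMatrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "transcripts x", ncol(x$counts),
      "samples (", sum(x$samples$fraction == "CPE"), "CPE /",
      sum(x$samples$fraction == "SNE"), "SNE )\n")
  invisible(x)
}

#' Read a count matrix and sample sheet from TSV
#'
#' @param counts_path TSV with transcript ids in the first column and one
#'   column per sample.
#' @param samples_path TSV sample sheet with header `id`, `fraction`,
#'   `cell_type`, `replicate`.
#' @return a `CountMatrix`.
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- utils::read.table(counts_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  samples <- utils::read.table(samples_path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE)
  count_matrix(m, samples)
}

#' Write a count matrix and sample sheet to TSV
#'
#' @param m a `CountMatrix`.
#' @param counts_path,samples_path output paths.
#' @export
write_counts <- function(m, counts_path, samples_path) {
  df <- data.frame(transcript_id = rownames(m$counts), m$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(m$samples, samples_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(counts_path)
}

.counts_of <- function(m) if (inherits(m, "CountMatrix")) m$counts else as.matrix(m)

#' Counts per million
#'
#' `cpm[i, j] = counts[i, j] / lib_size[j] * 1e6`. Library sizes default to
#' column sums of the supplied matrix; externally determined totals can be
#' passed instead.
#'
#' @param m a `CountMatrix` or plain counts matrix.
#' @param lib_sizes optional per-sample totals (positive).
#' @return CPM matrix of the same shape.
#' @export
compute_cpm <- function(m, lib_sizes = NULL) {
  counts <- .counts_of(m)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("library sizes must be positive")
  sweep(counts, 2, lib_sizes / 1e6, "/")
}

#' Fragments per kilobase per million
#'
#' `fpkm[i, j] = counts[i, j] / (length[i]/1e3) / (lib_size[j]/1e6)`.
#'
#' @param m a `CountMatrix` or plain counts matrix.
#' @param lengths per-transcript lengths in bp (>= 1), recycled by rowname
#'   when named.
#' @param lib_sizes optional per-sample totals.
#' @return FPKM matrix.
#' @export
compute_fpkm <- function(m, lengths, lib_sizes = NULL) {
  counts <- .counts_of(m)
  if (!is.null(names(lengths))) lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0))
    stop("transcript lengths must be positive for all transcripts")
  cpm <- compute_cpm(counts, lib_sizes)
  sweep(cpm, 1, lengths / 1e3, "/")
}

#' Empirical noise filter defining expressed transcripts
#'
#' A transcript is "expressed" when its CPM reaches `threshold` in at least
#' `min_fraction` of the samples (default: CPM >= 1 in at least half of the
#' samples; the sample count requirement is `ceiling(min_fraction * n)`, so
#' the boundary case of exactly half the samples passes).
#'
#' @param cpm CPM matrix with transcript rownames.
#' @param threshold CPM threshold (default 1).
#' @param min_fraction minimum fraction of samples, in (0, 1].
#' @return character vector of expressed transcript ids.
#' @export
filter_expressed <- function(cpm, threshold = 1, min_fraction = 0.5) {
  if (min_fraction <= 0 || min_fraction > 1)
    stop("min_fraction must be in (0, 1]")
  need <- ceiling(min_fraction * ncol(cpm))
  keep <- rowSums(cpm >= threshold) >= need
  rownames(cpm)[keep]
}

#' Expression vectors for correlation analysis
#'
#' Returns the per-transcript expression matrix on the scale used for
#' Pearson correlations; the default is `log2(FPKM + 1)`.
#'
#' @param m a `CountMatrix`.
#' @param lengths named per-transcript lengths in bp.
#' @param method one of `"log2fpkm"`, `"log2cpm"`, `"fpkm"`, `"cpm"`.
#' @param prior pseudo-count added inside the log (default 1).
#' @return numeric matrix, transcripts x samples.
#' @export
expression_vectors <- function(m, lengths = NULL,
                               method = c("log2fpkm", "log2cpm", "fpkm", "cpm"),
                               prior = 1) {
  method <- match.arg(method)
  if (method %in% c("log2fpkm", "fpkm") && is.null(lengths))
    stop("lengths are required for FPKM-based expression")
  x <- switch(method,
    log2fpkm = log2(compute_fpkm(m, lengths) + prior),
    fpkm = compute_fpkm(m, lengths),
    log2cpm = log2(compute_cpm(m) + prior),
    cpm = compute_cpm(m)
  )
  x
}
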