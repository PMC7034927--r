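# Genome model: transcript containers, GTF/BED I/O, overlap engine,
# positional classification. Coordinates are 0-based half-open throughout;
# GTF I/O converts to/from 1-based inclusive at the boundary.

#' Build a transcript table
#'
#' Constructs the data frame of transcript models used across the package.
#' One row per transcript with columns `transcript_id`, `gene_id`, `chrom`,
#' `start`, `end` (0-based half-open), `strand` (`+`/`-`), `biotype`
#' (`protein_coding` or `other`), `annotated` (logical) and a list-column
#' `exons` of two-column matrices (`start`, `end`, same convention, sorted,
#' non-overlapping, within the span).
#'
#' @param transcript_id character vector of unique ids.
#' @param chrom chromosome names.
#' @param start,end 0-based half-open span; `start < end` required.
#' @param strand `"+"` or `"-"`.
#' @param gene_id optional gene ids (default: same as `transcript_id`).
#' @param biotype `"protein_coding"` or `"other"`.
#' @param annotated logical; `FALSE` marks assembled/novel transcripts.
#' @param exons optional list of exon block matrices; default one exon
#'   spanning the whole transcript.
#' @return a `data.frame` of transcript models.
#' @export
transcript_models <- function(transcript_id, chrom, start, end, strand,
                              gene_id = transcript_id, biotype = "other",
                              annotated = FALSE, exons = NULL) {
  n <- length(transcript_id)
  df <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id = rep_len(as.character(gene_id), n),
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    biotype = rep_len(as.character(biotype), n),
    annotated = rep_len(as.logical(annotated), n),
    stringsAsFactors = FALSE
  )
  if (is.null(exons)) {
    exons <- lapply(seq_len(n), function(i) {
      cbind(start = df$start[i], end = df$end[i])
    })
  }
  df$exons <- exons
  validate_transcripts(df)
  df
}

validate_transcripts <- function(df) {
  stopifnot(is.data.frame(df))
  if (anyDuplicated(df$transcript_id))
    stop("transcript ids must be unique")
  if (any(df$start >= df$end))
    stop("transcript start must be < end (0-based half-open)")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  for (i in seq_len(nrow(df))) {
    ex <- df$exons[[i]]
    if (is.null(ex)) next
    if (any(ex[, 1] >= ex[, 2]))
      stop("exon start must be < end for transcript ", df$transcript_id[i])
    if (any(ex[, 1] < df$start[i]) || any(ex[, 2] > df$end[i]))
      stop("exon outside its transcript: ", df$transcript_id[i])
    if (nrow(ex) > 1) {
      o <- order(ex[, 1])
      if (any(ex[o, 1][-1] < ex[o, 2][-nrow(ex)]))
        stop("overlapping exons in transcript ", df$transcript_id[i])
    }
  }
  invisible(df)
}

#' Transcription start sites
#'
#' The TSS is the 5' end of the transcript: `start` on the plus strand and
#' `end` on the minus strand (half-open convention, so the minus-strand TSS
#' base itself is `end - 1`).
#'
#' @param transcripts transcript table.
#' @return numeric vector of TSS coordinates.
#' @export
tss <- function(transcripts) {
  ifelse(transcripts$strand == "+", transcripts$start, transcripts$end)
}

#' Genome annotation container
#'
#' Bundles a transcript table with chromosome sizes and validates that all
#' coordinates fall within the declared chromosomes.
#'
#' @param transcripts transcript table from [transcript_models()].
#' @param chrom_sizes named numeric vector of chromosome lengths (bp).
#' @return an object of class `GenomeAnnotation` with elements
#'   `$transcripts` and `$chrom_sizes`.
#' @export
genome_annotation <- function(transcripts, chrom_sizes) {
  validate_transcripts(transcripts)
  if (is.null(names(chrom_sizes)) || any(names(chrom_sizes) == ""))
    stop("chrom_sizes must be a named vector")
  bad <- !(transcripts$chrom %in% names(chrom_sizes))
  if (any(bad))
    stop("transcripts on undeclared chromosomes: ",
         paste(unique(transcripts$chrom[bad]), collapse = ", "))
  lim <- chrom_sizes[transcripts$chrom]
  if (any(transcripts$start < 0) || any(transcripts$end > lim))
    stop("transcript coordinates outside chromosome bounds")
  structure(list(transcripts = transcripts, chrom_sizes = chrom_sizes),
            class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  tr <- x$transcripts
  cat("GenomeAnnotation:", nrow(tr), "transcripts on",
      length(x$chrom_sizes), "chromosomes\n")
  cat("  protein_coding:", sum(tr$biotype == "protein_coding"),
      " other:", sum(tr$biotype != "protein_coding"),
      " annotated:", sum(tr$annotated), "\n")
  invisible(x)
}

#' Coding genes of an annotation
#'
#' @param annotation a `GenomeAnnotation`.
#' @return the subset of the transcript table with `biotype == "protein_coding"`.
#' @export
coding_genes <- function(annotation) {
  tr <- if (inherits(annotation, "GenomeAnnotation")) annotation$transcripts
        else annotation
  tr[tr$biotype == "protein_coding", , drop = FALSE]
}

# transcript table (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df, use_strand = TRUE) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end),
    strand = if (use_strand) df$strand else "*"
  )
}

## ---------------------------------------------------------------------------
## GTF / BED / chrom.sizes I/O

#' Read a GTF annotation
#'
#' Parses `transcript` and `exon` features of a GTF file into a
#' [genome_annotation()]. GTF 1-based inclusive coordinates are converted to
#' the internal 0-based half-open convention. Attributes `transcript_id`,
#' `gene_id`, `gene_biotype` and `annotated` are honored; missing
#' `gene_biotype` defaults to `"other"`, missing `annotated` to `TRUE`.
#'
#' @param path GTF file path.
#' @param chrom_sizes optional named vector of chromosome lengths; when
#'   omitted, sizes are taken as the maximum end coordinate per chromosome.
#' @return a `GenomeAnnotation`.
#' @export
read_gtf <- function(path, chrom_sizes = NULL) {
  .pre_validate_gtf(path)
  gr <- rtracklayer::import(path, format = "gtf")
  m <- S4Vectors::mcols(gr)
  if (is.null(m$transcript_id)) stop("GTF has no transcript_id attribute")
  type <- as.character(m$type)
  is_tr <- type == "transcript"
  is_ex <- type == "exon"
  if (!any(is_tr)) stop("GTF contains no transcript features")
  tr_gr <- gr[is_tr]
  tr_m <- S4Vectors::mcols(tr_gr)
  biotype <- if (!is.null(tr_m$gene_biotype)) as.character(tr_m$gene_biotype)
             else rep("other", length(tr_gr))
  biotype[is.na(biotype)] <- "other"
  annotated <- if (!is.null(tr_m$annotated)) as.logical(tr_m$annotated)
               else rep(TRUE, length(tr_gr))
  annotated[is.na(annotated)] <- TRUE
  gene_id <- if (!is.null(tr_m$gene_id)) as.character(tr_m$gene_id)
             else as.character(tr_m$transcript_id)

  ids <- as.character(tr_m$transcript_id)
  ex_by <- split(gr[is_ex], as.character(m$transcript_id[is_ex]))
  exons <- lapply(seq_along(tr_gr), function(i) {
    e <- ex_by[[ids[i]]]
    if (is.null(e) || length(e) == 0)
      return(cbind(start = GenomicRanges::start(tr_gr)[i] - 1,
                   end = GenomicRanges::end(tr_gr)[i]))
    e <- e[order(GenomicRanges::start(e))]
    cbind(start = GenomicRanges::start(e) - 1, end = GenomicRanges::end(e))
  })
  df <- transcript_models(
    transcript_id = ids,
    chrom = as.character(GenomicRanges::seqnames(tr_gr)),
    start = GenomicRanges::start(tr_gr) - 1,
    end = GenomicRanges::end(tr_gr),
    strand = as.character(GenomicRanges::strand(tr_gr)),
    gene_id = gene_id, biotype = biotype, annotated = annotated,
    exons = exons
  )
  if (is.null(chrom_sizes)) {
    chrom_sizes <- tapply(df$end, df$chrom, max)
    chrom_sizes <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  }
  genome_annotation(df, chrom_sizes)
}

# cheap structural validation so malformed lines are reported with a line number
.pre_validate_gtf <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9)
      stop("malformed GTF line ", i, ": expected 9 tab-separated fields")
    s <- suppressWarnings(as.numeric(f[4])); e <- suppressWarnings(as.numeric(f[5]))
    if (is.na(s) || is.na(e) || s > e)
      stop("malformed GTF line ", i, ": bad coordinates")
  }
  invisible(TRUE)
}

#' Write a GTF annotation
#'
#' Emits `transcript` and `exon` features in 1-based inclusive GTF
#' coordinates, with `gene_id`, `transcript_id`, `gene_biotype` and
#' `annotated` attributes, so that [read_gtf()] round-trips the annotation.
#'
#' @param annotation a `GenomeAnnotation`.
#' @param path output file path.
#' @export
write_gtf <- function(annotation, path) {
  tr <- annotation$transcripts
  attr_of <- function(i) {
    sprintf('gene_id "%s"; transcript_id "%s"; gene_biotype "%s"; annotated "%s";',
            tr$gene_id[i], tr$transcript_id[i], tr$biotype[i], tr$annotated[i])
  }
  lines <- character(0)
  for (i in seq_len(nrow(tr))) {
    a <- attr_of(i)
    lines <- c(lines, sprintf("%s\tchefind\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              tr$chrom[i], as.integer(tr$start[i] + 1),
                              as.integer(tr$end[i]), tr$strand[i], a))
    ex <- tr$exons[[i]]
    lines <- c(lines, sprintf("%s\tchefind\texon\t%d\t%d\t.\t%s\t.\t%s",
                              tr$chrom[i], as.integer(ex[, 1] + 1),
                              as.integer(ex[, 2]), tr$strand[i], a))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a BED interval file
#'
#' Native 0-based half-open coordinates are kept as-is. Columns beyond the
#' standard six may be named via `extra_cols` (e.g. a motif `family` label).
#'
#' @param path BED file path.
#' @param extra_cols optional character vector naming columns after the
#'   canonical six.
#' @return data.frame with `chrom`, `start`, `end`, `name`, `score`, `strand`
#'   (columns absent from the file are filled with defaults).
#' @export
read_bed <- function(path, extra_cols = NULL) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, comment.char = "#")
  base <- c("chrom", "start", "end", "name", "score", "strand")
  nm <- c(base, extra_cols)[seq_len(ncol(df))]
  names(df) <- nm
  if (!"name" %in% names(df)) df$name <- paste0("iv_", seq_len(nrow(df)))
  if (!"score" %in% names(df)) df$score <- 0
  if (!"strand" %in% names(df)) df$strand <- "*"
  df
}

#' Write a BED interval file
#'
#' @param df data.frame with at least `chrom`, `start`, `end`; `name`,
#'   `score`, `strand` and any columns named in `extra_cols` are appended.
#' @param path output file path.
#' @param extra_cols extra column names to write after the canonical six.
#' @export
write_bed <- function(df, path, extra_cols = NULL) {
  out <- data.frame(
    chrom = df$chrom,
    start = as.integer(df$start),
    end = as.integer(df$end),
    name = if ("name" %in% names(df)) df$name else paste0("iv_", seq_len(nrow(df))),
    score = if ("score" %in% names(df)) df$score else 0,
    strand = if ("strand" %in% names(df)) df$strand else "*",
    stringsAsFactors = FALSE
  )
  for (cc in extra_cols) out[[cc]] <- df[[cc]]
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a two-column chrom.sizes file
#'
#' @param path TSV with chromosome name and length.
#' @return named numeric vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}

## ---------------------------------------------------------------------------
## Overlap engine

#' Span overlap between transcripts
#'
#' Two features are considered overlapped when their span intersection covers
#' at least `min_bases` bases (default 1, following the convention that an
#' overlap of one base or more counts). Half-open adjacency (`end == start`)
#' is not an overlap. With `same_strand = TRUE` the strands must also agree.
#' With `use_exons = TRUE` the exon unions are intersected instead of the
#' spans.
#'
#' @param a,b single-row transcript tables (or anything with `chrom`, `start`,
#'   `end`, `strand`).
#' @param same_strand require equal strand (default `FALSE`).
#' @param min_bases minimum intersection width, >= 1.
#' @param use_exons intersect exon unions rather than spans.
#' @return logical.
#' @export
overlaps <- function(a, b, same_strand = FALSE, min_bases = 1,
                     use_exons = FALSE) {
  if (min_bases < 1) stop("min_bases must be >= 1")
  if (a$chrom != b$chrom) return(FALSE)
  if (same_strand && a$strand != b$strand) return(FALSE)
  if (use_exons && !is.null(a$exons) && !is.null(b$exons)) {
    ea <- a$exons[[1]]; eb <- b$exons[[1]]
    ia <- IRanges::IRanges(start = ea[, 1] + 1, end = ea[, 2])
    ib <- IRanges::IRanges(start = eb[, 1] + 1, end = eb[, 2])
    ov <- sum(IRanges::width(IRanges::intersect(ia, ib)))
    return(ov >= min_bases)
  }
  ov <- min(a$end, b$end) - max(a$start, b$start)
  ov >= min_bases
}

#' Positional classification of transcripts against coding genes
#'
#' Each transcript is assigned exactly one of three classes, tested in fixed
#' order against all coding genes: `sense_overlap` when its span overlaps any
#' coding gene span on the same strand by at least one base; otherwise
#' `antisense` when it overlaps any coding gene on the opposite strand;
#' otherwise `intergenic`.
#'
#' @param transcripts transcript table to classify.
#' @param coding transcript table of coding genes (nonempty).
#' @return character vector (`sense_overlap`/`antisense`/`intergenic`),
#'   one per transcript.
#' @export
classify_position <- function(transcripts, coding) {
  if (nrow(coding) == 0) stop("coding gene set must be nonempty")
  gt <- as_granges(transcripts)
  gc <- as_granges(coding)
  fo <- GenomicRanges::findOverlaps(gt, gc, ignore.strand = TRUE)
  cls <- rep("intergenic", nrow(transcripts))
  if (length(fo)) {
    same <- transcripts$strand[S4Vectors::queryHits(fo)] ==
      coding$strand[S4Vectors::subjectHits(fo)]
    hit_sense <- unique(S4Vectors::queryHits(fo)[same])
    hit_anti <- unique(S4Vectors::queryHits(fo)[!same])
    cls[hit_anti] <- "antisense"
    cls[hit_sense] <- "sense_overlap"   # sense rule wins over antisense
  }
  cls
}

#' Nearest flanking coding genes of an intergenic transcript
#'
#' For each query transcript, finds the nearest non-overlapping coding gene on
#' each genomic side (upstream = smaller coordinates, downstream = larger),
#' measured by span gap. Ties are broken toward the smaller-coordinate gene.
#'
#' @param transcripts transcript table of (intergenic) queries.
#' @param coding coding gene table.
#' @param same_strand restrict candidates to the query's strand.
#' @return data.frame with one row per query: `rna_id`, `upstream`,
#'   `downstream` (gene ids or `NA`), `upstream_gap`, `downstream_gap` (bp).
#' @export
flanking_genes <- function(transcripts, coding, same_strand = FALSE) {
  out <- data.frame(rna_id = transcripts$transcript_id,
                    upstream = NA_character_, downstream = NA_character_,
                    upstream_gap = NA_real_, downstream_gap = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(transcripts))) {
    t <- transcripts[i, ]
    cand <- coding[coding$chrom == t$chrom, , drop = FALSE]
    if (same_strand) cand <- cand[cand$strand == t$strand, , drop = FALSE]
    if (nrow(cand) == 0) next
    # exclude overlapping genes: gap must be > 0 in half-open arithmetic
    up <- cand[cand$end <= t$start, , drop = FALSE]
    dn <- cand[cand$start >= t$end, , drop = FALSE]
    if (nrow(up)) {
      gap <- t$start - up$end
      j <- which(gap == min(gap))
      j <- j[which.min(up$start[j])]   # tie: smaller-coordinate gene
      out$upstream[i] <- up$transcript_id[j]
      out$upstream_gap[i] <- gap[j]
    }
    if (nrow(dn)) {
      gap <- dn$start - t$end
      j <- which(gap == min(gap))
      j <- j[which.min(dn$start[j])]
      out$downstream[i] <- dn$transcript_id[j]
      out$downstream_gap[i] <- gap[j]
    }
  }
  out
}
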