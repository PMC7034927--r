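# Structural-motif overrepresentation (RR-score with the full-containment
# annotation rule) and Fisher-exact co-enrichment between transcript sets.

#' Annotate transcripts by full motif containment
#'
#' A transcript is annotated to a motif family when at least one motif
#' interval of that family lies entirely within the transcript span on the
#' same strand (full coverage required: a motif sticking out of either end
#' does not count; a motif exactly coextensive with the transcript does).
#'
#' @param transcripts transcript table.
#' @param motifs BED-style data.frame with `chrom`, `start`, `end`, `strand`
#'   and a `family` column.
#' @param family optional single family label to restrict to.
#' @param same_strand require the motif on the transcript's strand
#'   (default `TRUE`; motif models are stranded).
#' @return logical vector, one per transcript.
#' @export
annotate_by_containment <- function(transcripts, motifs, family = NULL,
                                    same_strand = TRUE) {
  if (!is.null(family)) motifs <- motifs[motifs$family == family, , drop = FALSE]
  if (nrow(motifs) == 0) return(rep(FALSE, nrow(transcripts)))
  gt <- as_granges(transcripts, use_strand = same_strand)
  gm <- GenomicRanges::GRanges(
    motifs$chrom, IRanges::IRanges(motifs$start + 1, motifs$end),
    strand = if (same_strand && "strand" %in% names(motifs)) motifs$strand else "*"
  )
  # full containment: motif 'within' transcript span
  fo <- GenomicRanges::findOverlaps(gm, gt, type = "within",
                                    ignore.strand = !same_strand)
  out <- rep(FALSE, nrow(transcripts))
  out[unique(S4Vectors::subjectHits(fo))] <- TRUE
  out
}

#' Relative-representation (RR) score of a motif family
#'
#' Overrepresentation of a motif family `r` in a transcript set `t` relative
#' to a background universe `T` (all noncoding transcripts):
#' `RR(t, r) = (|t n r| / |t|) / (|T n r| / |T|)`, where membership in `r`
#' means containment-annotated (see [annotate_by_containment()]) and `|.|`
#' counts transcripts. An RR-score above 1 indicates overrepresentation.
#'
#' @param target_ids transcript ids of the set `t` (subset of `universe_ids`).
#' @param family family label `r`.
#' @param universe_ids transcript ids of the background universe `T`.
#' @param transcripts transcript table covering the universe.
#' @param motifs motif data.frame as in [annotate_by_containment()].
#' @return one-row data.frame `family`, `n_target`, `n_target_annotated`,
#'   `observed_fraction`, `background_fraction`, `rr`.
#' @export
rr_score <- function(target_ids, family, universe_ids, transcripts, motifs) {
  if (!all(target_ids %in% universe_ids))
    stop("target set must be a subset of the universe")
  if (length(target_ids) == 0) stop("empty target set")
  uni <- transcripts[match(universe_ids, transcripts$transcript_id), , drop = FALSE]
  ann <- annotate_by_containment(uni, motifs, family = family)
  in_t <- universe_ids %in% target_ids
  obs <- mean(ann[in_t])
  bg <- mean(ann)
  if (bg == 0)
    stop("undefined RR-score: no transcript in the universe is annotated to ",
         family)
  data.frame(family = family,
             n_target = sum(in_t), n_target_annotated = sum(ann[in_t]),
             observed_fraction = obs, background_fraction = bg,
             rr = obs / bg, stringsAsFactors = FALSE)
}

#' RR-scores for every motif family
#'
#' Convenience wrapper applying [rr_score()] per (super-)family present in
#' the motif set; families with zero background are skipped.
#'
#' @inheritParams rr_score
#' @param superfamilies optional two-column mapping (`family`, `superfamily`)
#'   used to collapse annotating families into super-families before scoring.
#' @return data.frame with one row per scored family.
#' @export
rr_table <- function(target_ids, universe_ids, transcripts, motifs,
                     superfamilies = NULL) {
  if (!is.null(superfamilies)) {
    idx <- match(motifs$family, superfamilies$family)
    motifs$family <- ifelse(is.na(idx), motifs$family,
                            superfamilies$superfamily[idx])
  }
  fams <- sort(unique(motifs$family))
  out <- lapply(fams, function(f) {
    res <- try(rr_score(target_ids, f, universe_ids, transcripts, motifs),
               silent = TRUE)
    if (inherits(res, "try-error")) NULL else res
  })
  do.call(rbind, out)
}

#' Default super-family grouping table
#'
#' A fourteen-group mapping of structural-motif families to super-families,
#' mirroring the granularity of curated noncoding-RNA family groupings;
#' users supply their own two-column table to override it.
#'
#' @return data.frame with columns `family` and `superfamily`.
#' @export
default_superfamilies <- function() {
  path <- system.file("extdata", "superfamilies.tsv", package = "chefind")
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Fisher-exact co-enrichment of two transcript sets
#'
#' Builds the 2x2 table (`A n B`, `A \\ B`, `B \\ A`, neither) over a common
#' universe and applies Fisher's exact test (two-sided, conditional-MLE odds
#' ratio). The enrichment flag follows the convention: odds ratio larger
#' than `or_threshold` (default 2) and p-value below `alpha` (default 0.05).
#'
#' @param setA,setB character id sets, subsets of `universe`.
#' @param universe character id universe (nonempty).
#' @param or_threshold odds-ratio threshold for the enrichment flag.
#' @param alpha p-value threshold for the enrichment flag.
#' @return list with `table` (2x2 matrix), `odds_ratio`, `p_value`,
#'   `enriched`.
#' @export
fisher_co_enrichment <- function(setA, setB, universe, or_threshold = 2,
                                 alpha = 0.05) {
  if (length(universe) == 0) stop("empty universe")
  if (!all(setA %in% universe) || !all(setB %in% universe))
    stop("sets must be subsets of the universe")
  inA <- universe %in% setA
  inB <- universe %in% setB
  tab <- matrix(c(sum(inA & inB), sum(inA & !inB),
                  sum(!inA & inB), sum(!inA & !inB)),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("A", "notA"), c("B", "notB")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(table = tab,
       odds_ratio = unname(ft$estimate),
       p_value = ft$p.value,
       enriched = unname(ft$estimate) > or_threshold && ft$p.value < alpha)
}
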