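# Pipeline-comparison metrics: ROC/AUC against a proxy gold standard,
# positive predictive value on canonical loci, cell-type specificity (R1),
# and spike-in-normalized qPCR abundance.

#' Proxy gold standard from multiple call sets
#'
#' In the absence of a true gold standard, transcripts called by every
#' compared method serve as proxy positives.
#'
#' @param call_sets list of character id vectors, one per method.
#' @param universe ids scored by the evaluated method; defaults to the union
#'   of all call sets.
#' @return list with `positive_ids` and `universe`.
#' @export
proxy_gold_standard <- function(call_sets, universe = NULL) {
  pos <- Reduce(intersect, call_sets)
  if (is.null(universe)) universe <- Reduce(union, call_sets)
  if (!all(pos %in% universe)) stop("positives must lie in the universe")
  list(positive_ids = pos, universe = universe)
}

#' Default ranking statistic for ROC evaluation
#'
#' Signed evidence of chromatin enrichment:
#' `-log10(fdr) * sign(log2fc)`, so strong cheRNA calls rank highest.
#'
#' @param calls data.frame from [test_fraction_enrichment()].
#' @return named numeric vector of scores.
#' @export
enrichment_scores <- function(calls) {
  stats::setNames(-log10(pmax(calls$fdr, 1e-300)) * sign(calls$log2fc),
                  calls$transcript_id)
}

#' ROC curve and AUC against a proxy gold standard
#'
#' Standard ROC over score thresholds with trapezoidal AUC. Universe ids
#' without a score are ranked below all scored ids (pessimistic) and their
#' count is reported.
#'
#' @param scores named numeric vector (higher = more confident positive).
#' @param gs list from [proxy_gold_standard()].
#' @return list with `curve` (data.frame `threshold`, `fpr`, `tpr`), `auc`,
#'   `n_missing`.
#' @export
roc_auc <- function(scores, gs) {
  uni <- gs$universe
  lab <- uni %in% gs$positive_ids
  s <- unname(scores[uni])
  n_missing <- sum(is.na(s))
  s[is.na(s)] <- -Inf
  if (!any(lab) || all(lab)) stop("need both positives and negatives")
  o <- order(s, decreasing = TRUE)
  s <- s[o]; lab <- lab[o]
  # group tied scores so ties are swept in together
  grp_last <- cumsum(rle(s)$lengths)
  tp <- cumsum(lab)[grp_last]
  fp <- cumsum(!lab)[grp_last]
  tpr <- c(0, tp / sum(lab))
  fpr <- c(0, fp / sum(!lab))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  list(curve = data.frame(threshold = c(Inf, rle(s)$values),
                          fpr = fpr, tpr = tpr),
       auc = auc, n_missing = n_missing)
}

#' Positive predictive value on canonical loci
#'
#' Fraction of canonical loci whose predicted chromatin class matches the
#' expected class; loci without a prediction count as wrong.
#'
#' @param calls named character vector of predicted classes per locus id.
#' @param truth data.frame with `locus_id` and `expected_class`
#'   (`cheRNA`/`sneRNA`/`independent`).
#' @return proportion in `[0, 1]`.
#' @export
ppv_canonical <- function(calls, truth) {
  if (nrow(truth) == 0) stop("empty canonical locus set")
  pred <- calls[truth$locus_id]
  mean(!is.na(pred) & pred == truth$expected_class)
}

#' Cell-type specificity ratio (R1)
#'
#' `R1 = |ids in the focal cell type and in no other| / |ids in the focal
#' cell type|`. Higher values indicate more cell-type-specific
#' identification.
#'
#' @param sets_by_celltype named list of id sets, one per cell type (>= 2).
#' @param focal name of the focal cell type.
#' @return ratio in `[0, 1]`.
#' @export
r1_specificity <- function(sets_by_celltype, focal) {
  if (!focal %in% names(sets_by_celltype)) stop("focal cell type not present")
  if (length(sets_by_celltype) < 2) stop("need at least 2 cell types")
  f <- unique(sets_by_celltype[[focal]])
  if (length(f) == 0) stop("empty focal set")
  others <- unique(unlist(sets_by_celltype[names(sets_by_celltype) != focal]))
  length(setdiff(f, others)) / length(f)
}

#' Match transcripts across annotations by reciprocal span overlap
#'
#' Assembled coordinates of the same transcript can differ slightly between
#' cell types; ids are harmonized by clustering spans whose reciprocal
#' overlap is at least `reciprocal` (single-linkage over qualifying pairs),
#' so that set operations such as [r1_specificity()] compare loci rather
#' than assembly-specific ids.
#'
#' @param ann_list named list of transcript tables (one per cell type).
#' @param reciprocal minimum reciprocal overlap fraction (default 0.5).
#' @return named list of data.frames (`transcript_id`, `cluster_id`), one
#'   per input annotation.
#' @export
match_transcripts <- function(ann_list, reciprocal = 0.5) {
  all_tr <- do.call(rbind, lapply(names(ann_list), function(nm) {
    tr <- ann_list[[nm]]
    data.frame(source = nm, transcript_id = tr$transcript_id,
               chrom = tr$chrom, start = tr$start, end = tr$end,
               strand = tr$strand, stringsAsFactors = FALSE)
  }))
  gr <- as_granges(all_tr)
  fo <- GenomicRanges::findOverlaps(gr, gr)
  q <- S4Vectors::queryHits(fo); s <- S4Vectors::subjectHits(fo)
  keep <- q < s
  q <- q[keep]; s <- s[keep]
  w <- pmin(all_tr$end[q], all_tr$end[s]) - pmax(all_tr$start[q], all_tr$start[s])
  lq <- all_tr$end[q] - all_tr$start[q]
  ls <- all_tr$end[s] - all_tr$start[s]
  ok <- w / lq >= reciprocal & w / ls >= reciprocal
  # union-find over qualifying pairs
  parent <- seq_len(nrow(all_tr))
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (k in which(ok)) {
    a <- find(q[k]); b <- find(s[k])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  root <- vapply(seq_len(nrow(all_tr)), find, integer(1))
  cluster <- paste0("locus_", match(root, unique(root)))
  split(data.frame(transcript_id = all_tr$transcript_id,
                   cluster_id = cluster, stringsAsFactors = FALSE),
        all_tr$source)
}

#' Spike-in-normalized qPCR abundance
#'
#' Cycle-quantification values are normalized to a spike-in standard:
#' `dCq = cq - cq_spike`, abundance `A = 2^(-dCq)`; one extra cycle halves
#' the abundance.
#'
#' @param cq,cq_spike finite cycle values (vectorized).
#' @return abundance.
#' @export
spike_normalized_abundance <- function(cq, cq_spike) {
  if (any(!is.finite(cq)) || any(!is.finite(cq_spike)))
    stop("cycle values must be finite")
  2^(-(cq - cq_spike))
}
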