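# Neighbor-gene correlation: pair intergenic transcripts with one of their
# two flanking coding genes by the max-|PCC| rule, and compare the density of
# PCC values against a random-gene control via a kernel-density ratio.

#' Pearson correlation coefficient
#'
#' Standard Pearson r with explicit preconditions: equal length >= 3 and
#' nonzero variance in both vectors.
#'
#' @param x,y numeric vectors.
#' @return correlation in `[-1, 1]`.
#' @export
compute_pcc <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("at least 3 paired observations required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance")
  stats::cor(x, y)
}

#' Pair intergenic transcripts with a neighboring coding gene
#'
#' For each RNA, the Pearson correlation with each existing flanking gene is
#' computed across all supplied samples and the flank with the larger
#' absolute PCC is selected; at an exact tie the downstream gene is chosen
#' (deterministic rule). RNAs with no expressed flank yield an `NA` row.
#'
#' @param flanks data.frame from [flanking_genes()] (`rna_id`, `upstream`,
#'   `downstream`).
#' @param expr expression matrix (e.g. [expression_vectors()]) whose rows
#'   cover the RNAs and candidate genes; flanks absent from `expr` are
#'   treated as unexpressed.
#' @return data.frame `rna_id`, `gene_id`, `side`, `pcc` (class
#'   `NeighborPairs`).
#' @export
pair_neighbor_gene <- function(flanks, expr) {
  out <- data.frame(rna_id = flanks$rna_id, gene_id = NA_character_,
                    side = NA_character_, pcc = NA_real_,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(flanks))) {
    rna <- flanks$rna_id[i]
    if (!rna %in% rownames(expr)) next
    x <- expr[rna, ]
    if (stats::sd(x) == 0) next
    cand <- list()
    for (side in c("upstream", "downstream")) {
      g <- flanks[[side]][i]
      if (is.na(g) || !g %in% rownames(expr)) next
      y <- expr[g, ]
      if (stats::sd(y) == 0) next
      cand[[side]] <- stats::cor(x, y)
    }
    if (length(cand) == 0) next
    r <- unlist(cand)
    # max |PCC|; exact tie broken toward the downstream gene
    j <- which(abs(r) == max(abs(r)))
    side <- if (length(j) > 1) "downstream" else names(r)[j]
    out$gene_id[i] <- flanks[[side]][i]
    out$side[i] <- side
    out$pcc[i] <- r[[side]]
  }
  class(out) <- c("NeighborPairs", "data.frame")
  out
}

#' Random-gene control pairing
#'
#' Pairs each RNA with one coding gene drawn uniformly at random (without
#' replacement within the draw when possible), the control used as the
#' denominator of the relative-density curve. Size-matched to the group by
#' construction.
#'
#' @param rna_ids RNAs to pair.
#' @param gene_ids pool of coding gene ids present in `expr`.
#' @param expr expression matrix as in [pair_neighbor_gene()].
#' @return numeric vector of control PCC values (one per pairable RNA).
#' @export
random_control_pccs <- function(rna_ids, gene_ids, expr) {
  gene_ids <- intersect(gene_ids, rownames(expr))
  rna_ids <- intersect(rna_ids, rownames(expr))
  if (length(gene_ids) == 0) stop("no candidate genes in expression matrix")
  pick <- if (length(gene_ids) >= length(rna_ids))
    sample(gene_ids, length(rna_ids)) else
    sample(gene_ids, length(rna_ids), replace = TRUE)
  vapply(seq_along(rna_ids), function(i) {
    x <- expr[rna_ids[i], ]; y <- expr[pick[i], ]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(x, y)
  }, numeric(1))
}

#' Relative density of correlation values against a control
#'
#' Gaussian-kernel density estimates of a group's PCC values and of its
#' random control are evaluated on a common grid over `[-1, 1]` and their
#' ratio is returned. The control density is floored to keep the ratio
#' defined; grid points at the floor are flagged.
#'
#' @param pccs_group,pccs_control numeric PCC collections, each of size
#'   >= 20.
#' @param bandwidth kernel bandwidth; the default `"nrd0"` is Silverman's
#'   rule of thumb.
#' @param grid_n number of grid points on `[-1, 1]` (default 201).
#' @param floor lower bound applied to the control density (default 1e-6).
#' @return data.frame `grid`, `density_group`, `density_control`, `ratio`,
#'   `floored` (class `RelativeDensityCurve`).
#' @export
relative_density <- function(pccs_group, pccs_control, bandwidth = "nrd0",
                             grid_n = 201, floor = 1e-6) {
  pccs_group <- pccs_group[is.finite(pccs_group)]
  pccs_control <- pccs_control[is.finite(pccs_control)]
  if (length(pccs_group) < 20 || length(pccs_control) < 20)
    stop("each PCC collection must contain at least 20 values")
  dg <- stats::density(pccs_group, bw = bandwidth, n = grid_n,
                       from = -1, to = 1)
  dc <- stats::density(pccs_control, bw = bandwidth, n = grid_n,
                       from = -1, to = 1)
  floored <- dc$y < floor
  out <- data.frame(grid = dg$x, density_group = dg$y,
                    density_control = dc$y,
                    ratio = dg$y / pmax(dc$y, floor),
                    floored = floored)
  class(out) <- c("RelativeDensityCurve", "data.frame")
  out
}

#' Fractions of pairs beyond the significance cutoff
#'
#' Fraction of pairs with `pcc >= cutoff` (positive) and `pcc <= -cutoff`
#' (negative); the boundary value counts (inclusive).
#'
#' @param pairs a `NeighborPairs` data.frame or a numeric vector of PCCs.
#' @param cutoff significance cutoff (default 0.8).
#' @return named numeric: `pos_fraction`, `neg_fraction`.
#' @export
fraction_beyond_cutoff <- function(pairs, cutoff = 0.8) {
  pcc <- if (is.data.frame(pairs)) pairs$pcc else pairs
  pcc <- pcc[!is.na(pcc)]
  if (length(pcc) == 0) stop("no PCC values supplied")
  c(pos_fraction = mean(pcc >= cutoff),
    neg_fraction = mean(pcc <= -cutoff))
}
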