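# Chromatin signal: per-base coverage tracks (run-length encoded), bedGraph
# I/O, ChIP-versus-input ratios, strand-aware metagene profiles at TSSs and
# across scaled transcript bodies, peak-proximity grouping, and the
# rank-sum comparison of groups with the legend-style significance tiers.

#' Build a signal track
#'
#' A signal track is a per-chromosome run-length-encoded vector of per-base
#' coverage with a mark label attached as metadata.
#'
#' @param cov named list of numeric vectors (one per chromosome) or an
#'   `RleList`.
#' @param label mark name (e.g. `"H3K9me3"`).
#' @return an `RleList` with `metadata(x)$label` set.
#' @export
signal_track <- function(cov, label = "signal") {
  if (!methods::is(cov, "RleList"))
    cov <- methods::as(lapply(cov, S4Vectors::Rle), "RleList")
  if (any(min(cov) < 0)) stop("coverage must be non-negative")
  S4Vectors::metadata(cov)$label <- label
  cov
}

#' Read a bedGraph file into a signal track
#'
#' @param path bedGraph path (0-based half-open intervals with a score).
#' @param chrom_sizes named vector of chromosome lengths; determines the
#'   track's chromosome space.
#' @param label mark name.
#' @param rpm scale the track to reads-per-million (values sum to 1e6)?
#' @return an `RleList` track.
#' @export
read_bedgraph <- function(path, chrom_sizes, label = "signal", rpm = FALSE) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- unname(chrom_sizes)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  tr <- signal_track(cov, label)
  if (rpm) rpm_scale(tr) else tr
}

#' Write a signal track as bedGraph
#'
#' Runs of constant coverage become intervals; zero runs are skipped.
#'
#' @param track an `RleList` track.
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track)) {
    r <- track[[chrom]]
    ends <- cumsum(S4Vectors::runLength(r))
    starts <- c(0, ends[-length(ends)])
    vals <- S4Vectors::runValue(r)
    keep <- vals != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%g", chrom, starts[keep], ends[keep],
                       vals[keep]), con)
  }
  invisible(path)
}

#' Scale a track to reads per million
#'
#' @param track an `RleList` track.
#' @return the track rescaled so its total mass is 1e6.
#' @export
rpm_scale <- function(track) {
  tot <- sum(as.numeric(sum(track)))
  if (tot <= 0) stop("track has no signal to scale")
  out <- track * (1e6 / tot)
  S4Vectors::metadata(out) <- S4Vectors::metadata(track)
  out
}

#' Per-base ChIP-versus-input ratio track
#'
#' `(chip + pseudocount) / (input + pseudocount)` per base. The pseudo-count
#' (default 1 RPM) bounds ratios where the input track is sparse.
#'
#' @param chip,input `RleList` tracks over the same chromosome space,
#'   RPM-scaled.
#' @param pseudocount added to both tracks (default 1).
#' @return ratio track (`RleList`).
#' @export
signal_vs_input <- function(chip, input, pseudocount = 1) {
  if (!identical(names(chip), names(input)) ||
      !identical(unname(lengths(chip)), unname(lengths(input))))
    stop("chip and input tracks cover different chromosome spaces")
  out <- (chip + pseudocount) / (input + pseudocount)
  lab <- S4Vectors::metadata(chip)$label
  S4Vectors::metadata(out)$label <- paste0(lab, "_vs_input")
  out
}

# extract per-base values over [lo, hi) (0-based half-open); NULL if out of bounds
.window_values <- function(track, chrom, lo, hi) {
  if (!chrom %in% names(track)) return(NULL)
  r <- track[[chrom]]
  if (lo < 0 || hi > length(r)) return(NULL)
  as.numeric(S4Vectors::window(r, start = lo + 1, end = hi))
}

# bin a vector into nb equal-width consecutive bins by mean
.bin_means <- function(v, nb) {
  idx <- ceiling(seq_along(v) * nb / length(v))
  as.numeric(tapply(v, idx, mean))
}

#' Metagene profile centered at transcription start sites
#'
#' For each transcript the window `TSS +/- half_window` is extracted, oriented
#' 5' to 3' (per-base values reversed for minus-strand transcripts), and
#' averaged into fixed-width bins; the profile is the across-transcript mean
#' of the per-transcript binned means, so long or highly covered transcripts
#' do not dominate. Transcripts whose window leaves the chromosome are
#' dropped and counted.
#'
#' @param track signal (or ratio) track.
#' @param transcripts transcript table; strand orientation is honored.
#' @param half_window half-width in bp (default 1000).
#' @param bin_size bin width in bp (default 50); must divide `2 * half_window`.
#' @return data.frame `offset` (bin center, bp relative to TSS, 5'->3') and
#'   `mean_ratio`, with attributes `n_transcripts` and `n_dropped`
#'   (class `MetageneProfile`).
#' @export
tss_profile <- function(track, transcripts, half_window = 1000, bin_size = 50) {
  nb <- (2 * half_window) / bin_size
  if (nb != round(nb)) stop("bin_size must divide 2 * half_window")
  anchors <- tss(transcripts)
  acc <- matrix(NA_real_, nrow(transcripts), nb)
  for (i in seq_len(nrow(transcripts))) {
    v <- .window_values(track, transcripts$chrom[i],
                        anchors[i] - half_window, anchors[i] + half_window)
    if (is.null(v)) next
    if (transcripts$strand[i] == "-") v <- rev(v)
    acc[i, ] <- .bin_means(v, nb)
  }
  used <- !is.na(acc[, 1])
  if (!any(used)) stop("no transcript window lies within the track bounds")
  prof <- colMeans(acc[used, , drop = FALSE])
  out <- data.frame(
    offset = seq(-half_window, half_window - bin_size, by = bin_size) + bin_size / 2,
    mean_ratio = prof
  )
  attr(out, "n_transcripts") <- sum(used)
  attr(out, "n_dropped") <- sum(!used)
  class(out) <- c("MetageneProfile", "data.frame")
  out
}

#' Metagene profile across scaled transcript bodies
#'
#' Each transcript body is rescaled to `n_bins` equal-width bins (means of the
#' per-base signal), optionally flanked by fixed-width upstream/downstream
#' segments binned into `flank_bins` bins each; everything is oriented
#' 5' to 3'. Transcripts shorter than `n_bins` bases are dropped with a
#' recorded count.
#'
#' @param track signal (or ratio) track.
#' @param transcripts transcript table.
#' @param n_bins number of body bins (default 100).
#' @param flank flank width in bp on each side (default 1000; 0 disables).
#' @param flank_bins bins per flank (default 20).
#' @return data.frame `position` (percent of body; flanks < 0 and > 100) and
#'   `mean_ratio` (class `MetageneProfile`).
#' @export
body_profile <- function(track, transcripts, n_bins = 100, flank = 1000,
                         flank_bins = 20) {
  nf <- if (flank > 0) flank_bins else 0
  tot <- n_bins + 2 * nf
  acc <- matrix(NA_real_, nrow(transcripts), tot)
  dropped <- 0
  for (i in seq_len(nrow(transcripts))) {
    len <- transcripts$end[i] - transcripts$start[i]
    if (len < n_bins) { dropped <- dropped + 1; next }
    lo <- transcripts$start[i] - flank
    hi <- transcripts$end[i] + flank
    v <- .window_values(track, transcripts$chrom[i], lo, hi)
    if (is.null(v)) { dropped <- dropped + 1; next }
    if (transcripts$strand[i] == "-") v <- rev(v)
    row <- numeric(0)
    if (nf > 0) row <- .bin_means(v[seq_len(flank)], nf)
    row <- c(row, .bin_means(v[(flank + 1):(flank + len)], n_bins))
    if (nf > 0) row <- c(row, .bin_means(v[(flank + len + 1):(2 * flank + len)], nf))
    acc[i, ] <- row
  }
  used <- !is.na(acc[, 1])
  if (!any(used)) stop("no usable transcript for the body profile")
  if (dropped > 0)
    warning(dropped, " transcript(s) dropped (too short or out of bounds)")
  prof <- colMeans(acc[used, , drop = FALSE])
  # axis: body bins span (0, 100) percent; flank bins continue the axis on
  # either side, each flank mapped to a width of 100
  body_pos <- (seq_len(n_bins) - 0.5) / n_bins * 100
  left <- if (nf > 0) -rev((seq_len(nf) - 0.5) / nf * 100) else numeric(0)
  right <- if (nf > 0) 100 + (seq_len(nf) - 0.5) / nf * 100 else numeric(0)
  out <- data.frame(position = c(left, body_pos, right), mean_ratio = prof)
  attr(out, "n_transcripts") <- sum(used)
  attr(out, "n_dropped") <- dropped
  class(out) <- c("MetageneProfile", "data.frame")
  out
}

#' Partition transcripts by histone-mark peak proximity
#'
#' A transcript is in the `high` group when its span, extended by `proximity`
#' bp on both sides, intersects at least one peak; otherwise it is `low`.
#' With `proximity = 0` this reduces to span-peak overlap.
#'
#' @param transcripts transcript table.
#' @param peaks BED-style data.frame (`chrom`, `start`, `end`) of peak calls.
#' @param proximity extension in bp (default 1000).
#' @return list with character vectors `$high` and `$low` of transcript ids.
#' @export
group_by_mark <- function(transcripts, peaks, proximity = 1000) {
  if (nrow(peaks) == 0) stop("peak set is empty")
  ext <- transcripts
  ext$start <- pmax(0, ext$start - proximity)
  ext$end <- ext$end + proximity
  gt <- as_granges(ext, use_strand = FALSE)
  gp <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1, peaks$end))
  hit <- IRanges::overlapsAny(gt, gp)
  list(high = transcripts$transcript_id[hit],
       low = transcripts$transcript_id[!hit])
}

#' Significance tier of a p-value
#'
#' Tier mapping used in the figure legends: `NS` for p > 0.05, `*` for
#' p < 0.01, `**` for p < 1e-10, `****` for p < 2.2e-16. The legend leaves
#' the band 0.01 <= p <= 0.05 unnamed; it is reported as `ns*`.
#'
#' @param p p-value.
#' @return character tier.
#' @export
significance_tier <- function(p) {
  if (p < 2.2e-16) "****"
  else if (p < 1e-10) "**"
  else if (p < 0.01) "*"
  else if (p <= 0.05) "ns*"
  else "NS"
}

#' Compare two transcript groups by signal around the TSS
#'
#' Computes, per transcript, the mean of the (ratio) track in the window
#' `TSS +/- window`, then compares the two groups with a two-sided Wilcoxon
#' rank-sum test and reports the significance tier.
#'
#' @param track signal (or ratio) track.
#' @param group_a,group_b disjoint transcript tables, each with >= 5 usable
#'   transcripts.
#' @param window half-width in bp (default 1000).
#' @return list with `values_a`, `values_b` (per-transcript means),
#'   `p_value`, `tier`.
#' @export
compare_groups_at_tss <- function(track, group_a, group_b, window = 1000) {
  if (length(intersect(group_a$transcript_id, group_b$transcript_id)) > 0)
    stop("groups must be disjoint")
  mean_at_tss <- function(tr) {
    anchors <- tss(tr)
    v <- vapply(seq_len(nrow(tr)), function(i) {
      w <- .window_values(track, tr$chrom[i], anchors[i] - window,
                          anchors[i] + window)
      if (is.null(w)) NA_real_ else mean(w)
    }, numeric(1))
    v[!is.na(v)]
  }
  va <- mean_at_tss(group_a)
  vb <- mean_at_tss(group_b)
  if (length(va) < 5 || length(vb) < 5)
    stop("each group needs at least 5 usable transcripts")
  p <- stats::wilcox.test(va, vb, alternative = "two.sided", exact = FALSE)$p.value
  list(values_a = va, values_b = vb, p_value = p, tier = significance_tier(p))
}
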