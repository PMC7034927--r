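# Synthetic-data generator: seeded toy genomes with coding genes, intergenic
# and antisense lncRNAs, fractionated NB counts with planted chromatin
# classes, ChIP/input tracks with planted high-mark groups, and motif sets
# with planted containment rates. Every stage reads its parameters from a
# single config and all randomness flows from the single seed.

#' Simulation configuration
#'
#' Collects every generator parameter with its default. Defaults describe the
#' reference fixture: a 5 x 1 Mb toy genome carrying 500 coding genes, 300
#' intergenic and 200 antisense lncRNAs (1000 expressed transcripts in total)
#' plus 200 sub-threshold noise transcripts; 200 planted cheRNAs and 200
#' sneRNAs at |log2 fold-change| = 2 with NB dispersion 0.1 and 5 CPE + 5 SNE
#' replicates; library sizes log-normal around 1e6.
#'
#' @param seed integer seed (mandatory); all stage seeds derive from it.
#' @param n_chroms,chrom_length toy genome geometry (bp).
#' @param n_coding,n_intergenic,n_antisense,n_noise transcript counts.
#' @param gene_length,gene_gap,lnc_length,as_length uniform length/gap ranges
#'   (bp) for coding genes, inter-gene gaps, intergenic and antisense lncRNAs.
#' @param n_che,n_sne planted class sizes among expressed transcripts.
#' @param che_mix,sne_mix allocation of the planted classes over the
#'   positional groups (`intergenic`, `antisense`, `coding`).
#' @param log2fc planted |log2 fold-change| (CPE over SNE).
#' @param nb_dispersion NB dispersion phi (variance = mu + phi mu^2).
#' @param n_replicates replicates per fraction per cell type.
#' @param cell_types character vector of simulated cell types.
#' @param base_cpm_meanlog,base_cpm_sdlog,base_cpm_floor log-normal mean CPM
#'   of expressed transcripts, floored so every expressed transcript clears
#'   the noise filter.
#' @param noise_cpm_meanlog,noise_cpm_sdlog,noise_cpm_cap log-normal mean CPM
#'   of noise transcripts, capped well below the filter threshold.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library sizes.
#' @param corr_effect weight of the latent per-sample factor shared between
#'   an intergenic lncRNA and its designated neighbor gene; 1.5 yields a
#'   latent log-expression correlation around 0.95. The default is 0 so that
#'   the reference fixture's counts are exactly NB at the declared
#'   dispersion; correlation-analysis fixtures switch it on explicitly (the
#'   factor is genuine per-sample covariation and correspondingly inflates
#'   the within-fraction variance of the transcripts that carry it).
#' @param n_high_mark number of transcripts planted in the high-mark group.
#' @param peak_offset,peak_sd,peak_amplitude geometry of the two Gaussian
#'   ChIP bumps flanking each high-mark TSS (the signal dips at the TSS
#'   itself, emulating the precipitous drop seen at active start sites).
#' @param track_baseline Poisson mean of the smoothed background coverage.
#' @param proximity bp used both to place peaks clear of other transcripts
#'   and as the default grouping proximity.
#' @param motif_background_rate,motif_enriched_rate per-family containment
#'   probabilities for background and enriched transcript sets.
#' @param motif_enriched_families super-families planted as overrepresented
#'   in antisense cheRNAs.
#' @param motif_length motif length range (bp).
#' @return a `SimulationConfig` list.
#' @export
sim_config <- function(seed,
                       n_chroms = 5, chrom_length = 1e6,
                       n_coding = 500, n_intergenic = 300,
                       n_antisense = 200, n_noise = 200,
                       gene_length = c(2000, 5000), gene_gap = c(2500, 6500),
                       lnc_length = c(300, 2000), as_length = c(500, 2000),
                       n_che = 200, n_sne = 200,
                       che_mix = c(intergenic = 0.6, antisense = 0.3, coding = 0.1),
                       sne_mix = c(intergenic = 0.15, antisense = 0.2, coding = 0.65),
                       log2fc = 2, nb_dispersion = 0.1, n_replicates = 5,
                       cell_types = "K562",
                       base_cpm_meanlog = log(30), base_cpm_sdlog = 1,
                       base_cpm_floor = 5,
                       noise_cpm_meanlog = log(0.02), noise_cpm_sdlog = 0.5,
                       noise_cpm_cap = 0.05,
                       lib_size_meanlog = log(1e6), lib_size_sdlog = 0.2,
                       corr_effect = 0,
                       n_high_mark = 50, peak_offset = 500, peak_sd = 250,
                       peak_amplitude = 50, track_baseline = 5,
                       proximity = 1000,
                       motif_background_rate = 0.05,
                       motif_enriched_rate = 0.25,
                       motif_enriched_families = c("histone", "lncRNA", "antisense"),
                       motif_length = c(80, 300)) {
  if (missing(seed)) stop("seed is mandatory")
  cfg <- as.list(environment())
  stopifnot(cfg$nb_dispersion > 0, cfg$n_replicates >= 1)
  class(cfg) <- "SimulationConfig"
  cfg
}

.sim_seed <- function(cfg, stage) as.integer(cfg$seed) + stage

# split [start, end) into 1-3 exons separated by introns
.make_exons <- function(start, end) {
  len <- end - start
  k <- if (len < 600) 1L else sample(1:3, 1)
  if (k == 1) return(cbind(start = start, end = end))
  cuts <- sort(sample(seq(start + 50, end - 50), 2 * (k - 1)))
  bounds <- c(start, cuts, end)
  ex <- matrix(bounds, ncol = 2, byrow = TRUE)
  colnames(ex) <- c("start", "end")
  ex
}

#' Simulate a toy genome annotation with ground truth
#'
#' Coding genes are laid end to end with random gaps; intergenic lncRNAs are
#' dropped into gaps with at least one base of clearance, so they overlap no
#' coding gene; antisense lncRNAs are placed strictly inside a host gene on
#' the opposite strand; noise transcripts reuse the intergenic geometry but
#' are flagged unexpressed. Planted chromatin classes are allocated over the
#' positional groups per the configured mixes, and each intergenic expressed
#' transcript is assigned its nearest same-strand coding gene (closest side)
#' as correlation partner with sign +1 for cheRNAs, -1 for sneRNAs, 0
#' otherwise (each gene serves at most one lncRNA).
#'
#' @param cfg a [sim_config()].
#' @return list with `$annotation` (a [genome_annotation()]) and `$truth`
#'   (data.frame with per-transcript `kind`, `positional_class`, `expressed`,
#'   `chromatin_class`, `log2fc`, `corr_gene`, `corr_sign`).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(.sim_seed(cfg, 0L))
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  chrom_sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)

  per_chrom <- diff(round(seq(0, cfg$n_coding, length.out = cfg$n_chroms + 1)))
  genes <- NULL
  gaps <- NULL   # free intervals between consecutive genes
  gid <- 0
  for (ci in seq_along(chroms)) {
    pos <- 0
    for (k in seq_len(per_chrom[ci])) {
      gap <- round(stats::runif(1, cfg$gene_gap[1], cfg$gene_gap[2]))
      len <- round(stats::runif(1, cfg$gene_length[1], cfg$gene_length[2]))
      s <- pos + gap
      e <- s + len
      if (e > cfg$chrom_length - cfg$gene_gap[2])
        stop("infeasible geometry: chromosome ", chroms[ci], " overflows")
      gid <- gid + 1
      genes <- rbind(genes, data.frame(
        transcript_id = sprintf("gene_%04d", gid), chrom = chroms[ci],
        start = s, end = e, strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE))
      if (k > 1)
        gaps <- rbind(gaps, data.frame(chrom = chroms[ci], lo = pos, hi = s,
                                       stringsAsFactors = FALSE))
      pos <- e
    }
  }

  place_in_gaps <- function(n, prefix, len_range) {
    out <- NULL
    for (k in seq_len(n)) {
      g <- gaps[sample(nrow(gaps), 1), ]
      avail <- g$hi - g$lo - 2          # >= 1 base clearance on both sides
      len <- min(round(stats::runif(1, len_range[1], len_range[2])), avail)
      s <- g$lo + 1 + sample(avail - len + 1, 1) - 1
      out <- rbind(out, data.frame(
        transcript_id = sprintf("%s_%04d", prefix, k), chrom = g$chrom,
        start = s, end = s + len, strand = sample(c("+", "-"), 1),
        stringsAsFactors = FALSE))
    }
    out
  }
  lnc <- place_in_gaps(cfg$n_intergenic, "lnc", cfg$lnc_length)
  noise <- if (cfg$n_noise > 0) place_in_gaps(cfg$n_noise, "noise", cfg$lnc_length)

  hosts <- genes[sample(nrow(genes), cfg$n_antisense), ]
  asr <- NULL
  for (k in seq_len(cfg$n_antisense)) {
    h <- hosts[k, ]
    avail <- h$end - h$start - 2
    len <- min(round(stats::runif(1, cfg$as_length[1], cfg$as_length[2])), avail)
    s <- h$start + 1 + sample(avail - len + 1, 1) - 1
    asr <- rbind(asr, data.frame(
      transcript_id = sprintf("as_%04d", k), chrom = h$chrom,
      start = s, end = s + len,
      strand = if (h$strand == "+") "-" else "+", stringsAsFactors = FALSE))
  }

  all_df <- rbind(
    cbind(genes, kind = "coding"),
    if (cfg$n_intergenic > 0) cbind(lnc, kind = "intergenic"),
    if (cfg$n_antisense > 0) cbind(asr, kind = "antisense"),
    if (cfg$n_noise > 0) cbind(noise, kind = "noise")
  )
  exons <- lapply(seq_len(nrow(all_df)),
                  function(i) .make_exons(all_df$start[i], all_df$end[i]))
  tr <- transcript_models(
    transcript_id = all_df$transcript_id, chrom = all_df$chrom,
    start = all_df$start, end = all_df$end, strand = all_df$strand,
    biotype = ifelse(all_df$kind == "coding", "protein_coding", "other"),
    annotated = all_df$kind == "coding", exons = exons)
  ann <- genome_annotation(tr, chrom_sizes)

  truth <- data.frame(
    transcript_id = all_df$transcript_id, kind = all_df$kind,
    positional_class = c(coding = "sense_overlap", intergenic = "intergenic",
                         antisense = "antisense", noise = "intergenic")[all_df$kind],
    expressed = all_df$kind != "noise",
    chromatin_class = NA_character_, log2fc = 0,
    corr_gene = NA_character_, corr_sign = 0L,
    mark_group = NA_character_, stringsAsFactors = FALSE)

  # allocate planted chromatin classes over positional groups
  alloc <- function(n_total, mix) {
    sizes <- c(intergenic = cfg$n_intergenic, antisense = cfg$n_antisense,
               coding = cfg$n_coding)
    want <- round(n_total * mix[names(sizes)])
    want[is.na(want)] <- 0
    want <- pmin(want, sizes)
    # fix rounding drift deterministically on the largest group
    drift <- n_total - sum(want)
    if (drift != 0) want["coding"] <- min(sizes["coding"], want["coding"] + drift)
    want
  }
  expressed_ids <- split(truth$transcript_id[truth$expressed],
                         c(coding = "coding", intergenic = "intergenic",
                           antisense = "antisense")[truth$kind[truth$expressed]])
  assign_class <- function(quota, cls, taken) {
    for (grp in names(quota)) {
      pool <- setdiff(expressed_ids[[grp]], taken)
      pick <- if (quota[grp] > 0) sample(pool, min(quota[grp], length(pool))) else character(0)
      truth$chromatin_class[match(pick, truth$transcript_id)] <<- cls
      taken <- c(taken, pick)
    }
    taken
  }
  taken <- character(0)
  if (cfg$n_che > 0) taken <- assign_class(alloc(cfg$n_che, cfg$che_mix), "cheRNA", taken)
  if (cfg$n_sne > 0) taken <- assign_class(alloc(cfg$n_sne, cfg$sne_mix), "sneRNA", taken)
  truth$chromatin_class[truth$expressed & is.na(truth$chromatin_class)] <- "independent"
  truth$log2fc <- ifelse(truth$chromatin_class %in% "cheRNA", cfg$log2fc,
                         ifelse(truth$chromatin_class %in% "sneRNA", -cfg$log2fc, 0))
  truth$log2fc[is.na(truth$chromatin_class)] <- 0

  # designate neighbor-gene correlation partners for intergenic transcripts
  iche <- truth$transcript_id[truth$expressed & truth$kind == "intergenic"]
  fl <- flanking_genes(tr[match(iche, tr$transcript_id), , drop = FALSE],
                       coding_genes(tr), same_strand = TRUE)
  used_genes <- character(0)
  for (i in seq_len(nrow(fl))) {
    side <- if (is.na(fl$upstream[i])) "downstream"
            else if (is.na(fl$downstream[i])) "upstream"
            else if (fl$downstream_gap[i] <= fl$upstream_gap[i]) "downstream"
            else "upstream"
    g <- fl[[side]][i]
    if (is.na(g) || g %in% used_genes) next
    used_genes <- c(used_genes, g)
    j <- match(fl$rna_id[i], truth$transcript_id)
    truth$corr_gene[j] <- g
    cls <- truth$chromatin_class[j]
    truth$corr_sign[j] <- if (identical(cls, "cheRNA")) 1L
                          else if (identical(cls, "sneRNA")) -1L else 0L
  }
  list(annotation = ann, truth = truth)
}

#' Simulate fractionated NB counts with planted classes
#'
#' Expressed transcripts draw a log-normal baseline mean CPM (floored);
#' planted cheRNAs get mean ratio `2^log2fc` between CPE and SNE (split
#' symmetrically), sneRNAs the inverse, independent transcripts equal means.
#' Noise transcripts draw sub-threshold CPM. Where `truth$corr_gene` is set
#' with a nonzero `corr_sign`, a shared standard-normal factor per sample
#' multiplies both the lncRNA's and the gene's mean by `exp(sign * w * z)`,
#' inducing the configured correlation sign.
#' Counts are NB with variance `mu + phi mu^2`; library sizes are log-normal.
#'
#' @param cfg a [sim_config()].
#' @param truth truth table from [simulate_annotation()] (possibly edited to
#'   re-plant classes or correlation partners).
#' @return list with `$counts` (a [count_matrix()]) and `$truth`.
#' @export
simulate_counts <- function(cfg, truth) {
  set.seed(.sim_seed(cfg, 1L))
  samples <- do.call(rbind, lapply(cfg$cell_types, function(ct) {
    data.frame(
      id = c(sprintf("%s_CPE_%d", ct, seq_len(cfg$n_replicates)),
             sprintf("%s_SNE_%d", ct, seq_len(cfg$n_replicates))),
      fraction = rep(c("CPE", "SNE"), each = cfg$n_replicates),
      cell_type = ct,
      replicate = rep(seq_len(cfg$n_replicates), 2),
      stringsAsFactors = FALSE)
  }))
  ns <- nrow(samples)
  n <- nrow(truth)
  base_cpm <- numeric(n)
  ex <- truth$expressed
  # left-truncated log-normal (inverse CDF), so the floor guarantees every
  # expressed transcript clears the filter without a point mass at the floor
  p0 <- stats::plnorm(cfg$base_cpm_floor, cfg$base_cpm_meanlog,
                      cfg$base_cpm_sdlog)
  base_cpm[ex] <- stats::qlnorm(stats::runif(sum(ex), p0, 1),
                                cfg$base_cpm_meanlog, cfg$base_cpm_sdlog)
  base_cpm[!ex] <- pmin(stats::rlnorm(sum(!ex), cfg$noise_cpm_meanlog,
                                      cfg$noise_cpm_sdlog), cfg$noise_cpm_cap)
  lib <- stats::rlnorm(ns, cfg$lib_size_meanlog, cfg$lib_size_sdlog)

  # fraction effect: CPE mean = base * 2^(lfc/2), SNE mean = base * 2^(-lfc/2)
  half <- outer(truth$log2fc / 2,
                ifelse(samples$fraction == "CPE", 1, -1))
  mu <- base_cpm * 2^half

  # latent shared factors for designated lncRNA-gene pairs
  w <- cfg$corr_effect
  if (w > 0) {
    pairs <- which(truth$corr_sign != 0 & !is.na(truth$corr_gene))
    for (i in pairs) {
      z <- stats::rnorm(ns)
      # uncentered on purpose: the factor's mean exp(w^2/2) lifts the planted
      # pairs above the log-prior flattening regime, so the induced
      # correlation survives the log2(FPKM + 1) transform
      f_rna <- exp(w * z)
      f_gene <- exp(truth$corr_sign[i] * w * z)
      mu[i, ] <- mu[i, ] * f_rna
      j <- match(truth$corr_gene[i], truth$transcript_id)
      mu[j, ] <- mu[j, ] * f_gene
    }
  }
  mu <- sweep(mu, 2, lib / 1e6, "*")
  counts <- matrix(stats::rnbinom(n * ns, mu = mu, size = 1 / cfg$nb_dispersion),
                   nrow = n, dimnames = list(truth$transcript_id, samples$id))
  list(counts = count_matrix(counts, samples), truth = truth)
}

#' Simulate ChIP/input tracks and peak calls with a planted high-mark group
#'
#' The input track is smoothed Poisson noise. The ChIP track adds, for each
#' transcript planted in the high-mark group, two Gaussian bumps flanking its
#' TSS (centers at `+/- peak_offset`, sd `peak_sd`) so the signal is high
#' around but dips at the TSS. Matching peak intervals are emitted. High-mark
#' transcripts are chosen among expressed intergenic cheRNAs (all expressed
#' intergenic transcripts when no classes are planted) whose peak
#' neighborhood, extended by `proximity`, clears every other noncoding
#' transcript, so that peak-proximity grouping over the candidate set
#' recovers the planted partition exactly. Remaining candidates are labelled
#' `low`; transcripts outside the candidate set keep `NA` (mark grouping is
#' an analysis of a chosen transcript set, not of the whole annotation).
#' Both tracks are RPM-scaled.
#'
#' @param cfg a [sim_config()].
#' @param annotation a `GenomeAnnotation` from [simulate_annotation()].
#' @param truth matching truth table.
#' @return list with `$chip`, `$input` (RPM-scaled `RleList` tracks),
#'   `$peaks` (BED-style data.frame) and `$truth` (with `mark_group` filled).
#' @export
simulate_tracks <- function(cfg, annotation, truth) {
  set.seed(.sim_seed(cfg, 2L))
  tr <- annotation$transcripts
  sizes <- annotation$chrom_sizes
  # smoothed Poisson noise generated on a 10 bp grid (keeps the run-length
  # encoding and emitted bedGraphs compact) and expanded to per-base values
  smooth_noise <- function() {
    lapply(sizes, function(L) {
      step <- 10L
      nb <- ceiling(L / step)
      x <- stats::rpois(nb, cfg$track_baseline * step) / step
      k <- 11L
      cs <- c(0, cumsum(x))
      lo <- pmax(0L, seq_len(nb) - (k %/% 2L) - 1L)
      hi <- pmin(nb, seq_len(nb) + (k %/% 2L))
      sm <- (cs[hi + 1L] - cs[lo + 1L]) / (hi - lo)
      rep(sm, each = step)[seq_len(L)]
    })
  }
  input <- smooth_noise()
  chip <- smooth_noise()

  # candidate set: expressed intergenic cheRNAs (all expressed intergenic
  # transcripts when no classes are planted)
  cand <- truth$transcript_id[truth$expressed &
                              truth$kind == "intergenic" &
                              truth$chromatin_class %in% "cheRNA"]
  if (length(cand) == 0)
    cand <- truth$transcript_id[truth$expressed & truth$kind == "intergenic"]
  reach <- cfg$peak_offset + 3 * cfg$peak_sd
  ext <- cfg$peak_offset + 300 + cfg$proximity   # peak edge + proximity
  high <- character(0)
  peaks <- NULL
  nc <- tr[tr$biotype != "protein_coding", , drop = FALSE]
  gr_nc <- as_granges(nc, use_strand = FALSE)
  for (id in sample(cand)) {
    if (length(high) >= cfg$n_high_mark) break
    i <- match(id, tr$transcript_id)
    a <- tss(tr[i, ])
    lo <- a - reach; hi <- a + reach
    if (lo < 0 || hi > sizes[tr$chrom[i]]) next
    # peak neighborhood must clear every other candidate transcript (the
    # grouped universe), so that proximity grouping recovers the partition
    zone <- GenomicRanges::GRanges(tr$chrom[i],
                                   IRanges::IRanges(max(1, a - ext + 1), a + ext))
    hits <- S4Vectors::subjectHits(GenomicRanges::findOverlaps(zone, gr_nc))
    near <- nc$transcript_id[hits]
    if (any(near != id & near %in% cand)) next
    high <- c(high, id)
    # two Gaussian bumps flanking the TSS
    pos <- lo:(hi - 1)
    bump <- cfg$peak_amplitude * cfg$peak_sd * sqrt(2 * pi) *
      (stats::dnorm(pos, a - cfg$peak_offset, cfg$peak_sd) +
       stats::dnorm(pos, a + cfg$peak_offset, cfg$peak_sd))
    chip[[tr$chrom[i]]][pos + 1] <- chip[[tr$chrom[i]]][pos + 1] + bump
    peaks <- rbind(peaks, data.frame(
      chrom = tr$chrom[i],
      start = c(a - cfg$peak_offset - 300, a + cfg$peak_offset - 300),
      end = c(a - cfg$peak_offset + 300, a + cfg$peak_offset + 300),
      name = paste0(id, c("_pk1", "_pk2")), score = cfg$peak_amplitude,
      strand = "*", stringsAsFactors = FALSE))
  }
  truth$mark_group <- NA_character_
  truth$mark_group[truth$transcript_id %in% cand] <- "low"
  truth$mark_group[truth$transcript_id %in% high] <- "high"
  list(chip = rpm_scale(signal_track(chip, "chip")),
       input = rpm_scale(signal_track(input, "input")),
       peaks = if (is.null(peaks)) data.frame() else peaks,
       truth = truth)
}

#' Simulate motif interval sets with planted containment rates
#'
#' For each of fourteen structural super-families, each noncoding expressed
#' transcript contains a motif of that family with the background rate,
#' except that antisense cheRNAs contain motifs of the configured enriched
#' families at the elevated rate. Motifs are placed fully inside the
#' transcript span on the same strand.
#'
#' @param cfg a [sim_config()].
#' @param annotation a `GenomeAnnotation`.
#' @param truth matching truth table (chromatin classes filled).
#' @return list with `$motifs` (BED-style data.frame with `family`) and
#'   `$planted` (data.frame `transcript_id`, `family`).
#' @export
simulate_motifs <- function(cfg, annotation, truth) {
  set.seed(.sim_seed(cfg, 3L))
  tr <- annotation$transcripts
  fams <- default_superfamilies()$superfamily
  fams <- unique(fams)
  nc <- truth$expressed & tr$biotype[match(truth$transcript_id, tr$transcript_id)] != "protein_coding"
  as_che <- truth$kind == "antisense" & truth$chromatin_class %in% "cheRNA"
  motifs <- NULL; planted <- NULL
  for (f in fams) {
    rate <- ifelse(nc & as_che & f %in% cfg$motif_enriched_families,
                   cfg$motif_enriched_rate,
                   ifelse(nc, cfg$motif_background_rate, 0))
    hit <- stats::rbinom(nrow(truth), 1, rate) == 1
    for (i in which(hit)) {
      j <- match(truth$transcript_id[i], tr$transcript_id)
      len <- tr$end[j] - tr$start[j]
      ml <- min(round(stats::runif(1, cfg$motif_length[1], cfg$motif_length[2])),
                len)
      s <- tr$start[j] + sample(len - ml + 1, 1) - 1
      motifs <- rbind(motifs, data.frame(
        chrom = tr$chrom[j], start = s, end = s + ml,
        name = paste0(f, "_", tr$transcript_id[j]), score = 0,
        strand = tr$strand[j], family = f, stringsAsFactors = FALSE))
      planted <- rbind(planted, data.frame(
        transcript_id = tr$transcript_id[j], family = f,
        stringsAsFactors = FALSE))
    }
  }
  list(motifs = motifs, planted = planted)
}

#' Simulate a complete fractionation experiment
#'
#' Runs [simulate_annotation()], [simulate_counts()], [simulate_tracks()] and
#' [simulate_motifs()] off one config and returns the bundle.
#'
#' @param cfg a [sim_config()].
#' @return list `annotation`, `truth`, `counts`, `chip`, `input`, `peaks`,
#'   `motifs`, `planted_motifs`, `config`.
#' @export
simulate_cherna_experiment <- function(cfg) {
  sim <- simulate_annotation(cfg)
  cts <- simulate_counts(cfg, sim$truth)
  trk <- simulate_tracks(cfg, sim$annotation, cts$truth)
  mot <- simulate_motifs(cfg, sim$annotation, trk$truth)
  list(annotation = sim$annotation, truth = trk$truth, counts = cts$counts,
       chip = trk$chip, input = trk$input, peaks = trk$peaks,
       motifs = mot$motifs, planted_motifs = mot$planted, config = cfg)
}
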