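# Pipeline orchestration: staged analysis from a single config, writing
# provenance-stamped TSV outputs. Stages never mutate each other's outputs;
# re-running a downstream stage from cached upstream files is identical.

#' Pipeline configuration
#'
#' Analysis parameters with their defaults, merged over a [sim_config()]
#' (or paths to pre-existing inputs).
#'
#' @param seed integer seed forwarded to the simulation config.
#' @param sim a [sim_config()]; defaults to `sim_config(seed)`.
#' @param cpm_threshold,min_fraction noise-filter parameters.
#' @param alpha_fdr FDR threshold of the enrichment call.
#' @param dispersion_shrink shrinkage weight of the dispersion estimator.
#' @param pcc_cutoff neighbor-correlation significance cutoff.
#' @param proximity bp for peak-proximity grouping.
#' @param half_window,bin_size TSS metagene window geometry (bp).
#' @param pseudocount ratio-track pseudo-count (RPM).
#' @param expression_method scale for correlation vectors.
#' @return a `PipelineConfig` list.
#' @export
pipeline_config <- function(seed, sim = NULL,
                            cpm_threshold = 1, min_fraction = 0.5,
                            alpha_fdr = 0.05, dispersion_shrink = 0.5,
                            pcc_cutoff = 0.8, proximity = 1000,
                            half_window = 1000, bin_size = 50,
                            pseudocount = 1,
                            expression_method = "log2fpkm") {
  if (is.null(sim)) sim <- sim_config(seed)
  cfg <- as.list(environment())
  class(cfg) <- "PipelineConfig"
  cfg
}

# provenance header + TSV body; deterministic (no timestamps)
write_stamped_tsv <- function(df, path, stage, params = list()) {
  hdr <- sprintf("# chefind %s; stage=%s%s", .chefind_version(), stage,
                 if (length(params))
                   paste0("; ", paste(names(params), unlist(params),
                                      sep = "=", collapse = "; "))
                 else "")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a provenance-stamped TSV
#'
#' @param path file written by the pipeline.
#' @return data.frame (the header comment is skipped).
#' @export
read_stamped_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Run the full analysis pipeline on a simulated fixture
#'
#' Stages: simulate (annotation, counts, tracks, peaks, motifs with ground
#' truth), filter (CPM noise filter), call (exact NB enrichment test),
#' classify (positional classes and combined labels), correlate (neighbor
#' pairing, relative-density curve against a random-gene control, cutoff
#' fractions), metagene (ChIP-vs-input TSS profiles of the high/low mark
#' groups with the rank-sum tier), rr (motif-family RR-scores of antisense
#' cheRNAs), fisher (cheRNA x antisense co-enrichment), evaluate (ROC-AUC
#' against the planted classes and canonical-locus PPV). Outputs are TSVs in
#' `outdir`; everything is deterministic given the seed.
#'
#' @param cfg a [pipeline_config()].
#' @param outdir output directory (created if missing).
#' @return invisible list of stage results.
#' @export
run_pipeline <- function(cfg, outdir) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  seed <- cfg$seed

  ## simulate ---------------------------------------------------------------
  fx <- simulate_cherna_experiment(cfg$sim)
  ann <- fx$annotation
  tr <- ann$transcripts
  write_gtf(ann, p("annotation.gtf"))
  write_counts(fx$counts, p("counts.tsv"), p("samples.tsv"))
  write_bed(fx$peaks, p("peaks.bed"))
  write_bed(fx$motifs, p("motifs.bed"), extra_cols = "family")
  write_bedgraph(fx$chip, p("chip.bedGraph"))
  write_bedgraph(fx$input, p("input.bedGraph"))
  write_stamped_tsv(fx$truth, p("truth.tsv"), "simulate",
                    list(seed = seed))

  ## filter -----------------------------------------------------------------
  cpm <- compute_cpm(fx$counts)
  expressed <- filter_expressed(cpm, cfg$cpm_threshold, cfg$min_fraction)
  write_stamped_tsv(data.frame(transcript_id = expressed), p("expressed.tsv"),
                    "filter", list(seed = seed, cpm_threshold = cfg$cpm_threshold,
                                   min_fraction = cfg$min_fraction))

  ## call -------------------------------------------------------------------
  mexp <- count_matrix(fx$counts$counts[expressed, , drop = FALSE],
                       fx$counts$samples)
  disp <- estimate_dispersion(mexp, shrink = cfg$dispersion_shrink)
  calls <- test_fraction_enrichment(mexp, disp, alpha_fdr = cfg$alpha_fdr)

  ## classify ---------------------------------------------------------------
  coding <- coding_genes(ann)
  pos <- stats::setNames(
    classify_position(tr[match(expressed, tr$transcript_id), , drop = FALSE],
                      coding),
    expressed)
  calls <- combine_labels(calls, pos)
  write_stamped_tsv(calls, p("calls.tsv"), "call+classify",
                    list(seed = seed, alpha_fdr = cfg$alpha_fdr))

  ## correlate --------------------------------------------------------------
  lengths <- stats::setNames(tr$end - tr$start, tr$transcript_id)
  expr <- expression_vectors(fx$counts, lengths, method = cfg$expression_method)
  iche <- calls$transcript_id[calls$combined_label == "icheRNA"]
  corr_res <- NULL
  if (length(iche) >= 20) {
    fl <- flanking_genes(tr[match(iche, tr$transcript_id), , drop = FALSE],
                         coding, same_strand = TRUE)
    pairs <- pair_neighbor_gene(fl, expr)
    set.seed(seed + 100L)
    ctrl <- random_control_pccs(iche, coding$transcript_id, expr)
    ok <- sum(!is.na(pairs$pcc)) >= 20 && sum(!is.na(ctrl)) >= 20
    if (ok) {
      curve <- relative_density(pairs$pcc[!is.na(pairs$pcc)],
                                ctrl[!is.na(ctrl)])
      frac <- fraction_beyond_cutoff(pairs, cfg$pcc_cutoff)
      write_stamped_tsv(pairs, p("pairs.tsv"), "correlate",
                        list(seed = seed, pcc_cutoff = cfg$pcc_cutoff,
                             pos_fraction = signif(frac[1], 6),
                             neg_fraction = signif(frac[2], 6)))
      write_stamped_tsv(curve, p("relative_density.tsv"), "correlate",
                        list(seed = seed))
      corr_res <- list(pairs = pairs, curve = curve, fractions = frac)
    }
  }

  ## metagene ---------------------------------------------------------------
  ratio <- signal_vs_input(fx$chip, fx$input, pseudocount = cfg$pseudocount)
  grp <- group_by_mark(tr[match(expressed, tr$transcript_id), , drop = FALSE],
                       fx$peaks, proximity = cfg$proximity)
  high_tr <- tr[match(intersect(grp$high, iche), tr$transcript_id), , drop = FALSE]
  low_ids <- intersect(grp$low, iche)
  low_tr <- tr[match(utils::head(low_ids, max(nrow(high_tr), 5)),
                     tr$transcript_id), , drop = FALSE]
  meta_res <- NULL
  if (nrow(high_tr) >= 5 && nrow(low_tr) >= 5) {
    prof_high <- tss_profile(ratio, high_tr, cfg$half_window, cfg$bin_size)
    prof_low <- tss_profile(ratio, low_tr, cfg$half_window, cfg$bin_size)
    cmp <- compare_groups_at_tss(ratio, high_tr, low_tr, cfg$half_window)
    prof <- rbind(cbind(group = "high", prof_high),
                  cbind(group = "low", prof_low))
    write_stamped_tsv(prof, p("tss_profile.tsv"), "metagene",
                      list(seed = seed, proximity = cfg$proximity,
                           p_value = signif(cmp$p_value, 6), tier = cmp$tier))
    meta_res <- list(profile_high = prof_high, profile_low = prof_low,
                     comparison = cmp)
  }

  ## rr ---------------------------------------------------------------------
  noncoding <- calls$transcript_id[
    tr$biotype[match(calls$transcript_id, tr$transcript_id)] != "protein_coding"]
  as_che <- calls$transcript_id[calls$combined_label == "as-cheRNA"]
  rr_res <- NULL
  if (length(as_che) >= 5 && length(noncoding) >= 20 && !is.null(fx$motifs)) {
    rr_res <- rr_table(as_che, noncoding,
                       tr[match(noncoding, tr$transcript_id), , drop = FALSE],
                       fx$motifs)
    write_stamped_tsv(rr_res, p("rr.tsv"), "rr", list(seed = seed))
  }

  ## fisher -----------------------------------------------------------------
  che_ids <- calls$transcript_id[calls$chromatin_class == "cheRNA"]
  as_ids <- calls$transcript_id[calls$positional_class == "antisense"]
  fish <- fisher_co_enrichment(che_ids, as_ids, calls$transcript_id)
  write_stamped_tsv(
    data.frame(n_both = fish$table[1, 1], n_A_only = fish$table[1, 2],
               n_B_only = fish$table[2, 1], n_neither = fish$table[2, 2],
               odds_ratio = fish$odds_ratio, p_value = fish$p_value,
               enriched = fish$enriched),
    p("fisher.tsv"), "fisher", list(seed = seed))

  ## evaluate ---------------------------------------------------------------
  truth_exp <- fx$truth[fx$truth$transcript_id %in% expressed, ]
  gs <- list(positive_ids = truth_exp$transcript_id[
               truth_exp$chromatin_class %in% "cheRNA"],
             universe = truth_exp$transcript_id)
  roc <- roc_auc(enrichment_scores(calls), gs)
  set.seed(seed + 200L)
  canon <- do.call(rbind, lapply(c("cheRNA", "sneRNA", "independent"),
    function(cl) {
      ids <- truth_exp$transcript_id[truth_exp$chromatin_class %in% cl]
      data.frame(locus_id = sample(ids, min(6, length(ids))),
                 expected_class = cl, stringsAsFactors = FALSE)
    }))
  canon <- utils::head(canon, 16)
  ppv <- ppv_canonical(stats::setNames(calls$chromatin_class,
                                       calls$transcript_id), canon)
  write_stamped_tsv(
    data.frame(metric = c("auc_cheRNA", "ppv_canonical", "n_expressed",
                          "n_cheRNA", "n_sneRNA"),
               value = c(roc$auc, ppv, length(expressed),
                         sum(calls$chromatin_class == "cheRNA"),
                         sum(calls$chromatin_class == "sneRNA"))),
    p("metrics.tsv"), "evaluate", list(seed = seed))

  invisible(list(annotation = ann, truth = fx$truth, counts = fx$counts,
                 expressed = expressed, calls = calls, correlation = corr_res,
                 metagene = meta_res, rr = rr_res, fisher = fish,
                 roc = roc, ppv = ppv, outdir = outdir))
}
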