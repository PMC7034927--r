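# Annotation model, GTF I/O, the 1-base overlap rule, positional
# classification, and flanking-gene lookup.

test_that("GTF parsing converts 1-based inclusive to 0-based half-open", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1"; gene_biotype "other"; annotated "FALSE";',
    'chr1\tsrc\texon\t101\t140\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    'chr1\tsrc\texon\t161\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";'
  ), gtf)
  ann <- read_gtf(gtf)
  tr <- ann$transcripts
  expect_equal(nrow(tr), 1)
  expect_equal(tr$start, 100)
  expect_equal(tr$end, 200)
  expect_equal(tr$end - tr$start, 100)
  expect_equal(nrow(tr$exons[[1]]), 2)
  expect_equal(unname(tr$exons[[1]][, "start"]), c(100, 160))
  expect_equal(unname(tr$exons[[1]][, "end"]), c(140, 200))
  expect_false(tr$annotated)
})

test_that("malformed GTF lines are reported with their line number", {
  gtf <- tempfile(fileext = ".gtf")
  writeLines(c(
    'chr1\tsrc\ttranscript\t101\t200\t.\t+\t.\tgene_id "g1"; transcript_id "t1";',
    "chr1\tbroken line"
  ), gtf)
  expect_error(read_gtf(gtf), "line 2")
})

test_that("exons outside their transcript fail validation", {
  expect_error(
    transcript_models("t1", "chr1", 100, 200, "+",
                      exons = list(cbind(start = 50, end = 150))),
    "exon outside"
  )
})

test_that("a 50-transcript synthetic annotation round-trips through GTF", {
  cfg <- sim_config(seed = 7, n_chroms = 2, n_coding = 30, n_intergenic = 12,
                    n_antisense = 8, n_noise = 0, n_che = 10, n_sne = 10)
  ann <- simulate_annotation(cfg)$annotation
  f1 <- tempfile(fileext = ".gtf")
  write_gtf(ann, f1)
  back <- read_gtf(f1, chrom_sizes = ann$chrom_sizes)
  a <- ann$transcripts[order(ann$transcripts$transcript_id), ]
  b <- back$transcripts[order(back$transcripts$transcript_id), ]
  for (col in c("transcript_id", "gene_id", "chrom", "start", "end",
                "strand", "biotype", "annotated")) {
    expect_equal(a[[col]], b[[col]], info = col)
  }
  for (i in seq_len(nrow(a))) {
    expect_equal(unname(a$exons[[i]]), unname(b$exons[[i]]))
  }
  # second round trip is byte-identical
  f2 <- tempfile(fileext = ".gtf")
  write_gtf(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("overlap rule: >= 1 base counts, half-open adjacency does not", {
  a <- toy_transcripts(0, 100, "+")
  b1 <- toy_transcripts(99, 200, "+", ids = "b1")
  b2 <- toy_transcripts(100, 200, "+", ids = "b2")
  expect_true(overlaps(a, b1, same_strand = TRUE))
  expect_false(overlaps(a, b2))
  # strand gate
  c1 <- toy_transcripts(50, 60, "-", ids = "c1")
  expect_false(overlaps(a, c1, same_strand = TRUE))
  expect_true(overlaps(a, c1, same_strand = FALSE))
  expect_error(overlaps(a, b1, min_bases = 0), "min_bases")
})

test_that("overlaps is symmetric and matches a base-set oracle on 200 random intervals", {
  set.seed(3)
  n <- 200
  s <- sample(0:2000, n, replace = TRUE)
  len <- sample(1:150, n, replace = TRUE)
  iv <- toy_transcripts(s, s + len, sample(c("+", "-"), n, replace = TRUE))
  idx <- t(combn(n, 2))
  # subsample pairs for the symmetric check, full set against the oracle
  for (k in seq_len(nrow(idx))) {
    i <- idx[k, 1]; j <- idx[k, 2]
    got <- overlaps(iv[i, ], iv[j, ])
    want <- bf_overlap_bases(iv$start[i], iv$end[i], iv$start[j], iv$end[j]) >= 1
    if (got != want) fail(sprintf("pair %d-%d disagrees with oracle", i, j))
    got_strand <- overlaps(iv[i, ], iv[j, ], same_strand = TRUE)
    want_strand <- want && iv$strand[i] == iv$strand[j]
    if (got_strand != want_strand) fail(sprintf("pair %d-%d strand gate", i, j))
    if (got != overlaps(iv[j, ], iv[i, ]))
      fail(sprintf("pair %d-%d not symmetric", i, j))
  }
  succeed()
})

test_that("positional classification follows the sense > antisense > intergenic rule order", {
  coding <- toy_transcripts(c(1000, 20000), c(5000, 25000), c("+", "-"),
                            ids = c("g1", "g2"), biotype = "protein_coding")
  qs <- toy_transcripts(
    c(2000, 2000, 35000, 21000),
    c(3000, 3000, 36000, 22000),
    c("+", "-", "+", "-"),
    ids = c("inside_same", "inside_opp", "far", "inside_g2_same"))
  cls <- classify_position(qs, coding)
  expect_equal(cls, c("sense_overlap", "antisense", "intergenic", "sense_overlap"))
})

test_that("the three positional classes partition any annotation", {
  fx <- default_fixture()
  tr <- fx$annotation$transcripts
  cls <- classify_position(tr, coding_genes(fx$annotation))
  expect_length(cls, nrow(tr))
  expect_true(all(cls %in% c("sense_overlap", "antisense", "intergenic")))
  expect_identical(cls, fx$truth$positional_class)
})

test_that("flanking genes: nearest per side, boundary handling", {
  coding <- toy_transcripts(c(1000, 3000, 20000), c(2000, 4000, 21000),
                            "+", ids = c("gA", "gB", "gC"),
                            biotype = "protein_coding")
  # query between gB (gap 5 kb) and gC (gap 11 kb)
  q <- toy_transcripts(9000, 9500, "+", ids = "q")
  fl <- flanking_genes(q, coding)
  expect_equal(fl$upstream, "gB")
  expect_equal(fl$downstream, "gC")
  expect_equal(fl$upstream_gap, 5000)
  expect_equal(fl$downstream_gap, 10500)
  # at chromosome start: no upstream
  q2 <- toy_transcripts(100, 200, "+", ids = "q2")
  fl2 <- flanking_genes(q2, coding)
  expect_true(is.na(fl2$upstream))
  expect_equal(fl2$downstream, "gA")
})

test_that("flanking genes agree with a brute-force scan on 100 random layouts", {
  set.seed(11)
  for (rep in 1:100) {
    ng <- sample(3:8, 1)
    gs <- sort(sample(seq(0, 50000, by = 100), ng))
    coding <- toy_transcripts(gs, gs + 80, sample(c("+", "-"), ng, TRUE),
                              ids = paste0("g", seq_len(ng)),
                              biotype = "protein_coding")
    qpos <- sample(0:50000, 1)
    q <- toy_transcripts(qpos, qpos + 50, sample(c("+", "-"), 1), ids = "q")
    for (ss in c(FALSE, TRUE)) {
      fl <- flanking_genes(q, coding, same_strand = ss)
      cand <- coding
      if (ss) cand <- cand[cand$strand == q$strand, , drop = FALSE]
      up <- cand[cand$end <= q$start, , drop = FALSE]
      dn <- cand[cand$start >= q$end, , drop = FALSE]
      bf_up <- if (nrow(up)) up$transcript_id[which.max(up$end)] else NA_character_
      bf_dn <- if (nrow(dn)) dn$transcript_id[which.min(dn$start)] else NA_character_
      expect_identical(fl$upstream, bf_up)
      expect_identical(fl$downstream, bf_dn)
    }
  }
})
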