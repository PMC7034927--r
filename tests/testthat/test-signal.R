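# Signal tracks, metagene profiles, mark grouping, and significance tiers.

test_that("signal_vs_input is the elementwise pseudocounted ratio", {
  set.seed(1)
  v <- rpois(2000, 10)
  chip <- signal_track(list(chr1 = v))
  input <- signal_track(list(chr1 = v))
  r <- signal_vs_input(chip, input, pseudocount = 1)
  expect_true(all(as.numeric(r[["chr1"]]) == 1))
  # chip = 2 x input in the small-pseudocount limit
  chip2 <- signal_track(list(chr1 = 2 * v))
  r2 <- signal_vs_input(chip2, input, pseudocount = 1e-12)
  idx <- v > 0
  expect_equal(as.numeric(r2[["chr1"]])[idx], rep(2, sum(idx)), tolerance = 1e-6)
  # random tracks against the direct formula
  w <- rpois(2000, 5)
  r3 <- signal_vs_input(signal_track(list(chr1 = w)), input, pseudocount = 1)
  expect_equal(as.numeric(r3[["chr1"]]), (w + 1) / (v + 1))
  short <- signal_track(list(chr1 = v[1:10]))
  expect_error(signal_vs_input(chip, short), "chromosome space")
})

test_that("a constant track gives a flat TSS profile at its value", {
  tr <- toy_transcripts(c(3000, 6000), c(4000, 7000), c("+", "-"))
  prof <- tss_profile(flat_track(2.5), tr)
  expect_equal(prof$mean_ratio, rep(2.5, 40))
  expect_equal(attr(prof, "n_transcripts"), 2)
})

test_that("a unit impulse at each TSS lands in the single center bin", {
  tr <- toy_transcripts(c(3000, 6000), c(4000, 7000), c("+", "-"))
  v <- rep(0, 10000)
  v[3000 + 1] <- 50           # + strand TSS base (0-based 3000)
  v[7000 - 1 + 1] <- 50       # - strand 5' base is end - 1
  prof <- tss_profile(signal_track(list(chr1 = v)), tr)
  expect_equal(which(prof$mean_ratio > 0), 21)
  expect_equal(prof$mean_ratio[21], 1)   # 50 / 50-bp bin, averaged over 2
})

test_that("minus-strand profiles mirror the anchored plus-strand case", {
  set.seed(2)
  v <- rpois(10000, 3) + seq(0, 9.999, length.out = 10000)   # asymmetric
  track <- signal_track(list(chr1 = v))
  a <- 5000
  # both transcripts anchor the same window [a - hw, a + hw); the minus
  # strand one reads it 3' -> 5', so the binned profiles mirror exactly
  tp <- toy_transcripts(a, a + 800, "+", ids = "plus")
  tm <- toy_transcripts(a - 800, a, "-", ids = "minus")   # tss = end = a
  pp <- tss_profile(track, tp)
  pm <- tss_profile(track, tm)
  expect_equal(pm$mean_ratio, rev(pp$mean_ratio))
})

test_that("TSS profiles are linear in the track", {
  set.seed(3)
  v1 <- rpois(10000, 4)
  v2 <- rpois(10000, 7)
  tr <- toy_transcripts(c(2000, 5000, 8000), c(2500, 5600, 8900),
                        c("+", "-", "+"))
  p1 <- tss_profile(signal_track(list(chr1 = v1)), tr)
  p2 <- tss_profile(signal_track(list(chr1 = v2)), tr)
  p12 <- tss_profile(signal_track(list(chr1 = v1 + v2)), tr)
  expect_equal(p12$mean_ratio, p1$mean_ratio + p2$mean_ratio, tolerance = 1e-12)
})

test_that("out-of-bounds transcripts are dropped and counted", {
  tr <- toy_transcripts(c(500, 5000), c(900, 5400), c("+", "+"))
  prof <- tss_profile(flat_track(1), tr)   # window of the first leaves chr1
  expect_equal(attr(prof, "n_transcripts"), 1)
  expect_equal(attr(prof, "n_dropped"), 1)
})

test_that("body profiles: flat track, body-only signal, scaling invariance", {
  tr <- toy_transcripts(3000, 4000, "+")
  prof <- body_profile(flat_track(3), tr)
  expect_equal(prof$mean_ratio, rep(3, 140))
  # signal confined to the body
  v <- rep(0, 10000); v[3001:4000] <- 5
  p2 <- body_profile(signal_track(list(chr1 = v)), tr)
  expect_true(all(p2$mean_ratio[p2$position < 0] == 0))
  expect_true(all(p2$mean_ratio[p2$position > 100] == 0))
  expect_true(all(p2$mean_ratio[p2$position > 0 & p2$position < 100] == 5))
  # two lengths, same blockwise shape -> identical scaled profiles
  shape <- rep(seq_len(100), each = 10)          # 1000 bp, steps per 1%
  shape2 <- rep(seq_len(100), each = 20)         # 2000 bp, same shape
  w <- rep(0, 10000); w[3001:4000] <- shape; w[6001:8000] <- shape2
  t1 <- toy_transcripts(3000, 4000, "+", ids = "a")
  t2 <- toy_transcripts(6000, 8000, "+", ids = "b")
  b1 <- body_profile(signal_track(list(chr1 = w)), t1, flank = 0)
  b2 <- body_profile(signal_track(list(chr1 = w)), t2, flank = 0)
  expect_equal(b1$mean_ratio, b2$mean_ratio)
  # strand negation reverses the body profile exactly
  t1m <- t1; t1m$strand <- "-"
  b1m <- body_profile(signal_track(list(chr1 = w)), t1m, flank = 0)
  expect_equal(b1m$mean_ratio, rev(b1$mean_ratio))
  # too-short transcripts dropped with a warning
  tshort <- toy_transcripts(c(3000, 5000), c(4000, 5050), c("+", "+"))
  expect_warning(body_profile(signal_track(list(chr1 = w)), tshort), "dropped")
})

test_that("mark grouping matches a brute-force interval scan", {
  peaks <- data.frame(chrom = "chr1", start = c(1000, 8000),
                      end = c(1200, 8300))
  tr <- toy_transcripts(c(1050, 2500, 7200, 9350), c(1150, 3000, 7800, 9800),
                        "+", ids = c("inside", "far", "near800", "near1050"))
  g <- group_by_mark(tr, peaks, proximity = 1000)
  expect_setequal(g$high, c("inside", "near800"))
  expect_setequal(g$low, c("far", "near1050"))
  # proximity 0 equals span overlap
  g0 <- group_by_mark(tr, peaks, proximity = 0)
  expect_setequal(g0$high, "inside")
  # brute force on a random fixture
  set.seed(4)
  n <- 150
  s <- sample(0:50000, n)
  tr2 <- toy_transcripts(s, s + sample(50:500, n, TRUE), "+")
  ps <- sample(0:50000, 30)
  pk <- data.frame(chrom = "chr1", start = ps, end = ps + 200)
  for (prox in c(0, 250, 1000)) {
    got <- group_by_mark(tr2, pk, proximity = prox)
    bf_high <- tr2$transcript_id[vapply(seq_len(n), function(i) {
      any(pmin(tr2$end[i] + prox, pk$end) -
            pmax(tr2$start[i] - prox, pk$start) >= 1)
    }, logical(1))]
    expect_setequal(got$high, bf_high)
  }
  expect_error(group_by_mark(tr, peaks[0, ]), "empty")
})

test_that("significance tiers follow the legend mapping", {
  expect_equal(significance_tier(0.2), "NS")
  expect_equal(significance_tier(0.02), "ns*")   # unnamed legend gap
  expect_equal(significance_tier(0.001), "*")
  expect_equal(significance_tier(1e-12), "**")
  expect_equal(significance_tier(1e-17), "****")
})

test_that("group comparison at the TSS detects a planted shift", {
  set.seed(5)
  base <- rpois(60000, 5)
  starts_a <- seq(1500, by = 550, length.out = 50)
  starts_b <- seq(30000, by = 550, length.out = 50)
  v <- base
  for (s in starts_a) v[(s - 500):(s + 500) + 1] <- v[(s - 500):(s + 500) + 1] + 2
  track <- signal_track(list(chr1 = v))
  ga <- toy_transcripts(starts_a, starts_a + 400, "+",
                        ids = paste0("a", seq_along(starts_a)))
  gb <- toy_transcripts(starts_b, starts_b + 400, "+",
                        ids = paste0("b", seq_along(starts_b)))
  res <- compare_groups_at_tss(track, ga, gb, window = 500)
  expect_lt(res$p_value, 0.01)
  expect_true(res$tier %in% c("*", "**", "****"))
  # null case: both groups draw from the same background noise
  res0 <- compare_groups_at_tss(signal_track(list(chr1 = base)), ga, gb,
                                window = 500)
  expect_true(res0$tier %in% c("NS", "ns*"))
  expect_error(compare_groups_at_tss(track, ga, ga), "disjoint")
})
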