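# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# the reference fixture: 1000 expressed transcripts (200 che / 200 sne / 600
# independent at |log2fc| = 2, NB dispersion 0.1, 5+5 replicates), 200 noise
default_fixture <- function() {
  fixture("default", function() {
    cfg <- sim_config(seed = 1)
    sim <- simulate_annotation(cfg)
    cts <- simulate_counts(cfg, sim$truth)
    list(cfg = cfg, annotation = sim$annotation, truth = cts$truth,
         counts = cts$counts)
  })
}

# tracks/peaks over the reference fixture
default_tracks <- function() {
  fixture("tracks", function() {
    fx <- default_fixture()
    simulate_tracks(fx$cfg, fx$annotation, fx$truth)
  })
}

# quick transcript table on one chromosome
toy_transcripts <- function(starts, ends, strands, ids = NULL,
                            biotype = "other", chrom = "chr1") {
  if (is.null(ids)) ids <- paste0("t", seq_along(starts))
  transcript_models(ids, chrom, starts, ends, strands, biotype = biotype)
}

# constant-valued track over toy chromosomes
flat_track <- function(value, sizes = c(chr1 = 10000)) {
  signal_track(lapply(sizes, function(L) rep(value, L)))
}
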