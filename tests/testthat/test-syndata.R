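test_that("sim_config validates its inputs", {
  expect_s3_class(sim_config(n_genes = 10), "sim_config")
  expect_error(sim_config(target_fraction = 1.5), "target_fraction")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_error(sim_config(region_weights = c(0.5, 0.5, 0.5)), "sum")
  expect_error(sim_config(utr5_range = c(300, 100)), "increasing")
})

test_that("empty transcriptome for n_genes = 0", {
  sim <- simulate_transcriptome(sim_config(n_genes = 0))
  expect_equal(nrow(sim$transcripts), 0L)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("transcript regions partition the sequence and CDS is in frame", {
  sim <- simulate_transcriptome(sim_config(n_genes = 40, seed = 3))
  tx <- sim$transcripts
  expect_true(all(tx$utr5_len + tx$cds_len + tx$utr3_len == tx$length))
  expect_true(all(nchar(tx$sequence) == tx$length))
  expect_true(all(tx$cds_len %% 3 == 0))
})

test_that("observed target fraction is within the binomial 99% interval", {
  cfg <- sim_config(n_genes = 200, target_fraction = 0.3, seed = 1)
  sim <- simulate_transcriptome(cfg)
  n_t <- sum(sim$truth$is_target)
  bounds <- qbinom(c(0.005, 0.995), 200, 0.3)
  expect_gte(n_t, bounds[1])
  expect_lte(n_t, bounds[2])
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 30, depth_parclip = 500, depth_rna = 1e4,
                    depth_rpf = 1e4, seed = 11)
  run <- function() {
    sim <- simulate_transcriptome(cfg)
    list(
      sim = sim,
      reads = simulate_parclip_reads(sim$transcripts, sim$truth, cfg),
      counts = simulate_counts(sim$transcripts, sim$truth, cfg)
    )
  }
  a <- run()
  b <- run()
  expect_identical(a$sim, b$sim)
  expect_identical(a$reads, b$reads)
  expect_identical(a$counts, b$counts)
  # FASTA written from the same run is byte-identical
  f1 <- tempfile(fileext = ".fasta")
  f2 <- tempfile(fileext = ".fasta")
  write_fasta(a$sim$transcripts, f1)
  write_fasta(b$sim$transcripts, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("background sequence has no G-run of 3+ outside planted sites", {
  sim <- simulate_transcriptome(sim_config(n_genes = 30, seed = 5))
  for (i in seq_len(nrow(sim$transcripts))) {
    s <- sim$transcripts$sequence[i]
    runs <- gregexpr("G{3,}", s)[[1]]
    tr <- sim$truth[i, ]
    if (runs[1] == -1) next
    starts <- as.integer(runs) - 1L
    ends <- starts + attr(runs, "match.length")
    expect_true(tr$is_target)
    expect_true(all(starts >= tr$site_start & ends <= tr$site_end))
  }
})

test_that("planted truth is self-consistent on the log2 scale", {
  cfg <- sim_config(n_genes = 100, beta_mrna = 0.4, beta_rpf = 0.1, seed = 2)
  truth <- simulate_transcriptome(cfg)$truth
  expect_equal(truth$lfc_te, truth$lfc_rpf - truth$lfc_mrna)
  nt <- !truth$is_target
  expect_true(all(truth$occupancy[nt] == 0))
  expect_true(all(truth$lfc_mrna[nt] == 0 & truth$lfc_rpf[nt] == 0))
})

test_that("zero conversion probabilities give zero conversions", {
  cfg <- sim_config(n_genes = 20, depth_parclip = 300, conv_prob_site = 0,
                    conv_prob_background = 0, seed = 4)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_parclip_reads(sim$transcripts, sim$truth, cfg)
  expect_true(all(lengths(reads$conversion_offsets) == 0))
})

test_that("depth 0 gives an empty read set, not an error", {
  cfg <- sim_config(n_genes = 5, depth_parclip = 0, seed = 4)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_parclip_reads(sim$transcripts, sim$truth, cfg)
  expect_equal(nrow(reads), 0L)
})

test_that("conversions fall only on reference-T positions within the read", {
  cfg <- sim_config(n_genes = 20, depth_parclip = 1000,
                    conv_prob_site = 0.6, conv_prob_background = 0.3,
                    seed = 9)
  sim <- simulate_transcriptome(cfg)
  reads <- simulate_parclip_reads(sim$transcripts, sim$truth, cfg)
  seqs <- setNames(sim$transcripts$sequence, sim$transcripts$transcript_id)
  for (i in sample.int(nrow(reads), 200)) {
    offs <- reads$conversion_offsets[[i]]
    if (length(offs) == 0) next
    expect_true(all(offs >= 0 & offs < reads$end[i] - reads$start[i]))
    bases <- substring(seqs[reads$transcript_id[i]],
                       reads$start[i] + offs + 1,
                       reads$start[i] + offs + 1)
    expect_true(all(bases == "T"))
  }
})

test_that("site-read counts scale with occupancy within Poisson bounds", {
  # two target genes, occupancy ratio 10, equal lengths and expression
  cfg <- sim_config(n_genes = 2, target_fraction = 1,
                    utr5_range = c(200, 200), cds_range = c(600, 600),
                    utr3_range = c(400, 400), depth_parclip = 5000,
                    site_read_fraction = 1, seed = 21)
  sim <- simulate_transcriptome(cfg)
  sim$truth$occupancy <- c(10, 1)
  sim$truth$expr_rel <- c(1, 1)
  reads <- simulate_parclip_reads(sim$transcripts, sim$truth, cfg)
  n <- table(factor(reads$transcript_id,
                    levels = sim$transcripts$transcript_id))
  # Poisson 99% band on each count around its expectation
  exp_n <- 5000 * c(10, 1) / 11
  for (i in 1:2) {
    expect_gte(n[i], qpois(0.005, exp_n[i]))
    expect_lte(n[i], qpois(0.995, exp_n[i]))
  }
})

test_that("null planted effect gives matched WT/KO means", {
  cfg <- sim_config(n_genes = 300, beta_mrna = 0, beta_rpf = 0,
                    depth_rna = 5e5, depth_rpf = 5e5, seed = 6)
  sim <- simulate_transcriptome(cfg)
  counts <- simulate_counts(sim$transcripts, sim$truth, cfg)
  m <- as.matrix(counts[, -1])
  wt <- rowMeans(m[, grep("RNA_WT", colnames(m))])
  ko <- rowMeans(m[, grep("RNA_KO", colnames(m))])
  # same NB mean: paired per-gene log-ratios center at 0
  expect_lt(abs(median(log2((ko + 1) / (wt + 1)))), 0.05)
})

test_that("small dispersion approaches Poisson-scale replicate variance", {
  cfg <- sim_config(n_genes = 400, nb_dispersion = 1e-6, depth_rna = 4e5,
                    n_reps = 3, seed = 8)
  sim <- simulate_transcriptome(cfg)
  counts <- simulate_counts(sim$transcripts, sim$truth, cfg)
  m <- as.matrix(counts[, grep("RNA_WT", names(counts))])
  vm <- apply(m, 1, var) / rowMeans(m)
  # variance/mean ratio concentrates near 1 in the Poisson limit
  expect_lt(abs(median(vm, na.rm = TRUE) - 1), 0.25)
})

test_that("simulate_dataset writes a readable, consistent file set", {
  dir <- tempfile("simdata")
  cfg <- sim_config(n_genes = 15, depth_parclip = 300, depth_rna = 1e4,
                    depth_rpf = 1e4, seed = 13)
  paths <- simulate_dataset(cfg, dir)
  expect_true(all(file.exists(unlist(paths))))
  tx <- read_annotation_tsv(paths$annotation, fasta = paths$fasta)
  expect_equal(nrow(tx), 15L)
  expect_true(all(nchar(tx$sequence) == tx$length))
  reads <- read_reads_tsv(paths$reads)
  expect_true(is.list(reads$conversion_offsets))
  expect_true(all(reads$transcript_id %in% tx$transcript_id))
})
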