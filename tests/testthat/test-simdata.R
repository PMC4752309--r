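# Synthetic study generator: determinism, genome composition, planted
# hairpin geometry, read-library structure and ground-truth consistency.

test_that("genome generation honours length, GC target and determinism", {
  cfg <- sim_config(seed = 1L, n_scaffolds = 1L, scaffold_lengths = 1000L,
                    gc_fraction = 0.5)
  g <- generate_genome(cfg)
  expect_equal(nchar(g$seq), 1000L)
  expect_identical(generate_genome(cfg), g)

  gc_only <- generate_genome(sim_config(seed = 3L, n_scaffolds = 1L,
                                        scaffold_lengths = 100L,
                                        gc_fraction = 1.0))
  expect_equal(stringr::str_count(gc_only$seq, "[GC]"), 100L)

  big <- generate_genome(sim_config(seed = 4L, n_scaffolds = 1L,
                                    scaffold_lengths = 20000L,
                                    gc_fraction = 0.4))
  gc_frac <- stringr::str_count(big$seq, "[GC]") / 20000
  expect_lt(abs(gc_frac - 0.4), 0.05)

  expect_error(sim_config(scaffold_lengths = -5), class = "spongemir_config_error")
})

test_that("planted precursors have duplex geometry the folder can recover", {
  cfg <- sim_config(seed = 11L, n_scaffolds = 1L, scaffold_lengths = 6000L,
                    n_hairpins = 4L, mature_len_range = c(22L, 22L),
                    loop_len_range = c(12L, 12L), star_mutations = 0L,
                    overhang_len = 2L)
  pl <- plant_hairpins(generate_genome(cfg), cfg)
  expect_equal(nrow(pl$truth), 4L)
  for (i in seq_len(4)) {
    tr <- pl$truth[i, ]
    expect_equal(tr$precursor_end - tr$precursor_start, 22L + 12L + 22L)
    # fold the planted precursor with the discovery folder: the duplex must
    # pair at least 20 of the 22 mature bases
    pseq <- substr(pl$genome$seq[pl$genome$name == tr$scaffold],
                   tr$precursor_start + 1L, tr$precursor_end)
    if (tr$strand == "-") pseq <- revcomp(pseq)
    fold <- fold_nussinov(pseq)
    mat_paired <- sum(!is.na(fold$partner[1:22]))
    expect_gte(mat_paired, 20L)
  }
})

test_that("truth records match the genome slice strand-aware", {
  cfg <- sim_config(seed = 12L, n_hairpins = 8L, n_scaffolds = 2L,
                    scaffold_lengths = 10000L)
  pl <- plant_hairpins(generate_genome(cfg), cfg)
  seqs <- setNames(pl$genome$seq, pl$genome$name)
  for (i in seq_len(nrow(pl$truth))) {
    tr <- pl$truth[i, ]
    sl <- substr(seqs[[tr$scaffold]], tr$mature_start + 1L, tr$mature_end)
    if (tr$strand == "-") sl <- revcomp(sl)
    expect_identical(sl, tr$mature_seq)
    expect_true(tr$mature_start >= tr$precursor_start)
    expect_true(tr$star_end <= tr$precursor_end)
    expect_true(tr$mature_end <= tr$star_start || tr$star_end <= tr$mature_start)
  }
})

test_that("gap-interrupted hairpins carry an N run; zero hairpins is identity", {
  cfg <- sim_config(seed = 13L, n_hairpins = 3L, n_gap_hairpins = 1L,
                    n_scaffolds = 1L, scaffold_lengths = 8000L)
  pl <- plant_hairpins(generate_genome(cfg), cfg)
  expect_equal(sum(pl$truth$interrupted_by_gap), 1L)
  gap <- pl$truth[pl$truth$interrupted_by_gap, ]
  pseq <- substr(pl$genome$seq, gap$precursor_start + 1L, gap$precursor_end)
  expect_match(pseq, "N{10,}")

  cfg0 <- sim_config(seed = 13L, n_hairpins = 0L)
  g <- generate_genome(cfg0)
  pl0 <- plant_hairpins(g, cfg0)
  expect_identical(pl0$genome, g)
  expect_equal(nrow(pl0$truth), 0L)
})

test_that("simulated library is deterministic and honours forcing parameters", {
  cfg <- sim_config(seed = 21L, n_hairpins = 3L, n_scaffolds = 1L,
                    scaffold_lengths = 8000L, background_reads = 200L)
  pl <- plant_hairpins(generate_genome(cfg), cfg)
  s1 <- simulate_reads(pl$genome, pl$truth, cfg)
  s2 <- simulate_reads(pl$genome, pl$truth, cfg)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$truth, s2$truth)

  # p5_homogeneity = 1 with no 3' jitter: every mature read of a hairpin is
  # the same sequence
  cfg_h <- sim_config(seed = 22L, n_hairpins = 2L, n_scaffolds = 1L,
                      scaffold_lengths = 8000L, p5_homogeneity = 1,
                      jitter3_max = 0L, star_fraction = 0, loop_fraction = 0,
                      background_reads = 0L, p_low_qual_tail = 0,
                      readthrough_prob = 0)
  pl_h <- plant_hairpins(generate_genome(cfg_h), cfg_h)
  s_h <- simulate_reads(pl_h$genome, pl_h$truth, cfg_h)
  mat <- s_h$reads[startsWith(s_h$reads$id, "mat"), ]
  expect_equal(length(unique(mat$seq)), 2L) # one distinct sequence per hairpin
  expect_true(all(sort(unique(mat$seq)) == sort(pl_h$truth$mature_seq)))
  # star_fraction = 0: no star-derived reads at all
  expect_false(any(startsWith(s_h$reads$id, "star")))
})

test_that("mature read depth matches the lognormal model", {
  mu <- log(200); sigma <- 0.5
  cfg <- sim_config(seed = 23L, n_hairpins = 20L, n_scaffolds = 5L,
                    scaffold_lengths = 20000L, background_reads = 0L,
                    depth_lognormal = c(mu, sigma),
                    star_fraction = 0, loop_fraction = 0)
  pl <- plant_hairpins(generate_genome(cfg), cfg)
  s <- simulate_reads(pl$genome, pl$truth, cfg)
  n_mat <- sum(startsWith(s$reads$id, "mat"))
  expected <- 20 * exp(mu + sigma^2 / 2)
  sd_total <- sqrt(20 * (exp(sigma^2) - 1) * exp(2 * mu + sigma^2))
  expect_lt(abs(n_mat - expected), 3 * sd_total)
})

test_that("empty truth with no background warns and yields a valid empty library", {
  cfg <- sim_config(seed = 24L, n_hairpins = 0L, background_reads = 0L,
                    n_scaffolds = 1L, scaffold_lengths = 2000L)
  g <- generate_genome(cfg)
  expect_warning(s <- simulate_reads(g, plant_hairpins(g, cfg)$truth, cfg),
                 "empty")
  expect_equal(nrow(s$reads), 0L)
  f <- tempfile(fileext = ".fastq")
  write_fastq(s$reads, f)
  expect_equal(nrow(read_fastq(f)), 0L)
  unlink(f)
})

test_that("planted exact-read bookkeeping matches an exact-match tally", {
  cfg <- sim_config(seed = 25L, n_hairpins = 4L, n_scaffolds = 1L,
                    scaffold_lengths = 10000L, background_reads = 500L)
  sim <- simulate_study(cfg)
  collapsed <- collapse_reads(trim_reads(sim$reads))
  tally <- tally_exact_matches(collapsed,
                               tibble::tibble(name = sim$truth$hairpin_id,
                                              seq = sim$truth$mature_seq))
  expect_equal(tally$reads, sim$truth$planted_mature_count)
})
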