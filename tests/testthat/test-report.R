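# Pipeline orchestration: the bundled fixture, manifest reconciliation,
# determinism, artifact round-trips and report rendering.

test_that("the bundled mature-miRNA fixture matches its printed statistics", {
  t2 <- load_table2_fixture()
  expect_equal(nrow(t2), 30L)
  expect_equal(sum(t2$species == "sca"), 11L)
  expect_equal(sum(t2$species == "xte"), 19L)
  expect_equal(t2$mature_seq[t2$name == "sca-mir-temp-4"], "aaagugaucggguugccgucu")
  labs <- t2$known_match[!is.na(t2$known_match)]
  expect_equal(length(unique(labs)), 7L)
  expect_equal(sum(!is.na(t2$known_match) & t2$species == "sca"), 8L)
  expect_equal(sum(!is.na(t2$known_match) & t2$species == "xte"), 5L)
  expect_true(all(grepl("^[acgu]+$", t2$mature_seq)))
})

test_that("a pipeline run is reproducible and its manifest reconciles", {
  cfg <- pipeline_config(seed = 5L,
                         sim = sim_config(seed = 105L, n_hairpins = 4L,
                                          n_scaffolds = 2L,
                                          scaffold_lengths = 8000L,
                                          background_reads = 800L))
  r1 <- run_pipeline(cfg)
  r2 <- run_pipeline(cfg)
  expect_identical(r1$manifest$output_hash, r2$manifest$output_hash)
  expect_gt(nrow(tidy(r1)), 0L)
  # adjacent stages reconcile: reads_out of one equals reads_in of the next
  m <- r1$manifest
  expect_equal(m$reads_out[-nrow(m)], m$reads_in[-1])
  g <- glance(r1)
  expect_s3_class(g, "tbl_df")
  expect_equal(g$n_bona_fide, nrow(tidy(r1)))
  expect_s3_class(ggplot2::autoplot(r1), "ggplot")
})

test_that("relaxing the count filter never loses survivors", {
  base_sim <- sim_config(seed = 106L, n_hairpins = 3L, n_scaffolds = 1L,
                         scaffold_lengths = 8000L, background_reads = 800L)
  r5 <- run_pipeline(pipeline_config(seed = 5L, sim = base_sim,
                                     filter = filter_config(min_count = 5)))
  r1 <- run_pipeline(pipeline_config(seed = 5L, sim = base_sim,
                                     filter = filter_config(min_count = 1)))
  expect_gte(sum(r1$collapsed$count), sum(r5$collapsed$count))
})

test_that("run artifacts are written and validated by read-back", {
  cfg <- pipeline_config(seed = 6L,
                         sim = sim_config(seed = 107L, n_hairpins = 3L,
                                          n_scaffolds = 1L,
                                          scaffold_lengths = 8000L,
                                          background_reads = 400L))
  outdir <- tempfile("run_")
  run <- run_pipeline(cfg, outdir = outdir)
  expect_true(file.exists(file.path(outdir, "genome.fa")))
  expect_true(file.exists(file.path(outdir, "bona_fide.gff3")))
  gff <- readLines(file.path(outdir, "bona_fide.gff3"))
  expect_equal(gff[1], "##gff-version 3")
  body <- gff[-1]
  expect_equal(length(body), 3L * nrow(tidy(run)))
  cols <- strsplit(body, "\t")
  expect_true(all(lengths(cols) == 9L))
  # GFF3 is 1-based inclusive: starts are internal starts + 1
  starts <- as.integer(vapply(cols, `[[`, character(1), 4))
  pre <- starts[vapply(cols, `[[`, character(1), 3) == "pre_miRNA"]
  expect_equal(sort(pre), sort(tidy(run)$precursor_start + 1L))
  unlink(outdir, recursive = TRUE)
})

test_that("reports render deterministically with dashes for zero tallies", {
  outdir <- tempfile("rep_")
  t2 <- load_table2_fixture()
  bona <- tibble::tibble(name = t2$name, mature_seq = t2$mature_seq,
                         known_match = t2$known_match)
  tally <- tibble::tibble(name = c("x", "y"), seq = c("AA", "CC"),
                          reads = c(0L, 1234L))
  cl <- cluster_cross_species(t2[t2$species == "sca", ],
                              t2[t2$species == "xte", ])
  files <- render_reports(bona, tally = tally, clusters = cl, outdir = outdir)
  t2_out <- readr::read_tsv(file.path(outdir, "mature_mirnas.tsv"),
                            show_col_types = FALSE)
  expect_equal(nrow(t2_out), 30L)
  t3_out <- readr::read_tsv(file.path(outdir, "exact_match_tally.tsv"),
                            show_col_types = FALSE,
                            col_types = readr::cols(.default = "c"))
  expect_equal(t3_out$reads, c("-", "1,234"))
  prof <- readr::read_tsv(file.path(outdir, "conservation_profiles.tsv"),
                          show_col_types = FALSE)
  expect_true(all(prof$bin %in% c("dark", "mid", "light", "none")))
  # zero bona fide: valid empty table with header
  empty <- render_reports(bona[0, ], outdir = outdir)
  t2_empty <- readr::read_tsv(file.path(outdir, "mature_mirnas.tsv"),
                              show_col_types = FALSE)
  expect_equal(nrow(t2_empty), 0L)
  expect_equal(names(t2_empty), c("name", "mature_5p_to_3p", "known_match"))
  expect_error(render_reports(NULL), class = "spongemir_report_error")
  unlink(outdir, recursive = TRUE)
})

test_that("YAML configuration round-trips and rejects unknown keys", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("seed: 9", "species: demo",
               "sim:", "  n_hairpins: 3", "  background_reads: 100",
               "filter:", "  min_count: 4",
               "discovery:", "  score_threshold: 6"), f)
  cfg <- load_config(f)
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$species, "demo")
  expect_equal(cfg$sim$n_hairpins, 3L)
  expect_equal(cfg$filter$min_count, 4L)
  expect_equal(cfg$discovery$score_threshold, 6)
  writeLines(c("filter:", "  bogus_key: 1"), f)
  expect_error(load_config(f), class = "spongemir_config_error")
  unlink(f)
})
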