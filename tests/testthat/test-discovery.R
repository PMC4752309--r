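# Hairpin discovery: the folder against exhaustive enumeration, stack
# detection, window excision arithmetic, structural validation, the
# processing-signature metrics and bona fide selection.

dc <- discovery_config()

test_that("folding maximises nested pairs (exhaustive oracle, 200 sequences)", {
  set.seed(271)
  seqs <- c("GGGAAAACCC", "AAAAAA", strrep("N", 8),
            vapply(1:200, function(i) {
              paste(sample(c("A", "C", "G", "T"), sample(4:12, 1),
                           replace = TRUE), collapse = "")
            }, character(1)))
  expect_equal(fold_nussinov("GGGAAAACCC")$dot_bracket, "(((....)))")
  expect_equal(n_pairs(fold_nussinov("AAAAAA")), 0L)
  expect_equal(n_pairs(fold_nussinov(strrep("N", 8))), 0L)
  for (s in seqs) {
    pt <- fold_nussinov(s, min_loop = 3)
    expect_equal(n_pairs(pt), oracle_max_pairs(s, 3), info = s)
    # pairing is an involution consistent with the bracket string
    p <- pt$partner
    for (i in seq_along(p)) {
      if (!is.na(p[i])) expect_equal(p[p[i]], i)
    }
    expect_equal(stringr::str_count(pt$dot_bracket, "\\("), n_pairs(pt))
  }
})

test_that("read stacks cluster 5' positions within 3 nt", {
  aln <- function(starts, counts, strand = "+", scaffold = "s") {
    tibble::tibble(read_id = paste0("r", seq_along(starts)),
                   seq = strrep("A", 22), scaffold = scaffold,
                   start = as.integer(starts), end = as.integer(starts + 22),
                   strand = strand, mismatches = 0L, count = as.integer(counts))
  }
  one <- find_stacks(aln(rep(500, 4), rep(25, 4)), dc)
  expect_equal(nrow(one), 1L)
  expect_equal(one$modal_start, 500L)
  expect_equal(one$total_count, 100L)
  expect_equal(five_prime_consistency(one[1, ]), 1)

  two_pos <- find_stacks(aln(c(500, 501), c(90, 10)), dc)
  expect_equal(nrow(two_pos), 1L)
  expect_equal(two_pos$modal_start, 500L)
  expect_equal(five_prime_consistency(two_pos[1, ]), 0.9)

  split2 <- find_stacks(aln(c(500, 700), c(50, 50)), dc)
  expect_equal(nrow(split2), 2L)

  # below min_stack_count nothing is reported
  expect_equal(nrow(find_stacks(aln(500, 5), dc)), 0L)
  expect_error(five_prime_consistency(list(modal_count = 0, total_count = 0)),
               class = "spongemir_input_error")
  # uniform spread over 4 adjacent starts
  u4 <- find_stacks(aln(501:504, rep(25, 4)), dc)
  expect_equal(five_prime_consistency(u4[1, ]), 0.25)
})

test_that("precursor windows follow the stated excision arithmetic", {
  g <- tibble::tibble(name = "s", seq = strrep("ACGT", 1000))
  st <- tibble::tibble(stack_id = "stack_0001", scaffold = "s", strand = "+",
                       modal_start = 1000L, modal_len = 22L,
                       total_count = 50L, modal_count = 50L, starts = list(NULL))
  w <- excise_precursors(st, g, discovery_config(window_flank = 70))
  expect_equal(w$win_start[w$assume_arm == "5p"], 985L)
  expect_equal(w$win_end[w$assume_arm == "5p"], 1092L)
  expect_equal(w$win_start[w$assume_arm == "3p"], 930L)
  expect_equal(w$win_end[w$assume_arm == "3p"], 1037L)
  expect_equal(w$mature_local[w$assume_arm == "5p"], 15L)
  expect_equal(w$mature_local[w$assume_arm == "3p"], 70L)

  # near the scaffold start the window is clipped, not an error
  st2 <- dplyr::mutate(st, modal_start = 10L)
  w2 <- excise_precursors(st2, g, dc)
  expect_true(all(w2$win_start >= 0))
  expect_equal(w2$mature_local[w2$assume_arm == "5p"], 10L)

  # a >= 5-nt N run flags the window as gap-interrupted
  gN <- tibble::tibble(name = "s",
                       seq = paste0(strrep("ACGT", 250), strrep("N", 12),
                                    strrep("ACGT", 250)))
  stN <- dplyr::mutate(st, modal_start = 990L)
  wN <- excise_precursors(stN, gN, dc)
  expect_true(any(wN$gap_interrupted))
})

test_that("hairpin validation enforces single stem, arm placement and duplex strength", {
  # two side-by-side hairpins: multiloop
  toy <- fold_nussinov("GGAATTCCGGAATTCC", min_loop = 2)
  expect_gte(spongemir:::.n_hairpin_loops(toy), 0L) # structure exists
  pt2 <- structure(list(seq = "GGAATTGGAATT",
                        partner = c(6L, 5L, NA, NA, 2L, 1L, 12L, 11L, NA, NA, 8L, 7L),
                        dot_bracket = "((..))((..))"), class = "pair_table")
  v <- validate_hairpin(pt2, c(0L, 6L), dc)
  expect_false(v$accepted)
  expect_equal(v$reason, "multiloop")

  # a planted perfect hairpin validates with the star where it was planted
  cfg <- sim_config(seed = 77L, n_hairpins = 1L, n_scaffolds = 1L,
                    scaffold_lengths = 4000L, mature_len_range = c(22L, 22L),
                    loop_len_range = c(12L, 12L), star_mutations = 0L)
  pl <- plant_hairpins(generate_genome(cfg), cfg)
  tr <- pl$truth[1, ]
  pseq <- substr(pl$genome$seq, tr$precursor_start + 1L, tr$precursor_end)
  if (tr$strand == "-") pseq <- revcomp(pseq)
  fold <- fold_nussinov(pseq)
  v2 <- validate_hairpin(fold, c(0L, 22L), dc)
  expect_true(v2$accepted)
  expect_equal(v2$arm, "5p")
  expect_equal(v2$star_local, c(34L, 56L)) # = planted star position
  expect_gte(v2$pairing_fraction, 20 / 22)

  # a weak duplex is rejected with the stated reason
  weak <- structure(list(seq = strrep("A", 30),
                         partner = rep(NA_integer_, 30),
                         dot_bracket = strrep(".", 30)), class = "pair_table")
  v3 <- validate_hairpin(weak, c(0L, 20L), dc)
  expect_false(v3$accepted)
  expect_equal(v3$reason, "weak_duplex")
})

test_that("3' overhangs are measured from duplex geometry", {
  # duplex with 2-nt 3' offsets on both strands, pair table written out
  # explicitly: mature 1..22 pairs i <-> 55 - i for i = 1..20
  partner <- rep(NA_integer_, 56)
  for (i in 1:20) {
    partner[i] <- 55L - i
    partner[55L - i] <- i
  }
  db <- vapply(seq_len(56), function(i) {
    if (is.na(partner[i])) "." else if (partner[i] > i) "(" else ")"
  }, character(1))
  pt <- structure(list(seq = strrep("A", 56), partner = partner,
                       dot_bracket = paste(db, collapse = "")),
                  class = "pair_table")
  oh <- overhang_3p(pt, c(0L, 22L), c(34L, 56L))
  expect_equal(oh$overhang_mature, 2L)
  expect_equal(oh$overhang_star, 2L)

  # perfectly blunt toy duplex: GGGG....CCCC pairing 1:4 with 9:12
  blunt <- fold_nussinov("GGGGAAAACCCC")
  oh0 <- overhang_3p(blunt, c(0L, 4L), c(8L, 12L))
  expect_equal(oh0$overhang_mature, 0L)
  expect_equal(oh0$overhang_star, 0L)
  expect_error(overhang_3p(blunt, c(0L, 4L), c(8L, 20L)),
               class = "spongemir_input_error")
})

test_that("the additive score evaluates the stated formula and is monotone", {
  sig <- list(pairing_fraction = 0.9, overhang_3p_mature = 2,
              five_prime_consistency = 0.95, mature_count = 999)
  expect_equal(signature_score(sig, dc), 2 * 0.9 + 1 + 2 * 0.95 + 3)
  zero <- list(pairing_fraction = 0, overhang_3p_mature = 0,
               five_prime_consistency = 0, mature_count = 0)
  expect_equal(signature_score(zero, dc), 0)
  far <- modifyList(sig, list(overhang_3p_mature = 7))
  expect_lt(signature_score(far, dc), signature_score(sig, dc))
  # monotone in every component
  set.seed(5)
  for (i in 1:20) {
    s1 <- list(pairing_fraction = runif(1), overhang_3p_mature = sample(0:5, 1),
               five_prime_consistency = runif(1),
               mature_count = sample(1000, 1))
    s2 <- s1
    cmp <- sample(c("pairing_fraction", "five_prime_consistency",
                    "mature_count"), 1)
    s2[[cmp]] <- s1[[cmp]] * 1.2
    expect_gte(signature_score(s2, dc), signature_score(s1, dc))
  }
})

test_that("bona fide selection applies thresholds and locus dedup", {
  cand <- function(score, consistency = 0.95, oh = 2L, start = 100L,
                   count = 50L, mat = "ACGUACGUACGUACGUACGUA") {
    tibble::tibble(
      stack_id = "st", scaffold = "s", strand = "+", assume_arm = "5p",
      win_start = start - 20L, win_end = start + 90L,
      mature_start = start, mature_end = start + 21L,
      star_start = start + 30L, star_end = start + 51L,
      precursor_start = start, precursor_end = start + 51L,
      mature_arm = "5p", mature_seq = rna_to_dna(mat),
      star_seq = strrep("A", 21), precursor_seq = strrep("A", 51),
      dot_bracket = "", pairing_fraction = 0.9,
      overhang_3p_mature = oh, overhang_3p_star = 2L,
      five_prime_consistency = consistency, mature_count = count,
      star_count = 5L, loop_count = 0L, other_count = 0L, score = score,
      accepted = TRUE, reason = NA_character_
    )
  }
  # same locus: only the higher-scoring survives
  two <- dplyr::bind_rows(cand(7.7), cand(5.1))
  expect_equal(nrow(select_bona_fide(two, dc)), 1L)
  expect_equal(select_bona_fide(two, dc)$score, 7.7)
  # identical mature sequences at distinct loci are both kept
  twin <- dplyr::bind_rows(cand(7.7, start = 100L, mat = "auccuguucauccauguaa"),
                           cand(7.0, start = 5000L, mat = "auccuguucauccauguaa"))
  sel <- select_bona_fide(twin, dc)
  expect_equal(nrow(sel), 2L)
  expect_equal(unique(sel$mature_seq), "auccuguucauccauguaa")
  # threshold exclusions
  expect_equal(nrow(select_bona_fide(cand(4.9), dc)), 0L)
  expect_equal(nrow(select_bona_fide(cand(7.7, consistency = 0.8), dc)), 0L)
  expect_equal(nrow(select_bona_fide(cand(7.7, oh = 6L), dc)), 0L)
  # star requirement
  nostar <- dplyr::mutate(cand(7.7), star_count = 0L)
  expect_equal(nrow(select_bona_fide(nostar,
                                     discovery_config(require_star_reads = TRUE))), 0L)
})
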