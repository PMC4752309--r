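# Synthetic small-RNA study generator: a multi-scaffold genome with planted
# pre-miRNA hairpins and a simulated read library whose statistical structure
# (mature-arm dominance, 5'-end homogeneity, ragged degradation background,
# 3'-decaying qualities, adapter read-through) matches what the discovery
# pipeline assumes. Ground truth is returned for recovery tests.
#
# All coordinates are 0-based half-open; sequences are DNA.

# size-safe single draw: sample() treats a length-1 numeric as 1:n
.sample1 <- function(x, prob = NULL) x[sample.int(length(x), 1L, prob = prob)]

# run expr under a private RNG stream, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Generate a random multi-scaffold genome
#'
#' @param cfg A [sim_config()].
#' @return Tibble with columns `name`, `seq`: `n_scaffolds` sequences over
#'   `{A,C,G,T}` of the configured lengths and GC fraction. Deterministic for
#'   a fixed `cfg$seed`.
#' @export
generate_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed, {
    tibble(
      name = sprintf("scaffold_%d", seq_len(cfg$n_scaffolds)),
      seq = .random_dna(cfg$scaffold_lengths, cfg$gc_fraction)
    )
  })
}

# build one precursor; returns list(seq, mature_local, star_local, loop_local)
# local intervals are 0-based half-open within the precursor
.make_precursor <- function(mature_len, loop_len, star_mutations, overhang_len,
                            gc, gap_len = 0L) {
  mature <- .random_dna(mature_len, gc = 0.5)
  paired_len <- mature_len - overhang_len
  star_paired <- revcomp(substr(mature, 1L, paired_len))
  if (star_mutations > 0 && paired_len > 0) {
    pos <- sample.int(paired_len, min(star_mutations, paired_len))
    sp <- strsplit(star_paired, "")[[1]]
    for (p in pos) sp[p] <- sample(setdiff(c("A", "C", "G", "T"), sp[p]), 1L)
    star_paired <- paste(sp, collapse = "")
  }
  star <- paste0(star_paired, .random_dna(overhang_len, gc = 0.5))
  loop <- if (gap_len > 0) strrep("N", gap_len) else .random_dna(loop_len, gc = 0.5)
  loop_len_eff <- nchar(loop)
  seq <- paste0(mature, loop, star)
  list(
    seq = seq,
    mature_local = c(0L, mature_len),
    loop_local = c(mature_len, mature_len + loop_len_eff),
    star_local = c(mature_len + loop_len_eff, mature_len + loop_len_eff + nchar(star))
  )
}

# map a local 0-based half-open interval within a precursor planted at
# genome position `s` (precursor length `plen`) to genome coordinates
.local_to_genome <- function(interval, s, plen, strand) {
  if (strand == "+") c(s + interval[1], s + interval[2])
  else c(s + plen - interval[2], s + plen - interval[1])
}

#' Plant pre-miRNA hairpins into a genome
#'
#' Each planted precursor is mature arm + loop + star arm, the star being the
#' reverse complement of the mature with `star_mutations` substitutions,
#' arranged so the mature/star duplex carries a 3' overhang of `overhang_len`
#' nt on each strand. `n_gap_hairpins` precursors have their loop replaced by
#' a run of `N`s, emulating an assembly gap that splits the two arms.
#' Precursors are placed without overlap on a random strand.
#'
#' @param genome Tibble `name`, `seq` as from [generate_genome()].
#' @param cfg A [sim_config()].
#' @return List with elements `genome` (sequences with hairpins written in)
#'   and `truth`, a tibble of ground-truth records with 0-based half-open
#'   `precursor_start/end`, `mature_start/end`, `star_start/end`, `strand`,
#'   `mature_seq`, `star_seq`, `interrupted_by_gap` and placeholder planted
#'   read counts (filled by [simulate_reads()]).
#' @export
plant_hairpins <- function(genome, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_hairpins == 0L) {
    return(list(genome = genome, truth = .empty_truth()))
  }
  .with_seed(cfg$seed + 1L, {
    seqs <- setNames(genome$seq, genome$name)
    occupied <- lapply(seqs, function(x) integer(0)) # midpoint bookkeeping
    placed <- vector("list", cfg$n_hairpins)
    gap_ids <- sample.int(cfg$n_hairpins, cfg$n_gap_hairpins)
    for (i in seq_len(cfg$n_hairpins)) {
      mature_len <- .sample1(cfg$mature_len_range[1]:cfg$mature_len_range[2])
      loop_len <- .sample1(cfg$loop_len_range[1]:cfg$loop_len_range[2])
      pre <- .make_precursor(mature_len, loop_len, cfg$star_mutations,
                             cfg$overhang_len, cfg$gc_fraction,
                             gap_len = if (i %in% gap_ids) cfg$gap_len else 0L)
      plen <- nchar(pre$seq)
      ok <- FALSE
      for (try in 1:200) {
        sc <- sample(names(seqs), 1L, prob = nchar(seqs))
        max_start <- nchar(seqs[[sc]]) - plen
        if (max_start < 1L) next
        s <- sample.int(max_start, 1L) # 0-based start
        # keep >= 150 bp away from previously planted precursors
        if (any(abs(occupied[[sc]] - (s + plen / 2)) < 150 + plen)) next
        ok <- TRUE
        break
      }
      if (!ok) {
        abort("could not place hairpin without overlap; use longer scaffolds",
              class = "spongemir_placement_error")
      }
      strand <- sample(c("+", "-"), 1L)
      insert <- if (strand == "+") pre$seq else revcomp(pre$seq)
      substr(seqs[[sc]], s + 1L, s + plen) <- insert
      occupied[[sc]] <- c(occupied[[sc]], s + plen / 2)
      m <- .local_to_genome(pre$mature_local, s, plen, strand)
      st <- .local_to_genome(pre$star_local, s, plen, strand)
      placed[[i]] <- tibble(
        hairpin_id = sprintf("hp_%02d", i), scaffold = sc,
        precursor_start = s, precursor_end = s + plen, strand = strand,
        mature_start = m[1], mature_end = m[2],
        star_start = st[1], star_end = st[2],
        mature_seq = substr(pre$seq, pre$mature_local[1] + 1L, pre$mature_local[2]),
        star_seq = substr(pre$seq, pre$star_local[1] + 1L, pre$star_local[2]),
        planted_mature_count = 0L, planted_star_count = 0L,
        interrupted_by_gap = i %in% gap_ids
      )
    }
    list(genome = tibble(name = genome$name, seq = unname(seqs[genome$name])),
         truth = bind_rows(placed))
  })
}

.empty_truth <- function() {
  tibble(
    hairpin_id = character(), scaffold = character(),
    precursor_start = integer(), precursor_end = integer(), strand = character(),
    mature_start = integer(), mature_end = integer(),
    star_start = integer(), star_end = integer(),
    mature_seq = character(), star_seq = character(),
    planted_mature_count = integer(), planted_star_count = integer(),
    interrupted_by_gap = logical()
  )
}

# strand-aware genome slice: the 5'->3' sequence of [start,end) on `strand`
.genome_slice <- function(seqs, scaffold, start, end, strand = "+") {
  s <- substr(seqs[[scaffold]], start + 1L, end)
  if (strand == "+") s else revcomp(s)
}

# quality string for a read of length L
.make_qual <- function(L, phred_decay, p_low_qual_tail) {
  q <- pmax(2, round(38 - phred_decay * runif(1, 0.5, 1.5) * (seq_len(L) - 1L)))
  tail_len <- 0L
  if (runif(1) < p_low_qual_tail) {
    tail_len <- sample.int(5L, 1L)
    q[max(1L, L - tail_len + 1L):L] <- 10L
  }
  list(qual = .int_to_phred(q), tail_len = tail_len)
}

# one simulated read anchored at a 5' genome position on a strand
.emit_read <- function(seqs, scaffold, p5, len, strand, cfg) {
  sc_len <- nchar(seqs[[scaffold]])
  if (strand == "+") {
    start <- max(0L, p5); end <- min(sc_len, p5 + len)
  } else {
    end <- min(sc_len, p5 + 1L); start <- max(0L, end - len)
  }
  if (end - start < 16L) return(NULL)
  s <- .genome_slice(seqs, scaffold, start, end, strand)
  # the organism's transcript has real bases where the assembly has Ns
  if (grepl("N", s, fixed = TRUE)) {
    ch <- strsplit(s, "")[[1]]
    ch[ch == "N"] <- sample(c("A", "C", "G", "T"), sum(ch == "N"), replace = TRUE)
    s <- paste(ch, collapse = "")
  }
  if (runif(1) < cfg$readthrough_prob) s <- paste0(s, cfg$adapter)
  s
}

#' Simulate a small-RNA FASTQ library
#'
#' Per hairpin, the mature read count is drawn from
#' `lognormal(depth_lognormal)` (rounded, at least 1); star and loop reads
#' are `star_fraction` and `loop_fraction` of that. A fraction
#' `p5_homogeneity` of arm reads start exactly at the true 5' end, the rest
#' are shifted by 1-2 nt; 3' ends carry independent jitter of up to
#' `jitter3_max` nt. Background reads are drawn from decoy ncRNAs, random
#' genome slices and random sequence, as ragged-ended degradation products
#' with skewed per-product abundances. Every record carries a quality string
#' decaying toward the 3' end, and reads run into the 3' adapter with
#' probability `readthrough_prob`. Reads are emitted sense to the planted
#' precursor strand. Deterministic for a fixed `cfg$seed`.
#'
#' @param genome Tibble `name`, `seq` (with hairpins planted).
#' @param truth Truth tibble from [plant_hairpins()].
#' @param cfg A [sim_config()].
#' @param decoys Tibble `name`, `seq` of decoy ncRNAs (default: the bundled
#'   synthetic decoy set).
#' @return List with `reads` (tibble `id`, `seq`, `qual`) and `truth`: the
#'   input truth with `planted_mature_count`/`planted_star_count` set to the
#'   number of unshifted, unjittered, full-quality (hence exact-sequence)
#'   reads emitted per arm.
#' @export
simulate_reads <- function(genome, truth, cfg, decoys = load_decoys()) {
  stopifnot(inherits(cfg, "sim_config"))
  if (nrow(truth) == 0 && cfg$background_reads == 0) {
    warn("empty truth and no background: simulating an empty library")
    return(list(reads = tibble(id = character(), seq = character(),
                               qual = character()),
                truth = truth))
  }
  .with_seed(cfg$seed + 2L, {
    seqs <- setNames(genome$seq, genome$name)
    out <- list(); k <- 0L
    emit <- function(seq_str, tag) {
      if (is.null(seq_str)) return(invisible(NULL))
      k <<- k + 1L
      q <- .make_qual(nchar(seq_str), cfg$phred_decay, cfg$p_low_qual_tail)
      out[[k]] <<- list(id = sprintf("%s_%06d", tag, k), seq = seq_str,
                        qual = q$qual, tail_len = q$tail_len)
      invisible(NULL)
    }
    truth$planted_mature_count <- 0L
    truth$planted_star_count <- 0L
    # 3' jitter: dominant canonical isoform with geometrically decaying
    # off-by-n variants, as seen in real mature miRNA read stacks
    jit_vals <- seq(-cfg$jitter3_max, cfg$jitter3_max)
    jit_w <- 0.5^abs(jit_vals)
    draw_arm <- function(row, a_start, a_end, n_reads, tag) {
      len0 <- a_end - a_start
      for (r in seq_len(n_reads)) {
        shift <- if (runif(1) < cfg$p5_homogeneity) 0L else {
          sample(c(-2L, -1L, 1L, 2L), 1L, prob = c(1, 2, 2, 1))
        }
        jit <- .sample1(jit_vals, prob = jit_w)
        p5 <- if (row$strand == "+") a_start + shift else (a_end - 1L) - shift
        emit(.emit_read(seqs, row$scaffold, p5, len0 - shift + jit,
                        row$strand, cfg), tag)
      }
      invisible(NULL)
    }
    for (i in seq_len(nrow(truth))) {
      row <- truth[i, ]
      n_mat <- max(1L, round(rlnorm(1, cfg$depth_lognormal[1], cfg$depth_lognormal[2])))
      n_star <- round(cfg$star_fraction * n_mat)
      n_loop <- round(cfg$loop_fraction * n_mat)
      draw_arm(row, row$mature_start, row$mature_end, n_mat, sprintf("mat%03d", i))
      draw_arm(row, row$star_start, row$star_end, n_star, sprintf("star%03d", i))
      # loop/junction degradation fragments
      lo <- sort(c(row$mature_start, row$mature_end, row$star_start, row$star_end))
      for (r in seq_len(n_loop)) {
        p5 <- .sample1(lo[2]:lo[3])
        emit(.emit_read(seqs, row$scaffold, p5, sample(18:22, 1L), row$strand, cfg),
             "loop")
      }
    }
    # background: ragged degradation products with skewed abundances
    mix <- cfg$background_mix
    n_bg <- cfg$background_reads
    emitted <- 0L
    while (emitted < n_bg) {
      src <- sample(c("decoy", "genome", "random"), 1L, prob = mix)
      parent <- switch(src,
        decoy = decoys$seq[sample.int(nrow(decoys), 1L)],
        genome = {
          sc <- sample(names(seqs), 1L, prob = nchar(seqs))
          seqs[[sc]]
        },
        random = .random_dna(60L, cfg$gc_fraction)
      )
      plen <- sample(18:30, 1L)
      if (nchar(parent) < plen + 8L) next
      p_start <- sample.int(nchar(parent) - plen - 6L, 1L) + 3L
      copies <- min(max(1L, round(rlnorm(1, log(4), 1))), n_bg - emitted)
      strand <- sample(c("+", "-"), 1L)
      for (cpy in seq_len(copies)) {
        # degradation products have a dominant cleavage point with ragged
        # minority ends
        s5 <- p_start + (if (runif(1) < 0.5) 0L else sample(c(-3:-1, 1:3), 1L))
        s3 <- p_start + plen + (if (runif(1) < 0.5) 0L else sample(c(-2L, -1L, 1L, 2L), 1L))
        if (s5 < 1L || s3 > nchar(parent) || s3 - s5 < 16L) next
        frag <- substr(parent, s5, s3)
        if (strand == "-") frag <- revcomp(frag)
        if (runif(1) < cfg$readthrough_prob) frag <- paste0(frag, cfg$adapter)
        emit(frag, "bg")
        emitted <- emitted + 1L
      }
    }
    reads <- tibble(
      id = vapply(out, `[[`, character(1), "id"),
      seq = vapply(out, `[[`, character(1), "seq"),
      qual = vapply(out, `[[`, character(1), "qual")
    )
    # planted counts: arm reads that clean back to the exact arm sequence
    # under the default quality/adapter trimming
    fcfg <- filter_config(adapter = cfg$adapter)
    for (i in seq_len(nrow(truth))) {
      for (arm in c("mat", "star")) {
        sub <- reads[startsWith(reads$id, sprintf("%s%03d_", arm, i)), ]
        n_exact <- if (nrow(sub) == 0) 0L else {
          target <- if (arm == "mat") truth$mature_seq[i] else truth$star_seq[i]
          sum(trim_reads(sub, fcfg)$seq == target)
        }
        col <- paste0("planted_", if (arm == "mat") "mature" else "star", "_count")
        truth[[col]][i] <- n_exact
      }
    }
    list(reads = reads, truth = truth)
  })
}

#' Simulate a complete study
#'
#' Convenience wrapper: [generate_genome()], [plant_hairpins()] and
#' [simulate_reads()] in one call.
#'
#' @inheritParams simulate_reads
#' @param cfg A [sim_config()].
#' @return List with `genome`, `truth` and `reads` tibbles.
#' @export
simulate_study <- function(cfg, decoys = load_decoys()) {
  genome <- generate_genome(cfg)
  planted <- plant_hairpins(genome, cfg)
  sim <- simulate_reads(planted$genome, planted$truth, cfg, decoys)
  list(genome = planted$genome, truth = sim$truth, reads = sim$reads)
}

#' Generate a synthetic decoy ncRNA set
#'
#' Random tRNA/rRNA-sized sequences used as the non-coding-RNA decoy filter
#' database in simulations. The bundled fixture
#' `inst/extdata/synthetic_decoys.fa` was produced by this function with its
#' default arguments.
#'
#' @param n Number of decoys.
#' @param lengths Range of decoy lengths, nt.
#' @param seed Seed.
#' @return Tibble `name`, `seq`.
#' @export
synthetic_decoys <- function(n = 8L, lengths = c(75L, 320L), seed = 7L) {
  .with_seed(seed, {
    tibble(
      name = sprintf("synthetic_%s_%d",
                     rep_len(c("tRNA", "rRNA", "snoRNA", "snRNA"), n), seq_len(n)),
      seq = .random_dna(lengths[1] + sample.int(lengths[2] - lengths[1] + 1L, n, replace = TRUE) - 1L, 0.5)
    )
  })
}

#' Load the bundled synthetic decoy ncRNA set
#'
#' @return Tibble `name`, `seq`.
#' @export
load_decoys <- function() {
  read_fasta(system.file("extdata", "synthetic_decoys.fa",
                         package = "spongemir", mustWork = TRUE))
}

#' Write / read a ground-truth table
#'
#' Plain TSV with 0-based half-open intervals, one row per planted hairpin.
#'
#' @param truth Truth tibble.
#' @param path File path.
#' @return `write_truth()` returns `path` invisibly; `read_truth()` a tibble.
#' @export
write_truth <- function(truth, path) {
  readr::write_tsv(truth, path)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}
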