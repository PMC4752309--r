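# Independent oracles used to validate the package's core algorithms.
# These deliberately share no code with the implementation: the folder is an
# exhaustive enumeration, the mapper a full scan, the aligner a plain
# dynamic-programming matrix.

# exhaustive maximum nested pairing (Watson-Crick + GU, N never pairs),
# enumerating every nested structure; feasible for sequences up to ~12 nt
oracle_max_pairs <- function(seq, min_loop = 3L) {
  s <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  ok <- function(a, b) {
    paste0(a, b) %in% c("AT", "TA", "GC", "CG", "GT", "TG")
  }
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    best <- rec(i, j - 1L) # j unpaired
    for (k in i:(j - min_loop - 1L)) {
      if (!ok(s[k], s[j])) next
      left <- if (k > i) rec(i, k - 1L) else 0L
      inner <- if (k + 1L <= j - 1L) rec(k + 1L, j - 1L) else 0L
      best <- max(best, left + 1L + inner)
    }
    best
  }
  if (length(s) < 2) 0L else rec(1L, length(s))
}

# full-scan read mapper: every position, both strands, count mismatches
oracle_map <- function(seq, genome, max_mm) {
  seq <- toupper(seq)
  L <- nchar(seq)
  hits <- list()
  for (i in seq_len(nrow(genome))) {
    g <- genome$seq[i]
    n <- nchar(g)
    if (n < L) next
    for (st in 0:(n - L)) {
      w <- substr(g, st + 1L, st + L)
      if (grepl("N", w, fixed = TRUE)) {
        mm_f <- sum(strsplit(w, "")[[1]] != strsplit(seq, "")[[1]])
        mm_r <- sum(strsplit(w, "")[[1]] != strsplit(revcomp(seq), "")[[1]])
      } else {
        mm_f <- sum(charToRaw(w) != charToRaw(seq))
        mm_r <- sum(charToRaw(w) != charToRaw(revcomp(seq)))
      }
      if (mm_f <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          scaffold = genome$name[i], start = st, end = st + L, strand = "+",
          mismatches = mm_f, stringsAsFactors = FALSE)
      }
      if (mm_r <= max_mm) {
        hits[[length(hits) + 1L]] <- data.frame(
          scaffold = genome$name[i], start = st, end = st + L, strand = "-",
          mismatches = mm_r, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      mismatches = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(out$scaffold, out$start, out$strand), , drop = FALSE]
}

# affine-gap Smith-Waterman (match +1, mismatch -2, first gap base -5, each
# further gap base -2), best local score of `a` against `b`, one strand
oracle_sw <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  n <- length(a); m <- length(b)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1) # gap in b (vertical)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (a[i - 1] == b[j - 1]) 1 else -2
      Ix[i, j] <- max(M[i - 1, j] - 5, Ix[i - 1, j] - 2)
      Iy[i, j] <- max(M[i, j - 1] - 5, Iy[i, j - 1] - 2)
      M[i, j] <- max(0, s + max(M[i - 1, j - 1], Ix[i - 1, j - 1],
                                Iy[i - 1, j - 1]))
      best <- max(best, M[i, j])
    }
  }
  best
}

# best local score over both strands and all decoys
oracle_decoy_score <- function(read, decoys) {
  max(vapply(decoys$seq, function(d) {
    max(oracle_sw(read, d), oracle_sw(revcomp(read), d))
  }, numeric(1)))
}

# random DNA helper for property tests
random_dna <- function(n, len, alphabet = c("A", "C", "G", "T")) {
  vapply(seq_len(n), function(i) {
    paste(sample(alphabet, len, replace = TRUE), collapse = "")
  }, character(1))
}

# strand-aware 5' position of intervals
p5_of <- function(strand, start, end) ifelse(strand == "+", start, end - 1L)

# shared acceptance-scale simulation + pipeline run, computed once per test
# session (21 planted hairpins, one split by an assembly gap, 10k background)
acceptance_run <- local({
  cache <- NULL
  function(seed = 7L) {
    if (is.null(cache)) {
      simcfg <- sim_config(seed = seed + 195L, n_hairpins = 21L,
                           n_gap_hairpins = 1L, background_reads = 10000L)
      cfg <- pipeline_config(seed = seed, sim = simcfg)
      cache <<- run_pipeline(cfg)
    }
    cache
  }
})
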