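# Seed-and-verify short-read mapper: a k-mer position index over the genome
# plus end-to-end verification allowing substitutions only. Seeding on the
# read's first k-mer and the k-mer ending at its last base guarantees
# completeness for max_mm = 1 whenever read length >= k + 1 (one substitution
# can break at most one of the two seeds).

#' Build a k-mer index over a genome
#'
#' @param genome Tibble `name`, `seq`; must be non-empty.
#' @param k Seed length (>= 8; default 12).
#' @return A `genome_index` object: the scaffold sequences plus a hash from
#'   each k-mer of the forward strand to its `(scaffold, position)` list.
#'   Seeds containing `N` are skipped. Reverse-strand hits are found by
#'   looking up the reverse complement of the read.
#' @export
build_index <- function(genome, k = 12L) {
  if (nrow(genome) == 0 || all(nchar(genome$seq) == 0)) {
    abort("cannot index an empty genome", class = "spongemir_config_error")
  }
  if (k < 8) abort("seed length k must be >= 8", class = "spongemir_config_error")
  k <- as.integer(k)
  all_km <- character(0); all_sc <- integer(0); all_pos <- integer(0)
  for (i in seq_len(nrow(genome))) {
    s <- genome$seq[i]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    ok <- !grepl("N", kmers, fixed = TRUE)
    all_km <- c(all_km, kmers[ok])
    all_sc <- c(all_sc, rep.int(i, sum(ok)))
    all_pos <- c(all_pos, starts[ok] - 1L) # 0-based positions
  }
  tab <- new.env(parent = emptyenv(), size = max(2L * length(all_km), 16L))
  if (length(all_km) > 0) {
    entries <- lapply(split(seq_along(all_km), all_km),
                      function(ix) cbind(all_sc[ix], all_pos[ix]))
    list2env(entries, envir = tab)
  }
  structure(list(scaffolds = setNames(genome$seq, genome$name),
                 scaffold_raw = lapply(genome$seq, charToRaw),
                 names = genome$name, k = k, table = tab),
            class = "genome_index")
}

#' @export
print.genome_index <- function(x, ...) {
  cat(sprintf("<genome_index> %d scaffolds, %s bp, k = %d\n",
              length(x$names), format(sum(nchar(x$scaffolds)), big.mark = ","),
              x$k))
  invisible(x)
}

# candidate (scaffold, start) pairs for one oriented sequence. For reads
# shorter than 2k the first and last k-mers overlap, so one substitution in
# the overlap breaks both seeds; completeness for max_mm = 1 is restored by
# also looking up every single-substitution variant of the first k-mer.
.seed_candidates <- function(seq, index, max_mm = 0L) {
  k <- index$k
  L <- nchar(seq)
  lookup <- function(km, off) {
    hits <- get0(km, envir = index$table, inherits = FALSE)
    if (is.null(hits)) return(NULL)
    cbind(hits[, 1L], hits[, 2L] - off)
  }
  cand <- rbind(lookup(substr(seq, 1L, k), 0L),
                lookup(substr(seq, L - k + 1L, L), L - k))
  if (max_mm >= 1L && L < 2L * k) {
    km0 <- substr(seq, 1L, k)
    for (p in seq_len(k)) {
      for (b in setdiff(c("A", "C", "G", "T"), substr(km0, p, p))) {
        v <- km0
        substr(v, p, p) <- b
        cand <- rbind(cand, lookup(v, 0L))
      }
    }
  }
  if (is.null(cand)) return(NULL)
  unique(cand[cand[, 2L] >= 0L, , drop = FALSE])
}

#' Map one read to the genome
#'
#' Returns all end-to-end alignments with at most `max_mm` substitutions (no
#' indels), on both strands, found by seeding on the read's first and last
#' k-mers and verifying each candidate locus.
#'
#' @param seq Read sequence (length >= index k).
#' @param index A [build_index()] result.
#' @param max_mm Maximum substitutions.
#' @return Tibble `scaffold`, `start`, `end` (0-based half-open), `strand`,
#'   `mismatches`, sorted by `(scaffold, start, strand)`; empty if the read
#'   does not map.
#' @export
map_read <- function(seq, index, max_mm = 1L) {
  seq <- toupper(seq)
  L <- nchar(seq)
  stopifnot(L >= index$k)
  res <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") seq else revcomp(seq)
    cand <- .seed_candidates(oriented, index, max_mm)
    if (is.null(cand)) next
    for (r in seq_len(nrow(cand))) {
      sci <- cand[r, 1L]; st <- cand[r, 2L]
      if (st + L > nchar(index$scaffolds[sci])) next
      mm <- sum(index$scaffold_raw[[sci]][(st + 1L):(st + L)] != charToRaw(oriented))
      if (mm <= max_mm) {
        res[[length(res) + 1L]] <-
          list(scaffold = index$names[sci], start = st, strand = strand, mm = mm)
      }
    }
  }
  if (length(res) == 0) {
    return(tibble(scaffold = character(), start = integer(), end = integer(),
                  strand = character(), mismatches = integer()))
  }
  tibble(
    scaffold = vapply(res, `[[`, character(1), "scaffold"),
    start = vapply(res, `[[`, numeric(1), "start") |> as.integer(),
    strand = vapply(res, `[[`, character(1), "strand"),
    mismatches = vapply(res, `[[`, numeric(1), "mm") |> as.integer()
  ) |>
    mutate(end = .data$start + L) |>
    distinct(.data$scaffold, .data$start, .data$strand, .keep_all = TRUE) |>
    arrange(.data$scaffold, .data$start, .data$strand) |>
    select("scaffold", "start", "end", "strand", "mismatches")
}

#' Map a collapsed read library
#'
#' Applies [map_read()] to every collapsed read; reads hitting more than
#' `max_loci` positions are discarded as multi-mappers and counted in the
#' audit.
#'
#' @param collapsed Tibble `id`, `seq`, `count`.
#' @param index A [build_index()] result.
#' @param cfg A [mapper_config()].
#' @return List with `alignments` (tibble `read_id`, `seq`, `scaffold`,
#'   `start`, `end`, `strand`, `mismatches`, `count`) and `audit` (tibble
#'   with reads mapped / unmapped / discarded as multi-mappers, in collapsed
#'   and raw read units).
#' @export
map_library <- function(collapsed, index, cfg = mapper_config()) {
  empty <- tibble(read_id = character(), seq = character(), scaffold = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer(), count = integer())
  if (nrow(collapsed) == 0) {
    return(list(alignments = empty,
                audit = tibble(category = c("mapped", "unmapped", "multimapper"),
                               n_sequences = 0L, n_reads = 0L)))
  }
  per_read <- purrr::map(collapsed$seq, map_read, index = index, max_mm = cfg$max_mm)
  # best-stratum policy (as in bowtie --best --strata): only alignments with
  # the read's minimum mismatch count are reported
  per_read <- purrr::map(per_read, function(a) {
    if (nrow(a) == 0) a else filter(a, .data$mismatches == min(.data$mismatches))
  })
  n_hits <- vapply(per_read, nrow, integer(1))
  status <- dplyr::case_when(
    n_hits == 0L ~ "unmapped",
    n_hits > cfg$max_loci ~ "multimapper",
    TRUE ~ "mapped"
  )
  keep <- which(status == "mapped")
  alignments <- if (length(keep) == 0) empty else {
    purrr::map_dfr(keep, function(i) {
      mutate(per_read[[i]], read_id = collapsed$id[i], seq = collapsed$seq[i],
             count = collapsed$count[i])
    }) |>
      select("read_id", "seq", "scaffold", "start", "end", "strand",
             "mismatches", "count") |>
      arrange(.data$scaffold, .data$start, .data$strand)
  }
  audit <- tibble(status = factor(status, c("mapped", "unmapped", "multimapper")),
                  count = collapsed$count) |>
    group_by(category = .data$status) |>
    summarise(n_sequences = n(), n_reads = sum(.data$count), .groups = "drop") |>
    tidyr::complete(category = factor(c("mapped", "unmapped", "multimapper")),
                    fill = list(n_sequences = 0L, n_reads = 0L)) |>
    mutate(category = as.character(.data$category))
  list(alignments = alignments, audit = audit)
}

#' Write alignments as BED6
#'
#' 0-based half-open intervals; the BED score column carries the collapsed
#' read count.
#'
#' @param alignments Alignment tibble from [map_library()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignments_bed <- function(alignments, path) {
  bed <- tibble(chrom = alignments$scaffold, start = alignments$start,
                end = alignments$end, name = alignments$read_id,
                score = alignments$count, strand = alignments$strand)
  readr::write_tsv(bed, path, col_names = FALSE)
  invisible(path)
}
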