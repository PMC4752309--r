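# Read-cleaning cascade: quality end-trimming (Phred < 20), exact-match 3'
# adapter removal, minimum-length filter (16 nt), collapsing to unique
# sequences, a per-library minimum-count filter (5) and a local-alignment
# decoy filter standing in for a BLASTN search against an ncRNA database.

#' Trim a single read
#'
#' End bases with Phred below `cfg$min_phred` are removed from the 3' then
#' the 5' end; then the leftmost exact prefix match of the adapter (minimum
#' overlap `cfg$adapter_min_overlap`, no mismatches) and everything 3' of it
#' are removed. Reads ending up shorter than `cfg$min_len` are dropped.
#'
#' @param seq,qual Sequence and Phred+33 quality string of equal length.
#' @param cfg A [filter_config()].
#' @return The trimmed sequence, or `NA_character_` if the read is dropped.
#' @export
trim_read <- function(seq, qual, cfg = filter_config()) {
  if (nchar(seq) != nchar(qual)) {
    abort("sequence and quality strings differ in length",
          class = "spongemir_malformed_record")
  }
  trim_reads(tibble(id = "r", seq = seq, qual = qual), cfg)$seq[1] %||% NA_character_
}

#' Trim a read table
#'
#' Vectorised [trim_read()] over a tibble of reads. Dropped reads are
#' removed from the result.
#'
#' @param reads Tibble with columns `id`, `seq`, `qual`.
#' @param cfg A [filter_config()].
#' @return Tibble `id`, `seq` of surviving trimmed reads.
#' @export
trim_reads <- function(reads, cfg = filter_config()) {
  if (nrow(reads) == 0) return(tibble(id = character(), seq = character()))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    abort("sequence and quality strings differ in length",
          class = "spongemir_malformed_record")
  }
  quals <- .phred_to_int(reads$qual)
  bounds <- vapply(quals, function(q) {
    ok <- which(q >= cfg$min_phred)
    if (length(ok) == 0) c(1L, 0L) else c(min(ok), max(ok))
  }, integer(2))
  seqs <- substr(reads$seq, bounds[1, ], bounds[2, ])
  # leftmost full-adapter occurrence
  cut <- regexpr(cfg$adapter, seqs, fixed = TRUE)
  cut <- ifelse(cut > 0, cut, nchar(seqs) + 1L)
  # adapter prefix running off the 3' end (overlap >= min, < full length)
  alen <- nchar(cfg$adapter)
  for (ov in seq(cfg$adapter_min_overlap, max(cfg$adapter_min_overlap, alen - 1L))) {
    if (ov >= alen) break
    hit <- endsWith(seqs, substr(cfg$adapter, 1L, ov))
    pos <- nchar(seqs) - ov + 1L
    cut <- ifelse(hit & pos < cut, pos, cut)
  }
  seqs <- substr(seqs, 1L, cut - 1L)
  keep <- nchar(seqs) >= cfg$min_len
  tibble(id = reads$id[keep], seq = toupper(seqs[keep]))
}

#' Collapse reads to unique sequences
#'
#' One entry per distinct sequence, with its library count; the collapse is
#' lossless (counts sum to the number of input reads). Output is sorted by
#' count (descending) then sequence for determinism, and carries a stable
#' id derived from a hash of the sequence.
#'
#' @param reads Tibble with a `seq` column (e.g. from [trim_reads()]), or a
#'   character vector of sequences.
#' @return Tibble `id`, `seq`, `count`.
#' @export
collapse_reads <- function(reads) {
  seqs <- if (is.character(reads)) reads else reads$seq
  if (length(seqs) == 0) {
    return(tibble(id = character(), seq = character(), count = integer()))
  }
  tibble(seq = seqs) |>
    count(.data$seq, name = "count") |>
    arrange(desc(.data$count), .data$seq) |>
    mutate(id = .seq_id(.data$seq)) |>
    select("id", "seq", "count")
}

#' Filter collapsed reads on minimum copy number
#'
#' Sequences observed fewer than `cfg$min_count` times in the library are
#' removed; they are likely to carry sequencing errors. Order is preserved.
#'
#' @param collapsed Tibble `id`, `seq`, `count` from [collapse_reads()].
#' @param cfg A [filter_config()].
#' @return Filtered tibble.
#' @export
filter_min_count <- function(collapsed, cfg = filter_config()) {
  filter(collapsed, .data$count >= cfg$min_count)
}

# Smith-Waterman scoring used by the decoy filter
.sw_align_scores <- function(patterns, subject) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                  baseOnly = TRUE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(patterns),
    subject = Biostrings::DNAString(subject),
    type = "local", substitutionMatrix = mat,
    gapOpening = 3, gapExtension = 2, scoreOnly = TRUE
  )
}

#' Remove reads matching a decoy ncRNA set
#'
#' Each collapsed read is locally aligned (match +1, mismatch -2, gap open
#' -5, gap extend -2) against both strands of every decoy sequence; reads
#' whose best score reaches `cfg$ncrna_min_score` are removed and labelled
#' with the best-hit decoy (ties broken by decoy order). This is a
#' self-contained stand-in for a BLASTN search against an ncRNA family
#' database such as Rfam.
#'
#' @param collapsed Tibble `id`, `seq`, `count`.
#' @param decoys Tibble `name`, `seq` (a decoy FASTA read with
#'   [read_fasta()]); must be non-empty.
#' @param cfg A [filter_config()].
#' @return List with `kept` (input rows below threshold) and `removed`
#'   (input rows plus `hit` = best decoy name and `score`).
#' @export
filter_ncrna <- function(collapsed, decoys, cfg = filter_config()) {
  if (nrow(decoys) == 0) {
    abort("decoy set is empty", class = "spongemir_io_error")
  }
  if (nrow(collapsed) == 0) {
    return(list(kept = collapsed,
                removed = mutate(collapsed, hit = character(0), score = numeric(0))))
  }
  best <- rep(-Inf, nrow(collapsed))
  hit <- rep(NA_character_, nrow(collapsed))
  pats <- collapsed$seq
  pats_rc <- revcomp(pats)
  for (d in seq_len(nrow(decoys))) {
    sc <- pmax(.sw_align_scores(pats, decoys$seq[d]),
               .sw_align_scores(pats_rc, decoys$seq[d]))
    better <- sc > best
    best[better] <- sc[better]
    hit[better] <- decoys$name[d]
  }
  rm_idx <- best >= cfg$ncrna_min_score
  list(
    kept = collapsed[!rm_idx, ],
    removed = mutate(collapsed[rm_idx, ], hit = hit[rm_idx], score = best[rm_idx])
  )
}

#' Run the whole read-cleaning cascade
#'
#' Trim, collapse, apply the minimum-count filter and the decoy filter, and
#' record a per-stage audit of read counts.
#'
#' @param reads Raw reads tibble `id`, `seq`, `qual`.
#' @param decoys Decoy set tibble `name`, `seq`.
#' @param cfg A [filter_config()].
#' @return List with `collapsed` (surviving reads), `collapsed_raw`
#'   (collapsed before the count filter, used for exact-match tallies),
#'   `removed_ncrna`, and `audit` (tibble `stage`, `reads_in`, `reads_out`,
#'   `fraction_removed`; counts are raw read equivalents).
#' @export
preprocess_reads <- function(reads, decoys = load_decoys(), cfg = filter_config()) {
  n_raw <- nrow(reads)
  trimmed <- trim_reads(reads, cfg)
  collapsed_raw <- collapse_reads(trimmed)
  counted <- filter_min_count(collapsed_raw, cfg)
  nc <- filter_ncrna(counted, decoys, cfg)
  stage_row <- function(stage, n_in, n_out) {
    tibble(stage = stage, reads_in = n_in, reads_out = n_out,
           fraction_removed = if (n_in > 0) (n_in - n_out) / n_in else 0)
  }
  audit <- bind_rows(
    stage_row("trim", n_raw, nrow(trimmed)),
    stage_row("min_count", sum(collapsed_raw$count), sum(counted$count)),
    stage_row("ncrna_filter", sum(counted$count), sum(nc$kept$count))
  )
  list(collapsed = nc$kept, collapsed_raw = collapsed_raw,
       removed_ncrna = nc$removed, audit = audit)
}

#' Write collapsed reads as FASTA
#'
#' Headers follow the collapsed-read dialect `>id_xCOUNT` so counts survive
#' round-trips through FASTA.
#'
#' @param collapsed Tibble `id`, `seq`, `count`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_collapsed_fasta <- function(collapsed, path) {
  write_fasta(tibble(name = sprintf("%s_x%d", collapsed$id, collapsed$count),
                     seq = collapsed$seq), path)
}

#' Read collapsed reads from FASTA written by [write_collapsed_fasta()]
#'
#' @param path FASTA path.
#' @return Tibble `id`, `seq`, `count`.
#' @export
read_collapsed_fasta <- function(path) {
  x <- read_fasta(path)
  tibble(
    id = sub("_x\\d+$", "", x$name),
    seq = x$seq,
    count = as.integer(sub("^.*_x", "", x$name))
  )
}
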