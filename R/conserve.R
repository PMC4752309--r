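# Conservation analysis: mismatch-tolerant matching of mature miRNAs to
# known sets, cross-species single-linkage clustering, arm-dominance calls,
# per-column conservation profiles, and exact-match read tallies.
#
# Mature sequences are handled in the RNA alphabet (lower case, U) as they
# are conventionally printed; comparisons are U/T- and case-insensitive.

.norm_seq <- function(x) toupper(chartr("Uu", "Tt", x))

#' Match a mature miRNA against a reference set
#'
#' Ungapped comparison of the mature against every reference sequence at
#' every offset shift in `[-max_shift, max_shift]`, over the overlapping
#' window. Reports the reference with the fewest mismatches if that number
#' is at most `max_mm`; ties are broken by longest overlap, then reference
#' order. A self-contained stand-in for a BLASTN search against a miRNA
#' registry.
#'
#' @param mature Mature sequence (RNA or DNA alphabet).
#' @param reference Tibble `name`, `seq` (e.g. from [read_fasta()]).
#' @param max_mm Maximum mismatches (default 2).
#' @param max_shift Maximum offset between the two sequences (default 2).
#' @return One-row tibble `ref_name`, `mismatches`, `overlap`, `shift`, or a
#'   zero-row tibble if nothing matches.
#' @export
match_known <- function(mature, reference, max_mm = 2L, max_shift = 2L) {
  none <- tibble(ref_name = character(), mismatches = integer(),
                 overlap = integer(), shift = integer())
  if (nrow(reference) == 0) abort("reference set is empty",
                                  class = "spongemir_input_error")
  q <- .norm_seq(mature)
  qlen <- nchar(q)
  best <- NULL
  for (i in seq_len(nrow(reference))) {
    r <- .norm_seq(reference$seq[i])
    rlen <- nchar(r)
    for (shift in -max_shift:max_shift) {
      # query position x aligns with reference position x + shift
      qs <- max(1L, 1L - shift); qe <- min(qlen, rlen - shift)
      if (qe - qs + 1L < 10L) next
      a <- charToRaw(substr(q, qs, qe))
      b <- charToRaw(substr(r, qs + shift, qe + shift))
      mm <- sum(a != b)
      ov <- qe - qs + 1L
      if (mm <= max_mm) {
        better <- is.null(best) || mm < best$mismatches ||
          (mm == best$mismatches && ov > best$overlap)
        if (better) best <- tibble(ref_name = reference$name[i],
                                   mismatches = as.integer(mm),
                                   overlap = as.integer(ov),
                                   shift = as.integer(shift))
      }
    }
  }
  best %||% none
}

#' Cluster mature miRNAs across two species
#'
#' Single-linkage clustering over the union of two mature sets, where two
#' equal-length matures link iff their Hamming distance is at most `max_mm`
#' (sequences of unequal length never link). Conserved sponge miRNA homologs
#' are length-matched with at most a one-base mismatch between species, so
#' the default `max_mm = 1` recovers them without alignment parameters.
#'
#' @param set_a,set_b Tibbles with columns `name`, `species`, `mature_seq`
#'   (and optionally `known_match`).
#' @param max_mm Maximum Hamming distance for a link (default 1).
#' @return Tibble with one row per cluster: `cluster`, `family` (majority
#'   known-match label among members, if any), `n_members`, `n_species`,
#'   `shared_across_species`, `max_pairwise_mismatches` (over linked
#'   equal-length pairs) and `members` (list-column tibble).
#' @export
cluster_cross_species <- function(set_a, set_b, max_mm = 1L) {
  all_m <- bind_rows(set_a, set_b)
  if (nrow(all_m) == 0) {
    return(tibble(cluster = integer(), family = character(),
                  n_members = integer(), n_species = integer(),
                  shared_across_species = logical(),
                  max_pairwise_mismatches = integer(), members = list()))
  }
  if (!"known_match" %in% names(all_m)) all_m$known_match <- NA_character_
  n <- nrow(all_m)
  seqs <- .norm_seq(all_m$mature_seq)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i || nchar(seqs[i]) != nchar(seqs[j])) next
    if (hamming(seqs[i], seqs[j]) <= max_mm) parent[find(j)] <- find(i)
  }
  root <- vapply(seq_len(n), find, integer(1))
  all_m$cluster <- as.integer(factor(root, levels = sort(unique(root))))
  all_m |>
    group_by(.data$cluster) |>
    dplyr::group_modify(function(g, key) {
      s <- .norm_seq(g$mature_seq)
      dmax <- 0L
      if (nrow(g) > 1) {
        for (i in seq_len(nrow(g) - 1)) for (j in (i + 1):nrow(g)) {
          if (nchar(s[i]) == nchar(s[j])) {
            dmax <- max(dmax, hamming(s[i], s[j]))
          }
        }
      }
      labs <- g$known_match[!is.na(g$known_match) & g$known_match != ""]
      fam <- if (length(labs) == 0) NA_character_ else
        names(sort(table(labs), decreasing = TRUE))[1]
      tibble(
        family = fam, n_members = nrow(g),
        n_species = dplyr::n_distinct(g$species),
        shared_across_species = dplyr::n_distinct(g$species) >= 2L,
        max_pairwise_mismatches = dmax,
        members = list(select(g, "species", "name", "mature_seq"))
      )
    }) |>
    ungroup()
}

#' Arm dominance call
#'
#' Which hairpin arm contributed more reads; the dominant arm is the mature
#' arm for that miRNA. Equal counts are reported as a tie, not resolved.
#'
#' @param count_5p,count_3p Non-negative read counts of the 5p and 3p arms.
#' @return `"5p"`, `"3p"` or `"tie"` (vectorised).
#' @export
arm_dominance <- function(count_5p, count_3p) {
  stopifnot(all(count_5p >= 0), all(count_3p >= 0))
  dplyr::case_when(count_5p > count_3p ~ "5p",
                   count_3p > count_5p ~ "3p",
                   TRUE ~ "tie")
}

#' Per-column conservation profile of aligned matures
#'
#' For each column of a set of aligned equal-length sequences, the fraction
#' of sequences carrying the modal base, binned for display: `dark`
#' (> 0.80), `mid` (> 0.60), `light` (> 0.40), `none` otherwise. Shorter
#' sequences are padded with terminal gaps (`-`), which never count as
#' conserved.
#'
#' @param seqs Character vector of at least 2 sequences (RNA or DNA).
#' @param pad If `TRUE` (default), pad shorter sequences with terminal gaps;
#'   if `FALSE`, unequal lengths are an error.
#' @return A `conservation_profile`: tibble with `column`, `modal_base`,
#'   `fraction`, `bin`, and the input sequences as attribute `"seqs"`.
#' @export
conservation_profile <- function(seqs, pad = TRUE) {
  if (length(seqs) < 2) abort("need at least 2 sequences",
                              class = "spongemir_input_error")
  s <- .norm_seq(seqs)
  w <- max(nchar(s))
  if (any(nchar(s) != w)) {
    if (!pad) abort("sequences have unequal lengths",
                    class = "spongemir_input_error")
    s <- stringr::str_pad(s, w, side = "right", pad = "-")
  }
  mat <- do.call(rbind, strsplit(s, ""))
  prof <- purrr::map_dfr(seq_len(w), function(j) {
    col <- mat[, j]
    bases <- col[col != "-"]
    tab <- sort(table(bases), decreasing = TRUE)
    frac <- if (length(tab) == 0) 0 else tab[1] / length(col)
    tibble(column = j,
           modal_base = if (length(tab) == 0) "-" else names(tab)[1],
           fraction = as.numeric(frac))
  }) |>
    mutate(bin = dplyr::case_when(.data$fraction > 0.80 ~ "dark",
                                  .data$fraction > 0.60 ~ "mid",
                                  .data$fraction > 0.40 ~ "light",
                                  TRUE ~ "none"))
  structure(prof, seqs = s, class = c("conservation_profile", class(prof)))
}

#' Tally reads exactly matching reference matures
#'
#' For each reference mature, the summed count of collapsed reads whose
#' sequence equals it exactly (U/T-normalised, case-insensitive).
#'
#' @param collapsed Tibble `seq`, `count` (e.g. from [collapse_reads()]).
#' @param reference Tibble `name`, `seq` of reference matures.
#' @return Tibble `name`, `seq`, `reads`: reference order preserved, absent
#'   matures tallied as 0.
#' @export
tally_exact_matches <- function(collapsed, reference) {
  key <- tibble(seq_norm = .norm_seq(collapsed$seq), count = collapsed$count) |>
    group_by(.data$seq_norm) |>
    summarise(reads = sum(.data$count), .groups = "drop")
  tibble(name = reference$name, seq = reference$seq,
         seq_norm = .norm_seq(reference$seq)) |>
    left_join(key, by = "seq_norm") |>
    mutate(reads = ifelse(is.na(.data$reads), 0L, .data$reads)) |>
    select("name", "seq", "reads")
}

#' Plot a conservation profile
#'
#' Tile plot of the aligned sequences, coloured by per-column conservation
#' bin, in the style of published miRNA homolog alignments.
#'
#' @param object A [conservation_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.conservation_profile <- function(object, ...) {
  seqs <- attr(object, "seqs")
  long <- purrr::map_dfr(seq_along(seqs), function(i) {
    tibble(seq_id = factor(i, levels = rev(seq_along(seqs))),
           column = seq_len(nchar(seqs[i])),
           base = strsplit(seqs[i], "")[[1]])
  }) |>
    left_join(select(as_tibble(object), "column", "bin"), by = "column") |>
    mutate(bin = ifelse(.data$base == "-", "none", .data$bin),
           bin = factor(.data$bin, c("dark", "mid", "light", "none")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$column, y = .data$seq_id)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$bin), colour = "grey90") +
    ggplot2::geom_text(ggplot2::aes(label = tolower(chartr("T", "U", .data$base))),
                       size = 3) +
    ggplot2::scale_fill_manual(values = c(dark = "#2166ac", mid = "#67a9cf",
                                          light = "#d1e5f0", none = "white"),
                               name = "conservation") +
    ggplot2::labs(x = "alignment column", y = "sequence") +
    ggplot2::theme_minimal()
}
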