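# Hairpin discovery: read-stack detection, precursor window excision, fold
# validation (base-pair maximisation), Dicer processing-signature metrics
# (3' overhang, 5'-end consistency), an additive candidate score, and the
# bona fide selection step.
#
# Candidate windows are folded whole; the mature/star duplex is inferred
# from the pairing partners of the mature, the window is trimmed to the
# implied precursor extent and refolded, and the canonical-hairpin checks
# are applied to that refold. Trimming before validation keeps spurious
# base pairs in the excision flanks from masking a genuine single-stem
# precursor.

#' Fold a sequence by base-pair maximisation
#'
#' Returns a maximum-cardinality set of nested base pairs (Watson-Crick plus
#' GU wobble; `N` never pairs) with hairpin loops of at least `min_loop`
#' unpaired bases, computed by dynamic programming with a deterministic
#' traceback (pairing is preferred over leaving a base unpaired; the
#' smallest eligible partner is chosen).
#'
#' @param seq Sequence over `{A,C,G,T,U,N}`.
#' @param min_loop Minimum hairpin loop length (default 3).
#' @return A `pair_table`: list with `seq`, `partner` (integer vector,
#'   1-based partner index or `NA` if unpaired) and `dot_bracket`.
#' @export
fold_nussinov <- function(seq, min_loop = 3L) {
  res <- .nussinov_cpp(seq, as.integer(min_loop))
  partner <- res$partner
  partner[partner == 0L] <- NA_integer_
  structure(list(seq = toupper(chartr("U", "T", seq)), partner = partner,
                 dot_bracket = res$dot_bracket),
            class = "pair_table")
}

#' @export
print.pair_table <- function(x, ...) {
  cat(x$seq, "\n", x$dot_bracket, "\n", sep = "")
  cat(sprintf("%d base pairs\n", sum(!is.na(x$partner)) %/% 2L))
  invisible(x)
}

#' Number of base pairs in a pair table
#'
#' @param pt A `pair_table` from [fold_nussinov()].
#' @return Integer pair count.
#' @export
n_pairs <- function(pt) sum(!is.na(pt$partner)) %/% 2L

# hairpin loops = pairs enclosing no other paired base
.n_hairpin_loops <- function(pt) {
  p <- pt$partner
  idx <- which(!is.na(p) & p > seq_along(p))
  sum(vapply(idx, function(i) {
    p[i] - i <= 1L || all(is.na(p[(i + 1L):(p[i] - 1L)]))
  }, logical(1)))
}

#' Find 5'-position read stacks
#'
#' Groups alignments by scaffold and strand and single-links read 5'
#' positions at most 3 nt apart into stacks; stacks whose summed collapsed
#' count reaches `cfg$min_stack_count` are returned. The 5' position of a
#' minus-strand alignment is its genomic end.
#'
#' @param alignments Alignment tibble from [map_library()].
#' @param cfg A [discovery_config()].
#' @return Tibble with one row per stack: `stack_id`, `scaffold`, `strand`,
#'   `modal_start` (genome coordinate of the modal 5' base), `modal_len`
#'   (read length of the dominant sequence at the modal start),
#'   `total_count`, `modal_count`, and `starts`, a list-column tibble of
#'   per-5'-position counts.
#' @export
find_stacks <- function(alignments, cfg = discovery_config()) {
  empty <- tibble(stack_id = character(), scaffold = character(),
                  strand = character(), modal_start = integer(),
                  modal_len = integer(), total_count = integer(),
                  modal_count = integer(), starts = list())
  if (nrow(alignments) == 0) return(empty)
  aln <- alignments |>
    mutate(p5 = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
           len = .data$end - .data$start)
  out <- aln |>
    group_by(.data$scaffold, .data$strand) |>
    dplyr::group_modify(function(g, key) {
      g <- arrange(g, .data$p5)
      brk <- c(0L, cumsum(diff(g$p5) > 3L))
      g$cluster <- brk
      g |>
        group_by(.data$cluster) |>
        dplyr::group_modify(function(cl, k2) {
          per_start <- cl |>
            group_by(pos = .data$p5) |>
            summarise(count = sum(.data$count), .groups = "drop") |>
            arrange(.data$pos)
          modal <- per_start$pos[which.max(per_start$count)]
          at_modal <- filter(cl, .data$p5 == modal) |>
            arrange(desc(.data$count), .data$len)
          tibble(modal_start = modal,
                 modal_len = at_modal$len[1],
                 total_count = sum(per_start$count),
                 modal_count = max(per_start$count),
                 starts = list(per_start))
        }) |>
        ungroup() |>
        select(-"cluster")
    }) |>
    ungroup() |>
    filter(.data$total_count >= cfg$min_stack_count)
  if (nrow(out) == 0) return(empty)
  out |>
    arrange(.data$scaffold, .data$strand, .data$modal_start) |>
    mutate(stack_id = sprintf("stack_%04d", row_number())) |>
    select("stack_id", "scaffold", "strand", "modal_start", "modal_len",
           "total_count", "modal_count", "starts")
}

#' 5'-end consistency of a stack
#'
#' The proportion of stack reads whose 5' end is the modal 5' position —
#' high homogeneity is a hallmark of genuine Drosha/Dicer processing.
#'
#' @param stack One row of the [find_stacks()] result (or a list with
#'   `modal_count` and `total_count`).
#' @return Fraction in `[0, 1]`.
#' @export
five_prime_consistency <- function(stack) {
  if (stack$total_count[1] <= 0) {
    abort("stack has no reads", class = "spongemir_input_error")
  }
  stack$modal_count[1] / stack$total_count[1]
}

# transcript-local <-> genome transforms for a window on a strand
.win_local_to_genome <- function(l, win_start, win_end, strand) {
  if (strand == "+") win_start + l else (win_end - 1L) - l
}

#' Excise candidate precursor windows around a read stack
#'
#' Two windows are emitted per stack: one assuming the stack is the 5p arm
#' (15 nt upstream, `window_flank` nt downstream of the read) and one
#' assuming it is the 3p arm (mirrored). Windows are clipped to scaffold
#' bounds. Windows containing a run of at least `cfg$max_gap_run` `N`s are
#' flagged `gap_interrupted`; they are excluded from folding and reported
#' separately.
#'
#' @param stack One row of [find_stacks()] output.
#' @param genome Genome tibble `name`, `seq`.
#' @param cfg A [discovery_config()].
#' @return Tibble with one row per window: `assume_arm`, `win_start`,
#'   `win_end` (genome, 0-based half-open), `precursor_seq` (5'->3' in stack
#'   orientation), `mature_local` (0-based offset of the mature 5' end in
#'   `precursor_seq`), `mature_len`, `gap_interrupted`.
#' @export
excise_precursors <- function(stack, genome, cfg = discovery_config()) {
  seqs <- setNames(genome$seq, genome$name)
  sc_len <- nchar(seqs[[stack$scaffold[1]]])
  m <- stack$modal_start[1]
  rl <- stack$modal_len[1]
  strand <- stack$strand[1]
  one <- function(assume_arm) {
    ext5 <- if (assume_arm == "5p") 15L else cfg$window_flank
    ext3 <- if (assume_arm == "5p") cfg$window_flank else 15L
    if (strand == "+") {
      ws <- max(0L, m - ext5); we <- min(sc_len, m + rl + ext3)
      local <- m - ws
    } else {
      ws <- max(0L, m - rl - ext3 + 1L); we <- min(sc_len, m + ext5 + 1L)
      local <- (we - 1L) - m
    }
    pseq <- .genome_slice(seqs, stack$scaffold[1], ws, we, strand)
    tibble(assume_arm = assume_arm, win_start = ws, win_end = we,
           precursor_seq = pseq, mature_local = local, mature_len = rl,
           gap_interrupted = grepl(strrep("N", cfg$max_gap_run), pseq, fixed = TRUE))
  }
  bind_rows(one("5p"), one("3p")) |>
    filter(.data$mature_local >= 0L,
           .data$mature_local + .data$mature_len <= nchar(.data$precursor_seq))
}

#' Validate a candidate hairpin structure
#'
#' Accepts a folded candidate precursor iff its paired region forms a single
#' stem (at most one hairpin loop in the structure), the mature lies
#' entirely on one arm (protruding at most 2 nt into the loop), and at least
#' `cfg$min_pairing_fraction` of mature bases are paired into the duplex.
#' The star interval is inferred as the pairing partner of the mature
#' shifted 2 nt toward its 3' end — the canonical Dicer duplex geometry.
#'
#' @param pt A `pair_table` for the candidate precursor.
#' @param mature_local 0-based half-open mature interval `c(start, end)`
#'   within the folded sequence.
#' @param cfg A [discovery_config()].
#' @return List with `accepted` (logical), `reason` (`NA` or one of
#'   `"multiloop"`, `"weak_duplex"`, `"not_single_arm"`,
#'   `"mature_in_loop"`), `arm` (`"5p"`/`"3p"`), `star_local` (0-based
#'   half-open) and `pairing_fraction`.
#' @export
validate_hairpin <- function(pt, mature_local, cfg = discovery_config()) {
  reject <- function(reason) list(accepted = FALSE, reason = reason, arm = NA_character_,
                                  star_local = NULL, pairing_fraction = NA_real_)
  n <- nchar(pt$seq)
  ms <- mature_local[1] + 1L; me <- mature_local[2] # 1-based inclusive
  if (ms < 1L || me > n) abort("mature interval outside sequence",
                               class = "spongemir_input_error")
  if (.n_hairpin_loops(pt) > 1L) return(reject("multiloop"))
  mat_idx <- ms:me
  partners <- pt$partner[mat_idx]
  outside <- partners[!is.na(partners) & (partners < ms | partners > me)]
  # the duplex partners follow one helix register (i + partner(i) constant
  # up to small bulges); partners far off the modal register are chance
  # pairs with the loop or flanks, not duplex evidence
  c_reg <- NA_integer_
  if (length(outside) > 2) {
    paired_i <- mat_idx[!is.na(partners) & (partners < ms | partners > me)]
    reg <- paired_i + outside
    c_reg <- as.integer(names(sort(table(reg), decreasing = TRUE))[1])
    keep <- abs(reg - c_reg) <= 2L
    outside <- outside[keep]
  }
  pf <- length(outside) / length(mat_idx)
  if (pf < cfg$min_pairing_fraction) return(reject("weak_duplex"))
  up <- sum(outside < ms); down <- sum(outside > me)
  if (min(up, down) > 0L) return(reject("not_single_arm"))
  arm <- if (down > 0L) "5p" else "3p"
  # protrusion into the hairpin loop: mature bases inside the loop interior
  p <- pt$partner
  leaf <- which(vapply(seq_len(n), function(i) {
    !is.na(p[i]) && p[i] > i &&
      (p[i] - i <= 1L || all(is.na(p[(i + 1L):(p[i] - 1L)])))
  }, logical(1)))
  if (length(leaf) == 1L) {
    loop_int <- seq(leaf + 1L, p[leaf] - 1L)
    if (length(intersect(mat_idx, loop_int)) > 2L) return(reject("mature_in_loop"))
  }
  # canonical Dicer geometry: the star is the register image of the mature
  # shifted 2 nt toward its own 3' end (0-based half-open)
  star <- if (!is.na(c_reg)) c(c_reg - me + 1L, c_reg - ms + 2L) else
    c(min(outside) - 1L, max(outside) + 2L)
  star[1] <- max(0L, star[1]); star[2] <- min(n, star[2])
  list(accepted = TRUE, reason = NA_character_, arm = arm,
       star_local = as.integer(star), pairing_fraction = pf)
}

#' 3' overhang lengths of a mature/star duplex
#'
#' For each duplex strand, the overhang is the number of its 3'-terminal
#' bases extending beyond the pairing partner of the other strand's 5' end
#' (taking the 5'-most paired base of that strand). A blunt duplex scores 0;
#' recessed ends are reported as 0 with a `recessed` flag. The canonical
#' Drosha/Dicer signature is 2 nt on each strand.
#'
#' @param pt A `pair_table`.
#' @param mature_local,star_local 0-based half-open intervals within the
#'   folded sequence.
#' @return List with `overhang_mature`, `overhang_star`, `recessed_mature`,
#'   `recessed_star`.
#' @export
overhang_3p <- function(pt, mature_local, star_local) {
  n <- nchar(pt$seq)
  if (mature_local[2] > n || star_local[2] > n || mature_local[1] < 0 ||
        star_local[1] < 0) {
    abort("interval outside sequence", class = "spongemir_input_error")
  }
  first_paired <- function(interval) {
    idx <- (interval[1] + 1L):interval[2]
    paired <- idx[!is.na(pt$partner[idx])]
    if (length(paired) == 0) NA_integer_ else paired[1]
  }
  oh <- function(this_int, other_int) {
    fp <- first_paired(other_int)
    if (is.na(fp)) return(c(NA_integer_, NA))
    raw <- this_int[2] - pt$partner[fp] # 3'-terminal (1-based) minus partner
    c(max(0L, raw), raw < 0L)
  }
  m <- oh(mature_local, star_local)
  s <- oh(star_local, mature_local)
  list(overhang_mature = m[1], overhang_star = s[1],
       recessed_mature = isTRUE(m[2] == 1), recessed_star = isTRUE(s[2] == 1))
}

#' Additive processing-signature score
#'
#' `w_str * pairing_fraction + w_oh * g(overhang) + w_5p * consistency +
#' w_cnt * log10(mature_count + 1)`, where `g(2) = 1`, `g(1) = g(3) = 0.5`,
#' otherwise 0. A transparent surrogate for opaque probabilistic miRNA
#' scores; monotone nondecreasing in every component.
#'
#' @param sig List or one-row tibble with `pairing_fraction`,
#'   `overhang_3p_mature`, `five_prime_consistency`, `mature_count`.
#' @param cfg A [discovery_config()] (weights).
#' @return Numeric score.
#' @export
signature_score <- function(sig, cfg = discovery_config()) {
  g <- function(oh) dplyr::case_when(is.na(oh) ~ 0, oh == 2 ~ 1,
                                     oh %in% c(1, 3) ~ 0.5, TRUE ~ 0)
  cfg$w_str * sig$pairing_fraction[1] +
    cfg$w_oh * g(sig$overhang_3p_mature[1]) +
    cfg$w_5p * sig$five_prime_consistency[1] +
    cfg$w_cnt * log10(sig$mature_count[1] + 1)
}

# Overhang measurement on a candidate duplex: per strand, the number of
# 3'-terminal bases beyond the partner of the other strand's 5' end. When
# that 5'-end base is frayed (unpaired), its partner is projected from the
# duplex register (i + partner(i) constant along the helix) so a frayed
# terminal pair does not bias the measured overhang.
.measure_overhangs <- function(pt, mature_local, star_local) {
  p <- pt$partner
  mat_idx <- (mature_local[1] + 1L):mature_local[2]
  duplex <- mat_idx[!is.na(p[mat_idx]) & !(p[mat_idx] %in% mat_idx)]
  if (length(duplex) == 0) {
    return(list(overhang_mature = NA_integer_, overhang_star = NA_integer_))
  }
  reg <- duplex + p[duplex]
  c_reg <- as.integer(names(sort(table(reg), decreasing = TRUE))[1])
  # project each strand's boundary through the duplex register: the
  # partner of position i is c_reg - i along the helix, so the overhang is
  # a pure offset measurement, immune to frayed or chance terminal pairs
  oh_m <- mature_local[2] + (star_local[1] + 1L) - c_reg
  oh_s <- star_local[2] + (mature_local[1] + 1L) - c_reg
  list(overhang_mature = max(0L, as.integer(oh_m)),
       overhang_star = max(0L, as.integer(oh_s)))
}

# partition stack-neighbourhood alignments into mature/star/loop/other reads
.read_partition <- function(alignments, scaffold, strand, mature_g, star_g,
                            win_g) {
  near <- alignments |>
    filter(.data$scaffold == !!scaffold, .data$strand == !!strand,
           .data$start < win_g[2], .data$end > win_g[1]) |>
    mutate(p5 = ifelse(.data$strand == "+", .data$start, .data$end - 1L))
  m5 <- if (strand == "+") mature_g[1] else mature_g[2] - 1L
  s5 <- if (strand == "+") star_g[1] else star_g[2] - 1L
  lo <- sort(c(mature_g, star_g))
  cls <- dplyr::case_when(
    abs(near$p5 - m5) <= 3L ~ "mature",
    abs(near$p5 - s5) <= 3L ~ "star",
    near$p5 >= lo[2] & near$p5 < lo[3] ~ "loop",
    TRUE ~ "other"
  )
  counts <- tapply(near$count, factor(cls, c("mature", "star", "loop", "other")),
                   sum, default = 0L)
  as.list(counts)
}

.can_pair_bases <- function(a, b) {
  (a == "A" & (b == "T" | b == "U")) |
    ((a == "T" | a == "U") & (b == "A" | b == "G")) |
    (a == "G" & (b == "C" | b == "T" | b == "U")) |
    (a == "C" & b == "G")
}

# Close frayed duplex ends: base-pair maximisation can reroute mature bases
# beyond an internal star mismatch into nearby loop helices, leaving the
# duplex ends apparently unpaired. Given the duplex register implied by the
# fold (i + partner(i) is constant along a helix), re-close Watson-Crick/GU
# pairs between mature and star positions in that register, dropping the
# rerouted junk pairs. This mirrors how an energy-based folder would treat a
# terminal mismatch as a small internal loop rather than breaking the stem.
.extend_duplex_register <- function(partner, seq, mat_idx, outside) {
  paired_mat <- mat_idx[!is.na(partner[mat_idx]) & partner[mat_idx] %in% outside]
  if (length(paired_mat) < 3) return(list(partner = partner, outside = outside))
  reg <- paired_mat + partner[paired_mat]
  c_reg <- as.integer(names(sort(table(reg), decreasing = TRUE))[1])
  bases <- strsplit(seq, "")[[1]]
  lo <- min(outside) - 6L; hi <- max(outside) + 6L
  for (i in mat_idx) {
    j <- c_reg - i
    if (j < max(1L, lo) || j > min(length(bases), hi) || j %in% mat_idx) next
    if (!is.na(partner[i]) && partner[i] == j) next
    if (!.can_pair_bases(bases[i], bases[j])) next
    # only steal partners that are not themselves in-register duplex pairs
    pj <- partner[j]
    if (!is.na(pj) && (pj %in% mat_idx) && pj + j == c_reg) next
    if (!is.na(partner[i])) partner[partner[i]] <- NA_integer_
    if (!is.na(pj)) partner[pj] <- NA_integer_
    partner[i] <- j
    partner[j] <- i
  }
  outside <- partner[mat_idx]
  outside <- sort(outside[!is.na(outside) & !(outside %in% mat_idx) &
                            outside >= lo & outside <= hi])
  list(partner = partner, outside = outside)
}

# Restrict a window fold to the trimmed precursor: keep pairs with both
# ends inside `trim` (0-based half-open, window coordinates), remapped to
# trimmed coordinates, and unpair bases nested strictly inside the
# mature/star duplex loop (tiny loop-internal helices are irrelevant to the
# duplex geometry and would otherwise read as extra hairpin loops).
.restrict_pairs <- function(fold, trim, mat_idx, outside) {
  lo <- trim[1] + 1L; hi <- trim[2] # 1-based inclusive bounds
  p <- fold$partner
  keep <- !is.na(p) & seq_along(p) >= lo & seq_along(p) <= hi & p >= lo & p <= hi
  p[!keep] <- NA_integer_
  # drop micro-helices internal to one arm (mature self-pairs, star
  # self-pairs): they say nothing about the duplex and would read as extra
  # hairpin loops
  in_mat <- seq_along(p) %in% mat_idx
  in_star <- seq_along(p) >= min(outside) & seq_along(p) <= max(outside)
  drop_arm <- which((!is.na(p)) & ((in_mat & p %in% mat_idx) |
                                     (in_star & p >= min(outside) &
                                        p <= max(outside) & !(p %in% mat_idx) &
                                        !in_mat)))
  p[p[drop_arm]] <- NA_integer_
  p[drop_arm] <- NA_integer_
  paired_mat <- mat_idx[!is.na(fold$partner[mat_idx]) &
                          fold$partner[mat_idx] %in% outside]
  if (length(paired_mat) > 0) {
    inner_m <- if (min(outside) > max(mat_idx)) max(paired_mat) else min(paired_mat)
    inner_s <- fold$partner[inner_m]
    if (abs(inner_s - inner_m) > 2L) {
      interior <- (min(inner_m, inner_s) + 1L):(max(inner_m, inner_s) - 1L)
      drop <- intersect(which(!is.na(p)), interior)
      drop <- drop[p[drop] %in% interior]
      p[drop] <- NA_integer_
    }
  }
  p <- p[lo:hi] - trim[1]
  seq_trim <- substr(fold$seq, lo, hi)
  db <- rep(".", length(p))
  db[!is.na(p) & p > seq_along(p)] <- "("
  db[!is.na(p) & p < seq_along(p)] <- ")"
  structure(list(seq = seq_trim, partner = p,
                 dot_bracket = paste(db, collapse = "")),
            class = "pair_table")
}

.empty_candidates <- function() {
  tibble(
    stack_id = character(), scaffold = character(), strand = character(),
    assume_arm = character(), win_start = integer(), win_end = integer(),
    mature_start = integer(), mature_end = integer(), star_start = integer(),
    star_end = integer(), precursor_start = integer(), precursor_end = integer(),
    mature_arm = character(), mature_seq = character(), star_seq = character(),
    precursor_seq = character(), dot_bracket = character(),
    pairing_fraction = double(), overhang_3p_mature = integer(),
    overhang_3p_star = integer(), five_prime_consistency = double(),
    mature_count = integer(), star_count = integer(), loop_count = integer(),
    other_count = integer(), score = double(), accepted = logical(),
    reason = character()
  )
}

# Fold one (sub)window and try to validate a mature/star duplex in it.
# Returns a rejection reason (character) or a list with the trimmed
# precursor, restricted pair table and validation result, in subwindow
# coordinates.
.try_duplex <- function(pseq, m_loc, mature_len, cfg) {
  fold <- fold_nussinov(pseq, cfg$min_loop)
  mat_idx <- (m_loc[1] + 1L):m_loc[2]
  partners <- fold$partner[mat_idx]
  outside <- partners[!is.na(partners) & (partners < m_loc[1] + 1L |
                                            partners > m_loc[2])]
  # duplex partners lie on one side in a dense block; keep the majority side
  # and drop stray partners picked up from the excision flanks
  side_down <- outside > m_loc[2]
  outside <- if (sum(side_down) >= sum(!side_down)) outside[side_down] else
    outside[!side_down]
  outside <- sort(outside)
  if (length(outside) > 1L) {
    span_max <- mature_len + 8L
    runs <- cumsum(c(0L, diff(outside) > 6L))
    best_run <- names(which.max(table(runs)))
    outside <- outside[runs == as.integer(best_run)]
    if (max(outside) - min(outside) > span_max) {
      outside <- outside[outside - min(outside) <= span_max]
    }
  }
  if (length(outside) < 3) return("weak_duplex")
  ext <- .extend_duplex_register(fold$partner, fold$seq, mat_idx, outside)
  fold$partner <- ext$partner
  outside <- ext$outside
  if (length(outside) / length(mat_idx) < cfg$min_pairing_fraction) {
    return("weak_duplex")
  }
  star_loc <- c(min(outside) - 1L, min(nchar(pseq), max(outside) + 2L))
  trim <- c(min(m_loc[1], star_loc[1]), max(m_loc[2], star_loc[2]))
  trimmed_seq <- substr(pseq, trim[1] + 1L, trim[2])
  m_trim <- m_loc - trim[1]
  refold <- .restrict_pairs(fold, trim, mat_idx, outside)
  val <- validate_hairpin(refold, m_trim, cfg)
  if (!val$accepted) return(val$reason)
  list(trim = trim, trimmed_seq = trimmed_seq, m_trim = m_trim,
       refold = refold, val = val)
}

# evaluate one excised window for one stack; returns a one-row candidate
# tibble (accepted or rejected with reason)
.evaluate_window <- function(win, stack, alignments, cfg) {
  base <- tibble(
    stack_id = stack$stack_id[1], scaffold = stack$scaffold[1],
    strand = stack$strand[1], assume_arm = win$assume_arm,
    win_start = win$win_start, win_end = win$win_end,
    mature_start = NA_integer_, mature_end = NA_integer_,
    star_start = NA_integer_, star_end = NA_integer_,
    precursor_start = NA_integer_, precursor_end = NA_integer_,
    mature_arm = NA_character_, mature_seq = NA_character_,
    star_seq = NA_character_, precursor_seq = NA_character_,
    dot_bracket = NA_character_, pairing_fraction = NA_real_,
    overhang_3p_mature = NA_integer_, overhang_3p_star = NA_integer_,
    five_prime_consistency = NA_real_, mature_count = NA_integer_,
    star_count = NA_integer_, loop_count = NA_integer_,
    other_count = NA_integer_, score = NA_real_,
    accepted = FALSE, reason = NA_character_
  )
  if (win$gap_interrupted) {
    base$reason <- "gap_interrupted"
    return(base)
  }
  m_loc0 <- c(win$mature_local, win$mature_local + win$mature_len)
  wlen <- nchar(win$precursor_seq)
  # Base-pair maximisation over the full window can route the mature into
  # flank sequence instead of the star when the flank happens to offer as
  # many pairs. Real precursors are compact, so evaluation retries the fold
  # on progressively tighter subwindows around the stack (tightening the
  # loop-distal flank) and keeps the first subwindow that validates.
  cuts <- c(cfg$window_flank, 55L, 45L, 35L, 28L)
  attempts <- lapply(unique(pmin(cuts, cfg$window_flank)), function(k) {
    if (win$assume_arm == "5p") c(0L, min(wlen, m_loc0[2] + k))
    else c(max(0L, m_loc0[1] - k), wlen)
  })
  first_reason <- NULL
  hit <- NULL
  for (a in attempts) {
    r <- .try_duplex(substr(win$precursor_seq, a[1] + 1L, a[2]),
                     m_loc0 - a[1], win$mature_len, cfg)
    if (is.character(r)) {
      first_reason <- first_reason %||% r
    } else {
      hit <- r
      hit$off <- a[1]
      break
    }
  }
  if (is.null(hit)) {
    base$reason <- first_reason
    return(base)
  }
  trim <- hit$trim + hit$off
  trimmed_seq <- hit$trimmed_seq
  m_trim <- hit$m_trim
  refold <- hit$refold
  val <- hit$val
  # back-transform trimmed-local intervals to genome coordinates
  to_genome <- function(loc_trim) {
    l <- loc_trim + trim[1]
    g <- vapply(c(l[1], l[2] - 1L), .win_local_to_genome,
                numeric(1), win$win_start, win$win_end, stack$strand[1])
    as.integer(c(min(g), max(g) + 1L))
  }
  mature_g <- to_genome(m_trim)
  star_g <- to_genome(val$star_local)
  # star boundary: prefer read evidence (the Dicer cut leaves a stack of
  # star reads at a precise 5' end), falling back to the fold-implied one
  star_loc_final <- val$star_local
  s5_struct <- if (stack$strand[1] == "+") star_g[1] else star_g[2] - 1L
  near_star <- alignments |>
    filter(.data$scaffold == stack$scaffold[1], .data$strand == stack$strand[1]) |>
    mutate(p5 = ifelse(.data$strand == "+", .data$start, .data$end - 1L)) |>
    filter(abs(.data$p5 - s5_struct) <= 5L)
  if (nrow(near_star) > 0) {
    per5 <- near_star |>
      group_by(.data$p5) |>
      summarise(count = sum(.data$count), len = .data$end[which.max(.data$count)] -
                  .data$start[which.max(.data$count)], .groups = "drop")
    top <- per5[which.max(per5$count), ]
    sg <- if (stack$strand[1] == "+") c(top$p5, top$p5 + top$len) else
      c(top$p5 + 1L - top$len, top$p5 + 1L)
    # genome -> trimmed-local
    l <- vapply(c(sg[1], sg[2] - 1L), function(g) {
      if (stack$strand[1] == "+") g - win$win_start else (win$win_end - 1L) - g
    }, numeric(1))
    cand_loc <- as.integer(c(min(l), max(l) + 1L)) - trim[1]
    if (cand_loc[1] > -6L && cand_loc[2] < nchar(trimmed_seq) + 6L) {
      star_loc_final <- cand_loc
      star_g <- as.integer(c(min(sg), max(sg)))
    }
  }
  ohs <- .measure_overhangs(refold, m_trim, star_loc_final)
  # clamp for sequence extraction only; the overhang above uses the exact
  # read-defined boundary
  star_loc_clamp <- c(max(0L, star_loc_final[1]),
                      min(nchar(trimmed_seq), star_loc_final[2]))
  prec_g <- c(min(mature_g[1], star_g[1]), max(mature_g[2], star_g[2]))
  part <- .read_partition(alignments, stack$scaffold[1], stack$strand[1],
                          mature_g, star_g, prec_g)
  consistency <- five_prime_consistency(stack)
  sig <- list(pairing_fraction = val$pairing_fraction,
              overhang_3p_mature = ohs$overhang_mature,
              five_prime_consistency = consistency,
              mature_count = part$mature)
  base |>
    mutate(
      mature_start = mature_g[1], mature_end = mature_g[2],
      star_start = star_g[1], star_end = star_g[2],
      precursor_start = prec_g[1], precursor_end = prec_g[2],
      mature_arm = val$arm,
      mature_seq = substr(trimmed_seq, m_trim[1] + 1L, m_trim[2]),
      star_seq = substr(trimmed_seq, star_loc_clamp[1] + 1L, star_loc_clamp[2]),
      precursor_seq = trimmed_seq, dot_bracket = refold$dot_bracket,
      pairing_fraction = val$pairing_fraction,
      overhang_3p_mature = as.integer(ohs$overhang_mature),
      overhang_3p_star = as.integer(ohs$overhang_star),
      five_prime_consistency = consistency,
      mature_count = as.integer(part$mature), star_count = as.integer(part$star),
      loop_count = as.integer(part$loop), other_count = as.integer(part$other),
      score = signature_score(sig, cfg), accepted = TRUE
    )
}

#' Discover hairpin candidates from alignments
#'
#' Runs stack finding, window excision, folding, validation and scoring.
#'
#' @param alignments Alignment tibble from [map_library()].
#' @param genome Genome tibble `name`, `seq`.
#' @param cfg A [discovery_config()].
#' @return List with `candidates` (all evaluated windows, accepted and
#'   rejected, with reason codes), `gap_report` (stacks whose windows were
#'   gap-interrupted) and `stacks`.
#' @export
discover_candidates <- function(alignments, genome, cfg = discovery_config()) {
  stacks <- find_stacks(alignments, cfg)
  cands <- purrr::map_dfr(seq_len(nrow(stacks)), function(i) {
    st <- stacks[i, ]
    wins <- excise_precursors(st, genome, cfg)
    out <- purrr::map_dfr(seq_len(nrow(wins)), function(w) {
      .evaluate_window(wins[w, ], st, alignments, cfg)
    })
    # if both arm assumptions validate for one stack, keep the one with
    # star-read support (a read-backed duplex partner), then the higher
    # score; the other is demoted
    acc <- which(out$accepted)
    if (length(acc) > 1) {
      pref <- order(out$star_count[acc] > 0, out$score[acc], decreasing = TRUE)
      lose <- acc[pref[-1]]
      out$accepted[lose] <- FALSE
      out$reason[lose] <- "secondary_window"
    }
    out
  })
  if (nrow(cands) == 0) cands <- .empty_candidates()
  gap_report <- if (nrow(cands) == 0) {
    select(cands, "stack_id", "scaffold", "strand", "win_start", "win_end",
           "assume_arm")
  } else {
    cands |>
      filter(.data$reason == "gap_interrupted" & !is.na(.data$reason)) |>
      distinct(.data$stack_id, .keep_all = TRUE) |>
      select("stack_id", "scaffold", "strand", "win_start", "win_end",
             "assume_arm")
  }
  list(candidates = cands, gap_report = gap_report, stacks = stacks)
}

#' Select bona fide miRNAs from scored candidates
#'
#' Retains accepted candidates with score at least `cfg$score_threshold`,
#' 5'-end consistency at least `cfg$min_five_prime_consistency`, mature 3'
#' overhang within `cfg$overhang_range`, and (optionally) at least one
#' star-arm read. Overlapping candidates at the same locus are reduced to
#' the highest-scoring one (ties: higher mature count, then leftmost).
#' Identical mature sequences at distinct loci are all retained as separate
#' records.
#'
#' @param candidates Candidate tibble from [discover_candidates()].
#' @param cfg A [discovery_config()].
#' @param species Species tag used in assigned names.
#' @return Tibble of bona fide miRNAs: `name`, `species`, `scaffold`,
#'   `strand`, genome intervals, `mature_arm`, `mature_seq`/`star_seq` (RNA
#'   alphabet), read counts, signature metrics and `score`.
#' @export
select_bona_fide <- function(candidates, cfg = discovery_config(),
                             species = "sim") {
  ok <- candidates |>
    filter(.data$accepted,
           .data$score >= cfg$score_threshold,
           .data$five_prime_consistency >= cfg$min_five_prime_consistency,
           .data$overhang_3p_mature >= cfg$overhang_range[1],
           .data$overhang_3p_mature <= cfg$overhang_range[2])
  if (cfg$require_star_reads) ok <- filter(ok, .data$star_count >= 1L)
  ok <- arrange(ok, desc(.data$score), desc(.data$mature_count),
                .data$mature_start)
  kept <- ok[0, ]
  for (i in seq_len(nrow(ok))) {
    cand <- ok[i, ]
    # same locus regardless of strand: an antisense mirror of a hairpin is
    # the same physical locus and must not be reported twice
    clash <- kept$scaffold == cand$scaffold &
      kept$precursor_start < cand$precursor_end &
      cand$precursor_start < kept$precursor_end
    if (!any(clash)) kept <- bind_rows(kept, cand)
  }
  kept |>
    arrange(.data$scaffold, .data$precursor_start, .data$strand) |>
    mutate(name = sprintf("%s-mir-%d", species, row_number()),
           species = species,
           mature_seq = dna_to_rna(.data$mature_seq),
           star_seq = dna_to_rna(.data$star_seq)) |>
    select("name", "species", "scaffold", "strand", "precursor_start",
           "precursor_end", "mature_start", "mature_end", "star_start",
           "star_end", "mature_arm", "mature_seq", "star_seq", "mature_count",
           "star_count", "loop_count", "other_count", "pairing_fraction",
           "overhang_3p_mature", "overhang_3p_star", "five_prime_consistency",
           "score")
}

#' Write precursors and mature/star products as GFF3
#'
#' One `pre_miRNA` feature per record with child `miRNA` features for the
#' mature and star products. Internal 0-based half-open intervals are
#' converted to 1-based inclusive GFF3 coordinates.
#'
#' @param bona_fide Tibble from [select_bona_fide()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(bona_fide, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(bona_fide))) {
    b <- bona_fide[i, ]
    row <- function(type, s, e, id, parent = NULL) {
      attrs <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent),
                      ";Name=", id)
      paste(b$scaffold, "spongemir", type, s + 1L, e, ".", b$strand, ".", attrs,
            sep = "\t")
    }
    lines <- c(lines,
               row("pre_miRNA", b$precursor_start, b$precursor_end, b$name),
               row("miRNA", b$mature_start, b$mature_end,
                   paste0(b$name, "-mature"), b$name),
               row("miRNA", b$star_start, b$star_end,
                   paste0(b$name, "-star"), b$name))
  }
  writeLines(lines, path)
  invisible(path)
}
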