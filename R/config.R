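# Configuration records for each pipeline stage. Each constructor validates
# its arguments and returns a classed list so misconfigured runs fail early
# with a config error rather than midway through a stage.

.check <- function(ok, msg) {
  if (!ok) abort(msg, class = "spongemir_config_error")
}

.frac <- function(x, nm) .check(is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1,
                                paste0(nm, " must be a fraction in [0,1]"))

#' Simulation configuration
#'
#' Parameters of the synthetic small-RNA study: a multi-scaffold genome with
#' planted pre-miRNA hairpins and a read library with mature-arm dominance,
#' tunable 5'-end homogeneity, degradation/ncRNA background and 3'-decaying
#' qualities with adapter read-through.
#'
#' Defaults describe the simulated study conditions used throughout the
#' package's recovery tests: 5 scaffolds of 20 kb, 20 planted hairpins with
#' 2-nt 3' overhangs, roughly 200 mature reads per hairpin
#' (`depth_lognormal = c(log(200), 0.5)`), 95% 5'-end homogeneity and
#' 10,000 background reads.
#'
#' @param seed Integer seed; every random draw in the simulator derives
#'   from it.
#' @param n_scaffolds,scaffold_lengths Number of scaffolds and their lengths
#'   in bp (recycled to `n_scaffolds`).
#' @param gc_fraction Target genome GC fraction.
#' @param n_hairpins Number of planted pre-miRNA hairpins.
#' @param mature_len_range,loop_len_range Min/max mature and loop lengths, nt.
#' @param star_mutations Substitutions applied to the star arm relative to
#'   the exact reverse complement of the mature.
#' @param overhang_len 3' overhang of each duplex strand, nt (canonical 2).
#' @param depth_lognormal `c(mu, sigma)` of the per-hairpin mature read count.
#' @param star_fraction,loop_fraction Star / loop read counts as fractions of
#'   the mature count.
#' @param p5_homogeneity Probability that a mature-derived read starts exactly
#'   at the true mature 5' end; the rest are shifted by 1-2 nt either way.
#' @param jitter3_max Maximum 3'-end jitter of simulated reads, nt.
#' @param background_reads Total background reads (degradation products,
#'   ncRNA fragments, unassignable sequence).
#' @param background_mix Length-3 numeric: proportions of background drawn
#'   from decoy ncRNAs, from random genome slices, and from random sequence
#'   absent from both.
#' @param adapter 3' sequencing adapter literal.
#' @param readthrough_prob Probability a read runs into the 3' adapter.
#' @param phred_decay Per-base Phred drop toward the 3' end (start 38,
#'   floor 2).
#' @param p_low_qual_tail Probability a read carries a low-quality (Phred 10)
#'   3' tail of 1-5 bases, exercising the quality trimmer.
#' @param n_gap_hairpins Number of hairpins whose loop is replaced by a run
#'   of `N`s, emulating an assembly gap splitting the two arms.
#' @param gap_len Length of that N run (>= 10).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_scaffolds = 5L,
                       scaffold_lengths = 20000L,
                       gc_fraction = 0.4,
                       n_hairpins = 20L,
                       mature_len_range = c(21L, 23L),
                       loop_len_range = c(8L, 15L),
                       star_mutations = 1L,
                       overhang_len = 2L,
                       depth_lognormal = c(log(200), 0.5),
                       star_fraction = 0.10,
                       loop_fraction = 0.02,
                       p5_homogeneity = 0.95,
                       jitter3_max = 2L,
                       background_reads = 10000L,
                       background_mix = c(decoy = 1, genome = 1, random = 1) / 3,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       readthrough_prob = 0.3,
                       phred_decay = 0.3,
                       p_low_qual_tail = 0.1,
                       n_gap_hairpins = 0L,
                       gap_len = 12L) {
  scaffold_lengths <- rep_len(as.integer(scaffold_lengths), n_scaffolds)
  .check(all(scaffold_lengths > 0), "scaffold lengths must be positive")
  .check(n_scaffolds >= 1, "need at least one scaffold")
  .frac(gc_fraction, "gc_fraction")
  .frac(star_fraction, "star_fraction")
  .frac(loop_fraction, "loop_fraction")
  .frac(p5_homogeneity, "p5_homogeneity")
  .frac(readthrough_prob, "readthrough_prob")
  .frac(p_low_qual_tail, "p_low_qual_tail")
  .check(mature_len_range[1] >= 16 && mature_len_range[2] <= 30,
         "mature_len_range must lie within [16,30]")
  .check(overhang_len >= 0, "overhang_len must be >= 0")
  .check(n_hairpins >= 0 && n_gap_hairpins >= 0 && n_gap_hairpins <= n_hairpins,
         "n_gap_hairpins must be between 0 and n_hairpins")
  .check(gap_len >= 10, "gap_len must be >= 10 nt")
  .check(all(loop_len_range >= 3), "loops shorter than 3 nt cannot close a hairpin")
  structure(
    list(seed = as.integer(seed), n_scaffolds = as.integer(n_scaffolds),
         scaffold_lengths = scaffold_lengths, gc_fraction = gc_fraction,
         n_hairpins = as.integer(n_hairpins),
         mature_len_range = as.integer(mature_len_range),
         loop_len_range = as.integer(loop_len_range),
         star_mutations = as.integer(star_mutations),
         overhang_len = as.integer(overhang_len),
         depth_lognormal = depth_lognormal,
         star_fraction = star_fraction, loop_fraction = loop_fraction,
         p5_homogeneity = p5_homogeneity, jitter3_max = as.integer(jitter3_max),
         background_reads = as.integer(background_reads),
         background_mix = background_mix / sum(background_mix),
         adapter = toupper(adapter), readthrough_prob = readthrough_prob,
         phred_decay = phred_decay, p_low_qual_tail = p_low_qual_tail,
         n_gap_hairpins = as.integer(n_gap_hairpins),
         gap_len = as.integer(gap_len)),
    class = "sim_config"
  )
}

#' Read-filtering configuration
#'
#' Thresholds of the read-cleaning cascade: end bases below `min_phred` are
#' trimmed, the 3' adapter is removed by exact prefix match, reads shorter
#' than `min_len` are dropped, collapsed sequences seen fewer than
#' `min_count` times are dropped, and sequences whose best local-alignment
#' score against a decoy ncRNA set reaches `ncrna_min_score` are excluded.
#'
#' @param min_phred Minimum terminal base quality (default 20).
#' @param min_len Minimum surviving read length, nt (default 16).
#' @param min_count Minimum per-library copy number of a collapsed sequence
#'   (default 5).
#' @param adapter 3' adapter sequence.
#' @param adapter_min_overlap Minimum exact adapter prefix overlap, nt.
#' @param ncrna_min_score Smith-Waterman score (match +1, mismatch -2, gap
#'   open -5, gap extend -2) at or above which a read is called a decoy hit.
#'   The default 18 is calibrated so that ~20-nt exact ncRNA fragments are
#'   removed while random sequences pass; it emulates a BLASTN cut-off of
#'   about `ncrna_evalue_equiv`.
#' @param ncrna_evalue_equiv Nominal e-value the score threshold emulates.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_phred = 20L, min_len = 16L, min_count = 5L,
                          adapter = "TGGAATTCTCGGGTGCCAAGG",
                          adapter_min_overlap = 6L,
                          ncrna_min_score = 18, ncrna_evalue_equiv = 1e-5) {
  .check(min_phred >= 0 && min_phred <= 41, "min_phred must lie in [0,41]")
  .check(min_len >= 1, "min_len must be >= 1")
  .check(min_count >= 1, "min_count must be >= 1")
  .check(adapter_min_overlap >= 1, "adapter_min_overlap must be >= 1")
  structure(
    list(min_phred = as.integer(min_phred), min_len = as.integer(min_len),
         min_count = as.integer(min_count), adapter = toupper(adapter),
         adapter_min_overlap = as.integer(adapter_min_overlap),
         ncrna_min_score = ncrna_min_score,
         ncrna_evalue_equiv = ncrna_evalue_equiv),
    class = "filter_config"
  )
}

#' Hairpin discovery configuration
#'
#' Parameters of precursor excision, fold validation, the Dicer
#' processing-signature metrics and the bona fide selection step.
#'
#' The candidate score is the additive surrogate
#' `w_str * pairing_fraction + w_oh * g(overhang) + w_5p * consistency +
#' w_cnt * log10(mature_count + 1)` with `g(2) = 1`, `g(1) = g(3) = 0.5`
#' and `g = 0` otherwise; candidates scoring below `score_threshold`
#' (default 5) are discarded.
#'
#' @param min_stack_count Minimum summed read count of a 5'-position stack
#'   (default 10).
#' @param window_flank Flank excised beyond the read stack when building
#'   candidate precursor windows, nt (default 70).
#' @param min_loop Minimum hairpin loop length for folding (default 3).
#' @param min_pairing_fraction Minimum fraction of mature bases paired in the
#'   duplex (default 0.60).
#' @param min_five_prime_consistency Minimum fraction of stack reads sharing
#'   the modal 5' end (default 0.90).
#' @param overhang_range Acceptable mature 3'-overhang lengths, nt.
#' @param score_threshold Minimum candidate score (default 5).
#' @param w_str,w_oh,w_5p,w_cnt Score weights (defaults 2, 1, 2, 1).
#' @param require_star_reads If `TRUE`, require at least one star-arm read.
#' @param max_gap_run A candidate window containing this many consecutive
#'   `N`s is flagged gap-interrupted and excluded from folding (default 5).
#' @return A `discovery_config` list.
#' @export
discovery_config <- function(min_stack_count = 10L, window_flank = 70L,
                             min_loop = 3L, min_pairing_fraction = 0.60,
                             min_five_prime_consistency = 0.90,
                             overhang_range = c(0L, 4L),
                             score_threshold = 5,
                             w_str = 2, w_oh = 1, w_5p = 2, w_cnt = 1,
                             require_star_reads = FALSE,
                             max_gap_run = 5L) {
  .check(min_stack_count >= 1, "min_stack_count must be >= 1")
  .check(window_flank >= 0, "window_flank must be >= 0")
  .check(min_loop >= 0, "min_loop must be >= 0")
  .frac(min_pairing_fraction, "min_pairing_fraction")
  .frac(min_five_prime_consistency, "min_five_prime_consistency")
  .check(overhang_range[1] >= 0 && overhang_range[2] >= overhang_range[1],
         "overhang_range must be a non-negative [min,max]")
  structure(
    list(min_stack_count = as.integer(min_stack_count),
         window_flank = as.integer(window_flank), min_loop = as.integer(min_loop),
         min_pairing_fraction = min_pairing_fraction,
         min_five_prime_consistency = min_five_prime_consistency,
         overhang_range = as.integer(overhang_range),
         score_threshold = score_threshold,
         w_str = w_str, w_oh = w_oh, w_5p = w_5p, w_cnt = w_cnt,
         require_star_reads = isTRUE(require_star_reads),
         max_gap_run = as.integer(max_gap_run)),
    class = "discovery_config"
  )
}

#' Mapper configuration
#'
#' @param k Seed k-mer length (default 12).
#' @param max_mm Maximum substitutions per end-to-end alignment (default 1).
#' @param max_loci Reads hitting more loci than this are discarded as
#'   multi-mappers (default 5).
#' @return A `mapper_config` list.
#' @export
mapper_config <- function(k = 12L, max_mm = 1L, max_loci = 5L) {
  .check(k >= 8, "seed length k must be >= 8")
  .check(max_mm >= 0, "max_mm must be >= 0")
  .check(max_loci >= 1, "max_loci must be >= 1")
  structure(list(k = as.integer(k), max_mm = as.integer(max_mm),
                 max_loci = as.integer(max_loci)),
            class = "mapper_config")
}

#' Whole-pipeline configuration
#'
#' Bundles the per-stage configurations with a single global seed. The seed
#' fans out to the stages by fixed offsets so each stage is independently
#' reproducible.
#'
#' @param seed Global integer seed.
#' @param sim,filter,mapper,discovery Stage configurations; defaults are the
#'   package defaults with the fanned-out seed.
#' @param species Species tag attached to discovered miRNAs.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = sim_config(seed = seed + 101L),
                            filter = filter_config(),
                            mapper = mapper_config(),
                            discovery = discovery_config(),
                            species = "sim") {
  structure(list(seed = as.integer(seed), sim = sim, filter = filter,
                 mapper = mapper, discovery = discovery, species = species),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Unknown keys raise a config error; omitted keys take package defaults.
#'
#' @param path YAML file with optional top-level blocks `seed`, `species`,
#'   `sim`, `filter`, `mapper`, `discovery`.
#' @return A `pipeline_config` list.
#' @export
load_config <- function(path) {
  raw <- yaml::read_yaml(path)
  take <- function(block, fn) {
    args <- raw[[block]] %||% list()
    bad <- setdiff(names(args), names(formals(fn)))
    .check(length(bad) == 0,
           paste0("unknown ", block, " config keys: ", paste(bad, collapse = ", ")))
    do.call(fn, args)
  }
  seed <- as.integer(raw$seed %||% 1L)
  sim <- if (is.null(raw$sim$seed)) {
    do.call(sim_config, c(list(seed = seed + 101L), raw$sim %||% list()))
  } else take("sim", sim_config)
  pipeline_config(seed = seed, sim = sim,
                  filter = take("filter", filter_config),
                  mapper = take("mapper", mapper_config),
                  discovery = take("discovery", discovery_config),
                  species = raw$species %||% "sim")
}
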