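# Pipeline orchestration and publication-style reports: stage composition with a
# run manifest (counts, parameter/artifact hashes), the bundled printed
# mature-miRNA fixture, and TSV report rendering.

.table2_hash <- "0afa76b5fc53e12bc6cf205480288e50"

#' Load the bundled printed mature-miRNA fixture
#'
#' The 30 bona fide mature miRNAs reported for the two Red Sea demosponges
#' (11 from *S. carteri*, species tag `sca`; 19 from *X. testudinaria*, tag
#' `xte`) with their known-miRNA family annotations, in the RNA alphabet as
#' printed. The bundle is checksummed at load time.
#'
#' @return Tibble `name`, `species`, `mature_seq`, `known_match` (`NA` when
#'   the entry matches no known miRNA).
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_matures.tsv", package = "spongemir",
                      mustWork = TRUE)
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  h <- rlang::hash(paste(x$name, x$species, x$mature_seq,
                         ifelse(is.na(x$known_match), "", x$known_match),
                         collapse = "\n"))
  if (!identical(h, .table2_hash)) {
    abort("bundled mature-miRNA fixture failed its checksum",
          class = "spongemir_integrity_error")
  }
  x
}

#' Run the full discovery pipeline
#'
#' Executes preprocess, map, discover and (optionally) conserve on a read
#' library; if no reads are supplied, a study is first simulated from
#' `config$sim`. Re-running with an identical configuration reproduces
#' identical artifacts and manifest hashes.
#'
#' @param config A [pipeline_config()].
#' @param reads,genome Optional tibbles (`id`,`seq`,`qual` / `name`,`seq`);
#'   simulated from `config$sim` when `NULL`.
#' @param decoys Decoy ncRNA set for the filter stage.
#' @param reference Optional tibble `name`, `seq` of known matures; when
#'   given, bona fide calls are annotated by [match_known()] and an
#'   exact-match tally is computed.
#' @param outdir Optional directory; when given, stage artifacts are
#'   written (FASTA/FASTQ/TSV/BED/GFF3) and validated by read-back.
#' @return A `spongemir_run` list: `bona_fide`, `candidates`, `gap_report`,
#'   `stacks`, `collapsed`, `alignments`, `truth` (when simulated), `tally`,
#'   `manifest`, `audit`, `config`. Supports [tidy()], [glance()] and
#'   [autoplot()].
#' @export
run_pipeline <- function(config = pipeline_config(), reads = NULL, genome = NULL,
                         decoys = load_decoys(), reference = NULL,
                         outdir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  manifest <- list()
  note <- function(stage, n_in, n_out, params, output) {
    manifest[[length(manifest) + 1L]] <<- tibble(
      stage = stage, reads_in = n_in, reads_out = n_out,
      params_hash = rlang::hash(params), output_hash = rlang::hash(output)
    )
  }
  truth <- NULL
  if (is.null(reads)) {
    sim <- simulate_study(config$sim, decoys)
    genome <- sim$genome
    reads <- sim$reads
    truth <- sim$truth
    note("simulate", nrow(reads), nrow(reads), config$sim,
         list(genome, truth, reads))
  }
  if (is.null(genome)) {
    abort("genome must be supplied when reads are", class = "spongemir_config_error")
  }
  pp <- preprocess_reads(reads, decoys, config$filter)
  note("preprocess", nrow(reads), sum(pp$collapsed$count), config$filter,
       pp$collapsed)
  index <- build_index(genome, config$mapper$k)
  mp <- map_library(pp$collapsed, index, config$mapper)
  mapped_reads <- sum(mp$audit$n_reads[mp$audit$category == "mapped"])
  note("map", sum(pp$collapsed$count), mapped_reads, config$mapper,
       mp$alignments)
  disc <- discover_candidates(mp$alignments, genome, config$discovery)
  bona_fide <- select_bona_fide(disc$candidates, config$discovery,
                                species = config$species)
  note("discover", mapped_reads, sum(bona_fide$mature_count), config$discovery,
       bona_fide)
  tally <- NULL
  if (!is.null(reference)) {
    matches <- purrr::map_chr(bona_fide$mature_seq, function(m) {
      hit <- match_known(m, reference)
      if (nrow(hit) == 0) NA_character_ else hit$ref_name[1]
    })
    bona_fide$known_match <- matches
    tally <- tally_exact_matches(pp$collapsed_raw, reference)
    note("conserve", sum(bona_fide$mature_count), sum(bona_fide$mature_count),
         list(), list(bona_fide$known_match, tally))
  }
  run <- structure(
    list(bona_fide = bona_fide, candidates = disc$candidates,
         gap_report = disc$gap_report, stacks = disc$stacks,
         collapsed = pp$collapsed, collapsed_raw = pp$collapsed_raw,
         alignments = mp$alignments, truth = truth, tally = tally,
         manifest = bind_rows(manifest),
         audit = list(preprocess = pp$audit, map = mp$audit),
         config = config),
    class = "spongemir_run"
  )
  if (!is.null(outdir)) .write_run_artifacts(run, genome, reads, outdir)
  run
}

.write_run_artifacts <- function(run, genome, reads, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_fasta(genome, p("genome.fa"))
  write_fastq(reads, p("reads.fastq"))
  if (!is.null(run$truth)) write_truth(run$truth, p("truth.tsv"))
  write_collapsed_fasta(run$collapsed, p("collapsed.fa"))
  write_alignments_bed(run$alignments, p("alignments.bed"))
  write_gff3(run$bona_fide, p("bona_fide.gff3"))
  readr::write_tsv(select(run$bona_fide, -dplyr::any_of("starts")),
                   p("bona_fide.tsv"))
  readr::write_tsv(run$manifest, p("manifest.tsv"))
  readr::write_tsv(run$audit$preprocess, p("audit_preprocess.tsv"))
  # read-back schema validation
  stopifnot(identical(read_fasta(p("genome.fa"))$seq, genome$seq))
  rb <- read_collapsed_fasta(p("collapsed.fa"))
  stopifnot(identical(rb$seq, run$collapsed$seq),
            identical(rb$count, run$collapsed$count))
  gff <- readLines(p("bona_fide.gff3"))
  body <- gff[!startsWith(gff, "#")]
  stopifnot(all(lengths(strsplit(body, "\t", fixed = TRUE)) == 9L))
  invisible(outdir)
}

#' @export
print.spongemir_run <- function(x, ...) {
  cat("<spongemir_run>\n")
  print(glance(x))
  invisible(x)
}

#' Tidy a pipeline run
#'
#' @param x A `spongemir_run`.
#' @param ... Unused.
#' @return The bona fide miRNA tibble.
#' @export
tidy.spongemir_run <- function(x, ...) x$bona_fide

#' One-row summary of a pipeline run
#'
#' @param x A `spongemir_run`.
#' @param ... Unused.
#' @return One-row tibble with library, mapping and discovery summary counts.
#' @export
glance.spongemir_run <- function(x, ...) {
  mapped <- sum(x$audit$map$n_reads[x$audit$map$category == "mapped"])
  total_mappable <- sum(x$audit$map$n_reads)
  tibble(
    n_raw_reads = x$manifest$reads_in[1],
    n_collapsed_sequences = nrow(x$collapsed),
    surviving_reads = sum(x$collapsed$count),
    mapped_fraction = if (total_mappable > 0) mapped / total_mappable else NA_real_,
    n_stacks = nrow(x$stacks),
    n_candidates = sum(x$candidates$accepted, na.rm = TRUE),
    n_bona_fide = nrow(x$bona_fide),
    n_gap_loci = nrow(x$gap_report)
  )
}

#' Plot candidate signatures of a run
#'
#' Score against 5'-end consistency for every evaluated candidate window,
#' marking the bona fide selections.
#'
#' @param object A `spongemir_run`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spongemir_run <- function(object, ...) {
  cand <- filter(object$candidates, .data$accepted)
  sel <- tibble(mature_start = object$bona_fide$mature_start,
                scaffold = object$bona_fide$scaffold)
  cand <- mutate(cand, selected = paste(.data$scaffold, .data$mature_start) %in%
                   paste(sel$scaffold, sel$mature_start))
  ggplot2::ggplot(cand, ggplot2::aes(x = .data$five_prime_consistency,
                                     y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$selected,
                                     size = log10(.data$mature_count + 1)),
                        alpha = 0.7) +
    ggplot2::geom_hline(yintercept = object$config$discovery$score_threshold,
                        linetype = "dashed") +
    ggplot2::geom_vline(
      xintercept = object$config$discovery$min_five_prime_consistency,
      linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#b2182b",
                                            `FALSE` = "grey50"),
                                 name = "bona fide") +
    ggplot2::labs(x = "5'-end consistency", y = "signature score") +
    ggplot2::theme_minimal()
}

#' Render publication-style report tables
#'
#' Writes a mature-miRNA table (name, mature 5'->3', known match), an
#' exact-match tally table (zero rendered as `-`) and per-family
#' conservation profiles, all as deterministic TSV.
#'
#' @param bona_fide Tibble with `name`, `mature_seq` and optionally
#'   `known_match`.
#' @param tally Tibble from [tally_exact_matches()]; required for the tally
#'   report.
#' @param clusters Tibble from [cluster_cross_species()]; required for the
#'   conservation report.
#' @param outdir Output directory.
#' @return Invisible character vector of files written.
#' @export
render_reports <- function(bona_fide, tally = NULL, clusters = NULL,
                           outdir = ".") {
  if (is.null(bona_fide)) {
    abort("report error: missing artifact from stage 'discover'",
          class = "spongemir_report_error")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  t2 <- tibble(
    name = bona_fide$name,
    mature_5p_to_3p = dna_to_rna(bona_fide$mature_seq),
    known_match = if ("known_match" %in% names(bona_fide)) {
      ifelse(is.na(bona_fide$known_match), "", bona_fide$known_match)
    } else ""
  )
  f <- file.path(outdir, "mature_mirnas.tsv")
  readr::write_tsv(t2, f); files <- c(files, f)
  if (!is.null(tally)) {
    t3 <- tibble(name = tally$name,
                 reads = ifelse(tally$reads == 0, "-",
                                format(tally$reads, big.mark = ",", trim = TRUE)))
    f <- file.path(outdir, "exact_match_tally.tsv")
    readr::write_tsv(t3, f); files <- c(files, f)
  }
  if (!is.null(clusters)) {
    prof <- clusters |>
      filter(.data$n_members >= 2) |>
      purrr::pmap_dfr(function(cluster, family, members, ...) {
        pr <- conservation_profile(members$mature_seq)
        mutate(as_tibble(pr), cluster = cluster,
               family = family %||% NA_character_)
      })
    f <- file.path(outdir, "conservation_profiles.tsv")
    readr::write_tsv(prof, f); files <- c(files, f)
  }
  invisible(files)
}
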