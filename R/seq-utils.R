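# Low-level sequence helpers shared across modules. Sequences are plain
# character vectors of DNA (T, never U) except where a function says RNA.

#' Reverse-complement DNA sequences
#'
#' Vectorised reverse complement over the DNA alphabet `{A,C,G,T,N}`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGTN", "TTAA"))
revcomp <- function(x) {
  stringi_rev <- function(s) {
    vapply(s, function(z) intToUtf8(rev(utf8ToInt(z))), character(1), USE.NAMES = FALSE)
  }
  stringi_rev(chartr("ACGTacgtn", "TGCAtgcaN", x))
}

#' Convert between DNA and RNA alphabets
#'
#' `dna_to_rna()` lower-cases and swaps T for U (the convention used for
#' printed mature miRNA sequences); `rna_to_dna()` is its inverse,
#' upper-casing and swapping U for T.
#'
#' @param x Character vector of sequences.
#' @return Character vector.
#' @export
dna_to_rna <- function(x) chartr("t", "u", tolower(x))

#' @rdname dna_to_rna
#' @export
rna_to_dna <- function(x) chartr("U", "T", toupper(x))

#' Hamming distance between two equal-length sequences
#'
#' @param a,b Single sequences of equal length.
#' @return Integer count of mismatching positions.
#' @export
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort("hamming() requires equal-length sequences", class = "spongemir_input_error")
  }
  sum(charToRaw(toupper(a)) != charToRaw(toupper(b)))
}

# mismatches between x and same-length window of subject starting at `start`
# (1-based); vectorised over start
.count_mismatches <- function(x, subject_raw, starts) {
  xr <- charToRaw(x)
  L <- length(xr)
  vapply(starts, function(s) sum(subject_raw[s:(s + L - 1L)] != xr), integer(1))
}

# random DNA of given lengths with a target GC fraction
.random_dna <- function(lengths, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(lengths, function(L) {
    paste(sample(names(p), L, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# stable short id for a sequence
.seq_id <- function(x) {
  vapply(x, function(s) substr(rlang::hash(s), 1L, 12L), character(1), USE.NAMES = FALSE)
}

#' Read and write FASTA files
#'
#' Thin tidy wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()]. A genome (or any sequence set) is
#' represented throughout the package as a tibble with columns `name` and
#' `seq`.
#'
#' @param path File path.
#' @param x Tibble with columns `name`, `seq`.
#' @return `read_fasta()` returns a tibble with columns `name`, `seq`;
#'   `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  tibble(name = sub("\\s.*$", "", names(ss)),
         seq = unname(as.character(ss)))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(setNames(x$seq, x$name))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Read and write FASTQ files (Sanger Phred+33)
#'
#' Reads are represented as a tibble with columns `id`, `seq`, `qual`
#' (quality as the raw Phred+33 string).
#'
#' @param path File path.
#' @param x Tibble with columns `id`, `seq`, `qual`.
#' @return `read_fastq()` returns a tibble `id`, `seq`, `qual`;
#'   `write_fastq()` returns `path` invisibly.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0) {
    return(tibble(id = character(), seq = character(), qual = character()))
  }
  qs <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble(
    id = sub("\\s.*$", "", names(qs)),
    seq = unname(as.character(qs)),
    qual = unname(as.character(Biostrings::quality(qs)))
  )
}

#' @rdname read_fastq
#' @export
write_fastq <- function(x, path) {
  lines <- character(4L * nrow(x))
  if (nrow(x) > 0) {
    lines[seq(1, length(lines), 4)] <- paste0("@", x$id)
    lines[seq(2, length(lines), 4)] <- x$seq
    lines[seq(3, length(lines), 4)] <- "+"
    lines[seq(4, length(lines), 4)] <- x$qual
  }
  writeLines(lines, path)
  invisible(path)
}

# Phred+33 conversions
.phred_to_int <- function(q) lapply(q, function(s) utf8ToInt(s) - 33L)
.int_to_phred <- function(v) intToUtf8(pmin(pmax(v, 0L), 41L) + 33L)
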