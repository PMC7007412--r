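#' Nucleotide sequence record
#'
#' A minimal carrier for a named DNA sequence. Bases are restricted to
#' `A`, `C`, `G`, `T`, `N`.
#'
#' @param id Character label.
#' @param bases Character scalar of bases.
#' @return An object of class `nuc_sequence` with fields `id` and `bases`.
#' @examples
#' nuc_sequence("locus", "ACGTACGT")
#' @export
nuc_sequence <- function(id, bases) {
  stopifnot(is.character(id), length(id) == 1L,
            is.character(bases), length(bases) == 1L)
  bases <- toupper(bases)
  if (nchar(bases) == 0L) stop("sequence '", id, "' is empty")
  if (grepl("[^ACGTN]", bases)) {
    stop("sequence '", id, "' contains characters outside {A,C,G,T,N}")
  }
  structure(list(id = id, bases = bases), class = "nuc_sequence")
}

#' @export
print.nuc_sequence <- function(x, ...) {
  cat(sprintf("<nuc_sequence> %s (%d bp)\n", x$id, seq_len_bp(x)))
  invisible(x)
}

#' Sequence length in base pairs
#' @param x A `nuc_sequence` or character scalar.
#' @return Integer length.
#' @export
seq_len_bp <- function(x) nchar(seq_chr(x))

# accept either nuc_sequence or bare string
seq_chr <- function(x) {
  if (inherits(x, "nuc_sequence")) x$bases
  else if (is.character(x) && length(x) == 1L) toupper(x)
  else stop("expected a nuc_sequence or a single character string")
}

#' Reverse complement
#' @param x Character vector of DNA strings (or a `nuc_sequence`).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (inherits(x, "nuc_sequence")) x <- x$bases
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Random DNA string
#'
#' Uniform i.i.d. bases; used by the synthetic-data generator. Uses the
#' current RNG state (seed management is the caller's job).
#'
#' @param n Length in bp.
#' @return Character scalar.
#' @export
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# all k-mers of one string, vectorized
kmers_of <- function(x, k) {
  x <- seq_chr(x)
  L <- nchar(x)
  if (L < k) return(character(0))
  substring(x, 1:(L - k + 1L), k:L)
}

# canonical form: lexicographic min of k-mer and its reverse complement
canonical_kmers <- function(x, k) {
  km <- kmers_of(x, k)
  if (length(km) == 0L) return(km)
  rc <- revcomp(km)
  ifelse(km <= rc, km, rc)
}

#' Read a FASTA file as a list of `nuc_sequence` objects
#' @param path FASTA file path.
#' @return Named list of `nuc_sequence`.
#' @export
read_fasta_seqs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- lapply(seq_along(ss), function(i) {
    nuc_sequence(names(ss)[i], as.character(ss[[i]]))
  })
  names(out) <- names(ss)
  out
}

#' Write sequences to FASTA (60-column wrap)
#' @param seqs A `nuc_sequence`, a list of them, or a named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta_seqs <- function(seqs, path) {
  if (inherits(seqs, "nuc_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) {
    ss <- Biostrings::DNAStringSet(seqs)
  } else {
    ss <- Biostrings::DNAStringSet(vapply(seqs, seq_chr, character(1)))
    names(ss) <- vapply(seqs, function(s) s$id, character(1))
  }
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read FASTQ into a read tibble
#'
#' @param path FASTQ path (phred+33).
#' @param platform `"short"` or `"long"`, recorded per read.
#' @return Tibble with columns `read_id`, `bases`, `qualities`, `mate`,
#'   `platform`. Mate is parsed from `/1`/`/2` suffixes when present.
#' @export
read_fastq_reads <- function(path, platform = c("short", "long")) {
  platform <- match.arg(platform)
  # Biostrings warns that FASTQ metadata columns are dropped; the tibble
  # carries everything this package uses
  ss <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  ids <- names(ss)
  mate <- ifelse(grepl("/1$", ids), 1L, ifelse(grepl("/2$", ids), 2L, NA_integer_))
  tibble::tibble(
    read_id = sub("/[12]$", "", unname(ids)),
    bases = unname(as.character(ss)),
    qualities = unname(as.character(Biostrings::quality(ss))),
    mate = mate,
    platform = platform
  )
}

#' Write a read tibble to FASTQ
#' @param reads Tibble with `read_id`, `bases` and optional `qualities`, `mate`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fastq_reads <- function(reads, path) {
  stopifnot(all(c("read_id", "bases") %in% names(reads)))
  ids <- reads$read_id
  if ("mate" %in% names(reads)) {
    ids <- ifelse(is.na(reads$mate), ids, paste0(ids, "/", reads$mate))
  }
  qual <- if ("qualities" %in% names(reads) && !all(is.na(reads$qualities))) {
    reads$qualities
  } else {
    vapply(nchar(reads$bases), function(n) strrep("I", n), character(1))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads$bases, "\n+\n", qual), con)
  invisible(path)
}
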