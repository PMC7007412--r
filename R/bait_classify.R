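# k-mer baiting and junction classification of reads around the insertion.
#
# Reads sharing at least k (default 25) consecutive bases with the insertion
# sequence are selected, then classified against the unedited reference
# locus and the amended reference (reference carrying the insertion) into
# the three expected alignment classes:
#   A  clean full-length match to the reference (internal repeat or its 5'
#      junction),
#   B  full-length match with a single deletion at the repeat 3' end
#      matching a derived junction signature,
#   C  read spans a novel junction, resolvable only as a split alignment on
#      the reference but matching the amended reference cleanly.
# Anything else is UNEXPLAINED and reported with its alignments.

#' Build a canonical k-mer bait index
#'
#' @param baits A `nuc_sequence`, string, or list of them.
#' @param k k-mer size (default 25, the minimum shared stretch used for
#'   selection).
#' @return Object of class `bait_index` with the canonical k-mer set and a
#'   precompiled dictionary for fast counting.
#' @export
build_bait_index <- function(baits, k = 25L) {
  if (inherits(baits, "nuc_sequence") || is.character(baits)) baits <- list(baits)
  km <- character(0)
  for (b in baits) {
    s <- seq_chr(b)
    if (nchar(s) < k) {
      id <- if (inherits(b, "nuc_sequence")) b$id else s
      stop("bait '", id, "' is shorter than k = ", k)
    }
    km <- c(km, canonical_kmers(s, k))
  }
  km <- unique(km)
  # match either strand of a read: dictionary holds both orientations
  pats <- unique(c(km, revcomp(km)))
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(pats))
  structure(list(k = as.integer(k), kmers = km, pdict = pd),
            class = "bait_index")
}

#' @export
print.bait_index <- function(x, ...) {
  cat(sprintf("<bait_index> k=%d, %d canonical k-mers\n", x$k, length(x$kmers)))
  invisible(x)
}

#' Count bait k-mer hits per read
#'
#' @param reads Tibble with a `bases` column, or a character vector.
#' @param index A [build_bait_index()] result.
#' @return Integer vector of per-read hit counts (k-mer occurrences shared
#'   with the bait, either strand).
#' @export
count_bait_hits <- function(reads, index) {
  bases <- if (is.data.frame(reads)) reads$bases else reads
  if (length(bases) == 0L) return(integer(0))
  ss <- Biostrings::DNAStringSet(bases)
  as.integer(Biostrings::vcountPDict(index$pdict, ss, collapse = 2))
}

#' Select reads sharing k-mers with the bait
#'
#' A read is selected iff at least `min_hits` of its k-mers occur in the
#' bait index (canonical, so orientation-independent). Selection is
#' order-independent and deterministic.
#'
#' @param reads Read tibble (columns `read_id`, `bases`, ...).
#' @param index A [build_bait_index()] result.
#' @param min_hits Minimum k-mer hits (default 1).
#' @return The selected rows of `reads`, with a `bait_hits` column appended.
#' @export
bait_reads <- function(reads, index, min_hits = 1L) {
  hits <- count_bait_hits(reads, index)
  out <- reads
  out$bait_hits <- hits
  out[hits >= min_hits, , drop = FALSE]
}

#' Classify baited reads against reference and amended reference
#'
#' @param reads Read tibble (`read_id`, `bases`).
#' @param ref_locus Unedited reference locus sequence.
#' @param amended_locus Amended reference (the allele sequence).
#' @param signatures Junction signatures from
#'   [derive_junction_signatures()] for this locus pair.
#' @param scoring Alignment scoring.
#' @param tol_mm Mismatch fraction tolerated in a "clean" alignment
#'   (default 0.05; sequencing errors, not structure).
#' @param min_clip Clip length that triggers the supplementary-alignment
#'   search (default 20).
#' @param sig_slack Tolerated difference (bp) between an observed deletion
#'   and a signature deletion length (default 2).
#' @param junctions Optional integer vector of novel-junction positions in
#'   amended-locus coordinates used for the class-C span check; defaults to
#'   the signatures' junction positions (override when the amended locus
#'   carries more junctions than the signature set describes, e.g. the
#'   plasmid-integrated allele).
#' @return Tibble: `read_id`, `class` (one of `CLASS_A_INTERNAL_OR_5P_PERFECT`,
#'   `CLASS_B_3P_WITH_DELETION`, `CLASS_C_SPLIT_RESOLVED_ON_AMENDED`,
#'   `UNEXPLAINED`), `orientation`, `target`, `t_start`, `cigar`, `score`.
#' @export
classify_reads <- function(reads, ref_locus, amended_locus, signatures,
                           scoring = align_scoring(), tol_mm = 0.05,
                           min_clip = 20L, sig_slack = 2L, junctions = NULL) {
  ref <- seq_chr(ref_locus)
  amd <- seq_chr(amended_locus)
  del_sigs <- signatures[signatures$target == "reference" &
                           signatures$variant_op == "del", , drop = FALSE]
  if (is.null(junctions)) junctions <- unique(signatures$junction_pos)
  rows <- lapply(seq_len(nrow(reads)), function(i) {
    .classify_one(reads$read_id[i], reads$bases[i], ref, amd, del_sigs,
                  junctions, scoring, tol_mm, min_clip, sig_slack)
  })
  dplyr::bind_rows(rows)
}

.classify_one <- function(read_id, bases, ref, amd, del_sigs, junctions,
                          scoring, tol_mm, min_clip, sig_slack) {
  if (nchar(bases) == 0L) stop("empty read: ", read_id)
  # orientation by best score on the amended locus (which contains the read
  # origin for every expected read)
  fwd <- align_read(bases, amd, type = "global-local", scoring = scoring)
  rc <- revcomp(bases)
  rev <- align_read(rc, amd, type = "global-local", scoring = scoring)
  if (rev$score > fwd$score) {
    oriented <- rc; am_aln <- rev; orientation <- "-"
  } else {
    oriented <- bases; am_aln <- fwd; orientation <- "+"
  }
  L <- nchar(oriented)
  ref_aln <- align_read(oriented, ref, type = "global-local", scoring = scoring)

  row <- function(class, target, aln) {
    tibble::tibble(read_id = read_id, class = class,
                   orientation = orientation, target = target,
                   t_start = aln$t_start, cigar = aln$cigar,
                   score = aln$score)
  }

  if (.is_clean(ref_aln, L, tol_clip = 0L, tol_mm = tol_mm)) {
    return(row("CLASS_A_INTERNAL_OR_5P_PERFECT", "reference", ref_aln))
  }
  co <- .collapse_ops(ref_aln$ops)
  if (.single_indel_pattern(co, ref_aln) && co$op[2] == "del" &&
      .mismatch_frac(ref_aln$ops) <= tol_mm && nrow(del_sigs) > 0L &&
      any(abs(co$len[2] - del_sigs$variant_len) <= sig_slack)) {
    return(row("CLASS_B_3P_WITH_DELETION", "reference", ref_aln))
  }
  # a read that matches the amended locus cleanly but not the reference
  # necessarily spans a novel junction: its context is not reference
  # content. The junction list is used for reporting, not gating.
  if (.is_clean(am_aln, L, tol_clip = 0L, tol_mm = tol_mm)) {
    return(row("CLASS_C_SPLIT_RESOLVED_ON_AMENDED", "amended_reference",
               am_aln))
  }
  row("UNEXPLAINED", "reference", ref_aln)
}

#' Detect ectopic insertion sites from baited reads
#'
#' Places each baited read in the genome by exact-seed anchoring (k-mer
#' seeds at the read ends and middle, both strands) followed by local
#' alignment verification, then clusters best placements falling outside
#' the expected window. An empty result means the insertion sequence is
#' present only at the expected position.
#'
#' @param baited Read tibble from [bait_reads()].
#' @param genome Named character vector of contig sequences.
#' @param expected_window List `(contig, start, end)`, 0-based half-open.
#' @param min_support Minimum reads per cluster (default 3).
#' @param k Seed length (default 25).
#' @param scoring Alignment scoring.
#' @param margin Extra bases around the expected window treated as expected
#'   (default one read length).
#' @return Tibble: `contig`, `window_start`, `window_end`, `n_support`,
#'   `mean_score`, `read_ids` (list column). Zero rows = expected position
#'   only.
#' @export
detect_ectopic_insertions <- function(baited, genome, expected_window,
                                      min_support = 3L, k = 25L,
                                      scoring = align_scoring(),
                                      margin = NULL) {
  if (missing(expected_window) || is.null(expected_window)) {
    stop("expected_window (contig, start, end) is required")
  }
  if (nrow(baited) == 0L) {
    return(.empty_ectopic())
  }
  read_len <- max(nchar(baited$bases))
  if (is.null(margin)) margin <- read_len

  # seed table: (read index, offset in oriented read, seed, strand)
  seeds <- .read_seeds(baited$bases, k)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds$seed))
  placements <- list()
  for (ctg in names(genome)) {
    m <- Biostrings::matchPDict(pd, Biostrings::DNAString(genome[[ctg]]))
    starts <- Biostrings::startIndex(m)
    hit_idx <- which(lengths(starts) > 0L)
    for (si in hit_idx) {
      for (pos in starts[[si]]) {
        rd <- seeds$read[si]
        rl <- nchar(baited$bases[rd])
        place <- if (seeds$strand[si] == "+") (pos - 1L) - seeds$offset[si]
                 else (pos - 1L) - (rl - seeds$offset[si] - k)
        placements[[length(placements) + 1L]] <-
          c(read = rd, contig = ctg, place = place, strand = seeds$strand[si])
      }
    }
  }
  if (length(placements) == 0L) return(.empty_ectopic())
  pl <- as.data.frame(do.call(rbind, placements), stringsAsFactors = FALSE)
  pl$read <- as.integer(pl$read); pl$place <- as.integer(pl$place)

  # collapse seed hits to candidate placements per read, verify by local
  # alignment, keep the best placement per read
  pl$key <- paste(pl$read, pl$contig, pl$strand, round(pl$place / 50))
  pl <- pl[!duplicated(pl$key), , drop = FALSE]
  best <- vector("list", nrow(baited))
  for (i in seq_len(nrow(pl))) {
    rd <- pl$read[i]
    q <- baited$bases[rd]
    if (pl$strand[i] == "-") q <- revcomp(q)
    ctg_seq <- genome[[pl$contig[i]]]
    ws <- max(0L, pl$place[i] - read_len)
    we <- min(nchar(ctg_seq), pl$place[i] + 2L * read_len)
    aln <- align_read(q, substr(ctg_seq, ws + 1L, we), type = "local",
                      scoring = scoring)
    cand <- list(contig = pl$contig[i], start = ws + aln$t_start,
                 score = aln$score)
    if (is.null(best[[rd]]) || cand$score > best[[rd]]$score) best[[rd]] <- cand
  }
  keep <- !vapply(best, is.null, logical(1))
  placed <- tibble::tibble(
    read_id = baited$read_id[which(keep)],
    contig = vapply(best[keep], `[[`, character(1), "contig"),
    start = vapply(best[keep], function(b) as.numeric(b$start), numeric(1)),
    score = vapply(best[keep], `[[`, numeric(1), "score"))

  outside <- placed$contig != expected_window$contig |
    placed$start + read_len <= expected_window$start - margin |
    placed$start >= expected_window$end + margin
  placed <- placed[outside, , drop = FALSE]
  if (nrow(placed) == 0L) return(.empty_ectopic())

  # single-linkage clustering within 2*read_len windows per contig
  placed <- dplyr::arrange(placed, .data$contig, .data$start)
  cl <- integer(nrow(placed)); cur <- 0L
  for (i in seq_len(nrow(placed))) {
    if (i == 1L || placed$contig[i] != placed$contig[i - 1L] ||
        placed$start[i] - placed$start[i - 1L] > 2L * read_len) cur <- cur + 1L
    cl[i] <- cur
  }
  placed$cluster <- cl
  out <- placed |>
    dplyr::group_by(.data$contig, .data$cluster) |>
    dplyr::summarise(window_start = min(.data$start),
                     window_end = max(.data$start) + read_len,
                     n_support = dplyr::n(),
                     mean_score = mean(.data$score),
                     read_ids = list(.data$read_id), .groups = "drop") |>
    dplyr::filter(.data$n_support >= min_support) |>
    dplyr::select(-"cluster")
  out
}

.empty_ectopic <- function() {
  tibble::tibble(contig = character(0), window_start = numeric(0),
                 window_end = numeric(0), n_support = integer(0),
                 mean_score = numeric(0), read_ids = list())
}

# seed k-mers at read start, middle and end, both strands
.read_seeds <- function(bases, k) {
  out <- list()
  for (rd in seq_along(bases)) {
    s <- bases[rd]
    L <- nchar(s)
    if (L < k) next
    offs <- unique(c(0L, (L - k) %/% 2L, L - k))
    for (o in offs) {
      seed <- substr(s, o + 1L, o + k)
      out[[length(out) + 1L]] <- list(read = rd, offset = o,
                                      seed = seed, strand = "+")
      out[[length(out) + 1L]] <- list(read = rd, offset = o,
                                      seed = revcomp(seed), strand = "-")
    }
  }
  tibble::tibble(read = vapply(out, `[[`, integer(1), "read"),
                 offset = vapply(out, `[[`, integer(1), "offset"),
                 seed = vapply(out, `[[`, character(1), "seed"),
                 strand = vapply(out, `[[`, character(1), "strand"))
}

#' Write a classification table as TSV
#' @param classes Tibble from [classify_reads()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_classification_tsv <- function(classes, path) {
  write.table(classes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
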