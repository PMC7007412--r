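# Allele models of the edited POLLED locus.
#
# Three alleles are modelled: the wild-type horned allele p, the Celtic
# POLLED allele Pc (a 212-bp repeat duplicated in place of a 10-bp segment,
# CTGGTATTCT), and Pc* (the Celtic edit plus an adjacent integration of the
# donor-plasmid backbone and a second copy of the HDR template).
# All coordinates are 0-based half-open.

#' Celtic edit specification
#'
#' Describes where the duplicated repeat and the replaced segment sit within
#' a wild-type locus. The replaced segment must be immediately 3' of the
#' repeat (set `require_adjacent = FALSE` to relax).
#'
#' @param repeat_start,repeat_end 0-based half-open offsets of the repeat
#'   (default length 212 bp).
#' @param replaced_start,replaced_end Offsets of the replaced segment
#'   (default length 10 bp).
#' @param replaced_seq Expected bases of the replaced segment
#'   (default `"CTGGTATTCT"`); set `NULL` to skip the base check.
#' @param require_adjacent Enforce `repeat_end == replaced_start`.
#' @return Object of class `celtic_edit_spec`.
#' @export
celtic_edit_spec <- function(repeat_start, repeat_end,
                             replaced_start = repeat_end,
                             replaced_end = replaced_start + 10L,
                             replaced_seq = "CTGGTATTCT",
                             require_adjacent = TRUE) {
  stopifnot(repeat_start >= 0, repeat_end > repeat_start,
            replaced_end > replaced_start)
  if (require_adjacent && repeat_end != replaced_start) {
    stop("replaced segment must be immediately 3' of the repeat ",
         "(repeat_end ", repeat_end, " != replaced_start ", replaced_start, ")")
  }
  if (!is.null(replaced_seq) &&
      nchar(replaced_seq) != replaced_end - replaced_start) {
    stop("replaced_seq length does not match [replaced_start, replaced_end)")
  }
  structure(list(repeat_start = as.integer(repeat_start),
                 repeat_end = as.integer(repeat_end),
                 replaced_start = as.integer(replaced_start),
                 replaced_end = as.integer(replaced_end),
                 replaced_seq = replaced_seq),
            class = "celtic_edit_spec")
}

# internal allele constructor
.allele_model <- function(name, sequence, features) {
  stopifnot(name %in% c("p", "Pc", "Pc_star"))
  stopifnot(all(features$start >= 0), all(features$end <= seq_len_bp(sequence)),
            !anyDuplicated(features$label))
  structure(list(name = name, sequence = sequence, features = features),
            class = "allele_model")
}

#' @export
print.allele_model <- function(x, ...) {
  cat(sprintf("<allele_model> %s: %d bp, %d features\n",
              x$name, seq_len_bp(x$sequence), nrow(x$features)))
  print(x$features)
  invisible(x)
}

#' Wild-type allele model
#' @param wild_locus A `nuc_sequence` (or string) of the unedited locus.
#' @param spec A [celtic_edit_spec()] used to annotate the repeat and the
#'   replaced segment.
#' @return An `allele_model` named `"p"`.
#' @export
wildtype_allele <- function(wild_locus, spec) {
  s <- seq_chr(wild_locus)
  feats <- tibble::tibble(
    label = c("repeat", "replaced_segment"),
    start = c(spec$repeat_start, spec$replaced_start),
    end = c(spec$repeat_end, spec$replaced_end))
  .allele_model("p", nuc_sequence("p", s), feats)
}

#' Apply the Celtic POLLED edit to a wild-type locus
#'
#' Duplicates the repeat in place of the replaced segment:
#' wild = prefix + R + replaced + suffix becomes prefix + R + R + suffix.
#' The length change is `len(R) - len(replaced)` (202 bp with the defaults).
#'
#' @param wild_locus `nuc_sequence` or string.
#' @param spec [celtic_edit_spec()].
#' @return An `allele_model` named `"Pc"` with both repeat copies annotated.
#' @export
apply_celtic_edit <- function(wild_locus, spec) {
  s <- seq_chr(wild_locus)
  L <- nchar(s)
  if (spec$replaced_end > L) stop("edit spec exceeds locus length ", L)
  seg <- substr(s, spec$replaced_start + 1L, spec$replaced_end)
  if (!is.null(spec$replaced_seq) && seg != spec$replaced_seq) {
    stop("wild-type bases at [", spec$replaced_start, ",", spec$replaced_end,
         ") are '", seg, "', expected '", spec$replaced_seq, "'")
  }
  R <- substr(s, spec$repeat_start + 1L, spec$repeat_end)
  prefix <- substr(s, 1L, spec$replaced_start)   # includes R when adjacent
  suffix <- substr(s, spec$replaced_end + 1L, L)
  edited <- paste0(prefix, R, suffix)
  rl <- nchar(R)
  feats <- tibble::tibble(
    label = c("repeat_copy1", "repeat_copy2"),
    start = c(spec$repeat_start, spec$replaced_start),
    end = c(spec$repeat_end, spec$replaced_start + rl))
  .allele_model("Pc", nuc_sequence("Pc", edited), feats)
}

#' Plasmid integration specification for the Pc* allele
#'
#' The order and orientation of the integrated blocks are not observable from
#' the screen itself, so the arrangement is a parameter; the default places
#' the backbone (forward) then a second HDR-template copy immediately 3' of
#' the second repeat copy.
#'
#' @param backbone `nuc_sequence` of the vector backbone (~3.9 kb).
#' @param hdr_template `nuc_sequence` of the HDR template (~1.6 kb).
#' @param insertion_offset Position within the Pc allele where the extra
#'   material is inserted; `NULL` places it at the end of `repeat_copy2`.
#' @param orientation `"forward"` or `"reverse"` for the backbone block.
#' @param arrangement Character vector ordering the blocks; must contain
#'   exactly one `"backbone"` and one `"hdr_copy"`.
#' @return Object of class `plasmid_integration_spec`.
#' @export
plasmid_integration_spec <- function(backbone, hdr_template,
                                     insertion_offset = NULL,
                                     orientation = c("forward", "reverse"),
                                     arrangement = c("backbone", "hdr_copy")) {
  orientation <- match.arg(orientation)
  if (sum(arrangement == "backbone") != 1L ||
      sum(arrangement == "hdr_copy") != 1L) {
    stop("arrangement must contain exactly one 'backbone' and one 'hdr_copy'")
  }
  structure(list(backbone = backbone, hdr_template = hdr_template,
                 insertion_offset = insertion_offset,
                 orientation = orientation, arrangement = arrangement),
            class = "plasmid_integration_spec")
}

#' Build the plasmid-integrated Pc* allele
#'
#' Inserts the full plasmid backbone (in the specified orientation) and a
#' second HDR-template copy into a Pc allele at `insertion_offset`.
#'
#' @param pc An `allele_model` named `"Pc"`.
#' @param integ A [plasmid_integration_spec()].
#' @return An `allele_model` named `"Pc_star"`; its length equals
#'   `len(Pc) + len(backbone) + len(hdr_template)`.
#' @export
build_plasmid_allele <- function(pc, integ) {
  stopifnot(inherits(pc, "allele_model"), pc$name == "Pc")
  s <- seq_chr(pc$sequence)
  off <- integ$insertion_offset
  if (is.null(off)) {
    off <- pc$features$end[pc$features$label == "repeat_copy2"]
  }
  if (off < 0 || off > nchar(s)) stop("insertion_offset out of Pc bounds")
  bb <- seq_chr(integ$backbone)
  if (integ$orientation == "reverse") bb <- revcomp(bb)
  tpl <- seq_chr(integ$hdr_template)
  blocks <- lapply(integ$arrangement, function(b) {
    if (b == "backbone") list(label = "plasmid_backbone", seq = bb)
    else list(label = "hdr_copy", seq = tpl)
  })
  ins <- paste(vapply(blocks, `[[`, character(1), "seq"), collapse = "")
  edited <- paste0(substr(s, 1L, off), ins, substr(s, off + 1L, nchar(s)))
  starts <- off + cumsum(c(0L, head(vapply(blocks, function(b) nchar(b$seq),
                                           integer(1)), -1)))
  feats <- dplyr::bind_rows(
    dplyr::mutate(pc$features,
                  start = ifelse(.data$start >= off, .data$start + nchar(ins),
                                 .data$start),
                  end = ifelse(.data$end > off, .data$end + nchar(ins),
                               .data$end)),
    tibble::tibble(label = vapply(blocks, `[[`, character(1), "label"),
                   start = starts,
                   end = starts + vapply(blocks, function(b) nchar(b$seq),
                                         integer(1))))
  .allele_model("Pc_star", nuc_sequence("Pc_star", edited), feats)
}

#' Diff an edited allele against its source locus
#'
#' Recovers the single replacement event between two sequences via longest
#' common prefix/suffix. Used to locate novel junctions and for round-trip
#' checks of the edit constructors.
#'
#' @param original,edited Sequences.
#' @return Tibble with one row: `pos` (0-based event start), `del_len`
#'   (bases removed from original), `ins_len` (bases added); zero-row tibble
#'   when the sequences are identical.
#' @export
diff_replacement <- function(original, edited) {
  a <- seq_chr(original); b <- seq_chr(edited)
  if (a == b) {
    return(tibble::tibble(pos = integer(0), del_len = integer(0),
                          ins_len = integer(0)))
  }
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  nmin <- min(length(av), length(bv))
  pre <- 0L
  while (pre < nmin && av[pre + 1L] == bv[pre + 1L]) pre <- pre + 1L
  suf <- 0L
  while (suf < nmin - pre &&
         av[length(av) - suf] == bv[length(bv) - suf]) suf <- suf + 1L
  tibble::tibble(pos = pre,
                 del_len = length(av) - pre - suf,
                 ins_len = length(bv) - pre - suf)
}

#' Derive junction alignment signatures for an edited allele
#'
#' For every novel junction the edit creates, determines the minimal-cost
#' alignment pattern that an error-free read of `read_len` spanning the
#' junction exhibits against (i) the unedited reference locus and (ii) the
#' amended reference (the allele sequence itself). Deletion-type signatures
#' drive class-B read calls; junctions that can only be resolved by a split
#' alignment on the reference drive class C.
#'
#' @param ref_locus Unedited locus sequence.
#' @param allele An `allele_model` built from `ref_locus`.
#' @param read_len Read length the signatures are derived for.
#' @param scoring Alignment scoring, see [align_scoring()].
#' @return Tibble with columns `junction_label`, `junction_pos` (0-based,
#'   allele coordinates), `target`, `pattern` (CIGAR-like), `variant_op`
#'   (`"del"`, `"ins"`, `"split"` or `"none"`), `variant_len`. Zero rows when
#'   the allele equals the reference.
#' @export
derive_junction_signatures <- function(ref_locus, allele, read_len = 150L,
                                       scoring = align_scoring()) {
  ref <- seq_chr(ref_locus)
  alt <- seq_chr(allele$sequence)
  ev <- diff_replacement(ref, alt)
  if (nrow(ev) == 0L) {
    return(tibble::tibble(junction_label = character(0),
                          junction_pos = integer(0), target = character(0),
                          pattern = character(0), variant_op = character(0),
                          variant_len = integer(0)))
  }
  junctions <- unique(c(ev$pos, ev$pos + ev$ins_len))
  labels <- if (length(junctions) == 2L) c("insert_5p", "insert_3p")
            else "replacement"
  out <- list()
  for (i in seq_along(junctions)) {
    j <- junctions[i]
    half <- read_len %/% 2L
    rs <- max(0L, j - half)
    re <- min(nchar(alt), rs + read_len)
    rs <- max(0L, re - read_len)
    if (re - rs < read_len) {
      warning("read_len ", read_len, " cannot span junction at ", j,
              "; signature omitted")
      next
    }
    probe <- substr(alt, rs + 1L, re)
    # against the unedited reference: split search
    alns <- split_align(probe, ref, scoring = scoring)
    prim <- alns[[1]]
    co <- .collapse_ops(prim$ops)
    if (.is_clean(prim, read_len)) {
      vop <- "none"; vlen <- 0L; pat <- prim$cigar
    } else if (.single_indel_pattern(co, prim)) {
      idx <- which(co$op != "M")
      vop <- co$op[idx]
      vlen <- co$len[idx]
      pat <- prim$cigar
    } else {
      vop <- "split"; vlen <- NA_integer_
      pat <- paste(vapply(alns, `[[`, character(1), "cigar"), collapse = ";")
    }
    out[[length(out) + 1L]] <- tibble::tibble(
      junction_label = labels[i], junction_pos = j, target = "reference",
      pattern = pat, variant_op = vop, variant_len = vlen)
    # against the amended reference: spanning error-free reads match purely
    am <- align_read(probe, alt, type = "local", scoring = scoring)
    out[[length(out) + 1L]] <- tibble::tibble(
      junction_label = labels[i], junction_pos = j,
      target = "amended_reference", pattern = am$cigar,
      variant_op = "none", variant_len = 0L)
  }
  sig <- dplyr::bind_rows(out)
  sig <- sig[sig$variant_op != "none" | sig$target == "amended_reference", ]
  dplyr::distinct(sig)
}

# collapsed ops are M [indel] M with clip-free full-length read
.single_indel_pattern <- function(co, aln) {
  nrow(co) == 3L && co$op[1] == "M" && co$op[3] == "M" &&
    co$op[2] %in% c("ins", "del") &&
    aln$clip_left == 0L && aln$clip_right == 0L
}

#' Export allele features as BED
#'
#' Six-column BED (0-based half-open) of the allele's feature annotations.
#'
#' @param allele An `allele_model`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_features_bed <- function(allele, path) {
  bed <- tibble::tibble(
    chrom = allele$sequence$id,
    chromStart = allele$features$start,
    chromEnd = allele$features$end,
    name = allele$features$label,
    score = 0L, strand = "+")
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
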