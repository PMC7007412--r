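# Donor-plasmid backbone screening from short reads, and assignment of long
# reads to the Pc vs Pc* allele models via diagnostic junction windows.

#' Excise the HDR-insert-homologous region from a plasmid
#'
#' Backbone screening must not count coverage on the template insert, which
#' is homologous to the genome. The insert is located by local alignment of
#' the HDR template to the plasmid and excised; what remains is the
#' backbone-only sequence.
#'
#' @param plasmid Full plasmid sequence.
#' @param hdr_template HDR template sequence.
#' @param scoring Alignment scoring.
#' @return `nuc_sequence` of the backbone with the insert region removed.
#' @export
backbone_without_insert <- function(plasmid, hdr_template,
                                    scoring = align_scoring()) {
  p <- seq_chr(plasmid)
  aln <- align_read(seq_chr(hdr_template), p, type = "local",
                    scoring = scoring)
  if (aln$t_end <= aln$t_start) return(nuc_sequence("backbone_only", p))
  out <- paste0(substr(p, 1L, aln$t_start),
                substr(p, aln$t_end + 1L, nchar(p)))
  nuc_sequence("backbone_only", out)
}

#' Screen reads for plasmid backbone presence
#'
#' Baits reads sharing k-mers with the backbone, aligns them locally, and
#' computes per-base depth. Presence is called from breadth of coverage
#' (fraction of backbone positions with depth >= 1).
#'
#' @param reads Read tibble (`read_id`, `bases`).
#' @param backbone_only Backbone sequence with the HDR-insert region
#'   excised (see [backbone_without_insert()]).
#' @param breadth_threshold Presence threshold on breadth (default 0.25).
#' @param sample_id Label carried into the result.
#' @param k Bait k-mer size (default 25).
#' @param scoring Alignment scoring.
#' @return Tibble with one row: `sample_id`, `n_reads_aligned`, `breadth`,
#'   `mean_depth`, `present`; the per-position depth vector is attached as
#'   attribute `"depth"`.
#' @export
screen_backbone <- function(reads, backbone_only, breadth_threshold = 0.25,
                            sample_id = "sample", k = 25L,
                            scoring = align_scoring()) {
  bb <- seq_chr(backbone_only)
  L <- nchar(bb)
  depth <- integer(L)
  n_aln <- 0L
  if (nrow(reads) == 0L) {
    warning("empty read set; reporting absent backbone")
  } else {
    idx <- build_bait_index(bb, k = k)
    cand <- bait_reads(reads, idx, min_hits = 1L)
    for (i in seq_len(nrow(cand))) {
      q <- cand$bases[i]
      a_f <- align_read(q, bb, type = "local", scoring = scoring)
      a_r <- align_read(revcomp(q), bb, type = "local", scoring = scoring)
      a <- if (a_r$score > a_f$score) a_r else a_f
      if (a$t_end > a$t_start && a$score > 0) {
        depth[(a$t_start + 1L):a$t_end] <- depth[(a$t_start + 1L):a$t_end] + 1L
        n_aln <- n_aln + 1L
      }
    }
  }
  breadth <- mean(depth >= 1L)
  out <- tibble::tibble(sample_id = sample_id, n_reads_aligned = n_aln,
                        breadth = breadth, mean_depth = mean(depth),
                        present = breadth >= breadth_threshold)
  attr(out, "depth") <- depth
  out
}

# locate the diagnostic insertion event between the two allele models:
# pc = prefix + suffix, pcstar = prefix + INS + suffix
.diagnostic_junctions <- function(pc_allele, pcstar_allele) {
  ev <- diff_replacement(pc_allele$sequence, pcstar_allele$sequence)
  if (nrow(ev) == 0L) stop("allele models are identical: no diagnostic junction")
  list(pc_pos = ev$pos,                       # single junction point on Pc
       star_pos = c(ev$pos, ev$pos + ev$ins_len),  # 5' and 3' on Pc*
       ins_len = ev$ins_len)
}

# estimate candidate read->target diagonal offsets via exact k-mer seeds.
# A read spanning a structural difference has two seed diagonals (before
# and after the event), so diagonals are clustered (gap > 800 bp) and each
# cluster's median is returned as a separate anchoring hypothesis.
.anchor_offsets <- function(read, target, k = 15L, stride = 100L) {
  L <- nchar(read)
  if (L < k) return(numeric(0))
  offs <- seq(0L, L - k, by = stride)
  seeds <- substr(rep(read, length(offs)), offs + 1L, offs + k)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  m <- Biostrings::matchPDict(pd, Biostrings::DNAString(target))
  st <- Biostrings::startIndex(m)
  diags <- numeric(0)
  for (i in seq_along(st)) {
    if (length(st[[i]]) > 0L) diags <- c(diags, (st[[i]] - 1L) - offs[i])
  }
  if (length(diags) < 2L) return(numeric(0))
  diags <- sort(diags)
  cl <- cumsum(c(1, diff(diags) > 800))
  meds <- vapply(split(diags, cl), stats::median, numeric(1))
  sizes <- vapply(split(diags, cl), length, integer(1))
  unname(meds[sizes >= 2L])
}

#' Assign long reads to the Pc vs Pc* allele models
#'
#' Long reads with k-mer similarity to the insertion material are anchored
#' to each allele model by exact seeds, and scored over the diagnostic
#' junction windows (the insertion boundaries, and the corresponding
#' uninterrupted point on Pc). A read supports an allele iff it spans at
#' least one diagnostic junction and its alignment score there exceeds the
#' other model's by `min_margin`.
#'
#' @param long_reads Read tibble (`read_id`, `bases`).
#' @param pc_allele,pcstar_allele `allele_model` objects sharing flanks.
#' @param k_bait Bait k-mer size for noisy long reads (default 15).
#' @param min_hits Minimum bait k-mer hits (default 3).
#' @param min_margin Minimum score margin for an assignment (default 20).
#' @param window Half-width of the junction scoring window in bp
#'   (default 500).
#' @param scoring Alignment scoring.
#' @return List with `assignments` (tibble: `read_id`, `allele`,
#'   `score_margin`, `spans_diagnostic_junction`) and `counts` (tibble:
#'   `allele`, `n_support`).
#' @export
assign_long_reads <- function(long_reads, pc_allele, pcstar_allele,
                              k_bait = 15L, min_hits = 3L, min_margin = 20,
                              window = 500L, scoring = align_scoring()) {
  dj <- .diagnostic_junctions(pc_allele, pcstar_allele)
  pc <- seq_chr(pc_allele$sequence)
  star <- seq_chr(pcstar_allele$sequence)
  # bait on the material that distinguishes or surrounds the event: the
  # inserted segment plus the junction neighbourhood shared with Pc
  ins_seq <- substr(star, dj$pc_pos + 1L, dj$pc_pos + dj$ins_len)
  near_pc <- substr(pc, max(1L, dj$pc_pos - 2L * window),
                    min(nchar(pc), dj$pc_pos + 2L * window))
  idx <- build_bait_index(list(ins_seq, near_pc), k = k_bait)
  cand <- bait_reads(long_reads, idx, min_hits = min_hits)

  rows <- lapply(seq_len(nrow(cand)), function(i) {
    .assign_one(cand$read_id[i], cand$bases[i], pc, star, dj, window,
                min_margin, scoring)
  })
  assignments <- dplyr::bind_rows(rows)
  if (nrow(assignments) == 0L) {
    assignments <- tibble::tibble(read_id = character(0), allele = character(0),
                                  score_margin = numeric(0),
                                  spans_diagnostic_junction = logical(0))
  }
  counts <- tibble::tibble(
    allele = c("Pc", "Pc_star"),
    n_support = c(sum(assignments$allele == "Pc"),
                  sum(assignments$allele == "Pc_star")))
  list(assignments = assignments, counts = counts)
}

# score one read segment against the window around junction j of a target
.window_score <- function(seg, target, j, window, scoring) {
  ws <- max(0L, j - window); we <- min(nchar(target), j + window)
  align_read(substr(target, ws + 1L, we), seg, type = "local",
             scoring = scoring)$score
}

# support candidates of one oriented read: for every diagnostic junction
# the read fully spans on a model, the SAME read segment is scored against
# that model's junction window and against the other model's corresponding
# window(s); the margin is the difference.
.junction_candidates <- function(rd, pc, star, dj, window, scoring) {
  L <- nchar(rd)
  offs_pc <- .anchor_offsets(rd, pc)
  offs_star <- .anchor_offsets(rd, star)
  spans <- function(j, off) off <= j - window && off + L >= j + window
  seg_for <- function(j, off) {
    rs <- max(1L, round(j - window - off) - 200L)
    re <- min(L, round(j + window - off) + 200L)
    if (re - rs < window) return(NULL)
    substr(rd, rs, re)
  }
  cands <- list()
  for (js in dj$star_pos) {
    for (off in offs_star) {
      if (!spans(js, off)) next
      seg <- seg_for(js, off)
      if (is.null(seg)) next
      s1 <- .window_score(seg, star, js, window, scoring)
      s2 <- .window_score(seg, pc, dj$pc_pos, window, scoring)
      cands[[length(cands) + 1L]] <- list(allele = "Pc_star",
                                          margin = s1 - s2)
    }
  }
  for (off in offs_pc) {
    if (!spans(dj$pc_pos, off)) next
    seg <- seg_for(dj$pc_pos, off)
    if (is.null(seg)) next
    s1 <- .window_score(seg, pc, dj$pc_pos, window, scoring)
    s2 <- max(vapply(dj$star_pos, function(js) {
      .window_score(seg, star, js, window, scoring)
    }, numeric(1)))
    cands[[length(cands) + 1L]] <- list(allele = "Pc", margin = s1 - s2)
  }
  cands
}

.assign_one <- function(read_id, bases, pc, star, dj, window, min_margin,
                        scoring) {
  out <- function(allele, margin, spans) {
    tibble::tibble(read_id = read_id, allele = allele, score_margin = margin,
                   spans_diagnostic_junction = spans)
  }
  cands <- c(.junction_candidates(bases, pc, star, dj, window, scoring),
             .junction_candidates(revcomp(bases), pc, star, dj, window,
                                  scoring))
  if (length(cands) == 0L) return(out("ambiguous", NA_real_, FALSE))
  margins <- vapply(cands, `[[`, numeric(1), "margin")
  best <- cands[[which.max(margins)]]
  if (best$margin < min_margin) return(out("ambiguous", best$margin, TRUE))
  out(best$allele, best$margin, TRUE)
}
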