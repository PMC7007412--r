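# Locus-scale pairwise alignment built on Biostrings, with operation
# extraction and a one-level split (primary + supplementary) search.
# Scoring defaults follow the read-classification contract:
# match +1, mismatch -4, gap open -6, gap extend -1.

#' Alignment scoring parameters
#'
#' @param match,mismatch Per-base scores.
#' @param gap_open,gap_extend Positive penalties (subtracted).
#' @return List of scoring parameters.
#' @export
align_scoring <- function(match = 1, mismatch = -4, gap_open = 6, gap_extend = 1) {
  list(match = match, mismatch = mismatch,
       gap_open = gap_open, gap_extend = gap_extend)
}

.subst_matrix <- function(scoring) {
  Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
}

# ops from the gapped pattern/subject strings; returns tibble(op, len) with
# op in {match, mismatch, ins, del} (ins = extra read base, del = missing
# read base relative to target). Clips are added by the caller.
.ops_from_gapped <- function(p, s) {
  pc <- strsplit(p, "")[[1]]
  sc <- strsplit(s, "")[[1]]
  op <- ifelse(pc == "-", "del", ifelse(sc == "-", "ins",
        ifelse(pc == sc, "match", "mismatch")))
  r <- rle(op)
  tibble::tibble(op = r$values, len = r$lengths)
}

#' Align a read against a target sequence
#'
#' Thin wrapper over [Biostrings::pairwiseAlignment()] that reports the
#' alignment as an explicit operation list with 0-based half-open target
#' coordinates and soft-clip bookkeeping.
#'
#' @param query,target Character scalars or `nuc_sequence` objects.
#' @param type `"local"` or `"global-local"` (read global, target local).
#' @param scoring From [align_scoring()].
#' @return List with `score`, `q_start`, `q_end`, `t_start`, `t_end`
#'   (0-based half-open), `ops` tibble, and `cigar` (S = soft clip).
#' @export
align_read <- function(query, target, type = c("local", "global-local"),
                       scoring = align_scoring()) {
  type <- match.arg(type)
  q <- seq_chr(query); t <- seq_chr(target)
  aln <- Biostrings::pairwiseAlignment(
    q, t, type = type, substitutionMatrix = .subst_matrix(scoring),
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  pat <- Biostrings::pattern(aln)
  sub <- Biostrings::subject(aln)
  ops <- .ops_from_gapped(as.character(pat), as.character(sub))
  qs <- Biostrings::start(pat) - 1L
  qe <- Biostrings::end(pat)
  res <- list(
    score = Biostrings::score(aln),
    q_start = qs, q_end = qe,
    t_start = Biostrings::start(sub) - 1L,
    t_end = Biostrings::end(sub),
    ops = ops,
    clip_left = qs,
    clip_right = nchar(q) - qe
  )
  res$cigar <- ops_to_cigar(res, nchar(q))
  res
}

#' Render an alignment's operations as a CIGAR-like string
#' @param aln Result of [align_read()].
#' @param query_len Read length (for soft clips).
#' @return Character scalar, e.g. `"75M10D75M"`; `=`/`X` are collapsed to `M`,
#'   clips shown as `S`.
#' @export
ops_to_cigar <- function(aln, query_len) {
  code <- c(match = "M", mismatch = "M", ins = "I", del = "D")
  ops <- aln$ops
  v <- code[ops$op]
  r <- rle(v)
  lens <- vapply(seq_along(r$values), function(i) {
    idx <- cumsum(c(0, r$lengths))[i] + seq_len(r$lengths[i])
    sum(ops$len[idx])
  }, numeric(1))
  body <- paste0(lens, r$values, collapse = "")
  left <- if (aln$clip_left > 0) paste0(aln$clip_left, "S") else ""
  right <- if (aln$clip_right > 0) paste0(aln$clip_right, "S") else ""
  paste0(left, body, right)
}

# collapse match/mismatch into M blocks; returns tibble(op, len) with op in
# {M, ins, del}
.collapse_ops <- function(ops) {
  v <- ifelse(ops$op %in% c("match", "mismatch"), "M", ops$op)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1) + 1L)
  tibble::tibble(
    op = r$values,
    len = vapply(seq_along(starts),
                 function(i) sum(ops$len[starts[i]:ends[i]]), numeric(1)))
}

# fraction of aligned (non-indel) read bases that mismatch
.mismatch_frac <- function(ops) {
  al <- sum(ops$len[ops$op %in% c("match", "mismatch")])
  if (al == 0) return(1)
  sum(ops$len[ops$op == "mismatch"]) / al
}

# a "clean" alignment: full-length (no clips beyond tol bases), no indels,
# mismatch fraction within tol_mm
.is_clean <- function(aln, query_len, tol_clip = 0L, tol_mm = 0.05) {
  co <- .collapse_ops(aln$ops)
  aln$clip_left <= tol_clip && aln$clip_right <= tol_clip &&
    all(co$op == "M") && .mismatch_frac(aln$ops) <= tol_mm
}

#' Split-alignment search against one target
#'
#' Aligns the read locally, and if a soft-clipped tail of at least
#' `min_clip` bases remains, aligns that tail separately as a supplementary
#' piece. One level of splitting only, which resolves a single novel
#' junction.
#'
#' @param query,target Sequences.
#' @param scoring From [align_scoring()].
#' @param min_clip Minimum clipped length to attempt a supplementary
#'   alignment (default 20 bp).
#' @return List of alignment records; the first is primary
#'   (`is_supplementary = FALSE`).
#' @export
split_align <- function(query, target, scoring = align_scoring(),
                        min_clip = 20L) {
  q <- seq_chr(query)
  primary <- align_read(q, target, type = "local", scoring = scoring)
  primary$is_supplementary <- FALSE
  primary$q_offset <- 0L
  out <- list(primary)
  for (side in c("left", "right")) {
    cl <- if (side == "left") primary$clip_left else primary$clip_right
    if (cl >= min_clip) {
      piece <- if (side == "left") substr(q, 1L, primary$q_start)
               else substr(q, primary$q_end + 1L, nchar(q))
      supp <- align_read(piece, target, type = "local", scoring = scoring)
      supp$is_supplementary <- TRUE
      supp$q_offset <- if (side == "left") 0L else primary$q_end
      out <- c(out, list(supp))
    }
  }
  out
}

# read fraction explained by primary + supplementary aligned segments
.split_coverage <- function(alns, query_len) {
  covered <- logical(query_len)
  for (a in alns) {
    if (a$q_end > a$q_start) {
      covered[(a$q_offset + a$q_start + 1L):(a$q_offset + a$q_end)] <- TRUE
    }
  }
  mean(covered)
}
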