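# In-silico PCR for the polled/horned screen.
#
# The screen distinguishes the alleles by product size: on the wild-type
# horned allele a variant-spanning pair yields a 389-bp product, on the
# Celtic POLLED allele the same pair yields 591 bp (the edit adds 202 bp
# between any variant-spanning primer pair).

#' Primer pair
#'
#' @param name Pair label.
#' @param forward,reverse Primer sequences, both given 5'->3' as synthesized
#'   (the reverse primer anneals to the plus strand as its reverse
#'   complement).
#' @param max_mismatches Mismatches tolerated per binding site (default 0).
#' @param require_3prime_anchor If `TRUE`, no mismatches are allowed in the
#'   3'-terminal 3 bases of a primer.
#' @return Object of class `primer_pair`.
#' @export
primer_pair <- function(name, forward, reverse, max_mismatches = 0L,
                        require_3prime_anchor = TRUE) {
  fwd <- seq_chr(forward); rev <- seq_chr(reverse)
  if (nchar(fwd) < 15L || nchar(rev) < 15L) stop("primer lengths must be >= 15")
  if (max_mismatches >= min(nchar(fwd), nchar(rev))) {
    stop("max_mismatches must be smaller than the primer length")
  }
  structure(list(name = name, forward = fwd, reverse = rev,
                 max_mismatches = as.integer(max_mismatches),
                 require_3prime_anchor = require_3prime_anchor),
            class = "primer_pair")
}

# plus-strand binding sites of a primer given 5'->3' on that strand.
# Returns 0-based start offsets. anchor_end: "right" when the primer's 3'
# end is the rightmost base on the plus strand (forward primer), "left"
# when it is the leftmost (reverse primer match given as revcomp).
.primer_sites <- function(primer, template, max_mismatches, anchor3,
                          anchor_end) {
  hits <- Biostrings::matchPattern(primer, Biostrings::DNAString(template),
                                   max.mismatch = max_mismatches)
  starts <- Biostrings::start(hits) - 1L
  if (anchor3 && max_mismatches > 0L && length(starts) > 0L) {
    m <- nchar(primer)
    keep <- vapply(starts, function(s) {
      site <- substr(template, s + 1L, s + m)
      if (anchor_end == "right") {
        substr(site, m - 2L, m) == substr(primer, m - 2L, m)
      } else {
        substr(site, 1L, 3L) == substr(primer, 1L, 3L)
      }
    }, logical(1))
    starts <- starts[keep]
  }
  starts
}

#' Predict PCR amplicons on a template
#'
#' Finds every forward/reverse binding-site pairing with the forward site
#' upstream of the reverse site and product length at most `max_len`. All
#' products are reported (band-pattern genotyping needs the full set).
#'
#' @param template `nuc_sequence` or string.
#' @param pair A [primer_pair()].
#' @param max_len Maximum product length in bp (default 5000).
#' @return Tibble with `template_id`, `start`, `end` (0-based half-open),
#'   `length`, `forward_site`, `reverse_site`, sorted by start then length.
#'   Zero rows when there is no product.
#' @export
predict_amplicons <- function(template, pair, max_len = 5000L) {
  stopifnot(max_len > 0)
  tpl <- seq_chr(template)
  tid <- if (inherits(template, "nuc_sequence")) template$id else "template"
  f_sites <- .primer_sites(pair$forward, tpl, pair$max_mismatches,
                           pair$require_3prime_anchor, "right")
  r_sites <- .primer_sites(revcomp(pair$reverse), tpl, pair$max_mismatches,
                           pair$require_3prime_anchor, "left")
  if (length(f_sites) == 0L || length(r_sites) == 0L) {
    return(tibble::tibble(template_id = character(0), start = integer(0),
                          end = integer(0), length = integer(0),
                          forward_site = integer(0), reverse_site = integer(0)))
  }
  m_r <- nchar(pair$reverse)
  combos <- expand.grid(f = f_sites, r = r_sites)
  combos$end <- combos$r + m_r
  combos <- combos[combos$f < combos$r & combos$end - combos$f <= max_len, ,
                   drop = FALSE]
  out <- tibble::tibble(template_id = tid,
                        start = as.integer(combos$f),
                        end = as.integer(combos$end),
                        length = as.integer(combos$end - combos$f),
                        forward_site = as.integer(combos$f),
                        reverse_site = as.integer(combos$r))
  dplyr::arrange(out, .data$start, .data$length)
}

#' Call a genotype from per-allele band patterns
#'
#' Interprets gel bands from the polled screen: the polled-class band alone
#' is homozygous POLLED (PcPc), the horned-class band alone is homozygous
#' horned (pp), both bands are heterozygous (Pcp).
#'
#' @param amplicons_per_allele Named list (one or two alleles) of numeric
#'   vectors of product lengths in bp.
#' @param polled_len,horned_len Expected band lengths (defaults 591 and 389).
#' @param tol Band-size tolerance in bp (default 5).
#' @return Character scalar: `"PcPc"`, `"pp"`, `"Pcp"` or
#'   `"uninterpretable"`.
#' @export
genotype_from_bands <- function(amplicons_per_allele, polled_len = 591L,
                                horned_len = 389L, tol = 5L) {
  if (length(amplicons_per_allele) == 0L) stop("no allele band sets supplied")
  if (!length(amplicons_per_allele) %in% 1:2) {
    stop("input must cover 1 or 2 alleles")
  }
  bands <- unlist(amplicons_per_allele, use.names = FALSE)
  if (length(bands) == 0L) return("uninterpretable")
  cls <- ifelse(abs(bands - polled_len) <= tol, "polled",
         ifelse(abs(bands - horned_len) <= tol, "horned", "unknown"))
  if (any(cls == "unknown")) return("uninterpretable")
  has_p <- "polled" %in% cls
  has_h <- "horned" %in% cls
  if (has_p && has_h) "Pcp" else if (has_p) "PcPc" else "pp"
}

#' qPCR amplification efficiency from a standard-curve slope
#'
#' `E = 10^(-1/s) - 1`, where `s` is the slope of Ct against log10 template
#' dilution. A slope of -3.32 corresponds to perfect doubling (E = 1).
#'
#' @param slope Standard-curve slope (non-zero).
#' @return Efficiency as a fraction (1 = 100%).
#' @export
amplification_efficiency <- function(slope) {
  if (any(slope == 0)) stop("slope must be non-zero")
  10^(-1 / slope) - 1
}

#' Does an efficiency pass the validation gate?
#' @param efficiency Fraction from [amplification_efficiency()].
#' @param threshold Minimum acceptable efficiency (default 0.90).
#' @return Logical.
#' @export
efficiency_passes <- function(efficiency, threshold = 0.90) {
  efficiency > threshold
}

#' Read primers from a TSV (name, forward, reverse)
#' @param path TSV path with columns `name`, `forward`, `reverse`.
#' @param ... Passed to [primer_pair()].
#' @return List of `primer_pair`.
#' @export
read_primers_tsv <- function(path, ...) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(d)), function(i) {
    primer_pair(d$name[i], d$forward[i], d$reverse[i], ...)
  })
}
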