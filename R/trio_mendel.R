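# Trio Mendelian-error statistics: per-trio error counts and rates, the
# group-level one-way ANOVA, the 10-kb windowed error-hotspot scan, and an
# analytic expectation for the error rate under a symmetric genotyping-error
# model (used as an oracle in parameter-recovery tests).

#' Is an offspring genotype consistent with Mendelian transmission?
#'
#' Vectorized over trios of dosage genotypes (0/1/2). An offspring genotype
#' is consistent iff it can be formed by one allele from each parent;
#' equivalently it must lie in `[omin, omax]` where `omin = (s==2)+(d==2)`
#' and `omax = (s>=1)+(d>=1)`.
#'
#' @param s,d,o Sire, dam, offspring genotypes (integer vectors in 0..2).
#' @return Logical vector.
#' @export
is_mendelian_consistent <- function(s, d, o) {
  if (any(c(s, d, o) < 0 | c(s, d, o) > 2, na.rm = TRUE)) {
    stop("genotypes must be in {0, 1, 2}")
  }
  omin <- (s == 2L) + (d == 2L)
  omax <- (s >= 1L) + (d >= 1L)
  o >= omin & o <= omax
}

#' Trio specification table
#'
#' @param offspring_id,sire_id,dam_id Character vectors (recycled to the
#'   longest).
#' @param family Integer family labels.
#' @param group Study-group labels (free text, e.g. `"GH.H"`).
#' @return Tibble with one row per trio.
#' @export
trio_spec <- function(sire_id, dam_id, offspring_id, family, group) {
  tibble::tibble(sire_id = sire_id, dam_id = dam_id,
                 offspring_id = offspring_id, family = family, group = group)
}

#' Count Mendelian errors for one trio
#'
#' Sites with any missing genotype in the trio are skipped: they are
#' neither errors nor tested. The per-variant percentage is
#' `100 * n_errors / denominator`; the per-individual percentage divides
#' that by the 3 trio members. `fixed_denominator` supports reporting rates
#' against a cohort-wide variant count instead of the trio's tested sites.
#'
#' @param gm A [genotype_matrix()].
#' @param trio One-row tibble (or list) with `sire_id`, `dam_id`,
#'   `offspring_id` (and optionally `family`, `group`).
#' @param fixed_denominator Optional variant count to use as the rate
#'   denominator (default: the trio's tested sites).
#' @return One-row tibble: ids, `n_errors`, `n_sites_tested`,
#'   `pct_per_variant`, `pct_per_individual` (`NA` when the denominator
#'   is 0).
#' @export
count_trio_errors <- function(gm, trio, fixed_denominator = NULL) {
  ids <- c(trio$sire_id, trio$dam_id, trio$offspring_id)
  missing_ids <- setdiff(ids, gm$samples)
  if (length(missing_ids) > 0L) {
    stop("trio member(s) absent from matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  s <- gm$geno[, trio$sire_id]
  d <- gm$geno[, trio$dam_id]
  o <- gm$geno[, trio$offspring_id]
  tested <- !is.na(s) & !is.na(d) & !is.na(o)
  n_tested <- sum(tested)
  n_err <- if (n_tested == 0L) 0L else {
    sum(!is_mendelian_consistent(s[tested], d[tested], o[tested]))
  }
  den <- if (is.null(fixed_denominator)) n_tested else fixed_denominator
  pct <- if (den == 0) NA_real_ else 100 * n_err / den
  tibble::tibble(
    sire_id = trio$sire_id, dam_id = trio$dam_id,
    offspring_id = trio$offspring_id,
    family = if (!is.null(trio$family)) trio$family else NA_integer_,
    group = if (!is.null(trio$group)) trio$group else NA_character_,
    n_errors = n_err, n_sites_tested = n_tested,
    pct_per_variant = pct, pct_per_individual = pct / 3)
}

#' Mendelian-error table for a set of trios
#'
#' @param gm A [genotype_matrix()].
#' @param trios Tibble from [trio_spec()].
#' @param fixed_denominator See [count_trio_errors()].
#' @return Tibble with one row per trio.
#' @export
mendel_table <- function(gm, trios, fixed_denominator = NULL) {
  dplyr::bind_rows(lapply(seq_len(nrow(trios)), function(i) {
    count_trio_errors(gm, trios[i, ], fixed_denominator = fixed_denominator)
  }))
}

#' One-way ANOVA of values across groups
#'
#' Fits a fixed-effects one-way ANOVA (via [stats::aov()]) and optionally a
#' Tukey HSD post-hoc. With all group means equal and zero between-group
#' variance the F statistic is 0.
#'
#' @param data Tibble with columns `value` and `group` (or supply a named
#'   list of numeric vectors).
#' @param posthoc Run Tukey HSD (default FALSE).
#' @return Object of class `polled_anova` with `F`, `p`, `df_between`,
#'   `df_within`, `group_means`, the underlying `aov` fit and optionally
#'   `tukey`.
#' @export
oneway_anova <- function(data, posthoc = FALSE) {
  if (!is.data.frame(data)) {
    data <- tibble::tibble(
      value = unlist(data, use.names = FALSE),
      group = rep(names(data), lengths(data)))
  }
  stopifnot(all(c("value", "group") %in% names(data)))
  if (length(unique(data$group)) < 2L) stop("need at least 2 groups")
  data$group <- factor(data$group)
  fit <- stats::aov(value ~ group, data = data)
  tab <- stats::anova(fit)
  Fv <- tab$`F value`[1]
  pv <- tab$`Pr(>F)`[1]
  if (tab$`Sum Sq`[1] == 0 && tab$`Sum Sq`[2] == 0) {
    warning("no variance between or within groups; F defined as 0")
    Fv <- 0; pv <- 1
  }
  res <- list(F = Fv, p = pv,
              df_between = tab$Df[1], df_within = tab$Df[2],
              group_means = tapply(data$value, data$group, mean),
              fit = fit, data = data)
  if (posthoc) res$tukey <- stats::TukeyHSD(fit)
  structure(res, class = "polled_anova")
}

#' @export
print.polled_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' @rdname oneway_anova
#' @param x A `polled_anova` object.
#' @param ... Unused.
#' @method tidy polled_anova
#' @export
tidy.polled_anova <- function(x, ...) {
  tab <- stats::anova(x$fit)
  tibble::tibble(term = rownames(tab), df = tab$Df, sumsq = tab$`Sum Sq`,
                 meansq = tab$`Mean Sq`, statistic = tab$`F value`,
                 p.value = tab$`Pr(>F)`)
}

#' @rdname oneway_anova
#' @method glance polled_anova
#' @export
glance.polled_anova <- function(x, ...) {
  tibble::tibble(statistic = x$F, p.value = x$p, df_between = x$df_between,
                 df_within = x$df_within)
}

#' Windowed Mendelian-error scan
#'
#' Bins error positions per offspring into fixed windows (default 10 kb)
#' tiling each contig from 0. Bins with at most `min_total - 1` errors
#' summed over all offspring are excluded; the survivors are "error-prone".
#' Bins whose per-group error rate exceeds `high_rate_per_kb` errors per kb
#' in every group are additionally flagged "consistently high".
#'
#' @param errors Tibble with columns `offspring_id`, `contig`, `pos`
#'   (0-based position of each Mendelian error).
#' @param groups Named character vector mapping offspring_id to group.
#' @param window Window size in bp (default 10000).
#' @param min_total Minimum total errors for an error-prone bin
#'   (default 11, i.e. bins with <= 10 errors are excluded).
#' @param high_rate_per_kb Per-group rate defining "consistently high"
#'   (default 1 error per kb).
#' @return List with `window_table` (per-bin, per-offspring counts, long
#'   format, plus totals), `error_prone` and `consistently_high` bin
#'   tibbles.
#' @export
window_error_scan <- function(errors, groups, window = 10000L,
                              min_total = 11L, high_rate_per_kb = 1) {
  if (window <= 0) stop("window must be positive")
  if (nrow(errors) == 0L) {
    empty <- tibble::tibble(contig = character(0), bin_start = numeric(0),
                            total_errors = integer(0))
    return(list(window_table = empty, error_prone = empty,
                consistently_high = empty))
  }
  errors <- dplyr::mutate(errors,
                          bin_start = (.data$pos %/% window) * window)
  per_off <- errors |>
    dplyr::count(.data$contig, .data$bin_start, .data$offspring_id,
                 name = "n_errors")
  totals <- per_off |>
    dplyr::group_by(.data$contig, .data$bin_start) |>
    dplyr::summarise(total_errors = sum(.data$n_errors), .groups = "drop")
  error_prone <- dplyr::filter(totals, .data$total_errors >= min_total)

  per_off$group <- unname(groups[per_off$offspring_id])
  per_group <- per_off |>
    dplyr::group_by(.data$contig, .data$bin_start, .data$group) |>
    dplyr::summarise(group_errors = sum(.data$n_errors), .groups = "drop") |>
    dplyr::mutate(rate_per_kb = .data$group_errors / (window / 1000))
  n_groups <- length(unique(groups))
  high <- per_group |>
    dplyr::filter(.data$rate_per_kb > high_rate_per_kb) |>
    dplyr::count(.data$contig, .data$bin_start, name = "n_groups_high") |>
    dplyr::filter(.data$n_groups_high == n_groups) |>
    dplyr::select("contig", "bin_start")
  consistently_high <- dplyr::semi_join(
    totals, high, by = c("contig", "bin_start"))
  list(window_table = dplyr::left_join(
         per_off, totals, by = c("contig", "bin_start")),
       error_prone = error_prone,
       consistently_high = consistently_high)
}

# symmetric single-step genotype error matrix: adjacent states at rate eps,
# two-step (0 <-> 2) at eps^2
genotype_error_matrix <- function(eps) {
  stopifnot(eps >= 0, eps <= 0.4)
  matrix(c(1 - eps - eps^2, eps, eps^2,
           eps, 1 - 2 * eps, eps,
           eps^2, eps, 1 - eps - eps^2),
         nrow = 3, byrow = TRUE)
}

# P(observed trio inconsistent) at one allele frequency f
.mendel_error_prob_at_freq <- function(f, eps) {
  hwe <- c((1 - f)^2, 2 * f * (1 - f), f^2)
  gam <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))  # P(transmit alt | gt)
  Tm <- genotype_error_matrix(eps)
  p_err <- 0
  for (s in 0:2) for (d in 0:2) {
    # true offspring distribution given true parents
    po <- c(gam[s + 1, 1] * gam[d + 1, 1],
            gam[s + 1, 1] * gam[d + 1, 2] + gam[s + 1, 2] * gam[d + 1, 1],
            gam[s + 1, 2] * gam[d + 1, 2])
    for (o in 0:2) {
      p_true <- hwe[s + 1] * hwe[d + 1] * po[o + 1]
      if (p_true == 0) next
      for (so in 0:2) for (do in 0:2) for (oo in 0:2) {
        if (is_mendelian_consistent(so, do, oo)) next
        p_err <- p_err + p_true *
          Tm[s + 1, so + 1] * Tm[d + 1, do + 1] * Tm[o + 1, oo + 1]
      }
    }
  }
  p_err
}

#' Expected per-variant Mendelian error rate under genotyping error
#'
#' Exact expectation over the 27 true-genotype trio combinations: parents
#' drawn from Hardy-Weinberg at each allele frequency, offspring by
#' Mendelian transmission, all three genotypes independently perturbed by
#' the symmetric single-step error model (adjacent states at rate `eps`,
#' direct 0<->2 at `eps^2`). The allele-frequency distribution is
#' integrated by quadrature.
#'
#' @param eps Genotyping error probability in `[0, 0.4]`.
#' @param freq_dist Either a single frequency, a list
#'   `list(type = "uniform", min =, max =)`, or a density function on
#'   (0, 1).
#' @return Expected fraction of variants showing a Mendelian error.
#' @export
expected_error_rate <- function(eps, freq_dist = list(type = "uniform",
                                                      min = 0.05, max = 0.95)) {
  stopifnot(eps >= 0, eps <= 0.4)
  if (is.numeric(freq_dist) && length(freq_dist) == 1L) {
    return(.mendel_error_prob_at_freq(freq_dist, eps))
  }
  if (is.function(freq_dist)) {
    num <- stats::integrate(function(f) {
      vapply(f, function(fi) {
        .mendel_error_prob_at_freq(fi, eps) * freq_dist(fi)
      }, numeric(1))
    }, 0, 1)$value
    den <- stats::integrate(function(f) vapply(f, freq_dist, numeric(1)),
                            0, 1)$value
    return(num / den)
  }
  if (is.list(freq_dist) && identical(freq_dist$type, "uniform")) {
    a <- freq_dist$min; b <- freq_dist$max
    stopifnot(is.numeric(a), is.numeric(b), a < b)
    val <- stats::integrate(function(f) {
      vapply(f, function(fi) .mendel_error_prob_at_freq(fi, eps), numeric(1))
    }, a, b)$value
    return(val / (b - a))
  }
  stop("invalid freq_dist specification")
}

#' Write a Mendelian-error table as TSV
#' @param tab Tibble from [mendel_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mendel_tsv <- function(tab, path) {
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pedigree TSV
#'
#' Columns: `offspring`, `sire`, `dam`, `family`, `group`.
#'
#' @param path TSV path.
#' @return Trio tibble as from [trio_spec()].
#' @export
read_pedigree_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  trio_spec(d$sire, d$dam, d$offspring, d$family, d$group)
}
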