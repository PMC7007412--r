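# Packaged per-trio Mendelian error counts (the published cohort summary),
# enabling reproduction of the trio statistics with no simulation.

.TABLE1_DENOMINATOR <- 14084653L
.TABLE1_MD5 <- "c0f24dc89be938bc2cff47c4bb9fa741"

#' Packaged per-trio Mendelian error counts
#'
#' Returns the 12 published trio error counts (three study groups, 6/3/3,
#' four families) together with the cohort-wide biallelic variant count
#' (14,084,653) used as the rate denominator. The packaged file is
#' immutable and verified by checksum on every load.
#'
#' @return List with `trios` (tibble: `study_group`, `family`, `sire`,
#'   `dam`, `offspring`, `n_errors`) and `denominator` (integer).
#' @export
table1_fixture <- function() {
  path <- system.file("extdata", "table1_mendel.tsv", package = "polledcheck",
                      mustWork = TRUE)
  if (unname(tools::md5sum(path)) != .TABLE1_MD5) {
    stop("packaged trio-count fixture failed its checksum")
  }
  d <- read.delim(path, stringsAsFactors = FALSE)
  list(trios = tibble::as_tibble(d), denominator = .TABLE1_DENOMINATOR)
}

#' Trio error rates from the packaged counts
#'
#' Computes per-variant and per-individual percentages for the 12 packaged
#' trios against the cohort denominator, as in the published summary table.
#'
#' @return Tibble: fixture columns plus `pct_per_variant` and
#'   `pct_per_individual`.
#' @export
table1_rates <- function() {
  fx <- table1_fixture()
  dplyr::mutate(fx$trios,
                pct_per_variant = 100 * .data$n_errors / fx$denominator,
                pct_per_individual = .data$pct_per_variant / 3)
}
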