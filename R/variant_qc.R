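# Variant-level hard filters and cohort site filters.
#
# Hard-filter thresholds (defaults) follow standard short-variant
# hard-filtering practice as applied in the study cohort:
#   both types:  QD < 2.0, FS > 60.0, SOR > 4.0, ReadPosRankSum < -8.0,
#                DP > 3105 (interpreted as cohort-summed depth)
#   SNPs only:   MQ < 40.0, MQRankSum < -12.5
#   indels only: InbreedingCoeff < -0.8
# A missing INFO annotation leaves its rule unevaluated (the record passes
# that rule).

#' Default hard-filter thresholds
#' @return Named list of thresholds.
#' @export
hard_filter_thresholds <- function() {
  list(QD_min = 2.0, FS_max = 60.0, SOR_max = 4.0, ReadPosRankSum_min = -8.0,
       DP_max = 3105, MQ_min = 40.0, MQRankSum_min = -12.5,
       InbreedingCoeff_min = -0.8)
}

#' Classify variant type from REF/ALT lengths
#' @param ref,alt Character vectors of alleles.
#' @return `"SNP"` where both are single bases, else `"indel"`.
#' @export
variant_type <- function(ref, alt) {
  ifelse(nchar(ref) == 1L & nchar(alt) == 1L & !grepl(",", alt),
         "SNP", "indel")
}

#' Apply hard filters to variant records
#'
#' @param variants Tibble with columns `contig`, `pos`, `ref`, `alt` and any
#'   of the INFO columns `QD`, `FS`, `SOR`, `ReadPosRankSum`, `DP`, `MQ`,
#'   `MQRankSum`, `InbreedingCoeff` (missing columns or `NA` values leave
#'   the corresponding rule unevaluated).
#' @param thresholds From [hard_filter_thresholds()].
#' @return The input tibble with `vtype`, `pass` (logical) and `filter`
#'   (`"PASS"` or semicolon-joined failed-rule names) appended.
#' @export
hard_filter <- function(variants, thresholds = hard_filter_thresholds()) {
  n <- nrow(variants)
  vtype <- variant_type(variants$ref, variants$alt)
  g <- function(col) {
    if (col %in% names(variants)) variants[[col]] else rep(NA_real_, n)
  }
  fails <- list(
    QD = g("QD") < thresholds$QD_min,
    FS = g("FS") > thresholds$FS_max,
    SOR = g("SOR") > thresholds$SOR_max,
    ReadPosRankSum = g("ReadPosRankSum") < thresholds$ReadPosRankSum_min,
    DP = g("DP") > thresholds$DP_max,
    MQ = g("MQ") < thresholds$MQ_min & vtype == "SNP",
    MQRankSum = g("MQRankSum") < thresholds$MQRankSum_min & vtype == "SNP",
    InbreedingCoeff = g("InbreedingCoeff") < thresholds$InbreedingCoeff_min &
      vtype == "indel")
  fails <- lapply(fails, function(x) !is.na(x) & x)
  fm <- do.call(cbind, fails)
  reasons <- apply(fm, 1L, function(r) {
    paste(colnames(fm)[r], collapse = ";")
  })
  out <- variants
  out$vtype <- vtype
  out$pass <- reasons == ""
  out$filter <- ifelse(out$pass, "PASS", reasons)
  tibble::as_tibble(out)
}

#' Genotype matrix container
#'
#' Sites-by-samples biallelic genotypes in dosage coding (0/1/2, `NA` for
#' missing).
#'
#' @param sites Tibble with `contig`, `pos` (1-based), `ref`, `alt`.
#' @param samples Character vector of sample ids.
#' @param geno Integer matrix, `nrow(sites)` x `length(samples)`.
#' @return Object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(sites, samples, geno) {
  geno <- as.matrix(geno)
  stopifnot(nrow(geno) == nrow(sites), ncol(geno) == length(samples))
  stopifnot(all(geno %in% c(0L, 1L, 2L, NA)))
  colnames(geno) <- samples
  structure(list(sites = tibble::as_tibble(sites), samples = samples,
                 geno = geno),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d sites x %d samples (%.2f%% missing)\n",
              nrow(x$geno), ncol(x$geno), 100 * mean(is.na(x$geno))))
  invisible(x)
}

# minor allele frequency over non-missing genotypes; NA when all missing
.maf <- function(geno) {
  nn <- rowSums(!is.na(geno))
  af <- rowSums(geno, na.rm = TRUE) / (2 * nn)
  pmin(af, 1 - af)
}

#' Cohort-level site filters
#'
#' Applies, in order: biallelic-only, genotyping-rate, and minor-allele-
#' frequency filters. Thresholds are exclusive (`< 95%` rate and `< 5%`
#' MAF are removed; a site at exactly the threshold is retained).
#'
#' @param gm A [genotype_matrix()].
#' @param min_genotype_rate Minimum fraction of non-missing genotypes
#'   (default 0.95).
#' @param min_maf Minimum minor allele frequency (default 0.05).
#' @param biallelic_only Drop sites with multiple ALT alleles (default TRUE).
#' @return List with `matrix` (filtered `genotype_matrix`), `exclusions`
#'   (tibble `rule`, `n_excluded` in application order) and `kept` (indices
#'   into the input sites).
#' @export
site_filters <- function(gm, min_genotype_rate = 0.95, min_maf = 0.05,
                         biallelic_only = TRUE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (nrow(gm$geno) == 0L) stop("empty genotype matrix")
  keep <- rep(TRUE, nrow(gm$geno))
  excl <- tibble::tibble(rule = character(0), n_excluded = integer(0))
  if (biallelic_only) {
    multi <- grepl(",", gm$sites$alt)
    excl <- dplyr::bind_rows(excl, tibble::tibble(
      rule = "multiallelic", n_excluded = sum(multi & keep)))
    keep <- keep & !multi
  }
  rate <- rowSums(!is.na(gm$geno)) / ncol(gm$geno)
  low_rate <- rate < min_genotype_rate
  excl <- dplyr::bind_rows(excl, tibble::tibble(
    rule = "genotype_rate", n_excluded = sum(low_rate & keep)))
  keep <- keep & !low_rate
  maf <- .maf(gm$geno)
  low_maf <- !is.na(maf) & maf < min_maf
  excl <- dplyr::bind_rows(excl, tibble::tibble(
    rule = "maf", n_excluded = sum(low_maf & keep)))
  keep <- keep & !low_maf
  if (!any(keep)) warning("all sites removed by site filters")
  out <- genotype_matrix(gm$sites[keep, , drop = FALSE], gm$samples,
                         gm$geno[keep, , drop = FALSE])
  list(matrix = out, exclusions = excl, kept = unname(which(keep)))
}

#' Read a genotype matrix from TSV (sites x samples)
#'
#' Expects columns `contig`, `pos`, `ref`, `alt`, then one column per
#' sample with values 0/1/2 or `NA`/`.` for missing.
#'
#' @param path TSV path.
#' @return A [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("NA", "."))
  meta <- c("contig", "pos", "ref", "alt")
  stopifnot(all(meta %in% names(d)))
  samples <- setdiff(names(d), meta)
  geno <- as.matrix(d[, samples, drop = FALSE])
  mode(geno) <- "integer"
  genotype_matrix(tibble::as_tibble(d[, meta]), samples, geno)
}

#' Write a genotype matrix as TSV
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_genotype_tsv <- function(gm, path) {
  d <- cbind(as.data.frame(gm$sites), as.data.frame(gm$geno))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = ".")
  invisible(path)
}

#' Read a VCF into variant records and a genotype matrix
#'
#' Parses a VCF v4.2 file (via the vcfR package), extracting the INFO
#' annotations used by [hard_filter()] and dosage genotypes.
#'
#' @param path VCF path (plain or gzipped).
#' @return List with `variants` (tibble suitable for [hard_filter()]) and
#'   `matrix` (a [genotype_matrix()]; `NULL` when the VCF has no samples).
#' @export
read_vcf_records <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  info_keys <- c("QD", "FS", "SOR", "ReadPosRankSum", "DP", "MQ",
                 "MQRankSum", "InbreedingCoeff")
  variants <- tibble::tibble(
    contig = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT)
  for (key in info_keys) {
    variants[[key]] <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = key)))
  }
  gm <- NULL
  if (ncol(v@gt) > 1L) {
    gt <- vcfR::extract.gt(v, element = "GT")
    dose <- matrix(NA_integer_, nrow(gt), ncol(gt),
                   dimnames = dimnames(gt))
    clean <- gsub("\\|", "/", gt)
    dose[clean %in% c("0/0")] <- 0L
    dose[clean %in% c("0/1", "1/0")] <- 1L
    dose[clean %in% c("1/1")] <- 2L
    gm <- genotype_matrix(variants[, c("contig", "pos", "ref", "alt")],
                          colnames(gt), dose)
  }
  list(variants = variants, matrix = gm)
}

#' Write variant records with FILTER annotations as VCF v4.2 text
#'
#' @param variants Tibble from [hard_filter()] (must carry `filter`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_vcf_records <- function(variants, path) {
  stopifnot("filter" %in% names(variants))
  info_keys <- intersect(
    c("QD", "FS", "SOR", "ReadPosRankSum", "DP", "MQ", "MQRankSum",
      "InbreedingCoeff"),
    names(variants))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                       info_keys, info_keys),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  info <- vapply(seq_len(nrow(variants)), function(i) {
    vals <- vapply(info_keys, function(k) {
      v <- variants[[k]][i]
      if (is.na(v)) NA_character_ else paste0(k, "=", format(v))
    }, character(1))
    vals <- vals[!is.na(vals)]
    if (length(vals) == 0L) "." else paste(vals, collapse = ";")
  }, character(1))
  writeLines(paste(variants$contig, variants$pos, ".", variants$ref,
                   variants$alt, ".", variants$filter, info, sep = "\t"), con)
  invisible(path)
}
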