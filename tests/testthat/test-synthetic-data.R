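test_that("genomes embed the locus genotypes with correct length arithmetic", {
  cfg <- sim_config(genome_length = 20000L)
  gen <- make_genomes(cfg, c(w = "pp", het = "Pcp", star = "Pc*p",
                             hom = "PcPc"), seed = 110)
  L <- nchar(gen$reference[["chr1"]])
  expect_equal(L, 20000L)
  # pp: both haplotypes identical to the reference
  expect_identical(gen$animals$w$hap1[["chr1"]], gen$reference[["chr1"]])
  expect_identical(gen$animals$w$hap2[["chr1"]], gen$reference[["chr1"]])
  # Pcp: one haplotype longer by 202
  expect_equal(nchar(gen$animals$het$hap1[["chr1"]]) - L, 202L)
  expect_equal(nchar(gen$animals$het$hap2[["chr1"]]) - L, 0L)
  # Pc*p: longer by 202 + backbone + template
  expect_equal(nchar(gen$animals$star$hap1[["chr1"]]) - L,
               202L + 3900L + 1600L)
  expect_equal(nchar(gen$animals$hom$hap2[["chr1"]]) - L, 202L)
  # wild-type locus content sits at the recorded coordinates
  loc <- gen$truth$locus
  expect_equal(substr(gen$reference[["chr1"]], loc$end - 9, loc$end),
               "CTGGTATTCT")
  expect_error(make_genomes(cfg, c(x = "Pp"), seed = 1), "unknown genotype")
})

test_that("generation is deterministic from (seed, config)", {
  cfg <- sim_config(genome_length = 15000L)
  g1 <- make_genomes(cfg, c(a = "Pcp"), seed = 111)
  g2 <- make_genomes(cfg, c(a = "Pcp"), seed = 111)
  expect_identical(g1$reference, g2$reference)
  expect_identical(g1$animals, g2$animals)
  r1 <- simulate_short_reads(g1$animals$a, cfg, seed = 112)
  r2 <- simulate_short_reads(g2$animals$a, cfg, seed = 112)
  expect_identical(r1$reads, r2$reads)
  l1 <- simulate_long_reads(g1$animals$a, cfg, seed = 113)
  l2 <- simulate_long_reads(g2$animals$a, cfg, seed = 113)
  expect_identical(l1$reads, l2$reads)
  t1 <- simulate_trio_genotypes(sim_config(n_sites = 500L), seed = 114)
  t2 <- simulate_trio_genotypes(sim_config(n_sites = 500L), seed = 114)
  expect_identical(t1$matrix$geno, t2$matrix$geno)
})

test_that("short-read coverage and error rate match their settings", {
  cfg <- sim_config(genome_length = 50000L, short_error = 0)
  gen <- make_genomes(cfg, c(a = "pp"), seed = 115)
  sim <- simulate_short_reads(gen$animals$a, cfg, seed = 116)
  total <- sum(nchar(sim$reads$bases))
  expect_lt(abs(total - 20 * 2 * 50000) / (20 * 2 * 50000), 0.01)
  # reads are error-free: they match their origin substrings exactly
  org <- sim$origins
  key <- paste(sim$reads$read_id, sim$reads$mate)
  org <- org[match(key, paste(org$read_id, org$mate)), ]
  src <- substring(gen$reference[["chr1"]], org$start + 1, org$end)
  src[org$strand == "-"] <- revcomp(src[org$strand == "-"])
  expect_identical(sim$reads$bases, src)
  # at 1% error the realized mismatch rate is within 10% of 1%
  cfg2 <- sim_config(genome_length = 50000L, short_error = 0.01)
  sim2 <- simulate_short_reads(gen$animals$a, cfg2, seed = 117)
  org2 <- sim2$origins[match(paste(sim2$reads$read_id, sim2$reads$mate),
                             paste(sim2$origins$read_id, sim2$origins$mate)), ]
  src2 <- substring(gen$reference[["chr1"]], org2$start + 1, org2$end)
  src2[org2$strand == "-"] <- revcomp(src2[org2$strand == "-"])
  obs <- charToRaw(paste(sim2$reads$bases, collapse = ""))
  tru <- charToRaw(paste(src2, collapse = ""))
  expect_gte(length(tru), 1e6)
  rate <- mean(obs != tru)
  expect_lt(abs(rate - 0.01) / 0.01, 0.10)
})

test_that("long reads follow the configured length and depth", {
  cfg <- sim_config(genome_length = 80000L, long_error = 0)
  gen <- make_genomes(cfg, c(a = "pp"), seed = 118)
  sim <- simulate_long_reads(gen$animals$a, cfg, seed = 119)
  total <- sum(nchar(sim$reads$bases))
  expect_lt(abs(total - 14 * 2 * 80000) / (14 * 2 * 80000), 0.25)
  expect_gt(mean(nchar(sim$reads$bases)), 5000)
})

test_that("trio genotypes follow the generator contract", {
  # eps = 0, no missingness: zero Mendelian errors in every trio
  cfg0 <- sim_config(n_sites = 2000L, eps = 0, missing_rate = 0)
  sim0 <- simulate_trio_genotypes(cfg0, seed = 120)
  tab0 <- mendel_table(sim0$matrix, sim0$trios)
  expect_true(all(tab0$n_errors == 0L))
  expect_equal(nrow(sim0$trios), 12)
  expect_equal(as.integer(table(sim0$trios$group)[c("GH.H", "H.H", "Ho.H")]),
               c(6L, 3L, 3L))
  expect_error(simulate_trio_genotypes(sim_config(n_sites = 0L), seed = 1),
               "n_sites")
  # missingness close to its setting
  cfg1 <- sim_config(n_sites = 5000L, missing_rate = 0.01)
  sim1 <- simulate_trio_genotypes(cfg1, seed = 121)
  expect_lt(abs(mean(is.na(sim1$matrix$geno)) - 0.01), 0.003)
})

test_that("planted hotspot bins surface in the window scan", {
  cfg <- sim_config(n_sites = 20000L, eps = 0.001,
                    hotspot_bins = c(5L, 60L, 133L), hotspot_boost = 50)
  sim <- simulate_trio_genotypes(cfg, seed = 122)
  tab <- mendel_table(sim$matrix, sim$trios)
  expect_true(all(tab$n_errors > 0))
  groups <- setNames(sim$trios$group, sim$trios$offspring_id)
  errs <- dplyr::bind_rows(lapply(seq_len(nrow(sim$trios)), function(i) {
    s <- sim$matrix$geno[, sim$trios$sire_id[i]]
    d <- sim$matrix$geno[, sim$trios$dam_id[i]]
    o <- sim$matrix$geno[, sim$trios$offspring_id[i]]
    ok <- !is.na(s) & !is.na(d) & !is.na(o)
    bad <- ok
    bad[ok] <- !is_mendelian_consistent(s[ok], d[ok], o[ok])
    tibble::tibble(offspring_id = sim$trios$offspring_id[i],
                   contig = "1", pos = sim$matrix$sites$pos[bad] - 1L)
  }))
  scan <- window_error_scan(errs, groups)
  expect_setequal(scan$error_prone$bin_start / 10000, c(5, 60, 133))
  expect_setequal(scan$consistently_high$bin_start / 10000, c(5, 60, 133))
})

test_that("INFO simulation plants recoverable hard-filter failures", {
  cfg <- sim_config(n_sites = 3000L)
  sim <- simulate_trio_genotypes(cfg, seed = 123, with_info = TRUE)
  out <- hard_filter(sim$variants)
  planted <- sim$truth$planted_info_failures
  expect_true(all(!out$pass[planted$QD]))
  expect_true(all(grepl("QD", out$filter[planted$QD])))
  expect_true(all(!out$pass[planted$FS]))
  expect_true(all(!out$pass[planted$DP]))
  clean <- setdiff(seq_len(3000), unlist(planted))
  expect_true(all(out$pass[clean]))
})

test_that("the packaged trio-count fixture is intact and correctly shaped", {
  fx <- table1_fixture()
  expect_equal(nrow(fx$trios), 12)
  expect_equal(fx$denominator, 14084653L)
  first <- fx$trios[1, ]
  expect_equal(first$study_group, "GH.H")
  expect_equal(first$sire, "RCI002")
  expect_equal(first$dam, "RC.dam1")
  expect_equal(first$offspring, "RC.calf1")
  expect_equal(first$n_errors, 169672L)
  expect_equal(as.integer(table(fx$trios$study_group)[c("GH.H", "H.H", "Ho.H")]),
               c(6L, 3L, 3L))
})

test_that("FASTQ round-trips through the read tibble", {
  cfg <- sim_config(genome_length = 5000L, short_depth = 2)
  gen <- make_genomes(cfg, c(a = "pp"), seed = 124)
  sim <- simulate_short_reads(gen$animals$a, cfg, seed = 125)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_reads(sim$reads, path)
  back <- read_fastq_reads(path)
  expect_equal(nrow(back), nrow(sim$reads))
  expect_identical(sort(back$bases), sort(sim$reads$bases))
  expect_setequal(unique(back$mate), c(1L, 2L))
})
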