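test_that("bait index holds canonical k-mers with expected counts", {
  set.seed(30)
  bait <- random_dna(212)
  idx <- build_bait_index(bait, k = 25)
  expect_lte(length(idx$kmers), 188)   # 212 - 25 + 1 minus duplicates
  expect_gt(length(idx$kmers), 180)
  one <- build_bait_index(random_dna(25), k = 25)
  expect_length(one$kmers, 1)
  expect_error(build_bait_index(random_dna(20), k = 25), "shorter than k")
  # canonicalization: a bait and its reverse complement index identically
  idx_rc <- build_bait_index(revcomp(bait), k = 25)
  expect_setequal(idx$kmers, idx_rc$kmers)
})

test_that("baiting selects by shared k-mers with a hard 25-bp boundary", {
  set.seed(31)
  bait <- random_dna(212)
  idx <- build_bait_index(bait, k = 25)
  inside <- substr(bait, 30, 179)
  share24 <- paste0(substr(bait, 1, 24), random_dna(126))
  share25 <- paste0(substr(bait, 1, 25), random_dna(125))
  reads <- tibble::tibble(read_id = c("in", "s24", "s25"),
                          bases = c(inside, share24, share25))
  sel <- bait_reads(reads, idx)
  expect_setequal(sel$read_id, c("in", "s25"))
  # orientation-independent
  reads$bases <- revcomp(reads$bases)
  expect_setequal(bait_reads(reads, idx)$read_id, c("in", "s25"))
})

test_that("baiting over a tiled Celtic genome matches the overlap oracle", {
  fx <- make_test_locus(seed = 32)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  alt <- pc$sequence$bases
  ins <- substr(alt, 1013, 1224)     # homology-free: insertion = repeat copy
  idx <- build_bait_index(ins, k = 25)
  reads <- tile_reads(alt, 150L, stride = 7L)
  sel <- bait_reads(reads, idx)
  # oracle: >= 25 bp overlap with either repeat copy ([800,1012) or
  # [1012,1224)), from the tiling truth
  ov <- function(s, e, a, b) pmax(0, pmin(e, b) - pmax(s, a))
  expected <- reads$read_id[
    ov(reads$start, reads$start + 150, 800, 1012) >= 25 |
    ov(reads$start, reads$start + 150, 1012, 1224) >= 25]
  expect_setequal(sel$read_id, expected)
})

test_that("baiting sensitivity is monotone in the error rate", {
  fx <- make_test_locus(seed = 33, flank5 = 400, flank3 = 400)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  cfg0 <- sim_config(genome_length = 30000L)
  sens <- vapply(c(0, 0.001, 0.01), function(e) {
    cfge <- sim_config(genome_length = 30000L, short_error = e)
    gen <- make_genomes(cfge, c(a = "Pcp"), seed = 34)
    sim <- simulate_short_reads(gen$animals$a, cfge, seed = 35)
    idx <- build_bait_index(gen$truth$insertion_seq, k = 25)
    # truth: reads overlapping the insertion interval on hap1 by >= 25 bp
    ev <- diff_replacement(gen$truth$ref_window, gen$truth$alleles$Pc$sequence)
    ins_lo <- gen$truth$window$start + ev$pos
    ins_hi <- ins_lo + ev$ins_len
    org <- sim$origins
    truthy <- org$hap == "hap1" &
      pmin(org$end, ins_hi) - pmax(org$start, ins_lo) >= 25
    key <- paste(org$read_id, org$mate)
    sel_key <- paste(bait_reads(sim$reads, idx)$read_id,
                     bait_reads(sim$reads, idx)$mate)
    sum(key[truthy] %in% sel_key) / sum(truthy)
  }, numeric(1))
  expect_equal(sens[1], 1.0)   # error-free: perfect sensitivity
  expect_true(all(diff(sens) <= 1e-9))
})

test_that("read classes honor the three-class contract", {
  fx <- make_test_locus(seed = 36)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  alt <- pc$sequence$bases
  sig <- derive_junction_signatures(fx$wild, pc, 150L)
  # wholly within repeat copy 1 -> identical to reference -> class A
  # centered on copy1|copy2 junction (1012) -> split on ref -> class C
  # centered on copy2|suffix junction (1224) -> 10-bp deletion -> class B
  reads <- tibble::tibble(
    read_id = c("inA", "junC", "junB"),
    bases = c(substr(alt, 851, 1000), substr(alt, 938, 1087),
              substr(alt, 1150, 1299)))
  cls <- classify_reads(reads, fx$wild, alt, sig)
  expect_equal(cls$class[cls$read_id == "inA"],
               "CLASS_A_INTERNAL_OR_5P_PERFECT")
  expect_equal(cls$class[cls$read_id == "junC"],
               "CLASS_C_SPLIT_RESOLVED_ON_AMENDED")
  expect_equal(cls$class[cls$read_id == "junB"],
               "CLASS_B_3P_WITH_DELETION")
  # reverse-complemented reads get identical labels
  reads_rc <- dplyr::mutate(reads, bases = revcomp(bases))
  expect_identical(classify_reads(reads_rc, fx$wild, alt, sig)$class,
                   cls$class)
  expect_error(classify_reads(tibble::tibble(read_id = "e", bases = ""),
                              fx$wild, alt, sig), "empty read")
})

test_that("junction reads with heavy errors may go unexplained", {
  fx <- make_test_locus(seed = 37)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  sig <- derive_junction_signatures(fx$wild, pc, 150L)
  jun <- substr(pc$sequence$bases, 938, 1087)
  set.seed(38)
  pos <- sample(150, 18)             # 12% error, above the clean tolerance
  for (p in pos) substr(jun, p, p) <- sample(c("A", "C", "G", "T"), 1)
  cls <- classify_reads(tibble::tibble(read_id = "noisy", bases = jun),
                        fx$wild, pc$sequence, sig)
  expect_equal(cls$class, "UNEXPLAINED")
})

test_that("ectopic detection finds a planted copy and nothing else", {
  cfg <- sim_config(genome_length = 40000L)
  gen <- make_genomes(cfg, c(a = "Pcp"), seed = 39,
                      ectopic = list(animal = "a", pos = 9000L))
  sim <- simulate_short_reads(gen$animals$a, cfg, seed = 40)
  idx <- build_bait_index(gen$truth$insertion_seq, k = 25)
  baited <- bait_reads(sim$reads, idx)
  win <- list(contig = "chr1", start = gen$truth$window$start,
              end = gen$truth$window$end)
  calls <- detect_ectopic_insertions(baited, gen$reference, win)
  expect_equal(nrow(calls), 1)
  expect_equal(calls$contig, "decoy1")
  expect_lte(abs(calls$window_start - 9000), 150 + nrow(calls) * 0)
  # threshold dominance: an impossible support floor empties the calls
  expect_equal(nrow(detect_ectopic_insertions(baited, gen$reference, win,
                                              min_support = 10000L)), 0)
  expect_error(detect_ectopic_insertions(baited, gen$reference, NULL),
               "expected_window")
})

test_that("classification table round-trips as TSV", {
  tab <- tibble::tibble(read_id = "r1", class = "CLASS_A_INTERNAL_OR_5P_PERFECT",
                        orientation = "+", target = "reference",
                        t_start = 0L, cigar = "150M", score = 150)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_classification_tsv(tab, path)
  back <- read.delim(path)
  expect_equal(back$cigar, "150M")
})
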