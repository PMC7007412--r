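test_that("flankless edit duplicates the repeat exactly", {
  set.seed(10)
  R <- random_dna(212)
  substr(R, 1, 1) <- "A"
  wild <- paste0(R, "CTGGTATTCT")
  pc <- apply_celtic_edit(wild, celtic_edit_spec(0, 212))
  expect_equal(seq_len_bp(pc$sequence), 424)
  expect_identical(pc$sequence$bases, paste0(R, R))
  expect_identical(pc$features$label, c("repeat_copy1", "repeat_copy2"))
})

test_that("edit output equals the string-concatenation oracle", {
  fx <- make_test_locus(seed = 2, flank5 = 800, flank3 = 988)
  wild <- fx$wild
  pc <- apply_celtic_edit(wild, fx$spec)
  # independent oracle: wild = prefix + R + replaced + suffix
  prefix <- substr(wild, 1, 800)
  R <- substr(wild, 801, 1012)
  suffix <- substr(wild, 1023, nchar(wild))
  expect_identical(pc$sequence$bases, paste0(prefix, R, R, suffix))
  expect_equal(seq_len_bp(pc$sequence) - nchar(wild), 202)
})

test_that("length arithmetic holds for arbitrary valid specs", {
  set.seed(3)
  for (rep_len in c(50L, 212L, 301L)) {
    for (repl_len in c(4L, 10L)) {
      repl <- random_dna(repl_len)
      wild <- paste0(random_dna(200), random_dna(rep_len), repl,
                     random_dna(150))
      spec <- celtic_edit_spec(200, 200 + rep_len,
                               replaced_end = 200 + rep_len + repl_len,
                               replaced_seq = repl)
      pc <- apply_celtic_edit(wild, spec)
      expect_equal(seq_len_bp(pc$sequence) - nchar(wild), rep_len - repl_len)
    }
  }
})

test_that("edit-spec mismatch names the offending offset", {
  fx <- make_test_locus(seed = 4)
  bad <- fx$wild
  substr(bad, 1015, 1015) <- "A"   # corrupt the replaced segment
  expect_error(apply_celtic_edit(bad, fx$spec), "1012")
})

test_that("spec invariants are enforced at construction", {
  expect_error(celtic_edit_spec(800, 1012, replaced_start = 1015),
               "immediately 3'")
  expect_silent(celtic_edit_spec(800, 1012, replaced_start = 1015,
                                 require_adjacent = FALSE,
                                 replaced_seq = NULL))
})

test_that("diffing the edit recovers one replacement at spec coordinates", {
  fx <- make_test_locus(seed = 5)   # homology-free: exact coordinates
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  ev <- diff_replacement(fx$wild, pc$sequence)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$pos, 1012)
  expect_equal(ev$del_len, 10)
  expect_equal(ev$ins_len, 212)
  expect_identical(diff_replacement(fx$wild, fx$wild),
                   tibble::tibble(pos = integer(0), del_len = integer(0),
                                  ins_len = integer(0)))
})

test_that("plasmid allele length is additive and blocks annotated", {
  # wild 2212 bp -> Pc 2414 bp; + 3900 backbone + 1600 template = 7914
  fx <- make_test_locus(seed = 6, flank5 = 800, flank3 = 1190)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  expect_equal(seq_len_bp(pc$sequence), 2414)
  set.seed(7)
  bb <- nuc_sequence("bb", random_dna(3900))
  tpl <- nuc_sequence("tpl", random_dna(1600))
  star <- build_plasmid_allele(pc, plasmid_integration_spec(bb, tpl))
  expect_equal(seq_len_bp(star$sequence), 7914)
  f <- star$features
  expect_setequal(f$label, c("repeat_copy1", "repeat_copy2",
                             "plasmid_backbone", "hdr_copy"))
  # backbone block content is the backbone, forward by default
  expect_identical(substr(star$sequence$bases,
                          f$start[f$label == "plasmid_backbone"] + 1,
                          f$end[f$label == "plasmid_backbone"]),
                   bb$bases)
})

test_that("reverse orientation inserts the reverse complement backbone", {
  fx <- make_test_locus(seed = 8)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  set.seed(9)
  bb <- nuc_sequence("bb", random_dna(500))
  tpl <- nuc_sequence("tpl", random_dna(300))
  star <- build_plasmid_allele(
    pc, plasmid_integration_spec(bb, tpl, orientation = "reverse"))
  f <- star$features
  expect_identical(substr(star$sequence$bases,
                          f$start[f$label == "plasmid_backbone"] + 1,
                          f$end[f$label == "plasmid_backbone"]),
                   revcomp(bb$bases))
  expect_error(build_plasmid_allele(
    pc, plasmid_integration_spec(bb, tpl, insertion_offset = 10000L)),
    "bounds")
})

test_that("junction signatures: identity gives none, edit gives del + split", {
  fx <- make_test_locus(seed = 11)
  p <- wildtype_allele(fx$wild, fx$spec)
  expect_equal(nrow(derive_junction_signatures(fx$wild, p, 150L)), 0)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  sig <- derive_junction_signatures(fx$wild, pc, 150L)
  ref_sig <- sig[sig$target == "reference", ]
  expect_setequal(ref_sig$variant_op, c("split", "del"))
  # deletion length emerges from the sequences (10 bp, no micro-homology)
  expect_equal(ref_sig$variant_len[ref_sig$variant_op == "del"], 10)
  # amended target: spanning error-free reads are pure match
  amd_sig <- sig[sig$target == "amended_reference", ]
  expect_true(all(grepl("^150M$", amd_sig$pattern)))
})

test_that("tiled error-free reads match derived signatures or pure match", {
  # signature-completeness property over several random loci
  for (seed in 1:6) {
    fx <- make_test_locus(seed = 100 + seed, flank5 = 400, flank3 = 400)
    pc <- apply_celtic_edit(fx$wild, fx$spec)
    sig <- derive_junction_signatures(fx$wild, pc, 150L)
    reads <- tile_reads(pc$sequence$bases, 150L, stride = 25L)
    cls <- classify_reads(reads, fx$wild, pc$sequence, sig)
    expect_true(all(cls$class != "UNEXPLAINED"),
                label = sprintf("seed %d: all tiled reads explained", seed))
  }
})

test_that("feature BED export is 0-based half-open, six columns", {
  fx <- make_test_locus(seed = 12)
  pc <- apply_celtic_edit(fx$wild, fx$spec)
  path <- withr::local_tempfile(fileext = ".bed")
  write_features_bed(pc, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(ncol(bed), 6)
  expect_equal(bed$V2[bed$V4 == "repeat_copy1"], 800)
  expect_equal(bed$V3[bed$V4 == "repeat_copy2"], 1224)
})

test_that("nucleotide sequences are validated and FASTA round-trips", {
  expect_error(nuc_sequence("x", ""), "empty")
  expect_error(nuc_sequence("x", "ACGU"), "outside")
  s <- nuc_sequence("locus", strrep("ACGTN", 30))
  path <- withr::local_tempfile(fileext = ".fa")
  write_fasta_seqs(s, path)
  lines <- readLines(path)
  expect_true(all(nchar(lines[-1]) <= 60))   # wrapped at 60 columns
  back <- read_fasta_seqs(path)
  expect_identical(back[["locus"]]$bases, s$bases)
})
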