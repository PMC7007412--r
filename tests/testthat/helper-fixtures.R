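# Shared synthetic loci. The repeat's first/last bases are fixed to differ
# from the replaced segment's, so the edit event has no micro-homology and
# junction coordinates are exact.
make_test_locus <- function(seed = 1, flank5 = 800, flank3 = 988,
                            rep_len = 212, homology_free = TRUE) {
  set.seed(seed)
  R <- random_dna(rep_len)
  if (homology_free) {
    substr(R, 1, 1) <- "A"                       # replaced starts with C
    substr(R, rep_len, rep_len) <- "G"           # replaced ends with T
  }
  wild <- paste0(random_dna(flank5), R, "CTGGTATTCT", random_dna(flank3))
  list(wild = wild, R = R,
       spec = celtic_edit_spec(flank5, flank5 + rep_len))
}

# tile error-free reads across a sequence
tile_reads <- function(s, read_len = 150L, stride = 10L) {
  starts <- seq(1L, nchar(s) - read_len + 1L, by = stride)
  tibble::tibble(read_id = paste0("t", starts),
                 bases = substring(s, starts, starts + read_len - 1L),
                 start = starts - 1L)
}
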