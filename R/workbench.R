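# The three analysis tracks, tied together over simulated (or supplied)
# inputs, each returning a JSON-serializable run report.

.report_skeleton <- function(track, seed, cfg) {
  list(run_id = sprintf("%s-seed%d", track, seed),
       track = track, seed = seed,
       tool_version = as.character(utils::packageVersion("polledcheck")),
       config = cfg[setdiff(names(cfg), "class")])
}

.write_report <- function(report, out_dir) {
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(
      report, file.path(out_dir, paste0(report$run_id, ".json")),
      auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  }
  report
}

#' Run the insertion-integrity track
#'
#' Simulates a diploid animal (default heterozygous Celtic, `"Pcp"`) and
#' its short reads, then runs bait -> classify -> ectopic scan -> backbone
#' screen and, when `with_long_reads`, long-read allele assignment.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param genotype Locus genotype of the simulated animal (default
#'   `"Pcp"`).
#' @param ectopic Optional ectopic plant, see [make_genomes()].
#' @param with_long_reads Also simulate long reads and assign alleles
#'   (default FALSE).
#' @param out_dir Optional directory for the JSON report.
#' @return Run report list with per-class counts, ectopic calls, backbone
#'   screen verdict and (optionally) long-read support counts.
#' @export
run_integrity <- function(cfg = sim_config(), seed, genotype = "Pcp",
                          ectopic = NULL, with_long_reads = FALSE,
                          out_dir = NULL) {
  stopifnot(!missing(seed))
  gen <- make_genomes(cfg, genotypes = c(animal = genotype), seed = seed,
                      ectopic = ectopic)
  sim <- simulate_short_reads(gen$animals$animal, cfg, seed = seed + 1L)
  tr <- gen$truth
  idx <- build_bait_index(tr$insertion_seq, k = 25L)
  baited <- bait_reads(sim$reads, idx)
  amended <- if (genotype == "Pc*p") tr$alleles$Pc_star else tr$alleles$Pc
  sigs <- derive_junction_signatures(tr$ref_window, tr$alleles$Pc,
                                     read_len = cfg$read_len)
  # span check over every novel adjacency of the amended allele (feature
  # boundaries cover the integrated blocks of Pc*)
  junctions <- sort(unique(c(amended$features$start, amended$features$end)))
  classes <- classify_reads(baited, tr$ref_window, amended$sequence, sigs,
                            junctions = junctions)
  expected_window <- list(contig = tr$locus$contig,
                          start = tr$window$start, end = tr$window$end)
  ect <- detect_ectopic_insertions(baited, gen$reference, expected_window)
  screen <- screen_backbone(sim$reads,
                            backbone_only = tr$integration$backbone,
                            sample_id = "animal")
  report <- .report_skeleton("integrity", seed, unclass(cfg))
  report$class_counts <- as.list(table(classes$class))
  report$n_baited <- nrow(baited)
  report$ectopic_calls <- nrow(ect)
  report$ectopic <- ect[setdiff(names(ect), "read_ids")]
  report$backbone_screen <- as.list(screen)
  if (with_long_reads) {
    lr <- simulate_long_reads(gen$animals$animal, cfg, seed = seed + 2L)
    asg <- assign_long_reads(lr$reads, tr$alleles$Pc, tr$alleles$Pc_star)
    report$long_read_support <- setNames(as.list(asg$counts$n_support),
                                         asg$counts$allele)
  }
  report$classes <- classes
  report$baited <- baited
  .write_report(report, out_dir)
}

#' Run the trio-statistics track
#'
#' With `fixture_table1 = TRUE`, computes the published cohort's per-trio
#' rates, group ANOVA and summary from the packaged counts (no
#' simulation). Otherwise simulates trio genotypes, applies site filters,
#' counts Mendelian errors per trio, runs the group ANOVA and the windowed
#' hotspot scan.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed (ignored on the fixture path).
#' @param fixture_table1 Use the packaged printed counts (default FALSE).
#' @param out_dir Optional directory for the JSON report.
#' @return Run report list.
#' @export
run_trio_stats <- function(cfg = sim_config(), seed = 0L,
                           fixture_table1 = FALSE, out_dir = NULL) {
  report <- .report_skeleton("trio-stats", seed, unclass(cfg))
  if (fixture_table1) {
    rates <- table1_rates()
    an <- oneway_anova(tibble::tibble(value = rates$pct_per_variant,
                                      group = rates$study_group))
    report$source <- "packaged-counts"
    report$trio_rates <- rates
    report$mean_pct_per_variant <- mean(rates$pct_per_variant)
    report$sd_pct_per_variant <- sd(rates$pct_per_variant)
    report$anova <- list(F = an$F, p = an$p, df_between = an$df_between,
                         df_within = an$df_within)
    return(.write_report(report, out_dir))
  }
  sim <- simulate_trio_genotypes(cfg, seed = seed)
  filt <- site_filters(sim$matrix)
  tab <- mendel_table(filt$matrix, sim$trios)
  report$source <- "simulation"
  report$site_exclusions <- filt$exclusions
  report$trio_rates <- tab
  if (all(tab$n_errors == 0L)) {
    report$anova <- "skipped: no Mendelian errors observed"
  } else {
    an <- oneway_anova(tibble::tibble(value = tab$pct_per_variant,
                                      group = tab$group))
    report$anova <- list(F = an$F, p = an$p, df_between = an$df_between,
                         df_within = an$df_within)
  }
  errs <- .error_positions(filt$matrix, sim$trios)
  groups <- setNames(sim$trios$group, sim$trios$offspring_id)
  scan <- window_error_scan(errs, groups)
  report$n_error_prone_bins <- nrow(scan$error_prone)
  report$n_consistently_high_bins <- nrow(scan$consistently_high)
  report$window_scan <- scan
  .write_report(report, out_dir)
}

# per-offspring Mendelian-error positions (0-based) for the window scan
.error_positions <- function(gm, trios) {
  rows <- lapply(seq_len(nrow(trios)), function(i) {
    s <- gm$geno[, trios$sire_id[i]]
    d <- gm$geno[, trios$dam_id[i]]
    o <- gm$geno[, trios$offspring_id[i]]
    tested <- !is.na(s) & !is.na(d) & !is.na(o)
    bad <- tested
    bad[tested] <- !is_mendelian_consistent(s[tested], d[tested], o[tested])
    tibble::tibble(offspring_id = trios$offspring_id[i],
                   contig = gm$sites$contig[bad],
                   pos = gm$sites$pos[bad] - 1L)
  })
  dplyr::bind_rows(rows)
}

#' Run the relatedness track
#'
#' Simulates trio genotypes (or accepts a matrix), applies site filters,
#' VIF pruning (unless `prune = FALSE`), the 1-IBS distance, and builds a
#' dendrogram.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param gm Optional pre-built [genotype_matrix()] (skips simulation).
#' @param prune Run VIF pruning (default TRUE).
#' @param method Tree method, see [build_dendrogram()].
#' @param out_dir Optional directory for the JSON report.
#' @return Run report list including the Newick string and retention
#'   counts.
#' @export
run_relatedness <- function(cfg = sim_config(), seed = 0L, gm = NULL,
                            prune = TRUE, method = "average_linkage",
                            out_dir = NULL) {
  report <- .report_skeleton("relatedness", seed, unclass(cfg))
  if (is.null(gm)) {
    sim <- simulate_trio_genotypes(cfg, seed = seed)
    gm <- sim$matrix
  }
  if (length(gm$samples) < 2L) stop("need at least 2 samples")
  filt <- site_filters(gm)
  gmf <- filt$matrix
  report$n_sites_filtered <- nrow(gmf$geno)
  if (prune) {
    kept <- vif_prune(gmf)
    gmf <- genotype_matrix(gmf$sites[kept, , drop = FALSE], gmf$samples,
                           gmf$geno[kept, , drop = FALSE])
  }
  report$n_sites_retained <- nrow(gmf$geno)
  D <- ibs_distance(gmf)
  tree <- build_dendrogram(D, method = method)
  report$newick <- ape::write.tree(tree)
  report$distances <- ibs_tibble(D)
  report$tree <- tree
  .write_report(report, out_dir)
}
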