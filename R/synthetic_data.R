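# Synthetic-data generation with full ground truth.
#
# The generator emulates the study's structure: a locus carrying a 212-bp
# repeat followed by the 10-bp segment CTGGTATTCT, edited by duplicating
# the repeat in place of the 10-mer; optional adjacent integration of a
# ~3.9-kb plasmid backbone plus a second HDR-template copy; ~20x 2x150-bp
# paired reads and noisy ~10-kb long reads at 14x; and 12 sire/dam/offspring
# trios in three study groups (6/3/3) genotyped at biallelic sites with a
# controllable genotyping-error rate and plantable error hotspots.
# Repeat and backbone sequences are random by default (substitute real
# sequences via the `repeat_seq` / `backbone_seq` hooks).

#' Simulation configuration
#'
#' Defaults mirror the study conditions: 212-bp repeat + CTGGTATTCT edit,
#' 3.9-kb backbone and 1.6-kb HDR template, 20x 2x150 bp short reads
#' (insert 400 +/- 60), 14x long reads of mean 10 kb at 10% error, and a
#' 12-trio 6/3/3 design with a 99.8% genotyping rate.
#'
#' @param genome_length Main contig length in bp.
#' @param locus_start 0-based start of the repeat within the main contig
#'   (default: centered).
#' @param repeat_len,replaced_seq Edit geometry (defaults 212 bp and
#'   `"CTGGTATTCT"`).
#' @param backbone_len,hdr_template_len Plasmid block lengths.
#' @param short_depth,read_len,insert_mean,insert_sd,short_error Short-read
#'   parameters.
#' @param long_depth,long_mean_len,long_error Long-read parameters.
#' @param n_sites,site_spacing,freq_min,freq_max,eps,missing_rate Trio
#'   genotype parameters (`eps` = genotyping error probability).
#' @param hotspot_bins Integer vector of 10-kb bin indices with boosted
#'   error rate; `hotspot_boost` multiplies `eps` there.
#' @param hotspot_boost Multiplier for `eps` inside hotspot bins.
#' @param family_fst Balding-Nichols differentiation between families
#'   (default 0 = all parents drawn from one population; ~0.1-0.2 emulates
#'   breed-level structure).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(genome_length = 100000L, locus_start = NULL,
                       repeat_len = 212L, replaced_seq = "CTGGTATTCT",
                       backbone_len = 3900L, hdr_template_len = 1600L,
                       short_depth = 20, read_len = 150L, insert_mean = 400,
                       insert_sd = 60, short_error = 0,
                       long_depth = 14, long_mean_len = 10000L,
                       long_error = 0.10,
                       n_sites = 20000L, site_spacing = 100L,
                       freq_min = 0.05, freq_max = 0.95, eps = 0.005,
                       missing_rate = 0.002, hotspot_bins = integer(0),
                       hotspot_boost = 50, family_fst = 0) {
  cfg <- as.list(environment())
  stopifnot(cfg$short_error >= 0, cfg$short_error <= 1,
            cfg$long_error >= 0, cfg$long_error <= 1,
            cfg$eps >= 0, cfg$eps <= 1, cfg$missing_rate >= 0,
            cfg$missing_rate <= 1, cfg$short_depth > 0, cfg$long_depth > 0)
  structure(cfg, class = "sim_config")
}

# replace a window of a contig string
.splice <- function(s, start, end, replacement) {
  paste0(substr(s, 1L, start), replacement, substr(s, end + 1L, nchar(s)))
}

#' Generate reference and per-animal diploid genomes
#'
#' Builds a reference genome containing the wild-type locus, derives the
#' three allele models, and assembles diploid haplotypes for the requested
#' animals. Genotypes are `"pp"`, `"Pcp"`, `"Pc*p"` or `"PcPc"`. An ectopic
#' copy of the insertion sequence can be planted on a decoy contig of one
#' animal to exercise the ectopic-insertion detector.
#'
#' @param cfg A [sim_config()].
#' @param genotypes Named character vector, animal id -> genotype.
#' @param seed Integer seed (mandatory; the generator is deterministic
#'   given `(seed, cfg)`).
#' @param flank Flank width of the extracted locus window (default 2000).
#' @param ectopic Optional list `(animal, pos)`: plant a copy of the
#'   insertion sequence at `pos` on a decoy contig of that animal's first
#'   haplotype.
#' @param decoy_length Decoy contig length (created when `ectopic` is set).
#' @param repeat_seq,backbone_seq Optional real sequences to use instead of
#'   random ones.
#' @return List with `reference` (named character vector of contigs),
#'   `animals` (named list of `list(hap1, hap2)` contig vectors), and
#'   `truth` (locus coordinates, edit spec, allele models, locus windows,
#'   insertion sequence, ectopic plant).
#' @export
make_genomes <- function(cfg, genotypes, seed, flank = 2000L,
                         ectopic = NULL, decoy_length = 30000L,
                         repeat_seq = NULL, backbone_seq = NULL) {
  stopifnot(inherits(cfg, "sim_config"), !missing(seed))
  set.seed(seed)
  L <- cfg$genome_length
  rep_len <- if (is.null(repeat_seq)) cfg$repeat_len else nchar(repeat_seq)
  locus_start <- if (is.null(cfg$locus_start)) {
    as.integer(L / 2 - rep_len / 2)
  } else cfg$locus_start
  locus_len <- rep_len + nchar(cfg$replaced_seq)
  if (locus_start + locus_len + flank > L || locus_start < flank) {
    stop("locus does not fit in the genome with the requested flank")
  }
  R <- if (is.null(repeat_seq)) random_dna(rep_len) else seq_chr(repeat_seq)
  chr1 <- random_dna(L)
  chr1 <- .splice(chr1, locus_start, locus_start + locus_len,
                  paste0(R, cfg$replaced_seq))

  # locus window and allele models (window coordinates)
  ws <- locus_start - flank
  we <- locus_start + locus_len + flank
  ref_window <- nuc_sequence("locus_window", substr(chr1, ws + 1L, we))
  spec_w <- celtic_edit_spec(repeat_start = flank,
                             repeat_end = flank + rep_len,
                             replaced_seq = cfg$replaced_seq)
  p_allele <- wildtype_allele(ref_window, spec_w)
  pc_allele <- apply_celtic_edit(ref_window, spec_w)
  backbone <- nuc_sequence("backbone",
                           if (is.null(backbone_seq)) random_dna(cfg$backbone_len)
                           else seq_chr(backbone_seq))
  # HDR template: the edited locus sequence centered on the duplication
  tpl_half <- cfg$hdr_template_len %/% 2L
  tpl_mid <- flank + rep_len   # junction between the two repeat copies
  tpl <- nuc_sequence("hdr_template",
                      substr(seq_chr(pc_allele$sequence),
                             tpl_mid - tpl_half + 1L,
                             tpl_mid - tpl_half + cfg$hdr_template_len))
  integ <- plasmid_integration_spec(backbone, tpl)
  pcstar_allele <- build_plasmid_allele(pc_allele, integ)

  hap_for <- function(allele_name) {
    if (allele_name == "p") return(chr1)
    win <- if (allele_name == "Pc") pc_allele else pcstar_allele
    .splice(chr1, ws, we, seq_chr(win$sequence))
  }
  hap_pair <- list("pp" = c("p", "p"), "Pcp" = c("Pc", "p"),
                   "Pc*p" = c("Pc_star", "p"), "PcPc" = c("Pc", "Pc"))
  reference <- c(chr1 = chr1)
  ins_seq <- {
    ev <- diff_replacement(ref_window, pc_allele$sequence)
    substr(seq_chr(pc_allele$sequence), ev$pos + 1L, ev$pos + ev$ins_len)
  }
  need_decoy <- !is.null(ectopic)
  if (need_decoy) reference <- c(reference, decoy1 = random_dna(decoy_length))

  animals <- lapply(names(genotypes), function(a) {
    gt <- genotypes[[a]]
    if (!gt %in% names(hap_pair)) stop("unknown genotype '", gt, "' for ", a)
    alleles <- hap_pair[[gt]]
    haps <- lapply(alleles, function(al) {
      ctgs <- c(chr1 = hap_for(al))
      if (need_decoy) ctgs <- c(ctgs, decoy1 = reference[["decoy1"]])
      ctgs
    })
    names(haps) <- c("hap1", "hap2")
    haps
  })
  names(animals) <- names(genotypes)
  if (need_decoy) {
    a <- ectopic$animal
    pos <- ectopic$pos
    animals[[a]]$hap1[["decoy1"]] <-
      .splice(animals[[a]]$hap1[["decoy1"]], pos, pos, ins_seq)
  }
  list(reference = reference, animals = animals,
       truth = list(
         locus = list(contig = "chr1", start = locus_start,
                      end = locus_start + locus_len),
         window = list(start = ws, end = we),
         edit_spec = spec_w,
         ref_window = ref_window,
         alleles = list(p = p_allele, Pc = pc_allele, Pc_star = pcstar_allele),
         integration = integ,
         insertion_seq = ins_seq,
         genotypes = genotypes,
         ectopic = if (need_decoy) ectopic else NULL,
         seed = seed))
}

# inject symmetric substitution errors into a character vector of reads;
# returns the mutated vector
.add_substitutions <- function(bases, error_rate) {
  if (error_rate <= 0) return(bases)
  lens <- nchar(bases)
  total <- sum(lens)
  n_err <- rbinom(1L, total, error_rate)
  if (n_err == 0L) return(bases)
  rd <- sample.int(length(bases), n_err, replace = TRUE, prob = lens)
  off <- ceiling(runif(n_err) * lens[rd])
  alt <- c("A", "C", "G", "T")
  for (i in seq_len(n_err)) {
    cur <- substr(bases[rd[i]], off[i], off[i])
    sub <- sample(setdiff(alt, cur), 1L)
    substr(bases[rd[i]], off[i], off[i]) <- sub
  }
  bases
}

#' Simulate paired-end short reads from a diploid genome
#'
#' Uniform fragment starts, normal insert sizes, symmetric substitution
#' errors. Reads are emitted in FR orientation (mate 1 forward, mate 2
#' reverse complement of the fragment end).
#'
#' @param haplotypes List `(hap1, hap2)` of named contig vectors (one
#'   animal from [make_genomes()]), or a single named contig vector.
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param prefix Read-id prefix.
#' @return List with `reads` (tibble: `read_id`, `bases`, `mate`,
#'   `platform`) and `origins` (tibble: `read_id`, `mate`, `hap`, `contig`,
#'   `start`, `end`, `strand`; 0-based half-open on the source haplotype).
#' @export
simulate_short_reads <- function(haplotypes, cfg, seed, prefix = "sr") {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (!is.list(haplotypes)) haplotypes <- list(hap1 = haplotypes)
  rl <- cfg$read_len
  units <- dplyr::bind_rows(lapply(names(haplotypes), function(h) {
    tibble::tibble(hap = h, contig = names(haplotypes[[h]]),
                   len = nchar(unname(haplotypes[[h]])))
  }))
  total_len <- sum(units$len)
  n_pairs <- round(total_len * cfg$short_depth / (2 * rl))
  if (n_pairs == 0L) {
    warning("depth too low for any read pair")
    return(list(reads = tibble::tibble(read_id = character(0),
                                       bases = character(0), mate = integer(0),
                                       platform = character(0)),
                origins = tibble::tibble()))
  }
  u <- sample.int(nrow(units), n_pairs, replace = TRUE, prob = units$len)
  ins <- pmax(rl, round(rnorm(n_pairs, cfg$insert_mean, cfg$insert_sd)))
  ins <- pmin(ins, units$len[u])
  start <- floor(runif(n_pairs) * (units$len[u] - ins + 1))  # 0-based
  frag <- character(n_pairs)
  for (k in seq_len(nrow(units))) {
    sel <- which(u == k)
    if (length(sel) == 0L) next
    s <- haplotypes[[units$hap[k]]][[units$contig[k]]]
    frag[sel] <- substring(s, start[sel] + 1L, start[sel] + ins[sel])
  }
  r1 <- substr(frag, 1L, rl)
  r2 <- revcomp(substring(frag, ins - rl + 1L, ins))
  r1 <- .add_substitutions(r1, cfg$short_error)
  r2 <- .add_substitutions(r2, cfg$short_error)
  ids <- sprintf("%s%06d", prefix, seq_len(n_pairs))
  reads <- tibble::tibble(
    read_id = rep(ids, 2L), bases = c(r1, r2),
    mate = rep(c(1L, 2L), each = n_pairs), platform = "short")
  o_start <- c(start, start + ins - rl)
  o_end <- c(start + rl, start + ins)
  origins <- tibble::tibble(
    read_id = rep(ids, 2L), mate = rep(c(1L, 2L), each = n_pairs),
    hap = rep(units$hap[u], 2L), contig = rep(units$contig[u], 2L),
    start = o_start, end = o_end,
    strand = rep(c("+", "-"), each = n_pairs))
  list(reads = reads, origins = origins)
}

# substitution + indel errors for one read; returns mutated string
.add_long_errors <- function(s, error_rate) {
  L <- nchar(s)
  n_err <- rbinom(1L, L, error_rate)
  if (n_err == 0L) return(s)
  pos <- sample.int(L, min(n_err, L))
  type <- sample(c("sub", "ins", "del"), length(pos), replace = TRUE,
                 prob = c(0.6, 0.2, 0.2))
  v <- strsplit(s, "")[[1]]
  alt <- c("A", "C", "G", "T")
  for (i in seq_along(pos)) {
    p <- pos[i]
    if (type[i] == "sub") {
      v[p] <- sample(setdiff(alt, v[p]), 1L)
    } else if (type[i] == "ins") {
      v[p] <- paste0(v[p], sample(alt, 1L))
    } else {
      v[p] <- ""
    }
  }
  paste(v, collapse = "")
}

#' Simulate noisy long reads from a diploid genome
#'
#' Log-normal read lengths, substitution + indel errors (60/20/20 split),
#' random strand.
#'
#' @inheritParams simulate_short_reads
#' @param min_len Minimum read length (default 500).
#' @return List with `reads` and `origins` tibbles as for
#'   [simulate_short_reads()] (`mate` is `NA`).
#' @export
simulate_long_reads <- function(haplotypes, cfg, seed, prefix = "lr",
                                min_len = 500L) {
  stopifnot(!missing(seed))
  set.seed(seed)
  if (!is.list(haplotypes)) haplotypes <- list(hap1 = haplotypes)
  units <- dplyr::bind_rows(lapply(names(haplotypes), function(h) {
    tibble::tibble(hap = h, contig = names(haplotypes[[h]]),
                   len = nchar(unname(haplotypes[[h]])))
  }))
  total_len <- sum(units$len)
  n_reads <- max(1L, round(total_len * cfg$long_depth / cfg$long_mean_len))
  sdlog <- 0.25
  lens <- round(rlnorm(n_reads, log(cfg$long_mean_len) - sdlog^2 / 2, sdlog))
  u <- sample.int(nrow(units), n_reads, replace = TRUE, prob = units$len)
  lens <- pmax(min_len, pmin(lens, units$len[u]))
  start <- floor(runif(n_reads) * (units$len[u] - lens + 1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  bases <- character(n_reads)
  for (k in seq_len(nrow(units))) {
    sel <- which(u == k)
    if (length(sel) == 0L) next
    s <- haplotypes[[units$hap[k]]][[units$contig[k]]]
    bases[sel] <- substring(s, start[sel] + 1L, start[sel] + lens[sel])
  }
  neg <- strand == "-"
  if (any(neg)) bases[neg] <- revcomp(bases[neg])
  bases <- vapply(bases, .add_long_errors, character(1),
                  error_rate = cfg$long_error, USE.NAMES = FALSE)
  ids <- sprintf("%s%05d", prefix, seq_len(n_reads))
  list(reads = tibble::tibble(read_id = ids, bases = bases,
                              mate = NA_integer_, platform = "long"),
       origins = tibble::tibble(read_id = ids, mate = NA_integer_,
                                hap = units$hap[u], contig = units$contig[u],
                                start = start, end = start + lens,
                                strand = strand))
}

#' Default 12-trio study design (three groups, 6/3/3)
#'
#' Group 1 is one sire with six dams (family 1); group 2 is two sires over
#' three dams (families 2 and 3); group 3 is one sire with three dams
#' (family 4) -- mirroring the study's four-family design.
#'
#' @return Trio tibble as from [trio_spec()].
#' @export
default_trio_design <- function() {
  dplyr::bind_rows(
    trio_spec("g1.sire1", paste0("g1.dam", 1:6), paste0("g1.calf", 1:6),
              family = 1L, group = "GH.H"),
    trio_spec("g2.sire1", "g2.dam1", "g2.calf1", family = 2L, group = "H.H"),
    trio_spec("g2.sire2", paste0("g2.dam", 2:3), paste0("g2.calf", 2:3),
              family = 3L, group = "H.H"),
    trio_spec("g3.sire1", paste0("g3.dam", 1:3), paste0("g3.calf", 1:3),
              family = 4L, group = "Ho.H"))
}

# apply the symmetric single-step genotyping-error model entrywise;
# eps may be a per-site vector (recycled across samples)
.apply_genotype_errors <- function(G, eps) {
  n <- nrow(G); m <- ncol(G)
  E <- matrix(eps, n, m)
  U <- matrix(runif(n * m), n, m)
  out <- G
  # genotype 1: down with prob eps, up with prob eps
  h <- G == 1L
  out[h & U < E] <- 0L
  out[h & U >= E & U < 2 * E] <- 2L
  # genotype 0: up one with prob eps, two with prob eps^2
  z <- G == 0L
  out[z & U < E] <- 1L
  out[z & U >= E & U < E + E^2] <- 2L
  # genotype 2: symmetric
  t2 <- G == 2L
  out[t2 & U < E] <- 1L
  out[t2 & U >= E & U < E + E^2] <- 0L
  out
}

#' Simulate trio genotype matrices with ground truth
#'
#' Parents are drawn from Hardy-Weinberg equilibrium at site-specific
#' allele frequencies; offspring receive one allele from each parent;
#' genotyping errors follow the symmetric single-step model at rate `eps`
#' (multiplied by `hotspot_boost` inside planted hotspot bins); genotypes
#' are then set missing at `missing_rate`. Optionally draws VCF-style INFO
#' annotations exercising every hard-filter rule.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed.
#' @param trios Trio design tibble (default [default_trio_design()]).
#' @param with_info Also generate INFO annotations with planted hard-filter
#'   failures (default FALSE).
#' @param info_fail_frac Fraction of sites failing each rule when
#'   `with_info` (default 0.01).
#' @return List with `matrix` (a [genotype_matrix()]), `trios`, and `truth`
#'   (true pre-error genotypes, allele frequencies, hotspot bins, per-site
#'   error rates, planted INFO failures when requested), plus `variants`
#'   when `with_info`.
#' @export
simulate_trio_genotypes <- function(cfg, seed, trios = default_trio_design(),
                                    with_info = FALSE,
                                    info_fail_frac = 0.01) {
  stopifnot(inherits(cfg, "sim_config"), !missing(seed))
  if (cfg$n_sites < 1L) stop("n_sites must be at least 1")
  set.seed(seed)
  n <- cfg$n_sites
  samples <- unique(c(trios$sire_id, trios$dam_id, trios$offspring_id))
  f <- runif(n, cfg$freq_min, cfg$freq_max)
  pos <- (seq_len(n) - 1L) * cfg$site_spacing  # 0-based
  G <- matrix(NA_integer_, n, length(samples),
              dimnames = list(NULL, samples))
  # Balding-Nichols family-level frequencies when family_fst > 0
  fam_of <- c(setNames(trios$family, trios$sire_id),
              setNames(trios$family, trios$dam_id))
  fam_freq <- list()
  if (cfg$family_fst > 0) {
    lambda <- (1 - cfg$family_fst) / cfg$family_fst
    for (k in unique(trios$family)) {
      fam_freq[[as.character(k)]] <- rbeta(n, f * lambda, (1 - f) * lambda)
    }
  }
  parents <- unique(c(trios$sire_id, trios$dam_id))
  for (p in parents) {
    fp <- if (cfg$family_fst > 0) fam_freq[[as.character(fam_of[[p]])]] else f
    G[, p] <- rbinom(n, 2L, fp)
  }
  for (i in seq_len(nrow(trios))) {
    s <- G[, trios$sire_id[i]]; d <- G[, trios$dam_id[i]]
    G[, trios$offspring_id[i]] <- rbinom(n, 1L, s / 2) + rbinom(n, 1L, d / 2)
  }
  eps_site <- rep(cfg$eps, n)
  if (length(cfg$hotspot_bins) > 0L) {
    bin <- pos %/% 10000L
    eps_site[bin %in% cfg$hotspot_bins] <-
      pmin(0.4, cfg$eps * cfg$hotspot_boost)
  }
  Gobs <- .apply_genotype_errors(G, eps_site)
  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(length(Gobs)) < cfg$missing_rate,
                   nrow(Gobs), ncol(Gobs))
    Gobs[drop] <- NA_integer_
  }
  sites <- tibble::tibble(contig = "1", pos = pos + 1L,
                          ref = "A", alt = "G")
  gm <- genotype_matrix(sites, samples, Gobs)
  truth <- list(true_genotypes = G, freqs = f, eps_site = eps_site,
                hotspot_bins = cfg$hotspot_bins, seed = seed)
  out <- list(matrix = gm, trios = trios, truth = truth)
  if (with_info) {
    v <- tibble::tibble(
      contig = "1", pos = pos + 1L, ref = "A", alt = "G",
      QD = runif(n, 5, 35), FS = runif(n, 0, 10), SOR = runif(n, 0.3, 2),
      ReadPosRankSum = rnorm(n, 0, 1.5),
      DP = round(rnorm(n, 2000, 200)),
      MQ = runif(n, 50, 60), MQRankSum = rnorm(n, 0, 1),
      InbreedingCoeff = runif(n, -0.2, 0.2))
    planted <- list(
      QD = sample.int(n, max(1L, round(info_fail_frac * n))),
      FS = sample.int(n, max(1L, round(info_fail_frac * n))),
      DP = sample.int(n, max(1L, round(info_fail_frac * n))))
    v$QD[planted$QD] <- runif(length(planted$QD), 0, 1.9)
    v$FS[planted$FS] <- runif(length(planted$FS), 60.1, 200)
    v$DP[planted$DP] <- round(runif(length(planted$DP), 3106, 9000))
    out$variants <- v
    out$truth$planted_info_failures <- planted
  }
  out
}
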