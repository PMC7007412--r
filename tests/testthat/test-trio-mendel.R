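test_that("exactly 12 of 27 trio combinations are Mendelian errors", {
  combos <- expand.grid(s = 0:2, d = 0:2, o = 0:2)
  got <- is_mendelian_consistent(combos$s, combos$d, combos$o)
  # independent gamete-enumeration oracle
  gametes <- list(`0` = 0L, `1` = c(0L, 1L), `2` = 1L)
  oracle <- vapply(seq_len(nrow(combos)), function(i) {
    offs <- outer(gametes[[combos$s[i] + 1]], gametes[[combos$d[i] + 1]], `+`)
    combos$o[i] %in% offs
  }, logical(1))
  expect_identical(got, oracle)
  expect_equal(sum(!got), 12)
  expect_error(is_mendelian_consistent(3, 0, 0), "0, 1, 2")
})

sim_small_gm <- function(geno) {
  genotype_matrix(tibble::tibble(contig = "1", pos = seq_len(nrow(geno)),
                                 ref = "A", alt = "G"),
                  c("sire", "dam", "kid"), geno)
}

test_that("trio error counting skips missing sites and plants are recovered", {
  set.seed(80)
  n <- 500
  s <- rbinom(n, 2, 0.5); d <- rbinom(n, 2, 0.5)
  o <- rbinom(n, 1, s / 2) + rbinom(n, 1, d / 2)
  planted <- sample(which(s == 0 & d == 0), 7)
  o[planted] <- 2L                    # impossible transmissions
  miss <- sample(setdiff(seq_len(n), planted), 20)
  o[miss] <- NA
  gm <- sim_small_gm(cbind(sire = s, dam = d, kid = o))
  trio <- trio_spec("sire", "dam", "kid", 1L, "G")
  res <- count_trio_errors(gm, trio)
  expect_equal(res$n_errors, 7L)
  expect_equal(res$n_sites_tested, n - 20L)
  expect_equal(res$pct_per_individual, res$pct_per_variant / 3)
  # swap sire/dam: counting is symmetric in the parents
  swapped <- count_trio_errors(gm, trio_spec("dam", "sire", "kid", 1L, "G"))
  expect_equal(swapped$n_errors, res$n_errors)
  # site order invariance
  perm <- sample(n)
  gm2 <- genotype_matrix(gm$sites[perm, ], gm$samples, gm$geno[perm, ])
  expect_equal(count_trio_errors(gm2, trio)$n_errors, res$n_errors)
  expect_error(count_trio_errors(gm, trio_spec("sire", "dam", "ghost", 1L, "G")),
               "ghost")
})

test_that("a fixed denominator reproduces the published rate arithmetic", {
  g <- cbind(sire = c(0L, 0L), dam = c(0L, 0L), kid = c(2L, 0L))
  gm <- sim_small_gm(g)
  res <- count_trio_errors(gm, trio_spec("sire", "dam", "kid", 1L, "G"),
                           fixed_denominator = 14084653)
  expect_equal(res$n_errors, 1L)
  # the published first-trio count against the same denominator
  expect_equal(round(100 * 169672 / 14084653, 1), 1.2)
  expect_equal(round(100 * 169672 / 14084653 / 3, 1), 0.4)
  # all-missing offspring: no tested sites, rates undefined
  g2 <- cbind(sire = c(0L, 1L), dam = c(0L, 1L), kid = c(NA, NA))
  res2 <- count_trio_errors(sim_small_gm(g2),
                            trio_spec("sire", "dam", "kid", 1L, "G"))
  expect_equal(res2$n_sites_tested, 0L)
  expect_true(is.na(res2$pct_per_variant))
})

test_that("one-way ANOVA matches the textbook formula to 1e-10", {
  set.seed(81)
  vals <- tibble::tibble(value = rnorm(30),
                         group = rep(c("a", "b", "c"), each = 10))
  an <- oneway_anova(vals)
  # independent direct-formula evaluation
  gm <- tapply(vals$value, vals$group, mean)
  grand <- mean(vals$value)
  ssb <- sum(table(vals$group) * (gm - grand)^2)
  ssw <- sum((vals$value - gm[vals$group])^2)
  f_oracle <- (ssb / 2) / (ssw / 27)
  expect_equal(an$F, f_oracle, tolerance = 1e-10)
  expect_equal(an$p, pf(f_oracle, 2, 27, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(an$df_between, 2)
  # identical group means with spread: F = 0
  v0 <- tibble::tibble(value = c(1, 3, 1, 3, 1, 3),
                       group = rep(c("a", "b", "c"), each = 2))
  expect_equal(oneway_anova(v0)$F, 0)
  expect_error(oneway_anova(tibble::tibble(value = 1:3, group = "a")),
               "2 groups")
  # named-list input and Tukey post-hoc
  an2 <- oneway_anova(list(a = c(1, 2), b = c(4, 5), c = c(9, 10)),
                      posthoc = TRUE)
  expect_s3_class(an2$tukey, "TukeyHSD")
  expect_s3_class(tidy(an2), "tbl_df")
  expect_equal(glance(an2)$statistic, an2$F)
})

test_that("window scan applies the <= 10 exclusion and hotspot flags", {
  # bin 0: 10 errors total -> excluded; bin 3: 11 -> error-prone
  errs <- tibble::tibble(
    offspring_id = c(rep("k1", 10), rep(c("k1", "k2", "k3"), c(5, 3, 3))),
    contig = "1",
    pos = c(seq(100, 1000, by = 100), rep(30500, 11)))
  groups <- c(k1 = "g1", k2 = "g2", k3 = "g3")
  scan <- window_error_scan(errs, groups)
  expect_equal(scan$error_prone$bin_start, 30000)
  expect_equal(scan$error_prone$total_errors, 11L)
  # consistently high needs > 1/kb (i.e. >= 11 errors) in EVERY group
  expect_equal(nrow(scan$consistently_high), 0)
  errs2 <- tibble::tibble(
    offspring_id = rep(c("k1", "k2", "k3"), each = 12),
    contig = "1", pos = rep(45000, 36))
  scan2 <- window_error_scan(errs2, groups)
  expect_equal(scan2$consistently_high$bin_start, 40000)
  # no errors anywhere: nothing flagged
  empty <- window_error_scan(errs[0, ], groups)
  expect_equal(nrow(empty$error_prone), 0)
  expect_error(window_error_scan(errs, groups, window = 0), "positive")
})

test_that("analytic expected error rate agrees with Monte Carlo", {
  expect_equal(expected_error_rate(0), 0)
  # monotone increasing in eps
  grid <- vapply(c(0, 0.01, 0.05, 0.1), expected_error_rate, numeric(1))
  expect_true(all(diff(grid) > 0))
  # Monte-Carlo oracle at eps = 0.005, f ~ U(0.05, 0.95)
  eps <- 0.005
  analytic <- expected_error_rate(eps)
  set.seed(82)
  n <- 4e5
  f <- runif(n, 0.05, 0.95)
  s <- rbinom(n, 2, f); d <- rbinom(n, 2, f)
  o <- rbinom(n, 1, s / 2) + rbinom(n, 1, d / 2)
  jitter1 <- function(g) {
    u <- runif(n)
    out <- g
    out[g == 1 & u < eps] <- 0L
    out[g == 1 & u >= eps & u < 2 * eps] <- 2L
    out[g == 0 & u < eps] <- 1L
    out[g == 0 & u >= eps & u < eps + eps^2] <- 2L
    out[g == 2 & u < eps] <- 1L
    out[g == 2 & u >= eps & u < eps + eps^2] <- 0L
    out
  }
  mc <- mean(!is_mendelian_consistent(jitter1(s), jitter1(d), jitter1(o)))
  se <- sqrt(analytic * (1 - analytic) / n)
  expect_lt(abs(mc - analytic), 3 * se)
  expect_error(expected_error_rate(0.005, freq_dist = list(type = "what")),
               "invalid")
})

test_that("pedigree and Mendel tables round-trip as TSV", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("offspring\tsire\tdam\tfamily\tgroup",
               "kid\tsire\tdam\t1\tGH.H"), path)
  ped <- read_pedigree_tsv(path)
  expect_equal(ped$offspring_id, "kid")
  out <- withr::local_tempfile(fileext = ".tsv")
  write_mendel_tsv(tibble::tibble(a = 1), out)
  expect_true(file.exists(out))
})
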