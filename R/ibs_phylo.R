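# Relatedness from genotypes: VIF-based LD pruning, 1-IBS distance, and
# dendrogram construction with Newick export.

#' VIF-based LD pruning
#'
#' Slides a window of `window` SNPs in steps of `step` SNPs. Within each
#' window the SNP with the highest variance inflation factor
#' (VIF = 1/(1-R^2) from regressing it on the other retained SNPs in the
#' window) is removed, recursively, until all VIFs are at most
#' `vif_threshold`. A site removed in any window stays removed. Sites with
#' zero variance within a window are left out of that window's regression.
#' Ties on VIF remove the later site.
#'
#' @param gm A [genotype_matrix()] (pre-filtered for genotyping rate and
#'   MAF).
#' @param window Window size in SNPs (default 50).
#' @param step Window step in SNPs (default 5).
#' @param vif_threshold Maximum allowed VIF (default 2.0).
#' @return Integer vector of retained site indices.
#' @export
vif_prune <- function(gm, window = 50L, step = 5L, vif_threshold = 2.0) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (window < 2L) stop("window must be at least 2 SNPs")
  n <- nrow(gm$geno)
  retained <- rep(TRUE, n)
  starts <- seq(1L, max(1L, n - 1L), by = step)
  for (ws in starts) {
    we <- min(n, ws + window - 1L)
    repeat {
      idx <- which(retained[ws:we]) + ws - 1L
      if (length(idx) < 2L) break
      vifs <- window_vifs(gm$geno[idx, , drop = FALSE])
      worst <- max(vifs, na.rm = TRUE)
      if (is.na(worst) || worst <= vif_threshold) break
      # ties broken toward the later site
      drop_local <- max(which(vifs == worst))
      retained[idx[drop_local]] <- FALSE
    }
    if (we >= n) break
  }
  which(retained)
}

#' Variance inflation factors of SNPs within one window
#'
#' @param geno Sites-by-samples genotype matrix (the window's sites).
#' @return Numeric vector of VIFs (NA for sites with zero variance, which
#'   are excluded from the regression).
#' @export
window_vifs <- function(geno) {
  X <- t(geno)                     # samples x sites
  X[is.na(X)] <- matrix(colMeans(X, na.rm = TRUE),
                        nrow(X), ncol(X), byrow = TRUE)[is.na(X)]
  v <- apply(X, 2L, stats::var)
  out <- rep(NA_real_, ncol(X))
  use <- which(v > 0)
  if (length(use) == 1L) { out[use] <- 1; return(out) }
  C <- stats::cor(X[, use, drop = FALSE])
  # pseudo-inverse guards against singular windows (perfect LD)
  Ci <- tryCatch(solve(C), error = function(e) MASS::ginv(C))
  d <- diag(Ci)
  # numerically, perfect collinearity can yield huge or non-finite values;
  # treat them as infinite VIF
  d[!is.finite(d) | d < 1] <- Inf
  out[use] <- d
  # ginv of a singular matrix can give finite but meaningless diagonals;
  # flag exact collinearity explicitly
  if (any(!is.finite(d))) out[use][!is.finite(d)] <- Inf
  sing <- .collinear_sites(X[, use, drop = FALSE])
  out[use][sing] <- Inf
  out
}

# sites exactly predictable from the others (R^2 == 1 up to tolerance)
.collinear_sites <- function(X) {
  q <- qr(scale(X))
  if (q$rank >= ncol(X)) return(logical(ncol(X)))
  r2 <- vapply(seq_len(ncol(X)), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
  }, numeric(1))
  r2 > 1 - 1e-10
}

#' Identity-by-state distance matrix (1 - IBS)
#'
#' For samples i, j the distance is
#' `1 - sum_sites(2 - |g_i - g_j|) / (2 * M_ij)` over sites non-missing in
#' both, `M_ij` being that count. Identical genotype vectors are at
#' distance 0; opposite homozygotes everywhere are at distance 1.
#'
#' @param gm A [genotype_matrix()] with at least 2 samples.
#' @return Symmetric numeric matrix with zero diagonal and sample-id
#'   dimnames; `NA` (with a warning) for pairs with zero co-called sites.
#' @export
ibs_distance <- function(gm) {
  stopifnot(inherits(gm, "genotype_matrix"))
  G <- gm$geno
  ns <- ncol(G)
  if (ns < 2L) stop("need at least 2 samples")
  D <- matrix(0, ns, ns, dimnames = list(gm$samples, gm$samples))
  for (i in seq_len(ns - 1L)) {
    for (j in (i + 1L):ns) {
      ok <- !is.na(G[, i]) & !is.na(G[, j])
      M <- sum(ok)
      if (M == 0L) {
        warning("samples ", gm$samples[i], " and ", gm$samples[j],
                " share no co-called sites")
        d <- NA_real_
      } else {
        d <- 1 - sum(2 - abs(G[ok, i] - G[ok, j])) / (2 * M)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

#' Distance matrix as a tidy tibble
#' @param D Matrix from [ibs_distance()].
#' @return Long tibble `sample_a`, `sample_b`, `distance` (upper triangle).
#' @export
ibs_tibble <- function(D) {
  idx <- which(upper.tri(D), arr.ind = TRUE)
  tibble::tibble(sample_a = rownames(D)[idx[, 1]],
                 sample_b = colnames(D)[idx[, 2]],
                 distance = D[idx])
}

#' Build a dendrogram from a distance matrix
#'
#' Average-linkage (UPGMA) hierarchical clustering by default, or neighbor
#' joining. Samples are ordered lexicographically before clustering so tied
#' merges resolve deterministically.
#'
#' @param D Symmetric distance matrix with sample-id dimnames (no NA).
#' @param method `"average_linkage"` (default) or `"neighbor_joining"`.
#' @return An [ape] `phylo` tree whose leaves are the sample ids.
#' @export
build_dendrogram <- function(D, method = c("average_linkage",
                                           "neighbor_joining")) {
  method <- match.arg(method)
  if (any(is.na(D))) {
    stop("distance matrix contains NA; drop or impute those samples first")
  }
  ord <- order(rownames(D))
  D <- D[ord, ord]
  if (method == "average_linkage") {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    ape::as.phylo(hc)
  } else {
    ape::nj(stats::as.dist(D))
  }
}

#' Write a tree as Newick
#' @param tree An ape `phylo`.
#' @param path Output path.
#' @param digits Branch-length precision (default 6).
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path, digits = 6L) {
  ape::write.tree(tree, file = path, digits = digits)
  invisible(path)
}

#' Write a distance matrix as square TSV
#' @param D Distance matrix.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_distance_tsv <- function(D, path) {
  d <- data.frame(sample = rownames(D), D, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
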