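#' Pairwise Weir-Cockerham F_ST between two populations
#'
#' Multi-locus method-of-moments estimator of Weir & Cockerham (1984) for
#' two populations, as the ratio of sums over SNPs
#' \eqn{\sum_l a_l / \sum_l (a_l + b_l + c_l)} of the among-population (a),
#' among-individual (b) and within-individual (c) variance components.
#' SNPs monomorphic across the pooled pair, or with fewer than 2 called
#' genotypes in either population, are skipped. The estimator is symmetric
#' in the two populations and invariant to allele-label swaps.
#'
#' @param panel a [genotype_panel()].
#' @param pop_a,pop_b population labels (each with >= 2 samples).
#' @param estimator `"wc"` (Weir-Cockerham 1984, default) or `"hudson"`
#'   (Hudson et al. 1992 ratio-of-averages).
#' @return The multi-locus estimate, with attribute `n_snps` (SNPs used).
#'   `NA` with a warning when no polymorphic SNPs remain.
#' @examples
#' p <- sim_example_panel()
#' pairwise_fst(p, "B1", "B2")
#' @export
pairwise_fst <- function(panel, pop_a, pop_b, estimator = c("wc", "hudson")) {
  estimator <- match.arg(estimator)
  sa <- pop_snp_stats(panel, pop_a)
  sb <- pop_snp_stats(panel, pop_b)
  if (length(sa$rows) < 2 || length(sb$rows) < 2)
    stop("both populations need >= 2 samples")
  n1 <- sa$n_called; n2 <- sb$n_called
  p1 <- sa$p; p2 <- sb$p
  ok <- n1 >= 2 & n2 >= 2
  # skip SNPs monomorphic across the pooled pair
  pbar_all <- (2 * n1 * p1 + 2 * n2 * p2) / (2 * (n1 + n2))
  ok <- ok & !is.na(pbar_all) & pbar_all > 0 & pbar_all < 1
  if (!any(ok)) {
    warning("no polymorphic SNPs shared by ", pop_a, " and ", pop_b)
    return(structure(NA_real_, n_snps = 0L))
  }
  n1 <- n1[ok]; n2 <- n2[ok]; p1 <- p1[ok]; p2 <- p2[ok]
  h1 <- sa$het[ok]; h2 <- sb$het[ok]

  if (estimator == "hudson") {
    # Hudson ratio-of-averages with sample-size bias correction
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    fst <- sum(num) / sum(den)
    return(structure(fst, n_snps = sum(ok)))
  }

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  structure(sum(a) / sum(a + b + cc), n_snps = sum(ok))
}

#' All pairwise F_ST values of a panel
#'
#' @param panel a [genotype_panel()].
#' @param estimator passed to [pairwise_fst()].
#' @return Symmetric matrix of pairwise estimates (diagonal 0), with
#'   attribute `n_snps` (matrix of per-pair SNP counts used).
#' @export
fst_matrix <- function(panel, estimator = "wc") {
  pops <- unique(panel$populations)
  k <- length(pops)
  vals <- matrix(0, k, k, dimnames = list(pops, pops))
  nsnp <- matrix(0L, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    f <- pairwise_fst(panel, pops[i], pops[j], estimator)
    vals[i, j] <- vals[j, i] <- as.numeric(f)
    nsnp[i, j] <- nsnp[j, i] <- attr(f, "n_snps")
  }
  structure(vals, n_snps = nsnp)
}

#' Identity-by-state distance matrix
#'
#' For each pair of samples, over SNPs non-missing in both, the shared
#' allele count per SNP is \eqn{s = 2 - |g_i - g_j|} (0, 1 or 2); the IBS
#' similarity is `mean(s)/2` and the distance `1 - similarity`. A pair with
#' zero overlapping SNPs gets `NA` with a warning.
#'
#' @param panel a [genotype_panel()].
#' @return Symmetric matrix of distances in `[0, 1]`, zero diagonal,
#'   dimnames = sample ids.
#' @export
ibs_distance <- function(panel) {
  n <- length(panel$samples)
  if (n < 2) stop("need >= 2 samples")
  g <- panel$genotypes
  d <- matrix(0, n, n, dimnames = list(panel$samples, panel$samples))
  for (i in seq_len(n - 1)) {
    gi <- g[i, ]
    for (j in (i + 1):n) {
      gj <- g[j, ]
      ok <- gi != -1L & gj != -1L
      if (!any(ok)) {
        warning("samples ", panel$samples[i], " and ", panel$samples[j],
                " share no called SNPs")
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        s <- 2 - abs(gi[ok] - gj[ok])
        d[i, j] <- d[j, i] <- 1 - mean(s) / 2
      }
    }
  }
  d
}

#' Neighbour-joining tree from a distance matrix
#'
#' Saitou-Nei neighbour joining (via the standard agglomerative Q-criterion
#' implementation in \pkg{ape}) on a symmetric distance matrix. Negative
#' branch lengths, which NJ can produce on non-additive matrices, are
#' clamped to zero and flagged via the attribute `clamped`.
#'
#' @param dist symmetric distance matrix (>= 3 taxa) or `dist` object.
#' @return An \pkg{ape} `phylo` tree with attribute `clamped` (logical:
#'   were any negative branch lengths clamped).
#' @export
nj_tree <- function(dist) {
  dm <- as.matrix(dist)
  if (nrow(dm) < 3)
    stop("neighbour joining needs >= 3 taxa; with 2 the tree is a ",
         "single edge of length d(1,2)")
  if (any(!is.finite(dm))) stop("distances must be finite")
  tree <- ape::nj(stats::as.dist(dm))
  clamped <- any(tree$edge.length < 0)
  tree$edge.length[tree$edge.length < 0] <- 0
  attr(tree, "clamped") <- clamped
  tree
}

#' Write a tree in Newick format
#'
#' @param tree a `phylo` object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Principal component scores of a genotype panel
#'
#' Genotypes are mean-centred per SNP; missing calls are imputed to the SNP
#' mean; optional Patterson scaling divides each SNP by
#' \eqn{\sqrt{\hat p(1-\hat p)}}. Scores are eigenvectors of the sample
#' covariance scaled by the singular values, computed by singular value
#' decomposition.
#'
#' @param panel a [genotype_panel()].
#' @param n_components number of components to return (< n_samples).
#' @param patterson logical; apply Patterson et al. (2006) scaling.
#' @return A list: `scores` (samples x components), `eigenvalues` (all
#'   non-trivial eigenvalues of the sample covariance), `pct_var` (percent
#'   of total variance per returned component).
#' @export
pca_scores <- function(panel, n_components = 10L, patterson = FALSE) {
  n <- length(panel$samples)
  if (n < 2) stop("need >= 2 samples")
  n_components <- min(n_components, n - 1L)
  g <- panel$genotypes
  x <- apply(g, 2, function(col) {
    col <- as.numeric(col)
    col[col == -1] <- NA
    mu <- mean(col, na.rm = TRUE)
    col[is.na(col)] <- mu
    col - mu
  })
  if (patterson) {
    p <- apply(g, 2, function(col) {
      col <- col[col != -1L]
      if (!length(col)) return(NA_real_)
      mean(col) / 2
    })
    sc <- sqrt(pmax(p * (1 - p), 0))
    keep <- !is.na(sc) & sc > 0
    x <- sweep(x[, keep, drop = FALSE], 2, sc[keep], "/")
  }
  if (all(x == 0)) stop("panel is monomorphic: zero total variance")
  pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  ev <- ev[seq_len(min(length(ev), n - 1L))]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  rownames(scores) <- panel$samples
  list(scores = scores, eigenvalues = ev,
       pct_var = 100 * ev[seq_len(n_components)] / sum(ev))
}
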