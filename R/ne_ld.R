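#' Pairwise genotype r-squared within a population
#'
#' For every intra-chromosomal SNP pair separated by at most `max_dist_bp`,
#' the squared Pearson correlation of 0/1/2 genotype codes over the
#' population's samples non-missing at both SNPs. SNPs monomorphic in the
#' population (over non-missing calls) are skipped.
#'
#' @param panel a [genotype_panel()].
#' @param population population label (`NULL` uses all samples).
#' @param max_dist_bp maximum pair distance in bp. Default 5e6.
#' @return Data frame: `chrom`, `dist_bp`, `r2`.
#' @export
pairwise_r2 <- function(panel, population = NULL, max_dist_bp = 5e6) {
  rows <- if (is.null(population)) seq_along(panel$samples)
          else which(panel$populations == population)
  if (length(rows) < 2) stop("need >= 2 samples")
  g <- panel$genotypes[rows, , drop = FALSE]
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    jj <- which(panel$map$chrom == ch)
    pos <- panel$map$pos_bp[jj]
    gc <- g[, jj, drop = FALSE]
    called <- gc != -1L
    poly <- vapply(seq_along(jj), function(k) {
      v <- gc[called[, k], k]
      length(v) >= 2 && stats::var(v) > 0
    }, logical(1))
    keep <- which(poly)
    if (length(keep) < 2) next
    pos <- pos[keep]; gc <- gc[, keep, drop = FALSE]
    has_missing <- any(gc == -1L)
    if (!has_missing) {
      cmat <- suppressWarnings(stats::cor(gc))
      for (a in seq_len(ncol(gc) - 1)) {
        b <- which(pos > pos[a] & pos - pos[a] <= max_dist_bp)
        b <- b[b > a]
        if (!length(b)) next
        out[[length(out) + 1L]] <- data.frame(
          chrom = ch, dist_bp = pos[b] - pos[a], r2 = cmat[a, b]^2)
      }
    } else {
      for (a in seq_len(ncol(gc) - 1)) {
        b_idx <- which(pos > pos[a] & pos - pos[a] <= max_dist_bp)
        b_idx <- b_idx[b_idx > a]
        for (b in b_idx) {
          ok <- gc[, a] != -1L & gc[, b] != -1L
          if (sum(ok) < 2) next
          va <- gc[ok, a]; vb <- gc[ok, b]
          if (stats::var(va) == 0 || stats::var(vb) == 0) next
          out[[length(out) + 1L]] <- data.frame(
            chrom = ch, dist_bp = pos[b] - pos[a],
            r2 = stats::cor(va, vb)^2)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = integer(), dist_bp = numeric(),
                      r2 = numeric())
  rownames(res) <- NULL
  res
}

# Physical distance (bp) -> recombination fraction (Morgans).
map_distance <- function(dist_bp, recomb_rate, mapping) {
  d <- recomb_rate * dist_bp
  switch(mapping,
         linear = d,
         haldane = 0.5 * (1 - exp(-2 * d)),
         sved = d / (1 + 2 * d))
}

#' Historical effective population size from binned LD
#'
#' Implements the Sved-curve inversion used by LD-based Ne estimators: pair
#' distances are mapped to recombination fractions `c`, pairs are grouped
#' into distance bins, each bin's mean r-squared is adjusted for finite
#' sample size (`1/(2n)` for unphased genotype correlations, `1/n` when
#' phased), and inverting \eqn{E[r^2] = 1/(\alpha + 4 N c)} gives, per bin,
#' \deqn{N_e = \frac{1}{4\bar c}\left(\frac{1}{\bar r^2_{adj}} - \alpha\right)}
#' at a time \eqn{t = 1/(2\bar c)} generations in the past: short-range LD
#' reflects ancient population size, long-range LD recent size.
#'
#' Bins whose adjusted mean r-squared is not positive, or not greater than
#' \eqn{1/\alpha} inverted (i.e. \eqn{1/\bar r^2_{adj} \le \alpha}), are
#' dropped with a warning.
#'
#' @param pairs data frame from [pairwise_r2()] (columns `dist_bp`, `r2`).
#' @param n_samples number of samples the correlations were computed over.
#' @param bins numeric vector of distance bin edges in bp. Default 30
#'   log-spaced bins over 50 kb - 5 Mb (times of roughly 10 to 1000
#'   generations ago at 1 cM/Mb).
#' @param recomb_rate Morgans per bp; default 1e-8 (1 cM/Mb).
#' @param alpha mutation-adjustment constant: 2 (default) accounts for
#'   mutation, 1 ignores it.
#' @param mapping distance mapping: `"linear"` (c = rate x bp, default),
#'   `"haldane"` or `"sved"`.
#' @param phased logical; use the phased (`1/n`) instead of the unphased
#'   (`1/(2n)`) sample-size correction.
#' @return Data frame of class `ne_trajectory`: `bin_low_bp`, `bin_high_bp`,
#'   `mean_c`, `t_generations`, `mean_r2_adj`, `ne_estimate`, `n_pairs`.
#' @export
estimate_ne <- function(pairs, n_samples,
                        bins = exp(seq(log(5e4), log(5e6), length.out = 31)),
                        recomb_rate = 1e-8, alpha = 2,
                        mapping = c("linear", "haldane", "sved"),
                        phased = FALSE) {
  mapping <- match.arg(mapping)
  if (!nrow(pairs)) stop("empty pair list")
  stopifnot(recomb_rate > 0, n_samples >= 2)
  corr <- if (phased) 1 / n_samples else 1 / (2 * n_samples)
  bin_idx <- cut(pairs$dist_bp, breaks = bins, right = TRUE,
                 include.lowest = TRUE)
  keep <- !is.na(bin_idx)
  pairs <- pairs[keep, , drop = FALSE]
  bin_idx <- bin_idx[keep]
  cvals <- map_distance(pairs$dist_bp, recomb_rate, mapping)

  rows <- lapply(levels(bin_idx), function(lv) {
    sel <- bin_idx == lv
    if (!any(sel)) return(NULL)
    i <- match(lv, levels(bin_idx))
    r2_adj <- mean(pairs$r2[sel]) - corr
    mc <- mean(cvals[sel])
    data.frame(bin_low_bp = bins[i], bin_high_bp = bins[i + 1],
               mean_c = mc, t_generations = 1 / (2 * mc),
               mean_r2_adj = r2_adj,
               ne_estimate = if (r2_adj > 0 && 1 / r2_adj > alpha)
                 (1 / (4 * mc)) * (1 / r2_adj - alpha) else NA_real_,
               n_pairs = sum(sel))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no pairs fall inside the bins")
  dropped <- is.na(out$ne_estimate)
  if (any(dropped))
    warning(sum(dropped), " bin(s) dropped: adjusted r2 not invertible")
  out <- out[!dropped, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Write an Ne trajectory as TSV
#'
#' @param trajectory data frame from [estimate_ne()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_ne_tsv <- function(trajectory, path) {
  utils::write.table(trajectory, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
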