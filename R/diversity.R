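# Per-SNP within-population allele statistics.
# Returns, for the samples of one population: p (B-allele frequency over
# non-missing calls), n_al (non-missing allele observations = 2 x calls),
# het (observed heterozygote fraction among non-missing calls), n_called.
pop_snp_stats <- function(panel, population) {
  rows <- which(panel$populations == population)
  if (!length(rows)) stop("empty population: ", population)
  g <- panel$genotypes[rows, , drop = FALSE]
  called <- g != -1L
  n_called <- colSums(called)
  gz <- g
  gz[!called] <- 0L
  p <- ifelse(n_called > 0, colSums(gz) / (2 * n_called), NA_real_)
  het <- ifelse(n_called > 0, colSums(g == 1L) / n_called, NA_real_)
  list(p = p, n_al = 2L * n_called, het = het, n_called = n_called,
       rows = rows)
}

#' Per-population marker diversity statistics
#'
#' For the samples of one population, computes per-SNP B-allele frequencies
#' over non-missing calls and summarises: the count and proportion of
#' monomorphic SNPs, mean observed heterozygosity (fraction of heterozygous
#' calls), mean expected heterozygosity (2\eqn{\hat p \hat q} per SNP), mean
#' minor allele frequency, and the mean per-individual observed and expected
#' numbers of homozygous SNPs. The expected homozygous count applies the
#' small-sample correction \eqn{1 - 2\hat p\hat q \, n_{al}/(n_{al}-1)}
#' per SNP, consistent with [f_hom()].
#'
#' @param panel a [genotype_panel()].
#' @param population population label (at least 2 samples).
#' @return A one-row data frame: `population`, `n_birds`, `n_snps`,
#'   `n_monomorphic`, `pct_monomorphic`, `obs_het`, `exp_het`, `maf_mean`,
#'   `obs_hom_snps`, `exp_hom_snps`.
#' @examples
#' p <- sim_example_panel()
#' pop_diversity(p, p$populations[1])
#' @export
pop_diversity <- function(panel, population) {
  st <- pop_snp_stats(panel, population)
  if (length(st$rows) < 2) stop("population needs >= 2 samples")
  ok <- st$n_called > 0
  p <- st$p[ok]
  exp_het_snp <- 2 * p * (1 - p)
  mono <- p == 0 | p == 1
  g <- panel$genotypes[st$rows, ok, drop = FALSE]
  # mean per-individual count of homozygous genotypes
  obs_hom_ind <- rowSums(g == 0L | g == 2L)
  n_al <- st$n_al[ok]
  corr <- ifelse(n_al > 1, n_al / (n_al - 1), NA_real_)
  exp_hom_snp <- 1 - exp_het_snp * corr
  data.frame(
    population = population,
    n_birds = length(st$rows),
    n_snps = sum(ok),
    n_monomorphic = sum(mono),
    pct_monomorphic = 100 * sum(mono) / sum(ok),
    obs_het = mean(st$het[ok]),
    exp_het = mean(exp_het_snp),
    maf_mean = mean(pmin(p, 1 - p)),
    obs_hom_snps = mean(obs_hom_ind),
    exp_hom_snps = sum(exp_hom_snp[n_al > 1]),
    stringsAsFactors = FALSE
  )
}

#' Diversity table for every population of a panel
#'
#' @param panel a [genotype_panel()].
#' @return Data frame with one row per population (see [pop_diversity()]).
#' @export
diversity_table <- function(panel) {
  pops <- unique(panel$populations)
  out <- do.call(rbind, lapply(pops, function(b) pop_diversity(panel, b)))
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient from excess homozygosity (F_HOM)
#'
#' Method-of-moments estimator per sample:
#' \deqn{F_{HOM} = (O - E) / (L - E)}
#' where `O` is the observed number of homozygous genotypes among the
#' sample's non-missing SNPs, `L` the number of non-missing (typed) SNPs,
#' and `E` the expected homozygous count under within-population
#' Hardy-Weinberg with the small-sample correction
#' \eqn{E = \sum_{snps} [1 - 2\hat p\hat q \, n_{al}/(n_{al}-1)]}
#' (\eqn{n_{al}} = non-missing allele observations at the SNP in the
#' population). SNPs with fewer than 2 non-missing allele observations in
#' the population are excluded from both `O` and `E`. Values can be
#' negative (less homozygous than expected) and are not clamped.
#'
#' @param panel a [genotype_panel()].
#' @param population population label (at least 2 samples).
#' @return Data frame: `sample`, `o_hom`, `e_hom`, `l_typed`, `f_hom`.
#' @examples
#' p <- sim_example_panel()
#' head(f_hom(p, p$populations[1]))
#' @export
f_hom <- function(panel, population) {
  st <- pop_snp_stats(panel, population)
  if (length(st$rows) < 2) stop("population needs >= 2 samples")
  use <- st$n_al >= 2   # n_al < 2 excluded from both O and E
  p <- st$p[use]
  n_al <- st$n_al[use]
  e_snp <- 1 - 2 * p * (1 - p) * n_al / (n_al - 1)
  g <- panel$genotypes[st$rows, use, drop = FALSE]
  typed <- g != -1L
  o_hom <- rowSums(g == 0L | g == 2L)
  l_typed <- rowSums(typed)
  e_hom <- as.numeric(typed %*% e_snp)
  f <- ifelse(l_typed > e_hom, (o_hom - e_hom) / (l_typed - e_hom), NA_real_)
  data.frame(sample = panel$samples[st$rows], o_hom = o_hom,
             e_hom = e_hom, l_typed = l_typed, f_hom = f,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' F_HOM for every population of a panel
#'
#' @param panel a [genotype_panel()].
#' @return Data frame with one row per sample, including `population`.
#' @export
f_hom_all <- function(panel) {
  pops <- unique(panel$populations)
  out <- do.call(rbind, lapply(pops, function(b) {
    d <- f_hom(panel, b)
    d$population <- b
    d
  }))
  rownames(out) <- NULL
  out
}
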