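# Fixture builders and independent brute-force oracles used across tests.

# Random genotype panel (no population structure; arbitrary codes).
random_panel <- function(n_samples, n_snps, n_chrom = 2, miss_rate = 0.05,
                         chrom_length_bp = 1e7, pops = NULL) {
  m_chr <- n_snps %/% n_chrom
  m <- m_chr * n_chrom
  gt <- matrix(sample(c(-1L, 0L, 1L, 2L), n_samples * m, replace = TRUE,
                      prob = c(miss_rate, (1 - miss_rate) * 0.4,
                               (1 - miss_rate) * 0.2,
                               (1 - miss_rate) * 0.4)),
               n_samples, m)
  pos <- unlist(lapply(seq_len(n_chrom), function(ch)
    sort(sample.int(chrom_length_bp, m_chr))))
  map <- data.frame(snp_id = sprintf("c%ds%d", rep(1:n_chrom, each = m_chr),
                                     rep(seq_len(m_chr), n_chrom)),
                    chrom = rep(seq_len(n_chrom), each = m_chr),
                    pos_bp = pos, allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  if (is.null(pops)) pops <- rep("P1", n_samples)
  genotype_panel(gt, map, sprintf("s%02d", seq_len(n_samples)), pops)
}

# Exhaustive ROH oracle for max_het = max_missing = 0: every maximal
# all-homozygous, gap-bounded window meeting the thresholds. Enumerates
# from each homozygous start; maximality is checked explicitly on both
# sides, independently of the scan implementation's restart logic.
roh_oracle <- function(panel, sample, params) {
  row <- match(sample, panel$samples)
  out <- list()
  for (ch in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == ch)
    g <- panel$genotypes[row, idx]
    pos <- panel$map$pos_bp[idx]
    m <- length(g)
    hom <- g == 0L | g == 2L
    for (i in seq_len(m)) {
      if (!hom[i]) next
      # furthest valid right end from i
      j <- i
      while (j < m && hom[j + 1] && pos[j + 1] - pos[j] <= params$max_gap_bp)
        j <- j + 1
      left_maximal <- i == 1 || !hom[i - 1] ||
        pos[i] - pos[i - 1] > params$max_gap_bp
      if (!left_maximal) next
      n_snps <- j - i + 1
      len <- pos[j] - pos[i] + 1
      if (n_snps >= params$min_snps && len >= params$min_length_bp)
        out[[length(out) + 1]] <- data.frame(
          sample = sample, chrom = ch, start_bp = pos[i], end_bp = pos[j],
          n_snps = n_snps, length_bp = len, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer(), length_bp = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Scalar per-SNP recount of population diversity statistics.
diversity_oracle <- function(panel, population) {
  rows <- which(panel$populations == population)
  m <- nrow(panel$map)
  p <- het <- rep(NA_real_, m)
  for (j in seq_len(m)) {
    g <- panel$genotypes[rows, j]
    g <- g[g != -1L]
    if (!length(g)) next
    p[j] <- sum(g) / (2 * length(g))
    het[j] <- mean(g == 1L)
  }
  ok <- !is.na(p)
  list(n_snps = sum(ok),
       n_monomorphic = sum(p[ok] %in% c(0, 1)),
       obs_het = mean(het[ok]),
       exp_het = mean(2 * p[ok] * (1 - p[ok])),
       maf_mean = mean(pmin(p[ok], 1 - p[ok])))
}

# Direct genotype-count F_HOM oracle for one sample.
fhom_oracle <- function(panel, population, sample) {
  rows <- which(panel$populations == population)
  srow <- match(sample, panel$samples)
  O <- 0; E <- 0; L <- 0
  for (j in seq_len(nrow(panel$map))) {
    g <- panel$genotypes[rows, j]
    called <- g[g != -1L]
    n_al <- 2 * length(called)
    if (n_al < 2) next
    gs <- panel$genotypes[srow, j]
    if (gs == -1L) next
    p <- sum(called) / n_al
    L <- L + 1
    O <- O + (gs != 1L)
    E <- E + 1 - 2 * p * (1 - p) * n_al / (n_al - 1)
  }
  (O - E) / (L - E)
}

# Scalar IBS recount for one pair.
ibs_oracle <- function(panel, i, j) {
  gi <- panel$genotypes[i, ]; gj <- panel$genotypes[j, ]
  tot <- 0; shared <- 0
  for (k in seq_along(gi)) {
    if (gi[k] == -1L || gj[k] == -1L) next
    tot <- tot + 1
    shared <- shared + 2 - abs(gi[k] - gj[k])
  }
  unname(1 - shared / (2 * tot))
}

# Quadratic containment scan for incidence counts.
incidence_oracle <- function(segments, markers, population_size) {
  count <- integer(nrow(markers))
  for (k in seq_len(nrow(markers))) {
    covering <- character()
    for (r in seq_len(nrow(segments))) {
      if (segments$chrom[r] == markers$chrom[k] &&
          segments$start_bp[r] <= markers$pos_bp[k] &&
          segments$end_bp[r] >= markers$pos_bp[k])
        covering <- c(covering, segments$sample[r])
    }
    count[k] <- length(unique(covering))
  }
  count
}

# Brute-force exact-boundary island grouping.
island_oracle <- function(segments, population_size, fraction) {
  thr <- ceiling(fraction * population_size - 1e-9)
  seen <- unique(segments[c("chrom", "start_bp", "end_bp")])
  out <- list()
  for (r in seq_len(nrow(seen))) {
    who <- unique(segments$sample[
      segments$chrom == seen$chrom[r] &
      segments$start_bp == seen$start_bp[r] &
      segments$end_bp == seen$end_bp[r]])
    if (length(who) >= thr)
      out[[length(out) + 1]] <- cbind(seen[r, ],
                                      n_samples_sharing = length(who))
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Random ROH segment table for island/incidence fixtures: identical
# segments are produced deliberately by sampling boundaries from a small
# grid of SNP positions.
random_segments <- function(n_samples, markers, n_per_sample = 3) {
  out <- list()
  for (s in seq_len(n_samples)) {
    for (k in seq_len(sample.int(n_per_sample, 1))) {
      ch <- sample(unique(markers$chrom), 1)
      pos <- markers$pos_bp[markers$chrom == ch]
      ij <- sort(sample(seq_along(pos), 2))
      out[[length(out) + 1]] <- data.frame(
        sample = sprintf("s%02d", s), chrom = ch,
        start_bp = pos[ij[1]], end_bp = pos[ij[2]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# Panel with a hand-planted genotype row on one chromosome.
planted_panel <- function(genotypes_row, pos, chrom = 1L) {
  m <- length(genotypes_row)
  map <- data.frame(snp_id = sprintf("s%d", seq_len(m)), chrom = chrom,
                    pos_bp = pos, allele_a = "A", allele_b = "G",
                    stringsAsFactors = FALSE)
  genotype_panel(matrix(as.integer(genotypes_row), 1, m), map,
                 "s01", "P1")
}
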