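#' Configuration for the forward-time breed simulator
#'
#' Defines a multi-breed simulation: breeds diverge from shared ancestral
#' allele frequencies under the Balding-Nichols model (target differentiation
#' `theta_fst`), then each breed is bred forward in time through discrete
#' generations of random mating (monogamous pairs, selfing forbidden, no
#' sexes) with recombination, under an optional bottleneck schedule.
#' Founder-haplotype ancestry is tracked along every chromosome, so
#' autozygous (IBD) segments of the final generation are known exactly.
#'
#' @param n_breeds number of breeds.
#' @param n_per_breed samples drawn per breed from the final generation.
#' @param n_chrom number of chromosomes.
#' @param chrom_length_bp chromosome length in bp (all chromosomes equal).
#' @param n_snps_per_chrom SNPs per chromosome.
#' @param founder_haplotypes haplotypes in the founding generation
#'   (2 x founding population size). Default `2 * n_per_breed`.
#' @param generations number of discrete generations bred after founding.
#' @param bottleneck_schedule data frame with columns `generation`, `size`:
#'   from each listed generation onward the population has the given size
#'   (piecewise constant). `NULL` keeps the founding size throughout.
#' @param theta_fst Balding-Nichols differentiation parameter in (0, 1);
#'   the expected multi-locus F_ST between breeds.
#' @param recomb_rate recombination rate in Morgans per bp
#'   (default 1e-8 = 1 cM/Mb).
#' @param ancestral_maf_range range of the uniform distribution of ancestral
#'   allele frequencies.
#' @param snp_positions `"uniform"` (random uniform, sorted) or `"grid"`
#'   (evenly spaced; convenient for oracle tests).
#' @param seed integer RNG seed; the simulation is a pure function of
#'   (config, seed).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_breeds = 2L, n_per_breed = 25L, n_chrom = 3L,
                       chrom_length_bp = 1e8, n_snps_per_chrom = 2000L,
                       founder_haplotypes = NULL, generations = 20L,
                       bottleneck_schedule = NULL, theta_fst = 0.1,
                       recomb_rate = 1e-8,
                       ancestral_maf_range = c(0.05, 0.5),
                       snp_positions = c("uniform", "grid"), seed = 1L) {
  if (is.null(founder_haplotypes)) founder_haplotypes <- 2L * n_per_breed
  stopifnot(n_breeds >= 1, n_per_breed >= 1, n_chrom >= 1,
            chrom_length_bp > 0, n_snps_per_chrom >= 2,
            founder_haplotypes >= 4, generations >= 1,
            recomb_rate > 0, seed == floor(seed))
  if (theta_fst <= 0 || theta_fst >= 1) stop("theta_fst must be in (0, 1)")
  if (!is.null(bottleneck_schedule)) {
    bottleneck_schedule <- as.data.frame(bottleneck_schedule)
    stopifnot(all(c("generation", "size") %in% names(bottleneck_schedule)))
    if (any(bottleneck_schedule$generation < 1 |
            bottleneck_schedule$generation > generations))
      stop("schedule generations must lie in [1, generations]")
    if (any(bottleneck_schedule$size < 2))
      stop("population size < 2 in schedule")
  }
  structure(list(n_breeds = as.integer(n_breeds),
                 n_per_breed = as.integer(n_per_breed),
                 n_chrom = as.integer(n_chrom),
                 chrom_length_bp = chrom_length_bp,
                 n_snps_per_chrom = as.integer(n_snps_per_chrom),
                 founder_haplotypes = as.integer(founder_haplotypes),
                 generations = as.integer(generations),
                 bottleneck_schedule = bottleneck_schedule,
                 theta_fst = theta_fst, recomb_rate = recomb_rate,
                 ancestral_maf_range = ancestral_maf_range,
                 snp_positions = match.arg(snp_positions),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Draw breed allele frequencies under the Balding-Nichols model
#'
#' Each breed's frequency at each SNP is drawn from
#' \eqn{Beta(p(1-\theta)/\theta, (1-p)(1-\theta)/\theta)} around the
#' ancestral frequency `p`; the expectation of multi-locus Weir-Cockerham
#' F_ST between two breeds over many SNPs is approximately \eqn{\theta}.
#'
#' @param ancestral_freqs numeric vector of ancestral frequencies in (0, 1).
#' @param theta_fst differentiation parameter in (0, 1).
#' @param n_breeds number of breeds.
#' @param seed optional integer seed (fixed seed gives identical output).
#' @return Matrix of frequencies, `n_breeds` rows x SNPs columns.
#' @export
draw_breed_frequencies <- function(ancestral_freqs, theta_fst, n_breeds,
                                   seed = NULL) {
  if (theta_fst <= 0 || theta_fst >= 1) stop("theta_fst must be in (0, 1)")
  if (any(ancestral_freqs <= 0 | ancestral_freqs >= 1))
    stop("ancestral frequencies must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  m <- length(ancestral_freqs)
  k <- (1 - theta_fst) / theta_fst
  out <- matrix(NA_real_, n_breeds, m)
  for (b in seq_len(n_breeds))
    out[b, ] <- stats::rbeta(m, ancestral_freqs * k,
                             (1 - ancestral_freqs) * k)
  out
}

# Piecewise-constant generation sizes from a schedule.
generation_sizes <- function(config) {
  sizes <- rep(config$founder_haplotypes %/% 2L, config$generations)
  sch <- config$bottleneck_schedule
  if (!is.null(sch)) {
    sch <- sch[order(sch$generation), , drop = FALSE]
    for (k in seq_len(nrow(sch)))
      sizes[sch$generation[k]:config$generations] <- sch$size[k]
  }
  sizes
}

# One meiosis on one chromosome. hap_a/hap_b: allele vectors (this chrom's
# SNPs); anc_a/anc_b: list(ends, ids) founder-ancestry tracks; pos: SNP
# positions. Returns list(alleles, anc).
make_gamete <- function(hap_a, hap_b, anc_a, anc_b, pos, L, recomb_rate) {
  n_x <- stats::rpois(1, recomb_rate * L)
  # half-integer crossover positions: never coincide with integer SNP
  # positions, so allele phase and ancestry segments use the same partition
  xov <- if (n_x > 0)
    sort(unique(floor(stats::runif(n_x, 1, L - 1)) + 0.5)) else numeric()
  start <- sample.int(2L, 1L) - 1L            # 0 -> begin on hap_a
  phase <- (findInterval(pos, xov) + start) %% 2L
  alleles <- ifelse(phase == 0L, hap_a, hap_b)

  # ancestry: piece together segments, switching tracks at crossovers
  bounds <- c(0, xov, L)
  ends <- numeric(); ids <- integer()
  for (k in seq_len(length(bounds) - 1L)) {
    lo <- bounds[k]; hi <- bounds[k + 1L]
    src <- if ((k - 1L + start) %% 2L == 0L) anc_a else anc_b
    i0 <- findInterval(lo, src$ends, left.open = FALSE) + 1L
    # segments of src overlapping (lo, hi]
    while (i0 <= length(src$ends) && (i0 == 1L || src$ends[i0 - 1L] < hi)) {
      seg_end <- min(src$ends[i0], hi)
      if (seg_end > lo) {
        ends <- c(ends, seg_end); ids <- c(ids, src$ids[i0])
        lo <- seg_end
      }
      if (src$ends[i0] >= hi) break
      i0 <- i0 + 1L
    }
  }
  # simplify adjacent equal ids
  if (length(ids) > 1L) {
    keep <- c(ids[-length(ids)] != ids[-1L], TRUE)
    ends <- ends[keep]; ids <- ids[keep]
  }
  list(alleles = alleles, anc = list(ends = ends, ids = ids))
}

# Autozygous intervals of one individual on one chromosome: positions where
# both haplotypes carry the same founder-haplotype id.
autozygous_intervals <- function(anc1, anc2, L) {
  cuts <- sort(unique(c(anc1$ends, anc2$ends)))
  starts <- c(0, cuts[-length(cuts)])
  id1 <- anc1$ids[findInterval(starts, anc1$ends, left.open = FALSE) + 1L]
  id2 <- anc2$ids[findInterval(starts, anc2$ends, left.open = FALSE) + 1L]
  same <- id1 == id2
  if (!any(same)) return(cbind(start = numeric(), end = numeric()))
  # merge adjacent autozygous pieces
  out <- list()
  k <- 1L
  while (k <= length(same)) {
    if (same[k]) {
      j <- k
      while (j < length(same) && same[j + 1L]) j <- j + 1L
      out[[length(out) + 1L]] <- c(starts[k], cuts[j])
      k <- j + 1L
    } else k <- k + 1L
  }
  mat <- do.call(rbind, out)
  colnames(mat) <- c("start", "end")
  mat
}

#' Simulate a multi-breed genotype panel with known autozygosity
#'
#' Runs the forward-time simulation described in [sim_config()] and returns
#' the final-generation genotype panel together with a truth set: exact
#' autozygous (IBD) segments per sample at founder-haplotype resolution,
#' exact pedigree inbreeding coefficients (tabular kinship method), realized
#' autozygous genome fractions, and the true per-breed allele frequencies.
#' Inside every true IBD segment all SNP genotypes are homozygous by
#' construction (no genotyping error; add it with
#' [add_genotyping_noise()]).
#'
#' IBD segments spanning fewer than 2 SNPs are omitted from
#' `truth$ibd_segments` (they are undetectable by marker-based methods) but
#' still count towards `realized_f`.
#'
#' @param config a [sim_config()].
#' @return A list with elements:
#'   \describe{
#'     \item{panel}{a [genotype_panel()] (populations `"B1"`, `"B2"`, ...).}
#'     \item{truth}{list with `ibd_segments` (data frame: `sample`, `chrom`,
#'       `start_bp`, `end_bp`, `n_snps`), `per_sample` (data frame:
#'       `sample`, `population`, `pedigree_f`, `realized_f`), and
#'       `true_freqs` (breeds x SNPs matrix).}
#'   }
#' @examples
#' sim <- simulate_breeds(sim_config(n_breeds = 2, n_per_breed = 6,
#'                                   n_chrom = 1, n_snps_per_chrom = 200,
#'                                   generations = 3, seed = 7))
#' sim$panel
#' @export
simulate_breeds <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$chrom_length_bp
  m_chr <- config$n_snps_per_chrom
  m <- m_chr * config$n_chrom

  pos_list <- lapply(seq_len(config$n_chrom), function(ch) {
    if (config$snp_positions == "grid")
      round(seq(L / (m_chr + 1), L * m_chr / (m_chr + 1), length.out = m_chr))
    else sort(round(stats::runif(m_chr, 1, L)))
  })
  map <- data.frame(
    snp_id = sprintf("snp%d_%d", rep(seq_len(config$n_chrom), each = m_chr),
                     rep(seq_len(m_chr), config$n_chrom)),
    chrom = rep(seq_len(config$n_chrom), each = m_chr),
    pos_bp = unlist(pos_list),
    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)

  anc_freqs <- stats::runif(m, config$ancestral_maf_range[1],
                            config$ancestral_maf_range[2])
  breed_freqs <- draw_breed_frequencies(anc_freqs, config$theta_fst,
                                        config$n_breeds)
  rownames(breed_freqs) <- paste0("B", seq_len(config$n_breeds))

  sizes <- generation_sizes(config)
  chrom_of <- rep(seq_len(config$n_chrom), each = m_chr)
  idx_chr <- split(seq_len(m), chrom_of)

  all_gt <- NULL; all_samples <- character(); all_pops <- character()
  seg_list <- list(); per_sample <- list()

  for (b in seq_len(config$n_breeds)) {
    pb <- breed_freqs[b, ]
    n0 <- config$founder_haplotypes %/% 2L
    n_hap <- 2L * n0
    alleles <- matrix(stats::rbinom(n_hap * m, 1L, rep(pb, each = n_hap)),
                      n_hap, m)
    # ancestry: founder haplotype h is its own ancestor everywhere
    anc <- lapply(seq_len(n_hap), function(h)
      lapply(seq_len(config$n_chrom), function(ch)
        list(ends = L, ids = h)))
    K <- diag(0.5, n0)
    n_cur <- n0

    for (t in seq_len(config$generations)) {
      n_next <- sizes[t]
      if (n_cur < 2) stop("population size < 2 at generation ", t)
      perm <- sample.int(n_cur)
      n_pairs <- n_cur %/% 2L
      pair_of <- sample.int(n_pairs, n_next, replace = TRUE)
      new_alleles <- matrix(0L, 2L * n_next, m)
      new_anc <- vector("list", 2L * n_next)
      sire <- integer(n_next); dam <- integer(n_next)
      for (i in seq_len(n_next)) {
        s <- perm[2L * pair_of[i] - 1L]; d <- perm[2L * pair_of[i]]
        sire[i] <- s; dam[i] <- d
        for (par_k in 1:2) {
          par <- if (par_k == 1) s else d
          hap_row <- 2L * i - 2L + par_k
          gam_anc <- vector("list", config$n_chrom)
          for (ch in seq_len(config$n_chrom)) {
            jj <- idx_chr[[ch]]
            gam <- make_gamete(alleles[2L * par - 1L, jj],
                               alleles[2L * par, jj],
                               anc[[2L * par - 1L]][[ch]],
                               anc[[2L * par]][[ch]],
                               pos_list[[ch]], L, config$recomb_rate)
            new_alleles[hap_row, jj] <- gam$alleles
            gam_anc[[ch]] <- gam$anc
          }
          new_anc[[hap_row]] <- gam_anc
        }
      }
      # tabular kinship update
      Knew <- matrix(0, n_next, n_next)
      for (i in seq_len(n_next)) for (j in seq_len(n_next)) {
        if (i == j) next
        Knew[i, j] <- 0.25 * (K[sire[i], sire[j]] + K[sire[i], dam[j]] +
                              K[dam[i], sire[j]] + K[dam[i], dam[j]])
      }
      f_new <- vapply(seq_len(n_next), function(i) K[sire[i], dam[i]],
                      numeric(1))
      diag(Knew) <- 0.5 * (1 + f_new)
      K <- Knew
      # reorder rows so row 2i-1/2i are individual i's haplotypes
      hap_anc_reordered <- new_anc
      alleles <- new_alleles
      anc <- hap_anc_reordered
      n_cur <- n_next
      F_cur <- f_new
    }
    if (config$generations == 0) F_cur <- rep(0, n_cur)

    take <- sample.int(n_cur, min(config$n_per_breed, n_cur))
    pop <- paste0("B", b)
    ids <- sprintf("%s_i%02d", pop, seq_along(take))
    gt <- matrix(0L, length(take), m)
    for (k in seq_along(take)) {
      i <- take[k]
      gt[k, ] <- alleles[2L * i - 1L, ] + alleles[2L * i, ]
      total_ibd <- 0
      for (ch in seq_len(config$n_chrom)) {
        iv <- autozygous_intervals(anc[[2L * i - 1L]][[ch]],
                                   anc[[2L * i]][[ch]], L)
        if (nrow(iv)) {
          total_ibd <- total_ibd + sum(iv[, "end"] - iv[, "start"])
          pos <- pos_list[[ch]]
          for (r in seq_len(nrow(iv))) {
            inside <- pos > iv[r, "start"] & pos <= iv[r, "end"]
            if (sum(inside) >= 2) {
              seg_list[[length(seg_list) + 1L]] <- data.frame(
                sample = ids[k], chrom = ch,
                start_bp = min(pos[inside]), end_bp = max(pos[inside]),
                n_snps = sum(inside), stringsAsFactors = FALSE)
            }
          }
        }
      }
      per_sample[[length(per_sample) + 1L]] <- data.frame(
        sample = ids[k], population = pop, pedigree_f = F_cur[i],
        realized_f = total_ibd / (config$n_chrom * L),
        stringsAsFactors = FALSE)
    }
    all_gt <- rbind(all_gt, gt)
    all_samples <- c(all_samples, ids)
    all_pops <- c(all_pops, rep(pop, length(ids)))
  }

  panel <- genotype_panel(all_gt, map, all_samples, all_pops)
  ibd <- if (length(seg_list)) do.call(rbind, seg_list) else
    data.frame(sample = character(), chrom = integer(),
               start_bp = numeric(), end_bp = numeric(), n_snps = integer())
  list(panel = panel,
       truth = list(ibd_segments = ibd,
                    per_sample = do.call(rbind, per_sample),
                    true_freqs = breed_freqs))
}

#' Sample a genotype panel directly from breed allele frequencies
#'
#' Draws Hardy-Weinberg genotypes (Binomial(2, p)) for each breed from a
#' frequency matrix — the drift-free counterpart of [simulate_breeds()],
#' convenient for differentiation (F_ST) experiments.
#'
#' @param breed_freqs breeds x SNPs matrix (rows named with breed labels,
#'   or labels `B1..Bk` are assigned).
#' @param n_per_breed samples per breed.
#' @param chrom_length_bp chromosome length for the synthetic map (all SNPs
#'   on one chromosome, evenly spaced).
#' @param seed optional integer seed.
#' @return A [genotype_panel()].
#' @export
sample_panel_from_freqs <- function(breed_freqs, n_per_breed = 25L,
                                    chrom_length_bp = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  breed_freqs <- as.matrix(breed_freqs)
  k <- nrow(breed_freqs); m <- ncol(breed_freqs)
  labs <- rownames(breed_freqs)
  if (is.null(labs)) labs <- paste0("B", seq_len(k))
  if (is.null(chrom_length_bp)) chrom_length_bp <- m * 1e4
  map <- data.frame(snp_id = sprintf("snp%06d", seq_len(m)), chrom = 1L,
                    pos_bp = round(seq(1e4, chrom_length_bp, length.out = m)),
                    allele_a = "A", allele_b = "B", stringsAsFactors = FALSE)
  gt <- NULL; samples <- character(); pops <- character()
  for (b in seq_len(k)) {
    g <- matrix(stats::rbinom(n_per_breed * m, 2L,
                              rep(breed_freqs[b, ], each = n_per_breed)),
                n_per_breed, m)
    gt <- rbind(gt, g)
    samples <- c(samples, sprintf("%s_i%02d", labs[b], seq_len(n_per_breed)))
    pops <- c(pops, rep(labs[b], n_per_breed))
  }
  genotype_panel(gt, map, samples, pops)
}

#' Add genotyping noise to a panel
#'
#' Independently flips homozygous calls to heterozygous with probability
#' `het_error` and then sets cells to missing with probability
#' `missing_rate`. With both rates 0 the panel is returned unchanged.
#'
#' @param panel a [genotype_panel()].
#' @param het_error probability in `[0, 1)` of a hom-to-het flip.
#' @param missing_rate probability in `[0, 1)` of a cell becoming missing.
#' @param seed optional integer seed.
#' @return A [genotype_panel()].
#' @export
add_genotyping_noise <- function(panel, het_error = 0, missing_rate = 0,
                                 seed = NULL) {
  stopifnot(het_error >= 0, het_error < 1, missing_rate >= 0,
            missing_rate < 1)
  if (het_error == 0 && missing_rate == 0) return(panel)
  if (!is.null(seed)) set.seed(seed)
  g <- panel$genotypes
  if (het_error > 0) {
    hom <- which(g == 0L | g == 2L)
    flip <- hom[stats::runif(length(hom)) < het_error]
    g[flip] <- 1L
  }
  if (missing_rate > 0) {
    drop <- which(stats::runif(length(g)) < missing_rate)
    g[drop] <- -1L
  }
  genotype_panel(g, panel$map, panel$samples, panel$populations,
                 sort_map = FALSE)
}

#' Small example panel for documentation examples
#'
#' A quick two-breed simulated panel (deterministic seed), used in the
#' package's examples.
#'
#' @return A [genotype_panel()].
#' @export
sim_example_panel <- function() {
  simulate_breeds(sim_config(n_breeds = 2, n_per_breed = 8, n_chrom = 1,
                             chrom_length_bp = 5e7, n_snps_per_chrom = 500,
                             generations = 5, theta_fst = 0.2,
                             seed = 42))$panel
}

#' Write a simulation truth set as TSV
#'
#' @param truth the `truth` element of [simulate_breeds()].
#' @param segments_path path for the IBD segment table (1-based inclusive).
#' @param samples_path path for the per-sample table.
#' @return The paths, invisibly.
#' @export
write_truth_tsv <- function(truth, segments_path, samples_path) {
  utils::write.table(truth$ibd_segments, segments_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(truth$per_sample, samples_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(c(segments_path, samples_path))
}
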