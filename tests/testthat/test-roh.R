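empty_segments <- function() {
  data.frame(sample = character(), chrom = integer(), start_bp = numeric(),
             end_bp = numeric(), n_snps = integer(), length_bp = numeric())
}

test_that("a clean homozygous run is emitted with SNP-position boundaries", {
  pos <- seq(1e6, by = 10000, length.out = 200)   # spans ~2 Mb
  p <- planted_panel(rep(c(0L, 2L), 100), pos)
  segs <- detect_roh(p, "s01", roh_params())
  expect_equal(nrow(segs), 1)
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[200])
  expect_equal(segs$n_snps, 200L)
  expect_equal(segs$length_bp, pos[200] - pos[1] + 1)
})

test_that("a single heterozygote splits a run below the SNP threshold", {
  pos <- seq(1e6, by = 10000, length.out = 200)
  g <- rep(0L, 200); g[100] <- 1L
  p <- planted_panel(g, pos)
  expect_equal(nrow(detect_roh(p, "s01", roh_params())), 0)
  # with a relaxed SNP threshold both flanks qualify
  relaxed <- roh_params(min_snps = 50, min_length_bp = 5e5)
  expect_equal(nrow(detect_roh(p, "s01", relaxed)), 2)
})

test_that("a gap larger than max_gap_bp splits a run without disqualifying flanks", {
  pos <- c(seq(1e6, by = 10000, length.out = 150),
           seq(1e6 + 149 * 10000 + 1000001, by = 10000, length.out = 150))
  p <- planted_panel(rep(0L, 300), pos)
  segs <- detect_roh(p, "s01", roh_params(min_snps = 100, min_length_bp = 1e6))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$end_bp[1], pos[150])
  expect_equal(segs$start_bp[2], pos[151])
  # a gap of exactly 1,000,000 does not split
  pos2 <- c(seq(1e6, by = 10000, length.out = 150),
            seq(1e6 + 149 * 10000 + 1e6, by = 10000, length.out = 150))
  segs2 <- detect_roh(planted_panel(rep(0L, 300), pos2), "s01",
                      roh_params(min_snps = 100, min_length_bp = 1e6))
  expect_equal(nrow(segs2), 1)
})

test_that("a run of enough SNPs but short span is rejected on length", {
  pos <- seq(1e6, by = 1000, length.out = 200)    # 199 kb span
  p <- planted_panel(rep(0L, 200), pos)
  expect_equal(nrow(detect_roh(p, "s01", roh_params(min_snps = 150))), 0)
})

test_that("missing calls terminate runs when max_missing = 0", {
  pos <- seq(1e6, by = 10000, length.out = 120)
  g <- rep(2L, 120); g[60] <- -1L
  p <- planted_panel(g, pos)
  relaxed <- roh_params(min_snps = 50, min_length_bp = 5e5)
  segs <- detect_roh(p, "s01", relaxed)
  expect_equal(nrow(segs), 2)
  expect_true(all(segs$n_snps == c(59L, 60L)))
})

test_that("het/missing allowances absorb interior calls and trim to homozygous ends", {
  pos <- seq(1e6, by = 10000, length.out = 100)
  g <- rep(0L, 100); g[50] <- 1L
  p <- planted_panel(g, pos)
  segs <- detect_roh(p, "s01", roh_params(min_snps = 90, min_length_bp = 5e5,
                                          max_het = 1))
  expect_equal(nrow(segs), 1)
  expect_equal(segs$n_snps, 99L)                  # hets are not counted
  expect_equal(segs$start_bp, pos[1])
  expect_equal(segs$end_bp, pos[100])
})

test_that("detect_roh equals the exhaustive maximal-interval oracle on random panels", {
  set.seed(202)
  for (rep in 1:15) {
    p <- random_panel(sample(2:5, 1), sample(100:400, 1),
                      n_chrom = sample(1:3, 1), miss_rate = 0.03,
                      chrom_length_bp = 5e6)
    params <- roh_params(min_snps = sample(2:6, 1),
                         min_length_bp = sample(c(1e4, 1e5), 1),
                         max_gap_bp = sample(c(2e5, 1e6), 1))
    for (s in p$samples) {
      got <- detect_roh(p, s, params)
      want <- roh_oracle(p, s, params)
      expect_equal(got, want, info = sprintf("rep %d sample %s", rep, s))
    }
  }
})

test_that("relaxing any single threshold never decreases the segment count", {
  set.seed(303)
  for (rep in 1:8) {
    p <- random_panel(2, 300, n_chrom = 2, miss_rate = 0.02,
                      chrom_length_bp = 5e6)
    base <- roh_params(min_snps = 6, min_length_bp = 1e5, max_gap_bp = 3e5)
    n0 <- nrow(detect_roh_all(p, base))
    expect_gte(nrow(detect_roh_all(p, roh_params(min_snps = 3,
      min_length_bp = 1e5, max_gap_bp = 3e5))), n0)
    expect_gte(nrow(detect_roh_all(p, roh_params(min_snps = 6,
      min_length_bp = 5e4, max_gap_bp = 3e5))), n0)
    expect_gte(nrow(detect_roh_all(p, roh_params(min_snps = 6,
      min_length_bp = 1e5, max_gap_bp = 6e5))), n0)
  }
})

test_that("ROH calls on one chromosome ignore other chromosomes (locality)", {
  set.seed(404)
  p2 <- random_panel(2, 200, n_chrom = 2, chrom_length_bp = 5e6)
  p1 <- p2[, p2$map$chrom == 1L]
  params <- roh_params(min_snps = 4, min_length_bp = 5e4)
  for (s in p1$samples) {
    full <- detect_roh(p2, s, params)
    chr1 <- full[full$chrom == 1L, ]
    rownames(chr1) <- NULL
    expect_equal(chr1, detect_roh(p1, s, params))
  }
})

test_that("length classes bin left-closed right-open with an overflow class", {
  expect_equal(as.character(bin_length_class(1.5e6)), "1-2")
  expect_equal(as.character(bin_length_class(2e6)), "2-4")      # boundary
  expect_equal(as.character(bin_length_class(14291629)), "8-16")
  expect_equal(as.character(bin_length_class(2e7)), "16+")
  expect_error(bin_length_class(9e5), "1 Mb")
})

test_that("summarize_roh reports the documented statistics on a trivial case", {
  segs <- data.frame(sample = "s1", chrom = 1L, start_bp = 1e6,
                     end_bp = 3e6 - 1, n_snps = 200L, length_bp = 2e6)
  s <- summarize_roh(segs, samples = "s1", genome_length_bp = 1e8,
                     population = "P")
  expect_equal(s$total_roh, 1)
  expect_equal(s$mean_count, 1)
  expect_equal(s$mean_coverage_pct, 2)
  expect_equal(as.integer(s$class_counts["2-4"]), 1L)
  expect_equal(sum(s$class_counts), s$total_roh)
})

test_that("summarize_roh matches a flat recount on random populations", {
  set.seed(505)
  samples <- sprintf("s%02d", 1:6)
  segs <- do.call(rbind, lapply(1:5, function(k) {
    n <- sample(0:4, 1)
    if (n == 0) return(NULL)
    len <- runif(n, 1e6, 1.7e7)
    data.frame(sample = samples[k], chrom = 1L, start_bp = 1,
               end_bp = len, n_snps = 10L, length_bp = len)
  }))
  s <- summarize_roh(segs, samples, genome_length_bp = 1e9)
  counts <- vapply(samples, function(x) sum(segs$sample == x), numeric(1))
  expect_equal(s$total_roh, nrow(segs))
  expect_equal(s$mean_count, mean(counts))
  expect_equal(s$sd_count, sd(counts))
  expect_equal(s$min_count, min(counts))          # includes the 0 sample
  expect_equal(s$mean_length_bp, mean(segs$length_bp))
  per_sum <- vapply(samples, function(x)
    sum(segs$length_bp[segs$sample == x]), numeric(1))
  expect_equal(s$mean_coverage_bp, mean(per_sum))
  expect_equal(sum(s$class_counts), nrow(segs))
})

test_that("f_roh is summed ROH length over genome length", {
  expect_equal(f_roh(empty_segments(), "s1")$f_roh, 0)
  segs <- data.frame(sample = "s1", chrom = 1L, start_bp = 1,
                     end_bp = 902020024, n_snps = 100L,
                     length_bp = 902020024)
  expect_equal(f_roh(segs, "s1")$f_roh, 1)
  segs2 <- data.frame(sample = c("s1", "s1"), chrom = 1:2,
                      start_bp = 1, end_bp = c(2e6, 3e6), n_snps = 10L,
                      length_bp = c(2e6, 3e6))
  expect_equal(f_roh(segs2, "s1", genome_length_bp = 1e8)$f_roh, 0.05)
  expect_error(f_roh(segs2, "s1", genome_length_bp = 0), "positive")
})

test_that("froh_vs_fhom recovers a hand-computed OLS fit", {
  froh <- data.frame(sample = paste0("s", 1:5),
                     f_roh = c(0.10, 0.20, 0.30, 0.40, 0.50))
  fhom <- data.frame(sample = paste0("s", 1:5),
                     f_hom = c(0.05, 0.12, 0.34, 0.38, 0.52))
  r <- froh_vs_fhom(froh, fhom)
  # hand-computed: Sxx = 0.1, Sxy = 0.12, Syy = 0.14968
  expect_equal(r$slope, 1.2, tolerance = 1e-12)
  expect_equal(r$intercept, 0.282 - 1.2 * 0.3, tolerance = 1e-12)
  expect_equal(r$r, 0.12 / sqrt(0.1 * 0.14968), tolerance = 1e-12)
  # identity input: slope 1, correlation 1
  ident <- froh_vs_fhom(froh, data.frame(sample = froh$sample,
                                         f_hom = froh$f_roh))
  expect_equal(ident$slope, 1)
  expect_equal(ident$r, 1)
  expect_error(froh_vs_fhom(froh[1:2, ], fhom[1:2, ]), "3")
  expect_error(froh_vs_fhom(froh, data.frame(sample = froh$sample,
                                             f_hom = 0.2)), "variance")
})

test_that("noise-free simulated IBD segments are fully recovered; het noise reduces sensitivity", {
  sim <- simulate_breeds(sim_config(
    n_breeds = 4, n_per_breed = 2, founder_haplotypes = 4, n_chrom = 2,
    chrom_length_bp = 1e8, n_snps_per_chrom = 1200, generations = 8,
    theta_fst = 0.05, seed = 99))
  params <- roh_params(min_snps = 10, min_length_bp = 1e6)
  segs <- detect_roh_all(sim$panel, params)
  truth <- sim$truth$ibd_segments
  eligible <- truth[truth$n_snps >= params$min_snps &
                    (truth$end_bp - truth$start_bp + 1) >=
                      params$min_length_bp, ]
  covered <- function(segtab) vapply(seq_len(nrow(eligible)), function(r) {
    any(segtab$sample == eligible$sample[r] &
        segtab$chrom == eligible$chrom[r] &
        segtab$start_bp <= eligible$start_bp[r] &
        segtab$end_bp >= eligible$end_bp[r])
  }, logical(1))
  expect_true(nrow(eligible) > 0)
  expect_true(all(covered(segs)))                 # sensitivity = 1
  noisy <- add_genotyping_noise(sim$panel, het_error = 0.02, seed = 1)
  segs_noisy <- detect_roh_all(noisy, params)
  expect_lte(sum(covered(segs_noisy)), sum(covered(segs)))
})
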