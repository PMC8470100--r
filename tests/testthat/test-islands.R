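grid_markers <- function(m = 20, chrom = 1L, step = 1e5) {
  data.frame(snp_id = sprintf("c%dm%d", chrom, 1:m), chrom = chrom,
             pos_bp = (1:m) * step, allele_a = "A", allele_b = "G",
             stringsAsFactors = FALSE)
}

seg <- function(sample, chrom, start, end) {
  data.frame(sample = sample, chrom = chrom, start_bp = start,
             end_bp = end, stringsAsFactors = FALSE)
}

test_that("incidence counts samples whose ROH covers each SNP", {
  mk <- grid_markers(10)
  none <- incidence(seg(character(), integer(), numeric(), numeric()),
                    mk, 5)
  expect_true(all(none$count == 0))
  one <- incidence(seg("s1", 1L, 3e5, 7e5), mk, 5)
  expect_equal(one$count, c(0, 0, 1, 1, 1, 1, 1, 0, 0, 0))
  expect_equal(one$fraction, one$count / 5)
  # two ROH of the same sample over one SNP still count once
  dup <- incidence(rbind(seg("s1", 1L, 3e5, 5e5), seg("s1", 1L, 5e5, 7e5)),
                   mk, 5)
  expect_equal(max(dup$count), 1)
})

test_that("incidence equals the brute-force containment scan on random fixtures", {
  set.seed(61)
  for (rep in 1:10) {
    mk <- rbind(grid_markers(15, 1L), grid_markers(15, 2L))
    segs <- random_segments(sample(3:8, 1), mk)
    n <- length(unique(segs$sample))
    inc <- incidence(segs, mk, n)
    expect_equal(inc$count, incidence_oracle(segs, mk, n))
  }
})

test_that("sharing thresholds reproduce the printed worked examples", {
  expect_identical(sharing_threshold(181, 0.75), 136L)
  expect_identical(sharing_threshold(25, 0.60), 15L)
  expect_identical(sharing_threshold(4, 0.75), 3L)
  expect_identical(sharing_threshold(10, 0.7), 7L)
  expect_identical(sharing_threshold(31, 0.75), 24L)
  expect_identical(sharing_threshold(1, 1), 1L)
  expect_error(sharing_threshold(0, 0.5))
  expect_error(sharing_threshold(10, 0))
})

test_that("exact-boundary islands require the sharing threshold", {
  shared <- do.call(rbind, lapply(sprintf("s%02d", 1:8), function(s)
    seg(s, 1L, 3e5, 9e5)))
  segs <- rbind(shared, seg("s09", 1L, 3e5, 8e5))
  isl <- find_islands(segs, population_size = 10, fraction = 0.75)
  expect_equal(nrow(isl), 1)                      # 8 >= ceil(7.5)
  expect_equal(isl$n_samples_sharing, 8L)
  expect_equal(c(isl$start_bp, isl$end_bp), c(3e5, 9e5))
  isl7 <- find_islands(segs[segs$sample != "s08", ], 10, 0.75)
  expect_equal(nrow(isl7), 0)                     # 7 < 8
})

test_that("find_islands matches the brute-force grouping oracle and is monotone", {
  set.seed(62)
  for (rep in 1:10) {
    mk <- grid_markers(12)
    segs <- random_segments(10, mk, n_per_sample = 4)
    got <- find_islands(segs, 10, 0.3)
    want <- island_oracle(segs, 10, 0.3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(got[c("chrom", "start_bp", "end_bp",
                         "n_samples_sharing")],
                   want[c("chrom", "start_bp", "end_bp",
                          "n_samples_sharing")])
    }
    lower <- find_islands(segs, 10, 0.2)
    expect_gte(nrow(lower), nrow(got))
    key <- function(x) paste(x$chrom, x$start_bp, x$end_bp)
    expect_true(all(key(got) %in% key(lower)))
  }
})

test_that("exact-boundary sharing implies incidence sharing inside each island", {
  set.seed(63)
  mk <- grid_markers(12)
  segs <- random_segments(8, mk, n_per_sample = 4)
  isl <- find_islands(segs, 8, 0.25)
  inc <- incidence(segs, mk, 8)
  for (r in seq_len(nrow(isl))) {
    inside <- inc$chrom == isl$chrom[r] & inc$pos_bp >= isl$start_bp[r] &
      inc$pos_bp <= isl$end_bp[r]
    expect_true(all(inc$fraction[inside] >= 0.25))
  }
})

test_that("the incidence-based caller emits maximal qualifying SNP runs", {
  mk <- grid_markers(10)
  segs <- do.call(rbind, lapply(sprintf("s%02d", 1:8), function(s)
    seg(s, 1L, 3e5, 6e5)))
  segs$end_bp[1] <- 5e5   # one sample stops earlier
  isl <- find_islands(segs, 8, 0.75, method = "incidence", markers = mk)
  expect_equal(nrow(isl), 1)
  expect_equal(c(isl$start_bp, isl$end_bp), c(3e5, 6e5))
  expect_equal(isl$n_samples_sharing, 7L)   # min incidence inside the run
})

test_that("cross-population sharing merges overlapping islands with union bounds", {
  a <- data.frame(population = "A", chrom = 1L, start_bp = 1e5,
                  end_bp = 5e5, n_samples_sharing = 8L,
                  threshold_used = 0.75)
  b <- data.frame(population = "B", chrom = 1L, start_bp = 4e5,
                  end_bp = 9e5, n_samples_sharing = 9L,
                  threshold_used = 0.75)
  merged <- cross_breed_sharing(rbind(a, b))
  expect_equal(nrow(merged), 1)
  expect_equal(merged$populations, "A,B")
  expect_equal(c(merged$start_bp, merged$end_bp), c(1e5, 9e5))
  # identical intervals merge too; disjoint ones do not appear
  b2 <- b; b2$start_bp <- 6e5; b2$end_bp <- 9e5
  expect_equal(nrow(cross_breed_sharing(rbind(a, b2))), 0)
  c2 <- a; c2$population <- "C"
  expect_equal(cross_breed_sharing(rbind(a, c2))$n_populations, 2L)
})

test_that("cross-population sharing agrees with a pairwise-overlap oracle", {
  set.seed(64)
  for (rep in 1:10) {
    mk <- grid_markers(10)
    isl <- do.call(rbind, lapply(c("A", "B", "C"), function(pop) {
      n <- sample(1:4, 1)
      do.call(rbind, lapply(seq_len(n), function(k) {
        ij <- sort(sample(10, 2))
        data.frame(population = pop, chrom = 1L,
                   start_bp = mk$pos_bp[ij[1]], end_bp = mk$pos_bp[ij[2]],
                   n_samples_sharing = 5L, threshold_used = 0.75)
      }))
    }))
    merged <- cross_breed_sharing(isl)
    # every multi-population merged region must contain >= 2 populations'
    # islands, and every pair of islands from different populations that
    # overlap must fall inside a single merged region
    overlap <- function(a, b)
      a$start_bp <= b$end_bp & b$start_bp <= a$end_bp
    for (i in seq_len(nrow(isl))) for (j in seq_len(nrow(isl))) {
      if (i >= j) next
      if (isl$population[i] == isl$population[j]) next
      if (!overlap(isl[i, ], isl[j, ])) next
      hits <- merged$start_bp <= min(isl$start_bp[c(i, j)]) &
        merged$end_bp >= max(isl$end_bp[c(i, j)])
      expect_true(any(hits), info = sprintf("rep %d pair %d-%d", rep, i, j))
    }
  }
})

test_that("island-gene annotation follows 1 bp overlap semantics", {
  isl <- data.frame(population = "A", chrom = c(1L, 1L), start_bp = c(1e5, 7e5),
                    end_bp = c(3e5, 9e5), n_samples_sharing = 8L,
                    threshold_used = 0.75)
  genes <- data.frame(gene = c("G_in", "G_abut", "G_span", "G_other"),
                      chrom = c(1L, 1L, 1L, 1L),
                      start_bp = c(1.5e5, 3e5 + 1, 8e5, 5e5),
                      end_bp = c(2e5, 4e5, 1e6, 6e5))
  ann <- annotate_islands(isl, genes)
  expect_equal(ann$genes[1], "G_in")     # fully inside
  expect_equal(ann$genes[2], "G_span")   # 1-bp-or-more overlap
  expect_false(grepl("G_abut", ann$genes[1]))  # abuts at end+1: excluded
  expect_equal(ann$n_genes, c(1L, 1L))
  bad <- genes; bad$chrom <- 99L
  expect_error(annotate_islands(isl, bad), "chromosome labels")
})

test_that("annotation matches the all-pairs oracle and bedtools intersect", {
  set.seed(65)
  mk <- grid_markers(20)
  isl <- do.call(rbind, lapply(1:6, function(k) {
    ij <- sort(sample(20, 2))
    data.frame(population = "A", chrom = sample(1:2, 1),
               start_bp = mk$pos_bp[ij[1]], end_bp = mk$pos_bp[ij[2]],
               n_samples_sharing = 5L, threshold_used = 0.75)
  }))
  genes <- do.call(rbind, lapply(1:15, function(k) {
    s <- sample(2e6, 1)
    data.frame(gene = sprintf("g%02d", k), chrom = sample(1:2, 1),
               start_bp = s, end_bp = s + sample(5e4:5e5, 1))
  }))
  ann <- annotate_islands(isl, genes)
  for (r in seq_len(nrow(isl))) {
    hits <- character()
    gs <- genes[order(genes$chrom, genes$start_bp), ]
    for (k in seq_len(nrow(gs))) {
      if (gs$chrom[k] == isl$chrom[r] &&
          gs$start_bp[k] <= isl$end_bp[r] &&
          gs$end_bp[k] >= isl$start_bp[r])
        hits <- c(hits, gs$gene[k])
    }
    expect_equal(ann$genes[r], paste(hits, collapse = ","))
  }
  # cross-check against bedtools intersect (0-based half-open export)
  if (nzchar(Sys.which("bedtools"))) {
    dir <- withr::local_tempdir()
    write_islands_bed(isl, file.path(dir, "isl.bed"))
    gb <- data.frame(genes$chrom, genes$start_bp - 1, genes$end_bp,
                     genes$gene)
    write.table(gb[order(gb[[1]], gb[[2]]), ], file.path(dir, "genes.bed"),
                sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
    out <- system2("bedtools",
                   c("intersect", "-wa", "-wb", "-a",
                     file.path(dir, "isl.bed"), "-b",
                     file.path(dir, "genes.bed")), stdout = TRUE)
    bt_pairs <- if (length(out)) {
      parts <- do.call(rbind, strsplit(out, "\t"))
      sort(paste(parts[, 1], as.numeric(parts[, 2]) + 1, parts[, 9]))
    } else character()
    our_pairs <- sort(unlist(lapply(seq_len(nrow(ann)), function(r) {
      if (!nzchar(ann$genes[r])) return(NULL)
      paste(ann$chrom[r], ann$start_bp[r],
            strsplit(ann$genes[r], ",")[[1]])
    })))
    expect_equal(our_pairs, bt_pairs)
  }
})
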