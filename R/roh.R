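#' ROH detection parameters
#'
#' Parameters of the consecutive-run method. Defaults reproduce the standard
#' SNP-array setting for detecting autozygosity while avoiding runs created
#' by linkage disequilibrium alone: runs of at least 150 homozygous SNPs
#' spanning at least 1 Mb, with no heterozygous or missing call allowed
#' inside a run and a maximum gap of 1,000 kb between consecutive SNPs.
#'
#' @param min_length_bp minimum run length in bp (first to last member SNP,
#'   inclusive). Default 1e6.
#' @param min_snps minimum number of member SNPs in a run. Default 150.
#' @param max_het maximum heterozygous calls tolerated inside a run.
#'   Default 0.
#' @param max_missing maximum missing calls tolerated inside a run.
#'   Default 0.
#' @param max_gap_bp maximum bp distance between consecutive member SNPs.
#'   Default 1e6.
#' @return A list of class `roh_params`.
#' @export
roh_params <- function(min_length_bp = 1e6, min_snps = 150L,
                       max_het = 0L, max_missing = 0L, max_gap_bp = 1e6) {
  stopifnot(min_length_bp >= 0, min_snps >= 0, max_het >= 0,
            max_missing >= 0, max_gap_bp >= 0)
  structure(list(min_length_bp = min_length_bp, min_snps = as.integer(min_snps),
                 max_het = as.integer(max_het),
                 max_missing = as.integer(max_missing),
                 max_gap_bp = max_gap_bp),
            class = "roh_params")
}

# Scan one chromosome of one sample. g: genotype codes; pos: positions
# (sorted). Returns data.frame(start_idx, end_idx, n_snps).
# A run grows over consecutive homozygous SNPs, absorbing up to max_het
# heterozygous and max_missing missing calls; it is cut by an over-budget
# call or by a gap > max_gap_bp. Absorbed het/missing calls are interior:
# runs are trimmed to start and end on homozygous SNPs.
scan_chromosome <- function(g, pos, params) {
  m <- length(g)
  runs <- list()
  i <- 1L
  while (i <= m) {
    if (!(g[i] %in% c(0L, 2L))) { i <- i + 1L; next }
    # grow from i
    het_used <- 0L; miss_used <- 0L
    last_hom <- i
    j <- i + 1L
    while (j <= m) {
      if (pos[j] - pos[j - 1L] > params$max_gap_bp) break
      if (g[j] %in% c(0L, 2L)) {
        last_hom <- j
      } else if (g[j] == 1L) {
        if (het_used >= params$max_het) break
        het_used <- het_used + 1L
      } else {
        if (miss_used >= params$max_missing) break
        miss_used <- miss_used + 1L
      }
      j <- j + 1L
    }
    runs[[length(runs) + 1L]] <- c(i, last_hom)
    i <- if (j > last_hom) j else last_hom + 1L
    # skip the blocking call itself when it was a genotype (not a gap)
    if (i <= m && !(g[i] %in% c(0L, 2L)) &&
        (i == 1L || pos[i] - pos[i - 1L] <= params$max_gap_bp))
      i <- i + 1L
  }
  if (!length(runs))
    return(data.frame(start_idx = integer(), end_idx = integer()))
  out <- do.call(rbind, runs)
  data.frame(start_idx = out[, 1], end_idx = out[, 2])
}

#' Detect runs of homozygosity in one sample
#'
#' Consecutive-run scan: per chromosome, a maximal run grows over
#' consecutive homozygous SNPs and is terminated by a heterozygous call
#' (once `max_het` is exhausted), a missing call (once `max_missing` is
#' exhausted), or a positional gap greater than `max_gap_bp` between
#' consecutive SNPs. A terminated run is emitted iff it contains at least
#' `min_snps` member SNPs and spans at least `min_length_bp`
#' (`end_bp - start_bp + 1`, boundaries at the first and last member SNP).
#' Runs never span chromosomes; a gap splits a run but does not disqualify
#' its flanks.
#'
#' @param panel a [genotype_panel()] with a sorted marker map.
#' @param sample sample id (or `NULL` with `detect_roh_all()` for every
#'   sample).
#' @param params a [roh_params()] object.
#' @return Data frame of segments: `sample`, `chrom`, `start_bp`, `end_bp`,
#'   `n_snps`, `length_bp`; non-overlapping and sorted within the sample.
#' @examples
#' p <- sim_example_panel()
#' segs <- detect_roh(p, p$samples[1],
#'                    roh_params(min_snps = 10, min_length_bp = 1e5))
#' head(segs)
#' @export
detect_roh <- function(panel, sample, params = roh_params()) {
  row <- match(sample, panel$samples)
  if (is.na(row)) stop("unknown sample: ", sample)
  g_all <- panel$genotypes[row, ]
  out <- vector("list", 0)
  for (ch in unique(panel$map$chrom)) {
    idx <- which(panel$map$chrom == ch)
    g <- g_all[idx]
    pos <- panel$map$pos_bp[idx]
    runs <- scan_chromosome(g, pos, params)
    if (!nrow(runs)) next
    start_bp <- pos[runs$start_idx]
    end_bp <- pos[runs$end_idx]
    n_snps <- vapply(seq_len(nrow(runs)), function(k) {
      gg <- g[runs$start_idx[k]:runs$end_idx[k]]
      sum(gg %in% c(0L, 2L))
    }, integer(1))
    length_bp <- end_bp - start_bp + 1
    keep <- n_snps >= params$min_snps & length_bp >= params$min_length_bp
    if (!any(keep)) next
    out[[length(out) + 1L]] <- data.frame(
      sample = sample, chrom = ch, start_bp = start_bp[keep],
      end_bp = end_bp[keep], n_snps = n_snps[keep],
      length_bp = length_bp[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(empty_roh_frame())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start_bp), , drop = FALSE]
  rownames(res) <- NULL
  res
}

empty_roh_frame <- function() {
  data.frame(sample = character(), chrom = integer(), start_bp = numeric(),
             end_bp = numeric(), n_snps = integer(), length_bp = numeric(),
             stringsAsFactors = FALSE)
}

#' Detect ROH for every sample of a panel
#'
#' @param panel a [genotype_panel()].
#' @param params a [roh_params()] object.
#' @return One data frame of segments for all samples (see [detect_roh()]).
#' @export
detect_roh_all <- function(panel, params = roh_params()) {
  segs <- lapply(panel$samples, function(s) detect_roh(panel, s, params))
  out <- do.call(rbind, segs)
  if (is.null(out)) out <- empty_roh_frame()
  rownames(out) <- NULL
  out
}

#' Length class of an ROH segment
#'
#' Bins segment lengths into the four canonical classes 1--2, 2--4, 4--8 and
#' 8--16 Mb (left-closed, right-open) with an overflow class `"16+"`.
#'
#' @param length_bp numeric vector of segment lengths in bp (>= 1 Mb).
#' @return Factor with levels `"1-2"`, `"2-4"`, `"4-8"`, `"8-16"`, `"16+"`.
#' @examples
#' bin_length_class(c(1.5e6, 2e6, 14291629))
#' @export
bin_length_class <- function(length_bp) {
  if (any(length_bp < 1e6))
    stop("ROH shorter than 1 Mb cannot be binned")
  cut(length_bp / 1e6, breaks = c(1, 2, 4, 8, 16, Inf), right = FALSE,
      labels = c("1-2", "2-4", "4-8", "8-16", "16+"))
}

#' Per-population ROH summary
#'
#' Descriptive statistics of a population's ROH segments: total count,
#' per-animal count range and mean (SD), length range and mean, mean summed
#' coverage in bp and as a percent of the genome, and counts per length
#' class. Samples with zero ROH contribute zero counts.
#'
#' @param segments segment data frame from [detect_roh_all()] (any subset).
#' @param samples character vector of the population's sample ids (including
#'   samples without segments).
#' @param genome_length_bp autosomal genome length used for coverage
#'   percent. Default 902,020,024 bp (SNP-covered autosomal length of a
#'   600K turkey array panel).
#' @param population label stored in the output.
#' @return A list of class `roh_summary`.
#' @export
summarize_roh <- function(segments, samples, genome_length_bp = 902020024,
                          population = "ALL") {
  if (!length(samples)) stop("empty population")
  segments <- segments[segments$sample %in% samples, , drop = FALSE]
  counts <- table(factor(segments$sample, levels = samples))
  per_sample_sum <- tapply(segments$length_bp,
                           factor(segments$sample, levels = samples), sum)
  per_sample_sum[is.na(per_sample_sum)] <- 0
  class_levels <- c("1-2", "2-4", "4-8", "8-16", "16+")
  cls <- if (nrow(segments)) table(bin_length_class(segments$length_bp))
         else table(factor(character(), levels = class_levels))
  mean_cov <- mean(per_sample_sum)
  structure(list(
    population = population,
    n_samples = length(samples),
    total_roh = nrow(segments),
    min_count = min(counts), max_count = max(counts),
    mean_count = mean(counts), sd_count = stats::sd(counts),
    min_length_bp = if (nrow(segments)) min(segments$length_bp) else NA_real_,
    max_length_bp = if (nrow(segments)) max(segments$length_bp) else NA_real_,
    mean_length_bp = if (nrow(segments)) mean(segments$length_bp) else NA_real_,
    mean_coverage_bp = mean_cov,
    mean_coverage_pct = 100 * mean_cov / genome_length_bp,
    class_counts = cls,
    genome_length_bp = genome_length_bp
  ), class = "roh_summary")
}

#' @export
print.roh_summary <- function(x, ...) {
  cat(sprintf("ROH summary [%s]: %d samples, %d segments\n", x$population,
              x$n_samples, x$total_roh))
  cat(sprintf("  per-animal count: %d-%d, mean %.1f (sd %.1f)\n",
              x$min_count, x$max_count, x$mean_count, x$sd_count))
  if (x$total_roh)
    cat(sprintf("  length bp: %.0f-%.0f, mean %.0f\n", x$min_length_bp,
                x$max_length_bp, x$mean_length_bp))
  cat(sprintf("  mean coverage: %.0f bp (%.2f%% of genome)\n",
              x$mean_coverage_bp, x$mean_coverage_pct))
  print(x$class_counts)
  invisible(x)
}

#' Convert ROH summaries to a one-row-per-population data frame
#'
#' @param summaries a list of `roh_summary` objects.
#' @return Data frame mirroring the usual per-breed ROH table.
#' @export
roh_summary_table <- function(summaries) {
  rows <- lapply(summaries, function(s) {
    cc <- as.list(as.integer(s$class_counts))
    names(cc) <- paste0("n_", gsub("-", "_", names(s$class_counts)), "Mb")
    cbind(data.frame(population = s$population, n_samples = s$n_samples,
                     total_roh = s$total_roh, min_count = s$min_count,
                     max_count = s$max_count, mean_count = s$mean_count,
                     sd_count = s$sd_count, min_length_bp = s$min_length_bp,
                     max_length_bp = s$max_length_bp,
                     mean_length_bp = s$mean_length_bp,
                     mean_coverage_bp = s$mean_coverage_bp,
                     mean_coverage_pct = s$mean_coverage_pct),
          as.data.frame(cc))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genomic inbreeding coefficient from ROH (F_ROH)
#'
#' F_ROH of a sample is the summed length of its ROH segments divided by the
#' length of the autosomal genome covered by the marker panel.
#'
#' @param segments segment data frame (one or more samples).
#' @param samples sample ids to report (samples without segments get 0).
#' @param genome_length_bp denominator; default 902,020,024 bp.
#' @return Data frame: `sample`, `sum_roh_bp`, `genome_length_bp`, `f_roh`.
#' @examples
#' f_roh(data.frame(sample = "s1", chrom = 1, start_bp = 1e6,
#'                  end_bp = 362474e3 - 1, n_snps = 200,
#'                  length_bp = 361474000), "s1")
#' @export
f_roh <- function(segments, samples = unique(segments$sample),
                  genome_length_bp = 902020024) {
  if (genome_length_bp <= 0) stop("genome_length_bp must be positive")
  sums <- tapply(segments$length_bp,
                 factor(segments$sample, levels = samples), sum)
  sums[is.na(sums)] <- 0
  data.frame(sample = samples, sum_roh_bp = as.numeric(sums),
             genome_length_bp = genome_length_bp,
             f_roh = as.numeric(sums) / genome_length_bp,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Regression of F_HOM on F_ROH
#'
#' Ordinary least-squares fit and Pearson correlation between the two
#' genomic inbreeding coefficients over the samples of one population,
#' with F_ROH as the predictor.
#'
#' @param froh data frame from [f_roh()] (columns `sample`, `f_roh`).
#' @param fhom data frame from [f_hom()] (columns `sample`, `f_hom`).
#' @return A list: `slope`, `intercept`, `r` (Pearson), `n`.
#' @export
froh_vs_fhom <- function(froh, fhom) {
  merged <- merge(froh[c("sample", "f_roh")], fhom[c("sample", "f_hom")],
                  by = "sample")
  if (nrow(merged) < 3) stop("need at least 3 samples")
  if (stats::sd(merged$f_roh) == 0 || stats::sd(merged$f_hom) == 0)
    stop("zero variance in f_roh or f_hom")
  fit <- stats::lm(f_hom ~ f_roh, data = merged)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(merged$f_roh, merged$f_hom),
       n = nrow(merged))
}

#' Export ROH segments as BED
#'
#' Converts the package's 1-based inclusive coordinates to BED's 0-based
#' half-open convention.
#'
#' @param segments segment data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_roh_bed <- function(segments, path) {
  bed <- data.frame(chrom = segments$chrom,
                    start = segments$start_bp - 1,
                    end = segments$end_bp,
                    name = segments$sample)
  utils::write.table(format(bed, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
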