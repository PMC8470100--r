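#' Per-SNP ROH incidence track
#'
#' For every SNP of the map, counts the samples having at least one ROH
#' segment whose `[start_bp, end_bp]` interval contains the SNP position —
#' the quantity plotted in Manhattan-style homozygosity maps.
#'
#' @param segments ROH segment data frame (one population's samples).
#' @param markers marker map data frame (`snp_id`, `chrom`, `pos_bp`).
#' @param population_size number of samples in the population (denominator
#'   of the incidence fraction).
#' @return Data frame: `snp_id`, `chrom`, `pos_bp`, `count`, `fraction`.
#' @export
incidence <- function(segments, markers, population_size) {
  stopifnot(population_size >= 1)
  count <- integer(nrow(markers))
  for (s in unique(segments$sample)) {
    seg_s <- segments[segments$sample == s, , drop = FALSE]
    covered <- logical(nrow(markers))
    for (r in seq_len(nrow(seg_s))) {
      hit <- markers$chrom == seg_s$chrom[r] &
        markers$pos_bp >= seg_s$start_bp[r] &
        markers$pos_bp <= seg_s$end_bp[r]
      covered <- covered | hit
    }
    count <- count + covered
  }
  data.frame(snp_id = markers$snp_id, chrom = markers$chrom,
             pos_bp = markers$pos_bp, count = count,
             fraction = count / population_size, stringsAsFactors = FALSE)
}

#' Sample-sharing threshold for ROH islands
#'
#' Smallest integer number of samples that is at least `fraction` of `n` —
#' the within-breed threshold for calling an ROH island (the threshold in
#' birds is a function of each breed's sample size).
#'
#' @param n population size (>= 1).
#' @param fraction sharing fraction in (0, 1].
#' @return Integer count.
#' @examples
#' sharing_threshold(181, 0.75)  # 136
#' sharing_threshold(25, 0.60)   # 15
#' @export
sharing_threshold <- function(n, fraction) {
  stopifnot(n >= 1, fraction > 0, fraction <= 1)
  # tolerance guards against floating-point excess just above an integer
  as.integer(ceiling(fraction * n - 1e-9))
}

#' Find ROH islands of a population
#'
#' The default, exact-boundary definition groups segments by identical
#' `(chrom, start_bp, end_bp)` and emits groups shared by at least
#' [sharing_threshold()] distinct samples: an island is a run with the same
#' boundaries (and hence the same length) in a large fraction of the
#' population. The alternative `method = "incidence"` emits maximal runs of
#' consecutive SNPs whose per-SNP incidence fraction reaches the threshold
#' (boundaries at the first/last qualifying SNP).
#'
#' @param segments ROH segment data frame of the population's samples.
#' @param population_size number of samples in the population.
#' @param fraction sharing threshold fraction; default 0.75.
#' @param method `"exact"` (default) or `"incidence"`.
#' @param markers marker map; required for `method = "incidence"`.
#' @param population label stored in the output.
#' @return Data frame: `population`, `chrom`, `start_bp`, `end_bp`,
#'   `n_samples_sharing`, `threshold_used`, sorted by genome position.
#' @export
find_islands <- function(segments, population_size, fraction = 0.75,
                         method = c("exact", "incidence"), markers = NULL,
                         population = "ALL") {
  method <- match.arg(method)
  thr <- sharing_threshold(population_size, fraction)
  empty <- data.frame(population = character(), chrom = integer(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_samples_sharing = integer(),
                      threshold_used = numeric(), stringsAsFactors = FALSE)
  if (method == "exact") {
    if (!nrow(segments)) return(empty)
    key <- paste(segments$chrom, segments$start_bp, segments$end_bp,
                 sep = ":")
    n_share <- vapply(split(segments$sample, key),
                      function(s) length(unique(s)), integer(1))
    keep <- names(n_share)[n_share >= thr]
    if (!length(keep)) return(empty)
    parts <- do.call(rbind, strsplit(keep, ":", fixed = TRUE))
    out <- data.frame(population = population,
                      chrom = as.integer(parts[, 1]),
                      start_bp = as.numeric(parts[, 2]),
                      end_bp = as.numeric(parts[, 3]),
                      n_samples_sharing = as.integer(n_share[keep]),
                      threshold_used = fraction, stringsAsFactors = FALSE)
  } else {
    if (is.null(markers))
      stop("method = 'incidence' requires the marker map")
    inc <- incidence(segments, markers, population_size)
    qual <- inc$count >= thr
    if (!any(qual)) return(empty)
    out_rows <- list()
    for (ch in unique(inc$chrom[qual])) {
      sel <- which(inc$chrom == ch & qual)
      brk <- c(0, which(diff(sel) != 1), length(sel))
      for (k in seq_len(length(brk) - 1)) {
        run <- sel[(brk[k] + 1):brk[k + 1]]
        out_rows[[length(out_rows) + 1L]] <- data.frame(
          population = population, chrom = ch,
          start_bp = inc$pos_bp[run[1]],
          end_bp = inc$pos_bp[run[length(run)]],
          n_samples_sharing = min(inc$count[run]),
          threshold_used = fraction, stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, out_rows)
  }
  out <- out[order(out$chrom, out$start_bp), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-population sharing of ROH islands
#'
#' Merges islands from different populations into shared regions: islands
#' on the same chromosome whose intervals overlap by at least 1 bp (1-based
#' inclusive) are united transitively; each region reports the union
#' boundaries and its contributing populations.
#'
#' @param islands island data frame (rows from [find_islands()] across
#'   populations, column `population` distinguishing them).
#' @return Data frame: `chrom`, `start_bp`, `end_bp`, `populations`
#'   (comma-separated), `n_populations`, sorted by position.
#' @export
cross_breed_sharing <- function(islands) {
  if (length(unique(islands$population)) < 2)
    stop("need islands from >= 2 populations")
  rows <- list()
  for (ch in sort(unique(islands$chrom))) {
    x <- islands[islands$chrom == ch, , drop = FALSE]
    x <- x[order(x$start_bp, x$end_bp), , drop = FALSE]
    cur_start <- x$start_bp[1]; cur_end <- x$end_bp[1]
    cur_pops <- x$population[1]
    flush <- function() {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = ch, start_bp = cur_start, end_bp = cur_end,
        populations = paste(sort(unique(cur_pops)), collapse = ","),
        n_populations = length(unique(cur_pops)), stringsAsFactors = FALSE)
    }
    for (r in seq_len(nrow(x))[-1]) {
      if (x$start_bp[r] <= cur_end) {   # >= 1 bp overlap (inclusive coords)
        cur_end <- max(cur_end, x$end_bp[r])
        cur_pops <- c(cur_pops, x$population[r])
      } else {
        flush()
        cur_start <- x$start_bp[r]; cur_end <- x$end_bp[r]
        cur_pops <- x$population[r]
      }
    }
    flush()
  }
  out <- do.call(rbind, rows)
  out <- out[out$n_populations >= 2, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Annotate ROH islands with overlapping genes
#'
#' Pure interval intersection (intersectBed semantics on 1-based inclusive
#' coordinates): a gene is reported for an island iff the two intervals
#' overlap by at least 1 bp. Genes are listed in genome-position order.
#'
#' @param islands island data frame (`chrom`, `start_bp`, `end_bp`).
#' @param genes gene table: columns `gene`, `chrom`, `start_bp`, `end_bp`
#'   (see [read_gene_table()]).
#' @return The island data frame with added columns `genes`
#'   (comma-separated symbols, `""` when none) and `n_genes`.
#' @export
annotate_islands <- function(islands, genes) {
  stopifnot(all(c("gene", "chrom", "start_bp", "end_bp") %in% names(genes)))
  if (any(genes$start_bp > genes$end_bp)) stop("gene with start > end")
  if (nrow(islands) && nrow(genes) &&
      !any(unique(genes$chrom) %in% unique(islands$chrom)))
    stop("no shared chromosome labels between islands and genes; ",
         "gene labels: ", paste(utils::head(unique(genes$chrom), 5),
                                collapse = ","),
         " vs island labels: ", paste(utils::head(unique(islands$chrom), 5),
                                      collapse = ","))
  genes <- genes[order(genes$chrom, genes$start_bp), , drop = FALSE]
  res <- character(nrow(islands)); n_genes <- integer(nrow(islands))
  for (r in seq_len(nrow(islands))) {
    hit <- genes$chrom == islands$chrom[r] &
      genes$start_bp <= islands$end_bp[r] &
      genes$end_bp >= islands$start_bp[r]
    res[r] <- paste(genes$gene[hit], collapse = ",")
    n_genes[r] <- sum(hit)
  }
  islands$genes <- res
  islands$n_genes <- n_genes
  islands
}

#' Read a gene interval table
#'
#' Accepts BED (0-based half-open; converted to 1-based inclusive) or a
#' 4-column TSV with header `gene, chrom, start_bp, end_bp` (1-based
#' inclusive).
#'
#' @param path input path.
#' @param format `"tsv"` (default) or `"bed"`.
#' @return Data frame: `gene`, `chrom`, `start_bp`, `end_bp`.
#' @export
read_gene_table <- function(path, format = c("tsv", "bed")) {
  format <- match.arg(format)
  if (format == "bed") {
    x <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
    data.frame(gene = x[[4]], chrom = x[[1]], start_bp = x[[2]] + 1,
               end_bp = x[[3]], stringsAsFactors = FALSE)
  } else {
    utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                      colClasses = c(gene = "character"))
  }
}

#' Export islands as BED (0-based half-open)
#'
#' @param islands island data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_islands_bed <- function(islands, path) {
  bed <- data.frame(chrom = islands$chrom, start = islands$start_bp - 1,
                    end = islands$end_bp, name = islands$population,
                    score = islands$n_samples_sharing)
  utils::write.table(format(bed, scientific = FALSE, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
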