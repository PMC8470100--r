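#' Construct a genotype panel
#'
#' A `genotype_panel` holds diploid biallelic genotypes for a set of samples
#' at a set of mapped autosomal SNPs, together with the marker map and a
#' population label per sample. It is the substrate of every analysis in the
#' package.
#'
#' Genotypes are coded per SNP as the count of the B allele: `0` (homozygous
#' A), `1` (heterozygous), `2` (homozygous B), and `-1` for a missing call.
#' Coordinates are 1-based base-pair positions throughout the package; only
#' BED export converts to 0-based half-open.
#'
#' @param genotypes integer matrix, samples in rows and SNPs in columns,
#'   values in \{-1, 0, 1, 2\}. Row names (if any) must match `samples`.
#' @param map data frame with columns `snp_id`, `chrom` (integer autosome
#'   index), `pos_bp` (1-based position), `allele_a`, `allele_b`.
#' @param samples character vector of sample ids, one per genotype row.
#' @param populations character vector of population labels, parallel to
#'   `samples` (or a named vector keyed by sample id).
#' @param sort_map sort markers by (chrom, pos_bp) when they arrive unsorted
#'   (with a warning). Duplicate positions on a chromosome are allowed but
#'   flagged with a warning.
#'
#' @return An object of class `genotype_panel`: a list with elements
#'   `genotypes`, `map`, `samples`, `populations`.
#' @examples
#' gt <- rbind(c(0L, 1L, 2L), c(2L, 1L, -1L))
#' map <- data.frame(snp_id = paste0("rs", 1:3), chrom = 1L,
#'                   pos_bp = c(100L, 200L, 300L),
#'                   allele_a = "A", allele_b = "G")
#' p <- genotype_panel(gt, map, samples = c("s1", "s2"),
#'                     populations = c("POP1", "POP1"))
#' p
#' @export
genotype_panel <- function(genotypes, map, samples, populations,
                           sort_map = TRUE) {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "integer"
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  required <- c("snp_id", "chrom", "pos_bp", "allele_a", "allele_b")
  missing_cols <- setdiff(required, names(map))
  if (length(missing_cols))
    stop("marker map lacks columns: ", paste(missing_cols, collapse = ", "))
  map$chrom <- as.integer(map$chrom)
  map$pos_bp <- as.numeric(map$pos_bp)
  map$snp_id <- as.character(map$snp_id)

  samples <- as.character(samples)
  if (!is.null(names(populations)))
    populations <- unname(populations[samples])
  populations <- as.character(populations)

  if (nrow(genotypes) != length(samples))
    stop("genotype rows (", nrow(genotypes), ") != samples (",
         length(samples), ")")
  if (ncol(genotypes) != nrow(map))
    stop("genotype columns (", ncol(genotypes), ") != map rows (",
         nrow(map), ")")
  if (length(populations) != length(samples) || anyNA(populations))
    stop("every sample needs a population label")
  if (anyDuplicated(samples))
    stop("duplicate sample ids: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  if (anyDuplicated(map$snp_id))
    stop("duplicate snp ids in map")
  bad <- !(genotypes %in% c(-1L, 0L, 1L, 2L))
  if (any(bad))
    stop("genotype codes outside {-1,0,1,2} at ", sum(bad), " cells")

  ord <- order(map$chrom, map$pos_bp)
  if (is.unsorted(ord) || any(ord != seq_len(nrow(map)))) {
    if (!sort_map)
      stop("marker map is not sorted by (chrom, pos_bp)")
    if (nrow(map) > 0) {
      warning("marker map unsorted; sorting by (chrom, pos_bp)")
      map <- map[ord, , drop = FALSE]
      rownames(map) <- NULL
      genotypes <- genotypes[, ord, drop = FALSE]
    }
  }
  dup <- duplicated(map[c("chrom", "pos_bp")])
  if (any(dup))
    warning(sum(dup), " duplicate (chrom, pos_bp) positions in map")

  dimnames(genotypes) <- list(samples, map$snp_id)
  structure(
    list(genotypes = genotypes, map = map, samples = samples,
         populations = populations),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel: ", length(x$samples), " samples x ",
      nrow(x$map), " SNPs\n", sep = "")
  tab <- table(x$populations)
  cat("populations: ",
      paste(sprintf("%s (%d)", names(tab), tab), collapse = ", "), "\n",
      sep = "")
  if (nrow(x$map))
    cat("chromosomes: ", paste(sort(unique(x$map$chrom)), collapse = " "),
        "\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) c(length(x$samples), nrow(x$map))

#' Subset a genotype panel
#'
#' @param x a `genotype_panel`.
#' @param i sample index (integer, logical, or sample ids).
#' @param j SNP index (integer, logical, or snp ids).
#' @param ... unused.
#' @return A `genotype_panel` restricted to the selected samples/SNPs.
#' @export
`[.genotype_panel` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_along(x$samples)
  if (missing(j)) j <- seq_len(nrow(x$map))
  if (is.character(i)) i <- match(i, x$samples)
  if (is.character(j)) j <- match(j, x$map$snp_id)
  map <- x$map[j, , drop = FALSE]
  rownames(map) <- NULL
  genotype_panel(x$genotypes[i, j, drop = FALSE], map,
                 x$samples[i], x$populations[i], sort_map = FALSE)
}

#' Samples belonging to one population
#'
#' @param panel a `genotype_panel`.
#' @param population population label.
#' @return Character vector of sample ids.
#' @export
population_samples <- function(panel, population) {
  out <- panel$samples[panel$populations == population]
  if (!length(out)) stop("no samples in population '", population, "'")
  out
}

#' Write / read the native TSV genotype format
#'
#' The native format is a pair of tab-separated files: a genotype matrix with
#' a header row of SNP ids and columns `sample`, `population` followed by one
#' column per SNP (codes -1/0/1/2), and a marker map with columns
#' `snp_id`, `chrom`, `pos_bp`, `allele_a`, `allele_b`.
#'
#' @param panel a `genotype_panel`.
#' @param genotype_path path of the genotype TSV.
#' @param map_path path of the marker map TSV.
#' @return `write_genotypes_tsv` returns the paths invisibly;
#'   `read_genotypes_tsv` returns a `genotype_panel`.
#' @export
write_genotypes_tsv <- function(panel, genotype_path, map_path) {
  gdf <- data.frame(sample = panel$samples, population = panel$populations,
                    panel$genotypes, check.names = FALSE)
  utils::write.table(gdf, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(panel$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genotype_path, map_path))
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(genotype_path, map_path) {
  gdf <- utils::read.table(genotype_path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  map <- utils::read.table(map_path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  gt <- as.matrix(gdf[, -(1:2), drop = FALSE])
  genotype_panel(gt, map, gdf$sample, gdf$population)
}
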