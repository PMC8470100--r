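#' Read a PLINK text PED/MAP file pair
#'
#' Parses whitespace-separated PLINK text files into a [genotype_panel()].
#' The MAP file must have four columns (chromosome, snp id, genetic position,
#' bp position); the PED file six leading columns (family, individual,
#' father, mother, sex, phenotype) followed by two allele calls per marker.
#' The family id becomes the population label. Missing alleles are coded
#' `"0"`; a genotype with either allele missing becomes `-1`.
#'
#' Unless `allele_ref` is given, the A allele of each marker is the first
#' non-missing allele encountered in file order (all downstream statistics
#' are invariant to this orientation). A third allele at a marker is a parse
#' error naming the marker; a ragged PED row is a parse error naming the
#' line.
#'
#' @param ped_path path to the .ped file.
#' @param map_path path to the .map file.
#' @param allele_ref optional data frame with columns `snp_id`, `allele_a`,
#'   `allele_b` fixing the allele orientation per marker.
#' @return A [genotype_panel()].
#' @export
read_ped_map <- function(ped_path, map_path, allele_ref = NULL) {
  if (!file.exists(ped_path)) stop("PED file not found: ", ped_path)
  if (!file.exists(map_path)) stop("MAP file not found: ", map_path)

  map_raw <- utils::read.table(map_path, header = FALSE,
                               stringsAsFactors = FALSE,
                               col.names = c("chrom", "snp_id", "cm", "pos_bp"))
  m <- nrow(map_raw)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  expected <- 6L + 2L * m
  n <- length(fields)

  fam <- character(n); iid <- character(n)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (k in seq_len(n)) {
    f <- fields[[k]]
    if (length(f) != expected)
      stop("PED line ", k, " has ", length(f), " fields; expected ",
           expected)
    fam[k] <- f[1]; iid[k] <- f[2]
    al <- f[-(1:6)]
    a1[k, ] <- al[seq(1, by = 2, length.out = m)]
    a2[k, ] <- al[seq(2, by = 2, length.out = m)]
  }

  gt <- matrix(-1L, n, m)
  allele_a <- character(m); allele_b <- character(m)
  if (!is.null(allele_ref)) {
    idx <- match(map_raw$snp_id, allele_ref$snp_id)
    if (anyNA(idx))
      stop("allele_ref lacks markers: ",
           paste(map_raw$snp_id[is.na(idx)][1:min(5, sum(is.na(idx)))],
                 collapse = ", "))
    allele_a <- as.character(allele_ref$allele_a[idx])
    allele_b <- as.character(allele_ref$allele_b[idx])
  }
  for (j in seq_len(m)) {
    alleles <- c(a1[, j], a2[, j])
    obs <- unique(alleles[alleles != "0"])
    if (is.null(allele_ref)) {
      # first-seen allele in sample order (a1 then a2 within a sample)
      seen <- c(rbind(a1[, j], a2[, j]))
      seen <- seen[seen != "0"]
      aa <- if (length(seen)) seen[1] else "A"
      bb <- setdiff(obs, aa)
      if (length(bb) > 1)
        stop("marker ", map_raw$snp_id[j], " has >2 alleles: ",
             paste(sort(obs), collapse = "/"))
      allele_a[j] <- aa
      allele_b[j] <- if (length(bb)) bb else "B"
    } else {
      bad <- setdiff(obs, c(allele_a[j], allele_b[j]))
      if (length(bad))
        stop("marker ", map_raw$snp_id[j], " has allele(s) ",
             paste(bad, collapse = "/"), " not in reference {",
             allele_a[j], ",", allele_b[j], "}")
    }
    miss <- a1[, j] == "0" | a2[, j] == "0"
    gt[, j] <- (a1[, j] == allele_b[j]) + (a2[, j] == allele_b[j])
    gt[miss, j] <- -1L
  }

  map <- data.frame(snp_id = map_raw$snp_id, chrom = map_raw$chrom,
                    pos_bp = map_raw$pos_bp, allele_a = allele_a,
                    allele_b = allele_b, stringsAsFactors = FALSE)
  genotype_panel(gt, map, samples = iid, populations = fam)
}

#' Write a genotype panel as PLINK text PED/MAP
#'
#' Emits whitespace-separated PLINK-compatible text, missing genotypes as
#' `"0 0"`. The population label is written as the family id; father,
#' mother, sex and phenotype are written as 0/0/0/-9.
#'
#' @param panel a [genotype_panel()].
#' @param ped_path output .ped path.
#' @param map_path output .map path.
#' @return The two paths, invisibly.
#' @export
write_ped_map <- function(panel, ped_path, map_path) {
  if (nrow(panel$map)) {
    map_out <- data.frame(panel$map$chrom, panel$map$snp_id, 0,
                          panel$map$pos_bp)
    utils::write.table(map_out, map_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  } else writeLines(character(), map_path)

  n <- length(panel$samples); m <- nrow(panel$map)
  a1 <- matrix("0", n, m); a2 <- matrix("0", n, m)
  for (j in seq_len(m)) {
    g <- panel$genotypes[, j]
    aa <- panel$map$allele_a[j]; bb <- panel$map$allele_b[j]
    a1[, j] <- ifelse(g == 2L, bb, ifelse(g == -1L, "0", aa))
    a2[, j] <- ifelse(g >= 1L, bb, ifelse(g == -1L, "0", aa))
  }
  inter <- matrix("0", n, 2L * m)
  if (m) {
    inter[, seq(1L, 2L * m, 2L)] <- a1
    inter[, seq(2L, 2L * m, 2L)] <- a2
  }
  body <- if (m) apply(inter, 1, paste, collapse = " ") else rep("", n)
  lead <- paste(panel$populations, panel$samples, 0, 0, 0, -9)
  writeLines(if (m) paste(lead, body) else lead, ped_path)
  invisible(c(ped_path, map_path))
}

#' Quality-control filter on SNPs
#'
#' Retains SNPs that lie on an autosome (`chrom <= autosome_max`) and have a
#' per-SNP call rate strictly greater than `callrate_min`, preserving marker
#' order. Ties at exactly the threshold are removed (strict inequality).
#' The returned report reconciles counts exactly: a SNP failing both rules
#' is counted as non-autosomal.
#'
#' @param panel a [genotype_panel()].
#' @param callrate_min minimum call rate, in `[0, 1]`; default `0.99`.
#' @param autosome_max largest autosome index retained; default `30`.
#' @return A list with elements `panel` (the filtered panel) and `report`
#'   (a one-row data frame: `n_snps_in`, `n_snps_out`,
#'   `n_removed_nonautosomal`, `n_removed_callrate`, `callrate_threshold`).
#' @examples
#' p <- sim_example_panel()
#' qc <- qc_filter(p)
#' qc$report
#' @export
qc_filter <- function(panel, callrate_min = 0.99, autosome_max = 30L) {
  stopifnot(callrate_min >= 0, callrate_min <= 1)
  m <- nrow(panel$map)
  autosomal <- panel$map$chrom <= autosome_max & panel$map$chrom >= 1L
  callrate <- if (length(panel$samples))
    colMeans(panel$genotypes != -1L) else rep(1, m)
  pass_cr <- callrate > callrate_min
  keep <- autosomal & pass_cr

  report <- data.frame(
    n_snps_in = m,
    n_snps_out = sum(keep),
    n_removed_nonautosomal = sum(!autosomal),
    n_removed_callrate = sum(autosomal & !pass_cr),
    callrate_threshold = callrate_min
  )
  out <- panel[, keep]
  list(panel = out, report = report)
}

#' Write a QC report as TSV
#'
#' @param report the `report` element returned by [qc_filter()].
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
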