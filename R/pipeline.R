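#' Pipeline run configuration
#'
#' Bundles every stage's parameters for [run_pipeline()]. Exactly one of
#' `ped`/`map` paths, `genotypes`/`map` native TSV paths, or a `simulate`
#' block (a [sim_config()]) must identify the input panel.
#'
#' @param ped,map PLINK PED/MAP input paths (use `map` also with
#'   `genotypes`).
#' @param genotypes native genotype TSV path (see [read_genotypes_tsv()]).
#' @param simulate a [sim_config()] to generate the panel instead of
#'   reading one.
#' @param outdir output directory (created if absent).
#' @param callrate_min,autosome_max QC parameters (see [qc_filter()]).
#' @param roh a [roh_params()] object.
#' @param island_fraction ROH island sharing threshold; default 0.75.
#' @param genome_length_bp F_ROH denominator; default 902,020,024 bp.
#' @param genes optional gene table path (TSV, see [read_gene_table()]).
#' @param ne_max_dist_bp,ne_alpha,ne_recomb_rate Ne stage settings.
#' @param seed integer seed for any stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(ped = NULL, map = NULL, genotypes = NULL,
                       simulate = NULL, outdir = "rohdiv_out",
                       callrate_min = 0.99, autosome_max = 30L,
                       roh = roh_params(), island_fraction = 0.75,
                       genome_length_bp = 902020024, genes = NULL,
                       ne_max_dist_bp = 5e6, ne_alpha = 2,
                       ne_recomb_rate = 1e-8, seed = 1L) {
  n_inputs <- (!is.null(ped)) + (!is.null(genotypes)) + (!is.null(simulate))
  if (n_inputs != 1)
    stop("exactly one of ped, genotypes, simulate must be given")
  if (!is.null(ped) && is.null(map)) stop("ped input needs a map path")
  if (!is.null(genotypes) && is.null(map))
    stop("genotypes input needs a map path")
  structure(list(ped = ped, map = map, genotypes = genotypes,
                 simulate = simulate, outdir = outdir,
                 callrate_min = callrate_min,
                 autosome_max = as.integer(autosome_max), roh = roh,
                 island_fraction = island_fraction,
                 genome_length_bp = genome_length_bp, genes = genes,
                 ne_max_dist_bp = ne_max_dist_bp, ne_alpha = ne_alpha,
                 ne_recomb_rate = ne_recomb_rate, seed = as.integer(seed)),
            class = "run_config")
}

#' Load a run configuration from YAML
#'
#' The YAML mirrors [run_config()] arguments; nested blocks `roh` and
#' `simulate` map to [roh_params()] and [sim_config()].
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configs")
  y <- yaml::read_yaml(path)
  if (!is.null(y$roh)) y$roh <- do.call(roh_params, y$roh)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  do.call(run_config, y)
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Chains QC, per-population diversity, F_HOM, pairwise F_ST, IBS distances
#' with a neighbour-joining tree, PCA, per-sample ROH detection with
#' per-breed summaries, ROH islands (per population and pooled), optional
#' gene annotation, F_ROH with the F_HOM regression, and the LD-based Ne
#' trajectory, writing each result as TSV/Newick under `config$outdir` plus
#' a manifest with MD5 checksums. The run is deterministic given the inputs
#' and the seed. Failure of an optional stage (e.g. Ne on a panel with too
#' few usable SNP pairs) is logged in the manifest and the run continues.
#'
#' @param config a [run_config()].
#' @return Invisibly, a data frame manifest: `file`, `md5`, `status`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  files <- character(); notes <- character()
  add <- function(path, note = "ok") {
    files <<- c(files, path); notes <<- c(notes, note)
  }

  if (!is.null(config$simulate)) {
    sim <- simulate_breeds(config$simulate)
    panel <- sim$panel
    add(write_tsv(sim$truth$per_sample,
                  file.path(config$outdir, "truth_samples.tsv")))
    add(write_tsv(sim$truth$ibd_segments,
                  file.path(config$outdir, "truth_ibd_segments.tsv")))
  } else if (!is.null(config$ped)) {
    panel <- read_ped_map(config$ped, config$map)
  } else {
    panel <- read_genotypes_tsv(config$genotypes, config$map)
  }
  if (anyNA(panel$populations) || any(panel$populations == ""))
    stop("samples without population labels: ",
         paste(panel$samples[is.na(panel$populations) |
                             panel$populations == ""], collapse = ", "))

  qc <- qc_filter(panel, config$callrate_min, config$autosome_max)
  panel <- qc$panel
  add(write_tsv(qc$report, file.path(config$outdir, "qc_report.tsv")))

  add(write_tsv(diversity_table(panel),
                file.path(config$outdir, "diversity.tsv")))
  fhom <- f_hom_all(panel)
  add(write_tsv(fhom, file.path(config$outdir, "fhom.tsv")))

  pops <- unique(panel$populations)
  if (length(pops) >= 2) {
    fst <- fst_matrix(panel)
    add(write_tsv(data.frame(population = rownames(fst), fst,
                             check.names = FALSE),
                  file.path(config$outdir, "fst_matrix.tsv")))
  }
  dist <- ibs_distance(panel)
  add(write_tsv(data.frame(sample = rownames(dist), dist,
                           check.names = FALSE),
                file.path(config$outdir, "ibs_distance.tsv")))
  if (length(panel$samples) >= 3 && !anyNA(dist)) {
    add(write_newick(nj_tree(dist),
                     file.path(config$outdir, "nj_tree.nwk")))
  }
  pca <- tryCatch(pca_scores(panel), error = function(e) e)
  if (!inherits(pca, "error")) {
    add(write_tsv(data.frame(sample = rownames(pca$scores),
                             population = panel$populations, pca$scores),
                  file.path(config$outdir, "pca_scores.tsv")))
  } else add(file.path(config$outdir, "pca_scores.tsv"),
             paste("skipped:", conditionMessage(pca)))

  segs <- detect_roh_all(panel, config$roh)
  add(write_tsv(segs, file.path(config$outdir, "roh_segments.tsv")))
  add(write_roh_bed(segs, file.path(config$outdir, "roh_segments.bed")))

  summaries <- lapply(pops, function(b)
    summarize_roh(segs[segs$sample %in% population_samples(panel, b), ],
                  population_samples(panel, b),
                  config$genome_length_bp, population = b))
  add(write_tsv(roh_summary_table(summaries),
                file.path(config$outdir, "roh_summary.tsv")))

  isl_list <- lapply(pops, function(b) {
    ss <- population_samples(panel, b)
    find_islands(segs[segs$sample %in% ss, ], length(ss),
                 config$island_fraction, population = b)
  })
  islands <- do.call(rbind, isl_list)
  pooled <- find_islands(segs, length(panel$samples),
                         config$island_fraction, population = "ALL")
  add(write_tsv(rbind(islands, pooled),
                file.path(config$outdir, "roh_islands.tsv")))
  inc_all <- do.call(rbind, lapply(pops, function(b) {
    ss <- population_samples(panel, b)
    cbind(population = b,
          incidence(segs[segs$sample %in% ss, ], panel$map, length(ss)))
  }))
  add(write_tsv(inc_all, file.path(config$outdir, "roh_incidence.tsv")))
  if (sum(vapply(isl_list, nrow, integer(1)) > 0) >= 2) {
    add(write_tsv(cross_breed_sharing(islands),
                  file.path(config$outdir, "islands_shared.tsv")))
  }
  if (!is.null(config$genes) && nrow(islands)) {
    genes <- read_gene_table(config$genes)
    add(write_tsv(annotate_islands(islands, genes),
                  file.path(config$outdir, "islands_genes.tsv")))
  }

  froh <- f_roh(segs, panel$samples, config$genome_length_bp)
  froh$population <- panel$populations[match(froh$sample, panel$samples)]
  add(write_tsv(froh, file.path(config$outdir, "froh.tsv")))
  reg <- do.call(rbind, lapply(pops, function(b) {
    ss <- population_samples(panel, b)
    r <- tryCatch(froh_vs_fhom(froh[froh$sample %in% ss, ],
                               fhom[fhom$sample %in% ss, ]),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(population = b, slope = r$slope, intercept = r$intercept,
               r = r$r, n = r$n)
  }))
  if (!is.null(reg))
    add(write_tsv(reg, file.path(config$outdir, "froh_vs_fhom.tsv")))

  for (b in pops) {
    ne <- tryCatch({
      pr <- pairwise_r2(panel, b, config$ne_max_dist_bp)
      estimate_ne(pr, sum(panel$populations == b),
                  recomb_rate = config$ne_recomb_rate,
                  alpha = config$ne_alpha)
    }, error = function(e) e, warning = function(w) {
      suppressWarnings(estimate_ne(pairwise_r2(panel, b,
                                               config$ne_max_dist_bp),
                                   sum(panel$populations == b),
                                   recomb_rate = config$ne_recomb_rate,
                                   alpha = config$ne_alpha))
    })
    path <- file.path(config$outdir, paste0("ne_", b, ".tsv"))
    if (inherits(ne, "error")) add(path, paste("skipped:",
                                               conditionMessage(ne)))
    else add(write_ne_tsv(ne, path))
  }

  manifest <- data.frame(
    file = basename(files),
    md5 = ifelse(file.exists(files), unname(tools::md5sum(files)), ""),
    status = notes, stringsAsFactors = FALSE)
  write_tsv(manifest, file.path(config$outdir, "manifest.tsv"))
  invisible(manifest)
}
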