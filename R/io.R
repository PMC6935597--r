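#' Read a genotype table from TSV or VCF
#'
#' The canonical TSV dialect has one row per individual: metadata
#' columns (`id`, optionally `population`, `latitude`, `longitude`)
#' followed by one column per locus coded 0/1/2/NA (count of the
#' alternate allele).  VCF input maps diploid GT fields `0/0`, `0/1`,
#' `1/1`, `./.` to 0, 1, 2, NA; multi-allelic records are skipped and
#' counted.
#'
#' @param path File path.
#' @param format `"tsv"` or `"vcf"` (guessed from the extension by
#'   default).
#' @return A [genotype_table()]; for VCF input the number of skipped
#'   multi-allelic records is attached as `attr(, "n_multiallelic")`.
#' @export
read_genotypes <- function(path, format = NULL) {
  format <- format %||%
    (if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv")
  if (format == "tsv") {
    d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
    meta <- intersect(geno_meta_cols, names(d))
    loci <- setdiff(names(d), meta)
    g <- as.matrix(d[, loci, drop = FALSE])
    storage.mode(g) <- "double"
    return(genotype_table(g, d[, meta, drop = FALSE]))
  }
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  multi <- grepl(",", vcfR::getALT(v))
  n_multi <- sum(multi)
  v <- v[!multi, ]
  gt <- vcfR::extract.gt(v)
  code <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  code[gt %in% c("0/0", "0|0")] <- 0
  code[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
  code[gt %in% c("1/1", "1|1")] <- 2
  loci <- tibble::tibble(
    locus = rownames(gt) %||% sprintf("L%03d", seq_len(nrow(gt))),
    chrom = vcfR::getCHROM(v), pos = vcfR::getPOS(v)
  )
  out <- genotype_table(t(code),
                        tibble::tibble(id = colnames(gt)),
                        loci)
  attr(out, "n_multiallelic") <- n_multi
  out
}

#' Write a genotype table to the canonical TSV dialect
#' @param g A [genotype_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(g, path) {
  readr::write_tsv(tibble::as_tibble(g), path, progress = FALSE)
  invisible(path)
}

#' Read per-pool allelic depths from a VCF with AD fields
#'
#' @param path VCF path; samples are pools, `AD` holds `ref,alt` depths.
#' @param pool_sizes Named diploid pool sizes (default 20 each).
#' @return A `pool_counts` tibble (`pool`, `chrom`, `pos`, `ref_depth`,
#'   `alt_depth`, `coverage`).
#' @export
read_pool_counts <- function(path, pool_sizes = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("VCF input requires the vcfR package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  ad <- vcfR::extract.gt(v, element = "AD")
  chrom <- vcfR::getCHROM(v)
  pos <- vcfR::getPOS(v)
  long <- tibble::as_tibble(ad) |>
    dplyr::mutate(chrom = chrom, pos = pos) |>
    tidyr::pivot_longer(-c("chrom", "pos"),
                        names_to = "pool", values_to = "ad") |>
    tidyr::separate_wider_delim("ad", ",", names = c("ref_depth",
                                                     "alt_depth")) |>
    dplyr::mutate(ref_depth = as.integer(.data$ref_depth),
                  alt_depth = as.integer(.data$alt_depth),
                  coverage = .data$ref_depth + .data$alt_depth) |>
    dplyr::arrange(.data$pool, .data$chrom, .data$pos)
  pools <- unique(long$pool)
  if (is.null(pool_sizes)) pool_sizes <- setNames(rep(20L, length(pools)),
                                                  pools)
  structure(long, pool_sizes = pool_sizes,
            class = c("pool_counts", class(tibble::tibble())))
}

#' Write genomic regions as BED
#'
#' All coordinates inside the pipeline are 1-based inclusive; BED export
#' is the single 0-based half-open surface, so a region chr14:1000001-
#' 7000000 becomes the BED line `chr14 1000000 7000000`.  Output is
#' sorted by chromosome then start.
#'
#' @param regions A data frame with `chrom`, `start`, `end` (1-based
#'   inclusive).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  r <- tibble::as_tibble(regions)
  if (nrow(r) > 0 && any(r$start > r$end)) {
    abort("region start must not exceed end")
  }
  bed <- r |>
    dplyr::transmute(chrom = .data$chrom,
                     start = as.integer(.data$start - 1),
                     end = as.integer(.data$end)) |>
    dplyr::arrange(.data$chrom, .data$start)
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Assemble and validate a pipeline configuration
#'
#' Bundles every stage parameter with the survey's published defaults:
#' 10% missingness cutoff, Q-value thresholds 0.667 and 0.9, a 2% pool
#' detection limit, per-pool coverage 150-500 with merged minimum 200,
#' quality 20, and a 5% AFS corner mask.  The configuration round-trips
#' losslessly through YAML ([write_pipeline_config()] /
#' [read_pipeline_config()]).
#'
#' @param ... Overrides of the defaults (validated).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    missingness = 0.10,
    max_foreign_fraction = 0.1,
    max_mismatch = 0,
    q_thresholds = c(0.667, 0.9),
    min_pop_size = 3,
    n_perm = 999,
    detection_limit = 0.02,
    cov_range = c(150, 500),
    merged_min_cov = 200,
    min_qual = 20,
    afs_mask = 0.05,
    window_size_bp = 5e5,
    min_snps = 5,
    peak_quantile = 0.99,
    seed = 1L,
    sim = NULL,
    out_dir = NULL
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")))
  }
  cfg <- modifyList(cfg, over, keep.null = TRUE)
  if (cfg$missingness < 0 || cfg$missingness > 1) {
    abort("`missingness` must lie in [0, 1]")
  }
  if (cfg$detection_limit < 0 || cfg$detection_limit >= 0.5) {
    abort("`detection_limit` must lie in [0, 0.5)")
  }
  if (any(cfg$q_thresholds <= 0) || any(cfg$q_thresholds > 1)) {
    abort("`q_thresholds` must lie in (0, 1]")
  }
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg A `pipeline_config`.
#' @param path YAML path.
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

config_hash <- function(cfg) {
  # structural fingerprint of the analysis parameters for provenance;
  # the output location is not an analysis parameter
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  s <- paste(deparse(cfg), collapse = "")
  sum(utf8ToInt(s) * (seq_along(utf8ToInt(s)) %% 97 + 1)) %% 1e9
}

write_output_tsv <- function(x, path, cfg) {
  header <- sprintf("# popflow %s config_hash=%d",
                    as.character(packageVersion("popflow")),
                    config_hash(cfg))
  writeLines(header, path)
  suppressWarnings(
    readr::write_tsv(tibble::as_tibble(x), path, append = TRUE,
                     col_names = TRUE, progress = FALSE))
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in their fixed order — simulate, QC,
#' diversity statistics, lineage assignment, capture detection — and
#' writes each stage's report as a TSV under `cfg$out_dir` (when set)
#' with a provenance header.  Identical configuration and seed give
#' identical outputs.
#'
#' @param cfg A [pipeline_config()]; `cfg$sim` holds a
#'   [lineage_sim_spec()] (required: the pipeline's data source is the
#'   generator).
#' @return A list with the stage results: `sim`, `qc`, `diversity`,
#'   `amova`, `classes`, `capture`, `log` (tibble of key=value entries).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (is.null(cfg$sim)) abort("`cfg$sim` must hold a lineage_sim_spec")
  log <- list()
  note <- function(stage, ...) {
    kv <- c(...)
    log[[length(log) + 1]] <<- tibble::tibble(
      stage = stage, key = names(kv), value = as.character(kv))
  }
  sim <- simulate_lineages(cfg$sim)
  note("simulate", seed = cfg$sim$seed, n_individuals = nrow(sim$genotypes))
  qc <- run_qc(sim$genotypes, sim$diagnostic_panel,
               cfg$max_foreign_fraction, cfg$max_mismatch,
               cfg$missingness)
  note("qc", n_retained = qc$n_retained, n_localities = qc$n_localities)
  retained <- qc$genotypes
  q_sub <- sim$q[match(retained$id, sim$q$id), ]
  classes <- classify_individuals(q_sub, cfg$q_thresholds)
  note("assign", n_pure_0.667 = sum(classes[["pure@0.667"]]))
  div <- diversity_indices(retained, min_pop_size = cfg$min_pop_size)
  note("stats", Fst_gst = signif(div$summary$Fst_gst, 4))
  am <- amova_hierarchical(retained, classes$assigned,
                           min_pop_size = cfg$min_pop_size,
                           n_perm = cfg$n_perm, seed = cfg$seed)
  note("amova", Fct = signif(am$Fct, 4), Fsc = signif(am$Fsc, 4))
  cp_sub <- sim$cp[sim$cp$id %in% retained$id, ]
  hap <- build_cp_haplotypes(cp_sub)
  map <- suppressWarnings(
    map_haplotypes_to_lineages(hap, classes,
                               purity_threshold = max(cfg$q_thresholds)))
  cap <- detect_capture(hap, classes, map,
                        nuclear_threshold = min(cfg$q_thresholds))
  note("capture", n_discordant = cap$n_discordant)
  log <- dplyr::bind_rows(log)
  out <- list(sim = sim, qc = qc, diversity = div, amova = am,
              classes = classes, capture = cap, log = log)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_output_tsv(qc$report[, c("step", "n_in", "n_removed",
                                   "n_retained")],
                     file.path(cfg$out_dir, "qc_report.tsv"), cfg)
    write_output_tsv(div$summary,
                     file.path(cfg$out_dir, "diversity.tsv"), cfg)
    write_output_tsv(glance(am),
                     file.path(cfg$out_dir, "amova.tsv"), cfg)
    write_output_tsv(classes, file.path(cfg$out_dir, "classes.tsv"), cfg)
    write_output_tsv(cap$pairs, file.path(cfg$out_dir, "capture.tsv"),
                     cfg)
    write_output_tsv(log, file.path(cfg$out_dir, "run_log.tsv"), cfg)
  }
  out
}
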