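qc_report <- function(step, removed_ids, n_in, n_out) {
  tibble::tibble(step = step, n_in = n_in, n_removed = length(removed_ids),
                 n_retained = n_out,
                 removed = list(removed_ids))
}

#' Exclude interspecific hybrids by diagnostic-allele fraction
#'
#' Screens individuals against a species-diagnostic SNP panel at which
#' the focal species is expected to be fixed.  An individual's foreign
#' fraction is its share of non-focal alleles across non-missing panel
#' calls; individuals exceeding `max_foreign_fraction` are removed (an
#' F1 hybrid, heterozygous throughout the panel, scores 0.5).
#'
#' @param g A [genotype_table()] containing the panel loci.
#' @param diagnostic_panel Either a character vector of panel locus names
#'   (focal allele assumed to be the reference) or a data frame with
#'   columns `locus` and `focal` (`"ref"` or `"alt"`).
#' @param max_foreign_fraction Removal threshold on the foreign-allele
#'   fraction (strict `>`).
#' @return A list with the filtered `genotypes` (panel loci dropped), a
#'   one-row `report`, and the per-individual `foreign_fraction` tibble.
#' @export
exclude_hybrids <- function(g, diagnostic_panel, max_foreign_fraction = 0.1) {
  if (is.character(diagnostic_panel)) {
    diagnostic_panel <- tibble::tibble(locus = diagnostic_panel,
                                       focal = "ref")
  }
  diagnostic_panel <- tibble::as_tibble(diagnostic_panel)
  missing_loci <- setdiff(diagnostic_panel$locus, geno_locus_names(g))
  if (length(missing_loci) > 0) {
    abort(paste0("diagnostic panel loci absent from genotypes: ",
                 paste(missing_loci, collapse = ", ")))
  }
  m <- geno_matrix(g)[, diagnostic_panel$locus, drop = FALSE]
  # foreign allele dosage per call: alt count where focal is ref, and
  # vice versa
  flip <- diagnostic_panel$focal == "alt"
  m[, flip] <- 2 - m[, flip]
  foreign <- rowSums(m, na.rm = TRUE) / (2 * rowSums(!is.na(m)))
  foreign[is.nan(foreign)] <- 0  # no panel calls: cannot flag
  drop <- foreign > max_foreign_fraction
  kept <- g$id[!drop]
  out <- geno_subset_individuals(g, kept)
  # panel loci have served their purpose; drop them from the analysis set
  keep_loci <- setdiff(geno_locus_names(out), diagnostic_panel$locus)
  loci <- dplyr::filter(geno_loci(out), .data$locus %in% keep_loci)
  out <- new_geno_tbl(
    dplyr::select(tibble::as_tibble(out),
                  dplyr::any_of(geno_meta_cols), dplyr::all_of(keep_loci)),
    loci
  )
  list(genotypes = out,
       report = qc_report("hybrids", g$id[drop], nrow(g), nrow(out)),
       foreign_fraction = tibble::tibble(id = g$id,
                                         foreign_fraction = foreign))
}

#' Remove clonal duplicates
#'
#' Collapses sets of individuals whose pairwise genotype mismatch count
#' (ignoring loci missing in either member) is at most `max_mismatch`,
#' keeping the first member in input order.  `max_mismatch = 0` collapses
#' exact multilocus matches; a small positive value absorbs genotyping
#' error.
#'
#' @param g A [genotype_table()].
#' @param max_mismatch Maximum mismatching loci for two individuals to be
#'   called ramets of one genet.
#' @return A list with filtered `genotypes` and a one-row `report`.
#' @export
remove_clones <- function(g, max_mismatch = 0) {
  m <- geno_matrix(g)
  n <- nrow(m)
  # pairwise mismatches ignoring missing, via genotype-class indicators
  nonmiss <- (!is.na(m)) * 1
  matches <- Reduce(`+`, lapply(0:2, function(k) {
    tcrossprod((nonmiss == 1 & !is.na(m) & m == k) * 1)
  }))
  mismatch <- tcrossprod(nonmiss) - matches
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i] || i == n) next
    j <- seq.int(i + 1L, n)
    keep[j][keep[j] & mismatch[i, j] <= max_mismatch] <- FALSE
  }
  out <- geno_subset_individuals(g, g$id[keep])
  list(genotypes = out,
       report = qc_report("clones", g$id[!keep], nrow(g), nrow(out)))
}

#' Filter individuals by genotype missingness
#'
#' Removes individuals whose fraction of missing calls is strictly
#' greater than `threshold` (default 10%): with 93 loci, 10 missing
#' calls (10.75%) is removed, 9 (9.68%) is retained.
#'
#' @param g A [genotype_table()].
#' @param threshold Maximum tolerated missing fraction, in `[0, 1]`.
#' @return A list with filtered `genotypes` and a one-row `report`.
#' @export
filter_missingness <- function(g, threshold = 0.10) {
  if (threshold < 0 || threshold > 1) abort("`threshold` must be in [0, 1]")
  m <- geno_matrix(g)
  frac <- rowMeans(is.na(m))
  keep <- frac <= threshold
  out <- geno_subset_individuals(g, g$id[keep])
  list(genotypes = out,
       report = qc_report("missingness", g$id[!keep], nrow(g), nrow(out)))
}

#' Full sample-retention chain
#'
#' Applies the survey's QC pipeline in its fixed order — hybrid
#' exclusion, clone removal, missingness filtering — and returns the
#' retained genotypes with an additive report (removed counts per step
#' plus retained individuals and localities sum to the input).
#'
#' @inheritParams exclude_hybrids
#' @inheritParams remove_clones
#' @inheritParams filter_missingness
#' @return A list with `genotypes` and a three-row `report` tibble.
#' @export
run_qc <- function(g, diagnostic_panel, max_foreign_fraction = 0.1,
                   max_mismatch = 0, threshold = 0.10) {
  s1 <- exclude_hybrids(g, diagnostic_panel, max_foreign_fraction)
  s2 <- remove_clones(s1$genotypes, max_mismatch)
  s3 <- filter_missingness(s2$genotypes, threshold)
  report <- dplyr::bind_rows(s1$report, s2$report, s3$report)
  n_loc <- if ("population" %in% names(s3$genotypes)) {
    dplyr::n_distinct(s3$genotypes$population)
  } else NA_integer_
  list(genotypes = s3$genotypes, report = report,
       n_retained = nrow(s3$genotypes), n_localities = n_loc)
}
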