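#' Build chloroplast haplotypes from cpSNP calls
#'
#' Concatenates each individual's haploid chloroplast alleles across the
#' retained cp loci into a haplotype string, excludes individuals with
#' any missing cp call, and catalogues the haplotypes by frequency.
#' Heterozygous organellar calls are impossible for a haploid genome and
#' raise an error naming the individual and locus.
#'
#' @param cp A data frame with column `id` and one single-letter allele
#'   column per cp locus (`NA` for a failed call).  A call containing two
#'   different alleles (e.g. `"A/T"`) is rejected.
#' @return A list of class `haplotype_table`:
#'   `haplotypes` (tibble `id`, `haplotype`), `catalogue` (tibble
#'   `haplotype`, `n`, `freq`, sorted by frequency), `excluded`
#'   (ids with missing calls).
#' @export
build_cp_haplotypes <- function(cp) {
  cp <- tibble::as_tibble(cp)
  loci <- setdiff(names(cp), "id")
  if (length(loci) == 0) abort("no cp locus columns found")
  for (lc in loci) {
    calls <- as.character(cp[[lc]])
    het <- !is.na(calls) & grepl("[/|]", calls) &
      vapply(strsplit(calls, "[/|]"), function(x) length(unique(x)) > 1,
             logical(1))
    if (any(het)) {
      abort(sprintf(
        "heterozygous organellar call for individual %s at locus %s",
        cp$id[which(het)[1]], lc))
    }
    cp[[lc]] <- sub("[/|].*$", "", calls)
  }
  complete <- stats::complete.cases(cp[, loci])
  hap <- apply(cp[complete, loci, drop = FALSE], 1, paste0, collapse = "")
  haplotypes <- tibble::tibble(id = cp$id[complete], haplotype = hap)
  catalogue <- haplotypes |>
    dplyr::count(.data$haplotype, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n)) |>
    dplyr::mutate(freq = .data$n / sum(.data$n))
  structure(list(haplotypes = haplotypes, catalogue = catalogue,
                 excluded = cp$id[!complete], loci = loci),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("Chloroplast haplotypes over %d loci (%d individuals, %d excluded)\n",
              length(x$loci), nrow(x$haplotypes), length(x$excluded)))
  print(x$catalogue)
  invisible(x)
}

#' Map chloroplast haplotypes to nuclear lineages
#'
#' Assigns each haplotype to the modal nuclear lineage among its *pure*
#' carriers (pure at `purity_threshold` in the classification), with the
#' modal fraction reported as mapping confidence.  Exact ties map to the
#' lowest lineage index with a warning; haplotypes with no pure carrier
#' are left unmapped and flagged.
#'
#' @param h A [build_cp_haplotypes()] result.
#' @param cls A [classify_individuals()] result.
#' @param purity_threshold Which purity class defines a carrier
#'   (must be one of the classification's thresholds).
#' @return A tibble: `haplotype`, `lineage`, `confidence`, `n_pure`,
#'   `mapped`.
#' @export
map_haplotypes_to_lineages <- function(h, cls, purity_threshold = 0.9) {
  col <- sprintf("pure@%s", format(purity_threshold))
  if (!col %in% names(cls)) {
    abort(sprintf("classification carries no threshold %s",
                  format(purity_threshold)))
  }
  carriers <- dplyr::inner_join(h$haplotypes, cls, by = "id")
  clusters <- attr(cls, "clusters")
  out <- carriers |>
    dplyr::filter(.data[[col]]) |>
    dplyr::count(.data$haplotype, .data$assigned, name = "n") |>
    dplyr::group_by(.data$haplotype) |>
    dplyr::arrange(dplyr::desc(.data$n),
                   match(.data$assigned, clusters),
                   .by_group = TRUE) |>
    dplyr::summarise(
      lineage = .data$assigned[1],
      confidence = .data$n[1] / sum(.data$n),
      n_pure = sum(.data$n),
      tie = sum(.data$n == .data$n[1]) > 1
    )
  if (any(out$tie)) {
    warn(sprintf("tie while mapping haplotype(s) %s; lowest lineage index kept",
                 paste(out$haplotype[out$tie], collapse = ", ")))
  }
  all_haps <- h$catalogue["haplotype"]
  out <- dplyr::left_join(all_haps, out, by = "haplotype") |>
    dplyr::mutate(mapped = !is.na(.data$lineage),
                  n_pure = dplyr::coalesce(.data$n_pure, 0L)) |>
    dplyr::select(-"tie")
  if (any(!out$mapped)) {
    warn(sprintf("haplotype(s) %s have no pure carrier and are unmapped",
                 paste(out$haplotype[!out$mapped], collapse = ", ")))
  }
  out
}

#' Detect directional chloroplast-capture events
#'
#' Counts cytonuclear discordance: an individual is a capture event
#' `i -> j` when its nuclear class is pure lineage `j` (at the chosen
#' nuclear threshold) while its chloroplast haplotype maps to lineage
#' `i != j`.  Counts are reported per ordered lineage pair together with
#' the per-individual rows and the pooled asymmetry ratio
#' (larger direction / smaller direction).
#'
#' @param h A [build_cp_haplotypes()] result.
#' @param cls A [classify_individuals()] result.
#' @param map A haplotype-to-lineage map from
#'   [map_haplotypes_to_lineages()].
#' @param nuclear_threshold Purity threshold defining the nuclear class
#'   (default 0.667, the cluster-membership convention).
#' @return A list of class `capture_report`: `pairs` (tibble
#'   `cp_lineage`, `nuclear_lineage`, `n`), `individuals`,
#'   `n_concordant`, `n_excluded` (unmapped-haplotype or admixed
#'   carriers), `asymmetry`.
#' @export
detect_capture <- function(h, cls, map, nuclear_threshold = 0.667) {
  col <- sprintf("pure@%s", format(nuclear_threshold))
  if (!col %in% names(cls)) {
    abort(sprintf("classification carries no threshold %s",
                  format(nuclear_threshold)))
  }
  d <- h$haplotypes |>
    dplyr::inner_join(cls, by = "id") |>
    dplyr::left_join(map[, c("haplotype", "lineage", "mapped")],
                     by = "haplotype")
  unmapped <- !d$mapped | is.na(d$mapped)
  not_pure <- !d[[col]]
  usable <- !unmapped & !not_pure
  disc <- usable & d$lineage != d$assigned
  individuals <- tibble::tibble(
    id = d$id[disc],
    nuclear_lineage = d$assigned[disc],
    cp_lineage = d$lineage[disc],
    haplotype = d$haplotype[disc]
  )
  pairs <- individuals |>
    dplyr::count(.data$cp_lineage, .data$nuclear_lineage, name = "n")
  asym <- if (nrow(pairs) >= 2) max(pairs$n) / min(pairs$n) else NA_real_
  structure(
    list(pairs = pairs, individuals = individuals,
         n_discordant = sum(disc),
         n_concordant = sum(usable & !disc),
         n_excluded = sum(unmapped | not_pure),
         nuclear_threshold = nuclear_threshold,
         asymmetry = asym),
    class = "capture_report"
  )
}

#' @export
print.capture_report <- function(x, ...) {
  cat(sprintf(
    "Chloroplast capture: %d discordant, %d concordant, %d excluded\n",
    x$n_discordant, x$n_concordant, x$n_excluded))
  print(x$pairs)
  invisible(x)
}
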