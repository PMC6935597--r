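#' Assemble a genotype table
#'
#' The central container of the nuclear-SNP side of the pipeline: one row
#' per individual, one column per locus, genotypes coded as the count of
#' the alternate allele (0, 1, 2) with `NA` for a failed call.  Individual
#' metadata (population, coordinates) travel as leading columns; locus
#' metadata (chromosome, position, gene) travel as an attribute so the
#' table itself stays a plain tibble that pipes through dplyr verbs.
#'
#' @param genotypes A numeric matrix or data frame, individuals x loci,
#'   values in `{0, 1, 2, NA}`.
#' @param individuals A data frame with one row per individual: column
#'   `id` (unique) plus optional `population`, `latitude`, `longitude`.
#' @param loci Optional data frame with one row per locus: column `locus`
#'   (unique, matching the genotype column names) plus optional `chrom`,
#'   `pos`, `gene`.
#'
#' @return A tibble of class `geno_tbl`: metadata columns followed by one
#'   numeric column per locus, with the locus table in `attr(, "loci")`.
#' @examples
#' g <- genotype_table(
#'   matrix(c(0, 1, 2, 1), 2, 2, dimnames = list(NULL, c("L1", "L2"))),
#'   individuals = data.frame(id = c("a", "b"), population = "p1")
#' )
#' geno_loci(g)
#' @export
genotype_table <- function(genotypes, individuals, loci = NULL) {
  genotypes <- as.matrix(genotypes)
  if (is.null(colnames(genotypes))) {
    colnames(genotypes) <- sprintf("L%03d", seq_len(ncol(genotypes)))
  }
  bad <- !(genotypes %in% c(0, 1, 2) | is.na(genotypes))
  if (any(bad)) {
    abort("genotype codes must be 0, 1, 2 or NA")
  }
  individuals <- tibble::as_tibble(individuals)
  if (!"id" %in% names(individuals)) abort("`individuals` needs an `id` column")
  if (anyDuplicated(individuals$id)) abort("individual ids must be unique")
  if (nrow(individuals) != nrow(genotypes)) {
    abort("`individuals` and `genotypes` disagree on the number of rows")
  }
  if (is.null(loci)) {
    loci <- tibble::tibble(locus = colnames(genotypes))
  }
  loci <- tibble::as_tibble(loci)
  if (anyDuplicated(loci$locus)) abort("locus ids must be unique")
  if (!identical(loci$locus, colnames(genotypes))) {
    abort("`loci$locus` must match the genotype column names, in order")
  }
  out <- dplyr::bind_cols(individuals, tibble::as_tibble(genotypes))
  new_geno_tbl(out, loci)
}

new_geno_tbl <- function(x, loci) {
  structure(x, loci = loci, class = c("geno_tbl", class(tibble::tibble())))
}

#' Locus metadata of a genotype table
#' @param g A [genotype_table()].
#' @return A tibble with one row per locus.
#' @export
geno_loci <- function(g) {
  attr(g, "loci") %||% tibble::tibble(locus = geno_locus_names(g))
}

geno_meta_cols <- c("id", "population", "latitude", "longitude")

geno_locus_names <- function(g) setdiff(names(g), geno_meta_cols)

#' Genotypes of a genotype table as a numeric matrix
#' @param g A [genotype_table()].
#' @return Individuals x loci numeric matrix with `id` rownames.
#' @export
geno_matrix <- function(g) {
  m <- as.matrix(as.data.frame(g)[, geno_locus_names(g), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- g$id
  m
}

geno_subset_individuals <- function(g, keep) {
  new_geno_tbl(dplyr::filter(tibble::as_tibble(g), .data$id %in% keep),
               geno_loci(g))
}

#' @export
print.geno_tbl <- function(x, ...) {
  cat(sprintf("# genotype table: %d individuals x %d loci\n",
              nrow(x), length(geno_locus_names(x))))
  NextMethod()
}
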