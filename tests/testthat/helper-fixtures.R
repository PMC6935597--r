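# small constructors shared across test files

toy_genotypes <- function(m, pops = NULL, ids = NULL) {
  m <- as.matrix(m)
  if (is.null(colnames(m))) colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  ids <- ids %||% sprintf("i%02d", seq_len(nrow(m)))
  ind <- tibble::tibble(id = ids)
  if (!is.null(pops)) ind$population <- pops
  genotype_table(m, ind)
}

# genotype matrix for one population from genotype-class counts
geno_from_counts <- function(n0, n1, n2) {
  c(rep(0, n0), rep(1, n1), rep(2, n2))
}

# long pool-frequency tibble from a wide frequency table
toy_pool_freqs <- function(wide, pool_sizes = NULL) {
  pools <- setdiff(names(wide), c("chrom", "pos"))
  if (!"chrom" %in% names(wide)) wide$chrom <- "Chr01"
  if (!"pos" %in% names(wide)) wide$pos <- seq_len(nrow(wide))
  long <- tidyr::pivot_longer(wide, dplyr::all_of(pools),
                              names_to = "pool", values_to = "freq")
  long$coverage <- 300
  if (is.null(pool_sizes)) {
    pool_sizes <- stats::setNames(rep(20L, length(pools)), pools)
  }
  structure(long[, c("pool", "chrom", "pos", "freq", "coverage")],
            pool_sizes = pool_sizes, merged_pool = "merged",
            class = c("pool_freqs", class(tibble::tibble())))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
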