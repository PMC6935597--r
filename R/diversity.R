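#' Expected heterozygosity of a biallelic locus
#'
#' `He = 2 p (1 - p)` for allele frequency `p`.
#'
#' @param p Allele frequency (vectorized), each in `[0, 1]`.
#' @return Numeric vector of expected heterozygosities.
#' @examples
#' expected_heterozygosity(c(0, 0.1, 0.5))
#' @export
expected_heterozygosity <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("allele frequencies must lie in [0, 1]")
  }
  2 * p * (1 - p)
}

# per-population allele frequencies, heterozygote fractions and sizes
# from a genotype matrix; returns list of loci x pop matrices
pop_locus_summaries <- function(m, pop) {
  pops <- unique(pop)
  n <- vapply(pops, function(p) colSums(!is.na(m[pop == p, , drop = FALSE])),
              numeric(ncol(m)))
  s <- vapply(pops, function(p) colSums(m[pop == p, , drop = FALSE],
                                        na.rm = TRUE),
              numeric(ncol(m)))
  h <- vapply(pops, function(p) colSums(m[pop == p, , drop = FALSE] == 1,
                                        na.rm = TRUE),
              numeric(ncol(m)))
  if (ncol(m) == 1) {
    n <- matrix(n, nrow = 1); s <- matrix(s, nrow = 1)
    h <- matrix(h, nrow = 1)
  }
  colnames(n) <- colnames(s) <- colnames(h) <- pops
  list(pops = pops, n = n, freq = s / (2 * n), het = h / n)
}

# Weir & Cockerham (1984) variance components a, b, c per locus
wc_components <- function(n, p, h) {
  r <- ncol(n)
  a <- b <- cc <- numeric(nrow(n))
  for (l in seq_len(nrow(n))) {
    ok <- n[l, ] > 0
    if (sum(ok) < 2) { a[l] <- b[l] <- cc[l] <- NA_real_; next }
    ni <- n[l, ok]; pi <- p[l, ok]; hi <- h[l, ok]
    ri <- length(ni)
    nbar <- mean(ni)
    nc <- (ri * nbar - sum(ni^2) / (ri * nbar)) / (ri - 1)
    pbar <- sum(ni * pi) / (ri * nbar)
    s2 <- sum(ni * (pi - pbar)^2) / ((ri - 1) * nbar)
    hbar <- sum(ni * hi) / (ri * nbar)
    a[l] <- (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - s2 * (ri - 1) / ri - hbar / 4) / (nbar - 1))
    b[l] <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (ri - 1) / ri - hbar * (2 * nbar - 1) / (4 * nbar))
    cc[l] <- hbar / 2
  }
  list(a = a, b = b, c = cc)
}

#' Diversity and differentiation indices
#'
#' Computes the survey's standard table of indices over a genotype table:
#' observed heterozygosity (Ho), mean within-population expected
#' heterozygosity (Hs, with Nei's `2n/(2n-1)` small-sample correction
#' when `sample_size_correction` is set), total expected heterozygosity
#' (Ht, from the unweighted mean of population allele frequencies),
#' `Fis = 1 - Ho/Hs`, and two multilocus Fst estimators reported side by
#' side: Nei's `Gst = (Ht - Hs)/Ht` as a ratio of multilocus means, and
#' the Weir-Cockerham variance-components estimator `theta`.  Populations
#' below `min_pop_size` genotyped individuals are dropped before any
#' calculation.
#'
#' @param g A [genotype_table()] (or plain data frame with an `id`
#'   column and numeric locus columns).
#' @param populations Population label per individual; defaults to the
#'   table's `population` column.
#' @param min_pop_size Minimum individuals for a population to enter.
#' @param sample_size_correction Apply Nei's small-sample correction to
#'   Hs (and the matching `2n/(2n-1)` inflation inside Ht).
#' @return An object of class `div_stats`: a list with `summary` (one
#'   row), `per_locus` (tibble) and bookkeeping fields.  `tidy()` returns
#'   the per-locus table, `glance()` the one-row summary.
#' @export
diversity_indices <- function(g, populations = NULL, min_pop_size = 3,
                              sample_size_correction = TRUE) {
  populations <- populations %||% g$population
  m <- geno_matrix(g)
  sizes <- table(populations[rowSums(!is.na(m)) >= 0])
  keep_pops <- names(sizes)[sizes >= min_pop_size]
  if (length(keep_pops) < 2) {
    abort("need at least two populations passing `min_pop_size`")
  }
  sel <- populations %in% keep_pops
  m <- m[sel, , drop = FALSE]
  pop <- populations[sel]
  ps <- pop_locus_summaries(m, pop)

  ho_pl <- rowMeans(ps$het, na.rm = TRUE)
  hs_raw <- expected_heterozygosity(ps$freq)
  corr <- if (sample_size_correction) (2 * ps$n) / (2 * ps$n - 1) else 1
  hs_pl <- rowMeans(hs_raw * corr, na.rm = TRUE)
  pbar <- rowMeans(ps$freq, na.rm = TRUE)
  ht_pl <- expected_heterozygosity(pbar)
  if (sample_size_correction) {
    # Nei & Chesser (1983): Ht_hat = Ht + Hs_hat / (2 n_harm r)
    r <- ncol(ps$freq)
    nharm <- r / rowSums(1 / pmax(ps$n, 1e-12))
    ht_pl <- ht_pl + hs_pl / (2 * nharm * r)
  }
  wc <- wc_components(ps$n, ps$freq, ps$het)

  gst_raw <- (sum(ht_pl) - sum(hs_pl)) / sum(ht_pl)
  theta_raw <- sum(wc$a, na.rm = TRUE) /
    sum(wc$a + wc$b + wc$c, na.rm = TRUE)
  summary <- tibble::tibble(
    n = nrow(m), n_pop = length(keep_pops), n_loci = ncol(m),
    Ho = mean(ho_pl, na.rm = TRUE),
    Hs = mean(hs_pl, na.rm = TRUE),
    Ht = mean(ht_pl, na.rm = TRUE),
    Fis = 1 - mean(ho_pl, na.rm = TRUE) / mean(hs_pl, na.rm = TRUE),
    Fst_gst = max(gst_raw, 0), Fst_gst_raw = gst_raw,
    Fst_theta = max(theta_raw, 0), Fst_theta_raw = theta_raw
  )
  per_locus <- tibble::tibble(
    locus = colnames(m), Ho = ho_pl, Hs = hs_pl, Ht = ht_pl,
    Gst = (ht_pl - hs_pl) / ht_pl,
    theta = wc$a / (wc$a + wc$b + wc$c)
  )
  structure(list(summary = summary, per_locus = per_locus,
                 populations = keep_pops,
                 sample_size_correction = sample_size_correction),
            class = "div_stats")
}

#' @export
print.div_stats <- function(x, ...) {
  cat("Diversity and differentiation indices\n")
  print(x$summary)
  invisible(x)
}
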