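new_afs_grid <- function(counts, n, m, pools = c("A", "B"),
                         mask = NULL, n_snps = sum(counts),
                         normalized = FALSE) {
  if (is.null(mask)) mask <- matrix(FALSE, nrow(counts), ncol(counts))
  dimnames(counts) <- list(0:(2 * n), 0:(2 * m))
  structure(list(counts = counts, mask = mask, n = n, m = m,
                 pools = pools, n_snps = n_snps,
                 normalized = normalized,
                 polarization = "alternate allele vs reference genome"),
            class = "afs_grid")
}

#' Build the joint two-pool allele-frequency spectrum
#'
#' Bins each SNP's pool allele frequencies into joint allele-count
#' classes: for pools of `N` and `M` diploids the grid is
#' `(2N + 1) x (2M + 1)` (41 x 41 for two pools of 20), cell indices are
#' `round(freq * 2N)` with halves rounded away from zero, and each SNP
#' increments one cell, so the grid total equals the SNP count.
#'
#' @param p A `pool_freqs` tibble carrying `attr(, "pool_sizes")`, or a
#'   wide tibble of frequencies with columns named after the pools.
#' @param pool_a,pool_b Names of the two pools.
#' @param pool_sizes Named diploid pool sizes; taken from the attribute
#'   when absent.
#' @return An `afs_grid` object.
#' @examples
#' f <- tibble::tibble(chrom = "Chr01", pos = 1, A = 0.5, B = 0.5)
#' build_afs(f, "A", "B", pool_sizes = c(A = 20, B = 20))
#' @export
build_afs <- function(p, pool_a, pool_b, pool_sizes = NULL) {
  pool_sizes <- pool_sizes %||% attr(p, "pool_sizes")
  if (is.null(pool_sizes) || !all(c(pool_a, pool_b) %in% names(pool_sizes))) {
    abort("pool sizes missing for the requested pools")
  }
  w <- if ("pool" %in% names(p)) pool_freq_wide(p) else tibble::as_tibble(p)
  if (!all(c(pool_a, pool_b) %in% names(w))) {
    abort("requested pools not present in the frequency table")
  }
  n <- as.integer(pool_sizes[[pool_a]])
  m <- as.integer(pool_sizes[[pool_b]])
  fa <- w[[pool_a]]; fb <- w[[pool_b]]
  ok <- !is.na(fa) & !is.na(fb)
  ia <- round_half_up(fa[ok] * 2 * n)
  ib <- round_half_up(fb[ok] * 2 * m)
  counts <- matrix(0, 2 * n + 1, 2 * m + 1)
  tab <- table(factor(ia, levels = 0:(2 * n)),
               factor(ib, levels = 0:(2 * m)))
  counts[] <- as.numeric(tab)
  new_afs_grid(counts, n, m, pools = c(pool_a, pool_b),
               n_snps = sum(ok))
}

#' Mask the low-frequency corner of an AFS grid
#'
#' Cells whose allele frequency is at or below `cutoff` on *both* axes
#' (allele counts up to `floor(cutoff * 2N)`) are masked out of display
#' and model scoring; a cell rare on one axis only is kept.  With pools
#' of 20 and the default 5% cutoff this removes the 3 x 3 lower-left
#' corner.
#'
#' @param g An `afs_grid`.
#' @param cutoff Frequency cutoff in `[0, 0.5)`.
#' @return The grid with an updated mask.
#' @export
mask_low_freq <- function(g, cutoff = 0.05) {
  if (cutoff < 0 || cutoff >= 0.5) abort("`cutoff` must lie in [0, 0.5)")
  ka <- floor(cutoff * 2 * g$n)
  kb <- floor(cutoff * 2 * g$m)
  mask <- matrix(FALSE, nrow(g$counts), ncol(g$counts))
  mask[seq_len(ka + 1), seq_len(kb + 1)] <- TRUE
  g$mask <- mask
  g
}

#' Expected AFS grid under a divergence model
#'
#' Simulates loci under a [divergence_model_spec()], samples each deme's
#' final frequency down to `2N` / `2M` allele draws (binomial sampling,
#' as finite pools would), accumulates the joint spectrum, averages over
#' replicates and normalizes to sum 1 over unmasked cells.
#'
#' @param spec A [divergence_model_spec()].
#' @param n,m Diploid pool sizes.
#' @param n_reps Number of simulation replicates.
#' @param mask_cutoff Low-frequency mask applied before normalization
#'   (`NULL` for none).
#' @param sampling `"binomial"` draws `2N` / `2M` allele copies per deme
#'   (finite-pool noise); `"round"` grids the deme frequencies directly
#'   (sampling-free expectation).
#' @param seed Optional seed overriding the spec's (varied per
#'   replicate).
#' @return A normalized `afs_grid`.
#' @export
expected_afs <- function(spec, n = 20, m = 20, n_reps = 5,
                         mask_cutoff = 0.05,
                         sampling = c("binomial", "round"), seed = NULL) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(spec, "divergence_model_spec"))
  base_seed <- seed %||% spec$seed
  acc <- matrix(0, 2 * n + 1, 2 * m + 1)
  for (r in seq_len(n_reps)) {
    spec_r <- spec
    spec_r$seed <- (base_seed + 7919L * (r - 1L)) %% .Machine$integer.max
    sim <- simulate_divergence_afs(spec_r)
    draws <- if (sampling == "binomial") {
      with_seed(spec_r$seed + 1L, {
        list(a = rbinom(nrow(sim), 2 * n, sim$p1),
             b = rbinom(nrow(sim), 2 * m, sim$p2))
      })
    } else {
      list(a = round_half_up(sim$p1 * 2 * n),
           b = round_half_up(sim$p2 * 2 * m))
    }
    tab <- table(factor(draws$a, levels = 0:(2 * n)),
                 factor(draws$b, levels = 0:(2 * m)))
    acc <- acc + as.numeric(tab)
  }
  g <- new_afs_grid(acc / n_reps, n, m,
                    pools = c("deme1", "deme2"),
                    n_snps = spec$n_loci)
  if (!is.null(mask_cutoff)) g <- mask_low_freq(g, mask_cutoff)
  g$counts[!g$mask] <- g$counts[!g$mask] / sum(g$counts[!g$mask])
  g$normalized <- TRUE
  g
}

# Jensen-Shannon divergence between two non-negative weight vectors
js_divergence <- function(p, q) {
  p <- p / sum(p); q <- q / sum(q)
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log(a[i] / b[i]))
  }
  (kl(p, m) + kl(q, m)) / 2
}

#' Score an observed AFS grid against candidate divergence models
#'
#' Compares the observed joint spectrum with simulation-based expected
#' spectra for each candidate model using the Jensen-Shannon divergence
#' over unmasked cells (both grids normalized there).  The best model
#' attains the minimum score; candidates whose scores fall within
#' `tie_tol` (relative) of the minimum are reported as ties rather than
#' silently broken — isolation-with-migration, isolation-after-migration
#' and secondary-contact spectra are genuinely hard to tell apart.
#'
#' @param observed An `afs_grid` (masked as desired).
#' @param candidates Named list of [divergence_model_spec()]s, or of
#'   precomputed expected `afs_grid`s.
#' @param n_reps Simulation replicates per candidate spec.
#' @param seed Seed for candidate simulations.
#' @param tie_tol Relative score difference under which two candidates
#'   tie.
#' @return An object of class `model_score`: `scores` tibble (`model`,
#'   `score`), `best`, `ties`, `n_reps`, `seed`.
#' @export
classify_divergence_model <- function(observed, candidates, n_reps = 5,
                                      seed = 1L, tie_tol = 0.05) {
  if (length(candidates) < 2) abort("need at least two candidate models")
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("model", seq_along(candidates))
  }
  keep <- !observed$mask
  if (!any(keep)) abort("observed grid fully masked")
  obs <- observed$counts[keep]
  if (sum(obs) == 0) abort("observed grid empty after masking")
  scores <- vapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    if (inherits(cand, "divergence_model_spec")) {
      cand$seed <- (seed + 104729L * i) %% .Machine$integer.max
      cand <- expected_afs(cand, n = observed$n, m = observed$m,
                           n_reps = n_reps, mask_cutoff = NULL)
    }
    stopifnot(inherits(cand, "afs_grid"))
    js_divergence(obs, cand$counts[keep])
  }, numeric(1))
  ord <- order(scores)
  best <- names(candidates)[ord[1]]
  ties <- names(candidates)[scores <= scores[ord[1]] * (1 + tie_tol) &
                              names(candidates) != best]
  structure(list(scores = tibble::tibble(model = names(candidates),
                                         score = scores),
                 best = best, ties = ties,
                 n_reps = n_reps, seed = seed),
            class = "model_score")
}

#' @export
print.model_score <- function(x, ...) {
  print(x$scores)
  cat("best:", x$best,
      if (length(x$ties)) paste0("(tied with ",
                                 paste(x$ties, collapse = ", "), ")"),
      "\n")
  invisible(x)
}

#' @export
print.afs_grid <- function(x, ...) {
  cat(sprintf(
    "AFS grid %d x %d (%s vs %s), %s SNPs, %d masked cells\n",
    nrow(x$counts), ncol(x$counts), x$pools[1], x$pools[2],
    format(x$n_snps), sum(x$mask)))
  invisible(x)
}
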