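#' Read an admixture Q-matrix
#'
#' Parses per-individual ancestry proportions from either a plain TSV
#' (`id` column followed by K numeric cluster columns) or the Structure
#' output dialect in which each row carries leading index, label,
#' missing-percentage and population columns separated from the Q-values
#' by a colon.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"structure"`.
#' @param tol Maximum tolerated deviation of a row sum from 1.
#' @return A tibble of class `q_matrix`: `id` plus one column per
#'   cluster, each row summing to 1 within `tol`.
#' @export
read_q_matrix <- function(path, dialect = c("tsv", "structure"),
                          tol = 1e-3) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") {
    q <- readr::read_tsv(path, show_col_types = FALSE,
                         progress = FALSE)
    if (!"id" %in% names(q)) names(q)[1] <- "id"
    qm <- as.matrix(q[, -1, drop = FALSE])
    ids <- as.character(q$id)
  } else {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, ":", fixed = TRUE)
    if (any(lengths(parts) != 2)) {
      abort("structure dialect rows must contain a single ':' separator")
    }
    left <- vapply(parts, function(x) trimws(x[1]), character(1))
    right <- vapply(parts, function(x) trimws(x[2]), character(1))
    ids <- vapply(strsplit(left, "\\s+"), function(x) x[2], character(1))
    qs <- strsplit(right, "\\s+")
    k <- unique(lengths(qs))
    if (length(k) != 1) abort("ragged cluster count across rows")
    qm <- matrix(as.numeric(unlist(qs)), ncol = k, byrow = TRUE)
  }
  if (length(unique(ncol(qm))) != 1 || any(is.na(qm))) {
    abort("could not parse a rectangular numeric Q-matrix")
  }
  bad <- which(abs(rowSums(qm) - 1) > tol)
  if (length(bad) > 0) {
    abort(sprintf("Q-matrix row %d sums to %.4f, not 1", bad[1],
                  rowSums(qm)[bad[1]]))
  }
  qm <- qm / rowSums(qm)
  colnames(qm) <- colnames(qm) %||% sprintf("cluster%d", seq_len(ncol(qm)))
  out <- dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(qm))
  structure(out, class = c("q_matrix", class(tibble::tibble())))
}

q_values <- function(q) {
  qm <- as.matrix(as.data.frame(q)[, setdiff(names(q), "id"), drop = FALSE])
  rownames(qm) <- q$id
  qm
}

#' Classify individuals into pure and admixed lineage classes
#'
#' Applies the survey's Q-value thresholds: an individual is *pure* for
#' its maximum-Q cluster at threshold `t` iff that Q strictly exceeds
#' `t`, otherwise *admixed* at that threshold.  The default thresholds
#' 0.667 (cluster membership) and 0.9 (strict purity) nest: every
#' pure\@0.9 individual is pure\@0.667.  Ties in the maximum are broken
#' toward the lowest cluster index.
#'
#' @param q A Q-matrix tibble (`id` + cluster columns), e.g. from
#'   [read_q_matrix()] or `simulate_lineages()$q`.
#' @param thresholds Numeric thresholds, each in `(1/K, 1]`.
#' @return A tibble of class `lineage_classes`: `id`, `assigned`
#'   (max-Q cluster), `max_q`, and one logical `pure@<t>` column per
#'   threshold.
#' @export
classify_individuals <- function(q, thresholds = c(0.667, 0.9)) {
  qm <- q_values(q)
  k <- ncol(qm)
  if (any(thresholds <= 1 / k) || any(thresholds > 1)) {
    abort("thresholds must lie in (1/K, 1]")
  }
  best <- apply(qm, 1, which.max)  # which.max breaks ties low
  maxq <- qm[cbind(seq_len(nrow(qm)), best)]
  out <- tibble::tibble(id = q$id,
                        assigned = colnames(qm)[best],
                        max_q = maxq)
  for (t in thresholds) {
    out[[sprintf("pure@%s", format(t))]] <- maxq > t
  }
  structure(out, thresholds = thresholds,
            clusters = colnames(qm),
            class = c("lineage_classes", class(tibble::tibble())))
}

#' Supervised admixture estimation by EM
#'
#' Convenience estimator of per-individual ancestry proportions given
#' known reference allele frequencies per lineage: each of an
#' individual's two gene copies at a locus derives from lineage `k` with
#' probability `q_k` and is then the alternate allele with probability
#' `p_k`.  The EM algorithm maximizes the resulting binomial mixture
#' likelihood per individual; the log-likelihood is non-decreasing at
#' every iteration.
#'
#' @param g A [genotype_table()].
#' @param ref_freq Loci x lineages matrix (or data frame with a `locus`
#'   column) of reference alternate-allele frequencies; clamped to
#'   `[1e-4, 1 - 1e-4]`.
#' @param tol Convergence tolerance on the per-individual log-likelihood
#'   change.
#' @param max_iter Iteration cap; individuals still moving at the cap
#'   are flagged `converged = FALSE`.
#' @return A list: `q` (Q-matrix tibble), `log_lik`, `converged`,
#'   `n_iter` per individual.
#' @export
estimate_admixture_em <- function(g, ref_freq, tol = 1e-6,
                                  max_iter = 500, trace = FALSE) {
  m <- geno_matrix(g)
  if (is.data.frame(ref_freq)) {
    loc <- ref_freq$locus
    ref_freq <- as.matrix(ref_freq[, setdiff(names(ref_freq), "locus"),
                                   drop = FALSE])
    rownames(ref_freq) <- loc
  }
  if (!is.null(rownames(ref_freq))) {
    common <- intersect(colnames(m), rownames(ref_freq))
    if (length(common) == 0) abort("no loci shared with `ref_freq`")
    m <- m[, common, drop = FALSE]
    ref_freq <- ref_freq[common, , drop = FALSE]
  }
  if (nrow(ref_freq) != ncol(m)) {
    abort("`ref_freq` must have one row per locus")
  }
  p <- pmin(pmax(ref_freq, 1e-4), 1 - 1e-4)
  K <- ncol(p)
  if (max(apply(p, 1, function(x) diff(range(x)))) < 1e-12) {
    warn("reference frequencies identical across lineages; Q is not identifiable")
    qm <- matrix(1 / K, nrow(m), K,
                 dimnames = list(NULL, colnames(p)))
    return(list(q = dplyr::bind_cols(tibble::tibble(id = g$id),
                                     tibble::as_tibble(qm)),
                log_lik = rep(NA_real_, nrow(m)),
                converged = rep(TRUE, nrow(m)),
                n_iter = rep(0L, nrow(m))))
  }
  n_ind <- nrow(m)
  qm <- matrix(1 / K, n_ind, K)
  colnames(qm) <- colnames(p) %||% sprintf("cluster%d", seq_len(K))
  ll <- rep(NA_real_, n_ind)
  converged <- rep(FALSE, n_ind)
  n_iter <- rep(0L, n_ind)
  traces <- if (trace) vector("list", n_ind)
  for (i in seq_len(n_ind)) {
    gi <- m[i, ]
    ok <- !is.na(gi)
    gi <- gi[ok]
    pl <- p[ok, , drop = FALSE]
    qi <- rep(1 / K, K)
    ll_prev <- -Inf
    for (it in seq_len(max_iter)) {
      pi_mix <- pmin(pmax(drop(pl %*% qi), 1e-12), 1 - 1e-12)
      ll_new <- sum(dbinom(gi, 2, pi_mix, log = TRUE))
      # E-step: expected number of gene copies drawn from each lineage
      walt <- sweep(sweep(pl, 2, qi, "*"), 1, pi_mix, "/")
      wref <- sweep(sweep(1 - pl, 2, qi, "*"), 1, 1 - pi_mix, "/")
      qi <- colSums(gi * walt + (2 - gi) * wref) / (2 * length(gi))
      ll[i] <- ll_new
      n_iter[i] <- it
      if (trace) traces[[i]] <- c(traces[[i]], ll_new)
      if (is.finite(ll_prev) && abs(ll_new - ll_prev) < tol) {
        converged[i] <- TRUE
        break
      }
      ll_prev <- ll_new
    }
    qm[i, ] <- qi
  }
  if (!all(converged)) {
    warn(sprintf("%d individual(s) hit max_iter before converging",
                 sum(!converged)))
  }
  list(q = structure(
         dplyr::bind_cols(tibble::tibble(id = g$id),
                          tibble::as_tibble(qm)),
         class = c("q_matrix", class(tibble::tibble()))),
       log_lik = ll, converged = converged, n_iter = n_iter,
       ll_trace = if (trace) traces)
}
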