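#' Tidy per-locus diversity indices
#' @param x A `div_stats` object.
#' @param ... Unused.
#' @return Per-locus tibble (`locus`, `Ho`, `Hs`, `Ht`, `Gst`, `theta`).
#' @export
tidy.div_stats <- function(x, ...) x$per_locus

#' One-row diversity summary
#' @param x A `div_stats` object.
#' @param ... Unused.
#' @return One-row tibble of multilocus indices.
#' @export
glance.div_stats <- function(x, ...) x$summary

#' Tidy AMOVA variance components
#' @param x An `amova_fit`.
#' @param ... Unused.
#' @return Tibble `level`, `sigma2`, `pct`.
#' @export
tidy.amova_fit <- function(x, ...) x$components

#' One-row AMOVA summary
#' @param x An `amova_fit`.
#' @param ... Unused.
#' @return One-row tibble of F-statistics and permutation p-values.
#' @export
glance.amova_fit <- function(x, ...) {
  tibble::tibble(Fct = x$Fct, Fsc = x$Fsc, Fst = x$Fst,
                 p_Fct = x$p_Fct, p_Fsc = x$p_Fsc,
                 n_perm = x$n_perm, n_groups = x$n_groups,
                 n_pops = x$n_pops)
}

#' Tidy divergence-model scores
#' @param x A `model_score`.
#' @param ... Unused.
#' @return Tibble `model`, `score`, `best`, `tied`.
#' @export
tidy.model_score <- function(x, ...) {
  dplyr::mutate(x$scores,
                best = .data$model == x$best,
                tied = .data$model %in% x$ties)
}

#' One-row model-choice summary
#' @param x A `model_score`.
#' @param ... Unused.
#' @return One-row tibble (`best`, `n_ties`, `min_score`, `n_reps`).
#' @export
glance.model_score <- function(x, ...) {
  tibble::tibble(best = x$best, n_ties = length(x$ties),
                 min_score = min(x$scores$score), n_reps = x$n_reps)
}

#' Tidy a capture report
#' @param x A `capture_report`.
#' @param ... Unused.
#' @return The ordered-pair count tibble.
#' @export
tidy.capture_report <- function(x, ...) x$pairs

#' One-row capture summary
#' @param x A `capture_report`.
#' @param ... Unused.
#' @return One-row tibble of totals and the asymmetry ratio.
#' @export
glance.capture_report <- function(x, ...) {
  tibble::tibble(n_discordant = x$n_discordant,
                 n_concordant = x$n_concordant,
                 n_excluded = x$n_excluded,
                 asymmetry = x$asymmetry)
}
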